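# Automated evaluation of motor function: zero-phase low-pass filtering of
# the raw capture streams, then three descriptors per limb and session —
# work area of the wipe, maximal finger flexion and minimal finger
# extension of the squeeze.

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a second-order (by default) Butterworth low-pass at a 6 Hz
#' cut-off, forward and backward so the output is phase-free. Edge
#' transients are controlled by odd-reflection padding of the series before
#' filtering, which makes the DC gain exactly 1 in practice (a constant
#' series is returned unchanged to numerical precision). Because the filter
#' runs twice, the effective amplitude response is the squared single-pass
#' Butterworth magnitude.
#'
#' @param x A numeric vector, matrix or data frame of numeric channels
#'   (filtered column-wise).
#' @param rate_hz Sampling rate in Hz; must exceed `2 * cutoff_hz`.
#' @param cutoff_hz Cut-off frequency in Hz (default 6).
#' @param order Filter order (default 2).
#' @return Filtered series with the same shape and length as the input.
#' @examples
#' lowpass_filter(sin(2 * pi * 12 * (0:299) / 30), rate_hz = 30)[1:5]
#' @export
lowpass_filter <- function(x, rate_hz, cutoff_hz = 6, order = 2) {
  if (rate_hz <= 2 * cutoff_hz) {
    abort("`cutoff_hz` must be below the Nyquist frequency `rate_hz / 2`.")
  }
  filt <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  one <- function(v) {
    n <- length(v)
    if (n < 3 * order) {
      abort(sprintf("series too short to filter: %d samples, need >= %d.",
                    n, 3 * order))
    }
    pad <- min(n - 1L, max(12L, ceiling(10 * rate_hz / cutoff_hz)))
    vp <- c(2 * v[1] - rev(v[2:(pad + 1)]), v,
            2 * v[n] - rev(v[(n - pad):(n - 1)]))
    y <- as.numeric(signal::filter(filt, vp))
    y <- rev(as.numeric(signal::filter(filt, rev(y))))
    y[(pad + 1):(pad + n)]
  }
  if (is.data.frame(x)) {
    x[] <- lapply(x, one)
    x
  } else if (is.matrix(x)) {
    apply(x, 2, one)
  } else {
    one(x)
  }
}

#' Work area of a planar hand trajectory
#'
#' The dorsal work surface covered by the hand, operationalized as
#' occupancy-grid coverage of the horizontal plane: the number of distinct
#' grid cells visited by the trajectory samples times the cell area. The
#' grid is anchored at the trajectory's minimum corner by default, which
#' makes the estimate invariant to rigid translation; pass a fixed
#' `origin` to compare trajectories on a common grid.
#'
#' @param positions A data frame with `x_m` and `y_m` columns (metres), or
#'   a two-column numeric matrix.
#' @param cell_m Grid cell size in metres (default 0.02).
#' @param origin Optional numeric `c(x, y)` grid origin; default the
#'   trajectory's minimum corner.
#' @return The covered area in m^2. If all samples fall in a single cell
#'   the result carries attribute `degenerate = TRUE`.
#' @examples
#' sq <- expand.grid(x_m = seq(0, 0.3, 0.01), y_m = seq(0, 0.3, 0.01))
#' work_area(sq)
#' @export
work_area <- function(positions, cell_m = 0.02, origin = NULL) {
  if (is.matrix(positions)) {
    positions <- tibble(x_m = positions[, 1], y_m = positions[, 2])
  }
  if (!all(c("x_m", "y_m") %in% names(positions))) {
    abort("`positions` must have columns `x_m` and `y_m`.")
  }
  if (nrow(positions) < 2) abort("need at least 2 position samples.")
  if (cell_m <= 0) abort("`cell_m` must be positive.")
  if (is.null(origin)) origin <- c(min(positions$x_m), min(positions$y_m))
  ix <- floor((positions$x_m - origin[1]) / cell_m)
  iy <- floor((positions$y_m - origin[2]) / cell_m)
  n_cells <- nrow(unique(cbind(ix, iy)))
  area <- n_cells * cell_m^2
  if (n_cells == 1L) attr(area, "degenerate") <- TRUE
  area
}

#' Finger flexion and extension descriptors
#'
#' Per finger, the maximum and minimum flexion over time; the descriptors
#' are the two values averaged across the five fingers: maximal finger
#' flexion and minimal finger extension (glove units, 1 = full flexion).
#'
#' @param flexion A data frame or matrix with five numeric columns, values
#'   in \[0, 1\].
#' @return A one-row tibble with `max_flexion` and `min_extension`.
#' @examples
#' finger_descriptors(matrix(runif(50), ncol = 5))
#' @export
finger_descriptors <- function(flexion) {
  flexion <- as.matrix(flexion)
  if (ncol(flexion) != 5L) abort("`flexion` must have exactly 5 channels.")
  if (nrow(flexion) < 1L) abort("`flexion` must have at least 1 sample.")
  bad <- which(flexion < 0 | flexion > 1 | is.na(flexion), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("flexion value out of [0, 1] in channel %d at sample %d.",
                  bad[1, 2], bad[1, 1]))
  }
  tibble(max_flexion = mean(apply(flexion, 2, max)),
         min_extension = mean(apply(flexion, 2, min)))
}

#' Evaluate one kinematic session into motor-function descriptors
#'
#' Runs the full evaluation pipeline on one captured stream: zero-phase
#' low-pass filtering of every channel, then the task's descriptor — work
#' area for the wipe task, flexion/extension for the squeeze task.
#' Filtered glove channels are clipped back to \[0, 1\] before the
#' descriptor is computed (filter ringing can overshoot the physical range
#' by a fraction of the noise amplitude).
#'
#' @param session A stream tibble as produced by
#'   [generate_kinematic_session()]: metadata columns `subject`, `limb`,
#'   `task`, `session` plus `time_s`, `x_m`, `y_m`, `z_m`,
#'   `flex_f1`..`flex_f5`.
#' @param cutoff_hz,order Filter parameters, see [lowpass_filter()].
#' @param cell_m Occupancy-grid cell size for the work area.
#' @return A one-row tibble: `subject`, `limb`, `task`, `session`,
#'   `work_area_m2`, `max_flexion`, `min_extension`, `degenerate`. The
#'   descriptor not measured by the session's task is `NA`.
#' @export
evaluate_session <- function(session, cutoff_hz = 6, order = 2,
                             cell_m = 0.02) {
  need <- c("subject", "limb", "task", "session", "time_s", "x_m", "y_m",
            paste0("flex_f", 1:5))
  miss <- setdiff(need, names(session))
  if (length(miss) > 0) {
    abort(sprintf("session is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  task <- session$task[1]
  if (!task %in% c("wipe", "squeeze")) {
    abort(sprintf("unknown task '%s'; expected 'wipe' or 'squeeze'.", task))
  }
  rate <- 1 / median(diff(session$time_s))
  out <- tibble(subject = session$subject[1], limb = session$limb[1],
                task = task, session = session$session[1],
                work_area_m2 = NA_real_, max_flexion = NA_real_,
                min_extension = NA_real_, degenerate = FALSE)
  if (task == "wipe") {
    xy <- lowpass_filter(session[, c("x_m", "y_m")], rate, cutoff_hz, order)
    area <- work_area(xy, cell_m = cell_m)
    out$work_area_m2 <- as.numeric(area)
    out$degenerate <- isTRUE(attr(area, "degenerate"))
  } else {
    flex <- lowpass_filter(session[, paste0("flex_f", 1:5)], rate,
                           cutoff_hz, order)
    flex[] <- lapply(flex, function(v) pmin(pmax(v, 0), 1))
    out[, c("max_flexion", "min_extension")] <- finger_descriptors(flex)
  }
  out
}

#' Evaluate many kinematic sessions
#'
#' @param streams A tibble of concatenated streams (several
#'   subject/limb/task/session combinations) or a list of stream tibbles.
#' @inheritParams evaluate_session
#' @return A tibble with one descriptor row per stream.
#' @export
evaluate_sessions <- function(streams, cutoff_hz = 6, order = 2,
                              cell_m = 0.02) {
  if (is.data.frame(streams)) {
    streams <- streams |>
      dplyr::group_split(.data$subject, .data$limb, .data$task, .data$session)
  }
  purrr::map_dfr(streams, evaluate_session, cutoff_hz = cutoff_hz,
                 order = order, cell_m = cell_m)
}

#' Regression of clinical scores on kinematic descriptors
#'
#' Ordinary least-squares fit of a clinical scale (for instance an
#' arm-and-hand activity score) on a kinematic descriptor (for instance
#' the per-subject sum of maximal flexion and minimal extension), the
#' validation step that ties unsupervised kinematic measurements to
#' supervised clinical assessment.
#'
#' @param data A data frame.
#' @param descriptor,score Column names (tidy-eval) of predictor and
#'   response.
#' @return An object of class `aemf_fit` with [tidy()] and [glance()]
#'   methods; also contains `slope`, `intercept` and `r_squared`.
#' @examples
#' d <- tibble::tibble(k = 1:10, cahai = 3 * (1:10) + rnorm(10))
#' glance(descriptor_score_regression(d, k, cahai))
#' @export
descriptor_score_regression <- function(data, descriptor, score) {
  descriptor <- rlang::enquo(descriptor)
  score <- rlang::enquo(score)
  x <- rlang::eval_tidy(descriptor, data)
  y <- rlang::eval_tidy(score, data)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 paired observations.")
  if (sd(x) == 0) abort("descriptor is constant; R-squared is undefined.")
  fit <- lm(y ~ x)
  s <- summary(fit)
  structure(
    list(fit = fit,
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = s$r.squared,
         p_value = unname(s$coefficients[2, 4]),
         n = length(x)),
    class = "aemf_fit"
  )
}

#' @export
print.aemf_fit <- function(x, ...) {
  cat("<aemf_fit> score ~ descriptor (OLS)\n")
  cat(sprintf("  slope %.4g, intercept %.4g, R^2 %.3f, p %.3g, n %d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @rdname descriptor_score_regression
#' @param x An `aemf_fit` object.
#' @param ... Unused.
#' @export
tidy.aemf_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = c("(Intercept)", "descriptor"),
         estimate = unname(cf[, 1]), std.error = unname(cf[, 2]),
         statistic = unname(cf[, 3]), p.value = unname(cf[, 4]))
}

#' @rdname descriptor_score_regression
#' @export
glance.aemf_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$p_value, nobs = x$n)
}

#' @rdname descriptor_score_regression
#' @param object An `aemf_fit` object.
#' @export
autoplot.aemf_fit <- function(object, ...) {
  d <- tibble(x = object$fit$model$x, y = object$fit$model$y)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(x = "kinematic descriptor", y = "clinical score",
                  subtitle = sprintf("R² = %.3f", object$r_squared)) +
    ggplot2::theme_minimal()
}
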