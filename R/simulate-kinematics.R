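#' Generate a synthetic kinematic evaluation stream
#'
#' Emulates the 30 Hz capture of one unsupervised evaluation task for one
#' limb: a planar "wipe" task (serpentine hand sweep over a square work
#' surface whose side scales with the limb's reach factor) or a "squeeze"
#' task (periodic flexion-extension of the five fingers, capped at the
#' limb's flexion ceiling). White sensor noise is added to every channel;
#' glove channels are clipped to \[0, 1\].
#'
#' The noiseless wipe design sweeps a square of side
#' `base_side_m * reach_factor` with rows spaced `row_spacing_m` apart and
#' centred inside the square, so an occupancy-grid area estimator with cell
#' size equal to the row spacing recovers the designed square area up to
#' grid discretization.
#'
#' @param model A [patient_ability_model()] supplying the limb's reach
#'   factor and flexion ceiling.
#' @param task `"wipe"` or `"squeeze"`.
#' @param limb `"paretic"` or `"nonparetic"`.
#' @param duration_s Stream duration in seconds (> 0); default 150 s, the
#'   length of one home evaluation block.
#' @param rate_hz Sampling rate in Hz (> 0); default 30 Hz.
#' @param noise_sd Standard deviation of additive white sensor noise, in
#'   metres for positions and glove units for flexion.
#' @param base_side_m Side (m) of the work square an unimpaired reach
#'   sweeps; default 0.30 m.
#' @param row_spacing_m Spacing (m) between serpentine rows of the wipe.
#' @param squeeze_freq_hz Flexion-extension frequency of the squeeze task.
#' @param flexion_floor Resting extension level of the glove channels.
#' @param session Session index stamped on the stream.
#' @return A tibble (`time_s`, `x_m`, `y_m`, `z_m`, `flex_f1`..`flex_f5`,
#'   plus `subject`, `limb`, `task`, `session` metadata columns) with
#'   strictly increasing timestamps at the requested rate.
#' @examples
#' m <- patient_ability_model()
#' s <- generate_kinematic_session(m, "wipe", duration_s = 10, noise_sd = 0)
#' @export
generate_kinematic_session <- function(model, task = c("wipe", "squeeze"),
                                       limb = "paretic", duration_s = 150,
                                       rate_hz = 30, noise_sd = 0.003,
                                       base_side_m = 0.30,
                                       row_spacing_m = 0.02,
                                       squeeze_freq_hz = 0.5,
                                       flexion_floor = 0.05,
                                       session = 1L) {
  stopifnot(inherits(model, "patient_ability_model"))
  task <- match.arg(task)
  limb <- match.arg(limb, limb_labels())
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  if (rate_hz <= 0) abort("`rate_hz` must be positive.")
  n <- max(2L, floor(duration_s * rate_hz) + 1L)
  time_s <- (seq_len(n) - 1L) / rate_hz

  if (task == "wipe") {
    side <- base_side_m * model$reach_factor[[limb]]
    if (side < row_spacing_m) {
      # degenerate or near-degenerate reach: hand stays at the start point
      x <- rep(0, n); y <- rep(0, n)
    } else {
      xs <- seq(row_spacing_m / 2, side - row_spacing_m / 2,
                by = row_spacing_m)
      # serpentine way-points: down each row, alternating sweep direction
      wx <- rep(xs, each = 2L)
      wy <- as.vector(rbind(rep(c(0, side), length.out = length(xs)),
                            rep(c(side, 0), length.out = length(xs))))
      seg <- sqrt(diff(wx)^2 + diff(wy)^2)
      arc <- c(0, cumsum(seg))
      s_at <- seq(0, arc[length(arc)], length.out = n)
      x <- approx(arc, wx, xout = s_at, ties = "ordered")$y
      y <- approx(arc, wy, xout = s_at, ties = "ordered")$y
    }
    z <- rep(0, n)
    flex <- matrix(flexion_floor, n, 5L)
  } else {
    x <- rep(0, n); y <- rep(0, n); z <- rep(0, n)
    ceiling_f <- model$flexion_ceiling[[limb]]
    trace <- flexion_floor + (ceiling_f - flexion_floor) *
      0.5 * (1 - cos(2 * pi * squeeze_freq_hz * time_s))
    flex <- matrix(rep(trace, 5L), n, 5L)
  }

  if (noise_sd > 0) {
    x <- x + rnorm(n, 0, noise_sd)
    y <- y + rnorm(n, 0, noise_sd)
    z <- z + rnorm(n, 0, noise_sd)
    flex <- flex + matrix(rnorm(5L * n, 0, noise_sd), n, 5L)
  }
  flex <- pmin(pmax(flex, 0), 1)
  colnames(flex) <- paste0("flex_f", 1:5)

  tibble(subject = model$id, limb = limb, task = task,
         session = as.integer(session), time_s = time_s,
         x_m = x, y_m = y, z_m = z) |>
    dplyr::bind_cols(as_tibble(flex))
}

#' Plot a kinematic evaluation stream
#'
#' @param session A tibble from [generate_kinematic_session()].
#' @param ... Unused.
#' @return A ggplot: the horizontal-plane hand path for wipe streams, or
#'   the five flexion traces for squeeze streams.
#' @export
plot_kinematic_session <- function(session, ...) {
  task <- session$task[1]
  if (identical(task, "wipe")) {
    ggplot2::ggplot(session, ggplot2::aes(.data$x_m, .data$y_m)) +
      ggplot2::geom_path(alpha = 0.7) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (m)", y = "y (m)") +
      ggplot2::theme_minimal()
  } else {
    session |>
      tidyr::pivot_longer(dplyr::starts_with("flex_f"),
                          names_to = "finger", values_to = "flexion") |>
      ggplot2::ggplot(ggplot2::aes(.data$time_s, .data$flexion,
                                   colour = .data$finger)) +
      ggplot2::geom_line(alpha = 0.8) +
      ggplot2::labs(x = "time (s)", y = "flexion (glove units)") +
      ggplot2::theme_minimal()
  }
}
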