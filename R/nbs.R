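# Navigated-brain-stimulation metrics: resting motor threshold,
# stimulation efficacy, amplitude-weighted map centroid, centroid
# displacement and convex-hull map area, plus pre/post map comparison
# tables.

#' Estimate the resting motor threshold
#'
#' The resting motor threshold (RMT) is the smallest tested stimulator
#' intensity at which more than half of the delivered pulses evoke a
#' response above the amplitude threshold (strictly more than 50 uV by
#' default).
#'
#' @param responses A data frame with columns `intensity_pct_mso` and
#'   `mep_uv` (one row per pulse), e.g. from
#'   [simulate_recruitment_series()].
#' @param threshold_uv Response amplitude threshold (uV), default 50.
#' @param response_fraction Fraction of pulses that must respond, default
#'   0.5; the qualifying fraction must strictly exceed this.
#' @return The RMT in % of maximum stimulator output, or `NA` when no
#'   tested intensity qualifies (an unmappable muscle).
#' @examples
#' r <- simulate_recruitment_series(true_rmt = 45)
#' estimate_rmt(r)
#' @export
estimate_rmt <- function(responses, threshold_uv = 50,
                         response_fraction = 0.5) {
  if (!all(c("intensity_pct_mso", "mep_uv") %in% names(responses))) {
    abort("`responses` needs columns `intensity_pct_mso` and `mep_uv`.")
  }
  if (nrow(responses) == 0) abort("`responses` is empty.")
  frac <- responses |>
    group_by(.data$intensity_pct_mso) |>
    summarise(frac = mean(.data$mep_uv > threshold_uv), .groups = "drop")
  qual <- frac$intensity_pct_mso[frac$frac > response_fraction]
  if (length(qual) == 0) NA_real_ else min(qual)
}

#' Stimulation efficacy of a motor map
#'
#' The 80th-percentile MEP amplitude of the map (linear-interpolation
#' percentile) divided by the maximum stimulation intensity delivered in
#' the map — an intensity-normalized index of corticospinal excitability
#' in uV per % of maximum stimulator output.
#'
#' @param map A stimulation-site tibble with columns `mep_uv` and
#'   `intensity_pct_mso`.
#' @param denominator `"map_max"` (default) divides by the maximum
#'   intensity actually delivered in this map, which accommodates
#'   escalated acquisitions; `"device_max"` divides by 100% MSO.
#' @return SE in uV/%MSO; 0 for an all-zero-amplitude map.
#' @examples
#' stimulation_efficacy(tibble::tibble(
#'   mep_uv = c(100, 200, 300, 400, 500), intensity_pct_mso = 50))
#' @export
stimulation_efficacy <- function(map, denominator = c("map_max", "device_max")) {
  denominator <- match.arg(denominator)
  if (!all(c("mep_uv", "intensity_pct_mso") %in% names(map))) {
    abort("`map` needs columns `mep_uv` and `intensity_pct_mso`.")
  }
  if (nrow(map) == 0) abort("`map` is empty.")
  p80 <- unname(quantile(map$mep_uv, 0.8, type = 7))
  denom <- if (denominator == "map_max") max(map$intensity_pct_mso) else 100
  p80 / denom
}

#' Amplitude-weighted centroid of a motor map
#'
#' The centre of the cortical motor output map: the mean of the responsive
#' site coordinates weighted by MEP amplitude. Only sites with amplitude
#' strictly above the response threshold contribute.
#'
#' @inheritParams stimulation_efficacy
#' @param threshold_uv Response threshold (uV); defaults to the map's
#'   `threshold_uv` attribute, else 50.
#' @param weighted If `FALSE`, the unweighted mean of responsive-site
#'   coordinates is returned (sensitivity analysis).
#' @return Named numeric `c(ml, ap)` in mm.
#' @export
map_centroid <- function(map, threshold_uv = NULL, weighted = TRUE) {
  threshold_uv <- threshold_uv %||% attr(map, "threshold_uv") %||% 50
  need <- c("ml_mm", "ap_mm", "mep_uv")
  if (!all(need %in% names(map))) {
    abort("`map` needs columns ml_mm, ap_mm and mep_uv.")
  }
  resp <- map[map$mep_uv > threshold_uv, ]
  if (nrow(resp) == 0) {
    abort("no responsive sites: centroid undefined (unmappable map).")
  }
  w <- if (weighted) resp$mep_uv else rep(1, nrow(resp))
  c(ml = sum(w * resp$ml_mm) / sum(w), ap = sum(w * resp$ap_mm) / sum(w))
}

#' Centroid displacement between two sessions of a map
#'
#' Signed per-axis differences (post minus pre) and the Euclidean norm of
#' the displacement of the map centroid, in mm.
#'
#' @param pre,post Either centroids (named numeric `c(ml, ap)`) or
#'   stimulation-site tibbles (centroids are computed via
#'   [map_centroid()]). When tibbles carry `muscle`/`hemisphere` columns
#'   they must match between sessions.
#' @param ... Passed to [map_centroid()].
#' @return A one-row tibble: `d_ml_mm`, `d_ap_mm`, `displacement_mm`.
#' @examples
#' centroid_displacement(c(ml = 0, ap = 0), c(ml = 3, ap = 4))
#' @export
centroid_displacement <- function(pre, post, ...) {
  as_centroid <- function(x) {
    if (is.data.frame(x)) map_centroid(x, ...) else x[c("ml", "ap")]
  }
  if (is.data.frame(pre) && is.data.frame(post)) {
    for (col in c("muscle", "hemisphere")) {
      if (col %in% names(pre) && col %in% names(post) &&
          !identical(unique(pre[[col]]), unique(post[[col]]))) {
        abort(sprintf("pre and post maps differ in `%s`.", col))
      }
    }
  }
  a <- as_centroid(pre)
  b <- as_centroid(post)
  d <- b - a
  tibble(d_ml_mm = unname(d["ml"]), d_ap_mm = unname(d["ap"]),
         displacement_mm = sqrt(sum(d^2)))
}

# Shoelace polygon area (vertices in order).
polygon_area <- function(x, y) {
  x <- unname(x); y <- unname(y)
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Area of a motor map
#'
#' The area (mm^2) of the convex hull of responsive sites; 0 when fewer
#' than three non-collinear responsive sites exist.
#'
#' @inheritParams map_centroid
#' @return Area in mm^2.
#' @export
map_area <- function(map, threshold_uv = NULL) {
  threshold_uv <- threshold_uv %||% attr(map, "threshold_uv") %||% 50
  resp <- map[map$mep_uv > threshold_uv, c("ml_mm", "ap_mm")]
  resp <- unique(resp)
  if (nrow(resp) < 3) return(0)
  h <- chull(resp$ml_mm, resp$ap_mm)
  if (length(h) < 3) return(0)
  polygon_area(resp$ml_mm[h], resp$ap_mm[h])
}

#' Summary metrics of one motor map
#'
#' @inheritParams map_centroid
#' @param se_denominator Passed to [stimulation_efficacy()].
#' @return A one-row tibble: `se`, `ml_mm`, `ap_mm`, `area_mm2`,
#'   `n_responsive`. Centroid columns are `NA` for unmappable maps.
#' @export
map_metrics <- function(map, threshold_uv = NULL,
                        se_denominator = c("map_max", "device_max")) {
  se_denominator <- match.arg(se_denominator)
  threshold_uv <- threshold_uv %||% attr(map, "threshold_uv") %||% 50
  n_resp <- sum(map$mep_uv > threshold_uv)
  cent <- if (n_resp > 0) {
    map_centroid(map, threshold_uv)
  } else {
    c(ml = NA_real_, ap = NA_real_)
  }
  tibble(se = stimulation_efficacy(map, se_denominator),
         ml_mm = unname(cent["ml"]), ap_mm = unname(cent["ap"]),
         area_mm2 = map_area(map, threshold_uv),
         n_responsive = n_resp)
}

#' Compare pre and post motor maps across a cohort
#'
#' Computes per-map metrics for every `(subject, muscle, hemisphere,
#' session)` group of a long stimulation-site table and pairs the pre and
#' post sessions into a within-subject change table (stimulation-efficacy
#' change, centroid displacement, area change) ready for the statistical
#' layer. Subjects with an unmatched or unmappable session are excluded
#' with a warning.
#'
#' @param sites A tibble of stimulation sites with columns `subject`,
#'   `muscle`, `hemisphere`, `session` (`"pre"`/`"post"`), `ml_mm`,
#'   `ap_mm`, `intensity_pct_mso`, `mep_uv`.
#' @param threshold_uv Response threshold (uV), default 50.
#' @return A tibble with one row per subject by muscle by hemisphere:
#'   `se_pre`, `se_post`, `se_change`, `d_ml_mm`, `d_ap_mm`,
#'   `displacement_mm`, `area_pre`, `area_post`, `area_change`.
#' @export
compare_maps <- function(sites, threshold_uv = 50) {
  need <- c("subject", "muscle", "hemisphere", "session", "ml_mm", "ap_mm",
            "intensity_pct_mso", "mep_uv")
  miss <- setdiff(need, names(sites))
  if (length(miss) > 0) {
    abort(sprintf("`sites` is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  metrics <- sites |>
    group_by(.data$subject, .data$muscle, .data$hemisphere, .data$session) |>
    dplyr::group_modify(~ map_metrics(.x, threshold_uv)) |>
    ungroup()
  wide <- metrics |>
    tidyr::pivot_wider(id_cols = c("subject", "muscle", "hemisphere"),
                       names_from = "session",
                       values_from = c("se", "ml_mm", "ap_mm", "area_mm2"))
  complete <- !is.na(wide$se_pre) & !is.na(wide$se_post) &
    !is.na(wide$ml_mm_pre) & !is.na(wide$ml_mm_post)
  if (!"se_post" %in% names(wide) || any(!complete)) {
    dropped <- wide$subject[!complete]
    warn(sprintf("excluding %d unmatched/unmappable map pair(s): %s",
                 sum(!complete), paste(unique(dropped), collapse = ", ")))
    wide <- wide[complete, ]
  }
  wide |>
    mutate(se_change = .data$se_post - .data$se_pre,
           d_ml_mm = .data$ml_mm_post - .data$ml_mm_pre,
           d_ap_mm = .data$ap_mm_post - .data$ap_mm_pre,
           displacement_mm = sqrt(.data$d_ml_mm^2 + .data$d_ap_mm^2),
           area_change = .data$area_mm2_post - .data$area_mm2_pre) |>
    select("subject", "muscle", "hemisphere",
           se_pre = "se_pre", se_post = "se_post", "se_change",
           "d_ml_mm", "d_ap_mm", "displacement_mm",
           area_pre = "area_mm2_pre", area_post = "area_mm2_post",
           "area_change")
}

#' Plot a motor map
#'
#' @param object A stimulation-site tibble for one map.
#' @param threshold_uv Response threshold (uV).
#' @param ... Unused.
#' @return A ggplot of sites coloured by amplitude, the responsive convex
#'   hull, and the amplitude-weighted centroid.
#' @export
plot_motor_map <- function(object, threshold_uv = NULL, ...) {
  threshold_uv <- threshold_uv %||% attr(object, "threshold_uv") %||% 50
  resp <- object[object$mep_uv > threshold_uv, ]
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$ml_mm, .data$ap_mm,
                                    colour = .data$mep_uv)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_viridis_c(name = "MEP (uV)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mediolateral (mm)", y = "anteroposterior (mm)") +
    ggplot2::theme_minimal()
  if (nrow(resp) >= 3) {
    h <- chull(resp$ml_mm, resp$ap_mm)
    p <- p + ggplot2::geom_polygon(data = resp[h, ], fill = NA,
                                   colour = "grey40", linetype = "dashed")
  }
  if (nrow(resp) >= 1) {
    cent <- map_centroid(object, threshold_uv)
    p <- p + ggplot2::annotate("point", x = cent["ml"], y = cent["ap"],
                               shape = 4, size = 4, colour = "red")
  }
  p
}
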