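# Simulated navigated-brain-stimulation acquisition: a square lattice is
# grown outward from the start site (the hotspot found during threshold
# hunting) along primitive lattice rays; each ray stops after two
# consecutive no-response sites, mirroring the boundary-search rule used
# at acquisition time.

#' Acquisition protocol for simulated motor maps
#'
#' @param threshold_uv MEP response threshold (uV), default 50.
#' @param ladder Stimulation-intensity escalation ladder as multiples of
#'   the resting motor threshold; default `c(1.1, 1.2, 1.4)` — mapping
#'   starts at 110% RMT and escalates stepwise when the start site is
#'   silent.
#' @param mso_ceiling Maximum stimulator output (%), intensities are capped
#'   here.
#' @param max_radius_mm Largest distance from the start site that is
#'   stimulated.
#' @param stop_after Consecutive no-response sites that terminate a search
#'   direction (default 2).
#' @return A list of class `map_protocol`.
#' @export
map_protocol <- function(threshold_uv = 50, ladder = c(1.1, 1.2, 1.4),
                         mso_ceiling = 100, max_radius_mm = 25,
                         stop_after = 2L) {
  if (threshold_uv <= 0) abort("`threshold_uv` must be positive.")
  if (any(diff(ladder) <= 0) || any(ladder <= 0)) {
    abort("`ladder` must be increasing and positive.")
  }
  structure(list(threshold_uv = threshold_uv, ladder = ladder,
                 mso_ceiling = mso_ceiling,
                 max_radius_mm = max_radius_mm,
                 stop_after = as.integer(stop_after)),
            class = "map_protocol")
}

# Expected MEP amplitude at a site: Gaussian spatial profile around the
# true centroid, scaled linearly with intensity relative to 110% RMT and by
# the session's excitability multiplier.
expected_mep <- function(truth, ml, ap, intensity, session = "pre") {
  centre <- truth$centroid
  excit <- 1
  if (identical(session, "post")) {
    centre <- centre + truth$shift
    excit <- truth$excitability
  }
  r2 <- (ml - centre[["ml"]])^2 + (ap - centre[["ap"]])^2
  truth$peak * excit * exp(-r2 / (2 * truth$extent^2)) *
    (intensity / (1.1 * truth$rmt))
}

# Primitive lattice directions (coprime integer steps) reaching within the
# search radius.
primitive_directions <- function(max_steps) {
  dirs <- expand.grid(i = -max_steps:max_steps, j = -max_steps:max_steps)
  dirs <- dirs[!(dirs$i == 0 & dirs$j == 0), ]
  g <- mapply(function(a, b) {
    a <- abs(a); b <- abs(b)
    while (b > 0) { t <- a %% b; a <- b; b <- t }
    a
  }, dirs$i, dirs$j)
  dirs[g == 1L, ]
}

#' Simulate the acquisition of one cortical motor map
#'
#' Stimulates a square lattice grown outward from the start site at 110%
#' of the true resting motor threshold. Expected amplitudes fall off as a
#' Gaussian of distance from the true centroid and are corrupted by
#' multiplicative log-normal noise (mean-one, so amplitudes stay positive
#' and unbiased). If the start site is silent, the intensity is escalated
#' along the protocol ladder (capped at the stimulator ceiling); if it
#' stays silent at the last rung the map is returned empty-handed and
#' flagged unmappable. Each search direction (primitive lattice ray) stops
#' after two consecutive no-response sites; all stimulated sites,
#' including sub-threshold ones, are returned as measured.
#'
#' @param truth A [map_truth()].
#' @param grid_spacing_mm Lattice spacing in mm (default 5).
#' @param protocol A [map_protocol()].
#' @param session `"pre"` or `"post"`; the post session applies the
#'   truth's centroid shift and excitability multiplier.
#' @param muscle,hemisphere,subject Labels stamped on the sites.
#' @param start Optional `c(ml, ap)` start site; defaults to the truth
#'   centroid rounded to the lattice (the hotspot found while hunting the
#'   threshold).
#' @return A tibble of stimulation sites (`subject`, `muscle`,
#'   `hemisphere`, `session`, `ml_mm`, `ap_mm`, `intensity_pct_mso`,
#'   `mep_uv`) with attributes `rmt` (the operating RMT, % MSO),
#'   `threshold_uv` and `unmappable`.
#' @examples
#' map <- acquire_motor_map(map_truth())
#' map_centroid(map)
#' @export
acquire_motor_map <- function(truth, grid_spacing_mm = 5,
                              protocol = map_protocol(),
                              session = c("pre", "post"),
                              muscle = "APB", hemisphere = "pathological",
                              subject = "p01", start = NULL) {
  stopifnot(inherits(truth, "map_truth"))
  session <- match.arg(session)
  if (grid_spacing_mm <= 0) abort("`grid_spacing_mm` must be positive.")
  sdlog <- sqrt(log(1 + truth$noise_cv^2))
  draw <- function(ml, ap, intensity) {
    mu <- expected_mep(truth, ml, ap, intensity, session)
    if (sdlog > 0) mu * rlnorm(length(mu), -sdlog^2 / 2, sdlog) else mu
  }
  if (is.null(start)) {
    centre <- truth$centroid
    if (identical(session, "post")) centre <- centre + truth$shift
    start <- round(centre / grid_spacing_mm) * grid_spacing_mm
  }

  # threshold-escalation at the start site
  intensities <- pmin(protocol$ladder * truth$rmt, protocol$mso_ceiling)
  rows <- list()
  operating <- NA_real_
  for (int in intensities) {
    amp <- draw(start[1], start[2], int)
    rows[[length(rows) + 1L]] <- c(start[1], start[2], int, amp)
    if (amp > protocol$threshold_uv) { operating <- int; break }
  }
  unmappable <- is.na(operating)

  if (!unmappable) {
    max_steps <- floor(protocol$max_radius_mm / grid_spacing_mm)
    dirs <- primitive_directions(max_steps)
    for (k in seq_len(nrow(dirs))) {
      v <- c(dirs$i[k], dirs$j[k]) * grid_spacing_mm
      miss_run <- 0L
      step <- 1L
      while (miss_run < protocol$stop_after) {
        pos <- start + step * v
        if (sqrt(sum((pos - start)^2)) > protocol$max_radius_mm) break
        amp <- draw(pos[1], pos[2], operating)
        rows[[length(rows) + 1L]] <- c(pos[1], pos[2], operating, amp)
        miss_run <- if (amp > protocol$threshold_uv) 0L else miss_run + 1L
        step <- step + 1L
      }
    }
  }

  m <- do.call(rbind, rows)
  out <- tibble(subject = subject, muscle = muscle, hemisphere = hemisphere,
                session = session, ml_mm = m[, 1], ap_mm = m[, 2],
                intensity_pct_mso = m[, 3], mep_uv = m[, 4])
  attr(out, "rmt") <- if (unmappable) NA_real_ else operating / 1.1
  attr(out, "threshold_uv") <- protocol$threshold_uv
  attr(out, "unmappable") <- unmappable
  out
}

#' Simulate a recruitment series for threshold estimation
#'
#' Emulates threshold hunting: at each tested stimulator intensity a fixed
#' number of pulses is delivered and each pulse yields a response
#' (amplitude above the response threshold) with probability
#' `plogis((intensity - rmt) / spread)` — exactly 0.5 at the true
#' threshold. Response amplitudes are drawn above the threshold,
#' non-responses below it.
#'
#' @param true_rmt True resting motor threshold (% MSO).
#' @param intensities Tested intensity levels (% MSO); default 2%-MSO
#'   steps from 10 below to 10 above the true threshold.
#' @param pulses Pulses per level (default 10).
#' @param spread Logistic spread of the recruitment probability (% MSO).
#' @param threshold_uv Response threshold (uV).
#' @return A tibble with columns `intensity_pct_mso` and `mep_uv`, one row
#'   per pulse.
#' @export
simulate_recruitment_series <- function(true_rmt = 45,
                                        intensities = seq(true_rmt - 10,
                                                          true_rmt + 10, by = 2),
                                        pulses = 10, spread = 1,
                                        threshold_uv = 50) {
  if (pulses < 1) abort("`pulses` must be >= 1.")
  rows <- lapply(intensities, function(int) {
    p <- plogis((int - true_rmt) / spread)
    resp <- runif(pulses) < p
    amp <- ifelse(resp,
                  threshold_uv * (1 + rexp(pulses, rate = 1)),
                  runif(pulses, 0, threshold_uv))
    tibble(intensity_pct_mso = int, mep_uv = amp)
  })
  bind_rows(rows)
}
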