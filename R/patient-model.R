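# Difficulty space shared by the game task and the controller. Every
# dimension is a demand in [0, 1]: joint range-of-motion demand of the sphere
# trajectories, grasp-precision demand (small spheres are hard, so the
# dimension is the precision demand, not the radius), speed/timing demand of
# the sphere velocity, and the finger flexion-extension range demanded to
# grasp and release.
difficulty_dimensions <- function() {
  c("trajectory_range", "sphere_size", "sphere_velocity", "flexion_range")
}

limb_labels <- function() c("paretic", "nonparetic")

#' Synthetic patient ability model
#'
#' Describes one simulated patient: a latent ability on the same \[0, 1\]
#' scale as each task difficulty dimension (per limb), a logistic
#' psychometric slope, a lapse rate, kinematic impairment factors, and a
#' per-session additive improvement drift. The model is the ground truth
#' against which the adaptive controller, the kinematic evaluation and the
#' stimulation-map pipeline are tested.
#'
#' @param ability Named list with elements `paretic` and `nonparetic`. Each
#'   element is either a single number (recycled to all difficulty
#'   dimensions) or a named numeric vector over
#'   `trajectory_range`, `sphere_size`, `sphere_velocity`, `flexion_range`.
#' @param slope Positive psychometric slope: how sharply success probability
#'   falls as difficulty exceeds ability.
#' @param lapse Baseline lapse rate in \[0, 0.2\]: probability of failing a
#'   trivially easy trial (attention slips, sensor drops).
#' @param reach_factor Named numeric (per limb) in \[0, 1\]: scale factor on
#'   reaching amplitude; 1 is an unimpaired reach.
#' @param flexion_ceiling Named numeric (per limb) in \[0, 1\]: the maximal
#'   attainable finger flexion (glove units, 1 = full flexion).
#' @param improvement_rate Named numeric (per limb): additive drift of
#'   ability (and reach/flexion capacity) per training session; may be 0.
#' @param id Subject identifier carried into generated records.
#'
#' @return An object of class `patient_ability_model`.
#' @examples
#' m <- patient_ability_model(ability = list(paretic = 0.5, nonparetic = 0.8))
#' trial_success_prob(m, difficulty = rep(0.5, 4), limb = "paretic")
#' @export
patient_ability_model <- function(ability = list(paretic = 0.55, nonparetic = 0.75),
                                  slope = 8,
                                  lapse = 0.02,
                                  reach_factor = c(paretic = 0.6, nonparetic = 1),
                                  flexion_ceiling = c(paretic = 0.7, nonparetic = 0.95),
                                  improvement_rate = c(paretic = 0, nonparetic = 0),
                                  id = "p01") {
  dims <- difficulty_dimensions()
  stopifnot(is.list(ability), all(limb_labels() %in% names(ability)))
  expand <- function(a, limb) {
    if (length(a) == 1L && is.null(names(a))) {
      a <- setNames(rep(as.numeric(a), length(dims)), dims)
    }
    if (is.null(names(a)) && length(a) == length(dims)) names(a) <- dims
    missing <- setdiff(dims, names(a))
    if (length(missing) > 0) {
      abort(sprintf("ability[[%s]] is missing difficulty dimension(s): %s",
                    limb, paste(missing, collapse = ", ")))
    }
    a[dims]
  }
  ability <- list(paretic = expand(ability$paretic, "paretic"),
                  nonparetic = expand(ability$nonparetic, "nonparetic"))
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0) {
    abort("`slope` must be a single positive number.")
  }
  if (!is.numeric(lapse) || length(lapse) != 1L || lapse < 0 || lapse > 0.2) {
    abort("`lapse` must lie in [0, 0.2].")
  }
  norm_limb <- function(x, what, lo = 0, hi = 1) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- c(paretic = unname(x), nonparetic = unname(x))
    }
    if (!all(limb_labels() %in% names(x))) {
      abort(sprintf("`%s` must be named for both limbs.", what))
    }
    x <- x[limb_labels()]
    if (any(x < lo) || any(x > hi)) {
      abort(sprintf("`%s` must lie in [%g, %g].", what, lo, hi))
    }
    x
  }
  reach_factor <- norm_limb(reach_factor, "reach_factor")
  flexion_ceiling <- norm_limb(flexion_ceiling, "flexion_ceiling")
  improvement_rate <- norm_limb(improvement_rate, "improvement_rate",
                                lo = -1, hi = 1)
  structure(
    list(id = id, ability = ability, slope = slope, lapse = lapse,
         reach_factor = reach_factor, flexion_ceiling = flexion_ceiling,
         improvement_rate = improvement_rate),
    class = "patient_ability_model"
  )
}

#' @export
print.patient_ability_model <- function(x, ...) {
  cat("<patient_ability_model> ", x$id, "\n", sep = "")
  cat("  slope ", x$slope, ", lapse ", x$lapse, "\n", sep = "")
  for (limb in limb_labels()) {
    cat(sprintf("  %-10s ability %s | reach %.2f | flexion ceiling %.2f\n",
                limb,
                paste(sprintf("%.2f", x$ability[[limb]]), collapse = "/"),
                x$reach_factor[[limb]], x$flexion_ceiling[[limb]]))
  }
  invisible(x)
}

#' Ground truth for one cortical motor map
#'
#' Defines the generating truth used by [acquire_motor_map()]: the true
#' centroid of the excitable cortical patch (mediolateral/anteroposterior
#' mm), its spatial extent, the peak motor-evoked-potential amplitude, the
#' true resting motor threshold, multiplicative amplitude noise, and the
#' treatment-induced pre-to-post centroid shift and excitability change.
#'
#' @param centroid Numeric length-2 `c(ml, ap)` in mm.
#' @param extent Gaussian scale (mm) of the amplitude fall-off; > 0.
#' @param peak Peak expected MEP amplitude (uV) at the centroid at 110% of
#'   the resting motor threshold; must exceed 50 uV for a mappable truth.
#' @param rmt True resting motor threshold, % of maximum stimulator output,
#'   in (0, 100].
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   amplitude noise; >= 0.
#' @param shift Numeric length-2 pre-to-post centroid displacement (mm).
#' @param excitability Pre-to-post multiplicative excitability change (> 0);
#'   1 means no change.
#'
#' @return An object of class `map_truth`.
#' @export
map_truth <- function(centroid = c(ml = 0, ap = 0), extent = 8, peak = 400,
                      rmt = 45, noise_cv = 0.2, shift = c(0, 0),
                      excitability = 1) {
  stopifnot(length(centroid) == 2L, length(shift) == 2L)
  if (!(rmt > 0 && rmt <= 100)) abort("`rmt` must lie in (0, 100].")
  if (extent <= 0) abort("`extent` must be > 0.")
  if (peak <= 50) abort("`peak` must exceed 50 uV so the map is mappable.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (excitability <= 0) abort("`excitability` must be > 0.")
  structure(
    list(centroid = c(ml = unname(centroid[1]), ap = unname(centroid[2])),
         extent = extent, peak = peak, rmt = rmt, noise_cv = noise_cv,
         shift = c(ml = unname(shift[1]), ap = unname(shift[2])),
         excitability = excitability),
    class = "map_truth"
  )
}
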