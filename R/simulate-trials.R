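#' Closed-form success probability of one training trial
#'
#' The synthetic patient succeeds on a trial with probability
#' `(1 - lapse) * plogis(slope * margin)` where `margin` is the smallest
#' ability-minus-difficulty margin across difficulty dimensions. Using the
#' minimum margin makes the hardest demand the binding one, which reproduces
#' the floor effects seen on grasp-type subtasks when distal function is the
#' limiting factor.
#'
#' @param model A [patient_ability_model()].
#' @param difficulty Numeric difficulty vector, either named over the
#'   difficulty dimensions or unnamed with one entry per dimension.
#' @param limb `"paretic"` or `"nonparetic"`.
#' @return A single probability.
#' @export
trial_success_prob <- function(model, difficulty, limb = "paretic") {
  stopifnot(inherits(model, "patient_ability_model"))
  limb <- match.arg(limb, limb_labels())
  ability <- model$ability[[limb]]
  if (is.null(names(difficulty))) {
    if (length(difficulty) != length(ability)) {
      abort(sprintf(
        "difficulty has %d dimension(s) but the ability model has %d (%s).",
        length(difficulty), length(ability),
        paste(names(ability), collapse = ", ")))
    }
    names(difficulty) <- names(ability)
  }
  unknown <- setdiff(names(difficulty), names(ability))
  if (length(unknown) > 0) {
    abort(sprintf("unknown difficulty dimension(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(names(ability), names(difficulty))
  if (length(missing) > 0) {
    abort(sprintf("difficulty is missing dimension(s): %s",
                  paste(missing, collapse = ", ")))
  }
  margin <- min(ability[names(difficulty)] - difficulty)
  (1 - model$lapse) * plogis(model$slope * margin)
}

#' Simulate the outcome of one training trial
#'
#' Draws a Bernoulli success flag with the probability returned by
#' [trial_success_prob()]. Randomness comes from R's global random number
#' generator, so wrap calls in `set.seed()` (or `withr::with_seed()`) for
#' reproducibility.
#'
#' @inheritParams trial_success_prob
#' @return `TRUE` (success) or `FALSE`.
#' @export
simulate_trial_outcome <- function(model, difficulty, limb = "paretic") {
  runif(1) < trial_success_prob(model, difficulty, limb)
}
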