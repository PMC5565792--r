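#' Configuration of the adaptive difficulty controller
#'
#' The controller keeps the per-limb performance ratio (successful trials
#' over total trials) inside a target band by a windowed symmetric
#' staircase: after each completed window of trials it raises every
#' difficulty dimension by one step when the window ratio is above the band
#' and lowers every dimension by one step when it is below; ratios on the
#' band edges are treated as in-band (no move), which avoids chatter.
#'
#' @param lower,upper Band edges, `0 < lower < upper < 1`. Defaults 0.6 and
#'   0.8, the challenge band that balances effort and reinforcement.
#' @param window Number of trials per evaluation window (>= 1).
#' @param step Per-dimension difficulty step in \[0, 1\] units.
#' @param warmup Trials to play before the first adjustment; defaults to
#'   `window`. Post-warm-up statistics discard the first `warmup` trials of
#'   each limb-by-subtask block.
#' @param dim_min,dim_max Bounds every difficulty dimension is clipped to.
#'
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(lower = 0.6, upper = 0.8, window = 10,
                              step = 0.05, warmup = window,
                              dim_min = 0, dim_max = 1) {
  if (!(lower > 0 && upper < 1 && lower < upper)) {
    abort("band must satisfy 0 < lower < upper < 1.")
  }
  if (window < 1) abort("`window` must be >= 1.")
  if (step <= 0) abort("`step` must be > 0.")
  if (!(dim_min < dim_max)) abort("`dim_min` must be < `dim_max`.")
  structure(list(lower = lower, upper = upper, window = as.integer(window),
                 step = step, warmup = as.integer(warmup),
                 dim_min = dim_min, dim_max = dim_max),
            class = "controller_config")
}

#' Per-limb, per-subtask difficulty state
#'
#' @param limb `"paretic"` or `"nonparetic"`. Paretic and non-paretic
#'   states evolve independently (lateralized customization).
#' @param subtask One of `"hit"`, `"grasp"`, `"place"`.
#' @param difficulty Starting difficulty: a single number recycled over the
#'   four dimensions, or a named numeric vector.
#' @param config A [controller_config()]; used to clip the state to bounds.
#' @return An object of class `difficulty_state`.
#' @export
difficulty_state <- function(limb = "paretic",
                             subtask = c("hit", "grasp", "place"),
                             difficulty = 0.5,
                             config = controller_config()) {
  limb <- match.arg(limb, limb_labels())
  subtask <- match.arg(subtask)
  dims <- difficulty_dimensions()
  if (length(difficulty) == 1L) {
    difficulty <- setNames(rep(as.numeric(difficulty), length(dims)), dims)
  }
  if (is.null(names(difficulty))) names(difficulty) <- dims
  if (!setequal(names(difficulty), dims)) {
    abort(sprintf("difficulty must cover dimensions: %s",
                  paste(dims, collapse = ", ")))
  }
  difficulty <- pmin(pmax(difficulty[dims], config$dim_min), config$dim_max)
  structure(list(limb = limb, subtask = subtask, difficulty = difficulty),
            class = "difficulty_state")
}

#' Performance ratio of a block of trials
#'
#' The fraction of successful trials over total trials — the statistic the
#' adaptive difficulty controller regulates.
#'
#' @param trials A data frame of trial records with a logical `success`
#'   column, or a logical/0-1 vector of success flags.
#' @return A single number in \[0, 1\].
#' @examples
#' performance_ratio(c(TRUE, TRUE, FALSE, TRUE))
#' @export
performance_ratio <- function(trials) {
  success <- if (is.data.frame(trials)) {
    if (!"success" %in% names(trials)) {
      abort("`trials` must contain a `success` column.")
    }
    trials$success
  } else {
    trials
  }
  if (length(success) == 0) abort("performance ratio of zero trials is undefined.")
  if (anyNA(success)) abort("`success` contains missing values.")
  sum(as.logical(success)) / length(success)
}

#' One staircase update of a difficulty state
#'
#' Pure function: given the trials of the most recent window, returns a new
#' state with every dimension moved one step up (window ratio above the
#' band), one step down (below the band), or unchanged (in band, edges
#' inclusive). Dimensions are clipped to the configured bounds; the input
#' state is never modified.
#'
#' @param state A [difficulty_state()].
#' @param window_trials Data frame of trial records (needs `success`, and
#'   `limb`/`subtask` columns if present are checked against the state), or
#'   a success-flag vector.
#' @param config A [controller_config()].
#' @return A new `difficulty_state`.
#' @export
update_difficulty <- function(state, window_trials, config = controller_config()) {
  stopifnot(inherits(state, "difficulty_state"))
  if (is.data.frame(window_trials)) {
    if ("limb" %in% names(window_trials) &&
        !all(window_trials$limb == state$limb)) {
      abort("window mixes limbs or does not match the state's limb.")
    }
    if ("subtask" %in% names(window_trials) &&
        !all(window_trials$subtask == state$subtask)) {
      abort("window does not match the state's subtask.")
    }
  }
  ratio <- performance_ratio(window_trials)
  d <- state$difficulty
  if (ratio > config$upper) {
    d <- pmin(d + config$step, config$dim_max)
  } else if (ratio < config$lower) {
    d <- pmax(d - config$step, config$dim_min)
  }
  out <- state
  out$difficulty <- d
  out
}

# Simulate one limb-by-subtask block of the closed loop. Plain vectors in the
# hot path; assembled into a tibble by the caller.
simulate_block <- function(ability, difficulty, model, config, n_trials) {
  dims <- length(difficulty)
  dmat <- matrix(NA_real_, n_trials, dims)
  success <- logical(n_trials)
  p <- numeric(n_trials)
  slope <- model$slope
  lapse <- model$lapse
  for (t in seq_len(n_trials)) {
    dmat[t, ] <- difficulty
    margin <- min(ability - difficulty)
    p[t] <- (1 - lapse) * plogis(slope * margin)
    success[t] <- runif(1) < p[t]
    if (t >= config$warmup && t %% config$window == 0L) {
      ratio <- mean(success[(t - config$window + 1L):t])
      if (ratio > config$upper) {
        difficulty <- pmin(difficulty + config$step, config$dim_max)
      } else if (ratio < config$lower) {
        difficulty <- pmax(difficulty - config$step, config$dim_min)
      }
    }
  }
  list(dmat = dmat, success = success, p = p, final = difficulty)
}

#' Run the closed training loop for one session
#'
#' Simulates one training session of the gamified reaching task: the three
#' subtasks (hit, grasp, place) are each played with both limbs in
#' alternation with equal trial share, the synthetic patient generates
#' successes via [trial_success_prob()], and the controller adjusts each
#' limb-by-subtask difficulty state after every completed window.
#'
#' @param model A [patient_ability_model()].
#' @param config A [controller_config()].
#' @param states Optional named list of [difficulty_state()] objects keyed
#'   `"limb.subtask"`, carried over from the previous session; fresh states
#'   at `start_difficulty` are created when absent.
#' @param session Session index stamped on the records.
#' @param trials_per_subtask Trials per limb per subtask (default 30).
#' @param subtasks Character vector of subtasks to play.
#' @param start_difficulty Starting difficulty for fresh states.
#' @return A list with `trials` (a tibble of trial records: session, trial,
#'   limb, subtask, the four difficulty columns, `p_success`, `success`,
#'   `post_warmup`) and `states` (the updated controller states).
#' @export
run_training_session <- function(model, config = controller_config(),
                                 states = NULL, session = 1L,
                                 trials_per_subtask = 30,
                                 subtasks = c("hit", "grasp", "place"),
                                 start_difficulty = 0.5) {
  stopifnot(inherits(model, "patient_ability_model"))
  if (trials_per_subtask < 1) abort("`trials_per_subtask` must be positive.")
  dims <- difficulty_dimensions()
  if (is.null(states)) states <- list()
  out <- vector("list", 2L * length(subtasks))
  i <- 0L
  trial_counter <- 0L
  for (subtask in subtasks) {
    for (limb in limb_labels()) {
      key <- paste(limb, subtask, sep = ".")
      if (is.null(states[[key]])) {
        states[[key]] <- difficulty_state(limb, subtask, start_difficulty, config)
      }
      blk <- simulate_block(model$ability[[limb]], states[[key]]$difficulty,
                            model, config, trials_per_subtask)
      states[[key]]$difficulty <- blk$final
      d <- as_tibble(as.data.frame(blk$dmat))
      names(d) <- dims
      i <- i + 1L
      out[[i]] <- tibble(
        session = as.integer(session),
        trial = trial_counter + seq_len(trials_per_subtask),
        limb = limb, subtask = subtask
      ) |>
        dplyr::bind_cols(d) |>
        mutate(p_success = blk$p, success = blk$success,
               post_warmup = seq_len(trials_per_subtask) > config$warmup)
      trial_counter <- trial_counter + trials_per_subtask
    }
  }
  list(trials = bind_rows(out), states = states)
}

#' Run a multi-session training course
#'
#' Runs [run_training_session()] over consecutive sessions, carrying the
#' controller states across sessions and applying the patient's per-session
#' improvement drift to the ability vector, so difficulty trajectories can
#' track recovery. Floor effects — a post-warm-up ratio pinned below the
#' band with every dimension at its lower bound — are flagged per block.
#'
#' @inheritParams run_training_session
#' @param n_sessions Number of sessions (default 15: five weekly sessions
#'   for three consecutive weeks).
#' @return A tibble of trial records across sessions with a logical
#'   `floor_effect` column.
#' @export
run_training_course <- function(model, config = controller_config(),
                                n_sessions = 15, trials_per_subtask = 30,
                                subtasks = c("hit", "grasp", "place"),
                                start_difficulty = 0.5) {
  if (n_sessions < 1) abort("`n_sessions` must be positive.")
  states <- NULL
  sessions <- vector("list", n_sessions)
  m <- model
  for (s in seq_len(n_sessions)) {
    res <- run_training_session(m, config, states, session = s,
                                trials_per_subtask = trials_per_subtask,
                                subtasks = subtasks,
                                start_difficulty = start_difficulty)
    states <- res$states
    sessions[[s]] <- res$trials
    for (limb in limb_labels()) {
      m$ability[[limb]] <- pmin(m$ability[[limb]] + m$improvement_rate[[limb]], 1)
    }
  }
  trials <- bind_rows(sessions)
  dims <- difficulty_dimensions()
  flags <- trials |>
    group_by(.data$session, .data$limb, .data$subtask) |>
    summarise(
      floor_effect = mean(.data$success[.data$post_warmup]) < config$lower &&
        all(vapply(dplyr::pick(dplyr::all_of(dims)),
                   function(col) col[length(col)] <= config$dim_min,
                   logical(1))),
      .groups = "drop"
    )
  trials |>
    left_join(flags, by = c("session", "limb", "subtask")) |>
    mutate(patient = model$id, .before = 1)
}

#' Per-session difficulty and performance summary
#'
#' Averages each difficulty dimension (and the performance ratio) per
#' session, limb and subtask — the per-session means used for
#' within-subject time-series analysis of training progress.
#'
#' @param trials A trial-record tibble as returned by
#'   [run_training_course()].
#' @param post_warmup_only If `TRUE` (default), only post-warm-up trials
#'   enter the performance-ratio column; difficulty means always use all
#'   trials of the session.
#' @return A tibble with one row per session by limb by subtask.
#' @export
session_difficulty_summary <- function(trials, post_warmup_only = TRUE) {
  if (!all(c("session", "limb", "subtask", "success") %in% names(trials))) {
    abort("`trials` must contain session, limb, subtask and success columns.")
  }
  dims <- intersect(difficulty_dimensions(), names(trials))
  trials |>
    group_by(.data$session, .data$limb, .data$subtask) |>
    summarise(
      n_trials = dplyr::n(),
      across(dplyr::all_of(dims), mean),
      performance_ratio = if (post_warmup_only && any(.data$post_warmup)) {
        mean(.data$success[.data$post_warmup])
      } else {
        mean(.data$success)
      },
      .groups = "drop"
    )
}

#' Plot difficulty and performance trajectories of a training course
#'
#' @param trials A trial-record tibble from [run_training_course()].
#' @param ... Unused.
#' @return A ggplot: per-session mean of each difficulty dimension and the
#'   performance ratio, faceted by limb and subtask.
#' @export
plot_training_course <- function(trials, ...) {
  summ <- session_difficulty_summary(trials) |>
    tidyr::pivot_longer(dplyr::all_of(c(difficulty_dimensions(),
                                        "performance_ratio")),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(summ, ggplot2::aes(.data$session, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0.6, 0.8), linetype = "dotted") +
    ggplot2::facet_grid(limb ~ subtask) +
    ggplot2::labs(x = "session", y = "per-session mean",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
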