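# Synthetic cohort generation: patients, outcome panels, training logs,
# kinematic evaluation streams and stimulation maps, all with known ground
# truth. One global seed fans out into per-subject substreams so each
# subject is reproducible independently of the others.

default_scale_params <- function() {
  # Baseline moments typical of a mild-to-moderate chronic hemiparesis
  # cohort, and improvement SDs on the scale of short home interventions.
  tibble::tribble(
    ~scale,     ~baseline_mean, ~baseline_sd, ~improvement_sd,
    "UE-FM",    43,             14,           2.9,
    "CAHAI",    53,             23,           4.6,
    "Barthel",  87,             12,           2.4,
    "MRCp",     3.4,            0.6,          0.28,
    "MRCd",     3.0,            1.1,          0.45,
    "ASp",      1.2,            1.3,          0.30,
    "ASd",      1.2,            1.5,          0.34,
    "grip",     6.0,            5.4,          2.3,
    "Hamilton", 4.1,            3.3,          2.0,
    "VAS-S",    2.1,            2.7,          1.9,
    "MMSE",     28.2,           2.3,          1.0
  )
}

default_effects_w3 <- function() {
  # True standardized treated-minus-control effects at the end of therapy:
  # a moderate gain in arm-and-hand activity, small distal-function and
  # pain benefits, and near-null effects elsewhere.
  c("UE-FM" = -0.30, "CAHAI" = 0.48, "Barthel" = -0.41, "MRCp" = -0.17,
    "MRCd" = -0.12, "ASp" = 0.40, "ASd" = 0.36, "grip" = 0.01,
    "Hamilton" = 0.10, "VAS-S" = 0.37, "MMSE" = 0)
}

default_effects_w12 <- function() {
  # At follow-up the activity gain has washed out; a residual distal
  # spasticity benefit remains.
  c("UE-FM" = -0.34, "CAHAI" = -0.08, "Barthel" = -0.50, "MRCp" = -0.62,
    "MRCd" = -0.17, "ASp" = -0.12, "ASd" = 0.70, "grip" = -0.01,
    "Hamilton" = -0.25, "VAS-S" = -0.25, "MMSE" = 0)
}

# Derive a per-subject substream seed from the cohort seed (kept < 2^31).
substream_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 16807) %% 2147483647
}

#' Generate clinical outcome panels for a two-arm cohort
#'
#' Draws baseline scores and improvements per scale and subject. True
#' improvements are `N(d * sd, sd)` for the treated group and `N(0, sd)`
#' for controls, where `d` is the scale's configured standardized effect;
#' reversed-polarity scales are stored on their native orientation
#' (recovery decreases the score). A fraction of each CAHAI improvement is
#' driven by the subject's latent kinematic recovery when `ability_drift`
#' is supplied, so clinical and kinematic measures correlate.
#'
#' @param n_treated,n_control Group sizes (>= 2).
#' @param effects_w3,effects_w12 Named vectors of true standardized
#'   effects per scale.
#' @param scales Character vector of scales to generate.
#' @param scale_params Tibble of per-scale baseline and improvement
#'   moments; see `default_scale_params()` internals.
#' @param ability_drift Optional numeric vector (length
#'   `n_treated + n_control`) of per-subject latent recovery, used to
#'   correlate CAHAI improvements with kinematic ability.
#' @param treated Label of the treated arm.
#' @return A long tibble: `subject`, `group`, `scale`, `t0`, `t3`, `t12`.
#' @export
generate_outcome_panels <- function(n_treated = 17, n_control = 18,
                                    effects_w3 = default_effects_w3(),
                                    effects_w12 = default_effects_w12(),
                                    scales = trial_scales(),
                                    scale_params = default_scale_params(),
                                    ability_drift = NULL,
                                    treated = "RGS") {
  if (n_treated < 2 || n_control < 2) abort("need n >= 2 per group.")
  n <- n_treated + n_control
  subjects <- sprintf("s%03d", seq_len(n))
  group <- c(rep(treated, n_treated), rep("control", n_control))
  if (!is.null(ability_drift) && length(ability_drift) != n) {
    abort("`ability_drift` must have one value per subject.")
  }
  # centred within group so the latent recovery drives within-group
  # correlation with the clinical score without shifting the configured
  # between-group effect
  drift_z <- rep(0, n)
  if (!is.null(ability_drift) && sd(ability_drift) > 0) {
    for (g in unique(group)) {
      idx <- group == g
      s <- sd(ability_drift[idx])
      if (s > 0) {
        drift_z[idx] <- (ability_drift[idx] - mean(ability_drift[idx])) / s
      }
    }
  }
  rows <- lapply(scales, function(sc) {
    pars <- scale_params[scale_params$scale == sc, ]
    if (nrow(pars) != 1) abort(sprintf("no parameters for scale %s.", sc))
    d3 <- if (sc %in% names(effects_w3)) effects_w3[[sc]] else 0
    d12 <- if (sc %in% names(effects_w12)) effects_w12[[sc]] else 0
    mu3 <- ifelse(group == treated, d3 * pars$improvement_sd, 0)
    mu12 <- ifelse(group == treated, d12 * pars$improvement_sd, 0)
    t0 <- rnorm(n, pars$baseline_mean, pars$baseline_sd)
    if (sc == "CAHAI" && any(drift_z != 0)) {
      # split the improvement variance between the latent kinematic
      # recovery and independent noise
      imp3 <- mu3 + pars$improvement_sd * (0.6 * drift_z + 0.8 * rnorm(n))
    } else {
      imp3 <- mu3 + rnorm(n, 0, pars$improvement_sd)
    }
    imp12 <- mu12 + rnorm(n, 0, pars$improvement_sd)
    pol <- if (sc %in% reversed_scales()) -1 else 1
    tibble(subject = subjects, group = group, scale = sc,
           t0 = t0, t3 = t0 + pol * imp3, t12 = t0 + pol * imp12)
  })
  bind_rows(rows)
}

#' Generate a full synthetic trial cohort with ground truth
#'
#' Builds every input the analysis pipeline consumes: per-subject ability
#' models, clinical outcome panels (correlated with kinematic recovery),
#' closed-loop training logs for the treated arm, kinematic evaluation
#' streams with their descriptor table at the three evaluation epochs, and
#' pre/post stimulation maps for an NBS subsample. The generating truth is
#' returned alongside the data so parameter-recovery tests need no
#' external reference.
#'
#' @param n_treated,n_control Group sizes (>= 2).
#' @param seed Cohort seed; fans out deterministically into per-subject
#'   substreams.
#' @param n_sessions Training sessions for the treated arm (default 15).
#' @param trials_per_subtask Trials per limb per subtask per session.
#' @param n_nbs Size of the NBS subsample (default 17, of which 3
#'   controls, capped at the cohort size).
#' @param se_gain True post/pre excitability multiplier applied to the
#'   pathological-hemisphere APB maps of treated NBS subjects.
#' @param centroid_shift True pathological-hemisphere centroid shift (mm)
#'   for treated NBS subjects.
#' @param effects_w3,effects_w12 Passed to [generate_outcome_panels()].
#' @param eval_sessions Sessions at which kinematic evaluation streams are
#'   generated (default first, mid and last session).
#' @param eval_duration_s Duration of each evaluation stream.
#' @param controller,protocol Controller and map-acquisition
#'   configurations.
#' @param include Which components to generate (subset of `"panels"`,
#'   `"training"`, `"kinematics"`, `"maps"`).
#' @param keep_streams Keep raw kinematic streams (can be large); the
#'   descriptor table is always returned.
#' @return A list of class `rehab_cohort` with elements `patients`,
#'   `panels`, `training`, `kinematics` (descriptors), `streams`
#'   (optional), `map_sites`, `truth`.
#' @export
generate_cohort <- function(n_treated = 17, n_control = 18, seed = 1,
                            n_sessions = 15, trials_per_subtask = 30,
                            n_nbs = 17, se_gain = 1.5,
                            centroid_shift = c(2.5, -1),
                            effects_w3 = default_effects_w3(),
                            effects_w12 = default_effects_w12(),
                            eval_sessions = NULL,
                            eval_duration_s = 60,
                            controller = controller_config(),
                            protocol = map_protocol(),
                            include = c("panels", "training",
                                        "kinematics", "maps"),
                            keep_streams = FALSE,
                            treated = "RGS") {
  if (n_treated < 2 || n_control < 2) abort("need n >= 2 per group.")
  include <- match.arg(include, several.ok = TRUE)
  n <- n_treated + n_control
  eval_sessions <- eval_sessions %||%
    unique(c(1L, ceiling(n_sessions / 2), n_sessions))

  set.seed(seed)
  subjects <- sprintf("s%03d", seq_len(n))
  group <- c(rep(treated, n_treated), rep("control", n_control))
  # latent per-subject draws (cohort stream)
  base_ability <- runif(n, 0.35, 0.7)
  drift <- ifelse(group == treated,
                  pmax(rnorm(n, 0.010, 0.004), 0),
                  pmax(rnorm(n, 0.002, 0.002), 0))
  patients <- purrr::map(seq_len(n), function(i) {
    patient_ability_model(
      ability = list(
        paretic = c(trajectory_range = base_ability[i] + 0.05,
                    sphere_size = base_ability[i],
                    sphere_velocity = base_ability[i] + 0.05,
                    flexion_range = base_ability[i] - 0.05),
        nonparetic = base_ability[i] + 0.25),
      reach_factor = c(paretic = 0.4 + 0.6 * base_ability[i], nonparetic = 1),
      flexion_ceiling = c(paretic = 0.45 + 0.5 * base_ability[i],
                          nonparetic = 0.95),
      improvement_rate = c(paretic = drift[i], nonparetic = drift[i] / 4),
      id = subjects[i])
  })
  names(patients) <- subjects
  patient_tbl <- tibble(subject = subjects, group = group,
                        base_ability = base_ability,
                        improvement_rate = drift,
                        substream = vapply(seq_len(n), substream_seed,
                                           numeric(1), seed = seed))

  out <- list(patients = patients, patient_table = patient_tbl)
  truth <- list(base_ability = base_ability, drift = drift,
                effects_w3 = effects_w3, effects_w12 = effects_w12,
                se_gain = se_gain, centroid_shift = centroid_shift)

  if ("panels" %in% include) {
    set.seed(substream_seed(seed, 0))
    out$panels <- generate_outcome_panels(
      n_treated, n_control, effects_w3, effects_w12,
      ability_drift = drift, treated = treated)
  }

  if ("training" %in% include) {
    logs <- purrr::map(which(group == treated), function(i) {
      set.seed(substream_seed(seed, i))
      run_training_course(patients[[i]], controller,
                          n_sessions = n_sessions,
                          trials_per_subtask = trials_per_subtask)
    })
    out$training <- bind_rows(logs)
  }

  if ("kinematics" %in% include) {
    streams <- list()
    desc <- list()
    for (i in seq_len(n)) {
      if (group[i] != treated) next  # home evaluation runs on the treated arm
      set.seed(substream_seed(seed, 10000 + i))
      m <- patients[[i]]
      for (s in eval_sessions) {
        grown <- m
        for (limb in limb_labels()) {
          gain <- m$improvement_rate[[limb]] * (s - 1)
          grown$reach_factor[[limb]] <- min(1, m$reach_factor[[limb]] + gain)
          grown$flexion_ceiling[[limb]] <-
            min(1, m$flexion_ceiling[[limb]] + gain)
        }
        for (limb in limb_labels()) {
          for (task in c("wipe", "squeeze")) {
            st <- generate_kinematic_session(grown, task, limb,
                                             duration_s = eval_duration_s,
                                             session = s)
            desc[[length(desc) + 1L]] <- evaluate_session(st)
            if (keep_streams) streams[[length(streams) + 1L]] <- st
          }
        }
      }
    }
    out$kinematics <- bind_rows(desc)
    if (keep_streams) out$streams <- bind_rows(streams)
  }

  if ("maps" %in% include) {
    n_nbs <- min(n_nbs, n)
    n_nbs_ctrl <- min(3L, n_control, n_nbs)
    nbs_idx <- c(head(which(group == treated), n_nbs - n_nbs_ctrl),
                 head(which(group == "control"), n_nbs_ctrl))
    site_rows <- list()
    map_truths <- list()
    for (i in nbs_idx) {
      set.seed(substream_seed(seed, 20000 + i))
      for (hemi in c("pathological", "nonpathological")) {
        for (muscle in c("APB", "ECR")) {
          patho <- hemi == "pathological"
          gain_here <- group[i] == treated && patho && muscle == "APB"
          tr <- map_truth(
            centroid = c(ml = ifelse(muscle == "APB", 45, 38) *
                           ifelse(hemi == "pathological", -1, 1),
                         ap = ifelse(muscle == "APB", -10, -2)),
            extent = if (muscle == "ECR") 10 else 8,
            peak = if (patho) 250 else 450,
            rmt = if (patho) 55 else 45,
            noise_cv = 0.2,
            shift = if (group[i] == treated && patho) centroid_shift
                    else c(0, 0),
            excitability = if (gain_here) se_gain else 1)
          key <- paste(subjects[i], muscle, hemi, sep = ".")
          map_truths[[key]] <- tr
          for (sess in c("pre", "post")) {
            site_rows[[length(site_rows) + 1L]] <-
              acquire_motor_map(tr, protocol = protocol, session = sess,
                                muscle = muscle, hemisphere = hemi,
                                subject = subjects[i])
          }
        }
      }
    }
    out$map_sites <- bind_rows(site_rows)
    truth$maps <- map_truths
  }

  out$truth <- truth
  structure(out, class = "rehab_cohort", seed = seed)
}

#' @export
print.rehab_cohort <- function(x, ...) {
  cat("<rehab_cohort> seed", attr(x, "seed"), "\n")
  cat("  patients:", nrow(x$patient_table), "\n")
  if (!is.null(x$panels)) {
    cat("  panels:", nrow(x$panels), "rows,",
        length(unique(x$panels$scale)), "scales\n")
  }
  if (!is.null(x$training)) cat("  training trials:", nrow(x$training), "\n")
  if (!is.null(x$kinematics)) {
    cat("  kinematic descriptor rows:", nrow(x$kinematics), "\n")
  }
  if (!is.null(x$map_sites)) {
    cat("  stimulation sites:", nrow(x$map_sites), "\n")
  }
  invisible(x)
}
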