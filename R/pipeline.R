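#' Configuration of the end-to-end simulated trial pipeline
#'
#' Bundles and validates every stage's parameters: cohort sizes and seed,
#' the adaptive-controller configuration, kinematic-evaluation parameters
#' (filter cut-off and order, occupancy-grid cell size), the
#' map-acquisition protocol and the statistical options.
#'
#' @param seed Pipeline seed.
#' @param n_treated,n_control,n_nbs Cohort sizes.
#' @param n_sessions,trials_per_subtask Training calendar (default 15
#'   sessions — five weekly sessions for three weeks).
#' @param controller A [controller_config()].
#' @param cutoff_hz,filter_order,cell_m Kinematic evaluation parameters.
#' @param protocol A [map_protocol()].
#' @param alpha,correction Statistical options, see
#'   [build_outcomes_report()].
#' @param out_dir Output directory for [run_pipeline()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_treated = 17, n_control = 18,
                            n_nbs = 17, n_sessions = 15,
                            trials_per_subtask = 30,
                            controller = controller_config(),
                            cutoff_hz = 6, filter_order = 2, cell_m = 0.02,
                            protocol = map_protocol(),
                            alpha = 0.05,
                            correction = c("none", "bonferroni"),
                            out_dir = tempfile("rehabsim-run-")) {
  correction <- match.arg(correction)
  stopifnot(inherits(controller, "controller_config"),
            inherits(protocol, "map_protocol"))
  if (cutoff_hz <= 0 || cell_m <= 0) {
    abort("`cutoff_hz` and `cell_m` must be positive.")
  }
  structure(list(seed = seed, n_treated = n_treated, n_control = n_control,
                 n_nbs = n_nbs, n_sessions = n_sessions,
                 trials_per_subtask = trials_per_subtask,
                 controller = controller, cutoff_hz = cutoff_hz,
                 filter_order = filter_order, cell_m = cell_m,
                 protocol = protocol, alpha = alpha,
                 correction = correction, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full simulated trial pipeline
#'
#' Simulates a cohort, runs the closed training loop, scores the kinematic
#' evaluations, computes the stimulation-map change table and builds the
#' statistical outcome report; writes every table as CSV plus a JSON run
#' manifest (seed, configuration hash, row counts, package version) into
#' `config$out_dir`. Reruns with the same configuration are reproducible:
#' the manifest records a hash of all in-memory results.
#'
#' @param config A [pipeline_config()].
#' @param write If `FALSE`, skip writing files and return results only.
#' @return Invisibly, a list with `cohort`, `training_summary`,
#'   `descriptors`, `map_changes`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), write = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  cohort <- stage("simulate", generate_cohort(
    n_treated = config$n_treated, n_control = config$n_control,
    seed = config$seed, n_sessions = config$n_sessions,
    trials_per_subtask = config$trials_per_subtask, n_nbs = config$n_nbs,
    controller = config$controller, protocol = config$protocol))

  training_summary <- stage("train", session_difficulty_summary(cohort$training))
  inform(sprintf("stage train: %d trials, %d summary rows",
                 nrow(cohort$training), nrow(training_summary)))

  descriptors <- cohort$kinematics
  inform(sprintf("stage aemf: %d descriptor rows", nrow(descriptors)))

  map_changes <- stage("nbs", compare_maps(cohort$map_sites))
  inform(sprintf("stage nbs: %d map pairs", nrow(map_changes)))

  report <- stage("report", build_outcomes_report(
    cohort$panels, alpha = config$alpha, correction = config$correction))
  inform(sprintf("stage report: %d cells", nrow(report)))

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  manifest <- list(
    package = "rehabsim",
    version = as.character(utils::packageVersion("rehabsim")),
    seed = config$seed,
    config_hash = rlang::hash(cfg_for_hash),
    results_hash = rlang::hash(list(cohort$panels, cohort$training,
                                    descriptors, cohort$map_sites,
                                    as_tibble(report))),
    rows = list(trials = nrow(cohort$training),
                descriptors = nrow(descriptors),
                stimulation_sites = nrow(cohort$map_sites),
                panel = nrow(cohort$panels),
                report = nrow(report))
  )

  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_trial_log(cohort$training, p("trial_log.csv"))
    readr::write_csv(training_summary, p("training_summary.csv"))
    readr::write_csv(descriptors, p("aemf_descriptors.csv"))
    write_stimulation_sites(cohort$map_sites, p("stimulation_sites.csv"))
    readr::write_csv(map_changes, p("map_changes.csv"))
    write_outcome_panels(cohort$panels, p("outcome_panels.csv"))
    readr::write_csv(as_tibble(report), p("outcomes_report.csv"))
    writeLines(utils::capture.output(print(report)), p("outcomes_report.txt"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }

  invisible(list(cohort = cohort, training_summary = training_summary,
                 descriptors = descriptors, map_changes = map_changes,
                 report = report, manifest = manifest))
}
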