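# Plain-CSV interchange for every table the pipeline produces or consumes.
# Headers are stable and documented here:
#   trial log:        patient, session, trial, limb, subtask,
#                     trajectory_range, sphere_size, sphere_velocity,
#                     flexion_range, p_success, success, post_warmup,
#                     floor_effect
#   kinematic stream: subject, limb, task, session, time_s, x_m, y_m, z_m,
#                     flex_f1..flex_f5
#   descriptors:      subject, limb, task, session, work_area_m2,
#                     max_flexion, min_extension, degenerate
#   stimulation sites:subject, muscle, hemisphere, session, ml_mm, ap_mm,
#                     intensity_pct_mso, mep_uv
#   outcome panel:    subject, group, scale, t0, t3, t12

#' Read and write pipeline tables as CSV
#'
#' Thin readr wrappers with fixed, documented headers for the five table
#' kinds the pipeline exchanges: trial logs, kinematic streams, kinematic
#' descriptors, stimulation-site tables and clinical outcome panels.
#'
#' @param x The tibble to write.
#' @param path File path.
#' @return Readers return a tibble; writers return `x` invisibly.
#' @name rehab_io
NULL

#' @rdname rehab_io
#' @export
write_trial_log <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname rehab_io
#' @export
read_trial_log <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    limb = readr::col_character(),
                    subtask = readr::col_character(),
                    success = readr::col_logical()))
}

#' @rdname rehab_io
#' @export
write_kinematic_session <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname rehab_io
#' @export
read_kinematic_session <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject = readr::col_character(),
                    limb = readr::col_character(),
                    task = readr::col_character()))
}

#' @rdname rehab_io
#' @export
write_stimulation_sites <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname rehab_io
#' @export
read_stimulation_sites <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject = readr::col_character(),
                    muscle = readr::col_character(),
                    hemisphere = readr::col_character(),
                    session = readr::col_character()))
}

#' @rdname rehab_io
#' @export
write_outcome_panels <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname rehab_io
#' @export
read_outcome_panels <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject = readr::col_character(),
                    group = readr::col_character(),
                    scale = readr::col_character()))
}
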