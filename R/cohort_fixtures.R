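read_cohort_file <- function(name) {
  path <- system.file("extdata", name, package = "coordte")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged cohort fixture missing: ", name, call. = FALSE)
  }
  utils::read.delim(path)
}

#' Reference cohort: per-trial transfer entropies
#'
#' Transfer entropies between head and eye yaw rotation for the packaged
#' reference cohort — 12 participants, each driving four 3-minute VR
#' sessions at a target speed of 40 km/h. Values are on the conventional
#' x10^-2 printing scale (bits x 10^-2), as published for this cohort.
#'
#' @return Data frame with columns `participant`, `trial`,
#'   `te_eye_to_head_x100`, `te_head_to_eye_x100` (48 rows).
#' @export
cohort_te <- function() read_cohort_file("vr_driving_te.tsv")

#' Reference cohort: per-trial unidirectional information differences
#'
#' Published UID values for the reference cohort, on the x10^-2 scale; up to
#' the rounding of the underlying transfer entropies these equal
#' `te_head_to_eye_x100 - te_eye_to_head_x100` from [cohort_te()].
#'
#' @return Data frame with columns `participant`, `trial`, `uid_x100`.
#' @export
cohort_uid <- function() read_cohort_file("vr_driving_uid.tsv")

#' Reference cohort: NUID and driving performance
#'
#' Normalized unidirectional information difference (x10^-2) and driving
#' performance (1/AvgAcc, s^2/m) per trial for the reference cohort.
#'
#' @return Data frame with columns `participant`, `trial`, `nuid_x100`,
#'   `performance_s2_per_m`.
#' @export
cohort_nuid <- function() read_cohort_file("vr_driving_nuid_perf.tsv")
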