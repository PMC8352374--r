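#' Cohort measurement tables
#'
#' Per-subject measurements for the two study cohorts: five volunteers
#' (age, BMI, height, weight, pelvic tilt in the steep and shallow positions,
#' compressed gel-pad thickness and membrane bowing, where measurable) and
#' five patients (age, weight, treatment angle, measured gel-pad thickness
#' and membrane bowing, nominal pad thickness). These provide the deformation
#' defaults (volunteer means: 9.8 mm compressed thickness, 10.0 mm bowing)
#' and the descriptive-statistics inputs.
#'
#' @return `cohort_tables()` returns a list with data.frames `volunteers` and
#'   `patients`.
#' @export
cohort_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "hifucover", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(volunteers = rd("volunteer_measurements.csv"),
       patients = rd("patient_measurements.csv"))
}

#' @rdname cohort_tables
#' @return `volunteer_deformation_averages()` returns the cohort-mean
#'   [deformation_params()] computed from the measurable volunteer entries.
#' @export
volunteer_deformation_averages <- function() {
  v <- cohort_tables()$volunteers
  gp <- descriptive_stats(c(v$gelpad_steep_mm, v$gelpad_shallow_mm))
  bw <- descriptive_stats(c(v$bowing_steep_mm, v$bowing_shallow_mm))
  deformation_params(gelpad_thickness = gp$mean, membrane_bowing = bw$mean)
}
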