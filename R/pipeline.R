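#' Run the full referral-to-treatment coverage prediction pipeline
#'
#' Executes the study workflow on a paired referral / treatment dataset:
#' \enumerate{
#'   \item landmark affine registration of the referral dataset into
#'     treatment space, resampling its image and masks onto the treatment
#'     grid;
#'   \item automatic body-outline (and, for the treatment dataset,
#'     extracorporeal-air) segmentation — provided bone/target/OAR masks are
#'     consumed as-is, matching the manual-contouring workflow; the referral
#'     prediction assumes perfect acoustic coupling, so no interface air is
#'     segmented on the registered referral;
#'   \item home-position estimation for the registered referral dataset from
#'     the skin point under the treatment isocentre, using the assumed
#'     gel-pad compression and membrane bowing;
#'   \item exhaustive coverage computation on both datasets;
#'   \item comparison: per-dataset `tvc_pat` and the referral-vs-treatment
#'     covered-set agreement `tvc_vol`.
#' }
#'
#' @param referral,treatment `hifu_anatomy` objects or directories readable
#'   by [read_anatomy()].
#' @param landmarks_referral,landmarks_treatment paired landmark sets
#'   (data.frames or CSV paths).
#' @param deformation assumed [deformation_params()] for home-position
#'   estimation (defaults to the volunteer-cohort averages).
#' @param device list as returned by [read_device_config()] (or `NULL` for
#'   the standard device), or a path to a device YAML.
#' @param search_bounds optional LR/IS search bounds; defaults to the
#'   treatment target extents.
#' @param segment logical: run automatic body/air segmentation on the images
#'   (default) or trust the provided body/air masks.
#' @param sample_spacing ray sampling step (mm).
#' @param out optional directory for artifacts (report JSON, covered masks).
#' @return object of class `hifu_report`: settings plus `registration`
#'   (transform, mean landmark error), `home` (estimated and skin point),
#'   `coverage_referral`, `coverage_treatment`, `tvc_vol`, `tvc_pat_referral`,
#'   `tvc_pat_treatment` and `tvc_pat_difference`.
#' @export
run_pipeline <- function(referral, treatment,
                         landmarks_referral, landmarks_treatment,
                         deformation = volunteer_deformation_averages(),
                         device = NULL, search_bounds = NULL,
                         segment = TRUE, sample_spacing = 0.2, out = NULL) {
  if (is.character(device)) device <- read_device_config(device)
  if (is.null(device))
    device <- list(transducer = build_transducer(), limits = pose_limits(),
                   cell = treatment_cell(), couch = couch_geometry())
  if (is.character(referral)) referral <- read_anatomy(referral)
  if (is.character(treatment)) treatment <- read_anatomy(treatment)
  if (inherits(referral, "hifu_phantom")) referral <- referral$anatomy
  if (inherits(treatment, "hifu_phantom")) treatment <- treatment$anatomy
  if (is.character(landmarks_referral))
    landmarks_referral <- read_landmarks(landmarks_referral)
  if (is.character(landmarks_treatment))
    landmarks_treatment <- read_landmarks(landmarks_treatment)

  ## 1. registration: referral -> treatment space
  tr <- fit_landmark_affine(landmarks_referral, landmarks_treatment)
  reg_error <- registration_error(
    transform_points(tr, landmark_matrix(landmarks_referral)),
    landmarks_treatment)
  ref_grid <- treatment$image
  regref <- list(
    image = apply_transform(referral$image, tr, ref_grid),
    body = apply_transform(referral$body, tr, ref_grid),
    bone = apply_transform(referral$bone, tr, ref_grid),
    target = apply_transform(referral$target, tr, ref_grid),
    oar = apply_transform(referral$oar, tr, ref_grid))

  ## 2. segmentation
  treat_body <- if (segment) segment_body_outline(treatment$image)
                else treatment$body
  treat_air <- if (segment)
    segment_extracorporeal_air(treatment$image, treat_body)
    else treatment$extracorporeal_air
  regref_body <- if (segment) segment_body_outline(regref$image)
                 else regref$body
  treatment_used <- labelled_anatomy(
    treatment$image, body = treat_body, bone = treatment$bone,
    target = treatment$target, extracorporeal_air = treat_air,
    oar = treatment$oar, couch = device$couch)

  ## 3. home-position estimation for the registered referral
  iso <- device$couch$isocentre
  skin <- find_skin_point(regref_body, c(iso[1], iso[3]))
  home_est <- estimate_home_position(skin, deformation, device$couch)
  couch_ref <- couch_at_home(home_est, device$couch)
  # referral prediction assumes perfect coupling: no interface air
  regref_used <- labelled_anatomy(
    regref$image, body = regref_body, bone = regref$bone,
    target = regref$target, extracorporeal_air = NULL, oar = regref$oar,
    couch = couch_ref)

  ## 4. coverage on both datasets
  if (is.null(search_bounds))
    search_bounds <- target_search_bounds(treatment_used$target,
                                          couch_home(device$couch))
  cov_treat <- compute_coverage(treatment_used, device$transducer,
                                device$limits, search_bounds, device$cell,
                                sample_spacing)
  cov_ref <- compute_coverage(regref_used, device$transducer,
                              device$limits, search_bounds, device$cell,
                              sample_spacing)

  ## 5. comparison (tvc_vol undefined when nothing is reachable at treatment)
  tvv <- if (sum(cov_treat$covered_mask$data) == 0L) NA_real_
         else tvc_vol(cov_ref$covered_mask, cov_treat$covered_mask)
  report <- structure(list(
    settings = list(
      deformation = unclass(deformation),
      limits = unclass(device$limits),
      cell = list(diameter = device$cell$diameter,
                  length = device$cell$length),
      sample_spacing = sample_spacing,
      search_bounds = search_bounds,
      segment = segment,
      version = as.character(utils::packageVersion("hifucover"))),
    registration = list(transform = tr, mean_landmark_error_mm = reg_error),
    home = list(skin_point = skin, estimated_home = home_est,
                isocentre = couch_ref$isocentre),
    coverage_referral = cov_ref,
    coverage_treatment = cov_treat,
    tvc_pat_referral = cov_ref$tvc_pat,
    tvc_pat_treatment = cov_treat$tvc_pat,
    tvc_pat_difference = cov_ref$tvc_pat - cov_treat$tvc_pat,
    tvc_vol = tvv),
    class = "hifu_report")
  if (!is.null(out)) write_report(report, out)
  report
}

#' @export
print.hifu_report <- function(x, ...) {
  cat(sprintf(paste0("<hifu_report>\n",
                     "  registration error   %.2f mm (mean landmark distance)\n",
                     "  estimated home       (%s) mm\n",
                     "  TVC referral         %.1f %%\n",
                     "  TVC treatment        %.1f %%\n",
                     "  TVC difference       %.1f %%\n",
                     "  TVC_vol agreement    %.1f %%\n"),
              x$registration$mean_landmark_error_mm,
              paste(sprintf("%.1f", x$home$estimated_home), collapse = ", "),
              x$tvc_pat_referral, x$tvc_pat_treatment,
              x$tvc_pat_difference, x$tvc_vol))
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' Writes `report.json` (settings and scalar results) and the two
#' covered-voxel masks as NIfTI.
#'
#' @param report a `hifu_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tr <- report$registration$transform
  j <- list(
    settings = report$settings,
    registration = list(matrix = as.numeric(t(tr$matrix)),
                        translation = tr$translation,
                        mean_landmark_error_mm =
                          report$registration$mean_landmark_error_mm),
    home = report$home,
    CV_mm3_referral = report$coverage_referral$covered_volume,
    CV_mm3_treatment = report$coverage_treatment$covered_volume,
    TV_mm3_referral = report$coverage_referral$total_target_volume,
    TV_mm3_treatment = report$coverage_treatment$total_target_volume,
    n_poses_tested = report$coverage_treatment$n_poses_tested,
    n_poses_clear_referral = report$coverage_referral$n_poses_clear,
    n_poses_clear_treatment = report$coverage_treatment$n_poses_clear,
    tvc_pat_referral = report$tvc_pat_referral,
    tvc_pat_treatment = report$tvc_pat_treatment,
    tvc_pat_difference = report$tvc_pat_difference,
    tvc_vol = report$tvc_vol)
  jsonlite::write_json(j, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  write_mask(report$coverage_referral$covered_mask,
             file.path(dir, "covered_referral.nii.gz"))
  write_mask(report$coverage_treatment$covered_mask,
             file.path(dir, "covered_treatment.nii.gz"))
  invisible(dir)
}
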