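# Automated image quality control: numeric analogues of the masked
# reader's exclusion criteria, with the exclusion-reason taxonomy
# (projection, blur, motion, signal loss, low quality score, poor
# centration, segmentation error).

#' Extract the large-vessel mask from an SCP angiogram
#'
#' Binarizes the SCP image, removes capillary-scale structure by
#' morphological opening at the caliber threshold, and drops small
#' residual components, leaving only the major arterioles/venules.
#'
#' @param scp An SCP [enface_angiogram()].
#' @param caliber_mm Minimum vessel caliber retained, in mm.
#' @param min_area_mm2 Minimum component area retained, in mm^2.
#' @return Logical matrix (TRUE under large vessels).
#' @export
scp_large_vessel_mask <- function(scp, caliber_mm = 0.04, min_area_mm2 = 0.02) {
  check_angiogram(scp, "scp")
  px <- pixel_size_mm(scp)
  bin <- adaptive_binarize(scp$pixels, px)
  brush <- EBImage::makeBrush(odd_size(caliber_mm / px), "disc")
  opened <- EBImage::opening(bin, brush) > 0
  lab <- label_components(opened, connectivity = 4)
  if (max(lab) == 0) return(opened)
  areas <- component_areas_mm2(lab, px)
  keep <- which(areas >= min_area_mm2)
  matrix(lab %in% keep & lab > 0, nrow(opened))
}

#' Detect projection artifacts on a DCP image
#'
#' Two-step analogue of side-by-side SCP/DCP reading. Step 1 extracts
#' the SCP large-vessel mask and measures DCP intensity co-elevation
#' under that mask versus the off-mask background. Step 2 checks
#' whether the co-located elevated DCP structure is continuous vessel
#' (high binarized coverage of the mask) rather than a series of
#' vortexes with converged capillaries. The score is the product of the
#' two terms, in \[0, 1\].
#'
#' @param dcp,scp DCP and SCP [enface_angiogram()]s of the same eye and
#'   geometry.
#' @param threshold Flag when score exceeds this value.
#' @return A list `score`, `flag`.
#' @export
detect_projection_artifact <- function(dcp, scp, threshold = 0.25) {
  check_angiogram(dcp, "dcp"); check_angiogram(scp, "scp")
  check_same_geometry(dcp, scp)
  mask <- scp_large_vessel_mask(scp)
  if (mean(mask) < 0.005) return(list(score = 0, flag = FALSE))
  x <- dcp$pixels / 255
  coelev <- clamp((mean(x[mask]) - mean(x[!mask])) / 0.15, 0, 1)
  vb <- adaptive_binarize(dcp$pixels, pixel_size_mm(dcp))
  coverage <- mean(vb[mask])
  score <- coelev * coverage
  list(score = score, flag = score > threshold)
}

#' Detect motion artifacts
#'
#' Scores vessel discontinuity between adjacent rows together with
#' bright residual motion lines. A lateral row-block displacement
#' destroys the registration of the vascular texture across the break,
#' so the correlation between the two adjacent rows spanning it
#' collapses, while undisturbed texture keeps a high row-to-row
#' correlation; the discontinuity term rescales the minimum adjacent-row
#' correlation against `floor_cor`. Residual motion lines are rows whose
#' mean intensity is a strong positive outlier. A uniform shift of the
#' whole image scores zero: only relative displacement between rows
#' counts. Near-zero (signal-loss) rows are ignored so a blink band is
#' not mistaken for motion.
#'
#' @param img An [enface_angiogram()].
#' @param threshold Flag when score exceeds this value.
#' @param floor_cor Adjacent-row correlation below which the
#'   discontinuity term saturates.
#' @param dark_level Row-mean level (0-1 scale) under which rows are
#'   excluded from the discontinuity term.
#' @return A list `score`, `flag`.
#' @export
detect_motion_artifact <- function(img, threshold = 0.5, floor_cor = 0.5,
                                   dark_level = 0.05) {
  check_angiogram(img)
  x <- img$pixels / 255
  n <- img$n_px
  rm_ <- rowMeans(x)
  keep <- rm_ >= dark_level
  cors <- rep(NA_real_, n - 1)
  for (i in seq_len(n - 1)) {
    if (!keep[i] || !keep[i + 1]) next
    a <- x[i, ]; b <- x[i + 1, ]
    if (sd(a) == 0 || sd(b) == 0) next
    cors[i] <- stats::cor(a, b)
  }
  disc_score <- if (all(is.na(cors))) 0 else {
    clamp((floor_cor - min(cors, na.rm = TRUE)) / floor_cor, 0, 1)
  }
  madv <- mad(rm_)
  line_score <- if (madv == 0) 0 else {
    clamp((max(rm_) - median(rm_)) / madv / 12, 0, 1)
  }
  score <- max(disc_score, line_score)
  list(score = score, flag = score > threshold)
}

#' Detect blur
#'
#' Focus measure: the fraction of image energy in high spatial
#' frequencies (residual after Gaussian smoothing, normalized by the
#' image contrast). Blurry images have low scores; the flag fires when
#' the score falls *below* the threshold. A constant image scores 0.
#'
#' @param img An [enface_angiogram()].
#' @param threshold Flag when score is below this value.
#' @return A list `score`, `flag`.
#' @export
detect_blur <- function(img, threshold = 0.35) {
  check_angiogram(img)
  x <- img$pixels / 255
  s <- sd(x)
  if (s == 0) return(list(score = 0, flag = TRUE))
  hf <- x - EBImage::gblur(x, sigma = 2)
  score <- sd(hf) / s
  list(score = score, flag = score < threshold)
}

#' Detect signal loss
#'
#' Score is the longest run of contiguous rows whose mean intensity
#' falls below `dark_level`, as a fraction of the image height (an
#' all-zero image scores 1).
#'
#' @param img An [enface_angiogram()].
#' @param threshold Flag when score exceeds this value.
#' @param dark_level Row-mean darkness cutoff on the 0-1 scale.
#' @return A list `score`, `flag`.
#' @export
detect_signal_loss <- function(img, threshold = 0.08, dark_level = 0.05) {
  check_angiogram(img)
  dark <- rowMeans(img$pixels / 255) < dark_level
  run <- 0L
  if (any(dark)) {
    r <- rle(dark)
    run <- max(r$lengths[r$values])
  }
  score <- run / img$n_px
  list(score = score, flag = score > threshold)
}

#' Check foveal centration
#'
#' Locates the FAZ (largest central dark region of the binarized DCP
#' image) and measures the offset of its centroid from the image
#' center. The flag fires when the offset strictly exceeds
#' `threshold_mm`; an undetectable fovea is flagged with `NA` offset.
#'
#' @param dcp A DCP [enface_angiogram()].
#' @param threshold_mm Offset tolerance in mm (default 0.5).
#' @return A list `offset_mm`, `flag`.
#' @export
check_centration <- function(dcp, threshold_mm = 0.5) {
  check_angiogram(dcp, "dcp")
  vm <- binarize_angiogram(preprocess_angiogram(dcp))
  f <- locate_faz(vm, search_mm = max(1, threshold_mm * 2.5))
  if (is.null(f)) return(list(offset_mm = NA_real_, flag = TRUE))
  offset <- sqrt(sum(f$centroid_mm^2))
  list(offset_mm = offset, flag = offset > threshold_mm)
}

qc_reason_priority <- c("projection", "blur", "motion", "signal_loss",
                        "low_quality", "off_center", "seg_error")

#' Run the full quality-control battery on one eye
#'
#' Applies every artifact detector plus the metadata checks (device
#' quality score below `min_quality`, segmentation-error flag) and
#' produces a one-row QC report. The exclusion flags are the union of
#' the detector flags; `primary_reason` is the first triggered reason in
#' the fixed priority order projection > blur > motion > signal_loss >
#' low_quality > off_center > seg_error. When `scp` is missing the
#' projection check is recorded as not assessed (`NA`), and the image is
#' not auto-passed.
#'
#' @param dcp A DCP [enface_angiogram()].
#' @param scp The paired SCP [enface_angiogram()], or `NULL`.
#' @param min_quality Images with `quality_score` strictly below this
#'   are excluded (default 40).
#' @param projection_threshold,blur_threshold,motion_threshold,
#'   signal_loss_threshold,centration_threshold_mm Detector thresholds.
#' @return A one-row tibble of class `qc_report` with per-check scores,
#'   logical flags, `excluded`, and `primary_reason` (`NA` when not
#'   excluded).
#' @export
#' @examples
#' pair <- generate_dcp_angiogram(seed = 3)
#' scp <- generate_scp_angiogram(seed = 4)
#' apply_qc(pair$image, scp$image)
apply_qc <- function(dcp, scp = NULL, min_quality = 40,
                     projection_threshold = 0.25, blur_threshold = 0.35,
                     motion_threshold = 0.3, signal_loss_threshold = 0.08,
                     centration_threshold_mm = 0.5) {
  check_angiogram(dcp, "dcp")
  if (!is.null(scp)) {
    proj <- detect_projection_artifact(dcp, scp, projection_threshold)
  } else {
    proj <- list(score = NA_real_, flag = NA)
  }
  blur <- detect_blur(dcp, blur_threshold)
  mot <- detect_motion_artifact(dcp, motion_threshold)
  sl <- detect_signal_loss(dcp, signal_loss_threshold)
  cen <- check_centration(dcp, centration_threshold_mm)
  flags <- c(
    projection = isTRUE(proj$flag),
    blur = blur$flag,
    motion = mot$flag,
    signal_loss = sl$flag,
    low_quality = dcp$quality_score < min_quality,
    off_center = cen$flag,
    seg_error = isTRUE(dcp$seg_error)
  )
  excluded <- any(flags)
  primary <- if (excluded) qc_reason_priority[which(flags)[1]] else NA_character_
  out <- tibble(
    eye_id = dcp$eye_id, subject_id = dcp$subject_id,
    session_id = dcp$session_id,
    projection_score = proj$score, projection = proj$flag,
    blur_score = blur$score, blur = blur$flag,
    motion_score = mot$score, motion = mot$flag,
    signal_loss_score = sl$score, signal_loss = sl$flag,
    centration_offset_mm = cen$offset_mm, off_center = cen$flag,
    quality_score = dcp$quality_score, low_quality = flags[["low_quality"]],
    seg_error = flags[["seg_error"]],
    excluded = excluded, primary_reason = primary
  )
  class(out) <- c("qc_report", class(out))
  out
}

#' QC a batch of image pairs
#'
#' @param pairs A list whose elements are lists with components `dcp`
#'   and (optionally) `scp`.
#' @param ... Passed to [apply_qc()].
#' @return A `qc_report` tibble with one row per pair.
#' @export
qc_batch <- function(pairs, ...) {
  out <- dplyr::bind_rows(
    purrr::map(pairs, function(p) apply_qc(p$dcp, p$scp %||% NULL, ...))
  )
  class(out) <- c("qc_report", class(out))
  out
}

#' Arithmetic of a QC exclusion flow
#'
#' Summarizes an exclusion flow from per-reason exclusion counts and the
#' number of eligible eyes: total excluded, exclusion percentage, and
#' the number of included eyes.
#'
#' @param reasons Named integer vector of per-reason exclusion counts.
#' @param n_eligible Number of eligible eyes before QC.
#' @return A one-row tibble: `n_eligible`, `n_excluded`, `pct_excluded`,
#'   `n_included`.
#' @export
#' @examples
#' qc_flow_summary(c(projection = 53, blur = 67, motion = 27,
#'                   signal_loss = 10, low_quality = 8, off_center = 1),
#'                 n_eligible = 563)
qc_flow_summary <- function(reasons, n_eligible) {
  stopifnot(is.numeric(reasons), n_eligible > 0)
  n_exc <- sum(reasons)
  tibble(
    n_eligible = n_eligible,
    n_excluded = n_exc,
    pct_excluded = 100 * n_exc / n_eligible,
    n_included = n_eligible - n_exc
  )
}

#' Group percentages over a set of counts
#'
#' @param counts Named integer vector (e.g. eyes per DR-severity level).
#' @param total Denominator; defaults to `sum(counts)`.
#' @return A tibble `level`, `n`, `pct`.
#' @export
group_percentages <- function(counts, total = sum(counts)) {
  tibble(
    level = names(counts) %||% as.character(seq_along(counts)),
    n = as.numeric(counts),
    pct = 100 * as.numeric(counts) / total
  )
}

#' @export
autoplot.qc_report <- function(object, ...) {
  df <- dplyr::count(
    dplyr::filter(as_tibble(object), .data$excluded),
    .data$primary_reason
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$primary_reason, -.data$n), y = .data$n
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "primary exclusion reason", y = "eyes excluded",
                  title = "QC exclusions by reason") +
    ggplot2::theme_minimal()
}
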