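dcp_fix <- generate_dcp_angiogram(seed = 101)$image
scp_fix <- generate_scp_angiogram(seed = 102)$image

test_that("projection detector separates clean pairs from projected ones", {
  clean <- detect_projection_artifact(dcp_fix, scp_fix)
  expect_false(clean$flag)

  proj <- inject_artifact(dcp_fix, "projection", 1, aux = scp_fix)
  hit <- detect_projection_artifact(proj, scp_fix)
  expect_true(hit$flag)
  expect_gt(hit$score, clean$score)

  # degenerate copy: DCP identical to SCP is maximal co-localization
  twin <- scp_fix
  twin$layer <- "DCP"
  expect_true(detect_projection_artifact(twin, scp_fix)$flag)

  small <- enface_angiogram(matrix(0, 64, 64))
  expect_error(detect_projection_artifact(small, scp_fix),
               class = "deepangio_incompatible_images")
})

test_that("motion detector sees discontinuity but ignores global shifts", {
  flat <- enface_angiogram(matrix(100, 320, 320))
  m0 <- detect_motion_artifact(flat)
  expect_equal(m0$score, 0)
  expect_false(m0$flag)

  expect_false(detect_motion_artifact(dcp_fix)$flag)
  moved <- inject_artifact(dcp_fix, "motion", 8, seed = 3)
  expect_true(detect_motion_artifact(moved)$flag)

  # uniform lateral shift of the whole image is not discontinuity
  glob <- dcp_fix
  glob$pixels <- dcp_fix$pixels[, c(6:320, 1:5)]
  expect_false(detect_motion_artifact(glob)$flag)
})

test_that("blur detector is a monotone focus measure", {
  clean <- detect_blur(dcp_fix)
  smoothed <- detect_blur(inject_artifact(dcp_fix, "blur", 3))
  expect_lt(smoothed$score, clean$score)
  expect_false(clean$flag)
  expect_true(smoothed$flag)

  flat <- enface_angiogram(matrix(50, 64, 64))
  b <- detect_blur(flat)
  expect_equal(b$score, 0)
  expect_true(b$flag)
})

test_that("signal-loss score is the dark-row run fraction", {
  zero <- enface_angiogram(matrix(0, 320, 320))
  z <- detect_signal_loss(zero)
  expect_equal(z$score, 1)
  expect_true(z$flag)

  expect_false(detect_signal_loss(dcp_fix)$flag)

  banded <- inject_artifact(dcp_fix, "signal_loss", 40 / 320, seed = 4)
  s <- detect_signal_loss(banded)
  expect_equal(s$score, 0.125)
  expect_true(s$flag)
})

test_that("centration flags only offsets strictly beyond the threshold", {
  centred <- check_centration(dcp_fix)
  expect_lt(centred$offset_mm, 0.05)
  expect_false(centred$flag)

  off <- generate_dcp_angiogram(faz_center_mm = c(0.8, 0.6), seed = 103)$image
  expect_true(check_centration(off)$flag)

  # boundary convention: offset exactly at threshold passes
  expect_false(check_centration(dcp_fix, threshold_mm = centred$offset_mm)$flag)
})

test_that("apply_qc applies the quality-score rule strictly below 40", {
  q39 <- generate_dcp_angiogram(seed = 104, quality_score = 39)$image
  r39 <- apply_qc(q39, scp_fix)
  expect_true(r39$excluded)
  expect_equal(r39$primary_reason, "low_quality")

  q40 <- generate_dcp_angiogram(seed = 104, quality_score = 40)$image
  r40 <- apply_qc(q40, scp_fix)
  expect_false(r40$excluded)
  expect_true(is.na(r40$primary_reason))
})

test_that("apply_qc unions detector flags with the fixed reason priority", {
  seg <- generate_dcp_angiogram(seed = 105, seg_error = TRUE,
                                quality_score = 30)$image
  r <- apply_qc(seg, scp_fix)
  expect_true(r$excluded)
  expect_equal(r$primary_reason, "low_quality")  # low_quality precedes seg_error

  # missing SCP: projection not assessed, image not auto-passed
  rm_scp <- apply_qc(seg, NULL)
  expect_true(is.na(rm_scp$projection_score))
  expect_true(rm_scp$excluded)
})

test_that("a mixed batch excludes exactly the artifact eyes with matching reasons", {
  pairs <- list()
  injected <- character(10)
  for (i in 1:10) {
    d <- generate_dcp_angiogram(seed = 200 + i, eye_id = sprintf("eye%02d", i))$image
    if (i == 3) { d <- inject_artifact(d, "projection", 1, aux = scp_fix); injected[i] <- "projection" }
    if (i == 6) { d <- inject_artifact(d, "blur", 3); injected[i] <- "blur" }
    if (i == 9) { d <- inject_artifact(d, "signal_loss", 0.125, seed = i); injected[i] <- "signal_loss" }
    pairs[[i]] <- list(dcp = d, scp = scp_fix)
  }
  rep_ <- qc_batch(pairs)
  expect_equal(sum(rep_$excluded), 3)
  expect_equal(rep_$primary_reason[rep_$excluded],
               injected[injected != ""])
  expect_true(all(rep_$excluded == !is.na(rep_$primary_reason)))
})

test_that("QC flow arithmetic reproduces exclusion totals and percentages", {
  fl <- qc_flow_summary(
    c(projection = 53, blur = 67, motion = 27, signal_loss = 10,
      low_quality = 8, off_center = 1),
    n_eligible = 563
  )
  expect_equal(fl$n_excluded, 166)
  expect_equal(fl$n_included, 397)
  expect_equal(fl$pct_excluded, 100 * 166 / 563, tolerance = 1e-12)

  gp <- group_percentages(c(none = 170, mild = 101, moderate = 90, severe = 36))
  expect_equal(sum(gp$n), 397)
  expect_equal(gp$pct[gp$level == "mild"], 100 * 101 / 397)
})
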