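test_that("preprocessing at strength zero is the identity and reduces noise", {
  d <- generate_dcp_angiogram(noise_sd = 0, seed = 8)$image
  expect_identical(preprocess_angiogram(d, 0)$pixels, d$pixels)
  noisy <- d
  set.seed(1)
  noisy$pixels <- pmin(pmax(d$pixels + rnorm(length(d$pixels), 0, 20), 0), 255)
  mse_before <- mean((noisy$pixels - d$pixels)^2)
  mse_after <- mean((preprocess_angiogram(noisy, 1)$pixels - d$pixels)^2)
  expect_lt(mse_after, mse_before)
  expect_identical(preprocess_angiogram(noisy, 1)$pixels,
                   preprocess_angiogram(noisy, 1)$pixels)
})

test_that("adaptive binarization is exact on a bimodal image and offset-invariant", {
  n <- 64
  truth <- matrix(FALSE, n, n)
  set.seed(3)
  for (k in 1:12) {
    i <- sample(5:(n - 5), 1); j <- sample(5:(n - 5), 1)
    truth[i + (-1:1), j + (0:3)] <- TRUE   # thin bars, below window scale
  }
  img <- enface_angiogram(ifelse(truth, 200, 20), width_mm = 3 * n / 320)
  vm <- binarize_angiogram(img)
  expect_identical(vm$mask, truth)

  shifted <- img
  shifted$pixels <- img$pixels + 30
  expect_identical(binarize_angiogram(shifted)$mask, vm$mask)

  flat <- enface_angiogram(matrix(77, n, n), width_mm = 3 * n / 320)
  expect_false(any(binarize_angiogram(flat)$mask))
})

test_that("FAZ area is pixel count times pixel area, with circle recovery", {
  d <- generate_dcp_angiogram(faz_radius_mm = 0.3, seed = 21)
  vm <- binarize_angiogram(preprocess_angiogram(d$image))
  f <- segment_faz(vm)
  expect_equal(f$faz_area_mm2, sum(f$region) * vm$pixel_size_mm^2)
  expect_lt(abs(f$faz_area_mm2 - pi * 0.3^2) / (pi * 0.3^2), 0.1)

  # 1024-px region arithmetic (closing disabled so the count is exact)
  mask <- matrix(TRUE, 320, 320)
  mask[145:176, 145:176] <- FALSE  # 32 x 32 = 1024 dark px at the center
  f2 <- segment_faz(make_vm(mask), closing_mm = 0)
  expect_equal(f2$faz_area_mm2, 1024 * (3 / 320)^2)

  expect_error(segment_faz(make_vm(matrix(TRUE, 320, 320))),
               class = "deepangio_no_faz")
})

test_that("vessel density matches the brute-force per-pixel oracle", {
  px <- 3 / 320
  # rectangle centred in the annulus: 15x15 px = 0.0198 mm^2 (below cutoff)
  base <- matrix(TRUE, 320, 320)
  ij <- function(x_mm, y_mm) {
    c(round(y_mm / px + 160.5), round(x_mm / px + 160.5))
  }
  at <- ij(0.9, 0)
  m1 <- base
  m1[at[1] + (0:14), at[2] + (0:14)] <- FALSE
  expect_equal(compute_vd(make_vm(m1)), 100)
  expect_equal(compute_vd(make_vm(m1)), vd_oracle(m1, px))

  # 16x15 px = 0.0211 mm^2 (above cutoff): subtracted from the annulus
  m2 <- base
  m2[at[1] + (0:15), at[2] + (0:14)] <- FALSE
  vd2 <- compute_vd(make_vm(m2))
  expect_lt(vd2, 100)
  expect_equal(vd2, vd_oracle(m2, px), tolerance = 1e-12)

  # disc of ~0.0628 mm^2 wholly inside the annulus -> about 99.0
  r <- deepangio:::radial_dist_mm(320, 3, c(0.9, 0))
  m3 <- base
  m3[r < sqrt(0.0628 / pi)] <- FALSE
  vd3 <- compute_vd(make_vm(m3))
  expect_equal(vd3, vd_oracle(m3, px), tolerance = 1e-12)
  expect_equal(vd3, 100 * (1 - 0.0628 / (2 * pi)), tolerance = 0.05)

  # fully perfused
  expect_equal(compute_vd(make_vm(base)), 100)
  # scan too small for the annulus
  expect_error(compute_vd(make_vm(matrix(TRUE, 64, 64), px_mm = 0.009375)),
               class = "deepangio_annulus_oob")
})

test_that("a component straddling the annulus is classified by total area", {
  px <- 3 / 320
  base <- matrix(TRUE, 320, 320)
  # 0.018 mm^2 inside the annulus + 0.01 mm^2 outside, one 4-connected
  # component of total 0.028 mm^2 > cutoff: its annulus overlap counts
  m <- base
  # 8 x 44 px band at y ~ 0 spanning x in 0.29-0.70 mm: total 0.031 mm^2
  # straddles the 0.5 mm inner rim
  m[157:164, 192:235] <- FALSE
  vd <- compute_vd(make_vm(m))
  expect_equal(vd, vd_oracle(m, px), tolerance = 1e-12)
  expect_lt(vd, 100)
})

test_that("skeletonization thins to 1 px and preserves component count", {
  line <- matrix(FALSE, 64, 64); line[32, 5:60] <- TRUE
  expect_identical(skeletonize_vessels(make_vm(line))$mask, line)

  rect <- matrix(FALSE, 120, 120); rect[50:69, 10:109] <- TRUE
  sk <- skeletonize_vessels(make_vm(rect))$mask
  expect_true(all(sk[rect == FALSE] == FALSE))
  expect_equal(max(igraph_label(sk, 8)), 1)
  # 1-px wide: no 2x2 block fully on
  blocks <- sk[-1, -1] & sk[-nrow(sk), -1] & sk[-1, -ncol(sk)] & sk[-nrow(sk), -ncol(sk)]
  expect_false(any(blocks))

  set.seed(11)
  for (rep in 1:10) {
    noise <- matrix(runif(64^2), 64, 64)
    blobs <- EBImage::gblur(noise, 3) > quantile(EBImage::gblur(noise, 3), 0.8)
    sk2 <- skeletonize_vessels(make_vm(blobs))$mask
    expect_equal(max(igraph_label(sk2, 8)), max(igraph_label(blobs, 8)))
  }
})

test_that("box-counting dimension hits its analytic limits", {
  n <- 320
  line <- matrix(FALSE, n, n); line[160, ] <- TRUE
  expect_equal(compute_fd(make_skel(line)), 1, tolerance = 0.05)
  expect_equal(compute_fd(make_skel(matrix(TRUE, n, n))), 2, tolerance = 0.05)
  expect_equal(compute_fd(make_skel(sierpinski_mask(8))),
               log(3) / log(2), tolerance = 0.05)
  expect_error(compute_fd(make_skel(matrix(FALSE, n, n))),
               class = "deepangio_empty_skeleton")
})

test_that("FD is stable under translation and source intensity rescaling", {
  d <- generate_dcp_angiogram(seed = 9)$image
  vm <- binarize_angiogram(preprocess_angiogram(d))
  sk <- skeletonize_vessels(vm)$mask
  fd0 <- compute_fd(make_skel(sk))
  shifted <- matrix(FALSE, 320, 320)
  shifted[6:320, 8:320] <- sk[1:315, 1:313]
  expect_equal(compute_fd(make_skel(shifted)), fd0, tolerance = 0.02)

  rescaled <- d
  rescaled$pixels <- d$pixels * 0.7
  q1 <- quantify_dcp(d); q2 <- quantify_dcp(rescaled)
  expect_equal(q2$fd, q1$fd, tolerance = 0.02)
})

test_that("quantify_dcp recovers ground truth and is deterministic", {
  d <- generate_dcp_angiogram(faz_radius_mm = 0.3, seed = 30)
  q <- quantify_dcp(d$image)
  expect_lt(abs(q$faz_area_mm2 - d$truth$faz_area_mm2) / d$truth$faz_area_mm2, 0.1)
  expect_gte(q$vd_pct, 99)
  expect_true(q$fd > 1 && q$fd < 2)
  expect_identical(q, quantify_dcp(d$image))

  # vessel density non-increasing across a dropout sweep
  vd <- sapply(c(0, 0.03, 0.06, 0.1, 0.15), function(a) {
    ds <- if (a > 0) data.frame(area_mm2 = a, x_mm = 0.9, y_mm = 0.4) else NULL
    quantify_dcp(generate_dcp_angiogram(dropout_spec = ds, seed = 31)$image)$vd_pct
  })
  expect_true(all(diff(vd) <= 0))
})
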