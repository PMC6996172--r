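# Synthetic en-face angiogram generators.
#
# The DCP texture emulates the deep plexus morphology: capillaries
# arranged as polygonal (Voronoi-like) units whose capillaries radially
# converge on a "vortex" epicenter, with a capillary-free foveal zone
# bounded by a perifoveal capillary ring. The SCP texture is a finer
# polygonal capillary mesh plus smoothly curving large arterioles /
# venules arranged as arcades around the fovea.

# Voronoi-cell capillary texture in [0, 1]; consumes RNG state.
vortex_texture <- function(n_px, width_mm, cell_mm = 0.2,
                           arm_width_mm = 0.011, edge_width_mm = 0.011,
                           arms = TRUE) {
  g <- pixel_grid_mm(n_px, width_mm)
  X <- g$x; Y <- g$y
  half <- width_mm / 2
  ng <- max(1L, ceiling(width_mm / cell_mm))
  nge <- ng + 2L                       # one padding cell each side
  jit <- 0.38 * cell_mm
  cell_center <- (seq_len(nge) - 1.5) * cell_mm - half
  ex <- matrix(cell_center, nge, nge) + matrix(runif(nge^2, -jit, jit), nge, nge)
  ey <- matrix(cell_center, nge, nge, byrow = TRUE) +
    matrix(runif(nge^2, -jit, jit), nge, nge)
  n_arms <- matrix(sample(5:8, nge^2, replace = TRUE), nge, nge)
  phase <- matrix(runif(nge^2, 0, 2 * pi), nge, nge)
  swirl <- matrix(runif(nge^2, 1.5, 3.5) *
                    sample(c(-1, 1), nge^2, replace = TRUE), nge, nge)

  gx <- pmin(pmax(floor((X + half) / cell_mm), 0), ng - 1) + 2L
  gy <- pmin(pmax(floor((Y + half) / cell_mm), 0), ng - 1) + 2L
  d1 <- matrix(Inf, n_px, n_px)
  d2 <- d1
  nearest <- matrix(1L, n_px, n_px)
  for (da in -1L:1L) {
    for (db in -1L:1L) {
      li <- (gy + db - 1L) * nge + (gx + da)   # linear index into cell grids
      dd <- (X - ex[li])^2 + (Y - ey[li])^2
      closer <- dd < d1
      tmp <- pmin(d2, dd)
      tmp[closer] <- d1[closer]
      d2 <- tmp
      d1[closer] <- dd[closer]
      nearest[closer] <- li[closer]
    }
  }
  d1 <- sqrt(d1); d2 <- sqrt(d2)
  # capillaries along cell boundaries (closed polygonal loops)
  tex <- exp(-(((d2 - d1) / 2) / edge_width_mm)^2)
  if (arms) {
    rx <- X - ex[nearest]; ry <- Y - ey[nearest]
    r <- d1
    na <- n_arms[nearest]
    u <- na * (atan2(ry, rx) + swirl[nearest] * r) + phase[nearest]
    ang <- ((u + pi) %% (2 * pi)) - pi
    arc <- r * abs(ang) / na          # physical distance to the arm ridge
    tex <- pmax(tex, exp(-(arc / arm_width_mm)^2))
    tex <- pmax(tex, exp(-(r / 0.02)^2))   # converged capillaries at the vortex
  }
  tex
}

# carve the avascular zone and draw its bounding capillary ring
apply_faz <- function(tex, n_px, width_mm, faz_radius_mm, center_mm) {
  if (faz_radius_mm <= 0) return(tex)
  r <- radial_dist_mm(n_px, width_mm, center_mm)
  tex[r < faz_radius_mm] <- 0
  ring <- exp(-((r - faz_radius_mm - 0.006) / 0.009)^2)
  outside <- r >= faz_radius_mm
  tex[outside] <- pmax(tex[outside], ring[outside])
  tex
}

normalize_dropout_spec <- function(dropout_spec) {
  if (is.null(dropout_spec) || (is.data.frame(dropout_spec) && nrow(dropout_spec) == 0)) {
    return(tibble(area_mm2 = numeric(), x_mm = numeric(), y_mm = numeric()))
  }
  ds <- as_tibble(dropout_spec)
  stopifnot(all(c("area_mm2", "x_mm", "y_mm") %in% names(ds)))
  if (any(ds$area_mm2 <= 0)) abort("dropout areas must be positive")
  ds
}

#' Generate a synthetic deep capillary plexus angiogram
#'
#' Renders a DCP en-face angiogram with vortex-patterned capillary
#' texture (polygonal cells whose capillaries converge on an epicenter),
#' a central dark foveal avascular zone of known radius bounded by a
#' capillary ring, optional capillary-dropout (non-perfusion) regions,
#' and additive Gaussian acquisition noise. The ground truth of every
#' injected feature is returned alongside the image, so downstream
#' quality control and quantification can be validated against it.
#'
#' @param faz_radius_mm True FAZ radius in mm; must be `>= 0` and
#'   `< width_mm / 2`.
#' @param vortex_density Vortex (capillary cell) density per mm^2; the
#'   cell pitch is `1 / sqrt(vortex_density)` mm.
#' @param dropout_spec Optional data frame of non-perfusion regions with
#'   columns `area_mm2`, `x_mm`, `y_mm` (disc of the given area at the
#'   given centre). Regions must not overlap the FAZ.
#' @param noise_sd Additive Gaussian noise SD on the 0-255 intensity scale.
#' @param n_px,width_mm Image geometry (default 320 px over 3 mm).
#' @param faz_center_mm Length-2 mm offset of the FAZ centre from the
#'   image centre (non-zero values emulate poor fixation / decentration).
#' @param quality_score,seg_error,eye_id,subject_id,session_id Metadata
#'   passed to [enface_angiogram()]. The quality score is assigned, not
#'   computed (the device metric is proprietary).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and `seed`.
#'
#' @return A list with elements `image` (an [enface_angiogram()]) and
#'   `truth`, a `ground_truth` list with `faz_area_mm2`, `faz_center_mm`,
#'   `dropout` (tibble of injected regions), `artifact_labels`, `seed`.
#' @export
#' @examples
#' d <- generate_dcp_angiogram(faz_radius_mm = 0.3, seed = 1)
#' d$truth$faz_area_mm2   # pi * 0.3^2
generate_dcp_angiogram <- function(faz_radius_mm = 0.3, vortex_density = 25,
                                   dropout_spec = NULL, noise_sd = 8,
                                   n_px = 320L, width_mm = 3,
                                   faz_center_mm = c(0, 0),
                                   quality_score = 60L, seg_error = FALSE,
                                   eye_id = "eye01", subject_id = "subj01",
                                   session_id = "visit1_scan1", seed = 1L) {
  if (n_px <= 0 || width_mm <= 0) {
    abort("invalid geometry: n_px and width_mm must be positive",
          class = "deepangio_invalid_geometry")
  }
  if (faz_radius_mm < 0 || faz_radius_mm >= width_mm / 2) {
    abort("`faz_radius_mm` must be in [0, width_mm / 2)")
  }
  ds <- normalize_dropout_spec(dropout_spec)
  if (nrow(ds)) {
    dcent <- sqrt((ds$x_mm - faz_center_mm[1])^2 + (ds$y_mm - faz_center_mm[2])^2)
    if (any(dcent < sqrt(ds$area_mm2 / pi) + faz_radius_mm)) {
      abort("dropout regions must not overlap the FAZ")
    }
  }
  cell_mm <- 1 / sqrt(vortex_density)
  pixels <- withr::with_seed(seed, {
    tex <- vortex_texture(n_px, width_mm, cell_mm = cell_mm)
    tex <- apply_faz(tex, n_px, width_mm, faz_radius_mm, faz_center_mm)
    if (nrow(ds)) {
      for (k in seq_len(nrow(ds))) {
        r <- radial_dist_mm(n_px, width_mm, c(ds$x_mm[k], ds$y_mm[k]))
        tex[r < sqrt(ds$area_mm2[k] / pi)] <- 0
      }
    }
    clamp(30 + 180 * tex + rnorm(n_px^2, 0, noise_sd), 0, 255)
  })
  labels <- character()
  if (sqrt(sum(faz_center_mm^2)) > 0.5) labels <- "off_center"
  img <- enface_angiogram(
    pixels, width_mm = width_mm, layer = "DCP",
    quality_score = quality_score, seg_error = seg_error,
    eye_id = eye_id, subject_id = subject_id, session_id = session_id,
    artifacts = labels
  )
  truth <- structure(
    list(
      faz_area_mm2 = pi * faz_radius_mm^2,
      faz_center_mm = faz_center_mm,
      dropout = ds,
      artifact_labels = labels,
      seed = seed
    ),
    class = "ground_truth"
  )
  list(image = img, truth = truth)
}

#' Generate a synthetic superficial capillary plexus angiogram
#'
#' Renders an SCP en-face angiogram: a fine polygonal capillary mesh
#' plus `n_major_vessels` smoothly curving, continuous large vessels
#' (arterioles/venules) arranged as arcades around the fovea, each of
#' caliber at least `vessel_caliber_px`. The returned ground truth
#' carries the large-vessel mask, which drives projection-artifact
#' injection and detection.
#'
#' @param n_major_vessels Number of large vessels (`>= 0`).
#' @param vessel_caliber_px Vessel caliber (width) in pixels.
#' @param faz_radius_mm SCP FAZ radius in mm.
#' @param noise_sd,n_px,width_mm,quality_score,eye_id,subject_id,session_id,seed
#'   As in [generate_dcp_angiogram()].
#' @return A list `image` / `truth`; `truth$large_vessel_mask` is a
#'   logical matrix.
#' @export
generate_scp_angiogram <- function(n_major_vessels = 4, vessel_caliber_px = 6,
                                   faz_radius_mm = 0.25, noise_sd = 8,
                                   n_px = 320L, width_mm = 3,
                                   quality_score = 60L,
                                   eye_id = "eye01", subject_id = "subj01",
                                   session_id = "visit1_scan1", seed = 1L) {
  if (n_px <= 0 || width_mm <= 0 || vessel_caliber_px > n_px) {
    abort("invalid geometry: check n_px, width_mm, vessel_caliber_px",
          class = "deepangio_invalid_geometry")
  }
  if (n_major_vessels < 0) abort("`n_major_vessels` must be >= 0")
  s <- width_mm / n_px
  half <- width_mm / 2
  out <- withr::with_seed(seed, {
    tex <- vortex_texture(n_px, width_mm, cell_mm = 0.13,
                          edge_width_mm = 0.012, arms = FALSE)
    tex <- apply_faz(tex, n_px, width_mm, faz_radius_mm, c(0, 0))
    mask <- matrix(FALSE, n_px, n_px)
    if (n_major_vessels > 0) {
      path <- matrix(FALSE, n_px, n_px)
      base <- runif(1, 0, 2 * pi)
      wsec <- (2 * pi / n_major_vessels) * 0.38  # half-width of each sector
      for (k in seq_len(n_major_vessels)) {
        # gently curving radial vessel confined to its own angular sector
        phi0 <- base + 2 * pi * (k - 1) / n_major_vessels
        tpar <- seq(0, 1, length.out = 800)
        curv <- runif(1, -1, 1) * min(0.3, 0.5 * wsec)
        amp <- runif(1, 0.02, 0.08) * min(1, wsec)
        ph <- runif(1, 0, pi)
        ang <- phi0 + curv * tpar + amp * sin(2 * pi * tpar + ph)
        rr <- 0.3 + tpar * (0.95 * half * sqrt(2) - 0.3)
        xs <- rr * cos(ang)
        ys <- rr * sin(ang)
        i <- round((ys + half) / s + 0.5)
        j <- round((xs + half) / s + 0.5)
        ok <- i >= 1 & i <= n_px & j >= 1 & j <= n_px
        path[cbind(i[ok], j[ok])] <- TRUE
      }
      brush <- EBImage::makeBrush(odd_size(vessel_caliber_px), "disc")
      mask <- EBImage::dilate(path, brush) > 0
    }
    pix <- 30 + 170 * tex
    pix[mask] <- 225
    pix <- clamp(pix + rnorm(n_px^2, 0, noise_sd), 0, 255)
    list(pix = pix, mask = mask)
  })
  img <- enface_angiogram(
    out$pix, width_mm = width_mm, layer = "SCP",
    quality_score = quality_score, eye_id = eye_id,
    subject_id = subject_id, session_id = session_id
  )
  truth <- structure(
    list(
      faz_area_mm2 = pi * faz_radius_mm^2,
      faz_center_mm = c(0, 0),
      large_vessel_mask = out$mask,
      artifact_labels = character(),
      seed = seed
    ),
    class = "ground_truth"
  )
  list(image = img, truth = truth)
}

#' Inject an acquisition artifact into an angiogram
#'
#' Applies one of the four artifact classes seen on excluded DCP images:
#' projection of overlying SCP large vessels, motion (row-block lateral
#' displacement with a bright residual line), blur (isotropic
#' smoothing), or signal loss (a near-zero band of rows, as after a
#' blink). The artifact label is appended to the image's `artifacts`
#' field; labels are only ever appended, never removed.
#'
#' The meaning of `magnitude` depends on `kind`:
#' \describe{
#'   \item{projection}{overlay opacity in \[0, 1\] of the SCP large-vessel
#'     pattern (pixel intensities under the mask move toward the SCP
#'     values, never below the input).}
#'   \item{motion}{lateral shift in pixels applied to row blocks at two
#'     break lines (plus a bright residual line at each break).}
#'   \item{blur}{Gaussian kernel scale (sigma) in pixels.}
#'   \item{signal_loss}{fraction of rows in the contiguous near-zero band.}
#' }
#' `magnitude = 0` returns the input unchanged.
#'
#' @param image An [enface_angiogram()].
#' @param kind One of `"projection"`, `"motion"`, `"blur"`, `"signal_loss"`.
#' @param magnitude Non-negative artifact magnitude (see Details).
#' @param aux For `kind = "projection"`: the SCP [enface_angiogram()]
#'   whose large-vessel pattern is superimposed (required).
#' @param seed Seed for the placement randomness of motion breaks and the
#'   signal-loss band.
#' @return The modified [enface_angiogram()].
#' @export
inject_artifact <- function(image, kind = c("projection", "motion", "blur",
                                            "signal_loss"),
                            magnitude = 1, aux = NULL, seed = 1L) {
  check_angiogram(image)
  kind <- match.arg(kind)
  if (magnitude < 0) abort("`magnitude` must be >= 0")
  if (magnitude == 0) return(image)
  n <- image$n_px
  p <- image$pixels
  if (kind == "projection") {
    if (is.null(aux)) {
      abort("projection injection requires `aux` (the SCP image)",
            class = "deepangio_missing_input")
    }
    check_angiogram(aux, "aux")
    check_same_geometry(image, aux)
    mask <- scp_large_vessel_mask(aux)
    m <- min(magnitude, 1)
    p[mask] <- (1 - m) * p[mask] + m * pmax(p[mask], aux$pixels[mask])
  } else if (kind == "motion") {
    shift <- as.integer(round(magnitude))
    p <- withr::with_seed(seed, {
      breaks <- sort(sample(seq(floor(n * 0.2), ceiling(n * 0.8)), 2))
      sgn <- 1L
      for (b in breaks) {
        rows <- b:n
        cols <- ((seq_len(n) - 1L + sgn * shift) %% n) + 1L
        p[rows, ] <- p[rows, cols]
        p[b, ] <- pmax(p[b, ], 230)   # bright residual motion line
        sgn <- -sgn
      }
      p
    })
  } else if (kind == "blur") {
    p <- clamp(EBImage::gblur(p / 255, sigma = magnitude), 0, 1) * 255
  } else { # signal_loss
    nb <- max(1L, round(magnitude * n))
    p <- withr::with_seed(seed, {
      start <- sample(seq_len(max(1L, n - nb + 1L)), 1)
      band <- start:min(n, start + nb - 1L)
      p[band, ] <- p[band, ] * 0.02
      p
    })
  }
  image$pixels <- clamp(p, 0, 255)
  image$artifacts <- c(image$artifacts, kind)
  image
}
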