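# Quantification of the deep capillary network: FAZ area, parafoveal
# vessel density, and box-counting fractal dimension.

new_vessel_map <- function(mask, pixel_size_mm) {
  stopifnot(is.matrix(mask), is.logical(mask[1]), pixel_size_mm > 0)
  structure(list(mask = mask, pixel_size_mm = pixel_size_mm),
            class = "binary_vessel_map")
}

#' @export
print.binary_vessel_map <- function(x, ...) {
  cat(sprintf("<binary_vessel_map> %d x %d px, %.4f mm/px, %.1f%% vessel\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size_mm,
              100 * mean(x$mask)))
  invisible(x)
}

# adaptive mean threshold on a raw intensity matrix (0-255 scale);
# window expressed in mm so the rule is scale-covariant
adaptive_binarize <- function(pixels, px_mm, window_mm = 0.25, offset = 0.03) {
  w <- max(1L, round(window_mm / px_mm / 2))
  x <- pixels / 255
  mask <- EBImage::thresh(x, w = w, h = w, offset = offset) > 0
  matrix(as.logical(mask), nrow(pixels))
}

# bilateral filter: Gaussian spatial weights restricted by an intensity
# range kernel, so capillary edges are preserved while flat regions are
# averaged. Border handled by clamping (replication).
bilateral_filter <- function(p, radius = 1, sigma_s = 1, sigma_r = 45) {
  n <- nrow(p); m <- ncol(p)
  acc <- matrix(0, n, m)
  wacc <- matrix(0, n, m)
  for (di in -radius:radius) {
    for (dj in -radius:radius) {
      si <- pmin(pmax(seq_len(n) + di, 1), n)
      sj <- pmin(pmax(seq_len(m) + dj, 1), m)
      q <- p[si, sj]
      w <- exp(-(di^2 + dj^2) / (2 * sigma_s^2)) *
        exp(-(q - p)^2 / (2 * sigma_r^2))
      acc <- acc + w * q
      wacc <- wacc + w
    }
  }
  acc / wacc
}

#' Denoise an angiogram
#'
#' Edge-preserving bilateral smoothing ahead of binarization: spatial
#' Gaussian weights are attenuated across intensity edges, so capillary
#' boundaries survive while acquisition noise in locally uniform areas
#' is averaged out. `denoise_strength` is the window radius in pixels
#' (and the spatial sigma); strength 0 is the identity. Deterministic.
#'
#' @param img An [enface_angiogram()].
#' @param denoise_strength Non-negative integer window radius (default 1).
#' @param sigma_r Range (intensity) sigma on the 0-255 scale; edges with
#'   contrast well above this are preserved.
#' @return The smoothed [enface_angiogram()].
#' @export
preprocess_angiogram <- function(img, denoise_strength = 1, sigma_r = 45) {
  check_angiogram(img)
  if (denoise_strength < 0) abort("`denoise_strength` must be >= 0")
  r <- as.integer(round(denoise_strength))
  if (r == 0) return(img)
  img$pixels <- bilateral_filter(img$pixels, radius = r,
                                 sigma_s = max(denoise_strength, 0.5),
                                 sigma_r = sigma_r)
  img
}

#' Binarize an angiogram into a vessel map
#'
#' Locally adaptive mean thresholding: a pixel is vessel when its
#' intensity exceeds the mean of a square window (side `window_mm`,
#' expressed in physical units) by more than `offset` (on the
#' normalized 0-1 scale). A constant image yields an empty mask, and
#' the rule is invariant to a uniform intensity offset.
#'
#' @param img An [enface_angiogram()] (normally preprocessed).
#' @param window_mm Window side in mm (default 0.25).
#' @param offset Threshold excess over the local mean, 0-1 scale.
#' @return A `binary_vessel_map`: list of `mask` (logical matrix, TRUE =
#'   vessel) and `pixel_size_mm`.
#' @export
binarize_angiogram <- function(img, window_mm = 0.25, offset = 0.03) {
  check_angiogram(img)
  new_vessel_map(
    adaptive_binarize(img$pixels, pixel_size_mm(img), window_mm, offset),
    pixel_size_mm(img)
  )
}

# locate the FAZ: largest dark component near the image center after
# closing the vessel mask at capillary scale. Returns NULL when no dark
# component exists within `search_mm` of the center.
locate_faz <- function(vm, closing_mm = 0.03, search_mm = 0.5,
                       min_area_mm2 = 0.02) {
  mask <- vm$mask
  px <- vm$pixel_size_mm
  n <- nrow(mask)
  brush <- EBImage::makeBrush(odd_size(closing_mm / px * 2 + 1), "disc")
  closed <- EBImage::closing(mask, brush) > 0
  lab <- label_components(!closed, connectivity = 4)
  if (max(lab) == 0) return(NULL)
  r <- radial_dist_mm(n, n * px)
  cen <- as.integer(round((n + 1) / 2))
  areas <- component_areas_mm2(lab, px)
  id <- lab[cen, cen]
  if (id == 0 || areas[id] < min_area_mm2) {
    # center pixel is vessel (or sits in a capillary-scale gap): nearest
    # FAZ-scale dark component within the search disc
    near <- lab[r <= search_mm & lab > 0]
    cand <- unique(near)
    cand <- cand[areas[cand] >= min_area_mm2]
    if (!length(cand)) return(NULL)
    dmin <- vapply(cand, function(k) min(r[lab == k]), numeric(1))
    id <- cand[which.min(dmin)]
  }
  region <- lab == id
  list(
    region = region,
    area_mm2 = sum(region) * px^2,
    centroid_mm = c(
      x = mean(pixel_grid_mm(n, n * px)$x[region]),
      y = mean(pixel_grid_mm(n, n * px)$y[region])
    )
  )
}

#' Segment the foveal avascular zone
#'
#' The FAZ is taken as the connected non-vessel component containing
#' (or, if the center pixel is vessel, nearest to) the image center,
#' after morphological closing of the vessel mask at capillary scale.
#' Its area is the pixel count times the pixel area, with no boundary
#' smoothing.
#'
#' @param vm A `binary_vessel_map` from [binarize_angiogram()].
#' @param closing_mm Closing radius in mm (default 0.03, about the
#'   capillary caliber).
#' @param search_mm Radius of the central search disc in mm.
#' @return A list with `region` (logical matrix), `faz_area_mm2`, and
#'   `centroid_mm`.
#' @export
segment_faz <- function(vm, closing_mm = 0.03, search_mm = 0.5) {
  stopifnot(inherits(vm, "binary_vessel_map"))
  f <- locate_faz(vm, closing_mm, search_mm)
  if (is.null(f)) {
    abort("no FAZ: no non-vessel component within the central search disc",
          class = "deepangio_no_faz")
  }
  list(region = f$region, faz_area_mm2 = f$area_mm2, centroid_mm = f$centroid_mm)
}

#' Parafoveal vessel density
#'
#' Vessel density is the percentage of the parafoveal annulus (outer
#' diameter 3 mm, inner diameter 1 mm, centred on the image center) not
#' covered by non-perfusion. A non-perfusion region is a connected dark
#' (non-vessel) component of the binarized image whose *total* area is
#' strictly greater than `min_area_mm2`; only its intersection with the
#' annulus is subtracted.
#'
#' @param vm A `binary_vessel_map`.
#' @param min_area_mm2 Non-perfusion size cutoff (default 0.02, strict
#'   comparison).
#' @param outer_mm,inner_mm Annulus outer / inner radius in mm.
#' @return Vessel density in percent (scalar).
#' @export
compute_vd <- function(vm, min_area_mm2 = 0.02, outer_mm = 1.5, inner_mm = 0.5) {
  stopifnot(inherits(vm, "binary_vessel_map"))
  px <- vm$pixel_size_mm
  n <- nrow(vm$mask)
  if (n * px < 2 * outer_mm - 1e-9) {
    abort("annulus out of bounds: scan width smaller than the outer diameter",
          class = "deepangio_annulus_oob")
  }
  r <- radial_dist_mm(n, n * px)
  annulus <- r >= inner_mm & r <= outer_mm
  lab <- label_components(!vm$mask, connectivity = 4)
  if (max(lab) == 0) return(100)
  areas <- component_areas_mm2(lab, px)
  nonperf_ids <- which(areas > min_area_mm2)
  if (!length(nonperf_ids)) return(100)
  bad <- annulus & lab > 0 & matrix(lab %in% nonperf_ids, n)
  100 * (sum(annulus) - sum(bad)) / sum(annulus)
}

#' Skeletonize a vessel map
#'
#' Topology-preserving Zhang-Suen thinning of the vessel mask down to
#' 1-pixel-wide center lines.
#'
#' @param vm A `binary_vessel_map`.
#' @return A `skeleton_map`: list of `mask` (logical) and `pixel_size_mm`.
#' @export
skeletonize_vessels <- function(vm) {
  stopifnot(inherits(vm, "binary_vessel_map"))
  sk <- thin_zhang_suen(vm$mask)
  # parallel thinning can annihilate very small blobs (e.g. a 2x2
  # square); restore one pixel so every component keeps a point medial
  # axis and the component count is preserved
  lab <- label_components(vm$mask, connectivity = 8)
  if (max(lab) > 0) {
    gone <- setdiff(seq_len(max(lab)), unique(lab[sk]))
    for (k in gone) {
      px_idx <- which(lab == k)
      sk[px_idx[ceiling(length(px_idx) / 2)]] <- TRUE
    }
  }
  structure(
    list(mask = sk, pixel_size_mm = vm$pixel_size_mm),
    class = "skeleton_map"
  )
}

# Zhang-Suen thinning, vectorized over the full grid with a 1-px
# zero border. Preserves 8-connectivity of foreground components.
thin_zhang_suen <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(0L, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask)
  idx_core <- function(M) M[2:(nr + 1L), 2:(nc + 1L)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north (row-1)
      P2 <- m[1:nr, 2:(nc + 1L)]
      P3 <- m[1:nr, 3:(nc + 2L)]
      P4 <- m[2:(nr + 1L), 3:(nc + 2L)]
      P5 <- m[3:(nr + 2L), 3:(nc + 2L)]
      P6 <- m[3:(nr + 2L), 2:(nc + 1L)]
      P7 <- m[3:(nr + 2L), 1:nc]
      P8 <- m[2:(nr + 1L), 1:nc]
      P9 <- m[1:nr, 1:nc]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (step == 1) {
        c3 <- P2 * P4 * P6 == 0
        c4 <- P4 * P6 * P8 == 0
      } else {
        c3 <- P2 * P4 * P8 == 0
        c4 <- P2 * P6 * P8 == 0
      }
      del <- idx_core(m) == 1L & B >= 2 & B <= 6 & A == 1 & c3 & c4
      if (any(del)) {
        core <- idx_core(m)
        core[del] <- 0L
        m[2:(nr + 1L), 2:(nc + 1L)] <- core
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  idx_core(m) == 1L
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes N(s) over a dyadic ladder of box sizes s
#' (default 2, 4, ... up to a quarter of the image side) and returns the
#' negative slope of the least-squares fit of log N(s) on log s. A
#' straight line gives FD near 1, a filled plane near 2.
#'
#' @param skel A `skeleton_map` from [skeletonize_vessels()] (any logical
#'   matrix wrapped in one works).
#' @param min_box,max_box Smallest / largest box size in pixels;
#'   `max_box = NULL` uses `n_px / 4`. Sizes are powers of two.
#' @return The fractal dimension (scalar).
#' @export
compute_fd <- function(skel, min_box = 2, max_box = NULL) {
  stopifnot(inherits(skel, "skeleton_map"))
  mask <- skel$mask
  if (!any(mask)) {
    abort("undefined FD: empty skeleton", class = "deepangio_empty_skeleton")
  }
  n <- min(dim(mask))
  max_box <- max_box %||% (n / 4)
  sizes <- 2^(seq.int(floor(log2(min_box)), floor(log2(max_box))))
  sizes <- sizes[sizes >= min_box & sizes <= max_box]
  if (length(sizes) < 2) abort("need at least two box sizes")
  idx <- which(mask, arr.ind = TRUE)
  counts <- vapply(sizes, function(s) {
    bi <- (idx[, 1] - 1L) %/% s
    bj <- (idx[, 2] - 1L) %/% s
    length(unique(bi * (ceiling(nrow(mask) / s) + 1L) + bj))
  }, numeric(1))
  fit <- lm(log(counts) ~ log(sizes))
  -unname(coef(fit)[2])
}

#' Quantify a DCP angiogram
#'
#' Full quantification pipeline for a QC-passing DCP image:
#' denoise, binarize, then segment the FAZ, compute parafoveal vessel
#' density, and compute the fractal dimension of the skeletonized
#' network. Deterministic.
#'
#' @param dcp A DCP [enface_angiogram()].
#' @param denoise_strength,window_mm,offset,closing_mm,min_area_mm2
#'   Passed to the component steps.
#' @return A one-row tibble: `eye_id`, `subject_id`, `session_id`,
#'   `faz_area_mm2`, `vd_pct`, `fd`.
#' @export
#' @examples
#' d <- generate_dcp_angiogram(seed = 7)
#' quantify_dcp(d$image)
quantify_dcp <- function(dcp, denoise_strength = 1, window_mm = 0.25,
                         offset = 0.03, closing_mm = 0.03,
                         min_area_mm2 = 0.02) {
  check_angiogram(dcp)
  vm <- binarize_angiogram(
    preprocess_angiogram(dcp, denoise_strength),
    window_mm = window_mm, offset = offset
  )
  faz <- segment_faz(vm, closing_mm = closing_mm)
  vd <- compute_vd(vm, min_area_mm2 = min_area_mm2)
  fd <- compute_fd(skeletonize_vessels(vm))
  tibble(
    eye_id = dcp$eye_id, subject_id = dcp$subject_id,
    session_id = dcp$session_id,
    faz_area_mm2 = faz$faz_area_mm2, vd_pct = vd, fd = fd
  )
}
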