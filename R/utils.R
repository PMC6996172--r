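clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

odd_size <- function(k) {
  k <- max(1L, as.integer(round(k)))
  if (k %% 2L == 0L) k + 1L else k
}

# mm coordinates of pixel centers; rows index y, columns index x,
# origin at the image center (fovea by convention)
pixel_grid_mm <- function(n_px, width_mm) {
  s <- width_mm / n_px
  v <- (seq_len(n_px) - (n_px + 1) / 2) * s
  list(
    x = matrix(v, n_px, n_px, byrow = TRUE),
    y = matrix(v, n_px, n_px),
    px_mm = s
  )
}

radial_dist_mm <- function(n_px, width_mm, center_mm = c(0, 0)) {
  g <- pixel_grid_mm(n_px, width_mm)
  sqrt((g$x - center_mm[1])^2 + (g$y - center_mm[2])^2)
}

# 4- or 8-connected component labelling of a logical matrix.
# EBImage::bwlabel is 4-connected; the 8-connected variant bridges
# diagonal touches by dilating labels through diagonal neighbours.
label_components <- function(mask, connectivity = 4) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask)
  if (connectivity == 4 || max(lab) <= 1) {
    return(matrix(as.integer(lab), nrow(mask)))
  }
  # union 4-connected labels that touch diagonally
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (di in c(-1L, 1L)) {
    a <- lab[if (di == 1) -nr else -1, -nc]
    b <- lab[if (di == 1) -1 else -nr, -1]
    sel <- which(a > 0 & b > 0 & a != b)
    if (length(sel)) for (k in sel) union2(a[k], b[k])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nr, nc)
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

component_areas_mm2 <- function(lab, px_mm) {
  if (max(lab) == 0) return(numeric(0))
  tabulate(lab[lab > 0], nbins = max(lab)) * px_mm^2
}
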