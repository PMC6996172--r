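# Independent oracles used to validate the package's image routines.

# connected-component labelling via igraph (independent of the
# package's labelling code)
igraph_label <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nr, nc))
  offs <- if (connectivity == 4) {
    list(c(1L, 0L), c(0L, 1L))
  } else {
    list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  }
  pos <- arrayInd(idx, dim(mask))
  edges <- list()
  for (o in offs) {
    i2 <- pos[, 1] + o[1]; j2 <- pos[, 2] + o[2]
    ok <- i2 >= 1 & i2 <= nr & j2 >= 1 & j2 <= nc
    tgt <- (j2[ok] - 1L) * nr + i2[ok]
    src <- idx[ok]
    both <- mask[tgt]
    edges[[length(edges) + 1]] <- cbind(src[both], tgt[both])
  }
  em <- do.call(rbind, edges)
  verts <- as.character(idx)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(em[, 1]), to = as.character(em[, 2])),
    directed = FALSE, vertices = verts
  )
  comp <- igraph::components(g)$membership
  lab <- matrix(0L, nr, nc)
  lab[as.integer(names(comp))] <- as.integer(comp)
  lab
}

# brute-force per-pixel vessel-density oracle: classify every annulus
# pixel explicitly using igraph components of the dark phase
vd_oracle <- function(mask, px_mm, min_area_mm2 = 0.02,
                      outer_mm = 1.5, inner_mm = 0.5) {
  n <- nrow(mask)
  v <- (seq_len(n) - (n + 1) / 2) * px_mm
  r <- sqrt(outer(v^2, v^2, "+"))
  annulus <- r >= inner_mm & r <= outer_mm
  lab <- igraph_label(!mask, connectivity = 4)
  in_nonperf <- matrix(FALSE, n, n)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab)) * px_mm^2
    in_nonperf <- lab > 0 & matrix(areas[pmax(lab, 1)] > min_area_mm2, n)
  }
  good <- 0L
  for (k in which(annulus)) {
    if (!in_nonperf[k]) good <- good + 1L
  }
  100 * good / sum(annulus)
}

# vessel map wrapper for hand-built masks
make_vm <- function(mask, px_mm = 3 / 320) {
  deepangio:::new_vessel_map(mask, px_mm)
}

make_skel <- function(mask, px_mm = 3 / 320) {
  structure(list(mask = mask, pixel_size_mm = px_mm), class = "skeleton_map")
}

# Sierpinski triangle raster of side 2^k (depth-k recursion)
sierpinski_mask <- function(k = 8) {
  n <- 2^k
  i <- matrix(0:(n - 1), n, n)
  j <- matrix(0:(n - 1), n, n, byrow = TRUE)
  matrix(bitwAnd(i, j) == 0, n, n)
}
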