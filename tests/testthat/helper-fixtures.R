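# Fixture builders and independent oracles used across the suite.

# digitized ball: voxel centres within radius r (voxel units), isotropic grid
ball_mask <- function(r, margin = 3L, spacing = c(1, 1, 1)) {
  n <- as.integer(2 * ceiling(r) + 1L + 2L * margin)
  ctr <- rep((n + 1) / 2, 3)
  co <- as.matrix(expand.grid(seq_len(n), seq_len(n), seq_len(n)))
  inside <- sqrt(colSums((t(co) - ctr)^2)) <= r
  binary_mask(array(inside, c(n, n, n)), vol_geom(c(n, n, n), spacing))
}

# solid axis-aligned cuboid of a x b x c voxels with 2-voxel padding
cuboid_mask <- function(a, b, c, spacing = c(1, 1, 1)) {
  dm <- c(a, b, c) + 4L
  arr <- array(FALSE, dim = dm)
  arr[3:(a + 2), 3:(b + 2), 3:(c + 2)] <- TRUE
  binary_mask(arr, vol_geom(dm, spacing))
}

mask_from_voxels <- function(vox, dims, spacing = c(1, 1, 1)) {
  arr <- array(FALSE, dim = dims)
  arr[vox] <- TRUE
  binary_mask(arr, vol_geom(dims, spacing))
}

# component partition oracle: adjacency graph + igraph::components,
# independent of the package's BFS labeling
flood_fill_oracle <- function(mask, connectivity) {
  vox <- which(mask$data, arr.ind = TRUE)
  n <- nrow(vox)
  if (n == 0L) return(integer(0))
  key <- vox[, 1] + (vox[, 2] - 1) * 10000 + (vox[, 3] - 1) * 1e8
  lookup <- seq_len(n)
  names(lookup) <- as.character(key)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  edges <- NULL
  for (i in seq_len(nrow(offs))) {
    nb_key <- (vox[, 1] + offs$dx[i]) + (vox[, 2] + offs$dy[i] - 1) * 10000 +
      (vox[, 3] + offs$dz[i] - 1) * 1e8
    j <- lookup[as.character(nb_key)]
    ok <- !is.na(j)
    if (any(ok)) edges <- rbind(edges, cbind(which(ok), unname(j[ok])))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

# two labelings describe the same partition iff their contingency table has
# exactly one nonzero cell per row and per column
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# O(N^2) exact distance oracle in physical mm
brute_force_distance <- function(mask) {
  ref <- which(mask$data, arr.ind = TRUE)
  rp <- sweep(ref, 2, mask$geometry$spacing, `*`)
  co <- as.matrix(expand.grid(seq_len(mask$geometry$dims[1]),
                              seq_len(mask$geometry$dims[2]),
                              seq_len(mask$geometry$dims[3])))
  pts <- sweep(co, 2, mask$geometry$spacing, `*`)
  d <- apply(pts, 1, function(p) sqrt(min(colSums((t(rp) - p)^2))))
  array(d, dim = mask$geometry$dims)[co]  # in expand.grid (column-major) order
}

# convenience: standard kappa-ladder lesion used by the irregularity checks
ladder_lesion <- function(kappa, seed) {
  make_lesion(vol_geom(c(96, 96, 96)), center_mm = c(47, 47, 47),
              semi_axes_mm = c(9, 7, 6), kappa = kappa, seed = seed)
}
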