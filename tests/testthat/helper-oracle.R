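# independent brute-force oracle: enumerate analytic-geometry subvoxels at
# `ss`-fold supersampling and compute statistics directly, bypassing the
# package's voxelization/sampling/statistics path entirely
brute_force_stats <- function(grid, inside_fn, dose_fn, threshold, ss = 10L) {
  d <- grid_dim(grid)
  sub <- (seq_len(ss) - 0.5) / ss - 0.5
  xs <- as.vector(outer(grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
                        sub * grid$spacing[1], "+"))
  ys <- as.vector(outer(grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
                        sub * grid$spacing[2], "+"))
  zs <- as.vector(outer(grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3],
                        sub * grid$spacing[3], "+"))
  doses <- NULL
  count <- 0
  for (z in zs) {                       # slab-wise to bound memory
    pts <- cbind(rep(xs, length(ys)), rep(ys, each = length(xs)), z)
    keep <- inside_fn(pts)
    if (any(keep)) doses <- c(doses, dose_fn(pts[keep, , drop = FALSE]))
  }
  subvol <- prod(grid$spacing) / ss^3 / 1000
  list(volume_ml = length(doses) * subvol,
       min = min(doses), max = max(doses),
       median = stats::median(doses),
       vol_in_isodose_ml = sum(doses >= threshold) * subvol)
}

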