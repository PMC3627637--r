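# Fixtures are built in code; no binary data ships with the package.

# volume whose masked voxels take exactly `values` (column-major fill)
vol_from_values <- function(values, spacing = c(1, 1, 1)) {
  attenuation_volume(array(values, dim = c(length(values), 1, 1)), spacing)
}

mask_all <- function(dims) lung_segmentation(array(TRUE, dim = dims))

random_volume <- function(dims, lo = -1024, hi = 0) {
  attenuation_volume(array(stats::runif(prod(dims), lo, hi), dim = dims))
}

# per-voxel loop oracle: one pass over every voxel, no vectorised shortcuts
loop_oracle <- function(grid, mask, emph_threshold = -950,
                        trap_threshold = -856) {
  n <- 0L; below_emph <- 0L; below_trap <- 0L
  band <- 0L; nonemph <- 0L; total <- 0
  for (i in seq_along(grid)) {
    if (mask[i]) {
      n <- n + 1L
      v <- grid[i]
      total <- total + v
      if (v < emph_threshold) below_emph <- below_emph + 1L
      if (v < trap_threshold) below_trap <- below_trap + 1L
      if (v >= emph_threshold) {
        nonemph <- nonemph + 1L
        if (v < trap_threshold) band <- band + 1L
      }
    }
  }
  list(pct_below_emph = 100 * below_emph / n,
       pct_below_trap = 100 * below_trap / n,
       mla = total / n,
       relvol = if (nonemph > 0) band / nonemph else NA_real_)
}

# identity pair: same acquisition used for both phases
identity_pair <- function(seed = 1, dims = c(8, 8, 8)) {
  set.seed(seed)
  vol <- random_volume(dims)
  msk <- lung_segmentation(array(stats::runif(prod(dims)) > 0.3, dim = dims))
  scan_pair(vol, msk, vol, msk, smoking_status = "former")
}
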