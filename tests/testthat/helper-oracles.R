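# Independent oracles, deliberately naive: enumeration and direct counting
# only, no shared code with the implementation they check.

# exact two-sided Mann-Whitney p by enumeration of all assignments of the
# pooled sample to the first group (tie-free inputs)
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">"))
  u_obs <- u_stat(x, y)
  combs <- utils::combn(n, m)
  us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  # two-sided: double the smaller tail (the convention of the exact
  # rank-sum distribution), capped at 1
  n_u <- length(us)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# exact maximum pairwise distance over ALL voxel centres (no boundary
# shortcut), for small masks
brute_diameter <- function(mask_arr, spacing) {
  idx <- which(mask_arr, arr.ind = TRUE)
  pts <- sweep(idx - 0.5, 2, spacing, "*")
  best <- 0
  for (i in seq_len(nrow(pts)))
    best <- max(best, max(colSums((t(pts) - pts[i, ])^2)))
  sqrt(best)
}

# CSH volume fraction by direct counting at arbitrary threshold fractions
csh_direct <- function(vals, t_fracs) {
  smax <- max(vals)
  vapply(t_fracs, function(t) mean(vals > t * smax), numeric(1))
}

# hand-computed Pearson chi-square statistic, sum (O-E)^2 / E
chisq_by_hand <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# a volume whose masked voxels carry the given values (10 mm cubes = 1 ml)
make_volume_mask <- function(vals_in_mask, voxel_mm = 10) {
  k <- length(vals_in_mask)
  v <- array(0, c(k + 2, 3, 3))
  m <- array(FALSE, c(k + 2, 3, 3))
  v[1 + seq_len(k), 2, 2] <- vals_in_mask
  m[1 + seq_len(k), 2, 2] <- TRUE
  list(vol = suv_volume(v, voxel_mm), mask = voi_mask(m, voxel_mm))
}

# a small noiseless phantom with one lesion centred in the grid
one_lesion_phantom <- function(diameter, uptake, spacing = 1,
                               margin = 6, noise = 0, seed = 1) {
  n <- ceiling((diameter + 2 * margin) / spacing)
  ctr <- rep(n * spacing / 2, 3)
  generate_phantom(phantom_spec(
    grid_shape = rep(n, 3), voxel_spacing = spacing,
    background_fields = c(ruf = 0.5, luf = 0.5, rmf = 0.5, lmf = 0.5,
                          rlf = 0.5, llf = 0.5, blood_pool = 0.5),
    noise_sigma = noise,
    lesions = list(lesion_spec(ctr, diameter, uptake)), seed = seed))
}
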