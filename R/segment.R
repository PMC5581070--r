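# 26-neighbourhood offsets (rows), excluding the null offset
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# 26-connected component of 'candidate' containing linear index 'start'
# (vectorised flood fill; no 3-D labelling exists in the installed stack)
connected_component_26 <- function(candidate, start) {
  d <- dim(candidate)
  if (!candidate[start]) stop("start voxel is not in the candidate set")
  offs <- neighbor_offsets_26()
  visited <- array(FALSE, d)
  visited[start] <- TRUE
  frontier <- matrix(arrayInd(start, d), ncol = 3)
  while (nrow(frontier) > 0) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), , drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), nrow(frontier)), , drop = FALSE]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    if (nrow(nb) == 0) break
    lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
    lin <- unique(lin[candidate[lin] & !visited[lin]])
    if (length(lin) == 0) break
    visited[lin] <- TRUE
    frontier <- matrix(arrayInd(lin, d), ncol = 3)
  }
  visited
}

# local peak (max SUV voxel) within 'radius' mm of a world-mm seed point;
# also returns a robust local background level and spread for the same ball
local_peak <- function(volume, seed_point, radius = 20) {
  d <- dim(volume$values); sp <- volume$spacing; o <- volume$origin
  si <- world_to_index(seed_point, sp, d, o)
  half <- ceiling(radius / sp)
  lo <- pmax(si - half, 1L); hi <- pmin(si + half, d)
  xs <- axis_centers(d[1], sp[1], o[1])[lo[1]:hi[1]]
  ys <- axis_centers(d[2], sp[2], o[2])[lo[2]:hi[2]]
  zs <- axis_centers(d[3], sp[3], o[3])[lo[3]:hi[3]]
  sub <- volume$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dist2 <- outer(outer((xs - seed_point[1])^2, (ys - seed_point[2])^2, "+"),
                 (zs - seed_point[3])^2, "+")
  inball <- dist2 <= radius^2
  vals <- sub[inball]
  peak_val <- max(vals)
  # among voxels attaining the max, take the one nearest the seed
  cand <- which(sub == peak_val & inball)
  cand <- cand[which.min(dist2[cand])]
  w <- arrayInd(cand, dim(sub))[1, ]
  peak_idx <- as.integer(w + lo - 1L)
  list(index = peak_idx,
       center = volume$origin + (peak_idx - 0.5) * sp,
       value = peak_val,
       background = stats::median(vals),
       spread = stats::mad(vals))
}

#' Gradient-based metabolic tumor delineation from a seed point
#'
#' Delineates the FDG-avid lesion around a seed point: the local SUV peak near
#' the seed is located, rays are cast from the peak in the 26 lattice
#' directions, the SUV profile along each ray is resampled at 1 mm and the edge
#' is placed at the maximum spatial-gradient magnitude (central differences,
#' with parabolic sub-sample refinement), and the boundary between rays is
#' interpolated over direction. The result is the single 26-connected
#' component containing the peak.
#'
#' This emulates the class of commercial gradient-based PET delineation tools
#' (the mask provenance tag records \code{method = "petedge"}, an emulation,
#' not any vendor's algorithm). It is scale-invariant: multiplying the volume
#' by a positive constant does not change the mask.
#'
#' @param volume an \code{\link{suv_volume}}.
#' @param seed_point world mm coordinates (length 3) inside or near the lesion.
#' @param max_radius_mm longest ray length searched for an edge, mm.
#' @param search_radius_mm radius of the neighbourhood used to locate the
#'   local peak and the local background level, mm.
#' @return A \code{\link{voi_mask}} with \code{method = "petedge"}. The
#'   \code{border_warning} flag is set when the mask touches the volume border.
#' @details A seed placed in background raises the error
#'   \code{"no lesion at seed"}: no voxel within \code{search_radius_mm}
#'   exceeds the local background (median) by more than 3 robust SDs.
#' @export
petedge_segment <- function(volume, seed_point, max_radius_mm = 60,
                            search_radius_mm = 20) {
  pk <- local_peak(volume, seed_point, search_radius_mm)
  if (pk$value <= pk$background + 3 * pk$spread)
    stop("no lesion at seed: no peak above background + 3 local SD within ",
         search_radius_mm, " mm")
  dirs <- neighbor_offsets_26()
  dirs <- dirs / sqrt(rowSums(dirs^2))
  step <- 1  # mm resampling along each ray
  radii <- seq(0, max_radius_mm, by = step)
  edge_r <- numeric(nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    pts <- outer(radii, dirs[k, ]) +
      matrix(pk$center, nrow = length(radii), ncol = 3, byrow = TRUE)
    prof <- trilinear(volume, pts)
    g <- abs(c(0, (prof[-(1:2)] - prof[1:(length(prof) - 2)]) / (2 * step), 0))
    j <- which.max(g)
    r <- radii[j]
    # parabolic refinement of the gradient-magnitude peak
    if (j > 1 && j < length(g)) {
      den <- g[j - 1] - 2 * g[j] + g[j + 1]
      if (den < 0) r <- r + step * 0.5 * (g[j - 1] - g[j + 1]) / den
    }
    edge_r[k] <- max(r, step / 2)
  }
  # candidate voxels: centre within the direction-interpolated edge radius
  d <- dim(volume$values); sp <- volume$spacing; o <- volume$origin
  half <- ceiling(max(edge_r) / sp) + 1L
  lo <- pmax(pk$index - half, 1L); hi <- pmin(pk$index + half, d)
  grid <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
  cen <- sweep(sweep(grid - 0.5, 2, sp, "*"), 2, o, "+")
  rel <- sweep(cen, 2, pk$center, "-")
  rr <- sqrt(rowSums(rel^2))
  inside <- rr < 1e-9
  nz <- which(!inside)
  if (length(nz)) {
    u <- rel[nz, , drop = FALSE] / rr[nz]
    # angular inverse-distance interpolation of edge radius over the 26 rays
    cosang <- pmin(pmax(u %*% t(dirs), -1), 1)
    ang <- acos(cosang)
    w <- 1 / (ang^2 + 1e-6)
    rdir <- as.numeric((w %*% edge_r) / rowSums(w))
    inside[nz] <- rr[nz] <= rdir + 1e-9
  }
  candidate <- array(FALSE, d)
  candidate[grid[inside, , drop = FALSE]] <- TRUE
  start <- pk$index[1] + d[1] * (pk$index[2] - 1) + d[1] * d[2] * (pk$index[3] - 1)
  candidate[start] <- TRUE
  comp <- connected_component_26(candidate, start)
  voi_mask(comp, sp, method = "petedge",
           params = list(seed_point = seed_point, n_rays = nrow(dirs),
                         resample_mm = step, connectivity = 26,
                         emulation = TRUE),
           origin = o, border_warning = touches_border(comp))
}

touches_border <- function(mask) {
  d <- dim(mask)
  any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) || any(mask[, , c(1, d[3])])
}

#' Fixed-fraction threshold segmentation
#'
#' The standard alternative delineation: the 26-connected component, containing
#' the local SUV peak near the seed, of voxels with SUV >= \code{fraction}
#' times the local SUVmax. Used for sensitivity analysis of the delineation
#' choice. Scale-invariant like \code{\link{petedge_segment}}.
#'
#' @inheritParams petedge_segment
#' @param fraction threshold as a fraction of the local SUVmax, in (0, 1).
#' @return A \code{\link{voi_mask}} with \code{method = "threshold"}.
#' @export
threshold_segment <- function(volume, seed_point, fraction = 0.42,
                              search_radius_mm = 20) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("'fraction' must be in (0, 1)")
  pk <- local_peak(volume, seed_point, search_radius_mm)
  candidate <- volume$values >= fraction * pk$value
  d <- dim(volume$values)
  start <- pk$index[1] + d[1] * (pk$index[2] - 1) + d[1] * d[2] * (pk$index[3] - 1)
  if (!candidate[start]) stop("empty component at threshold ", fraction)
  comp <- connected_component_26(candidate, start)
  voi_mask(comp, volume$spacing, method = "threshold",
           params = list(seed_point = seed_point, fraction = fraction,
                         connectivity = 26),
           origin = volume$origin, border_warning = touches_border(comp))
}

#' Circular 10 mm ROI statistics on a transaxial plane
#'
#' Statistics over the voxels of one axial (xy) plane whose in-plane centre
#' distance from \code{center} is at most half of \code{diameter_mm}. This is
#' the measurement used for normal-lung background fields and the aortic
#' blood pool.
#'
#' @param volume an \code{\link{suv_volume}}.
#' @param center in-plane world mm coordinates (x, y) of the ROI centre.
#' @param plane_index axial slice index (z, 1-based).
#' @param diameter_mm ROI diameter in mm (default 10).
#' @return A list of class \code{roi_stats}: \code{mean}, \code{sd}
#'   (population), \code{min}, \code{max}, \code{n}, and the ROI geometry.
#'   Errors if the full disc does not fit inside the grid.
#' @export
circular_roi <- function(volume, center, plane_index, diameter_mm = 10) {
  d <- dim(volume$values); sp <- volume$spacing; o <- volume$origin
  if (plane_index < 1 || plane_index > d[3]) stop("plane_index outside volume")
  r <- diameter_mm / 2
  ext_lo <- o[1:2]; ext_hi <- o[1:2] + d[1:2] * sp[1:2]
  if (any(center - r < ext_lo) || any(center + r > ext_hi))
    stop(sprintf("10 mm ROI at (%.1f, %.1f) mm exceeds the grid", center[1], center[2]))
  xs <- axis_centers(d[1], sp[1], o[1])
  ys <- axis_centers(d[2], sp[2], o[2])
  dist2 <- outer((xs - center[1])^2, (ys - center[2])^2, "+")
  sel <- dist2 <= r^2
  if (!any(sel)) stop("ROI smaller than one voxel")
  vals <- volume$values[, , plane_index][sel]
  n <- length(vals)
  structure(list(mean = mean(vals),
                 sd = sqrt(sum((vals - mean(vals))^2) / n),
                 min = min(vals), max = max(vals), n = n,
                 center = center, diameter_mm = diameter_mm,
                 plane_index = plane_index),
            class = "roi_stats")
}

# boundary voxels of a mask: mask voxels with a 6-neighbour outside the mask
# (or on the grid border); the pairwise-distance maximum is attained there
boundary_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  core & !nb
}

# blocked exact maximum pairwise distance between rows of an n x 3 matrix
max_pairwise_dist <- function(pts, block = 2000L) {
  n <- nrow(pts)
  if (n < 2) return(0)
  best <- 0
  for (i0 in seq(1, n, by = block)) {
    i1 <- min(i0 + block - 1L, n)
    a <- pts[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(pts^2), "+") - 2 * a %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Metabolic tumor diameter
#'
#' The longest diameter of the delineated FDG uptake region: the maximum
#' pairwise Euclidean distance between mask voxel centres, in mm. Computed in
#' 3-D by default; \code{mode = "axial"} restricts pairs to a common axial
#' plane (the in-plane longest diameter, maximised over planes). Only boundary
#' voxels are searched; the maximum cannot be attained at an interior voxel.
#'
#' @param mask a \code{\link{voi_mask}}.
#' @param mode \code{"3d"} (default) or \code{"axial"}; recorded in the result.
#' @return Diameter in mm. A single-voxel mask returns 0 with attribute
#'   \code{sub_resolution = TRUE}.
#' @export
metabolic_diameter <- function(mask, mode = c("3d", "axial")) {
  mode <- match.arg(mode)
  m <- mask$mask
  if (sum(m) == 1L)
    return(structure(0, sub_resolution = TRUE, mode = mode))
  bnd <- boundary_voxels(m)
  pts <- mask_centers(bnd, mask$spacing, mask$origin)
  if (mode == "3d") {
    dmax <- max_pairwise_dist(pts)
  } else {
    dmax <- 0
    for (z in unique(pts[, 3]))
      dmax <- max(dmax, max_pairwise_dist(pts[pts[, 3] == z, 1:2, drop = FALSE]))
  }
  structure(dmax, mode = mode)
}
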