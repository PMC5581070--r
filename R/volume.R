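#' SUV volume container
#'
#' A 3-D grid of standardized uptake values (SUV, body-weight normalized,
#' dimensionless) with voxel spacing in mm. This is the imaging substrate for
#' segmentation and metric extraction. Voxel \code{(i, j, k)} is centred at
#' \code{origin + (c(i, j, k) - 0.5) * spacing} in world mm coordinates, so a
#' grid of \code{n} voxels along an axis spans \code{[origin, origin + n *
#' spacing]}.
#'
#' @param values 3-D numeric array of SUVs; all values must be >= 0.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#'   A scalar is recycled (isotropic voxels).
#' @param origin numeric length-3, world mm coordinate of the grid corner.
#' @return An object of class \code{suv_volume}: a list with elements
#'   \code{values}, \code{spacing}, \code{origin}.
#' @export
suv_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive voxel dimensions in mm")
  if (anyNA(values) || any(values < 0))
    stop("SUV values must be non-negative and non-missing")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("SUV volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  SUV range: %.3g - %.3g\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.suv_volume <- function(x) dim(x$values)

#' Binary volume-of-interest mask
#'
#' A lesion mask aligned to an \code{\link{suv_volume}}, carrying provenance:
#' which delineation produced it (\code{"petedge"}, \code{"threshold"} or
#' \code{"ground_truth"}) and with what parameters. Masks produced by the
#' segmenters are a single 26-connected component by construction.
#'
#' @param mask 3-D logical array.
#' @param spacing voxel spacing in mm (length 3).
#' @param method provenance tag: \code{"petedge"}, \code{"threshold"},
#'   \code{"ground_truth"} or \code{"manual"}.
#' @param params list of delineation parameters recorded for provenance.
#' @param origin world mm coordinate of the grid corner.
#' @param border_warning logical; \code{TRUE} when the mask touches the volume
#'   border (the delineation may be truncated).
#' @return An object of class \code{voi_mask}.
#' @export
voi_mask <- function(mask, spacing, method = "manual", params = list(),
                     origin = c(0, 0, 0), border_warning = FALSE) {
  if (length(dim(mask)) != 3L)
    stop("'mask' must be a 3-D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask))
    stop("mask is empty")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 method = method, params = params,
                 border_warning = isTRUE(border_warning)),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("VOI mask (%s): %d voxels, %.2f ml%s\n", x$method, sum(x$mask),
              sum(x$mask) * prod(x$spacing) / 1000,
              if (x$border_warning) " [touches volume border]" else ""))
  invisible(x)
}

# voxel volume in ml (spacing is mm, 1 ml = 1000 mm^3)
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

# world mm coordinates of voxel centres along one axis
axis_centers <- function(n, spacing, origin) origin + (seq_len(n) - 0.5) * spacing

# matrix of world mm centre coordinates for the TRUE voxels of a logical array
mask_centers <- function(mask, spacing, origin = c(0, 0, 0)) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(sweep(idx - 0.5, 2, spacing, "*"), 2, origin, "+")
}

# nearest voxel index for a world mm point (clamped into the grid)
world_to_index <- function(point, spacing, dims, origin = c(0, 0, 0)) {
  i <- ceiling((point - origin) / spacing)
  pmin(pmax(i, 1L), dims)
}

check_alignment <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$mask)))
    stop("mask and volume grids differ in shape")
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9)
    stop("mask and volume voxel spacings differ")
  invisible(TRUE)
}

# trilinear interpolation of the volume at world mm points (n x 3 matrix);
# points outside the centre lattice are clamped to the nearest face
trilinear <- function(volume, points) {
  v <- volume$values; d <- dim(v); sp <- volume$spacing; o <- volume$origin
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  # continuous index coordinate: voxel i centre at index i
  ci <- sweep(sweep(points, 2, o, "-"), 2, sp, "/") + 0.5
  out <- numeric(nrow(points))
  i0 <- floor(ci)
  fr <- ci - i0
  for (ax in 1:3) {
    lo <- i0[, ax] < 1
    hi <- i0[, ax] >= d[ax]
    i0[lo, ax] <- 1; fr[lo, ax] <- 0
    i0[hi, ax] <- d[ax] - 1; fr[hi, ax] <- 1
    if (d[ax] == 1) { i0[, ax] <- 1; fr[, ax] <- 0 }
  }
  ii <- function(dx, dy, dz) {
    cbind(pmin(i0[, 1] + dx, d[1]), pmin(i0[, 2] + dy, d[2]),
          pmin(i0[, 3] + dz, d[3]))
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    out <- out + w * v[ii(dx, dy, dz)]
  }
  out
}
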