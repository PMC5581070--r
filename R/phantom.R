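#' Lesion specification for the phantom simulator
#'
#' Describes one synthetic FDG-avid lesion: its geometry (sphere or axis-
#' aligned ellipsoid) and its uptake model. Uptake models, all expressed in
#' terms of the normalized radius u in [0, 1] from the lesion centre to its
#' surface:
#' \describe{
#'   \item{uniform}{constant \code{peak} SUV.}
#'   \item{radial_gradient}{linear falloff from \code{peak} at the centre to
#'     \code{rim_fraction * peak} at the surface.}
#'   \item{necrotic_core}{\code{core_suv} inside a concentric core of
#'     \code{core_fraction} of the diameter, \code{peak} outside it.}
#'   \item{two_compartment}{a concentric inner region holding volume fraction
#'     \code{f} at \code{peak}, the remainder at \code{s * peak}. Closed
#'     forms: SUVmean = (f + (1-f)s) peak, SD = sqrt(f(1-f)) (1-s) peak,
#'     AUC-CSH = s + (1-s) f.}
#' }
#'
#' @param center lesion centre, world mm (length 3).
#' @param diameter mm; a scalar for a sphere, length 3 for an ellipsoid.
#' @param uptake a list with element \code{model} (one of the names above),
#'   \code{peak} (> 0) and the model's extra parameters (\code{rim_fraction},
#'   \code{core_fraction}/\code{core_suv}, \code{f}/\code{s}, all fractions
#'   in [0, 1]).
#' @param shape \code{"sphere"} or \code{"ellipsoid"}; inferred from
#'   \code{diameter} length if missing.
#' @return An object of class \code{lesion_spec}.
#' @export
lesion_spec <- function(center, diameter, uptake = list(model = "uniform", peak = 5),
                        shape = NULL) {
  if (is.null(shape)) shape <- if (length(diameter) == 3L) "ellipsoid" else "sphere"
  shape <- match.arg(shape, c("sphere", "ellipsoid"))
  diameter <- if (shape == "sphere") rep(diameter[1], 3L) else as.numeric(diameter)
  if (any(diameter <= 0)) stop("diameter must be > 0")
  stopifnot(is.list(uptake), !is.null(uptake$model), !is.null(uptake$peak))
  uptake$model <- match.arg(uptake$model,
    c("uniform", "radial_gradient", "necrotic_core", "two_compartment"))
  if (uptake$peak <= 0) stop("peak SUV must be > 0")
  defaults <- switch(uptake$model,
    uniform = list(),
    radial_gradient = list(rim_fraction = 0.3),
    necrotic_core = list(core_fraction = 0.5, core_suv = 0.5),
    two_compartment = list(f = 0.5, s = 0.5))
  for (nm in names(defaults))
    if (is.null(uptake[[nm]])) uptake[[nm]] <- defaults[[nm]]
  frac <- intersect(names(uptake), c("rim_fraction", "core_fraction", "f", "s"))
  for (nm in frac)
    if (uptake[[nm]] < 0 || uptake[[nm]] > 1)
      stop("'", nm, "' must be in [0, 1]")
  structure(list(center = as.numeric(center), shape = shape,
                 diameter = diameter, uptake = uptake),
            class = "lesion_spec")
}

# SUV at normalized radius u in [0,1] for a lesion uptake model (vectorised)
uptake_at <- function(uptake, u) {
  p <- uptake$peak
  switch(uptake$model,
    uniform = rep(p, length(u)),
    radial_gradient = p * (1 - (1 - uptake$rim_fraction) * u),
    necrotic_core = ifelse(u <= uptake$core_fraction, uptake$core_suv, p),
    two_compartment = ifelse(u <= uptake$f^(1 / 3), p, uptake$s * p))
}

# analytic moments over the lesion volume; u has density 3u^2 on [0,1]
uptake_moments <- function(uptake) {
  p <- uptake$peak
  switch(uptake$model,
    uniform = list(mean = p, sd = 0, max = p),
    radial_gradient = {
      a <- 1 - uptake$rim_fraction
      m <- p * (1 - a * 3 / 4)
      m2 <- p^2 * (1 - 2 * a * 3 / 4 + a^2 * 3 / 5)
      list(mean = m, sd = sqrt(max(m2 - m^2, 0)), max = p)
    },
    necrotic_core = {
      vf <- uptake$core_fraction^3
      m <- vf * uptake$core_suv + (1 - vf) * p
      m2 <- vf * uptake$core_suv^2 + (1 - vf) * p^2
      list(mean = m, sd = sqrt(max(m2 - m^2, 0)), max = max(p, uptake$core_suv))
    },
    two_compartment = {
      f <- uptake$f; s <- uptake$s
      list(mean = (f + (1 - f) * s) * p,
           sd = sqrt(f * (1 - f)) * (1 - s) * p,
           max = p)
    })
}

#' Phantom specification
#'
#' A synthetic thorax-like SUV volume: six axis-aligned rectangular lung
#' fields (upper/middle/lower x right/left) at the background SUVmean levels
#' observed in normal lung, a central blood-pool column, zero-mean Gaussian
#' noise clipped at 0 (SUV cannot be negative), and a list of lesions. The
#' default background levels (right/left upper 0.5, right middle 0.4, left
#' middle 0.5, lower 0.6 each, blood pool 1.7) match normal-lung FDG uptake
#' reference values.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param voxel_spacing mm per axis (scalar or length 3); all > 0.
#' @param background_fields named numeric: \code{ruf, luf, rmf, lmf, rlf,
#'   llf, blood_pool} mean SUV per field; all >= 0.
#' @param noise_sigma additive Gaussian noise SD in SUV units; >= 0.
#' @param lesions list of \code{\link{lesion_spec}}.
#' @param seed integer RNG seed, recorded in all outputs.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(60, 60, 60), voxel_spacing = 2,
                         background_fields = c(ruf = 0.5, luf = 0.5,
                                               rmf = 0.4, lmf = 0.5,
                                               rlf = 0.6, llf = 0.6,
                                               blood_pool = 1.7),
                         noise_sigma = 0.1, lesions = list(), seed = 1L) {
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  if (any(voxel_spacing <= 0)) stop("voxel spacings must be > 0")
  if (any(background_fields < 0)) stop("background means must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  need <- c("ruf", "luf", "rmf", "lmf", "rlf", "llf", "blood_pool")
  if (!all(need %in% names(background_fields)))
    stop("background_fields must name: ", paste(need, collapse = ", "))
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 background_fields = background_fields,
                 noise_sigma = noise_sigma, lesions = lesions,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# field layout geometry: extents, blood-pool half width, representative ROI
# centres per field (used to place 10 mm background ROIs)
phantom_field_regions <- function(spec) {
  ext <- spec$grid_shape * spec$voxel_spacing
  bpw <- max(8, 0.08 * ext[1])
  xmid <- ext[1] / 2; ymid <- ext[2] / 2
  zc <- c(upper = 5 * ext[3] / 6, middle = ext[3] / 2, lower = ext[3] / 6)
  centers <- rbind(
    ruf = c((xmid - bpw) / 2, ymid, zc["upper"]),
    luf = c((xmid + bpw + ext[1]) / 2, ymid, zc["upper"]),
    rmf = c((xmid - bpw) / 2, ymid, zc["middle"]),
    lmf = c((xmid + bpw + ext[1]) / 2, ymid, zc["middle"]),
    rlf = c((xmid - bpw) / 2, ymid, zc["lower"]),
    llf = c((xmid + bpw + ext[1]) / 2, ymid, zc["lower"]),
    blood_pool = c(xmid, ymid, zc["middle"]))
  colnames(centers) <- c("x", "y", "z")
  list(extent = ext, blood_halfwidth = bpw, roi_centers = centers)
}

#' Generate a synthetic SUV phantom with ground truth
#'
#' Builds the background fields, paints each lesion's uptake model into the
#' grid (a voxel belongs to a lesion iff its centre lies inside the analytic
#' shape), records the noiseless ground truth per lesion (closed-form moments
#' of the uptake model and the analytic shape volume), then adds clipped
#' Gaussian noise.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A list with elements \code{volume} (\code{\link{suv_volume}}, noisy),
#'   \code{masks} (one ground-truth \code{\link{voi_mask}} per lesion),
#'   \code{truth} (data.frame of analytic noiseless lesion metrics: suv_max,
#'   suv_mean, suv_sd, mtv (ml, analytic shape volume), mtv_voxel (ml, from
#'   centre-sampled voxel counting), tlg, diameter, inv_cov, auc_csh), and
#'   \code{spec}. Errors if a lesion extends outside the grid or two lesions
#'   overlap.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape; sp <- spec$voxel_spacing
  geo <- phantom_field_regions(spec)
  ext <- geo$extent; bpw <- geo$blood_halfwidth
  xs <- axis_centers(d[1], sp[1], 0)
  ys <- axis_centers(d[2], sp[2], 0)
  zs <- axis_centers(d[3], sp[3], 0)
  bf <- spec$background_fields
  # lung fields: right = low x, left = high x; z thirds upper/middle/lower
  side <- ifelse(xs <= ext[1] / 2, "r", "l")
  level <- ifelse(zs > 2 * ext[3] / 3, "u", ifelse(zs < ext[3] / 3, "l", "m"))
  fname <- outer(side, level, function(s, l) paste0(s, l, "f"))
  vol <- array(0, d)
  for (k in seq_len(d[3])) vol[, , k] <- bf[fname[, k]]
  # central blood-pool square column
  bp <- outer(abs(xs - ext[1] / 2) <= bpw, abs(ys - ext[2] / 2) <= bpw, "&")
  for (k in seq_len(d[3])) vol[, , k][bp] <- bf[["blood_pool"]]

  masks <- list(); truth <- list()
  for (li in seq_along(spec$lesions)) {
    ls <- spec$lesions[[li]]
    r <- ls$diameter / 2
    if (any(ls$center - r < 0) || any(ls$center + r > ext))
      stop(sprintf("lesion %d extends outside the grid", li))
    half <- ceiling(r / sp) + 1L
    ci <- world_to_index(ls$center, sp, d, 0)
    lo <- pmax(ci - half, 1L); hi <- pmin(ci + half, d)
    u2 <- outer(outer(((xs[lo[1]:hi[1]] - ls$center[1]) / r[1])^2,
                      ((ys[lo[2]:hi[2]] - ls$center[2]) / r[2])^2, "+"),
                ((zs[lo[3]:hi[3]] - ls$center[3]) / r[3])^2, "+")
    member <- u2 <= 1
    if (!any(member)) stop(sprintf("lesion %d is below voxel resolution", li))
    m <- array(FALSE, d)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- member
    for (prev in masks)
      if (any(m & prev$mask)) stop(sprintf("lesion %d overlaps another lesion", li))
    bg_here <- vol[ci[1], ci[2], ci[3]]
    if (ls$uptake$peak <= bg_here)
      stop(sprintf("lesion %d peak SUV (%.2f) not above background (%.2f)",
                   li, ls$uptake$peak, bg_here))
    sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    sub[member] <- uptake_at(ls$uptake, sqrt(u2[member]))
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
    masks[[li]] <- voi_mask(m, sp, method = "ground_truth",
                            params = list(lesion = li, seed = spec$seed))
    mo <- uptake_moments(ls$uptake)
    mtv_an <- pi / 6 * prod(ls$diameter) / 1000
    truth[[li]] <- data.frame(
      lesion = li, suv_max = mo$max, suv_mean = mo$mean, suv_sd = mo$sd,
      mtv = mtv_an, mtv_voxel = sum(m) * prod(sp) / 1000,
      tlg = mtv_an * mo$mean, diameter = max(ls$diameter),
      inv_cov = if (mo$sd > 0) mo$mean / mo$sd else NA_real_,
      auc_csh = mo$mean / mo$max)
  }
  if (spec$noise_sigma > 0) {
    rng <- local({ set.seed(spec$seed); stats::rnorm(prod(d), 0, spec$noise_sigma) })
    vol <- pmax(vol + array(rng, d), 0)
  }
  list(volume = suv_volume(vol, sp),
       masks = masks,
       truth = if (length(truth)) do.call(rbind, truth) else NULL,
       spec = spec)
}
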