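# Synthetic tumor phantoms and simulated observer segmentations.
#
# The generator emulates the role of a CT lung-tumor cohort: each tumor is a
# star-shaped lesion (sphere plus von Mises-Fisher spiculation bumps) with
# spatially correlated interior texture, a partial-volume edge ramp and
# additive acquisition noise, embedded in a lung-like background. Observers
# are simulated in two families: "manual" contouring (smooth random radial
# boundary displacement plus morphological smoothing and an optional
# systematic bias) and "semiauto" GrowCut segmentation seeded by randomized
# foreground/background strokes.

#' Specification of one synthetic tumor phantom
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing numeric length-3, mm per voxel (anisotropic allowed).
#' @param lesion_radius base lesion radius in mm.
#' @param spiculation_count number of spiculation bumps on the surface.
#' @param spiculation_amplitude maximal bump height in mm.
#' @param core_intensity tumor intensity in HU.
#' @param background_intensity background (lung parenchyma) intensity in HU.
#' @param texture_correlation_length Gaussian correlation length (mm) of the
#'   intratumoral texture field.
#' @param texture_sd standard deviation (HU) of the correlated texture field.
#' @param noise_sd standard deviation (HU) of uncorrelated acquisition noise.
#' @param edge_blur partial-volume edge ramp width (Gaussian sigma, mm).
#' @param seed RNG seed; the phantom is a pure function of the spec.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 22L),
                         spacing = c(1, 1, 2),
                         lesion_radius = 10,
                         spiculation_count = 4L,
                         spiculation_amplitude = 1.5,
                         core_intensity = 40,
                         background_intensity = -800,
                         texture_correlation_length = 3,
                         texture_sd = 50,
                         noise_sd = 20,
                         edge_blur = 0.8,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
               lesion_radius = lesion_radius,
               spiculation_count = as.integer(spiculation_count),
               spiculation_amplitude = spiculation_amplitude,
               core_intensity = core_intensity,
               background_intensity = background_intensity,
               texture_correlation_length = texture_correlation_length,
               texture_sd = texture_sd, noise_sd = noise_sd,
               edge_blur = edge_blur, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 5L))
    stopf("grid_shape must be 3 integers >= 5")
  if (any(spec$spacing <= 0)) stopf("spacing must be positive")
  for (f in c("lesion_radius", "spiculation_amplitude", "core_intensity",
              "background_intensity", "texture_correlation_length",
              "texture_sd", "noise_sd", "edge_blur"))
    if (!is.finite(spec[[f]])) stopf("phantom field %s must be finite", f)
  if (spec$noise_sd < 0 || spec$texture_sd < 0 || spec$spiculation_amplitude < 0)
    stopf("noise_sd, texture_sd and spiculation_amplitude must be >= 0")
  if (spec$lesion_radius <= 0) stopf("lesion_radius must be > 0")
  # lesion (with spiculations) must fit with >= 2 voxels to spare on all axes
  max_extent <- spec$lesion_radius + spec$spiculation_amplitude
  half_extent <- ((spec$grid_shape - 1) / 2 - 2) * spec$spacing
  if (any(max_extent > half_extent))
    stopf(paste0("lesion of radial extent %.1f mm does not fit the %s grid ",
                 "at spacing (%s) with a 2-voxel margin"),
          max_extent, paste(spec$grid_shape, collapse = "x"),
          paste(spec$spacing, collapse = ", "))
  invisible(spec)
}

# mm coordinates of voxel centers relative to the grid center, per axis
grid_coords <- function(grid_shape, spacing) {
  lapply(1:3, function(ax) {
    (seq_len(grid_shape[ax]) - 1 - (grid_shape[ax] - 1) / 2) * spacing[ax]
  })
}

#' Generate a synthetic tumor phantom
#'
#' Returns a CT-like intensity volume and the ground-truth tumor mask. The
#' lesion surface is a sphere of radius `lesion_radius` modulated by
#' `spiculation_count` random von Mises-Fisher bumps; the interior carries
#' Gaussian-correlated texture plus white noise and the boundary a
#' partial-volume ramp. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (`image_volume`) and `mask`
#'   (`seg_mask`, the ground truth).
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' ph$volume; ph$mask
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  d <- spec$grid_shape
  sp <- spec$spacing
  cc <- grid_coords(d, sp)
  X <- array(cc[[1]], d)
  Y <- aperm(array(cc[[2]], d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(cc[[3]], d[c(3, 1, 2)]), c(2, 3, 1))
  r <- sqrt(X^2 + Y^2 + Z^2)
  with_seed(spec$seed, {
    # spiculated boundary radius as a function of direction
    Rfield <- array(spec$lesion_radius, d)
    if (spec$spiculation_count > 0 && spec$spiculation_amplitude > 0) {
      rs <- pmax(r, 1e-9)
      ux <- X / rs; uy <- Y / rs; uz <- Z / rs
      for (k in seq_len(spec$spiculation_count)) {
        v <- rnorm(3); v <- v / sqrt(sum(v^2))
        amp <- spec$spiculation_amplitude * runif(1, 0.5, 1)
        kappa <- runif(1, 20, 60)   # angular width of the bump
        Rfield <- Rfield + amp * exp(kappa * (ux * v[1] + uy * v[2] + uz * v[3] - 1))
      }
    }
    truth <- r <= Rfield
    dim(truth) <- d
    # partial-volume ramp: blurred indicator, exactly 1 deep inside
    S <- if (spec$edge_blur > 0)
      gaussian_smooth(array(as.double(truth), d), spec$edge_blur, sp)
    else array(as.double(truth), d)
    # snap kernel-truncation residue so the deep interior/exterior are exact
    S[S > 1 - 1e-9] <- 1
    S[S < 1e-9] <- 0
    vol <- spec$background_intensity +
      (spec$core_intensity - spec$background_intensity) * S
    if (spec$texture_sd > 0) {
      tex <- gaussian_smooth(array(rnorm(prod(d)), d),
                             spec$texture_correlation_length, sp)
      tex <- tex / sd(tex)
      vol <- vol + spec$texture_sd * tex * S
    }
    if (spec$noise_sd > 0)
      vol <- vol + array(rnorm(prod(d), sd = spec$noise_sd), d)
    list(volume = image_volume(vol, sp), mask = seg_mask(truth, sp))
  })
}

#' Simulated observer model
#'
#' @param kind `"manual"` (contouring with smooth random boundary
#'   displacement) or `"semiauto"` (GrowCut from randomized seed strokes).
#' @param boundary_jitter_sd sd (mm) of the radial boundary displacement
#'   field (manual only).
#' @param smoothing_fwhm FWHM (mm) of the displacement-field correlation;
#'   also sets the extra morphological smoothing (radius = FWHM / 2) that
#'   emulates the smoothing-out of fine shape detail in manual contours.
#' @param systematic_bias signed dilation (+) / erosion (-) in mm applied by
#'   this observer to every contour.
#' @param n_seed_strokes number of foreground seed strokes (semiauto only).
#' @param margin_factor semiauto observer idiosyncrasy: multiplies the
#'   erosion/dilation margin used for stroke placement (default 1).
#' @param seed RNG seed of this observer/run.
#' @export
observer_model <- function(kind = c("manual", "semiauto"),
                           boundary_jitter_sd = if (kind[1] == "manual") 1.5 else 0,
                           smoothing_fwhm = 4,
                           systematic_bias = 0,
                           n_seed_strokes = 3L,
                           margin_factor = 1,
                           seed = 1L) {
  kind <- match.arg(kind)
  if (boundary_jitter_sd < 0) stopf("boundary_jitter_sd must be >= 0")
  if (smoothing_fwhm < 0) stopf("smoothing_fwhm must be >= 0")
  if (n_seed_strokes < 1) stopf("n_seed_strokes must be >= 1")
  structure(list(kind = kind, boundary_jitter_sd = boundary_jitter_sd,
                 smoothing_fwhm = smoothing_fwhm,
                 systematic_bias = systematic_bias,
                 n_seed_strokes = as.integer(n_seed_strokes),
                 margin_factor = margin_factor, seed = as.integer(seed)),
            class = "observer_model")
}

# centroid (mm, relative to grid center) and volume-equivalent radius
mask_centroid <- function(mask, spacing) {
  d <- dim(mask)
  cc <- grid_coords(d, spacing)
  idx <- which(mask)
  ai <- arrayInd(idx, d)
  c(mean(cc[[1]][ai[, 1]]), mean(cc[[2]][ai[, 2]]), mean(cc[[3]][ai[, 3]]))
}

equiv_radius <- function(mask, spacing) {
  (3 * sum(mask) * prod(spacing) / (4 * pi))^(1 / 3)
}

#' Simulate a manual delineation
#'
#' Perturbs the ground-truth mask by a smoothed random radial displacement
#' field (evaluated on the spherical parameterization of the surface, so the
#' displacement is constant along rays), applies the observer's systematic
#' bias as a signed offset of the boundary, then morphological smoothing and
#' largest-component extraction. Deterministic given `model$seed`.
#'
#' @param truth ground-truth `seg_mask`.
#' @param model an [observer_model()] with `kind = "manual"`.
#' @param spacing voxel spacing; defaults to the mask's.
#' @return perturbed `seg_mask` (single connected component).
#' @export
simulate_manual_mask <- function(truth, model, spacing = NULL) {
  if (model$kind != "manual") stopf("observer model is not of kind 'manual'")
  spacing <- spacing %||% attr(truth, "spacing") %||% c(1, 1, 1)
  if (!any(truth)) stopf("truth mask is empty")
  d <- dim(truth)
  sdist <- signed_distance(truth, spacing)
  delta <- 0
  if (model$boundary_jitter_sd > 0) {
    ctr <- mask_centroid(truth, spacing)
    req <- equiv_radius(truth, spacing)
    field <- with_seed(model$seed, {
      w <- gaussian_smooth(array(rnorm(prod(d)), d),
                           model$smoothing_fwhm / 2.355, spacing)
      w / sd(w)
    })
    # sample the field on the sphere of volume-equivalent radius: project
    # each voxel along its ray from the centroid onto that sphere
    cc <- grid_coords(d, spacing)
    ai <- arrayInd(seq_len(prod(d)), d)
    px <- cc[[1]][ai[, 1]] - ctr[1]
    py <- cc[[2]][ai[, 2]] - ctr[2]
    pz <- cc[[3]][ai[, 3]] - ctr[3]
    nr <- pmax(sqrt(px^2 + py^2 + pz^2), 1e-9)
    sx <- ctr[1] + req * px / nr
    sy <- ctr[2] + req * py / nr
    sz <- ctr[3] + req * pz / nr
    ix <- pmin(pmax(round((sx - cc[[1]][1]) / spacing[1]) + 1, 1), d[1])
    iy <- pmin(pmax(round((sy - cc[[2]][1]) / spacing[2]) + 1, 1), d[2])
    iz <- pmin(pmax(round((sz - cc[[3]][1]) / spacing[3]) + 1, 1), d[3])
    delta <- model$boundary_jitter_sd *
      field[cbind(ix, iy, iz)]
    dim(delta) <- d
  }
  pert <- sdist <= delta + model$systematic_bias
  dim(pert) <- d
  if (!any(pert)) stopf("boundary perturbation emptied the mask")
  sm <- smooth_mask(pert, model$smoothing_fwhm / 2, spacing)
  if (!any(sm)) stopf("morphological smoothing emptied the mask")
  seg_mask(largest_component(sm), spacing)
}

#' Simulate a semi-automatic (GrowCut) segmentation
#'
#' Draws `model$n_seed_strokes` random foreground strokes inside the eroded
#' truth and a ring of background strokes outside the dilated truth
#' (erosion/dilation margin = 20% of the volume-equivalent radius, scaled by
#' the observer's `margin_factor`), runs [growcut()] and keeps the largest
#' foreground component. Deterministic given `model$seed`.
#'
#' @param volume `image_volume` to segment.
#' @param truth ground-truth `seg_mask` guiding stroke placement.
#' @param model an [observer_model()] with `kind = "semiauto"`.
#' @param margin_voxels,max_iters passed to [growcut()].
#' @return `seg_mask` (single connected component).
#' @export
simulate_semiauto_mask <- function(volume, truth, model,
                                   margin_voxels = 2, max_iters = 500) {
  if (model$kind != "semiauto") stopf("observer model is not of kind 'semiauto'")
  check_aligned(volume, truth)
  spacing <- spacing(volume)
  d <- dim(truth)
  req <- equiv_radius(truth, spacing)
  margin <- 0.2 * req * model$margin_factor
  fg_region <- erode_mm(truth, margin, spacing)
  if (!any(fg_region)) fg_region <- erode_mm(truth, margin / 2, spacing)
  if (!any(fg_region)) fg_region <- truth
  bg_band <- dilate_mm(truth, 2 * margin + 2, spacing) &
    !dilate_mm(truth, margin, spacing)
  dim(bg_band) <- d
  if (!any(bg_band)) stopf("no room outside the lesion for background strokes")

  seeds <- with_seed(model$seed, {
    s <- array(0L, d)
    place_strokes(s, fg_region, 1L, model$n_seed_strokes, spacing)
  })
  seeds <- with_seed(derive_seed(model$seed, 17L), {
    n_bg <- max(6L, 2L * model$n_seed_strokes)
    place_ring_strokes(seeds, bg_band, 2L, n_bg, truth, spacing)
  })
  res <- growcut(volume, seeds, margin_voxels = margin_voxels,
                 max_iters = max_iters)
  if (!res$converged)
    stopf("GrowCut did not converge within %d iterations (%d ROI voxels)",
          max_iters, sum(res$roi))
  growcut_postprocess(res, 1L, spacing)
}

# Random walk strokes inside `region`; marks `label` into `seeds`.
place_strokes <- function(seeds, region, label, n_strokes, spacing) {
  d <- dim(seeds)
  cand <- which(region)
  len <- max(3L, round(0.8 * equiv_radius(region, spacing) / min(spacing)))
  for (k in seq_len(n_strokes)) {
    start <- arrayInd(sample(cand, 1L), d)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    pos <- as.numeric(start)
    for (step in seq_len(len)) {
      ip <- round(pos)
      if (any(ip < 1) || any(ip > d)) break
      if (!region[ip[1], ip[2], ip[3]]) break
      seeds[ip[1], ip[2], ip[3]] <- label
      pos <- pos + dir
    }
  }
  # at least one voxel must be seeded
  if (!any(seeds == label)) {
    ip <- arrayInd(cand[ceiling(length(cand) / 2)], d)
    seeds[ip[1], ip[2], ip[3]] <- label
  }
  seeds
}

# Background strokes stratified over directions so the seed hull surrounds
# the lesion: for each of `n_strokes` quasi-uniform directions, start at the
# band voxel closest (in angle) to that direction, then walk randomly
# within the band.
place_ring_strokes <- function(seeds, band, label, n_strokes, truth, spacing) {
  d <- dim(seeds)
  ctr <- mask_centroid(truth, spacing)
  cc <- grid_coords(d, spacing)
  cand <- which(band)
  ai <- arrayInd(cand, d)
  vx <- cc[[1]][ai[, 1]] - ctr[1]
  vy <- cc[[2]][ai[, 2]] - ctr[2]
  vz <- cc[[3]][ai[, 3]] - ctr[3]
  nr <- pmax(sqrt(vx^2 + vy^2 + vz^2), 1e-9)
  ux <- vx / nr; uy <- vy / nr; uz <- vz / nr
  len <- max(3L, round(0.6 * equiv_radius(truth, spacing) / min(spacing)))
  for (k in seq_len(n_strokes)) {
    az <- 2 * pi * (k - 1) / n_strokes + runif(1, -0.3, 0.3)
    el <- asin(runif(1, -0.8, 0.8))
    tv <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
    best <- which.max(ux * tv[1] + uy * tv[2] + uz * tv[3])
    pos <- as.numeric(ai[best, ])
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    for (step in seq_len(len)) {
      ip <- round(pos)
      if (any(ip < 1) || any(ip > d)) break
      if (!band[ip[1], ip[2], ip[3]]) break
      seeds[ip[1], ip[2], ip[3]] <- label
      pos <- pos + dir
    }
  }
  if (!any(seeds == label)) {
    ip <- ai[1, ]
    seeds[ip[1], ip[2], ip[3]] <- label
  }
  seeds
}
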