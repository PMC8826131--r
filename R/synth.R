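# Synthetic data: ground-truth phantom volumes (ellipsoidal "bone"
# inclusions over a smooth background with a low-frequency gradient) and a
# simulator of the multi-acquisition scan protocol (vertical stage series,
# flipped series, per-acquisition gain/offset, additive noise, motor-position
# error). Everything is seed-controlled so runs are bit-identical.

#' Specify a phantom volume
#'
#' @param shape Dimensions `c(nz, ny, nx)`, each at least 8.
#' @param voxel_size_um Isotropic voxel size (default 100).
#' @param n_bodies Number of ellipsoidal inclusions (default 12); 0 gives
#'   pure background plus gradient.
#' @param density_range `c(lo, hi)` intensity added by an inclusion.
#' @param background Background intensity (default 0.05).
#' @param gradient_amplitude Amplitude of the low-frequency intensity
#'   gradient (default 0.1). A nonzero gradient makes the high-pass step of
#'   slice matching non-trivial, as in real reconstructions.
#' @param seed Integer seed; identical specs give bit-identical volumes.
#' @return An object of class `PhantomSpec`.
#' @export
phantom_spec <- function(shape = c(240L, 64L, 64L), voxel_size_um = 100,
                         n_bodies = 12L, density_range = c(0.3, 1.0),
                         background = 0.05, gradient_amplitude = 0.1,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L), voxel_size_um > 0,
            n_bodies >= 0L, length(density_range) == 2L,
            density_range[2] >= density_range[1])
  structure(list(shape = shape, voxel_size_um = as.numeric(voxel_size_um),
                 n_bodies = as.integer(n_bodies),
                 density_range = as.numeric(density_range),
                 background = as.numeric(background),
                 gradient_amplitude = as.numeric(gradient_amplitude),
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic fan-out of one master seed into per-stage child seeds, all
# below 2^31, so any stage can be re-run in isolation
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Generate a ground-truth phantom volume
#'
#' Builds a float32 volume of smooth background plus a low-frequency
#' intensity gradient plus `n_bodies` randomly placed ellipsoids of varying
#' density, every inclusion lying fully inside the volume. The returned
#' ground-truth record (background, gradient coefficients, body geometry
#' and densities) is sufficient to reconstruct the volume independently.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `stack` (float32 [image_stack()]) and `truth` (the
#'   ground-truth record).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  with_seed(spec$seed, {
    # normalised centred coordinates in [-0.5, 0.5]
    xn <- (seq_len(nx) - 1) / (nx - 1) - 0.5
    yn <- (seq_len(ny) - 1) / (ny - 1) - 0.5
    zn <- (seq_len(nz) - 1) / (nz - 1) - 0.5
    gcoef <- stats::runif(5, -1, 1)
    sep_sum <- function(cy, cx, cz)
      array(outer(cy, cx, "+"), c(ny, nx, nz)) + rep(cz, each = ny * nx)
    XY <- sep_sum(gcoef[2] * yn, gcoef[1] * xn, gcoef[3] * zn)
    XZ <- outer(rep(1, ny), outer(xn, zn))           # x * z term
    YZ <- aperm(outer(rep(1, nx), outer(yn, zn)), c(2, 1, 3))
    vol <- spec$background +
      spec$gradient_amplitude * (XY + gcoef[4] * XZ + gcoef[5] * YZ)

    bodies <- list()
    max_semi <- pmax(2, floor(c(nx, ny, nz) / 5))
    for (b in seq_len(spec$n_bodies)) {
      placed <- FALSE
      for (try_i in 1:100) {
        semi <- c(stats::runif(1, 1.5, max_semi[1]),
                  stats::runif(1, 1.5, max_semi[2]),
                  stats::runif(1, 1.5, max_semi[3]))
        lo <- semi; hi <- c(nx, ny, nz) - 1 - semi
        if (any(hi < lo)) next
        ctr <- c(stats::runif(1, lo[1], hi[1]),
                 stats::runif(1, lo[2], hi[2]),
                 stats::runif(1, lo[3], hi[3]))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place inclusion ", b,
             " inside the volume after 100 tries; enlarge the phantom")
      dens <- stats::runif(1, spec$density_range[1], spec$density_range[2])
      bodies[[b]] <- list(center = ctr, semi_axes = semi, density = dens)
      ex <- ((seq_len(nx) - 1 - ctr[1]) / semi[1])^2
      ey <- ((seq_len(ny) - 1 - ctr[2]) / semi[2])^2
      ez <- ((seq_len(nz) - 1 - ctr[3]) / semi[3])^2
      inside <- sep_sum(ey, ex, ez) <= 1
      vol[inside] <- vol[inside] + dens
    }
    truth <- list(shape = spec$shape, background = spec$background,
                  gradient_amplitude = spec$gradient_amplitude,
                  gradient_coef = gcoef, bodies = bodies,
                  seed = spec$seed)
    list(stack = image_stack(vol, dtype = "float32",
                             voxel_size_um = spec$voxel_size_um),
         truth = truth)
  })
}

#' Specify one simulated acquisition
#'
#' @param z_start_slice 0-based index of the first phantom slice covered.
#' @param n_slices Number of slices acquired.
#' @param gain,offset Per-acquisition intensity transform
#'   `gain * v + offset` applied after cutting (detector drift between
#'   scans).
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param flip_axis `NULL` for a normal series, or `"x"`/`"y"`/`"z"` for a
#'   series acquired with the specimen rotated 180 degrees about that axis.
#' @param motor_error_slices Error injected into the *recorded* motor
#'   position, in whole slices; the true cut is unaffected.
#' @param seed Seed for this acquisition's noise.
#' @return An object of class `AcquisitionSim`.
#' @export
acquisition_sim <- function(z_start_slice, n_slices, gain = 1, offset = 0,
                            noise_sigma = 0, flip_axis = NULL,
                            motor_error_slices = 0L, seed = 1L) {
  stopifnot(n_slices >= 1L, gain > 0, noise_sigma >= 0)
  if (!is.null(flip_axis)) flip_axis <- match.arg(flip_axis, c("x", "y", "z"))
  structure(list(z_start_slice = as.integer(z_start_slice),
                 n_slices = as.integer(n_slices), gain = as.numeric(gain),
                 offset = as.numeric(offset),
                 noise_sigma = as.numeric(noise_sigma),
                 flip_axis = flip_axis,
                 motor_error_slices = as.integer(motor_error_slices),
                 seed = as.integer(seed)),
            class = "AcquisitionSim")
}

#' Simulate a multi-acquisition scan series from a phantom
#'
#' Cuts each acquisition's slice range out of the phantom, then applies (in
#' order) the per-acquisition gain/offset, seeded Gaussian noise, and the
#' optional 180-degree flip. The returned metadata carries the *recorded*
#' motor position, which differs from the truth by exactly
#' `motor_error_slices * spacing`; the truth table records true slice
#' ranges, true pairwise overlaps and true flip transforms.
#'
#' @param phantom A float32 [image_stack()] (the ground-truth volume).
#' @param sims List of [acquisition_sim()] specs; slice ranges must lie
#'   inside the phantom.
#' @param base_motor_z_mm Motor position of phantom slice 0 (default 0).
#' @return A list with `acquisitions` (list of `list(stack, meta)`) and
#'   `truth` (true starts, overlaps between consecutive acquisitions, and
#'   flip axes).
#' @export
simulate_acquisitions <- function(phantom, sims, base_motor_z_mm = 0) {
  validate_image_stack(phantom)
  stopifnot(length(sims) >= 1L)
  nz <- n_slices(phantom)
  sp <- phantom$voxel_size_um / 1000
  out <- vector("list", length(sims))
  true_start <- integer(length(sims))
  for (i in seq_along(sims)) {
    s <- sims[[i]]
    stopifnot(inherits(s, "AcquisitionSim"))
    z0 <- s$z_start_slice
    if (z0 < 0L || z0 + s$n_slices > nz)
      stop("acquisition ", i, " slice range [", z0, ", ",
           z0 + s$n_slices - 1, "] lies outside the phantom (",
           nz, " slices)")
    sub <- phantom$data[, , (z0 + 1L):(z0 + s$n_slices), drop = FALSE]
    sub <- s$gain * sub + s$offset
    if (s$noise_sigma > 0)
      sub <- sub + with_seed(s$seed,
                             array(stats::rnorm(length(sub), 0, s$noise_sigma),
                                   dim(sub)))
    if (!is.null(s$flip_axis)) sub <- flip_volume(sub, s$flip_axis)
    meta <- acquisition_meta(
      base_motor_z_mm + (z0 + s$motor_error_slices) * sp,
      sp, s$n_slices,
      orientation = if (is.null(s$flip_axis)) "down" else "up",
      label = sprintf("acq_%02d", i))
    out[[i]] <- list(stack = image_stack(sub, dtype = "float32",
                                         voxel_size_um = phantom$voxel_size_um),
                     meta = meta)
    true_start[i] <- z0
  }
  overlaps <- if (length(sims) >= 2L) {
    vapply(2:length(sims), function(i) {
      prev_end <- true_start[i - 1L] + sims[[i - 1L]]$n_slices
      max(0L, min(prev_end - true_start[i], sims[[i]]$n_slices,
                  sims[[i - 1L]]$n_slices))
    }, 0L)
  } else integer(0)
  truth <- list(
    true_z_start = true_start,
    true_overlap_slices = as.integer(overlaps),
    flip_axis = lapply(sims, function(s)
      if (is.null(s$flip_axis)) "none" else s$flip_axis),
    motor_error_slices = vapply(sims, function(s) s$motor_error_slices, 0L),
    gain = vapply(sims, function(s) s$gain, 0),
    offset = vapply(sims, function(s) s$offset, 0),
    noise_sigma = vapply(sims, function(s) s$noise_sigma, 0))
  list(acquisitions = out, truth = truth)
}
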