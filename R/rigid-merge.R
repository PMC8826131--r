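# Rigid flip-merge path: merging an acquisition taken with the specimen
# flipped (180 degrees about one axis) onto an unflipped one. The search is
# deliberately constrained to the physically known move -- one 180-degree
# flip plus an integer-voxel translation -- which keeps it exhaustive,
# deterministic and checkable against a ground-truth phantom.
#
# Coordinate convention: a stack's own world frame places voxel index
# (0-based) i at position voxel_size_mm * (x, y, z), with x along columns,
# y along rows, z along slices. A RigidTransform maps moving-frame world
# coordinates into fixed-frame world coordinates: p_fixed = R p_moving + T.

#' Create a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1),
#'   acting on (x, y, z) world coordinates.
#' @param translation_mm Length-3 translation in mm.
#' @param provenance `"user-supplied"` or `"searched"`.
#' @return An object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation, translation_mm,
                            provenance = c("user-supplied", "searched")) {
  provenance <- match.arg(provenance)
  rotation <- as.matrix(rotation)
  if (!identical(dim(rotation), c(3L, 3L)) || !is.numeric(rotation))
    stop("rotation must be a numeric 3x3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal (tolerance 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix must be proper (det = +1)")
  translation_mm <- as.numeric(translation_mm)
  if (length(translation_mm) != 3L || any(!is.finite(translation_mm)))
    stop("translation_mm must be a finite length-3 vector")
  structure(list(rotation = rotation, translation_mm = translation_mm,
                 provenance = provenance),
            class = "RigidTransform")
}

#' Invert a rigid transform
#' @param t A [rigid_transform()].
#' @return The inverse `RigidTransform`.
#' @export
invert_rigid <- function(t) {
  stopifnot(inherits(t, "RigidTransform"))
  rigid_transform(t(t$rotation),
                  as.numeric(-t(t$rotation) %*% t$translation_mm),
                  provenance = t$provenance)
}

#' Rotation matrix of a 180-degree flip
#' @param axis Axis to flip about: `"x"`, `"y"`, `"z"`, or `"none"` for the
#'   identity.
#' @return A 3x3 rotation matrix.
#' @export
flip_rotation <- function(axis = c("x", "y", "z", "none")) {
  axis <- match.arg(axis)
  switch(axis,
         x = diag(c(1, -1, -1)),
         y = diag(c(-1, 1, -1)),
         z = diag(c(-1, -1, 1)),
         none = diag(3))
}

#' Describe a target resampling grid
#'
#' @param dim Target dimensions `c(ny, nx, nz)`.
#' @param voxel_size_um Isotropic voxel size of the target grid.
#' @param origin_mm World position (fixed frame, mm) of target voxel
#'   (0, 0, 0), as `c(x, y, z)`.
#' @return An object of class `RefGeometry`.
#' @export
ref_geometry <- function(dim, voxel_size_um, origin_mm = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L), voxel_size_um > 0,
            length(origin_mm) == 3L)
  structure(list(dim = dim, voxel_size_um = as.numeric(voxel_size_um),
                 origin_mm = as.numeric(origin_mm)),
            class = "RefGeometry")
}

#' Resample a stack through a rigid transform
#'
#' Resamples the source stack into the reference grid by trilinear
#' interpolation. For every target voxel the inverse transform gives the
#' source position; positions that fall outside the source volume are
#' marked empty in the returned stack's `mask` and excluded from any later
#' blending. Source positions within 1e-7 voxel of a lattice point are
#' snapped to it, so lattice-aligned flips and integer-voxel translations
#' are value-exact with no interpolation blur.
#'
#' @param stack Source [image_stack()].
#' @param t A [rigid_transform()] mapping source world coordinates into the
#'   reference frame.
#' @param reference A [ref_geometry()] describing the target grid.
#' @return An [image_stack()] on the reference grid with a validity `mask`.
#' @export
apply_rigid <- function(stack, t, reference) {
  validate_image_stack(stack)
  stopifnot(inherits(t, "RigidTransform"), inherits(reference, "RefGeometry"))
  d_s <- dim(stack$data)
  ny_s <- d_s[1]; nx_s <- d_s[2]; nz_s <- d_s[3]
  ny <- reference$dim[1]; nx <- reference$dim[2]; nz <- reference$dim[3]
  v_t <- reference$voxel_size_um / 1000
  v_s <- stack$voxel_size_um / 1000

  # target world coordinates, separable per axis
  px <- reference$origin_mm[1] + v_t * (seq_len(nx) - 1)
  py <- reference$origin_mm[2] + v_t * (seq_len(ny) - 1)
  pz <- reference$origin_mm[3] + v_t * (seq_len(nz) - 1)
  Rt <- t(t$rotation)  # inverse rotation
  tr <- t$translation_mm
  # source coords s = R^T (p - T); build as separable sums over (y, x, z)
  sep_sum <- function(cy, cx, cz) {
    m <- outer(cy, cx, "+")
    array(m, c(ny, nx, nz)) + rep(cz, each = ny * nx)
  }
  sx <- sep_sum(Rt[1, 2] * (py - tr[2]), Rt[1, 1] * (px - tr[1]),
                Rt[1, 3] * (pz - tr[3])) / v_s
  sy <- sep_sum(Rt[2, 2] * (py - tr[2]), Rt[2, 1] * (px - tr[1]),
                Rt[2, 3] * (pz - tr[3])) / v_s
  sz <- sep_sum(Rt[3, 2] * (py - tr[2]), Rt[3, 1] * (px - tr[1]),
                Rt[3, 3] * (pz - tr[3])) / v_s

  snap <- function(g) {
    r <- round(g)
    near <- abs(g - r) < 1e-7
    g[near] <- r[near]
    g
  }
  sx <- snap(sx); sy <- snap(sy); sz <- snap(sz)
  valid <- sx >= 0 & sx <= nx_s - 1 & sy >= 0 & sy <= ny_s - 1 &
    sz >= 0 & sz <= nz_s - 1
  out <- array(0, c(ny, nx, nz))
  idx <- which(valid)
  if (length(idx) > 0L) {
    gx <- sx[idx]; gy <- sy[idx]; gz <- sz[idx]
    x0 <- floor(gx); y0 <- floor(gy); z0 <- floor(gz)
    fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
    x1 <- pmin(x0 + 1, nx_s - 1); y1 <- pmin(y0 + 1, ny_s - 1)
    z1 <- pmin(z0 + 1, nz_s - 1)
    lin <- function(yy, xx, zz) yy + ny_s * xx + ny_s * nx_s * zz + 1
    V <- stack$data
    val <-
      (1 - fx) * (1 - fy) * (1 - fz) * V[lin(y0, x0, z0)] +
      fx       * (1 - fy) * (1 - fz) * V[lin(y0, x1, z0)] +
      (1 - fx) * fy       * (1 - fz) * V[lin(y1, x0, z0)] +
      fx       * fy       * (1 - fz) * V[lin(y1, x1, z0)] +
      (1 - fx) * (1 - fy) * fz       * V[lin(y0, x0, z1)] +
      fx       * (1 - fy) * fz       * V[lin(y0, x1, z1)] +
      (1 - fx) * fy       * fz       * V[lin(y1, x0, z1)] +
      fx       * fy       * fz       * V[lin(y1, x1, z1)]
    out[idx] <- val
  }
  if (stack$dtype == "uint16") {
    out <- round_half_up(out)
    out[out < 0] <- 0; out[out > 65535] <- 65535
    storage.mode(out) <- "integer"
  }
  image_stack(out, dtype = stack$dtype,
              voxel_size_um = reference$voxel_size_um, mask = valid)
}

# reverse the two axes orthogonal to `axis` (the index-space action of a
# 180-degree rotation); axis = "none" returns the input
flip_volume <- function(arr, axis) {
  d <- dim(arr)
  switch(axis,
         x = arr[d[1]:1, , d[3]:1, drop = FALSE],
         y = arr[, d[2]:1, d[3]:1, drop = FALSE],
         z = arr[d[1]:1, d[2]:1, , drop = FALSE],
         none = arr)
}

#' Search the alignment of a flipped acquisition
#'
#' Constrained stand-in for interactive rigid registration: the rotation is
#' fixed to a known 180-degree flip about one axis (or the identity), and an
#' exhaustive, deterministic search over integer-voxel translations inside
#' the given windows minimises the mean [match_score()] (standard deviation
#' of high-pass-filtered slice differences) over the candidate overlap band.
#'
#' @param fixed,moving [image_stack()]s with identical in-plane shape and
#'   voxel size. `moving` is the flipped series.
#' @param axis Flip axis (`"x"`, `"y"`, `"z"`) or `"none"` to allow the
#'   identity rotation.
#' @param z_window_slices Half-width of the slice-offset search: offsets
#'   `z_offset_hint - z_window_slices .. z_offset_hint + z_window_slices`
#'   are scored.
#' @param z_offset_hint Centre of the slice-offset search window (default
#'   0). For a flipped series stacked on top of the fixed one, pass the
#'   offset predicted by the motor positions, e.g.
#'   `n_fixed - expected_overlap`.
#' @param inplane_window_px Half-width of the in-plane shift search
#'   (default 0: no in-plane search, matching a shared rotation axis).
#' @param sigma_px High-pass scale (default 4).
#' @return A [rigid_transform()] (provenance `"searched"`) with attributes
#'   `offset_voxels` (the `c(dx, dy, dz)` integer shift), `at_edge` (`TRUE`
#'   when the optimum lies on the window boundary -- reported, never a
#'   silent success), and `score_table` (slice offset vs score at the best
#'   in-plane shift).
#' @export
search_flip_alignment <- function(fixed, moving, axis = c("x", "y", "z", "none"),
                                  z_window_slices = 15L, z_offset_hint = 0L,
                                  inplane_window_px = 0L, sigma_px = 4.0) {
  axis <- match.arg(axis)
  validate_image_stack(fixed); validate_image_stack(moving)
  if (!identical(dim(fixed$data)[1:2], dim(moving$data)[1:2]))
    stop("fixed and moving stacks differ in in-plane shape")
  if (abs(fixed$voxel_size_um - moving$voxel_size_um) >
      1e-6 * fixed$voxel_size_um)
    stop("fixed and moving stacks differ in voxel size")
  zw <- as.integer(z_window_slices); pw <- as.integer(inplane_window_px)
  hint <- as.integer(z_offset_hint)
  stopifnot(zw >= 1L, pw >= 0L)
  d <- dim(fixed$data); ny <- d[1]; nx <- d[2]
  nf <- d[3]; nm <- dim(moving$data)[3]

  mflip <- flip_volume(moving$data, axis)
  hpf <- array(0, dim(fixed$data))
  for (k in seq_len(nf)) hpf[, , k] <- highpass(fixed$data[, , k], sigma_px)
  hpm <- array(0, dim(mflip))
  for (k in seq_len(nm)) hpm[, , k] <- highpass(mflip[, , k], sigma_px)

  dzs <- hint + (-zw:zw)
  shifts <- expand.grid(dx = -pw:pw, dy = -pw:pw)
  best <- NULL
  dz_scores <- rep(NA_real_, length(dzs))
  any_band <- FALSE
  for (si in seq_len(nrow(shifts))) {
    dx <- shifts$dx[si]; dy <- shifts$dy[si]
    rm0 <- max(0L, -dy); rm1 <- min(ny - 1L, ny - 1L - dy)
    cm0 <- max(0L, -dx); cm1 <- min(nx - 1L, nx - 1L - dx)
    if (rm0 > rm1 || cm0 > cm1) next
    rows_m <- (rm0:rm1) + 1L; rows_f <- rows_m + dy
    cols_m <- (cm0:cm1) + 1L; cols_f <- cols_m + dx
    for (zi in seq_along(dzs)) {
      dz <- dzs[zi]
      j0 <- max(0L, -dz); j1 <- min(nm - 1L, nf - 1L - dz)
      if (j0 > j1) next
      any_band <- TRUE
      band <- j0:j1
      s <- vapply(band, function(j) {
        sd_pop(hpm[rows_m, cols_m, j + 1L] -
                 hpf[rows_f, cols_f, j + dz + 1L])
      }, 0)
      sc <- mean(s)
      dz_scores[zi] <- if (is.na(dz_scores[zi])) sc else
        min(dz_scores[zi], sc)
      cand <- list(score = sc, dx = dx, dy = dy, dz = dz)
      if (is.null(best) || sc < best$score ||
          (sc == best$score &&
           (abs(dz - hint) < abs(best$dz - hint) ||
            (abs(dz - hint) == abs(best$dz - hint) && dz < best$dz))))
        best <- cand
    }
  }
  if (!any_band)
    stop("no candidate placement yields an overlap band; ",
         "widen z_window_slices or check the stacks")
  at_edge <- abs(best$dz - hint) == zw ||
    (pw > 0L && (abs(best$dx) == pw || abs(best$dy) == pw))
  if (at_edge)
    warning("best flip alignment lies on the search-window boundary; ",
            "the true offset may be outside the window")
  v <- fixed$voxel_size_um / 1000
  r0 <- switch(axis,
               x = c(0, ny - 1, nm - 1),
               y = c(nx - 1, 0, nm - 1),
               z = c(nx - 1, ny - 1, 0),
               none = c(0, 0, 0))
  tr <- rigid_transform(flip_rotation(axis),
                        v * (r0 + c(best$dx, best$dy, best$dz)),
                        provenance = "searched")
  attr(tr, "offset_voxels") <- c(dx = best$dx, dy = best$dy, dz = best$dz)
  attr(tr, "at_edge") <- at_edge
  attr(tr, "score_table") <- data.frame(dz = dzs, score = dz_scores)
  tr
}

#' Merge two stacks resampled onto one reference grid
#'
#' Combines a fixed and a resampled (moved) stack living on the same grid.
#' Voxels covered by only one source are copied; voxels covered by both are
#' blended with the [blend_weights()] ramp along the slice axis across the
#' overlap band (the source whose footprint starts lower fades out going
#' up). The output has no empty voxels inside the union of the two
#' footprints.
#'
#' @param fixed,moved [image_stack()]s with identical dimensions, dtype and
#'   voxel size; missing `mask` means fully valid.
#' @return The merged [image_stack()] with the union mask.
#' @export
merge_registered <- function(fixed, moved) {
  validate_image_stack(fixed); validate_image_stack(moved)
  if (!identical(dim(fixed$data), dim(moved$data)))
    stop("stacks are not on the same reference grid")
  if (fixed$dtype != moved$dtype) stop("stacks differ in dtype")
  if (abs(fixed$voxel_size_um - moved$voxel_size_um) >
      1e-6 * fixed$voxel_size_um)
    stop("stacks differ in voxel size")
  d <- dim(fixed$data)
  mA <- fixed$mask %||% array(TRUE, d)
  mB <- moved$mask %||% array(TRUE, d)
  if (!any(mA) && !any(mB)) stop("both sources are empty")
  out <- array(0, d)
  out[mA] <- fixed$data[mA]
  onlyB <- mB & !mA
  out[onlyB] <- moved$data[onlyB]
  both <- mA & mB
  if (any(both)) {
    zs_both <- which(apply(both, 3, any))
    band <- min(zs_both):max(zs_both)
    L <- length(band)
    plan <- blend_weights(L)
    zA <- min(which(apply(mA, 3, any)))
    zB <- min(which(apply(mB, 3, any)))
    a_is_bottom <- zA <= zB
    for (t_i in seq_len(L)) {
      k <- band[t_i]
      sel <- both[, , k]
      if (!any(sel)) next
      # weight of the lower source decreases going up through the band
      w_low <- plan$w_bottom[L - t_i + 1L]
      wA <- if (a_is_bottom) w_low else 1 - w_low
      # fixed + (1-wA) * (moved - fixed): weighted average that returns the
      # shared value exactly when the sources agree
      sl <- fixed$data[, , k] +
        (1 - wA) * (moved$data[, , k] - fixed$data[, , k])
      cur <- out[, , k]
      cur[sel] <- sl[sel]
      out[, , k] <- cur
    }
  }
  if (fixed$dtype == "uint16") {
    out <- round_half_up(out)
    storage.mode(out) <- "integer"
  }
  image_stack(out, dtype = fixed$dtype, voxel_size_um = fixed$voxel_size_um,
              mask = mA | mB)
}

#' Merge a flipped acquisition onto a fixed one
#'
#' High-level flip-merge: finds (or accepts) the rigid transform aligning
#' the flipped series, builds a reference grid covering the union of both
#' footprints along the slice axis, resamples both stacks onto it, and
#' blends with [merge_registered()].
#'
#' @param fixed,moving [image_stack()]s; `moving` is the flipped series.
#' @param transform Optional [rigid_transform()] (user-supplied). When
#'   `NULL`, [search_flip_alignment()] is run with the remaining arguments.
#' @param axis,z_window_slices,z_offset_hint,inplane_window_px,sigma_px
#'   Passed to [search_flip_alignment()] when `transform` is `NULL`.
#' @return A list with `stack` (the merged volume), `transform` (the one
#'   used) and `report` (offsets, scores, warnings).
#' @export
merge_flip <- function(fixed, moving, transform = NULL,
                       axis = c("x", "y", "z", "none"),
                       z_window_slices = 15L, z_offset_hint = 0L,
                       inplane_window_px = 0L, sigma_px = 4.0) {
  axis <- match.arg(axis)
  validate_image_stack(fixed); validate_image_stack(moving)
  warnings <- character()
  if (is.null(transform)) {
    transform <- withCallingHandlers(
      search_flip_alignment(fixed, moving, axis = axis,
                            z_window_slices = z_window_slices,
                            z_offset_hint = z_offset_hint,
                            inplane_window_px = inplane_window_px,
                            sigma_px = sigma_px),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  v <- fixed$voxel_size_um / 1000
  dm <- dim(moving$data)
  corners <- as.matrix(expand.grid(x = c(0, dm[2] - 1), y = c(0, dm[1] - 1),
                                   z = c(0, dm[3] - 1)))
  mapped_z <- apply(corners, 1, function(cn) {
    (transform$rotation %*% (v * cn) + transform$translation_mm)[3] / v
  })
  nf <- n_slices(fixed)
  z_lo <- floor(min(0, round(min(mapped_z), 6)))
  z_hi <- ceiling(max(nf - 1, round(max(mapped_z), 6)))
  grid <- ref_geometry(c(dim(fixed$data)[1:2], z_hi - z_lo + 1L),
                       fixed$voxel_size_um, origin_mm = c(0, 0, z_lo * v))
  fixed_rs <- apply_rigid(fixed, rigid_transform(diag(3), c(0, 0, 0)), grid)
  moving_rs <- apply_rigid(moving, transform, grid)
  merged <- merge_registered(fixed_rs, moving_rs)
  report <- list(
    transform = list(rotation = transform$rotation,
                     translation_mm = transform$translation_mm,
                     provenance = transform$provenance),
    offset_voxels = as.list(attr(transform, "offset_voxels")),
    at_edge = attr(transform, "at_edge"),
    grid = list(dim = grid$dim, origin_mm = grid$origin_mm),
    warnings = warnings)
  list(stack = merged, transform = transform, report = report)
}
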