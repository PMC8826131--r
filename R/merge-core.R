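# Algorithmic core of the vertical merge: dynamic-range conversion, coarse
# overlap from motor positions, fine overlap by high-pass / standard-deviation
# slice matching, weighted-average blending, and the pairwise vertical merge.

#' Dynamic-range scaling parameters
#'
#' The affine map taking 32-bit reconstructed intensities onto the 16-bit
#' output range: `lo` maps to 0 and `hi` to 65535. In practice `lo`/`hi` are
#' chosen by the user from the 32-bit histogram, and the *same* pair must be
#' applied to every acquisition of one specimen so that intensities remain
#' comparable across the merged volume.
#'
#' @param lo Intensity mapped to 0.
#' @param hi Intensity mapped to 65535; must exceed `lo`.
#' @return An object of class `RangeScaling`.
#' @export
range_scaling <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L,
            length(hi) == 1L, is.finite(lo), is.finite(hi))
  if (hi <= lo) stop("range scaling requires hi > lo (got lo=", lo,
                     ", hi=", hi, ")")
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "RangeScaling")
}

#' Convert a 32-bit float stack to 16-bit unsigned
#'
#' Each voxel `v` maps to `round(65535 * (v - lo) / (hi - lo))` with round
#' half up, clamped to `[0, 65535]`. The map is monotone non-decreasing, so
#' intensity ordering is preserved up to rounding/clamping ties. Shape and
#' voxel geometry are unchanged.
#'
#' @param stack A float32 [image_stack()].
#' @param scaling A [range_scaling()].
#' @return A uint16 [image_stack()].
#' @export
convert_dynamic_range <- function(stack, scaling) {
  validate_image_stack(stack)
  stopifnot(inherits(scaling, "RangeScaling"))
  q <- round_half_up(65535 * (stack$data - scaling$lo) /
                       (scaling$hi - scaling$lo))
  q[q < 0] <- 0
  q[q > 65535] <- 65535
  storage.mode(q) <- "integer"
  image_stack(q, dtype = "uint16", voxel_size_um = stack$voxel_size_um,
              slice_axis_label = stack$slice_axis_label, mask = stack$mask)
}

#' Coarse slice overlap from motor positions
#'
#' First stage of overlap estimation: from the recorded stage motor
#' positions alone, count the whole slice positions the two acquisitions'
#' physical spans have in common:
#' `round((z_bottom_end - z_top_start) / spacing) + 1`, floored at 0 and
#' capped at `min(n_bottom, n_top)`.
#'
#' @param meta_bottom,meta_top [acquisition_meta()] for the physically lower
#'   and upper acquisition; they must share the slice spacing (relative
#'   tolerance 1e-6) and `meta_top` must not start below `meta_bottom`.
#' @return Non-negative integer overlap in slices. Zero comes with a
#'   no-overlap warning.
#' @export
coarse_overlap <- function(meta_bottom, meta_top) {
  stopifnot(inherits(meta_bottom, "AcquisitionMeta"),
            inherits(meta_top, "AcquisitionMeta"))
  sp <- meta_bottom$slice_spacing_mm
  if (abs(sp - meta_top$slice_spacing_mm) > 1e-6 * sp)
    stop("slice spacing mismatch between '", meta_bottom$label, "' (",
         sp, " mm) and '", meta_top$label, "' (",
         meta_top$slice_spacing_mm, " mm)")
  if (meta_top$motor_z_mm < meta_bottom$motor_z_mm)
    stop("'", meta_top$label, "' starts below '", meta_bottom$label,
         "'; pass the physically lower acquisition first")
  z_bottom_end <- meta_bottom$motor_z_mm +
    (meta_bottom$n_slices - 1) * sp
  ov <- round_half_up((z_bottom_end - meta_top$motor_z_mm) / sp) + 1
  if (ov <= 0) {
    warning("acquisitions '", meta_bottom$label, "' and '", meta_top$label,
            "' do not overlap according to motor positions")
    return(0L)
  }
  as.integer(min(ov, meta_bottom$n_slices, meta_top$n_slices))
}

#' Choose the reference slice and the candidate target window
#'
#' Second-stage setup: the overlap occupies the bottom end of the top stack
#' (0-based indices `0 .. coarse-1`), so the reference slice is its middle,
#' `floor((coarse - 1) / 2)`. The candidates are `window` consecutive
#' 0-based indices of the bottom stack centred (floor-centred for even
#' windows, i.e. the extra candidate goes to the lower side) on the
#' position the motor estimate predicts for the reference,
#' `n_bottom - coarse + reference`, clipped to the stack bounds.
#'
#' @param n_top,n_bottom Slice counts of the two stacks.
#' @param coarse Coarse overlap from [coarse_overlap()]; must be in
#'   `[1, min(n_top, n_bottom)]`. A coarse overlap of 0 cannot be refined:
#'   supply a manual offset instead.
#' @param window Number of candidate target slices (default 30).
#' @return A list with `reference_index_top` (0-based), `candidates`
#'   (0-based bottom indices) and `at_window_edge` (`TRUE` when the window
#'   was clipped by the stack bounds).
#' @export
select_reference_and_targets <- function(n_top, n_bottom, coarse,
                                         window = 30L) {
  n_top <- as.integer(n_top); n_bottom <- as.integer(n_bottom)
  coarse <- as.integer(coarse); window <- as.integer(window)
  stopifnot(n_top >= 1L, n_bottom >= 1L, window >= 1L)
  if (coarse < 1L)
    stop("coarse overlap is 0: the fine search cannot be anchored; ",
         "supply a manual offset or corrected motor positions")
  if (coarse > min(n_top, n_bottom))
    stop("coarse overlap ", coarse, " exceeds the shorter stack (",
         min(n_top, n_bottom), " slices)")
  ref <- (coarse - 1L) %/% 2L
  centre <- n_bottom - coarse + ref
  lo <- centre - as.integer(ceiling((window - 1) / 2))
  hi <- centre + (window - 1L) %/% 2L
  cand <- lo:hi
  clipped <- cand >= 0L & cand <= n_bottom - 1L
  list(reference_index_top = ref,
       candidates = cand[clipped],
       at_window_edge = any(!clipped))
}

#' High-pass filter a slice
#'
#' Subtracts a Gaussian blur at scale `sigma_px` from the image (difference
#' of original and low-pass). This removes slowly varying illumination and
#' reconstruction gradients so that slice matching keys on anatomy; the
#' output has mean approximately 0 for large images and is exactly invariant
#' to adding a constant. Boundaries are handled by edge replication.
#'
#' @param image 2D numeric matrix with finite values.
#' @param sigma_px Gaussian scale in pixels (default 4).
#' @return A matrix of the same shape.
#' @export
highpass <- function(image, sigma_px = 4.0) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix")
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || sigma_px <= 0)
    stop("sigma_px must be a single positive number")
  if (any(!is.finite(image))) stop("image must be finite")
  image - lowpass_gaussian(image, sigma_px)
}

lowpass_gaussian <- function(image, sigma_px) {
  k <- gaussian_kernel(sigma_px, max_size = min(dim(image)))
  EBImage::filter2(image, k, boundary = "replicate")
}

# normalised 2D Gaussian kernel sampled at integer offsets, truncated at
# radius ceil(3*sigma) (capped so the convolution stays valid for small
# images), then renormalised to sum exactly 1
gaussian_kernel <- function(sigma_px, max_size = Inf) {
  r <- as.integer(ceiling(3 * sigma_px))
  if (2L * r + 1L > max_size) r <- max(0L, (as.integer(max_size) - 1L) %/% 2L)
  g1 <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Match score between two slices
#'
#' The fine-matching criterion: the population standard deviation (divide by
#' N) of the pixelwise difference between the high-pass-filtered target and
#' reference slices. It is 0 when the slices are identical and (numerically)
#' 0 when they differ only by an additive constant; the candidate with the
#' smallest score is the best-fitting slice pair.
#'
#' @param reference,target 2D matrices of identical shape.
#' @param sigma_px High-pass scale passed to [highpass()].
#' @return A non-negative number.
#' @export
match_score <- function(reference, target, sigma_px = 4.0) {
  if (!identical(dim(reference), dim(target)))
    stop("reference and target slices differ in shape")
  d <- highpass(target, sigma_px) - highpass(reference, sigma_px)
  sd_pop(d)
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Refine the overlap by high-pass / standard-deviation matching
#'
#' Scores every candidate slice of the bottom stack against the reference
#' slice of the top stack with [match_score()]; the candidate `j*` with the
#' smallest score fixes the refined overlap
#' `n_bottom - j* + reference_index_top`. Exact score ties are broken by
#' (1) the candidate whose implied overlap is closest to the coarse
#' estimate, then (2) the smaller candidate index. When the best candidate
#' sits at the window edge the estimate is flagged (and a warning suggests a
#' wider window), because the true optimum may lie outside.
#'
#' @param bottom,top [image_stack()]s sharing the in-plane shape.
#' @param coarse Coarse overlap estimate (slices), at least 1.
#' @param window Candidate window size (default 30).
#' @param sigma_px High-pass scale (default 4).
#' @return An object of class `OverlapEstimate`: a list with
#'   `coarse_overlap_slices`, `reference_index_top` (0-based),
#'   `best_target_index_bottom` (0-based), `refined_overlap_slices`,
#'   `score_table` (data frame of candidate index and score), `n_tied`,
#'   and `at_window_edge`.
#' @export
refine_overlap <- function(bottom, top, coarse, window = 30L,
                           sigma_px = 4.0) {
  validate_image_stack(bottom); validate_image_stack(top)
  if (!identical(dim(bottom$data)[1:2], dim(top$data)[1:2]))
    stop("stacks differ in in-plane shape")
  nb <- n_slices(bottom); nt <- n_slices(top)
  sel <- select_reference_and_targets(nt, nb, coarse, window)
  ref <- sel$reference_index_top
  cand <- sel$candidates
  # drop candidates whose implied overlap is infeasible for these stacks
  implied <- nb - cand + ref
  feasible <- implied >= 1L & implied <= min(nb, nt)
  truncated <- any(!feasible)
  cand <- cand[feasible]
  if (length(cand) == 0L)
    stop("no feasible candidate slices for coarse overlap ", coarse)
  hp_ref <- highpass(top$data[, , ref + 1L], sigma_px)
  scores <- vapply(cand, function(j) {
    sd_pop(highpass(bottom$data[, , j + 1L], sigma_px) - hp_ref)
  }, 0)
  if (all(!is.finite(scores)))
    stop("all candidate match scores are non-finite; cannot refine overlap")
  smin <- min(scores[is.finite(scores)])
  tied <- which(scores == smin)
  if (length(tied) > 1L) {
    dist <- abs((nb - cand[tied] + ref) - coarse)
    tied <- tied[dist == min(dist)]
    tied <- tied[which.min(cand[tied])]
  }
  best <- tied[1L]
  jstar <- cand[best]
  at_edge <- sel$at_window_edge || truncated ||
    best == 1L || best == length(cand)
  if (best == 1L || best == length(cand))
    warning("best match lies at the edge of the candidate window; ",
            "consider a wider window")
  structure(
    list(coarse_overlap_slices = as.integer(coarse),
         reference_index_top = as.integer(ref),
         best_target_index_bottom = as.integer(jstar),
         refined_overlap_slices = as.integer(nb - jstar + ref),
         score_table = data.frame(candidate = as.integer(cand),
                                  score = scores),
         n_tied = length(which(scores == smin)),
         at_window_edge = at_edge),
    class = "OverlapEstimate")
}

#' @export
print.OverlapEstimate <- function(x, ...) {
  cat(sprintf(
    "OverlapEstimate: coarse %d -> refined %d slices (ref slice %d, best target %d, min score %.6g)%s\n",
    x$coarse_overlap_slices, x$refined_overlap_slices,
    x$reference_index_top, x$best_target_index_bottom,
    min(x$score_table$score),
    if (x$at_window_edge) " [at window edge]" else ""))
  invisible(x)
}

#' Blending weights across an overlap band
#'
#' Linear weighted-average ramp over `n_overlap` shared slices, giving a
#' smooth hand-off from one acquisition to the other. `w_bottom[k]` is the
#' weight of the bottom acquisition for the k-th overlap slice counted
#' downward from the top of the band: `w_bottom[k] = k / (n_overlap + 1)`,
#' strictly increasing and never exactly 0 or 1, so neither source is ever
#' fully discarded inside the band. The top acquisition's weights are
#' `1 - w_bottom`, so each pair sums to 1 exactly.
#'
#' @param n_overlap Number of overlap slices, at least 1.
#' @return An object of class `BlendPlan` with fields `n_overlap` and
#'   `w_bottom`.
#' @export
blend_weights <- function(n_overlap) {
  n_overlap <- as.integer(n_overlap)
  if (is.na(n_overlap) || n_overlap < 1L)
    stop("n_overlap must be a positive integer")
  structure(list(n_overlap = n_overlap,
                 w_bottom = seq_len(n_overlap) / (n_overlap + 1)),
            class = "BlendPlan")
}

#' Merge two vertically overlapping stacks
#'
#' Joins a bottom and a top stack along z. Non-overlap slices are copied
#' verbatim; each of the `o` overlap slice positions is a weighted average
#' of the analogous bottom and top slices using the [blend_weights()] ramp
#' (the bottom stack's weight decreases going up through the band), computed
#' in floating point and rounded half-up only when the stacks are uint16.
#' The output has `n_bottom + n_top - o` slices, ordered bottom-first.
#'
#' @param bottom,top [image_stack()]s with identical in-plane shape, the
#'   same dtype, and matching voxel size (relative tolerance 1e-6).
#' @param overlap An `OverlapEstimate` from [refine_overlap()] or a plain
#'   non-negative integer overlap in slices.
#' @param allow_zero_overlap When `TRUE`, an overlap of 0 degenerates to
#'   plain concatenation instead of an error.
#' @return The merged [image_stack()].
#' @export
merge_vertical <- function(bottom, top, overlap, allow_zero_overlap = FALSE) {
  validate_image_stack(bottom); validate_image_stack(top)
  o <- if (inherits(overlap, "OverlapEstimate"))
    overlap$refined_overlap_slices else as.integer(overlap)
  if (!identical(dim(bottom$data)[1:2], dim(top$data)[1:2]))
    stop("stacks differ in in-plane shape")
  if (bottom$dtype != top$dtype)
    stop("stacks differ in dtype (", bottom$dtype, " vs ", top$dtype, ")")
  if (abs(bottom$voxel_size_um - top$voxel_size_um) >
      1e-6 * bottom$voxel_size_um)
    stop("stacks differ in voxel size")
  nb <- n_slices(bottom); nt <- n_slices(top)
  if (o == 0L) {
    if (!allow_zero_overlap)
      stop("overlap is 0; set allow_zero_overlap = TRUE to concatenate")
    out <- array(0, c(dim(bottom$data)[1:2], nb + nt))
    out[, , seq_len(nb)] <- bottom$data
    out[, , nb + seq_len(nt)] <- top$data
    if (bottom$dtype == "uint16") storage.mode(out) <- "integer"
    return(image_stack(out, dtype = bottom$dtype,
                       voxel_size_um = bottom$voxel_size_um))
  }
  if (o < 0L || o > min(nb, nt))
    stop("overlap must be between 1 and min(n_bottom, n_top) = ",
         min(nb, nt), ", got ", o)
  nz <- nb + nt - o
  out <- array(0, c(dim(bottom$data)[1:2], nz))
  if (nb - o >= 1L)
    out[, , seq_len(nb - o)] <- bottom$data[, , seq_len(nb - o)]
  plan <- blend_weights(o)
  for (i in seq_len(o)) {
    # ascending overlap slice i: bottom weight from the ramp's far end
    wb <- plan$w_bottom[o - i + 1L]
    wt <- 1 - wb
    # bottom + wt * (top - bottom): algebraically the weighted average, and
    # exactly the shared value when the two slices are identical
    bsl <- bottom$data[, , nb - o + i]
    s <- bsl + wt * (top$data[, , i] - bsl)
    if (bottom$dtype == "uint16") s <- round_half_up(s)
    out[, , nb - o + i] <- s
  }
  if (nt - o >= 1L)
    out[, , (nb + 1L):nz] <- top$data[, , (o + 1L):nt]
  if (bottom$dtype == "uint16") storage.mode(out) <- "integer"
  image_stack(out, dtype = bottom$dtype,
              voxel_size_um = bottom$voxel_size_um)
}

#' Run the full vertical merge pipeline
#'
#' Applies the same dynamic-range conversion to every acquisition (so
#' intensities stay comparable across parts of one specimen), then folds
#' [merge_vertical()] pairwise left-to-right in ascending motor position,
#' estimating each overlap coarsely from motor positions and refining it by
#' slice matching. Emits a machine-readable report of every coarse/refined
#' overlap, score table and warning.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{acquisitions}{list of acquisitions, each a list with `stack`
#'       (an [image_stack()]) or `path` (read via [read_stack()]), plus
#'       `motor_z_mm`, `slice_spacing_mm` and optionally `orientation` and
#'       `label`; must be in ascending motor position.}
#'     \item{scaling}{optional list with `lo`, `hi`; when present, float32
#'       acquisitions are converted with [convert_dynamic_range()] using
#'       this shared scaling (uint16 acquisitions pass through unchanged).}
#'     \item{window, sigma_px}{matching parameters (defaults 30 and 4).}
#'     \item{allow_zero_overlap}{logical, default `FALSE`.}
#'   }
#' @return A list with `stack` (the merged [image_stack()]) and `report`
#'   (a list ready for JSON serialisation: per-merge coarse/refined
#'   overlaps, score tables, tie and edge warnings, and the effective
#'   configuration).
#' @export
merge_pipeline <- function(config) {
  window <- config$window %||% 30L
  sigma_px <- config$sigma_px %||% 4.0
  allow0 <- isTRUE(config$allow_zero_overlap)
  acqs <- config$acquisitions
  if (is.null(acqs) || length(acqs) < 1L)
    stop("config must list at least one acquisition")
  scaling <- if (!is.null(config$scaling))
    range_scaling(config$scaling$lo, config$scaling$hi) else NULL

  stacks <- list(); metas <- list()
  for (i in seq_along(acqs)) {
    a <- acqs[[i]]
    label <- a$label %||% sprintf("acq_%02d", i)
    st <- if (!is.null(a$stack)) a$stack else read_stack(a$path)
    validate_image_stack(st)
    sp <- a$slice_spacing_mm %||% (st$voxel_size_um / 1000)
    metas[[i]] <- acquisition_meta(a$motor_z_mm, sp, n_slices(st),
                                   orientation = a$orientation %||% "down",
                                   label = label)
    if (!is.null(scaling) && st$dtype == "float32")
      st <- convert_dynamic_range(st, scaling)
    stacks[[i]] <- st
  }
  mz <- vapply(metas, function(m) m$motor_z_mm, 0)
  if (is.unsorted(mz))
    stop("acquisitions must be listed in ascending motor position")
  dtypes <- vapply(stacks, function(s) s$dtype, "")
  if (length(unique(dtypes)) != 1L)
    stop("acquisitions have mixed dtypes after scaling (",
         paste(unique(dtypes), collapse = ", "),
         "); supply a shared scaling so all parts are 16-bit")

  report <- list(
    parameters = list(window = window, sigma_px = sigma_px,
                      allow_zero_overlap = allow0,
                      scaling = if (is.null(scaling)) NULL else
                        list(lo = scaling$lo, hi = scaling$hi)),
    acquisitions = lapply(metas, function(m)
      list(label = m$label, motor_z_mm = m$motor_z_mm,
           slice_spacing_mm = m$slice_spacing_mm, n_slices = m$n_slices,
           orientation = m$orientation)),
    merges = list())

  cur <- stacks[[1L]]
  cur_meta <- metas[[1L]]
  if (length(stacks) >= 2L) {
    for (i in 2L:length(stacks)) {
      top <- stacks[[i]]; mt <- metas[[i]]
      entry <- list(bottom = cur_meta$label, top = mt$label)
      co <- withCallingHandlers(
        coarse_overlap(cur_meta, mt),
        warning = function(w) {
          entry$warnings <<- c(entry$warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      entry$coarse_overlap_slices <- co
      if (co == 0L) {
        if (!allow0)
          stop("acquisitions '", cur_meta$label, "' and '", mt$label,
               "' have zero overlap; set allow_zero_overlap to concatenate")
        cur <- merge_vertical(cur, top, 0L, allow_zero_overlap = TRUE)
        entry$refined_overlap_slices <- 0L
      } else {
        est <- withCallingHandlers(
          refine_overlap(cur, top, co, window = window,
                         sigma_px = sigma_px),
          warning = function(w) {
            entry$warnings <<- c(entry$warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        cur <- merge_vertical(cur, top, est)
        entry$refined_overlap_slices <- est$refined_overlap_slices
        entry$reference_index_top <- est$reference_index_top
        entry$best_target_index_bottom <- est$best_target_index_bottom
        entry$min_score <- min(est$score_table$score)
        entry$n_tied <- est$n_tied
        entry$at_window_edge <- est$at_window_edge
        entry$score_table <- est$score_table
      }
      # keep coarse estimates for later pairs anchored on recorded motor
      # positions: the merged stack's top end is the last acquisition's end
      top_end_z <- mt$motor_z_mm + (mt$n_slices - 1) * mt$slice_spacing_mm
      cur_meta <- acquisition_meta(
        top_end_z - (n_slices(cur) - 1) * mt$slice_spacing_mm,
        mt$slice_spacing_mm, n_slices(cur),
        orientation = cur_meta$orientation,
        label = paste0(cur_meta$label, "+", mt$label))
      report$merges[[length(report$merges) + 1L]] <- entry
    }
  }
  report$output <- list(n_slices = n_slices(cur),
                        dtype = cur$dtype,
                        voxel_size_um = cur$voxel_size_um)
  list(stack = cur, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
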