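---
title: "Stitching overlapping micro-CT acquisitions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitching overlapping micro-CT acquisitions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctstitch)
```

## The problem

When a specimen is larger than a micro-CT scanner's field of view, it is
imaged as several acquisitions: the stage motor moves the specimen along the
vertical axis between scans, and for very long objects the specimen may also
be physically flipped (rotated 180°) to image its far end. Each acquisition
is reconstructed independently into a stack of 2D slices, typically as
32-bit float volumes. Producing one coherent volume then requires three
post-processing steps, all implemented here:

1. **Dynamic-range conversion** — mapping the 32-bit intensities onto the
   16-bit output range with a user-chosen `(lo, hi)` window, applied
   *identically* to every acquisition of one specimen so intensities remain
   comparable across parts.
2. **Vertical merging** — estimating how many slices consecutive
   acquisitions share and blending the shared band.
3. **Flip merging** — aligning a 180°-flipped series by a rigid transform
   and blending it onto the unflipped part.

## Two-stage overlap estimation

The slice overlap between two vertically shifted acquisitions is estimated
in two stages.

**Coarse stage.** The recorded stage motor positions predict the overlap
directly: with `z_b` the motor position of the bottom acquisition's first
slice, `n_b` slices at spacing `s`, and `z_t` the top acquisition's start,
the shared whole-slice count is

```
round((z_b + (n_b - 1) s - z_t) / s) + 1
```

floored at 0 and capped at the shorter stack. Motor positions are accurate
to a few slices at most, so this anchors the fine search but is not trusted
further.

**Fine stage.** The overlap occupies the bottom end of the top stack
(0-based indices `0 .. coarse-1`), so a single *reference* slice is taken
from its middle, index `floor((coarse-1)/2)`. In the bottom stack, a window
of `window` (default 30) consecutive *target* slices is floor-centred on
the position the coarse estimate predicts for the reference. Every target
is scored against the reference, and the minimizing target `j*` fixes the
refined overlap `n_b - j* + ref`.

The score is the population standard deviation of the difference between
high-pass-filtered slices. High-pass filtering (subtraction of a Gaussian
blur, `sigma_px = 4` by default, edge-replicated boundaries) removes the
slowly varying illumination and reconstruction gradients that differ
between acquisitions, so the matching keys on anatomy; it also makes the
score exactly invariant to a constant intensity offset between
acquisitions, and in practice insensitive to modest gain drift, since a
global gain rescales all candidate scores without moving the argmin.

Numerical choices, fixed and documented so results are deterministic:

* *SD flavour*: population (divide by N). The choice cannot move the
  argmin; population SD is used because it is the plain RMS of the
  mean-removed difference.
* *Rounding*: round-half-up everywhere a slice count or pixel value is
  quantised, so nothing depends on R's round-half-to-even rule.
* *Even windows*: the extra candidate goes to the lower index.
* *Score ties*: broken toward the candidate whose implied overlap is
  closest to the coarse estimate (trust the stage metadata), then toward
  the smaller index. Tie events are counted in the report.
* *Window edges*: when the best candidate sits on the window boundary, or
  the window was clipped by the stack bounds, the estimate is flagged and a
  warning suggests a wider window. Note that a window of 30 centred on the
  predicted match *necessarily* clips whenever fewer than 14 candidate
  positions exist above it (e.g. any coarse overlap below about 29 with the
  default centring); the flag is informational, not an error.
* *Degenerate inputs*: a coarse overlap of 0 cannot anchor the fine search
  and is a hard error instructing a manual offset; `window = 1` returns
  the coarse prediction unchanged.

Only integer-slice offsets are searched — the acquisitions share a rotation
axis, so in-plane shifts are assumed absent and no sub-slice interpolation
is performed in the vertical merge.

## Blending

The `o` shared slice positions are combined by a weighted average with a
linear ramp: counting slices upward through the band, the top acquisition's
weight is `i/(o+1)` for `i = 1..o` and the bottom's is the complement. The
weights are never exactly 0 or 1 inside the band, so neither source is
discarded at the seam; pairs sum to 1 exactly. The blend is computed in
floating point as `bottom + w_top * (top - bottom)`, which returns the
shared value *exactly* when both acquisitions agree, and is rounded
(half-up) only when the output is 16-bit. Outside the band slices are
copied verbatim, giving the slice-count identity
`n_out = n_bottom + n_top - o`.

## Dynamic-range conversion

`convert_dynamic_range` maps voxel `v` to
`round(65535 (v - lo)/(hi - lo))`, clamped to `[0, 65535]`. The `(lo, hi)`
window is a user decision made once per specimen from the 32-bit histogram;
`merge_pipeline` applies the same window to every acquisition and refuses
to merge stacks of mixed pixel type, which enforces the cross-part
consistency the protocol requires. The map is monotone, so intensity
ordering is preserved up to rounding/clamping ties.

## Flip merging

The flipped series differs from the fixed one by a physically known move:
one 180° rotation about a horizontal (or, optionally, any) axis plus a
translation. Rather than emulate a general-purpose interactive
registration, `search_flip_alignment` constrains the search to exactly that
family — the fixed 180° rotation composed with integer-voxel translations —
and scores candidates with the same high-pass/SD criterion, averaged over
the candidate overlap band. The search is exhaustive inside the given
windows, hence deterministic and verifiable against ground truth.

The slice-offset window is *centred on a hint* supplied by the caller
(default 0): for a flipped series stacked on top of the fixed one the true
offset is near `n_fixed - overlap`, far from 0, so a window of fixed width
can only contain it if centred from the motor-position bookkeeping — the
same coarse-then-fine pattern as the vertical merge. An optimum on the
window boundary is flagged and warned about, never silently accepted.

Resampling (`apply_rigid`) is trilinear, with voxels that map outside the
source marked in an explicit validity mask rather than by sentinel
intensities. Source positions within 1e-7 voxel of a lattice point are
snapped, so lattice-aligned flips and integer translations are value-exact
— this is what makes "recovered exactly" a meaningful test outcome, and it
is why 180° rotations about the volume centre are exact involutions here.
`merge_registered` then copies voxels covered by a single source, blends
the z-band covered by both with the same linear ramp (the lower source
fades out going up), and guarantees no empty voxels inside the union of
footprints.

## The synthetic acquisition model

Because the original scan data cannot ship with a package, every stage is
validated against a simulator that plays the role of the scanner:

* **Phantom** (`generate_phantom`): smooth background, a low-frequency
  polynomial intensity gradient (so high-pass matching is non-trivial), and
  seed-controlled ellipsoidal inclusions of varying density standing in for
  bone, always fully inside the volume. The ground-truth record (gradient
  coefficients, body geometry, densities) can rebuild the volume
  independently, which the tests exploit as an oracle.
* **Acquisitions** (`simulate_acquisitions`): each series is cut from the
  phantom, then per-acquisition gain/offset (detector drift between
  scans), additive Gaussian noise, and an optional 180° flip are applied,
  in that order. The *recorded* motor position can be corrupted by a known
  number of slices while the true cut stays put, which is exactly the error
  the fine matching stage exists to absorb. Additive Gaussian noise is the
  appropriate model *after* reconstruction; projection-domain (Poisson)
  noise and reconstruction artifacts are out of scope along with
  reconstruction itself.
* **Seeding**: one master seed fans out to per-stage child seeds through a
  fixed derivation, so a full simulate-and-merge run is bit-identical
  across machines and any single stage can be re-run in isolation.

What the simulator does *not* emulate: beam hardening, ring artifacts,
cone-beam geometry, scatter, detector afterglow, or the high-frequency
trabecular texture of real bone. The phantom's anatomy is *smoother* than
real bone, which makes slice matching strictly harder at a given
signal-to-noise ratio (adjacent slices are more alike), so the robustness
results below are conservative in that one respect; conversely, passing
tests say nothing about artifact-contaminated data.

## Validation conditions and what they show

The test-suite problem sizes are chosen to represent the protocol at desk
scale: phantoms of 64 x 64 x 240 voxels split into two ~130-slice
acquisitions for overlap recovery (overlaps 1–40), 200 replicates at
signal-to-noise ratio 10 with gain 1.1 / offset 50 drift and up to ±10
slices of motor error for robustness (the acceptance threshold is ≥95%
within ±1 slice), a 50-case sweep comparing the windowed search against
exhaustive search, 20 lattice-exact flip cases, and a three-acquisition
end-to-end run through the command-line interface that must reproduce the
scaled phantom voxel-exactly in the noise-free case. In the noisy
end-to-end case the refinement may legitimately land one slice off (the
regime the robustness criterion accepts), so the intensity check there
compares against the same-overlap merge of the noise-free acquisitions —
identical to the phantom whenever registration is exact — and requires the
mean absolute error to stay below the injected noise sigma.

## Known limitations

* In-plane shifts between vertically merged acquisitions are assumed
  absent (shared rotation axis); the flip path searches them only if asked
  (`inplane_window_px > 0`).
* No sub-voxel registration anywhere: offsets are whole slices/voxels by
  design, matching the slice-pairing structure of the protocol.
* Intensity harmonisation is limited to the shared affine scaling; no
  histogram matching across acquisitions.
* The flip search's constrained transform family is a functional
  replacement for interactive rigid registration, not a re-implementation
  of any particular commercial tool's optimiser.
* TIFF support covers uncompressed/baseline grayscale 16-bit unsigned and
  32-bit float; vendor formats and colour are out of scope.
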