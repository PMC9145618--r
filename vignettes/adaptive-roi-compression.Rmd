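---
title: "Adaptive ROI-based compression of CT angiography volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive ROI-based compression of CT angiography volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aroi)
```

## The problem

A lower-limb CT angiography (CTA) exam is on the order of a thousand
512×512 16-bit slices — half a gigabyte per study — yet the structures a
vascular radiologist actually reads, the contrast-enhanced arteries, occupy
a few percent of each slice. Whole-volume lossless compression preserves
everything but only shrinks the data ~2–3.5×; whole-volume lossy
compression shrinks it far more but risks degrading exactly the pixels that
matter. `aroi` implements the hybrid alternative: partition every slice by
clinical relevance and spend bits accordingly.

Each slice is split into three regions that exactly tile the pixel grid:

* **PROI** (primary region of interest): the segmented arterial tree,
  enlarged by a safety margin — compressed **losslessly**;
* **SROI** (secondary region of interest): the remaining body tissue —
  compressed lossily at a **rate-controlled** bit rate;
* **background**: air outside the patient — compressed heavily at a fixed
  very low rate.

## Segmentation and the 8× safety margin

The body mask is obtained per slice by thresholding, keeping the largest
connected component (8-neighbourhood), and filling holes; the vessel mask
by thresholding inside the body and linking voxels across slices with
26-connected 3D components, discarding speckle components below a minimum
size. Both stages are deliberately biased toward over-inclusion: labelling
patient tissue as background, or vessel lumen as tissue, is the one failure
mode that would destroy clinically relevant pixels, while the converse
merely wastes a few bits.

The PROI is then grown from the vessel mask by iterated binary dilation
(3×3 cross structuring element) until its area reaches `factor` times the
vessel area, with `factor = 8` by default, capped at the full frame. The
area rule is applied **per slice**: the alternative reading (one global
factor over the whole-volume artery surface) would let vessel-poor slices
starve while vessel-rich slices over-dilate, and a per-slice rule is the
one that can be checked against a step-by-step dilation oracle. The PROI is
*not* clipped to the body mask — the margin may cover bone or adjacent
air — because clipping would reintroduce the under-segmentation risk the
margin exists to remove. With default settings the ground-truth vessels of
the phantom are always a subset of the PROI, and the SROI comes out at
roughly a third to a half of the frame, as in real abdominal-to-calf
cross-sections.

## The codec layer

The scheme is engine-agnostic; any coder meeting two contracts can be
plugged in behind the `encode_lossless()` / `encode_lossy()` /
`decode_region()` surface:

* lossless: decode is the identity on in-mask pixels for arbitrary 16-bit
  content;
* lossy: the codestream length respects the byte budget
  `bpp × n_region_pixels / 8`.

The default lossless engine serialises the in-mask pixels (column-major)
as 16-bit words and deflate-compresses them, embedding the run-length-coded
mask so the stream is self-contained. The default lossy engine fills the
frame outside the region with the region mean, subtracts that mean,
applies a multi-level (≤5) 2D Haar transform in the averaging convention
`a = (x+y)/2, d = (x−y)/2` (which keeps coefficient magnitudes within the
input range), quantises coefficients uniformly, and deflate-compresses
them. The quantisation step is found by bisection on its base-2 logarithm
over `[1, 2^17]`, 12 iterations, keeping the finest step whose codestream
fits the budget; measured rates land at or below the target with ≤10%
overshoot only in degenerate tiny-region cases where the fixed stream
header dominates. Mean-filling matters beyond ringing control: at extreme
quantisation the reconstruction degrades gracefully *to the region mean*
rather than to zero.

Out-of-region pixels carry no contract; `compose_slice()` reassembles a
frame by mask ownership, so composition with an exact partition writes
every pixel exactly once and is independent of argument order.

## Rate control: the 40 dB floor

A 40 dB PSNR is the conventional bar above which original and
reconstruction are visually indistinguishable. The variable-bit-rate
controller (`mvar_compress()`) maintains that floor per slice while
pressing the rate down wherever content allows:

1. the candidate SROI rate for slice *i* is slice *i−1*'s final rate
   reduced by 10% (multiplicative `step_down`, floored at `bpp_min`);
2. the slice is encoded (PROI lossless, SROI at the candidate rate,
   background at `bpp_background`) and the full-frame PSNR of the composed
   reconstruction against the original is measured;
3. while the PSNR is below the threshold, the SROI rate is doubled (capped
   at `bpp_max`) and the slice re-encoded — the *drop-back*;
4. if the floor is still unreachable at `bpp_max`, the run aborts naming
   the slice: the background rate is fixed, so pathologically noisy content
   can exceed what SROI bits alone can repair.

The per-slice quality target is stated in terms of slice-to-slice PSNR
behaviour; this package implements it as **rate carry-over** — each slice
inherits its predecessor's final rate as the starting candidate, with PSNR
always measured between each original slice and *its own* reconstruction.
That is the only reading under which a per-slice 40 dB guarantee and the
characteristic serrated rate/PSNR trajectory can both hold; a literal
PSNR-between-neighbouring-originals reading guarantees nothing about
reconstruction fidelity. The trace (`schedule$trace`) records attempted
rate, final rate, PSNR and retry count per slice, and the serration is
visible there: strictly decaying attempted rates except immediately after
a drop-back.

Defaults: `initial_bpp = 2`, `step_down = 0.10`, drop-back factor 2,
`bpp ∈ [0.05, 8]`, `bpp_background = 0.05`. The step sizes reproduce the
sawtooth qualitatively; no published values exist for them. The background
rate likewise has no published number — only "very high compression" — so
0.05 bpp is a documented default, not a claim.

The fixed-rate variant (`mfix_compress()`) runs every slice at the
arithmetic mean of a first variable-rate pass (`mfix_rate()`); it has no
floor, and on noisy proximal slices it drops below 40 dB — the failure
mode that motivates the controller. `plain_lossy_compress()` (whole-frame
lossy, no regions) and `lossless_baseline_compress()` (whole-frame
lossless) complete the comparator set.

## Quality metrics and the MAX = 255 convention

PSNR is `10·log10(MAX²/MSE)` with `MAX = 255`: both volumes are first
windowed linearly to the 8-bit display range (`window` defaults to the
original volume's stored range, no rounding), mirroring how CT images are
assessed on display rather than on raw 16-bit storage. The shipped
reference measurement tables (`inst/extdata/`) confirm this convention:
recomputing PSNR from the printed MSE values with MAX = 255 reproduces the
printed PSNR essentially to printed precision, while no other common peak
(4095, 65535) comes within 10 dB. The exact display window the reference
measurements used is not recoverable from the tables; only the peak
convention is. An MSE of zero reports as an infinite ("∞ dB") PSNR
sentinel. `quality_curve()` cross-checks every (PSNR, MSE) pair it emits to
1e-9 dB, and the controller uses the same windowing, so post-hoc curves
and controller traces agree exactly.

Sizes are reported in kB = 1024 bytes with the uncompressed slice as
`rows × cols × 2` bytes; compression ratios display as `"N:1"` — the
integer form when the ratio is within 1% of an integer (9.07 → "9:1"),
otherwise one decimal (3.51 → "3.5:1"). Mask overhead is charged to the
compressed size: the container stores run-length-coded PROI and body masks
per slice, and `size_summary()` works from total container bytes.

## The phantom: what it emulates, and what it does not

Patient CTA data cannot ship with a package, so `generate_phantom()`
builds the study conditions synthetically: an elliptical soft-tissue
cross-section (air 50, tissue 1080, vessels 1600 on the stored-value
scale — with intercept −1024 about +56 HU tissue and +576 HU contrast)
that tapers linearly to 80% of its proximal axes; 2–5 px-radius vessel
discs riding piecewise-linear, optionally once-branching 3D centerlines in
body-normalised coordinates (so vessels follow the taper and stay inside
the body by construction); and additive Gaussian noise interpolated from
σ = 20 proximally to σ = 5 distally, clipped to the 16-bit range. Those
sigmas sit inside the realistic 10–30 HU abdominal / 3–10 HU extremity CT
noise range and were fixed so that the default conditions exhibit the
regime the method addresses: minimum-rate SROI coding of proximal slices
falls just below the 40 dB floor, so the controller's drop-back actually
engages, and a fixed mean rate fails proximally while passing distally.
Vessels occupy well under 5% of every slice; the body covers 0.34–0.53 of
the frame.

What the phantom does **not** model: partial-volume edges (vessel discs
are binary), beam hardening, reconstruction-kernel noise correlation
(noise is white), bone, and anatomy beyond one tapering compartment.
Passing tests therefore demonstrate the *mechanism* — partition exactness,
lossless-PROI preservation, floor maintenance, rate adaptation — not
clinical image quality on real data, which additionally depends on the
segmentation thresholds transferring to real HU distributions.

## Problem sizes and numerical choices

The test suite runs most checks on 12-slice 64×64 phantoms and the
study-scale checks on the default 64-slice 256×256 phantom — large enough
for all mask-fraction and noise-gradient properties to hold at their
full-scale values, small enough that the whole suite completes in well
under a minute. 512×512 slices are supported throughout (any even
dimensions; odd dimensions degrade gracefully to fewer transform levels,
down to plain quantisation).

Other numerical choices: wide (double) accumulation in MSE; quantised
coefficients stored as 16-bit words when they fit and 32-bit otherwise;
deflate (gzip) as the entropy stage everywhere, which is deterministic, so
fixed seeds give byte-identical containers; little-endian layout
throughout the container, with integrity checked on open via magic bytes,
version, and per-region byte totals in the footer. DICOM I/O covers
exactly the uncompressed Explicit-VR-little-endian single-frame subset the
pipeline needs, with slices ordered by instance number (falling back to z
position), and is cross-validated against an independent DICOM
implementation in the test suite.

## Known limitations

* The lossy engine is a plain Haar coder, not JPEG2000: rate targeting and
  monotonicity hold, but absolute rate-distortion performance is below a
  production wavelet coder, so compression ratios measured on the phantom
  understate what a JPEG2000-family engine would achieve at the same
  floor.
* The controller guarantees the floor only where `bpp_max` plus the fixed
  background rate can reach it; it reports the offending slice otherwise
  rather than silently degrading.
* Segmentation thresholds default to phantom-calibrated midpoints; real
  exams need them set from HU landmarks.
* The human-observer side of quality assessment (opinion scoring) is out
  of scope; only the quantitative metrics are implemented.
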