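---
title: "MRI-PET fusion by band splitting, bidimensional EMD and phase congruency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRI-PET fusion by band splitting, bidimensional EMD and phase congruency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusemd)
```

## The fusion model

`fusemd` fuses a co-registered pair of 2-D slices — an anatomical MRI image
A and the luminance of a functional PET image B — on the premise that the
two carry complementary information: fine structural detail exists mostly
in A, smooth metabolic signal mostly in B.  Both images live on the
internal [0,1] float scale; 8-bit conversion happens only at file I/O and
inside histogram-based metrics.

The chain is: band split of each source, bidimensional empirical mode
decomposition (EMD) of the high bands, rolling-guidance denoising of the
intrinsic mode functions (IMFs), phase-congruency (PC) fusion of
corresponding IMF pairs, mean fusion of everything slow, additive
recombination.  Two structural identities anchor the implementation and
are enforced to machine precision:

* **band completeness** — `h1 + h2 + low` reproduces the source exactly in
  the undecimated mode, and the decimated pyramid reconstructs exactly by
  expand-and-add;
* **EMD completeness** — `imf1 + imf2 + residue` equals the decomposed band
  exactly, because the residue is defined by subtraction.

A useful corollary, exploited by the tests: with the rolling-guidance
stage disabled, fusing an image with itself returns the image (PC maps of
identical inputs tie everywhere, ties average, and all decompositions are
additive), so the whole pipeline is an exact identity on duplicated input.

## Stages and their tunables

### Band split

Undecimated mode (default): `h1 = X − G1(X)`, `h2 = G1(X) − G2(X)`,
`low = G2(X)` with Gaussian scales `sigma1 = 1` px and `sigma2 = 4` px —
one octave-plus of separation between the two detail bands, with `h1`
capturing wavelengths up to roughly 4 px and `low` everything slower than
~16 px.  All bands keep the source size, which lets every later stage work
pixel-aligned and makes the final recombination a plain sum.  The
decimated alternative (Burt–Adelson, 5-tap kernel with a = 0.375, reflect
borders) halves sizes per level; it exists for fidelity to the classical
pyramid, and fusion then operates per level with expand-and-add
recombination.  The two detail levels and one low band are fixed — the
method is defined with exactly that structure.

### Bidimensional EMD

Each high band is sifted into exactly two IMFs plus a residue.  One
sifting pass subtracts the mean envelope: strict 8-neighbour extrema are
located, each extrema set is extrapolated to a full surface by
nearest-extremum filling (nearest under the chessboard metric, by
8-neighbour distance propagation — every pixel takes the value of its
nearest masked site), the surface is Gaussian-smoothed, and
`h ← h − (upper + lower)/2`.  Design points:

* **Envelope construction.**  Scattered-data spline interpolation over
  thousands of extrema is slow and numerically fragile; the
  fill-and-smooth construction is a standard fast-BEMD approach, is a
  convex combination of the masked values (so envelopes can never escape
  their range), and degenerates gracefully (a single masked pixel gives a
  constant surface).
* **Smoothing scale.**  By default the Gaussian std is half the mean
  extrema spacing `d = sqrt(npix / nextrema)` of the current iterate, so
  the envelope follows trends slower than the oscillation being extracted
  without tracking the oscillation itself.
* **Stopping.**  A Cauchy-type criterion
  `SD = Σ(h_k − h_{k−1})² / Σh_{k−1}² < 0.2`, at most 8 passes per IMF —
  canonical EMD practice.  Sifting does not start when a band has fewer
  than 4 extrema (or lacks both a maximum and a minimum), the least
  support on which two envelopes are meaningful; such bands pass through
  as residue.

On a mixture of two product gratings (periods 4 and 32 px), the first IMF
recovers the fast component and the slow component lands in the *slow
side* of the split (`imf2 + residue`).  Note that classical EMD extracts a
pure slow sinusoid as an IMF of its own — a sinusoid *is* an intrinsic
mode — so the residue alone is a near-empty remainder on such fixtures;
tests therefore measure frequency separation at the imf1 / slow-side
boundary, which is the scientifically meaningful split.

### Rolling-guidance IMF enhancement

The rolling guidance filter is a Gaussian pre-filter followed by `n_iter`
joint bilateral stages, each guided by the previous output (`J1 = G`).  It
removes structures smaller than its spatial scale and recovers
larger-scale edges with increasing sharpness per iteration.  Generic
defaults for images are `sigma_s = 3` px, `sigma_r = 0.1` (on [0,1]),
`n_iter = 4`, window radius `ceiling(3*sigma_s)`, reflect padding (zero
padding would darken borders under the window renormalization).

Applying this stage to IMFs needs two adaptations, both defaults of
`fusion_config()`:

* **Relative range width.**  IMF dynamic ranges differ by orders of
  magnitude between bands and modalities, so `sigma_r` is interpreted in
  units of each IMF's standard deviation (the IMF is normalized by its
  dispersion, filtered, and rescaled).  The default of 0.5 standard
  deviations averages sub-dispersion fluctuation while oscillations of
  several standard deviations survive.
* **Sub-wavelength spatial scale.**  An IMF is a bandpass field: its
  "edges" are 2–4 px ridge–trough oscillations, not steps.  A spatial
  scale at or above that wavelength removes the band's entire content
  rather than denoising it (rolling guidance removes small scales
  regardless of contrast).  The stage therefore defaults to
  `sigma_s = 0.5` px, putting the scale selection below the band's own
  wavelength so that denoising is driven by the range term instead.

The enhanced copy deliberately breaks the EMD additivity identity — it is
a denoising step applied before fusion, not a re-decomposition.

### Phase-congruency fusion

Phase congruency marks pixels where log-Gabor filter responses agree in
phase across scales — edges and lines, independent of contrast polarity
and of global intensity offset (the filters have no DC response).  The
measure follows the standard log-Gabor formulation: 4 scales from a
minimum wavelength of 3 px with multiplier 2.1, 6 orientations, bandwidth
parameter 0.55, noise threshold at 2 noise-amplitude standard deviations
(Rayleigh model estimated from the smallest-scale response), and the
frequency-spread sigmoid weighting (cut-off 0.5, gain 10) that
down-weights locations where only a narrow range of scales responds —
without it, the far tails of a lone edge excite a single scale, which is
trivially "phase aligned" with itself and saturates the normalized ratio.

Two numerical choices matter:

* **Border handling.**  The image is extended to twice its size by
  even-symmetric mirroring before the FFT.  A plain periodic extension
  (with or without mean padding to even sizes) makes the image border a
  high-contrast wrap-around edge that can dominate the PC map; the mirror
  extension is exactly continuous under periodic tiling, and the result is
  cropped back.
* **Fusion rule.**  The per-pixel rule takes the value of the IMF with the
  larger PC; exact ties (including the common case of both PCs suppressed
  to zero by the noise threshold) take the mean, which makes the rule an
  automatic blend in featureless regions.  A soft variant weighting by
  `PC_a / (PC_a + PC_b)` is available (`pc_rule = "soft"`); selection is
  the default as the conventional reading of significance-driven fusion.

### Mean fusion and recombination

Residues and low bands are averaged pixel-wise.  The fused components are
summed directly in undecimated mode; in decimated mode each pyramid level
is fused at its native size and recombined by expand-and-add (a literal
sum of different-sized bands is undefined).  The output is clipped to
[0,1] by default — mean fusion and selection keep values near range, so
clipping only trims filter over/undershoot; renormalization would change
contrast globally and distort the metrics.

## The synthetic phantom generator

Real MRI–PET pairs cannot ship with the package, so all evaluation runs on
seeded phantoms (`phantom_spec()` / `generate_phantom_pair()`), built to
emulate the statistical structure of co-registered brain slice pairs:

* 4 nested random ellipses define the shared anatomy; the identical label
  mask paints both modalities, so co-registration is exact by
  construction;
* the MRI paints regions with distinct intensities and adds band-limited
  (high-pass) noise texture inside the head — fine structural detail that
  exists only in the MRI;
* the PET luminance paints regions with independent smooth uptake levels,
  blurs them (3 px, emulating low PET resolution), and adds a Gaussian
  hotspot (σ = 6 px, amplitude 0.5) inside the innermost structure —
  functional signal that exists only in the PET — before rendering through
  a fixed hot-iron pseudo-color map;
* independent additive Gaussian noise (σ = 0.01) per modality.

The default texture amplitude (0.06) was calibrated so that fused phantom
images have an average gradient in the 9–11 gray-level/pixel range
reported for fused brain MRI–PET corpora; the first-guess value (0.15)
produced fused AG near twice that range, i.e. phantoms substantially
busier than real data.

**What phantoms do not emulate.**  Real pairs share detail: anatomy shapes
uptake, so MRI structure usually has a (blurred) PET counterpart.  The
phantom design makes detail *disjoint* by construction.  One measurable
consequence: pixel-wise mean fusion is close to optimal for the
two-source-average SSIM when detail is disjoint, so PC-driven transfer of
unilateral MRI detail raises edge-transfer scores (QABF up, LABF down)
while the mean SSIM can decrease from the mean-fusion baseline — on real
data, where detail is shared, PC fusion can raise both.  Passing phantom
tests demonstrates the pipeline's structural correctness and the direction
of its edge-information gains, not clinical image quality.

A second structural fact: the ablation's phase 2 (band split + EMD with
mean fusion of every component) is *exactly* phase 1 (band split + mean
fusion), because an exact EMD is additive and averaging telescopes.  Any
observed phase-1→2 difference in an EMD fusion implementation measures its
decomposition leakage, not a fusion improvement.

## Problem sizes and runtime choices

Defaults are sized for interactive use and continuous testing: phantoms
are 128×128 (64×64 where only structure matters), the ablation and
acceptance runs use 12–20 phantom pairs, and the brute-force
double-loop oracle for the windowed filters runs on 16×16 images.  The
filters are exact windowed evaluations (no O(1) bilateral
approximations); a full default fusion of a 128×128 pair takes a few
seconds on one core.

## Known limitations

* 2-D single-slice fusion only; no registration (inputs must be
  co-registered), no DICOM, no 3-D volumes (NIfTI input is reduced to one
  axial slice).
* Exactly two IMFs per band and two detail bands — the method's fixed
  structure, not a tunable depth.
* The PC-selection rule is per-pixel; on pairs whose IMFs are dominated by
  independent noise it can splice the two noise fields (visible as a
  nonzero spurious-edge fraction NABF).  The noise threshold plus
  tie-averaging mitigates but does not remove this; the soft rule trades
  some edge transfer for smoother blending.
* Histogram metrics (EN, MI) use 256 fixed bins; the MI estimator carries
  the usual chance-agreement bias of order `(K−1)(L−1)/(2N ln 2)` bits,
  noticeable when comparing images of ~256×256 pixels.
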