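---
title: "Quality metrics for serial FIB/SEM volumes: models and methods"
author: "fibsemqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality metrics for serial FIB/SEM volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibsemqc)
```

Serial FIB/SEM imaging alternates two physical processes: a focussed ion
beam mills a thin layer off a frozen-hydrated sample, and a scanning
electron microscope images the freshly exposed block face. Repeating the
cycle yields a 3D stack whose lateral sampling is the SEM pixel size
(nm/px) and whose axial sampling is the milling step (nm/slice). Each part
of the process leaves a measurable fingerprint in the images; `fibsemqc`
implements the measurements. This vignette explains the underlying models,
the tunable parameters, what the synthetic generators emulate, and the
numerical choices that were genuinely open.

All arrays follow the `(z, y, x)` axis convention with y increasing
downward (raster row order); images are matrices `(y, x)`.

## Curtaining score

Uneven milling produces *curtains*: streaks parallel to the milling
direction, which appear as strictly vertical stripes in the block-face
image. Their spectral signature is energy concentrated near the horizontal
frequency axis (the axis encoding variation along x). The score isolates
that energy with a narrow wedge mask in the Fourier domain:

1. `stripe_image()` keeps only spectral samples whose angle from the
   horizontal frequency axis is at most `wedge_half_angle_deg` (default
   2.5&deg;, i.e. a wedge of 5&deg; total angle; whether a stated "5&deg;
   mask" means total or half angle is ambiguous, so the half-angle is an
   explicit parameter). The DC sample and a one-sample guard ring around
   it are always excluded, which makes the score exactly invariant to
   adding a constant grey offset.
2. The magnitudes of the filtered image are pooled into per-column
   medians. Curtains are by definition constant along y, so this is a
   matched aggregation along the known stripe direction: it suppresses
   isolated noise pixels and removes sensitivity to local attenuation.
3. The pooled magnitudes are thresholded by the minimum cross-entropy
   criterion (`li_threshold()`), computed image-wide; the ROI argument
   only determines *where* curtain pixels are counted. The score is
   `100 * |curtain pixels in ROI| / |ROI|`.

Two robustness rules guard degenerate inputs. If the pooled magnitudes
are constant the threshold is flagged degenerate and the score is 0. If
the two classes split by the threshold are not separated by an empty
margin of at least a quarter of the threshold — the situation for a
stripe-free image, where the magnitudes form a unimodal noise continuum
that any threshold splits somewhere in the bulk — a noise floor of
`noise_floor_k` (default 3) times the robust half-normal scale estimate
(median / 0.6745) is applied, driving the score of clean images to ~0
instead of the ~45% a blind threshold would report.

Apodization deserves a note: `stripe_image()` can taper the image with a
Tukey(0.1) window before the FFT, the usual remedy against wrap-around
leakage. For this particular filter the cure is worse than the disease:
the wedge is narrower than the taper's spectral mainlobe at low
frequencies, so windowing smears genuine stripe energy *out* of the wedge
and attenuates reconstructed curtains, while the un-windowed wrap-around
leakage produces at most a spurious column at the image border — which
the column pooling confines. `curtain_score()` therefore defaults to
`apodize = FALSE`; the flag remains for images with violent edge
gradients.

## Fourier ring correlation

`frc_two_image()` is the standard estimator: the spectra of two
independent-noise images of the same field of view are cross-correlated
within radial frequency rings,

$$\mathrm{FRC}(r) = \frac{\Re \sum_{|f| \in r} F_a(f) \overline{F_b(f)}}
  {\sqrt{\sum_{|f| \in r} |F_a|^2 \sum_{|f| \in r} |F_b|^2}},$$

with frequency normalized to Nyquist (1 = Nyquist) so that images of
different sizes compare directly. The resolution is the first frequency
where the curve falls below 0.143, linearly interpolated between rings
(`crossing_frequency()`), and converts to nm as `2 * pixel_nm / crossing`
— a crossing of 1 is the Nyquist period of two pixels, so resolution can
never beat `2 * pixel_nm`. Rings are one frequency sample wide by default
(`ring_width`); both FRC routines apodize with a Tukey(0.25) taper,
applied identically during calibration and application.

### One-image FRC

Serial data contain no second exposure, so the resolution of a single
image is estimated by splitting it into two images with independent
noise. Two splits are implemented:

* **Parity (default).** The checkerboard parity classes (pixels with
  even vs odd y+x) are kept on the full-size grid, with the other class
  zero-filled, and correlated ring by ring. Multiplying by a checkerboard
  shifts a copy of the spectrum to the Nyquist corner, so each half is
  `(F ± G)/2` with `G` the corner-shifted spectrum; the cross-spectrum
  `(|F|^2 − |G|^2)/4` is an unbiased FRC numerator wherever the
  corner-fold carries only noise. Ring samples closer to the Nyquist
  corner than to DC — exactly the samples whose fold could carry signal
  at the crossing — are excluded, as is DC; each half is de-meaned on its
  own support, because the two parity sums otherwise carry large
  opposite-sign offsets that leak into the lowest rings. This estimator
  preserves frequency support all the way to Nyquist and is nearly
  unbiased on band-limited test images across the whole 0.2–0.8 range.
* **Sublattice.** The literal half-size diagonal sub-images
  (`checkerboard_split()`: even-even and odd-odd pixels). The two
  sub-lattices are offset by one full pixel, which rescales the frequency
  axis and sign-flips odd-order aliases; the resulting crossing is a
  *tent-shaped* (two-to-one) function of the true band edge, so no
  single-valued calibration can undo it over a wide band. The method is
  retained for comparison and for the narrow-band regimes where it is
  monotone.

Residual bias of either split is absorbed by `fit_calibration()`: the
ratio `r_co1 / r_ref` of one-image to two-image crossings, measured on
image pairs, is fitted as a quadratic polynomial `g(r_co1)` by least
squares, and the corrected crossing is `r_co1 / g(r_co1)`. Fitting the
*ratio* rather than the difference makes the correction exactly the
identity when the two measures already agree. The model serializes to
JSON with hex-float coefficients, so a reloaded model is bit-identical.
Calibration models store the split method and refuse nothing — pooling
models across acquisition conditions is left to the user, and the model
records its provenance (`n_pairs`, fitted domain).

`local_resolution_map()` tiles the image with non-overlapping patches
(256 px by default, the conventional patch size regardless of pixel
size), estimates each patch's calibrated one-image resolution, and
summarizes included patches as mean ± sd. Patches overlapping an
exclusion mask (e.g. the protective organoplatinum layer) by more than
50% are dropped from the summary.

### Depth of field

A through-focus series (stage height stepped ~5 µm between images, focus
fixed) gives a resolution-vs-position profile with a minimum at best
focus. `depth_of_field()` tests every position against the best one with
a two-tailed, two-sample equal-variance t-test (α = 0.05, df = n1+n2−2);
positions with p ≥ 0.05 are "similar", exact ties count as similar, and
the contiguous run of similar positions containing the best one defines
the depth of field. Because each stage position represents one focus
increment, the span is the run extent plus one median inter-position
spacing — four similar positions at 5 µm spacing span 20 µm. Note a
statistical subtlety the simulations make visible: the reference group is
the *selected* minimum, so neighbour comparisons are biased toward
rejection slightly beyond the nominal α even for a truly flat plateau;
single-series spans are therefore noisy, and simulation studies should
summarize several replicate series (the acceptance script reports the
median of 9).

## Charging artifacts

Poorly conducting inclusions (lipid droplets especially) accumulate
charge under the electron beam and image as intense dark centres with
asymmetric tails along the scan direction. With a mask of the charged
centres (from any segmentation; a naive dark-blob fallback detector is
included as `detect_charge_centres()` but is explicitly not the curated
route), `suppress_charging()` removes the tails row by row:

* The model for one row is a pair of Fermi sigmoids,
  `tail_left(x) = A (1/(e^{(x-x_0)/\sigma}+1) - 1)` rising from 0 far
  left of the centre to −A at it, and
  `tail_right(x) = -A/(e^{(x-x_0)/\sigma}+1)` recovering from −A to 0 on
  the right; both equal −A/2 at their inflection `x_0`.
* The background for a centre is the mean of the `n_background_rows`
  (default 20) rows immediately *above* its row extent (top pass) and
  immediately *below* it (bottom pass), with pixels inside any centre
  mask excluded from the means. Using the rows adjacent to the artifact,
  rather than a per-row trailing window, keeps the background free of the
  artifact's own tails.
* Per row and per pass, the sigmoids are fitted by bounded
  Levenberg–Marquardt on `row − background` over windows extending
  `window_factor` (default 4.5, matching the 9-diameter profile boxes)
  times the centre's equivalent-circle diameter on each side. `A ≥ 0`;
  `sigma ∈ [0.5, window]`; `x_0` is fitted but constrained to within one
  pixel of the mask edge — the inflection physically sits at the
  segmented boundary, and with `x_0` free the half-sigmoid visible
  outside the mask makes `(A, x_0)` nearly collinear and the estimates
  strongly biased under noise. A short multi-start over `sigma` guards
  against a boundary-trapped local minimum. Initialization follows the
  geometry: `x_0` at the mask edge, `A` from the residual depth there,
  `sigma` at a quarter diameter.
* The final correction is the average of the available passes, pixels
  inside the centre mask are copied unchanged (there is no information to
  recover there), and `corrected + artifact == image` holds bit-exactly
  everywhere.

A single row at realistic noise does not determine `(A, sigma)` to a few
percent — that is an information limit, not an implementation one — so
quantitative use should aggregate: the median over all row fits of one
artifact recovers the generator's parameters to ~2–3% at snr 10.
`line_profiles()` provides the standard verification view: column-wise
means over a box 1 diameter high and 9 wide (and the transposed box for
the vertical profile); after correction the horizontal profile regains
the same sharp, symmetric dip the vertical profile always had.

## Calibration metrics

* **Stage drift** (`landmark_drift()`): Euclidean distances between
  matched landmark pairs, normalized by the FOV diagonal so differently
  sized images compare fairly. Landmark detection is upstream; CSV pairs
  are the interface.
* **Bead-based Z-step calibration** (`bead_areas()`, `fit_bead()`):
  spherical beads of known diameter are milled through; each slice shows
  a circular cross-section whose area follows
  `A(z) = pi * max(0, (d/2)^2 - (alpha (z s_nom - z_c))^2)` with the
  nominal step `s_nom`. The milling-thickness coefficient `alpha` sits
  *inside* the square so that the realized step is simply
  `alpha * s_nom`; `d` and the centre depth `z_c` are per-bead free
  parameters. Since `A/pi` is quadratic in the slice index wherever
  positive, a linear solve gives exact starting values (and the exact
  answer for noiseless data); Nelder–Mead then polishes on the truncated
  model. The fit is invariant to relabelling the slice origin (only
  `z_c` shifts) and tolerant of multiplicative area noise; degenerate
  (constant-area) inputs return `ok = FALSE`.
* **2D shape metrics** (`shape_metrics()`): circularity
  `4 pi A / P^2`, aspect ratio and roundness from the second-moment
  ellipse (with the 1/12 px² finite-pixel term), all normalized to 1 for
  a perfect circle. The perimeter is a Moore boundary-chain length with
  corner-corrected weights (0.948 per axial step, 1.340 per diagonal):
  the naive (1, √2) weights overestimate a smooth digital boundary by
  ~5.5% on average over orientations, which would push a digital
  circle's circularity to ~0.90; the corrected weights are unbiased for
  smooth boundaries.
* **Tilt foreshortening** (`tilt_foreshortening()`, `stretch_image()`):
  imaging at angle α to the surface compresses y by sin(α); lengths are
  corrected by 1/sin(α) and images resampled with linear interpolation.
* **Beam FWHM** (`fwhm()`): baseline from the median of the outer decile
  samples on each end, peak as the largest deviation (dips treated like
  peaks), width between linearly interpolated half-maximum crossings.
* **Electron dose** (`electron_dose()`): `N = I/e` electrons per second,
  exposure `dwell x line_integration` per pixel (the `"total"`
  convention) or `dwell` alone (`"single_pass"`), dose = electrons per
  pixel area in e⁻/nm² and e⁻/Å². Both conventions are exposed because
  published dose tables are frequently computed from measured rather
  than nominal currents and cannot be reproduced from nominal parameters
  under a single convention; users comparing to such tables should
  expect ~10% discrepancies from the current alone.
* **Dice** (`dice()`): `2|A∩B| / (|A|+|B|)`, two empty masks defined to
  agree (1.0).

## 3D quantification

`components3d()` labels 26-connected components (8-connected in 2D),
drops components below `min_voxels` (the small-segmentation filter used
when counting organelles from automated segmentations), and reports
volumes in µm³ from the anisotropic voxel `(pixel_nm, pixel_nm,
step_nm)` plus the component density per analysed µm³. The labelling is
a compiled flood fill; tests check it against an independent graph-based
oracle.

`contact_sites()` implements the membrane-contact-site rule: a contact
is the set of voxels within `gap_nm` (default 25 nm, the conventional
maximum membrane separation) of *both* organelle masks, excluding the
masks themselves but including any mask overlap; its 26-connected
components are individual sites with volumes in µm³. Distances are
physical: an exact anisotropic Euclidean distance transform (separable
lower-envelope algorithm, compiled) over `(step_nm, pixel_nm, pixel_nm)`
voxels. The criterion is mask-to-mask voxel distance; if masks trace
membrane mid-planes rather than surfaces, the effective gap differs by
about a membrane thickness, which is the main interpretive caveat.

## Synthetic data: what it does and does not emulate

Every generator is a pure function of its arguments including the seed,
and returns the ground truth needed to score the matching analysis:

* `gen_curtain_image()`: strictly vertical stripes of exact column
  coverage and random sign on a flat or Gaussian-smoothed-noise
  background (default texture sd 5 grey at mean 100, smoothing 3 px —
  chosen as a plausible cytoplasmic texture scale; fixtures keep the
  background statistically stationary and periodic, which real images
  are not).
* `gen_frc_pair()`: one isotropic, hard band-limited Gaussian random
  field shared by two images plus independent white noise at a given
  snr (`sd(signal)/sd(noise)`). Real SEM spectra decay smoothly rather
  than cutting off, and real noise is not white; the hard edge is what
  makes the band edge a sharp, testable truth.
* `gen_charge_image()`: isolated dark disks (Gaussian dip of depth 3A,
  FWHM = diameter, truncated to the disk so the surroundings carry only
  the tails) whose rows carry the exact sigmoid tails with `x_0` at the
  disk edges and constant `(A, sigma)` over rows. Real charging varies
  along the streak and between rows.
* `gen_bead_stack()`: uniform-intensity spheres rasterized by
  pixel-centre inclusion, milled at a *true* step while the stack
  metadata carries the *nominal* step. Bead grey-level profiles are not
  modelled (area-based fitting does not need them). Note a small
  arithmetic fact the tests encode: a 1000 nm bead sampled at a 50 nm
  step shows at most 20 slices with positive section area (19 if the
  centre lies on the slice grid), since the open 1000 nm depth interval
  contains at most 20 grid points.

Passing tests on these fixtures demonstrates correctness of the
*procedures* under known truth; they do not certify performance on real
volumes, whose artifacts (texture nonstationarity, correlated noise,
focus gradients, segmentation errors) the generators deliberately omit.

## Problem sizes and numerics

The test suite and the acceptance script run on deliberately modest
sizes chosen as the smallest that exercise each property cleanly:
512×512 images for FRC calibration (7 cutoffs × 3–5 seeds), 128×128 for
curtain scoring, 140×280 for charging fixtures (20 seeded artifacts),
26-slice bead stacks, and ≤64³ random volumes for the labelling oracle.
Tolerances in tests come from the analytic arguments above (e.g. ±1 ring
for band-edge crossings, half-perimeter pixel tolerance for rasterized
areas), not from tuning. Degenerate inputs — constant arrays, empty
masks, empty ROIs, monotone profiles, all-equal calibration pairs — are
either handled with documented flags or rejected with clear errors, as
listed in each function's documentation.

## Known limitations

* The one-image FRC fold-exclusion rule discards diagonal ring samples
  at high frequency, so crossings very near Nyquist rest on few samples
  and are noisier there; the at-Nyquist flag marks saturated estimates.
* Curtain scoring assumes curtains are vertical in the image as
  acquired; rotated data must be rectified first.
* Charging suppression corrects scan-direction tails only, and only
  outside the charged centre; the centre itself is left untouched.
* The MCS rule measures mask-to-mask distance; it does not attempt
  membrane-surface reconstruction.
* The CLI's `simulate` subcommand writes integer TIFF or float MRC;
  general float data should use MRC, since TIFF floats are restricted
  to [0, 1].
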