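---
title: "Quantitative retinal vessel analysis for smartphone fundus photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative retinal vessel analysis for smartphone fundus photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Smartphone-mounted direct ophthalmoscopes produce inexpensive, portable
fundus photographs whose modest resolution (video frames of nominally
1024 x 720 px covering about a 25 degree field) still carries quantifiable
information about the retinal microvasculature. Two metrics are of clinical
interest because systemic vascular disease alters them: the
**arteriole-to-venule (A/V) caliber ratio** of a parallel vessel pair near
the optic disc (narrowed arterioles push it below its typical value of
roughly 0.7-0.8), and the **vessel density**, the percentage of image
pixels occupied by vessels after segmentation of the vascular tree.

`retvas` implements the full measurement chain for such photographs —
image conditioning, U-Net vessel segmentation, caliber and density
measurement, and test-retest agreement statistics — together with a
synthetic fundus generator that provides exact ground truth, so every
stage is verifiable without access to patient data.

## The processing model

### Calibration and conditioning

A portrait video frame is cropped to a square by removing
`floor((H-W)/2)` rows from the top and the remainder from the bottom; the
square covers a calibrated 7.0 x 7.0 mm retinal field, so a 720 px frame
has a scale of 7.0/720 = 0.009722 mm/px. All physical widths reported in
micrometres use this scale.

The analysis frame is a 565 x 565 px grayscale image obtained by bilinear
resampling and the weighted sum `0.299 R + 0.587 G + 0.114 B`. All three
channels are retained (rather than the green channel alone, common in
vessel segmentation) because these red-heavy photographs carry vessel
detail in the red channel too. Contrast is then enhanced by CLAHE on a
25 x 25 tile grid with normalized clip limit 0.01 (tile kernel
`ceiling(565/25) = 23` px, 256 bins, uniform target distribution, bilinear
interpolation between tile mappings), followed by an intensity stretch to
[0,1] between the 1% saturation quantiles with gamma 0.6.

The final conditioning step is an 11 x 11 uniform averaging filter with
replicate boundary handling whose purpose is to suppress the frame-edge
artifact amplified by CLAHE. A global 11 x 11 blur would plainly degrade
vessels, which contradicts its stated purpose of leaving vessel extraction
unaffected; the filter is therefore blended only into a border band
(default 11 px wide, linear ramp), and a `band = Inf` option applies it
globally for anyone wanting the literal operation. This is the one place
where the package deliberately restricts a published operation to its
stated intent; the band width is configurable.

### Segmentation

Vessels are extracted by a U-Net with exactly 23 convolutional layers:
four contraction levels of two 3 x 3 convolutions each (8), a
two-convolution bottleneck (2), four expansion levels of one 2 x 2
up-convolution plus two 3 x 3 convolutions (12), and a final 1 x 1
convolution (1) with per-pixel sigmoid output. `unet_layer_count()` audits
a built model. Training is patch-based: random congruent image/mask
patches (48 px default) drawn uniformly over a DRIVE-layout or synthetic
training set, minimizing per-pixel binary cross-entropy with Adam. The
paper-scale architecture is `base_channels = 16`; the test suite and the
acceptance script use 8 so that training takes minutes on one CPU. Neither
the patch size, channel width, optimizer, nor epoch count is prescribed by
the source protocol; the defaults here are chosen for CPU feasibility and
recorded in the configuration (whose hash is stamped into every output).

Inference tiles the frame with overlapping patches (stride = half patch by
default), averaging probabilities over all patches covering a pixel, with
the final row/column of tiles clamped to the image edge for complete
coverage. The probability map is binarized at a recorded threshold
(default 0.5; the source protocol's binarization tool and threshold are
unstated, so this is an explicit, configurable parameter).

### Vessel density

Density is the exact integer count of mask pixels divided by the full
frame size, times 100. There is no subsampling or field-of-view masking:
the denominator is the entire analysis frame, which also means the dark
corners outside the circular field depress the absolute percentage — a
property of the definition, not an artifact.

### A/V caliber ratio

The measurement zone is an annulus 0.5 to 1 disc diameter outward from the
optic disc margin: with disc diameter `D`, radii `[D, 1.5 D]` from the
disc center. Published A/V protocols differ in how this zone is anchored;
here the offsets are added to the disc radius, and the convention is
stated everywhere it matters. The disc geometry and the identity of the
measured arteriole/venule pair are *inputs* (ground truth for synthetic
scenes, user annotation for real photographs), mirroring protocols in
which a human selects one parallel pair; automatic disc detection and
artery/vein classification are out of scope.

For each vessel, the centerline is the longest geodesic path through the
Guo-Hall skeleton of the seed's 8-connected component, restricted to the
annulus. Zhang-Suen thinning — the more common textbook choice — was
rejected after it annihilated thin diagonal bands entirely (a known
failure mode that retinal vessels at about 45 degrees trigger). Five
measurement sites are placed evenly along the in-annulus arc (this
maximizes the minimal pairwise spacing and is deterministic); sites must
be at least `max(local width, 5)` px apart or the vessel is reported
unmeasurable. At each site the width is the perpendicular chord through
the mask, with the 0.5-level crossing of bilinear interpolation located to
subpixel precision on each side. The A/V ratio is the ratio of the two
five-measurement means; the pixel scale cancels.

A caveat worth stating: a *binary* mask quantizes width information. For a
straight tube rasterized by the hard rule "pixel center within
`width/2`", the mask itself can misrepresent the nominal width by up to
about half a pixel at unfavourable lattice phases (and the phase is
constant along an exactly axis-aligned or diagonal tube, so averaging
along the vessel does not help). Test fixtures therefore place tubes at
generic sub-pixel offsets; vessels in generated scenes have generic
positions with probability one. Width recovery on such tubes is within
0.5 px for widths of 6 px and more across orientations
{0, 30, 45, 60, 90} degrees.

### Repeatability statistics

Two measurements per eye are compared with a paired two-sided Student's t
(df = n-1), Pearson correlation, and Bland-Altman 95% limits of agreement
`bias +/- 1.96 x SD` using the sample (n-1) standard deviation of the
differences — the Bland-Altman convention; the source protocol does not
state the denominator. Eyes are treated as independent observations, as
in the source study that pools 19 eyes from 10 subjects; this ignores
within-subject correlation and is a documented limitation, not corrected
with mixed models. Degenerate inputs are flagged rather than forced:
identical vectors give a flagged t (p = 1) and an undefined correlation
instead of r = 1. The 0.05 significance level is recorded as metadata and
never used to drop data.

## The synthetic world

`generate_scene()` builds a circular-field fundus with an optic disc
(default diameter 0.21 x canvas, about 1.5 mm) slightly nasal of center
and six major vessels (three arteriole/venule pairs) radiating from the
disc margin to near the field edge, with midpoint-displacement curvature.
Venules are drawn wider (10.5-14 px at 720 px canvas) and darker than
arterioles (7-11 px), so designed A/V ratios fall around 0.6-1.0; a
per-scene global caliber scale factor (uniform on 0.75-1.25) emulates
between-subject variation in overall vessel caliber, giving the
population of synthetic eyes a density coefficient of variation near 20%,
comparable to the spread reported for real eyes (6.11 +/- 1.39%). Optional
child branches attach with width attenuation 0.8 — *beyond* the
measurement annulus, so the five-site caliber protocol is junction-free by
construction. None of this claims physiological realism: no tortuosity
statistics, no central reflex, no pathology, no choroidal texture. A green
test on this world establishes that the measurement chain recovers known
geometry; it does not validate segmentation quality on real photographs.

The renderer draws anti-aliased dark tubes on a vignetted, red-tinted
background, while the ground-truth mask uses the hard geometric rule
(pixel center within `width/2` of a centerline) so that density and
calibers are exactly countable. `make_repeat_pair()` re-renders the same
anatomy under small rigid pose changes, illumination shift, and fresh
noise — geometry is transformed and re-rendered rather than the image
being resampled, so truth centerlines shift exactly with the jitter.

## Numerical and design choices

- **CLAHE internals** ("other parameters default"): 2^14 internal gray
  levels, reflect padding to a whole number of tiles, integer clip limit
  `clip x tile pixels`, iterative excess redistribution. These follow the
  published Zuiderveld algorithm in the same conventions as the
  scikit-image reference implementation, against which the acceptance
  suite checks agreement within 2/255 per pixel.
- **Stretch limits**: 1% low/high saturation fractions, the documented
  default of the tool the protocol names; exposed in the configuration.
- **Resample-then-gray order** follows the stated order of operations;
  bilinear interpolation is used (the protocol is silent).
- **Training determinism**: all sampling is seeded through R's RNG; the
  same seed, data and hyperparameters reproduce loss traces exactly.
- **Degenerate images**: a constant frame has nothing to equalize or
  stretch; CLAHE returns it unchanged and the stretch stage returns zeros
  with a warning.
- **Scaling in tests**: training-dependent checks run a reduced problem
  (8 scenes, 2000 patches, 3 epochs, 8 base channels; repeatability
  emulation on a 192 px world with 20 Monte-Carlo runs instead of 100 at
  full scale) to fit a CPU-minutes budget. The pass criteria (Dice >= 0.7,
  density within 15%, A/V within 5%, agreement interval containing 0 with
  r > 0.8 in >= 90% of runs) are not relaxed.

## Known limitations

- The A/V headline numbers of the motivating study (0.77 +/- 0.09 etc.)
  come from 19 real eyes whose photographs are not public; they are not
  reproducible here and are not targets of the test suite.
- DRIVE's original TIFF/GIF files cannot be read in this environment; the
  DRIVE-layout reader accepts PNG conversions of the standard directory
  structure. It accepts any number of image/annotation pairs (the source
  protocol cites 40 training images where the public set ships 20+20;
  the discrepancy is documented, not resolved).
- Artery/vein identity, disc geometry, and the measured pair are inputs;
  no automatic classification is attempted.
- Measurement on the binary mask inherits rasterization quantization
  (about +/- half a pixel in unfavourable configurations), as discussed
  above.
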