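---
title: "Models and methods behind microwellflux"
author: "microwellflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microwellflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microwellflux)
```

# The measurement problem

A sealed-microwell bioenergetics assay isolates single cells (or small
groups of cells) in hermetically sealed sub-nanoliter chambers whose lids
carry a thin-film optical sensor stack: an oxygen-sensitive phosphor, a
pH-sensitive fluorophore, and a reference fluorophore that is inert to both
analytes. As a cell respires it depletes the dissolved oxygen in its ~64.5
pL chamber within minutes, and as it ferments it acidifies the chamber.
Time-lapse fluorescence imaging of the sensor in three spectral channels
therefore encodes, well by well, the oxygen consumption rate (OCR, fmol
O2/min) and the extracellular acidification rate (ECAR, pH/min) of the
enclosed cells. `microwellflux` implements the full data-processing chain
from raw image stacks to per-cell rate tables and population statistics,
together with a forward-model simulator that renders complete synthetic
assays with known ground truth so that every stage can be validated without
laboratory data.

# Sensor physics

**Oxygen.** The phosphor is dynamically quenched by oxygen following the
Stern-Volmer relation

$$\frac{I_0}{I} = 1 + k_{SV}\,[\mathrm{O_2}],$$

where $I_0$ is the emission intensity at zero oxygen and $k_{SV}$ (1/uM)
the quenching constant. Two-point calibration between air-saturated medium
($[\mathrm{O_{air}}]$, default 200 uM for aqueous medium near 36-37 C at
~20 kPa pO2) and nitrogen-purged medium gives
$k_{SV} = (I_0/I_{air} - 1)/[\mathrm{O_{air}}]$; typical sensors show
$I_0/I_{air}$ of 2.7-3.0, and the simulator defaults to the lower bound
2.7. Because sensor films vary from well to well, the package also
implements a *local* calibration inferred from the assay itself
(`localO2Calibration()`): for each well that fully depletes its oxygen, the
intensity at sealing is the air point and the post-depletion plateau the
zero point; the per-well constants are averaged over all completing wells
and the average is applied to the wells that never complete, including
empty wells. A useful identity exploited throughout is that $1/I$ is
*linear* in $[\mathrm{O_2}]$, hence linear in time under constant
consumption, which lets the generic linear-window finder detect the
drawdown/plateau breakpoint on $1/I$ before any calibration exists.

**pH.** The pH sensor follows a Boltzmann/Henderson-Hasselbalch sigmoid

$$I(\mathrm{pH}) = I_2 + \frac{I_1 - I_2}{1 + 10^{\theta\,(pK_a - \mathrm{pH})}},$$

with dynamic-range limits $I_2 < I_1$, midpoint $pK_a$ and sensitivity
$\theta$ (1/pH). Intensities are normalized to the assay-medium point
(`fitPhSigmoid()` renormalizes to the *fitted* curve's value at the medium
pH, which is exact where a linearly interpolated anchor is not). The
response is close to linear over the physiological working band
pH 6.4-7.4. The inverse,
$\mathrm{pH} = pK_a - \theta^{-1}\log_{10}\{(I_1 - I)/(I - I_2)\}$, is
closed-form; intensities marginally outside the dynamic range (noise at
the range edges) are clamped and flagged rather than propagated to
infinite pH.

# Rates

OCR and ECAR are regression slopes. Dissolved oxygen declines linearly
under the assumption of constant consumption (no diffusion modelling inside
the 80 um well), so
$\mathrm{OCR} = -\hat\beta\,[\mathrm{uM/min}] \times V\,[\mathrm{pL}]/1000$
in fmol/min, and $\mathrm{ECAR} = -\hat\beta_{\mathrm{pH}}$ in pH/min
(positive = acidification). The regression window is chosen by a two-phase
breakpoint scan (`findLinearWindow()`): every candidate window end is
scored by the pooled residual variance of a line fitted before it and a
second line after it, and among statistically tied candidates (within a
factor 1.25 of the minimal score) the longest early window wins, so an
unbroken linear trace keeps its full window. A plateau is declared when the
post-window segment is flat within noise, the series moved by well over the
noise scale, and (for concentration traces) the post-window mean is near
zero. The per-frame noise scale is estimated from second differences,
which vanish on linear segments and are therefore not inflated by the
trend or the breakpoint itself. 95% confidence intervals come from the
ordinary least-squares slope standard error and are reported as relative
half-widths.

Empty wells act as negative controls. The oxygen sensor photo-consumes
oxygen under excitation, so empty sealed wells drift upward by a few
percent over an assay; the median *effective* OCR of empty wells is
reported as a background/error bound (`estimateBackgroundOcr()`).
Subtracting it from occupied wells is supported but off by default - the
background is an error estimate, not a measured offset of each well.

# Image processing

Detection operates on the first reference-channel frame: large-scale
illumination and sensor-concentration gradients are divided out (heavy
Gaussian blur, or an order-2 polynomial fit which is exact on low-order
fields), the image is binarized so that the white fraction equals the
geometric lip-area fraction of the array, and circular Hough transforms of
both polarities (bright lip pixels, and boundary pixels of the dark
complement) vote for circle centers via FFT ring correlation at 1-px
radius steps with 1-px accumulator smoothing. Duplicate detections merge
by single-linkage clustering at half a pitch (connected components of the
proximity graph - implemented with grid hashing and union-find so it
scales to tens of thousands of candidates), collapsing each group to its
confidence-weighted mean center. Centers are then refined to sub-pixel
accuracy by background-subtracted intensity centroids, which tolerate
partially binarized lips. Finally a hexagonal lattice is fitted (pitch from
nearest-neighbour distances, orientation from nearest-neighbour angles
folded into the 60-degree sector, then least-squares affine refinement) and
detections farther than a quarter pitch from their node are discarded; at
most one locus survives per node (highest confidence, ties to the smaller
distance). The accumulator peak height serves as the detection confidence
metric - the original metric is unspecified, and this is the natural
choice for a voting transform.

Because the sealed array moves rigidly, per-frame translation is estimated
from a cropped sub-region only (`trackArray()`): wells are re-detected in
the crop and matched to frame-0 loci by mutual nearest neighbours; the
mean displacement is applied to all wells. Cell-count images taken at
higher magnification are registered through a non-reflective similarity
transform (`fitSimilarityTransform()`, the closed-form orthogonal-
Procrustes solution with the determinant constrained positive),
initialized in practice by the nominal objective ratio and refined on
grid-index-matched well detections from both image sets.

Per-well signals are read from three concentric regions - center disk
(0.75 r), lip annulus (0.9-1.15 r) and outside annulus (1.25-1.5 r) -
by an exact pixel-center-in-circle membership test with no interpolation,
so a brute-force per-pixel oracle reproduces the means bit for bit. The
lip and outside regions monitor the surrounding environment: a responding
center with a flat outside trace ties the signal to the cell rather than
the neighbourhood. Sensor channels are divided frame-wise by the reference
channel and rescaled to the raw frame-0 value (`normalizeRatiometric()`),
cancelling common-mode gain drift while preserving intensity units; the
paper-level rationale fixes the reference's purpose but not the
arithmetic, so the divide-then-rescale form is this package's documented
choice, and the unnormalized path remains available.

# Quality control and the seal test

Well inspection assumes most wells are valid: segments of the first
reference frame are divided by their pixel-wise mean (the internal
reference well), mean-normalized to remove bulk-intensity differences from
film heterogeneity, and summarized by the pixel coefficient of variation.
A perfect well scores CV 0%. Segments are lightly smoothed (sigma 1 px)
before the ratio: without this, sub-pixel differences in crop alignment at
the steep lip edge dominate the CV of perfectly good wells. The default
cutoff is robust - median + 5 MAD across wells - and overridable as a
fixed percentage; no cutoff value is inherited from the source
instrumentation, which reports none.

The terminal seal test floods the fixture with oxygen. Sealed wells are
insensitive; partially sealed wells are quenched. Per well, the slope over
the purge frames is tested one-sided at alpha = 0.01 against a noise floor
estimated from the pre-purge trace; the purge itself is confirmed globally
by the drop of the outside-region trace, without which all seal calls are
flagged unreliable. Leaky wells are excluded from every downstream rate
table. The statistical rule is a documented choice - the observed ~70%
sealed fraction in real assays is reported without a slope threshold.

# Cell counting

Counting operates on the Hoechst-stained nuclei images: per-well segments
are cleared of well-associated artifacts by subtracting the mean segment
pattern scaled to each segment's average intensity (so the subtraction
adapts to bulk brightness), then scale-normalized Laplacian-of-Gaussian
blob detection finds nuclei; candidate maxima within a nucleus radius merge
to the stronger response. Responses are normalized by the mean-pattern
intensity, making counts invariant to global gain while keeping empty
segments at zero. `tuneParameters()` minimizes total false counts over a
bounded parameter box by multi-start coordinate descent with the incumbent
always among the candidates - any constrained minimizer of this objective
is conformant, the original optimizer being under-specified.

# The synthetic assay generator

`renderAssay()` composes the forward models into images: hexagonally
packed bright-lipped wells (80 um diameter, 200 um pitch, 64 x 64 by
default, 64.5 pL volume - the volume is taken as authoritative and well
depth is never used), interiors following the oxygen/pH traces, a smooth
low-order polynomial gain field shared by all channels (film
heterogeneity, cancelled by ratiometric normalization), multiplicative
Gaussian noise of configurable CV plus optional additive read noise, rigid
stage drift, malformed-lip/sensor-void defects, unsealed wells with
first-order oxygen exchange, a terminal purge phase at elevated oxygen,
and a 2.5x-magnified nuclei image pair for the counting chain.

Default parameters are the study conditions the generator emulates, chosen
once: Poisson seeding truncated at 8 cells/well with mean 0.22 (giving the
~17% average single-cell occupancy of real assays; dilute random seeding
is canonically Poisson), lognormal per-cell OCR (median 0.80 fmol/min for
the cancer-line phenotype, 0.46 for normal epithelium in the comparison
cohorts; geometric SD 1.8 reflecting the observed right-skewed
distributions) with a well's rate the sum of its cells' rates, lognormal
ECAR (median 0.010 pH/min, geometric SD 1.8), I0/I_air = 2.7, 2%
multiplicative noise, 30% leaky wells (70% sealed on average), 5%
defective wells, a 7% empty-well intensity drift (the middle of the
observed 5-10% photo-consumption range), assay pH starting at 7.4 with a
floor of 6.0 so the sigmoid's nonlinearity is exercised while traces stay
in the near-linear band, and 1-minute frames. Pixel centers sit at integer
coordinates, origin top-left, x rightward, y downward, 0-based everywhere.

What the simulator does *not* model - and hence what passing tests do not
establish about real data: optics point-spread functions, photobleaching
kinetics, intra-well diffusion gradients (the linear drawdown is an
approximation), focus drift, non-rigid deformation, autofluorescence, and
biological artifacts such as cell death or division mid-assay. Recovery
results on synthetic data bound algorithmic error, not instrument error.

# Numerical choices and degenerate inputs

Binarization breaks threshold ties toward the higher threshold; blank
Hough masks yield empty candidate lists, not errors; wells whose regions
leave the image are flagged, never silently dropped; zero reference pixels
are excluded from QC ratios rather than divided; intensities above $I_0$
clip to zero oxygen with a flag; sigmoid fits use multi-start
Levenberg-Marquardt with data-quantile starting values and a deterministic
low-discrepancy jitter so the user's RNG state is untouched; the KS test
uses the exact two-sample distribution when the smaller sample has at most
25 observations and the asymptotic formula otherwise. The local-calibration
plateau requires the post-window mean to exceed the sealing intensity, so
empty and non-completing wells can never masquerade as completed.

# Problem sizes used in validation

The bundled tests and the acceptance script run entirely on synthetic
data at sizes chosen for thorough yet quick validation: one full 64 x 64
array render for the detection count; 300-well single-cell cohorts
(15 x 20 grids, 70 one-minute frames plus 8 purge frames) for the
median-recovery checks; a 12 x 12 array at the default study conditions
for seal/QC accuracy; and 100-well mixed-occupancy sets for counting.
At these sizes the recovered median per-cell OCR carries an intrinsic
sampling uncertainty of about 4% (the median of 300 lognormal draws with
geometric SD 1.8), which dominates the small (~2-3%) upward bias
contributed by sensor photo-consumption when background subtraction is
left off.

# Known limitations

Radius estimates are limited to the 1-px Hough accumulator resolution (the
region geometry therefore follows the layout radius); tracking assumes
strictly rigid motion; ECAR is reported in pH/min without
buffering-capacity conversion to proton flux; perturbagen conditions are
compared as separate assays (no injection scheduling); and the per-cell
normalization divides the well rate by the count - a regression through
occupancy would weight multi-cell wells differently, but simple division
is the transparent convention adopted here.
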