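---
title: "Color-card standardization of phenotyping image sets: methods and design notes"
author: "colorCard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-card standardization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colorCard)
```

## The problem

Automated imaging platforms photograph hundreds of plants per day over
weeks. The analysis downstream — thresholding plants out of the
background, measuring shapes, profiling hue — silently assumes that a
given surface maps to the same pixel values in every frame. In practice
it does not: lamp output drifts with ambient temperature, so images
taken at night-time temperatures are dimmer and color-shifted relative
to daytime ones, and a fixed segmentation threshold tuned on bright
frames falls apart on dark ones.

`colorCard` standardizes such sets against a single declared reference
image using a 24-chip reference color card present in every frame. The
chips are homologous measurement anchors: the same physical colors
photographed under every condition.

## The color model

Let $S$ and $T$ be the $k \times 3$ matrices of mean chip intensities
(columns R, G, B on the native 0–255 scale) sampled from a source image
and the reference. $S$ is extended column-wise with the elementwise
squares and cubes of its channels,

$$S_{ext} = [\,r\; g\; b\; r^2\; g^2\; b^2\; r^3\; g^3\; b^3\,],$$

and each reference channel is regressed on this 9-column design through
the Moore–Penrose inverse $M = (S_{ext}^{*}S_{ext})^{-1}S_{ext}^{*}$:
the three standardization vectors are $M T_R$, $M T_G$, $M T_B$.
Applying them to the extended value of every pixel rewrites the source
image in the reference's brightness, contrast and color profile. The
model is a full cross-channel cubic polynomial through the origin (no
intercept: black maps to black); it deliberately changes hue, since hue
bias between lighting conditions is exactly what needs removing.

To score an image without transforming it, the *reference* chips are
also extended to their squares and cubes and all nine columns are
regressed on the source design. Stacking the nine coefficient vectors
gives the $9 \times 9$ color homography $H$; the scalar report is the
deviance

$$D = 1 - \det(H),$$

which is 0 when the profiles already agree ($H = I$) and grows in
magnitude as they diverge. $D$ is signed and is reported signed: a
uniformly dimmed source needs an inflating correction, each diagonal
block of $H$ picks up factors $1/s$, $1/s^2$, $1/s^3$, and
$\det(H) \approx s^{-18}$ — hence the very large negative deviances that
dim frames produce. That $s^{-18}$ growth is also why `deviance()` is a
sensitive change detector for a monitoring workflow.

### Numerical choices

* **Scale.** Fitting is done in double precision on the native 0–255
  scale, with no pre-normalization, so deviance magnitudes are
  comparable across tools that work on 8-bit data.
* **Solver.** Cubed 8-bit values make the normal equations severely
  ill-conditioned ($\mathrm{cond}(S^*S) = \mathrm{cond}(S)^2$), so the
  pseudoinverse is computed by SVD. Numerical rank is judged against
  $10^{-10}\,\sigma_{max}$; a deficient design — e.g. too few distinct
  chip colors left after damage or occlusion — raises a singular-design
  error naming the rank found, rather than returning an unusable
  transform. For the packaged canonical chip palette the smallest
  singular value of the extended design is about 7.9 against a
  tolerance of about 0.004, a comfortable margin.
* **Clipping and rounding.** The polynomial is applied unclipped; for
  8-bit output the result is clipped to [0, 255] and then rounded
  half-up. A float mode keeps out-of-gamut excursions visible for
  analysis. Clipping is never applied during fitting.
* **Correspondence.** Chips are matched by id, in the canonical
  row-major card order, never by list position; mismatched ids are a
  hard error because the regression is only meaningful on homologous
  points.

## Chip sampling

Chip ROIs come from a YAML card layout (fixed-camera setting; automatic
card detection is out of scope). Each ROI is shrunk on every side by an
inset fraction (default 0.25) before averaging, which keeps chip
borders, bevel shadows and slight layout misregistration out of the
statistic. The arithmetic mean over the inset core is used; with
uniform chips it is exact, and with zero-mean sensor noise its error
shrinks as $\sigma/\sqrt{n}$. Chips whose mean reaches 254.5 in any
channel are flagged as saturated but remain fit-eligible — the flag
marks the top of the intensity range where the cubic is extrapolating.

## Segmentation and shapes

Fixed-threshold segmentation classifies a pixel as plant iff all
configured RGB/HSV bounds hold. No morphological cleanup is applied by
default: salt-and-pepper misclassification is a *signal* about image
quality here, not noise to erase. An opt-in flag keeps only the largest
8-connected component.

The 19-descriptor shape panel uses these conventions (pixels, 0-based
coordinates, origin top-left):

* 8-connectivity for components and contours;
* perimeter = arc length of the outer contour of every component (unit
  steps between orthogonal neighbors, $\sqrt 2$ diagonal), summed over
  components — so one stray background pixel adds measurably, as it
  should;
* convex hull over pixel *corners*, so hull area bounds pixel-count
  area from above and solidity is always in [0, 1];
* the ellipse shares the mask's second-order central moments (axis
  lengths $4\sqrt{\lambda_i}$); eccentricity and roundness derive from
  its axes; circularity $= 4\pi A/P^2$; aspect ratio is the bounding
  box width/height;
* fractal dimension is a box-counting slope over dyadic box sizes,
  capped at a quarter of the object extent — larger boxes sit in the
  saturation regime (count → 1) and bias the slope down. A filled
  square measures within 0.1 of 2.0, a thin line within 0.1 of 1.0.

Physical calibration (cm per pixel) is out of scope; everything is
reported in pixels.

## Hue analysis

Hue (HSV angle, degrees) of masked pixels is histogrammed in 1° bins
over the full 0–360° support; the 0–140° window often shown for plants
is presentation metadata only, and all statistics use the full support.
Achromatic pixels get hue 0 and are counted in an attribute. Two
histograms are compared with the two-sample Kolmogorov–Smirnov test on
their cumulative distributions: reject when

$$K = \sup_{hue}\,|F_x - F_y| \; > \; c(\alpha)\sqrt{\tfrac{n+m}{nm}},
\qquad c(\alpha) = \sqrt{-\tfrac12 \ln(\alpha/2)},$$

so $c(0.05) = 1.3581$. What to use for $n$ and $m$ is genuinely open
when the inputs are *averaged* histograms rather than raw samples; both
readings are implemented and selectable. `"pixels"` (total masked
pixels, the default) is the most conservative reading for per-image
comparisons but makes the test astronomically sensitive for
plant-sized masks; `"bins"` (number of bins) treats an averaged
histogram as one binned observation per degree and is the mode used in
the packaged end-to-end study, where the compared objects are
group-averaged histograms. Averaging uses the arithmetic mean of
per-image percentage histograms with a 95% band of $\pm 1.96$ standard
errors per bin.

## The synthetic study conditions

The generator renders a 256 × 192 scene: the 24-chip card (16 px chips,
classic nominal chart colors as fixture constants) and a radially
shaded green disc "plant" (radius 30 px, hue grading from about 117° at
the center to about 94° at the rim) on a light gray background, with
exact ground-truth mask, chip colors and layout. Distortions model
temperature-dependent lamp output: per channel
$v' = 255\,(s\,v/255)^{\gamma_c}$, optionally followed by a full cubic
cross-channel polynomial and additive Gaussian noise (truncated at the
channel bounds), then 8-bit quantization. All randomness is
seed-controlled (default seed 4242).

The packaged diurnal family is 10 "day" scenes (brightness scale
uniform in [0.80, 0.90], gammas (1.02, 1.00, 0.98)) and 10 "night"
scenes (scale in [0.50, 0.60], gammas (1.10, 1.00, 0.92)), noise sd
1.5. Two of these choices deserve a word:

* *Per-channel gamma is essential, not decorative.* A uniform
  brightness scale multiplies all three channels equally and leaves hue
  mathematically unchanged; only a channel-asymmetric distortion can
  reproduce the hue divergence that temperature-cycled lighting shows.
  The chosen night gammas shift the plant's hue by roughly 15–20°,
  against an intrinsic within-plant spread of about 25°.
* *The plant is shaded, not flat.* A flat-colored disc would have a
  near-degenerate hue distribution whose comparisons are dominated by
  quantization artifacts; the radial grade gives the hue histogram
  realistic width.

On these conditions the end-to-end test verifies the full qualitative
pattern: median $|D|$ above 0.1 before standardization and below 0.01
after re-scoring the standardized images; fixed-threshold plant area
within 1% of ground truth after standardization and badly wrong before
(night masks are typically empty — the plant's green falls below the
bounds); and the day/night averaged hue histograms significantly
different before standardization but not after (KS, bins mode,
$\alpha = 0.05$). Hue comparisons in this study are computed over the
ground-truth plant mask so that the color effect is isolated from the
segmentation effect — on a night image segmented before correction
there is often no mask at all to compare.

What the generator does *not* emulate: optical blur and chromatic
aberration, spatially varying illumination, specular highlights, leaf
self-shadowing, demosaicing artifacts, or any real plant architecture.
Passing the packaged study therefore shows the machinery is correct and
the method behaves as designed under in-model distortions; it does not
certify performance on any particular camera or growth facility, where
the distortion may fall partly outside the cubic model's expressive
range.

## Batch pipeline

`runPipeline()` processes a directory in lexicographic filename order:
sample chips → fit against the reference → deviance → standardize →
re-sample and re-score → segment and measure shapes and hue before and
after. Per-image failures are recorded in an errors table without
aborting the batch; an unreadable reference is fatal. Numeric CSV cells
are written with 6 significant digits so reruns are byte-identical and
diffable. Image ids are filename stems; collisions are a fatal
configuration error. The same operations are exposed as subcommands of
the `exec/colorcard` script.

## Known limitations

* The cubic polynomial can overfit when many chips are saturated or the
  chip palette degenerates; the rank guard catches the extreme case but
  mild ill-conditioning shows up as unstable out-of-gamut behavior
  (inspect with the float output mode).
* Deviance compares card regions only; it cannot detect variation that
  leaves the card unchanged (e.g. a shadow across the plant but not the
  card).
* The KS decision on averaged histograms depends on the sample-size
  reading; report the mode used alongside any result.
* Box-counting dimension is scale-limited on objects smaller than ~16
  px extent, where only two box sizes survive the saturation cap.
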