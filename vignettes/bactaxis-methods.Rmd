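---
title: "Quantifying fluorescence localization along the bacterial long axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescence localization along the bacterial long axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactaxis)
```

## The problem

Immune effectors such as the complement membrane attack complex (MAC, the
C5b-9 pore) do not land uniformly on *E. coli*: deposition can concentrate at
cell poles or at the division septum, and whether a cell dies depends on
where the pores sit. Answering "where on the cell is this signal?" at scale
requires reducing every segmented cell in a micrograph to a common,
comparable coordinate system — its long axis — and summarizing per-channel
fluorescence along it. `bactaxis` implements that reduction end to end:
instance segmentation post-processing of a three-class semantic prediction,
growth-stage classification and filtering, axial intensity profiling with a
left-orientation convention, fluorescence positivity gating, and average
cell shapes per growth stage. A synthetic scene generator with full ground
truth makes every stage testable without any imaging data.

## Segmentation: tiles, blending, and the 3-px membrane convention

The phase-contrast frame is reflect-padded and cut into 256 × 256 tiles with
50% overlap. Tile origins sit at multiples of the stride in padded
coordinates and the per-axis count is `ceiling(dim / stride) + 1`, so the
reference 1392 × 1040 px frame (0.102 µm/px) yields exactly 12 × 10 = 120
tiles. Padding is split as evenly as possible per side. The exact padding
rule is a reconstruction — only the tile count is externally fixed — and the
grid object is the tested contract.

Each tile is scored into three classes (background, membrane, cell body) by
a pluggable backend. The package does not bundle a trained network; it ships
two reference backends: an *oracle* backend that replays a known semantic
mask (used with synthetic ground truth), and a *classical* backend (Otsu
threshold on the phase channel, hole filling, 3-px inner rim as membrane)
that handles clean images without any learned model. Any function mapping
tiles to three class planes — e.g. a wrapper around an external U-Net
service — satisfies the same contract.

Tile scores are blended with a separable squared-triangle window
("second-order spline"), renormalized so weights sum to one at every pixel,
interior or edge. Constant tiles therefore reproduce a constant frame and
smooth fields round-trip through tiling to floating-point accuracy. After
arg-max (ties resolved body > membrane > background, so borderline pixels
never split a cell), each 8-connected body component becomes one instance.
8-connectivity matters: the body of a deeply constricted dividing cell can
narrow to a single-pixel digital line, which 4-connectivity would fragment.

The membrane class is annotated 3 px wide, so each body component is dilated
by *exactly* 3 px to recover the full cell mask. The structuring element is
a true Euclidean disc of radius 3 (29 px), built in-package because common
"disc" brushes of nominal size 7 include corner pixels beyond radius 3.
Dilation never merges instances — every component keeps its own mask.
Instances whose **dilated** mask touches the frame border are discarded;
filtering after dilation is the conservative choice (a profile sampled from
a truncated mask would be biased) and is applied consistently everywhere.

## Growth-stage classification

Instances are associated with detector boxes by highest intersection over
union, with confidence and then detection index as tie-breaks. Boxes are
compared box-to-box in pixel-edge (half-open) coordinates; any positive
overlap is accepted by default and one detection may serve several
instances, since no exclusivity or floor is imposed. A geometric stand-in
detector ships for synthetic work: a cell whose width profile dips below 85%
of its median width near mid-cell is dividing, a dip elsewhere marks an
intermediate cell, otherwise it is a rod.

Residual rod/dividing confusion is cleaned by an Otsu threshold on the
pooled cell-length histogram (64 bins over the observed range): rods longer
than the threshold and dividing cells at or below it are *discarded*, not
relabeled. When two length modes leave empty bins between them the
between-class variance is flat across the gap; the implementation takes the
middle of the maximizing plateau so the cut sits centrally, a convention the
brute-force oracle in the test suite shares. A constant length sample has no
threshold and passes through with a warning.

## Axial intensity profiles

Cell orientation comes from image moments: with centroid
$c_x = m_{10}/m_{00}$, $c_y = m_{01}/m_{00}$ and central second moments
$\mu_{11}, \mu_{20}, \mu_{02}$, the long-axis angle is
$\theta = \tfrac{1}{2}\,\mathrm{atan2}(2\mu_{11},\; \mu_{20}-\mu_{02})$.
The two-argument arctangent resolves the 90° ambiguity of the one-argument
form and is validated against PCA (agreement within 1° on rectangles and
ellipses). A line at angle $\theta$ is marched from the centroid at 0.25-px
steps in both directions until it leaves the mask; the axis is the linear
(degree-1) spline through the two border points. Alternative estimators —
PCA, a direct least-squares ellipse fit (stable Halir–Flusser variant), and
a Zhang–Suen skeleton whose longest medial path is spline-smoothed and
extended to the border — expose the same interface; on straight cells all
four agree, on bent cells the skeleton tracks the midline and measures
longer. Cells whose centroid falls outside their mask (strong concavity) are
skipped and logged.

$N$ positions (default 21) are spread equidistantly from 5% to 95% of the
axis length, i.e. $p_i = (5 + (i-1)\,90/(N-1))/100$, so $p_2 = 9.5\%$ and
$p_{20} = 90.5\%$. At each position the chord perpendicular to the axis is
clipped to the mask, sampled at 0.5-px spacing with bilinear interpolation,
and reduced per channel by the maximum (default; robust for membrane-rim
signals) or the mean. Uniform coverage yields flat profiles under both
reductions — the validation the synthetic generator reproduces.

Cells are then oriented: if the right half of the designated orientation
channel (positions $1..\lfloor N/2\rfloor$ vs the mirror set, middle
position excluded for odd $N$, compared by arithmetic mean) is brighter,
every channel's value order is reversed, putting the brighter pole on the
left. The half-comparison statistic is not externally fixed; the arithmetic
mean is the package's choice, and orientation is idempotent by
construction. Each channel is finally normalized to its own per-cell
maximum ("relative intensity"); per-cell normalization is the default
reading of the figure convention, and an all-zero channel stays zero with a
warning rather than producing NaNs.

Positivity gating (e.g. selecting cells with Sytox influx, i.e. inner
membrane damage) blurs the gate channel with a σ = 5 px Gaussian,
triangle-thresholds the blurred histogram (256 bins), and calls a cell
positive when any mask pixel exceeds the threshold. The threshold is
computed per frame, not per experiment, because illumination varies between
fields; whether the histogram should cover the whole frame or only in-mask
pixels is not externally fixed — the whole frame is used, which keeps the
background mode that the triangle geometry needs. Per-class distributions
use type-7 (linear-interpolation) quartiles and Tukey whiskers at the most
extreme values within 1.5 × IQR; the quartile convention is recorded because
whisker values depend on it.

## Average shapes

Per growth stage, instance contours are normalized — ellipse-fitted,
translated to the ellipse center, rotated so the major axis lies along x,
and scaled per axis into [−1, 1] (anisotropic by default, matching a
per-axis reading of "normalized between minus and plus one"; an isotropic
option preserves aspect ratio) — and resampled to a common vertex count
(default 64) equally spaced by arc length, starting at the vertex nearest
angle 0 so batches stay in vertex correspondence.

The average shape minimizes the mean over members of the symmetric mean
Hausdorff distance (average nearest-vertex distance, symmetrized),
initialized at the member contour with the lowest summed distance to all
others — the same mean variant is used for initialization and loss, the
simpler of the two possible readings. Optimization uses adaptive-moment
gradient steps (step 1e-2, conventional moment parameters; only the
optimizer family is externally fixed) on the exact subgradient at the
nearest-vertex assignment, for at most 1000 iterations with early stop when
the loss changes by less than 10⁻⁸. Because adaptive-moment steps are not
monotone, the incumbent best iterate is tracked: the reported trace is
non-increasing and the returned shape can never fall behind its
initialization. An identical-contour batch converges immediately with zero
loss, and the average of two concentric circles stays radially between them.

## The synthetic generator: what it emulates, and what it does not

Scenes emulate the reference acquisition geometry (1392 × 1040 px at
0.102 µm/px) with rod-shaped and dividing cells: spherocylinders (rectangle
capped by half-discs) with, for dividing cells, a Gaussian mid-cell
constriction (σ = width/3) whose minimal width is `width × (1 − depth)`.
Defaults chosen once for exponentially growing *E. coli* at this pixel
size: width ≈ 11 px (≈1.1 µm), newly divided rods ≈ 22 px, dividing cells
≈ 40 px, septum depth 0.25–0.35. The depth cap keeps the neck half-width
above the 3-px membrane rim so a dividing cell's body class remains one
8-connected component — geometrically, a cell constricted further than its
membrane thickness reads as two daughters, which is the boundary the
annotation convention itself draws. Cells are placed by rejection sampling
with a minimum 2-px gap (10⁴ attempts, then an error).

The phase channel is dark cells on a bright background; fluorescence models
(uniform, single-pole Gaussian cap, septal Gaussian band, random speckle)
paint the 3-px membrane rim; noise is additive Gaussian at SNR ≈ 10 by
default — chosen over Poisson noise for bit-exact reproducibility under a
fixed seed. The generator does **not** model optics (no PSF beyond optional
blur), photobleaching, halo artifacts, cell crowding/microcolonies, or
time-lapse growth. Passing tests on these scenes therefore validates the
*computational* pipeline — geometry, sampling, thresholds, orientation — not
robustness to real phase-contrast texture; on real data the segmentation
backend carries that burden.

## Numerical choices and degenerate inputs

- Coordinates are 1-based pixel centers (x right, y down); bounding boxes
  are pixel-edge (half-open), so widths equal pixel counts.
- Subpixel mask membership is nearest-pixel; intensity sampling is bilinear
  with border clamping.
- Masks of fewer than 2 px, zero-length axes, collinear contours, flat gate
  images, and constant length samples all fail softly (skip, warning, or
  pass-through) rather than erroring the whole run; the pipeline logs every
  excluded cell with its reason.
- Problem sizes used in the validation suite: full-size 1392 × 1040 scenes
  with 110–120 cells for the flat-profile and polar-recovery properties,
  696 × 520 scenes for segmentation round trips, 100-case batches for the
  angle and IoU oracle comparisons.

## Known limitations

Box-IoU association can mislabel closely packed cells whose boxes overlap
heavily (a mask-in-box option exists). The geometric stand-in classifier
knows nothing about defocus or microcolonies — those classes only arrive
via an external detector. The skeleton axis is biased slightly short/rotated
on low-resolution masks. Average-shape vertex correspondence assumes
roughly convex, x-major contours; strongly bent cells would need an
arc-length registration the package does not attempt.
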