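---
title: "Models and methods behind swarmstall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind swarmstall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmstall)
```

`swarmstall` studies temporarily immobile cells inside a bacterial swarm:
how they are detected from long-exposure microscopy, how their occupation of
space behaves statistically, and how their flagellar dynamics are modelled
as a continuous-time Markov chain (CTMC). This vignette documents the models
and the numerical decisions behind each stage, in the same spirit as the
methods vignettes of the established Bioconductor analysis packages.

## The flagellar-state chain

A swarmer cell's flagella occupy one of three arrangements, mapped onto
motility modes: **CLOSED** (tight bundle — "run", persistent motion),
**PARTIAL** (partially unbundled — "tumble", reorienting motion) and
**OPEN** (fully unbundled — "stall", no motion). The dynamics are a CTMC:
the dwell in state $i$ is exponential with exit rate $\lambda_i$, and jumps
follow the embedded matrix $P$ (row-stochastic, zero diagonal). The fitted
model shipped as `swarm_transition_model()` uses

$$\lambda = (4,\; 4.76,\; 1.05)\ \mathrm{s}^{-1}, \qquad
P = \begin{pmatrix} 0 & 1 & 0 \\ 1/2 & 0 & 1/2 \\ 0 & 1 & 0 \end{pmatrix},$$

i.e. mean dwells of $0.25$, $0.21$ and $0.95$ s and no direct
closed$\leftrightarrow$open jumps. The even $1/2$–$1/2$ split out of the
partial state reflects that the observed transitions from the tumble state
to the run and stall states are close to equally frequent; only the
structural zeros and this near-equality are constrained by observation, so
the model adopts the exact even split and flags it as a modelling choice.

Two consequences are used as oracles in the test suite. First, the embedded
stationary vector solves $\pi = \pi P$ ($\pi = (1/4, 1/2, 1/4)$ here), and
the long-run fraction of *time* in state $i$ is
$\pi_i/\lambda_i \big/ \sum_j \pi_j/\lambda_j$ — about $0.587$ for OPEN.
Second, the Markov property implies the two-step jump matrix equals $P^2$
(Chapman–Kolmogorov); `memorylessness_error()` reports the maximum relative
deviation over entries whose expected two-step probability exceeds
$\varepsilon = 0.01$ (structurally zero entries carry no information, and
relative error on a near-zero entry is dominated by noise). Whether the
"relative error" of such a comparison is a maximum or a mean is a
convention; the maximum is the conservative choice and is what the package
reports.

`simulate_ctmc()` is a Gillespie sampler. The jump sequence is drawn first
(one categorical draw per jump); dwell durations are then drawn in a single
vectorised pass, since each duration depends only on the occupied state.
Either a total duration (final dwell truncated and flagged censored) or a
jump budget can be requested; the first and last dwells are always flagged
censored so that inference can drop them.

## Dwell-time inference

`extract_dwells()` turns labelled tracks into dwells and transition counts.
Frame-sampled labels use run-length encoding (duration = run length × frame
interval); interval-form `state_track` input is exact. Two-step counts pair
the states at jumps $n$ and $n+2$ for **all** $n$ (overlapping pairs, the
maximal-data convention). Note that frame sampling at 0.02 s can miss dwells
shorter than one frame, which slightly biases rates and can create rare
apparent closed–open adjacencies in pipeline output; interval input has no
such artefact.

The exponential MLE is closed-form: mean $=$ sample mean, log-likelihood
$n(-\log\hat m - 1)$. Censored dwells are excluded by default — keeping them
biases the mean low, which the suite asserts as a directional test. The
two-component exponential mixture is fitted by EM with 10 restarts
(quantile-based and random initialisations, plus one start at the
single-exponential solution so the mixture log-likelihood can never fall
below the nested model's), convergence at $|\Delta \ell| < 10^{-8}$ or 500
iterations. AIC uses $2k - 2\ell$ with $k = 1$ for the single exponential
and $k = 3$ for the mixture; `aic_compare()` reports
$\mathrm{AIC}_{\text{single}} - \mathrm{AIC}_{\text{mixture}}$, negative
when the mixture is not justified.

## The synthetic swarm generator

`simulate_swarm()` provides ground truth with the statistical structure the
analysis assumes:

* rod cells of 1 × 7 μm on a periodic arena at surface fraction
  $\rho = 0.3$ by default (cell count derived as
  $\rho \cdot \text{arena area} / 7\ \mu m^2$);
* an independent flagellar CTMC per cell; stalled (OPEN) cells have
  *exactly* zero displacement;
* run speeds drawn per dwell from a Rayleigh distribution whose mean is
  19.5 μm/s (the observed moving-cell average; Rayleigh because 2-D
  isotropic Gaussian velocity components give a Rayleigh speed magnitude
  with a Gaussian tail). Tumble dwells move at a configurable fraction
  (default 0.4) of a run draw and reorient each frame by a uniform angle
  within ±90°;
* neighbour coupling $g(k) = \min(k, k_{\mathrm{sat}})/k_{\mathrm{sat}}$
  with $k_{\mathrm{sat}} = 5$: isolated cells do not move and speed
  saturates with crowding. The observed speed-versus-neighbours curve is
  qualitative (zero at $k = 0$, saturating near 20 μm/s), so a
  piecewise-linear ramp is the simplest shape consistent with it;
* a per-cell wetness scalar relaxing first-order toward 0 when isolated
  (time constant 2 s) and toward 1 otherwise (1 s) — chosen so dry spells
  seen through the hue pathway live on the same scale as the open-state
  dwells (roughly one to a few seconds);
* sampling at 50 frames/s (0.02 s interval).

Steric exclusion is deliberately **not** simulated: the analyses under test
(detection, occupancy, kinematics, inference) do not depend on contact
mechanics, and overlaps only reduce the rendered surface fraction slightly.
Consequences: rendered coverage falls below $\rho$ as $\rho$ grows (random
overlap gives roughly $1 - e^{-\rho}$), so the rendering-fraction test runs
at low density where the deficit is within rasterisation error; and the
generator does not reproduce rafting, jets or whirls — passing tests show
the analysis chain is correct on data with the assumed statistical
structure, not that real swarms have that structure.

## Rendering

`render_frame()` averages `n_subsamples = 11` instantaneous rasterisations
spanning the exposure (odd count, endpoints included; at 0.2 μm/px a
20 μm/s × 0.2 s streak is gap-free). Cells are filled rotated rectangles at
intensity 1 on background 0; positions are linearly interpolated with
minimum-image displacements so periodic wrapping interpolates correctly.
Pixels are 0.2 μm (a 63× objective scale regime), with the origin at the
top-left pixel centre, x rightward, y downward, 0-based.
`synthesize_long_exposure()` averages blocks of `ratio` frames (default 10:
50 frames/s → 5 frames/s) and scales the frame interval and exposure
accordingly; a trailing remainder is dropped.

The DIC-like hue map treats hue as an abstract axis carrying the
classification thresholds — no colour-space conversion is attempted, since
the underlying hue units are not defined by the thresholds themselves.
Background and wet cells draw hues uniform in [43, 45]. A cell drier than
the wet threshold draws hue $27 - 19\,d\,s$ where $d$ is its dryness and
$s \in [0, 1]$ grows from the rod's ridge line toward its long edges and
poles, so a fully dry rod spans green, blue and black; hues in (28, 42)
occur only as rare noise (0.2% of pixels by default).

## Immobility detection and occupancy statistics

`detect_immobile()` thresholds a long-exposure frame at 0.9 and removes
connected components below 140 px. The geometry behind the defaults: a cell
translating distance $D$ during the exposure keeps a core above threshold
$q$ of width about $L - (2q - 1)D$ along the motion axis. At $q = 0.9$ and
$D = 4$ μm (20 μm/s × 0.2 s) that core is ≈95 px at 0.2 μm/px, safely below
the 140 px cut, while a truly stalled 1 × 7 μm body is ≈175 px. For scoring
against the generator, a cell counts as temporarily immobile over a window
when it is in OPEN for at least 90% of it.

`bin_occupancy()` requires image dimensions divisible by the grid (10 × 10
by default; the full-scale geometry of 1000 × 1000 px guarantees this) and
marks a bin occupied when the masked area inside it reaches one third of
the nominal body area — the area interpretation of "a third of a cell"; a
length-based reading was considered and not used. `occupancy_stats()` cuts
the series into **disjoint** windows per duration and reports the mean and
standard deviation of the per-bin, per-window occupation fractions. The
spread must be taken over single-window fractions: averaging each bin over
all windows first would use the entire series for every duration and erase
the $T^{-1/2}$ central-limit scaling that the statistic exists to measure.
Disjoint (not sliding) windows keep the samples independent.

`occupancy_autocorrelation()` averages per-bin mean-subtracted
autocorrelations over bins with positive variance. The primary decay time is
the first crossing of $1/e$; the first zero crossing is reported alongside
because "decays to zero" is the field's phrasing but zero crossings of a
noisy estimate are erratic. For an on/off renewal process with exponential
on- and off-rates $a$ and $b$ the autocorrelation is $e^{-(a+b)t}$, which
the suite uses as its oracle. `normality_check()` is a Shapiro–Wilk test,
with constant input reported as degenerate rather than an error.

## Kinematics

Speeds are central differences (forward/backward at the ends) — less biased
by localisation noise than one-sided differences; the estimator used for
the original measurements is not documented, so this is the package's
choice. Track linking is greedy mutual-nearest-neighbour within a maximum
displacement; tracks shorter than 5 frames are excluded from statistics as
an anti-noise rule. Neighbour distances are centre-to-centre with the
minimum-image convention, scanned over cutoffs {3, 5, 7, 10} μm by default
(the cutoff axis is a configuration choice, not a measured constant). The
Gaussian-tail check fits $\log f(v) - \log v$ above the mode to a quadratic
— exact for a Rayleigh density, with curvature $-1/(2\sigma^2)$ — weighting
bins by their counts so sparse far-tail bins do not dominate; the speed
prefactor is removed because it is the geometric (phase-space) factor, not
part of the Gaussian tail.

## Hue classification and events

`classify_hue()` floors fractional hues and applies the integer band edges
(≤20 black, 21–24 blue, 25–27 green, 28–42 unclassified, ≥43 background);
the bands are integers with no stated interpolation rule, so flooring is the
faithful reading. The unclassified band is reported but never merged into
wet or dry. A cell's dryness over time is the fraction of non-background
pixels in a padded axis-aligned bounding box around it (the region over
which a cell's colour is judged is not otherwise defined); with
`normalize = TRUE` the count is expressed relative to the cell-body area so
a fully dry cell reads ≈1 regardless of box padding. Stopping/wetting events
use hysteresis (on = 0.5, off = 0.2 of the normalised fraction), which
guarantees alternating event types; the WETTING event's duration — from the
on-crossing to the off-crossing — is the stall interval comparable to
open-state dwells.

## Determinism, problem sizes and limits

Every stochastic function takes a seed; `run_pipeline()` fans per-stage
seeds out deterministically from the master seed, so identical seeds give
byte-identical summary JSON and changing one stage's seed leaves upstream
artifacts unchanged. The test suite and the acceptance script run
reduced-scale scenes chosen to keep the full run around a minute: arenas of
20–60 μm (100–300 px), 4–70 cells, simulated durations of 1–6 s for image
stages, and direct (image-free) occupancy series of 100 bins × 240–1440 s
for the statistics whose laws need long windows; the memorylessness check
uses 10⁶ jumps. Known limitations: no steric exclusion or hydrodynamics, no
optical PSF or true DIC interference model, hue treated as an abstract
axis, and frame-sampled state labels quantise dwells at the frame interval.
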