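---
title: "Models and methods behind rehabsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rehabsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rehabsim implements the computational core of a home-based
virtual-reality upper-limb rehabilitation trial: the adaptive difficulty
controller of a gamified reaching-and-grasping task, the automated
kinematic evaluation of motor function, navigated-brain-stimulation
(NBS) motor-map metrics, and the nonparametric statistical layer of a
two-arm comparison. Because clinical recordings of this kind are not
publicly available, the package pairs every analysis stage with a
synthetic generator whose ground truth is known, so that each stage can
be validated by parameter recovery rather than by reference data. This
vignette documents the models, the tunable parameters, and the design
choices that were genuinely open.

## The adaptive difficulty controller

Training consists of three subtasks (hit, grasp, place) played with
each limb separately. A trial is a sphere to intercept, grasp or place;
its demand is a four-dimensional difficulty vector, each dimension a
bounded value in [0, 1]:

* `trajectory_range` — joint range-of-motion demanded by the sphere
  trajectories,
* `sphere_size` — grasp-precision demand (small spheres are hard; the
  dimension stores the demand, not the radius),
* `sphere_velocity` — speed and timing demand,
* `flexion_range` — finger flexion–extension range required to grasp
  and release.

The controller's objective is to keep the *performance ratio* —
successful trials over total trials — inside the band (0.6, 0.8), a
challenge level that balances effort against reinforcement. The
adaptation law is a windowed symmetric staircase: after each completed
window of `window` trials (default 10), if the window ratio exceeds the
upper edge every dimension is raised by one `step` (default 0.05,
clipped to its bounds); below the lower edge every dimension is
lowered; ratios on the edges are treated as in-band so the controller
does not chatter at the boundary. Each limb-by-subtask combination has
an independent state (lateralized customization), and the first
`warmup` trials of a block (default: one window) are never used for
adjustment and are excluded from post-warm-up statistics.

Two cadence variants were considered: evaluating a sliding window after
every trial, and evaluating non-overlapping windows. The non-overlapping
cadence is the classic staircase; the sliding variant reacts faster but
re-counts the same trials up to `window` times after each move, which
produces overshoot. The package uses the non-overlapping cadence;
`update_difficulty()` itself is cadence-free and pure, so either policy
can be built from it.

At equilibrium the staircase alternates around the difficulty whose
success probability sits in the band, so the long-run mean ratio sits
near the band centre 0.7. This is the property the acceptance check
asserts on a 17-patient, 15-session simulated course (about 46,000
trials): the grand post-warm-up mean falls inside (0.6, 0.8) and within
0.05 of 0.7.

## The synthetic patient

The success-generating mechanism is a logistic psychometric model. A
patient has a latent ability on the same scale as each difficulty
dimension, per limb. For a trial at difficulty $d$ with ability $a$,

$$
p(\text{success}) = (1 - \lambda)\,\sigma\!\big(k \cdot
\min_j (a_j - d_j)\big),
$$

with slope $k$ (default 8), lapse rate $\lambda$ (default 0.02,
bounded at 0.2), and $\sigma$ the logistic function. The *minimum*
margin across dimensions makes the hardest demand binding; this is what
produces floor effects in grasp-type subtasks when distal (finger)
function is the limiting dimension — the controller then pins all
dimensions at their lower bounds while the ratio stays below the band,
and the course flags the block (`floor_effect`).

Defaults for cohorts are chosen once to represent mild-to-moderate
chronic hemiparesis: base ability uniform on (0.35, 0.7) with the
flexion dimension 0.05–0.1 lower for the paretic limb (the distal-worse
gradient typical of hemiparesis), treated-arm recovery drift of
0.010 per session (SD 0.004, truncated at 0) versus 0.002 for controls,
paretic reach factor 0.4–0.82 and flexion ceiling 0.45–0.8. The slope
and lapse defaults are ordinary psychophysics values; no per-trial
response distributions exist to calibrate against, so only the band
behaviour and the printed effect-size magnitudes constrain the
generator.

## Automated evaluation of motor function

The evaluation scenario captures hand position (metres) and five
finger-flexion channels (glove units in [0, 1], 1 = full flexion) at
30 Hz during two unsupervised tasks: a planar *wipe* over a virtual
surface and a *squeeze* of a virtual object.

**Filtering.** All channels are low-pass filtered with a second-order
Butterworth at 6 Hz, applied forward and backward (zero-phase). Phase
handling matters here: a causal single pass delays extrema and biases
max/min descriptors, so the zero-phase choice is deliberate; the
effective attenuation is then the squared single-pass magnitude,
$|H(f)|^2$ with
$|H(f)| = (1 + (\tan(\pi f/f_s)/\tan(\pi f_c/f_s))^{4})^{-1/2}$
for the digital filter. Edge transients are controlled by odd-reflection
padding (pad length ten time-constants of the cut-off, capped at the
series length); a constant series passes through unchanged to numerical
precision, and the test suite checks the 12 Hz attenuation against the
closed-form response within 2%.

**Work area.** The "surface covered" by the wipe is computed as
occupancy-grid coverage of the horizontal plane: distinct 2 cm cells
visited by the trajectory, times the cell area. A convex hull was the
alternative; the grid was chosen because the task semantics are
coverage (clearing cubes off a surface), coverage is meaningful for
non-convex sweeps, and subset-monotonicity holds on a fixed grid. The
grid origin is anchored to the trajectory's minimum corner, which makes
the estimate translation-invariant; an explicit shared origin supports
cross-trajectory comparisons. A 2 cm cell matches the generator's
serpentine row spacing, and the acceptance check requires a designed
0.09 m² square sweep to be recovered within the 7% discretization
tolerance of that cell size. A single-cell trajectory is reported as
one cell with a `degenerate` flag rather than zero, so downstream
tables can distinguish "did not move" from "not measured".

**Finger descriptors.** Per finger, the maximum and minimum flexion
over the filtered trace; the five maxima and five minima are averaged
into maximal finger flexion and minimal finger extension. Values stay
in native glove units; no conversion to degrees is attempted because
the glove calibration is per-subject and monotone, and the statistics
downstream are rank-based. Filtered glove traces are clipped back to
[0, 1] before the extrema are taken (zero-phase ringing can overshoot
the physical range by a fraction of the noise amplitude).

**Validation regression.** `descriptor_score_regression()` fits a
clinical scale on a kinematic descriptor by ordinary least squares and
reports $R^2 = 1 - SSE/SST$; with broom-style `tidy()`/`glance()`
methods. It requires a non-constant descriptor and at least three
pairs.

## NBS motor-map metrics

A motor map is a set of stimulation sites (mediolateral and
anteroposterior coordinates in mm — planar projections, since the
analysis is axis-wise), the delivered intensity in % of maximum
stimulator output (MSO), and the evoked-potential amplitude in uV.

* **RMT** — the smallest tested intensity at which strictly more than
  50% of pulses exceed 50 uV. The estimator is deliberately the
  printed clinical rule, not a curve fit; on simulated recruitment
  series (response probability exactly 0.5 at threshold, 10 pulses per
  2%-MSO level) it recovers the true threshold within one level, with
  the small positive bias inherent to a "first qualifying level" rule.
* **Stimulation efficacy (SE)** — the 80th-percentile MEP amplitude
  (linear-interpolation percentile) divided by the maximum stimulation
  intensity. The phrase "greatest value in the 80th percentile" is
  ambiguous; the percentile-amplitude reading is the only one that is
  robust to outliers and homogeneous of degree 1 in amplitudes, so it
  is used, and the denominator is the maximum intensity actually
  delivered within the map (accommodating escalated acquisitions), with
  the device maximum available as an option.
* **Centroid** — the amplitude-weighted mean of responsive-site
  coordinates (amplitude strictly above 50 uV, the same strictness as
  the RMT rule). Weighting by motor output is the conventional reading
  of a "motor output map" centre; the unweighted variant is a switch.
* **Centroid displacement** — signed post-minus-pre per-axis
  differences and their Euclidean norm.
* **Map area** — area of the convex hull of responsive sites; zero
  below three non-collinear sites. A cortical-surface area is out of
  scope; the planar hull is the declared stand-in.

The simulated acquisition mirrors the clinical protocol: mapping starts
at the hotspot at 110% RMT; a silent start site escalates stepwise
(110%, 120%, 140% of RMT, capped at 100% MSO) and a map silent at the
last rung is returned flagged unmappable. The lattice grows outward
from the start site along primitive lattice rays, and each ray stops
after two consecutive no-response sites — the lattice makes that
"two aligned no-response points" stop rule well-defined. Expected
amplitudes follow a Gaussian fall-off from the true centroid
(scale = extent) times a linear intensity factor, corrupted by
mean-one log-normal noise (CV 0.2 by default), which keeps amplitudes
positive and the acquisition unbiased: over 50 replicate map pairs the
mean recovered centroid displacement is within 1 mm per axis of the
generating shift.

## Statistical layer

Scales where lower is better (Hamilton, shoulder-pain VAS, proximal and
distal Ashworth) are negated once — an idempotence marker prevents
double reversal — so positive change always expresses recovery.
Within-group changes use the Wilcoxon signed-rank test (zeros dropped,
Wilcoxon's original convention; exact sign-enumeration distribution up
to n = 25 untied differences, otherwise the normal approximation with
tie and continuity correction). Between-group comparisons use the
two-sided Mann–Whitney U with midrank ties (exact when untied, normal
approximation with tie correction otherwise). Time effects use the
Friedman rank test with tie correction; a fully tied matrix is reported
as statistic 0, p = 1. Correlations use Spearman's rank coefficient
(exact permutation p up to n = 8 untied pairs, t-approximation beyond).
The exact-mode thresholds are desk-scale choices: at this trial's
sample sizes the exact distributions are cheap wherever they are used.

Effect sizes are pooled-SD Cohen's d,
$d = (\bar{x}_A - \bar{x}_B)/s_p$ with the df-weighted pooled SD, the
treated group first; Hedges' correction is off by default. No
multiple-comparison correction is applied by default — the report is
intentionally the uncorrected per-scale table, with Bonferroni as an
option — and alpha is two-sided 0.05 throughout.

Type-I calibration of the full reporting pipeline is part of the test
suite: on 1000 null cohorts (true effect 0, n = 17/18) the
between-group rejection rate per scale must lie in [0.035, 0.065] at
alpha = 0.05; the exact U distribution at these group sizes has a
realized size of about 0.049, so the band brackets the attainable
rate. Power at a standardized effect of 0.48 with these group sizes is
about 0.29 two-sided (0.41 one-sided); `mc_power_mann_whitney()`
estimates it by simulation and the tests compare it against the
normal-approximation closed form rather than a fixed figure, since the
tail convention behind published post-hoc power figures of this kind is
rarely stated.

## Cohort generation and reproducibility

`generate_cohort()` draws per-subject ability models, clinical panels,
closed-loop training logs, kinematic evaluation streams and pre/post
motor maps from one seed that fans out into per-subject substreams, so
any subject is reproducible in isolation and identical
seed-plus-parameters reproduce the cohort byte for byte. Group sizes
default to 17 treated and 18 controls with an NBS subsample of 17 (3
controls). True between-group standardized effects default to a
moderate arm-and-hand activity gain (0.48 at end of treatment, washed
out at follow-up) with small effects elsewhere; the treatment truth on
maps is an excitability gain of 1.5 on the pathological-hemisphere
thumb-muscle representation and a (2.5, −1) mm pathological centroid
shift. Clinical improvement on the activity scale shares variance with
the latent kinematic recovery (drift standardized *within* group, so
the correlation does not inflate the configured between-group effect).

Problem sizes are the package's defaults for test and demonstration
work: evaluation streams are generated at sessions 1, 8 and 15 at 60 s
each (daily 150 s streams are available from
`generate_kinematic_session()` directly), and Monte-Carlo suites use
50–1000 replicates depending on the statistic.

What the generator does *not* emulate: real reaching is not a
serpentine sweep and real finger traces are not sinusoids (only their
extrema and covered area are calibrated); amplitudes, not EMG
waveforms, are simulated; cortical geometry is a plane, with no sulcus
boundaries by default; clinical scales are generated as continuous
scores, without the integer granularity, floors and ceilings of the
real instruments; and dropout and missing visits are absent unless
introduced. Passing tests therefore demonstrate correctness of the
computations and internal consistency of the pipeline on data with
these idealizations — not clinical validity on real recordings.

## Known limitations

* The adaptation law of the original game controller is not public;
  the windowed staircase is a declared stand-in realizing the same
  band objective.
* The work-area estimator depends on the cell size; 2 cm is tied to
  the generator's row spacing and task geometry, and should be
  re-examined for other capture setups.
* The RMT rule inherits the discreteness of the tested intensity
  ladder; its bias is bounded by one level but not zero.
* Map metrics assume a planar projection; curvature of the cortical
  surface is ignored.
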