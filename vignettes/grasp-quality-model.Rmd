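---
title: "Modelling precision-grip grasp quality and simulated 2AFC judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling precision-grip grasp quality and simulated 2AFC judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspquality)
```

## The problem

When people pick up a small object with thumb and index finger, they choose
contact points from an enormous set of possibilities: a hand-sized surface
sampled at fingertip resolution offers on the order of a hundred candidate
locations and ten thousand ordered two-digit configurations
(`combinatorial_budget(300, 3)`). Human choices are nonetheless highly
regular, and can be described as near-optimal under a small set of
physics- and biomechanics-based costs, subject to a hard force-closure
constraint. This package implements that computational chain for polycube
stimuli — rigid objects built from 2.5-cm cubes of beech wood and brass —
and the psychophysics around it: choosing, for each object, one
near-optimal and one sub-optimal grasp that differ on a single cost;
simulating cohorts of participants who judge which of the two marked grasps
is better across vision, video and grasping sessions; and analysing
percent-correct judgments with frequentist and Bayesian tools.

## Objects

An object is a face-connected set of lattice cubes with a material per cube
(`build_object()`). Mass is $\sum_i s^3 \rho_{m_i}$ with cube side $s$ and
material densities $\rho$; the center of mass is the mass-weighted mean of
cube centroids. Densities are configurable with defaults of 0.62 g/cm³
(beech wood, so a 10-cube all-wood object weighs 96.875 g ≈ 97 g) and
8.5 g/cm³ (brass). The heavy wood/brass reference mass of 716 g is treated
as a reference value only: it depends on a brass-cube count that is not
derivable from the object descriptions, so no object is constrained to it.

The world frame is right-handed with $z$ up (gravity $-z$) and $y$ pointing
from the participant toward the object; objects stand on the table plane
$z = 0$ and may be rotated about $z$ (a turntable pose) and translated
horizontally. Candidate contacts are sampled on exposed cube faces
(`sample_contacts()`), by default one per face center: a deliberately
coarse, fingertip-sized discretization that keeps exhaustive pair
enumeration trivial while matching the combinatorial budget above.

## Grasp scoring

A candidate grasp is an unordered pair of contacts (thumb/index assignment
changes no cost, so enumeration uses unordered pairs; the ordered-pair
budget is exposed separately by `combinatorial_budget()`). Grasps must pass
**force closure**: the line between the contacts must lie inside both
friction cones, i.e. the angle between each outward contact normal and the
direction toward that contact from the other must not exceed
$\arctan\mu$. The default $\mu = 0.5$ (cone half-angle ≈ 26.6°) admits
opposed-face grips and rejects same-side and strongly skewed
configurations; the constraint is qualitative in origin and $\mu$ is
configurable.

Admissible grasps are scored on four costs:

* **Aperture** — Euclidean contact distance; the penalty is the hinge
  $\max(0, a - a_0)$ in cm of excess over $a_0 = 2.5$ cm, the span above
  which people abandon two-digit precision grips. The hinge shape is a
  design choice; only the 2.5-cm limit is empirically anchored.
* **Natural grasp axis** — the acute angle between the undirected
  thumb–index axis and the preferred hand orientation. The default axis is
  horizontal at 45° between the frontal and lateral axes, a configurable
  stand-in for the measured natural grasp axis of right-handed reaches.
* **Torque** — the magnitude of the gravitational moment about the grasp
  axis, $|((\mathbf{c} - \mathbf{p}) \times m g \hat{\mathbf{g}}) \cdot
  \hat{\mathbf{a}}|$ in N·m: zero when the center of mass lies in the
  vertical plane through the contact line, and growing linearly with the
  perpendicular horizontal offset.
* **Visibility** — the fraction of surface sample points whose line of
  sight to the viewpoint (34 cm toward the participant, 30 cm above the
  table) is blocked by a rectangular hand slab spanning the contacts,
  3 cm thick and extruded 10 cm toward the viewer. The slab is invented
  plumbing; only the ordering of grasps by occlusion is treated as
  meaningful.

Costs are min–max normalized within each object's candidate set
(`normalize_costs()`), so 0 is the best and 1 the worst candidate on each
criterion (normalized, arbitrary units), and combined with nonnegative
weights (default uniform). A criterion constant across candidates
normalizes to zero for all — a degenerate-set rule that keeps the combined
cost well defined.

## Stimulus design

`select_pair()` searches all ordered candidate pairs for one near-optimal
and one sub-optimal grasp: among pairs whose off-target optimality
differences are all within $\varepsilon$ (default 0.2 normalized units —
our operationalization of "approximately constant", since no tolerance is
empirically fixed), it maximizes the target-criterion difference
$\Delta$. If no pair is feasible, a fallback picks, within the top decile
of target differences, the pair minimizing the worst off-target
difference, and flags it `relaxed`. `design_experiment()` assigns objects
to criteria in fixed blocks (assignment is configuration, not
optimization, mirroring hand-assignment of objects to criteria), yielding
with the defaults 16 pairs — 4 per criterion — and the 4 × 16
criteria-by-objects difference matrix; `counterbalance_report()` sums the
signed off-target differences per block so near-cancellation across
objects can be verified. Near/sub roles are mapped to blue/green sticker
colors at random from the seed.

## The synthetic observer

The study's response data are binary "which grasp is better" judgments. No
generative model of participants is empirically fixed, so the simulator is
explicit scaffolding: the probability of choosing the near-optimal grasp
is a lapse-contaminated logistic,
$p = \lambda/2 + (1 - \lambda)\,\mathrm{logistic}(k\,\Delta)$, in the
pair's target-criterion optimality difference $\Delta$, with a sensitivity
$k$ per session. At $k = 0$ or $\Delta = 0$ the observer is exactly at
chance. Using the combined-cost difference instead of the target-criterion
difference is a configuration switch. The observer is memoryless across
trials — consistent with the absence of within-session learning in the
study — with an optional log-odds drift per trial for power analyses of
learning-trend detection.

Default sensitivities (vision 1.0, video 2.1, grasping 2.2 per normalized
unit, lapse 0.02) were chosen once so that the default design reproduces
the experiments' qualitative accuracy pattern: roughly mid-60s percent
correct from vision alone and around 80% when grasping, with video close
to grasping. They are emulation parameters, not estimates of human
mechanism. Each participant draws from an independent RNG stream derived
from the master seed, so enlarging a cohort never perturbs existing
participants and trial tables are byte-identical across runs.
`fit_observer()` recovers $k$ per session by bounded one-dimensional
maximum likelihood (lapse fixed), returning a classed fit with
`print`/`coef`/`summary`/`predict` methods; boundary estimates (e.g. from
all-constant responses) are flagged.

What the simulation does *not* emulate: per-participant criterion weights,
object-specific difficulty beyond an optional sensitivity multiplier,
response times, kinematics, or any video content. Passing tests therefore
show that the analysis chain behaves correctly on data with the
experiment's structure and noise, not that the observer model describes
human judgment.

## Analysis

The dependent measure is percent correct per participant and session
(chance 50%). The chain mirrors standard practice: two-sided one-sample
and paired t-tests against chance or between sessions; percentile
bootstrap CIs of the mean (10,000 resamples, seeded; percentile rather
than BCa, as the simpler estimator suffices for symmetric percent-correct
means); standardized effect sizes $(\mu - 50)/\sigma$ and paired
analogues; and BEST-style robust Bayesian estimation with a Student-t
likelihood. Priors are broad defaults: normal on $\mu$ centered at the
sample mean with 1000× the sample SD, uniform on $\log\sigma$ within a
factor 1000 of the sample SD, and a shifted exponential (mean 30) on the
normality parameter $\nu$. Sampling is adaptive random-walk Metropolis, 4
chains × 10,000 retained draws after 2,000 burn-in, seeded, with a
split-$\hat R \le 1.1$ convergence gate that aborts with per-chain
diagnostics otherwise. The 95% HDI is the shortest window over sorted
draws (window size $\lceil 0.95 n \rceil$), and the ROPE is ±0.4 on effect
size, reported as the posterior fraction inside it. No multiple-testing
correction is applied, matching per-contrast reporting.

Two further operations close the loop on the replication design:
`select_replication_subset()` returns the objects at chance in the vision
session (bootstrap CI of the mean containing 50) and significantly above
chance when grasping (two-sided $p < 0.05$ with positive mean — our
operationalization of "significantly above chance", which is not otherwise
pinned down); and `learning_trend()` regresses correctness on
within-session trial index per participant and t-tests the slopes against
zero. For the unpaired contrast between independent cohorts both Welch and
pooled variants are exposed (`unpaired_t()`), since the intended variant
is ambiguous; neither is asserted as canonical.

## Numerical choices and problem sizes

Deterministic enumeration order breaks combined-cost ties; coincident
contacts and zero-variance samples raise errors rather than returning
degenerate statistics; the zero-variance edge of the t-tests is treated as
an error consistently (a constant sample has no defined t statistic, so
"all values at chance" errors rather than reporting $t = 0$). All
stochastic components take explicit integer seeds and keep derived seeds
below $2^{31}$.

The shipped tests and the acceptance script run the study-sized designs
(16 pairs, 21–25 participants) and, where distributional calibration is
asserted, batches of 500–2000 simulated cohorts and MCMC runs of a few
thousand draws; these sizes give Monte-Carlo error comfortably below the
asserted tolerances while keeping a full run in the minutes range.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1, out_dir = "run1")
res <- run_pipeline(cfg)
res$design             # 16 pairs, 4 per criterion
res$report$sessions    # per-session means with bootstrap CIs
fit_observer(res$records, res$design)
```

## Known limitations

The four cost functions fix reasonable functional forms where the
underlying work defines them only up to a framework; all four are exposed
as configuration. The hand/occlusion model is a slab, not a hand. Pose is
restricted to turntable rotations; palm contact, multi-digit grasps, grip
forces and movement kinematics are out of scope. The shipped 16-object set
consists of plausible 10-cube shapes and material layouts with the study's
structure, not the original physical stimuli, and the package analyses
simulated judgments — a loader schema for archived human trial tables is
the CSV interchange format, but mapping real datasets onto it is not
implemented.
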