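---
title: "Methods: analytic E-I homeostasis in large-scale cortical network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analytic E-I homeostasis in large-scale cortical network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eicortex)
```

This vignette is the package's own account of its models, the choices made
where the design was genuinely open, and what the shipped tests do and do
not establish.

## The two local models

**Wilson–Cowan.** Every region is a pair of excitatory/inhibitory neural
masses with logistic gains. The excitatory population receives recurrent
excitation and the long-range network input, both scaled by `G^E`;
inhibition enters unscaled. Delays `tau_ij` are tract lengths divided by a
single global velocity chosen so that the mean delay over connected pairs
hits a prescribed value (`delaysFromLengths()`); the zero-mean-delay case
is the infinite-velocity limit. Integration is Euler–Maruyama at
`dt = 0.2 ms`, with delayed rates read from a ring buffer by
nearest-sample lookup (delays below `dt/2` round to the undelayed sample).
States are clamped to `[0, 1]` after each step — the sigmoid targets are
bounded but an Euler step can overshoot — and clamp events are counted on
the returned `RateTimeSeries`.

**Wong–Wang.** The contrast model replaces fast AMPA-like excitation by
slow NMDA gating (`tauE = 100 ms` versus `tauI = 10 ms`), with the
divisive-saturation gain `(a*x - b)/(1 - exp(-d*(a*x - b)))` and the
standard reduced-mean-field constants (`I0 = 0.382 nA`, `w+ = 1.4`,
`J_NMDA = 0.15 nA`, `J_GABA = 1 nA`, `gamma = 0.641`, `W^E = 1`,
`W^I = 0.7`). Because excitation is an order of magnitude slower than
inhibition, the node has no Hopf bifurcation: `wwHopfScan()` classifies
every probed input level as non-oscillatory, and the test suite confirms
this against finite-difference Jacobian eigenvalues. Conduction delays are
neglected in this model (their effect on ~100 ms dynamics is marginal),
and `dt = 1 ms` suffices.

## Default Wilson–Cowan parameters

The local-circuit constants are package defaults chosen by an explicit
calibration (they are not fitted to any data set):

| parameter | value | role |
|---|---|---|
| `tauE`, `tauI` | 9.84 ms | tuned so the near-threshold node peaks at 40 Hz |
| `cEE`, `cEI`, `cIE` | 3.5, 4.74, 3.75 | recurrent/feedback couplings |
| `muE`, `sigmaE` | −1.054, 0.25 | excitatory gain threshold/slope |
| `muI`, `sigmaI` | 0.65, 0.35 | inhibitory gain threshold/slope |
| `P` | 0.31 | background input |
| `noiseVariance` | 0.01 | additive Gaussian noise |

Four conditions fixed these numbers. (1) The uncoupled node's Hopf
threshold in the external input must sit just above `P = 0.31`
(`findHopfThreshold()` locates it at ≈ 0.312), so the default node is
*close to but below* its bifurcation. (2) Just above threshold the node
must oscillate at ~40 Hz after `tuneTimeConstants()` rescales both time
constants (their ratio is held fixed; rescaling both is an exact time
rescaling, so frequency is inversely proportional to the scale and one
measurement plus one verification suffice). (3) The bifurcation must be
*supercritical*: with inhibition operating near the mid-range of its
sigmoid (`muI = 0.65`, `sigmaI = 0.35`), oscillation amplitude grows
continuously from zero above onset rather than jumping to a large
coexisting cycle. This matters because the mean of an oscillating rate is
biased away from the fixed point in proportion to the squared amplitude;
with a subcritical onset the validity criterion below fails abruptly.
(4) No saturated high-rate fixed point may coexist, which bounds `cEI`
from below. The resulting balance is inhibition-dominated (the inhibitory
current exceeds the excitatory drive at the baseline fixed point), in line
with tight E–I balance; the negative `muE` simply reflects that balance.

## Noise convention

The noise term is written additively in both population equations and is
drawn independently for every population at every step. Its *variance* is
a model parameter (default 0.01), but a variance alone does not determine
a discrete-time increment. The default convention is the standard SDE
reading: variance per unit time, state increment
`sqrt(noiseVariance * dt) * N(0,1)`. The alternative — a fresh
`N(0, noiseVariance)` draw entering the Euler right-hand side each step —
is available as `noiseMode = "per-step"` on `simulationConfig()`. The
default was chosen on internal-consistency grounds: under the per-step
reading at `dt = 0.2 ms`, the scatter of 10-s node means alone exceeds the
1% validity criterion everywhere on a 40-node network, i.e. that reading
is incompatible with the model family's own acceptance surface; under the
SDE reading the criterion is met with a comfortable margin.

## Analytic homeostasis

`estimateExternalInput()` exploits the timescale separation between fast
dynamics and slow homeostasis: at the set point the average input of node
*i* is `I_i = P + C*rho*sum_j W_ij`. With `rI* = F^I(c^IE * rho)` fixed,
the excitatory steady-state equation
`G^E (c^EE rho + I_i) - c^EI rI* = (F^E)^{-1}(rho)` is solved per node for
the free parameters of the active mechanism set (`solveSetPointWC()`).
Single mechanisms are closed-form. Combined mechanisms need an allocation
rule, which was genuinely open; the package uses, in the order inhibition
→ excitation → excitability:

* `c^EI` scales so the inhibitory current tracks the node's raw excitatory
  drive at the baseline node's current ratio `k0`;
* `G^E` anchors at `X0/drive + k0*G0^E` in the `GE+cEI` and all-mechanisms
  models (`X0` is the baseline inverse-gain at `rho`), and normalises the
  total drive to the uncoupled baseline in `GE+cEI+muE`;
* `mu^E` absorbs the remainder exactly, and in the synergistic rule
  `sigma^E = sigma0 * sqrt(drive/driveBase)`, so strongly driven nodes get
  shallower slopes and sit farther from the bifurcation while weakly
  driven nodes stay near it.

All seven combinations land every feasible node's steady state exactly on
`rho` (residuals at machine precision, asserted below 1e-10 across
randomised draws), while producing distinct parameter sets. Nodes whose
solution would need an inadmissible parameter (e.g. `G^E <= 0` for
GE-only scaling at low `rho`) are flagged infeasible per node, never
silently patched — these are the blank regions of the validity maps.
Local stability at the set point is checked from the analytic Jacobian and
reported; set points beyond the local bifurcation are reported as
unstable, not rejected.

The Wong–Wang solver mirrors this: `S^E* = gamma*rho*tauE/(1 +
gamma*rho*tauE)`, the required excitatory current comes from the numeric
inverse of the monotone gain, and `J_GABA` is found by 1-D root-finding
because it also enters the inhibitory population's own current.

For the chronic lesion stage, the re-solve uses the *same baseline
anchors* as the healthy solve. Anchoring instead at the healthy solved
parameters (one possible reading of the protocol) is not idempotent under
the allocation above: it moves the parameters of nodes whose inputs the
lesion never touched, and in trials degraded chronic FC below the acute
stage. With the fixed-anchor rule, untouched nodes keep exactly their
prelesion parameters and only input-deprived nodes are re-balanced, which
produces the intended recovery (chronic FC distance below acute in every
probed lesion).

## Validity criterion

`checkValidity()` implements the post-hoc rule: 15-s run, mean rate of
each node over the last 10 s, relative deviation at most 1%
(Wilson–Cowan) or 15% (Wong–Wang, target 3.0631 Hz); the comparison is
`<=`, so boundary cases pass. `runPoint()` uses it as the cheap gate
before the full simulation, mirroring the two-step sweep procedure.

## Hemodynamics

The Balloon–Windkessel stage uses the standard constant set
(`kappa = 0.65 s^-1`, `gamma = 0.41 s^-1`, `tau = 0.98 s`,
`alpha = 0.32`, `E0 = 0.34`, `V0 = 0.02`), all overridable. Cited sources
differ slightly on these constants; the defaults are documented and
swappable. Integration is RK4 at 10 ms on rates block-averaged from the
neural grid (the hemodynamic timescales are ~1 s; agreement with finer
grids and with an adaptive stiff solver is asserted in the tests). States
start at the equilibrium of each node's baseline drive, so the output is a
%-change signal that is exactly zero for baseline input. Downsampling to
TR = 0.72 s applies a zero-phase Butterworth guard below the TR Nyquist
before decimation; the guard is inconsequential downstream because all
analyses band-pass at 0.008–0.08 Hz.

## Observables

* **Band-pass**: 2nd-order zero-phase Butterworth (order is configurable),
  mirror-padded against edge transients, mean removed.
* **FC**: Pearson correlations of the filtered series.
* **FCD**: windows of 80 samples with 80% overlap (step 16); the value
  distribution is the full upper triangle of the window-by-window
  correlation matrix, *including* overlapping-window pairs — nothing in
  the procedure's definition excludes them, and an exclusion offset would
  be a one-line change.
* **Fitting score**: `(r_FC - MSE_FC - KS_FCD - S_min)/(S_max - S_min)`
  with `S_max = 1` and `S_min = -1 - maxMSE(ref) - 1`, where `maxMSE` is
  the largest MSE an FC bounded in [-1, 1] can reach against the
  reference (per-entry `(|ref|+1)^2`, averaged).
* **Synchrony/metastability**: time-mean and time-SD of the Kuramoto order
  parameter of Hilbert phases (FFT analytic signal on mirror-padded data;
  10 samples trimmed from each end of `R(t)`).
* **Functional complexity**: deviation of the FC-weight histogram from
  uniformity over 40 right-closed bins spanning [-1, 1] (bin 0.05), with
  −1 included in the first bin; 0 for a degenerate distribution, 1 for a
  bin-uniform one.
* **FC modularity**: deterministic Louvain (fixed seed, resolution 1) on
  the positive-thresholded FC graph; swappable.

Note a finite-size floor: for *N* independent nodes the order parameter
has mean ≈ `0.89/sqrt(N)` and SD ≈ `sqrt(0.43/N)`, so synchrony ~0.14 and
metastability ~0.13 on 24 nodes carry no information by themselves; only
elevations above this floor indicate collective dynamics.

## Synthetic data

`generateConnectome()` emulates the gross organisation of DTI-derived
cortical connectomes: spatially clustered modules (members jittered around
module centres, so intra-module tracts are short and inter-module tracts
long), a fraction of connector hubs with elevated inter-module degree,
log-normal weights with configurable dispersion, and tract lengths scaled
to a mean of ~70 mm so delay/velocity numbers are brain-plausible.
Weights are scaled so the *mean row sum is 1* and are otherwise used raw —
the coupling term applies `C` to the unnormalised matrix, which many
whole-brain models do not do; this is deliberate and loud. What the
generator does **not** reproduce: the empirical 78-area cortical
connectome's specific topology (its hub hierarchy, weight tail spanning
several decades, and spatial embedding), or any subject-level variability.
`makeSurrogateReference()` substitutes a held-out simulation (≥ 10 min)
for group-averaged empirical FC/FCD, so fitting scores measure
self-consistency of the model family, not fidelity to human data.

## Problem sizes and operating points

The test suite runs at desk scale: 16–40-node connectomes, 15-s validity
runs, 3–6-min scored simulations (an FCD with ~11–27 windows), and a
12-point input grid for the Wong–Wang scan. Two canonical operating
points recur: a *valid reference point* (`C = 1.5`, `rho = 0.12`, mean
delay 4 ms) where all deviations sit near 0.5%, and a *metastable point*
(`C = 2`, `rho = 0.14`, mean delay 12 ms on the 24-node scaffold) just
past the collective oscillation onset, where independent-seed FC patterns
correlate at ~0.77 and metastability rises clearly above the finite-size
floor. In this reconstruction the two regimes do not overlap: collective
dynamics strong enough to imprint structure on FC bias the 10-s mean
rates by 1.5–3%, beyond the 1% rule. The homeostatic set point is exact
either way; the trade-off concerns the *fluctuations* around it.

## Known limitations

* The shuffled-connectome control (lower FC complexity and metastability
  than the original topology) does not reproduce at 24–40 nodes in any
  probed regime — the synthetic scaffold's topology is evidently not rich
  enough for shuffling to impoverish the dynamics; the corresponding
  acceptance expectations are left failing by design rather than
  weakened.
* Likewise, a single-node lesion does not displace the FCD value
  distribution beyond seed-to-seed KS noise at desk scale, so only the FC
  -distance recovery (which does hold in every probed lesion) is
  informative about the chronic stage.
* A sweep-wide score–metastability correlation is not asserted in the
  suite: across the narrow valid regime the metastability spread is
  comparable to its seed noise at desk-scale durations.
* Homeostasis acts only on the excitatory population's parameters;
  inhibitory-population homeostasis is out of scope.
* The per-step noise mode is retained for comparison but is
  dt-dependent; results under it should state the step size.
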