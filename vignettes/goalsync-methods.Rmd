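---
title: "Methods: multi-scale analysis of dCA1-mOFC coordination during goal learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale analysis of dCA1-mOFC coordination during goal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`goalsync` implements a multi-scale analysis pipeline for dual-region
electrophysiology recorded while rodents learn two daily-changing hidden
goal locations on a circular cheeseboard arena (150 cm), together with a
synthetic-session generator that provides ground truth for every stage and
a recurrent-network navigation model with short-term synaptic plasticity
(STSP). This vignette documents the models and procedures, the parameters
that matter, and the design decisions taken where the problem was
genuinely open.

## Session model

A session bundles spike trains (units with region and cell-type labels),
a 50-Hz head-position track, one 1-kHz LFP channel per region (dCA1,
mOFC), two rewarded goal coordinates for the current and previous day, 40
learning-trial windows, and pre-/post-probe windows. Everything is stored
as plain text (JSON metadata plus CSV tables) so sessions diff cleanly
and round-trip exactly.

Cell types follow a two-parameter rule on waveform trough-to-peak latency
and the autocorrelogram rise time constant: narrow-waveform interneurons
at trough-to-peak <= 0.425 ms; wide-waveform interneurons above that when
the rise constant exceeds 6 ms (strict inequality — the rule's boundary
behavior at exactly 6 ms is not specified anywhere, so the printed strict
">" is used); all remaining units are putative pyramidal cells. Units
below 0.3 Hz mean rate are excluded (inclusive bound).

## Behavior

Running speed is a centered finite difference smoothed with a 5-sample
moving average; this single definition is computed once on the track and
shared by every stage (spatial speed gating, theta-cycle and ripple
detection, speed-power controls). Goal visits merge consecutive in-ROI
frames (15-cm radius) and bridge gaps of up to 50 frames (~1 s). Each
complete trial is segmented into four contiguous epochs ordered by the
first-reached goal: Navigation1 (start-box exit to first goal-zone
entry), Goal1 (dwell), Navigation2, Goal2. Two operationalizations were
required where the behavioral criterion is unobservable in synthetic or
neutral data:

* *start-box exit* is the first frame outside the start-box rectangle
  stored in the session;
* a *Goal dwell ends* at the last in-zone frame before a continuous
  absence of at least 1 s, reusing the visit-merge logic. This stands in
  for "obtained the reward", which no tracking-only dataset can encode.

Learning curves (per-trial path length) are fit with a continuous
one-breakpoint piecewise-linear model `y = b0 + b1 x + b2 (x - tau)+` by
ordinary least squares over a grid of integer breakpoints; the grid runs
from the 3rd to the (n-2)th trial so both sides of the break carry at
least two observations, and RSS ties resolve to the smallest candidate.

## Spatial maps and goal-overlap classification

Rate maps use 5 x 5 cm bins over the arena square, occupancy and spikes
restricted to speeds above 4 cm/s, bins under 200 ms of occupancy masked.
The rate map (spikes/occupancy) is smoothed *after* the division with a
5-bin Gaussian kernel (sigma 1.5 bins) whose weights are renormalized
over valid bins, so unvisited bins neither receive nor donate rate. The
alternative (smoothing spike and occupancy maps before dividing) changes
values near mask boundaries; smoothing the rate map is the reading most
consistent with "the resulting maps were smoothed". Skaggs information
`I = sum p_i (r_i/rbar) log2(r_i/rbar)` is computed on the same smoothed
map used everywhere else (a config switch can use raw maps; smoothed is
the default for internal consistency).

A unit's peak region is every valid bin at or above 80% of its map peak
(units with peaks of 1 Hz or less are excluded). Each goal contributes a
3 x 3-bin window centered on its bin; the overlap score per goal set is
the larger of the two per-goal overlaps (0..9 bins). Goal-related units
overlap the previous-day set pre-probe or the current-day set post-probe;
reorganization units do both; among goal-related units the rest are
non-reorganization. Session-level fractions are computed within session x
region x cell-type strata before any cross-session comparison.

## Oscillations

Filtering is a 4th-order Butterworth applied forward-backward (zero net
phase). Bands: theta 4-12, low gamma 30-60, high gamma 60-90, ripple
150-250 Hz; the delta band used only in the theta/delta gate is 1-4 Hz (a
conventional choice — the band is never defined in the source analyses).
Two numerical points matter at 1 kHz sampling:

* the analytic-signal transform zero-pads to a 2-3-5-composite length
  before the FFT (mixed-radix FFTs degrade to quadratic cost near prime
  lengths) and truncates afterwards;
* a 1-4 Hz 4th-order band-pass is numerically singular at 1 kHz, so the
  theta/delta envelope ratio is evaluated on a 10x-decimated copy and the
  binary gate interpolated back; `bandpass()` refuses to return
  non-finite output.

Welch PSDs use 1-s Hann windows at 90% overlap (1-Hz grid), scaled so the
PSD integrates to the signal variance. Band power is the mean PSD inside
the band. PLV is the modulus of the mean phase-difference unit vector.
The phase-amplitude modulation index divides the slow phase into 18 bins
of 20 degrees, normalizes the mean fast-band envelope per bin into a
distribution, and reports `(Hmax - H)/Hmax` with `Hmax = log 18`; empty
bins contribute zero mass and are flagged.

For n:m phase-phase coupling the implemented statistic is
`r_nm = |mean exp(i (m phi_slow - n phi_fast))|`: the exponent is
stationary exactly when `m f_slow = n f_fast`, so a 1:5 theta-gamma scan
peaks when gamma runs at five times theta. (With the factors the other
way round the statistic cannot detect the ratio it is named for; the
package follows the semantics and the worked examples rather than the
ambiguous symbol order.)

Theta cycles are trough-to-trough intervals (analytic phase +/-pi) kept
when speed exceeds 4 cm/s and the theta envelope exceeds three times the
delta envelope, excluding ripple periods. Sharp-wave ripples are
intervals where the z-scored ripple-band envelope exceeds 3 SD during
immobility (< 4 cm/s); the baseline mean/SD come from all immobile
samples of the session. Two stabilizing criteria are added on top of the
bare threshold: crossings closer than 10 ms are merged and events must
last at least 20 ms — a plain 3-SD threshold fires dozens of brief chance
crossings per minute on featureless noise. The exclusion mask covers each
event plus the following 100 ms and is shared by the phase-locking,
coupling, pairwise-timing and assembly stages. PLV/MI over epochs are
computed on concatenated epoch samples (a per-trial option exists).

## Spike timing

Theta phase locking restricts spikes to valid theta cycles, tests
uniformity with the Rayleigh test (refined large-sample approximation),
and for units passing p < 0.05 estimates the von Mises concentration
kappa by maximum likelihood (standard piecewise inversion of the resultant
length). Units with fewer than 50 in-cycle spikes are excluded.

Pairwise short-latency coordination binarizes both trains at 1 ms,
computes the +/-50 ms cross-correlogram normalized by the reference spike
count, subtracts the mean over absolute lags 20-50 ms (both signs
jointly), and takes the maximum excess at lags 1-3 ms (within-region) or
1-5 ms (cross-region), end lags inclusive. Significance uses 1,000
surrogates in which every target spike is shifted by an independent
integer offset uniform on -25..25 ms and re-binarized (collisions in one
bin collapse to 1); the one-sided empirical p is `(1 + #{T_k >= T_obs}) /
1001`. Within each block, Benjamini-Hochberg correction runs within the
family of pairs sharing a reference neuron (q < 0.05). Learning trends
over the four blocks combine the OLS slope beta (on block indices 1..4,
uncentered) with the net change Delta = B4 - B1; a pair is increased only
when both are positive, decreased only when both are negative. Surrogate
RNG streams are seeded per (pair, block) from a master seed. The
surrogate loop is compiled (Rcpp) and draws from R's RNG, so results are
reproducible from `set.seed()`.

## Assemblies

Spikes are binned at 20 ms (ripple bins plus 100 ms dropped), z-scored
per neuron (zero-variance neurons dropped with a warning). Significant
dimensionality is the number of correlation-matrix eigenvalues above the
Marchenko-Pastur upper edge `(1 + sqrt(n/T))^2` — the standard edge for
unit-variance data; the threshold is named but never written out in the
source analyses. FastICA (logcosh contrast, symmetric decorrelation,
deterministic seed) runs on the PCA-whitened significant subspace — the
standard estimator family for this method; running ICA on raw z is the
unstated alternative and is not used. Weight vectors are mapped back to
neuron space, unit-normalized, sign-fixed so the largest-magnitude weight
is positive. Activation is `S(t) = z' P z` with the projection diagonal
zeroed (isolated single-neuron spiking contributes nothing); events are
strict local maxima above 5, plateau ties taking the first bin.

## Decoding

Each labeled epoch is cut into non-overlapping 400-ms windows (trailing
remainders dropped); features are per-neuron spike counts in 20-ms bins
converted to rates and concatenated (20 features per neuron). The stage
task uses the four Block-4 epoch labels; block tasks use Goal-only or
Navigation-only windows labeled 1..4. Classes are balanced once per task
by subsampling to the smallest class (a flag allows re-drawing).
Cross-validation is leave-one-trial-out; z-scoring statistics come from
the training fold only (fold discipline is the leakage-safe reading of
"features were z-scored"). The classifier is Gaussian naive Bayes with
training-fold priors and a variance floor of 1e-9 on constant features.
Performance is the micro-average ROC-AUC: one-hot labels and posteriors
flattened across classes, AUC by the rank (Mann-Whitney) formulation with
tie correction; chance for the 4-class problems is 0.5. The fixed-N
replacement control swaps `floor(fraction x N)` source-region neurons for
randomly drawn other-region neurons, keeping N constant, re-running the
full decode per resample (200 by default) and averaging.

## STSP network model

Two recurrent subnetworks — a reward subnetwork (4 reward inputs onto 80
neurons, 64E/16I) and a spatial subnetwork (10 place inputs onto 100
neurons, 90E/10I) — project through their excitatory neurons to two
readout units encoding x/y velocity. Synaptic efficacy is the product of
a resource variable x and a utilization variable u per synapse, with
facilitating (tau_x 0.2 s, tau_u 1.5 s, U 0.15) or depressing (tau_x
1.5 s, tau_u 0.2 s, U 0.45) dynamics integrated by forward Euler at
dt = 10 ms. The state is per-synapse rather than per-presynaptic-neuron
because the default pathway assignment — cross-subnetwork E->E synapses
facilitating, within-subnetwork synapses depressing — gives one
presynaptic neuron synapses of both classes; per-synapse x/u is the
minimal generalization (and reduces to per-neuron state when all of a
neuron's synapses share a class). Variants: `no_stsp` freezes efficacy at
its rest value U; `no_cross` removes all cross-subnetwork recurrent
connections.

Everything about training is unpublished in the source analyses, so the
package makes and documents these choices: rates pass through a
saturating `r_max tanh(max(z, 0))` nonlinearity (r_max 100 Hz); the
readout velocity is bounded at 50 cm/s by a tanh; the arena is a 60-cm
square with ten Gaussian place inputs on a fixed grid and a goal radius
of 5 cm; the loss is the episode-mean squared distance to goal
(normalized by the arena size) plus small saturation penalties (1e-2) on
normalized rates and readout drive; gradients come from backpropagation
through the rate recursion and the position integral, treating the STSP
trajectories and the position-to-input dependence as given (recorded in
the forward pass); updates use Adam with connectivity-masked gradients
clipped to unit norm, and the Dale sign pattern plus the mask are
re-imposed after every step so masked entries stay exactly zero. The
saturation penalties are load-bearing: without them a long-trained
network sits in the flat region of its nonlinearities, its gradients
vanish, and it cannot adapt when the goal moves — the goal-switch
comparison would measure saturation, not flexibility.

The goal-switch experiment trains a copy of the pretrained network and a
naive network on the new goal with identical budgets, learning rate and
criterion (an evaluation episode from the fixed start reaching the goal),
evaluating after every other training episode; both arms start the
optimizer cold. The switched goal is displaced by roughly a quarter of
the arena — proportionally matching the daily goal displacement on the
cheeseboard (tens of centimeters on a 150-cm board) — so the transferable
component (an efficient locomotion policy over the shared route segment)
is large relative to the component that must be unlearned. Only the
qualitative contrast (pretrained adapts in fewer episodes than naive, in
the median over seeds) is contractual.

## Synthetic sessions

The generator emulates, with known ground truth: place-tuned and
goal-tuned inhomogeneous-Poisson spiking (thinning at 1 kHz), goal cells
whose fields sit at previous-day goals before learning and (for remapping
cells) at current-day goals afterwards, von Mises theta-phase rate
modulation, planted short-latency pairs (target spikes inserted at fixed
latency after reference spikes with a set excess probability), planted
assemblies (members co-spiking around latent events), theta/gamma LFP
with controllable phase-lag jitter (PLV), envelope modulation depth
(PAC) and ripple bursts at immobile at-goal times, and cheeseboard
trajectories: 40 trials whose target path length follows a
piecewise-linear schedule with a breakpoint at trial 10, each trial
leaving the start box, dwelling at both goals and returning. Goal
placement obeys the task's constraints (> 50 cm between same-day goals
and from the previous day's goals, > 20 cm from the edge). Trajectories
are polyline traversals with slowly varying positional wobble — white
positional jitter would inflate realized path lengths far above the
schedule. Probe durations default to the recorded 25 minutes; tests and
examples use shorter probes (60-300 s) and state so where map quality
matters (a 5-cm-bin map needs roughly 10 minutes of foraging before most
bins clear the 200-ms occupancy mask).

What the generator does *not* emulate: biophysical LFP realism
(oscillations are phase-jittered sinusoids plus noise), ripple content
beyond band-limited bursts, theta sequences/phase precession, spatially
correlated noise across units, and electrode artifacts. Passing tests
therefore demonstrate correctness of the estimators on data matching
their model assumptions, not robustness to every pathology of real
recordings.

## Problem sizes used by the test suite

Unit tests run on compact versions of the study conditions chosen for
desk-scale runtimes: sessions with 60-300 s probes and 40 fast trials,
20-60 s LFP segments for spectral checks, 200 null pairs at 2 Hz x 300 s
for the surrogate calibration, 100 neurons x 10,000 bins for assembly
recovery, 50 place cells x 600 s for field recovery, and 20/25-neuron
subnetworks (scaled from 80/100) with 250-step episodes for the model
experiments. The statistical structure (rates, effect sizes, coupling
depths, trial counts) follows the study conditions; only durations and
network sizes are scaled.

## Known limitations

* Epoch segmentation requires trials that actually visit both goals;
  incomplete trials are excluded with a warning rather than imputed.
* The Goal-epoch end rule is a stand-in for reward consumption (flagged
  above); datasets with reward-delivery events should replace it.
* The jitter surrogate preserves spike counts but only approximately
  preserves slow rate co-modulation, as in the original procedure.
* The model is a hypothesis-generating consistency test: its training
  objective, encodings and protocol are package choices, and only
  direction-of-effect contrasts are meaningful.
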