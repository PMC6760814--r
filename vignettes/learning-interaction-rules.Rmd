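---
title: "Learning interaction rules of collective motion with attention networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning interaction rules of collective motion with attention networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

Groups of fish (and many other animal collectives) coordinate through
local interactions: each individual reacts to the positions and motion of
its neighbours. Classical zonal models posit hand-written rules —
repulsion when a neighbour is too close, alignment at intermediate range,
attraction further out — that are insightful but rarely tested against
each individual's actual decisions. At the other extreme, a generic deep
network trained to predict individual motion can be very accurate but
opaque.

`fishrules` implements a middle path: a *constrained attention network*
whose structure forces the learned model into two small, plottable
modules. The prediction task is deliberately simple — a binary
classification of which side (left or right) a focal individual will have
turned to after a fixed horizon — because a binary logit is easy to read:
its sign is a decision, its magnitude an intensity.

## Variables

All quantities are expressed in body lengths (BL) and seconds, in an
instantaneous frame centred on the focal individual with the +y axis along
its velocity and +x to its right. For a focal with speed $v$ and normal
acceleration $a_\perp$ (positive rightward), each of its $n$ nearest
neighbours $i$ contributes a social vector: relative position
$(x_i, y_i)$, velocity $(v_{i,x}, v_{i,y})$, equivalently speed $v_i$ and
relative heading $\theta_i \in [-\pi, \pi)$ ($\theta_i = 0$ means moving
parallel, positive means heading to the focal's right). The default input
set is $\{v, a_\perp\}$ for the focal and $\{x_i, y_i, v_{i,x}, v_{i,y}\}$
per neighbour — six variables per pair, $25 \times 6 = 150$ inputs in all
for the default $n = 25$ — with tangential and neighbour accelerations
available as options, plus an optional *topological index* (the
neighbour's distance rank).

The label is the side of the heading change after $N_f$ frames: right
when the future velocity has a positive x-component in the current focal
frame. The associated *turning angle* (the unsigned angle between the two
velocities, degrees) is carried along so accuracy can be reported per
angle band; small-angle turns are intrinsically noisy, large turns are
the informative ones. Exact zero turns are ties; they are labelled right,
which a reflection-antisymmetric model cannot exploit (its prediction at
a mirror-symmetric input is exactly 0.5). Samples where the focal speed
vanishes at either end of the horizon are dropped — the egocentric frame
is undefined there.

## The two model families

**Interaction network.** A pair-embedding MLP $\Pi_I(\alpha, \sigma_i)$
(3 hidden layers of 128 rectified-linear units, 128-unit linear readout,
parameters shared across neighbours) maps each (focal, neighbour) pair to
an embedding; the embeddings are summed over neighbours, rectified, and
an aggregator MLP $\Gamma$ (one 128-unit hidden layer, 1-unit readout)
produces the logit $z = \Gamma(\mathrm{relu}(\sum_i \Pi_I))$. The sum
makes the model exactly permutation-invariant. This is the
high-accuracy, low-insight reference model.

**Attention network.** The logit is an explicit weighted average of pair
contributions,
$$z = \frac{\sum_i \Pi_A(\alpha, \sigma_i)\, W(\alpha^{(w)}, \sigma_i^{(w)})}
           {\sum_j W(\alpha^{(w)}, \sigma_j^{(w)})},$$
with three structural constraints. (i) $W > 0$: an exponential follows
its single-unit readout. (ii) $\Pi_A$ is odd and $W$ even under
body-axis reflection: $\Pi_A$ is antisymmetrized per neighbour
($\Pi_A(\alpha,\sigma_i) - \Pi_A(\alpha^*,\sigma_i^*)$, where $^*$ flips
the sign of all x-components), and $W$ receives only
reflection-invariant inputs — by default $(v, v_i, |x_i|, y_i)$, with the
topological index optionally appended. (iii) The weights are normalized
to sum to one, so $\omega_i = W_i / \sum_j W_j$ is the fraction of the
decision attributable to neighbour $i$. Both subnetworks use the same
3x128 stack. A focal-only baseline (an MLP on $\alpha$ alone,
antisymmetrized the same way) bounds how much of the behaviour is
asocial.

The whole-model antisymmetrization of the interaction network and the
per-neighbour antisymmetrization of $\Pi_A$ both guarantee
$z(\text{mirrored scene}) = -z(\text{scene})$ exactly — the property the
tests verify to float tolerance.

Probabilities come from the logistic link $p = 1/(1+e^{-z})$ and training
minimises mean cross-entropy with Adam ($\beta_1 = 0.9,
\beta_2 = 0.999$). The attention network uses minibatches of 500 and a
learning rate annealed from $10^{-4}$ to $10^{-5}$; the interaction
network minibatches of 200 and $5\times10^{-5}$ to $10^{-5}$. The
annealing shape is an exponential decay per epoch across `max_epochs`
(the endpoints are fixed; the shape in between was an open choice). Training stops after `max_epochs` (100 by default), or
early when the validation loss has not improved for 10 epochs *and* sits
at least 25% above its minimum; the returned parameters are those of the
best validation epoch. No dropout is used. Given a seed, training is
bit-reproducible within a BLAS build.

Inputs are z-scored with statistics fitted on the training split only.
Features that are odd under reflection ($x_i$, $v_{i,x}$, $a_\perp$,
accelerations) are scaled but *not* centred: centring them would break
the exact reflection antisymmetry of the architecture. Whether the
original experiments standardized inputs is not recorded; z-scoring is
the conventional choice and interacts correctly with the symmetry
constraints under this centring rule.

## Preprocessing

`preprocess_trajectories()` chains the standard steps, each causal:

1. **Gap interpolation** (`interpolate_gaps`): tracking gaps of at most
   `max_gap` frames (default 5) are filled linearly per coordinate;
   longer, leading and trailing gaps stay missing. The default matches
   the "very small holes" this step is meant for — the reported gap mass
   in the recordings this method was developed on is ~0.03% of points.
2. **Normalization and border mask** (`normalize_and_mask`): positions
   are translated so the arena centre is the origin and, for pixel-unit
   recordings, divided by the body length in pixels, so everything
   downstream is in BL. Points beyond 80% of the arena radius are
   border-masked: they are not used as focal samples (wall interactions
   would contaminate the social model) but still appear as neighbours.
3. **Causal smoothing** (`smooth_causal`): a 5-frame half-Gaussian kernel
   ($\sigma$ = 1 frame) over the current and past frames only, truncated
   and renormalized at the start of the recording.
4. **Causal differentiation** (`differentiate`): backward differences for
   velocity and acceleration; the first two frames are invalid.

Nothing computed at frame $t$ depends on frames after $t$; the tests
check this by perturbing future frames.

**Shuffle control.** To verify that a trained model captures genuine
interactions rather than shared arena statistics, each individual's
series is circularly shifted by $(i-1)\,T/N$ frames
(`shuffle_preprocessed`). The shift is applied after preprocessing, to
positions and kinematics as one block, so every focal's own kinematics
remain genuine while all cross-individual timing — hence all real
interaction — is destroyed. For a 10-minute, 100-individual recording at
32 fps the minimum nonzero circular shift is 6 s and the mean is 150 s.

**Splits.** Recordings are divided into contiguous train / validation /
test blocks; the conventional fractions for long experimental videos are
97% / 2% / 1%, and `split_frames(rotate =)` moves the validation+test
region to other parts of the recording. For the simulated-data
experiments in this package the fractions are 85% / 5% / 10%: the
simulated recordings are deliberately short, and a 1% test slice would
make the accuracy estimate's binomial error larger than the effects being
measured.

## Reading the trained model

**Score maps.** `pair_logit_map()` evaluates the antisymmetrized $\Pi_A$
on a grid of neighbour positions (default the 8x8 odd-coordinate grid
from -7 to 7 BL), relative orientations (64 uniform samples of
$[-\pi,\pi)$) and neighbour speeds, at a fixed focal context. Per spatial
cell:

* *attraction–repulsion score* $= \mathrm{sign}(x)\,\langle z
  \rangle_\theta$ — positive when the focal tends to turn toward the
  neighbour's side regardless of the neighbour's heading;
* *alignment score* $= \max_\theta\{z\,\mathrm{sign}(\theta)\} -
  \max_\theta\{-z\,\mathrm{sign}(\theta)\}$ — positive when the focal
  turns toward the side the neighbour is heading to. For a
  $\theta$-constant logit both maxima equal the same constant and the
  score is zero, which is the reading that makes orientation-insensitive
  cells non-aligned.

`classify_regions()` labels a cell *alignment*/*anti-alignment* when the
logit changes sign across $\theta$ (by the alignment score's sign), and
*attraction*/*repulsion* otherwise (by the attraction–repulsion score's
sign). Cells whose |logit| never exceeds 1% of the map's maximum are
flagged low-confidence rather than reclassified. The scores agree with
dense-$\theta$ brute-force evaluation to quadrature tolerance (tested).

**Effective neighbour numbers.** The normalized weights of a decision
define a typical weight $\omega_t$ through the weight entropy:
$N_{\mathrm{total}} = 1/\omega_t = \exp(-\sum_i \omega_i \ln \omega_i)$,
the perplexity of $\omega$ (natural log, so the identity
$N_{\mathrm{total}} = $ perplexity holds exactly). It equals $n$ for
uniform weights and 1 for a one-hot vector. $N_{\mathrm{important}}$
counts the neighbours with $\omega_i \ge \omega_t$. The printed
definition in the source text ("weight smaller than the typical weight")
contradicts both the word *important* and the uniform-weight case, so the
$\ge$ reading is the default and the strict-below variant is available
behind `definition = "below-typical"`. `power_spectrum()` (averaged
periodogram, 256-frame segments, 50% overlap, no taper) summarises the
time scales of the per-frame count series.

## The zonal ground-truth simulator

`simulate_zonal()` generates trajectories from known rules so that the
whole inference chain can be validated. Agents move at a constant
3 BL/s in a circular arena of radius 25 BL with a time step of 1/32 s.
At each step an agent keeps its heading with probability 2/3; otherwise
it computes a desired direction from three egocentric zones — turn away
from any neighbour inside the repulsion zone (overriding everything
else), otherwise align with orientation-zone neighbours' headings and
head toward attraction-zone neighbours — perturbs that desired direction
with Gaussian error (SD 0.2 rad), and rotates toward it by at most the
turning rate (0.2 rad). At the wall the perpendicular velocity component
is reversed. A topological cap restricts the candidate neighbours to the
cap nearest, and the simulator records per frame the ground-truth count
of interacting neighbours (the repulsion-zone occupancy when that zone
is occupied, the orientation+attraction occupancy otherwise).

The noise enters *before* the turning-rate clamp. This follows the
classical zonal formulation (the error perturbs the desired direction,
the realized turn is rate-limited); it also means a single heading update
never exceeds the turning rate, and the sign of a turn is informative
about the desired direction whenever the misalignment exceeds the noise.

Zone geometry was an open choice (the source figures show shapes, not
radii). The defaults — repulsion within 1 BL, orientation 1–5 BL,
attraction 5–10 BL — were chosen once so that all three zones fit inside
the ±7 BL plotting window with room to spare, and are scaled variants of
the classical three-zone models. The geometry presets mirror the
published variations: `large-repulsion` (repulsion to 2 BL), `displaced`
(orientation annulus moved 2 BL forward), `elliptical` (orientation
annulus elongated fore–aft, axis ratio 2), `blind-angle` (a rear blind
cone of half-angle $\pi/4$ on every zone). Simulated training predicts
the side after 125 ms (4 frames).

## What the recovery experiments show — and what they cannot

`run_recovery()` executes the full loop: simulate, preprocess, build
125-ms samples, train the attention network, and compare the learned
structure against the generator: the mean attraction–repulsion score
inside the true repulsion zone should be negative, inside the true
attraction zone positive, and a majority of orientation-zone points
should classify as alignment; for capped runs, the run-averaged
$N_{\mathrm{total}}$ should track the run-averaged true count
(one topo-aware model per cap, mirroring the one-model-per-recording
design of the original validation).

The simulator emulates the container and statistics of tracked recordings
(constant frame rate, arena confinement, occasional short gaps in the
test fixtures) but deliberately not their full richness: speeds are
constant, decisions are Markovian with i.i.d. update times, there is no
posture, no individuality, no history dependence. Passing recovery
therefore shows the *inference chain* is sound — it does not certify any
particular biological claim about real fish, and real-recording accuracy
values cannot be reproduced without the original videos (the pipeline
accepts such recordings through `read_trajectories()` +
`run_fish_analysis()` when available).

A structural property of the zonal generator matters when reading
all-angle accuracies: with update probability 1/3 per frame, about
$(2/3)^4 \approx 20\%$ of 125-ms windows contain no heading update at
all, and smoothing spreads many others into sub-5-degree pseudo-turns
whose sign carries mostly noise. Accuracy on decided turns (20–160
degrees) is the informative quantity; all-angle accuracy is bounded well
below 100% by this tie mass regardless of model quality.

## Problem sizes used by the shipped experiments

The package's own validation runs (tests and the acceptance script) use
scaled-down study sizes, chosen once: 6 topological caps
{3, 7, 11, 15, 19, 23} at 110 simulated seconds each for the pooled
accuracy experiment (20 training epochs at the reference batch size);
60-second runs with 22 epochs (minibatches of 250) for the per-preset
recovery suite and 50-second runs with 15 epochs for the per-cap count
recovery; 85/5/10 splits throughout (see above). Short runs keep the
reference learning-rate schedule by annealing over a 100-epoch horizon
while capping the epoch count (`anneal_epochs`), which converges
markedly better at fixed budget than compressing the anneal. With the
single-precision network kernels in `src/`, one pooled training takes a
few minutes on one CPU core. Larger sizes sharpen every estimate; the
defaults of the exported functions are the full-scale settings.

## Numerical choices and degenerate inputs

* Attention weights are computed through a per-sample max-shifted
  softmax, so extreme raw readouts cannot overflow; the raw readout
  (log W) is what `weight_map()` plots.
* Cross-entropy clamps probabilities to $[10^{-12}, 1-10^{-12}]$.
* Ties in neighbour distance are broken by individual index; the
  turn-side tie (exact zero x-component) is labelled right.
* `attraction_repulsion_score` at $x = 0$ returns 0 (sign convention);
  the recovery grid simply omits the $x = 0$ axis.
* Zero-length desired directions in the simulator (no zone neighbour)
  keep the current heading as the target.
* Network initialization is fan-in-scaled Gaussian (He); all random
  draws (initialization, batch order, simulator) go through R's RNG and
  are controlled by explicit seeds.

## Known limitations

* The all-angle accuracy ceiling of the zonal generator discussed above.
* Single-precision training: two runs agree bit-for-bit under one BLAS,
  but not necessarily across BLAS builds.
* `read_trajectories()` implements the long-CSV dialect (plus YAML
  metadata); array containers from other ecosystems need a one-off
  conversion to it.
* The simulator is 2-D and constant-speed by design; speed dynamics,
  hydrodynamics and 3-D motion are out of scope.
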