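# fishrules

Learning the interaction rules of collective motion from multi-individual
trajectories, with constrained deep attention networks.

## What this package does, and for whom

Given per-frame 2-D positions of every individual in a group (schooling
fish tracked at a fixed frame rate, or any comparable recording),
`fishrules` fits a model of how each individual decides where to turn,
structured so the fitted model can be *read*:

* a **pair-interaction subnetwork** Π(α, σᵢ) maps the focal's kinematics
  α = {v, a⊥} and one neighbour's kinematics σᵢ = {xᵢ, yᵢ, v_{i,x},
  v_{i,y}} (egocentric frame, body lengths) to a per-neighbour logit of
  turning right;
* an **aggregation subnetwork** W(α⁽ʷ⁾, σᵢ⁽ʷ⁾) > 0 assigns each
  neighbour a weight, normalized to ωᵢ = Wᵢ/ΣⱼWⱼ;
* the model's logit of a right turn after the horizon is the attention
  average

  z = Σᵢ Π(α, σᵢ) ωᵢ,  p(right) = 1/(1+e⁻ᶻ),

  with Π exactly odd and W exactly even under reflection along the body
  axis, so mirror scenes give mirror predictions.

From a trained model the package extracts the field's classical
interaction structure without assuming it: attraction–repulsion scores
(sign(x)·⟨z⟩_θ), alignment scores (max_θ{z·sign θ} − max_θ{−z·sign θ}),
region classification (alignment / anti-alignment / attraction /
repulsion), and the effective number of interacting neighbours
N_total = exp(−Σ ωᵢ ln ωᵢ) with its "important" subset
(ωᵢ ≥ 1/N_total). A permutation-invariant interaction network (summed
128-d pair embeddings) serves as the high-accuracy reference, and a
focal-only baseline bounds the asocial share of the behaviour.

Because real recordings come with no ground truth, the package includes a
**zonal agent-based simulator** (repulsion / orientation / attraction
zones, constant speed, rate-limited noisy turning, topological caps,
wall reflection) that produces trajectories with known rules and known
per-frame interacting-neighbour counts, so the entire inference chain —
preprocessing → features → training → maps → weight entropy — can be
validated by recovering what generated the data.

It is aimed at researchers in collective animal behaviour working with
trajectory output from tracking systems (one array of frames ×
individuals × 2, plus arena metadata).

## Worked example

Simulate a group with known rules, train the attention network on 125-ms
turn decisions, and ask the model what it learned:

```r
library(fishrules)

config <- zonal_config("circular", topological_cap = 15)
rec <- run_recovery(config, duration = 60, seed = 925, stride = 3,
                    batch_size = 250, max_epochs = 22, topo_index = TRUE)
print(rec)
```

```
<recovery_report: preset 'circular', cap 15>
  test accuracy: 66.0% (all angles), 88.6% (20-160 deg)
  mean score: repulsion zone -0.026, attraction zone +0.084
  orientation zone classified alignment: 100%
  N_total: estimated 18.46 vs ground truth 12.85
```

Reading the output: turn-side prediction is strongest for decided turns
(20–160°; all-angle accuracy is capped by the ~20% of 125-ms windows in
which a simulated agent never updates its heading, plus a mass of
near-zero noise-driven turns). The learned pair-interaction map
classifies the generator's orientation annulus as alignment everywhere
and scores its attraction annulus positive and its repulsion zone
negative. The perplexity of the attention weights tracks the true
interacting-neighbour count but overestimates it at this short training
scale: the learned weights decay smoothly with distance rank instead of
gating sharply at the cap, a bias that shrinks with training scale (see
the methods vignette).

The observational arm runs the same chain on any recording in the
standard container (CSV `frame,id,x,y` plus a YAML sidecar with `fps`,
`arena_center`, `arena_radius`, `body_length_px`):

```r
ts  <- read_trajectories("school.csv")       # reads school.csv.yaml too
res <- run_fish_analysis(ts, n = 25, horizon_s = 1)
res$accuracy                                  # all / 20-160 / 30-100 deg
classify_regions(res$map)                     # interaction regions
res$counts                                    # per-frame N_total, N_important
```

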