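---
title: "Methods: an attention-network crop simulator and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an attention-network crop simulator and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(attncrop)
```

## The modelling problem

`attncrop` simulates greenhouse crop growth the way a process-based model
does — advancing a daily state from environmental drivers — but the
"process" is a learned sequence-to-sequence attention network rather than
physiological equations. The package covers the full workflow: feature
engineering from hourly sensor data, turning sparse destructive
measurements into daily labels, training, recursive simulation, and
modeling-efficiency evaluation, plus a synthetic greenhouse that makes
every step testable without external data.

The crop state is 21 per-plant factors in six groups (see
`crop_factors()`). The "one big organ" abstraction sums all organs of a
type — total leaf area, summed node lengths, cumulative harvested fresh
weight — because per-organ averages of a long-fruiting crop are diluted by
old organs, while totals accumulate information. Two *status* factors
(cumulative radiation, cumulative growing degree days) are recomputable
from the environment; they act as auxiliary targets that anchor the
model's internal clock.

## Input features

Seven encoder features, hourly over a window of `L` days (`24 L` rows):
temperature (°C), relative humidity (%), radiation (W m⁻²), and four daily
values broadcast to all 24 rows of their day — DIF (mean day minus mean
night temperature), daily cumulative radiation (kJ m⁻² day⁻¹), cumulative
GDD, and daily VPD (kPa).

Numerical conventions, chosen where the standard forms are ambiguous:

- **GDD floor.** Daily GDD is `max(0, mean(T) - T_base)` with
  `T_base = 10` °C. Without the floor, cold days would make cumulative
  thermal time decrease, which is biologically meaningless; the floored
  daily-mean form is the standard agronomic choice.
- **Day/night split for DIF.** "Day" is the set of hours with radiation
  > 0 (configurable to a fixed clock window). A radiation-based split
  follows the actual photoperiod through the seasons.
- **Daily VPD** is computed from the daily mean temperature and daily mean
  RH rather than averaging hourly VPDs. Both are defensible; the
  mean-inputs form was fixed once and is configurable at the hourly level
  through `compute_vpd()`.
- **Radiation integration** uses a 1-h rectangle rule (the data are hourly
  means), giving kJ m⁻² day⁻¹ daily and MJ m⁻² cumulatively.
- Missing sensor hours are filled by 1-D linear interpolation per
  variable; leading/trailing gaps are an error because they have no
  bracketing values.

## Labels from destructive sampling

Destructive investigations give per-factor means and SDs on ~5 dates per
cultivation. Daily labels are formed by:

1. prepending a virtual day-0 anchor at 50 % of the first observation
   (`start_rule = 0.5`) — the transplant is taken as half its first
   measured size, value-anchored at day 0 rather than shifting the
   calendar;
2. linear interpolation of means and SDs to every day;
3. stochastic augmentation: per draw and day, `Normal(mean, SD)` samples,
   truncated at 0 (growth factors are non-negative), with cumulative
   factors re-monotonized by a running maximum — an augmented trajectory
   must not "unharvest". The truncation and running maximum slightly bias
   cumulative columns upward; the expectation-preservation property is
   therefore only asserted for non-cumulative factors.

The number of draws is a configuration parameter (the experiment default
is 3; augmentation mainly acts as label-noise regularization on the
synthetic data, and small counts keep an epoch's size proportionate to the
desk-scale budget below). Fitting parametric growth curves to the
observations is deliberately avoided: labels derived from a formula would
leak that formula into the learned model.

## Window alignment

A training sample is `(features, prev, target)`: the decoder input `prev`
is the growth sequence for days `d … d+L−1`, the target is the same
sequence shifted forward one day (`d+1 … d+L`), and the encoder features
cover the predicted days. This language-model alignment is what makes the
published simulation recipe coherent: the *last* position of the output
sequence is the day after the previous window ends, so taking the last
output vector advances the simulation by exactly one day, and the output
can recursively replace the previous-growth input. The alternative —
a target window of `L` fresh days following the input window — was
considered and rejected: it either advances `L` days per step or misreads
the last output position, and it breaks the one-day recursion. A
cultivation of `n` labeled days therefore yields `n − L` windows.

## Architecture

Defaults (`attncrop_config()`): `L = 7` days, `d_model = 64`, 4 heads,
2 encoder and 2 decoder blocks, kernel sizes {1, 3, 5, 7}, feed-forward
width 128, dropout 0. These are deliberately small: the package trains on
one CPU in minutes, and the synthetic signal does not support a larger
model. All are tunable; `d_model` must be divisible by both the head count
and the number of convolution branches.

Structural choices worth recording:

- **Convolutional embeddings.** Input and output sequences are embedded by
  parallel 1-D convolutions with different receptive fields, concatenated
  channel-wise to exactly `d_model` — the embedding expands the channel
  dimension, never reduces it, because the features are concrete physical
  quantities whose local temporal context carries information. Encoder
  branches use centered (same-padded) windows. **Decoder branches are
  causal** (left-padded): a centered window would let output position `i`
  see previous-growth day `i+1`, silently defeating the look-ahead mask.
  This constraint is enforced by a test that perturbs future days and
  requires bit-identical earlier outputs.
- **Normalization placement.** Embeddings are batch-normalized (running
  statistics stored with the model); attention blocks use post-residual
  layer normalization. Exact placement is an open choice in this model
  family; this split keeps per-channel scale stable at the embedding (where
  mixed physical units enter) and per-position stable inside the blocks.
- **Input gate.** `g = σ(W_g [proj(raw) ∥ encoded] + b_g)`,
  `memory = g ⊙ encoded + (1−g) ⊙ proj(raw)`: an element-wise learned
  blend, placed on the encoder output so all six decoders see the same
  gated memory. The gate exists because the raw, un-encoded input is
  itself informative for the targets; the sigmoid-blend form is one
  reasonable reading of a "gate for residual calculation" and degenerates
  cleanly (g→1 pure encoder, g→0 pure raw projection), which the tests pin.
- **Decoders.** Six structurally identical stacks (masked self-attention,
  cross-attention over the full `24 L` memory, feed-forward; post-residual
  layer norm throughout) with a linear head per factor group. Cross-
  attention is unmasked: the encoder window covers the predicted days, and
  environment is a known driver, not a prediction target. No padding masks
  or end tokens exist anywhere — all windows have fixed length.
- The factor table has 21 entries because the six groups enumerate
  2+2+4+5+3+5 factors; the decoder map is configurable and validated to be
  a disjoint cover.

## Loss and training

The loss is the unweighted mean of 8 terms: one MSE per decoder (over its
factors and `L` days) plus two consistency terms comparing predicted and
labeled total vegetative fresh and dry weight (leaf+stem+petiole). The
conservation terms vanish whenever organ predictions sum correctly even if
individually wrong in compensating ways — they constrain the sum, not the
parts; a constructed test asserts this consequence. All losses are
computed in standardized space (z-scores from the training split only);
without this, the factor with the largest natural units would dominate the
mixed-unit objective. Reported metrics are always in natural units after
inversion.

Training is mini-batched Adam (learning rate 1e-3, default moments, batch
32) with teacher forcing; cumulative input features keep the dataset's own
values during training (replacement is a simulation-time device — swapping
them mid-training destabilizes the loss). The state with the lowest
validation total is returned; early stopping by patience is available but
off by default at these epoch counts. A fixed seed makes initialization,
shuffling, dropout and hence the whole run reproducible; the
reproducibility test reruns a small experiment twice and requires
identical trace, trajectory and metrics files.

The forward and backward passes are hand-written vectorized base R (there
is no deep-learning runtime among the package's dependencies, and the
network is the package's core, so owning its gradients is part of the
design). Activations live in `(B·T, C)` matrices so every linear layer is
one BLAS call; attention loops only over samples and heads. The backward
pass is verified against central finite differences at tolerance 1e-3 on
a down-scaled configuration in every test run.

## Simulation

`run_simulation()` seeds the first `L` days by holding the initial growth
vector constant (only "initial growth factors" exist at transplanting; a
constant-hold is the least-information choice and its error washes out of
the window after `L` steps), then rolls forward one day at a time. Each
step standardizes the feature window ending on the next day and the last
`L` states, runs the model, takes the last output position per decoder,
and inverts the scaler.

*Guidance* (default on): the cumulative-GDD and daily-cumulative-radiation
encoder columns always come from the measured environment — they are
computable from sensors, so feeding back the model's own status outputs
would only inject avoidable drift. With guidance off, exactly those two
columns are reconstructed from the predicted status trajectory (cumulative
GDD directly; daily radiation by differencing predicted total cumulative
radiation), which isolates the effect for ablation. Previous-growth
factors are always recursively replaced by model output in both modes.

*Sanitation* (default off): clipping negatives and running-maximum
enforcement on cumulative factors is available but off, so the raw model
behaviour — including possible mid-season dips in cumulative outputs — is
visible; turn it on for production use.

## The synthetic greenhouse and reference grower

The generator exists to give the network a learnable, internally
consistent signal with the shape of real greenhouse data — not to
reproduce sweet-pepper physiology. It emulates:

- hourly climate: sinusoidal diurnal temperature/humidity around seasonal
  curves, half-sine daylight radiation with seasonal daylength and a
  per-day cloudiness factor, additive sensor noise; radiation exactly 0 at
  night;
- a minimal radiation-use-efficiency grower: Gompertz canopy
  `LAI(TS) = LAI_max · exp(log(LAI_init/LAI_max)·e^{−C·TS})` over thermal
  time (same `T_base = 10` as the GDD feature, for coherence), Beer-law
  interception (k = 0.7, house transmissivity 0.7), fixed RUE
  (3 g DW MJ⁻¹), thermal-time-dependent partitioning to
  leaf/stem/petiole/fruit (fractions always summing to 1), fresh weight
  from per-organ dry-matter contents, counts and dimensions from specific
  dimensions (SLA 0.020 m² g⁻¹, 3 cm node length per g stem DW, …), and
  twice-weekly harvest events moving half the fruit pool to the cumulative
  harvest;
- destructive observations: 5 evenly spaced dates, multiplicative noise
  with cv = 0.08, SD = cv·mean.

The default study is four cultivations — spring (≈110–115 d) and autumn
(≈90 d) in each of two "years" differing in weather draws and slightly in
seasonal means; planting density is held constant across cultivations
because density is not a model input, and varying an unobserved driver
would make the task unidentifiable by construction rather than by
modelling failure.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: management interventions (topping, deliberate
fruiting delay), water or nutrient stress, pests, sensor drift,
inter-plant competition, or year effects beyond smooth climate shifts.
Its vegetative factors are exact linear transforms of the organ dry-weight
pools, so they are perfectly correlated — visibly, all vegetative factors
share one baseline-EF value in the experiment report. Real destructive
data are far rougher; EF ≈ 0.95 on this testbed is an upper bound on the
method's behaviour, not a field forecast.

## Evaluation

`modeling_efficiency()` (Nash–Sutcliffe form) and `nrmse()` follow the
standard definitions and are property-tested against brute-force formula
evaluation at 1e-10. EF is undefined for constant observations and NRMSE
for zero range; both raise errors, and the report marks such factors NA
(the constant stem count is the standing example). The report's aggregate
is the unweighted mean over the evaluated factor subset; evaluation is at
observation days by default in the scoring helpers, with full-trajectory
evaluation against synthetic truth used by the experiment harness, where
daily truth exists. The naming follows the root form (NRMSE) throughout;
a normalized *mean* squared error would be its square and is not used.

## Desk-scale problem sizes

The default experiment trains ~580 windows (two cultivations × 3
augmentation draws) for 16 epochs, ~10 minutes on one CPU, and the
held-out simulation covers ~103 days. The test suite's structural and
gradient checks run on a reduced configuration (`L = 2–4`, `d_model = 16`,
1+1 blocks). These sizes were chosen so the complete evidence chain —
generator, training, rollout, evaluation — runs comfortably on a laptop;
nothing in the implementation is specific to them.

## Known limitations

- The network sees no management inputs (density, topping, irrigation), so
  cultivations differing mainly in management are outside what training
  can identify.
- The two status factors are auxiliary targets only; with guidance on,
  simulation ignores their predictions entirely.
- Batch normalization ties training statistics to batch composition;
  with very small batches the running statistics are noisy (the defaults
  keep batches ≥ 32).
- Checkpoints are R serialization (RDS); they are runtime artifacts, not
  an interchange format.
- The ablation harness retrains each variant from scratch; a full
  four-axis sweep at default sizes is an overnight job, which is why its
  tests run at reduced scale.
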