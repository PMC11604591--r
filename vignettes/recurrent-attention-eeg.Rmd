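---
title: "A recurrent hard-attention model for EEG classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A recurrent hard-attention model for EEG classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegram)
```

## The model

`eegram` implements a recurrent attention agent for classifying signals it
never observes in full. At each of T steps the agent extracts a small
multi-scale *glimpse* around a focal location, integrates it into a recurrent
state, and decides where to look next; only at the final step does it emit a
class. Because the focal locations are *sampled* (hard attention), the
classification path and the attention path are trained by different rules:

1. **Glimpse sensor.** `extract_glimpse()` reads k patches centred on a
   location `l` in normalized coordinates `[-1, 1]^2`. The innermost patch is
   the raw `base_rows x base_cols` window; scale s covers a window
   `scale_factor^(s-1)` larger per axis, mean-pooled back to base size. The
   sensor therefore sees a small region sharply and a wide context coarsely,
   and its cost is independent of the input dimension — the property that
   motivates the architecture for long multichannel epochs.
2. **Glimpse network.** `g = ReLU(Linear(h_MS) + Linear(h_l))` with
   `h_MS = ReLU(Linear(patches))`, `h_l = ReLU(Linear(l))`; widths 128/128/256
   by default.
3. **Core.** A single GRU (256 units by default) carries the agent's belief
   state `h_t` across glimpses: `h_t = GRU(h_{t-1}, g_t)`.
4. **Heads.** A location head maps `h_t` to the mean of a two-component
   Gaussian policy with fixed standard deviation `sigma`; an action head maps
   `h_T` to softmax class probabilities; a baseline head maps `h_t` to a
   scalar state-value estimate.
5. **Reward.** Terminal-only 0/1: the return of an episode is 1 exactly when
   the final argmax class is correct (discounting by `gamma^(T-1)` is
   supported but inert at the default `gamma = 1`).

Training is hybrid (`hybrid_update()`): cross-entropy at the final step is
backpropagated through the action head, GRU and glimpse network; the location
head is trained by the REINFORCE score-function estimator
`(1/M) sum_i sum_t grad log pi(l_t | h_t) (R_i - b_t)` with the learned
baseline `b_t` subtracted from the return; the baseline head is regressed on
the realized return by mean squared error. No gradient flows through the
sampled coordinates themselves, and the baseline and location terms treat
`h_t` as a constant, so the three learning signals do not interfere.

## Numerical and design choices

Decisions the source material left open, and how this package resolves them:

- **Coordinate convention.** Continuous coordinates map affinely to cell
  centres (cell i of extent e sits at `(2i-1)/e - 1`); nearest-cell rounding
  resolves exact ties toward the grid centre, and even-width windows extend
  the extra cell toward the index origin. This makes extraction deterministic
  and exactly translation-equivariant for interior shifts — the property the
  tests assert bitwise.
- **Pooling.** Coarse scales use non-overlapping block *mean* pooling rather
  than interpolation: it is exactly checkable against a brute-force oracle
  and conserves window means.
- **Boundaries.** Out-of-bounds cells read `pad_value = 0`. Inputs are
  z-scored per epoch, so zero padding is neutral.
- **Channel clamping.** For channels x time signals the scale doubling applies
  to both axes, but windows wider than the channel extent are clamped to the
  full channel range (a 2x7 base on 22 channels would otherwise overflow the
  channel axis at scale 5 while the time axis still has room).
- **Squashed policy mean.** The location head is `tanh`-squashed. A plain
  linear head is unbounded and can drive the whole policy off-canvas early in
  training, after which no reward gradient can recover it.
- **Log-density at the pre-clip draw.** Sampled locations are clipped into
  the valid box before extraction, but the policy log-density (and its score)
  is evaluated at the raw Gaussian draw: clipping is an environment effect,
  not part of the policy, and this keeps the score function exact.
- **Baseline training.** The paper-level formulation introduces the state
  value as a variance reducer without a training rule; here it is a detached
  per-timestep value head regressed on the return by MSE.
- **Initialization.** Uniform `±1/sqrt(fan_in)`, biases zero, seeded.
- **Optimizer.** Adam (lr `1e-3` default) with global gradient-norm clipping
  at 5 — standard stabilizers for REINFORCE-trained attention models.
- **Evaluation determinism.** At evaluation time the initial location is the
  centre and subsequent locations follow the policy mean; sampling is a
  training behaviour. Reported accuracy is therefore reproducible without a
  seed.
- **Glimpse count.** `T = 6` by default, matching the reported optimum of six
  receptors for the four-class motor-imagery task; T is configurable because
  the alternative reading ("one step per sample dimension") would imply
  thousands of steps per trial and contradicts that optimum.

## What the synthetic data emulates — and what it does not

`gen_bci2a_shaped_dataset()` reproduces the *structure* of the BCI Competition
IV-2a motor-imagery recordings: 9 subjects x 2 sessions x 6 runs x 48 trials
(5,184 epochs; 288 per subject-session), 22 channels, 4 s at 250 Hz, 4
balanced classes, with per-subject perturbations of the class feature loci to
emulate inter-subject variability. Class information is carried by
Hann-windowed sinusoidal bursts (8–30 Hz carriers, mimicking the
band-limited, spatially localized power changes of sensorimotor rhythms) at
class-specific channel/time loci, with channel/time jitter and random phase,
in Gaussian noise, z-scored per epoch.

This is a *stand-in built to exercise the attention mechanism*, not an EEG
simulator: there is no volume conduction, no 1/f background, no artifacts,
no event-related desynchronization dynamics. A green learning test therefore
establishes that the implementation can discover and exploit localized
class-discriminative structure through hard attention — it does not establish
performance on real EEG, and the published headline numbers (86.78 %
subject-dependent accuracy, kappa 0.83, 71.54 % subject-independent) are
explicitly out of desk-scale reach: they require the real competition
recordings and long stochastic training.

Default generator values and their provenance: geometry and counts follow the
dataset description (22 channels, 1000 samples, the 9x2x6x48 scaffold);
burst amplitude 2 against noise sd 1 and duration of one quarter epoch are
package choices for a signal that is invisible in any single coarse glance
but reliably detectable once attended — about the hardest setting at which a
6-glimpse budget remains sufficient.

## The desk-scale learning benchmark

The acceptance-level learning run trains on the 2-class burst task (500
train / 200 held-out epochs, T = 6, 30 epochs, three seeds) and requires
seed-median held-out accuracy above 0.80, plus attention concentration:
the policy means visited on test epochs must lie closer (seed-median mean
Euclidean distance) to the true class locus than uniform random locations.

The glimpse geometry for this run is k = 3 scales with a 6x60 base patch
(scale 3 spans the full channel range and ~240 samples), batch 32, Adam lr
`3e-3`. The paper's 2x7 patch is tuned to its real-data, long-training
regime; at desk scale it is too information-poor — mean pooling of an
oscillatory carrier cancels most of the signal at coarse scales, and with
only 30 epochs the agent rarely bootstraps past chance. Widening the base
patch keeps the task honest (each glimpse still sees a small fraction of the
epoch) while making the 15-minute budget attainable. These are method
parameters; the generator's world was fixed first and never adjusted against
test outcomes.

## Known limitations

- Pure-R training: minibatched BLAS keeps the desk-scale runs in minutes, but
  this is not a platform for the paper-scale experiments.
- The REINFORCE estimator is M = 1 per sample per update; variance is managed
  by the learned baseline, minibatching and gradient clipping rather than by
  multiple rollouts.
- `read_external_eeg()` covers plain EDF with one trial per data record and a
  LABEL signal; GDF and EDF+ annotation parsing are not implemented, so real
  BCI-2a competition files need external conversion first.
- Cohen's kappa is computed from the pooled confusion matrix; per-subject
  reports expose both pooled and per-fold numbers because the published
  figures do not state which aggregation they use.
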