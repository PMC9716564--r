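---
title: "Attentional search in a cube world: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentional search in a cube world: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented in **bias3d**, the design
decisions behind it, and what the synthetic benchmark does and does not
show. The package implements a brain-inspired active-vision agent: a camera
orbits a textured cube at fixed radius and elevation, sees 75x100 views,
and must steer itself - by discrete azimuth jumps - toward the one vertical
face carrying a target image, then classify that image. The agent mirrors
the "what / where" division of the primate visual system: one convolutional
pipeline classifies the glimpse, a second predicts the value of the three
camera actions, and a third injects the camera's azimuth into both.

## The environment

The cube (edge length 2, faces spanning \[-1, 1\]) sits at the origin; the
camera orbits at radius `r = 2.5` in the horizontal plane (polar angle
fixed at 0), always looking at the origin, with its azimuth the single
degree of freedom. Views are rendered by a software pinhole projector
(vertical FOV 45 deg, chosen so a face nearly fills the view height at
`r = 2.5`; the source environment never states its intrinsics): rays
through pixel centres are intersected with the planes of the
outward-facing cube faces, texture coordinates recovered analytically, and
textures sampled bilinearly. Back-face culling alone suffices for a convex
cube. Rendering is deterministic and exactly periodic in the azimuth,
which the test suite asserts bit-exactly; the visible-face geometry is
verified against an analytic corner-projection oracle.

The camera moves by one of three actions - right, left, stay - with a
fixed jump length (12 deg for the digit-style cubes, 20 deg for
sketch-style ones). With a fixed jump the reachable azimuths form a finite
grid; training start positions are drawn uniformly on that grid (the
process distribution is unchanged by the cube's rotational symmetry, and
rendered views can then be cached per cube across epochs), and evaluation
starts the same way.

## The glimpse

Rather than consuming the full view, the agent extracts a foveated glimpse
at the view centre: three concentric windows of 16, 32 and 50 px; the two
larger ones are bilinearly downscaled to 16x16, and the three are stacked
along depth, fovea first. A grayscale view gives a 16x16x3 glimpse, an RGB
view 16x16x9. Crop intervals are half-open,
`[centre - floor(size/2), centre + size - floor(size/2))`, which
reproduces all six published example ranges for a crop centred at
(35, 50). The runtime centre is `(floor(h/2), floor(w/2))`.

## The network

Three pipelines run in parallel on each step:

* **Classifier ("what")**: Conv16 - LRN - ReLU - pool, Conv32 - LRN -
  ReLU - pool, Conv64 - ReLU, flatten, then a 512-unit fully connected
  layer with Elman and Jordan context inputs (FCEJ). All convolutions are
  3x3, stride 1, same-padded; pooling is 2x2/stride 2.
* **Camera motion ("where")**: two convolutional JK flip-flop layers
  (16 then 32 kernels) each followed by LRN - ReLU - pool, flatten, an
  FCEJ of 512, then a dense flip-flop layer (FCJKFF) of 512.
* **Camera position**: the azimuth enters as `(sin, cos)`, through an
  Elman-only FC layer of 128 and an FCJKFF of 64.

The three outputs (512 + 512 + 64) are concatenated and fused by one FC
layer (width 512; the source architecture leaves this width unstated),
which feeds two parallel heads: a linear head with the three action
Q-values and a softmax head with `n + 1` class probabilities (`n` target
classes plus background/clutter).

**Flip-flop neurons.** The recurrent unit is a JK flip-flop: two sigmoid
gates J (set) and K (reset) computed from the concatenation of the layer
input and the previous hidden state, updating a bounded state
`H_t = J (1 - H_{t-1}) + (1 - K) H_{t-1}`, read out through a tanh
projection; no bias terms anywhere in the unit. `H_0 = 1`. By induction
`H_t` stays in \[0, 1\]; the partials `dH/dJ = 1 - H_{t-1}` and
`dH/dK = -H_{t-1}` are verified against finite differences in the tests.
The convolutional variant computes the gates as 3x3 same-padded
convolutions over the channel concatenation of input map and hidden map,
and the read-out as a 1x1 convolution; this parameterization is the
package's own (the source describes the dense unit only), and the
implementation is pinned by an oracle that applies the dense unit
site-wise with centre-tap kernels.

**Recurrence wiring.** Each first FC layer feeds its own previous output
back (Elman); the classifier FCEJ additionally receives the previous
softmax output and the motion FCEJ the previous Q-values (Jordan); the
position pipeline is Elman-only. Contexts reset to zero and flip-flop maps
to one at episode start.

**LRN.** Channels are normalized as
`N = X / (k + alpha * sum_j X_j^2)^beta` with the window `|j - f| <=
floor(c/2)` clipped at the channel ends; the default constants
`(0, 1, 1, C)` follow the source's "standard normalization", with a 1e-8
guard added to the denominator when `k = 0`. Layer order is conv - LRN -
ReLU - pool. (The source text also contains a ReLU-then-LRN ordering in an
overview paragraph; the detailed walk-through ordering is used.)

**Initialization.** All weight matrices are Xavier-normal,
`N(0, 2/(fan_in + fan_out))`, biases zero.

## Training

**Pretraining.** Views are collected on a 9-degree orbital grid (40 per
cube), labelled with the target class within +/-45 deg of the target face
(inclusive) and background outside - 11 target and 29 background views per
cube - and balanced by subsampling the background to 11. The feed-forward
classifier (conv stack + FC + its own softmax head, no recurrence) is
trained on glimpses of these balanced views with cross-entropy and
minibatch Adam (batch 32, lr 1e-3; 12 epochs by default - at the benchmark
sizes the loss has flattened by then while held-out accuracy has not yet
started to fall).

**Warm-start transplant.** The pretrained conv and FC weights are loaded
into the classifier pipeline of the full model. The package additionally
carries over the classification *capability*, not just the features: the
classifier-pipeline context weights start at zero, the first 512 fusion
units are initialized as an exact pass-through of the classifier FC
output (identity block, no cross-talk from the other pipelines), the
classification head starts as the pretrained read-out on those units (zero
elsewhere), and the Q head starts at zero. Every one of these weights
remains trainable; only the initialization is structured. Rationale:
discarding the pretraining head leaves the full model's class output at
chance, so the confidence-gated reward cannot fire and searches cannot
terminate until the head has been relearned inside the RL loop - far
beyond a 5-epoch budget. Zeroing the Q head
means early Q-values are built from the temporal-difference signal alone
instead of initialization noise; with the selector's lowest-index
tie-break the early greedy policy is then a deterministic sweep of the
orbit rather than a random walk that parks wherever "stay" happens to win
the argmax of noise.

**End-to-end episodes.** Each training episode runs exactly 50 steps on
one cube from a random grid azimuth: render, glimpse, one synchronous
forward step of online and target networks, epsilon-greedy action
(uniform with probability epsilon, else the race-model selection
described under "Ambiguities resolved"), camera jump. The reward (0 or 1) is
evaluated on the *next* state's class probabilities: 1 only if the argmax
matches the cube's target class and the confidence reaches the threshold
`lambda = 0.85`. The TD error is
`r + gamma * max(Q_target(next)) - Q(taken)` with `gamma = 0.43` and a
target network hard-synced every 10 episodes. The episode loss is the sum
of the mean TD square over the 50 steps and a weighted mean cross-entropy
of the per-step class predictions against view-dependent labels (the same
+/-45-degree rule as pretraining); background-labelled steps carry weight
0.25, applying to the episode stream the same class-imbalance correction
that pretraining applies by subsampling (an orbit shows about three
background views per target view; left unweighted, the imbalance drags
on-face confidence down toward the stopping threshold). One backward pass per
episode runs through the fully unrolled recurrences (no replay buffer -
the training is online and episodic), gradients are clipped at global norm
5, and one Adam update (lr 1e-4, L2 weight decay 0.1 on weight matrices)
is applied. Epsilon decays once per episode from 0.99 by 0.999, floored
at 0.1.

The rollout and backward pass are implemented twice: a pure-R reference
(R/model.R, R/train.R) whose gradients are verified against central finite
differences on every parameter tensor, and a compiled C++ fast path used
for actual training; the test suite asserts the two agree to 1e-9 on fixed
trajectories. The compiled path runs an episode roughly an order of
magnitude faster than the reference.

**Ambiguities resolved.** The source's race model ("the action which
crosses the threshold first") is not fully operationalized for a single
forward pass. The package reads it as a race with response persistence:
the Q-values are softmax-normalized and an action is emitted once its
probability crosses the decision threshold lambda; when no response
separates within the single evaluation, the previously winning response
keeps running (plain argmax when there is none). This is how race models
behave on undecided single-look trials, and it produces the continuous,
non-alternating camera movements the original study reports for its
agent. It also matters at desk scale: far from the target the optimal Q-value
differences shrink like `gamma^k` and fall below what the function
approximator resolves in a short training budget, so with plain argmax
selection the greedy policy parks wherever "stay" happens to win the
argmax of unresolved value noise - persistence removes exactly those
traps while leaving decisive selections untouched. Whether the TD
mean-square averages over all three actions or only the taken one is not
stated; the taken action is used (standard Q-learning), with the
alternative behind `trainer_config(mse_all_actions = TRUE)`. The reward's
desired vector is the cube's target class (reward fires only for a
confident *target* classification); the cross-entropy labels, by contrast,
are view-dependent - rewarding confident background classification would
teach the agent to look away from the target. Episodes are fixed-length,
not absorbing, so the last step bootstraps as usual.

## Inference

At test time the agent is purely greedy (epsilon = 0). From a random grid
azimuth it renders, glimpses, and forwards; the search stops as soon as
the maximum class probability crosses the testing threshold (0.95 for
MNIST-style, 0.85 for sketch-style data) *with a non-background argmax* -
confidence about the background class never terminates a search, it only
means there is nothing to report yet. If the threshold is never crossed
within 50 camera moves the search fails. Success additionally requires the
predicted class to equal the target class; both the search success rate
and the classification accuracy among threshold-stops are reported, since
published accuracy figures do not fully specify which of the two they
count.

## The synthetic benchmark

The cube datasets in the original study are built from downloadable image
sets at a scale (48,000 training cubes, 20-25 epochs) far beyond a desk
run. The package therefore ships a procedural generator so every stage is
testable from code alone: ten distinct stroke templates (cross, X, circle,
bars, triangle, T, Z, L, diamond, V) rasterized with a soft-edged stroke
of width ~3.2 px on 28x28 canvases, jittered per sample by +/-15 deg
rotation, +/-2 px translation and stroke-width noise. Classes are
separable by a nearest-template correlation oracle at >= 95%, which the
tests assert. Clutter faces are composites of 2-4 random fragments (8-16
px) cropped from other-class images - deliberately hard negatives that
share local stroke statistics with the targets. RGB mode colorizes
glyphs and clutter with distinct foreground/background colours from a
fixed 8-colour palette (threshold 0.2).

The benchmark used by `scripts/acceptance.R` and the acceptance tests:
3 classes, 300 training / 25 validation / 50 test cubes, 15 pretraining
epochs, 5 end-to-end epochs (1,500 episodes), jump 12 deg, testing
threshold 0.85, compared against a baseline that couples uniformly random
actions with the pretrained feed-forward classifier under the identical
stopping rule. These sizes are the package's scaled-down study
conditions; they fit in minutes on one CPU core.

What passing at this scale shows: the full pipeline - rendering, glimpse,
recurrent architecture, pretraining, reward, TD learning, stopping rule -
is wired correctly and the agent measurably improves over an undirected
policy with the same classifier. What it does not show: the published
full-scale accuracies (95.6% / 83% / 91.5% on the three cube datasets),
which require the original image sets and orders of magnitude more
training; glyphs are also cleaner than handwriting, and the procedural
clutter, while hard, is not the published clutter.

## Parameter count

The published trainable-parameter total (2,668,362) cannot be
reconstructed exactly: the fusion width, the convolutional flip-flop gate
parameterization and the bias conventions are unstated. With this
package's choices (fusion 512, 3x3 conv gates + 1x1 read-out, biases in
conv/FC layers only) the 10-class grayscale architecture counts 3,297,806
parameters - the same order of magnitude; `summary()` on a fitted
model prints the per-layer breakdown, and `count_params()` /
`param_table()` expose it programmatically.

## Numerical choices and degenerate inputs

Softmax is max-stabilized; cross-entropy guards `log(p + 1e-12)`; LRN adds
1e-8 to the denominator only when `k = 0`; max-pooling breaks ties by the
first corner in (top-left, bottom-left, top-right, bottom-right) order,
and the action argmax by lowest index - both deterministic. The +/-45 deg
view-label boundary is inclusive. If a cube yields more target than
background views, balancing keeps everything and flags the imbalance.
Rendering rays that miss every face take the background fill; texture
lookups clamp at the image border. All randomness flows through explicit
integer seeds (child seeds derived by `sample.int` from one master seed),
and seeded runs are bit-reproducible, which the tests assert.

## Known limitations

* Only the four vertical faces are searchable; polar angle and radius are
  fixed; the two horizontal faces are a constant fill.
* One cube per episode; no batch-parallel rollouts.
* The Q function is learned at a single discount (0.43) with a short
  effective horizon; far from the target the policy is driven by the
  zero-initialized sweep rather than by resolved value differences. At
  full scale the values would resolve further out.
* The compiled and R paths duplicate the forward/backward math by design
  (the R path is the oracle-checked reference); any change must keep the
  equivalence tests green.
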