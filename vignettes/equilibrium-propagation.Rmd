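---
title: "Equilibrium Propagation: model, estimators, and verification at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium Propagation: model, estimators, and verification at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqprop)
```

## The model

`eqprop` trains *convergent* recurrent networks: the input $x$ is static,
and the state $s = (s^1, \dots, s^N)$ relaxes to a fixed point $s_*$ that
carries the prediction. For shared (bidirectional) weights the dynamics
derive from a scalar primitive
$$
\Phi(x, s) \;=\; \sum_{n} s^{n+1} \bullet P\!\left(w_{n+1} \star s^{n} + b_{n+1}\right)
            \;+\; \sum_{n} s^{n+1\,\top} \left(w_{n+1} s^{n} + b_{n+1}\right),
$$
with $\star$ a 2-d convolution, $P$ max pooling, and $\bullet$ the
elementwise scalar product; fully connected layers contribute the second
sum. The synchronous update is
$s_{t+1}^n = \sigma\!\left(\partial \Phi / \partial s^n\right)$, where
$\sigma(z) = \min(1, \max(0, z))$ is the hard sigmoid. Because $\Phi$ is
bilinear across adjacent layers, $\partial \Phi/\partial s^n$ is a
bottom-up drive (conv + bias, pooled) plus a top-down drive (the adjoint
convolution of the layer above, routed through the *same* pooling argmax
indices recorded at that time step). Inverse pooling scatters to exactly
those indices, so `P^{-1}` followed by gathering is the identity —
a property the tests assert.

Two output couplings are supported. In **squared-error mode** the topmost
layer *is* the prediction and the nudged phases add
$\beta\,(y - \hat y_t)$ to its pre-activation (an elastic force toward the
one-hot target). In **cross-entropy readout mode** the prediction is
$\hat y_t = \mathrm{softmax}(w_{\mathrm{out}} \, s^N_t)$: the readout does
not participate in the free dynamics, and nudging feeds
$\beta \, w_{\mathrm{out}}^\top (y - \hat y_t)$ back into the top layer.
Since $s_*$ does not depend on $w_{\mathrm{out}}$, the readout's own
update $(y - \hat y_*)\, s_*^{N\,\top}$ is the *exact* negative
cross-entropy gradient — local in pre- and post-synaptic activity, and
carrying no nudging bias.

## Gradient estimators

All estimators combine steady states of at most three phases (free, $+\beta$,
$-\beta$; the nudged phases always start from $s_*$):

* **one_sided** $\; \frac{1}{\beta}\left(\partial_\theta\Phi(s_*^{\beta}) - \partial_\theta\Phi(s_*)\right)$ — bias $O(\beta)$;
* **symmetric** $\; \frac{1}{2\beta}\left(\partial_\theta\Phi(s_*^{\beta}) - \partial_\theta\Phi(s_*^{-\beta})\right)$ — bias $O(\beta^2)$; algebraically the average of the one-sided estimates at $\pm\beta$, an identity the package reproduces to $10^{-12}$ relative error;
* **random_sign** — one nudged phase with a uniformly random sign of $\beta$; unbiased to first order on average, but with the variance of a two-point mixture;
* **vf / sym_vf** — vector-field estimators $\frac{1}{\beta}(\partial_\theta F)^\top(x, s_*, \theta)\,(s_*^{\beta} - s_*)$ for general transition functions $F$, valid when forward and backward weights are distinct; forward and backward slots each receive their own contraction;
* **kp_vf** — the Kolen–Pollack-style rule: for each of $\theta_f$ and $\theta_b$ the symmetric contraction $\frac{1}{2\beta}\left[(\partial_{\theta_i} F)^\top(s_*^{\beta})\, s_*^{\beta} - (\partial_{\theta_i} F)^\top(s_*^{-\beta})\, s_*^{-\beta}\right]$ is formed, the two shape-matched halves are averaged, and the *same* array updates both slots, together with an equal leakage $-\lambda\theta$. With plain SGD one step contracts $\lVert\theta_f - \theta_b\rVert$ by exactly $(1 - \eta\lambda)$, so independently initialized forward and backward weights converge to each other while training.

The derivative $\partial F/\partial\theta$ includes the activation
subgradient, taken as 1 strictly inside $(0,1)$ and 0 at saturation. The
reference for every estimator is **truncated BPTT**: under the convergence
hypothesis all Jacobians of the unrolled free phase can be evaluated at
$s_*$, so the adjoint recursion needs no stored trajectory ($O(1)$ memory
in the truncation length $t$; the first truncated step is the loss
insertion, an indexing convention that is immaterial at a fixed point).
The oracle itself is validated against central finite differences of the
steady-state loss to $10^{-5}$ relative error, closing the loop: finite
differences validate BPTT, BPTT validates the EP estimators.

The paper-level definition of the symmetric vector-field estimate is not
fully pinned down in the available material; this package defines it as
the symmetric difference contracted at $s_*$ with per-slot gradients,
which preserves the property that distinguishes it from `kp_vf`: nothing
ties the forward and backward updates together, so the weights stay
misaligned.

## Tunable parameters

| parameter | meaning | default (desk scale) |
|---|---|---|
| `T` | free-phase steps (unitless iterations) | 30 for training, 120–400 for diagnostics |
| `K` | nudged-phase steps | 10 (training), larger for steady-state scans |
| `beta` | nudging strength | 1.0 (bidirectional CE study), 0.2 (unidirectional study), 0.01 (gradient-matching diagnostic) |
| `lr_per_layer` | learning rates, first layer to readout | 0.25 / 0.15 / 0.05 (tapered like the full-scale recipe) |
| `weight_decay`, `momentum` | SGD hyper-parameters | 3e-4, 0.9 |
| `lambda` | KP leakage | 0.25 |
| `dropout_p` | keep-fixed inverted dropout on the last conv layer | 0 |

The full-scale recipe this mirrors uses $T = 250$, $K = 25$–$30$, 120
epochs with cosine annealing over 100; the desk-scale defaults shrink the
phase lengths and epoch counts to what the two-conv-layer fixture needs
(free-phase residuals reach $10^{-16}$ well before $T = 30$), keeping the
whole verification suite in minutes on one CPU. The cosine schedule
interpolates each rate to `lr_final = 1e-5` and is exact at its midpoint
and endpoints, which the tests pin down.

Leakage `lambda = 0.25`: the available material does not state a value.
With per-layer rates around 0.05 and a few hundred optimizer steps, the
pair difference contracts by $(1-\eta\lambda)^{steps} \approx 10^{-2}$,
fast enough that alignment (and therefore honest gradients) arrives
within the 10-epoch study. Leakage acts only on forward/backward *pairs*;
applying it to unpaired parameters (the first layer, biases, the readout)
would shrink capacity without aligning anything.

## The synthetic task and the fixtures

`make_toy_images()` draws one fixed Gaussian spatial template per class
and adds unit Gaussian pixel noise: samples are
$\mathrm{clip}(0.5 + a\,(\mathrm{snr}\cdot T_c + \varepsilon))$ with
$a = 0.25/\sqrt{1+\mathrm{snr}^2}$, so the pre-clip pixel sd is 0.25 and
the class separability is controlled by a single knob. At
`template_snr = 3` a least-squares linear classifier exceeds 95% test
accuracy, which is what makes "symmetric EP reaches $\le 10\%$ train
error" a principled bar rather than a tuned one. What the generator does
*not* emulate: natural-image statistics, augmentation, label noise, class
imbalance. Passing these studies therefore demonstrates the *estimator
properties* (bias orders, variance, alignment), not vision performance.

Three fixtures cover the verification needs:

* `scalar` — one unit, one weight fixed at 0.5: the free fixed point is
  $\sigma(wx)$ in closed form and every estimator's bias is computable by
  hand;
* `fc_small` — two 16-unit layers on $1\times4\times4$ inputs;
* `conv_small` — two $3\times3$ conv layers (8, 16 channels, $2\times2$
  max pool, stride 2) on $1\times8\times8$ inputs, the reduced-width
  analogue of the four-conv full-scale architecture.

Fixture construction *verifies its own contracts* rather than hoping for
them. First, the spectral norm of the step linearization (power iteration
with an all-ones activation mask, the worst case over saturation
patterns) is estimated and inter-layer weights rescaled until the free
phase is a contraction. Second, a kink margin is enforced: on a
deterministic probe battery, no pre-activation may come within a margin
of the hard-sigmoid boundaries between the free and the $\pm\beta$-nudged
steady states ($\beta$ up to 0.25 with margin 0.02 for `fc_small`, whose
role is the bias-order scans at $\beta \le 0.2$; up to 0.015 with margin
0.003 for `conv_small`, whose role is the $\beta = 0.01$
gradient-matching diagnostic). The reason is structural: a unit sitting
on a kink responds to nudging in one direction only, contributing an
$O(1)$ asymmetry to a symmetric difference quotient — the smoothness
hypothesis behind the $O(\beta^2)$ bias and the EP↔BPTT limit simply does
not hold there. For the conv fixture the margin is only attainable
because its conv biases are initialized positive ($U(0.1, 0.4)$, weights
uniform Kaiming): a zero-initialized free phase otherwise leaves a
continuum of pre-activations hugging the floor, and some always straddle
the kink.

## Numerical choices and degenerate inputs

* Pooling argmax ties break deterministically to the first position in
  scan order; inverse pooling scatters (and accumulates on collision,
  which cannot occur for non-overlapping windows).
* Relaxation length is a fixed step count with residuals
  $\lVert s_{t+1}-s_t\rVert / (\lVert s_t\rVert + 10^{-12})$ logged, so
  convergence is asserted by tests rather than adaptively decided.
* `beta = 0` nudged dynamics are bit-identical to the free dynamics (the
  nudging branch is skipped entirely).
* Nudging is added *inside* the activation argument, so states stay in
  $[0,1]$ by construction; the free/nudged fixed-point algebra and the
  BPTT oracle use the same convention (the oracle masks the adjoint with
  the same subgradient), which keeps the two sides of the
  gradient-matching diagnostic consistent.
* Estimates are averaged over the mini-batch before the optimizer step;
  weight decay is decoupled (additive $-\eta\,\mathrm{wd}\,\theta$) and
  momentum buffers are zero-initialized.
* Dropout masks are drawn once per mini-batch (per sample, inverted
  scaling $1/(1-p)$) and held fixed across all time steps and phases of
  that iteration; evaluation never applies dropout. The mask sits on the
  last conv layer — the layer the readout consumes.
* Checkpoints are RDS files (bit-exact round trip) with an embedded JSON
  architecture descriptor.

## Study designs at desk scale

The estimator-comparison study (five seeds, 10 epochs, $\beta = 1$, rates
0.25/0.15/0.05) reproduces the qualitative full-scale contrast: symmetric
EP reaches ~0% test error with negligible spread, constant-sign one-sided
nudging lands at 15–25% with large spread, and the randomized sign has
the largest inter-seed variance of the three (individual runs land at
either ~0% or chance — exactly the high-variance mixture the sign
randomization produces). The alignment study (unidirectional coupling,
$\beta = 0.2$, rates 0.05/0.03/0.05, $\lambda = 0.25$) shows `kp_vf`
driving forward/backward angles from ~90° to 10–20° while `sym_vf` stays
near 65–75°. The choice of a smaller $\beta$ here is deliberate: the KP
contraction evaluates its activation masks at $s_*^{+\beta}$ and
$s_*^{-\beta}$ separately, so large nudging makes saturation-pattern
differences between the phases inject $O(1/\beta)$ noise into the shared
update.

## Known limitations

* The full-scale error *contrast* between `sym_vf` and `kp_vf` does not
  reproduce on the easy synthetic task: both reach ~0% test error at this
  scale, so only the alignment contrast (and the fact that `kp_vf` trains
  well below chance) is asserted.
* The gradient-matching diagnostic is a population-RMS statement per
  parameter group; it holds on fixtures engineered into the smooth
  regime. On saturated networks the hard-sigmoid kinks make individual
  coordinates deviate at finite $\beta$, which is a property of the
  clamp, not an implementation artifact.
* Continuous-time dynamics, asynchronous updates, spiking neurons, and
  full-scale image benchmarks are out of scope; absolute full-scale error
  rates are not reproducible at this problem size.
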