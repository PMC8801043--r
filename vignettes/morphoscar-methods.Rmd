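---
title: "Methods: morphoelastic contraction modelling and its neural surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphoelastic contraction modelling and its neural surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscar)
```

## The model

Post-burn scars contract because myofibroblasts pull on the collagen matrix
of the dermis. `morphoscar` simulates this in one spatial dimension with a
morphoelastic continuum model of six coupled fields on the symmetric half
domain $[0, X]$ (default $X = 10$ cm, wound occupying $[0, L)$):

* $c$ — a generic pro-inflammatory signalling molecule (g/cm$^3$),
* $N$, $M$ — fibroblasts and myofibroblasts (cells/cm$^3$),
* $\rho$ — collagen (g/cm$^3$),
* $v$ — displacement velocity (cm/day),
* $\varepsilon$ — effective (elastic) strain, dimensionless.

The species obey conservation laws of the form
$\dot z + (z v)' = -J_z' + R_z$; the velocity obeys the momentum balance
$\rho_t(\dot v + 2 v v') = \sigma' + f$; and morphoelasticity enters through
$\dot\varepsilon + v\varepsilon' + (\varepsilon - 1)v' = -G$, which splits
the deformation into an elastic part ($\varepsilon$) and a permanent part
(whatever $G$ has converted). The closures are the standard family for this
model class:

* Fickian diffusion for $c$; cell random walk with diffusivity
  $D_F (N + M)$ plus chemotaxis $\chi_F z\, c'$ for the two cell species;
  collagen does not migrate.
* Logistic proliferation with chemical enhancement
  $r_F\left(1 + r_{F,\max} \frac{c}{a_c^{I} + c}\right)
  (1 - \kappa_F(N + M))\,z$, signalling-driven differentiation
  $k_F c N$ from $N$ to $M$, and linear apoptosis.
* Saturating secretion $k_c \frac{c}{a_c^{II} + c}(N + \eta^I M)$ against
  proteolytic decay $\delta_c (N + \eta^I M)\rho c$; collagen production
  $k_\rho (1 + k_{\rho,\max}\frac{c}{a_c^{IV}+c})(N + \eta^{II} M)$ against
  density-dependent degradation $\delta_\rho (N + \eta^I M)\rho$.
* Viscoelastic stress $\sigma = \mu v' + E\sqrt{\rho}\,\varepsilon$ with
  collagen-linked stiffness; traction body force
  $f = \partial_x\!\left(\xi M \frac{\rho}{R^2 + \rho^2}\right)$;
  growth $G = \zeta \frac{c}{a_c^{III}+c} M \varepsilon$, so permanent
  contraction requires simultaneous signalling, myofibroblasts and strain.

Two constants are derived rather than free, so the healthy state
$(c, N, M, \rho, v, \varepsilon) = (0, \bar N, 0, \bar\rho, 0, 0)$ is an
exact equilibrium: $\kappa_F = (1 - \delta_N/r_F)/\bar N$ and
$\delta_\rho = k_\rho/\bar\rho$.

With this secretion/decay closure, linearising the $c$-equation about the
equilibrium gives the eigenvalue
$\bar N\,(k_c / a_c^{II} - \delta_c \bar\rho)$, so the admissibility
condition used throughout the package,
$$k_c < \delta_c\, \bar\rho\, a_c^{II} \quad (\text{strict}),$$
is exactly the linear-stability threshold of signalling homeostasis.
`check_stability()` applies it, and the corpus sampler rejects draws that
violate it.

## Numerics

The six equations are discretised with linear finite elements on a moving
(updated-Lagrangian) mesh — nodes travel with the converged velocity, which
removes the convective derivative from the material frame — and integrated
with backward Euler at a one-day step over 365 days. Each step solves the
monolithic six-field system with inner Picard iterations: nonlinear
coefficients are frozen at the current iterate, giving a block-tridiagonal
system (6×6 blocks) solved by a block Thomas algorithm in compiled code.
Unknowns are scaled per field ($c$ by the initial wound signalling $c_w$,
cells by $\bar N$, collagen by $\bar\rho$) so the blocks are well
conditioned despite the $10^{12}$ spread in physical magnitudes.

Numerical choices that were genuinely open:

* **Picard controls.** Relative-update tolerance $10^{-4}$ over all six
  fields (each scaled by its own magnitude), at most 50 iterations.
* **Stabilised linearisation.** The saturating secretion and the quadratic
  logistic crowding are linearised Newton-style about the iterate. Plain
  coefficient lagging makes the fixed-point map repel whenever the
  proliferation rate exceeds about $1/\Delta t$; the Newton terms restore
  attraction near the solution while leaving the homeostatic equilibrium an
  exact fixed point of every sweep.
* **Relaxation and rescue.** Successive updates pointing in opposite
  directions signal a limit cycle; the iterate is then under-relaxed
  (adaptively, down to $\omega = 0.05$). If a day still fails, the solver
  integrates that day as two (recursively up to sixteen) half steps and
  re-starts the full-step iteration from the result; in the rare stiff
  regimes where the full-step map has no attracting fixed point at all, the
  refined substeps themselves become the day's state and the event is
  counted in `n_substepped`. Hard failure would silently bias a training
  corpus against stiff parameter regions, which we consider worse than
  locally refining the integrator.
* **Boundary conditions.** Symmetry at $x = 0$ (zero velocity, zero flux);
  at $x = X$ the dermis is pinned at its healthy equilibrium
  ($v = 0$, $c = 0$, $N = \bar N$, $M = 0$). A `"closed"` mode with
  all-natural boundaries exists for spatially homogeneous reductions.
* **Initial profile.** A sigmoid of steepness $s$ interpolates between
  wounded values ($c = c_w$, $N$, $\rho$ at 20% of equilibrium, $M = 0$)
  and healthy tissue across $x = L$, avoiding Gibbs oscillations on linear
  elements.
* **Negative undershoots.** Species are clipped at zero after each
  converged step; the run aborts if the clipped mass exceeds $10^{-3}$ of
  the species total (floored at $10^{-6}$ of the species scale so a field
  that has physically vanished cannot trip the abort on roundoff).
* **RSA extraction.** The wound edge is the material point initially at
  $x = L$; on a Lagrangian mesh it keeps fixed barycentric coordinates in
  its element, so the daily relative surface area is simply its current
  position divided by $L$. `RSA[k]` is the value after $k$ daily steps.

The solver is verified against independent oracles in the test suite: the
equilibrium is preserved to $10^{-6}$ over a year; a coupling-free
configuration reproduces the closed-form heat-mode decay to 1%; the
spatially homogeneous reduction matches a stiff `deSolve::lsoda`
integration of the hand-written reaction system to 0.5% per species (365
backward-Euler steps at $\Delta t = 0.1$ day — at a full one-day step a
first-order integrator cannot track a year of exponential decay to that
accuracy, so the refinement probes the same operator at the accuracy the
comparison needs); observed convergence orders are $\geq 1$ in time and
$\approx 2$ in space.

## The simulated corpus

The surrogate's training data are generated, not collected. Twenty-five
patient- and wound-specific parameters are drawn uniformly from the ranges
in `inst/extdata/param_ranges.yaml`; the full vector is redrawn until the
stability condition holds ("rejection sampling over the joint box"). Each
accepted draw is simulated for 365 days and contributes one row
$(x \in \mathbb{R}^{25}, y \in (0,1]^{365})$.

The exact constants of the underlying physiology are spread across the
specialised literature; the shipped defaults are physically plausible
placeholders calibrated **once** so the generated corpus spans clinically
reported contraction intensities — minimum RSA roughly 0.15–0.93 with mean
near 0.6, last RSA roughly 0.7–0.99 with mean near 0.91 — and they are not
revisited. Users with better constants can supply their own configuration
file; every entry carries units and a one-line meaning.

What the generator deliberately does *not* emulate: measurement noise (the
targets are exact solver output), inter-parameter correlations (draws are
independent uniforms), multi-dimensional wound geometry, and any
age-to-parameter mapping (a scenario interface accepts explicit
distributions instead). Tests passing on this corpus therefore demonstrate
that the surrogate can learn the simulator, not that the simulator matches
any individual patient.

Row seeds derive from the master seed by a counter scheme, so any row is
reproducible in isolation; solver failures are logged and resampled, and a
failure rate above 5% aborts corpus generation.

## The surrogate

A feed-forward network maps the 25 Min-Max-scaled inputs to the 365-day RSA
course: layers 25–100–100–365, rectified-linear hidden units, sigmoid
output (the RSA is bounded in $(0,1)$), 49,565 learnable parameters. Inputs
are scaled to $[0,1]$ with a scaler fitted on the training split only;
targets stay on their natural scale, already matched to the sigmoid range.

Training minimises mean squared error with Adamax, initial learning rate
0.015 multiplied by 0.99 each epoch, minibatches of 64, and early stopping:
an epoch improves only if it undercuts the best monitored loss by more than
$10^{-5}$, thirty non-improving epochs stop training, and the best-epoch
weights are restored. The monitored loss is the validation MSE when a
validation set is attached (as in cross-validation folds) and the training
MSE otherwise. A hard cap of 2000 epochs guards automated runs. The
learning-rate range test (`lr_range_test()`) sweeps each optimizer (seven
are implemented: SGD, Adagrad, Adadelta, RMSprop, Adam, Adamax, Nadam) over
a grid in $[10^{-4}, 1]$ for 150 epochs without early stopping and records
the moving-average-smoothed loss, flagging divergence instead of raising.

The implementation is plain R matrix code. At this network size a
BLAS-backed dense pass is fast (sub-millisecond per minibatch), and keeping
the arithmetic in the package makes the training protocol — the part under
test — fully inspectable.

## Evaluation

`split_and_scale()` holds out 20% of the corpus, partitions the remaining
80% into ten folds, and fits the input scaler on the training portion only.
`cross_validate()` trains one model per fold (fold held out and monitored);
`evaluate_surrogate()` reports pooled test $R^2$ (over all sample–day
pairs), aRRMSE (mean over the 365 target dimensions of the
deviation-normalised RMSE), aRelErr (flat mean of $|e|/|y|$), and, for the
two clinically interesting characteristics — minimum RSA (maximum
contraction) and last RSA (permanent contraction) — $R^2$, MAE and the
distribution of the characteristic over the test set. Fold scores aggregate
as mean ± sample standard deviation ($n-1$). The test-set model is a single
model retrained on the full 80%.

At desk scale the package runs the whole loop on a 2,000-row corpus with a
101-node mesh (the reference resolution is 202 nodes; the coarser mesh
halves corpus cost with no visible change in the RSA course at these
wound lengths). `scripts/acceptance.R` reproduces exactly this pipeline.

## Monte-Carlo uncertainty

`scar_scenario()` assigns each of the 25 inputs a point value or a uniform
interval; `run_monte_carlo()` filters draws through the stability
condition, predicts all courses in one batch, and summarises per-day
quantile bands (default 5/25/50/75/95%), the distributions of minimum and
last RSA, and the probability that peak contraction $1 - \min \text{RSA}$
exceeds a threshold (default 25%, a conventional marker of clinically
worrying contraction; it is a reporting choice, not a calibrated clinical
cut-off). Draw-level predictions are retained (capped at 10,000) so every
summary can be recounted from the artifacts. Quantiles use the empirical
(type-7) estimator.

The scenario layer is where an age-to-parameter interpolation would plug
in; the package keeps that mapping out of scope because its source data are
not reproducible from the literature at hand, and accepts explicit
distributions instead.

## Known limitations

* One spatial dimension: no wound shape, depth or anisotropy; "surface
  area" is an interval length.
* The constitutive constants are calibrated placeholders; absolute RSA
  values should not be read clinically without re-fitting to data.
* The surrogate extrapolates poorly outside the sampled parameter box;
  out-of-range inputs are flagged with a warning, and Monte-Carlo summaries
  record whether extrapolation occurred.
* Uniform, independent parameter distributions understate the correlation
  structure real patients surely have.
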