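---
title: "Quantum circuit learning for QSPR regression: model, training, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum circuit learning for QSPR regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qclr)
```

## The model

`qclr` implements quantum circuit learning (QCL): a hybrid
quantum–classical regression in which a parameterized quantum circuit plays
the role of the model family and a classical optimizer tunes its parameters.
The intended application is quantitative structure–property relationship
(QSPR) modelling — predicting a polymer property such as the glass
transition temperature from numeric molecular descriptors of the monomer —
but nothing in the package is specific to that property.

The prediction pipeline for one sample is:

1. **Compression.** The `d` descriptors (10 by default) are projected onto
   the first `n_components` principal components (4 by default). With
   strongly correlated descriptor sets, four components typically carry
   more than 99% of the variance, and each retained component becomes one
   qubit.
2. **Encoding.** Each component score is min–max scaled to $[-\pi, \pi]$
   (training ranges) and used directly as a rotation angle: per repetition,
   $R_Y(x_i)$ then $R_Z(x_i)$ on qubit $i$, followed by a CNOT entangling
   chain; the block is repeated twice by default. The encoder has no
   trainable parameters.
3. **Variational circuit.** Either the layered ("original") ansatz — per
   layer a CNOT chain then one generic rotation $U_3$ per qubit, $3nL$
   trainable angles — or the four-qubit MERA ansatz: four two-qubit blocks
   (disentangler, two isometries, top block), eight $U_3$ gates, 24
   parameters, the same count as the layered ansatz at $L = 2$.
4. **Readout.** The prediction in model space is the Pauli-Z expectation
   $\langle Z \rangle \in [-1, 1]$ of the readout qubit: the last wire for
   the layered ansatz, the third wire for MERA. On hardware this
   expectation is estimated from a finite number of measurement *shots*;
   the simulator reproduces that with a binomial draw, or returns the exact
   statevector expectation.
5. **Inverse target transform.** Training targets are min–max scaled to
   $[-1, 1]$ and squashed with $\tanh$, so the training range maps to
   $[-\tanh 1, \tanh 1] \approx [-0.76, 0.76]$. Because the readout can
   reach $\pm 1$, the model retains headroom to predict *beyond* the
   training range of the property; predictions are mapped back through
   $\mathrm{atanh}$ and the inverse min–max.

Training minimizes the mean squared error in the scaled space. Performance
is reported as $R^2$ (in-sample) and $Q^2$ (the same formula applied to
pooled out-of-fold predictions from 10-fold cross-validation), both in
property units.

## Why shot-robust training matters

On hardware, each expectation costs `shots` measurements, and a full-batch
objective costs `shots × n_samples` per optimization step (860,000 at
10,000 shots and 86 samples). Derivative-free simplex search (Nelder–Mead)
over such a stochastic objective stalls: the simplex ordering is corrupted
by sampling noise unless shots are large.

The package's alternative follows the shot-frugal recipe: **single-sample
stochastic gradient descent with the parameter-shift rule.** Every
trainable angle $\theta$ generates a Pauli rotation
($U(\theta) = e^{-i\theta P/2}$; each of the three $U_3$ angles is such an
angle through the $R_Z R_Y R_Z$ decomposition), so the derivative of the
readout expectation is exact:

$$\frac{dB}{d\theta} = \frac{1}{2}\left[B\!\left(\theta + \tfrac{\pi}{2}\right)
  - B\!\left(\theta - \tfrac{\pi}{2}\right)\right].$$

One step draws one sample, evaluates $B$ once and the two shifted circuits
per parameter, and applies the squared-error chain rule
$dL/d\theta = -2(y - B)\,dB/d\theta$ through an Adam update. The per-step
cost, `shots × (1 + 2 × n_params)` (4,900 at 100 shots and 24 parameters),
is independent of the dataset size — roughly 1/180 of the full-batch
Nelder–Mead step above. Because the parameter-shift estimate is an unbiased
finite-difference-free gradient, SGD keeps making progress at shot counts
where the simplex method does not; the acceptance suite checks exactly this
ordering under an equal total shot budget.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `n_components` | 4 | retained PCs = qubits; MERA requires 4 |
| `repetitions` | 2 | encoder rotation+CNOT repetitions |
| `entangler` | `"linear"` | CNOT chain 1→2, 2→3, 3→4; `"ring"` closes the loop |
| `layers` (`L`) | 2 | layered-ansatz depth, $3nL$ parameters |
| `shots` | `"exact"` / 100 | per-expectation measurements; `"exact"` = statevector |
| `lr` | 0.05 | Adam step size (radians per unit gradient) |
| `n_steps` | 200–250 | SGD steps / Nelder–Mead objective evaluations |
| `noise_sd` | 0.1 | generator target noise (property units) |
| `x_noise_sd` | 0.05 | generator descriptor noise |

Adam uses $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$. The
learning rate 0.05 is slightly larger than the 0.001 textbook default:
with 24 parameters, bounded gradients ($|dB/d\theta| \le 1$) and a noisy
single-sample objective, larger steps traverse the periodic landscape in a
few hundred steps without divergence. The comparative conclusions below are
not sensitive to this choice, which is exposed as `lr`.

## Design choices where the architecture was open

- **Gate conventions.** Half-angle conventions
  ($R_Y(\theta) = e^{-i\theta Y/2}$, $R_Z$ likewise,
  $U_3(\theta,\phi,\lambda) = R_Z(\phi) R_Y(\theta) R_Z(\lambda)$ up to
  global phase), under which $\langle Z\rangle = \cos\theta$ after
  $R_Y(\theta)\lvert 0\rangle$ — the identity the gradient tests rely on.
  Simulators differ in these conventions, so absolute parameter values are
  not portable across implementations; behaviors are.
- **Encoding map.** The scaled feature *is* the angle ($R_Y(x_i)$ then
  $R_Z(x_i)$); no arcsin/arccos re-mapping. Scaling to $[-\pi,\pi]$ only
  makes sense if the scaled value is used directly as a Bloch angle.
- **CNOT topology.** Linear chain by default; wiring diagrams admit
  variants, so the topology is a constructor argument (`linear`/`ring`) and
  is recorded in serialized circuits.
- **MERA wiring.** Disentangler on (q2,q3), isometries on (q1,q2) and
  (q3,q4), top block on (q2,q3); each block is $U_3 \otimes U_3$ followed
  by a CNOT. This is the canonical four-qubit MERA layout and yields
  exactly 8 $U_3$ = 24 parameters with the readout on wire 3 (1-based).
- **Qubit indexing.** 1-based wire numbers in the API (R convention);
  amplitudes are little-endian (bit $q-1$ of the basis index is qubit $q$).
- **Initialization.** Trainable angles i.i.d. uniform on $[0, 2\pi)$ under
  a recorded seed — full period coverage. Training speed (steps to a given
  $R^2$) depends strongly on the draw, which is why comparative claims are
  made on medians over seeds, with initializations shared between arms.
- **Cross-validation scope.** The preprocessor (PCA, min–max ranges, target
  range) is re-fitted inside each fold on that fold's training rows only;
  held-out component scores falling outside the training range are clipped
  to $[\pm\pi]$, and fold assignment is a seeded shuffle. This avoids
  information leakage at the cost of slightly pessimistic $Q^2$; fold seeds
  are recorded because $Q^2$ varies with the assignment.
- **Evaluation readout.** Learning-curve and reported $R^2$/$Q^2$ values
  are always computed from the exact statevector at the current
  parameters, even when *training* uses finite shots — the curves then
  compare optimization trajectories without sampling noise in the metric
  itself. Shot-based prediction remains available via the `shots` argument
  of `predict()`.

## Numerical choices and degenerate inputs

- Gate application keeps the statevector norm within $10^{-10}$; at 4
  qubits the dense 16-amplitude representation is exact and fast (no
  tensor-network shortcuts).
- Nelder–Mead (`stats::optim`) stops at `reltol = 1e-4` on the simplex
  function values or at `max_iter` objective evaluations, whichever comes
  first. With a stochastic objective the tolerance can trigger early —
  itself a symptom of shot noise, and part of what the comparison measures.
- $\mathrm{atanh}$ inputs are clipped to $\pm(1 - 10^{-9})$ with a warning;
  sampled readouts can hit $\pm 1$ exactly.
- Constant descriptor columns are dropped with a warning before PCA;
  zero-variance targets and zero-range retained components are errors.
- Non-finite losses or gradients abort training with a diagnostic rather
  than propagating NaN through Adam.
- SGD sample selection is uniform with replacement under the run seed.

## The synthetic data generator

The package is benchmarked on synthetic data because the original
descriptor table is proprietary. `generate_qspr()` draws latent factors
$Z \sim N(0, \mathrm{diag}(4, 2, 1, 0.5))$, mixes them into 10 descriptors
through a random row-orthonormal matrix, and adds isotropic noise
($\sigma_x = 0.05$), giving a descriptor covariance with four dominant
eigenvalues — the population top-4 explained-variance fraction is 99.8%,
mirroring the "4 PCs carry > 99%" compressibility typical of correlated
monomer descriptor tables. The
default target is $y = \sum_k a_k \sin(z_k)$, $a = (1, 0.8, 0.6, 0.4)$,
plus $N(0, 0.1)$ noise: smooth, bounded, nonlinear, and spanning most of
the usable $[-0.76, 0.76]$ readout range after scaling. Defaults (86
samples, 10 descriptors) reproduce the benchmark shapes exactly.

What the generator does *not* emulate: real descriptor semantics
(connectivity indices, molecular weight and the like are emulated only
statistically), heavy-tailed or clustered chemical spaces, heteroscedastic
property noise, and the actual nonlinearity of a property map computed by
a group-contribution engine. Passing tests on this data therefore
demonstrate that the machinery — circuits, gradients, optimizers, metrics —
behaves as designed, and that the *orderings* (deeper circuits fit better
with exact readout; parameter-shift SGD tolerates low shot counts better
than Nelder–Mead) hold on data with the assumed statistical shape. Absolute
$R^2$/$Q^2$ levels on real polymer data are not predicted by these tests.

## Problem sizes used in the shipped checks

The test and acceptance runs use sizes chosen to finish in minutes on one
CPU: the optimizer comparison runs MERA at 100 shots for 150 SGD steps
(735,000 total shots) against Nelder–Mead given the same budget (85
full-batch evaluations), over 5 seeds with shared initializations; the
depth sweep trains the layered ansatz at $L \in \{1, 2, 4\}$ with exact
gradients for 250 steps over 5 seeds; cross-validation in the unit tests
uses reduced datasets (15–30 samples) and short runs. Gradient checks use
20 random parameter draws per ansatz against central finite differences at
$h = 10^{-6}$.

## Known limitations

- The simulator is a dense statevector engine capped at 12 qubits, with no
  decoherence or gate-error channels — finite-shot sampling is the only
  noise modelled. Results on hardware will additionally reflect device
  noise.
- Only MSE loss and single-sample SGD are implemented (mini-batches would
  change the shot-budget arithmetic the method is built around).
- The MERA builder is fixed at four qubits, the only published size.
- Step counts to reach a given accuracy depend on the random
  initialization and on the Adam step size; they are not comparable across
  implementations with different conventions, and the package asserts
  orderings, not step counts.
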