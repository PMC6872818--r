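---
title: "Methods: chaos-enhanced swarm training of deep QSPR networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chaos-enhanced swarm training of deep QSPR networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`capsonet` predicts molecular absorption energies (eV) from eight numeric
descriptors with a deep feedforward network whose parameters are found by
a chaos-enhanced accelerated particle swarm (CAPSO) rather than by
gradient descent. This vignette is the package's own account of the
method: the update rule and its assumptions, every tunable that matters,
the synthetic data the tests rely on, and the numerical and design
choices that were genuinely open.

## The optimizer

A particle is a candidate parameter vector $\theta \in \mathbb{R}^D$
(all weights and biases of the network, flattened). With global best $g$,
iteration $t$ updates every particle coordinate-wise by

$$x' \;=\; (1 - C_2)\,x \;+\; C_2\, g \;+\; C_1\, r ,$$

clamped to the search box. The accelerated family deliberately drops
velocities, inertia and personal bests: particles are constrained only by
the global best. Two schedules drive the search:

* **Cognitive amplitude** $C_1 = \delta^t$ decays geometrically and sets
  the exploration step size.
* **Social weight** $C_2$ is the running orbit of the logistic map at
  full chaos, $x_{k+1} = 4 x_k (1 - x_k)$, one shared value per iteration
  for all particles and dimensions. The orbit's arcsine-shaped invariant
  density concentrates near 0 and 1, so iterations alternate between
  "hold position, explore" and "snap to the global best" with an
  ergodic, reproducible schedule in between.

Three numerical choices deserve justification:

* **Centered perturbation.** The perturbation $r$ is drawn uniformly and
  centered, $r = 2u - 1$ with $u \sim U(0,1)$, giving zero-mean noise of
  amplitude $C_1$. A one-sided $U(0,1)$ perturbation is sometimes written
  for this update rule, but it cannot work: a particle sitting on the
  global best can then only *increase* its coordinates, so once the swarm
  collapses (which the chaotic contraction does within tens of
  iterations) no coordinate can ever decrease and the search stalls
  permanently. With centering, the same rule solves the 10-D sphere
  benchmark to the $10^{-7}$ floor from every seed we test.
* **$\delta$ matched to the budget.** With the default 2000-iteration
  budget, $\delta = 0.99$ keeps $C_1$ above $10^{-6}$ until iteration
  ~1375, so the whole budget contributes to refinement; at
  $\delta = 0.97$ the amplitude is spent by iteration ~500 and the
  remaining 75 % of iterations cannot move the swarm. $\delta$ remains a
  user-visible control for shorter runs.
* **Clamping, not reflecting.** Out-of-box proposals are clamped to the
  nearest bound — the simplest contract, and directly testable.

The stopping rules are an iteration cap (default 2000) and an objective
floor (default $10^{-7}$ on the training MSE). The global best is updated
only on strict improvement, ties inside one iteration resolving to the
lowest particle index; the best-value trace is therefore non-increasing
by construction, and the evaluation count is exactly
$m \times (\text{iterations} + 1)$. Runs are bit-reproducible from the
two seeds (RNG seed and chaos seed). The chaos seed must avoid
$\{0, 0.25, 0.5, 0.75, 1\}$, where the logistic orbit freezes or
collapses; the default is 0.7. A classical inertia-weight PSO
(`pso_optimize()`) with the standard constriction coefficients is
included as an internal baseline with the same contract.

## The network and its encoding

The default architecture is 8-4-4-4-4-4-1: eight descriptors in, five
hidden layers of four sigmoid units, one output. Hidden activations are
$\sigma(z) = 1/(1+e^{-z})$; saturation is numerically safe (exact 0/1,
no overflow) for any $|z|$. The output node is **linear** by default. A
softmax output is the textbook choice for classification heads, but with
a single regression output softmax is degenerate (identically 1), so the
package defaults to a linear unit and offers a sigmoid output for
targets rescaled into (0, 1); both preserve the regression semantics of
the AARD/RMSEP/R² evaluation.

The particle encoding is fixed and documented: layer by layer, the
weight matrix in column-major order (column $j$ collects the fan-in of
destination node $j$), then that layer's biases. The codec is bijective
and the forward pass is invariant under a round trip; a wrong-length
vector fails with the expected and actual lengths in the message.

## Training, refinement, architecture search

`capso_train()` fits min–max normalization (descriptors and target) on
the **training rows only**, runs the swarm on the training MSE, and
reports validation MSE at checkpoints for monitoring — validation never
drives early stopping, and there is no early stopping by default. The
default weight box is $[-3, 3]$: with inputs in $[0,1]$ and fan-in at
most 8, weights of magnitude 3 already reach deep sigmoid saturation, so
the box covers the useful parameter range; initializing uniformly over a
much wider box (say $\pm 10$) saturates essentially every hidden unit,
the landscape becomes flat, and the annealed search cannot traverse it.

"BP" in this model family's name refers to the back-propagation-style
multilayer perceptron, not to gradient training; the swarm is the
trainer. Full-batch gradient refinement (`gradient_refine()`) is
available but **off by default**: it backtracks (halving the step until
the MSE does not increase), so the returned training MSE never exceeds
the input's, and its gradients are verified against central finite
differences in the tests.

`search_architecture()` re-trains the model for shared hidden-node
counts 2–8 (all five hidden layers share the count), reusing identical
swarm seeds so candidates differ only in topology, and selects the
validation-MSE minimizer with ties broken toward fewer nodes. A failing
candidate is recorded in the result table rather than aborting the
sweep.

## Data handling

The stratified splitter bins molecules by target energy. The default
breaks cut at the midpoints of the gaps between the five published
energy bands (2.69–2.99, 3.01–3.96, 4.00–4.68, 4.70–5.08, 5.10–6.66 eV),
so values falling in a gap join the nearest band. Within a stratum of
size $n$, the validation and test quotas are `round(0.15 n)` under R's
round-half-to-even, and training takes the remainder. This is the unique
simple rounding rule that reproduces the published per-stratum counts —
including the $n = 30$ stratum, where 22/4/4 requires rounding 4.5 down —
and it is an inference from those counts, not a documented procedure of
the original study. Membership within a stratum is uniform at random
given the split seed; quotas depend only on stratum sizes, so different
seeds move molecules but never counts.

Metrics are computed on the de-normalized eV scale, where RMSEP has
physical units. AARD divides by the *actual* value, so it is
scale-invariant but argument-order-sensitive; actuals are validated
strictly positive (absorption energies are), and zero actuals raise a
domain error instead of silently producing infinities. R² for a constant
vector is an error, not 0. The report's `average` row is the arithmetic
mean of the three subset rows — with a single 70/15/15 split that is the
convention which matches published report layouts of this kind; a pooled
mean would weight training 4.7× more.

## What the synthetic generator does and does not emulate

`simulate_qspr()` produces tables with the statistical structure the
method assumes: integer counts with composition consistency
($N_a = N_c + N_h + N_N + \text{O-atoms} \ge N_h + N_c + N_N$), electron
counts from standard atomic numbers, double bonds bounded by half the
carbon count, right-skewed positive oscillator strengths, targets
spanning 2.69–6.66 eV with all five strata populated, and — the premise
the whole descriptor set rests on — the theoretical energy `Ec` as the
dominant single predictor (|r| ≈ 0.99 versus ≤ 0.82 for every other
descriptor at n = 500). Observation noise defaults to 0.05 eV, a level
at which a well-trained model's RMSEP lands in the 0.1 eV decade —
deliberately near the magnitude real absorption-energy models report,
without claiming to reproduce any published dataset.

Two teachers generate targets. The **analytic teacher** is a documented
closed form (logistic squash of a linear-plus-sine score of the counts
and oscillator strength) useful for interpretable tests and exact
self-consistency checks at zero noise. The **teacher network** is a
fixed, seeded network of the default architecture for realizable-recovery
experiments. Its construction is deliberate: i.i.d. random weights in a
five-hidden-layer sigmoid stack attenuate the signal almost completely
(raw output span ~10⁻³), so affinely mapping such outputs onto the eV
range amplifies noise-like fine structure no trainer could recover.
Instead the teacher mirrors the assumed data structure — a dominant
pathway from the first descriptor, identity-carry weights through the
depth keeping units responsive, mild seeded mixing elsewhere — giving a
well-conditioned target that is exactly representable by the student
architecture (up to the affine output rescaling a linear output node
absorbs).

What the generator does **not** emulate: real molecular classes, any
particular quantum-chemistry level of theory, descriptor redundancy
patterns of real dye families, or heavy-tailed measurement error.
Passing the recovery and pipeline tests therefore demonstrates that the
optimizer, network, splitter and metrics work as specified on data with
this structure — not that the trained models would match any particular
published accuracy on real molecules.

## Problem sizes used by the tests

The test suite and the acceptance script run at the method's standard
settings where that is cheap (60 particles × 2000 iterations for the
sphere benchmark, teacher recovery over five seeds, and the pipeline
demonstration) and at reduced budgets where full runs add nothing
(unit tests use 10–20 particles and tens of iterations; the
architecture sweep uses 200 iterations per candidate, which compares
candidates fairly because they share seeds). Recovery is measured as
test-set RMSEP on the normalized target over 150 teacher molecules split
106/22/22; the equal-budget baseline evaluates exactly as many random
parameter vectors as the swarm consumed evaluations.

## Known limitations

* Swarm search over 121 dimensions is a global method with local-search
  tail behavior; on hard or ill-conditioned targets it plateaus well
  above the gradient-descent optimum. The optional refinement step
  exists precisely for that case.
* The quota rounding rule and gap-midpoint bin edges are inferences that
  reproduce the published split exactly; other procedures could too.
* AARD's positivity requirement makes the metrics module unsuitable for
  targets crossing zero without rescaling.
* One chaotic scalar is shared per iteration. That is the documented
  reading of a single "social component" generator; a per-particle
  chaos option would decorrelate particle moves but is not what the
  default implements.
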