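---
title: "Cellular memory in mutual repression networks: models, noise and first passage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular memory in mutual repression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrnmem)
```

## The system

`mrnmem` analyses a three-protein gene regulatory circuit built around a
mutually repressing pair. An input signal $S$ drives the synthesis of a
transcription factor $y_1$; $y_1$ activates $y_2$ and shuts off the basal
synthesis of $y_3$; $y_2$ and $y_3$ repress each other cooperatively with
Hill coefficient $n$. The *mutual repression network* (MRN) is this core
alone; the *MRN-NA* adds negative autoregulation, a synthesis channel of
each repressor that its own product inhibits. The rate equations are

$$\frac{dy_1}{dt} = k_1 S - k_2 y_1$$

$$\frac{dy_2}{dt} = k_3\frac{y_1}{y_1+K_1}
  + k_4\frac{K_2^n}{y_3^n+K_2^n}
  + k_9\frac{K_5}{y_2+K_5} - k_5 y_2$$

$$\frac{dy_3}{dt} = k_6\frac{K_3}{y_1+y_2+K_3}
  + k_7\frac{K_4^n}{y_2^n+K_4^n}
  + k_{10}\frac{K_6}{y_3+K_6} - k_8 y_3$$

with $k_9 = k_{10} = 0$ recovering the MRN. All quantities are in
molecule-count units; rate constants are per unit of dimensionless model
time ("simulation steps"). The canonical parameter values ship as the
presets `standard_params("MRN-baseline")`, `"MRN-NA"` and
`"MRN-NA-calibrated"`.

**A deliberate design choice sits in the basal channel of $y_3$.** We model
it as *competitively* repressed by $y_1$ and $y_2$ together,
$k_6 K_3/(y_1+y_2+K_3)$, i.e. both proteins can occupy the site that
licenses basal $y_3$ synthesis. This is the only wiring under which the
circuit behaves as a usable memory module across its whole published
parameter range: it is exactly the form whose signal-free quasi-steady-state
reduction is the closed-form partner expression used throughout the
one-variable theory below, and it is required for the induced state to be
deep enough that the stochastic memory experiments are meaningful. With the
basal channel gated by $y_1$ alone, the $y_3$ level can never fall below
$k_6/k_8 \approx 22.6$ once the signal is gone; we verified that in that
case the system is monostable for $n \le 4$ at every $K_2 = K_4$ between 5
and 300, no double well exists at $n = 3$ for any $K$ in the 5–50 sweep,
and no 18-of-20 stochastic memory criterion is met at $K = 43$ for any
$n \le 12$ — i.e. essentially none of the analyses this package exists to
perform would have a non-trivial answer.

A consequence worth knowing: at $S = 0$ the basin of the origin belongs to
the *induced* attractor (starting from the empty state, $y_2$ wins the
race). The resting state of an uninduced cell — low $y_2$, high $y_3$ — is
an attractor reached from $y_3$-dominant history, and `off_state()`
computes it by relaxing from $y_3$ at its synthesis/degradation ceiling.
All memory protocols start there.

## The memory protocol

`default_schedule()` encodes the canonical experiment: 1000 time units,
signal amplitude $S = 1$ applied from $t = 250$ to $t = 500$. The
amplitude default puts the induced $y_1$ plateau at $k_1 S / k_2 = 100$,
the natural scale of the model; it is a configuration knob, not a fitted
value. Memory means that after the signal is removed the system stays on
the induced side: $y_2$ above, and $y_3$ below, the *separatrix* of the
signal-free system. We use the unstable fixed point of each species'
reduced one-variable system (below) as that separatrix, falling back to
the midpoint of the two stable steady levels when a reduced barrier does
not exist; trajectories are classified over $t \in [520, 1000]$, the first
20 units after switch-off being treated as settling time (the same
convention the noise windows use). A deterministic verdict integrates the
rate equations once (`deterministic_memory()`); the stochastic verdict
(`stochastic_memory()`) runs 20 exact Gillespie replicates and requires 18
(90%) of them to hold the state — both the replicate count and the pass
count are arguments.

The deterministic integrator is `deSolve::lsoda` with relative tolerance
$10^{-8}$ and the pulse edges passed as event times; halving the
tolerances moves steady levels by well under 0.01%. The Gillespie engine
treats the system as six birth–death channels (one lumped birth and one
linear death channel per species — the same decomposition the chemical
master equation below uses), regenerates the waiting time at the two
switching instants, and records the state at the latest event before each
unit-step grid point. Randomness comes from a package-internal
xoshiro256++ generator, so a replicate is bit-reproducible from its seed
alone, independent of R's RNG state; replicate $r$ of a batch uses seed
$\mathrm{seed} + r - 1$, and sweep cells derive their seed blocks from the
master seed and the cell index, making whole phase diagrams reproducible
and evaluation-order-independent.

## One-variable reduction and the stationary theory

At $t \to \infty$ with $S = 0$ ($y_1 = 0$), fixing one repressor at the
steady level implied by the other (the quasi-steady-state assumption)
reduces the pair to a single variable. For focal $y_2$ at level $y$, the
partner balance is quadratic in $y_3$ and its unique non-negative root is
taken in closed form (`qss_partner()`); a scalar root-find on the defining
balance equation is kept in the test suite as the independent oracle. The
reduced process has drift $A(y) = W_\mathrm{birth}(y) - W_\mathrm{death}(y)$
and noise $B(y) = W_\mathrm{birth}(y) + W_\mathrm{death}(y)$, where
$W_\mathrm{birth}$ collects the focal species' synthesis channels (mutual
repression evaluated at the slaved partner, plus autoregulation) and
$W_\mathrm{death}$ is linear degradation.

The stationary Fokker–Planck density and the stochastic potential are

$$P_\mathrm{st}(y) = \frac{N_c}{B(y)}
   \exp\!\Big[2\!\int^y \frac{A(z)}{B(z)}\,dz\Big],
\qquad
\Phi_s(y) = \tfrac12 \ln B(y) - \int^y \frac{A(z)}{B(z)}\,dz,$$

so $P_\mathrm{st} \propto e^{-2\Phi_s}$. `stationary_density()` computes
the integral by cumulative trapezoid on a 4000-point grid over
$[0, y_\mathrm{max}]$ with $y_\mathrm{max} = 1.5\times$ (maximal synthesis
rate / degradation constant) — beyond that point degradation dominates any
attainable synthesis and the density is provably negligible — and
exponentiates with max-subtraction before normalizing. The integration
constant is anchored at $y = 0$; it cancels in the normalization.
`is_bistable()` declares a double well only when *both* detectors agree:
three roots of $A$ (sign-scan plus bisection polish to $10^{-9}$,
classified by the sign of $A'$) *and* two minima of $\Phi_s$ separated by
a maximum. The second condition is strictly stronger: the
$\tfrac12\ln B$ term erases wells that are shallow relative to the noise,
which is precisely what makes the *stochastic* bistable region narrower
than the deterministic one — at moderate $n$ a sizeable set of
three-root cells has no double well, and those cells are reported as
monostable in `bistable_region()`.

Because the reduced process is, exactly, a birth–death chain on the
integers, its chemical master equation has the product-form stationary law
$\pi(y) \propto \prod_{i=1}^{y} W_\mathrm{birth}(i-1)/W_\mathrm{death}(i)$
(`birth_death_stationary()`, computed in the log domain). This is the
benchmark the Fokker–Planck density is validated against: at the canonical
parameter sets the total-variation distance between the two is below 0.02
for every species and variant, and a long exact simulation of the chain
(`chain_occupancy()`) agrees with $\pi$ to TV < 0.02 within $10^6$ events
at a fast-mixing (monostable) corner.

What the reduction does *not* capture: the full system's $y_2$ marginal.
The asymmetric QSS over-separates the two states of $y_2$, so its
one-variable density concentrates on the wrong well relative to a full
simulation started near the origin. The $y_3$ side is faithful — pooled
occupancy histograms of full Gillespie runs at the canonical MRN-NA
parameters match the $y_3$ Fokker–Planck density to TV $\approx$ 0.05 —
and it is the $y_3$ side on which the density validation in the test suite
is performed. This limitation is intrinsic to one-variable QSS reductions
of asymmetric toggles, not a numerical artifact.

## Mean first-passage times

The stability of each memory state is quantified by the expected time for
noise to carry the reduced process from a stable state to the barrier
$y_b$:

$$T_L = 2\int_{y_l}^{y_b} \frac{dx}{\Psi(x)} \int_0^x
 \frac{\Psi(z)}{B(z)}dz,
\qquad
T_U = 2\int_{y_b}^{y_u} \frac{dx}{\Psi(x)} \int_x^{\infty}
 \frac{\Psi(z)}{B(z)}dz,
\qquad
\Psi(y) = \exp\!\Big(\int_{y_0}^{y}\frac{2A}{B}\,dw\Big).$$

`mfpt()` evaluates both by nested cumulative-trapezoid quadrature with all
exponentials handled in the log domain ($\Psi$ spans hundreds of orders of
magnitude at large $n$; results are reported on the $\log_{10}$ scale as
well). The infinite upper limit is truncated at $y_\mathrm{max}$; doubling
the truncation moves $T_U$ by under 0.1%, and doubling the grid moves
either time by under 0.5%. The anchor $y_0$ of $\Psi$ cancels between the
two integrals, so it is a convention, not a parameter.

The quadrature is validated against `chain_first_passage()`, a Monte-Carlo
first-passage sampler of the integer chain. Two conventions matter at
molecule counts this small (the induced $y_3$ state sits near 6):
the chain absorbs at an *integer* state, so the comparison evaluates the
quadrature to that same integer (`mfpt_between()`); and the residual
continuum-vs-chain bias is of order 10% here, so the benchmark uses a
replicate count (200) at which that bias sits within the Monte-Carlo
3-standard-error band. At larger barriers (the $y_2$ side) the
Fokker–Planck approximation *underestimates* the passage time by tens of
percent — expected behaviour for diffusion approximations of discrete
jump processes, and the reason the package reports orderings and
log-scale magnitudes rather than treating absolute MFPTs as exact.

## Calibration and scenario generation

Comparisons between the MRN and MRN-NA are made at conserved steady-state
levels. `calibrate_match()` tunes one MRN-NA parameter (default $k_4$,
alternatives $k_7$ or the joint autoregulation strength) by root-finding
so that the upper stable $y_2$ state of the reduced system matches the
MRN's; with the canonical sets this lands $k_4$ near 60.8, close to the
shipped `"MRN-NA-calibrated"` preset value of 61.04. The lower states cannot be
matched simultaneously — the autoregulation lifts them — and the residual
mismatch is attached to the result rather than hidden.

`perturbed_scenarios()` generates randomized test inputs: independent
log-normal multiplicative jitter on every nonzero rate and dissociation
constant, integer Hill coefficient held fixed, deterministic given the
seed. The default relative spread of 5% was chosen once, as the scale of
kinetic uncertainty a practitioner would call realistic, and is small
enough that the canonical MRN-NA stays bistable in essentially all draws —
which is what makes the fixture informative for downstream tests. What
the generator deliberately does not emulate: correlated parameter errors,
extrinsic noise, or cell-to-cell volume variation; conclusions from
passing tests are about the intrinsic-noise model only.

## Phase diagrams and noise quantification

`memory_region()` and `bistable_region()` sweep the two parameters the
memory function is most sensitive to — the Hill coefficient and the joint
mutual-repression dissociation constant $K_2 = K_4$ — over configurable
grids (default $K \in \{5,10,12,15,20,25,30,35,40,43,45,50\}$, which
includes every canonical value). Intrinsic noise is summarized by
`coefficient_of_variation()` over the windows $[270, 500]$ (signal period,
20 settling steps skipped) and $[500, 750]$ (post-signal); the sample
(n−1) standard deviation convention is pinned for reproducibility.
`cv_comparison()` re-calibrates the MRN-NA at each $K$ before comparing.
Two robust findings: the species held low by the signal ($y_3$) carries
most of the intrinsic noise, and the autoregulation cuts its CV roughly in
half at every $K$ tested, in both windows. The $y_2$ CVs of the two
variants, by contrast, differ by less than their replicate scatter, and the
signal-period versus post-signal CV difference is likewise within noise —
the package's tests assert only the reproducible parts.

Against expectation, the autoregulation *shortens* the reduced-system
first-passage times at matched parameters (calibrated or not): the extra
synthesis floor it puts under each repressor weakens the partner's well
more than the added restoring force stabilizes it. The first-passage
sweeps in `mfpt_curves()` therefore show MRN-NA curves below the MRN's,
and times decreasing with autoregulation strength, while both increase
steeply with $n$. Where the memory improvement of autoregulation does show
up robustly is in the noise metric (the $y_3$ CV) and in the dominance of
the induced state's probability mass (`upper_state_mass()` of the $y_2$
density is far larger for the MRN-NA at matched $n$ and $K$).

## Numerical and testing notes

- Degenerate inputs: zero-amplitude schedules are legal (memory is then
  false by construction); monostable systems raise an error from the MFPT
  quadrature and return `NA` barriers from `fixed_points()`; a zero
  windowed mean flags the CV as undefined instead of erroring.
- Hill terms are evaluated as $1/(1+(y/K)^n)$ so that $y^n$ can never
  overflow; the SSA evaluates them at the current integer counts with no
  volume scaling (the model is already in molecule-count units).
- Problem sizes in the shipped tests — $10^6$-event occupancy runs,
  200-replicate passage sampling, 12-replicate CV sweeps, 20-replicate
  memory verdicts on single cells — were chosen so the whole suite runs in
  about two minutes while keeping every Monte-Carlo comparison inside its
  stated tolerance band.
- The `scripts/acceptance.R` entry point recomputes the four headline
  thresholds (deterministic memory onset, the two stochastic onsets at
  $K = 43$, and the double-well onset) from scratch; see the README.
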