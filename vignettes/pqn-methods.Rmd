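---
title: "PQN model simulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PQN model simulation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqnsim)
```

## The model family

The Piecewise Quadratic Neuron (PQN) model is a qualitative spiking neuron
model: rather than tracking ionic conductances it reproduces the phase-plane
structure that generates spiking, with right-hand sides cheap enough to map
onto fixed-point digital hardware. Every nullcline-defining function is
piecewise quadratic — two parabolas joined at a junction — and the model
family has four variants:

* **two-variable** (`v`, `n`): membrane potential and recovery; Class II
  excitability,
* **three-variable** (+`q`): a slow subtractive variable with its own
  piecewise-quadratic nullcline `h(v)`; regular spiking, fast spiking and
  elliptic bursting,
* **four-variable** (+`u`): a linear slower variable feeding back
  positively into `dv/dt`; parabolic bursting,
* **extended four-variable**: `u` instead switches the recovery time
  constant through the step function `eta(u)`; low-threshold spiking and
  intrinsic bursting.

All variables and parameters are dimensionless; time is carried in seconds.
Integration is forward Euler with a *synchronous* update: each step
evaluates every derivative from the time-`t` state before any assignment,
and in the extended variant `eta` reads the time-`t` value of `u`. This
mirrors a pipelined hardware engine in which `v_next`, `n_next`, `q_next`
and `u_next` are all produced from the current registers, and it is part of
the model definition here, not a numerical choice: a bit-exact hardware
emulation must step exactly as the hardware does.

### Smoothness completion

Only the left-branch coefficients (`a_*n`, `b_*n`, `c_*n`) and the
right-branch curvature (`a_*p`) of each nullcline function are free. The
right-branch vertex and offset are derived from the requirement that the
function be continuous with continuous first derivative at its junction
`r` (0 for `f`, `r_g` for `g`, `r_h` for `h`):

$$b_p = r - \frac{a_n (r - b_n)}{a_p}, \qquad
  c_p = a_n (r - b_n)^2 + c_n - a_p (r - b_p)^2.$$

Cellular nullclines are expected to be smooth, so this constraint is
biologically natural, and it removes six free parameters per mode compared
with fully free branches. `complete_parameters()` always recomputes the
derived fields — values found in a parameter file are documentation, not
data — and the completion is idempotent. Junction inclusivity follows the
printed inequalities: the right branch applies *at* the junction
(`v >= r`). For `f`, `g`, `h` continuity makes this choice unobservable;
for the genuinely discontinuous `eta(u)` the `u >= r_u` branch is
normative and tested.

## Integration backends

**Float.** Plain double-precision Euler. A divergence guard aborts with the
step index when `|v| > 1e6`; the quadratic right-hand side grows without
bound under bad parameters and silent `Inf`s help nobody.

**Fixed.** Emulates the FPGA arithmetic. The Euler update of each state
variable is folded into per-signal constants, e.g. for the two-variable
`v` update with `alpha = dt*phi/tau`:

$$v' = v + (\alpha a)\,v^2 + (-2\alpha a b)\,v
       + (-\alpha)\,n + (\alpha k)\,I + \alpha(ab^2 + c + I_0),$$

with the branch-dependent constants selected by a comparator exactly as the
hardware's multiplexers do. Every constant is quantized once on entry; each
product is a full-precision integer multiply right-shifted by the
fraction-bit count with truncation toward minus infinity; register writes
wrap in two's complement (policies `saturate` and `error` are available,
and a global counter makes silent overflow visible). Q-formats are written
`q<total>.<integer>`; the integer part *includes* the sign bit, so `q18.8`
carries 10 fraction bits and `q28.8` twenty. This reading is consistent
with the worked coefficient 0.037109375 = binary 0.000010011, which needs
9 fraction bits.

Raw values are held in doubles; because a 28-bit times 28-bit raw product
can exceed the 53-bit exact-integer range of a double, multiplication runs
on base-2^20 limbs with an exact long division by the fraction-bit power of
two. The arithmetic is therefore bit-exact for any supported format (up to
40 total bits), which the test-suite checks against an exhaustive integer
oracle on a small format and an algebraic oracle beyond 2^53.

Per step, the fixed backend deviates from float by a few resolution units
(one truncation per folded product plus coefficient quantization — the
suite asserts eight units of 2^-20 for `q28.8`). Over long simulations of
an oscillator the backends drift apart in phase while remaining on the same
attractor; agreement is therefore asserted as monotone convergence of the
trace error as fraction bits grow (10, 20, 30), not as pointwise closeness
at a fixed width.

**Shift-add multiplication.** Constant multipliers in the hardware are
realized as one arithmetic right shift per set bit of the coefficient's
plain binary representation, summed. Plain binary — not canonical signed
digit — is the resource model, because each additional one costs one
shifter/adder pair; `decompose_coefficient()` returns that bit set and
`ones_count` as the resource proxy. Each shift truncates independently, so
a shift-add product may differ from the quantize-then-multiply route by up
to one raw unit per set bit; the two agree exactly whenever no shift
discards set bits, which the suite verifies. Negative coefficients are
decomposed by magnitude with the sign carried alongside; the quantization
before decomposition defaults to round-to-nearest.

## Equilibria, spikes and statistics

`find_equilibrium()` scans the `v` bracket (1000 intervals) for a sign
change of the nullcline-intersection residual, refines with
`stats::uniroot` (tolerance 1e-14) and returns the *leftmost* root with the
slow variables at their own equilibria; an exact zero on the scan grid is
accepted directly, which also catches tangent (double) roots. Simulations
default to starting at this resting equilibrium at zero stimulus, else at
the zero state; the choice is recorded in the trace metadata because the
model's figures never state initial conditions anywhere.

The model has no stereotyped spike event, so `detect_spikes()` uses an
upward threshold crossing at `v = 0` — the junction of `f`, which every
bundled spiking cycle traverses — with linear sub-grid interpolation and a
debounce of two grid steps. Detection at a given threshold is invariant
under linear upsampling of the trace, which the suite checks.

CV and LV follow the convention in which the normalizing count is the
number of *intervals* `m`:

$$CV = \frac{\sqrt{\tfrac{1}{m-1}\sum_i (T_i - \bar T)^2}}{\bar T},\qquad
  LV = \frac{1}{m-1}\sum_{i=1}^{m-1} \frac{3 (T_i - T_{i+1})^2}{(T_i + T_{i+1})^2}.$$

Under this convention both statistics are exactly zero for constant ISIs
and LV has Poisson expectation one, which a seeded 100 000-interval
exponential train verifies to within ±0.02. Both are invariant under
uniform time rescaling. Fewer than two intervals raises a typed error
rather than returning `NaN`.

Phase-resetting curves measure the first-order (within-cycle) shift only:
after discarding the first 20% of the record as transient (overridable),
the baseline must show at least ten consecutive ISIs within two grid steps
of their mean; the pulse is then applied at phases `j/n_phases` of the
cycle starting at a post-transient spike, and
`Delta(theta) = (T - T_i)/T` with `T_i` the length of the cycle containing
the pulse. Second-order (next-cycle) effects are out of scope. Burst
segmentation opens a new burst when an ISI exceeds a gap threshold
defaulting to five median ISIs — scale-free across the bursting classes —
and flags the first and last bursts as window-truncated rather than
dropping them.

## The bundled parameter sets

The per-class parameter tables of the original hardware study are not
reproduced here; the bundled modes are **synthetic sets designed in-house**
so that each class exhibits its defining dynamics, and they are labelled as
such. They emulate the qualitative phenotypes — not any particular cell's
firing rates or the resource-optimized coefficient values a fitted table
would contain — so passing tests demonstrate that the model equations and
the toolbox reproduce the class phenomenology, not that any biological
recording is matched. The design logic, briefly:

* **CLASS2** (two-variable): an N-shaped `f` (branch curvatures +1/−1,
  vertices at `v = ±1`) with a piecewise `g` that crosses it exactly once
  on the rising middle branch. With `phi = 4` the rest state destabilizes
  through a Hopf bifurcation at finite frequency: a discontinuous
  frequency-current curve, graded spike peaks, and a sign-changing
  (Type II) PRC, all asserted by the suite.
* **RS_EXC / RS_INH / FS** (three-variable): the Class II fast subsystem
  plus `q` with `h` negligible at rest and growing at spike voltages.
  `eps_q = 0.02` gives adaptation over tens of spikes; the inhibitory set
  doubles the adaptation gain (`a_hp` 4 vs 2); FS uses a small, fast
  (`eps_q = 0.15`) `q` so adaptation is weak and settles immediately.
* **EB** (three-variable): a *bistable* fast subsystem (steeper left
  `f`-branch, shallow `g` right branch) in which a stable rest focus
  coexists with the spiking cycle. Slow `q` moves the effective drive
  across the bistable window: bursts terminate when drive falls below the
  cycle fold and re-ignite when rest destabilizes, with damped subthreshold
  oscillations in between — the elliptic signature. The stimulus scaling
  `k = 0.04` places the bursting regime at stimulus values 2.75–4.25, and
  across that range spikes-per-burst grow while interburst intervals
  shrink monotonically.
* **IB / LTS** (extended four-variable): `u` relaxes toward
  `v + 1.3` and the step `eta(u)` switches the recovery rate. In IB the
  mean of `v` *falls* during tonic spiking (the undershoot dominates), so
  `u` decays from its resting value through `r_u`, dropping `eta` from 1
  to 0.25: a fast initial burst followed by roughly three-fold slower
  regular firing. In LTS the same switch is armed by hyperpolarization:
  `eta = 0.25` lowers the Hopf threshold below the standing bias
  (`I0 = 0.03`), so release from a long inhibitory input yields a
  transient rebound burst before `u` recovers; positive steps meet the
  `eta = 1` configuration and show strong adaptation.
* **PB** (four-variable, `dt` = 1 ms, `tau` scaled tenfold): repetitive
  bursting from the bistable fast subsystem with `q` as the burst-
  terminating variable and `u` a slowly varying depolarizing offset
  (`alpha_u = 4` keeps its gain small). *Known limitation:* the interburst
  dynamics are of the damped-oscillation type rather than a true parabolic
  slow wave; a genuine two-slow-variable wave was explored and abandoned
  because the linear positive feedback of `u` creates runaway or
  multistable states in this nullcline geometry.

The toy sets (`toy2var` etc., `f = v^2`, `g = 2 v^2`, unit time scales)
exist for arithmetic-level testing where hand computation is possible;
`toy2var_osc` duplicates the Class II coefficients under a neutral name for
tests that need any oscillator.

The only stochastic generator in the package is the seeded Poisson spike
train used to calibrate LV/CV. It emulates a homogeneous Poisson process
and nothing else — no refractoriness, no rate drift — so it validates the
statistics' normalization, not their behaviour on realistic irregular
trains.

## Numerical choices and degenerate inputs

* Euler step sizes default per mode (1 ms for PB, 0.1 ms otherwise) but are
  stored with the parameters and overridable, since convergence testing
  needs other values; halving `dt` halves the global error on the toy
  system (ratio asserted within [1.7, 2.3]).
* Junction continuity is asserted to 1e-12 in value (closed form) and to
  finite-difference tolerance in slope; the PLS-style reformulation of the
  right-hand sides (core functions `P1`, `L1`, `S1`, time scale
  `theta = 1/phi`, bias omitted) agrees with the direct implementation to
  1e-12 on randomized states and parameters, providing a second,
  independently written route through every equation.
* Monotonicity assertions on ISI sequences allow one grid step of slack:
  interpolated spike times carry sub-grid jitter of order 1e-6 s that is
  physically meaningless.
* Zero-length stimulus programs, a zero coefficient to decompose, a
  constant trace to `detect_spikes`, and a single-spike train to
  `segment_bursts` (with an explicit threshold) are all defined, not
  errors; statistics on fewer than two intervals, `eval_eta` outside the
  extended variant, and simulation divergence raise typed conditions.

## Problem sizes

The test-suite and the acceptance script are sized to run in minutes on one
core: simulations of 0.05–8 s at 0.1 ms steps (up to 80 000 Euler steps),
60 s at 1 ms steps for PB, an exhaustive 65 536-pair small-format
multiplication oracle, 40 randomized parameter sets for the structural
properties, and 10^5 Poisson intervals for the statistic calibration.

## Limitations

* The bundled modes are qualitative: quantitative comparison against
  ionic-conductance targets (MSE of ISI transitions or CV–LV points) is
  out of scope because those reference models are not implemented here.
* Parameter fitting is out of scope; parameters are loaded, completed and
  validated, never optimized.
* Networks, synapses, adaptive integrators and VHDL emission are out of
  scope; the hardware module predicts arithmetic structure (shift counts,
  DSP tiles, cycle budgets), not synthesized LUT/FF totals, which are
  toolchain-dependent.
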