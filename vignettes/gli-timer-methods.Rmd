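---
title: "Methods: the Gli timer model and its numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Gli timer model and its numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glitimer)
```

## The model

`glitimer` simulates a four-variable gene-regulatory timer. The Gli
activator `A` and repressor `R` decay exponentially from `A(0) = R(0) = 1`
with rates `lambda_A = lambda_R = 0.86` per day; all other dynamics hang
off this clock. Tgfβ (`T`) integrates a weighted activation by GliA, a
weighted repression by GliR and its own positive feedback; Phox2b (`P`)
is produced under GliA control and repressed by Tgfβ. Both `T` and `P`
use production/decay constants (`v_T = 50`, `v_P = 90` per day) chosen so
that their maximal steady concentration is 1 and they relax fast relative
to the Gli decay: `T` and `P` are effectively slaved to the slowly
decaying inputs, which is what makes the timer interpretable.

Links are encoded by weighted Hill functions
`Hw±(x, h, ω) = (1 − ω) + ω H±(x, h)` with Hill exponent 2. A weight of 0
makes the factor identically 1 (link absent), a weight of 1 recovers the
plain Hill function. Thresholds paired with a zero weight are unused and
may be absent; the code never reads them.

**The self-activation term.** Tgfβ production is implemented as

```
(1 − ω_TT) · Hw+(A, h_AT, ω_AT) · Hw−(R, h_RT, ω_RT)  +  ω_TT · H⁺(T_eff, h_TT)
```

i.e. the feedback weight `ω_TT` appears once, as the convex-combination
prefactor, and the feedback itself is the plain Hill function. Applying
the weight a second time inside a weighted Hill factor would add a
constant production floor `ω_TT (1 − ω_TT)` (≈ 0.056 at `ω_TT = 0.94`)
that makes the strongly self-activating configurations monostable at the
high-Tgfβ state from `t = 0` — Phox2b would then be repressed from the
start and no bistability could exist, contradicting the intended biology
of the circuit. The convex-combination form keeps total production in
`[0, 1]` (so `T` and `P` stay in `[0, 1]` under noise-free dynamics, a
property the test-suite asserts over random configurations) and vanishes
cleanly at `ω_TT = 0`.

**Effective Tgfβ input.** The right-hand side takes an explicit `T_eff`
argument used *only* in the self-activation and Phox2b-repression terms;
the linear `−T` decay always uses the cell's own `T`. Single-cell
simulations pass `T_eff = T`; the lattice module substitutes the
diffusion-averaged field. Threading one argument avoids duplicating the
equations for the spatially coupled case.

**Initial conditions.** Only `A(0) = R(0) = 1` are fixed by the
biological normalization. The package starts Tgfβ at `T(0) = 0` (the
signal is off at the start of the MN window) and Phox2b at its
quasi-steady value `Hw+(A0, h_AP) · Hw−(T0, h_TP)` (≈ 0.994 in the WT
network), reflecting the strong Phox2b expression at that stage. Because
`v_P = 90`/day, any other start would relax to this value within ~0.02
days, so the choice shifts nothing but the first few time steps; it is
exposed through `P0` for sensitivity checks.

## Integration

Deterministic trajectories use a fixed-step classical Runge–Kutta scheme
(deSolve, `method = "rk4"`) on the configured grid, `dt = 1e-3` days by
default. With `v_P = 90`/day this gives `dt·v_P = 0.09`, comfortably
stable; halving `dt` moves trajectories by less than `1e-6` (asserted in
the tests).

Stochastic paths use fixed-step Euler–Maruyama for
`dx = f(x) dt + ε x dW`, one independent Wiener increment per variable,
at the same `dt`. When `correlated_AR = TRUE`, GliR receives GliA's
increment, making `A(t) = R(t)` exactly when rates and initial values
match. The engine always *draws* all four streams so that correlated and
uncorrelated runs from the same seed share identical randomness in `T`
and `P`, which makes paired-seed comparisons exact in the common noise.
States are clipped at 0 after each step: zero is absorbing for the exact
multiplicative-noise process, and clipping preserves that. Excursions of
`T` and `P` above 1 are possible under noise but are pulled back by the
`−v x` drift; their stationary scale is `ε/√(2v)` (≈ 0.02 at `ε = 0.2`),
which the tests bound.

A noise-free Euler path differs from the RK4 solution at order `dt`
(≲ 0.02 absolute on this system); tests compare the two at that
tolerance, and lattice-versus-single-cell identities are asserted within
the Euler scheme where they are exact.

## Noise conventions

The kinetic noise amplitude `ε` and the threshold noise `η` have no
single canonical value; figures in this literature sweep them. The
package's reference conventions are `ε = 0.1` (mid-range: visible
cell-to-cell dispersion without destroying the switch) and `η = 1`.
Sweeps (`sweep_delta_t()`) span grids around these values; the defaults
are conventions, not fitted quantities.

## The differentiation readout

A cell's likelihood of MN differentiation at Phox2b level `P` is the CDF
of a gamma-distributed threshold with shape `k = 10/η` and scale
`θ = 0.04η`: the mean threshold is `kθ = 0.4` for every `η` while the
variance `kθ² = 0.016η` grows linearly, so `η` tunes readout noisiness
without moving the average threshold. The CDF is evaluated with the
regularized lower incomplete gamma function (`stats::pgamma`).

For ensembles and lattices the **population likelihood** is the mean of
per-replicate likelihoods at each time (nonlinearity first, averaging
second), preserving cell-to-cell variability; the alternative
`method = "mean_path"` (likelihood of the mean Phox2b path) is exposed
for comparison. Per-cell statistics (`cell_switch_times()`,
`replicate_switch_times()`) apply the readout to each path individually.

Switch statistics use the *last* downward crossing of 0.95 and the
*first* downward crossing of 0.05 — the widest, most conservative
transition interval when noise makes the curve non-monotone — with
linear interpolation between grid points. Curves that never rise above
0.95 are flagged `no_mn_phase`; curves that never fall below 0.05 are
flagged `no_switch` and reported as censored, never dropped. (The
constitutive-GliA mutant is the designed example of the latter; less
obviously, the hysteresis-only network at `η = 4` is also censored,
because its post-switch Phox2b level ≈ 0.11 still sits above the 5th
percentile of so wide a threshold distribution.)

## Bifurcation analysis

`t_steady_states()` freezes `A` and `R` and finds all roots of the Tgfβ
balance in `[0, 1]` by sign-change scanning on a fine grid (default 10⁴
points; the sweep uses 4·10³) followed by bisection to `1e-10`;
stability follows the sign of the derivative. Brute force is cheap for a
one-dimensional problem and doubles as an independent oracle in the test
suite, which also cross-checks stability by forward integration from
perturbed initial values. Fold points are refined by bisection on the
root count; the tests assert the locations are invariant under doubling
of the scan resolution.

For diagrams versus GliR the frozen GliA follows an explicit policy:
`"off"` (A = 0) for the reduced networks, whose GliA→Tgfβ link is absent
anyway, and `"parallel"` (A = R) for the full network, mirroring the
parallel decay of the two gradients.

A finding worth stating plainly: with the published parameters
(`ω_TT = 0.94`, `h_TT = 0.3`, `h_RT = 0.2`), the hysteretic configuration
is bistable for all GliR above the up-fold at `R ≈ 0.240`, and the
high-Tgfβ branch satisfies the fold condition only at negative
production — it persists for *every* GliR ≥ 0. The switch is therefore
strictly one-way: once jumped, no restoration of GliR can revert it.
`sweep_bifurcation()` reports this as a return fold at `Inf` with a
`one_way` flag rather than inventing a finite second fold. The weak
self-activation row (`ω_TT = 0.4`) has a maximal feedback slope below 1
and can never fold; the scan finds a single branch everywhere.

## The lattice

"Nearest neighbours" is read as the von Neumann 4-neighbourhood on a
square grid with periodic boundaries; a Moore (8-cell) option and a
radius-2 shell are exposed, and the tests assert that widening the range
changes the population transition interval only mildly. The effective
input is `0.5·T + 0.5·⟨T⟩_nn`; symmetric averaging with periodic
boundaries conserves the spatial mean exactly.

The default analysis grid is 20 × 20 cells. The averaging mechanism is
local and grid-size-insensitive, so this desk-scale default captures the
synchronization phenomenology; larger grids (e.g. 100 × 100) are
available directly through `rows`/`cols`, with a guard at 2.5·10⁵ cells.
Per-cell initial conditions are uniform — heterogeneity enters only
through the independent kinetic noise of each cell.

## Sweeps, scenario panels, and the correlated-noise comparison

Scenario sweeps default to ensembles of ~10³ replicates (or a 20 × 20
lattice when spatial averaging is on); these sizes put Monte-Carlo error
well below the effect sizes the package asserts while keeping every
analysis runnable on a laptop in minutes. Seeds are explicit everywhere;
paired comparisons (coupling on/off, correlated/uncorrelated) reuse the
same base seed so the contrast is taken within a common noise
realization.

The correlated-versus-uncorrelated GliA/GliR comparison deserves its
footnote. Run on the full network with spatial averaging (the setting in
which the GliA link is analysed on top of the coupled lattice), two
robust effects appear, and both are asserted in the acceptance tests:
the collective switch comes consistently *later* under correlated noise
— with `A = R`, downward Gli excursions lower `H⁺(A)` exactly when they
raise `H⁻(R)`, and this negative covariance depresses mean Tgfβ
production, delaying the collective jump — and no cell's own transition
through the threshold distribution becomes faster (per-cell Δt is not
reduced). Under the *population*-window convention, correlation does
additionally narrow the collective window somewhat, because identical
noise streams synchronize replicates; without spatial averaging this
synchronization effect dominates and the population window narrows
markedly. Both conventions are computable from the same objects
(`switch_statistics()` on the population likelihood versus
`cell_switch_times()`/`replicate_switch_times()`); the package default
for Δt remains the population convention.

One scaling subtlety: the switch time of the *direct* GliA→Phox2b chain
scales exactly as `1/λ`, because the whole trajectory is a function of
`λt`. For the Tgfβ-relaying networks the switch rides the passage
through the fold, whose dynamic delay scales more weakly than `1/λ`
(finite `v_T`), so doubling the decay rate halves the wild-type switch
time only to within ~11%. The tests assert exact scaling where it is
exact and approximate scaling where it is approximate.

## The synthetic expression generator

The gene-screen filters consume per-gene summary tables — FPKM per time
point, pairwise log2 fold-changes, p-values, biotype — exactly as a
differential-expression pipeline (e.g. limma/voom) would emit them; the
package deliberately computes none of those quantities itself. The
generator plants seven gene classes around noiseless log2-FPKM template
curves: two biphasic classes engineered to satisfy every peak-rule
inequality with ≥ 0.08 log2 margin, monotone and flat negatives, and two
decoy classes that each violate *exactly one* printed rule (biotype, or
the SAG-versus-cyclopamine fold-change gate). Observed values add
log-normal noise (`noise_sd = 0.1` by default, a moderate
between-replicate spread); p-values are small (≤ 0.01) for template
contrasts that truly change and uniform otherwise.

What passing tests show: at zero noise both filters recover the planted
labels exactly, each decoy is rejected and is admitted when its one rule
is relaxed (`relax =`), and the down-regulated filter is monotone in its
fold-change cutoff and idempotent. What they do not show: performance on
real RNA-seq summaries, whose fold-change/p-value correlation structure,
dispersion heterogeneity and biotype composition the simple template
model does not emulate, and the generator makes no attempt to reproduce
published gene counts, which depend on data that are not deposited. The
`lfc(2DDC − 1DDC) ≥ 0` condition inside the peak-at-3.5 rule constrains
the 2-DDC point and looks like a transcription quirk of the published
rule set; it is implemented verbatim and can be disabled via
`relax = "peak3p5_up_2_1"`.

## Known limitations

* The SDE scheme is fixed-step Euler–Maruyama; no higher-order or
  adaptive stochastic integrators, which is standard practice for scalar
  multiplicative noise at this step size.
* No parameter inference from data: the parameterization is taken as
  given, and the package performs no fitting.
* The lattice is discrete and algebraic (neighbour averaging), not a
  continuous reaction–diffusion solver.
* Mechanisms upstream of the Gli gradients (Shh ligand dynamics, Ptch1
  feedback, Smo trafficking) are outside the model's scope.
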