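---
title: "The AC-DC motif: model, analysis and numerical methods"
author: "acdcmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The AC-DC motif: model, analysis and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acdcmotif)
```

## The model

Ventral neural tube progenitors read the Sonic Hedgehog gradient through
Gli transcriptional activity (the scalar input `S` here) and resolve it
into discrete transcription-factor codes: Pax6 (`P`) at low signal, Olig2
(`O`) at intermediate signal, Nkx2.2 (`N`) at high signal. The three
factors form a cross-repressive circuit: N and P repress each other, N and
O repress each other, and O represses P; S induces O and N with a shared
half-maximal level (`S_half`, default 1, which simply fixes the signal
units). Induction is Michaelis-Menten, `d(S) = S/(S_half + S)`; adding
cooperativity to the induction changes little, so it is not a parameter
here.

The dynamical system for the concentrations `(P, O, N)` is

```
dP/dt = alpha / (1 + (N/N_crit)^h1 + (O/O_crit)^h2) - k1 P
dO/dt = beta  * d(S) * rho_NO(N)                    - k2 O
dN/dt = gamma * d(S) * rho_PN(P) * rho_ON(O)        - k3 N
```

The repressions of P are graded Hill functions, because Pax6 levels are
observed to fall off gradually; the repressions acting on O and N are
experimentally close to all-or-nothing, and the package offers them in two
variants:

* **threshold mode** — Heaviside steps, `rho(x) = H(crit - x)` with the
  convention `H(0) = 1` (a repressor exactly at its critical level still
  permits production). This is a piecewise-smooth (Glass-type) system whose
  steady states are available in closed form.
* **graded mode** — Hill functions with coefficients `h3` (P on N), `h4`
  (N on O), `h5` (O on N). As these coefficients grow, the graded model
  converges to the threshold model.

All quantities are dimensionless; the presets set `k1 = k2 = k3 = 1`, which
makes one time unit the protein half-life scale and the saturated levels
`P_max = alpha/k1`, `O_max = beta/k2`, `N_max = gamma/k3`.

### The form of the double repression on P

With two repressors acting on one promoter there are two standard
single-denominator choices: a *product* of independent Hill repressors, or
a shared *additive* denominator `1/(1 + (N/N_crit)^h1 + (O/O_crit)^h2)`
(competitive repression). The two forms agree whenever one repressor is
absent, hence on the N-absent and O-absent steady-state branches and in
every existence criterion built from them; they differ only on the
co-expressed branch and in the transient/oscillatory dynamics. This package
uses the additive form by default (`p_repression = "additive"`) because it
is the form under which the graded model with `h3 = h4 = h5 = 5` shows its
documented oscillation windows in *both* preset variants (`fig5a`,
`fig5b`), including a bounded window for `fig5b` with `S = 5` inside it; in
tests under the product form the `fig5a` system has a stable fixed point at
every signal level. The product form remains available as an option flag.

## Analytic structure of the threshold model

With Heaviside repressions, every steady state falls on one of three
branches, parameterised by the drive `d = d(S)`:

* **B1** (N absent): `O = O_max d`, `P = P_max / (1 + (O/O_crit)^h2)`;
* **B2** (O absent): `N = N_max d`, `P = P_max / (1 + (N/N_crit)^h1)`;
* **B3** (co-expressed): `O = O_max d`, `N = N_max d`, P under both
  repressors.

Existence is self-consistency with the assumed switch configuration
(`branch_exists()`); where a branch exists, the Jacobian of the smooth
piece is triangular with eigenvalues `(-k1, -k2, -k3)`, so every existing
branch is a stable node — the threshold model has no damped oscillations.
B2 and B3 can never coexist (same N value, complementary `N_crit1`
requirements), and once B2 exists it persists for all larger S.

Because every branch value is monotone in `d`, each transition point is the
exact inverse image of a threshold crossing: `S = S_half d/(1-d)` evaluated
at, e.g., the drive where B1's P component reaches `P_crit1`. The only
transition without an algebraic closed form is the onset of B3 under the
additive double repression; it is computed by `uniroot` on a strictly
monotone function to `1e-14` tolerance, which is exact for all practical
purposes.

`validity_conditions()` collects the constraints that make the circuit a
morphogen interpreter (N silent at zero signal, B1 eventually lost, B2
reachable and self-maintaining, O never repressing N — the latter needed
only because repression here is all-or-nothing). Within valid parameters,
the adiabatic route as S rises is either `B1 -> B2` (route 1) or
`B1 -> B3 -> B2` (route 2), and the transition into B2 either overlaps the
previous branch (bistability, hysteresis) or leaves a **gap** with no
stable steady state, where the system cycles N high, P high, O high. That
yields four regimes (`classify_regime()`): direct switch, switch through
co-expression, and each of these with an oscillatory window. For
`h1 = h2`, the route-1 gap criterion reduces to
`N_max/N_crit < O_max/O_crit` — oscillation when O's repression of P beats
N's — and the route-2 criterion is
`P_max/P_crit1 > 1 + (N_crit1/N_crit)^h1`. Setting `O_crit1` arbitrarily
large changes none of the criteria: the circuit minus the O-on-N edge (the
AC-DC motif proper) controls the qualitative dynamics.

## Numerical methods

**Integration.** The threshold vector field is discontinuous across the
switching surfaces, so `integrate_circuit()` integrates segment by segment:
the switch configuration is frozen, `deSolve::lsodar` locates the first
threshold crossing as a root, and integration restarts there with the
configuration re-evaluated and the state nudged off the surface along the
new field (crossings are transversal in this circuit — no switching
variable feeds back instantaneously on itself, so there are no sliding
modes). Between events the O and N sub-dynamics are linear, and the test
suite checks them against their exponential closed forms at `1e-8`.
Convergence to steady state is itself a root (`stop_at_steady`), so runs
end as soon as the RHS norm falls below `ss_tol` (default `1e-9`).

**Attractor detection** (`detect_attractor()`): a trajectory is a fixed
point when the terminal RHS max-norm is below `tol_ss = 1e-8` and the
relative amplitude over the analysis window (the second half of the run)
is below `tol_amp = 1e-3`; a limit cycle when successive periods — taken
from recorded event times in threshold mode, which is exact, or from
quadratically refined peaks in graded mode — agree within
`tol_per = 0.5%`; a damped oscillation when a fixed point is approached
through at least three decaying extrema. Anything else is reported as
`undecided`, never silently coerced. The tolerance defaults are the
package's own choices; they are loose enough to be insensitive to solver
error (`rtol 1e-9`, `atol 1e-11` by default) and tight enough to separate
cycles from transients at the presets' time scales.

**Bifurcation scans** (`scan_bifurcation()`) integrate each point of an
increasing signal grid (default 201 points on [0, 10]; the acceptance
checks use 101, which resolves every preset's window comfortably) to
`t = 500` from the pre-signal state `(P_max, 0, 0)` and tabulate the O
steady value or cycle extrema — the data behind the model's bifurcation
diagrams. In graded mode, `find_fixed_points()` locates *all* roots by
multi-start damped Newton on the reduced `(O, N)` system (P is explicit at
steady state), annotates them with full-Jacobian eigenvalues, and exposes
the unstable focus that accompanies each oscillatory window.

**Hysteresis sweeps** (`sweep_hysteresis()`) carry the converged state up
and then down a uniform signal grid and report branch changes; the up- and
down-transitions bracket the analytic boundaries within one grid step.

**Simulated regime classification** (`simulate_regime()`) is the
simulation-side oracle for `classify_regime()`. It sweeps the *drive*
uniformly (100 steps on [0.005, 0.995]) rather than the signal — every
transition depends on S only through `d(S)`, so a uniform drive grid
resolves high-signal transitions that a uniform S grid compresses — and
classifies each converged state by which induced genes are expressed. Two
refinements matter:

* *Coexisting cycles.* The threshold model can sustain a limit cycle even
  where a stable steady state exists; an adiabatic path that falls off B1
  can be trapped by it. Since the regime definitions concern the existence
  structure, an oscillating sweep step only counts as a gap after basin
  probing: the classifier also integrates from three saturated corner
  states, and if any of them converges a stable state exists and the step
  is labelled a coexisting cycle instead.
* *Thin windows.* A co-expressed window or gap narrower than the drive
  step would be skipped, so every direct steady-to-B2 jump is re-swept on
  a 20x finer local grid.

## The parameter sampler and the census

`sample_parameters()` draws production rates and thresholds log-uniformly
on [0.1, 10] (a range that brackets all shipped presets), a shared integer
Hill coefficient `h1 = h2` from 1-5, fixes `k_i = 1` and `S_half = 1`, and
rejects sets failing `validity_conditions()`. `run_census()` classifies
each draw with both classifiers; all four regimes appear in a few hundred
draws and the two classifiers agree on essentially all of them, with the
rare disagreements sitting at regime boundaries where a window is
comparable to the grid resolution.

## Spatial patterning

`simulate_gradient()` runs independent cells (no coupling, no gradient
formation — the profile is an input) from the pre-signal state across an
exponential or linear signal profile. `label_domains()` uses the threshold
model's Boolean structure by default: an induced gene is ON above
`on_tol = 1%` of its own maximum (silenced genes decay to exactly zero in
threshold mode, so this is robust); two or more induced genes ON is the
co-expressed state; a single ON gene is compared with the constitutive gene
on each gene's own normalized scale — level over saturated level — so that
a weakly scaled induced gene is not drowned out by residual constitutive
expression; oscillating cells are their own label. An alternative
rule — label by arg-max with "coexpressed" when the top two are
within a factor `r = 2` — is available as `rule = "ratio"`, but it
mislabels *graded* co-expression (two genes ON at a constant ratio set by
their production rates) as a single-gene domain, which misrepresents the
symmetric three-gene topology: that circuit's middle band expresses both
induced genes, and counting it as a third single-gene domain would
contradict what the circuit can actually encode. With the ON/OFF rule, the
symmetric topology never exceeds two single-gene domains, while the AC-DC
topology gives three for valid, gap-free parameters whose transitions fall
inside the gradient — the design argument for the motif.

The four-stripe demonstration circuit (`multigene_circuit(4)`) extends the
motif with a fourth gene Q repressing P, O and N and repressed by P. Its
constants are a package choice (no reference values exist): production 5
and decay 1 for P, O, N as in the three-gene presets; Q at production 2.5,
decay 0.5 — the same saturated level but a 2x slower response — with
graded repressions of P at half-max 1 (O), 0.9 (N), 0.5 (Q), all with
Hill coefficient 2, P thresholds 0.5 on N and 0.25 on Q, and thresholds 2
for N's repressions and 3 for Q's. The slower Q and higher Q thresholds
keep Q's transient excursions during the O-to-N handover subcritical (a
fast Q would capture cells during the brief dip of P below 0.25), while
the steady-state stripe boundaries, S near 0.45 / 1.5 / 3.6 with
consecutive ratios above 2, are set by the graded thresholds alone. Only
the stripe count and order are asserted about this demo.

## Problem sizes and reproducibility

The shipped checks use: 201-point scans for figures and 101-point scans in
acceptance tests; 500 sampled parameter sets for the census (about five
minutes); 100 sets for the symmetric-topology comparison; 100-cell
gradients; 200 random (parameter, signal) pairs for the
branch-versus-integration equivalence at `1e-6`. All randomness flows
through explicit seeds, so every experiment is reproducible bit for bit.

## Known limitations

The model ignores transcriptional noise, time delays, cell-cell coupling
and gradient formation by design; nothing here says how robust the regimes
are to fluctuations. The synthetic parameter sampler matches the printed
presets' scales but real kinetic constants are unknown, so census
fractions describe the sampler's measure, not biology. The threshold model
is a limit: with weak (low-Hill) repression the graded model moves
transitions to higher signal and reshapes oscillation windows, as the
`fig4*`/`fig5*` presets show, so quantitative conclusions should use the
graded variant with measured sharpness. Domain labelling of graded-mode
patterns uses the same 1% ON rule, which is a convention rather than a
derived quantity.
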