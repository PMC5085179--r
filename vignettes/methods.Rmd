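---
title: "Critical-dose sensitivity analysis of a TNF-alpha survival/apoptosis switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical-dose sensitivity analysis of a TNF-alpha survival/apoptosis switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and the protocol

`tnfswitch` analyses mass-action reaction networks of the TNF-alpha
cell-fate decision.  A network is a set of species amounts
$C_1,\dots,C_n$ (amol) coupled through irreversible reactions with rates

$$J_B = k_B \prod_{r \in \mathrm{reactants}(B)} C_r^{\,\nu_{rB}^-},$$

so that $\dot C_A = \sum_B \nu_{AB} J_B$, with $\nu$ the stoichiometric
matrix.  TNF-alpha is a clamped input: its derivative is forced to zero,
which models a sustained stimulus.  Transient-stimulus protocols are out
of scope.

The analysis pipeline has four layers:

1. **Dose response.** For each dose the system is integrated from the
   common resting state until the relative derivative
   $\max_A |\dot C_A|/(1+|C_A|)$ stays below `ss_tol` (default 1e-9)
   both at the end of the current integration chunk and at a checkpoint
   5% earlier, or until `t_max` (48 simulated hours — the dynamics of
   interest settle within hours).  The executioner caspase's steady
   state against dose forms an all-or-none curve; the *critical dose*
   `Cd` is where it jumps from the low (survival) branch to the high
   (apoptosis) branch.  `find_critical_dose()` brackets the jump on a
   geometric coarse grid and bisects a midpoint fate classifier down to
   `tol` (default `dose_max/2000`); `critical_dose_grid()` is the
   brute-force uniform-grid reference.  The dose cap `dose_max` defaults
   to 1e-2 amol, the in-vitro-equivalent stimulation range.
2. **Sensitivity.** Every rate constant is varied by ±20%
   (`perturb_fraction`), the critical dose recomputed in both
   directions, and the recorded increase
   $\Delta Cd = \max(0, \max(Cd_{+}, Cd_{-}) - Cd)$ makes a parameter
   *sensitive* when $\Delta Cd \ge 10\%\cdot Cd$ (`sensitive_cutoff`).
   A perturbation that abolishes apoptosis within `dose_max` is an
   infinite shift, hence sensitive: losing the switch entirely is the
   extreme threshold increase.  If neither direction increases the
   critical dose, $\Delta Cd = 0$: only increases are recorded, because
   the question is which parameter changes enlarge the survival region.
   `cutoff_roc()` sweeps the cutoff and reports Youden's
   $J = TPR - FPR$ against any Boolean reference labelling, with ties
   broken toward the smaller cutoff.
3. **Spectra.** Per-gene somatic point-mutation counts (missense,
   synonymous, nonsense) are binarized at $\ge 1$ mutated sample, or
   combined — two types: mutated if at least one type is; three types:
   mutated if at least two are (the at-least-one variant is selectable).
   Gene bits are projected onto parameter order through an editable
   gene-to-parameter map; production-process parameters are excluded
   from the map (they correspond to gene amplification/deletion rather
   than point mutation) and are removed from *both* spectra before
   comparison, keeping lengths equal.  Agreement is the Hamming
   distance over identically ordered ids; misaligned ids are an error,
   never silently reindexed.
4. **Feedback screening.** A candidate caspase-on-NFkB interaction is
   injected as an extra rate term: positive, $+k_{pos}[\mathrm{casp}]$
   (production); negative, $-k_{neg}[\mathrm{casp}][\mathrm{NFkB}]$
   (bimolecular degradation).  The admissible strength range keeps the
   perturbed phenotype within 20% of baseline: the bounded phenotype is
   the initial death time for negative loops (they accelerate death) and
   the executioner plateau for positive loops (they depress it), scanned
   on a log grid at 5 points per decade and reported as the maximal
   contiguous prefix.  `hd_strength_scan()` then rebuilds the full
   sensitivity spectrum at each strength and tracks the Hamming distance
   to a mutation spectrum; a strength whose spectrum agrees better than
   the base model's supports the candidate interaction.

## Numerical choices

* Integration is `deSolve::lsoda` with `rtol = 1e-8`,
  `atol = 1e-12` amol; amounts are clipped at zero below solver noise
  and a state more negative than `-10*rtol` is an error.  The rate
  kernel is evaluated in log space, which is exact for zero amounts
  because a positive stoichiometric power of an (underflowed) zero
  amount underflows to zero.
* Steady states integrate in doubling chunks (first chunk 1800 s) so
  cheap doses converge quickly and stiff ones get geometrically longer
  horizons; non-convergence at `t_max` is a flagged result, not an
  exception, and flagged points are excluded from plateau estimation.
* The all-or-none switch is detected on an ordered steady-state
  sequence as a consecutive jump that both exceeds a 4x ratio and
  carries at least 25% of the curve's total range.  The two conditions
  are deliberately conjunctive: a ratio alone misfires when the resting
  branch sits near zero, a range fraction alone misfires on smooth
  growth along a geometric dose grid.
* Fate classification uses the midpoint of the two plateaus (medians of
  the three lowest-dose and three highest apoptotic-dose points); a
  steady state exactly at the midpoint classifies as apoptosis.  The
  midpoint rule is robust to plateau drift and configurable.  Steady
  states are always computed from the same resting initial condition —
  one steady-state curve, not a hysteresis sweep, which the protocol
  never requires.
* The death time is the first crossing of half the final executioner
  level at a supra-critical probe dose (default 1e-2 amol), linearly
  interpolated inside one reporting step.  Across a strength scan every
  model is timed against the *base* model's half-level: feedback shifts
  the plateau itself, and timing each model against its own plateau
  would confound faster dynamics with a moved target.
* Critical-dose results are cached by (network hash, `dose_max`, `tol`),
  which makes spectrum builds over many parameters and strength scans
  tractable; `clear_cd_cache()` empties the cache.

## The reduced network and what it does (not) show

The bundled toy (`make_toy_network()`) is a 13-species, 30-reaction
caricature of the full published 47-species TNF-alpha network: clamped
TNF binds a turned-over receptor into a Complex I analog, which both
activates NFkB (inducing an anti-apoptotic FLIP/XIAP-like inhibitor)
and converts to a Complex II analog that activates the initiator
caspase; the initiator activates the executioner, and a bimolecular
executioner self-amplification step (`2 casp3 + pro3 -> 3 casp3`)
supplies the bistability that makes the steady-state response
all-or-none.  The full model achieves its switch through its own
structure; any switch-generating motif suffices to exercise the
protocol, which is what the toy is for.

Designed guarantees at the default rates, each verified by the
dense-grid oracle during generator design and re-checked by the test
suite: survival at dose 0; a critical dose near 4e-3 amol inside
(0, 1e-2) amol; a right-shifted critical dose when the caspase-production
analog `kp_c8` is scaled by 0.8 and loss of apoptosis at 0.6; ground
truth sensitivity labels for all 30 parameters (shipped as
`attr(net, "truth")`); a decoy species and two downstream-only caspase6
parameters that are fully decoupled from the fate readout; and three
deliberately minor parallel routes (`ka_c1c2b`, `ka_c8b`, `ka_c3b`,
each 5% of its main route) that are individually weak but whose joint
perturbation accumulates a visible critical-dose shift.  The 5% share
keeps their relative critical-dose shifts clear of the 10% label cutoff
across the whole jitter envelope, where the dose-response slope — and
with it the amplification of a given rate change into a critical-dose
shift — varies with where the jittered critical dose lands.

Random re-parameterizations multiply every rate constant by an
independent log-uniform factor within ±1% (`jitter`).  The envelope is
deliberately narrow: the switch lives in a small operating window, and
the shallow dose-response slope amplifies parameter changes into large
critical-dose shifts — wide joint jitter of 30 constants walks the
critical dose out of the dose range or across the 10% label cutoff.
Every generated instance is validated (switch present; for the
unmodified default, also the 0.6x abolition); a configuration that
breaks the switch errors at generation rather than returning a silently
monostable model.

The synthetic mutation generator emulates only the statistical link the
correlation analysis needs: one gene per non-excluded parameter whose
per-type mutation bit equals the parameter's sensitivity bit with
probability `concordance`, independently across genes and types, so the
expected Hamming distance is exactly $n(1-p)$.  Count magnitudes are
cosmetic (binarization at $\ge 1$ erases them).  It does *not* emulate
mutational signatures, gene length effects, hotspots, shared samples
across genes, or COSMIC's sampling structure — passing tests show the
pipeline recovers planted statistical structure, not that real cancer
spectra behave this way.

## Design choices where the protocol was open

* **Joint perturbations** reuse each parameter's own single-parameter
  critical-dose-increasing direction at the same ±20% magnitude; the
  published worked example states neither directions nor magnitudes, so
  the single-parameter protocol is carried over unchanged.
* **Feedback terms vs reactions.** Injected terms live outside the
  reaction list (`evaluate_rates()` never sees them; the derivative adds
  them), but export materializes them as ordinary mass-action reactions
  — catalytic production `src -> src + tgt`, bimolecular degradation
  `src + tgt -> src` — so written SBML/TSV files are self-contained.
* **Strength grids.** Ranges are reported as single intervals via the
  contiguous-prefix rule on a log grid; scans beyond the calibrated
  range are supported (the screening question sometimes needs them) and
  simply recorded.
* **Parameter identities** are opaque strings taken from the loaded
  model; the source literature is internally inconsistent about a few
  names (e.g. one rate appears as both `ka_68` and `ka_86`), so nothing
  is inferred from an id's spelling.
* **SBML scope.** The loader accepts only kinetic laws that are exactly
  `k * prod(reactant^stoichiometry)`; anything else is rejected naming
  the reaction.  Local parameters are promoted to the global table with
  a reaction-scoped prefix.  Declared substance units are recorded in
  the manifest, not interpreted.
* **Key-species roles** (`tnf_input`, `complex1`, ..., `caspase6_active`)
  are supplied by the caller for foreign SBML files — species naming in
  deposited models cannot be assumed — and are fixed by construction for
  the toy.

## Problem sizes

The shipped tests and the acceptance script run entirely on the toy
network: bisection against a 4000-point uniform-grid oracle; five
re-parameterized instances for label recovery (30 parameters, two
directions each); 100–120 seeds for the Hamming calibration at
$n = 106$ genes; strength calibration at 5 points per decade over 3–4
decades; and three planted-feedback instances scanned over
$10^{-2}\dots10^{1}$ in decade steps.  A full 106-parameter spectrum of
the published model (two critical-dose searches per parameter) is the
same code path and is cached by model hash; it is minutes-to-hours
work on one CPU depending on solver tolerances.

## Known limitations

* Only mass-action kinetics; no SBML rules, events, assignments,
  Michaelis–Menten laws, or stochastic/spatial simulation.
* Fate is read from one executioner species against two plateaus; a
  model without a clean all-or-none switch is reported as
  `apoptosis_achievable = FALSE` rather than analysed further.
* Hysteresis is not probed: each dose starts from the resting state.
* The toy's shallow dose-response slope — needed for the
  0.6x-abolition regime — makes most pathway parameters sensitive;
  insensitive labels come from decoupled species and the minor parallel
  routes.  That asymmetry is a property of this reduced model, not of
  the method.

## A worked run

```{r, eval = FALSE}
library(tnfswitch)
net <- make_toy_network()
find_critical_dose(net)
spec <- build_spectrum(net)
syn <- make_synthetic_mutations(
  as_boolean_spectrum(spec)[setdiff(spec$parameter_ids,
                                    production_parameters(net))],
  concordance = 0.9, seed = 1)
hamming(project_to_parameters(combine_mutations(syn$table), syn$map,
                              spec$parameter_ids),
        as_boolean_spectrum(spec)[syn$map$entries$parameter_id])
```
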