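---
title: "The Cyp33/MLL1/H3K4me3 switch: model, assays, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Cyp33/MLL1/H3K4me3 switch: model, assays, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyp33switch)
```

## The biological system

MLL1 keeps its target genes transcriptionally active in part by holding on to
the H3K4me3 mark through its PHD3-BRD reader module. Cyclophilin 33 binds the
same PHD3 surface with its RRM domain, and regulatory RNA binds that RRM on
the surface PHD3 uses — so RNA, MLL1 and Cyp33 form a chain of mutually
exclusive contacts. The package models the hypothesis that transcription of
Cyp33-binding RNAs flips chromatin from an active state (mark held by MLL1)
to a repressive one (mark free or RNA-bound, exposed to erasers), and that
*both* RNA and Cyp33 are needed to flip it.

## Species and reactions

Four monomers — `M` (MLL1 PHD3-BRD), `H` (H3K4me3 tail), `C` (Cyp33), `R`
(one RNA site) — and five complexes (`MH`, `CM`, `CMH`, `CR`, `RH`) interact
through six reversible mass-action reactions:

| reaction        | Kd (uM) | origin                          |
|-----------------|---------|---------------------------------|
| M + H <-> MH    | 4       | measured (reader on the mark)   |
| C + M <-> CM    | 4.6     | measured                        |
| CM + H <-> CMH  | 70      | measured                        |
| C + R <-> CR    | 300     | measured (wild type, one motif) |
| R + H <-> RH    | 30      | measured                        |
| C + MH <-> CMH  | 80.5    | derived by detailed balance     |

Two structural facts shape the species list: no `C.R.H` or `C.R.M` ternaries
exist (RNA and protein partners compete for the same surfaces), and RNA is
treated as carrying a single H3K4me3 site — the conservative choice when the
true transcript carries several motifs and gains avidity.

The model deliberately omits explicit cis/trans conformers of the MLL1
reader and the catalytic isomerisation step that interconverts them: the
4 uM `M:H` constant describes the intact reader, and Cyp33 binding events
implicitly include the conformational work, whose microscopic rates are not
separately constrained by the available measurements. The consequences of
this choice are discussed under *Limitations*.

### Detailed balance

The four states M, MH, CM, CMH form a thermodynamic cycle, so only three of
its four edges are independent. The package never lets the fourth edge be
set: `C:MH` is always recomputed as `Kd(C:M) * Kd(CM:H) / Kd(M:H)` (80.5 uM
from the defaults), and [scan_kd()] and the CLI `--override` flag refuse it.
This makes silent thermodynamic inconsistency unrepresentable rather than
merely checked.

### Kinetic parameterisation

Equilibrium constants alone do not fix dynamics. Every association is
assigned the same diffusion-limited on-rate, `kon_default` = 10 uM^-1 s^-1
(1e7 M^-1 s^-1, a standard protein-association estimate), and off-rates
follow as `koff = kon * Kd`, spanning 40 to 3000 s^-1 across the network.
Because all binding steps are fast on the minutes time scale of the
transcription pulse, the simulated system stays near quasi-equilibrium
throughout, and conclusions depend on the measured constants, not on the
assumed on-rate. Units are fixed package-wide: uM, seconds, uM^-1 s^-1.

Censored constants (the triple mutant's RNA affinity, stored as a lower
bound of 10000 uM) are refused by every kinetic conversion: a bound is not a
point estimate.

## Equilibrium solver

[equilibrate()] solves the competitive equilibrium algebraically rather than
by long integration: damped fixed-point iteration (damping 0.5, cap 1e5
iterations) on the free monomer concentrations, with complexes reconstructed
from overall formation constants, and a Newton fallback on log free
concentrations if the fixed point stalls. Computing complexes from formation
constants makes every reaction's net flux vanish to rounding at the
solution, so detailed balance holds to ~1e-12 uM/s rather than to a loose
numerical tolerance. The solver requires conservation to close to 1e-6
relative and errors otherwise. The test suite cross-checks it against stiff
integration of the ODE to t = 1e4 s (agreement to 1e-4 uM per species) and
against the closed-form single-site quadratic on every two-species
subnetwork.

Integration uses `deSolve::lsoda` with relative tolerance 1e-8 and absolute
tolerance 1e-10 uM; species ordering is lexicographic so stoichiometry
matrices and CSV outputs are reproducible.

## The transcription pulse

[transcription_pulse_scenario()] encodes the reference experiment: MLL1 and
the histone mark equilibrated at 100 uM each (81.90 uM bound, the single-site
quadratic), transcription switched on at t = 336 s, off at t = 1320 s. While
on, RNA and Cyp33 are synthesised at constant rates and their free forms
decay at kdeg = 0.005 s^-1; synthesis rates are solved numerically
(fixed-point rescaling over repeated integrations) so each total peaks at
100 uM at switch-off. Decay acts on free monomer only — complexes release
partners by mass action before removal — because no complex-degradation
channel is part of the model. Only the peak and the event times are
constrained; any (ksyn, kdeg) pair matching the peak gives the same
qualitative three-phase shape, and 0.005 s^-1 is a typical nuclear transcript
half-life scale (~2.3 min).

[classify_state()] partitions the H pool: active = `MH` + `CMH` (mark held
by MLL1), repressive = `H` + `RH` (mark exposed). The partition is exhaustive
by construction and errors on unclassified H-containing species. "Plateau"
readings are taken at switch-off, the point of maximal loading.

Single-component controls ([control_scenarios()]) reuse the two-component
calibrated rates with one synthesis switched off, so the comparison isolates
the presence of a component, not its dose. At the defaults the plateau
partitions are: both components 55.0/45.0 repressive/active; RNA only
31.4/68.6; Cyp33 only 40.2/59.8 — both are required to tip the balance, and
either alone leaves the active state in charge.

## Limitations of the minimal network

Weakening the RNA-H3K4me3 constant degrades repression monotonically (the
scan tests assert this). At the default constants the repressive state keeps
its slight majority only while Kd(R:H) stays below about 60 uM (the balance
is essentially even there, 49.8/50.2); at 500 uM this nine-species network
hands a clear majority back to the active state (40.9/59.1
repressive/active at equal 100 uM totals). Because equilibrium
populations depend only on formation constants and totals, no reconnection
of this species set can change that outcome; robustness of repression to
very weak RNA-H coupling would require mechanisms outside the minimal model
— most plausibly explicit reader conformers whose slow uncatalysed
re-isomerisation kinetically traps MLL1 in its weak-binding form while
Cyp33 is present. The corresponding acceptance expectation is left failing
rather than met by retuning constants, and the package documents the
boundary instead: the switch's robustness claim holds in this model for
moderate, not arbitrary, weakening of the RNA-histone interaction.

## Assay models

**Fast-exchange NMR titration.** Under fast exchange the observed shift is
the population-weighted average of free and bound states, so
[predict_shift()] is the single-site quadratic rescaled between the limiting
shifts. [fit_titration()] profiles (Kd, bound shift) by Levenberg-Marquardt
from a multi-start grid over Kd decades 0.1-1e5 uM, with the free shift
fixed by the zero-ligand point. Series flatter than three times the
point-scatter estimate are declared non-binding; designs that never leave
the <10% or >90% saturation window are flagged poorly identifying. One
caveat worth recording: at 100 uM protein and 300 uM Kd, even a large RNA
excess leaves binding visibly incomplete under this 1:1 model (~71% bound at
8 equivalents), so statements about "mostly bound" protein at moderate
excess require either avidity or a tighter full-length interaction; the
package does not attempt to reconcile this.

**Combined chemical shift perturbation.** [csp_combined()] uses
`sqrt(dH^2 + (0.2 dN)^2)`; 0.2 is the conventional nitrogen scaling and is
configurable.

**ITC.** [itc_heats()] implements the incremental-injection one-site model
with displacement dilution: each injection dilutes prior cell contents by
(1 - v/V0), and the heat of injection i is `V0 * dH * ([PL]_i -
[PL]_{i-1} (1 - v/V0))`. [fit_itc()] fits (n, Kd, dH) with the same
multi-start strategy, optionally discarding the routinely corrupted first
injection, and flags the constant low-confidence when the Wiseman c-value
`n [cell]/Kd` leaves [0.1, 1e4] or the linearised uncertainty rivals the
estimate. Baselines are assumed pre-subtracted.

**PPIase coupled assay.** The chymotrypsin-coupled assay consumes the trans
substrate isomer instantly, so the absorbance follows the cis pool's
pseudo-first-order decay: `signal = A_inf - dA exp(-k_obs t)` with
`k_obs = k0 + TN * [E]/[S_cis0]`. Because the reported turnover numbers come
without a Km or substrate concentration, the package *defines* TN
operationally as initial enzymatic velocity per enzyme at the assay
substrate concentration (default S_cis0 = 50 uM), and generator and fitter
share the definition so recovery is well-posed. [fit_ppiase()] fits each
curve as a single exponential, excludes curves that dip more than 20% of
their amplitude below their running maximum, and regresses k_obs on
[E]/[S_cis0] (inverse-variance weights): slope = TN, intercept = k0. The
slope is invariant to the arbitrary absorbance scale.

All fitters terminate on relative step < 1e-10 or 500 iterations and report
standard errors from the linearised covariance at the optimum.

## Synthetic data

The generators ([gen_titration()], [gen_itc()], [gen_ppiase()]) draw additive
Gaussian noise on top of the exact forward models, with defaults at
instrument scale: 0.005 ppm for shifts, 2% of the largest heat for ITC, 1%
of the curve amplitude for progress curves. Default designs mirror the
assays: 100 uM observed species titrated to 8 equivalents (40 for weak
binders), 20 x 2 uL injections into a 200 uL cell, and an enzyme grid of
5-40 nM over 50 uM cis substrate, 151 one-second time points. The default
titration shift span is 0.2 ppm, a typical amplitude for a strongly
perturbed amide followed to saturation. Identical seeds give bit-identical
data, and generation never disturbs the session RNG stream. Generator
parameters are embedded in object metadata and file comments so recovery
tests read their truth from the data, never from constants in the test.

What the generators do *not* emulate: intermediate-exchange line broadening,
baseline drift and first-injection artifacts in ITC, coupled-enzyme lag
phases, or correlated noise of any kind. Passing recovery tests therefore
demonstrates correctness of the estimators under their own assumptions, not
robustness to the full pathology of real instrument data.

## Problem sizes

The shipped tests and the acceptance script use 20 seeded replicates per
recovery estimate, 151-point progress curves, 20-injection thermograms,
10-14-point titrations, and pulse simulations of 10800 s at 1 s output
resolution (5 s where only the plateau matters); a full run completes in
well under a minute on a single core.
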