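---
title: "Model and methods: flow-limited PBPK and Cmax-based reverse dosimetry"
author: "revdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: flow-limited PBPK and Cmax-based reverse dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revdose)
```

# Scope and intended use

`revdose` is a screening-level toolkit for placing in vitro bioactivity
concentrations in an in vivo context. It does two things:

1. **Forward dosimetry.** Given a chemical's physicochemical/ADME
   parameters, a species physiology, and a dosing schedule, it integrates a
   flow-limited compartmental PBPK model and reports tissue concentration
   time-series, Cmax/Tmax, and AUC.
2. **Reverse dosimetry (IVIVE).** It normalizes in vitro AC50
   concentrations by the plasma Cmax of a unit (1 mg/kg per administration)
   dose under the same schedule, yielding equivalent administered doses
   (EADs, mg/kg/day), and divides EAD statistics by expected daily exposure
   to obtain margins of exposure (MoE) for priority ranking.

The model is deliberately generalized: it trades chemical-specific fidelity
for uniform applicability across large chemical sets, which is the standard
trade-off for screening-level PK. It is not a substitute for a calibrated,
chemical-specific PK model.

# The compartmental model

Six compartments are reported: venous plasma, arterial plasma, gut, liver,
kidney, and a lumped rest-of-body tissue; an unreported gut-lumen state
holds unabsorbed oral doses, and three ledgers accumulate eliminated
amounts (hepatic metabolism, urine, feces). All states are amounts in
µmol; concentrations are $C_x = A_x / V_x$ in µM. Tissues are
flow-limited: the venous blood leaving tissue $t$ is in equilibrium with
the tissue at $C_t / K_{p,t}$, where $K_{p,t}$ is the tissue:plasma
partition coefficient.

$$
\begin{aligned}
\dot A_{\mathrm{lumen}} &= -k_a A_{\mathrm{lumen}} \\
\dot A_{\mathrm{gut}} &= F_{\mathrm{abs}} k_a A_{\mathrm{lumen}}
  + Q_{\mathrm{gut}} (C_{\mathrm{art}} - C_{\mathrm{gut}}/K_{p,\mathrm{gut}}) \\
\dot A_{\mathrm{liv}} &= Q_{\mathrm{ha}} C_{\mathrm{art}}
  + Q_{\mathrm{gut}} C_{\mathrm{gut}}/K_{p,\mathrm{gut}}
  - (Q_{\mathrm{ha}} + Q_{\mathrm{gut}}) C_{\mathrm{liv}}/K_{p,\mathrm{liv}}
  - CL_{\mathrm{int}}^{\mathrm{whole}} f_{ub}\, C_{\mathrm{liv}}/K_{p,\mathrm{liv}} \\
\dot A_{\mathrm{kid}} &= Q_{\mathrm{kid}} (C_{\mathrm{art}} - C_{\mathrm{kid}}/K_{p,\mathrm{kid}})
  - GFR\, f_{ub}\, C_{\mathrm{kid}}/K_{p,\mathrm{kid}} \\
\dot A_{\mathrm{rest}} &= Q_{\mathrm{rest}} (C_{\mathrm{art}} - C_{\mathrm{rest}}/K_{p,\mathrm{rest}}) \\
\dot A_{\mathrm{ven}} &= (Q_{\mathrm{ha}} + Q_{\mathrm{gut}}) C_{\mathrm{liv}}/K_{p,\mathrm{liv}}
  + Q_{\mathrm{kid}} C_{\mathrm{kid}}/K_{p,\mathrm{kid}}
  + Q_{\mathrm{rest}} C_{\mathrm{rest}}/K_{p,\mathrm{rest}}
  - Q_{\mathrm{card}} C_{\mathrm{ven}} \\
\dot A_{\mathrm{art}} &= Q_{\mathrm{card}} (C_{\mathrm{ven}} - C_{\mathrm{art}})
\end{aligned}
$$

The unabsorbed fraction $(1 - F_{\mathrm{abs}}) k_a A_{\mathrm{lumen}}$
passes to the feces ledger. Oral administrations add
$\mathrm{dose} \times BW / MW \times 1000$ µmol to the gut lumen at each
administration time; IV administrations add the same amount to venous
plasma.

Modeling assumptions worth stating explicitly:

* **Flow-limited distribution** — membrane permeation is never rate
  limiting; each tissue is a single well-mixed space.
* **Well-stirred hepatic clearance on unbound drug** — metabolism removes
  $CL_{\mathrm{int}}^{\mathrm{whole}} f_{ub} C_{\mathrm{liv}}/K_{p,\mathrm{liv}}$;
  for large intrinsic clearance the systemic clearance saturates at the
  hepatic plasma flow, giving first-pass extraction of orally absorbed
  chemical. No saturable (Michaelis–Menten) kinetics.
* **Renal elimination by filtration only** — $GFR \cdot f_{ub}$ acting on
  the kidney venous-equivalent concentration; no tubular secretion or
  reabsorption.
* **The lung is lumped into the arterial leg**; the compartment set is the
  smallest that exhibits first-pass and accumulation behavior, and the
  tissue map is configuration-extensible.
* **"Plasma" means venous plasma** for Cmax and IVIVE. The blood:plasma
  ratio `rb2p` defaults to 1 so blood and plasma coincide unless
  overridden; it is stored with provenance but does not enter the
  oral-route equations.
* Everything is first order, so the model is exactly dose-linear — a
  property the test suite exploits.

# Chemical parameters

## Sources and provenance

Each parameter may arrive as a *measured* and/or a *predicted* (in silico,
e.g. QSAR) candidate. `resolve_parameters()` takes the measured value where
available and the predicted value otherwise; `rb2p` (default 1) is the only
model parameter with a hard default, and `fabs` (default 1, conservative
100% absorption) lives on the dosing schedule. Molecular weight, fraction
unbound, and intrinsic clearance are required; a chemical missing all
candidates for one of these is rejected by name. The chosen source of every
parameter is recorded and propagated into every output file, so any number
can be traced to its inputs. A Henry's law constant or other non-model
parameters are accepted and stored (schema parity with upstream QSAR
parameter suites) but do not enter the oral-route model.

## Intrinsic clearance scaling

In vitro intrinsic clearance is measured in µL/min per 10⁶ hepatocytes and
scaled to the whole organ:

$$CL_{\mathrm{int}}^{\mathrm{whole}}\ [\mathrm{L/h}] =
  CL_{\mathrm{int}} \times \mathrm{hepatocellularity} \times
  M_{\mathrm{liver}} \times 60 \times 10^{-6}$$

with defaults of 110×10⁶ cells/g and 1800 g liver (reference adult human,
both configurable through the physiology).

## Partition coefficients

The spread of a chemical across tissues is driven by tissue:plasma
partition coefficients. Where these are not supplied directly, a
Poulin–Theil-style volume-fraction formula predicts them from tissue
composition. With $P = 10^{\log P} \times f_{\mathrm{neutral}}$ (the
ionization-corrected, effective neutral-species partition coefficient at
pH 7.4 — an effective logD),

$$K_{p,t} = \frac{P (f_{nl,t} + 0.3 f_{pl,t}) + (f_{w,t} + 0.7 f_{pl,t})}
                 {P (f_{nl,p} + 0.3 f_{pl,p}) + (f_{w,p} + 0.7 f_{pl,p})}$$

over volume fractions of neutral lipid, phospholipid, and water in tissue
and plasma. Design choices, made where the method was genuinely open:

* The unbound-fraction tissue/plasma ratio is set to 1 — a documented
  simplification; protein-binding differences between tissue and plasma
  are not modeled.
* Ionization uses Henderson–Hasselbalch neutral fractions at pH 7.4,
  multiplied across groups for multiprotic chemicals — the simplest
  defensible correction.
* Direct `kp_overrides` always win, so values from any external prediction
  method (or measurement) can be injected per tissue. This is also the
  escape hatch for chemistry the volume-fraction formula cannot represent,
  e.g. permanently charged surfactants with strong plasma binding.

A consequence of the formula worth knowing: as $P \to \infty$, $K_p$
saturates at the tissue:plasma neutral-lipid ratio (≈ 39 for the default
rest-of-body composition), so extreme lipophilicity does not produce
unbounded partitioning.

# Physiology

The shipped default is a 70 kg reference adult human with plasma flows
(L/h): hepatic artery 13.2, gut 49.5, kidney 39.6, rest 82.5, cardiac
output 184.8 (their sum); venous/arterial plasma 2.0/1.0 L; GFR 6.7 L/h;
tissue volumes gut 1.65, liver 1.8, kidney 0.31, rest 61 L; and standard
tissue lipid/water compositions. The liver receives the hepatic artery plus
the portal (gut) outflow — this flow balance is validated at load and
violation is an error. The physiology is a YAML file
(`inst/extdata/human_70kg.yaml`) with units in the key names; it is
configuration, not ground truth, and every run's outputs embed a hash of
the configuration actually used. Non-human species are a matter of
supplying another file with the same schema.

# Numerical choices

* **Integrator:** `deSolve::lsoda` — adaptive, stiff-capable — with
  rtol 1e-8 and atol 1e-10 µmol. These are tight on purpose: the suite
  asserts mass balance to 0.1% and dose linearity to ~1e-6, and those
  assertions are only meaningful well above solver error.
* **Dosing events** are exact state jumps. The solver reports the
  *pre-event* state at an event time, so the output grid carries an extra
  point just after each administration; mass-balance accounting counts a
  dose as delivered strictly after its administration time, with the first
  dose in the initial state.
* **Output grid:** at least 20 points per dosing interval (minimum 100)
  plus all event times. AUC is trapezoidal on this grid.
* **Cmax ties** break to the earliest time (`which.max` semantics).
* **Degenerate inputs:** zero dose yields identically zero series; zero
  CLint and (effectively) zero GFR conserve mass indefinitely — both are
  tested against closed forms.
* **Printed precision** is 6 significant digits in CSV/JSON outputs, and a
  re-read CSV reproduces the printed values exactly.

Two closed-form oracles anchor the integrator's correctness: with all
partition coefficients overridden to 1 and flows scaled ×10⁶ the model
collapses to a one-compartment system whose oral-bolus solution is the
Bateman equation (agreement within 1% everywhere, AUC within 1% of
$F D / (V_{tot} k_e)$); and with elimination off, an IV bolus equilibrates
every $C_t / K_{p,t}$ to $D / \sum_j V_j K_{p,j}$.

# Reverse dosimetry

The EAD rule is Cmax normalization under the user's schedule:

$$EAD = \frac{AC_{50}}{C_{max}^{\mathrm{1\,mg/kg}}} \times 1\ \mathrm{mg/kg/day}$$

where $C_{max}^{\mathrm{1\,mg/kg}}$ is the venous plasma Cmax over the full
simulation window at 1 mg/kg per administration. Because EADs depend on the
dosing frequency (an accumulating chemical has a much higher Cmax under
hourly dosing than under a single bolus), the schedule is recorded in every
`ead_result`. AC50 tables are normalized to µM on ingest (`uM`/`nM`/`M`
accepted), so EADs are invariant to the input unit. Summaries use the
midpoint-of-two median convention; the MoE statistic defaults to the median
EAD and is selectable and logged. MoE is `EAD / exposure`, and ranking is a
stable ascending sort so ties preserve input order.

One known arithmetical wrinkle in published screening workflows of this
kind: a median EAD, a median AC50, and a reported "Cmax below X" bound need
not be mutually consistent to better than rounding, because the EAD
arithmetic uses unrounded intermediates while prose reports rounded bounds.
This package always reports the unrounded computed values at 6 significant
digits.

# The synthetic-fixture generators

`make_archetypes()` produces two fully synthetic chemicals chosen to
exhibit, qualitatively, the two canonical screening behaviors:

* **`dtac_like`** (MW 263.89, logP 3.8, fub 0.08, CLint 0.5 µL/min/10⁶
  cells, liver Kp overridden to 0.3): slow clearance and strong
  partitioning into the bulk tissue compartment (Kp ≈ 37) make it
  accumulate under hourly dosing (last-interval peak ≈ 3.6× the first),
  and the liver override — representing a plasma-retained cation —
  keeps its plasma Cmax above its liver Cmax despite portal absorption
  spikes.
* **`cnpa_like`** (MW 169.61, logP 1.0, fub 0.7, CLint 150): hepatic
  extraction is flow-limited at this CLint, so first-pass metabolism keeps
  the liver its highest-concentration compartment and interval peaks reach
  periodic steady state within a few intervals (the last-interval peak
  exceeds the 12th-interval peak by ~1%).

A note on "no accumulation": in this physiology the half-life of *any*
chemical is bounded below by roughly 0.5 h (hepatic clearance cannot exceed
the 62.7 L/h hepatic plasma flow, and the distribution volume cannot fall
below ~50 L), so under hourly dosing even the fastest-cleared chemical
shows ~30% peak growth before stabilizing. The generator therefore
operationalizes "no accumulation" as rapid attainment of periodic steady
state rather than as multi-dose Cmax equal to single-dose Cmax.

The shared assay table carries 21 and 28 active receptor-effects records
for the two archetypes, drawn log-normally (GSD 2.2) and *median-anchored*:
each chemical's draws are rescaled so the sample medians are exactly
20.04 µM and 29.16 µM. Anchoring makes the "similar in vitro bioactivity"
condition (medians within 1.5×) hold deterministically at these small
table sizes, where raw log-normal sampling noise would otherwise dominate.
The fixture exposure estimates are 0.106 and 7.19e-4 mg/kg/day
(95th-percentile-style values).

What the fixtures do **not** emulate: real cHTS data has assay-specific
noise structure, inactive flags correlated with potency, and curation
artifacts; real chemicals have measured-vs-predicted parameter
disagreement and correlated parameter errors. Passing the fixture-based
tests demonstrates that the machinery is correct and the qualitative
contrasts are reproduced — not that any specific real chemical's EAD is
accurate. The general-purpose generators (`random_profiles()`,
`synthetic_assays()`) draw log-uniformly within documented screening-library
ranges (MW 150–500, logP −1–4.5, fub 0.01–1, CLint 0.1–300) with ~10%
inactive assay records, and are pure functions of their seeds.

# Problem sizes

The shipped test suite and the acceptance script run the 24 h hourly-dosing
scenario (≈ 500-point output grids) a few dozen times, a ~2000 h
equilibrium run, and randomized mass-balance checks over a handful of drawn
chemicals — small enough to re-run on a laptop in well under a minute per
file, and chosen because every asserted property is already decisive at
these sizes.

# Known limitations

* Oral and IV bolus routes only; no inhalation/dermal, no enterohepatic
  recirculation, no food-matrix or absorption modeling beyond
  ($F_{\mathrm{abs}}$, $k_a$).
* No population variability or uncertainty propagation — single
  deterministic parameter sets.
* The composition-based Kp formula with unit unbound-fraction ratio is
  coarse for strongly protein-bound or permanently ionized chemicals; use
  `kp_overrides` there.
* Cmax-based IVIVE is one convention; steady-state-concentration variants
  are deliberately out of scope.
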