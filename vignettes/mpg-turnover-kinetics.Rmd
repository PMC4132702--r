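---
title: "Glycosylase turnover kinetics and in-cell repair quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycosylase turnover kinetics and in-cell repair quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpgrepair)
library(dplyr)
```

## The scientific problem

MPG (N-methylpurine-DNA glycosylase) initiates base excision repair of
1,N⁶-ethenoadenine (εA), an adenine adduct formed by lipid-peroxidation
aldehydes, and of hypoxanthine (Hx). In the tumor suppressor p53, adenine
mutations concentrate at hotspot codons 249, 179 and 255, while codons 246
and 247 are rarely mutated. One candidate explanation is that repair itself
is sequence-dependent: if εA persists longer at some codons, replication has
more chances to miscopy it there. This package provides the quantitative
machinery to dissect that hypothesis — which step of the excision reaction
(binding, catalysis, or product release) is sequence-sensitive, and how in-cell
repair kinetics differ between codons — on synthetic data whose ground truth
is fully known.

## The kinetic model

The minimal excision mechanism is

$$\mathrm{E} + \mathrm{S} \rightleftharpoons \mathrm{ES}
  \xrightarrow{k_\mathrm{chem}} \mathrm{EP}
  \xrightarrow{k_\mathrm{pd}} \mathrm{E} + \mathrm{P}$$

with binding characterized by the equilibrium dissociation constant
$K_D = k_\mathrm{off}/k_\mathrm{on}$, chemistry by the glycosidic-bond
cleavage rate $k_\mathrm{chem}$, and turnover by the product-dissociation
rate $k_\mathrm{pd}$. Two classical limiting regimes make the individual
constants observable:

* **Single turnover (STO)**: enzyme in large excess. Every substrate
  molecule is bound before it reacts, so product follows
  $[P] = A_0(1 - e^{-k_\mathrm{obs}t})$ with $k_\mathrm{obs} \approx
  k_\mathrm{chem}$.
* **Burst / multiple turnover (MTO)**: substrate in large excess. The first
  round of chemistry is fast (burst of amplitude $A_0$ ≈ active enzyme),
  after which each new round must wait for product release, giving a linear
  phase of slope $k_\mathrm{ss}$ and
  $k_\mathrm{pd} = k_\mathrm{ss}/A_0$.

The ratio $k_\mathrm{ss}/A_0$ is forced by dimensional analysis:
$k_\mathrm{ss}$ is in nM·min⁻¹ and $A_0$ in nM, so only this ordering
yields a rate in min⁻¹.

### What the ODE simulator measures

`simulate_mechanism_ode()` integrates the scheme under mass action
(`deSolve::lsoda`, `rtol = 1e-10`) and reports the product trace as
**total excised substrate** $[\mathrm{EP}] + [\mathrm{P}]$, not free P.
A quench-and-gel assay denatures the enzyme, so every cleaved molecule is
counted whether or not it has been released. This choice is what makes the
burst amplitude count active enzyme and lets the trace approach the STO
closed form in the enzyme-excess limit; with free P alone, neither holds.
Product rebinding is off by default, treating release as the committed
turnover step. Only `active_fraction × enzyme_total` participates; the
inactive remainder is modeled as kinetically invisible.

Two analytic limits are enforced by tests: in the enzyme-excess limit the
trace matches the STO closed form within 1% of the amplitude (pointwise
relative agreement additionally requires deep saturation, $E \gg K_D$ —
at $E/K_D = 50$ the equilibrium occupancy $E/(E+K_D)$ alone leaves a ~2%
early-time relative gap, which no choice of $k_\mathrm{on}$ removes); in
the substrate-excess limit the late-phase slope matches
$k_\mathrm{pd} A_0$ within 5%. The 5% bound has a real margin only when
$K_D \ll S$: the steady-state flux is
$k_\mathrm{pd}A_0 / (1 + \tfrac{k_\mathrm{pd}}{k_\mathrm{chem}}(1 +
K_D/S))$, about 4.7% below $k_\mathrm{pd}A_0$ at the fixture values. For
that reason the fixture catalog sets $K_D = 1$ nM, a typical low-nM
glycosylase affinity. Substrate conservation
$[S]+[ES]+[EP]+[P] = S_\mathrm{tot}$ is checked to $10^{-9}$ relative at
every step.

## Fitting choices

All nonlinear fits use bounded Levenberg–Marquardt (`minpack.lm::nlsLM`,
`ftol = ptol = 1e-15`) with non-negativity bounds, and the burst amplitude
additionally bounded by the curve's total enzyme. Initialization is
deterministic and data-driven: `A0` from the maximum (STO) or the
linear-tail intercept (burst), `k_ss` from the slope of the final third of
the points, `k_obs` from $\ln 2 / t_{1/2\text{-rise}}$ with ties broken by
the earliest index. Standard errors come from the local linearization; the
`k_pd` SE uses the delta method on the ratio. Degenerate inputs (all-zero
traces, amplitudes indistinguishable from zero) return flagged results
rather than errors or silent numbers, and non-convergence is flagged, never
masked. Tests verify that the optimizer's RSS never exceeds that of an
exhaustive log-grid search over the parameters.

```{r burst}
curve <- generate_mto_curve(A0 = 0.22 * 7, k_obs = 1.2, k_ss = 0.24 * 0.22 * 7,
                            times = seq(0, 10, 0.25), label = "246eA",
                            enzyme_total = 7, substrate_total = 75)
tidy(fit_burst(curve))
```

The active-site titration regresses fitted burst amplitudes on total enzyme
*through the origin*: a zero-enzyme reaction produces no burst, so the
intercept is structural, and the slope estimates the active fraction
directly.

```{r titration}
concs <- c(3.5, 7, 10, 20)
series <- generate_titration_series(concs, active_fraction = 0.22,
                                    k_obs = 1.2, k_pd = 0.24,
                                    times = seq(0, 10, 0.25))
glance(active_site_titration(series, concs))
```

## In-cell repair quantification

The in-cell assay transfects a plasmid carrying a single εA (or AP-site) at
a codon of interest, retrieves it over time, converts remaining lesions to
nicks, and quantifies amplifiable (= repaired) template by qPCR with
primers flanking the damage site. The package adopts an
**amplification-blocking model**: a nicked template does not amplify, so
the repaired fraction is $\mathrm{eff}^{\,\Delta C_t}$ against a
fully-repaired reference. This formula is a declared stand-in — the assay's
own normalization details are not part of the model — but it is exactly
invertible, and the generator/converter round trip is tested to $10^{-12}$.
qPCR efficiency defaults to 2.0 (100%) and is configurable per assay.

Repair time courses are modeled as a single-exponential approach to a
plateau (default 100%). The true in-cell curve shape is not derivable from
tabulated half-lives alone; the exponential is the simplest saturating form
that makes $t_{1/2}$ well-defined, and a model-free linear-interpolation
estimator is retained as an auditable alternative (the two agree within 2%
on densely sampled noise-free data, a tested property). A curve that never
reaches 50% is reported as *censored* with the last observation time as a
lower bound — never as infinity — which is how the Mpg-null
(no-detectable-repair) condition flows through group summaries. The assay
time axis starts at the first harvest; any post-transfection offset is
metadata.

Group contrasts use the unpaired two-tailed Student's (pooled-variance)
t-test, matching the field's default report, with the sign convention
non-hotspot minus hotspot. Note that at codon-level granularity (2 vs 3
half-lives) the HepG2 εA grouping does *not* reach p < 0.05 — significance
in the source assays comes from replicate-level data — whereas the HUVEC
grouping does; the tests assert exactly what the arithmetic gives. No
multiple-testing correction is applied by default, matching single pooled
tests per experiment.

## The fixture catalog and the synthetic-data philosophy

`mpg_fixtures()` packages the study's ground truth: εA turnover
$k_\mathrm{pd}$ of 0.24 and 0.11 min⁻¹ at codons 246/247 versus
0.02–0.04 min⁻¹ at hotspots; Hx turnover 0.25/0.26 versus 0.01–0.08
min⁻¹; preparation active fractions 22% (εA study) and 83% (Hx study);
HepG2 εA half-lives 3.0/16.5 h versus 18.5–20.5 h; HUVEC 4.0/5.0 h versus
9.1–15.3 h; AP-site half-lives with group medians 1.5/1.3 h. Quantities
published only as ranges are assigned fixed within-range per-codon values
tagged `"range-interpolated"`; quantities with no published number
($k_\mathrm{obs} = 1.2$ min⁻¹, $k_\mathrm{chem} = 5$ min⁻¹, $K_D = 1$ nM,
$k_\mathrm{on} = 10$ nM⁻¹min⁻¹) are single documented choices tagged
`"chosen"` — turnover recovery is insensitive to $k_\mathrm{obs}$ as long
as the burst and linear phases are separated. These defaults *are* the
study conditions; they are set once and not tuned.

The noise model is multiplicative Gaussian (coefficient of variation) plus
an additive floor, clamped to physical bounds, with a mandatory seed for
any noisy draw; the global RNG stream is never disturbed. What the
generators deliberately do **not** emulate: sequence-level chemistry (a
codon is a label, not a base string), PCR amplification beyond the
Ct↔fraction map, transfection efficiency or copy-number normalization,
AP-site lability, and SPR artifacts (mass transport, drift, regeneration).
Passing tests therefore demonstrate that the *analysis pipeline* recovers
known parameters under idealized measurement noise — not that real gels or
sensorgrams are this clean.

## SPR binding

`fit_langmuir()` fits the 1:1 Langmuir model globally across a
concentration series with shared $(k_a, k_d, R_\mathrm{max})$ and reports
$K_D = k_d/k_a$ — an identity that holds exactly in every result. A single
concentration confounds $k_a$ with $R_\mathrm{max}$; the fit is then
flagged but still reported. `kobs_linearity()` — the classical regression
of per-concentration association rates on concentration (slope $k_a$,
intercept $k_d$) — serves as an independent cross-check; the two routes
agree within 1% on noisy data by test. Per-codon $K_D$ values are not part
of the catalog (only their equality across codons is a testable claim), so
binding fixtures are parameter round-trips.

```{r spr}
set <- generate_sensorgram_set(ka = 1e-3, kd = 1e-3, Rmax = 100,
                               concs = c(5, 10, 20, 40))
tidy(fit_langmuir(set))
```

## The pipeline and problem sizes

`run_pipeline()` drives the whole study from a YAML/list config with a
closed schema (unknown keys are rejected before any computation): simulate
from fixtures (or analyze user CSV curves), fit every stage, compare
groups, and emit per-codon tables plus a provenance block (seed, config
hash, package version). Identical config and seed give identical tables.
`validate_report()` checks a report against the packaged expectations and
flags, among other things, an inverted turnover formula ($A_0/k_\mathrm{ss}$)
— a deliberate-bug sentinel.

Default problem sizes are the assay designs themselves: 41 points over
0–10 min for progress curves, four enzyme concentrations for titration,
five time points over 0–48 h in-cell, seven mixing levels, and ~120 s SPR
phases at 1 Hz. Everything — full test suite included — runs in seconds on
one core.

## Known limitations

* The percent-repair formula is a modeling decision; if the original assay
  normalized to a co-transfected control amplicon, absolute percentages
  would shift while half-lives (shape-based) would not.
* Replicate-level scatter is not part of the fixture catalog, so
  codon-level group tests are underpowered relative to the source assays.
* The exponential repair model cannot represent lag or sigmoidal kinetics;
  use `linear_interpolation` when the shape is in doubt.
* The mechanism ODE treats release as irreversible; product inhibition by
  AP-site DNA is outside the default model even though it is the
  biological reason turnover is slow.
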