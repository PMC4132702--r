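# mpgrepair

Kinetic simulation and analysis toolkit for the base excision repair (BER)
glycosylase **MPG** (N-methylpurine-DNA glycosylase), built around one
scientific question: *why is the lipid-peroxidation adduct
1,N⁶-ethenoadenine (εA) repaired more slowly at p53 mutation-hotspot codons
(249, 179, 255) than at non-hotspots (246, 247)?* The package is aimed at
enzymologists and DNA-repair researchers who want to simulate, fit and
stress-test the standard pre-steady-state and in-cell repair analyses on
fully specified synthetic data before (or instead of) applying them to gel
or qPCR readouts.

## The models

**Single turnover (STO)** — enzyme in excess; product formation follows

    [P] = A0 (1 - exp(-k_obs t)),    k_obs ≈ k_chem

where `k_chem` is the glycosidic-bond cleavage rate.

**Burst / multiple turnover (MTO)** — substrate in excess; the curve is
biphasic:

    [P] = A0 (1 - exp(-k_obs t)) + k_ss t

The burst amplitude `A0` counts active enzyme, the linear slope `k_ss` is
the steady-state turnover rate, and the **product-dissociation rate**
(turnover number) is `k_pd = k_ss / A0` (min⁻¹). Fitting burst amplitudes
across several enzyme concentrations and regressing `A0` on total enzyme
through the origin titrates the **active fraction** of a preparation.

**Mechanism ODE** — the full scheme `E + S ⇌ ES → EP → E + P` is integrated
under mass action (`deSolve`), with the measured product taken as total
excised substrate `[EP] + [P]`; the closed forms above are its limiting
cases and the package tests that agreement.

**In-cell repair** — percent repair from a qPCR Ct shift under an
amplification-blocking model, `fraction = efficiency^(Ct_ref − Ct_sample)`;
repair time courses are fitted with
`percent = plateau (1 − exp(−ln2 · t / t½))` to estimate the repair
half-life `t½`, with mixing standards (0–100% repaired-equivalent blends)
validating assay linearity.

**SPR binding** — concentration-series sensorgrams fitted globally with the
1:1 Langmuir model to give `ka`, `kd` and `K_D = kd/ka`.

Every generator takes an explicit `noise_spec(cv, floor_sd, seed)`; noise
off means exact evaluation, and identical seeds give bit-identical data.

## Worked example

Generate a noise-free burst curve from the packaged codon-246 εA fixture
(22%-active preparation, 7 nM enzyme, 75 nM substrate) and recover its
turnover rate:

```r
library(mpgrepair)

curve <- generate_mto_curve(A0 = 0.22 * 7, k_obs = 1.2,
                            k_ss = 0.24 * 0.22 * 7,
                            times = seq(0, 10, 0.25), label = "246eA",
                            enzyme_total = 7, substrate_total = 75)
fit_burst(curve)
#> <burst_fit> 41 points; RSS = 3.365e-30
#> # A tibble: 4 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 A0       1.54   1.91e-16
#> 2 k_obs    1.2    4.03e-16
#> 3 k_ss     0.370  2.75e-17
#> 4 k_pd     0.24   3.47e-17
```

`A0 = 1.54 nM` is the active enzyme (22% of 7 nM) and `k_pd = 0.24 min⁻¹`
is the product-dissociation rate — the quantity that separates hotspot from
non-hotspot codons. The whole study runs as one pipeline:

```r
report <- run_pipeline(list(mode = "simulate", seed = 1))
dplyr::filter(report$enzymology, lesion == "eA")[, c("label", "hotspot", "k_pd")]
#>   label hotspot  k_pd
#> 1 246eA FALSE    0.24
#> 2 247eA FALSE    0.11
#> 3 249eA TRUE     0.02
#> 4 179eA TRUE     0.03
#> 5 255eA TRUE     0.04
report$ap_medians
#>   hotspot median_t_half     n
#> 1 FALSE             1.5     2
#> 2 TRUE              1.3     3
```

Non-hotspot turnover is 3–12-fold faster than hotspot turnover, while
AP-site repair half-lives (the post-excision steps) are indistinguishable
between groups — low MPG turnover, not downstream BER, is the bottleneck.
`validate_report(report)` checks every recovered number against the
packaged ground truth.

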