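# chelspec

Chemical-equilibrium speciation and balance-study statistics for
gadolinium chelation therapy.

MRI contrast agents are Gd(III)-chelator complexes, and several clinical
formulations are now known to leave gadolinium deposits in bone, brain and
other organs. Evaluating a chelator — either as a contrast-agent ligand or
as a decorporation (metal-removal) drug — raises two computational
problems, and this package implements both:

1. **Speciation under physiological competition.** A multi-component
   equilibrium engine solves the mass-action / mass-balance system
   *c*ᵢ = βᵢ ∏ⱼ *x*ⱼ^νᵢⱼ, *T*ⱼ = *x*ⱼ + Σᵢ νᵢⱼ*c*ᵢ at fixed pH
   (Newton iteration in log space, analytic Jacobian, damped steps,
   relative mass-balance tolerance 10⁻¹²). On top of it sit the protocols
   that rank chelators: co-dilution of Gd and chelator at 1:1 mol/mol
   against a constant endogenous ligand pool (phosphates 1.1 mM,
   carbonates 25 mM, oxalates 9.2 µM, lactates 1.5 mM, citrates 160 µM,
   pH 7.4), the release threshold where the bound fraction crosses 0.5,
   tie-aware ranking, and transmetallation scans with physiological Ca²⁺
   (1.1 mM) or Zn²⁺ (15 µM). pH-conditional stability constants
   (log *K*cond = log β − log α_L(H) − log α_M(OH)) come from the same
   constants table.
2. **Radiotracer balance-study statistics.** For metabolic balance studies
   in which all tissues and excreta are radioanalyzed: percent of
   recovered dose (%RD) accounting with cage-pooled excreta, radiochemical
   recovery checks, Dixon's Q outlier screening (r10, two-sided,
   Rorabacher critical values), classical one-way ANOVA, Dunnett
   many-to-one and Tukey all-pairs adjusted p-values, and excretion time
   courses — plus a synthetic study generator so the whole pipeline is
   testable end to end.

The packaged constants table (`gd_constants()`) covers Gd(III), Ca(II) and
Zn(II) with five chelators — 3,4,3-LI(1,2-HOPO) ("HOPO"), DTPA, DOTA,
DTPA-BMA, EDTA — and six endogenous ligand classes. It is assembled from
published stability-constant literature with per-entry provenance notes
(see the vignette); it is a constructed stand-in, not a transcription of a
single source.

## Worked example

Rank the five chelators by their release thresholds under the
physiological reference medium:

```r
library(chelspec)
tab <- gd_constants()
med <- serum_medium()

conditional_stability_constant(tab, "Gd", "HOPO", 7.4)
#> [1] 20.37697

ths <- lapply(c("HOPO", "DTPA", "DOTA", "DTPABMA", "EDTA"),
              function(ch) release_threshold(dilution_scan(tab, med, ch)))
chelator_ranking(ths)
#> <chelator_ranking> weakest -> strongest:
#>   DTPABMA = EDTA < DOTA = DTPA < HOPO
#>   chelator threshold log10_threshold tier
#> 1  DTPABMA 4.407e-11          -10.36    1
#> 2     EDTA 4.291e-11          -10.37    1
#> 3     DOTA 2.522e-14          -13.60    2
#> 4     DTPA 1.975e-14          -13.70    2
#> 5     HOPO 1.232e-16          -15.91    3
```

Reading: DTPA-BMA and EDTA release half their Gd already at ~4 × 10⁻¹¹ M
total Gd (weakest, tied within the 0.3-log resolution of the protocol);
DTPA and DOTA hold on ~3 log units further; HOPO's threshold lies more
than two orders of magnitude below every competitor — the thermodynamic
signature of an effective decorporation agent. Thresholds are
relative-stability measures: only the ratios matter.

Simulate a balance study and push it through the statistics pipeline:

```r
st <- generate_balance_study(generator_config(seed = 1))
gs <- summarize_groups(st)
gs$totals[, c("group", "retained_mean", "retained_sd", "recovery_pct")]
#>       group retained_mean retained_sd recovery_pct
#> 1   control        55.375       1.536         95.7
#> 2 HOPO_-24h         6.806       1.897         94.5
#> 3  HOPO_-1h         0.991       0.121         94.0
#> 4  HOPO_+1h        12.070       0.990         95.7
#> 5 HOPO_+24h        29.348       1.445         94.7
#> 6 HOPO_+48h        41.203       2.103         97.2
#> 7  DTPA_-1h         8.411       1.157         95.2
#> 8  DTPA_+1h        24.213       0.935         94.7
```

Reading: the untreated control retains ~55% of the recovered dose after
four days, HOPO given 1 h before contamination cuts that about 50-fold
(~1 %RD) and roughly 9-fold relative to DTPA at the same schedule; every
group's recovery clears the 90% bar, and retained + excreted closes at
100% exactly. `dunnett_vs_control()` and `tukey_pairwise()` then test the
group contrasts, and `dixon_q_test()` screens small samples
(Q = gap/range; at n = 4 the 95% critical value is 0.829).

A thin command-line wrapper (`inst/cli.R`) exposes the same operations as
`speciate`, `dilution-scan`, `transmetallation` and `simulate`
subcommands.

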