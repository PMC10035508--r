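# splicescreen

Tools for linking alternative terminal exon inclusion to trans-acting
regulators and patient outcome, starting from splice-junction read counts.

Inclusion of an alternative terminal exon — such as the γ exon of *TP63*,
whose inclusion in head and neck squamous cell carcinoma tumors marks poor
survival and is repressed by the splicing factor PTBP1 — leaves a quantitative
footprint in RNA-seq: the split reads supporting the inclusion junction
compete with those supporting the exclusion junction at a shared 5′ splice
site. `splicescreen` implements the full desk half of that analysis as
composable, pipe-friendly functions over data frames:

* **Depth normalization.** Per sample *s*, the total read count *Tₛ* and the
  median read depth *Mrd* over samples define the normalization factor
  *Nₛ = Mrd / Tₛ*; normalized expression is *E₉ₛ = raw × Nₛ*, so every
  normalized column total equals *Mrd*.
* **Junction usage and PSI.** Junctions are grouped into competing sets
  (sharing a donor site by default); usage(j, s) = *Nⱼₛ / Σₖ Nₖₛ* over the
  set, missing below a coverage floor. Percent spliced in is
  PSI = 100 · inclusion / (inclusion + exclusion) on the 0–100 scale.
* **Regulator screen.** For each RNA-binding protein, the Pearson correlation
  (with the *t*-based two-sided p-value) between its normalized expression
  and the target junction's usage across individual samples; candidates are
  ranked by |r| and then filtered for tumor sign concordance: a negatively
  correlated candidate must also be significantly *lower* (Wilcoxon,
  p < 0.05) in high-PSI tumors to remain plausible (the PTBP1 pattern), a
  positively correlated one must be higher; the opposite pattern is
  discarded.
* **Survival stratification.** Patients split at a PSI threshold (boundary to
  the high stratum), compared with a from-scratch Kaplan–Meier product-limit
  estimator and two-group log-rank test (exact hypergeometric variance at
  tied times); an explicit cutpoint scan with a multiple-testing caveat is
  provided instead of an unexplained threshold.
* **Differential expression and enrichment.** Gene-wise two-sided Wilcoxon
  rank-sum between PSI groups, Benjamini–Hochberg adjustment, pseudocount
  log2 fold changes, prognostic-marker overlay, and classic hypergeometric
  gene-set enrichment with fold enrichment = (k/n)/(K/N).
* **Binding isotherm.** Least-squares fit of the single-site equilibrium
  model bound/total = 1/(1 + Kd/[protein]) in log-Kd space, replicate or
  bootstrap SDs, a censored "unbound" verdict for flat curves, and fold-change
  comparison between probes.
* **Synthetic data.** Seeded generators for every input — a multi-tissue
  junction/RBP panel with a planted logistic regulator, a tumor cohort with a
  planted hazard ratio and planted differential genes, and titration curves
  with known Kd — so every stage is testable without downloads.

Every result type has `tidy()`, `glance()` and `autoplot()`/`plot_*()`
methods.

## Worked example

```r
library(splicescreen)
library(dplyr)

# multi-tissue panel with a planted repressor (slope -1.5)
panel <- sim_multitissue_panel(n_tissues = 10, samples_per_tissue = 30,
  expressing_tissue_count = 10, slope = -1.5, seed = 2026)
factors <- compute_depth_factors(panel$junction_counts)
sets <- build_competing_sets(panel$junction_counts, mode = "shared_donor")
usage <- compute_junction_usage(panel$junction_counts, factors, sets,
  min_coverage = 8)
screen <- correlate_rbp_usage(
  filter(panel$expression, gene %in% panel$truth$rbps),
  usage, junction = "chr3:189500001-189520000")
head(tidy(screen), 3)
#> # A tibble: 3 × 6
#>   rbp         r        p     n sign   rank
#>   <chr>   <dbl>    <dbl> <int> <chr> <int>
#> 1 RBP001 -0.723 9.08e-50   300 -         1
#> 2 RBP027  0.336 2.38e- 9   300 +         2
#> 3 RBP047 -0.326 7.48e- 9   300 -         3
panel$truth$regulator
#> [1] "RBP001"
```

The planted repressor is recovered at rank 1 with a strong negative
correlation (more of the repressor, less exon inclusion); the remaining RBPs
show only the weak background correlations expected by chance at n = 300.

```r
# PSI-threshold survival stratification (planted hazard ratio 3)
cohort <- sim_cohort(n_patients = 300, hazard_ratio = 3, seed = 2026)
surv_df <- left_join(cohort$clinical, cohort$psi, by = "patient_id")
strata <- stratify_by_psi(surv_df, threshold = 4.07)
logrank_test(strata)
#> Two-group log-rank test
#> # A tibble: 2 × 4
#>   stratum     n observed expected
#>   <chr>   <int>    <dbl>    <dbl>
#> 1 high      159      134     79.4
#> 2 low       141       73    128.
#> chi-square = 65.49 on 1 df, p = 5.855e-16
```

Patients whose PSI is at or above 4.07% (the high-inclusion stratum) die
faster than expected under the null; their Kaplan–Meier median survival is
796 days against 2327 days for the low stratum (`km_median()` on each
stratum's `km_estimate()`), matching the planted direction.

```r
# Kd estimation from a simulated EMSA titration (true Kd = 104 nmol/L)
fit_kd(sim_titration(104, noise_sd = 0.05, seed = 2026))
#> Kd fit (probe1): Kd = 106.4 nmol/L (SD 19, replicate), 32 points, SSE 0.0852
```

`plot_km_strata(strata)`, `autoplot(screen)` and `autoplot(fit)` draw the
corresponding survival curves, correlation bars and binding isotherm.

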