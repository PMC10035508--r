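---
title: "Methods: junction usage, regulator screening, outcome and binding affinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction usage, regulator screening, outcome and binding affinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette describes the statistical models behind `splicescreen`, the
assumptions they make, the defaults and why they were chosen, and what the
synthetic-data generators do and do not emulate.

## The quantification model

### Depth normalization

Raw junction or gene counts are made comparable across samples by a single
per-sample factor. With $T_s$ the total read count of sample $s$ and
$Mrd = \mathrm{median}_s\, T_s$ over retained samples, the factor is

$$N_s = \frac{Mrd}{T_s}, \qquad E_{gs} = \text{raw}_{gs} \times N_s .$$

This is the unique depth-equalizing scheme in which a sample at exactly the
median depth is untouched ($N_s = 1$) and every normalized column total
equals $Mrd$ — a conservation property the tests assert to $10^{-9}$.
Samples with $T_s = 0$ carry no information and are excluded (and reported)
rather than given an infinite factor. The scheme deliberately does **not**
correct for library composition (TMM-style) or transcript length (TPM/FPKM):
the downstream statistics are within-sample ratios and rank-based tests, for
which a single depth factor is sufficient, and anything more would change
the quantity being modelled.

### Competing-junction usage

Junctions compete when they consume the same splice site of the same gene.
For an alternative terminal exon the inclusion junction and the exclusion
junction share one 5′ splice site, so the default competing-set mode anchors
on the **donor** coordinate. With normalized junction reads
$N_{js} = c_{js} N_s$, usage is

$$u_{js} = \frac{N_{js}}{\sum_{k \in \mathrm{set}(j)} N_{ks}} ,$$

which sums to one within each (sample, set) and is invariant to any uniform
rescaling of a sample's counts, since $N_s$ cancels. Three alternative modes
are provided for sensitivity analysis: `shared_acceptor`, `either_end`
(transitive closure over both anchors, computed by union–find), and
`whole_gene`, which divides by all of a gene's junctions. The donor-anchored
default is the reading forced by the biology of a terminal exon choice; the
`whole_gene` mode answers the broader "fraction of the gene's splicing"
question and will give smaller values for genes with many constitutive
junctions.

Usage is declared only when the set's normalized denominator reaches
`min_coverage` (default 8 normalized reads). Below that it is **missing,
never zero** — a ratio of tiny counts is an estimate with enormous variance,
and 0/0 is not evidence of absent usage. The same rule applies to percent
spliced in, $PSI = 100\,\mathrm{inc}/(\mathrm{inc}+\mathrm{exc})$, reported
on the 0–100 percent scale so that thresholds such as 4.07% read naturally.

## The regulator screen

For each RNA-binding protein (RBP) the screen computes the Pearson
correlation $r$ between its normalized expression and the target junction's
usage across **individual samples** (not tissue means — tissue means would
discard within-tissue variation and overstate certainty), with the two-sided
p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom over
pairwise-complete samples. RBPs with fewer than 3 complete pairs or zero
variance are reported as untestable rather than silently ranked.

Candidates are ranked by $|r|$ — both strong activators and strong
repressors are biologically interesting — with deterministic tie-breaking by
smaller p-value and then gene symbol. Correlation is computed on expression
as-is; a `log1p` flag is available since a log scale is equally defensible
and neither choice changes the planted-regulator recovery in the synthetic
panels.

The **sign-concordance filter** then demands that the tumor cohort agree
with the tissue panel: a repressor-like candidate ($r < 0$) must be
significantly *lower* (two-sided Wilcoxon rank-sum, $\alpha = 0.05$) in
high-PSI tumors, an activator-like candidate higher. A candidate significant
in the opposite direction is positively discordant — the panel and the tumors
disagree about its sign — and is discarded, as is a non-significant one.

## Survival analysis

Patients are stratified at a PSI threshold with the boundary assigned to the
high-inclusion stratum (the convention "PSI ≥ threshold is high"). The
Kaplan–Meier estimator and the log-rank test are implemented from first
principles (the survival package serves only as an independent oracle in the
tests, which require agreement at all event times to $10^{-12}$):

* product-limit $S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$ with tied deaths
  aggregated into a single $d_i$;
* median survival = smallest $t$ with $S(t) \le 0.5$, reported as `NA` when
  the curve never reaches 0.5 (never $+\infty$);
* log-rank with the exact hypergeometric variance per (possibly tied) event
  time, $V_i = d_i \frac{n_{1i}}{n_i}\left(1-\frac{n_{1i}}{n_i}\right)
  \frac{n_i-d_i}{n_i-1}$, and $\chi^2 = (O_1-E_1)^2/\sum_i V_i$ on 1 df.

Published PSI cutoffs often arrive without a derivation. `scan_cutpoints()`
is the package's explicit substitute: it evaluates the log-rank test on a
quantile grid of candidate thresholds (each leaving at least
`min_group_frac` of patients per stratum, default 10%) and returns the
minimizing threshold **together with a multiple-testing caveat flag** — a
minimum over many looks is an exploratory statistic, not an honest p-value.

## Differential expression and enrichment

Gene-wise comparison between PSI groups uses the two-sided Wilcoxon rank-sum
test — exact for small groups without ties, normal approximation with tie
correction otherwise — consistent with the rank-based group tests used
elsewhere in the pipeline, followed by Benjamini–Hochberg adjustment across
testable genes. Genes constant across all samples are untestable and are
excluded from the adjustment (including them would only dilute it). Fold
changes use a pseudocount, $\log_2\frac{\bar{x}_{high}+1}{\bar{x}_{low}+1}$,
to remain finite at zero means on normalized counts.

Gene-set enrichment is the classic one-sided hypergeometric
over-representation test with fold enrichment $(k/n)/(K/N)$, BH-adjusted
across sets. Graph-aware decorrelation schemes (such as topGO's *elim*) are
deliberately out of scope; results are labelled `"classic hypergeometric"`
so they cannot be mistaken for decorrelated ones. Parent terms that merely
inherit their children's genes will therefore co-appear; interpret nested
significant sets jointly.

## The binding isotherm

Equilibrium binding of a protein to RNA at a single site gives the bound
fraction

$$f([P]) = \frac{1}{1 + K_d/[P]},$$

with $f = 0.5$ exactly at $[P] = K_d$ (nmol/L throughout). The fit minimizes
squared error in $\log K_d$ — positivity by construction and good
conditioning across the working range $1$–$10^4$ nmol/L; the optimum is
located by golden-section/parabolic search on a generous bracket, flagged
unconverged if it lands at the bracket edge. The amplitude is fixed at 1
(fully bindable RNA), since the printed model has no plateau parameter; a
`free_plateau` option exists for probes suspected of a partially inactive
fraction. Bound fractions outside $[0,1]$ (gel quantification noise) are
clipped with a report.

Uncertainty is the SD of per-replicate fits when at least three replicates
exist — matching how titration experiments are replicated — otherwise a
seeded nonparametric bootstrap over points (200 resamples). A curve whose
maximum bound fraction stays below 0.2 is declared **unbound** and reported
as the censored bound $K_d > \max[P]$ rather than an unstable number;
fold-change comparisons against a censored fit propagate the bound
($\ge$). Fold changes between converged fits carry a delta-method interval
on the log scale.

## The synthetic-data generators

The generators are pure functions of their arguments and a mandatory seed.

`sim_multitissue_panel()` emulates a reduced GTEx-like panel: 54 tissues ×
30 samples by default, of which 10 tissues express the target gene (the
10/54 selection the bundled defaults reproduce at the default expression
threshold of 50 normalized units); RBP log-expression with lognormal tissue
means (between-tissue SD 0.7, within-tissue 0.5); a **logistic link**
between standardized regulator expression and true inclusion,
$\pi = \mathrm{logit}^{-1}(a + b z)$, with $b = -1.5$ the default
PTBP1-like repressor and $a = -1$ a baseline inclusion near 27%; junction
totals negative-binomial (mean 200, dispersion 0.3) — overdispersion is the
realistic stress for a ratio estimator — split binomially between the
inclusion and exclusion junctions.

`sim_cohort()` emulates a reduced tumor cohort: PSI from a beta mixture
(low component mean ≈ 2.4%, matching the weak terminal-exon inclusion
typical of these tumors; high component mean 10%), the group defined by the
realized PSI against the planted threshold 4.07%; exponential survival with
proportional hazard (default ratio 3, low-group median 2319 days) — the
minimal model under which the log-rank test is exactly proportional-hazards
correct, keeping calibration and power targets clean; independent uniform
censoring calibrated analytically to the requested rate (default 30%);
planted differential genes at one log2 unit with lognormal noise
(sdlog 0.5), labelled as unfavorable prognostic markers since high inclusion
is the poor-survival group.

`sim_titration()` draws isotherm values on a two-fold ladder
(12.5–1600 nmol/L, 4 replicates) plus Gaussian noise (SD 0.05), clipped to
$[0,1]$.

**What passing tests show — and don't.** The generators reproduce the
statistical *structure* the methods assume: overdispersed counts, a monotone
regulator–inclusion link, proportional hazards, lognormal expression noise,
additive titration noise. They do not reproduce correlated RBP co-expression
networks, batch effects, isoform-level ambiguity in junction assignment,
informative censoring, or cooperative binding. Recovery rates on these
panels therefore validate the implementation and its power under the stated
model, not performance on any particular real cohort.

## Numerical and design choices

* Junction coordinates are 1-based with inclusive ends and must satisfy
  start < end; malformed identifiers are format errors, never coerced.
* Sample joins use intersection with a report of unmatched samples; silent
  drops are avoided everywhere (dropped clinical rows, clipped bound
  fractions, untestable genes and RBPs are all counted in the output).
* Tissue-level "expressing" calls use the median by default (robust to a
  single outlier sample); the mean is available by flag.
* p-values from perfect correlations are clamped to the smallest positive
  double so that downstream code can rely on $p \in (0,1]$.
* Calibration checks run the log-rank test on cohorts of 200 patients and
  500 simulated nulls: large enough that the $\chi^2_1$ reference is
  accurate (at 100 patients the test is measurably anticonservative), small
  enough to keep the whole suite fast. Screen recovery uses 20 replicates of
  a 10-tissue × 30-sample panel with 50 RBPs; DE recovery uses 1000 genes
  with 100 planted at 2-fold in cohorts of 80.
* All simulation entry points take an explicit seed and restore the RNG
  state afterwards; the bootstrap inside `fit_kd()` is separately seeded so
  a fit is reproducible independent of call order.

## Known limitations

* The screen is marginal correlation: co-expressed RBPs share credit, and no
  covariate adjustment (purity, batch, HPV status) is attempted — attribute
  filtering is the supported way to restrict to a subgroup.
* The cutpoint scan's best p-value is exploratory by construction.
* The enrichment test treats gene sets as flat lists.
* The Kd model is single-site and non-cooperative; strongly sigmoidal curves
  (Hill coefficient > 1) will fit poorly and should be flagged by their
  residuals.
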