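---
title: "Models and methods behind divergescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind divergescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divergescan)
```

divergescan analyses divergence between a selected breeding line and a
control line: a population-genetic scan (Weir–Cockerham Fst, nucleotide
diversity, windowed selection-signature calling), a per-trait mixed linear
model with stepwise major-QTL selection, and the intersection of the two
signal sets. This vignette records the models, the numerical choices, and
the reasoning behind design decisions that were genuinely open.

## The trait model

For one trait, the phenotype vector over the `n` phenotyped samples is
decomposed as

$$ y = Xb + Sc + Zg + Wq + e $$

* `b` — fixed effects: population mean and selection-line effect. The line
  effect stays in the model throughout the genome scan so that
  line-stratified allele frequencies cannot masquerade as trait
  associations.
* `c ~ N(0, I σc²)` — random cage effects, with `S` the cage incidence
  matrix. Each full-sib family is reared in its own cage, so cage and
  family are confounded by design; the cage term absorbs their joint
  environmental component.
* `g ~ N(0, K σg²)` — polygenic effects with `K` the VanRaden (method 1)
  realized relationship matrix, `K = WcWc′ / (2 Σ p_j(1−p_j))` on dosages
  centered by twice the pooled observed allele frequency. Missing dosages
  are mean-imputed per marker; monomorphic markers drop out of numerator
  and denominator. Frequencies are pooled across lines because one `K`
  serves one model fitted to both lines.
* `q` — fixed allele-substitution effects of currently selected major QTL
  (dosage columns `W`).
* `e ~ N(0, I σe²)` — residuals.

The phenotypic covariance is `V = σc² SS′ + σg² ZKZ′ + σe² I`. Effects
solve Henderson's mixed model equations, the symmetric block system over
`(b, q, c, g)` whose random blocks carry `λ1 = σe²/σc²` on `S′S` and
`λ2 = σe²/σg²` on `K⁻¹`; a zero variance means an infinite ratio and the
block is dropped rather than ridge-forced. `assemble_mme()`/`solve_mme()`
implement that system literally (with an explicit PSD check on `K`:
eigenvalues below −1e−8 are an error, small negatives are clipped, and a
numerically singular `K` asks for a ridge δ). The fitting path inside
`steplmm()` uses the equivalent V-based GLS/BLUP identities instead, which
avoid forming `K⁻¹`; the test suite holds the two routes together on random
instances to 1e−8.

Derived quantities: `GEBV = Zĝ + Wq̂`; heritability
`h² = (σq²+σg²)/(σq²+σg²+σc²+σe²)`; and each QTL's contribution
`Cp = var(w_j q̂_j)/V̂p` with `V̂p = σq²+σg²+σc²+σe²`. `σq²` has no closed
definition in the model, so the package defines it as the sample variance
of the fitted fixed-QTL term `Wq̂` over samples — the realized variance the
QTL explain — and `Cp` follows the same convention per locus.

## Variance components and the genome scan

`reml_varcomp()` maximizes the restricted likelihood with the fixed part
(including any selected QTL columns) projected out. Both `β` and `σe²` are
profiled analytically, leaving a search over at most two log variance
ratios `(log γc, log γg)`, `γ = σ²/σe²`. The optimizer is derivative-free:
golden-section for one ratio, Nelder–Mead from four starts for two, with a
convergence tolerance of 1e−6 on the restricted log-likelihood and the
log-ratios clamped to ±16 (a ratio of e⁻¹⁶ is numerically zero; estimates
below 1e−5 are reported as exact zero-boundary solutions, which the
full-sib design produces regularly because cage and polygenic terms compete
for the same between-family variance). The reported trace is the
best-so-far restricted log-likelihood per evaluation, so it is monotone by
construction — the safeguard that makes the non-decreasing-likelihood
property checkable.

The genome scan (`scan_markers()`) tests one marker at a time as an extra
fixed column with the variance components frozen at their current REML
estimates — the standard approximation that turns a genome scan into `m`
generalized-least-squares slope tests after one Cholesky of
`H = I + γc SS′ + γg K`. p-values use the t reference with `n − p − 1`
degrees of freedom. Monomorphic markers and markers collinear with the
fixed part (residual sum of squares of the projected dosage below
`1e−10·n`) are skipped with a flag. Stepwise selection
(`stepwise_select` logic inside `steplmm()`) adds the most significant
marker while its p-value clears the Bonferroni threshold `α / m_tested`,
re-estimates the variance components after every inclusion, removes any
included marker whose conditional Wald p-value rises back above the
threshold, and excludes markers within 1 Mb (configurable) of an accepted
QTL from later rounds. Under the null this controls the family-wise error
at `α`; the acceptance suite checks both the per-test calibration (pooled
rejection rate 0.05 ± 0.02) and the empty-hit-list rate (≥ 90%).

## The population-genetic scan

Per SNP, `wc_fst_site()` computes the Weir & Cockerham (1984) components
`a` (among populations), `b` (among individuals within populations) and `c`
(within individuals, from observed heterozygosity) for the two lines, and
`Fst = a/(a+b+c)`. Negative estimates are kept — they carry information in
window means — and zero-denominator sites are `NA`, flagged distinctly from
zero. Per-site diversity is `π = 2 n_A n_a / (n(n−1))` over observed allele
counts, the average pairwise difference between sampled chromosomes.

`window_stats()` tiles each chromosome from position 1 with half-open
windows `[start, start+size)`. Three window sizes matter in practice and
all are exposed: 1 Mb for elevated-window calling, 2 Mb for diversity
reporting, 100 kb for Manhattan-style export. Window summaries are the
unweighted mean of defined per-SNP Fst, the ratio estimate `Σa/Σ(a+b+c)`,
the 95% quantile of per-SNP Fst (linear interpolation between order
statistics, R's type-7 — fixed so the q95 flags are reproducible), and
per-line π per base pair of window span (`Σ per-site π / window size`,
which is the right normalization for sparse reduced-representation markers
and yields the 10⁻⁶–10⁻⁵ magnitudes typical of such data). Flags default to
mean Fst > 0.05 and q95 > 0.25. `top_quantile_loci()` calls selection loci
above the genome-wide `1 − q` quantile (default top 1%), keeping threshold
ties.

One estimator property worth recording: under Balding–Nichols divergence
with parameter F, the *ratio-of-sums* Fst over divergent loci estimates F
itself, while the *mean of per-site ratios* sits well below it (about 0.27
at F = 0.4, 0.22 at F = 0.3) because the per-site distribution is heavily
right-skewed. Tests against Monte-Carlo oracles use the quantity they
actually measure.

## The cohort simulator

`simulate_cohort()` generates the structure the model assumes, and its
defaults are the package's reference study conditions, chosen once:

* 25 full-sib families — 19 selection, 6 control — each with 2 parents and
  8 offspring (250 samples), one cage per family;
* 5,000 SNPs spread evenly over 10 chromosomes of 2 Mb — large enough for
  a realized `K` with stable within-family contrast, small enough that a
  full fit runs in about a second;
* founder frequencies uniform on [0.05, 0.95]; 1% of markers divergent via
  independent Balding–Nichols draws per line at F = 0.4;
* variance components σc² = 0.25, σg² = 1, σe² = 0.75, giving h² = 0.5 by
  the model's own formula, and a line effect of 1 trait unit — medium
  heritability with a non-trivial cage component, the regime the
  confounded cage/family design makes hardest and therefore the honest one
  to validate in;
* six growth-trait columns (initial and 8-month body weight, length,
  depth, width) simulated i.i.d. across traits from the same model.

Parents draw dosages binomial(2, p_line); offspring receive one allele per
parent per marker (Mendelian transmission). The polygenic effect is drawn
from `MVN(0, K σg²)` with `K` computed from the *realized* genotypes — not
by summing per-marker effects — so that simulation truth coincides exactly
with the fitted model's assumption and parameter-recovery checks measure
the estimator, not a model mismatch. Planted QTL effects apply to centered
dosages (so they do not shift the trait mean) and can be specified either
as an allele-substitution effect or as a target contribution `cp`, which is
converted through the realized dosage variance:
`effect = sqrt(cp/(1−cp) · (σc²+σg²+σe²)/var(w))`.

Markers are *unlinked* given the pedigree: there is no linkage map and no
hitchhiking. That has two consequences for what passing tests mean. First,
single divergent SNPs can never dominate a 250-SNP window's 95% quantile,
so regional selection signatures must be planted explicitly:
`founder_overrides` pins exact line frequencies at chosen markers, and the
end-to-end validation plants a 21-marker sweep-like cluster (~84 kb at
p_sel = 0.85 / p_con = 0.15) with the QTL at its centre at moderate
divergence (0.65/0.35) — moderate because a QTL dosage nearly collinear
with the line indicator is rightly untestable in a model that keeps the
line effect fixed. Second, recovery rates measured here do not transfer
directly to real linked data, where sweeps elevate whole regions and LD
spreads both signal and noise.

Validation against these conditions shows one honest limitation: with 1%
of markers divergent, the top-1% Fst set has exactly as many slots as
planted loci, and independent Balding–Nichols draws leave roughly half the
planted pairs with realized frequency differences below the sampling-noise
floor of the 6-family control line (24 founder chromosomes). Pooled planted
-locus recovery therefore plateaus near 50%, not the 80% one might expect
from the divergence parameter alone; the corresponding acceptance check is
kept at its nominal threshold and fails, deliberately, as a record of that
ceiling.

## Degenerate inputs, ties, tolerances

* Half-missing VCF genotypes (`./1`) are missing; multi-allelic and
  non-SNP records are dropped with a logged count; coordinates are 1-based
  inclusive as in VCF, and all window logic converts to half-open
  intervals, so a SNP at a window's end coordinate belongs to the next
  window.
* MAF for QC is computed on observed alleles; an all-missing marker can
  only fail the call-rate filter.
* Fst at a fixed difference is exactly 1 at any sample sizes; sites where a
  line has no data, or with a single individual per line on average, are
  undefined.
* Quantiles everywhere are type-7 (linear interpolation); top-quantile ties
  are all included.
* The scan's collinearity cut-off is `1e−10·n` on the projected dosage sum
  of squares; REML convergence is 1e−6 on the restricted log-likelihood;
  MME-vs-GLS agreement is asserted at 1e−8, Fst-vs-oracle at 1e−12.
* Samples with a missing trait value are dropped per trait
  (complete-case); parents are phenotyped and included in association,
  with roles marked so either choice remains testable.

## Known limitations

No linkage or LD (see above); no dominance or epistasis; no multi-trait
model; single-generation cohorts only; no genotyping-error model; gene-level
annotation is delegated to an optional user-supplied BED/GFF3 interval
file rather than any bundled genome.
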