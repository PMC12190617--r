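---
title: "Methods: proteome-wide cis-pQTL MR, colocalization and tiering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide cis-pQTL MR, colocalization and tiering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqtlmr)
```

This vignette documents the statistical model behind `pqtlmr`, the
decisions taken where the design was genuinely open, the synthetic-cohort
generator that the test suite calibrates against, and the limits of what
those tests establish.

## The causal model and its assumptions

The pipeline treats a circulating protein as the exposure and a binary
disease as the outcome of a two-sample Mendelian randomization design.
The estimand throughout is θ, the change in log odds of disease per
standard deviation of protein level. Identification rests on the usual
instrumental-variable assumptions — relevance, independence from
confounders, and exclusion (no path to disease other than through the
protein). Using only *cis* instruments (within 1 Mb of the encoding gene)
and excluding SNPs associated with three or more proteins are the two
design-level defenses of exclusion; MR-Egger's intercept, the reverse-MR
check, colocalization, and the cis pleiotropy scan are the analytic ones.

Exposure and outcome summary statistics are assumed to come from
non-overlapping samples. For case-control outcomes every internal
computation uses the effective sample size
`N_eff = 4·n_case·n_control/(n_case + n_control)`, one consistent scalar
for the F statistic and the simulator.

## Instrument selection

Filters are applied in a fixed order: cis restriction → significance
threshold → cross-protein filter → F filter → LD clumping →
harmonization. The order of the threshold filters only affects the
per-step removal counts in the selection log, not the final set, but
clumping *after* the F filter does matter: it prevents a weak variant
from claiming a clump and shadowing a strong near-independent one.
Clumping itself is greedy on p-value with deterministic tie-breaks
(larger F, then lexicographic SNP id) so that identical inputs always
give identical instrument sets; it operates inside the cis region, since
instruments are cis-only by construction.

The discovery pQTL threshold defaults to 1.7e-11 (5e-8 / 2923 assayed
proteins) and is configurable for replication panels, where the number
of proteins differs. The cross-protein filter counts associations *at
the instrument threshold*; counting at genome-wide significance instead
would exclude more SNPs — the stricter-threshold reading was chosen
because the map of SNP-to-protein associations is itself built from
instrument-grade signals.

## Harmonization

Alleles are aligned across the four orientations (identical, swapped,
strand-complemented, both). Palindromic SNPs (A/T, C/G) carry no strand
information in their allele labels, so they are oriented by allele
frequency when both minor-allele frequencies are below 0.42 and dropped
as ambiguous otherwise. This is the conservative convention in
two-sample MR practice; it is a package decision, documented in every
harmonization report, not something the upstream study specifies. The
swap transform (negate β, complement EAF) is an involution, which the
suite asserts exactly.

## Estimators

* **Wald ratio** (single instrument): θ̂ = βy/βx with first-order delta
  SE `se(βy)/|βx|`. The second-order term is negligible at F above ~100
  and is omitted.
* **IVW**: weighted through-origin regression; with k ≤ 3 instruments a
  fixed-effect model (a dispersion estimate from 2–3 points is too
  unstable to use), with k > 3 multiplicative random effects, i.e. SE
  inflation by `max(1, sqrt(Q/df))`. The model actually used is recorded
  in the result. A single instrument reduces to the Wald ratio to
  machine precision (asserted).
* **MR-Egger**: instruments oriented so βx ≥ 0 before fitting, weights
  1/se(βy)²; SEs use the weighted-regression dispersion floored at 1.
  The floor makes the intercept test slightly conservative in
  well-specified data — the calibration test (KS on intercept p-values
  under a zero-intercept model) confirms the p-values are close to
  uniform and not anti-conservative.
* **Weighted median**: ratios weighted by inverse ratio-variance,
  midpoint-interpolated weighted CDF at 0.5; SE from a parametric
  bootstrap (default 1000 draws) under an explicit seed carried in the
  result, so repeated runs are identical.
* **SMR**: the single-variant summary-based test
  `T = zx²zy²/(zx²+zy²) ~ χ²₁` at the lead cis-pQTL. The cited toolchain
  for this step in the literature is ambiguous between the single-variant
  SMR statistic and multi-SNP GSMR; the single-variant statistic is what
  a lead-pQTL analysis uses and is what is implemented. The companion
  HEIDI heterogeneity test requires a reference LD panel workflow that
  is out of scope here; Cochran's Q on the clumped set plays the
  heterogeneity role instead.

## Colocalization

Per-SNP Wakefield log approximate Bayes factors with prior effect SD
0.15 for the quantitative trait and 0.2 for the binary trait — the
field-standard defaults, recorded in every output since the upstream
priors p1 = p2 = 1e-4, p12 = 1e-5 say nothing about effect scale. All
five hypothesis likelihoods are accumulated with log-sum-exp: a strong
pQTL easily produces log ABFs above 700, which overflow any direct
summation. The H3 term is the product-sum minus the shared-SNP diagonal,
computed as a log-space difference; a single-SNP region therefore gets
PPH3 = 0 exactly. The colocalization window is gene ± 500 kb, distinct
from the 1 Mb instrument window; both are configurable. Classification:
"robust" when PPH4 > 0.9 at p12 = 1e-5, "supported" when PPH4 > 0.8 at
the p12 = 5e-6 sensitivity prior. PPH4 is provably non-decreasing in
p12, which the suite also checks numerically.

## Reverse MR and its adjudication

Reverse MR instruments the disease (genome-wide p < 5e-8, F ≥ 10,
clumped at r² < 0.001 — "cis" is undefined for a disease, so the
criteria are the genome-wide analogue of the pQTL rules) and estimates
disease → protein by IVW and MR-Egger. The adjudication rule is a pure
function of the two p-values: a protein is declared reverse-causal only
when both IVW and Egger are significant at 0.05; an IVW-only signal with
a null Egger is annotated "not considered reverse causal" — the pattern
by which borderline reverse IVW hits are discounted when the
pleiotropy-robust estimator does not confirm them. The phrase "did not
pass the heterogeneity test" in this context is directionally ambiguous;
both readings are available behind `reverse_rule` (`"egger_gate"`,
default, and `"ivw_only"`), and Cochran's Q is always reported
alongside. With fewer than 3 instruments Egger is undefined and IVW
alone decides, flagged low-confidence.

## Tiering

The four tiers are a total, mutually exclusive partition driven by three
flags: replication availability, number of passing replications
(p < 0.05 *and*, by default, direction concordant with discovery —
concordance prevents a sign-flipped association from counting as a
replication; it can be switched off), and robust colocalization.
Tier 1 requires ≥ 2 passing replications and robust colocalization;
Tier 3 is reserved for proteins with no external data; Tier 4 for
proteins that failed every available replication. A protein with exactly
one passing replication falls in Tier 2 — the upstream scheme has no
such case, so the boundary is a package decision: one replication is
evidence, but not the "at least two datasets" standard of Tier 1.

## The synthetic cohort

The generator works on the standardized-genotype, standardized-trait
scale. With AR(1) LD matrix R (`r[i,j] = ρ^|i−j|`, default ρ = 0.9,
typical of 5-kb-spaced markers in a cis region) and one causal variant
with standardized effect b, the true marginal effects are `R[,causal]·b`
and estimated standardized effects are drawn from
`MVN(truth, R/N)` — the exact sampling distribution of marginal GWAS
coefficients under this model, which avoids simulating individual-level
genotypes entirely. Reported effects are rescaled per SNP by
`1/sqrt(2f(1−f))` so the dosage-scale SE is exactly
`1/sqrt(2f(1−f)N)`; z-scores are unchanged by the rescaling, so every
downstream statistic is identical on either scale. EAFs are
Uniform(0.05, 0.5). P-values are floored at the smallest positive
normal double so extreme signals never round to an invalid p = 0.

Default sample sizes and effects are the study conditions the generator
emulates: a ~54,000-sample proteomic GWAS (`n_exposure = 54219`), a
10,312-case / 397,564-control disease GWAS (N_eff ≈ 40,200), causal pQTL
effect 0.15 SD, θ = 0.2. Scenarios H0–H4 mirror the colocalization
hypotheses; under H2/H3 the disease causal variant receives the same
magnitude `θ·b_protein + direct_effect` at a distinct position. One
causal variant per trait per region, matching the single-causal-variant
assumption of the colocalization model; multi-causal regions,
exposure/outcome sample overlap, and confounder-induced correlation are
deliberately not simulated — so the calibration results say nothing
about those failure modes in real data, where allelic heterogeneity in
particular can break both clumping and coloc.

Single-cell counts are negative binomial (default dispersion 0.5,
depth 5000 — typical droplet-data values) with log-normal baseline
means; a DE gene's mean is multiplied by `2^effect` in its (cell type,
condition) stratum. Real droplet data additionally carry batch effects,
ambient RNA and doublets, none of which are modelled; the screen here
takes cell-type labels as input and is calibrated only for
label-conditional questions.

All randomness flows from a single integer seed through an RNG-state
preserving wrapper: generation never disturbs the caller's RNG, and
identical configs are byte-reproducible (asserted down to the MTX file
bytes).

## Single-cell screen decisions

QC removes genes expressed in fewer than 3 cells, then cells with fewer
than 200 expressed genes, in that order (idempotent; asserted).
Normalization is CP10K-log1p, the common default of the standard
toolchain. The Wilcoxon test is the tie-corrected normal approximation
without continuity correction; the rank-sum statistic is checked against
exact brute-force enumeration, and the p-value against the reference
implementation. `log2FC` uses natural-scale means of `expm1(expr)` with
a 1e-9 pseudocount; significance is log2FC > 0.5 with Bonferroni p <
0.05, the Bonferroni denominator covering every comparison run in the
call. A gene is "specific to cell type T in condition C" when its
one-vs-rest test is significant in C and not in the other condition.

## Problem sizes and numerical tolerances

The suite runs its calibration at sizes chosen to give stable Monte
Carlo answers with fast feedback: 2000 null regions for the KS
uniformity check, 200 replicates for IVW bias/coverage, 100 seeds per
colocalization scenario, 500 random flag vectors for tier totality.
Oracle equivalences (IVW vs explicit normal equations, log-space coloc
vs the naive product form, rank-sum vs enumeration) are asserted at
1e-10; posterior normalization at 1e-9. The acceptance script uses the
same designs at slightly smaller replicate counts and derives every
stream from its `--seed` argument.

## Known limitations

* Single causal variant per region end to end; no fine-mapping, no
  SuSiE-style multi-causal colocalization.
* First-order ratio SEs; no MR-PRESSO, mode-based or multivariable
  estimators; no Steiger filtering.
* No proxy-SNP lookup when an instrument is missing from the outcome;
  no genome-build liftover; SNVs only.
* The LD matrix is always an explicit input (simulated or
  user-supplied); there is no reference-panel retrieval.
* Reverse MR in a single simulated region cannot distinguish direction
  at a shared variant — in real use its instruments span the genome,
  which the single-region simulations do not emulate.
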