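---
title: "Evaluating polygenic score transferability in structured cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating polygenic score transferability in structured cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgseval)
library(dplyr)
```

## The problem

A polygenic score (PGS) is a weighted sum of effect-allele dosages,
$S_j = \sum_i w_i \, d^*_{ij}$, with weights $w_i$ taken from a published
scoring file and $d^*_{ij} \in [0, 2]$ the expected count of the effect
allele in sample $j$. Scores trained on large, mostly North-European
biobanks are routinely applied to cohorts whose ancestry composition
differs — including populations with *internal* structure, such as Italy's
North–South cline and its island populations. Two distinct questions then
arise: does the score separate cases from controls in the target cohort,
and does its *distribution* shift between subpopulations in a way that
would distort any fixed percentile threshold?

`pgseval` implements the full evaluation protocol for both questions:
scoring-file harmonization and coverage accounting, weighted-dosage
scoring, distributional and contingency testing, percentile-threshold
adjusted odds ratios, covariate + PGS predictive modelling with Boruta
feature selection and DeLong AUC comparison, and all of the above
stratified by subpopulation. A synthetic-cohort generator with a known
genetic and covariate truth makes every stage testable end to end without
access to any individual-level data.

## Harmonization

Scoring files identify variants by rsID or by chromosome/position, and
state an effect allele, usually an other allele, and a weight. We match on
**(chromosome, position)** with allele reconciliation rather than on rsID:
position matching is robust to identifier drift across dbSNP builds, and
the rsID is retained only as an annotation. For each score variant with
genotype REF/ALT at the same position:

* **direct** match — \{effect, other\} equals \{REF, ALT\};
* **flip** match — the strand complements equal \{REF, ALT\};
* **ambiguous** — A/T or C/G pairs, where direct and flip are
  indistinguishable from alleles alone; dropped by default (`"keep"`
  accepts them on an as-is comparison);
* **mismatch** — irreconcilable alleles; dropped;
* **absent** — no genotype at that position.

The five counts partition the score and define
`coverage = (direct + flip) / total`, the fraction of the published score
actually represented in the cohort — worth reporting because small
GWAS-significant scores can lose 20–25% of their variants this way while
genome-wide scores lose almost none. Each match carries an orientation
flag: when the effect allele is REF, the scorer uses $2 - d$.

Multi-allelic VCF records are excluded at load (dosage semantics would be
ambiguous), variants with imputation quality `Rsq < 0.6` are dropped by
default, and a missing `Rsq` is treated as passing, which fits fully
imputed inputs and unannotated synthetic fixtures alike.

## Scoring conventions

Missing dosages are mean-imputed per variant by default, keeping scores
comparable across samples with unequal missingness (`"omit"` drops the
term instead). Standardization uses the **sample (n−1) SD**; this matters
whenever an effect is reported per SD of the score, so it is stated here
once and used everywhere. Percentiles are empirical ranks over $n$ with
ties sharing their **maximum** rank, so "above the $q$-th percentile" is
the strict comparison `percentile > q`; a tie group straddling the cut is
therefore included wholesale, the conservative direction for a
high-risk-group definition. Thresholds are computed over the full cohort
by default — whether the source studies set them on controls only is not
documented, so a `percentile_basis = "controls"` switch is provided.

## The statistical battery

Case/control distributions are compared with the two-sample
Kolmogorov–Smirnov test (exact p-value when $n_a n_b \le 10^4$ and there
are no ties, asymptotic otherwise) and the Mann–Whitney test (normal
approximation with midrank ties and continuity correction — cohorts of
hundreds to thousands make exact enumeration pointless). Categorical
contrasts use Fisher's exact test with the probability-mass two-sided rule;
the reported statistic is the sample cross-product odds ratio. A Pearson
correlation screen flags any score with $|r| > 0.75$ (strict inequality)
against a cardiometabolic covariate; sex and yes/no covariates are encoded
0/1 and smoking as ordinal no = 0, former = 1, yes = 2 (an explicit,
documented choice — switch to one-hot by encoding upstream if preferred).

Percentile odds ratios come from logistic regression of status on the
above-threshold indicator, adjusted for age, sex and BMI by default, with
everyone at or below the cut as the reference. Confidence intervals are
Wald on the log-odds scale — hence asymmetric on the OR scale — with a
profile-likelihood option; the method behind the published asymmetric
intervals is not stated, and Wald is the default convention. Complete
separation (a zero cell in the above/below × case/control table) is
flagged and reported as non-estimable with a direction, never as a number.
Adjusted fits are complete-case, and the analyzed $n$ is always reported:
per-variable missingness silently changes categorical denominators, which
is also why two published summary-table p-values with unprinted
denominators are not reproduced here.

## Predictive modelling

The protocol is: stratified 80/20 split; Boruta selection of covariates on
the training set; per score, three logistic models (covariates-only,
score-only, covariates + score) with 10×10 repeated stratified
cross-validation inside the training set; headline AUCs with DeLong 95%
CIs on the held-out 20%; and a paired DeLong test of covariates-only
versus combined on the test set. The repeated CV is treated as an internal
sanity check only (its mean AUC is logged), because a single held-out AUC
per model is what the protocol reports. The DeLong comparison is run on
the shared test set, where the paired form is valid.

Boruta here means: per iteration, every candidate feature gets a
row-permuted "shadow" copy; a random forest (via `ranger`, permutation
importance, 200 trees, depth cap 5 — the algorithm's source names no
hyperparameters, so these conservative values are exposed as arguments)
is fitted on real + shadow features, and a feature scores a hit when it
beats the best shadow. Decisions are two-sided binomial tests of the hit
count against $p = 0.5$, Bonferroni-corrected over candidates, with
rejected features leaving the active set (step-down); undecided features
stay tentative. All-tentative is a legal outcome; if nothing is confirmed
the model suite falls back to all candidates with a warning.

AUC uses the Mann–Whitney formulation (half credit for ties) computed via
midranks, and its variance DeLong's placement-value estimator; the paired
test uses the 2×2 placement covariance. Identical scores give $z = 0$,
$p = 1$ by convention. These are implemented in-package and cross-checked
in the tests against `pROC` to $10^{-10}$.

## The synthetic cohort

`sim_config()` defaults describe the study design the package is built to
exercise: four geographic macro-areas of 2030/420/744/68 samples, a
balanced case-control draw (50% cases per area), and several partially
overlapping scoring files of very different character. Genotypes follow
the **Balding–Nichols** model — the minimal standard divergence model:
ancestral frequency $p_i \sim U(0.05, 0.95)$, area frequency
$\mathrm{Beta}\!\left(p_i\frac{1-F_a}{F_a}, (1-p_i)\frac{1-F_a}{F_a}\right)$,
genotypes Hardy–Weinberg. Default $F_{ST}$ values (0.002 for the mainland
areas, 0.004 for the South, 0.015 for the island population) are of the
order reported for within-Italy differentiation, with the island
substantially more diverged.

Disease follows a liability logit:
$\mathrm{logit}\, P(\text{case}) = \beta_0 + \log(\mathrm{OR}_{SD})\, z +
\sum_c \beta_c c$, with $z$ the true score standardized over the simulated
*population* (the generator stores these constants in its truth record —
standardizing inside a balanced case-control sample inflates the SD and
would bias any per-SD effect by construction). The default
$\mathrm{OR}_{SD} = 2$ puts score-only AUCs near 0.65–0.70, the middle of
the range such evaluations report. Covariate distributions loosely follow
a young myocardial-infarction cohort (age 40 ± 4.9, ~88% male, BMI
26 ± 3.8, …); they are scaffolding for realistic adjusted models, not
claims about any population. Cases and controls are sampled per area from
a 3× oversampled pool; an unattainable case fraction is an error that
names the knobs to turn.

Four scoring files are emitted: a small rsID-dialect causal subset; a
chr:pos-dialect file over all causal variants padded with absent and
deliberately mismatched records to a configured coverage (default 77.4%)
and with 10% of records strand-complemented; a third file sharing a
configured 57% of its variants with the second; and a
**structure-confounded** score — non-causal variants with weights
proportional to the allele-frequency difference between the first two
areas plus noise. The last reproduces the signature of residual
stratification: a score that separates subpopulations without any causal
content, increasingly so as $F_{ST}$ grows. Weights were made
*proportional to the divergence axis* deliberately: weights drawn
independently of it produce a between-area shift of only ~0.25 SD at
$F_{ST} = 0.05$, too weak for a reliable KS signal at realistic area
sizes, and a confounded score, not a random one, is the phenomenon of
interest.

What the generator does **not** emulate: linkage disequilibrium (variants
are independent, so LD-aware re-weighting methods cannot be exercised),
local ancestry and admixture, genotyping/imputation error beyond the `Rsq`
annotation, and covariate–area interactions. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
generative model, not robustness to everything real cohorts do.

## Numerical choices and degenerate inputs

Logistic fits use IRLS (`glm`) tightened to $\varepsilon = 10^{-12}$, 100
iterations; rank-deficient designs are an error naming the aliased
columns; quasi-separation (fitted probabilities at 0/1 or runaway
coefficients) sets a flag rather than failing. Stratified tests skip
groups below 2 per side with a warning — small strata are legitimately
analyzable (the smallest default area has 68 samples) and wide intervals,
not exclusion, are the honest output. Stratified test matrices report raw
p-values by default, with an optional, clearly labelled
Bonferroni/BH switch. Every pipeline output file starts with a comment
header carrying the package version, run seed and configuration hash, and
a run-level seed fans out deterministically to the split, Boruta, CV and
all simulations.

Problem sizes in the test suite are chosen to make each statistical claim
decisive at a desk scale: 1000 replicates for type-I-error calibration
(binomial 99% bands around 5%), 200 replicates at $n = 4000$ for per-SD
effect recovery, $2 \times 20000$ for the binormal AUC limit, and 40
replicates at 500/area for the structure phenomenon.

## A short tour

```{r tour, eval = FALSE}
sim <- simulate_cohort(sim_config(seed = 1))

# score every emitted file and inspect coverage
res <- score_pgs_set(sim$scoring_files, sim$geno)
res$coverage

# distribution shift between areas, per score
scores_wide <- tidyr::pivot_wider(res$scores[, c("sample_id", "pgs_id", "z")],
                                  names_from = pgs_id, values_from = z)
data <- dplyr::inner_join(sim$cohort, scores_wide, by = "sample_id")
ks_matrix_wide(pairwise_area_ks(data, names(sim$scoring_files)))

# percentile odds ratios, adjusted for age, sex, BMI
raw2 <- res$scores |> dplyr::filter(pgs_id == "SIM000002")
percentile_or_table(raw2$raw[match(data$sample_id, raw2$sample_id)], data)

# the full protocol in one call, TSVs written to `out/`
cfg <- run_config(simulation = sim_config(seed = 1), seed = 1)
ev <- run_evaluate(cfg, outdir = "out")
autoplot(ev$suite)
```

## Known limitations

Percentile ORs and AUCs are estimated on the balanced case-control design;
they are not population-prevalence quantities. No per-ancestry score
recalibration (e.g., PC-based normalization) is performed — the package
stratifies, as the protocol it implements does. Genome-build liftover,
imputation and rsID resolution against external databases are out of
scope: inputs are assumed to be on one build with positions already
reconciled.
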