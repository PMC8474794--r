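---
title: "Deriving and evaluating matrisome expression signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating matrisome expression signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matrisig)
```

# The problem

Fibroblasts remodel the extracellular matrix (ECM) both when mammary
epithelium branches into the fat pad during early pregnancy and when
breast-cancer cells invade their surrounding stroma. If the two processes
share molecular machinery, the expression changes of matrisome genes in
pregnancy-associated fibroblasts (PAFs) should reappear — in part — in
tumours with a poor prognosis. `matrisig` implements the complete analysis
chain needed to test that idea: rank-product differential expression of a
tiny two-arm array experiment, matrisome filtering, construction of a
fold-change centroid, correlation-based stratification of tumour cohorts,
survival evaluation, and refinement of the signature by per-gene subgroup
screening with sign reversal of discordant ("tumour-suppressor-like")
genes.

This vignette records the model choices, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and
the numerical edge cases.

# Rank-product differential expression

With three biological replicates per arm, moderated t-statistics are
fragile; the rank product is the field's standard alternative. For probe
$g$ the package forms all $k = n_\mathrm{case} \times n_\mathrm{ctrl}$
pairwise log2 ratios (9 for the default 3 + 3 design), ranks each
comparison across probes (midranks for ties), and summarises
$\mathrm{RP}(g) = \left(\prod_{i=1}^k r_{g,i}\right)^{1/k}$, once with
ranks ascending in the ratio (down-regulation, `rp_down`) and once
descending (`rp_up`). The statistic is rank-based and therefore invariant
under any strictly monotone transform applied uniformly within a
comparison; it always lies in $[1, n_\mathrm{features}]$.

**Significance.** Condition labels are permuted (default
`n_perm = 1000`, a mandatory seed; `"exhaustive"` enumerates all
$\binom{n}{n_\mathrm{case}}$ assignments). The one-sided p-value pools
permuted rank products over *all* probes and permutations:
$p = (\#\{\mathrm{RP}^\mathrm{perm} \le \mathrm{RP}^\mathrm{obs}\} + 1) /
(n\,B + 1)$; the +1 correction keeps $p > 0$.

**Why the reported p-value is two-sided.** Each probe's direction is taken
from its fold-change sign, i.e. picked from the data. The one-sided p of
the selected direction is stochastically smaller than uniform under the
null, which would break the basic sanity requirement that null p-values
be approximately U(0,1). The reported `p_value` therefore applies the same
pooled-count formula to the direction-free statistic
$\min(\mathrm{RP_{up}}, \mathrm{RP_{down}})$, whose observed value is
exchangeable with its own permutation pool; in a 200-probe null
simulation its Kolmogorov–Smirnov distance from U(0,1) is about 0.05.
The one-sided machinery still drives the proportion of false prediction,
$\mathrm{pfp}(g) = p_\mathrm{dir}(g)\, n / \mathrm{rank}(\mathrm{RP}(g))$,
the rank-product analogue of an FDR.

**Fold changes** are ratios of condition medians on linear scale:
$\max(m_c, m_v)/\min(m_c, m_v)$, signed negative when the control median
is larger, so $|\mathrm{FC}| \ge 1$ by construction. Reported values are
rounded half away from zero to two decimals. Probes with non-positive
linear intensities are rejected rather than offset, since a ratio of
medians is meaningless at zero. The downstream significance filter is raw
$p < 0.05$ (`alpha_de`).

# Matrisome filtering and ortholog mapping

Gene-set membership is a case-insensitive symbol comparison after
whitespace stripping — no fuzzy matching. Probe multiplicity is preserved
(several probes of one gene all pass the filter), which is why probe and
gene counts differ downstream. The shipped matrisome list is a 64-symbol
excerpt adequate for tests and examples; real analyses should substitute
the published matrisome master list via `read_gene_set_tsv()`.

Mouse symbols map to human ones by uppercasing, with an override table
for renamed or dual-named genes (e.g. `Figf/Vegfd` → `VEGFD`). Overrides
win over the rule; conflicting overrides fail at load time, because a
silent arbitrary choice would corrupt the join between the DE and cohort
worlds.

# Centroids and stratification

A centroid is an ordered gene → weight map, the weights being signed fold
changes, averaged over probes per gene (a gene whose probes cancel to
exactly zero is an error — a zero weight carries no direction).

**Weight transform.** Pearson correlation against raw linear ratios would
be dominated by the largest ratios, so patient profiles are compared with
$t(w) = \mathrm{sign}(w)\,\log_2 |w|$: a fold change of +4 contributes
+2, −4 contributes −2, ±1 contributes 0. One subtlety follows: linear
rescaling of mixed-sign weights ($w \mapsto a\,w$) is *not* an affine map
of $t$ and hence not exactly invariant under Pearson correlation; powering
of the magnitudes ($|w| \mapsto |w|^a$) is the rescaling that the
transformed template inherits exactly, and that is the invariance the
test suite asserts.

**Classification.** The cohort matrix is log2-transformed (if needed) and
each gene median-centred across patients; each patient's correlation $r$
with the transformed centroid over the shared genes defines the split at
a cut-off of 0: $r > 0$ is `positive` (centroid-like), $r \le 0$
`negative` — the measure-zero tie is deliberately assigned to the
non-risk group. Centroid genes absent from the cohort are dropped with a
logged count (at least 3 shared genes are required); patients with
zero-variance profiles over the centroid genes are unclassifiable, and
more than 5% of them aborts the run. The alternative `composite_score()`
stratifier computes the mean of sign-weighted centred expression and
splits at the cohort median, scores equal to the median going to `low`.

# Survival evaluation

Follow-up is administratively truncated (default `cutoff_months = 120`,
the 10-year convention): times beyond the horizon are censored at it,
while an event exactly at the horizon is kept — administrative censoring
applies strictly beyond follow-up. Kaplan–Meier curves and the
$O\!-\!E/V$ log-rank chi-square ($g - 1$ df) are implemented directly and
verified against hand computations; the Cox model is fitted with
`survival::coxph` using the Efron tie approximation. Covariates mirror the
standard multivariate panel: ER (pos vs neg), LN (pos vs neg), grade as
the indicator grade = 3, age > 50, size > 20 mm. Unknown covariate values
exclude the patient listwise from the Cox fit (with a message) but not
from KM/log-rank. Reported per-term p-values are Wald; hazard-ratio CIs
are 95% Wald intervals. Perfect separation, non-convergence and collinear
covariates raise errors rather than returning unstable estimates.

# Refinement

`per_gene_screen()` evaluates each signature gene in each of a panel of
cohort subgroups (default: all, ER±, LN±, ER⁺/LN⁻, grades 1–3, and five
intrinsic subtypes — 14 predicates; any named list of predicates may be
substituted). Within a subgroup the gene's patients are split at the
median expression (two quantiles; ties to the low-expression half, which
makes a constant gene a degenerate but valid $p = 1$ cell), the log-rank
p is recorded, and the half with the excess of observed over expected
events defines the prognostic direction. Subgroups with fewer than 20
patients or 5 events are skipped with a log entry; genes absent from the
cohort yield missing cells.

Benjamini–Hochberg adjustment is applied **jointly across all computed
gene × subgroup cells**; the family is whatever was actually screened, so
changing the subgroup panel changes adjusted p-values — this is stated
loudly because it is the main lever on signature size. Genes with an
adjusted $p < \alpha$ in at least one subgroup enter the signature, tagged
with their most significant subgroup. A gene is a *driver* when its DE
direction matches its prognostic direction (up & high-expression-poor, or
down & low-expression-poor) and a *suppressor* otherwise; genes whose
significant cells disagree on direction are flagged ambiguous and
excluded. The refined centroid restricts to the classified genes and
negates suppressor weights, so its sign structure is prognostic rather
than developmental. An alternative screening design — per-gene
"best-separation" cut-offs instead of median splits — exists in some
web tools; the median split is implemented here because it is the only
fully specified, reproducible choice.

# Synthetic data: the stated world

Two generators make the pipeline testable end to end without downloads.

**Fibroblast arrays** (`simulate_fibroblast`): log2 intensities =
baseline (default 8, i.e. a few hundred fluorescence units) + per-gene
effect (sd 1) + planted condition effect ($\pm\log_2|fc|$ on the case
arm) + N(0, `noise_sigma`), default σ = 0.2 — typical replicate noise for
arrays, and the level at which planted |FC| ≥ 3 features are reliably
recovered by the rank product in a 3 + 3 design. Intensities are
log-normal by construction, a modelling choice, not a claim about any
particular platform.

**Tumour cohorts** (`simulate_cohort`): a latent carrier state $z \in
\{0, 1\}$ (prevalence `frac_centroid_like`, default 0.4) adds the
transformed centroid template to carriers' log2 expression; all patients
share per-gene baselines and N(0, σ = 0.5) noise, plus unrelated noise
genes. Survival is exponential with hazard
$\lambda_0 \cdot \mathrm{HR}^z$ (defaults $\lambda_0 = 0.0015$/month —
about 16% cumulative event probability over 10 years for non-carriers,
realistic for distant-metastasis endpoints — and HR = 2.42, a strong
prognostic signature), administratively censored at 180 months.
Covariates are drawn independently at typical breast-cancer prevalences
(ER⁺ 0.75, LN⁺ 0.35, grade 1/2/3 = 0.2/0.45/0.35, age > 50 0.6,
size > 20 mm 0.5, five subtypes 0.45/0.2/0.1/0.15/0.1), with an optional
odds-ratio association to the latent state for confounding experiments.

A non-obvious property makes correlation classification work here even
though non-carriers receive *no* template signal: gene-wise
median-centring places the per-gene median inside the non-carrier cluster
(carriers are a minority), so non-carriers end up offset *against* the
template direction by about $0.97\sigma$ per gene. Over ≥ 7 genes this
yields reliably negative correlations for non-carriers, and the
classification agrees with the latent state at ≥ 95% — which the suite
verifies rather than assumes.

What the generators do **not** emulate: batch structure, platform-specific
intensity distributions, correlated co-expression beyond the single latent
state, subtype-specific expression programmes, or informative censoring. A
green test therefore establishes that the statistical machinery recovers
planted truth under clean conditions, not that any particular biological
cohort would reproduce the original study's numbers.

# Numerical choices and degenerate inputs

* Permutation p-values are +1-corrected; exhaustive enumeration is exact.
* Fold-change rounding is half-away-from-zero (reporting only).
* Ties: midranks in rank products; median-split ties to the
  low-expression group; $r = 0$ to the negative group; composite score at
  the median to `low`.
* A constant gene in a screen yields $p = 1$, not an error; a constant
  patient profile is unclassifiable; a constant centroid template over the
  shared genes is an error.
* Cox equivariance (flipping group labels inverts HR) holds to 1e−6,
  limited by the fitter's convergence tolerance.
* All simulation seeds are explicit arguments; the pipeline records its
  master seed, parameters and versions in `manifest.json`, and a rerun of
  the same configuration is byte-identical.

# Known limitations

* The matrisome excerpt shipped for testing is not the full published
  list; membership counts depend on the list version.
* The per-gene screen uses median splits only; optimal-cut-off screening
  is out of scope.
* No competing risks, time-varying covariates, or proportional-hazards
  diagnostics beyond convergence checks.
* The refinement's BH family depends on the subgroup panel; results are
  only comparable across runs with the same panel.
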