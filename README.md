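# matrisig

Derivation and evaluation of prognostic matrisome RNA signatures from
small-replicate two-condition expression arrays.

## What this package is for

Stromal fibroblasts remodel the extracellular matrix (ECM) both during
normal mammary branching morphogenesis — for example in early pregnancy —
and during breast-cancer invasion. A recurring analysis pattern in this
field is:

1. profile fibroblasts from two conditions (e.g. day-3-pregnant vs
   age-matched virgin mice) on expression arrays with very few biological
   replicates (n = 3 per arm);
2. call differential expression with the **rank-product** statistic, which
   is robust at tiny sample sizes;
3. restrict the hits to the **matrisome** (core ECM, ECM-modifying enzymes,
   matricellular proteins, secreted factors);
4. use the signed fold changes of the human orthologues as a
   **fold-change centroid** and stratify tumour cohorts by the sign of the
   Pearson correlation between each patient's centred log2 profile and the
   centroid (or by a weighted median-split composite score);
5. evaluate the split by Kaplan–Meier / log-rank / multivariate Cox
   proportional hazards with a 10-year follow-up cut-off;
6. **refine** the signature: screen each gene's prognostic effect across
   cohort subgroups with median splits, adjust jointly by
   Benjamini–Hochberg, keep genes significant in any subgroup, and reverse
   the centroid signs of genes whose prognostic direction opposes their
   differential expression (tumour-suppressor-like behaviour).

`matrisig` implements this entire pipeline as tested, reusable R functions
plus a command-line driver, together with seeded synthetic-data generators
(planted fold-change arrays; tumour cohorts with a latent signature-like
state carrying a known hazard ratio) so every stage can be exercised and
validated without any external download.

## Core statistics

- **Rank product**: for probe *g* with ranks *r(g,i)* across *k* = n_case ×
  n_ctrl pairwise case/control comparisons, RP(g) = (∏ r(g,i))^(1/k).
  Significance is by permutation of condition labels; the one-sided p is
  the pooled proportion of permuted RPs ≤ the observed one (+1-corrected),
  the reported p-value applies the same formula to the two-sided statistic
  min(RP_up, RP_down), and pfp (proportion of false prediction, the RP
  analogue of FDR) is p·n/rank.
- **Signed fold change**: max(median_case, median_ctrl) / min(...), signed
  negative when control is higher, so |FC| ≥ 1 always.
- **Centroid classification**: Pearson r between a patient's gene-wise
  median-centred log2 profile and sign(w)·log2|w| of the centroid weights;
  r > 0 ⇒ centroid-like (poor-prognosis candidate) group.
- **Survival**: product-limit curves, the O−E/V log-rank chi-square, and
  Cox proportional hazards (Efron ties; Wald CIs) with the standard
  breast-cancer covariates (ER, LN, grade 3, age > 50, size > 20 mm).

## Worked example

```r
library(matrisig)

# the shipped 18-gene signature (7 suppressor-like genes already reversed)
cen <- paf18_signature()
cen
#> <centroid> 18 genes (7 up, 11 down)

# a synthetic 1000-patient cohort: 40% of patients carry the
# signature-like expression state, which has a true hazard ratio of 2.42
sim <- simulate_cohort(cohort_sim_spec(n_patients = 1000, cent = cen, seed = 7))

# stratify by centroid correlation and evaluate with a 10-year cut-off
strat <- classify_by_centroid(sim$expr, cen)
table(strat$group)
#> negative positive
#>      592      408

clin <- apply_followup_cutoff(sim$clinical, 120)
cox_fit(clin, strat, c("er", "ln", "grade3", "age_gt50", "size_gt20mm"))
#> log-rank p = 7.631e-17; Cox fit on 1000 patients (0 excluded)
#>         term               hr            p
#>        group 2.88 (2.22-3.72) 1.081560e-15
#>           er 1.00 (0.75-1.33) 9.836800e-01
#>           ln 1.14 (0.88-1.48) 3.127221e-01
#>       grade3 1.31 (1.02-1.70) 3.789525e-02
#>     age_gt50 1.02 (0.79-1.31) 9.011676e-01
#>  size_gt20mm 0.96 (0.75-1.24) 7.733016e-01

# agreement between the classification and the planted latent state
mean((strat$group == "positive") == (sim$latent == 1))
#> [1] 0.998
```

The stratification recovers the planted carrier state almost perfectly and
the adjusted hazard ratio (2.88, CI 2.22–3.72 at this seed) brackets the
simulated truth of 2.42; only the group term and (weakly) grade carry
signal, as simulated.

For the full workflow from raw arrays — DE, matrisome filter, ortholog
mapping, centroid, stratification, subgroup screening, BH adjustment,
sign-reversal refinement and re-stratification — see `?run_pipeline` and
the command-line verbs in `?matrisig_main`
(`de`, `filter`, `centroid`, `stratify`, `survive`, `screen`, `refine`,
`simulate`, `run`).

## Vignette

`vignettes/matrisome-signatures.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generators do and do not emulate, and the numerical edge
cases (tie-breaks, degenerate splits, zero-variance profiles).
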