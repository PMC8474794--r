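#' Specification for a small-replicate fibroblast array simulation
#'
#' Emulates a two-arm bead-array experiment with a handful of biological
#' replicates per arm: log-normal intensities with per-gene baselines and
#' planted signed fold changes on chosen features.
#'
#' @param n_features number of probes.
#' @param n_case,n_ctrl replicates per arm (default 3 + 3, the
#'   small-replicate design the pipeline targets).
#' @param planted data.frame with columns `feature` (index or probe id)
#'   and `fc` (signed fold change, `|fc| >= 1`); may be empty.
#' @param noise_sigma log2-scale noise standard deviation (default 0.2,
#'   typical array replicate noise).
#' @param baseline log2 location of intensities (default 8, i.e. median
#'   intensities of a few hundred fluorescence units).
#' @param gene_sd log2 spread of per-gene baselines (default 1).
#' @param seed integer seed.
#' @return a `fibroblast_sim_spec` list.
#' @export
fibroblast_sim_spec <- function(n_features = 200, n_case = 3, n_ctrl = 3,
                                planted = data.frame(feature = integer(),
                                                     fc = numeric()),
                                noise_sigma = 0.2, baseline = 8,
                                gene_sd = 1, seed = 1) {
  stopifnot(n_features >= 1, n_case >= 2, n_ctrl >= 2, noise_sigma >= 0)
  if (nrow(planted) > 0) {
    if (any(abs(planted$fc) < 1))
      stop("planted fold changes must have |fc| >= 1")
    if (is.numeric(planted$feature) &&
        any(planted$feature < 1 | planted$feature > n_features))
      stop("planted feature index out of range")
  }
  structure(list(n_features = n_features, n_case = n_case, n_ctrl = n_ctrl,
                 planted = planted, noise_sigma = noise_sigma,
                 baseline = baseline, gene_sd = gene_sd, seed = seed),
            class = "fibroblast_sim_spec")
}

#' Simulate a two-arm fibroblast expression array
#'
#' Log2 intensities are `baseline + gene effect + condition effect +
#' N(0, noise_sigma)`, where the condition effect adds
#' `sign(fc) * log2(|fc|)` to the case arm of each planted feature; the
#' matrix is returned on linear scale with condition labels.  In the
#' noiseless limit each planted feature's case/control median ratio equals
#' its planted fold change exactly.
#'
#' @param spec a [fibroblast_sim_spec()].
#' @return an [expr_matrix()] (linear scale, `case`/`control` labels);
#'   probe ids are `probe_0001`, ... with planted features recorded in the
#'   `planted` attribute.
#' @export
simulate_fibroblast <- function(spec) {
  stopifnot(inherits(spec, "fibroblast_sim_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_features
    ids <- sprintf("probe_%04d", seq_len(n))
    pl <- spec$planted
    idx <- if (nrow(pl) == 0) integer(0)
           else if (is.numeric(pl$feature)) as.integer(pl$feature)
           else match(pl$feature, ids)
    if (anyNA(idx)) stop("planted feature not found")
    delta <- numeric(n)
    delta[idx] <- sign(pl$fc) * log2(abs(pl$fc))

    n_samp <- spec$n_case + spec$n_ctrl
    gene_eff <- stats::rnorm(n, 0, spec$gene_sd)
    L <- matrix(spec$baseline + gene_eff, n, n_samp) +
      matrix(stats::rnorm(n * n_samp, 0, spec$noise_sigma), n, n_samp)
    L[, seq_len(spec$n_case)] <- L[, seq_len(spec$n_case)] + delta
    colnames(L) <- c(sprintf("case_%d", seq_len(spec$n_case)),
                     sprintf("ctrl_%d", seq_len(spec$n_ctrl)))
    rownames(L) <- ids
    cond <- stats::setNames(rep(c("case", "control"),
                                c(spec$n_case, spec$n_ctrl)), colnames(L))
    out <- expr_matrix(2^L, scale = "linear", condition = cond)
    attr(out, "planted") <- ids[idx]
    out
  })
}

#' Specification for a tumour-cohort simulation
#'
#' Emulates a breast-tumour expression cohort in which a latent
#' "signature-like" stromal expression state carries a proportional-hazards
#' effect on survival: carriers' log2 expression follows the transformed
#' centroid template, survival times are exponential with hazard
#' `baseline_hazard * hr_true^state`, follow-up is administratively
#' censored, and standard clinical covariates are drawn at stated
#' prevalences (optionally with an odds association to the latent state
#' for confounding experiments).
#'
#' @param n_patients cohort size (default 1881, the scale of the public
#'   breast-cancer compendium the pipeline targets).
#' @param cent a [centroid()] defining the expression template.
#' @param frac_centroid_like proportion of carriers (default 0.4).
#' @param hr_true hazard ratio of the latent state (default 2.42, a
#'   strong prognostic signature).
#' @param baseline_hazard events per month for non-carriers (default
#'   0.0015, about 16% cumulative event probability over 10 years).
#' @param admin_censor_months end of follow-up (default 180).
#' @param noise_sigma log2 expression noise sd (default 0.5).
#' @param n_noise_genes unrelated genes added to the matrix (default 50).
#' @param prevalences named list of covariate prevalences:
#'   `er` (pos), `ln` (pos), `age_gt50`, `size_gt20mm`; `grade` and
#'   `subtype` are probability vectors.
#' @param state_or odds ratio linking covariate positivity to the latent
#'   state (1 = independent draws).
#' @param seed integer seed.
#' @return a `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_patients = 1881, cent, frac_centroid_like = 0.4,
                            hr_true = 2.42, baseline_hazard = 0.0015,
                            admin_censor_months = 180, noise_sigma = 0.5,
                            n_noise_genes = 50,
                            prevalences = list(
                              er = 0.75, ln = 0.35, age_gt50 = 0.6,
                              size_gt20mm = 0.5,
                              grade = c(`1` = 0.2, `2` = 0.45, `3` = 0.35),
                              subtype = c(lumA = 0.45, lumB = 0.2, her2 = 0.1,
                                          basal = 0.15, normal = 0.1)),
                            state_or = 1, seed = 1) {
  stopifnot(inherits(cent, "centroid"),
            frac_centroid_like >= 0, frac_centroid_like <= 1,
            hr_true > 0, baseline_hazard > 0, admin_censor_months > 0,
            noise_sigma >= 0, state_or > 0)
  for (v in c("er", "ln", "age_gt50", "size_gt20mm"))
    stopifnot(prevalences[[v]] >= 0, prevalences[[v]] <= 1)
  structure(list(n_patients = n_patients, cent = cent,
                 frac_centroid_like = frac_centroid_like, hr_true = hr_true,
                 baseline_hazard = baseline_hazard,
                 admin_censor_months = admin_censor_months,
                 noise_sigma = noise_sigma, n_noise_genes = n_noise_genes,
                 prevalences = prevalences, state_or = state_or, seed = seed),
            class = "cohort_sim_spec")
}

# bernoulli draw whose odds are multiplied by `or` for carriers
.draw_assoc <- function(p, z, or) {
  odds <- p / (1 - p) * ifelse(z == 1, or, 1)
  stats::rbinom(length(z), 1, odds / (1 + odds))
}

#' Simulate a tumour cohort with a latent signature-like state
#'
#' @param spec a [cohort_sim_spec()].
#' @return list with `expr` (log2-scale [expr_matrix()], genes x
#'   patients), `clinical` (a [clinical_table()]) and `latent` (named 0/1
#'   vector of carrier states — the ground truth).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (length(spec$cent) == 0) stop("empty centroid")
  .with_seed(spec$seed, {
    n <- spec$n_patients
    ids <- sprintf("pt_%05d", seq_len(n))
    z <- stats::rbinom(n, 1, spec$frac_centroid_like)
    names(z) <- ids

    t <- transform_weights(spec$cent)
    genes <- c(names(t), sprintf("noise_gene_%03d", seq_len(spec$n_noise_genes)))
    template <- c(as.numeric(t), rep(0, spec$n_noise_genes))
    base_g <- stats::rnorm(length(genes), 7, 1)
    E <- matrix(base_g, length(genes), n) +
      outer(template, as.numeric(z)) +
      matrix(stats::rnorm(length(genes) * n, 0, spec$noise_sigma),
             length(genes), n)
    rownames(E) <- genes
    colnames(E) <- ids

    rate <- spec$baseline_hazard * spec$hr_true^z
    T_event <- stats::rexp(n, rate)
    time <- pmin(T_event, spec$admin_censor_months)
    event <- as.numeric(T_event <= spec$admin_censor_months)

    pv <- spec$prevalences
    er <- .draw_assoc(pv$er, z, spec$state_or)
    ln <- .draw_assoc(pv$ln, z, spec$state_or)
    clin <- clinical_table(data.frame(
      sample_id = ids,
      time = time, event = event, endpoint = "DMFS",
      er = ifelse(er == 1, "pos", "neg"),
      ln = ifelse(ln == 1, "pos", "neg"),
      grade = as.integer(sample(names(pv$grade), n, TRUE, pv$grade)),
      age_gt50 = stats::rbinom(n, 1, pv$age_gt50) == 1,
      size_gt20mm = stats::rbinom(n, 1, pv$size_gt20mm) == 1,
      subtype = sample(names(pv$subtype), n, TRUE, pv$subtype),
      stringsAsFactors = FALSE))

    list(expr = expr_matrix(E, scale = "log2"),
         clinical = clin,
         latent = z)
  })
}
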