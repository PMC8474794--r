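test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # a worked mixed case: p = (0.005, 0.04, 0.03, 0.9)
  # sorted: .005 -> .02, .03 -> .06, .04 -> .053.. -> cummin .053.., .9
  expect_equal(bh_adjust(c(0.005, 0.04, 0.03, 0.9)),
               c(0.02, 0.04 * 4 / 3, 0.04 * 4 / 3, 0.9))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("bh_adjust is monotone, bounded, and identity on step-up-tight input", {
  set.seed(21)
  for (i in 1:5) {
    p <- runif(30)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # order statistics of adjusted follow those of raw
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # agrees with the reference implementation in stats
    expect_equal(adj, p.adjust(p, "BH"))
  }
  # already satisfying the step-up bound exactly: p_i = i * alpha / n
  n <- 8; p <- (1:n) * 0.4 / n
  expect_equal(bh_adjust(p), rep(0.4, n))  # n*p_i/i = 0.4 for all i
})

screen_fixture <- function() {
  sm <- data.frame(
    gene = rep(c("G1", "G2", "G3"), each = 2),
    subgroup = rep(c("all", "er_pos"), 3),
    raw_p = c(0.001, 0.2, 0.5, 0.04, NA, 0.8),
    adj_p = NA_real_,
    direction = c("high-poor", "high-poor", "low-poor", "low-poor",
                  NA, "high-poor"),
    n = 100, n_events = 30, stringsAsFactors = FALSE)
  class(sm) <- c("screen_matrix", "data.frame")
  bh_adjust_screen(sm)
}

test_that("bh_adjust_screen adjusts jointly over computed cells only", {
  sm <- screen_fixture()
  expect_true(is.na(sm$adj_p[is.na(sm$raw_p)]))
  ok <- !is.na(sm$raw_p)
  expect_equal(sm$adj_p[ok], p.adjust(sm$raw_p[ok], "BH"))
  expect_true(all(sm$adj_p[ok] >= sm$raw_p[ok]))
})

test_that("select_signature respects alpha with exact boundary behaviour", {
  sm <- screen_fixture()
  expect_equal(nrow(select_signature(sm, alpha = 0)), 0)
  all_g <- select_signature(sm, alpha = 1)
  expect_setequal(all_g$gene, c("G1", "G2", "G3"))  # every screened gene
  hit <- select_signature(sm, alpha = 0.05)
  expect_equal(hit$gene, "G1")
  expect_equal(hit$best_subgroup, "all")
  # monotone in alpha
  alphas <- c(0, 0.01, 0.1, 0.5, 1)
  sizes <- vapply(alphas, function(a) nrow(select_signature(sm, a)), 1)
  expect_true(all(diff(sizes) >= 0))
})

test_that("per_gene_screen computes subgroup cells from subgroup data only", {
  cen <- centroid(c(G1 = 3, G2 = -2.5, G3 = 2))
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 300, cent = cen,
                                         hr_true = 3, n_noise_genes = 5,
                                         seed = 31))
  ct <- apply_followup_cutoff(sim$clinical, 120)
  subs <- list(er_pos = function(ct) ct$er == "pos",
               er_neg = function(ct) ct$er == "neg")
  sm <- per_gene_screen(sim$expr, ct, c("G1", "G2"), subgroups = subs)
  # oracle: recompute each cell on the manually subset data
  for (sg in names(subs)) {
    sel <- subs[[sg]](ct)
    for (g in c("G1", "G2")) {
      x <- sim$expr$values[g, ct$sample_id[sel]]
      hi <- x > median(x)
      lr <- logrank(ct$time[sel], ct$event[sel], ifelse(hi, "high", "low"))
      cell <- sm[sm$gene == g & sm$subgroup == sg, ]
      expect_equal(cell$raw_p, lr$p_value)
    }
  }
})

test_that("per_gene_screen flags degenerate and missing genes", {
  cen <- centroid(c(G1 = 3, G2 = -2.5, G3 = 2))
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 120, cent = cen,
                                         n_noise_genes = 2, seed = 5))
  ct <- apply_followup_cutoff(sim$clinical, 120)
  flat <- sim$expr
  flat$values["G3", ] <- 4.2   # identical in all patients
  expect_message(
    sm <- per_gene_screen(flat, ct, c("G1", "G3", "ABSENT"),
                          subgroups = list(all = function(ct)
                            rep(TRUE, nrow(ct)))),
    "not found")
  expect_equal(sm$raw_p[sm$gene == "G3"], 1)       # no information
  expect_true(is.na(sm$raw_p[sm$gene == "ABSENT"]))
  # small subgroups are skipped with a log entry
  subs <- list(tiny = function(ct) seq_len(nrow(ct)) <= 10)
  expect_message(sm2 <- per_gene_screen(sim$expr, ct, "G1", subgroups = subs),
                 "skipped")
  expect_true(is.na(sm2$raw_p[1]))
})

test_that("a planted high-risk gene screens significant in the full cohort", {
  cen <- centroid(c(G = 4))
  # G's carriers (40%) have HR 3; n = 600
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 600,
                                         cent = centroid(c(G = 4, H = 2, I = 2)),
                                         hr_true = 3, seed = 61))
  ct <- apply_followup_cutoff(sim$clinical, 120)
  sm <- per_gene_screen(sim$expr, ct, "G",
                        subgroups = list(all = function(ct)
                          rep(TRUE, nrow(ct))))
  expect_lt(sm$raw_p[1], 0.01)
  expect_equal(sm$direction[1], "high-poor")
})

test_that("classify_direction applies the concordance rule", {
  de <- data.frame(probe_id = c("a", "b", "c"),
                   gene_symbol = c("POSTN", "VCAN", "SFRP1"),
                   fold_change = c(1.785, 3.1, -2.21),
                   p_value = 0.001, pfp = 0.01,
                   direction = c("up", "up", "down"),
                   stringsAsFactors = FALSE)
  class(de) <- c("de_table", "data.frame")
  sm <- data.frame(
    gene = c("POSTN", "VCAN", "SFRP1"),
    subgroup = "all",
    raw_p = c(0.001, 0.001, 0.001),
    adj_p = c(0.01, 0.01, 0.01),
    direction = c("high-poor", "low-poor", "low-poor"),
    n = 500, n_events = 100, stringsAsFactors = FALSE)
  class(sm) <- c("screen_matrix", "data.frame")
  calls <- classify_direction(de, sm)
  expect_equal(calls$concordance[calls$gene == "POSTN"], "driver")
  expect_equal(calls$concordance[calls$gene == "VCAN"], "suppressor")
  expect_equal(calls$concordance[calls$gene == "SFRP1"], "driver")
})

test_that("conflicting significant directions are flagged ambiguous", {
  de <- data.frame(probe_id = "a", gene_symbol = "G1", fold_change = 2,
                   p_value = 0.001, pfp = 0.01, direction = "up",
                   stringsAsFactors = FALSE)
  class(de) <- c("de_table", "data.frame")
  sm <- data.frame(gene = "G1", subgroup = c("all", "er_neg"),
                   raw_p = c(0.001, 0.002), adj_p = c(0.01, 0.02),
                   direction = c("high-poor", "low-poor"),
                   n = 400, n_events = 90, stringsAsFactors = FALSE)
  class(sm) <- c("screen_matrix", "data.frame")
  calls <- classify_direction(de, sm)
  expect_equal(calls$concordance, "ambiguous")
  expect_error(build_refined_centroid(centroid(c(G1 = 2)), calls),
               "no unambiguous")
})

test_that("build_refined_centroid restricts and reverses suppressors", {
  cen <- paf18_signature(refined = FALSE)
  calls <- data.frame(
    gene = c("POSTN", "WISP2", "VCAN", "TGFBI"),
    de_direction = c("up", "down", "up", "down"),
    prognostic_direction = c("high-poor", "low-poor", "low-poor", "high-poor"),
    concordance = c("driver", "driver", "suppressor", "suppressor"),
    stringsAsFactors = FALSE)
  refined <- build_refined_centroid(cen, calls)
  expect_equal(length(refined), 4)
  expect_equal(unname(refined$weights["POSTN"]), 1.785)
  expect_equal(unname(refined$weights["VCAN"]), -3.1)
  expect_equal(unname(refined$weights["TGFBI"]), 1.73)
  expect_error(build_refined_centroid(cen,
    transform(calls, gene = c("POSTN", "WISP2", "VCAN", "NOPE"))),
    "missing from centroid")
})

test_that("the shipped 18-gene signature encodes the documented reversals", {
  raw <- paf18_signature(refined = FALSE)
  refined <- paf18_signature(refined = TRUE)
  flipped <- names(raw$weights)[sign(raw$weights) != sign(refined$weights)]
  expect_setequal(flipped,
                  c("VCAN", "TIMP1", "IGF1", "SLIT2", "TGFBI", "CTSC", "VTN"))
  expect_equal(length(refined), 18)
})

test_that("end-to-end refinement recovers the planted suppressor set", {
  sc <- planted_scenario()
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 600, cent = sc$truth,
                                         hr_true = 2.42, seed = 77))
  ct <- apply_followup_cutoff(sim$clinical, 120)
  sm <- bh_adjust_screen(per_gene_screen(sim$expr, ct,
                                         names(sc$full$weights)))
  calls <- classify_direction(sc$de, sm)
  expect_setequal(calls$gene[calls$concordance == "suppressor"],
                  sc$suppressors)
  refined <- build_refined_centroid(sc$full, calls)
  expect_equal(sign(refined$weights[names(sc$truth$weights)]),
               sign(sc$truth$weights))
})
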