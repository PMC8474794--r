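# cohort matrix where each patient's profile is a multiple of the
# transformed template plus optional noise
template_cohort <- function(cent, coefs, noise = 0, seed = 1) {
  t <- matrisig:::transform_weights(cent)
  set.seed(seed)
  m <- outer(as.numeric(t), coefs) +
    matrix(rnorm(length(t) * length(coefs), 0, noise), length(t))
  rownames(m) <- names(t)
  colnames(m) <- sprintf("pt_%03d", seq_along(coefs))
  expr_matrix(m, scale = "log2")
}

test_that("build_centroid averages probes per gene and rejects degenerates", {
  de <- data.frame(probe_id = c("a", "b", "c"),
                   gene_symbol = c("Gpc1", "Tnc", "Tnc"),
                   fold_change = c(3.74, 2.38, 2.4),
                   p_value = 0.001, pfp = 0.01, direction = "up",
                   stringsAsFactors = FALSE)
  class(de) <- c("de_table", "data.frame")
  cen <- build_centroid(de)
  expect_equal(unname(cen$weights["Gpc1"]), 3.74)
  expect_equal(unname(cen$weights["Tnc"]), 2.39)
  expect_error(build_centroid(de[0, ]), "empty")
  de$fold_change <- c(3.74, 2, -2)   # probes cancel
  expect_error(build_centroid(de), "zero")
})

test_that("reverse_signs negates listed genes and is an involution", {
  cen <- centroid(c(VCAN = 3.1, POSTN = 1.785, WISP2 = -3.31))
  r <- reverse_signs(cen, "VCAN")
  expect_equal(unname(r$weights["VCAN"]), -3.1)
  expect_equal(unname(r$weights["POSTN"]), 1.785)
  expect_identical(reverse_signs(r, "VCAN")$weights, cen$weights)
  expect_identical(reverse_signs(cen, character())$weights, cen$weights)
  expect_error(reverse_signs(cen, "NOPE"), "not in centroid")
  # involution for arbitrary subsets
  cen18 <- paf18_signature(refined = FALSE)
  sub <- names(cen18$weights)[c(2, 5, 11, 17)]
  expect_equal(reverse_signs(reverse_signs(cen18, sub), sub)$weights,
               cen18$weights)
})

test_that("centroid_correlation matches hand computations", {
  cen <- centroid(c(A = 4, B = 2, C = -4))   # transformed: 2, 1, -2
  t <- c(A = 2, B = 1, C = -2)
  expect_equal(centroid_correlation(t, cen), 1)
  expect_equal(centroid_correlation(-t, cen), -1)
  # centred template (1, 0, -1) against profile (0, 1, 0): r = 0
  cen2 <- centroid(c(A = 2, B = 1, C = 1 / 2))  # transformed: 1, 0, -1
  expect_equal(centroid_correlation(c(A = 0, B = 1, C = 0), cen2), 0)
  expect_error(centroid_correlation(c(A = 1, B = 2), cen), "3 genes")
  expect_error(centroid_correlation(c(A = 1, B = 1, C = 1), cen),
               "zero variance")
})

test_that("classify_by_centroid splits by correlation sign, ties to negative", {
  cen <- paf18_signature()
  x <- template_cohort(cen, c(1, -1))
  s <- classify_by_centroid(x, cen)
  expect_equal(s$group, c("positive", "negative"))
  expect_equal(s$score, c(1, -1))
})

test_that("classification flips under a fully reversed centroid", {
  cen <- paf18_signature()
  x <- template_cohort(cen, seq(-1, 1, length.out = 11), noise = 0.4)
  a <- classify_by_centroid(x, cen)
  b <- classify_by_centroid(x, reverse_signs(cen, names(cen$weights)))
  nonzero <- a$score != 0
  expect_identical(a$group[nonzero] == "positive",
                   b$group[nonzero] == "negative")
})

test_that("classification is invariant to per-gene location shifts", {
  cen <- paf18_signature()
  x <- template_cohort(cen, c(1.2, 0.5, -0.3, -1, 0.8), noise = 0.3)
  shifted <- x
  shifted$values <- x$values + rnorm(nrow(x$values), 0, 5)
  a <- classify_by_centroid(x, cen)
  b <- classify_by_centroid(shifted, cen)
  expect_equal(a$score, b$score)
})

test_that("classification is invariant to powering the weight magnitudes", {
  # |w| -> |w|^a rescales the signed-log template by a > 0, which Pearson
  # correlation ignores; plain linear rescaling of mixed-sign weights is
  # not an affine map of the template and is not expected to be invariant
  cen <- paf18_signature()
  x <- template_cohort(cen, c(1, 0.2, -0.7, 0.4), noise = 0.3, seed = 7)
  pow <- centroid(sign(cen$weights) * abs(cen$weights)^1.7)
  expect_equal(classify_by_centroid(x, cen)$score,
               classify_by_centroid(x, pow)$score)
})

test_that("centroid genes absent from the cohort are dropped with a note", {
  cen <- paf18_signature()
  x <- template_cohort(cen, c(1, -1, 0.5, -0.4), noise = 0.1)
  x$values <- x$values[1:10, , drop = FALSE]   # drop 8 signature genes
  expect_message(s <- classify_by_centroid(x, cen), "not found in cohort")
  expect_length(attr(s, "dropped_genes"), 8)
  tiny <- x; tiny$values <- tiny$values[1:2, , drop = FALSE]
  expect_error(classify_by_centroid(tiny, cen), "3 centroid genes")
})

test_that("classification recovers the planted latent state", {
  cen <- paf18_signature()
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 500, cent = cen,
                                         seed = 42))
  s <- classify_by_centroid(sim$expr, cen)
  agree <- mean((s$group == "positive") == (sim$latent == 1))
  expect_gte(agree, 0.95)
})

test_that("composite_score is a median split with monotone scores", {
  cen <- centroid(c(A = 2, B = -2, C = 4))
  set.seed(5)
  m <- matrix(rnorm(3 * 40, 7, 1), 3, 40,
              dimnames = list(c("A", "B", "C"), sprintf("pt_%02d", 1:40)))
  # one patient maximizes every positively-weighted gene and minimizes
  # the negatively-weighted one
  m[c("A", "C"), 40] <- 20
  m["B", 40] <- 0
  s <- composite_score(expr_matrix(m, scale = "log2"), cen)
  expect_equal(which.max(s$score), 40L)
  expect_lte(abs(sum(s$group == "high") - sum(s$group == "low")), 1)
  # a patient sitting exactly at the cohort medians scores exactly 0
  m2 <- matrix(c(1, 5, 9,
                 2, 6, 10,
                 0, 4, 8), nrow = 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("p1", "p2", "p3")))
  s2 <- composite_score(expr_matrix(m2, scale = "log2"), cen)
  expect_equal(s2$score[2], 0)
  expect_equal(s2$group[2], "low")   # median tie goes to low
})

test_that("centroids and stratifications round-trip through TSV", {
  cen <- paf18_signature()
  f <- tempfile(fileext = ".tsv")
  write_centroid_tsv(cen, f)
  back <- read_centroid_tsv(f)
  expect_equal(back$weights, cen$weights)
  x <- template_cohort(cen, c(1, -1, 0.3, -0.6), noise = 0.1)
  s <- classify_by_centroid(x, cen)
  f2 <- tempfile(fileext = ".tsv")
  write_stratification_tsv(s, f2)
  back2 <- read.delim(f2, stringsAsFactors = FALSE)
  expect_equal(back2$group, s$group)
})
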