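test_that("unique signatures are plain set differences", {
  s <- derive_unique_signatures(c("a", "b"), "c")
  expect_identical(sort(s$R_unique$genes), c("a", "b"))
  expect_identical(s$NR_unique$genes, "c")
  s2 <- derive_unique_signatures(c("a", "b", "c"), c("c", "d"))
  expect_identical(sort(s2$R_unique$genes), c("a", "b"))
  expect_identical(s2$NR_unique$genes, "d")
  expect_error(derive_unique_signatures(c("a", "b"), c("a", "b")),
               "classifier undefined")
  expect_error(derive_unique_signatures(character(0), "a"), "non-empty")
  expect_error(gene_signature("empty", character(0)), "no genes")
})

test_that("scores are cohort z-score means with the zero-sd rule", {
  set.seed(31)
  expr <- matrix(rnorm(10 * 8, 50, 5), 10, 8,
                 dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:8)))
  sig <- gene_signature("sig", c("g01", "g03", "g05"))
  sc <- score_samples(expr, sig)
  oracle <- colMeans(t(scale(t(expr[sig$genes, ]))))
  expect_equal(unname(sc), unname(oracle), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant genes contribute 0 -> all-constant signature scores 0
  expr[c(1, 3, 5), ] <- 7
  expect_equal(unname(score_samples(expr, sig)), rep(0, 8),
               ignore_attr = TRUE)
})

test_that("a uniformly elevated sample gets the top score", {
  set.seed(32)
  expr <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:10)))
  expr[1:5, 10] <- expr[1:5, 10] + 5
  sc <- score_samples(expr, sprintf("g%02d", 1:5))
  expect_equal(unname(which.max(sc)), 10)
  expect_gt(sc["s10"], max(sc[-10]) + 1)
})

test_that("symbol matching is case-insensitive and coverage is enforced", {
  expr <- matrix(rnorm(4 * 5), 4, 5,
                 dimnames = list(c("TP53", "brca1", " KRAS ", "MYC"),
                                 paste0("s", 1:5)))
  sc <- score_samples(expr, c("tp53", "BRCA1", "KRAS"))
  expect_equal(attr(sc, "n_matched"), 3)
  expect_error(score_samples(expr, c("TP53", "NPM1", "FLT3", "WT1"),
                             scoring_policy(min_gene_coverage = 0.5)),
               "NPM1")
  expect_error(score_samples(expr[, 1:2, drop = FALSE], "TP53"), "3 samples")
})

test_that("scores are invariant to rescaling and per-gene shifts", {
  set.seed(33)
  expr <- matrix(rlnorm(30 * 12, 3, 1), 30, 12,
                 dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:12)))
  sig_r <- sprintf("g%02d", 1:8); sig_nr <- sprintf("g%02d", 21:30)
  base <- score_cohort(expr, sig_r, sig_nr)
  scaled <- score_cohort(expr * 37.5, sig_r, sig_nr)
  expect_equal(scaled[c("r_score", "nr_score", "delta")],
               base[c("r_score", "nr_score", "delta")], tolerance = 1e-12)
  shifted <- expr; shifted["g05", ] <- shifted["g05", ] + 100
  expect_equal(score_cohort(shifted, sig_r, sig_nr)$delta, base$delta,
               tolerance = 1e-12)
  # labels and strata equally unchanged
  a <- stratify_within_class(classify_delta(base))
  b <- stratify_within_class(classify_delta(scaled))
  expect_identical(a$label, b$label)
  expect_identical(a$stratum, b$stratum)
})

test_that("raising NR-signature genes in one sample cannot lower its delta", {
  set.seed(34)
  expr <- matrix(rlnorm(30 * 12, 3, 1), 30, 12,
                 dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:12)))
  sig_r <- sprintf("g%02d", 1:8); sig_nr <- sprintf("g%02d", 21:30)
  for (bump in c(0.5, 2, 10)) {
    before <- score_cohort(expr, sig_r, sig_nr)
    pushed <- expr
    pushed[sig_nr, 4] <- pushed[sig_nr, 4] + bump
    after <- score_cohort(pushed, sig_r, sig_nr)
    expect_gte(after$delta[4], before$delta[4])
  }
})

test_that("median split follows the >= rule", {
  sc <- data.frame(sample_id = paste0("s", 1:5), r_score = 0,
                   nr_score = c(5, 3, 1, 2, 4), delta = c(5, 3, 1, 2, 4))
  lab <- classify_delta(sc)
  expect_equal(lab$label[lab$delta == 3], "NR_like")  # the median sample
  expect_equal(sum(lab$label == "NR_like"), 3)
  same <- within(sc, {delta <- 2; nr_score <- 2})
  expect_true(all(classify_delta(same)$label == "NR_like"))
  expect_error(classify_delta(sc[1, ]), "at least 2")
})

test_that("even cohorts with distinct deltas split exactly in half", {
  for (s in 1:10) {
    set.seed(40 + s)
    n <- sample(c(4, 10, 50), 1)
    sc <- data.frame(sample_id = seq_len(n), r_score = 0,
                     nr_score = sample(seq_len(1000), n))
    sc$delta <- sc$nr_score
    lab <- classify_delta(sc)
    expect_equal(sum(lab$label == "NR_like"), n / 2)
    expect_equal(sum(table(lab$label)), n)
  }
})

test_that("within-class stratification median-splits the class's own score", {
  sc <- data.frame(sample_id = paste0("s", 1:6), r_score = c(1, 2, 9, 9, 9, 9),
                   nr_score = c(10, 4, 0, 0, 0, 0))
  sc$delta <- sc$nr_score - sc$r_score
  lab <- classify_delta(sc)
  st <- stratify_within_class(lab)
  nr <- st[st$label == "NR_like", ]
  expect_setequal(st$stratum[st$nr_score == 10 & st$label == "NR_like"], "high")
  # ties at the class median go high
  tied <- data.frame(sample_id = 1:4, r_score = 1, nr_score = 1,
                     delta = c(1, 1, -1, -1))
  tied$label <- c("NR_like", "NR_like", "R_like", "R_like")
  expect_true(all(stratify_within_class(tied)$stratum == "high"))
  single <- lab; single$label <- c("NR_like", rep("R_like", 5))
  expect_error(stratify_within_class(single), "fewer than 2")
})

test_that("self-transfer and case-renamed transfer reproduce labels", {
  set.seed(35)
  expr <- matrix(rlnorm(40 * 16, 3, 1), 40, 16,
                 dimnames = list(sprintf("Gene%02d", 1:40), paste0("s", 1:16)))
  sig_r <- gene_signature("R", sprintf("Gene%02d", 1:10), "R_unique")
  sig_nr <- gene_signature("NR", sprintf("Gene%02d", 31:40), "NR_unique")
  in_cohort <- classify_delta(score_cohort(expr, sig_r, sig_nr))
  transferred <- transfer_signatures(sig_r, sig_nr, expr)
  expect_identical(transferred$label, in_cohort$label)
  lower <- expr
  rownames(lower) <- tolower(rownames(lower))
  relabeled <- transfer_signatures(sig_r, sig_nr, lower)
  expect_identical(relabeled$label, in_cohort$label)
  expect_equal(unname(attr(relabeled, "coverage")[c("R", "NR")]), c(10, 10))
})
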