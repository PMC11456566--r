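test_that("size factors behave under duplication and scaling", {
  m <- matrix(rpois(200, 50), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(normalize_median_of_ratios(same)$size_factors),
               rep(1, 3))
  doubled <- cbind(m, s5 = 2L * m[, 1])
  sf <- normalize_median_of_ratios(doubled)$size_factors
  expect_equal(unname(sf["s5"] / sf["s1"]), 2)
  # multiplying one sample by c multiplies its size factor by c relative to
  # the others, leaving normalized values unchanged up to the estimator's
  # overall scale (the median-of-ratios reference is defined only up to a
  # constant)
  scaled <- m; scaled[, 2] <- m[, 2] * 3L
  a <- normalize_median_of_ratios(m); b <- normalize_median_of_ratios(scaled)
  expect_equal(unname((b$size_factors[2] / b$size_factors[1]) /
                        (a$size_factors[2] / a$size_factors[1])), 3,
               tolerance = 1e-12)
  rescale <- a$normalized[1, 1] / b$normalized[1, 1]
  expect_equal(b$normalized * rescale, a$normalized, tolerance = 1e-12)
})

test_that("size factors match the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(21)
  m <- matrix(rnbinom(50 * 6, mu = 80, size = 5), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  sf <- normalize_median_of_ratios(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-12)
})

test_that("normalization refuses a matrix with no always-expressed gene", {
  m <- matrix(c(0L, 5L, 5L, 0L), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(normalize_median_of_ratios(m), "pseudocount")
})

test_that("duplicated identical samples give zero fold change and p = 1", {
  m <- matrix(rpois(100, 30), 25, 4,
              dimnames = list(sprintf("g%02d", 1:25), c("a1", "a2", "b1", "b2")))
  m[, 3:4] <- m[, 1:2]
  res <- de_test(m, c("a1", "a2"), c("b1", "b2"))
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$p_value == 1))
})

test_that("Welch and paired p-values match stats::t.test", {
  set.seed(22)
  m <- matrix(rnbinom(10 * 6, mu = 60, size = 8), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
  res <- de_test(m, paste0("s", 1:3), paste0("s", 4:6))
  lg <- log2(m + 1)
  for (i in c(1, 5, 10)) {
    tt <- t.test(lg[i, 1:3], lg[i, 4:6])
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$log2fc[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
  resp <- de_test(m, paste0("s", 1:3), paste0("s", 4:6), paired = TRUE)
  for (i in c(2, 7)) {
    tt <- t.test(lg[i, 1:3], lg[i, 4:6], paired = TRUE)
    expect_equal(resp$p_value[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("swapping groups negates fold changes and preserves p-values", {
  set.seed(23)
  m <- matrix(rnbinom(40 * 8, mu = 40, size = 5), 40, 8,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:8)))
  ab <- de_test(m, paste0("s", 1:4), paste0("s", 5:8))
  ba <- de_test(m, paste0("s", 5:8), paste0("s", 1:4))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(de_test(m, paste0("s", 1:4), paste0("s", 4:8)), "overlap")
  expect_error(de_test(m, "s1", paste0("s", 5:8)), "at least 2")
})

test_that("DEG thresholds are inclusive on fold change, strict on p", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1.0, 2.0, -1.0, 0.5),
                    p_value = c(0.005, 0.01, 0.002, 0.001))
  d <- call_degs(res)
  expect_identical(d$up, "a")        # log2fc exactly 1 qualifies
  expect_identical(d$down, "c")
  expect_false("b" %in% d$up)        # p exactly 0.01 excluded
  expect_length(intersect(d$up, d$down), 0)
})

test_that("DEG lists are ordered by p then gene", {
  res <- data.frame(gene = c("z", "a", "m"),
                    log2fc = c(2, 2, 2), p_value = c(0.001, 0.001, 0.0001))
  expect_identical(call_degs(res)$up, c("m", "a", "z"))
})

test_that("group means equal an independent tapply computation", {
  set.seed(24)
  m <- matrix(rnorm(30 * 6, 100, 10), 30, 6,
              dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:6)))
  grp <- c("x", "x", "y", "y", "z", "z")
  tab <- group_mean_table(m, grp)
  oracle <- t(apply(m, 1, function(r) tapply(r, grp, mean)))[, c("x", "y", "z")]
  expect_equal(tab, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # one sample per group reproduces the columns
  tab1 <- group_mean_table(m[, 1:3], c("a", "b", "c"))
  expect_equal(unname(tab1), unname(m[, 1:3]))
  expect_error(group_mean_table(m, grp, group_order = c("x", "w")), "'w'")
})

test_that("directional counts use strict comparisons and equal column weights", {
  tab <- matrix(c(10, 5, 3, 1,
                  8, 5, 4, 2), ncol = 2,
                dimnames = list(c("g1", "g2", "g3", "g4"), c("L", "R")))
  expect_equal(count_directional(tab, "L", "R", "<")$n, 2)  # g3, g4
  expect_equal(count_directional(tab, "L", "R", ">")$n, 1)  # g1; tie g2 uncalled
  expect_equal(count_directional(tab, "L", "L", "<")$n, 0)
  expect_error(count_directional(tab, "L", "Q", "<"), "unknown")
})

test_that("the bundled B-cell panel reproduces its directional summary", {
  res <- panel_directional_counts(fixture_path("bcell_panel_means.tsv"))
  expect_equal(res$n_genes, 56)
  expect_equal(res$n_down_pre_vs_control, 43)
  expect_equal(res$n_up_post_vs_pre, 30)
})
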