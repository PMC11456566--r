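test_that("paired rescue keeps expanding and collapsing clones", {
  calls <- rbind(
    vrow("P2", "NRAS", "c.35G>A", "pre", 1.27),   # expands post-treatment
    vrow("P2", "NRAS", "c.35G>A", "post", 15.29),
    vrow("P2", "KRAS", "c.38G>A", "pre", 1.83),
    vrow("P2", "KRAS", "c.38G>A", "post", 7.19),
    vrow("P5", "TP53", "c.524G>A", "pre", 87.48), # collapses post-treatment
    vrow("P5", "TP53", "c.524G>A", "post", 3.98))
  kept <- filter_by_vaf(calls, cutoff_pct = 5, paired_rescue = TRUE)
  expect_identical(kept, calls)  # every sub-cutoff call rescued by its pair
  # without rescue the low-VAF observations fall away
  strict <- filter_by_vaf(calls, cutoff_pct = 5, paired_rescue = FALSE)
  expect_identical(sort(strict$vaf_pct), c(7.19, 15.29, 87.48))
})

test_that("cutoff boundary is inclusive and lone sub-cutoff calls drop", {
  calls <- rbind(vrow("P1", "TET2", "c.1A>G", "pre", 4.99),
                 vrow("P1", "ASXL1", "c.2C>T", "pre", 5.00))
  kept <- filter_by_vaf(calls, 5, paired_rescue = TRUE)
  expect_identical(kept$gene, "ASXL1")
  expect_error(filter_by_vaf(vrow("P1", "TET2", "x", "pre", -1)), "vaf_pct")
  expect_error(filter_by_vaf(calls, cutoff_pct = 0), "cutoff_pct")
})

test_that("filtering is idempotent and order-stable on synthetic tables", {
  vt <- generate_variant_table(variant_sim_config(n_patients = 40, seed = 11))
  calls <- vt$calls
  once <- filter_by_vaf(calls, 5)
  twice <- filter_by_vaf(once, 5)
  expect_identical(once, twice)
  # output preserves input row order
  expect_true(all(diff(match(paste(once$patient_id, once$change, once$timepoint,
                                   once$compartment),
                             paste(calls$patient_id, calls$change,
                                   calls$timepoint, calls$compartment))) > 0))
})

test_that("pair_variants groups by mutation and flags duplicates", {
  one_pre <- vrow("P1", "SF3B1", "c.3A>G", "pre", 22)
  p <- pair_variants(one_pre)
  expect_equal(nrow(p), 1)
  expect_equal(p$pre_vaf_pct, 22)
  expect_true(is.na(p$post_vaf_pct))

  both <- rbind(one_pre, vrow("P1", "SF3B1", "c.3A>G", "post", 11))
  p2 <- pair_variants(both)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$post_vaf_pct, 11)

  dup <- rbind(one_pre, one_pre)
  expect_error(pair_variants(dup), "duplicate.*P1.*SF3B1", ignore.case = TRUE)
  mixed <- rbind(one_pre, vrow("P1", "SF3B1", "c.3A>G", "post", 11,
                               compartment = "BMMC"))
  expect_error(pair_variants(mixed), "compartment")
})

test_that("synthetic pair count equals the truth record", {
  vt <- generate_variant_table(variant_sim_config(n_patients = 12, seed = 12))
  paired <- pair_variants(vt$calls[vt$calls$compartment == "CD34", ])
  expect_equal(nrow(paired), nrow(vt$truth))
})

test_that("dynamics classification matches the observed clonal trajectories", {
  expect_equal(as.character(classify_dynamics(87.48, 3.98)), "DECREASED")
  expect_equal(as.character(classify_dynamics(1.27, 15.29)), "INCREASED")
  expect_equal(as.character(classify_dynamics(10, 10)), "STABLE")
  expect_equal(as.character(classify_dynamics(NA, 7.2)), "ACQUIRED")
  expect_equal(as.character(classify_dynamics(7.2, NA)), "LOST")
  expect_error(classify_dynamics(NA, NA), "at least one timepoint")
  expect_error(classify_dynamics(10, 12, rel_change_min = 0), "rel_change_min")
})

test_that("dynamics classification is exhaustive and mutually exclusive", {
  set.seed(1)
  pre <- c(runif(300, 0.1, 95), rep(NA, 50))
  post <- c(runif(300, 0.1, 95), runif(50, 0.1, 95))
  keep <- !(is.na(pre) & is.na(post))
  dyn <- classify_dynamics(pre[keep], post[keep])
  expect_false(anyNA(dyn))
  expect_true(all(dyn %in% c("ACQUIRED", "INCREASED", "STABLE",
                             "DECREASED", "LOST")))
  # band boundary: exactly 25% relative change is not stable
  expect_equal(as.character(classify_dynamics(20, 25)), "INCREASED")
  expect_equal(as.character(classify_dynamics(20, 15)), "DECREASED")
  expect_equal(as.character(classify_dynamics(20, 24.9)), "STABLE")
})

test_that("substitution classes follow the purine/pyrimidine rule", {
  expect_equal(classify_substitution("C", "T"), "transition")
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("C", "A"), "transversion")
  # full enumeration against an independent purine-set oracle
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  oracle <- with(combos, ifelse((ref %in% c("A", "G")) == (alt %in% c("A", "G")),
                                "transition", "transversion"))
  expect_identical(classify_substitution(combos$ref, combos$alt), oracle)
  expect_equal(sum(oracle == "transition"), 4)   # 4 transitions, 8 transversions
  expect_error(classify_substitution("C", "C"), "differ")
  expect_error(classify_substitution("N", "A"), "bases")
})

test_that("spectrum proportions are exact on a constructed 60/30/10 mix", {
  rows <- list()
  add <- function(i, ref, alt, class, pre, post) {
    rows[[length(rows) + 1]] <<- vrow("P1", "TET2", paste0("m", i), "pre", pre,
                                      ref, alt, class)
    rows[[length(rows) + 1]] <<- vrow("P1", "TET2", paste0("m", i), "post", post,
                                      ref, alt, class)
  }
  for (i in 1:6) add(i, "C", "T", "SNV", 30, 30)            # transitions, stable
  for (i in 7:9) add(i, "C", "A", "SNV", 30, 10)            # transversions, down
  add(10, "", "", "indel", 30, 30)
  paired <- pair_variants(do.call(rbind, rows))
  s <- spectrum_summary(paired)
  expect_equal(s$n_total, 10)
  expect_equal(s$prop_transition, 0.6)
  expect_equal(s$prop_transversion, 0.3)
  expect_equal(s$prop_other, 0.1)
  expect_equal(s$prop_transition + s$prop_transversion + s$prop_other, 1)
  expect_equal(sum(s$per_substitution), s$n_total)
  expect_equal(unname(s$change_by_class["transition"]), 1)   # all stable
  expect_equal(unname(s$change_by_class["transversion"]), 0) # all decreased
  expect_equal(s$per_substitution["C>T", "STABLE"], 6,
               ignore_attr = TRUE)
})

test_that("all-transition input gives prop_transition 1", {
  paired <- pair_variants(rbind(vrow("P1", "TP53", "a", "pre", 40),
                                vrow("P1", "DNMT3A", "b", "pre", 20,
                                     ref = "A", alt = "G")))
  s <- spectrum_summary(paired)
  expect_equal(s$prop_transition, 1)
  expect_error(spectrum_summary(paired[0, ]), "non-empty")
})

test_that("compartment correlation matches the covariance formula", {
  expect_equal(compartment_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compartment_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  set.seed(2)
  x <- runif(200, 0, 100); y <- pmin(100, pmax(0, x + rnorm(200, 0, 15)))
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(compartment_correlation(y, x), brute, tolerance = 1e-12)
  expect_error(compartment_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(compartment_correlation(1, 1), "3 VAF pairs")
})

test_that("cohort burden summary counts patients and reductions", {
  empty <- pair_variants(vrow("PX", "TET2", "z", "pre", 10))[0, ]
  s0 <- cohort_mutation_summary(empty, patients = "P1")
  expect_equal(s0$n_mutations_total, 0)
  expect_equal(s0$median_per_patient, 0)

  vt <- generate_variant_table(variant_sim_config(n_patients = 12, seed = 13))
  paired <- pair_variants(vt$calls[vt$calls$compartment == "CD34", ])
  roster <- sprintf("P%02d", 1:12)
  s <- cohort_mutation_summary(paired, roster)
  expect_equal(s$n_mutations_total, nrow(vt$truth))
  tt <- table(factor(vt$truth$patient_id, levels = roster))
  expect_equal(s$median_per_patient, median(as.numeric(tt)))
  expect_equal(s$n_patients_with_mutations, sum(tt > 0))
  red_truth <- tapply(vt$truth$dynamics %in% c("decreased", "lost"),
                      factor(vt$truth$patient_id, levels = roster),
                      any, default = FALSE)
  expect_equal(s$n_patients_with_any_vaf_reduction, sum(red_truth))
  expect_error(cohort_mutation_summary(paired, character(0)), "roster")
})
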