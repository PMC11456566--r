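#' Configuration for a synthetic paired variant (VAF) table
#'
#' Describes per-patient somatic mutations carried through a pre/post
#' treatment pair in two marrow compartments (sorted CD34+ cells and bulk
#' BMMCs). Each mutation is assigned a true clonal dynamics category
#' (acquired / increased / stable / decreased / lost) drawn from
#' \code{dynamics_mix}, realized in its pre/post VAFs so that the dynamics
#' classifier at relative-change threshold \code{rel_change_min} recovers the
#' category exactly. SNV ref/alt bases are drawn to match \code{ti_fraction}
#' transitions among SNVs (C>T most frequent), and BMMC VAFs are generated
#' from the CD34+ VAFs by additive Gaussian noise on the logit scale, with
#' the noise scale solved numerically so the realized Pearson correlation
#' equals \code{compartment_rho}.
#'
#' Default mix and fractions are chosen so that a cohort at defaults lands
#' near the observed spectrum of AZA-treated MDS panels: roughly 48%
#' transitions, 35% transversions, the remainder indels.
#'
#' @param n_patients Number of patients.
#' @param mutations_per_patient Integer range \code{c(lo, hi)}; each patient's
#'   mutation count is uniform on it (zeros allowed).
#' @param ti_fraction Target transition proportion among SNVs.
#' @param snv_fraction Fraction of mutations that are SNVs (the rest indels).
#' @param dynamics_mix Named probabilities over
#'   \code{c("acquired","increased","stable","decreased","lost")}; must sum
#'   to 1 (tolerance 1e-9).
#' @param compartment_rho Target Pearson correlation between BMMC and CD34+
#'   VAFs.
#' @param rel_change_min Relative-change band the realized VAF trajectories
#'   respect (see [classify_dynamics()]).
#' @param seed Integer seed.
#' @return A list of class \code{"variant_sim_config"}.
#' @export
variant_sim_config <- function(n_patients = 12,
                               mutations_per_patient = c(0, 9),
                               ti_fraction = 0.575,
                               snv_fraction = 10 / 12,
                               dynamics_mix = c(acquired = 0.08, increased = 0.12,
                                                stable = 0.35, decreased = 0.30,
                                                lost = 0.15),
                               compartment_rho = 0.73,
                               rel_change_min = 0.25,
                               seed = 1L) {
  cats <- c("acquired", "increased", "stable", "decreased", "lost")
  if (!all(cats %in% names(dynamics_mix)) || length(dynamics_mix) != 5L)
    stopf("`dynamics_mix` must be named probabilities over %s",
          paste(cats, collapse = "/"))
  dynamics_mix <- dynamics_mix[cats]
  if (any(dynamics_mix < 0) || abs(sum(dynamics_mix) - 1) > 1e-9)
    stopf("`dynamics_mix` must be non-negative and sum to 1 (tolerance 1e-9)")
  if (length(mutations_per_patient) != 2L ||
      any(mutations_per_patient < 0) ||
      mutations_per_patient[1] > mutations_per_patient[2])
    stopf("`mutations_per_patient` must be an increasing non-negative range")
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients"),
    mutations_per_patient = as.integer(mutations_per_patient),
    ti_fraction = check_fraction(ti_fraction, "ti_fraction"),
    snv_fraction = check_fraction(snv_fraction, "snv_fraction"),
    dynamics_mix = dynamics_mix,
    compartment_rho = check_fraction(compartment_rho, "compartment_rho", lo = -1),
    rel_change_min = rel_change_min,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$rel_change_min <= 0) stopf("`rel_change_min` must be > 0")
  class(cfg) <- "variant_sim_config"
  cfg
}

# Recurrently mutated myeloid-neoplasm genes used as the simulated panel.
myeloid_panel_genes <- c(
  "TP53", "NRAS", "KRAS", "DNMT3A", "BCOR", "TET2", "ASXL1", "SRSF2",
  "SF3B1", "RUNX1", "U2AF1", "EZH2", "IDH1", "IDH2", "CBL", "MTOR",
  "STAG2", "ZRSR2", "ETV6", "JAK2")

transition_pairs <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"),
                           ncol = 2, byrow = TRUE)
transversion_pairs <- matrix(c("A", "C", "C", "A", "A", "T", "T", "A",
                               "G", "C", "C", "G", "G", "T", "T", "G"),
                             ncol = 2, byrow = TRUE)

# Realize a (pre, post) CD34 VAF pair for one true dynamics category, keeping
# relative changes well inside (stable) or outside (increased/decreased) the
# classifier band so recovery is exact.
realize_vafs <- function(category, band) {
  pre <- stats::runif(1, 5, 60)
  switch(category,
    acquired = c(NA_real_, stats::runif(1, 5, 40)),
    lost = c(pre, NA_real_),
    stable = c(pre, pre * (1 + stats::runif(1, -0.6, 0.6) * band)),
    increased = c(pre, min(95, pre * (1 + stats::runif(1, 1.5 * band, 4 * band)))),
    decreased = c(pre, pre * (1 - stats::runif(1, 1.5 * band, 0.9))))
}

#' Generate a synthetic paired variant table
#'
#' Draws per-patient mutations with known dynamics categories and realizes
#' their pre/post VAFs in the CD34+ compartment; BMMC VAFs are derived from
#' the CD34+ values with logit-scale noise calibrated so the realized
#' Pearson correlation between compartments equals
#' \code{cfg$compartment_rho} (BMMC values carry a small constant positive
#' logit shift, reflecting the slightly higher bulk VAFs seen in practice;
#' a constant shift leaves the correlation unchanged).
#'
#' @param cfg A \code{variant_sim_config}.
#' @return List with \code{calls} (long-format data.frame: one row per
#'   mutation x timepoint x compartment, columns \code{patient_id, gene,
#'   change, ref, alt, variant_class, timepoint, compartment, vaf_pct}),
#'   \code{truth} (one row per mutation: true dynamics category and CD34+
#'   pre/post VAFs) and \code{config}.
#' @examples
#' vs <- generate_variant_table(variant_sim_config(n_patients = 6, seed = 3))
#' head(vs$calls)
#' table(vs$truth$dynamics)
#' @export
generate_variant_table <- function(cfg) {
  if (!inherits(cfg, "variant_sim_config"))
    stopf("`cfg` must come from variant_sim_config()")
  set.seed(cfg$seed)
  cats <- names(cfg$dynamics_mix)
  rng <- cfg$mutations_per_patient

  truth <- list()
  for (i in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", i)
    n_mut <- sample(seq.int(rng[1], rng[2]), 1L)
    if (n_mut == 0L) next
    gs <- sample(myeloid_panel_genes, n_mut, replace = n_mut > length(myeloid_panel_genes))
    for (k in seq_len(n_mut)) {
      is_snv <- stats::runif(1) < cfg$snv_fraction
      if (is_snv) {
        is_ti <- stats::runif(1) < cfg$ti_fraction
        pair <- if (is_ti) {
          # C>T dominates among transitions, as in deaminated CpG contexts.
          transition_pairs[sample(4, 1, prob = c(0.2, 0.15, 0.45, 0.2)), ]
        } else {
          transversion_pairs[sample(8, 1), ]
        }
        ref <- pair[1]; alt <- pair[2]
        vclass <- "SNV"
        change <- sprintf("c.%d%s>%s", sample(3000, 1), ref, alt)
      } else {
        ref <- ""; alt <- ""
        vclass <- "indel"
        change <- sprintf("p.X%dfs", sample(800, 1))
      }
      dyn <- sample(cats, 1, prob = cfg$dynamics_mix)
      v <- realize_vafs(dyn, cfg$rel_change_min)
      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = pid, gene = gs[k], change = paste0(change, "_", k),
        ref = ref, alt = alt, variant_class = vclass, dynamics = dyn,
        pre_vaf = v[1], post_vaf = v[2], stringsAsFactors = FALSE)
    }
  }
  if (length(truth) == 0L)
    return(list(calls = empty_variant_calls(), truth = NULL, config = cfg))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  # Long format: CD34 rows for each observed timepoint.
  long <- function(tp, vaf) {
    keep <- !is.na(vaf)
    data.frame(truth[keep, c("patient_id", "gene", "change", "ref", "alt",
                             "variant_class")],
               timepoint = tp, compartment = "CD34", vaf_pct = vaf[keep],
               stringsAsFactors = FALSE)
  }
  cd34 <- rbind(long("pre", truth$pre_vaf), long("post", truth$post_vaf))

  # BMMC: logit-scale noise, scale solved so realized cor equals the target.
  x <- logit(pmin(pmax(cd34$vaf_pct / 100, 1e-4), 1 - 1e-4))
  z <- stats::rnorm(length(x))
  shift <- 0.15
  bm_vaf <- function(s) 100 * inv_logit(x + shift + s * z)
  s_star <- if (length(x) >= 3 && cfg$compartment_rho < 1 &&
                stats::var(x) > 0) {
    f <- function(s) stats::cor(bm_vaf(s), cd34$vaf_pct) - cfg$compartment_rho
    if (f(0) < 0) 0 else stats::uniroot(f, c(0, 50), tol = 1e-10)$root
  } else 0
  bmmc <- cd34
  bmmc$compartment <- "BMMC"
  bmmc$vaf_pct <- bm_vaf(s_star)

  calls <- rbind(cd34, bmmc)
  rownames(calls) <- NULL
  list(calls = calls, truth = truth, config = cfg)
}

empty_variant_calls <- function() {
  data.frame(patient_id = character(0), gene = character(0),
             change = character(0), ref = character(0), alt = character(0),
             variant_class = character(0), timepoint = character(0),
             compartment = character(0), vaf_pct = numeric(0),
             stringsAsFactors = FALSE)
}
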