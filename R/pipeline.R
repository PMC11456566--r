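#' Run the full response-signature pipeline on synthetic cohorts
#'
#' Executes the end-to-end flow the package models: simulate a derivation
#' cohort (controls plus paired pre/post patients with planted arm-specific
#' genes), run differential expression of responder and non-responder
#' pre-treatment samples against controls, derive the R-unique/NR-unique
#' signatures, simulate an independent validation cohort whose survival
#' hazard depends on a latent non-responder burden, score and classify the
#' validation samples by the delta(NR-R) median split, stratify high/low
#' within class, and evaluate survival separation between the classifier
#' groups. A paired variant table is simulated and summarized alongside.
#'
#' All randomness is derived from \code{seed}: the three simulator
#' configurations receive distinct sub-seeds computed from it, so a rerun
#' with the same seed reproduces every stage output exactly.
#'
#' @param seed Master integer seed.
#' @param sim A [sim_config()] for the derivation cohort; its \code{seed} is
#'   overridden from \code{seed}.
#' @param surv A [survival_sim_config()] for the validation cohort; its
#'   \code{seed} is overridden.
#' @param vsim A [variant_sim_config()] or NULL to skip the variant stage;
#'   its \code{seed} is overridden.
#' @param min_abs_log2fc,max_p DEG thresholds (defaults 1 and 0.01).
#' @param policy A [scoring_policy()].
#' @param vaf_cutoff_pct,rel_change_min Variant-stage parameters.
#' @param out_dir Optional directory; when given, stage outputs (counts,
#'   metadata, signatures as GMT, scores, survival report, variant summary,
#'   manifest) are written there.
#' @return List of class \code{"aza_pipeline"}: \code{derivation},
#'   \code{de} (per-arm DE tables and DEG calls), \code{signatures},
#'   \code{validation}, \code{scores} (labeled, stratified),
#'   \code{survival_report}, \code{variants} (filtered, paired, spectrum,
#'   burden summary; NULL when skipped) and \code{manifest}.
#' @examples
#' \donttest{
#' res <- run_aza_pipeline(seed = 1,
#'   sim = sim_config(n_controls = 10, n_patients = 20, n_undetermined = 0,
#'                    frac_R = 0.5, n_genes = 500, seed = 1),
#'   surv = survival_sim_config(n_samples = 60, n_background_genes = 100))
#' res$manifest$stages
#' }
#' @export
run_aza_pipeline <- function(seed = 1L,
                             sim = sim_config(),
                             surv = survival_sim_config(),
                             vsim = variant_sim_config(),
                             min_abs_log2fc = 1, max_p = 0.01,
                             policy = scoring_policy(),
                             vaf_cutoff_pct = 5, rel_change_min = 0.25,
                             out_dir = NULL) {
  seed <- check_count(seed, "seed", min = 0L)
  sim$seed <- (seed * 3L + 1L) %% .Machine$integer.max
  surv$seed <- (seed * 3L + 2L) %% .Machine$integer.max
  cfg_all <- list(sim = sim, surv = surv, vsim = vsim,
                  min_abs_log2fc = min_abs_log2fc, max_p = max_p,
                  policy = policy, vaf_cutoff_pct = vaf_cutoff_pct,
                  rel_change_min = rel_change_min, seed = seed)
  hash <- config_hash(cfg_all)
  started <- Sys.time()

  # -- derivation cohort and per-arm DE against controls
  coh <- generate_expression_cohort(sim)
  nm <- normalize_median_of_ratios(coh$counts)
  meta <- coh$meta
  controls <- meta$sample_id[meta$group == "control"]
  pre_of <- function(lab)
    meta$sample_id[meta$group == "pre" & !is.na(meta$blast_response) &
                     meta$blast_response == lab]
  de_R <- de_test(nm$normalized, pre_of("R"), controls)
  de_NR <- de_test(nm$normalized, pre_of("NR"), controls)
  degs_R <- call_degs(de_R, min_abs_log2fc, max_p)
  degs_NR <- call_degs(de_NR, min_abs_log2fc, max_p)
  sigs <- derive_unique_signatures(c(degs_R$up, degs_R$down),
                                   c(degs_NR$up, degs_NR$down))

  # -- validation cohort: score, classify, stratify, survival
  val <- generate_validation_cohort(surv, list(R = sigs$R_unique,
                                               NR = sigs$NR_unique))
  vn <- normalize_median_of_ratios(val$counts)
  expr_val <- log2(vn$normalized + 1)
  scores <- transfer_signatures(sigs$R_unique, sigs$NR_unique, expr_val, policy)
  scores <- stratify_within_class(scores)
  report <- evaluate_classifier_survival(scores, val$survival)

  # -- variant dynamics stage
  variants <- NULL
  if (!is.null(vsim)) {
    vsim$seed <- (seed * 3L + 3L) %% .Machine$integer.max
    vt <- generate_variant_table(vsim)
    if (nrow(vt$calls) > 0) {
      cd34 <- vt$calls[vt$calls$compartment == "CD34", , drop = FALSE]
      kept <- filter_by_vaf(cd34, vaf_cutoff_pct, paired_rescue = TRUE)
      paired <- pair_variants(kept)
      paired$dynamics <- classify_dynamics(paired$pre_vaf_pct,
                                           paired$post_vaf_pct, rel_change_min)
      spec <- spectrum_summary(paired, rel_change_min)
      roster <- sprintf("P%02d", seq_len(vsim$n_patients))
      burden <- cohort_mutation_summary(paired, roster, rel_change_min)
      bm <- vt$calls[vt$calls$compartment == "BMMC", , drop = FALSE]
      key <- function(d) paste(d$patient_id, d$gene, d$change, d$timepoint)
      mi <- match(key(cd34), key(bm))
      rho <- compartment_correlation(bm$vaf_pct[mi], cd34$vaf_pct)
      variants <- list(table = vt, filtered = kept, paired = paired,
                       spectrum = spec, burden = burden,
                       compartment_r = rho)
    }
  }

  manifest <- list(
    tool = "azasig", version = pkg_version(), seed = seed,
    config_hash = hash,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(
      derivation = list(genes = nrow(coh$counts), samples = ncol(coh$counts)),
      de = list(degs_R = length(c(degs_R$up, degs_R$down)),
                degs_NR = length(c(degs_NR$up, degs_NR$down))),
      signatures = list(R_unique = length(sigs$R_unique$genes),
                        NR_unique = length(sigs$NR_unique$genes)),
      validation = list(samples = ncol(val$counts),
                        NR_like = sum(scores$label == "NR_like"),
                        R_like = sum(scores$label == "R_like")),
      survival = list(events = sum(val$survival$event)),
      variants = if (is.null(variants)) NULL else
        list(n_calls = nrow(variants$table$calls),
             n_paired = nrow(variants$paired))
    ))

  out <- structure(list(derivation = coh,
                        de = list(R = de_R, NR = de_NR,
                                  degs_R = degs_R, degs_NR = degs_NR),
                        signatures = sigs, validation = val, scores = scores,
                        survival_report = report, variants = variants,
                        manifest = manifest),
                   class = "aza_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, seed, hash)
  out
}

write_pipeline_outputs <- function(res, out_dir, seed, hash) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_counts(res$derivation$counts, res$derivation$meta, p("derivation"),
               seed = seed, hash = hash)
  write_gmt(list(R_unique = res$signatures$R_unique,
                 NR_unique = res$signatures$NR_unique), p("signatures.gmt"))
  write_table_with_header(res$scores, p("scores.tsv"), seed = seed, hash = hash)
  write_survival(res$validation$survival, p("validation_survival.csv"),
                 seed = seed, hash = hash)
  write_json_report(res$derivation$truth[c("planted_R", "planted_NR")],
                    p("derivation_truth.json"))
  if (!is.null(res$variants)) {
    write_variants(res$variants$table$calls, p("variants.tsv"),
                   seed = seed, hash = hash)
    s <- res$variants$spectrum
    write_json_report(list(
      n_total = s$n_total, prop_transition = s$prop_transition,
      prop_transversion = s$prop_transversion, prop_other = s$prop_other,
      compartment_r = res$variants$compartment_r,
      burden = res$variants$burden[c("n_mutations_total", "median_per_patient",
                                     "n_patients_with_mutations",
                                     "n_patients_with_any_vaf_reduction",
                                     "frac_with_reduction")]),
      p("variant_summary.json"))
  }
  write_json_report(res$manifest, p("manifest.json"))
  invisible(out_dir)
}

#' @export
print.aza_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("aza_pipeline run (seed %d, config %s)\n", m$seed,
              substr(m$config_hash, 1, 8)))
  cat(sprintf("  signatures: %d R-unique, %d NR-unique genes\n",
              m$stages$signatures$R_unique, m$stages$signatures$NR_unique))
  cat(sprintf("  validation: %d samples -> %d NR-like / %d R-like\n",
              m$stages$validation$samples, m$stages$validation$NR_like,
              m$stages$validation$R_like))
  if (!is.null(x$survival_report$tests))
    cat(sprintf("  log-rank NR-like vs R-like: p = %.3g\n",
                x$survival_report$tests$p[1]))
  invisible(x)
}

#' Directional counts on a mean-expression panel table
#'
#' Convenience wrapper around [count_directional()] for the shipped B-cell
#' development panel layout (columns \code{Control}, \code{BLR_Pre},
#' \code{BLR_Post}, \code{BLNR_Pre}, \code{BLNR_Post}): counts genes whose
#' equal-weight pre-treatment mean lies below the control mean, and genes
#' whose equal-weight post-treatment mean lies above the pre-treatment mean.
#'
#' @param panel Matrix from [read_panel_table()], or a path to the TSV.
#' @return List: \code{n_genes}, \code{n_down_pre_vs_control},
#'   \code{n_up_post_vs_pre}, and the per-gene call vectors.
#' @examples
#' panel <- system.file("extdata", "bcell_panel_means.tsv", package = "azasig")
#' panel_directional_counts(panel)[c("n_genes", "n_down_pre_vs_control",
#'                                   "n_up_post_vs_pre")]
#' @export
panel_directional_counts <- function(panel) {
  if (is.character(panel) && length(panel) == 1L) panel <- read_panel_table(panel)
  down <- count_directional(panel, left = c("BLR_Pre", "BLNR_Pre"),
                            right = "Control", direction = "<")
  up <- count_directional(panel, left = c("BLR_Post", "BLNR_Post"),
                          right = c("BLR_Pre", "BLNR_Pre"), direction = ">")
  list(n_genes = nrow(panel),
       n_down_pre_vs_control = down$n,
       n_up_post_vs_pre = up$n,
       down_calls = down$calls, up_calls = up$calls)
}
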