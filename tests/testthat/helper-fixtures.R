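# Shared fixtures and small utilities for the suite.

balanced_accuracy <- function(pred, truth) {
  (mean(pred[truth]) + mean(!pred[!truth])) / 2
}

# A small derivation cohort at 20 samples per group, the size used throughout
# the recovery properties.
derivation_config <- function(seed, planted_log2fc = 2) {
  sim_config(n_controls = 20, n_patients = 40, n_undetermined = 0,
             frac_R = 0.5, n_genes = 2000, n_sig_R = 50, n_sig_NR = 70,
             planted_log2fc = planted_log2fc, nb_dispersion = 0.1,
             seed = seed)
}

# Run per-arm DE against controls on a generated cohort; returns the DE
# tables, DEG calls and the truth record.
run_arm_de <- function(coh, min_abs_log2fc = 1, max_p = 0.01) {
  nm <- normalize_median_of_ratios(coh$counts)
  meta <- coh$meta
  ctl <- meta$sample_id[meta$group == "control"]
  pre_of <- function(lab)
    meta$sample_id[meta$group == "pre" & !is.na(meta$blast_response) &
                     meta$blast_response == lab]
  de_R <- de_test(nm$normalized, pre_of("R"), ctl)
  de_NR <- de_test(nm$normalized, pre_of("NR"), ctl)
  list(de_R = de_R, de_NR = de_NR,
       degs_R = call_degs(de_R, min_abs_log2fc, max_p),
       degs_NR = call_degs(de_NR, min_abs_log2fc, max_p),
       truth = coh$truth, norm = nm$normalized, meta = meta)
}

deg_union <- function(d) c(d$up, d$down)

# Hand-buildable variant table rows.
vrow <- function(patient, gene, change, tp, vaf, ref = "C", alt = "T",
                 class = "SNV", compartment = "CD34") {
  data.frame(patient_id = patient, gene = gene, change = change, ref = ref,
             alt = alt, variant_class = class, timepoint = tp,
             compartment = compartment, vaf_pct = vaf,
             stringsAsFactors = FALSE)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "azasig")
}
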