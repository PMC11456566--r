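#' Configuration for a synthetic paired pre/post expression cohort
#'
#' Describes a cohort of healthy controls plus MDS patients sampled before
#' (`pre`) and after (`post`) azacytidine, with negative-binomial counts
#' (variance \eqn{\mu + \phi \mu^2}), log-normal per-gene baselines, and
#' arm-specific planted signature genes: responder (R) signature genes are
#' shifted by \code{planted_log2fc} in responder patients only, non-responder
#' (NR) genes in non-responders only. Post-treatment samples are paired
#' perturbations of the same patient's pre sample: both share a per-patient
#' log-normal effect, and a set of treatment-responsive genes is shifted by
#' \code{treatment_log2fc} in all post samples.
#'
#' Defaults mirror the study design this package models: 14 patients, of whom
#' 12 have a determined blast response (5 responders, 7 non-responders) and 2
#' are undetermined.
#'
#' @param n_controls Number of healthy control samples.
#' @param n_patients Total number of patients (each contributes a pre and a
#'   post sample).
#' @param n_undetermined Number of patients with undetermined response (no
#'   arm-specific planted shift; response recorded as \code{NA}).
#' @param frac_R Fraction of determined patients labeled responder.
#' @param n_genes Number of genes.
#' @param n_sig_R,n_sig_NR Number of planted responder- / non-responder-
#'   specific genes (disjoint sets).
#' @param planted_log2fc Magnitude of the planted arm-specific log2
#'   fold-change (each planted gene is randomly up or down). May be 0 for a
#'   null cohort.
#' @param treatment_log2fc Magnitude of the treatment shift applied to
#'   \code{n_treatment_genes} random genes in every post sample.
#' @param n_treatment_genes Number of treatment-responsive genes (disjoint
#'   from planted signature genes).
#' @param nb_dispersion NB dispersion \eqn{\phi}; 0 gives Poisson counts.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of per-gene
#'   baseline means (natural-log scale).
#' @param patient_effect_sd SD of the per-patient log2-scale random effect
#'   shared by that patient's pre and post samples.
#' @param seed Integer seed; identical configurations produce identical
#'   cohorts.
#' @return A list of class \code{"sim_config"}.
#' @seealso [generate_expression_cohort()]
#' @export
sim_config <- function(n_controls = 5, n_patients = 14, n_undetermined = 2,
                       frac_R = 5 / 12, n_genes = 2000,
                       n_sig_R = 50, n_sig_NR = 70,
                       planted_log2fc = 2, treatment_log2fc = 0.5,
                       n_treatment_genes = 100, nb_dispersion = 0.1,
                       baseline_log_mean = 4, baseline_log_sd = 1.5,
                       patient_effect_sd = 0.15, seed = 1L) {
  cfg <- list(
    n_controls = check_count(n_controls, "n_controls"),
    n_patients = check_count(n_patients, "n_patients"),
    n_undetermined = check_count(n_undetermined, "n_undetermined", min = 0L),
    frac_R = check_fraction(frac_R, "frac_R", open_lo = TRUE, open_hi = TRUE),
    n_genes = check_count(n_genes, "n_genes"),
    n_sig_R = check_count(n_sig_R, "n_sig_R"),
    n_sig_NR = check_count(n_sig_NR, "n_sig_NR"),
    planted_log2fc = planted_log2fc,
    treatment_log2fc = treatment_log2fc,
    n_treatment_genes = check_count(n_treatment_genes, "n_treatment_genes", min = 0L),
    nb_dispersion = nb_dispersion,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    patient_effect_sd = patient_effect_sd,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(cfg$planted_log2fc) || cfg$planted_log2fc < 0)
    stopf("`planted_log2fc` must be >= 0")
  if (cfg$nb_dispersion < 0) stopf("`nb_dispersion` must be >= 0")
  if (cfg$n_undetermined >= cfg$n_patients)
    stopf("`n_undetermined` must be smaller than `n_patients`")
  if (cfg$n_sig_R + cfg$n_sig_NR + cfg$n_treatment_genes > cfg$n_genes)
    stopf("planted gene sets exceed `n_genes`")
  n_det <- cfg$n_patients - cfg$n_undetermined
  n_R <- round(cfg$frac_R * n_det)
  if (n_R < 1L || n_R >= n_det)
    stopf("`frac_R` leaves an empty responder or non-responder arm")
  class(cfg) <- "sim_config"
  cfg
}

# NB draws with mu vector; phi = 0 degenerates to Poisson.
rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Generate a synthetic paired pre/post expression cohort
#'
#' Draws a gene-by-sample count matrix under the model described in
#' [sim_config()], together with sample metadata and a truth record listing
#' every planted gene with its direction, sufficient to score downstream
#' differential-expression and signature recovery without re-simulation.
#'
#' @param cfg A \code{sim_config}.
#' @return A list of class \code{"aza_cohort"} with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples;}
#'     \item{meta}{data.frame with \code{sample_id}, \code{patient_id},
#'       \code{group} (control/pre/post), \code{blast_response} (R/NR/NA),
#'       \code{hem_response};}
#'     \item{truth}{list with \code{planted_R}, \code{planted_NR},
#'       \code{treatment_genes} (data.frames of gene + direction) and the
#'       patient roster;}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' coh <- generate_expression_cohort(sim_config(n_genes = 200, seed = 7))
#' dim(coh$counts)
#' table(coh$meta$group)
#' @export
generate_expression_cohort <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stopf("`cfg` must come from sim_config()")
  set.seed(cfg$seed)

  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  baseline <- stats::rlnorm(cfg$n_genes, cfg$baseline_log_mean, cfg$baseline_log_sd)

  planted <- sample(cfg$n_genes, cfg$n_sig_R + cfg$n_sig_NR + cfg$n_treatment_genes)
  idx_R <- planted[seq_len(cfg$n_sig_R)]
  idx_NR <- planted[cfg$n_sig_R + seq_len(cfg$n_sig_NR)]
  idx_trt <- planted[cfg$n_sig_R + cfg$n_sig_NR + seq_len(cfg$n_treatment_genes)]
  dir_R <- sample(c(-1, 1), cfg$n_sig_R, replace = TRUE)
  dir_NR <- sample(c(-1, 1), cfg$n_sig_NR, replace = TRUE)
  dir_trt <- if (cfg$n_treatment_genes > 0)
    sample(c(-1, 1), cfg$n_treatment_genes, replace = TRUE) else numeric(0)

  n_det <- cfg$n_patients - cfg$n_undetermined
  n_R <- round(cfg$frac_R * n_det)
  resp <- c(rep("R", n_R), rep("NR", n_det - n_R), rep(NA_character_, cfg$n_undetermined))
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))

  log2base <- log2(baseline)
  arm_shift <- function(label) {
    s <- numeric(cfg$n_genes)
    if (identical(label, "R")) s[idx_R] <- dir_R * cfg$planted_log2fc
    if (identical(label, "NR")) s[idx_NR] <- dir_NR * cfg$planted_log2fc
    s
  }
  trt_shift <- numeric(cfg$n_genes)
  trt_shift[idx_trt] <- dir_trt * cfg$treatment_log2fc

  sample_ids <- character(0)
  meta <- list()
  cols <- list()
  add_sample <- function(id, pid, group, resp_label, mu) {
    cols[[length(cols) + 1L]] <<- rnb(cfg$n_genes, mu, cfg$nb_dispersion)
    meta[[length(meta) + 1L]] <<- data.frame(
      sample_id = id, patient_id = pid, group = group,
      blast_response = resp_label, hem_response = NA_character_,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(cfg$n_controls))
    add_sample(sprintf("C%02d", i), NA_character_, "control", NA_character_,
               2^log2base)
  for (j in seq_len(cfg$n_patients)) {
    pe <- stats::rnorm(1, 0, cfg$patient_effect_sd)
    mu_pre <- 2^(log2base + pe + arm_shift(resp[j]))
    mu_post <- 2^(log2base + pe + arm_shift(resp[j]) + trt_shift)
    add_sample(paste0(patients[j], "_pre"), patients[j], "pre", resp[j], mu_pre)
    add_sample(paste0(patients[j], "_post"), patients[j], "post", resp[j], mu_post)
  }

  meta <- do.call(rbind, meta)
  counts <- matrix(as.integer(unlist(cols)), nrow = cfg$n_genes,
                   dimnames = list(genes, meta$sample_id))

  truth <- list(
    planted_R = data.frame(gene = genes[idx_R], direction = dir_R,
                           stringsAsFactors = FALSE),
    planted_NR = data.frame(gene = genes[idx_NR], direction = dir_NR,
                            stringsAsFactors = FALSE),
    treatment_genes = data.frame(gene = genes[idx_trt],
                                 direction = dir_trt,
                                 stringsAsFactors = FALSE),
    patients = data.frame(patient_id = patients, blast_response = resp,
                          stringsAsFactors = FALSE),
    baseline_mean = stats::setNames(baseline, genes)
  )
  structure(list(counts = counts, meta = meta, truth = truth, config = cfg),
            class = "aza_cohort")
}

#' @export
print.aza_cohort <- function(x, ...) {
  cat(sprintf("aza_cohort: %d genes x %d samples (%d control, %d patients)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$meta$group == "control"),
              length(unique(stats::na.omit(x$meta$patient_id)))))
  invisible(x)
}
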