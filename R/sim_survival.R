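#' Configuration for a synthetic validation cohort with survival outcomes
#'
#' Each sample carries a latent non-responder expression burden
#' \eqn{b \sim N(0, 1)}. Genes belonging to the supplied NR signature are
#' up-shifted by \code{burden_log2fc * b} log2 units in that sample; all other
#' genes sit at their log-normal baseline. Event times are exponential with
#' hazard \code{baseline_rate * exp(hazard_beta * b)}, with independent
#' exponential censoring at rate \code{censor_rate} (0 disables censoring).
#'
#' @param n_samples Number of samples.
#' @param hazard_beta Log-hazard coefficient on the latent burden; 0 gives a
#'   null cohort in which expression structure persists but survival is
#'   independent of it.
#' @param baseline_rate Exponential baseline hazard (> 0).
#' @param censor_rate Independent censoring hazard (>= 0).
#' @param burden_log2fc Expression shift per unit burden on NR-signature genes.
#' @param n_background_genes Unshifted genes added alongside the signature
#'   genes.
#' @param nb_dispersion,baseline_log_mean,baseline_log_sd Count model
#'   parameters as in [sim_config()].
#' @param seed Integer seed.
#' @return A list of class \code{"survival_sim_config"}.
#' @export
survival_sim_config <- function(n_samples = 180, hazard_beta = 1,
                                baseline_rate = 0.05, censor_rate = 0.02,
                                burden_log2fc = 1, n_background_genes = 500,
                                nb_dispersion = 0.1, baseline_log_mean = 4,
                                baseline_log_sd = 1.5, seed = 1L) {
  if (!is.numeric(baseline_rate) || baseline_rate <= 0)
    stopf("`baseline_rate` must be > 0")
  if (!is.numeric(censor_rate) || censor_rate < 0)
    stopf("`censor_rate` must be >= 0")
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples"),
    hazard_beta = hazard_beta,
    baseline_rate = baseline_rate,
    censor_rate = censor_rate,
    burden_log2fc = burden_log2fc,
    n_background_genes = check_count(n_background_genes, "n_background_genes", min = 0L),
    nb_dispersion = nb_dispersion,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    seed = check_count(seed, "seed", min = 0L)
  )
  class(cfg) <- "survival_sim_config"
  cfg
}

#' Generate a synthetic validation cohort with expression-linked survival
#'
#' @param cfg A \code{survival_sim_config}.
#' @param signatures A list with elements \code{R} and \code{NR}, each a
#'   [gene_signature()] (or plain character vector of gene symbols). The
#'   cohort's gene space is the union of both signatures plus
#'   \code{cfg$n_background_genes} background genes; only NR-signature genes
#'   respond to the latent burden.
#' @return List with \code{counts} (genes x samples), \code{meta},
#'   \code{survival} (data.frame \code{sample_id, time, event}),
#'   \code{truth} (data.frame \code{sample_id, burden}) and \code{config}.
#' @examples
#' sigs <- list(R = paste0("R", 1:20), NR = paste0("N", 1:30))
#' vc <- generate_validation_cohort(survival_sim_config(n_samples = 40, seed = 2), sigs)
#' head(vc$survival)
#' @export
generate_validation_cohort <- function(cfg, signatures) {
  if (!inherits(cfg, "survival_sim_config"))
    stopf("`cfg` must come from survival_sim_config()")
  sig_genes <- function(s) if (inherits(s, "gene_signature")) s$genes else as.character(s)
  r_genes <- unique(sig_genes(signatures$R %||% character(0)))
  nr_genes <- unique(sig_genes(signatures$NR %||% stop("missing NR signature")))
  if (length(nr_genes) == 0L) stopf("NR signature is empty")
  set.seed(cfg$seed)

  bg <- if (cfg$n_background_genes > 0)
    sprintf("BG%05d", seq_len(cfg$n_background_genes)) else character(0)
  genes <- unique(c(r_genes, nr_genes, bg))
  n_genes <- length(genes)
  baseline <- stats::rlnorm(n_genes, cfg$baseline_log_mean, cfg$baseline_log_sd)
  is_nr <- genes %in% nr_genes

  b <- stats::rnorm(cfg$n_samples)
  sample_ids <- sprintf("V%03d", seq_len(cfg$n_samples))
  counts <- matrix(0L, n_genes, cfg$n_samples, dimnames = list(genes, sample_ids))
  log2base <- log2(baseline)
  for (j in seq_len(cfg$n_samples)) {
    shift <- ifelse(is_nr, cfg$burden_log2fc * b[j], 0)
    counts[, j] <- rnb(n_genes, 2^(log2base + shift), cfg$nb_dispersion)
  }

  rate <- cfg$baseline_rate * exp(cfg$hazard_beta * b)
  t_event <- stats::rexp(cfg$n_samples, rate)
  t_cens <- if (cfg$censor_rate > 0) stats::rexp(cfg$n_samples, cfg$censor_rate) else Inf
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  list(counts = counts,
       meta = data.frame(sample_id = sample_ids, stringsAsFactors = FALSE),
       survival = data.frame(sample_id = sample_ids, time = time, event = event,
                             stringsAsFactors = FALSE),
       truth = data.frame(sample_id = sample_ids, burden = b,
                          stringsAsFactors = FALSE),
       config = cfg)
}
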