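#' Construct a gene signature
#'
#' @param name Signature label.
#' @param genes Character vector of gene symbols (non-empty; duplicates
#'   removed).
#' @param provenance One of \code{"R_unique"}, \code{"NR_unique"},
#'   \code{"external"}.
#' @param source_contrast Free-text description of the deriving contrast.
#' @return Object of class \code{"gene_signature"}.
#' @export
gene_signature <- function(name, genes,
                           provenance = c("external", "R_unique", "NR_unique"),
                           source_contrast = "") {
  provenance <- match.arg(provenance)
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stopf("signature '%s' has no genes", name)
  structure(list(name = name, genes = genes, provenance = provenance,
                 source_contrast = source_contrast),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s' (%s): %d genes\n", x$name, x$provenance,
              length(x$genes)))
  invisible(x)
}

#' Derive responder- and non-responder-unique signatures
#'
#' Given the differentially expressed gene sets of the responder-vs-control
#' and non-responder-vs-control contrasts, the R-unique signature is the set
#' difference R \\ NR and the NR-unique signature NR \\ R; genes shared by
#' both contrasts are excluded from both. This captures genes significantly
#' and uniquely expressed in each response arm relative to healthy controls.
#'
#' @param deg_R,deg_NR Non-empty character vectors of DEG symbols from the
#'   two contrasts.
#' @return List with \code{R_unique} and \code{NR_unique}
#'   [gene_signature()] objects.
#' @examples
#' derive_unique_signatures(c("a", "b", "c"), c("c", "d"))
#' @export
derive_unique_signatures <- function(deg_R, deg_NR) {
  deg_R <- unique(as.character(deg_R)); deg_NR <- unique(as.character(deg_NR))
  if (length(deg_R) == 0L || length(deg_NR) == 0L)
    stopf("both DEG sets must be non-empty")
  r_u <- setdiff(deg_R, deg_NR)
  nr_u <- setdiff(deg_NR, deg_R)
  if (length(r_u) == 0L || length(nr_u) == 0L)
    stopf("a unique set is empty after differencing; classifier undefined")
  list(R_unique = gene_signature("R_unique", r_u, "R_unique",
                                 "responders vs controls, minus shared"),
       NR_unique = gene_signature("NR_unique", nr_u, "NR_unique",
                                  "non-responders vs controls, minus shared"))
}

#' Scoring policy for signature scores
#'
#' @param min_gene_coverage Minimum fraction of signature genes that must be
#'   present in the expression matrix (default 0.5).
#' @param case_insensitive Match gene symbols case-insensitively after
#'   trimming whitespace (default TRUE).
#' @return List of class \code{"scoring_policy"}. Standardization is always
#'   the cohort z-score; ties at the median go to NR_like (classification)
#'   and high (stratification).
#' @export
scoring_policy <- function(min_gene_coverage = 0.5, case_insensitive = TRUE) {
  structure(list(
    standardization = "cohort_zscore",
    min_gene_coverage = check_fraction(min_gene_coverage, "min_gene_coverage",
                                       open_lo = TRUE),
    case_insensitive = isTRUE(case_insensitive)
  ), class = "scoring_policy")
}

norm_symbol <- function(x, policy) {
  x <- trimws(as.character(x))
  if (policy$case_insensitive) toupper(x) else x
}

#' Score samples against a gene signature
#'
#' Each signature gene present in the matrix is standardized across the
#' cohort (mean 0, sd 1; zero-sd genes contribute 0) and a sample's score is
#' the mean of its standardized values over the present signature genes.
#' Scores are therefore invariant to per-gene shifts and to global positive
#' rescaling of the expression matrix.
#'
#' @param expr Expression matrix, genes x samples (>= 3 samples).
#' @param signature A [gene_signature()] or character vector of symbols.
#' @param policy A [scoring_policy()].
#' @return Named numeric score vector (one per sample) with attributes
#'   \code{n_matched} and \code{missing} (symbols absent from \code{expr}).
#' @export
score_samples <- function(expr, signature, policy = scoring_policy()) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stopf("need at least 3 samples to standardize scores")
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else unique(as.character(signature))
  key <- norm_symbol(rownames(expr), policy)
  idx <- match(norm_symbol(genes, policy), key)
  missing <- genes[is.na(idx)]
  idx <- idx[!is.na(idx)]
  coverage <- length(idx) / length(genes)
  if (coverage < policy$min_gene_coverage)
    stopf("signature coverage %.2f below minimum %.2f; missing genes: %s",
          coverage, policy$min_gene_coverage,
          paste(utils::head(missing, 10), collapse = ", "))
  x <- expr[idx, , drop = FALSE]
  m <- rowMeans(x)
  s <- sqrt(row_vars(x))
  z <- (x - m) / ifelse(s == 0, Inf, s)  # zero-sd genes contribute 0
  out <- colMeans(z)
  names(out) <- colnames(expr)
  attr(out, "n_matched") <- length(idx)
  attr(out, "missing") <- missing
  out
}

#' Score a cohort against paired R / NR signatures
#'
#' Convenience wrapper producing the per-sample score table used by the
#' delta(NR-R) classifier.
#'
#' @inheritParams score_samples
#' @param sig_R,sig_NR Responder / non-responder signatures.
#' @return Data.frame: \code{sample_id, r_score, nr_score, delta} where
#'   \code{delta = nr_score - r_score}.
#' @export
score_cohort <- function(expr, sig_R, sig_NR, policy = scoring_policy()) {
  r <- score_samples(expr, sig_R, policy)
  nr <- score_samples(expr, sig_NR, policy)
  data.frame(sample_id = colnames(as.matrix(expr)),
             r_score = unname(r), nr_score = unname(nr),
             delta = unname(nr - r), stringsAsFactors = FALSE)
}

#' Classify samples by median split of delta(NR-R)
#'
#' The cohort median of \code{delta = nr_score - r_score} is computed over
#' all samples; samples with delta at or above the median are labeled
#' \code{NR_like}, the rest \code{R_like}.
#'
#' @param scores Data.frame from [score_cohort()] (needs \code{delta}).
#' @return The input with a \code{label} column; label counts are attached
#'   as attribute \code{counts}.
#' @export
classify_delta <- function(scores) {
  if (is.null(scores$delta)) stopf("`scores` must contain a `delta` column")
  if (nrow(scores) < 2L) stopf("need at least 2 samples to median-split")
  med <- stats::median(scores$delta)
  scores$label <- ifelse(scores$delta >= med, "NR_like", "R_like")
  attr(scores, "median_delta") <- med
  attr(scores, "counts") <- table(scores$label)
  scores
}

#' Stratify labeled samples into high/low within their class
#'
#' Within each label class, samples are median-split on that class's own
#' signature score — \code{nr_score} for NR_like samples, \code{r_score} for
#' R_like — with scores at or above the within-class median assigned
#' \code{high}.
#'
#' @param scores Labeled data.frame from [classify_delta()].
#' @return The input with a \code{stratum} column.
#' @export
stratify_within_class <- function(scores) {
  if (is.null(scores$label)) stopf("`scores` must be labeled; run classify_delta()")
  scores$stratum <- NA_character_
  for (lab in unique(scores$label)) {
    j <- scores$label == lab
    if (sum(j) < 2L) stopf("class '%s' has fewer than 2 members", lab)
    sc <- if (lab == "NR_like") scores$nr_score[j] else scores$r_score[j]
    scores$stratum[j] <- ifelse(sc >= stats::median(sc), "high", "low")
  }
  scores
}

#' Transfer signatures to an independent cohort and classify it
#'
#' Scoring, standardization and the median split are computed entirely
#' within the target cohort: the signatures carry only gene membership
#' across cohorts.
#'
#' @param sig_R,sig_NR Signatures derived in the source cohort.
#' @param expr_b Expression matrix of the target cohort.
#' @param policy A [scoring_policy()]; symbol matching and the coverage
#'   requirement apply to each signature separately.
#' @return Labeled score data.frame (as [classify_delta()]), with attribute
#'   \code{coverage} giving the per-signature matched gene counts.
#' @export
transfer_signatures <- function(sig_R, sig_NR, expr_b, policy = scoring_policy()) {
  scores <- score_cohort(expr_b, sig_R, sig_NR, policy)
  out <- classify_delta(scores)
  n_r <- if (inherits(sig_R, "gene_signature")) length(sig_R$genes) else length(unique(sig_R))
  n_nr <- if (inherits(sig_NR, "gene_signature")) length(sig_NR$genes) else length(unique(sig_NR))
  key <- norm_symbol(rownames(as.matrix(expr_b)), policy)
  cov_of <- function(s) {
    g <- if (inherits(s, "gene_signature")) s$genes else unique(as.character(s))
    sum(norm_symbol(g, policy) %in% key)
  }
  attr(out, "coverage") <- c(R = cov_of(sig_R), NR = cov_of(sig_NR),
                             R_total = n_r, NR_total = n_nr)
  out
}
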