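#' Median-of-ratios normalization
#'
#' Computes per-sample size factors as the median, over genes expressed in
#' every sample, of the ratio of the gene's count to its across-sample
#' geometric mean; normalized values are counts divided by the size factor.
#' This is the classical size-factor scheme used for bulk RNA-seq count
#' matrices.
#'
#' @param counts Non-negative count matrix, genes x samples (>= 2 samples).
#' @return List with \code{size_factors} (named numeric) and
#'   \code{normalized} (matrix of the same shape).
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' normalize_median_of_ratios(m)$size_factors
#' @export
normalize_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stopf("need at least 2 samples")
  if (any(counts < 0)) stopf("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stopf(paste("no gene has non-zero counts in every sample;",
                "consider adding a pseudocount before normalization"))
  lc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(lc)
  sf <- apply(lc, 2, function(col) exp(stats::median(col - loggeo)))
  list(size_factors = sf,
       normalized = sweep(counts, 2, sf, "/"))
}

#' Two-group differential expression on normalized counts
#'
#' Per gene, the log2 fold change is the difference of group means of
#' \code{log2(normalized + 1)} (group A minus group B) and the p-value comes
#' from a Welch two-sample t-test on the same transformed values (a paired t
#' in paired mode). Genes with zero variance in both groups and equal means
#' get p = 1; a deterministic nonzero difference with zero variance gets
#' p = 0. A Benjamini-Hochberg adjusted column is included for reference.
#'
#' @param norm Normalized expression matrix, genes x samples.
#' @param group_a,group_b Disjoint sample-id (or column index) vectors, each
#'   of size >= 2. In paired mode the i-th sample of \code{group_a} is
#'   matched to the i-th sample of \code{group_b}.
#' @param paired Use a paired t-test on within-pair differences.
#' @return Data.frame: \code{gene, log2fc, p_value, padj, mean_a, mean_b}
#'   (group means on the normalized, untransformed scale).
#' @export
de_test <- function(norm, group_a, group_b, paired = FALSE) {
  norm <- as.matrix(norm)
  resolve <- function(g, nm) {
    idx <- if (is.character(g)) match(g, colnames(norm)) else as.integer(g)
    if (anyNA(idx) || any(idx < 1 | idx > ncol(norm)))
      stopf("unknown samples in `%s`", nm)
    idx
  }
  ia <- resolve(group_a, "group_a")
  ib <- resolve(group_b, "group_b")
  if (length(ia) < 2L || length(ib) < 2L)
    stopf("each group needs at least 2 samples")
  if (length(intersect(ia, ib)) > 0L) stopf("groups must not overlap")
  if (paired && length(ia) != length(ib))
    stopf("paired mode requires matched groups of equal size")

  a <- log2(norm[, ia, drop = FALSE] + 1)
  b <- log2(norm[, ib, drop = FALSE] + 1)
  ma <- rowMeans(a); mb <- rowMeans(b)
  lfc <- ma - mb

  if (paired) {
    d <- a - b
    nd <- ncol(d)
    md <- rowMeans(d)
    vd <- row_vars(d)
    tt <- md / sqrt(vd / nd)
    p <- 2 * stats::pt(-abs(tt), df = nd - 1)
    degenerate <- vd == 0
    p[degenerate] <- ifelse(md[degenerate] == 0, 1, 0)
  } else {
    na <- ncol(a); nb <- ncol(b)
    va <- row_vars(a); vb <- row_vars(b)
    se2 <- va / na + vb / nb
    tt <- lfc / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tt), df = df)
    degenerate <- se2 == 0
    p[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)
  }

  data.frame(
    gene = rownames(norm) %||% as.character(seq_len(nrow(norm))),
    log2fc = unname(lfc),
    p_value = unname(p),
    padj = stats::p.adjust(unname(p), method = "BH"),
    mean_a = unname(rowMeans(norm[, ia, drop = FALSE])),
    mean_b = unname(rowMeans(norm[, ib, drop = FALSE])),
    stringsAsFactors = FALSE)
}

#' Call differentially expressed genes from a DE result table
#'
#' Up-regulated genes satisfy \code{log2fc >= min_abs_log2fc} with
#' \code{p_value < max_p}; down-regulated genes the mirror-image rule. The
#' fold-change bound is inclusive and the p-value bound strict, matching the
#' usual "|log2FC| >= 1, p < 0.01" convention. Lists are sorted by p-value,
#' ties broken by gene id.
#'
#' @param results Data.frame from [de_test()].
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 1).
#' @param max_p Strict p-value bound (default 0.01).
#' @return List with character vectors \code{up} and \code{down}.
#' @export
call_degs <- function(results, min_abs_log2fc = 1, max_p = 0.01) {
  if (min_abs_log2fc < 0) stopf("`min_abs_log2fc` must be >= 0")
  if (max_p <= 0 || max_p > 1) stopf("`max_p` must lie in (0, 1]")
  pick <- function(sel) {
    r <- results[sel, , drop = FALSE]
    r$gene[order(r$p_value, r$gene)]
  }
  list(up = pick(results$log2fc >= min_abs_log2fc & results$p_value < max_p),
       down = pick(results$log2fc <= -min_abs_log2fc & results$p_value < max_p))
}

#' Per-group mean expression table
#'
#' Arithmetic mean per gene within each requested group, columns in the
#' requested order.
#'
#' @param expr Expression matrix, genes x samples.
#' @param groups Character/factor vector of group labels, one per column of
#'   \code{expr}.
#' @param group_order Optional column order; defaults to order of first
#'   appearance. Every requested group must contain at least one sample.
#' @return Matrix, genes x groups.
#' @export
group_mean_table <- function(expr, groups, group_order = NULL) {
  expr <- as.matrix(expr)
  groups <- as.character(groups)
  if (length(groups) != ncol(expr))
    stopf("`groups` must have one label per sample")
  lev <- group_order %||% unique(groups)
  out <- vapply(lev, function(g) {
    j <- which(groups == g)
    if (length(j) == 0L) stopf("group '%s' has no samples", g)
    rowMeans(expr[, j, drop = FALSE])
  }, numeric(nrow(expr)))
  dimnames(out) <- list(rownames(expr), lev)
  out
}

#' Directional gene counts between column sets of a group-mean table
#'
#' Averages the left and right column sets with equal weight per column and
#' counts genes whose left mean is strictly below (\code{"<"}) or above
#' (\code{">"}) the right mean. Ties are not called. This reproduces panel
#' summaries such as "43 of 56 B-cell genes lower in pre-treatment patients
#' than controls".
#'
#' @param table Group-mean matrix or data.frame with genes in rows.
#' @param left,right Column-name sets.
#' @param direction \code{"<"} or \code{">"} (comparison of left vs right).
#' @return List: \code{n} (count of called genes), \code{calls} (named
#'   logical per gene).
#' @export
count_directional <- function(table, left, right, direction = c("<", ">")) {
  direction <- match.arg(direction)
  tab <- as.matrix(table)
  unknown <- setdiff(c(left, right), colnames(tab))
  if (length(unknown)) stopf("unknown columns: %s", paste(unknown, collapse = ", "))
  lm <- rowMeans(tab[, left, drop = FALSE])
  rm_ <- rowMeans(tab[, right, drop = FALSE])
  calls <- if (direction == "<") lm < rm_ else lm > rm_
  names(calls) <- rownames(tab)
  list(n = sum(calls), calls = calls)
}
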