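#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator: at each distinct event time t_i with
#' d_i events among n_i at risk, the survival curve drops by the factor
#' (1 - d_i / n_i). Censoring times remove subjects from the risk set
#' without a drop; a fully censored dataset yields S identically 1.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Object of class \code{"km_curve"}: data.frame with
#'   \code{time}, \code{n_risk}, \code{n_event}, \code{survival} at each
#'   distinct event time (increasing).
#' @examples
#' km <- km_estimate(c(2, 3, 3, 5, 8), c(1, 1, 0, 1, 0))
#' km
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stopf("need at least one record")
  if (any(is.na(time)) || any(time <= 0)) stopf("`time` must be positive")
  if (!all(event %in% c(0, 1))) stopf("`event` must be 0 or 1")
  if (length(event) != length(time)) stopf("`time` and `event` lengths differ")
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = et, n_risk = n_risk, n_event = n_event,
                       survival = surv),
            class = c("km_curve", "data.frame"),
            n = length(time), n_events = sum(event))
}

#' Median survival time of a KM curve
#'
#' First time at which the survival curve is at or below 0.5; \code{NA}
#' (with attribute \code{reached = FALSE}) if the curve never reaches 0.5.
#'
#' @param km A \code{km_curve}.
#' @return Numeric time or NA.
#' @export
median_survival <- function(km) {
  i <- which(km$survival <= 0.5)
  if (length(i) == 0L) structure(NA_real_, reached = FALSE)
  else structure(km$time[min(i)], reached = TRUE)
}

#' Log-rank test between survival groups
#'
#' Standard k-group log-rank chi-square with k - 1 degrees of freedom. At
#' each distinct event time the observed per-group events are compared with
#' expectation under the null (events allocated proportionally to the groups'
#' risk sets), with the usual hypergeometric variance-covariance; the
#' statistic is the quadratic form of the first k - 1 components.
#'
#' @param time,event As in [km_estimate()].
#' @param group Group labels (>= 2 non-empty groups; >= 1 event overall).
#' @return List of class \code{"logrank_result"}: \code{chi2}, \code{df},
#'   \code{p}, \code{observed}, \code{expected} (per group).
#' @export
logrank_test <- function(time, event, group) {
  if (any(is.na(time)) || any(time <= 0)) stopf("`time` must be positive")
  if (!all(event %in% c(0, 1))) stopf("`event` must be 0 or 1")
  group <- factor(group)
  if (nlevels(group) < 2L) stopf("need at least 2 groups")
  if (any(table(group) == 0L)) stopf("every group must be non-empty")
  if (sum(event) == 0L) stopf("degenerate test: no events in any group")
  k <- nlevels(group)
  et <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  V <- matrix(0, k, k, dimnames = list(levels(group), levels(group)))
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_g <- as.numeric(tapply(at_risk, group, sum, default = 0))
    d <- sum(time == t & event == 1)
    d_g <- as.numeric(tapply(time == t & event == 1, group, sum, default = 0))
    O <- O + d_g
    E <- E + n_g * d / n
    if (n > 1) {
      f <- d * (n - d) / (n - 1)
      V <- V + f * (diag(n_g / n, k) - tcrossprod(n_g / n))
    }
  }
  U <- (O - E)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  chi2 <- if (all(abs(U) < 1e-12)) 0 else {
    inv <- tryCatch(solve(Vsub), error = function(e) {
      s <- svd(Vsub)
      keep <- s$d > max(s$d) * 1e-10
      s$v[, keep, drop = FALSE] %*% diag(1 / s$d[keep], sum(keep)) %*%
        t(s$u[, keep, drop = FALSE])
    })
    drop(t(U) %*% inv %*% U)
  }
  structure(list(chi2 = chi2, df = k - 1,
                 p = stats::pchisq(chi2, df = k - 1, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Pearson chi-square with the continuity correction: each |O - E| is
#' reduced by 0.5 (floored at 0) before squaring. One degree of freedom.
#'
#' @param table 2x2 matrix of non-negative counts; all row and column
#'   marginals must be positive.
#' @return List: \code{statistic}, \code{p}, \code{expected}.
#' @examples
#' chisq_yates(matrix(c(12, 7, 5, 14), 2))
#' @export
chisq_yates <- function(table) {
  O <- as.matrix(table)
  if (!all(dim(O) == c(2L, 2L))) stopf("`table` must be 2x2")
  if (any(O < 0)) stopf("counts must be non-negative")
  r <- rowSums(O); cs <- colSums(O)
  if (any(r == 0) || any(cs == 0)) stopf("all marginals must be positive")
  E <- outer(r, cs) / sum(O)
  stat <- sum(pmax(abs(O - E) - 0.5, 0)^2 / E)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = E)
}

#' Survival evaluation of classifier groups
#'
#' Joins classifier labels onto survival records, fits a KM curve per group,
#' reports each group's median survival and runs pairwise log-rank tests
#' between all label pairs (no test when only one label is present).
#'
#' @param labels Data.frame with \code{sample_id} and \code{label} (e.g. from
#'   [classify_delta()] or [transfer_signatures()]).
#' @param records Data.frame with \code{sample_id}, \code{time},
#'   \code{event}; every record must have a label.
#' @return List of class \code{"survival_report"}: \code{curves} (named list
#'   of \code{km_curve}), \code{median_survival} (named numeric, NA when not
#'   reached), \code{tests} (data.frame of pairwise log-rank results),
#'   \code{n} per group.
#' @export
evaluate_classifier_survival <- function(labels, records) {
  m <- match(records$sample_id, labels$sample_id)
  if (anyNA(m))
    stopf("records without a classifier label: %s",
          paste(utils::head(records$sample_id[is.na(m)], 10), collapse = ", "))
  grp <- labels$label[m]
  curves <- lapply(split(seq_len(nrow(records)), grp), function(i)
    km_estimate(records$time[i], records$event[i]))
  med <- vapply(curves, function(k) as.numeric(median_survival(k)), numeric(1))
  labs <- names(curves)
  tests <- NULL
  if (length(labs) > 1L) {
    pairs <- utils::combn(labs, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      sel <- grp %in% pairs[, j]
      lr <- logrank_test(records$time[sel], records$event[sel], grp[sel])
      data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
                 chi2 = lr$chi2, p = lr$p, stringsAsFactors = FALSE)
    }))
  }
  structure(list(curves = curves, median_survival = med, tests = tests,
                 n = table(grp)),
            class = "survival_report")
}

#' @export
print.survival_report <- function(x, ...) {
  cat("Survival report\n")
  for (g in names(x$curves))
    cat(sprintf("  %s: n = %d, events = %d, median survival = %s\n", g,
                attr(x$curves[[g]], "n"), attr(x$curves[[g]], "n_events"),
                ifelse(is.na(x$median_survival[[g]]), "not reached",
                       format(x$median_survival[[g]], digits = 4))))
  if (!is.null(x$tests))
    for (i in seq_len(nrow(x$tests)))
      cat(sprintf("  log-rank %s vs %s: chi2 = %.3g, p = %.3g\n",
                  x$tests$group1[i], x$tests$group2[i], x$tests$chi2[i],
                  x$tests$p[i]))
  invisible(x)
}
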