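# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' @importFrom stats median rnorm runif rexp rlnorm rnbinom rpois pt pchisq
#'   p.adjust setNames uniroot var cor
NULL

# Row variances of a numeric matrix (denominator n - 1).
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Stable short hash of an arbitrary R object (md5 of its serialization).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

pkg_version <- function() {
  as.character(utils::packageVersion("azasig"))
}

# Header comment stamped on every delimited output file.
output_header <- function(seed = NA, hash = NA) {
  sprintf("# azasig %s seed=%s config=%s", pkg_version(),
          as.character(seed), as.character(hash))
}

write_table_with_header <- function(df, path, sep = "\t", seed = NA, hash = NA) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(output_header(seed, hash), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) stopf("`%s` must lie in %s%g, %g%s", name,
                 if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]")
  as.numeric(x)
}
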