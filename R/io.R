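#' @name io
#' @title Readers and writers for the pipeline's file formats
#' @description
#' Count matrices as TSV (genes in rows) or MatrixMarket MTX with gene/sample
#' side files; sample metadata TSV; variant TSV; survival CSV; GMT gene-set
#' files; JSON truth records and run manifests. Delimited files written by
#' this package carry a `#` header comment with the package version, seed and
#' configuration hash; all readers skip `#` comments.
NULL

#' Write a count matrix with metadata
#'
#' @param counts Integer matrix, genes x samples.
#' @param meta Sample metadata data.frame (must contain \code{sample_id}
#'   matching the matrix columns).
#' @param prefix Output path prefix; files written are
#'   \code{<prefix>_counts.tsv} (or \code{.mtx} + \code{_genes.txt} +
#'   \code{_samples.txt}) and \code{<prefix>_meta.tsv}.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @param seed,hash Stamped into the header comment.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(counts, meta, prefix, format = c("tsv", "mtx"),
                         seed = NA, hash = NA) {
  format <- match.arg(format)
  if (!identical(colnames(counts), meta$sample_id))
    stopf("matrix columns and metadata sample_id must match in order")
  paths <- character(0)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    p <- paste0(prefix, "_counts.tsv")
    write_table_with_header(df, p, seed = seed, hash = hash)
    paths <- p
  } else {
    p <- paste0(prefix, "_counts.mtx")
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), p)
    writeLines(rownames(counts), paste0(prefix, "_genes.txt"))
    writeLines(colnames(counts), paste0(prefix, "_samples.txt"))
    paths <- c(p, paste0(prefix, "_genes.txt"), paste0(prefix, "_samples.txt"))
  }
  mp <- paste0(prefix, "_meta.tsv")
  write_table_with_header(meta, mp, seed = seed, hash = hash)
  invisible(c(paths, mp))
}

#' Read a count matrix written by [write_counts()]
#'
#' @param prefix Path prefix used when writing.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @return List with \code{counts} (integer matrix) and \code{meta}.
#' @export
read_counts <- function(prefix, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    p <- paste0(prefix, "_counts.tsv")
    df <- utils::read.delim(p, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (anyDuplicated(df$gene))
      stopf("duplicate gene symbols in %s: %s", p,
            paste(utils::head(unique(df$gene[duplicated(df$gene)]), 5),
                  collapse = ", "))
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df$gene
    if (any(counts < 0)) stopf("negative counts in %s", p)
    if (any(counts != round(counts))) stopf("non-integer counts in %s", p)
    storage.mode(counts) <- "integer"
  } else {
    m <- Matrix::readMM(paste0(prefix, "_counts.mtx"))
    genes <- readLines(paste0(prefix, "_genes.txt"))
    samples <- readLines(paste0(prefix, "_samples.txt"))
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
      stopf("MTX dimensions do not match gene/sample side files")
    if (anyDuplicated(genes)) stopf("duplicate gene symbols in side file")
    counts <- as.matrix(m)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(genes, samples)
  }
  meta <- utils::read.delim(paste0(prefix, "_meta.tsv"), comment.char = "#",
                            stringsAsFactors = FALSE)
  if (!identical(colnames(counts), meta$sample_id))
    stopf("metadata sample_id does not match count matrix columns")
  list(counts = counts, meta = meta)
}

#' Write / read a variant call table (TSV)
#'
#' @param calls Variant call data.frame.
#' @param path Output path.
#' @param seed,hash Header stamp.
#' @return \code{write_variants}: invisibly, \code{path};
#'   \code{read_variants}: the data.frame.
#' @export
write_variants <- function(calls, path, seed = NA, hash = NA) {
  check_variant_calls(calls)
  write_table_with_header(calls, path, seed = seed, hash = hash)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = NA)
  for (col in c("ref", "alt")) if (!is.null(df[[col]])) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  check_variant_calls(df)
  df
}

#' Write / read a survival table (CSV: sample_id, time, event)
#'
#' @param records Data.frame with \code{sample_id}, \code{time}, \code{event}.
#' @param path Output path.
#' @param seed,hash Header stamp.
#' @export
write_survival <- function(records, path, seed = NA, hash = NA) {
  if (any(records$time <= 0)) stopf("`time` must be positive")
  if (!all(records$event %in% c(0, 1))) stopf("`event` must be 0 or 1")
  write_table_with_header(records, path, sep = ",", seed = seed, hash = hash)
}

#' @rdname write_survival
#' @export
read_survival <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (any(df$time <= 0)) stopf("`time` must be positive in %s", path)
  if (!all(df$event %in% c(0, 1))) stopf("`event` must be 0 or 1 in %s", path)
  df
}

#' Read / write gene signatures in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return \code{read_gmt}: named list of character vectors (the description
#'   field is kept as attribute \code{description}).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("malformed GMT line (need name, description, >=1 gene)")
    genes <- unique(f[-(1:2)])
    attr(genes, "description") <- f[2]
    out[[f[1]]] <- genes
  }
  out
}

#' @rdname read_gmt
#' @param signatures Named list of character vectors, or of
#'   [gene_signature()] objects.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(names(signatures), function(nm) {
    s <- signatures[[nm]]
    genes <- if (inherits(s, "gene_signature")) s$genes else as.character(s)
    desc <- if (inherits(s, "gene_signature")) s$source_contrast else
      attr(s, "description") %||% ""
    paste(c(nm, desc, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a group-mean expression panel table
#'
#' Loads a genes-by-groups mean-expression TSV (first column \code{gene})
#' such as the bundled B-cell development panel
#' (\code{system.file("extdata", "bcell_panel_means.tsv", package = "azasig")}),
#' a 56-gene panel of average expression in healthy controls and in
#' responder / non-responder patients pre and post treatment.
#'
#' @param path TSV path.
#' @return Numeric matrix, genes x group columns.
#' @export
read_panel_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) stopf("duplicate gene symbols in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  if (!is.numeric(m)) stopf("panel table must be numeric")
  m
}

#' Minimal VCF ingestion into the variant-call table
#'
#' Reads CHROM/POS/REF/ALT plus an allele frequency (the \code{AF} INFO
#' field, or the first sample's \code{AF} FORMAT field) and maps each record
#' into the package's variant-call columns. Gene symbols are taken from a
#' \code{GENE} INFO field when present, otherwise \code{CHROM:POS} is used.
#' Multi-allelic records are not expanded (first ALT taken).
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @param patient_id,timepoint,compartment Constant annotation applied to
#'   every record.
#' @return Variant call data.frame.
#' @export
read_vcf_variants <- function(path, patient_id, timepoint = "pre",
                              compartment = "CD34") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  if (all(is.na(af))) {
    gt_af <- tryCatch(vcfR::extract.gt(v, "AF", as.numeric = TRUE),
                      error = function(e) NULL)
    if (!is.null(gt_af)) af <- as.numeric(gt_af[, 1])
  }
  if (all(is.na(af))) stopf("no AF found in INFO or FORMAT of %s", path)
  gene <- suppressWarnings(vcfR::extract.info(v, "GENE"))
  gene <- ifelse(is.na(gene) | !nzchar(gene),
                 paste0(fix$CHROM, ":", fix$POS), gene)
  alt1 <- sub(",.*", "", fix$ALT)
  snv <- nchar(fix$REF) == 1 & nchar(alt1) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  df <- data.frame(
    patient_id = patient_id, gene = gene,
    change = paste0(fix$REF, fix$POS, alt1),
    ref = ifelse(snv, fix$REF, ""), alt = ifelse(snv, alt1, ""),
    variant_class = ifelse(snv, "SNV", "indel"),
    timepoint = timepoint, compartment = compartment,
    vaf_pct = 100 * af, stringsAsFactors = FALSE)
  check_variant_calls(df)
  df
}

#' Write a JSON report or truth record
#'
#' @param x A list.
#' @param path Output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}
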