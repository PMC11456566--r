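#' @name variant_dynamics
#' @title Paired VAF dynamics: filtering, pairing, classification, spectrum
#' @description
#' Tools for paired pre/post-treatment variant tables on the percent VAF
#' scale: a 5% VAF cutoff with a symmetric paired rescue rule (a sub-cutoff
#' call is kept when the same mutation clears the cutoff at the other
#' timepoint, the situation seen for expanding NRAS/KRAS subclones and for a
#' TP53 clone collapsing from 87.48% to 3.98%), per-mutation dynamics
#' classification, the transition/transversion spectrum, compartment VAF
#' correlation and per-patient burden summaries.
NULL

dynamics_levels <- c("ACQUIRED", "INCREASED", "STABLE", "DECREASED", "LOST")

check_variant_calls <- function(calls) {
  need <- c("patient_id", "gene", "change", "timepoint", "compartment", "vaf_pct")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stopf("variant table lacks columns: %s", paste(miss, collapse = ", "))
  if (any(is.na(calls$vaf_pct)) || any(calls$vaf_pct < 0) || any(calls$vaf_pct > 100))
    stopf("`vaf_pct` must lie in [0, 100] with no missing values")
  bad <- !calls$timepoint %in% c("pre", "post")
  if (any(bad)) stopf("`timepoint` must be 'pre' or 'post'")
  invisible(calls)
}

#' Filter variant calls by VAF cutoff with paired rescue
#'
#' A call is retained iff its VAF is at or above the cutoff, or (with
#' \code{paired_rescue}) the same mutation — identified by patient, gene,
#' protein/nucleotide change and compartment — clears the cutoff at the other
#' timepoint. The rescue is symmetric: a rising subclone's low pre-treatment
#' VAF is kept because its post-treatment VAF is high, and vice versa.
#' Output row order is stable. Filtering is idempotent.
#'
#' @param calls Variant call data.frame (see [generate_variant_table()] for
#'   the column contract).
#' @param cutoff_pct VAF cutoff on the percent scale, in (0, 100]. Default 5.
#' @param paired_rescue Apply the cross-timepoint rescue rule. Default TRUE.
#' @return The retained rows of \code{calls}.
#' @examples
#' x <- data.frame(patient_id = "P1", gene = "NRAS", change = "c.1A>G",
#'                 timepoint = c("pre", "post"), compartment = "CD34",
#'                 vaf_pct = c(1.27, 15.29))
#' nrow(filter_by_vaf(x))  # both kept: post rescues pre
#' @export
filter_by_vaf <- function(calls, cutoff_pct = 5, paired_rescue = TRUE) {
  check_variant_calls(calls)
  if (!is.numeric(cutoff_pct) || cutoff_pct <= 0 || cutoff_pct > 100)
    stopf("`cutoff_pct` must lie in (0, 100]")
  if (nrow(calls) == 0L) return(calls)
  keep <- calls$vaf_pct >= cutoff_pct
  if (paired_rescue) {
    key <- paste(calls$patient_id, calls$gene, calls$change, calls$compartment,
                 sep = "\r")
    # retained if a same-key call at the other timepoint passes
    passing <- paste(key, calls$timepoint, sep = "\r")[keep]
    other_tp <- ifelse(calls$timepoint == "pre", "post", "pre")
    keep <- keep | paste(key, other_tp, sep = "\r") %in% passing
  }
  calls[keep, , drop = FALSE]
}

#' Pair pre/post variant calls into one row per mutation
#'
#' Groups calls from a single compartment by (patient, gene, change);
#' a missing timepoint is recorded as \code{NA}. Duplicate
#' (patient, gene, change, timepoint) entries are a data-integrity error.
#'
#' @param calls Variant call data.frame from one compartment.
#' @return Data.frame with one row per mutation: identity columns plus
#'   \code{pre_vaf_pct} and \code{post_vaf_pct}.
#' @export
pair_variants <- function(calls) {
  check_variant_calls(calls)
  if (length(unique(calls$compartment)) > 1L)
    stopf("`calls` must come from a single compartment; found: %s",
          paste(unique(calls$compartment), collapse = ", "))
  key <- paste(calls$patient_id, calls$gene, calls$change, sep = "\r")
  kt <- paste(key, calls$timepoint, sep = "\r")
  if (anyDuplicated(kt)) {
    d <- calls[duplicated(kt), c("patient_id", "gene", "change", "timepoint")][1, ]
    stopf("duplicate variant call for (%s, %s, %s, %s)",
          d$patient_id, d$gene, d$change, d$timepoint)
  }
  first <- !duplicated(key)
  keep_cols <- intersect(c("patient_id", "gene", "change", "ref", "alt",
                           "variant_class"), names(calls))
  out <- calls[first, keep_cols, drop = FALSE]
  idx <- function(tp) match(paste(key[first], tp, sep = "\r"), kt)
  out$pre_vaf_pct <- calls$vaf_pct[idx("pre")]
  out$post_vaf_pct <- calls$vaf_pct[idx("post")]
  rownames(out) <- NULL
  out
}

#' Classify the clonal dynamics of a paired mutation
#'
#' Vectorized over mutations. Absent-to-present is \code{ACQUIRED},
#' present-to-absent \code{LOST}; among mutations seen at both timepoints,
#' a relative VAF change below \code{rel_change_min} is \code{STABLE},
#' otherwise \code{INCREASED}/\code{DECREASED} by sign. "Absent" means not
#' detected (\code{NA}), not merely below the reporting cutoff — a clone
#' falling from 87.48% to 3.98% is \code{DECREASED}, not lost.
#'
#' @param pre_vaf,post_vaf Percent VAFs; \code{NA} = not detected.
#' @param rel_change_min Relative-change threshold of the STABLE band
#'   (fraction of the pre-treatment VAF). Default 0.25.
#' @return Factor with levels ACQUIRED, INCREASED, STABLE, DECREASED, LOST.
#' @examples
#' classify_dynamics(c(87.48, 1.27, 10, NA), c(3.98, 15.29, 10, 7.2))
#' @export
classify_dynamics <- function(pre_vaf, post_vaf, rel_change_min = 0.25) {
  if (!is.numeric(rel_change_min) || rel_change_min <= 0)
    stopf("`rel_change_min` must be > 0")
  n <- max(length(pre_vaf), length(post_vaf))
  pre <- rep_len(as.numeric(pre_vaf), n)
  post <- rep_len(as.numeric(post_vaf), n)
  if (any(is.na(pre) & is.na(post)))
    stopf("a mutation must be detected at at least one timepoint")
  out <- character(n)
  out[is.na(pre)] <- "ACQUIRED"
  out[is.na(post)] <- "LOST"
  both <- !is.na(pre) & !is.na(post)
  # pre == 0 with a detected post reading is treated as newly acquired
  zero_pre <- both & pre == 0
  out[zero_pre & post > 0] <- "ACQUIRED"
  out[zero_pre & post == 0] <- "STABLE"
  b <- both & !zero_pre
  rel <- (post - pre) / pre
  out[b & abs(rel) < rel_change_min] <- "STABLE"
  out[b & rel >= rel_change_min] <- "INCREASED"
  out[b & rel <= -rel_change_min] <- "DECREASED"
  factor(out, levels = dynamics_levels)
}

#' Classify a single-nucleotide substitution as transition or transversion
#'
#' Purine-to-purine (A<->G) and pyrimidine-to-pyrimidine (C<->T) changes are
#' transitions; purine<->pyrimidine changes are transversions.
#'
#' @param ref_base,alt_base Single uppercase bases in A/C/G/T; ref != alt.
#' @return Character vector, "transition" or "transversion".
#' @examples
#' classify_substitution(c("C", "A", "C"), c("T", "G", "A"))
#' @export
classify_substitution <- function(ref_base, alt_base) {
  ref <- as.character(ref_base); alt <- as.character(alt_base)
  valid <- c("A", "C", "G", "T")
  if (!all(ref %in% valid) || !all(alt %in% valid))
    stopf("bases must be one of A, C, G, T")
  if (any(ref == alt)) stopf("ref and alt bases must differ")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Summarize the substitution spectrum of a paired variant table
#'
#' Headline proportions (transition / transversion / other) are computed over
#' the pre-treatment mutation set; non-SNVs count as "other". Per-substitution
#' dynamics counts (e.g. how many C>T mutations decreased) and the fraction
#' of unchanged (STABLE) VAFs among transitions and transversions are
#' reported alongside.
#'
#' @param paired Output of [pair_variants()]; a \code{dynamics} column is
#'   computed with [classify_dynamics()] if absent.
#' @param rel_change_min Passed to [classify_dynamics()] when needed.
#' @return A list of class \code{"spectrum_summary"}: \code{n_total},
#'   \code{prop_transition}, \code{prop_transversion}, \code{prop_other},
#'   \code{per_substitution} (substitution x dynamics count table) and
#'   \code{change_by_class} (unchanged-VAF fraction for transitions and
#'   transversions).
#' @export
spectrum_summary <- function(paired, rel_change_min = 0.25) {
  if (nrow(paired) == 0L) stopf("`paired` must be non-empty")
  if (is.null(paired$dynamics))
    paired$dynamics <- classify_dynamics(paired$pre_vaf_pct, paired$post_vaf_pct,
                                         rel_change_min)
  pre <- paired[!is.na(paired$pre_vaf_pct), , drop = FALSE]
  if (nrow(pre) == 0L) stopf("no pre-treatment mutations in `paired`")
  is_snv <- !is.na(pre$variant_class) & pre$variant_class == "SNV" &
    nzchar(pre$ref) & nzchar(pre$alt)
  cls <- rep("other", nrow(pre))
  if (any(is_snv))
    cls[is_snv] <- classify_substitution(pre$ref[is_snv], pre$alt[is_snv])
  n <- nrow(pre)
  subs <- ifelse(is_snv, paste0(pre$ref, ">", pre$alt), "non-SNV")
  per_sub <- table(substitution = subs,
                   dynamics = factor(as.character(pre$dynamics),
                                     levels = dynamics_levels))
  unchanged <- function(which_cls) {
    m <- cls == which_cls
    if (!any(m)) return(NA_real_)
    mean(pre$dynamics[m] == "STABLE")
  }
  structure(list(
    n_total = n,
    prop_transition = sum(cls == "transition") / n,
    prop_transversion = sum(cls == "transversion") / n,
    prop_other = sum(cls == "other") / n,
    per_substitution = per_sub,
    change_by_class = c(transition = unchanged("transition"),
                        transversion = unchanged("transversion"))
  ), class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("Substitution spectrum over %d pre-treatment mutations\n", x$n_total))
  cat(sprintf("  transitions %.1f%%, transversions %.1f%%, other %.1f%%\n",
              100 * x$prop_transition, 100 * x$prop_transversion,
              100 * x$prop_other))
  cat(sprintf("  unchanged VAF: %.1f%% of transitions, %.1f%% of transversions\n",
              100 * x$change_by_class[["transition"]],
              100 * x$change_by_class[["transversion"]]))
  invisible(x)
}

#' Pearson correlation between compartment VAFs
#'
#' Standard product-moment correlation between matched bulk (BMMC) and
#' sorted CD34+ VAFs.
#'
#' @param bmmc_vaf_pct,cd34_vaf_pct Matched percent VAF vectors (>= 3 pairs,
#'   each with non-zero variance).
#' @return Correlation coefficient in [-1, 1].
#' @export
compartment_correlation <- function(bmmc_vaf_pct, cd34_vaf_pct) {
  if (length(bmmc_vaf_pct) != length(cd34_vaf_pct))
    stopf("VAF vectors must have equal length")
  if (length(bmmc_vaf_pct) < 3L) stopf("need at least 3 VAF pairs")
  if (anyNA(bmmc_vaf_pct) || anyNA(cd34_vaf_pct))
    stopf("VAF pairs must be complete")
  if (stats::var(bmmc_vaf_pct) == 0 || stats::var(cd34_vaf_pct) == 0)
    stopf("correlation undefined: constant VAF vector")
  stats::cor(bmmc_vaf_pct, cd34_vaf_pct)
}

#' Per-cohort mutation burden summary
#'
#' Counts mutations per patient over a paired variant table. Patients in the
#' roster with no mutations count toward the median and range. "Any VAF
#' reduction" means at least one mutation classified DECREASED or LOST; the
#' corresponding fraction is reported over patients that carry mutations.
#'
#' @param paired Output of [pair_variants()] (a \code{dynamics} column is
#'   computed if absent).
#' @param patients Character vector: the full patient roster.
#' @param rel_change_min Passed to [classify_dynamics()] when needed.
#' @return List: \code{n_mutations_total}, \code{median_per_patient},
#'   \code{range}, \code{n_patients_with_mutations},
#'   \code{n_patients_with_any_vaf_reduction}, \code{frac_with_reduction}.
#' @export
cohort_mutation_summary <- function(paired, patients, rel_change_min = 0.25) {
  if (length(patients) == 0L) stopf("patient roster must be non-empty")
  patients <- unique(as.character(patients))
  if (nrow(paired) > 0 && is.null(paired$dynamics))
    paired$dynamics <- classify_dynamics(paired$pre_vaf_pct, paired$post_vaf_pct,
                                         rel_change_min)
  extra <- setdiff(unique(paired$patient_id), patients)
  if (length(extra)) stopf("mutations for patients missing from roster: %s",
                           paste(extra, collapse = ", "))
  per_patient <- table(factor(paired$patient_id, levels = patients))
  reduced <- tapply(paired$dynamics %in% c("DECREASED", "LOST"),
                    factor(paired$patient_id, levels = patients),
                    any, default = FALSE)
  n_with <- sum(per_patient > 0)
  n_red <- sum(reduced, na.rm = TRUE)
  list(
    n_mutations_total = nrow(paired),
    median_per_patient = stats::median(as.numeric(per_patient)),
    range = range(as.numeric(per_patient)),
    n_patients_with_mutations = n_with,
    n_patients_with_any_vaf_reduction = n_red,
    frac_with_reduction = if (n_with > 0) n_red / n_with else NA_real_,
    per_patient = per_patient
  )
}
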