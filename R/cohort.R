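#' Summarize per-case driver calls into cohort statistics
#'
#' Computes the headline numbers of a driver-nomination study: per-gene
#' mutation frequencies (integer percentages, half rounded away from zero),
#' the combined MAPK-driver frequency, VAF summaries over cases with a
#' measured VAF, and an anatomic-site breakdown. Cases carry at most one
#' driver call, so HRAS + BRAF + wild-type counts partition the cohort.
#' Cases with a mutation call but no measured VAF count toward frequencies
#' but are excluded from the VAF statistics.
#'
#' @param cases data.frame with columns case_id, location ("Mandible" or
#'   "Maxilla"), tissue ("FFPE" or "fresh"), gene (driver gene symbol or
#'   `NA`), protein_change, vaf (fraction or `NA`), read_depth
#' @return object of class `cohort_summary`
#' @export
summarize_cohort <- function(cases) {
  if (!nrow(cases)) stop("no cases to summarize")
  loc <- cases$location
  if (any(!loc %in% c("Mandible", "Maxilla")))
    stop("unknown anatomic site label: ",
         paste(unique(setdiff(loc, c("Mandible", "Maxilla"))), collapse = ", "))
  n <- nrow(cases)
  n_hras <- sum(cases$gene == "HRAS", na.rm = TRUE)
  n_braf <- sum(cases$gene == "BRAF", na.rm = TRUE)
  n_wt <- sum(is.na(cases$gene))
  stopifnot(n_hras + n_braf + n_wt == n)
  vafs <- cases$vaf[!is.na(cases$vaf)]
  out <- list(
    n_cases = n, n_hras = n_hras, n_braf = n_braf, n_wildtype = n_wt,
    n_q61r = sum(!is.na(cases$protein_change) & cases$protein_change == "Q61R"),
    freq_hras = percent_of(n_hras, n),
    freq_braf = percent_of(n_braf, n),
    freq_mapk = percent_of(n_hras + n_braf, n),
    n_vaf = length(vafs),
    vaf_mean = if (length(vafs)) mean(vafs) else NA_real_,
    vaf_min = if (length(vafs)) min(vafs) else NA_real_,
    vaf_max = if (length(vafs)) max(vafs) else NA_real_,
    by_site = site_breakdown(cases)
  )
  class(out) <- "cohort_summary"
  out
}

#' Anatomic-site by driver-genotype breakdown
#'
#' @inheritParams summarize_cohort
#' @return integer matrix, rows Mandible/Maxilla, columns HRAS/BRAF/none
#' @export
site_breakdown <- function(cases) {
  loc <- cases$location
  if (any(!loc %in% c("Mandible", "Maxilla")))
    stop("unknown anatomic site label: ",
         paste(unique(setdiff(loc, c("Mandible", "Maxilla"))), collapse = ", "))
  geno <- ifelse(is.na(cases$gene), "none", cases$gene)
  tab <- table(factor(loc, levels = c("Mandible", "Maxilla")),
               factor(geno, levels = c("HRAS", "BRAF", "none")))
  m <- matrix(as.integer(tab), nrow = 2,
              dimnames = list(c("Mandible", "Maxilla"),
                              c("HRAS", "BRAF", "none")))
  m
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d case(s)\n", x$n_cases))
  cat(sprintf("  HRAS mutant: %d (%d%%)\n", x$n_hras, x$freq_hras))
  cat(sprintf("  BRAF mutant: %d (%d%%)\n", x$n_braf, x$freq_braf))
  cat(sprintf("  MAPK driver combined: %d%%\n", x$freq_mapk))
  if (x$n_vaf > 0)
    cat(sprintf("  VAF over %d measured case(s): mean %.3f, range %.3f-%.3f\n",
                x$n_vaf, x$vaf_mean, x$vaf_min, x$vaf_max))
  cat("  By site:\n")
  print(x$by_site)
  invisible(x)
}

#' Cohort summary as a flat JSON-ready list
#'
#' Percentages are integers; VAF statistics are also given as integer
#' percentages (`vaf_*_pct`) alongside the fractional values.
#'
#' @param x a `cohort_summary`
#' @return named list of scalars plus the by_site count table
#' @export
summary_as_list <- function(x) {
  list(
    n_cases = x$n_cases, n_hras = x$n_hras, n_braf = x$n_braf,
    n_wildtype = x$n_wildtype, n_q61r = x$n_q61r,
    freq_hras = x$freq_hras, freq_braf = x$freq_braf,
    freq_mapk = x$freq_mapk,
    n_vaf = x$n_vaf, vaf_mean = x$vaf_mean, vaf_min = x$vaf_min,
    vaf_max = x$vaf_max,
    vaf_mean_pct = if (is.na(x$vaf_mean)) NA else round_half_up(100 * x$vaf_mean),
    vaf_min_pct = if (is.na(x$vaf_min)) NA else round_half_up(100 * x$vaf_min),
    vaf_max_pct = if (is.na(x$vaf_max)) NA else round_half_up(100 * x$vaf_max),
    by_site = as.data.frame.matrix(x$by_site)
  )
}
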