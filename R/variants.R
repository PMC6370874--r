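#' Construct a table of single-nucleotide variant records
#'
#' The package's working representation of called SNVs is a plain data.frame
#' with one row per (site, alt allele). Later pipeline stages append
#' annotation columns (gene symbol, consequence class, hotspot match, filter
#' status) without changing these core columns.
#'
#' @param chrom contig name
#' @param pos 1-based genomic position
#' @param ref_allele,alt_allele single bases in A/C/G/T; must differ
#' @param total_depth read count at the site (>= 0); may be `NA` when the
#'   source VCF carried no usable depth field (the record is then flagged
#'   `no_evidence`)
#' @param alt_depth reads supporting the alt allele; `0 <= alt_depth <=
#'   total_depth`
#' @param sample_id case identifier
#' @param no_evidence logical; `TRUE` for records whose depth could not be
#'   recovered from the VCF
#' @return data.frame of class `caa_variants`
#' @export
variant_records <- function(chrom, pos, ref_allele, alt_allele,
                            total_depth, alt_depth,
                            sample_id = NA_character_,
                            no_evidence = FALSE) {
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref_allele = as.character(ref_allele),
    alt_allele = as.character(alt_allele),
    total_depth = as.integer(total_depth),
    alt_depth = as.integer(alt_depth),
    sample_id = as.character(sample_id),
    no_evidence = as.logical(no_evidence),
    stringsAsFactors = FALSE
  )
  validate_variants(df)
  class(df) <- c("caa_variants", class(df))
  df
}

#' Validate SNV record invariants
#'
#' Checks the contract every retained record must satisfy: alleles are single
#' distinct A/C/G/T bases, positions are >= 1, and
#' `0 <= alt_depth <= total_depth` wherever depths are known.
#'
#' @param df a variant data.frame
#' @return `df` invisibly; stops on violation
#' @export
validate_variants <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "pos", "ref_allele", "alt_allele",
            "total_depth", "alt_depth")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$pos < 1L, na.rm = TRUE)) stop("positions must be 1-based (>= 1)")
  bad_allele <- !(df$ref_allele %in% VALID_BASES) |
    !(df$alt_allele %in% VALID_BASES)
  if (any(bad_allele)) stop("alleles must be single A/C/G/T bases")
  if (any(df$ref_allele == df$alt_allele)) stop("ref and alt alleles must differ")
  known <- !is.na(df$total_depth) & !is.na(df$alt_depth)
  if (any(df$alt_depth[known] < 0L | df$total_depth[known] < 0L))
    stop("depths must be non-negative")
  if (any(df$alt_depth[known] > df$total_depth[known]))
    stop("alt_depth must not exceed total_depth")
  invisible(df)
}

#' Variant allele fraction
#'
#' @param v variant data.frame
#' @return numeric VAF per record, `NA` where total depth is 0 or unknown
#' @export
vaf <- function(v) {
  out <- rep(NA_real_, nrow(v))
  ok <- !is.na(v$total_depth) & v$total_depth > 0L & !is.na(v$alt_depth)
  out[ok] <- v$alt_depth[ok] / v$total_depth[ok]
  out
}

empty_variants <- function() {
  variant_records(character(), integer(), character(), character(),
                  integer(), integer(), character(), logical())
}
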