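#' Read a cancer-gene symbol list
#'
#' One symbol per line; `#` starts a comment (whole-line or trailing);
#' symbols are upper-cased and de-duplicated.
#'
#' @param path text file of gene symbols
#' @return character vector (a set) of gene symbols
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  syms <- toupper(trimws(lines))
  syms <- unique(syms[nzchar(syms)])
  if (!length(syms)) stop("gene list is empty: ", path)
  syms
}

#' Read capture-target intervals from a BED file
#'
#' BED is already 0-based half-open, matching the package's internal interval
#' convention, so coordinates pass through unchanged.
#'
#' @param path BED3/BED4 file
#' @return data.frame chrom, start, end, label
#' @export
read_targets_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "label")[seq_len(ncol(df))]
  if (!"label" %in% names(df)) df$label <- sprintf("target_%d", seq_len(nrow(df)))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start >= df$end)) stop("BED intervals must have start < end")
  df
}

#' Write capture targets as BED
#' @param targets data.frame chrom, start, end, label (0-based half-open)
#' @param path output BED file
#' @export
write_targets_bed <- function(targets, path) {
  write_lines_atomic(sprintf("%s\t%d\t%d\t%s", targets$chrom,
                             targets$start, targets$end, targets$label), path)
}

#' Read a human cancer-hotspot catalog
#'
#' Tab-separated with header `gene  human_pos  ref_aa  alt_aas`; `alt_aas`
#' is a comma-separated set of permitted substitutions, empty meaning any
#' non-reference residue. A small demonstration catalog (RAS codons 12/13/61,
#' BRAF 600, SMO 412/535) ships with the package; swap in a COSMIC-derived
#' file of the same shape for real use.
#'
#' @param path TSV catalog; default the packaged demo catalog
#' @return data.frame gene, human_pos, ref_aa, alt_aas
#' @export
read_hotspot_catalog <- function(path = caa_extdata("hotspot_catalog.tsv")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = c("character", "integer",
                                         "character", "character"))
  stopifnot(all(c("gene", "human_pos", "ref_aa", "alt_aas") %in% names(df)))
  if (any(df$human_pos < 1L)) stop("hotspot positions are 1-based residues")
  df
}

hotspot_allows <- function(alt_aas, aa) {
  !nzchar(alt_aas) | vapply(strsplit(alt_aas, ",", fixed = TRUE),
                            function(s) aa %in% trimws(s), TRUE)
}

#' Read / write per-target coverage profiles
#'
#' TSV with header `chrom  start  end  depth` (0-based half-open bins in
#' genome order).
#'
#' @param path TSV file
#' @return data.frame chrom, start, end, depth
#' @export
read_coverage_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(df)))
  if (any(df$depth < 0)) stop("coverage depths must be non-negative")
  df
}

#' @rdname read_coverage_tsv
#' @param profile data.frame chrom, start, end, depth
#' @export
write_coverage_tsv <- function(profile, path) {
  write_tsv_atomic(profile[, c("chrom", "start", "end", "depth")], path)
}

#' Load the packaged 24-case cohort fixture
#'
#' A transcription of the study cohort table shipped as TSV: 20 FFPE and 4
#' fresh-tissue canine acanthomatous ameloblastoma cases with anatomic site,
#' breed, driver mutation call, and (for nine FFPE cases) the read depth and
#' variant allele fraction at the mutant base.
#'
#' @return data.frame with columns case_id, location, breed, age, sex,
#'   weight_kg, tissue, gene, protein_change, read_depth, vaf
#' @export
load_table1_cases <- function() {
  df <- utils::read.table(caa_extdata("table1_cases.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  df$gene <- ifelse(df$mutation == "", NA_character_,
                    sub("-.*$", "", df$mutation))
  df$protein_change <- ifelse(df$mutation == "", NA_character_,
                              sub("^[^-]*-", "", df$mutation))
  bad <- !is.na(df$vaf) & (df$vaf <= 0 | df$vaf >= 1)
  if (any(bad)) stop("VAF entries must lie in (0, 1)")
  df
}
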