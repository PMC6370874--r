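#' Round half away from zero
#'
#' Commercial rounding: 62.5 becomes 63. `round()` in R rounds half to even,
#' which does not reproduce the conventions of published frequency tables.
#'
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @export
round_half_up <- function(x) {
  trunc(x + 0.5 * sign(x))
}

#' Integer percentage of a count
#'
#' @param k numerator count
#' @param n denominator count (> 0)
#' @return `round_half_up(100 * k / n)`
#' @export
percent_of <- function(k, n) {
  stopifnot(n > 0)
  round_half_up(100 * k / n)
}

# Atomic text write: write to a temp file in the target directory, then rename.
write_lines_atomic <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

VALID_BASES <- c("A", "C", "G", "T")

comp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Convert between 1-based and 0-based half-open coordinates
#'
#' VCF and GTF positions are 1-based inclusive; all interval arithmetic inside
#' the package is 0-based half-open. A 1-based position `p` occupies the
#' half-open interval `[p - 1, p)`.
#'
#' @param pos1 1-based position(s)
#' @return 0-based start(s)
#' @export
pos1_to_start0 <- function(pos1) as.integer(pos1 - 1L)

#' @rdname pos1_to_start0
#' @param start0 0-based start(s)
#' @export
start0_to_pos1 <- function(start0) as.integer(start0 + 1L)

# Locate a file shipped under inst/extdata.
caa_extdata <- function(file) {
  p <- system.file("extdata", file, package = "caahotspot")
  if (!nzchar(p)) stop("packaged fixture not found: ", file)
  p
}
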