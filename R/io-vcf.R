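#' Read SNV records from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into the package's flat variant
#' table. Only single-nucleotide substitutions are retained: multi-allelic
#' records are split into one row per alt allele, and indel alleles are
#' skipped with their count recorded in the `skipped_indels` attribute.
#'
#' Depth recovery tries, in order: per-sample `FORMAT/AD` (with `FORMAT/DP`
#' for the total where present, else the AD sum), per-sample `FORMAT/AO`/`RO`
#' counts, an `INFO/DP4` strand-split sum (biallelic records only, since DP4
#' cannot attribute reads among several alt alleles), and finally `INFO/DP`
#' alone. Records whose alt-read support cannot be recovered are kept but
#' flagged `no_evidence = TRUE` rather than silently dropped; the evidence
#' filter later rejects them with reason `"no-evidence"`.
#'
#' @param path VCF file
#' @param sample_id case label to store with each record; defaults to the
#'   first sample column name, or the file stem for site-only VCFs
#' @return a `caa_variants` data.frame (possibly 0-row) with attribute
#'   `skipped_indels`
#' @export
read_vcf <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf < 8) stop(sprintf("malformed VCF line %d in %s: %d fields (need >= 8)",
                             i, path, nf))
  }
  if (length(body) == 0) {
    out <- empty_variants()
    attr(out, "skipped_indels") <- 0L
    return(out)
  }

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  has_gt <- !is.null(gt) && ncol(gt) >= 2
  if (is.null(sample_id)) {
    sample_id <- if (has_gt) colnames(gt)[2] else
      sub("\\.vcf(\\.gz)?$", "", basename(path))
  }

  rows <- vector("list", nrow(fix))
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (is.na(ref) || nchar(ref) != 1L || !(ref %in% VALID_BASES)) {
      skipped <- skipped + length(alts)
      next
    }
    snv <- nchar(alts) == 1L & alts %in% VALID_BASES & alts != ref
    skipped <- skipped + sum(!snv)
    alts <- alts[snv]
    if (!length(alts)) next

    info <- parse_info(fix[i, "INFO"])
    fmt <- if (has_gt) parse_format(gt[i, 1], gt[i, 2]) else list()
    d <- recover_depths(info, fmt, n_alts = length(alts),
                        biallelic = length(alts) == 1L && snv_only_record(fix[i, "ALT"]))
    rows[[i]] <- data.frame(
      chrom = unname(fix[i, "CHROM"]), pos = as.integer(fix[i, "POS"]),
      ref_allele = unname(ref), alt_allele = unname(alts),
      total_depth = unname(d$total), alt_depth = unname(d$alt),
      sample_id = sample_id, no_evidence = d$no_evidence,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_variants()
  validate_variants(out)
  class(out) <- c("caa_variants", "data.frame")
  rownames(out) <- NULL
  attr(out, "skipped_indels") <- skipped
  out
}

snv_only_record <- function(alt_field) {
  alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
  length(alts) == 1L
}

parse_info <- function(s) {
  if (is.na(s) || s == "." || !nzchar(s)) return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) > 1) x[2] else TRUE)
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

parse_format <- function(format_str, sample_str) {
  if (is.na(format_str) || is.na(sample_str)) return(list())
  keys <- strsplit(format_str, ":", fixed = TRUE)[[1]]
  vals <- strsplit(sample_str, ":", fixed = TRUE)[[1]]
  out <- as.list(vals[seq_along(keys)])
  names(out) <- keys
  out
}

int_csv <- function(x) suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))

# Depth fallback order: FORMAT AD (+DP) -> FORMAT AO/RO -> INFO DP4 -> INFO DP.
recover_depths <- function(info, fmt, n_alts, biallelic) {
  na_out <- list(total = rep(NA_integer_, n_alts),
                 alt = rep(NA_integer_, n_alts), no_evidence = TRUE)
  dp <- NA_integer_
  if (!is.null(fmt$DP)) dp <- suppressWarnings(as.integer(fmt$DP))
  if (is.na(dp) && !is.null(info$DP)) dp <- suppressWarnings(as.integer(info$DP))

  ad_src <- if (!is.null(fmt$AD)) fmt$AD else if (is.character(info$AD)) info$AD else NULL
  if (!is.null(ad_src)) {
    ad <- int_csv(ad_src)
    if (length(ad) >= n_alts + 1L && !anyNA(ad)) {
      total <- if (!is.na(dp)) dp else sum(ad)
      return(list(total = rep(total, n_alts), alt = ad[1L + seq_len(n_alts)],
                  no_evidence = FALSE))
    }
  }
  ao_src <- if (!is.null(fmt$AO)) fmt$AO else if (is.character(info$AO)) info$AO else NULL
  ro_src <- if (!is.null(fmt$RO)) fmt$RO else if (is.character(info$RO)) info$RO else NULL
  if (!is.null(ao_src) && !is.null(ro_src)) {
    ao <- int_csv(ao_src); ro <- suppressWarnings(as.integer(ro_src))
    if (length(ao) >= n_alts && !anyNA(ao) && !is.na(ro)) {
      total <- if (!is.na(dp)) dp else ro + sum(ao)
      return(list(total = rep(total, n_alts), alt = ao[seq_len(n_alts)],
                  no_evidence = FALSE))
    }
  }
  if (biallelic && is.character(info$DP4)) {
    d4 <- int_csv(info$DP4)
    if (length(d4) == 4L && !anyNA(d4)) {
      total <- if (!is.na(dp)) dp else sum(d4)
      return(list(total = total, alt = d4[3] + d4[4], no_evidence = FALSE))
    }
  }
  if (!is.na(dp)) {
    out <- na_out
    out$total <- rep(dp, n_alts)
    return(out)
  }
  na_out
}

#' Write SNV records as a VCF 4.2 file
#'
#' Emits one biallelic record per row with `INFO/DP` and a single sample
#' column carrying `GT:DP:AD`, so that `read_vcf()` round-trips
#' chrom/pos/ref/alt and both depths exactly. Records are sorted by
#' (chrom, pos, alt). The write is atomic (temp file + rename).
#'
#' @param variants a `caa_variants` data.frame
#' @param path output file
#' @param sample sample column name; defaults to the records' `sample_id`
#'   (or "SAMPLE")
#' @param contigs optional named integer vector of contig lengths for
#'   `##contig` header lines
#' @return `path`, invisibly
#' @export
write_vcf <- function(variants, path, sample = NULL, contigs = NULL) {
  validate_variants(variants)
  if (is.null(sample)) {
    ids <- unique(stats::na.omit(variants$sample_id))
    sample <- if (length(ids) == 1) ids else "SAMPLE"
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=caahotspot",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">'
  )
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sample), collapse = "\t"))
  v <- variants[order(variants$chrom, variants$pos, variants$alt_allele), ,
                drop = FALSE]
  recs <- character(0)
  if (nrow(v) > 0) {
    known <- !is.na(v$total_depth) & !is.na(v$alt_depth)
    info <- ifelse(known, paste0("DP=", v$total_depth), ".")
    geno <- ifelse(known,
                   sprintf("0/1:%d:%d,%d", v$total_depth,
                           v$total_depth - v$alt_depth, v$alt_depth),
                   "0/1:.:.")
    recs <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:DP:AD\t%s",
                    v$chrom, v$pos, v$ref_allele, v$alt_allele, info, geno)
  }
  write_lines_atomic(c(hdr, recs), path)
}

#' Read a known-SNP site list from a VCF
#'
#' Population germline sites used by the filter cascade's SNP-exclusion
#' stage. Matching is by exact (chrom, pos, alt allele).
#'
#' @param path VCF of known germline sites
#' @return data.frame with columns chrom, pos, ref_allele, alt_allele
#' @export
read_known_snps <- function(path) {
  v <- read_vcf(path, sample_id = "sites")
  v[, c("chrom", "pos", "ref_allele", "alt_allele")]
}
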