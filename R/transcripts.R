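#' Construct a protein-coding transcript model
#'
#' One transcript per gene: ordered exons, the genomic bounds of the
#' translated region, and the strand. Coordinates are 0-based half-open.
#' CDS features are taken to include the stop codon, so the encoded protein
#' has `CDS length / 3 - 1` residues.
#'
#' @param transcript_id,gene_symbol identifiers
#' @param chrom contig name
#' @param strand "+" or "-"
#' @param exons data.frame with columns start, end (0-based half-open),
#'   sorted, non-overlapping
#' @param cds_start,cds_end genomic bounds (0-based half-open) of the
#'   translated region including the stop codon
#' @return object of class `transcript_model`
#' @export
transcript_model <- function(transcript_id, gene_symbol, chrom, strand,
                             exons, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (any(exons$start >= exons$end)) stop("exons must have start < end")
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("exons must be non-overlapping")
  if (cds_start >= cds_end) stop("empty CDS")

  # genomic 0-based positions of CDS bases, 5'->3' in transcription order
  cds_pos <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    s <- max(exons$start[i], cds_start); e <- min(exons$end[i], cds_end)
    if (s < e) seq.int(s, e - 1L) else integer(0)
  }))
  if (length(cds_pos) %% 3L != 0L)
    stop("CDS length must be a multiple of 3 (got ", length(cds_pos), ")")
  if (strand == "-") cds_pos <- rev(cds_pos)

  tx <- list(
    transcript_id = transcript_id, gene_symbol = gene_symbol,
    chrom = chrom, strand = strand, exons = exons,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    cds_genomic_pos = as.integer(cds_pos),
    protein_length = length(cds_pos) %/% 3L - 1L,
    tx_start = min(exons$start), tx_end = max(exons$end)
  )
  class(tx) <- "transcript_model"
  tx
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%s], %d exon(s), %d aa\n",
              x$transcript_id, x$gene_symbol, x$chrom, x$tx_start, x$tx_end,
              x$strand, nrow(x$exons), x$protein_length))
  invisible(x)
}

#' Read one-transcript-per-gene models from a GTF file
#'
#' Uses `exon` and `CDS` features grouped by `transcript_id`. GTF is 1-based
#' inclusive; models are converted to the internal 0-based half-open
#' convention. CDS features are expected to include the stop codon.
#'
#' @param path GTF file
#' @return named list of `transcript_model` (names = transcript ids)
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (!"transcript_id" %in% names(df)) stop("GTF lacks transcript_id attributes")
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  out <- list()
  for (txid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == txid, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    if (!nrow(ex) || !nrow(cds)) next
    gene <- if ("gene_name" %in% names(sub) && !is.na(sub$gene_name[1]))
      sub$gene_name[1] else sub$gene_id[1]
    out[[txid]] <- transcript_model(
      transcript_id = txid, gene_symbol = gene,
      chrom = as.character(ex$seqnames[1]),
      strand = as.character(ex$strand[1]),
      exons = data.frame(start = ex$start - 1L, end = ex$end),
      cds_start = min(cds$start) - 1L, cds_end = max(cds$end)
    )
  }
  if (!length(out)) stop("no usable transcripts in ", path)
  out
}

#' Load a genome FASTA as a named base-string set
#'
#' @param path FASTA file
#' @return named character vector, one element per contig
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

genome_base <- function(genome, chrom, pos1) {
  if (!chrom %in% names(genome)) stop("contig not in genome: ", chrom)
  substr(genome[[chrom]], pos1, pos1)
}

# Spliced CDS in transcription orientation (coding strand), as a character
# string; includes the stop codon.
cds_sequence <- function(tx, genome) {
  contig <- genome[[tx$chrom]]
  pieces <- vapply(seq_len(nrow(tx$exons)), function(i) {
    s <- max(tx$exons$start[i], tx$cds_start)
    e <- min(tx$exons$end[i], tx$cds_end)
    if (s < e) substr(contig, s + 1L, e) else ""
  }, "")
  seq <- paste(pieces, collapse = "")
  if (tx$strand == "-") seq <- revcomp(seq)
  seq
}

# 1-based index into the spliced CDS for a 1-based genomic position, or NA.
cds_index <- function(tx, pos1) {
  match(as.integer(pos1 - 1L), tx$cds_genomic_pos)
}

# Splice-site windows: the two intronic bases flanking each exon boundary,
# labelled donor/acceptor in transcription direction. Returns a data.frame
# of 1-based genomic positions.
splice_windows <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2) return(data.frame(pos = integer(0), side = character(0)))
  rows <- lapply(seq_len(n - 1L), function(i) {
    left_end <- tx$exons$end[i]        # 0-based half-open
    right_start <- tx$exons$start[i + 1L]
    left2 <- start0_to_pos1(c(left_end, left_end + 1L))
    right2 <- start0_to_pos1(c(right_start - 2L, right_start - 1L))
    if (tx$strand == "+") {
      data.frame(pos = c(left2, right2),
                 side = rep(c("splice_donor", "splice_acceptor"), each = 2L))
    } else {
      data.frame(pos = c(right2, left2),
                 side = rep(c("splice_donor", "splice_acceptor"), each = 2L))
    }
  })
  do.call(rbind, rows)
}

in_intron <- function(tx, pos0) {
  inside <- pos0 >= tx$tx_start && pos0 < tx$tx_end
  in_exon <- any(pos0 >= tx$exons$start & pos0 < tx$exons$end)
  inside && !in_exon
}
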