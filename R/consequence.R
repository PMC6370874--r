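#' Consequence classes counted as "High consequence"
#'
#' The driver-nomination cascade retains missense, stop-gain, and canonical
#' splice donor/acceptor variants only; start-loss and stop-loss are
#' deliberately excluded from this set.
#' @export
HIGH_CONSEQUENCE <- c("missense", "stop_gain", "splice_donor", "splice_acceptor")

#' Classify one SNV against one transcript model
#'
#' Determines the consequence class of a single-nucleotide substitution:
#' `missense`, `stop_gain`, `splice_donor`, `splice_acceptor`, `synonymous`,
#' `stop_loss`, `start_loss`, `intronic`, `noncoding` (exonic UTR), or
#' `intergenic` (outside the transcript footprint plus `padding`). For coding
#' variants the affected codon is looked up in the spliced CDS, the alt
#' allele reverse-complemented first on minus-strand transcripts, and the
#' protein change reported as e.g. `"Q61R"`. Splice sites are the two
#' intronic bases adjacent to each exon boundary (the canonical GT/AG
#' dinucleotide positions), named donor/acceptor in transcription direction.
#'
#' Any substitution inside the initiation codon is called `start_loss`; a
#' substitution in the stop codon is `synonymous` if the mutant codon is
#' still a stop, else `stop_loss`.
#'
#' @param v a one-row variant data.frame (see [variant_records()])
#' @param tx a [transcript_model()]
#' @param genome named character vector of contig sequences
#'   (see [read_genome_fasta()]); must carry the reference base at `v$pos`
#' @param padding footprint slack in bp before a variant is `intergenic`
#' @return one-row data.frame: transcript_id, gene_symbol, klass,
#'   protein_pos, ref_aa, alt_aa, protein_change
#' @export
classify_variant <- function(v, tx, genome, padding = 1000L) {
  stopifnot(nrow(v) == 1L)
  if (v$chrom != tx$chrom)
    return(call_row(tx, "intergenic"))
  gref <- genome_base(genome, v$chrom, v$pos)
  if (gref != v$ref_allele)
    stop(sprintf("reference mismatch at %s:%d: genome has %s, record has %s",
                 v$chrom, v$pos, gref, v$ref_allele))
  pos0 <- pos1_to_start0(v$pos)
  if (pos0 < tx$tx_start - padding || pos0 >= tx$tx_end + padding)
    return(call_row(tx, "intergenic"))

  sw <- if (!is.null(tx$sw_cache)) tx$sw_cache else splice_windows(tx)
  hit <- which(sw$pos == v$pos)
  if (length(hit)) return(call_row(tx, sw$side[hit[1]]))
  if (pos0 < tx$tx_start || pos0 >= tx$tx_end)
    return(call_row(tx, "intergenic"))
  if (in_intron(tx, pos0)) return(call_row(tx, "intronic"))

  ci <- cds_index(tx, v$pos)
  if (is.na(ci)) return(call_row(tx, "noncoding"))

  cds <- if (!is.null(tx$cds_cache)) tx$cds_cache else cds_sequence(tx, genome)
  codon_idx <- (ci - 1L) %/% 3L + 1L
  offset <- (ci - 1L) %% 3L + 1L
  codon <- substr(cds, 3L * (codon_idx - 1L) + 1L, 3L * codon_idx)
  alt_coding <- if (tx$strand == "+") v$alt_allele else comp_base(v$alt_allele)
  mut <- codon
  substr(mut, offset, offset) <- unname(alt_coding)

  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[codon]); alt_aa <- unname(code[mut])
  stop_codon_idx <- tx$protein_length + 1L

  klass <- if (codon_idx == 1L) "start_loss"
  else if (codon_idx == stop_codon_idx) {
    if (alt_aa == "*") "synonymous" else "stop_loss"
  } else if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "stop_gain"
  else "missense"

  if (klass %in% c("missense", "stop_gain", "synonymous", "stop_loss") &&
      codon_idx <= tx$protein_length) {
    call_row(tx, klass, protein_pos = codon_idx, ref_aa = ref_aa,
             alt_aa = alt_aa)
  } else if (klass %in% c("synonymous", "stop_loss")) {
    # substitution within the stop codon: no residue index inside the protein
    call_row(tx, klass)
  } else {
    call_row(tx, klass)
  }
}

call_row <- function(tx, klass, protein_pos = NA_integer_,
                     ref_aa = NA_character_, alt_aa = NA_character_) {
  change <- if (!is.na(protein_pos))
    paste0(ref_aa, protein_pos, alt_aa) else NA_character_
  data.frame(transcript_id = tx$transcript_id, gene_symbol = tx$gene_symbol,
             klass = klass, protein_pos = protein_pos, ref_aa = ref_aa,
             alt_aa = alt_aa, protein_change = change,
             stringsAsFactors = FALSE)
}

#' Is a consequence class retained by the cascade?
#'
#' @param klass character vector of consequence classes
#' @return logical; `TRUE` iff missense, stop-gain, or splice donor/acceptor
#' @export
is_high_consequence <- function(klass) {
  klass %in% HIGH_CONSEQUENCE
}

#' Annotate a variant table against a transcript set
#'
#' Assigns each variant to the transcript whose (padded) footprint contains
#' it — first by genomic order on ties, `NA`/intergenic otherwise — and
#' appends the [classify_variant()] columns.
#'
#' @param variants `caa_variants` data.frame
#' @param transcripts named list of transcript models
#' @param genome named character vector of contig sequences
#' @param padding intergenic slack in bp
#' @return `variants` with annotation columns appended
#' @export
classify_variants <- function(variants, transcripts, genome, padding = 1000L) {
  ann <- data.frame(transcript_id = NA_character_, gene_symbol = NA_character_,
                    klass = "intergenic", protein_pos = NA_integer_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    protein_change = NA_character_, stringsAsFactors = FALSE)
  ann <- ann[rep(1L, nrow(variants)), , drop = FALSE]
  if (nrow(variants)) {
    # memoise per-transcript derived data for repeated lookups
    transcripts <- lapply(transcripts, function(tx) {
      tx$cds_cache <- cds_sequence(tx, genome)
      tx$sw_cache <- splice_windows(tx)
      tx
    })
    txdf <- data.frame(
      id = names(transcripts),
      chrom = vapply(transcripts, `[[`, "", "chrom"),
      start = vapply(transcripts, `[[`, 0L, "tx_start"),
      end = vapply(transcripts, `[[`, 0L, "tx_end"),
      stringsAsFactors = FALSE
    )
    txdf <- txdf[order(txdf$chrom, txdf$start), , drop = FALSE]
    for (i in seq_len(nrow(variants))) {
      p0 <- pos1_to_start0(variants$pos[i])
      hit <- txdf$id[txdf$chrom == variants$chrom[i] &
                     p0 >= txdf$start - padding & p0 < txdf$end + padding]
      if (length(hit)) {
        ann[i, ] <- classify_variant(variants[i, , drop = FALSE],
                                     transcripts[[hit[1]]], genome, padding)
      }
    }
  }
  rownames(ann) <- NULL
  cbind(variants, ann)
}

#' Build a consequence-annotator callback for the filter cascade
#'
#' @inheritParams classify_variants
#' @return function(variants) -> annotated variants
#' @export
make_consequence_annotator <- function(transcripts, genome, padding = 1000L) {
  function(variants) classify_variants(variants, transcripts, genome, padding)
}
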