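#' Packaged toy reference set
#'
#' A small synthetic two-contig genome with ten protein-coding genes used by
#' the simulator, the tests, and the worked examples. Gene names follow the
#' human cancer genes whose hotspot geometry they emulate: the HRAS-like
#' gene carries glycines at codons 12/13 and a glutamine at codon 61; the
#' BRAF-like canine gene carries a valine at codon 595 while its "human"
#' protein partner carries a 5-residue insertion upstream, so human residue
#' 600 is orthologous to canine residue 595. These are synthetic fixtures,
#' not the real canine or human sequences.
#'
#' @return `toy_reference()` returns a list: `genome` (named character,
#'   per contig), `transcripts` (named list of [transcript_model()]),
#'   `proteins` (named character: translated canine proteins),
#'   `targets` (exon capture intervals, 0-based half-open)
#' @export
toy_reference <- function() {
  genome <- read_genome_fasta(toy_genome_path())
  transcripts <- read_transcripts_gtf(toy_gtf_path())
  proteins <- vapply(transcripts, function(tx) {
    cds <- cds_sequence(tx, genome)
    sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAString(cds))))
  }, "")
  names(proteins) <- vapply(transcripts, `[[`, "", "gene_symbol")
  targets <- do.call(rbind, lapply(transcripts, function(tx) {
    data.frame(chrom = tx$chrom, start = tx$exons$start, end = tx$exons$end,
               label = sprintf("%s_exon%d", tx$gene_symbol,
                               seq_len(nrow(tx$exons))),
               stringsAsFactors = FALSE)
  }))
  targets <- targets[order(targets$chrom, targets$start), , drop = FALSE]
  rownames(targets) <- NULL
  list(genome = genome, transcripts = transcripts, proteins = proteins,
       targets = targets)
}

#' @rdname toy_reference
#' @export
toy_genome_path <- function() caa_extdata("toy_genome.fa")

#' @rdname toy_reference
#' @export
toy_gtf_path <- function() caa_extdata("toy_genes.gtf")

#' @rdname toy_reference
#' @export
toy_proteins_path <- function() caa_extdata("toy_proteins.faa")

#' @rdname toy_reference
#' @export
toy_gene_list_path <- function() caa_extdata("cancer_genes.txt")

#' @rdname toy_reference
#' @export
toy_hotspot_catalog_path <- function() caa_extdata("hotspot_catalog.tsv")
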