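# Builds the plain-text fixtures under inst/extdata/:
#   toy_genome.fa, toy_genes.gtf  - synthetic 2-contig genome, 10 genes
#   toy_proteins.faa              - GENE|human / GENE|canine ortholog pairs
#   hotspot_catalog.tsv           - demo hotspot catalog (human coordinates)
#   cancer_genes.txt              - demo cancer-gene list
#   table1_cases.tsv              - 24-case cohort table transcription
# Deterministic: fixed seed, committed outputs. Run from the package root:
#   Rscript data-raw/make_fixtures.R

set.seed(4217)

STOPS <- c("TAA", "TAG", "TGA")
CODONS <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T")), 1, paste, collapse = "")
SENSE_CODONS <- setdiff(CODONS, STOPS)

rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")
revcomp <- function(s) chartr("ACGT", "TGCA",
                              paste(rev(strsplit(s, "")[[1]]), collapse = ""))

make_cds <- function(protein_len, fixed = integer(0)) {
  codons <- sample(SENSE_CODONS, protein_len, replace = TRUE)
  codons[1] <- "ATG"
  for (i in seq_along(fixed)) codons[as.integer(names(fixed)[i])] <- fixed[[i]]
  paste(c(codons, "TAA"), collapse = "")
}

# Build one gene's genomic block. Returns list(seq, exons, cds, strand) with
# 0-based half-open coordinates local to the block.
build_gene <- function(protein_len, fixed, strand, n_exons = 3L,
                       utr = 30L, intron_len = 120L) {
  cds <- make_cds(protein_len, fixed)
  tx <- paste0(rand_dna(utr), cds, rand_dna(utr))
  L <- nchar(tx)
  cuts <- round(L * seq_len(n_exons - 1L) / n_exons)
  exon_bounds <- cbind(c(0L, cuts), c(cuts, L))          # tx coords
  introns <- replicate(n_exons - 1L,
                       paste0("GT", rand_dna(intron_len - 4L), "AG"))
  pieces <- character(0)
  offsets <- integer(n_exons)   # tx coord -> sense-genomic shift per exon
  shift <- 0L
  for (i in seq_len(n_exons)) {
    offsets[i] <- shift
    pieces <- c(pieces, substr(tx, exon_bounds[i, 1] + 1L, exon_bounds[i, 2]))
    if (i < n_exons) {
      pieces <- c(pieces, introns[i])
      shift <- shift + intron_len
    }
  }
  sense_seq <- paste(pieces, collapse = "")
  sense_exons <- data.frame(start = exon_bounds[, 1] + offsets,
                            end = exon_bounds[, 2] + offsets)
  sense_cds <- c(utr, utr + nchar(cds))   # tx coords == exon1-anchored coords
  # map tx coordinate to sense-genomic
  tx2g <- function(p) {
    i <- findInterval(p, c(exon_bounds[, 1][-1], L), left.open = FALSE) + 1L
    i <- min(i, n_exons)
    p + offsets[i]
  }
  sense_cds_g <- c(tx2g(sense_cds[1]), tx2g(sense_cds[2] - 1L) + 1L)
  Lg <- nchar(sense_seq)
  if (strand == "+") {
    list(seq = sense_seq, exons = sense_exons,
         cds = sense_cds_g, strand = strand)
  } else {
    mirror <- function(s, e) c(Lg - e, Lg - s)
    ex <- t(apply(sense_exons, 1, function(r) mirror(r[1], r[2])))
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    list(seq = revcomp(sense_seq),
         exons = data.frame(start = ex[, 1], end = ex[, 2]),
         cds = mirror(sense_cds_g[1], sense_cds_g[2]), strand = strand)
  }
}

genes <- list(
  HRAS   = list(len = 189, strand = "+", chrom = "chr1",
                fixed = c(`12` = "GGA", `13` = "GGC", `61` = "CAA")),
  KRAS   = list(len = 188, strand = "-", chrom = "chr1",
                fixed = c(`12` = "GGT", `13` = "GGC")),
  TP53   = list(len = 300, strand = "+", chrom = "chr1", fixed = c()),
  EGFR   = list(len = 250, strand = "+", chrom = "chr1", fixed = c()),
  CTNNB1 = list(len = 240, strand = "+", chrom = "chr1", fixed = c()),
  BRAF   = list(len = 640, strand = "+", chrom = "chr2",
                fixed = c(`595` = "GTG")),
  NRAS   = list(len = 189, strand = "+", chrom = "chr2",
                fixed = c(`61` = "CAA")),
  SMO    = list(len = 560, strand = "-", chrom = "chr2",
                fixed = c(`412` = "CTG", `535` = "TGG")),
  PTEN   = list(len = 200, strand = "+", chrom = "chr2", fixed = c()),
  SMAD4  = list(len = 250, strand = "-", chrom = "chr2", fixed = c())
)

contigs <- list(chr1 = "", chr2 = "")
gtf <- character(0)
spacer <- 300L
for (chrom in names(contigs)) contigs[[chrom]] <- rand_dna(200L)

for (g in names(genes)) {
  spec <- genes[[g]]
  blk <- build_gene(spec$len, spec$fixed, spec$strand)
  off <- nchar(contigs[[spec$chrom]])
  contigs[[spec$chrom]] <- paste0(contigs[[spec$chrom]], blk$seq,
                                  rand_dna(spacer))
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                      g, g, g)
  ex <- blk$exons
  for (i in seq_len(nrow(ex))) {
    gtf <- c(gtf, sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s",
                          spec$chrom, off + ex$start[i] + 1L, off + ex$end[i],
                          spec$strand, attr_str))
    cs <- max(ex$start[i], blk$cds[1]); ce <- min(ex$end[i], blk$cds[2])
    if (cs < ce)
      gtf <- c(gtf, sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                            spec$chrom, off + cs + 1L, off + ce,
                            spec$strand, attr_str))
  }
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

fa <- character(0)
for (chrom in names(contigs)) {
  s <- contigs[[chrom]]
  fa <- c(fa, paste0(">", chrom),
          substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60),
                                                  nchar(s))))
}
writeLines(fa, "inst/extdata/toy_genome.fa")
writeLines(gtf, "inst/extdata/toy_genes.gtf")

# --- proteins: translate each gene's CDS via the package's own readers -----
devtools::load_all(".", quiet = TRUE)
ref <- toy_reference()
stopifnot(identical(sort(names(ref$proteins)), sort(names(genes))))
check <- c(HRAS = substr(ref$proteins[["HRAS"]], 61, 61) == "Q",
           HRAS13 = substr(ref$proteins[["HRAS"]], 13, 13) == "G",
           BRAF = substr(ref$proteins[["BRAF"]], 595, 595) == "V",
           KRAS = substr(ref$proteins[["KRAS"]], 12, 12) == "G",
           NRAS = substr(ref$proteins[["NRAS"]], 61, 61) == "Q",
           SMO = substr(ref$proteins[["SMO"]], 535, 535) == "W")
stopifnot(all(check))

wrap <- function(s) substring(s, seq(1, nchar(s), 60),
                              pmin(seq(60, nchar(s) + 59, 60), nchar(s)))
faa <- character(0)
for (g in names(genes)) {
  canine <- ref$proteins[[g]]
  human <- if (g == "BRAF")
    paste0(substr(canine, 1, 559), "GGSGG", substr(canine, 560, nchar(canine)))
  else canine
  faa <- c(faa, paste0(">", g, "|human"), wrap(human),
           paste0(">", g, "|canine"), wrap(canine))
}
writeLines(faa, "inst/extdata/toy_proteins.faa")

writeLines(c(
  "gene\thuman_pos\tref_aa\talt_aas",
  "HRAS\t12\tG\tV,D,S",
  "HRAS\t13\tG\tR,V,D",
  "HRAS\t61\tQ\tR,K,L",
  "KRAS\t12\tG\tD,V,C",
  "KRAS\t13\tG\tD",
  "NRAS\t61\tQ\tR,K,L",
  "BRAF\t600\tV\tE,K",
  "SMO\t412\tL\tF",
  "SMO\t535\tW\tL"
), "inst/extdata/hotspot_catalog.tsv")

writeLines(c("# demo cancer-gene list (one symbol per line)",
             names(genes)), "inst/extdata/cancer_genes.txt")

table1 <- c(
  "case_id\tlocation\tbreed\tage\tsex\tweight_kg\ttissue\tmutation\tread_depth\tvaf",
  "CAA-01\tMandible\tGerman Shepherd\t8\tMC\t42\tFFPE\t\tNA\tNA",
  "CAA-02\tMandible\tLabrador Retriever\t13\tFS\t31\tFFPE\t\tNA\tNA",
  "CAA-03\tMandible\tLabrador Retriever\t11\tFS\t33\tFFPE\tHRAS-Q61R\t72\t0.278",
  "CAA-04\tMandible\tPit Bull Terrier\t10\tFS\t27\tFFPE\tHRAS-Q61R\tNA\tNA",
  "CAA-05\tMandible\tShetland Sheepdog\t11\tMC\t22\tFFPE\tBRAF-V595E\t197\t0.289",
  "CAA-06\tMandible\tBorder Collie\t8\tMC\t29\tFFPE\tHRAS-Q61R\t63\t0.270",
  "CAA-07\tMandible\tAustralian Shepherd\t9\tMC\t31\tFFPE\tHRAS-G13R\t38\t0.421",
  "CAA-08\tMandible\tBasset Hound\t15\tMC\t36\tFFPE\tHRAS-Q61R\tNA\tNA",
  "CAA-09\tMandible\tCocker Spaniel\t9\tFS\t15\tFFPE\tHRAS-Q61R\t95\t0.263",
  "CAA-10\tMandible\tHusky mix\t10\tFS\t39\tFFPE\t\tNA\tNA",
  "CAA-11\tMandible\tChesapeake Bay Retriever\t6\tMC\t33\tFFPE\tHRAS-Q61R\tNA\tNA",
  "CAA-12\tMaxilla\tSamoyed\t10\tFS\t36\tFFPE\tHRAS-Q61R\t63\t0.238",
  "CAA-13\tMaxilla\tBeagle\t10\tMC\t12\tFFPE\t\tNA\tNA",
  "CAA-14\tMaxilla\tCollie\t11\tMC\t30\tFFPE\t\tNA\tNA",
  "CAA-15\tMaxilla\tLabrador Retriever\t12\tMC\t39\tFFPE\tBRAF-V595E\tNA\tNA",
  "CAA-16\tMaxilla\tCollie\t11\tMC\t31\tFFPE\t\tNA\tNA",
  "CAA-17\tMaxilla\tStandard Poodle\t7\tMC\t25\tFFPE\t\tNA\tNA",
  "CAA-18\tMaxilla\tLabrador Retriever\t11\tFS\t26\tFFPE\tHRAS-Q61R\t90\t0.267",
  "CAA-19\tMaxilla\tEnglish Bulldog\t10\tMC\tNA\tFFPE\tHRAS-Q61R\t57\t0.456",
  "CAA-20\tMaxilla\tBeagle mix\t5\tMC\t17\tFFPE\tHRAS-Q61R\t101\t0.109",
  "CAA-21\tMandible\tLabrador Retriever\t8\tFS\t31\tfresh\tHRAS-Q61R\tNA\tNA",
  "CAA-22\tMandible\tTerrier mix\t8\tFS\t22\tfresh\tHRAS-Q61R\tNA\tNA",
  "CAA-23\tMandible\tGreat Dane\t9\tFS\t53\tfresh\tHRAS-Q61R\tNA\tNA",
  "CAA-24\tMandible\tStandard Poodle\t3\tMC\t40\tfresh\tHRAS-Q61R\tNA\tNA"
)
writeLines(table1, "inst/extdata/table1_cases.tsv")

cat("fixtures written to inst/extdata/\n")
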