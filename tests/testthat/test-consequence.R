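# SNV consequence classification against transcript models.

test_that("a codon-61 CAA>CGA substitution is called Q61R missense", {
  b <- toy_bundle()
  tx <- b$ref$transcripts[["HRAS.t1"]]
  pos <- start0_to_pos1(tx$cds_genomic_pos[3L * 60L + 2L])
  v <- variant_records(tx$chrom, pos, "A", "G", 72L, 20L, "CAA-03")
  cc <- classify_variant(v, tx, b$ref$genome)
  expect_equal(cc$klass, "missense")
  expect_equal(cc$protein_pos, 61L)
  expect_equal(cc$ref_aa, "Q")
  expect_equal(cc$alt_aa, "R")
  expect_equal(cc$protein_change, "Q61R")
})

test_that("the first intronic base past an exon end is a splice donor", {
  b <- toy_bundle()
  tx <- b$ref$transcripts[["HRAS.t1"]]   # plus strand, 3 exons
  donor1 <- start0_to_pos1(tx$exons$end[1])
  ref <- substr(b$ref$genome[[tx$chrom]], donor1, donor1)
  expect_equal(ref, "G")                 # canonical GT donor
  v <- variant_records(tx$chrom, donor1, ref,
                       setdiff(c("A", "C", "G", "T"), ref)[1], 50L, 20L)
  expect_equal(classify_variant(v, tx, b$ref$genome)$klass, "splice_donor")
  # two bases before the next exon start: acceptor side
  acc <- start0_to_pos1(tx$exons$start[2] - 2L)
  refa <- substr(b$ref$genome[[tx$chrom]], acc, acc)
  expect_equal(refa, "A")                # canonical AG acceptor
  va <- variant_records(tx$chrom, acc, refa,
                        setdiff(c("A", "C", "G", "T"), refa)[1], 50L, 20L)
  expect_equal(classify_variant(va, tx, b$ref$genome)$klass, "splice_acceptor")
})

test_that("deep intronic, UTR, and far-out variants get the right classes", {
  b <- toy_bundle()
  tx <- b$ref$transcripts[["HRAS.t1"]]
  g <- b$ref$genome
  mk <- function(pos) {
    ref <- substr(g[[tx$chrom]], pos, pos)
    variant_records(tx$chrom, pos, ref,
                    setdiff(c("A", "C", "G", "T"), ref)[1], 50L, 20L)
  }
  mid_intron <- start0_to_pos1(tx$exons$end[1] + 15L)
  expect_equal(classify_variant(mk(mid_intron), tx, g)$klass, "intronic")
  utr5 <- start0_to_pos1(tx$tx_start + 2L)   # exonic, upstream of CDS
  expect_equal(classify_variant(mk(utr5), tx, g)$klass, "noncoding")
  far <- start0_to_pos1(tx$tx_end + 2000L)
  expect_equal(classify_variant(mk(far), tx, g, padding = 1000L)$klass,
               "intergenic")
})

test_that("reference mismatches are rejected with the locus named", {
  b <- toy_bundle()
  tx <- b$ref$transcripts[["HRAS.t1"]]
  pos <- start0_to_pos1(tx$cds_genomic_pos[10])
  ref <- substr(b$ref$genome[[tx$chrom]], pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  alt <- setdiff(c("A", "C", "G", "T"), c(ref, wrong))[1]
  v <- variant_records(tx$chrom, pos, wrong, alt, 50L, 20L)
  expect_error(classify_variant(v, tx, b$ref$genome),
               paste0(tx$chrom, ":", pos))
})

test_that("every SNV over a 45-bp toy CDS matches the mutant-translation oracle", {
  # 15 codons = 45 coding bases; all 3 alts at each -> 135 variants
  rt <- local({
    found <- NULL
    for (s in 1:50) {
      cand <- random_transcript(s, n_exons = 2)
      if (cand$tx$protein_length == 14L) { found <- cand; break }
    }
    found
  })
  expect_false(is.null(rt))
  expect_equal(length(rt$tx$cds_genomic_pos), 45L)
  snvs <- all_coding_snvs(rt$tx, rt$genome)
  expect_equal(nrow(snvs), 135L)
  for (i in seq_len(nrow(snvs))) {
    got <- classify_variant(snvs[i, ], rt$tx, rt$genome)
    want <- oracle_classify_coding(snvs[i, ], rt$tx, rt$genome)
    expect_equal(got$klass, want$klass,
                 info = sprintf("pos %d %s>%s", snvs$pos[i],
                                snvs$ref_allele[i], snvs$alt_allele[i]))
    if (got$klass %in% c("missense", "stop_gain")) {
      expect_equal(got$protein_pos, want$protein_pos)
      expect_equal(got$ref_aa, want$ref_aa)
      expect_equal(got$alt_aa, want$alt_aa)
    }
  }
})

test_that("classification agrees with the oracle on random transcripts, both strands", {
  seen_strands <- character(0)
  for (s in 1:12) {
    rt <- random_transcript(1000 + s)
    seen_strands <- c(seen_strands, rt$tx$strand)
    snvs <- all_coding_snvs(rt$tx, rt$genome)
    got <- classify_variants(snvs, list(tx1 = rt$tx), rt$genome)
    for (i in seq_len(nrow(snvs))) {
      want <- oracle_classify_coding(snvs[i, ], rt$tx, rt$genome)
      expect_equal(got$klass[i], want$klass,
                   info = sprintf("seed %d pos %d", 1000 + s, snvs$pos[i]))
    }
  }
  expect_setequal(unique(seen_strands), c("+", "-"))
})

test_that("strand symmetry: a mirrored minus-strand gene yields mirrored calls", {
  rt <- random_transcript(77, n_exons = 2)
  tx <- rt$tx
  g <- rt$genome
  L <- nchar(g[["chrT"]])
  # mirror the whole contig: reverse complement, flip coordinates
  g2 <- c(chrT = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g[["chrT"]]))))
  mirror <- function(s, e) c(L - e, L - s)
  ex <- t(apply(tx$exons, 1, function(r) mirror(r[1], r[2])))
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  tx2 <- transcript_model("tx1m", tx$gene_symbol, "chrT",
                          if (tx$strand == "+") "-" else "+",
                          data.frame(start = ex[, 1], end = ex[, 2]),
                          mirror(tx$cds_start, tx$cds_end)[1],
                          mirror(tx$cds_start, tx$cds_end)[2])
  snvs <- all_coding_snvs(tx, g)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq(1, nrow(snvs), by = 7)) {
    v <- snvs[i, ]
    v2 <- variant_records("chrT", L - v$pos + 1L, comp[[v$ref_allele]],
                          comp[[v$alt_allele]], v$total_depth, v$alt_depth)
    a <- classify_variant(v, tx, g)
    bm <- classify_variant(v2, tx2, g2)
    expect_equal(a$klass, bm$klass)
    expect_equal(a$protein_pos, bm$protein_pos)
    expect_equal(a$ref_aa, bm$ref_aa)
    expect_equal(a$alt_aa, bm$alt_aa)
  }
})

test_that("each SNV hits exactly one codon; shifting 3 bp shifts the residue by 1", {
  rt <- random_transcript(31, n_exons = 1)   # single exon: contiguous CDS
  tx <- rt$tx
  snvs <- all_coding_snvs(tx, rt$genome)
  calls <- classify_variants(snvs, list(tx1 = tx), rt$genome)
  coding <- calls[!is.na(calls$protein_pos), ]
  pos_sorted <- sort(tx$cds_genomic_pos) + 1L
  for (i in seq_len(nrow(coding))) {
    k <- match(coding$pos[i], pos_sorted)
    k_cds <- if (tx$strand == "+") k else length(pos_sorted) - k + 1L
    expect_equal(coding$protein_pos[i], (k_cds - 1L) %/% 3L + 1L)
  }
})

test_that("only the published High-consequence classes are retained", {
  expect_true(all(is_high_consequence(c("missense", "stop_gain",
                                        "splice_donor", "splice_acceptor"))))
  expect_false(any(is_high_consequence(c("synonymous", "stop_loss",
                                         "start_loss", "intronic",
                                         "noncoding", "intergenic"))))
})
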