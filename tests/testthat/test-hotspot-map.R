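# Cross-species hotspot position transfer by protein alignment.

test_that("identical sequences align to the identity map", {
  s <- "MTEYKLVVVGAGGVGKSALTIQ"
  om <- align_orthologs(s, s, "HRAS")
  expect_equal(om$aligned_pairs$human_pos, seq_len(nchar(s)))
  expect_equal(om$aligned_pairs$canine_pos, seq_len(nchar(s)))
  m <- map_hotspot(data.frame(gene = "HRAS", human_pos = 17L, ref_aa = "S",
                              alt_aas = ""), om)
  expect_equal(m$canine_pos, 17L)
  expect_equal(m$status, "ok")
})

test_that("an internal 5-residue deletion shifts all downstream positions by -5", {
  set.seed(9)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  h <- paste(sample(aas, 40, replace = TRUE), collapse = "")
  d <- paste0(substr(h, 1, 10), substr(h, 16, 40))   # drop residues 11-15
  om <- align_orthologs(h, d, "G1")
  ap <- om$aligned_pairs
  expect_true(all(ap$canine_pos[ap$human_pos <= 10] ==
                    ap$human_pos[ap$human_pos <= 10]))
  down <- ap[ap$human_pos > 15, ]
  expect_equal(down$canine_pos, down$human_pos - 5L)
  expect_false(11 %in% ap$human_pos || 13 %in% ap$human_pos)
  # deleted residues map nowhere
  m <- map_hotspot(data.frame(gene = "G1", human_pos = 12L,
                              ref_aa = substr(h, 12, 12), alt_aas = ""), om)
  expect_equal(m$status, "gapped")
  expect_true(is.na(m$canine_pos))
  # score agrees with the independent DP oracle
  expect_equal(om$alignment_score, oracle_nw_score(h, d), tolerance = 1e-9)
})

test_that("the packaged BRAF-like pair maps human 600 to canine 595", {
  b <- toy_bundle()
  om <- b$omaps$BRAF
  entry <- b$catalog[b$catalog$gene == "BRAF" & b$catalog$human_pos == 600, ]
  m <- map_hotspot(entry, om)
  expect_equal(m$canine_pos, 595L)
  expect_equal(m$canine_ref_aa, "V")
  expect_equal(m$status, "ok")
  # and HRAS maps as the identity (same toy sequence in both species)
  hm <- map_hotspot(b$catalog[b$catalog$gene == "HRAS" &
                                b$catalog$human_pos == 61, ], b$omaps$HRAS)
  expect_equal(hm$canine_pos, 61L)
})

test_that("alignment score and pair decomposition match the DP oracle", {
  set.seed(123)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:15) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    a <- paste(sample(aas, n1, replace = TRUE), collapse = "")
    bseq <- if (rep %% 3 == 0) {
      # related pair: mutate/delete from a
      x <- strsplit(a, "")[[1]]
      x[sample(n1, ceiling(n1 / 10))] <- sample(aas, ceiling(n1 / 10),
                                                replace = TRUE)
      paste(x[-sample(n1, min(3, n1 - 1))], collapse = "")
    } else paste(sample(aas, n2, replace = TRUE), collapse = "")
    om <- align_orthologs(a, bseq, "R")
    want <- oracle_nw_score(a, bseq)
    expect_equal(om$alignment_score, want, tolerance = 1e-9,
                 info = paste("rep", rep))
    # the returned pairs describe an alignment achieving the optimal score
    expect_equal(score_from_pairs(om), want, tolerance = 1e-9,
                 info = paste("rep", rep))
  }
  # the packaged fixture pairs too
  for (g in names(toy_bundle()$omaps)) {
    om <- toy_bundle()$omaps[[g]]
    expect_equal(score_from_pairs(om), om$alignment_score, tolerance = 1e-9,
                 info = g)
  }
})

test_that("aligned pairs never cross and invert cleanly over matched columns", {
  set.seed(5)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:10) {
    a <- paste(sample(aas, sample(10:50, 1), replace = TRUE), collapse = "")
    d <- paste(sample(aas, sample(10:50, 1), replace = TRUE), collapse = "")
    ap <- align_orthologs(a, d)$aligned_pairs
    expect_true(all(diff(ap$human_pos) > 0))
    expect_true(all(diff(ap$canine_pos) > 0))
    expect_true(all(ap$human_pos >= 1 & ap$human_pos <= nchar(a)))
    expect_true(all(ap$canine_pos >= 1 & ap$canine_pos <= nchar(d)))
    # human -> canine -> human over matched columns is the identity
    c_of_h <- stats::setNames(ap$canine_pos, ap$human_pos)
    h_of_c <- stats::setNames(ap$human_pos, ap$canine_pos)
    expect_equal(unname(h_of_c[as.character(c_of_h[as.character(ap$human_pos)])]),
                 ap$human_pos)
  }
})

test_that("empty or invalid sequences are rejected", {
  expect_error(align_orthologs("", "MKT"), "non-empty")
  expect_error(align_orthologs("MKT", "MK9T"), "alphabet")
})

test_that("variant-to-hotspot matching honors class, position, residues and allowed set", {
  b <- toy_bundle()
  call <- data.frame(gene_symbol = "HRAS", klass = "missense",
                     protein_pos = 61L, ref_aa = "Q", alt_aa = "R",
                     stringsAsFactors = FALSE)
  hit <- match_variant_to_hotspot(call, b$catalog, b$omaps)
  expect_false(is.null(hit))
  expect_equal(hit$human_pos, 61L)

  call$alt_aa <- "P"   # not in the permitted substitution set {R,K,L}
  expect_null(match_variant_to_hotspot(call, b$catalog, b$omaps))

  braf <- data.frame(gene_symbol = "BRAF", klass = "missense",
                     protein_pos = 595L, ref_aa = "V", alt_aa = "E",
                     stringsAsFactors = FALSE)
  hit2 <- match_variant_to_hotspot(braf, b$catalog, b$omaps)
  expect_false(is.null(hit2))
  expect_equal(hit2$human_pos, 600L)

  braf$klass <- "synonymous"
  expect_null(match_variant_to_hotspot(braf, b$catalog, b$omaps))
  braf$klass <- "missense"; braf$protein_pos <- 600L
  expect_null(match_variant_to_hotspot(braf, b$catalog, b$omaps))
  none <- data.frame(gene_symbol = "TP53", klass = "missense",
                     protein_pos = 10L, ref_aa = "A", alt_aa = "V",
                     stringsAsFactors = FALSE)
  expect_null(match_variant_to_hotspot(none, b$catalog, b$omaps))
})

test_that("catalog residue mismatches are flagged, not fatal", {
  om <- align_orthologs("MKTAYIAK", "MKTAYIAK", "G2")
  m <- map_hotspot(data.frame(gene = "G2", human_pos = 4L, ref_aa = "W",
                              alt_aas = ""), om)
  expect_equal(m$status, "residue_mismatch")
  expect_equal(m$canine_pos, 4L)
  expect_equal(m$canine_ref_aa, "A")
})
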