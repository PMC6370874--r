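# Independent oracles and fixture builders used across the suite. Everything
# here is deliberately written without reference to the package internals it
# checks: alignment scoring by direct Gotoh DP, consequence classes by
# translating the whole mutant CDS, the filter cascade by a flat conjunction
# of its rules.

suppressPackageStartupMessages(library(Biostrings))
BLOSUM62 <- local({
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# ---- global alignment score oracle (affine gaps, Gotoh, row-vectorized) ----
# Gap of length L costs gap_open + gap_extend * L, matching the convention
# of the implementation under test.
oracle_nw_score <- function(a, b, gap_open = 10, gap_extend = 0.5,
                            mat = BLOSUM62) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e15
  Mprev <- c(0, rep(NEG, m))
  Xprev <- c(NEG, rep(NEG, m))
  Yprev <- c(NEG, -(gap_open + gap_extend * seq_len(m)))
  for (i in seq_len(n)) {
    sub <- mat[A[i], B]
    best_prev <- pmax(Mprev, Xprev, Yprev)
    Mi <- c(NEG, best_prev[seq_len(m)] + sub)
    Xi <- pmax(Mprev - gap_open - gap_extend, Xprev - gap_extend)
    Xi[1] <- -(gap_open + gap_extend * i)
    # Y[i, j] = max(M[i, j-1] - go - ge, Y[i, j-1] - ge): running cummax
    j0 <- 0:(m - 1)
    z <- cummax(Mi[j0 + 1] + gap_extend * j0 - gap_open)
    Yi <- c(NEG, z - gap_extend * seq_len(m))
    Mprev <- Mi; Xprev <- Xi; Yprev <- Yi
  }
  max(Mprev[m + 1], Xprev[m + 1], Yprev[m + 1])
}

# Score of the specific alignment an ortholog map represents: substitution
# scores over aligned pairs plus affine penalties for every skipped run.
score_from_pairs <- function(omap, gap_open = 10, gap_extend = 0.5,
                             mat = BLOSUM62) {
  h <- strsplit(omap$human_seq, "")[[1]]
  c_ <- strsplit(omap$canine_seq, "")[[1]]
  ap <- omap$aligned_pairs
  sc <- sum(mat[cbind(h[ap$human_pos], c_[ap$canine_pos])])
  gap_runs <- function(lens) sum(ifelse(lens > 0, gap_open + gap_extend * lens, 0))
  dh <- diff(c(0, ap$human_pos, length(h) + 1L)) - 1L
  dc <- diff(c(0, ap$canine_pos, length(c_) + 1L)) - 1L
  sc - gap_runs(dh) - gap_runs(dc)
}

# ---- consequence oracle: rebuild and translate the whole mutant CDS -------
# Returns NULL for variants outside the CDS (the oracle covers coding SNVs).
oracle_classify_coding <- function(v, tx, genome) {
  contig <- genome[[tx$chrom]]
  pieces <- character(0)
  gpos <- integer(0)
  for (i in seq_len(nrow(tx$exons))) {
    s <- max(tx$exons$start[i], tx$cds_start)
    e <- min(tx$exons$end[i], tx$cds_end)
    if (s < e) {
      pieces <- c(pieces, substr(contig, s + 1L, e))
      gpos <- c(gpos, seq.int(s, e - 1L))
    }
  }
  cds <- paste(pieces, collapse = "")
  k <- match(v$pos - 1L, gpos)
  if (is.na(k)) return(NULL)
  mut <- cds
  substr(mut, k, k) <- v$alt_allele
  if (tx$strand == "-") {
    rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    cds <- rc(cds); mut <- rc(mut)
  }
  tr <- function(s) strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(s), no.init.codon = TRUE)), "")[[1]]
  rp <- tr(cds); mp <- tr(mut)
  codon_idx <- if (tx$strand == "+") (k - 1L) %/% 3L + 1L else
    (nchar(cds) - k) %/% 3L + 1L
  stop_idx <- length(rp)
  if (codon_idx == 1L)
    return(list(klass = "start_loss"))
  if (codon_idx == stop_idx) {
    if (mp[stop_idx] == "*") return(list(klass = "synonymous"))
    return(list(klass = "stop_loss"))
  }
  if (identical(rp, mp)) {
    return(list(klass = "synonymous", protein_pos = codon_idx,
                ref_aa = rp[codon_idx], alt_aa = mp[codon_idx]))
  }
  if (mp[codon_idx] == "*")
    return(list(klass = "stop_gain", protein_pos = codon_idx,
                ref_aa = rp[codon_idx], alt_aa = "*"))
  list(klass = "missense", protein_pos = codon_idx,
       ref_aa = rp[codon_idx], alt_aa = mp[codon_idx])
}

# ---- random toy transcript on its own mini-contig -------------------------
random_transcript <- function(seed, n_exons = NULL) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand_dna <- function(n) paste(sample(bases, n, replace = TRUE),
                                collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  sense <- setdiff(codons, stops)
  plen <- sample(8:16, 1)
  cds <- paste(c("ATG", sample(sense, plen - 1L, replace = TRUE),
                 sample(stops, 1)), collapse = "")
  utr5 <- sample(4:10, 1); utr3 <- sample(4:10, 1)
  tx_seq <- paste0(rand_dna(utr5), cds, rand_dna(utr3))
  L <- nchar(tx_seq)
  if (is.null(n_exons)) n_exons <- sample(1:3, 1)
  cuts <- sort(sample((utr5 + 2L):(L - utr3 - 2L), n_exons - 1L))
  bounds <- cbind(c(0L, cuts), c(cuts, L))
  intron_len <- 30L
  strand <- sample(c("+", "-"), 1)
  pieces <- character(0); offs <- integer(n_exons); shift <- 0L
  for (i in seq_len(n_exons)) {
    offs[i] <- shift
    pieces <- c(pieces, substr(tx_seq, bounds[i, 1] + 1L, bounds[i, 2]))
    if (i < n_exons) {
      pieces <- c(pieces, paste0("GT", rand_dna(intron_len - 4L), "AG"))
      shift <- shift + intron_len
    }
  }
  sense_seq <- paste(pieces, collapse = "")
  exons <- data.frame(start = bounds[, 1] + offs, end = bounds[, 2] + offs)
  tx2g <- function(p) {
    i <- min(sum(p >= c(bounds[, 1][-1])) + 1L, n_exons)
    p + offs[i]
  }
  cds_g <- c(tx2g(utr5), tx2g(L - utr3 - 1L) + 1L)
  Lg <- nchar(sense_seq)
  flank <- 25L
  if (strand == "-") {
    rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    sense_seq <- rc(sense_seq)
    mirror <- function(s, e) c(Lg - e, Lg - s)
    ex <- t(apply(exons, 1, function(r) mirror(r[1], r[2])))
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    exons <- data.frame(start = ex[, 1], end = ex[, 2])
    cds_g <- mirror(cds_g[1], cds_g[2])
  }
  contig <- paste0(rand_dna(flank), sense_seq, rand_dna(flank))
  tx <- transcript_model("tx1", "TOYGENE", "chrT", strand,
                         data.frame(start = exons$start + flank,
                                    end = exons$end + flank),
                         cds_g[1] + flank, cds_g[2] + flank)
  list(tx = tx, genome = c(chrT = contig))
}

# All coding SNVs of a transcript as a variant table.
all_coding_snvs <- function(tx, genome, depth = 100L, alt = 30L) {
  pos1 <- sort(tx$cds_genomic_pos) + 1L
  rows <- lapply(pos1, function(p) {
    ref <- substr(genome[[tx$chrom]], p, p)
    alts <- setdiff(c("A", "C", "G", "T"), ref)
    data.frame(chrom = tx$chrom, pos = p, ref_allele = ref,
               alt_allele = alts, total_depth = depth, alt_depth = alt,
               sample_id = "toy", no_evidence = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("caa_variants", "data.frame")
  out
}

# ---- flat reimplementation of the filter cascade rules --------------------
oracle_survivor_keys <- function(ann, cfg, hotspot_labels) {
  f <- ifelse(!is.na(ann$total_depth) & ann$total_depth > 0,
              ann$alt_depth / ann$total_depth, NA)
  snp_key <- if (is.null(cfg$known_snp_sites)) character(0) else
    paste(cfg$known_snp_sites$chrom, cfg$known_snp_sites$pos,
          cfg$known_snp_sites$alt_allele)
  keep <- !is.na(ann$gene_symbol) &
    toupper(ann$gene_symbol) %in% cfg$gene_list &
    !(paste(ann$chrom, ann$pos, ann$alt_allele) %in% snp_key) &
    !ann$no_evidence & !is.na(ann$total_depth) &
    ann$total_depth >= cfg$min_depth &
    !is.na(f) & f >= cfg$vaf_low & f <= cfg$vaf_high &
    ann$klass %in% c("missense", "stop_gain", "splice_donor",
                     "splice_acceptor")
  if (cfg$hotspot_only) keep <- keep & !is.na(hotspot_labels)
  paste(ann$sample_id, ann$chrom, ann$pos, ann$alt_allele)[which(keep)]
}

# Rescue rule, restated flatly: among the non-survivors at hotspot loci that
# pass every rule except the depth/VAF evidence band (and are not above it),
# keep those clearing the rescue thresholds.
oracle_rescued_keys <- function(ann, cfg, hotspot_labels, hot_loci) {
  f <- ifelse(!is.na(ann$total_depth) & ann$total_depth > 0,
              ann$alt_depth / ann$total_depth, NA)
  snp_key <- if (is.null(cfg$known_snp_sites)) character(0) else
    paste(cfg$known_snp_sites$chrom, cfg$known_snp_sites$pos,
          cfg$known_snp_sites$alt_allele)
  pre_ok <- !is.na(ann$gene_symbol) &
    toupper(ann$gene_symbol) %in% cfg$gene_list &
    !(paste(ann$chrom, ann$pos, ann$alt_allele) %in% snp_key)
  ev_fail_low <- !ann$no_evidence & !is.na(f) &
    (ann$total_depth < cfg$min_depth | f < cfg$vaf_low) & f <= cfg$vaf_high
  at_hot <- paste(ann$chrom, ann$pos) %in% paste(hot_loci$chrom, hot_loci$pos)
  keep <- pre_ok & ev_fail_low & at_hot &
    f >= cfg$rescue_vaf_floor & ann$alt_depth >= cfg$rescue_min_alt_reads
  paste(ann$sample_id, ann$chrom, ann$pos, ann$alt_allele)[which(keep)]
}

trace_keys <- function(trace, statuses) {
  sel <- trace$final_status %in% statuses
  paste(trace$sample_id, trace$chrom, trace$pos, trace$alt_allele)[sel]
}

# Shared lazily-built reference bundle for tests that need the toy genome.
toy_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- toy_reference()
      catalog <- read_hotspot_catalog(toy_hotspot_catalog_path())
      omaps <- read_ortholog_maps(toy_proteins_path())
      cache <<- list(
        ref = ref, catalog = catalog, omaps = omaps,
        genes = read_gene_list(toy_gene_list_path()),
        loci = hotspot_genomic_loci(catalog, omaps, ref$transcripts),
        ann_fn = make_consequence_annotator(ref$transcripts, ref$genome),
        hot_fn = make_hotspot_matcher(catalog, omaps))
    }
    cache
  }
})
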