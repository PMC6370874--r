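#' Configuration for the synthetic FFPE tumor-exome cohort generator
#'
#' Defaults encode the emulated study conditions: a 24-case cohort sequenced
#' to a 116x mean depth, drivers at the cohort frequencies HRAS 0.63 and
#' BRAF 0.08 (combined 0.71), single-clone diploid tumors with purity
#' uniform on (0.2, 0.9) so heterozygous driver VAF = purity/2 spans
#' roughly 0.10-0.45, per-case personal germline heterozygous/homozygous
#' SNPs drawn from a population pool, and low-VAF cytosine-deamination
#' artifacts with VAF ~ Beta(1.5, 40).
#'
#' @param n_cases number of tumor cases
#' @param driver_freqs named list gene -> list(hotspot, freq); assignment is
#'   mutually exclusive per case and frequencies must sum to <= 1
#' @param purity_range uniform sampling bounds for tumor purity, in (0, 1]
#' @param mean_depth negative-binomial mean per-site read depth
#' @param depth_dispersion negative-binomial size (smaller = more
#'   overdispersed), for per-variant-site depths
#' @param n_germline_het,n_germline_hom germline SNP sites per case
#' @param n_artifacts FFPE C>T (G>A) artifact sites per case
#' @param artifact_beta shape1/shape2 of the artifact VAF Beta distribution
#' @param known_snp_fraction fraction of the population SNP pool present in
#'   the known-SNP resource given to the filter
#' @param snp_pool_size population SNP pool size shared by all cases
#' @param coverage_nb_size negative-binomial size for per-target coverage
#'   (on top of a shared lognormal capture-efficiency effect per target);
#'   default `Inf` = Poisson counting noise at the expected depth
#' @param cna_event_prob per-case probability of one clonal copy-number
#'   event visible in the coverage profile
#' @param seed master RNG seed; each case derives its own stream from it,
#'   so per-case outputs are stable under cohort resizing
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_cases = 24L,
                       driver_freqs = list(
                         HRAS = list(hotspot = "Q61R", freq = 0.63),
                         BRAF = list(hotspot = "V595E", freq = 0.08)),
                       purity_range = c(0.2, 0.9),
                       mean_depth = 116, depth_dispersion = 8,
                       n_germline_het = 30L, n_germline_hom = 15L,
                       n_artifacts = 12L, artifact_beta = c(1.5, 40),
                       known_snp_fraction = 0.9, snp_pool_size = 400L,
                       coverage_nb_size = Inf, cna_event_prob = 1 / 16,
                       seed = 1L) {
  freqs <- vapply(driver_freqs, `[[`, 0, "freq")
  if (any(freqs < 0 | freqs > 1) || sum(freqs) > 1)
    stop("driver frequencies must lie in [0,1] and sum to <= 1")
  if (!(purity_range[1] > 0 && purity_range[2] <= 1 &&
        purity_range[1] <= purity_range[2]))
    stop("purity_range must lie within (0, 1]")
  if (n_cases < 0) stop("n_cases must be >= 0")
  if (mean_depth <= 0 || depth_dispersion <= 0) stop("invalid depth model")
  if (known_snp_fraction < 0 || known_snp_fraction > 1)
    stop("known_snp_fraction must lie in [0,1]")
  structure(list(n_cases = as.integer(n_cases), driver_freqs = driver_freqs,
                 purity_range = purity_range, mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 n_germline_het = as.integer(n_germline_het),
                 n_germline_hom = as.integer(n_germline_hom),
                 n_artifacts = as.integer(n_artifacts),
                 artifact_beta = artifact_beta,
                 known_snp_fraction = known_snp_fraction,
                 snp_pool_size = as.integer(snp_pool_size),
                 coverage_nb_size = coverage_nb_size,
                 cna_event_prob = cna_event_prob, seed = as.integer(seed)),
            class = "sim_config")
}

# Poisson counting noise when size is infinite, else negative binomial.
draw_depths <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = size)
}

case_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + i * 9973) %% 2147483647)
}

# Find the genomic SNV turning protein_pos's residue into alt_aa for a gene.
hotspot_snv <- function(tx, genome, protein_pos, alt_aa) {
  idx <- (3L * (protein_pos - 1L) + 1L):(3L * protein_pos)
  for (ci in idx) {
    pos1 <- start0_to_pos1(tx$cds_genomic_pos[ci])
    ref <- genome_base(genome, tx$chrom, pos1)
    for (alt in setdiff(VALID_BASES, ref)) {
      v <- variant_records(tx$chrom, pos1, ref, alt, 100L, 50L)
      cc <- classify_variant(v, tx, genome)
      if (cc$klass == "missense" && !is.na(cc$alt_aa) && cc$alt_aa == alt_aa)
        return(list(chrom = tx$chrom, pos = pos1, ref = ref, alt = alt,
                    protein_change = cc$protein_change))
    }
  }
  stop("no single-base change yields ", alt_aa, " at residue ", protein_pos,
       " of ", tx$gene_symbol)
}

# All genic positions (1-based) of a transcript set, as a data.frame.
genic_positions <- function(transcripts) {
  do.call(rbind, lapply(transcripts, function(tx) {
    data.frame(chrom = tx$chrom,
               pos = start0_to_pos1(seq.int(tx$tx_start, tx$tx_end - 1L)),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a tumor-only FFPE exome cohort with known truth
#'
#' Writes one VCF and one per-target coverage TSV per case, a cohort-wide
#' known-SNP site VCF, a capture-target BED, and a truth TSV tracing every
#' emitted variant record to exactly one category (driver, germline_het,
#' germline_hom, artifact). Driver VAF is Binomial(depth, purity/2)/depth —
#' a clonal heterozygous mutation in a diploid tumor diluted by stroma;
#' germline het sites draw at p = 0.5, homozygous at p = 0.98, artifacts at
#' a Beta-distributed low VAF. Identical seed and config give byte-identical
#' outputs.
#'
#' @param cfg a [sim_config()]
#' @param outdir output directory (created)
#' @param ref reference set, default [toy_reference()]
#' @return list: case table (case_id, vcf, coverage, driver gene, purity,
#'   ...), truth data.frame, cna_truth data.frame, paths of the cohort-level
#'   files
#' @export
simulate_cohort <- function(cfg, outdir, ref = toy_reference()) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  contig_lengths <- stats::setNames(nchar(ref$genome), names(ref$genome))

  catalog <- read_hotspot_catalog(toy_hotspot_catalog_path())
  omaps <- read_ortholog_maps(toy_proteins_path())
  hot_loci <- hotspot_genomic_loci(catalog, omaps, ref$transcripts)
  tx_by_gene <- stats::setNames(ref$transcripts,
                                vapply(ref$transcripts, `[[`, "", "gene_symbol"))
  driver_sites <- lapply(names(cfg$driver_freqs), function(g) {
    hs <- cfg$driver_freqs[[g]]$hotspot
    ppos <- as.integer(gsub("[^0-9]", "", hs))
    alt_aa <- sub(".*[0-9]", "", hs)
    hotspot_snv(tx_by_gene[[g]], ref$genome, ppos, alt_aa)
  })
  names(driver_sites) <- names(cfg$driver_freqs)

  # cohort-level randomness: population SNP pool and target capture effects
  set.seed(cfg$seed)
  genic <- genic_positions(ref$transcripts)
  genic_key <- paste(genic$chrom, genic$pos)
  hot_key <- paste(hot_loci$chrom, hot_loci$pos)
  pool_cand <- genic[!(genic_key %in% hot_key), , drop = FALSE]
  pool_idx <- sample(nrow(pool_cand), min(cfg$snp_pool_size, nrow(pool_cand)))
  pool <- pool_cand[sort(pool_idx), , drop = FALSE]
  pool$ref_allele <- mapply(function(ch, p) genome_base(ref$genome, ch, p),
                            pool$chrom, pool$pos)
  pool$alt_allele <- vapply(pool$ref_allele, function(r)
    sample(setdiff(VALID_BASES, r), 1L), "")
  pool$known <- seq_len(nrow(pool)) %in%
    sample(nrow(pool), round(cfg$known_snp_fraction * nrow(pool)))
  # artifact candidates: genic C or G reference bases off the SNP pool
  art_cand <- pool_cand[!(paste(pool_cand$chrom, pool_cand$pos) %in%
                            paste(pool$chrom, pool$pos)), , drop = FALSE]
  art_ref <- mapply(function(ch, p) genome_base(ref$genome, ch, p),
                    art_cand$chrom, art_cand$pos)
  art_cand <- art_cand[art_ref %in% c("C", "G"), , drop = FALSE]
  targets <- ref$targets
  target_effect <- stats::rlnorm(nrow(targets), 0, 0.5)

  snp_vcf <- file.path(outdir, "known_snps.vcf")
  known <- pool[pool$known, , drop = FALSE]
  write_vcf(variant_records(known$chrom, known$pos, known$ref_allele,
                            known$alt_allele, NA_integer_, NA_integer_,
                            "sites", no_evidence = TRUE),
            snp_vcf, sample = "sites", contigs = contig_lengths)
  bed_path <- file.path(outdir, "targets.bed")
  write_targets_bed(targets, bed_path)

  rdepth <- function(n) pmax(1L, stats::rnbinom(n, mu = cfg$mean_depth,
                                                size = cfg$depth_dispersion))
  freqs <- vapply(cfg$driver_freqs, `[[`, 0, "freq")
  cum <- cumsum(freqs)

  cases <- list(); truth <- list(); cna_truth <- list()
  for (i in seq_len(cfg$n_cases)) {
    case_id <- sprintf("SIM-%03d", i)
    set.seed(case_seed(cfg$seed, i))
    purity <- stats::runif(1, cfg$purity_range[1], cfg$purity_range[2])
    u <- stats::runif(1)
    gene <- names(freqs)[which(u <= cum)[1]]
    has_driver <- !is.na(gene) && length(gene) == 1 && !is.null(gene)

    recs <- list(); tr <- list()
    if (has_driver) {
      ds <- driver_sites[[gene]]
      dp <- rdepth(1L)
      ad <- max(1L, stats::rbinom(1L, dp, purity / 2))
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = ds$chrom, pos = ds$pos, ref_allele = ds$ref,
        alt_allele = ds$alt, total_depth = dp, alt_depth = ad,
        sample_id = case_id, no_evidence = FALSE, stringsAsFactors = FALSE)
      tr[[length(tr) + 1L]] <- data.frame(
        case_id = case_id, chrom = ds$chrom, pos = ds$pos,
        ref_allele = ds$ref, alt_allele = ds$alt, category = "driver",
        gene = gene, protein_change = ds$protein_change,
        true_vaf = purity / 2, stringsAsFactors = FALSE)
    }

    n_g <- cfg$n_germline_het + cfg$n_germline_hom
    if (n_g > 0 && nrow(pool) > 0) {
      gi <- sample(nrow(pool), min(n_g, nrow(pool)))
      het <- gi[seq_len(min(cfg$n_germline_het, length(gi)))]
      hom <- setdiff(gi, het)
      for (set in list(list(idx = het, p = 0.5, cat = "germline_het"),
                       list(idx = hom, p = 0.98, cat = "germline_hom"))) {
        if (!length(set$idx)) next
        dp <- rdepth(length(set$idx))
        ad <- pmax(1L, stats::rbinom(length(set$idx), dp, set$p))
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = pool$chrom[set$idx], pos = pool$pos[set$idx],
          ref_allele = pool$ref_allele[set$idx],
          alt_allele = pool$alt_allele[set$idx],
          total_depth = dp, alt_depth = ad, sample_id = case_id,
          no_evidence = FALSE, stringsAsFactors = FALSE)
        tr[[length(tr) + 1L]] <- data.frame(
          case_id = case_id, chrom = pool$chrom[set$idx],
          pos = pool$pos[set$idx], ref_allele = pool$ref_allele[set$idx],
          alt_allele = pool$alt_allele[set$idx], category = set$cat,
          gene = NA_character_, protein_change = NA_character_,
          true_vaf = set$p, stringsAsFactors = FALSE)
      }
    }

    if (cfg$n_artifacts > 0 && nrow(art_cand) > 0) {
      ai <- sample(nrow(art_cand), min(cfg$n_artifacts, nrow(art_cand)))
      aref <- mapply(function(ch, p) genome_base(ref$genome, ch, p),
                     art_cand$chrom[ai], art_cand$pos[ai])
      aalt <- ifelse(aref == "C", "T", "A")     # C>T, G>A deamination
      dp <- rdepth(length(ai))
      av <- stats::rbeta(length(ai), cfg$artifact_beta[1], cfg$artifact_beta[2])
      ad <- pmin(dp, pmax(1L, stats::rbinom(length(ai), dp, av)))
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = art_cand$chrom[ai], pos = art_cand$pos[ai],
        ref_allele = unname(aref), alt_allele = unname(aalt),
        total_depth = dp, alt_depth = ad, sample_id = case_id,
        no_evidence = FALSE, stringsAsFactors = FALSE)
      tr[[length(tr) + 1L]] <- data.frame(
        case_id = case_id, chrom = art_cand$chrom[ai], pos = art_cand$pos[ai],
        ref_allele = unname(aref), alt_allele = unname(aalt),
        category = "artifact", gene = NA_character_,
        protein_change = NA_character_, true_vaf = av,
        stringsAsFactors = FALSE)
    }

    v <- do.call(rbind, recs)
    if (is.null(v)) v <- empty_variants()
    class(v) <- c("caa_variants", "data.frame")
    validate_variants(v)
    vcf_path <- file.path(outdir, paste0(case_id, ".vcf"))
    write_vcf(v, vcf_path, sample = case_id, contigs = contig_lengths)

    # coverage with shared per-target capture effect, optional CNA event
    mult <- rep(1, nrow(targets))
    ev <- NULL
    if (stats::runif(1) < cfg$cna_event_prob && nrow(targets) >= 20) {
      chrom_ev <- sample(unique(targets$chrom), 1)
      on_chr <- which(targets$chrom == chrom_ev)
      span <- min(length(on_chr), sample(15:40, 1))
      s0 <- sample(length(on_chr) - span + 1L, 1)
      bins <- on_chr[s0:(s0 + span - 1L)]
      m <- sample(c(0.5, 2), 1)
      mult[bins] <- m
      ev <- data.frame(case_id = case_id, chrom = chrom_ev,
                       start = targets$start[bins[1]],
                       end = targets$end[bins[length(bins)]],
                       log2_mult = log2(m), n_bins = span,
                       stringsAsFactors = FALSE)
    }
    cov <- targets[, c("chrom", "start", "end")]
    cov$depth <- draw_depths(nrow(targets),
                             cfg$mean_depth * target_effect * mult,
                             cfg$coverage_nb_size)
    cov_path <- file.path(outdir, paste0(case_id, "_coverage.tsv"))
    write_coverage_tsv(cov, cov_path)

    cases[[i]] <- data.frame(
      case_id = case_id, vcf = vcf_path, coverage = cov_path,
      driver_gene = if (has_driver) gene else NA_character_,
      purity = purity, stringsAsFactors = FALSE)
    truth[[i]] <- do.call(rbind, tr)
    if (!is.null(ev)) cna_truth[[length(cna_truth) + 1L]] <- ev
  }

  truth_df <- do.call(rbind, truth)
  if (is.null(truth_df))
    truth_df <- data.frame(case_id = character(), chrom = character(),
                           pos = integer(), ref_allele = character(),
                           alt_allele = character(), category = character(),
                           gene = character(), protein_change = character(),
                           true_vaf = numeric())
  truth_path <- file.path(outdir, "truth.tsv")
  write_tsv_atomic(truth_df, truth_path)
  cna_df <- do.call(rbind, cna_truth)
  if (is.null(cna_df))
    cna_df <- data.frame(case_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         log2_mult = numeric(), n_bins = integer())
  write_tsv_atomic(cna_df, file.path(outdir, "cna_truth.tsv"))

  list(cases = do.call(rbind, cases), truth = truth_df, cna_truth = cna_df,
       known_snps = snp_vcf, targets_bed = bed_path, truth_path = truth_path,
       outdir = outdir)
}

#' Run the full nomination pipeline on a simulated cohort and score it
#'
#' Simulates a cohort, runs the filter cascade (optionally with hotspot
#' rescue) on every per-case VCF, and compares the nominated drivers with
#' the simulation truth: per-case sensitivity and specificity, the
#' estimated MAPK-driver frequency with the 95% binomial confidence
#' interval of the realized truth, and the number of FFPE-artifact records
#' nominated (expected 0: artifacts sit off the hotspot loci and below the
#' evidence band).
#'
#' @param cfg a [sim_config()]
#' @param outdir where to place simulated files (default a temp directory)
#' @param rescue apply [rescue_at_hotspots()]?
#' @return list of cohort-level metrics plus a per-case call table
#' @export
end_to_end_recovery <- function(cfg, outdir = tempfile("simcohort"),
                                rescue = TRUE) {
  ref <- toy_reference()
  sim <- simulate_cohort(cfg, outdir, ref = ref)
  catalog <- read_hotspot_catalog(toy_hotspot_catalog_path())
  omaps <- read_ortholog_maps(toy_proteins_path())
  genes <- read_gene_list(toy_gene_list_path())
  snps <- read_known_snps(sim$known_snps)
  fcfg <- filter_config(gene_list = genes, known_snp_sites = snps)
  ann_fn <- make_consequence_annotator(ref$transcripts, ref$genome)
  hot_fn <- make_hotspot_matcher(catalog, omaps)
  loci <- hotspot_genomic_loci(catalog, omaps, ref$transcripts)

  calls <- lapply(seq_len(nrow(sim$cases)), function(i) {
    v <- read_vcf(sim$cases$vcf[i], sample_id = sim$cases$case_id[i])
    trace <- run_cascade(v, fcfg, ann_fn, hot_fn)
    if (rescue) trace <- rescue_at_hotspots(trace, fcfg, loci)
    surv <- trace[trace$final_status %in% c("nominated", "rescued"), ,
                  drop = FALSE]
    tkey <- paste(sim$truth$case_id, sim$truth$chrom, sim$truth$pos,
                  sim$truth$alt_allele)
    skey <- paste(sim$cases$case_id[i], surv$chrom, surv$pos, surv$alt_allele)
    cat_of <- sim$truth$category[match(skey, tkey)]
    best <- if (nrow(surv)) surv[which.max(vaf(surv)), , drop = FALSE] else NULL
    data.frame(
      case_id = sim$cases$case_id[i],
      called_gene = if (is.null(best)) NA_character_ else best$gene_symbol,
      called_change = if (is.null(best)) NA_character_ else best$protein_change,
      called_status = if (is.null(best)) NA_character_ else best$final_status,
      n_survivors = nrow(surv),
      n_artifact_nominated = sum(cat_of == "artifact", na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)

  truth_gene <- sim$cases$driver_gene
  pos <- !is.na(truth_gene)
  called_pos <- !is.na(calls$called_gene)
  correct <- pos & called_pos & calls$called_gene == truth_gene
  n <- nrow(sim$cases)
  ci <- if (sum(pos) > 0 && n > 0)
    stats::binom.test(sum(pos), n)$conf.int else c(NA_real_, NA_real_)
  list(
    n_cases = n,
    n_true_drivers = sum(pos),
    true_freq = if (n) sum(pos) / n else NA_real_,
    est_freq = if (n) sum(called_pos) / n else NA_real_,
    ci_low = ci[1], ci_high = ci[2],
    sensitivity = if (sum(pos)) sum(correct) / sum(pos) else NA_real_,
    specificity = if (sum(!pos)) sum(!called_pos & !pos) / sum(!pos)
                  else NA_real_,
    artifact_nominations = sum(calls$n_artifact_nominated),
    calls = calls
  )
}

#' Simulate a cohort of coverage profiles with known copy-number events
#'
#' Stand-alone coverage simulator for the copy-number module: `n_samples`
#' profiles over `n_bins` targets share a lognormal per-target capture
#' effect; the first `n_aberrant` samples carry one contiguous event of
#' `event_bins` bins multiplied by `2^log2_effect`.
#'
#' @param n_samples,n_aberrant cohort size and number of event-bearing
#'   samples
#' @param n_bins targets per profile (single contig)
#' @param mean_depth mean per-target depth
#' @param nb_size negative-binomial size of per-target noise; the default
#'   `Inf` gives pure Poisson counting noise at the target's expected depth
#' @param target_sd sd of the shared lognormal capture effect
#' @param event_bins event width in bins
#' @param log2_effect event magnitude in log2 units (sign gives gain/loss)
#' @param seed RNG seed
#' @return list: profiles (list of coverage data.frames), events
#'   (data.frame sample, first_bin, last_bin, log2_effect)
#' @export
simulate_coverage_cohort <- function(n_samples = 16L, n_aberrant = 1L,
                                     n_bins = 300L, mean_depth = 116,
                                     nb_size = Inf, target_sd = 0.5,
                                     event_bins = 30L, log2_effect = 1,
                                     seed = 1L) {
  stopifnot(n_aberrant <= n_samples, event_bins < n_bins)
  set.seed(seed)
  bins <- data.frame(chrom = "chr1",
                     start = seq.int(0L, by = 120L, length.out = n_bins))
  bins$end <- bins$start + 120L
  eff <- stats::rlnorm(n_bins, 0, target_sd)
  events <- list(); profiles <- list()
  for (s in seq_len(n_samples)) {
    mult <- rep(1, n_bins)
    if (s <= n_aberrant) {
      first <- sample(n_bins - event_bins + 1L, 1)
      last <- first + event_bins - 1L
      mult[first:last] <- 2^log2_effect
      events[[length(events) + 1L]] <- data.frame(
        sample = s, first_bin = first, last_bin = last,
        log2_effect = log2_effect)
    }
    p <- bins
    p$depth <- draw_depths(n_bins, mean_depth * eff * mult, nb_size)
    profiles[[s]] <- p
  }
  list(profiles = profiles,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(sample = integer(), first_bin = integer(),
                    last_bin = integer(), log2_effect = numeric()))
}
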