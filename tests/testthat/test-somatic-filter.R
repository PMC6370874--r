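# The tumor-only filter cascade and the low-VAF hotspot rescue.

make_filter_cfg <- function(..., b = toy_bundle()) {
  filter_config(gene_list = b$genes, ...)
}

# A variant at the toy HRAS codon-61 hotspot (CAA>CGA, Q61R).
hras_q61r_variant <- function(total, alt, sample_id = "T") {
  b <- toy_bundle()
  tx <- b$ref$transcripts[["HRAS.t1"]]
  pos <- start0_to_pos1(tx$cds_genomic_pos[3L * 60L + 2L])
  variant_records(tx$chrom, pos, "A", "G", total, alt, sample_id)
}

test_that("evidence filter applies the depth and inclusive VAF band", {
  cfg <- filter_config(gene_list = "HRAS")
  ev <- function(total, alt) {
    evidence_filter(variant_records("c", 1L, "A", "G", total, alt), cfg)
  }
  expect_true(ev(72L, 20L)$pass)                       # VAF 0.278
  r <- ev(101L, 11L); expect_false(r$pass)             # VAF 0.109
  expect_equal(r$reason, "vaf-below-band")
  r <- ev(19L, 6L); expect_false(r$pass)               # depth boundary
  expect_equal(r$reason, "low-depth")
  expect_true(ev(20L, 4L)$pass)                        # VAF exactly 0.20
  expect_true(ev(20L, 10L)$pass)                       # VAF exactly 0.50
  r <- ev(100L, 51L); expect_false(r$pass)
  expect_equal(r$reason, "vaf-above-band")
  v <- variant_records("c", 1L, "A", "G", NA, NA, no_evidence = TRUE)
  r <- evidence_filter(v, cfg)
  expect_false(r$pass); expect_equal(r$reason, "no-evidence")
})

test_that("the nine printed depth/VAF pairs: one evidence failure, then rescued", {
  cases <- load_table1_cases()
  measured <- cases[!is.na(cases$vaf), ]
  cfg <- filter_config(gene_list = "X")
  v <- variant_records("c", seq_len(nrow(measured)), "A", "G",
                       measured$read_depth,
                       round(measured$vaf * measured$read_depth),
                       measured$case_id)
  ev <- evidence_filter(v, cfg)
  expect_equal(sum(!ev$pass), 1L)
  failed <- measured$case_id[!ev$pass]
  expect_equal(failed, "CAA-20")
  expect_equal(measured$vaf[measured$case_id == failed], 0.109)
  # the failing record clears the rescue thresholds
  vf <- v[!ev$pass, ]
  expect_true(vaf(vf) >= cfg$rescue_vaf_floor)
  expect_true(vf$alt_depth >= cfg$rescue_min_alt_reads)
})

test_that("cascade nominates a clean hotspot driver and traces each stage", {
  b <- toy_bundle()
  cfg <- make_filter_cfg()
  v <- hras_q61r_variant(72L, 20L)
  tr <- run_cascade(v, cfg, b$ann_fn, b$hot_fn)
  expect_equal(tr$final_status, "nominated")
  expect_equal(tr$hotspot, "HRAS-Q61R")
  expect_true(all(unlist(tr[, paste0("stage_", c("gene_list", "known_snp",
                                                 "evidence", "consequence",
                                                 "hotspot"))]) == "pass"))
  # same record, gene excluded from the list -> rejected at the first stage,
  # later stages not evaluated
  cfg2 <- filter_config(gene_list = "TP53")
  tr2 <- run_cascade(v, cfg2, b$ann_fn, b$hot_fn)
  expect_equal(tr2$final_status, "rejected:gene_list")
  expect_true(is.na(tr2$stage_evidence))
  expect_true(is.na(tr2$stage_hotspot))
})

test_that("known-SNP sites are excluded by exact site and allele", {
  b <- toy_bundle()
  v <- hras_q61r_variant(72L, 20L)
  snp_here <- data.frame(chrom = v$chrom, pos = v$pos, alt_allele = "G")
  tr <- run_cascade(v, make_filter_cfg(known_snp_sites = snp_here),
                    b$ann_fn, b$hot_fn)
  expect_equal(tr$final_status, "rejected:known_snp")
  snp_other_allele <- data.frame(chrom = v$chrom, pos = v$pos,
                                 alt_allele = "T")
  tr2 <- run_cascade(v, make_filter_cfg(known_snp_sites = snp_other_allele),
                     b$ann_fn, b$hot_fn)
  expect_equal(tr2$final_status, "nominated")
})

test_that("cascade survivors equal a flat reimplementation on a simulated cohort", {
  b <- toy_bundle()
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(sim_config(n_cases = 4L, seed = 303L), dir,
                         ref = b$ref)
  v <- do.call(rbind, lapply(seq_len(nrow(sim$cases)), function(i)
    read_vcf(sim$cases$vcf[i], sample_id = sim$cases$case_id[i])))
  class(v) <- c("caa_variants", "data.frame")
  cfg <- make_filter_cfg(known_snp_sites = read_known_snps(sim$known_snps))
  tr <- run_cascade(v, cfg, b$ann_fn, b$hot_fn)
  ann <- b$ann_fn(v)
  hot <- b$hot_fn(ann)
  expect_setequal(trace_keys(tr, "nominated"),
                  oracle_survivor_keys(ann, cfg, hot))
  # rescue agrees with the flat rescue rule too
  tr2 <- rescue_at_hotspots(tr, cfg, b$loci)
  expect_setequal(trace_keys(tr2, "rescued"),
                  oracle_rescued_keys(ann, cfg, hot, b$loci))
})

test_that("a CAA-20-like low-VAF hotspot record is rescued; non-hotspot and sub-floor are not", {
  b <- toy_bundle()
  cfg <- make_filter_cfg()
  v <- hras_q61r_variant(101L, 11L, "CAA-20")      # VAF 0.109
  tr <- run_cascade(v, cfg, b$ann_fn, b$hot_fn)
  expect_equal(tr$final_status, "rejected:evidence")
  tr <- rescue_at_hotspots(tr, cfg, b$loci)
  expect_equal(tr$final_status, "rescued")

  # same VAF at a non-hotspot coding position stays rejected
  tx <- b$ref$transcripts[["HRAS.t1"]]
  pos2 <- start0_to_pos1(tx$cds_genomic_pos[3L * 99L + 2L])  # codon 100
  ref2 <- substr(b$ref$genome[[tx$chrom]], pos2, pos2)
  v2 <- variant_records(tx$chrom, pos2, ref2,
                        setdiff(c("A", "C", "G", "T"), ref2)[1],
                        101L, 11L, "X")
  tr2 <- rescue_at_hotspots(run_cascade(v2, cfg, b$ann_fn, b$hot_fn),
                            cfg, b$loci)
  expect_match(tr2$final_status, "^rejected")

  # VAF below the rescue floor stays rejected even at the hotspot
  v3 <- hras_q61r_variant(100L, 2L, "Y")           # VAF 0.02
  tr3 <- rescue_at_hotspots(run_cascade(v3, cfg, b$ann_fn, b$hot_fn),
                            cfg, b$loci)
  expect_equal(tr3$final_status, "rejected:evidence")
  ann3 <- b$ann_fn(v3)
  expect_length(oracle_rescued_keys(ann3, cfg, b$hot_fn(ann3), b$loci), 0)

  # above-band records are never rescued (rescue targets the low-VAF miss)
  v4 <- hras_q61r_variant(100L, 80L, "Z")          # VAF 0.8
  tr4 <- rescue_at_hotspots(run_cascade(v4, cfg, b$ann_fn, b$hot_fn),
                            cfg, b$loci)
  expect_equal(tr4$final_status, "rejected:evidence")
})

test_that("tightening thresholds never enlarges the survivor set", {
  b <- toy_bundle()
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(sim_config(n_cases = 6L, seed = 99L), dir,
                         ref = b$ref)
  v <- do.call(rbind, lapply(seq_len(nrow(sim$cases)), function(i)
    read_vcf(sim$cases$vcf[i], sample_id = sim$cases$case_id[i])))
  class(v) <- c("caa_variants", "data.frame")
  snps <- read_known_snps(sim$known_snps)
  base <- run_cascade(v, make_filter_cfg(known_snp_sites = snps),
                      b$ann_fn, b$hot_fn)
  base_keys <- trace_keys(base, "nominated")
  tighter <- list(
    make_filter_cfg(known_snp_sites = snps, min_depth = 40L),
    make_filter_cfg(known_snp_sites = snps, vaf_low = 0.30),
    make_filter_cfg(known_snp_sites = snps, vaf_high = 0.40),
    make_filter_cfg(known_snp_sites = snps, min_depth = 60L,
                    vaf_low = 0.25, vaf_high = 0.45))
  for (cfg in tighter) {
    keys <- trace_keys(run_cascade(v, cfg, b$ann_fn, b$hot_fn), "nominated")
    expect_true(all(keys %in% base_keys))
  }
})

test_that("survivor set is invariant under input permutation", {
  b <- toy_bundle()
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(sim_config(n_cases = 3L, seed = 17L), dir,
                         ref = b$ref)
  v <- do.call(rbind, lapply(seq_len(nrow(sim$cases)), function(i)
    read_vcf(sim$cases$vcf[i], sample_id = sim$cases$case_id[i])))
  class(v) <- c("caa_variants", "data.frame")
  cfg <- make_filter_cfg(known_snp_sites = read_known_snps(sim$known_snps))
  set.seed(1)
  perm <- v[sample(nrow(v)), ]
  expect_setequal(
    trace_keys(run_cascade(v, cfg, b$ann_fn, b$hot_fn), "nominated"),
    trace_keys(run_cascade(perm, cfg, b$ann_fn, b$hot_fn), "nominated"))
})

test_that("rescue only promotes: statuses move rejected->rescued, never off nominated", {
  b <- toy_bundle()
  cfg <- make_filter_cfg()
  v <- rbind(hras_q61r_variant(72L, 20L, "A"),
             hras_q61r_variant(101L, 11L, "B"),
             hras_q61r_variant(100L, 2L, "C"))
  class(v) <- c("caa_variants", "data.frame")
  tr <- run_cascade(v, cfg, b$ann_fn, b$hot_fn)
  tr2 <- rescue_at_hotspots(tr, cfg, b$loci)
  expect_equal(tr2$final_status[tr$final_status == "nominated"], "nominated")
  changed <- tr$final_status != tr2$final_status
  expect_true(all(tr$final_status[changed] == "rejected:evidence"))
  expect_true(all(tr2$final_status[changed] == "rescued"))
})

test_that("hotspot_only=FALSE yields a superset of the hotspot-restricted survivors", {
  b <- toy_bundle()
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(sim_config(n_cases = 5L, seed = 41L), dir,
                         ref = b$ref)
  v <- do.call(rbind, lapply(seq_len(nrow(sim$cases)), function(i)
    read_vcf(sim$cases$vcf[i], sample_id = sim$cases$case_id[i])))
  class(v) <- c("caa_variants", "data.frame")
  snps <- read_known_snps(sim$known_snps)
  on <- trace_keys(run_cascade(v, make_filter_cfg(known_snp_sites = snps),
                               b$ann_fn, b$hot_fn), "nominated")
  off <- trace_keys(run_cascade(
    v, make_filter_cfg(known_snp_sites = snps, hotspot_only = FALSE),
    b$ann_fn, b$hot_fn), "nominated")
  expect_true(all(on %in% off))
})

test_that("filter_config rejects inconsistent thresholds", {
  expect_error(filter_config(vaf_low = 0.5, vaf_high = 0.2), "vaf")
  expect_error(filter_config(rescue_vaf_floor = 0.3), "vaf")
  expect_error(filter_config(min_depth = 0), "min_depth")
})
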