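#' Configuration for the tumor-only filter cascade
#'
#' Defaults encode the study conditions: read depth >= 20 and VAF within
#' 20–50% (both endpoints inclusive) define "High evidence"; nomination is
#' restricted to a cancer-gene list and, when `hotspot_only = TRUE`, to
#' variants at orthologous human hotspot positions. The rescue thresholds
#' govern targeted recovery of low-VAF hotspot calls (an 11% VAF true driver
#' diluted by stroma should be recoverable; FFPE-artifact-level support
#' should not).
#'
#' @param min_depth minimum total read depth (reads)
#' @param vaf_low,vaf_high inclusive variant-allele-fraction band
#' @param rescue_vaf_floor minimum VAF for hotspot rescue
#' @param rescue_min_alt_reads minimum alt-supporting reads for rescue
#' @param gene_list character set of eligible gene symbols
#' @param known_snp_sites data.frame chrom, pos, alt_allele (and optionally
#'   ref_allele) of known germline sites, or `NULL` for none
#' @param hotspot_only apply the hotspot-orthology stage?
#' @return object of class `filter_config`
#' @export
filter_config <- function(min_depth = 20L, vaf_low = 0.20, vaf_high = 0.50,
                          rescue_vaf_floor = 0.05, rescue_min_alt_reads = 4L,
                          gene_list = character(), known_snp_sites = NULL,
                          hotspot_only = TRUE) {
  if (!(0 < rescue_vaf_floor && rescue_vaf_floor < vaf_low &&
        vaf_low < vaf_high && vaf_high <= 1))
    stop("need 0 < rescue_vaf_floor < vaf_low < vaf_high <= 1")
  if (min_depth < 1L) stop("min_depth must be >= 1")
  structure(list(min_depth = as.integer(min_depth), vaf_low = vaf_low,
                 vaf_high = vaf_high, rescue_vaf_floor = rescue_vaf_floor,
                 rescue_min_alt_reads = as.integer(rescue_min_alt_reads),
                 gene_list = toupper(gene_list),
                 known_snp_sites = known_snp_sites,
                 hotspot_only = isTRUE(hotspot_only)),
            class = "filter_config")
}

#' High-evidence filter
#'
#' Passes a record iff `total_depth >= min_depth` and its VAF lies inside
#' the inclusive `[vaf_low, vaf_high]` band. Records without recoverable
#' depth fail with reason `"no-evidence"`.
#'
#' @param v variant data.frame (any number of rows)
#' @param cfg a [filter_config()]
#' @return data.frame pass (logical), reason (character: "" when passing,
#'   else one of "no-evidence", "low-depth", "vaf-below-band",
#'   "vaf-above-band")
#' @export
evidence_filter <- function(v, cfg) {
  f <- vaf(v)
  reason <- character(nrow(v))
  noev <- v$no_evidence | is.na(v$total_depth) | is.na(v$alt_depth)
  reason[noev] <- "no-evidence"
  low_d <- !noev & v$total_depth < cfg$min_depth
  reason[low_d] <- "low-depth"
  below <- !noev & !low_d & f < cfg$vaf_low
  reason[below] <- "vaf-below-band"
  above <- !noev & !low_d & f > cfg$vaf_high
  reason[above] <- "vaf-above-band"
  data.frame(pass = reason == "", reason = reason, stringsAsFactors = FALSE)
}

CASCADE_STAGES <- c("gene_list", "known_snp", "evidence", "consequence",
                    "hotspot")

#' Run the tumor-only driver-nomination cascade
#'
#' Applies the filter stages in their narrative order — cancer-gene list,
#' known-SNP exclusion, High evidence (depth and VAF band), High consequence
#' (missense / stop-gain / splice donor/acceptor), hotspot orthology — and
#' records a per-variant trace. A variant failing stage k has `NA` for every
#' later stage; survivors get `final_status = "nominated"`. Because the
#' stages are conjunctive the survivor *set* does not depend on stage order,
#' but the per-stage rejection counts do.
#'
#' @param variants `caa_variants` data.frame
#' @param cfg a [filter_config()]
#' @param consequence_fn function(variants) appending annotation columns
#'   (see [make_consequence_annotator()])
#' @param hotspot_fn function(annotated variants) returning a hotspot label
#'   or `NA` per row (see [make_hotspot_matcher()]); required when
#'   `cfg$hotspot_only`
#' @return data.frame of class `filter_trace`: variant and annotation
#'   columns, one `stage_*` column per stage ("pass"/"fail"/NA), `hotspot`,
#'   and `final_status` ("nominated" or "rejected:<stage>")
#' @export
run_cascade <- function(variants, cfg, consequence_fn, hotspot_fn = NULL) {
  stopifnot(inherits(cfg, "filter_config"))
  if (cfg$hotspot_only && is.null(hotspot_fn))
    stop("hotspot_only cascade needs a hotspot_fn")
  ann <- consequence_fn(variants)
  n <- nrow(ann)
  stages <- if (cfg$hotspot_only) CASCADE_STAGES else
    setdiff(CASCADE_STAGES, "hotspot")
  res <- matrix(NA_character_, nrow = n, ncol = length(stages),
                dimnames = list(NULL, paste0("stage_", stages)))
  alive <- rep(TRUE, n)
  hotspot <- rep(NA_character_, n)

  for (st in stages) {
    ok <- switch(st,
      gene_list = !is.na(ann$gene_symbol) &
        toupper(ann$gene_symbol) %in% cfg$gene_list,
      known_snp = !is_known_snp(ann, cfg$known_snp_sites),
      evidence = evidence_filter(ann, cfg)$pass,
      consequence = is_high_consequence(ann$klass),
      hotspot = {
        idx <- which(alive)
        hs <- rep(NA_character_, n)
        if (length(idx)) hs[idx] <- hotspot_fn(ann[idx, , drop = FALSE])
        hotspot <- hs
        !is.na(hs)
      })
    res[alive, paste0("stage_", st)] <- ifelse(ok[alive], "pass", "fail")
    alive <- alive & ok
  }

  first_fail <- apply(res, 1, function(r) {
    f <- which(r == "fail")
    if (length(f)) stages[f[1]] else NA_character_
  })
  out <- cbind(ann, as.data.frame(res, stringsAsFactors = FALSE))
  out$hotspot <- hotspot
  out$final_status <- ifelse(is.na(first_fail), "nominated",
                             paste0("rejected:", first_fail))
  class(out) <- c("filter_trace", "data.frame")
  out
}

is_known_snp <- function(v, sites) {
  if (is.null(sites) || nrow(sites) == 0) return(rep(FALSE, nrow(v)))
  key <- function(d) paste(d$chrom, d$pos, d$alt_allele, sep = ":")
  key(v) %in% key(sites)
}

#' Rescue low-VAF calls at mapped hotspot loci
#'
#' Re-examines variants that were rejected by the evidence stage alone
#' (all prior stages passed) and sit at a mapped canine hotspot locus:
#' those with `vaf >= rescue_vaf_floor` and
#' `alt_depth >= rescue_min_alt_reads` are promoted to
#' `final_status = "rescued"`. Records rejected for VAF *above* the band
#' (likely germline homozygotes) or with no depth evidence are never
#' rescued; rescue targets the low-VAF, stroma-diluted miss. Nominated
#' records are never demoted.
#'
#' @param trace a [run_cascade()] result
#' @param cfg a [filter_config()]
#' @param hotspot_loci data.frame chrom, pos of canine hotspot-codon bases
#'   (see [hotspot_genomic_loci()])
#' @return the trace with rescued rows' `final_status` updated
#' @export
rescue_at_hotspots <- function(trace, cfg, hotspot_loci) {
  if (!nrow(trace)) return(trace)
  ev <- evidence_filter(trace, cfg)
  at_hot <- paste(trace$chrom, trace$pos) %in%
    paste(hotspot_loci$chrom, hotspot_loci$pos)
  f <- vaf(trace)
  eligible <- trace$final_status == "rejected:evidence" &
    at_hot &
    ev$reason %in% c("low-depth", "vaf-below-band") &
    !is.na(f) & f >= cfg$rescue_vaf_floor &
    !is.na(trace$alt_depth) & trace$alt_depth >= cfg$rescue_min_alt_reads
  trace$final_status[eligible] <- "rescued"
  trace
}

#' Genomic positions of mapped canine hotspot codons
#'
#' For each catalog entry with a mapped canine residue, returns the three
#' genomic base positions of that codon in the gene's transcript model —
#' the loci the rescue step re-examines.
#'
#' @param catalog hotspot catalog
#' @param omaps named list of ortholog maps
#' @param transcripts named list of transcript models
#' @return data.frame gene, canine_pos, chrom, pos (1-based)
#' @export
hotspot_genomic_loci <- function(catalog, omaps, transcripts) {
  mapped <- map_catalog(catalog, omaps)
  mapped <- mapped[!is.na(mapped$canine_pos), , drop = FALSE]
  by_gene <- stats::setNames(
    lapply(transcripts, identity),
    vapply(transcripts, `[[`, "", "gene_symbol"))
  rows <- lapply(seq_len(nrow(mapped)), function(i) {
    tx <- by_gene[[mapped$gene[i]]]
    if (is.null(tx)) return(NULL)
    c0 <- mapped$canine_pos[i]
    if (c0 > tx$protein_length) return(NULL)
    idx <- (3L * (c0 - 1L) + 1L):(3L * c0)
    data.frame(gene = mapped$gene[i], canine_pos = c0, chrom = tx$chrom,
               pos = start0_to_pos1(tx$cds_genomic_pos[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), canine_pos = integer(),
                      chrom = character(), pos = integer())
  out
}

#' Write a filter trace as TSV and the survivors as VCF
#'
#' @param trace a [run_cascade()] (optionally rescued) result
#' @param prefix output path prefix; writes `<prefix>_trace.tsv` and
#'   `<prefix>_survivors.vcf`
#' @return named character vector of the two paths, invisibly
#' @export
write_filter_outputs <- function(trace, prefix) {
  trace_path <- paste0(prefix, "_trace.tsv")
  vcf_path <- paste0(prefix, "_survivors.vcf")
  write_tsv_atomic(as.data.frame(trace), trace_path)
  surv <- trace[trace$final_status %in% c("nominated", "rescued"), , drop = FALSE]
  keep <- c("chrom", "pos", "ref_allele", "alt_allele", "total_depth",
            "alt_depth", "sample_id", "no_evidence")
  surv <- surv[, keep, drop = FALSE]
  class(surv) <- c("caa_variants", "data.frame")
  write_vcf(surv, vcf_path)
  invisible(c(trace = trace_path, survivors = vcf_path))
}
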