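#' Align a human protein to its canine ortholog
#'
#' Global (Needleman–Wunsch) alignment with BLOSUM62 substitution scores and
#' affine gap penalties, used to transfer hotspot residue numbering across
#' species — the computation behind equating, e.g., canine BRAF position 595
#' with human BRAF position 600. Deterministic for fixed inputs and
#' parameters. The aligned-pair list contains every column in which both
#' sequences have a residue (matched or mismatched, never gapped).
#'
#' @param human_seq,canine_seq protein sequences (character); standard amino
#'   acid alphabet, `*` allowed only as a trailing stop
#' @param gene_symbol label carried on the map
#' @param gap_open,gap_extend affine gap penalties (cost of a length-L gap is
#'   `gap_open + gap_extend * L`)
#' @return object of class `ortholog_map`: gene_symbol, human_seq,
#'   canine_seq, aligned_pairs (data.frame human_pos, canine_pos),
#'   alignment_score
#' @export
align_orthologs <- function(human_seq, canine_seq, gene_symbol = "",
                            gap_open = 10, gap_extend = 0.5) {
  human_seq <- sub("\\*$", "", toupper(human_seq))
  canine_seq <- sub("\\*$", "", toupper(canine_seq))
  if (!nzchar(human_seq) || !nzchar(canine_seq))
    stop("ortholog alignment requires two non-empty protein sequences")
  ok <- function(s) grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", s)
  if (!ok(human_seq) || !ok(canine_seq))
    stop("invalid amino-acid alphabet in ortholog pair ", gene_symbol)

  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(human_seq), Biostrings::AAString(canine_seq),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  # alignedPattern/alignedSubject keep end-gap columns, so residue counters
  # index the original sequences correctly even with terminal gaps
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  hp <- cumsum(p != "-")
  cp <- cumsum(s != "-")
  both <- p != "-" & s != "-"
  pairs <- data.frame(human_pos = hp[both], canine_pos = cp[both])

  out <- list(gene_symbol = gene_symbol, human_seq = human_seq,
              canine_seq = canine_seq, aligned_pairs = pairs,
              alignment_score = Biostrings::score(aln))
  class(out) <- "ortholog_map"
  out
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %s: human %d aa / canine %d aa, %d aligned pairs, score %.1f\n",
              x$gene_symbol, nchar(x$human_seq), nchar(x$canine_seq),
              nrow(x$aligned_pairs), x$alignment_score))
  invisible(x)
}

#' Map one human hotspot position onto the canine ortholog
#'
#' Looks up the alignment column holding the hotspot's human residue. If that
#' column is gapped in the canine sequence the hotspot has no orthologous
#' position (`status = "gapped"`). If the canine residue differs from the
#' catalog's reference residue the mapping is returned but flagged
#' (`status = "residue_mismatch"`) — genuine inter-species reference
#' differences exist and should not abort the transfer.
#'
#' @param entry one-row hotspot catalog entry (gene, human_pos, ref_aa,
#'   alt_aas)
#' @param omap an [align_orthologs()] map for the same gene
#' @return list(canine_pos, canine_ref_aa, status) with status one of
#'   "ok", "gapped", "residue_mismatch", "out_of_range"
#' @export
map_hotspot <- function(entry, omap) {
  stopifnot(entry$gene == omap$gene_symbol)
  hp <- as.integer(entry$human_pos)
  if (hp > nchar(omap$human_seq))
    return(list(canine_pos = NA_integer_, canine_ref_aa = NA_character_,
                status = "out_of_range"))
  k <- match(hp, omap$aligned_pairs$human_pos)
  if (is.na(k))
    return(list(canine_pos = NA_integer_, canine_ref_aa = NA_character_,
                status = "gapped"))
  cpos <- omap$aligned_pairs$canine_pos[k]
  caa <- substr(omap$canine_seq, cpos, cpos)
  list(canine_pos = cpos, canine_ref_aa = caa,
       status = if (caa == entry$ref_aa) "ok" else "residue_mismatch")
}

#' Map a whole hotspot catalog into canine protein coordinates
#'
#' @param catalog data.frame from [read_hotspot_catalog()]
#' @param omaps named list of ortholog maps (names = gene symbols)
#' @return catalog with canine_pos, canine_ref_aa, map_status appended;
#'   genes without an ortholog map get status "no_map"
#' @export
map_catalog <- function(catalog, omaps) {
  out <- catalog
  out$canine_pos <- NA_integer_
  out$canine_ref_aa <- NA_character_
  out$map_status <- "no_map"
  for (i in seq_len(nrow(catalog))) {
    om <- omaps[[catalog$gene[i]]]
    if (is.null(om)) next
    m <- map_hotspot(catalog[i, , drop = FALSE], om)
    out$canine_pos[i] <- m$canine_pos
    out$canine_ref_aa[i] <- m$canine_ref_aa
    out$map_status[i] <- m$status
  }
  out
}

#' Test a consequence call against the hotspot catalog
#'
#' A variant matches a hotspot entry iff its class is missense (or stop-gain
#' when the catalog permits `*`), its protein position equals the hotspot's
#' mapped canine position, its reference residue equals the catalog's, and
#' its substituted residue is permitted (an empty `alt_aas` permits any
#' non-reference residue). Gapped or unmapped entries can never match.
#'
#' @param call one-row annotated variant (gene_symbol, klass, protein_pos,
#'   ref_aa, alt_aa columns)
#' @param catalog hotspot catalog
#' @param omaps named list of ortholog maps
#' @return the matching catalog row (with canine coordinates), or `NULL`
#' @export
match_variant_to_hotspot <- function(call, catalog, omaps) {
  if (is.na(call$gene_symbol)) return(NULL)
  ent <- catalog[catalog$gene == call$gene_symbol, , drop = FALSE]
  if (!nrow(ent)) return(NULL)
  mapped <- map_catalog(ent, omaps)
  mapped <- mapped[!is.na(mapped$canine_pos), , drop = FALSE]
  for (i in seq_len(nrow(mapped))) {
    e <- mapped[i, , drop = FALSE]
    class_ok <- call$klass == "missense" ||
      (call$klass == "stop_gain" && hotspot_allows(e$alt_aas, "*"))
    if (!class_ok) next
    if (is.na(call$protein_pos) || call$protein_pos != e$canine_pos) next
    if (call$ref_aa != e$ref_aa) next
    if (!hotspot_allows(e$alt_aas, call$alt_aa)) next
    return(e)
  }
  NULL
}

#' Build a hotspot-matcher callback for the filter cascade
#'
#' @inheritParams match_variant_to_hotspot
#' @return function(annotated variants) -> character vector of hotspot labels
#'   (`"GENE-REF<pos>ALT"` style, e.g. `"HRAS-Q61R"`) or `NA` per row
#' @export
make_hotspot_matcher <- function(catalog, omaps) {
  function(ann) {
    vapply(seq_len(nrow(ann)), function(i) {
      m <- match_variant_to_hotspot(ann[i, , drop = FALSE], catalog, omaps)
      if (is.null(m)) NA_character_ else
        paste0(m$gene, "-", ann$ref_aa[i], ann$protein_pos[i], ann$alt_aa[i])
    }, "")
  }
}

#' Read ortholog protein pairs from a FASTA file
#'
#' Entries are named `GENE|human` and `GENE|canine`; each complete pair is
#' globally aligned.
#'
#' @param path protein FASTA
#' @param ... passed to [align_orthologs()]
#' @return named list of ortholog maps
#' @export
read_ortholog_maps <- function(path, ...) {
  aa <- Biostrings::readAAStringSet(path)
  nm <- sub("\\s.*$", "", names(aa))
  parts <- strsplit(nm, "|", fixed = TRUE)
  genes <- vapply(parts, `[`, "", 1)
  species <- vapply(parts, `[`, "", 2)
  out <- list()
  for (g in unique(genes)) {
    h <- which(genes == g & species == "human")
    d <- which(genes == g & species == "canine")
    if (length(h) == 1 && length(d) == 1) {
      out[[g]] <- align_orthologs(as.character(aa[[h]]), as.character(aa[[d]]),
                                  gene_symbol = g, ...)
    }
  }
  if (!length(out)) stop("no complete GENE|human + GENE|canine pairs in ", path)
  out
}
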