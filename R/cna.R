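#' Normalize a coverage profile against a panel of other samples
#'
#' Tumor-only copy-number profiling: each bin's value is
#' `log2(bin depth / sample median depth) - log2(panel median of the same
#' normalized quantity)`, so per-target capture efficiency shared across the
#' cohort cancels. The panel is normally the other cohort samples (no
#' matched normals). Bins whose panel-median normalized depth is 0, or whose
#' own depth is 0, are masked (`NA`). Ratios are invariant to rescaling all
#' depths of any sample by a constant.
#'
#' @param profile data.frame chrom, start, end, depth for the sample
#' @param panel list of such data.frames over the *same* bins
#' @return data.frame chrom, start, end, ratio (log2), with attribute
#'   `no_panel = TRUE` when the panel was empty (ratios are then against the
#'   sample median only)
#' @export
normalize_coverage <- function(profile, panel = list()) {
  d <- profile$depth
  if (all(d == 0)) stop("all-zero coverage profile")
  med <- stats::median(d)
  norm_s <- d / med
  out <- profile[, c("chrom", "start", "end")]
  if (length(panel) == 0) {
    out$ratio <- ifelse(norm_s > 0, log2(norm_s), NA_real_)
    attr(out, "no_panel") <- TRUE
    return(out)
  }
  pm <- vapply(panel, function(p) {
    if (nrow(p) != nrow(profile) || any(p$start != profile$start))
      stop("panel profiles must share the sample's bins")
    p$depth / stats::median(p$depth)
  }, numeric(nrow(profile)))
  panel_med <- apply(as.matrix(pm), 1, stats::median)
  ratio <- rep(NA_real_, nrow(profile))
  ok <- panel_med > 0 & norm_s > 0
  ratio[ok] <- log2(norm_s[ok]) - log2(panel_med[ok])
  out$ratio <- ratio
  attr(out, "no_panel") <- FALSE
  out
}

# Best contiguous segment of x by the two-sample t statistic (segment mean
# vs the mean of the rest), maximized over all windows [i, j] with both the
# window and its complement at least min_seg bins. Returns list(i, j, t) or
# NULL. Ties resolve to the first (smallest i, then smallest j) window.
best_segment <- function(x, min_seg) {
  n <- length(x)
  if (n < 2L * min_seg) return(NULL)
  cs <- c(0, cumsum(x)); css <- c(0, cumsum(x^2))
  tot <- cs[n + 1L]; tot2 <- css[n + 1L]
  best <- NULL; best_t <- -Inf
  for (i in 1:(n - min_seg + 1L)) {
    js <- (i + min_seg - 1L):n
    nin <- js - i + 1L
    nout <- n - nin
    ok <- nout >= min_seg | nout == 0L
    js <- js[ok & nout >= min_seg]
    if (!length(js)) next
    nin <- js - i + 1L; nout <- n - nin
    sin <- cs[js + 1L] - cs[i]
    sin2 <- css[js + 1L] - css[i]
    min_ <- sin / nin; mout <- (tot - sin) / nout
    ss <- pmax((sin2 - nin * min_^2) + ((tot2 - sin2) - nout * mout^2), 0)
    s2 <- pmax(ss / pmax(n - 2L, 1L), 1e-12)
    t <- abs(min_ - mout) / sqrt(s2 * (1 / nin + 1 / nout))
    k <- which.max(t)
    if (t[k] > best_t) {
      best_t <- t[k]
      best <- list(i = i, j = js[k], t = t[k])
    }
  }
  best
}

#' Segment per-bin log2 ratios by recursive binary splitting
#'
#' Recursively splits at the maximal mean-shift t statistic while it exceeds
#' `t_threshold` and both parts hold at least `min_seg_size` bins; adjacent
#' segments whose means differ by less than `merge_delta` are then merged.
#' Masked (`NA`) bins are excluded from segment statistics but remain inside
#' the segment span. Deterministic: ties resolve to the first maximal split.
#' Flatness is the fraction of bins whose segment mean satisfies
#' `|log2 ratio| < flat_threshold`.
#'
#' @param ratios data.frame chrom, start, end, ratio from
#'   [normalize_coverage()]
#' @param sample_id label for the profile
#' @param min_seg_size minimum bins per segment
#' @param t_threshold split acceptance threshold on the t statistic
#' @param merge_delta adjacent segments closer than this (log2) are merged
#' @param flat_threshold |log2| below which a segment counts as neutral
#' @return object of class `segmented_profile`: sample_id, segments
#'   (data.frame chrom, start, end, log2_ratio, n_bins), flatness,
#'   bin_segment (segment index per input bin)
#' @export
segment_ratios <- function(ratios, sample_id = "sample", min_seg_size = 5L,
                           t_threshold = 5, merge_delta = 0.1,
                           flat_threshold = 0.3) {
  segs <- list()
  bin_seg <- rep(NA_integer_, nrow(ratios))
  for (chrom in unique(ratios$chrom)) {
    idx <- which(ratios$chrom == chrom)
    keep <- idx[!is.na(ratios$ratio[idx])]
    if (!length(keep)) next
    x <- ratios$ratio[keep]
    bounds <- recurse_split(smooth_outliers(x), min_seg_size, t_threshold)
    bounds <- merge_segments(x, bounds, merge_delta)
    for (b in bounds) {
      bi <- keep[b[1]:b[2]]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = ratios$start[bi[1]],
        end = ratios$end[bi[length(bi)]],
        log2_ratio = mean(ratios$ratio[bi]), n_bins = length(bi),
        stringsAsFactors = FALSE)
      bin_seg[bi] <- length(segs)
    }
  }
  segments <- do.call(rbind, segs)
  seg_of_bin <- segments$log2_ratio[bin_seg]
  flatness <- mean(abs(seg_of_bin[!is.na(seg_of_bin)]) < flat_threshold)
  structure(list(sample_id = sample_id, segments = segments,
                 flatness = flatness, bin_segment = bin_seg,
                 flat_threshold = flat_threshold),
            class = "segmented_profile")
}

# Outlier smoothing for breakpoint *detection* only (segment means are
# always computed from the raw ratios): a bin deviating from its local
# running median by more than k robust SDs is pulled to that median plus
# k SDs, so single noisy low-coverage targets cannot drag a boundary.
smooth_outliers <- function(x, half_window = 2L, k = 3) {
  n <- length(x)
  if (n < 2L * half_window + 1L) return(x)
  s <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(s) || s == 0) return(x)
  med <- stats::runmed(x, 2L * half_window + 1L, endrule = "median")
  dev <- x - med
  out <- x
  big <- abs(dev) > k * s
  out[big] <- med[big] + sign(dev[big]) * k * s
  out
}

recurse_split <- function(x, min_seg, t_threshold) {
  seg_rec <- function(lo, hi) {
    sp <- best_segment(x[lo:hi], min_seg)
    if (is.null(sp) || sp$t < t_threshold) return(list(c(lo, hi)))
    i <- lo + sp$i - 1L; j <- lo + sp$j - 1L
    out <- list()
    if (i > lo) out <- c(out, seg_rec(lo, i - 1L))
    out <- c(out, seg_rec(i, j))
    if (j < hi) out <- c(out, seg_rec(j + 1L, hi))
    out
  }
  seg_rec(1L, length(x))
}

merge_segments <- function(x, bounds, merge_delta) {
  repeat {
    if (length(bounds) < 2L) return(bounds)
    means <- vapply(bounds, function(b) mean(x[b[1]:b[2]]), 0)
    d <- abs(diff(means))
    if (!length(d) || min(d) >= merge_delta) return(bounds)
    i <- which.min(d)
    bounds[[i]] <- c(bounds[[i]][1], bounds[[i + 1L]][2])
    bounds[[i + 1L]] <- NULL
  }
}

#' @export
print.segmented_profile <- function(x, ...) {
  cat(sprintf("<segmented_profile> %s: %d segment(s), flatness %.3f\n",
              x$sample_id, nrow(x$segments), x$flatness))
  invisible(x)
}

#' Is a segmented profile copy-number flat?
#'
#' @param seg a [segment_ratios()] result
#' @param cutoff minimum flatness fraction to call the profile flat
#' @return logical
#' @export
is_flat_profile <- function(seg, cutoff = 0.95) {
  seg$flatness >= cutoff
}

#' Profile one sample against a coverage panel
#'
#' Convenience wrapper: normalize then segment.
#'
#' @param profile sample coverage data.frame
#' @param panel list of panel coverage data.frames
#' @param sample_id label
#' @param ... passed to [segment_ratios()]
#' @return a `segmented_profile`
#' @export
cna_profile <- function(profile, panel, sample_id = "sample", ...) {
  segment_ratios(normalize_coverage(profile, panel), sample_id = sample_id, ...)
}
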