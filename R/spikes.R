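#' Detect exon-scale non-conversion spikes in mCH data
#'
#' Slides a window of `window` consecutive eligible non-CG cytosines (both
#' strands interleaved by position) along each chromosome; a window
#' qualifies when its mean per-site methylation level (`n_meth / n_total`)
#' strictly exceeds `threshold`. Overlapping or adjacent qualifying windows
#' are merged into one region spanning the first to last member cytosine.
#'
#' @param records filtered non-CG [cytosine_records] (>= 6 informative
#'   reads), sorted by position within each chromosome.
#' @param window window size in cytosines, default 10.
#' @param threshold mean-level threshold, default 0.20 (strict inequality).
#' @return BED-style data.frame of class `"spike_regions"` (0-based
#'   half-open; sorted, disjoint) with extra columns `n_cytosines` and
#'   `mean_nonconversion`.
#' @export
detect_spikes <- function(records, window = 10L, threshold = 0.20) {
  if (any(substr(records$context, 2L, 2L) == "G"))
    stop("detect_spikes: CG-context records passed; spikes are non-CG only")
  out <- list()
  for (chrom in unique(records$chrom)) {
    r <- records[records$chrom == chrom, , drop = FALSE]
    if (is.unsorted(r$pos)) stop("detect_spikes: records not position-sorted on ", chrom)
    n <- nrow(r)
    if (n < window) next
    lev <- r$n_meth / r$n_total
    cs <- cumsum(c(0, lev))
    wmean <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
    # strict inequality, guarded against accumulated floating-point error so
    # a window at exactly the threshold never qualifies
    qual <- which(wmean > threshold + 1e-9)
    if (length(qual) == 0L) next
    grp <- cumsum(c(1L, diff(qual) > window))
    for (g in split(qual, grp)) {
      first <- min(g)
      last <- max(g) + window - 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = r$pos[first] - 1L,
        end = r$pos[last],
        n_cytosines = last - first + 1L,
        mean_nonconversion = mean(lev[first:last]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = integer(),
                      strand = character(), n_cytosines = integer(),
                      mean_nonconversion = numeric())
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$chrom, res$start), , drop = FALSE]
    res <- data.frame(chrom = res$chrom, start = res$start, end = res$end,
                      name = sprintf("spike_%03d", seq_len(nrow(res))),
                      score = 0L, strand = ".",
                      n_cytosines = res$n_cytosines,
                      mean_nonconversion = res$mean_nonconversion,
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  class(res) <- c("spike_regions", "data.frame")
  res
}

#' Annotate spike regions against exon intervals
#'
#' Overlap is any shared base. Reports, per spike, the identifiers of
#' overlapping exons, and summary counts: spikes overlapping at least one
#' exon and distinct exons containing at least one spike.
#'
#' @param spikes output of [detect_spikes].
#' @param exons exon intervals (BED-style data.frame with `name` column,
#'   0-based half-open), on the same assembly.
#' @return list with `spikes` (the input plus an `overlapping_features`
#'   character column, comma-separated), `n_spikes_in_exons`, and
#'   `n_exons_hit`.
#' @export
annotate_spikes <- function(spikes, exons) {
  feats <- character(nrow(spikes))
  hit_exons <- character()
  if (nrow(spikes) > 0L && nrow(exons) > 0L) {
    for (chrom in unique(spikes$chrom)) {
      si <- which(spikes$chrom == chrom)
      ei <- which(exons$chrom == chrom)
      if (length(ei) == 0L) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(spikes$start[si] + 1L, spikes$end[si]),
        IRanges::IRanges(exons$start[ei] + 1L, exons$end[ei]))
      if (length(ov) == 0L) next
      by_spike <- split(exons$name[ei][S4Vectors::subjectHits(ov)],
                        S4Vectors::queryHits(ov))
      for (k in names(by_spike)) {
        feats[si[as.integer(k)]] <- paste(by_spike[[k]], collapse = ",")
      }
      hit_exons <- c(hit_exons, exons$name[ei][S4Vectors::subjectHits(ov)])
    }
  }
  ann <- spikes
  ann$overlapping_features <- feats
  list(spikes = ann,
       n_spikes_in_exons = sum(feats != ""),
       n_exons_hit = length(unique(hit_exons)))
}
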