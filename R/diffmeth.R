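#' Differential methylation test at one CpG
#'
#' Tests the 2x2 contingency table {methylated, unmethylated} x
#' {sample 1, sample 2}. When any expected cell count (from the table
#' margins) is below ten, Fisher's exact test (two-sided, summing
#' hypergeometric tables no more probable than the observed one) is used;
#' otherwise a Pearson chi-square test with 1 degree of freedom and no
#' continuity correction. A zero margin yields `p = 1`, flagged
#' `"degenerate"`.
#'
#' @param counts1,counts2 integer pairs `c(n_meth, n_unmeth)` for the two
#'   samples.
#' @return list with `test_used` (`"fisher"`, `"chisq"`, or
#'   `"degenerate"`), `p`, and `delta` (level of sample 2 minus sample 1).
#' @export
dm_test <- function(counts1, counts2) {
  tab <- rbind(counts1, counts2)
  n1 <- sum(counts1)
  n2 <- sum(counts2)
  delta <- if (n1 > 0 && n2 > 0) counts2[1L] / n2 - counts1[1L] / n1 else
    NA_real_
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(test_used = "degenerate", p = 1, delta = delta))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 10)) {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    e <- expected
    x2 <- sum((tab - e)^2 / e)
    p <- stats::pchisq(x2, df = 1L, lower.tail = FALSE)
    test <- "chisq"
  }
  list(test_used = test, p = min(p, 1), delta = delta)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment; `q >= p`, monotone
#' non-decreasing in rank order.
#'
#' @param p numeric vector of p-values in `[0,1]`.
#' @return vector of q-values.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("fdr_adjust: p outside [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-CpG differential methylation between two samples
#'
#' Matches CG positions present in both record tables (same chromosome,
#' position and strand; positions genotype-excluded in either sample are
#' dropped, mirroring the homozygous-CG requirement), applies [dm_test] at
#' each, and adjusts p-values with [fdr_adjust]. The chi-square branch is
#' computed vectorised; Fisher rows individually.
#'
#' @param records1,records2 filtered CG-context [cytosine_records].
#' @return data.frame with `chrom`, `pos`, `strand`, counts for both
#'   samples, `test_used`, `p`, `q`, `delta` (sample 2 minus sample 1
#'   methylation level).
#' @export
dm_scan <- function(records1, records2) {
  k1 <- paste(records1$chrom, records1$pos, records1$strand)
  k2 <- paste(records2$chrom, records2$pos, records2$strand)
  m <- match(k1, k2)
  sel <- which(!is.na(m) & !records1$exclude_flag &
                 !records2$exclude_flag[m])
  r1 <- records1[sel, , drop = FALSE]
  r2 <- records2[m[sel], , drop = FALSE]
  a <- r1$n_meth; b <- r1$n_total - r1$n_meth
  c_ <- r2$n_meth; d <- r2$n_total - r2$n_meth
  N <- a + b + c_ + d
  # expected counts from margins
  e11 <- (a + b) * (a + c_) / N
  e12 <- (a + b) * (b + d) / N
  e21 <- (c_ + d) * (a + c_) / N
  e22 <- (c_ + d) * (b + d) / N
  degen <- (a + b) == 0 | (c_ + d) == 0 | (a + c_) == 0 | (b + d) == 0
  use_fisher <- !degen & (e11 < 10 | e12 < 10 | e21 < 10 | e22 < 10)
  p <- rep(1, length(a))
  test <- ifelse(degen, "degenerate", ifelse(use_fisher, "fisher", "chisq"))
  chisq_i <- which(!degen & !use_fisher)
  if (length(chisq_i) > 0L) {
    i <- chisq_i
    x2 <- (a[i] - e11[i])^2 / e11[i] + (b[i] - e12[i])^2 / e12[i] +
      (c_[i] - e21[i])^2 / e21[i] + (d[i] - e22[i])^2 / e22[i]
    p[i] <- stats::pchisq(x2, df = 1L, lower.tail = FALSE)
  }
  for (i in which(use_fisher)) {
    p[i] <- stats::fisher.test(matrix(c(a[i], c_[i], b[i], d[i]), 2L))$p.value
  }
  p <- pmin(p, 1)
  data.frame(chrom = r1$chrom, pos = r1$pos, strand = r1$strand,
             n_meth1 = a, n_unmeth1 = b, n_meth2 = c_, n_unmeth2 = d,
             test_used = test, p = p, q = fdr_adjust(p),
             delta = c_ / (c_ + d) - a / (a + b),
             stringsAsFactors = FALSE)
}

#' Classify anchor offsets into linker / nucleosome phase bands
#'
#' From the wavelet-identified first peak (linker) and valley (nucleosome)
#' offsets, band centres are extended periodically at the oscillation
#' period `P`; each offset is assigned to the band of the nearest centre
#' when within `P/4` of it, separately per side of the anchor (each side
#' uses its own extrema). Offsets near neither centre, at zero, or on a
#' side without located extrema are `"unassigned"`. Linker and nucleosome
#' bands are disjoint by construction.
#'
#' @param metrics an [nucleosome_influence] result.
#' @param halfwidth profile half-width in bases.
#' @param period override the period (defaults to `metrics$period`).
#' @return data.frame with `offset` and `phase`
#'   (`linker` / `nucleosome` / `unassigned`).
#' @export
phase_classification <- function(metrics, halfwidth = 2000L, period = NULL) {
  P <- if (is.null(period)) metrics$period else period
  if (is.na(P) || P <= 0) stop("phase_classification: no usable period")
  offsets <- seq.int(-halfwidth, halfwidth)
  phase <- rep("unassigned", length(offsets))
  assign_side <- function(side, sel) {
    pk <- metrics$peak_offset[[side]]
    vl <- metrics$valley_offset[[side]]
    if (is.na(pk) || is.na(vl)) return()
    x <- offsets[sel]
    d_pk <- abs((x - pk + P / 2) %% P - P / 2)
    d_vl <- abs((x - vl + P / 2) %% P - P / 2)
    lab <- rep("unassigned", length(x))
    lab[d_pk <= P / 4 & d_pk < d_vl] <- "linker"
    lab[d_vl <= P / 4 & d_vl < d_pk] <- "nucleosome"
    phase[sel] <<- lab
  }
  assign_side("downstream", offsets > 0)
  assign_side("upstream", offsets < 0)
  data.frame(offset = offsets, phase = phase, stringsAsFactors = FALSE)
}

#' Enrichment of methylation gains/losses by nucleosome phase
#'
#' Maps significant differential-methylation positions into anchor windows
#' (offsets oriented by anchor strand), labels each with its
#' linker/nucleosome phase band, and tests the 2x2 table
#' (gain/loss x linker/nucleosome) with a two-sided Fisher test. The odds
#' ratio is the cross-product ratio with a Haldane correction (+0.5 to
#' every cell) when any cell is zero; `odds_ratio > 1` means gains favour
#' linker DNA and losses nucleosome-occupied DNA.
#'
#' @param dm output of [dm_scan].
#' @param metrics an [nucleosome_influence] result for the anchor set.
#' @param anchors stranded anchor motif intervals.
#' @param halfwidth anchor window half-width.
#' @param q_threshold significance threshold on the FDR-adjusted q.
#' @param period optional period override for [phase_classification].
#' @return list with `table` (2x2 counts), `odds_ratio`, `p`, and
#'   `n_significant`.
#' @export
phase_enrichment <- function(dm, metrics, anchors, halfwidth = 2000L,
                             q_threshold = 0.05, period = NULL) {
  sig <- dm[!is.na(dm$q) & dm$q < q_threshold & dm$delta != 0, , drop = FALSE]
  if (nrow(sig) == 0L)
    stop("phase_enrichment undefined: no significant positions")
  centers <- anchor_centers(anchors)
  off <- rep(NA_real_, nrow(sig))
  for (chrom in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == chrom)
    si <- which(sig$chrom == chrom)
    if (length(si) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sig$pos[si], width = 1L),
      IRanges::IRanges(centers[ai] - halfwidth, centers[ai] + halfwidth),
      select = "first")
    hit <- !is.na(ov)
    a <- ai[ov[hit]]
    off[si[hit]] <- ifelse(anchors$strand[a] == "-",
                           centers[a] - sig$pos[si][hit],
                           sig$pos[si][hit] - centers[a])
  }
  phases <- phase_classification(metrics, halfwidth, period)
  lab <- rep(NA_character_, nrow(sig))
  ok <- !is.na(off)
  lab[ok] <- phases$phase[match(off[ok], phases$offset)]
  keep <- !is.na(lab) & lab != "unassigned"
  direction <- ifelse(sig$delta > 0, "gain", "loss")
  tab <- table(factor(direction[keep], levels = c("gain", "loss")),
               factor(lab[keep], levels = c("linker", "nucleosome")))
  if (sum(tab) == 0L)
    stop("phase_enrichment undefined: no significant positions in phase bands")
  ft <- stats::fisher.test(tab)
  m <- tab
  if (any(m == 0L)) m <- m + 0.5   # Haldane correction
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(table = tab, odds_ratio = unname(or), p = ft$p.value,
       n_significant = nrow(sig))
}
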