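#' Call methylated non-CG cytosines against the conversion-error background
#'
#' Under-conversion makes every unmethylated cytosine appear methylated in a
#' fraction `e` of its reads, so apparent mCH must be tested against a
#' Binomial(`n_total`, `e`) background. A non-CG cytosine is called
#' methylated iff it has at least two unconverted reads and its unconverted
#' count exceeds the background mean by more than two standard deviations:
#' `n_meth >= 2` and `n_meth > n_total * e + 2 * sqrt(n_total * e * (1-e))`.
#'
#' `e` should be the under-conversion rate estimated from the same sample's
#' unmethylated spike-in control (see [estimate_conversion]).
#'
#' The optional `exact` mode replaces the normal-approximation margin with
#' the exact binomial tail: called iff `n_meth >= 2` and
#' `P(Binomial(n_total, e) >= n_meth) < 1 - pnorm(2)`. It is never more
#' permissive than the default rule at the same `e`.
#'
#' @param records filtered non-CG [cytosine_records] (>= 6 informative
#'   reads); passing CG-context records is an error.
#' @param e background unconverted-read rate in (0, 1).
#' @param exact use the exact binomial tail instead of the 2-SD margin.
#' @return the records with columns `called` (logical) and `margin` (the
#'   2-SD count threshold) appended; attribute `"background_rate"` holds `e`.
#' @export
call_mch <- function(records, e, exact = FALSE) {
  if (any(substr(records$context, 2L, 2L) == "G"))
    stop("call_mch: CG-context records passed; mCH calling is non-CG only")
  if (!(e > 0 && e < 1)) stop("call_mch: background rate e must be in (0,1)")
  n <- records$n_total
  margin <- n * e + 2 * sqrt(n * e * (1 - e))
  if (exact) {
    tail_p <- stats::pbinom(records$n_meth - 1L, n, e, lower.tail = FALSE)
    called <- records$n_meth >= 2L & tail_p < (1 - stats::pnorm(2))
  } else {
    called <- records$n_meth >= 2L & records$n_meth > margin
  }
  out <- records
  out$margin <- margin
  out$called <- called
  attr(out, "background_rate") <- e
  class(out) <- c("mch_calls", class(records))
  out
}

#' Genome-wide mCH fraction
#'
#' The fraction of methylated non-CG cytosines: number of called sites
#' divided by the number of non-CG cytosines read with adequate coverage
#' (the eligible set, i.e. the rows of the call table).
#'
#' @param calls output of [call_mch] over the eligible records.
#' @return a single fraction.
#' @export
mch_fraction <- function(calls) {
  if (nrow(calls) == 0L) stop("mch_fraction undefined: no eligible records")
  mean(calls$called)
}

#' Sequence context of called mCH sites
#'
#' Extracts the 11-mer centred on each called cytosine (position 6) from the
#' reference, reverse-complemented for minus-strand calls, and summarises
#' the dinucleotide (CA/CC/CT) and trinucleotide context fractions plus a
#' per-position base-frequency matrix with Shannon information content
#' (`2 - entropy`, bits).
#'
#' @param calls output of [call_mch]; only rows with `called = TRUE` are
#'   used. All calls must be on one chromosome matching `reference`.
#' @param reference the chromosome sequence as a single character string or
#'   a [Biostrings::DNAString].
#' @return list with `dinucleotide` and `trinucleotide` named fraction
#'   vectors, `context_matrix` (4 x 11 base frequencies), an
#'   `information_content` vector (bits, length 11), `n_used` and
#'   `n_skipped` (calls within 5 bases of a contig edge are skipped).
#' @export
context_composition <- function(calls, reference) {
  reference <- as.character(reference)
  hits <- calls[calls$called, , drop = FALSE]
  if (nrow(hits) == 0L) stop("context_composition: no called sites")
  L <- nchar(reference)
  ok <- hits$pos > 5L & hits$pos <= L - 5L
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    warning(n_skipped, " call(s) within 5 bases of a contig edge skipped")
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) == 0L) stop("context_composition: no usable called sites")

  mers <- substring(reference, hits$pos - 5L, hits$pos + 5L)
  minus <- hits$strand == "-"
  if (any(minus)) {
    mers[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(mers[minus])))
  }
  mat <- matrix(unlist(strsplit(mers, "", fixed = TRUE)), nrow = 11L)
  freq <- vapply(seq_len(11L), function(i) {
    tab <- table(factor(mat[i, ], levels = BASES))
    as.numeric(tab) / ncol(mat)
  }, numeric(4L))
  rownames(freq) <- BASES
  ent <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  dinuc <- table(substring(mers, 6L, 7L)) / length(mers)
  trinuc <- table(substring(mers, 6L, 8L)) / length(mers)
  list(dinucleotide = c(dinuc),
       trinucleotide = c(trinuc),
       context_matrix = freq,
       information_content = 2 - ent,
       n_used = length(mers),
       n_skipped = n_skipped)
}

#' Depletion of mCH calls from lamina-associated domains
#'
#' Tests whether called mCH sites are under-represented inside LADs relative
#' to the eligible non-CG sites. Under the null, the number of calls inside
#' LADs is Binomial(number of calls, fraction of eligible sites in LADs);
#' the reported `p` is the one-sided lower tail `P[X <= observed]`. A
#' permutation p-value (shuffling call labels among eligible sites) is
#' reported alongside when `n_perm > 0`.
#'
#' @param calls output of [call_mch] over the eligible records (all rows are
#'   the eligible set; `called` rows are the calls).
#' @param lads LAD intervals (BED-style data.frame, 0-based half-open).
#' @param n_perm permutation replicates, default 0 (binomial test only).
#' @return list of class `"lad_depletion_test"`: `observed_in_lad`,
#'   `expected_in_lad`, `depletion_ratio`, `p` (one-sided binomial),
#'   `p_perm` (or `NA`), plus the eligible-site counts.
#' @export
lad_depletion <- function(calls, lads, n_perm = 0L) {
  if (is.null(lads) || nrow(lads) == 0L)
    stop("lad_depletion undefined: LAD set is empty")
  in_lad <- in_intervals(calls$pos, lads)
  n_elig <- nrow(calls)
  n_elig_in <- sum(in_lad)
  n_called <- sum(calls$called)
  if (n_called == 0L) stop("lad_depletion undefined: no calls")
  p_in <- n_elig_in / n_elig
  observed <- sum(calls$called & in_lad)
  expected <- n_called * p_in
  p <- stats::pbinom(observed, n_called, p_in)
  p_perm <- NA_real_
  if (n_perm > 0L) {
    draws <- stats::rhyper(n_perm, n_elig_in, n_elig - n_elig_in, n_called)
    p_perm <- (1 + sum(draws <= observed)) / (n_perm + 1)
  }
  out <- list(observed_in_lad = observed,
              expected_in_lad = expected,
              depletion_ratio = if (expected > 0) observed / expected else NA_real_,
              p = p,
              p_perm = p_perm,
              n_called = n_called,
              n_eligible = n_elig,
              n_eligible_in_lad = n_elig_in)
  class(out) <- "lad_depletion_test"
  out
}

#' @export
print.lad_depletion_test <- function(x, ...) {
  cat(sprintf(
    "LAD depletion of mCH calls\n  calls in LADs: %d observed vs %.1f expected (ratio %.3f)\n  one-sided binomial p = %.3g%s\n",
    x$observed_in_lad, x$expected_in_lad, x$depletion_ratio, x$p,
    if (is.na(x$p_perm)) "" else sprintf("; permutation p = %.3g", x$p_perm)))
  invisible(x)
}
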