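test_that("the 2-SD call rule requires two reads and beats the background", {
  # n=10, e=0.003: margin = 0.03 + 2*sqrt(10*0.003*0.997) ~ 0.376 < 2,
  # so two unconverted reads suffice
  r <- rec(c(2L, 1L, 0L), rep(10L, 3))
  calls <- call_mch(r, e = 0.003)
  expect_equal(calls$called, c(TRUE, FALSE, FALSE))
  expect_equal(calls$margin[1], 10 * 0.003 + 2 * sqrt(10 * 0.003 * 0.997))

  # exact-mode decision agrees with the exact binomial tail here
  exact <- call_mch(r, e = 0.003, exact = TRUE)
  expect_equal(exact$called[1],
               pbinom(1, 10, 0.003, lower.tail = FALSE) < 1 - pnorm(2))

  expect_error(call_mch(rec(1L, 10L, context = "CGA"), 0.003), "CG")
  expect_error(call_mch(r, e = 0), "\\(0,1\\)")
})

test_that("calling is monotone in the unconverted read count", {
  for (e in c(0.001, 0.003, 0.01)) {
    for (n in c(6L, 10L, 30L, 100L, 250L)) {
      r <- rec(0:n, rep(n, n + 1L), pos = seq_len(n + 1L) * 10L)
      called <- call_mch(r, e)$called
      expect_true(all(diff(called) >= 0),
                  info = sprintf("e=%g n=%d", e, n))
      expect_true(all(diff(call_mch(r, e, exact = TRUE)$called) >= 0))
    }
  }
})

test_that("false-call rate under a null methylome matches the exact binomial", {
  set.seed(77)
  n_sites <- 2e5
  e <- 0.003
  n_total <- rpois(n_sites, 30)
  n_total <- n_total[n_total >= 6L]
  r <- cytosine_records("chr1", seq_along(n_total) * 3L, "+", "CAA",
                        rbinom(length(n_total), n_total, e), n_total)
  observed <- mean(call_mch(r, e)$called)

  # brute-force oracle: per site, the exact exceedance probability of the
  # smallest count satisfying the rule
  kmin <- vapply(sort(unique(n_total)), function(n) {
    margin <- n * e + 2 * sqrt(n * e * (1 - e))
    k <- 0L
    while (!(k >= 2L && k > margin)) k <- k + 1L
    k
  }, integer(1))
  names(kmin) <- sort(unique(n_total))
  p_site <- pbinom(kmin[as.character(n_total)] - 1L, n_total, e,
                   lower.tail = FALSE)
  expected <- mean(p_site)
  se <- sqrt(sum(p_site * (1 - p_site))) / length(p_site)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("mCH fraction is calls over eligible sites", {
  r <- rec(c(0L, 0L, 5L, 0L), rep(10L, 4))
  calls <- call_mch(r, 0.003)
  expect_equal(mch_fraction(calls), 0.25)
  none <- call_mch(rec(rep(0L, 4), rep(10L, 4)), 0.003)
  expect_equal(mch_fraction(none), 0)
  expect_error(mch_fraction(calls[0, ]), "eligible")
})

test_that("context composition extracts oriented 11-mers and information content", {
  # reference with CAC sites embedded in T runs; cytosines at 11, 31
  ref <- paste(rep("T", 60), collapse = "")
  substr(ref, 9, 15) <- "TTCACTT"
  substr(ref, 29, 35) <- "TTCACTT"
  calls <- call_mch(rec(c(5L, 5L), c(10L, 10L), context = "CAC",
                        pos = c(11L, 31L)), 0.003)
  comp <- context_composition(calls, ref)
  expect_equal(unname(comp$dinucleotide["CA"]), 1)
  expect_equal(unname(comp$trinucleotide["CAC"]), 1)
  expect_equal(comp$information_content[[7]], 2)   # all 'A' after the C
  expect_equal(unname(comp$context_matrix["C", 6]), 1)

  # a uniformly varying column carries zero information
  ref2 <- paste(rep("T", 80), collapse = "")
  bases <- c("A", "C", "G", "T")
  pos <- c(11L, 31L, 51L, 71L)
  for (i in 1:4) substr(ref2, pos[i], pos[i] + 2) <- paste0("CA", bases[i])
  calls2 <- call_mch(rec(rep(5L, 4), rep(10L, 4),
                         context = paste0("CA", bases), pos = pos), 0.003)
  comp2 <- context_composition(calls2, ref2)
  expect_equal(comp2$information_content[[8]], 0)
  expect_equal(comp2$information_content[[7]], 2)

  # minus-strand calls are read on their own strand (reverse complement)
  ref3 <- paste0(paste(rep("T", 10), collapse = ""), "GTG",
                 paste(rep("T", 10), collapse = ""))
  callm <- call_mch(rec(5L, 10L, context = "CAC", pos = 13L, strand = "-"),
                    0.003)
  comp3 <- context_composition(callm, ref3)
  expect_equal(unname(comp3$trinucleotide["CAC"]), 1)

  # edge sites are skipped with a warning
  calle <- call_mch(rec(c(5L, 5L), c(10L, 10L), context = "CAC",
                        pos = c(3L, 31L)), 0.003)
  expect_warning(comp4 <- context_composition(calle, ref), "edge")
  expect_equal(comp4$n_skipped, 1L)
})

test_that("LAD depletion test: closed form, null behaviour, permutation", {
  lads <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  # 3000 eligible sites, one third in the LAD; 1000 calls, none inside
  pos <- seq_len(3000L)
  called <- rep(c(FALSE, TRUE), c(2000L, 1000L))  # calls at pos 2001..3000
  calls <- rec(ifelse(called, 5L, 0L), rep(10L, 3000L), pos = pos)
  calls <- call_mch(calls, 0.003)
  res <- lad_depletion(calls, lads)
  expect_equal(res$observed_in_lad, 0L)
  expect_equal(res$expected_in_lad, 1000 / 3)
  expect_equal(log(res$p), 1000 * log(2 / 3))
  expect_lt(res$p, 1e-6)

  # null: calls scattered uniformly over eligible sites
  set.seed(5)
  called_u <- sample(c(TRUE, FALSE), 3000L, TRUE, prob = c(0.2, 0.8))
  calls_u <- call_mch(rec(ifelse(called_u, 5L, 0L), rep(10L, 3000L),
                          pos = pos), 0.003)
  res_u <- lad_depletion(calls_u, lads)
  expect_gt(res_u$depletion_ratio, 0.8)
  expect_lt(res_u$depletion_ratio, 1.2)
  expect_gt(res_u$p, 0.001)

  expect_error(lad_depletion(calls, lads[0, ]), "empty")
})

test_that("binomial-tail p agrees with a large permutation p on small instances", {
  set.seed(12)
  pos <- seq_len(600L)
  lads <- data.frame(chrom = "chr1", start = 0L, end = 200L)
  called <- rep(FALSE, 600L)
  called[sample.int(600L, 40L)] <- TRUE
  calls <- call_mch(rec(ifelse(called, 5L, 0L), rep(10L, 600L), pos = pos),
                    0.003)
  res <- lad_depletion(calls, lads, n_perm = 1e5)
  mc_se <- sqrt(res$p * (1 - res$p) / 1e5)
  # binomial (with replacement) vs permutation (without): close but not
  # identical on a 600-site instance; allow the hypergeometric correction
  expect_lt(abs(res$p - res$p_perm), max(5 * mc_se, 0.05 * res$p + 0.005))
})
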