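fisher_oracle <- function(tab) {
  # full enumeration of 2x2 tables with the observed margins: two-sided p
  # is the total probability of tables no more likely than the observed one
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  x <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(x, c1, N - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("the test switches between Fisher and chi-square on expected counts", {
  # complete separation with margins 10/10: both extreme tables
  res <- dm_test(c(10L, 0L), c(0L, 10L))
  expect_equal(res$test_used, "fisher")
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$delta, -1)

  expect_equal(dm_test(c(5L, 5L), c(5L, 5L))$p, 1)

  big <- dm_test(c(40L, 40L), c(40L, 40L))
  expect_equal(big$test_used, "chisq")
  expect_equal(big$p, 1)

  # expected counts from margins, not observed cells, drive the switch
  mixed <- dm_test(c(19L, 21L), c(2L, 38L))  # min expected = 40*21/80 > 10
  expect_equal(mixed$test_used, "chisq")

  degen <- dm_test(c(0L, 10L), c(0L, 10L))
  expect_equal(degen$test_used, "degenerate")
  expect_equal(degen$p, 1)
})

test_that("Fisher branch equals the enumeration oracle for margins <= 15", {
  set.seed(55)
  for (i in 1:200) {
    n1 <- sample(1:15, 1); n2 <- sample(1:15, 1)
    a <- sample(0:n1, 1); c_ <- sample(0:n2, 1)
    res <- dm_test(c(a, n1 - a), c(c_, n2 - c_))
    if (res$test_used != "fisher") next
    tab <- rbind(c(a, n1 - a), c(c_, n2 - c_))
    expect_equal(res$p, fisher_oracle(tab), tolerance = 1e-10,
                 info = paste(a, n1, c_, n2))
  }
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(fdr_adjust(0.05), 0.05)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("dm_scan matches positions, drops excluded, controls the null FDR", {
  set.seed(66)
  n <- 10000L
  pos <- seq_len(n) * 50L
  p0 <- 0.7
  mk <- function() {
    nt <- rpois(n, 30)
    cytosine_records("chr1", pos, "+", "CGA", rbinom(n, nt, p0), nt)
  }
  r1 <- mk()
  r2 <- mk()
  r1$exclude_flag[1:100] <- TRUE
  dm <- dm_scan(r1, r2)
  expect_equal(nrow(dm), n - 100L)
  # same generating methylome: essentially nothing passes BH at 5%
  frac_sig <- mean(dm$q < 0.05, na.rm = TRUE)
  expect_lte(frac_sig, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(dm)))

  # per-row results agree with the scalar test
  i <- which(dm$test_used == "fisher")[1]
  if (!is.na(i)) {
    expect_equal(dm$p[i],
                 dm_test(c(dm$n_meth1[i], dm$n_unmeth1[i]),
                         c(dm$n_meth2[i], dm$n_unmeth2[i]))$p)
  }
  j <- which(dm$test_used == "chisq")[1]
  expect_equal(dm$p[j],
               dm_test(c(dm$n_meth1[j], dm$n_unmeth1[j]),
                       c(dm$n_meth2[j], dm$n_unmeth2[j]))$p)

  # unmatched positions are dropped
  r3 <- mk()
  r3$pos <- r3$pos + 7L
  expect_equal(nrow(dm_scan(r1, r3)), 0L)
})

# Extrema of the generating sine A*sin(2*pi*(x - 87.5)/175): the phase runs
# continuously through the anchor, so the first upstream peak sits at
# -43.75, not at the mirror image of the downstream peak (131.25).
fake_metrics <- function(P = 175) {
  structure(list(
    peak_offset = c(upstream = -43.75, downstream = 131.25),
    valley_offset = c(upstream = -131.25, downstream = 43.75),
    period = P), class = "oscillation_metrics")
}

test_that("phase bands are disjoint and follow the extended extrema", {
  ph <- phase_classification(fake_metrics(), halfwidth = 1000L)
  expect_equal(ph$phase[ph$offset == 131L], "linker")
  expect_equal(ph$phase[ph$offset == 44L], "nucleosome")
  expect_equal(ph$phase[ph$offset == -44L], "linker")
  expect_equal(ph$phase[ph$offset == -131L], "nucleosome")
  # one period further out
  expect_equal(ph$phase[ph$offset == 131L + 175L], "linker")
  expect_equal(ph$phase[ph$offset == 0L], "unassigned")
  expect_true(all(ph$phase %in% c("linker", "nucleosome", "unassigned")))
  expect_error(phase_classification(fake_metrics(NA)), "period")
})

test_that("gains at linkers and losses at nucleosomes give an odds ratio > 1", {
  # two stages sharing a baseline; stage 2 oscillates more strongly
  off <- -2000:2000
  P <- 175
  p1 <- 0.72 + 0.02 * sin(2 * pi * (off - 87.5) / P)
  p2 <- 0.70 + 0.08 * sin(2 * pi * (off - 87.5) / P)
  set.seed(88)
  n_reads <- 3000L
  center <- 50000L
  pos <- center + off
  mk <- function(p) {
    nt <- rep(n_reads, length(off))
    cytosine_records("chr1", pos, "+", "CGA", rbinom(length(off), nt, p), nt)
  }
  dm <- dm_scan(mk(p1), mk(p2))
  anchors <- data.frame(chrom = "chr1", start = center - 10L,
                        end = center + 9L, name = "a", score = 0L,
                        strand = "+")
  enr <- phase_enrichment(dm, fake_metrics(), anchors, halfwidth = 2000L)
  expect_gt(enr$odds_ratio, 1)
  expect_lt(enr$p, 1e-3)
  # gains concentrate in linker bands, losses in nucleosome bands
  expect_gt(enr$table["gain", "linker"], enr$table["gain", "nucleosome"])
  expect_gt(enr$table["loss", "nucleosome"], enr$table["loss", "linker"])

  # perfectly balanced significant changes: odds ratio 1
  dm_bal <- data.frame(
    chrom = "chr1",
    pos = center + c(131L, 131L + P, 44L, 44L + P,
                     131L + 2L * P, -131L, 44L + 2L * P, -44L),
    strand = "+",
    q = rep(0.001, 8),
    delta = rep(c(0.1, 0.1, 0.1, 0.1, -0.1, -0.1, -0.1, -0.1)))
  bal <- phase_enrichment(dm_bal, fake_metrics(), anchors,
                          halfwidth = 2000L)
  expect_equal(bal$odds_ratio, 1)

  expect_error(phase_enrichment(dm_bal[0, ], fake_metrics(), anchors),
               "no significant")
})
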