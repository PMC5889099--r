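test_that("occupancy classification applies the 95% rule and specificity", {
  types <- paste0("ct", 1:20)
  presence <- matrix(FALSE, 5, 20, dimnames = list(NULL, types))
  presence[1, ] <- TRUE                    # all 20 -> constitutive
  presence[2, 1:19] <- TRUE                # 19/20 = 0.95 -> constitutive
  presence[3, "ct1"] <- TRUE               # focal only -> focal-specific
  presence[4, "ct5"] <- TRUE               # specific elsewhere -> unoccupied
  # row 5: absent everywhere -> other
  cls <- classify_sites(presence, focal_type = "ct1",
                        reference_types = c("ct2", "ct3"))
  expect_equal(cls, c("constitutive", "constitutive",
                      "cell_type_specific:ct1", "unoccupied", "other"))
  expect_error(classify_sites(presence, focal_type = "nope",
                              reference_types = "ct2"), "unknown")
})

single_anchor <- function(strand) {
  data.frame(chrom = "chr1", start = 1000L, end = 1019L, name = "a",
             score = 0L, strand = strand, class = "constitutive")
}

test_that("profiles are anchored at the motif centre and mirror minus strands", {
  # centre = floor((1001 + 1019) / 2) = 1010
  r <- rec(3L, 6L, context = "CGA", pos = 1020L)
  p <- aggregate_profile(r, single_anchor("+"), halfwidth = 400L,
                         context_filter = "CG")
  expect_equal(p$value[p$offset == 10L], 0.5)
  expect_equal(sum(!is.na(p$value)), 1L)

  pm <- aggregate_profile(r, single_anchor("-"), halfwidth = 400L,
                          context_filter = "CG")
  expect_equal(pm$value[pm$offset == -10L], 0.5)
})

test_that("pooled aggregation is read-weighted; mean mode is site-weighted", {
  anchors <- rbind(single_anchor("+"), single_anchor("+"))
  anchors$start <- c(1000L, 2000L)
  anchors$end <- c(1019L, 2019L)
  r <- rec(c(3L, 0L), c(6L, 6L), context = "CGA", pos = c(1020L, 2020L))
  pooled <- aggregate_profile(r, anchors, halfwidth = 400L,
                              context_filter = "CG")
  expect_equal(pooled$value[pooled$offset == 10L], 0.25)
  expect_equal(pooled$n_obs[pooled$offset == 10L], 12)
  m <- aggregate_profile(r, anchors, halfwidth = 400L, mode = "mean",
                         context_filter = "CG")
  expect_equal(m$value[m$offset == 10L], 0.25)
})

test_that("strand mirroring is an involution and flips the profile", {
  r <- random_records(2000, seed = 19)
  anchors <- data.frame(chrom = "chr1",
                        start = c(2e5L, 5e5L, 8e5L),
                        end = c(2e5L, 5e5L, 8e5L) + 19L,
                        name = c("a", "b", "c"), score = 0L,
                        strand = c("+", "-", "+"))
  flip <- function(a) {
    a$strand <- ifelse(a$strand == "+", "-", "+")
    a
  }
  p0 <- aggregate_profile(r, anchors, halfwidth = 500L, context_filter = "all",
                          strand_resolved = TRUE)
  p2 <- aggregate_profile(r, flip(flip(anchors)), halfwidth = 500L,
                          context_filter = "all", strand_resolved = TRUE)
  expect_identical(p0, p2)
  p1 <- aggregate_profile(r, flip(anchors), halfwidth = 500L,
                          context_filter = "all", strand_resolved = TRUE)
  expect_equal(p1$value, rev(p0$value))
  expect_equal(p1$value_motif, rev(p0$value_opposite))
})

test_that("anchors with out-of-bounds windows are skipped with a warning", {
  r <- rec(3L, 6L, context = "CGA", pos = 1020L)
  near_edge <- single_anchor("+")
  expect_warning(
    expect_error(aggregate_profile(r, near_edge, halfwidth = 2000L,
                                   context_filter = "CG"), "no usable"),
    "skipped")
  anchors <- rbind(single_anchor("+"), single_anchor("+"))
  anchors$start[2] <- 5000L
  anchors$end[2] <- 5019L
  expect_warning(p <- aggregate_profile(r, anchors, halfwidth = 2000L,
                                        context_filter = "CG"), "skipped")
  expect_equal(attr(p, "n_skipped"), 1L)
})

test_that("anchor motifs must have uniform length", {
  r <- rec(3L, 6L, context = "CGA", pos = 1020L)
  anchors <- rbind(single_anchor("+"), single_anchor("+"))
  anchors$end[2] <- anchors$end[2] + 4L
  expect_error(aggregate_profile(r, anchors, halfwidth = 100L), "uniform")
})

test_that("the aggregated CG profile converges to the observed-signal model", {
  sim <- moderate_sim()
  cfg <- sim$truth$config
  ann <- sim$truth$annotations
  flt <- filter_records(sim$report)
  cctcf <- ann$ctcf[ann$ctcf$class == "constitutive", ]
  prof <- aggregate_profile(flt, cctcf, halfwidth = cfg$window_halfwidth,
                            context_filter = "CG")
  p_true <- true_cg_probability(prof$offset, cfg)
  p_obs <- p_true * (1 - cfg$over_conversion_error) +
    (1 - p_true) * cfg$under_conversion_error
  ok <- !is.na(prof$value) & prof$n_obs > 0
  # mean deviation over all offsets within 3 SE of the pooled estimator
  se_mean <- sqrt(sum(p_obs[ok] * (1 - p_obs[ok]) / prof$n_obs[ok])) / sum(ok)
  expect_lt(abs(mean(prof$value[ok] - p_obs[ok])), 3 * se_mean)

  # unoccupied anchors carry no oscillation: nucleosome-scale detail
  # variance under 10% of the constitutive profile's
  unocc <- ann$ctcf[ann$ctcf$class == "unoccupied", ]
  prof_u <- aggregate_profile(flt, unocc, halfwidth = cfg$window_halfwidth,
                              context_filter = "CG")
  d_c <- mra(prof)
  d_u <- mra(prof_u)
  expect_lt(var(d_u$detail), 0.1 * var(d_c$detail))
})
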