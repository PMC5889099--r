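# Shorthand record builder for unit tests.
rec <- function(n_meth, n_total, context = "CAA", pos = NULL, strand = "+",
                chrom = "chr1", exclude = FALSE) {
  k <- max(length(n_meth), length(n_total), length(context))
  if (length(n_meth) == 0L || length(n_total) == 0L) {
    return(cytosine_records(character(), integer(), character(),
                            character(), integer(), integer(), logical()))
  }
  if (is.null(pos)) pos <- seq_len(k) * 10L
  cytosine_records(chrom, pos, strand, context, n_meth, n_total, exclude)
}

random_records <- function(n, seed = 1) {
  set.seed(seed)
  ctx <- paste0("C", sample(c("A", "C", "G", "T"), n, TRUE),
                sample(c("A", "C", "G", "T"), n, TRUE))
  n_total <- sample(0:60, n, TRUE)
  cytosine_records("chr1", sort(sample.int(1e6, n)),
                   sample(c("+", "-"), n, TRUE), ctx,
                   rbinom(n, n_total, 0.3), n_total,
                   sample(c(TRUE, FALSE), n, TRUE, prob = c(0.05, 0.95)))
}

# A small, fast simulation configuration for tests that need a full sample
# but not the default genome scale.
small_config <- function(seed = 11L, ...) {
  args <- list(genome_length = 2e5, n_ctcf_constitutive = 10L,
               n_ctcf_specific = 3L, n_ctcf_unoccupied = 3L,
               window_halfwidth = 2000L, n_lads = 4L,
               phage_sites = 5000L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# One moderate-scale shared simulation, built lazily and cached for the
# whole test run (used by profile-convergence and phase tests).
.sim_cache <- new.env(parent = emptyenv())
moderate_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(genome_length = 1.3e6, n_ctcf_constitutive = 150L,
                      n_ctcf_specific = 20L, n_ctcf_unoccupied = 60L,
                      n_lads = 6L, phage_sites = 10000L, seed = 23L)
    .sim_cache$sim <- simulate_sample(cfg)
  }
  .sim_cache$sim
}
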