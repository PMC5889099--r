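#' Configuration of the synthetic methylome generator
#'
#' The generator emulates the statistical structure of a WGBS experiment in
#' a lymphocyte-like cell: binomial read sampling at Poisson coverage with
#' bisulfite conversion errors; a CG methylation landscape that is flat at a
#' genome-wide baseline except around occupied CTCF motifs, where it follows
#' a wide "V" trend plus a nucleosome-phased sinusoidal oscillation; diffuse
#' non-CG methylation concentrated in CA (and especially CAC) contexts and
#' excluded from lamina-associated domains; and optional exon-localised
#' non-conversion spikes. Spiked-in phage controls (fully methylated /
#' fully unmethylated) are generated alongside for conversion QC.
#'
#' The defaults define the reference study condition: a naive-T-like sample
#' that passes conversion QC, with prominent diffuse mCH, 175 bp nucleosome
#' repeat, coverage 30, under-conversion error 0.0025 (conversion rate
#' 0.9975, above the 0.997 retention threshold) and over-conversion error
#' 0.05.
#'
#' @param genome_length genome size in bases.
#' @param n_ctcf_constitutive,n_ctcf_specific,n_ctcf_unoccupied numbers of
#'   CTCF sites per occupancy class.
#' @param motif_length CTCF motif length in bases.
#' @param window_halfwidth half-width of the anchor window in bases; CTCF
#'   windows are placed non-overlapping at this spacing.
#' @param baseline_cg_meth genome-wide CG methylation baseline, in `[0,1]`.
#' @param trend_depth depth of the "V" trend at the motif centre
#'   (methylation-fraction units).
#' @param trend_halfwidth half-width of the "V" in bases; the trend decays
#'   linearly to zero at this distance.
#' @param osc_amplitude_half half peak-to-valley oscillation amplitude `A`.
#' @param nucleosome_repeat oscillation period `P` in bases (nucleosome
#'   repeat length), default 175.
#' @param phase_offset offset in bases of the oscillation phase zero from
#'   the motif centre; the default `P/2` places a methylation valley
#'   (nucleosome) adjacent to the motif-proximal dip.
#' @param coverage_mean Poisson mean of informative read coverage.
#' @param under_conversion_error probability an unmethylated cytosine is
#'   read as methylated (1 - conversion rate), default 0.0025: the rate of
#'   a sample retained under the 0.997 conversion-rate QC threshold.
#' @param over_conversion_error probability a methylated cytosine is read as
#'   converted, default 0.05.
#' @param mch_rate_in fraction of non-CG cytosines outside LADs that are
#'   truly methylated.
#' @param mch_rate_lad same, inside LADs (default 0: complete exclusion).
#' @param mch_level true methylation level of a methylated non-CG cytosine.
#' @param mch_context_weights named numeric vector over non-CG
#'   trinucleotides: the context distribution of true mCH sites. Must sum
#'   to 1. The defaults put 95.5% of true mCH in CA context and 74.6% in
#'   CAC, so that the composition observed among *called* sites - after
#'   conversion-error background calls (which carry the genomic context
#'   distribution) mix in - lands at roughly 93% CA and 72% CAC under the
#'   default coverage and error rates.
#' @param lad_fraction fraction of the genome covered by LADs, default 1/3.
#' @param n_lads number of LAD intervals.
#' @param n_exons,exon_length number and length of exon intervals.
#' @param spike_exons list of `list(exon = i, level = l)`: render the non-CG
#'   cytosines of exon `i` as a non-conversion spike at level `l`.
#' @param cg_spacing_mean mean spacing of planted CG dinucleotides in bases.
#' @param phage_sites number of cytosines per phage spike-in control.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(genome_length = 3e6,
                       n_ctcf_constitutive = 500L,
                       n_ctcf_specific = 50L,
                       n_ctcf_unoccupied = 50L,
                       motif_length = 19L,
                       window_halfwidth = 2000L,
                       baseline_cg_meth = 0.7,
                       trend_depth = 0.3,
                       trend_halfwidth = 1000L,
                       osc_amplitude_half = 0.05,
                       nucleosome_repeat = 175,
                       phase_offset = nucleosome_repeat / 2,
                       coverage_mean = 30,
                       under_conversion_error = 0.0025,
                       over_conversion_error = 0.05,
                       mch_rate_in = 0.10,
                       mch_rate_lad = 0,
                       mch_level = 0.25,
                       mch_context_weights = c(
                         CAA = 0.070, CAC = 0.746, CAG = 0.070, CAT = 0.069,
                         CCA = 0.003, CCC = 0.002, CCG = 0.002, CCT = 0.003,
                         CTA = 0.010, CTC = 0.012, CTG = 0.008, CTT = 0.005),
                       lad_fraction = 1 / 3,
                       n_lads = 10L,
                       n_exons = 20L,
                       exon_length = 150L,
                       spike_exons = list(),
                       cg_spacing_mean = 30,
                       phage_sites = 20000L,
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_ctcf_constitutive = as.integer(n_ctcf_constitutive),
              n_ctcf_specific = as.integer(n_ctcf_specific),
              n_ctcf_unoccupied = as.integer(n_ctcf_unoccupied),
              motif_length = as.integer(motif_length),
              window_halfwidth = as.integer(window_halfwidth),
              baseline_cg_meth = baseline_cg_meth,
              trend_depth = trend_depth,
              trend_halfwidth = trend_halfwidth,
              osc_amplitude_half = osc_amplitude_half,
              nucleosome_repeat = nucleosome_repeat,
              phase_offset = phase_offset,
              coverage_mean = coverage_mean,
              under_conversion_error = under_conversion_error,
              over_conversion_error = over_conversion_error,
              mch_rate_in = mch_rate_in,
              mch_rate_lad = mch_rate_lad,
              mch_level = mch_level,
              mch_context_weights = mch_context_weights,
              lad_fraction = lad_fraction,
              n_lads = as.integer(n_lads),
              n_exons = as.integer(n_exons),
              exon_length = as.integer(exon_length),
              spike_exons = spike_exons,
              cg_spacing_mean = cg_spacing_mean,
              phage_sites = as.integer(phage_sites),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fracs <- c("baseline_cg_meth", "trend_depth", "osc_amplitude_half",
             "under_conversion_error", "over_conversion_error",
             "mch_rate_in", "mch_rate_lad", "mch_level", "lad_fraction")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config: ", f, " must lie in [0,1]")
  }
  if (cfg$nucleosome_repeat <= 0) stop("sim_config: nucleosome_repeat must be > 0")
  if (abs(sum(cfg$mch_context_weights) - 1) > 1e-6)
    stop("sim_config: mch_context_weights must sum to 1")
  if (any(cfg$mch_context_weights < 0))
    stop("sim_config: mch_context_weights must be non-negative")
  if (any(substr(names(cfg$mch_context_weights), 2L, 2L) == "G"))
    stop("sim_config: mch_context_weights must be non-CG trinucleotides")
  if (cfg$window_halfwidth < 2 * cfg$nucleosome_repeat)
    stop("sim_config: window_halfwidth must be >= 2 * nucleosome_repeat")
  invisible(cfg)
}

# Places n non-overlapping intervals of the given lengths uniformly at
# random on [0, genome_length), returned sorted; 0-based half-open.
place_nonoverlapping <- function(genome_length, lengths) {
  n <- length(lengths)
  slack <- genome_length - sum(lengths)
  if (slack < 0)
    stop("genome too short to place the requested intervals (need ",
         sum(lengths), " bases, have ", genome_length, ")")
  gaps <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  starts <- gaps + cumsum(c(0L, lengths[-n]))
  data.frame(start = as.integer(starts),
             end = as.integer(starts + lengths))
}

#' Simulate genome annotations
#'
#' Draws CTCF motif sites with occupancy class labels and random strands
#' (windows of `2 * window_halfwidth + 1` bases around each motif are
#' non-overlapping), LAD intervals covering `lad_fraction` of the genome,
#' and exon intervals. Deterministic given `config$seed`.
#'
#' @param config a [sim_config].
#' @return list of class `"sim_annotations"` with BED-style data.frames
#'   `ctcf` (with `class` column), `lads`, `exons` (0-based half-open).
#' @export
simulate_annotations <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  W <- config$window_halfwidth
  span <- 2L * W + 1L

  n_sites <- config$n_ctcf_constitutive + config$n_ctcf_specific +
    config$n_ctcf_unoccupied
  ctcf <- NULL
  if (n_sites > 0L) {
    win <- place_nonoverlapping(config$genome_length, rep(span, n_sites))
    # motif centred in the window: centre position (1-based) = start + W + 1
    motif_start <- win$start + W - config$motif_length %/% 2L
    classes <- sample(rep(c("constitutive", "cell_type_specific:focal",
                            "unoccupied"),
                          c(config$n_ctcf_constitutive, config$n_ctcf_specific,
                            config$n_ctcf_unoccupied)))
    ctcf <- data.frame(
      chrom = "chr1",
      start = as.integer(motif_start),
      end = as.integer(motif_start + config$motif_length),
      name = sprintf("ctcf_%04d", seq_len(n_sites)),
      score = 0L,
      strand = sample(c("+", "-"), n_sites, replace = TRUE),
      class = classes,
      stringsAsFactors = FALSE
    )
  } else {
    ctcf <- data.frame(chrom = character(), start = integer(), end = integer(),
                       name = character(), score = integer(),
                       strand = character(), class = character())
  }

  lad_total <- round(config$lad_fraction * config$genome_length)
  if (lad_total > 0 && config$n_lads > 0L) {
    stick <- stats::rexp(config$n_lads) + 0.1
    lens <- floor(lad_total * stick / sum(stick))
    lens[1L] <- lens[1L] + (lad_total - sum(lens))  # exact total coverage
    pos <- place_nonoverlapping(config$genome_length, lens)
    lads <- data.frame(chrom = "chr1", start = pos$start, end = pos$end,
                       name = sprintf("lad_%02d", seq_len(config$n_lads)),
                       score = 0L, strand = "*", stringsAsFactors = FALSE)
  } else {
    lads <- data.frame(chrom = character(), start = integer(),
                       end = integer(), name = character(),
                       score = integer(), strand = character())
  }

  if (config$n_exons > 0L) {
    pos <- place_nonoverlapping(config$genome_length,
                                rep(config$exon_length, config$n_exons))
    exons <- data.frame(chrom = "chr1", start = pos$start, end = pos$end,
                        name = sprintf("exon_%03d", seq_len(config$n_exons)),
                        score = 0L,
                        strand = sample(c("+", "-"), config$n_exons,
                                        replace = TRUE),
                        stringsAsFactors = FALSE)
  } else {
    exons <- data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        score = integer(), strand = character())
  }

  ann <- list(ctcf = ctcf, lads = lads, exons = exons)
  class(ann) <- "sim_annotations"
  ann
}

#' True CG methylation probability around an occupied CTCF motif
#'
#' The generating model of the anchored CG profile: a genome-wide baseline,
#' minus a "V"-shaped trend that is deepest at the motif centre and decays
#' linearly to zero at `trend_halfwidth`, plus a sinusoid of period
#' `nucleosome_repeat` and half-amplitude `osc_amplitude_half` whose phase
#' places methylation peaks on linker DNA. Clipped to `[0,1]`.
#'
#' @param offset base offsets from the motif centre (anchor-oriented).
#' @param config a [sim_config].
#' @return numeric vector of methylation probabilities.
#' @export
true_cg_probability <- function(offset, config) {
  trend <- config$trend_depth *
    pmax(0, 1 - abs(offset) / config$trend_halfwidth)
  p <- config$baseline_cg_meth - trend +
    config$osc_amplitude_half *
      sin(2 * pi * (offset - config$phase_offset) / config$nucleosome_repeat)
  pmin(1, pmax(0, p))
}

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G in integer coding

# Random genome as integer codes 1..4 with no CG dinucleotides except those
# planted at geometrically spaced positions (mean spacing cg_spacing_mean).
simulate_reference <- function(genome_length, cg_spacing_mean) {
  x <- sample.int(4L, genome_length, replace = TRUE)
  repeat {
    i <- which(x[-genome_length] == 2L & x[-1L] == 3L)
    if (length(i) == 0L) break
    x[i + 1L] <- sample(c(1L, 2L, 4L), length(i), replace = TRUE)
  }
  gap_mean <- max(cg_spacing_mean - 2, 1)
  n_est <- ceiling(genome_length / cg_spacing_mean * 1.4) + 100L
  gaps <- 2L + stats::rgeom(n_est, 1 / gap_mean)
  p <- cumsum(gaps)
  p <- p[p >= 2L & p <= genome_length - 6L]
  x[p] <- 2L
  x[p + 1L] <- 3L
  x
}

# Tabulate all cytosines of an integer-coded genome (both strands), with
# 1-based position, strand, integer context code and CG flag.
enumerate_cytosines <- function(x) {
  L <- length(x)
  trinucs <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  dim(trinucs) <- NULL
  tri_name <- function(b1, b2, b3) trinucs[(b1 - 1L) * 1L +
                                             (b2 - 1L) * 4L + (b3 - 1L) * 16L + 1L]
  # plus strand: C at i, context x[i..i+2]
  ip <- which(x == 2L)
  ip <- ip[ip >= 6L & ip <= L - 6L]   # keep 11-mer context extractable
  ctx_p <- tri_name(x[ip], x[ip + 1L], x[ip + 2L])
  # minus strand: G at i, context = revcomp(x[(i-2)..i])
  im <- which(x == 3L)
  im <- im[im >= 6L & im <= L - 6L]
  ctx_m <- tri_name(COMPLEMENT[x[im]], COMPLEMENT[x[im - 1L]],
                    COMPLEMENT[x[im - 2L]])
  df <- data.frame(
    pos = c(ip, im),
    strand = rep(c("+", "-"), c(length(ip), length(im))),
    context = c(ctx_p, ctx_m),
    is_cg = c(x[ip + 1L] == 3L, x[im - 1L] == 2L),
    stringsAsFactors = FALSE
  )
  ord <- order(df$pos, df$strand)
  df[ord, , drop = FALSE]
}

in_intervals <- function(pos, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  o <- order(intervals$start)
  s1 <- intervals$start[o] + 1L   # 1-based inclusive
  e1 <- intervals$end[o]
  idx <- findInterval(pos, s1)
  idx > 0L & pos <= e1[pmax(idx, 1L)]
}

#' Simulate a WGBS sample from annotations
#'
#' Generates a reference genome, assigns every cytosine a true methylation
#' probability under the generating model (anchored CG oscillation, diffuse
#' context-weighted mCH with LAD exclusion, exon non-conversion spikes),
#' and samples read counts: `n_total ~ Poisson(coverage_mean)` and
#' `n_meth ~ Binomial(n_total, p_obs)` with
#' `p_obs = p_true * (1 - over_conversion_error) +
#' (1 - p_true) * under_conversion_error`. Phage spike-in controls are
#' generated with `p_true = 1` (methylated control) and `p_true = 0`
#' (unmethylated control).
#'
#' @param config a [sim_config].
#' @param annotations output of [simulate_annotations]; regenerated from
#'   `config` when omitted.
#' @return list of class `"sim_sample"` with elements `report`
#'   ([cytosine_records], position-sorted), `controls` (named list
#'   `methylated_control` / `unmethylated_control` of [cytosine_records]),
#'   `reference` (genome as a single character string), and `truth`
#'   (class `"sim_truth"`: the config, annotations, the per-record true
#'   methylation probability track `p_true`, and the logical `is_true_mch`
#'   marker, all parallel to `report` rows).
#' @export
simulate_sample <- function(config, annotations = simulate_annotations(config)) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)

  x <- simulate_reference(config$genome_length, config$cg_spacing_mean)
  cyt <- enumerate_cytosines(x)
  n <- nrow(cyt)
  p_true <- numeric(n)

  ## CG landscape
  cg <- cyt$is_cg
  p_true[cg] <- config$baseline_cg_meth
  occ <- annotations$ctcf[annotations$ctcf$class != "unoccupied", , drop = FALSE]
  if (nrow(occ) > 0L) {
    center <- (occ$start + 1L + occ$end) %/% 2L
    o <- order(center)
    center <- center[o]
    a_strand <- occ$strand[o]
    W <- config$window_halfwidth
    idx <- findInterval(cyt$pos, center - W)
    hit <- idx > 0L & cyt$pos <= center[pmax(idx, 1L)] + W
    sel <- which(cg & hit)
    if (length(sel) > 0L) {
      a <- idx[sel]
      off <- ifelse(a_strand[a] == "+",
                    cyt$pos[sel] - center[a],
                    center[a] - cyt$pos[sel])
      p_true[sel] <- true_cg_probability(off, config)
    }
  }

  ## diffuse mCH
  is_true_mch <- logical(n)
  ch <- which(!cg)
  if (length(ch) > 0L) {
    in_lad <- in_intervals(cyt$pos[ch], annotations$lads)
    w <- config$mch_context_weights
    # Stratified by context: draw the per-context site counts from a
    # multinomial over the weights, then sample sites uniformly within
    # each context, so the true-mCH composition matches the weights up to
    # multinomial sampling error (capped at the available sites).
    pick_mch <- function(cand, rate) {
      if (length(cand) == 0L || rate <= 0) return(integer())
      k <- round(rate * length(cand))
      if (k == 0L) return(integer())
      by_ctx <- split(cand, cyt$context[cand])
      wk <- w[names(by_ctx)]
      wk[is.na(wk)] <- 0
      if (sum(wk) == 0) return(integer())
      k_ctx <- stats::rmultinom(1L, k, wk)[, 1L]
      unlist(lapply(seq_along(by_ctx), function(i) {
        sites <- by_ctx[[i]]
        ki <- min(k_ctx[i], length(sites))
        if (ki == 0L) integer() else sites[sample.int(length(sites), ki)]
      }), use.names = FALSE)
    }
    mch_idx <- c(pick_mch(ch[!in_lad], config$mch_rate_in),
                 pick_mch(ch[in_lad], config$mch_rate_lad))
    p_true[mch_idx] <- config$mch_level
    is_true_mch[mch_idx] <- TRUE
  }

  ## exon non-conversion spikes
  for (sp in config$spike_exons) {
    ex <- annotations$exons[sp$exon, , drop = FALSE]
    sel <- which(!cg & cyt$pos >= ex$start + 1L & cyt$pos <= ex$end)
    if (length(sel) < 10L)
      warning("spike exon ", sp$exon, " has fewer than 10 non-CG cytosines")
    p_true[sel] <- sp$level
    is_true_mch[sel] <- FALSE
  }

  e <- config$under_conversion_error
  ov <- config$over_conversion_error
  n_total <- stats::rpois(n, config$coverage_mean)
  p_obs <- p_true * (1 - ov) + (1 - p_true) * e
  n_meth <- stats::rbinom(n, n_total, p_obs)

  report <- data.frame(chrom = "chr1", pos = cyt$pos, strand = cyt$strand,
                       context = cyt$context, n_meth = n_meth,
                       n_total = n_total, exclude_flag = FALSE,
                       stringsAsFactors = FALSE)
  class(report) <- c("cytosine_records", "data.frame")

  sim_control <- function(chrom, p_true_ctrl) {
    m <- config$phage_sites
    ctx <- paste0("C", sample(BASES, m, replace = TRUE),
                  sample(BASES, m, replace = TRUE))
    nt <- stats::rpois(m, config$coverage_mean)
    po <- p_true_ctrl * (1 - ov) + (1 - p_true_ctrl) * e
    cytosine_records(chrom, seq_len(m) * 5L,
                     sample(c("+", "-"), m, replace = TRUE),
                     ctx, stats::rbinom(m, nt, po), nt)
  }
  controls <- list(methylated_control = sim_control("T7", 1),
                   unmethylated_control = sim_control("lambda", 0))

  truth <- list(config = config, annotations = annotations,
                p_true = p_true, is_true_mch = is_true_mch,
                is_cg = cg)
  class(truth) <- "sim_truth"

  out <- list(report = report, controls = controls,
              reference = paste(BASES[x], collapse = ""), truth = truth)
  class(out) <- "sim_sample"
  out
}

#' Write a simulated sample to disk
#'
#' Writes the cytosine report and control tables as TSV, the annotations as
#' BED, and the generating truth (config, annotation coordinates, true mCH
#' positions) as JSON.
#'
#' @param sim output of [simulate_sample].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
save_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cytosine_report(sim$report, file.path(dir, "sample.tsv"))
  write_cytosine_report(sim$controls$methylated_control,
                        file.path(dir, "methylated_control.tsv"))
  write_cytosine_report(sim$controls$unmethylated_control,
                        file.path(dir, "unmethylated_control.tsv"))
  write_bed(sim$truth$annotations$ctcf, file.path(dir, "ctcf.bed"))
  write_bed(sim$truth$annotations$lads, file.path(dir, "lads.bed"))
  write_bed(sim$truth$annotations$exons, file.path(dir, "exons.bed"))
  truth <- list(
    config = unclass(sim$truth$config),
    mch_positions = sim$report$pos[sim$truth$is_true_mch],
    mch_strands = sim$report$strand[sim$truth$is_true_mch]
  )
  truth$config$spike_exons <- lapply(truth$config$spike_exons, unclass)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
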