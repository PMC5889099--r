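#' Construct a cytosine record table
#'
#' The atomic unit of a WGBS analysis is the per-cytosine count pair from a
#' "cytosine report": how many aligned reads were informative for methylation
#' status at the position (`n_total`) and how many of those were unconverted,
#' i.e. read as methylated (`n_meth`). Records carry the strand of the
#' cytosine and its trinucleotide context *on that strand* (the cytosine is
#' the first base, so CG-context records have "G" as the second character).
#' `exclude_flag` marks positions excluded upstream for genotype reasons
#' (heterozygous or genotype-uncertain sites).
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based base positions of the cytosine.
#' @param strand character vector, `"+"` or `"-"`.
#' @param context character vector of 3-mers starting with `"C"`.
#' @param n_meth integer vector, unconverted (methylated-call) read counts.
#' @param n_total integer vector, informative read counts; `n_meth <= n_total`.
#' @param exclude_flag logical vector; `TRUE` marks genotype-excluded sites.
#' @return A `data.frame` with the seven columns above, class
#'   `"cytosine_records"`.
#' @examples
#' cytosine_records("chr1", 101L, "+", "CAC", 2L, 10L)
#' @export
cytosine_records <- function(chrom, pos, strand, context, n_meth, n_total,
                             exclude_flag = FALSE) {
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    strand = as.character(strand),
    context = as.character(context),
    n_meth = as.integer(n_meth),
    n_total = as.integer(n_total),
    exclude_flag = as.logical(exclude_flag),
    stringsAsFactors = FALSE
  )
  validate_records(df)
  class(df) <- c("cytosine_records", "data.frame")
  df
}

validate_records <- function(df) {
  bad_count <- which(df$n_meth > df$n_total | df$n_meth < 0L | df$n_total < 0L)
  if (length(bad_count) > 0L) {
    stop("invalid read counts (n_meth > n_total or negative) at row(s): ",
         paste(utils::head(bad_count, 5L), collapse = ", "))
  }
  bad_ctx <- which(substr(df$context, 1L, 1L) != "C")
  if (length(bad_ctx) > 0L) {
    stop("context does not start with 'C' at row(s): ",
         paste(utils::head(bad_ctx, 5L), collapse = ", "))
  }
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand) > 0L) {
    stop("strand must be '+' or '-' at row(s): ",
         paste(utils::head(bad_strand, 5L), collapse = ", "))
  }
  invisible(df)
}

REPORT_COLUMNS <- c("chrom", "pos", "strand", "context",
                    "n_meth", "n_total", "exclude_flag")

#' Read / write a cytosine report
#'
#' The cytosine report is a tab-separated table with a `#`-prefixed header
#' line and columns `chrom`, `pos` (1-based), `strand`, `context` (3-mer on
#' the cytosine's strand), `n_meth`, `n_total`, `exclude_flag` (0/1).
#' `write_cytosine_report()` followed by `read_cytosine_report()` is the
#' identity on valid record tables. Malformed rows are reported with their
#' line numbers.
#'
#' @param path file path.
#' @return For `read_cytosine_report`, a [cytosine_records] table.
#' @export
read_cytosine_report <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file, header line required: ", path)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1L]]
  if (!identical(cols, REPORT_COLUMNS)) {
    stop("unexpected cytosine report columns in ", path, ": ",
         paste(cols, collapse = ","))
  }
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = REPORT_COLUMNS,
                          colClasses = c("character", "integer", "character",
                                         "character", "integer", "integer",
                                         "integer"),
                          comment.char = "", quote = "")
  df$exclude_flag <- df$exclude_flag != 0L
  out <- tryCatch(validate_records(df), error = function(e) {
    stop("malformed cytosine report ", path, " (data line numbers offset ",
         "by 1 for the header): ", conditionMessage(e))
  })
  class(df) <- c("cytosine_records", "data.frame")
  df
}

#' @rdname read_cytosine_report
#' @param records a [cytosine_records] table.
#' @export
write_cytosine_report <- function(records, path) {
  validate_records(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(REPORT_COLUMNS, collapse = "\t")), con)
  out <- records[, REPORT_COLUMNS]
  out$exclude_flag <- as.integer(out$exclude_flag)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write stranded BED intervals
#'
#' Intervals are 0-based half-open. Columns: chrom, start, end, name, score,
#' strand, and an optional seventh `class` column used for anchor occupancy
#' classes (`constitutive`, `cell_type_specific:<name>`, `unoccupied`) and
#' for LAD/exon annotation names.
#'
#' @param path file path.
#' @return For `read_bed`, a `data.frame` with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand` and, when present in the file, `class`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name" else df$name <- "."
  if (ncol(df) >= 5L) names(df)[5L] <- "score" else df$score <- 0L
  if (ncol(df) >= 6L) names(df)[6L] <- "strand" else df$strand <- "*"
  if (ncol(df) >= 7L) names(df)[7L] <- "class"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df[, intersect(c("chrom", "start", "end", "name", "score", "strand",
                   "class"), names(df))]
}

#' @rdname read_bed
#' @param intervals interval `data.frame` as returned by `read_bed()`.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  out <- intervals
  for (k in cols) if (is.null(out[[k]])) {
    out[[k]] <- switch(k, name = ".", score = 0L, strand = "*")
  }
  keep <- c(cols, intersect("class", names(out)))
  utils::write.table(out[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Record-level quality filter
#'
#' Keeps cytosines with enough informative reads to support a methylation
#' call and drops pile-up artifacts: retained iff
#' `n_total >= min_cov` and `n_total <= max_depth`, and (when
#' `drop_excluded`) the genotype exclusion flag is unset. The defaults are
#' the standard WGBS thresholds: at least six informative reads, at most
#' 250-fold depth.
#'
#' Idempotent and order-preserving.
#'
#' @param records a [cytosine_records] table.
#' @param min_cov minimum informative reads (inclusive), default 6.
#' @param max_depth maximum informative reads (inclusive), default 250.
#' @param drop_excluded drop rows with `exclude_flag` set, default `TRUE`.
#' @return The filtered record table.
#' @export
filter_records <- function(records, min_cov = 6L, max_depth = 250L,
                           drop_excluded = TRUE) {
  keep <- records$n_total >= min_cov & records$n_total <= max_depth
  if (drop_excluded) keep <- keep & !records$exclude_flag
  records[keep, , drop = FALSE]
}

#' Estimate bisulfite conversion rates from spike-in controls
#'
#' Conversion efficiency is measured from spiked-in control DNA of known
#' methylation state: a fully unmethylated genome (e.g. phage lambda), where
#' every unconverted read reflects under-conversion, and a fully methylated
#' genome (e.g. phage T7), where every converted read reflects
#' over-conversion. Rates are pooled over all control cytosines. A sample
#' passes QC when its conversion rate (1 - under-conversion) is at least
#' 0.997.
#'
#' @param methylated_control [cytosine_records] from the fully methylated
#'   control.
#' @param unmethylated_control [cytosine_records] from the fully
#'   unmethylated control.
#' @param qc_threshold minimum conversion rate to pass, default 0.997.
#' @return An object of class `"conversion_qc"`: a list with
#'   `under_conversion_rate`, `conversion_rate`, `over_conversion_rate`,
#'   `pass_qc`, and the pooled read totals.
#' @export
estimate_conversion <- function(methylated_control, unmethylated_control,
                                qc_threshold = 0.997) {
  if (nrow(unmethylated_control) == 0L || sum(unmethylated_control$n_total) == 0L)
    stop("QC undefined: unmethylated control is empty")
  if (nrow(methylated_control) == 0L || sum(methylated_control$n_total) == 0L)
    stop("QC undefined: methylated control is empty")
  under <- sum(unmethylated_control$n_meth) / sum(unmethylated_control$n_total)
  over <- 1 - sum(methylated_control$n_meth) / sum(methylated_control$n_total)
  qc <- list(
    under_conversion_rate = under,
    conversion_rate = 1 - under,
    over_conversion_rate = over,
    pass_qc = (1 - under) >= qc_threshold,
    n_reads_unmethylated = sum(unmethylated_control$n_total),
    n_reads_methylated = sum(methylated_control$n_total)
  )
  class(qc) <- "conversion_qc"
  qc
}

#' @export
print.conversion_qc <- function(x, ...) {
  cat(sprintf(
    "Bisulfite conversion QC\n  conversion rate:      %.5f (%s reads, unmethylated control)\n  over-conversion rate: %.5f (%s reads, methylated control)\n  pass QC (>= 0.997):   %s\n",
    x$conversion_rate, format(x$n_reads_unmethylated, big.mark = ","),
    x$over_conversion_rate, format(x$n_reads_methylated, big.mark = ","),
    x$pass_qc))
  invisible(x)
}

#' Genome-wide CG methylation level
#'
#' Pools reads over CG-context records: the primary statistic is
#' read-weighted, `sum(n_meth) / sum(n_total)`; the unweighted mean of
#' per-site levels is reported alongside.
#'
#' @param records filtered, CG-context [cytosine_records].
#' @return list with `pooled` and `mean_of_sites`.
#' @export
global_cg_methylation <- function(records) {
  is_cg <- substr(records$context, 2L, 2L) == "G"
  if (!all(is_cg)) stop("global_cg_methylation expects CG-context records only")
  tot <- sum(records$n_total)
  if (tot == 0L) stop("undefined: zero total reads")
  list(pooled = sum(records$n_meth) / tot,
       mean_of_sites = mean(records$n_meth / records$n_total))
}

#' Export per-site methylation levels as bedGraph
#'
#' @param records filtered [cytosine_records].
#' @param path output path.
#' @export
write_bedgraph <- function(records, path) {
  df <- data.frame(chrom = records$chrom,
                   start = records$pos - 1L,
                   end = records$pos,
                   value = records$n_meth / records$n_total)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
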