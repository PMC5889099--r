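#' Classify CTCF-binding sites by occupancy across cell types
#'
#' Given a site-by-cell-type presence matrix, a site is *constitutive* when
#' it is occupied in at least `constitutive_threshold` of the cell types
#' (default 95%). A site is specific to the focal type when it is present in
#' the focal type and absent in all reference types. As a negative control,
#' *unoccupied* sites (for the focal type) are those absent in the focal
#' type but specifically occupied in some other cell type (present there,
#' absent in the remaining reference types).
#'
#' @param presence logical matrix, sites x cell types, with column names.
#' @param constitutive_threshold presence fraction for constitutive sites,
#'   default 0.95 (inclusive).
#' @param focal_type column name of the focal cell type.
#' @param reference_types column names of the reference cell types used for
#'   specificity.
#' @return character vector per site: `"constitutive"`,
#'   `"cell_type_specific:<focal>"`, `"unoccupied"`, or `"other"`. Classes
#'   are disjoint, assigned in that priority order.
#' @export
classify_sites <- function(presence, constitutive_threshold = 0.95,
                           focal_type, reference_types) {
  if (nrow(presence) == 0L || ncol(presence) == 0L)
    stop("classify_sites: presence matrix is empty")
  missing_types <- setdiff(c(focal_type, reference_types), colnames(presence))
  if (length(missing_types) > 0L)
    stop("classify_sites: unknown cell type(s): ",
         paste(missing_types, collapse = ", "))
  frac <- rowMeans(presence)
  constitutive <- frac >= constitutive_threshold
  refs <- presence[, reference_types, drop = FALSE]
  focal_specific <- presence[, focal_type] & rowSums(refs) == 0L

  others <- setdiff(colnames(presence), focal_type)
  specific_elsewhere <- rep(FALSE, nrow(presence))
  for (t in others) {
    other_refs <- setdiff(reference_types, t)
    spec_t <- presence[, t] &
      rowSums(presence[, other_refs, drop = FALSE]) == 0L
    specific_elsewhere <- specific_elsewhere | spec_t
  }
  unoccupied <- !presence[, focal_type] & specific_elsewhere

  cls <- rep("other", nrow(presence))
  cls[unoccupied] <- "unoccupied"
  cls[focal_specific] <- paste0("cell_type_specific:", focal_type)
  cls[constitutive] <- "constitutive"
  cls
}

anchor_centers <- function(anchors) {
  len <- anchors$end - anchors$start
  if (length(unique(len)) > 1L)
    stop("aggregate_profile: anchor motifs must have uniform length")
  (anchors$start + 1L + anchors$end) %/% 2L
}

#' Aggregate an orientation-aware methylation profile around anchors
#'
#' For each anchor, record offsets are measured from the motif centre (the
#' floor midpoint of the motif interval); anchors on the minus strand are
#' mirrored (`offset -> -offset`) so that binding orientation is preserved,
#' and when `strand_resolved` the record strands are swapped accordingly.
#' The profile value at each offset is either the read-pooled fraction
#' `sum(n_meth) / sum(n_total)` across anchors (`mode = "pooled"`) or the
#' unweighted mean of per-site levels (`mode = "mean"`). Offsets with no
#' observation are `NA`.
#'
#' @param records filtered [cytosine_records].
#' @param anchors BED-style data.frame of uniform-length stranded motif
#'   intervals (0-based half-open).
#' @param halfwidth window half-width in bases, default 2000.
#' @param mode `"pooled"` (read-weighted, default) or `"mean"`.
#' @param context_filter `"CG"`, `"CH"`, or `"all"`.
#' @param strand_resolved also return the profile split by motif-strand vs
#'   opposite-strand records.
#' @param seqlengths optional named vector of contig lengths; anchors whose
#'   window would run past a contig end are skipped with a warning count.
#' @return data.frame of class `"anchor_profile"` with columns `offset`
#'   (-halfwidth..halfwidth), `value`, `n_obs` (reads), `n_sites`, and when
#'   `strand_resolved` also `value_motif`, `n_obs_motif`, `value_opposite`,
#'   `n_obs_opposite`. Opposite-strand values are stored as positive
#'   numbers; plotting them as negative is a display convention.
#'   Attributes: `n_anchors`, `n_skipped`, `mode`, `context`.
#' @export
aggregate_profile <- function(records, anchors, halfwidth = 2000L,
                              mode = c("pooled", "mean"),
                              context_filter = c("CG", "CH", "all"),
                              strand_resolved = FALSE,
                              seqlengths = NULL) {
  mode <- match.arg(mode)
  context_filter <- match.arg(context_filter)
  is_cg <- substr(records$context, 2L, 2L) == "G"
  records <- switch(context_filter,
                    CG = records[is_cg, , drop = FALSE],
                    CH = records[!is_cg, , drop = FALSE],
                    all = records)

  centers <- anchor_centers(anchors)
  keep <- centers - halfwidth >= 1L
  if (!is.null(seqlengths)) {
    lim <- seqlengths[anchors$chrom]
    keep <- keep & !is.na(lim) & centers + halfwidth <= lim
  }
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    warning(n_skipped, " anchor(s) with window exceeding contig bounds skipped")
  anchors <- anchors[keep, , drop = FALSE]
  centers <- centers[keep]
  if (nrow(anchors) == 0L) stop("aggregate_profile: no usable anchors")

  offsets <- seq.int(-halfwidth, halfwidth)
  n_off <- length(offsets)
  acc <- function(idx, off) {
    # idx: record rows; off: their oriented offsets in [-W, W]
    key <- off + halfwidth + 1L
    meth <- rowsum_vec(records$n_meth[idx], key, n_off)
    tot <- rowsum_vec(records$n_total[idx], key, n_off)
    sites <- rowsum_vec(rep(1L, length(idx)), key, n_off)
    lev <- rowsum_vec(records$n_meth[idx] / records$n_total[idx], key, n_off)
    value <- if (mode == "pooled") ifelse(tot > 0, meth / tot, NA_real_)
             else ifelse(sites > 0, lev / sites, NA_real_)
    list(value = value, n_obs = tot, n_sites = sites)
  }

  hit_rec <- integer()
  hit_anchor <- integer()
  for (chrom in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == chrom)
    ri <- which(records$chrom == chrom)
    if (length(ri) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(records$pos[ri], width = 1L),
      IRanges::IRanges(centers[ai] - halfwidth, centers[ai] + halfwidth))
    hit_rec <- c(hit_rec, ri[S4Vectors::queryHits(ov)])
    hit_anchor <- c(hit_anchor, ai[S4Vectors::subjectHits(ov)])
  }
  minus_anchor <- anchors$strand[hit_anchor] == "-"
  off <- ifelse(minus_anchor,
                centers[hit_anchor] - records$pos[hit_rec],
                records$pos[hit_rec] - centers[hit_anchor])

  full <- acc(hit_rec, off)
  prof <- data.frame(offset = offsets, value = full$value,
                     n_obs = full$n_obs, n_sites = full$n_sites)
  if (strand_resolved) {
    rel_motif <- records$strand[hit_rec] == anchors$strand[hit_anchor]
    m <- acc(hit_rec[rel_motif], off[rel_motif])
    o <- acc(hit_rec[!rel_motif], off[!rel_motif])
    prof$value_motif <- m$value
    prof$n_obs_motif <- m$n_obs
    prof$value_opposite <- o$value
    prof$n_obs_opposite <- o$n_obs
  }
  attr(prof, "n_anchors") <- nrow(anchors)
  attr(prof, "n_skipped") <- n_skipped
  attr(prof, "mode") <- mode
  attr(prof, "context") <- context_filter
  class(prof) <- c("anchor_profile", "data.frame")
  prof
}

rowsum_vec <- function(x, key, n) {
  out <- numeric(n)
  if (length(x) == 0L) return(out)
  s <- rowsum(x, key)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}
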