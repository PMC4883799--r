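#' Detect false-positive IBD hotspots ("forbidden" regions)
#'
#' IBD callers over-report sharing at problem loci (assembly gaps, structural
#' variation), producing positions overlapped by far more segments than the
#' genome-wide average. Coverage is counted on a regular cM grid (the
#' computable surrogate for "each genomic position"); grid points whose
#' overlap count exceeds the threshold are marked forbidden, and forbidden
#' intervals closer than \code{merge_gap} are merged.
#'
#' @param segments an IBD segment table.
#' @param grid_step grid resolution, cM.
#' @param threshold absolute overlap-count threshold, or \code{"auto"} to use
#'   \code{ceiling(auto_k * genome-wide mean coverage)}.
#' @param merge_gap regions closer than this (cM) are merged.
#' @param auto_k multiplier for the automatic threshold (default 5/3, i.e. a
#'   25,000 threshold at a genome-wide mean of 15,000).
#' @return An object of class \code{forbidden_regions}: a list with per
#'   chromosome a two-column matrix of half-open cM intervals, plus the
#'   parameters used and the realized threshold.
#' @export
detect_forbidden_regions <- function(segments, grid_step = 0.05,
                                     threshold = 25000, merge_gap = 0.1,
                                     auto_k = 25000 / 15000) {
  stopifnot(grid_step > 0)
  segments <- validate_ibd_segments(segments)
  out <- structure(list(regions = list(), grid_step = grid_step,
                        merge_gap = merge_gap, threshold = NA_real_),
                   class = "forbidden_regions")
  if (nrow(segments) == 0L) return(out)

  cover <- lapply(split(segments, segments$chrom), function(seg) {
    lo <- floor(min(seg$start) / grid_step)
    hi <- ceiling(max(seg$end) / grid_step)
    x <- seq(lo, hi) * grid_step
    # count of segments with start <= x < end at each grid point
    n_started <- findInterval(x, sort(seg$start), left.open = FALSE)
    n_ended <- findInterval(x, sort(seg$end), left.open = FALSE)
    list(x = x, count = n_started - n_ended)
  })

  thr <- threshold
  if (identical(threshold, "auto")) {
    counts <- unlist(lapply(cover, `[[`, "count"), use.names = FALSE)
    thr <- ceiling(auto_k * mean(counts))
  }
  stopifnot(is.numeric(thr), thr >= 0)

  regions <- lapply(cover, function(cv) {
    hot <- cv$count > thr
    if (!any(hot)) return(matrix(numeric(0), 0L, 2L))
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    iv <- cbind(cv$x[starts[r$values]],
                cv$x[ends[r$values]] + grid_step)
    merge_intervals(iv, gap = merge_gap)
  })
  out$regions <- regions[vapply(regions, nrow, 1L) > 0L]
  out$threshold <- thr
  out
}

#' Filter IBD segments against forbidden regions
#'
#' Segments not overlapping any forbidden region are kept. A segment that
#' overlaps one or more forbidden regions is kept only if its maximal
#' contiguous extent outside the union of forbidden regions is at least
#' \code{min_flank} cM (long genuine segments spanning a hotspot carry enough
#' evidence outside it; one flank suffices). Filtering is idempotent.
#'
#' @param segments an IBD segment table.
#' @param regions a \code{forbidden_regions} object.
#' @param min_flank minimum contiguous extent outside forbidden regions, cM.
#' @return The retained segments, with an attribute \code{filter_log}
#'   recording input, removed and retained counts.
#' @export
filter_by_forbidden <- function(segments, regions, min_flank = 3) {
  segments <- validate_ibd_segments(segments)
  stopifnot(inherits(regions, "forbidden_regions"))
  if (nrow(segments) == 0L || length(regions$regions) == 0L) {
    attr(segments, "filter_log") <-
      list(n_in = nrow(segments), n_removed = 0L, n_kept = nrow(segments),
           flank_rule = "one-sided (max contiguous extent outside regions)")
    return(segments)
  }
  keep <- rep(TRUE, nrow(segments))
  for (chrom in names(regions$regions)) {
    iv <- regions$regions[[chrom]]
    idx <- which(segments$chrom == chrom)
    if (length(idx) == 0L) next
    for (i in idx) {
      s <- segments$start[i]; e <- segments$end[i]
      overlaps <- any(iv[, 1L] < e & iv[, 2L] > s)
      if (!overlaps) next
      keep[i] <- max(uncovered_extents(s, e, iv)) >= min_flank
    }
  }
  out <- segments[keep, , drop = FALSE]
  attr(out, "filter_log") <-
    list(n_in = nrow(segments), n_removed = sum(!keep), n_kept = sum(keep),
         flank_rule = "one-sided (max contiguous extent outside regions)")
  out
}
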