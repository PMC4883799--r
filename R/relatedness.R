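#' Construct a cohort object
#'
#' Bundles individual metadata with the list of excluded close-relative pairs
#' (e.g. kinship coefficient >= 0.1) whose contributions must be removed from
#' relatedness summaries.
#'
#' @param individuals data.frame with at least a unique character \code{id}
#'   column; optional columns \code{group} (e.g. AFR/EUR), \code{region},
#'   \code{region_birth}, \code{x}, \code{y} (km-projected sampling
#'   coordinates), \code{birth_year}.
#' @param excluded_pairs optional data.frame with columns \code{id_a},
#'   \code{id_b}; unordered pairs, every id must be known.
#' @return An object of class \code{ibd_cohort}.
#' @export
cohort <- function(individuals, excluded_pairs = NULL) {
  stopifnot(is.data.frame(individuals), "id" %in% names(individuals))
  individuals$id <- as.character(individuals$id)
  if (anyDuplicated(individuals$id)) stop("cohort ids must be unique")
  if (is.null(excluded_pairs))
    excluded_pairs <- data.frame(id_a = character(), id_b = character())
  stopifnot(all(c("id_a", "id_b") %in% names(excluded_pairs)))
  excluded_pairs$id_a <- as.character(excluded_pairs$id_a)
  excluded_pairs$id_b <- as.character(excluded_pairs$id_b)
  unknown <- setdiff(c(excluded_pairs$id_a, excluded_pairs$id_b),
                     individuals$id)
  if (length(unknown))
    stop("excluded pairs reference unknown ids: ",
         paste(unknown, collapse = ", "))
  structure(list(individuals = individuals, excluded_pairs = excluded_pairs),
            class = "ibd_cohort")
}

#' Read cohort metadata (and optionally an exclusion-pair list) from TSV
#'
#' The metadata file is a header-bearing TSV with at least an \code{id}
#' column; the optional exclusion file has columns \code{id_a}, \code{id_b}.
#'
#' @param path metadata TSV path.
#' @param exclusions_path optional exclusion-pair TSV path.
#' @return An [cohort()] object.
#' @export
read_cohort <- function(path, exclusions_path = NULL) {
  ind <- utils::read.delim(path, stringsAsFactors = FALSE)
  ep <- if (!is.null(exclusions_path))
    utils::read.delim(exclusions_path, stringsAsFactors = FALSE)
  cohort(ind, ep)
}

excluded_key <- function(ch) {
  ep <- ch$excluded_pairs
  if (nrow(ep) == 0L) return(character(0))
  paste(pmin(ep$id_a, ep$id_b), pmax(ep$id_a, ep$id_b), sep = "\r")
}

#' Pairwise relatedness matrices from IBD segments
#'
#' Builds the symmetric matrix \code{L} of total shared IBD length (cM) and
#' the matrix \code{N} of shared segment counts between every pair of cohort
#' individuals, restricted to segments whose length falls in the half-open
#' window \code{[window[1], window[2])} cM. Contributions of excluded
#' (closely related) pairs are zeroed and diagonals (self-IBD) are zero by
#' definition.
#'
#' @param segments an IBD segment table.
#' @param ch an [cohort()] object.
#' @param window length window in cM, e.g. \code{c(18, Inf)}.
#' @return Object of class \code{relatedness_matrices}: list with \code{L},
#'   \code{N} (dimnames = ids) and \code{window}.
#' @export
build_relatedness_matrices <- function(segments, ch, window = c(18, Inf)) {
  segments <- validate_ibd_segments(segments)
  stopifnot(inherits(ch, "ibd_cohort"), length(window) == 2L,
            window[1L] < window[2L])
  ids <- ch$individuals$id
  unknown <- setdiff(c(segments$id_a, segments$id_b), ids)
  if (length(unknown))
    stop("segments reference ids not in cohort: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  n <- length(ids)
  L <- matrix(0, n, n, dimnames = list(ids, ids))
  N <- matrix(0L, n, n, dimnames = list(ids, ids))
  seg <- segments[segments$length >= window[1L] &
                    segments$length < window[2L], , drop = FALSE]
  if (nrow(seg) > 0L) {
    ia <- match(seg$id_a, ids); ib <- match(seg$id_b, ids)
    lo <- pmin(ia, ib); hi <- pmax(ia, ib)
    key <- (lo - 1L) * n + hi
    lsum <- rowsum(seg$length, key)
    csum <- rowsum(rep(1L, nrow(seg)), key)
    k <- as.integer(rownames(lsum))
    i <- (k - 1L) %/% n + 1L; j <- (k - 1L) %% n + 1L
    L[cbind(i, j)] <- lsum[, 1L]; L[cbind(j, i)] <- lsum[, 1L]
    N[cbind(i, j)] <- as.integer(csum[, 1L])
    N[cbind(j, i)] <- as.integer(csum[, 1L])
  }
  ek <- excluded_key(ch)
  if (length(ek)) {
    ep <- do.call(rbind, strsplit(ek, "\r", fixed = TRUE))
    i <- match(ep[, 1L], ids); j <- match(ep[, 2L], ids)
    L[cbind(i, j)] <- 0; L[cbind(j, i)] <- 0
    N[cbind(i, j)] <- 0L; N[cbind(j, i)] <- 0L
  }
  structure(list(L = L, N = N, window = window),
            class = "relatedness_matrices")
}

#' Average regional relatedness
#'
#' Mean total shared IBD length between two (region, group) strata: the sum of
#' pairwise \code{L} entries over relevant pairs divided by the number of
#' possible pairs, \code{n1 * n2} for distinct strata or
#' \code{n1 * (n1 - 1) / 2} within one stratum. Estimates based on fewer than
#' \code{min_pairs} possible pairs are suppressed (too noisy to display).
#'
#' @param mats a \code{relatedness_matrices} object.
#' @param ch the matching [cohort()].
#' @param stratum1,stratum2 lists with elements \code{region} and (optionally)
#'   \code{group}.
#' @param min_pairs suppression threshold on the number of possible pairs.
#' @return Mean shared length in cM, or the string \code{"suppressed"}.
#' @export
regional_relatedness <- function(mats, ch, stratum1, stratum2,
                                 min_pairs = 0) {
  stopifnot(inherits(mats, "relatedness_matrices"), inherits(ch, "ibd_cohort"))
  pick <- function(s) {
    ind <- ch$individuals
    sel <- rep(TRUE, nrow(ind))
    if (!is.null(s$region)) sel <- sel & ind$region == s$region
    if (!is.null(s$group)) sel <- sel & ind$group == s$group
    ind$id[sel]
  }
  ids1 <- pick(stratum1); ids2 <- pick(stratum2)
  if (length(ids1) == 0L || length(ids2) == 0L)
    stop("empty stratum in regional_relatedness")
  same <- setequal(ids1, ids2)
  if (same) {
    n1 <- length(ids1)
    n_pairs <- n1 * (n1 - 1) / 2
    total <- sum(mats$L[ids1, ids1]) / 2
  } else {
    n_pairs <- length(ids1) * length(ids2)
    total <- sum(mats$L[ids1, ids2])
  }
  if (n_pairs < min_pairs) return("suppressed")
  if (n_pairs == 0) stop("stratum with a single individual has no pairs")
  total / n_pairs
}

#' Distance-binned decay of pairwise IBD sharing
#'
#' Every unordered pair of individuals (excluded pairs omitted) is placed into
#' a km distance bin by the Euclidean distance between their sampling
#' coordinates; per bin, the mean and standard error of total shared IBD
#' length are reported at the bin midpoint. The default bins
#' \code{[0,1), [1,101), [101,201), ...} put same-location pairs into the
#' first bin; the midpoint of \code{[1,101)} is 51 km.
#'
#' @param mats a \code{relatedness_matrices} object.
#' @param ch the matching [cohort()]; coordinates \code{x}, \code{y} (km)
#'   must be present for every individual used.
#' @param bin_edges increasing km bin edges.
#' @return Object of classes \code{decay_curve} and \code{data.frame} with
#'   columns \code{bin_lo}, \code{bin_hi}, \code{midpoint_km}, \code{mean_cM},
#'   \code{se_cM}, \code{n_pairs}; empty bins carry \code{NA} means.
#' @export
distance_decay_curve <- function(mats, ch,
                                 bin_edges = c(0, 1, seq(101, 1001, 100))) {
  stopifnot(inherits(mats, "relatedness_matrices"), inherits(ch, "ibd_cohort"))
  ind <- ch$individuals
  if (!all(c("x", "y") %in% names(ind)) || anyNA(ind$x) || anyNA(ind$y)) {
    bad <- if (all(c("x", "y") %in% names(ind)))
      ind$id[is.na(ind$x) | is.na(ind$y)] else ind$id
    stop("missing coordinates for: ", paste(utils::head(bad, 5L),
                                            collapse = ", "))
  }
  ids <- ind$id
  n <- length(ids)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (nrow(pr) > 0L) {
    key <- paste(pmin(ids[pr[, 1L]], ids[pr[, 2L]]),
                 pmax(ids[pr[, 1L]], ids[pr[, 2L]]), sep = "\r")
    pr <- pr[!(key %in% excluded_key(ch)), , drop = FALSE]
  }
  d <- sqrt((ind$x[pr[, 1L]] - ind$x[pr[, 2L]])^2 +
              (ind$y[pr[, 1L]] - ind$y[pr[, 2L]])^2)
  lvals <- mats$L[cbind(pr[, 1L], pr[, 2L])]
  bin <- findInterval(d, bin_edges, left.open = FALSE)
  nb <- length(bin_edges) - 1L
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1L])
  out$midpoint_km <- (out$bin_lo + out$bin_hi) / 2
  out$mean_cM <- NA_real_
  out$se_cM <- NA_real_
  out$n_pairs <- 0L
  for (b in seq_len(nb)) {
    sel <- bin == b
    k <- sum(sel)
    out$n_pairs[b] <- k
    if (k > 0L) {
      out$mean_cM[b] <- mean(lvals[sel])
      out$se_cM[b] <- if (k > 1L) stats::sd(lvals[sel]) / sqrt(k) else NA_real_
    }
  }
  class(out) <- c("decay_curve", "data.frame")
  out
}
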