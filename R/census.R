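#' Generation-stratified migration counts from census microdata
#'
#' Sums sampling weights of census records into origin-by-destination
#' migration matrices, one per generation. Records are filtered to an age
#' window (migration-active adults) and a single ancestry group; census years
#' are pooled into generations via \code{generation_map} (default: a 30-year
#' generation time, so 1900/1910/1920 are generation 3, 1930/1940/1950
#' generation 2, 1960/1970/1980 generation 1). Records whose birthplace is not
#' among \code{regions} count as external inflow to their destination.
#'
#' @param records data.frame with columns \code{year}, \code{age},
#'   \code{group}, \code{region_birth}, \code{region_residence}, \code{weight}.
#' @param regions character vector of region names (fixes matrix order).
#' @param generation_map named integer vector, census year -> generation.
#' @param age_window inclusive age bounds, years.
#' @param group group label to keep.
#' @return List of \code{migration_counts} objects (one per generation), each
#'   with matrix \code{m} (rows = origin, cols = destination), external inflow
#'   vector \code{m_out}, \code{regions} and \code{generation}.
#' @export
build_migration_counts <- function(records, regions,
                                   generation_map = c(
                                     "1900" = 3, "1910" = 3, "1920" = 3,
                                     "1930" = 2, "1940" = 2, "1950" = 2,
                                     "1960" = 1, "1970" = 1, "1980" = 1),
                                   age_window = c(20, 30), group = NULL) {
  need <- c("year", "age", "group", "region_birth", "region_residence",
            "weight")
  stopifnot(all(need %in% names(records)))
  stopifnot(all(records$weight >= 0, na.rm = TRUE))
  gens <- sort(unique(as.integer(generation_map)))
  unmapped <- !(as.character(records$year) %in% names(generation_map))
  if (any(unmapped)) {
    warning(sum(unmapped), " records with unmapped census year skipped")
    records <- records[!unmapped, , drop = FALSE]
  }
  keep <- records$age >= age_window[1L] & records$age <= age_window[2L]
  if (!is.null(group)) keep <- keep & records$group == group
  records <- records[keep, , drop = FALSE]
  if (nrow(records) && any(!(records$region_residence %in% regions)))
    stop("records with residence outside the region list")
  g_of <- as.integer(generation_map[as.character(records$year)])
  lapply(gens, function(g) {
    r <- records[which(g_of == g), , drop = FALSE]
    m <- matrix(0, length(regions), length(regions),
                dimnames = list(regions, regions))
    m_out <- stats::setNames(numeric(length(regions)), regions)
    if (nrow(r)) {
      internal <- r$region_birth %in% regions
      ri <- r[internal, , drop = FALSE]
      if (nrow(ri)) {
        agg <- rowsum(ri$weight, paste(ri$region_birth, ri$region_residence,
                                       sep = "\r"))
        ij <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
        m[cbind(match(ij[, 1L], regions), match(ij[, 2L], regions))] <-
          agg[, 1L]
      }
      re <- r[!internal, , drop = FALSE]
      if (nrow(re)) {
        agg <- rowsum(re$weight, re$region_residence)
        m_out[rownames(agg)] <- agg[, 1L]
      }
    }
    structure(list(m = m, m_out = m_out, regions = regions, generation = g),
              class = "migration_counts")
  })
}

#' Ancestral-origin transition matrix for one generation
#'
#' Entry (i, j) is the probability that the ancestor, one generation up, of a
#' resident of region j was in region i: the inbound count from i divided by
#' total inbound to j including migrants from outside the study area. Columns
#' sum to at most 1; the deficit is the external-origin probability (with no
#' external inflow the matrix is column-normalized).
#'
#' @param counts a \code{migration_counts} object.
#' @return Square matrix with columns indexing destination.
#' @export
transition_matrix <- function(counts) {
  stopifnot(inherits(counts, "migration_counts"))
  denom <- colSums(counts$m) + counts$m_out
  if (any(denom <= 0))
    stop("zero total inbound count for region(s): ",
         paste(counts$regions[denom <= 0], collapse = ", "))
  sweep(counts$m, 2L, denom, "/")
}

#' Compose per-generation transition matrices
#'
#' The matrix product over generations (oldest first) accounts for all
#' possible migration routes from the starting to the ending region across
#' the composed generations. With a single matrix (birth-region analyses over
#' one generation) the input is returned unchanged.
#'
#' @param ... square matrices of identical dimension, oldest generation first.
#' @return The composed matrix.
#' @export
compose_transitions <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !is.matrix(mats[[1L]]))
    mats <- mats[[1L]]
  stopifnot(length(mats) >= 1L)
  dims <- vapply(mats, function(m) dim(m), integer(2L))
  if (any(dims != dims[1L, 1L])) stop("dimension mismatch in composition")
  Reduce(`%*%`, mats)
}

#' Census-based coalescent relatedness metric between regions
#'
#' \code{I[i, j] = sum_k P[k, i] P[k, j] / N[k]}: the probability that
#' individuals sampled in regions i and j both trace ancestors to some region
#' k, weighted by the coalescence rate 1/N_k there (recent shared ancestry is
#' inversely proportional to ancestral population size under random mating).
#'
#' @param P composed transition matrix (columns = sampled region).
#' @param N positive ancestral population sizes per region.
#' @return Symmetric matrix, units 1/persons.
#' @export
census_relatedness <- function(P, N) {
  stopifnot(is.matrix(P), length(N) == nrow(P), all(N > 0))
  I <- crossprod(P, P / N)
  (I + t(I)) / 2
}
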