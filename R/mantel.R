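#' Element-permutation Mantel test
#'
#' Tests the Pearson correlation between two equally shaped matrices by
#' permuting the \emph{elements} of \code{B} (not rows and columns jointly, as
#' in the classical Mantel convention; the classical variant is available via
#' \code{variant = "rowcol"}). The p-value is the fraction of permutations
#' whose correlation with \code{A} is at least the observed correlation; ties
#' count against the hypothesis (conservative).
#'
#' @param A,B numeric matrices of identical shape, neither constant.
#' @param mode \code{"exhaustive"} enumerates every permutation (element
#'   variant: at most 9 elements; rowcol variant: at most 7 rows) and is exact;
#'   \code{"random"} draws \code{n_perm} uniform permutations.
#' @param n_perm number of random permutations.
#' @param seed RNG seed for random mode.
#' @param variant \code{"element"} (default) or classical \code{"rowcol"}
#'   (rows and columns permuted jointly; square matrices only).
#' @return List with \code{statistic} (observed Pearson correlation),
#'   \code{p_value}, \code{n_perm}, \code{mode}, \code{variant}.
#' @export
mantel_element_test <- function(A, B, mode = c("exhaustive", "random"),
                                n_perm = 1e5, seed = NULL,
                                variant = c("element", "rowcol")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  stopifnot(is.matrix(A), is.matrix(B), all(dim(A) == dim(B)))
  a <- as.vector(A); b <- as.vector(B)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a zero-variance matrix")
  obs <- stats::cor(a, b)

  perm_stats <- if (variant == "element") {
    k <- length(b)
    if (mode == "exhaustive") {
      if (k > 9L) stop("exhaustive element mode limited to 9 elements")
      P <- all_permutations(k)
      # sd(b) is permutation-invariant, so cor is affine in the cross product
      cross <- matrix(b[P], nrow(P), k) %*% a
      (cross / k - mean(a) * mean(b)) /
        (stats::sd(a) * stats::sd(b) * (k - 1) / k)
    } else {
      with_seed(seed, vapply(seq_len(n_perm), function(i)
        stats::cor(a, sample(b)), 0))
    }
  } else {
    if (nrow(B) != ncol(B)) stop("rowcol variant requires square matrices")
    n <- nrow(B)
    if (mode == "exhaustive") {
      if (n > 7L) stop("exhaustive rowcol mode limited to 7 rows")
      P <- all_permutations(n)
      apply(P, 1L, function(p) stats::cor(a, as.vector(B[p, p])))
    } else {
      with_seed(seed, vapply(seq_len(n_perm), function(i) {
        p <- sample(n)
        stats::cor(a, as.vector(B[p, p]))
      }, 0))
    }
  }
  list(statistic = obs,
       p_value = mean(perm_stats >= obs - 1e-12),
       n_perm = length(perm_stats), mode = mode, variant = variant)
}
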