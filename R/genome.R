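#' Default autosomal genetic map lengths
#'
#' Genetic lengths of the 22 human autosomes in Morgans (sex-averaged,
#' HapMap-derived values rounded to 0.1 cM). The total is about 35.5 Morgans.
#' Any named positive numeric vector of per-chromosome lengths can be used in
#' its place throughout the package.
#'
#' @return Named numeric vector of length 22, units Morgans.
#' @export
#' @examples
#' sum(default_genome_map()) # > 30 Morgans
default_genome_map <- function() {
  cm <- c(286.3, 268.8, 223.4, 214.6, 204.1, 192.0, 187.2, 168.0,
          166.4, 181.1, 158.2, 174.7, 125.7, 120.2, 141.8, 134.0,
          128.5, 117.9, 107.9, 108.3, 62.8, 74.1)
  stats::setNames(cm / 100, as.character(1:22))
}

validate_genome_map <- function(genome) {
  if (!is.numeric(genome) || length(genome) < 1L || any(!is.finite(genome)) ||
      any(genome <= 0))
    stop("genome map must be a positive numeric vector of Morgan lengths")
  if (is.null(names(genome))) names(genome) <- as.character(seq_along(genome))
  genome
}

#' Unit conversion between centiMorgans and Morgans
#'
#' All model-level computations in this package are carried out in Morgans
#' (and km); centiMorgans appear only at input/output boundaries. These two
#' helpers are the single conversion point.
#'
#' @param x numeric vector.
#' @return numeric vector in the other unit.
#' @export
cm_to_morgans <- function(x) x / 100

#' @rdname cm_to_morgans
#' @export
morgans_to_cm <- function(x) x * 100
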