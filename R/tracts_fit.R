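#' Validate a local-ancestry tract table
#'
#' @param tracts data.frame with columns \code{id}, \code{haplotype} (0/1),
#'   \code{chrom}, \code{start}, \code{end} (cM), \code{ancestry}.
#' @return The validated data.frame.
#' @export
validate_tracts <- function(tracts) {
  need <- c("id", "haplotype", "chrom", "start", "end", "ancestry")
  if (!all(need %in% names(tracts)))
    stop("missing tract columns: ",
         paste(setdiff(need, names(tracts)), collapse = ", "))
  if (nrow(tracts) && any(tracts$end <= tracts$start))
    stop("tracts must have end > start")
  tracts
}

#' Per-individual global ancestry proportions from local-ancestry tracts
#'
#' The proportion of each ancestry is the total tract length assigned to it
#' divided by the total assigned length. Tracts of each haplotype and
#' chromosome must tile the chromosome without gaps or overlaps.
#'
#' @param tracts a tract table (see [validate_tracts()]).
#' @param genome named chromosome lengths, Morgans; used to check tiling.
#' @param tol tiling tolerance, cM.
#' @return data.frame with column \code{id} and one proportion column per
#'   ancestry; rows sum to 1.
#' @export
global_ancestry <- function(tracts, genome = default_genome_map(),
                            tol = 1e-6) {
  tracts <- validate_tracts(tracts)
  genome <- validate_genome_map(genome)
  key <- paste(tracts$id, tracts$haplotype, tracts$chrom, sep = "\r")
  for (k in unique(key)) {
    tr <- tracts[key == k, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    Lc <- morgans_to_cm(genome[[as.character(tr$chrom[1L])]])
    gaps <- c(tr$start[1L] - 0,
              if (nrow(tr) > 1L) tr$start[-1L] - tr$end[-nrow(tr)],
              Lc - tr$end[nrow(tr)])
    if (any(abs(gaps) > tol))
      stop("tracts do not tile chromosome ", tr$chrom[1L], " of ",
           tr$id[1L], " haplotype ", tr$haplotype[1L])
  }
  len <- tracts$end - tracts$start
  tab <- rowsum(len, paste(tracts$id, tracts$ancestry, sep = "\r"))
  parts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  ids <- sort(unique(tracts$id))
  ancs <- sort(unique(tracts$ancestry))
  out <- matrix(0, length(ids), length(ancs), dimnames = list(ids, ancs))
  out[cbind(match(parts[, 1L], ids), match(parts[, 2L], ancs))] <- tab[, 1L]
  out <- out / rowSums(out)
  data.frame(id = ids, out, row.names = NULL, check.names = FALSE)
}

#' Observed tract-length histogram
#'
#' Bins observed tract lengths per ancestry. Bins lying entirely below
#' \code{exclude_below} are masked for fitting (short tracts are enriched in
#' local-ancestry false positives) but predictions are still reported for
#' them.
#'
#' @param tracts a tract table.
#' @param bin_edges cM bin edges ([default_tract_bins()] by default).
#' @param exclude_below cM cutoff masking whole bins below it (default
#'   11.7 cM, the first two default bins).
#' @param genome named chromosome lengths, Morgans.
#' @return Object of class \code{tract_histogram}: list with \code{bin_edges},
#'   integer \code{counts} (bins x ancestries), \code{n_haplotypes},
#'   \code{excluded} (logical per bin).
#' @export
tract_histogram <- function(tracts, genome = default_genome_map(),
                            bin_edges = default_tract_bins(genome),
                            exclude_below = 11.7) {
  tracts <- validate_tracts(tracts)
  len <- tracts$end - tracts$start
  ancs <- sort(unique(tracts$ancestry))
  nb <- length(bin_edges) - 1L
  counts <- matrix(0L, nb, length(ancs), dimnames = list(NULL, ancs))
  bin <- findInterval(len, bin_edges, left.open = FALSE,
                      rightmost.closed = TRUE)
  bin <- pmin(bin, nb)
  for (a in ancs) {
    t <- tabulate(bin[tracts$ancestry == a], nbins = nb)
    counts[, a] <- t
  }
  structure(list(bin_edges = bin_edges, counts = counts,
                 n_haplotypes = length(unique(paste(tracts$id,
                                                    tracts$haplotype))),
                 excluded = bin_edges[-1L] <= exclude_below + 1e-9),
            class = "tract_histogram")
}

#' Fit a discrete-pulse admixture model to a tract-length histogram
#'
#' Maximizes the Poisson likelihood of per-bin, per-ancestry tract counts
#' (excluded bins left out of the objective, predictions still reported for
#' them) over the event times and the relative pulse contributions, with the
#' present-day ancestry totals held fixed. A brute-force scan over a grid of
#' parameter points is followed by Nelder-Mead refinement from the best grid
#' point; the procedure is deterministic.
#'
#' @param hist a [tract_histogram()].
#' @param family model string, e.g. \code{"pp"} or \code{"pp_xp"}.
#' @param totals fixed present-day ancestry proportions (named, sum 1).
#' @param genome named chromosome lengths, Morgans.
#' @param time_grid candidate event times for the grid stage (generations).
#' @param rel_grid candidate relative contributions for double-pulsed
#'   populations.
#' @param refine run local refinement after the grid stage.
#' @return Object of class \code{pulse_fit}: \code{model} (the best
#'   [pulse_model()]), \code{times}, \code{rel}, \code{loglik}, \code{k},
#'   \code{AIC}, \code{BIC}, \code{n_points}, \code{predicted}.
#' @export
fit_pulse_model <- function(hist, family, totals,
                            genome = default_genome_map(),
                            time_grid = seq(1, 20, by = 0.25),
                            rel_grid = seq(0.05, 0.95, by = 0.05),
                            refine = TRUE) {
  stopifnot(inherits(hist, "tract_histogram"))
  fam <- parse_pulse_family(family, names(totals))
  if (any(totals <= 0) || any(totals >= 1))
    stop("model is not identifiable: an ancestry has total 0 or 1")
  use_anc <- intersect(colnames(hist$counts), names(totals))
  if (length(use_anc) < length(totals))
    stop("histogram lacks counts for: ",
         paste(setdiff(names(totals), colnames(hist$counts)), collapse = ", "))
  obs <- hist$counts[, names(totals), drop = FALSE]
  keep_bins <- !hist$excluded

  ll_of <- function(times, rel) {
    model <- tryCatch(pulse_model(family, times, totals, rel),
                      error = function(e) NULL)
    if (is.null(model)) return(list(ll = -Inf, model = NULL))
    mu <- expected_tract_histogram(model, genome, hist$n_haplotypes,
                                   hist$bin_edges)[, names(totals),
                                                   drop = FALSE]
    ll <- sum(stats::dpois(obs[keep_bins, ],
                           pmax(mu[keep_bins, ], 1e-12), log = TRUE))
    list(ll = ll, model = model, mu = mu)
  }

  n_ev <- fam$n_events
  n_rel <- length(fam$multi_pulse_pops)
  time_sets <- if (n_ev == 1L) matrix(time_grid, ncol = 1L) else {
    cmb <- t(utils::combn(sort(time_grid, decreasing = TRUE), n_ev))
    cmb
  }
  rel_sets <- if (n_rel == 0L) matrix(numeric(0), 1L, 0L) else
    as.matrix(expand.grid(rep(list(rel_grid), n_rel)))

  best <- list(ll = -Inf)
  for (i in seq_len(nrow(time_sets))) for (j in seq_len(nrow(rel_sets))) {
    cand <- ll_of(time_sets[i, ], as.numeric(rel_sets[j, ]))
    if (cand$ll > best$ll)
      best <- c(cand, list(times = time_sets[i, ],
                           rel = as.numeric(rel_sets[j, ])))
  }
  if (!is.finite(best$ll))
    stop("no feasible parameter point on the grid; model may be ",
         "non-identifiable for these totals")

  if (refine) {
    par0 <- c(best$times, best$rel)
    negll <- function(par) {
      times <- par[seq_len(n_ev)]
      rel <- if (n_rel) par[n_ev + seq_len(n_rel)] else numeric(0)
      if (any(times < 1) || (n_ev > 1L && any(diff(times) >= -1e-9)) ||
          (n_rel && (any(rel <= 0) || any(rel >= 1)))) return(1e12)
      v <- ll_of(times, rel)$ll
      if (!is.finite(v)) 1e12 else -v
    }
    opt <- if (length(par0) == 1L) {
      step <- diff(range(time_grid)) / (length(time_grid) - 1L)
      o <- stats::optimize(negll, c(max(1, par0 - step), par0 + step),
                           tol = 1e-6)
      list(par = o$minimum, value = o$objective)
    } else {
      stats::optim(par0, negll, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-9))
    }
    if (-opt$value > best$ll) {
      times <- opt$par[seq_len(n_ev)]
      rel <- if (n_rel) opt$par[n_ev + seq_len(n_rel)] else numeric(0)
      cand <- ll_of(times, rel)
      best <- c(cand, list(times = times, rel = rel))
    }
  }
  n_points <- sum(keep_bins) * length(totals)
  k <- fam$k
  structure(list(family = family, model = best$model, times = best$times,
                 rel = best$rel, loglik = best$ll, k = k,
                 AIC = 2 * k - 2 * best$ll,
                 BIC = k * log(n_points) - 2 * best$ll,
                 n_points = n_points, predicted = best$mu),
            class = "pulse_fit")
}

#' Information-criterion comparison of pulse-model fits
#'
#' AIC = 2k - 2 logLik and BIC = k log(n) - 2 logLik, with k the number of
#' free parameters of each family (event times plus relative contributions;
#' the fixed ancestry totals are not counted) and n the number of data points
#' (histogram bins times populations).
#'
#' @param fits list of [fit_pulse_model()] results, or a data.frame with
#'   columns \code{family}, \code{k}, \code{loglik}.
#' @param n_points number of data points; defaults to the fits' own.
#' @return data.frame with AIC, BIC, and delta columns; lower is better.
#' @export
model_selection <- function(fits, n_points = NULL) {
  df <- if (is.data.frame(fits)) fits else
    data.frame(family = vapply(fits, `[[`, "", "family"),
               k = vapply(fits, `[[`, 0, "k"),
               loglik = vapply(fits, `[[`, 0, "loglik"))
  n <- if (!is.null(n_points)) n_points else
    unique(vapply(fits, `[[`, 0, "n_points"))
  stopifnot(length(n) == 1L)
  df$AIC <- 2 * df$k - 2 * df$loglik
  df$BIC <- df$k * log(n) - 2 * df$loglik
  df$dAIC <- df$AIC - min(df$AIC)
  df$dBIC <- df$BIC - min(df$BIC)
  df[order(df$AIC), ]
}

#' Generation time from the birth-year gradient of inferred admixture times
#'
#' Individuals born tau years earlier sit one generation closer to a fixed
#' calendar onset of admixture, so the inferred single-pulse time g grows by
#' one generation per tau years of birth year: regressing g on group mean
#' birth year gives slope 1/tau. A non-positive slope contradicts a shared
#' onset and is an error.
#'
#' @param groups data.frame with columns \code{mean_year} and \code{g}
#'   (inferred generations since admixture per birth-year group).
#' @return List with \code{tau} (years/generation), \code{r_squared},
#'   \code{slope}, \code{intercept}, \code{degenerate} (TRUE when only two
#'   groups, giving an exact interpolation).
#' @export
generation_time_fit <- function(groups) {
  stopifnot(all(c("mean_year", "g") %in% names(groups)))
  if (nrow(groups) < 2L) stop("need at least 2 birth-year groups")
  fit <- stats::lm(g ~ mean_year, data = groups)
  slope <- stats::coef(fit)[["mean_year"]]
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive slope: inferred admixture time does not grow with ",
         "birth year, contradicting a shared admixture onset")
  r2 <- summary(fit)$r.squared
  list(tau = 1 / slope, r_squared = r2, slope = slope,
       intercept = stats::coef(fit)[[1L]],
       degenerate = nrow(groups) == 2L)
}

#' Calendar year of admixture onset
#'
#' Converts an inferred admixture time in generations to a calendar year:
#' \code{T = T_s - (g - 1) tau}, where \code{T_s} is the cohort mean birth
#' year (g = 1 means the sampled individuals are the first admixed
#' generation). No rounding is applied; round at the reporting layer.
#'
#' @param T_s mean birth year of the cohort.
#' @param g generations since admixture onset (>= 1).
#' @param tau generation time, years.
#' @export
#' @examples
#' round(admixture_calendar_year(1939.8, 5.8, 27.4)) # 1808
admixture_calendar_year <- function(T_s, g, tau) {
  if (any(g < 1)) stop("g must be at least 1")
  T_s - (g - 1) * tau
}

#' Percentile bootstrap over individuals
#'
#' Resamples individuals (not their tracts or segments) with replacement,
#' re-runs an arbitrary fitting procedure on each resample, and reports
#' percentile confidence intervals. Failed replicates are dropped with a
#' warning.
#'
#' @param statistic function taking a resampled data subset and returning a
#'   named numeric vector of parameters.
#' @param data a data.frame (resampled by rows of \code{ids}) or list
#'   indexed by individual.
#' @param ids vector identifying the individual of each row/element.
#' @param id_column optional name of a data.frame column holding the
#'   individual identifier; when given, resampled copies of the same
#'   individual are relabelled uniquely (so that statistics counting
#'   individuals treat each drawn copy as distinct), and \code{ids} defaults
#'   to this column.
#' @param reps bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @param level confidence level.
#' @return List with \code{ci} (2 x p matrix of percentile bounds),
#'   \code{estimates} (replicate x parameter matrix), \code{n_failed}.
#' @export
bootstrap_ci <- function(statistic, data, ids = NULL, id_column = NULL,
                         reps = 100, seed = NULL, level = 0.95) {
  stopifnot(reps >= 2)
  if (!is.null(id_column)) {
    stopifnot(is.data.frame(data), id_column %in% names(data))
    if (is.null(ids)) ids <- data[[id_column]]
  }
  if (is.null(ids))
    ids <- if (is.data.frame(data)) seq_len(nrow(data)) else
      seq_along(data)
  uid <- unique(ids)
  take <- function(chosen) {
    picks <- lapply(seq_along(chosen), function(j) which(ids == chosen[j]))
    rows <- unlist(picks, use.names = FALSE)
    out <- if (is.data.frame(data)) data[rows, , drop = FALSE] else
      data[rows]
    if (!is.null(id_column))
      out[[id_column]] <- rep(paste0("boot", seq_along(chosen)),
                              lengths(picks))
    out
  }
  res <- with_seed(seed, lapply(seq_len(reps), function(r) {
    chosen <- sample(uid, length(uid), replace = TRUE)
    tryCatch(statistic(take(chosen)), error = function(e) NULL)
  }))
  ok <- !vapply(res, is.null, TRUE)
  if (!any(ok)) stop("all bootstrap replicates failed")
  if (any(!ok))
    warning(sum(!ok), " of ", reps, " bootstrap replicates failed and were ",
            "dropped")
  est <- do.call(rbind, res[ok])
  alpha <- (1 - level) / 2
  ci <- apply(est, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  ci <- matrix(ci, nrow = 2L, dimnames = list(c("lower", "upper"),
                                              colnames(est)))
  list(ci = ci, estimates = est, n_failed = sum(!ok))
}

#' Sex-biased contributor fractions from autosomal and X ancestry
#'
#' Under a single admixture pulse with male contributor fractions m and
#' female fractions f per ancestry, autosomes carry a = (m + f)/2 and the X
#' chromosome x = (m + 2f)/3. Solves for m and f by least squares with
#' 0 <= m, f <= 1 and both vectors summing to 1 (soft equality via a penalty;
#' the unconstrained per-ancestry solution m = 4a - 3x, f = 3x - 2a already
#' sums to 1 when a and x do).
#'
#' @param autosomal named autosomal ancestry proportions (sum to 1).
#' @param x_linked named X-chromosome ancestry proportions (sum to 1).
#' @param tol maximum admissible residual before the inputs are declared
#'   infeasible.
#' @return List with vectors \code{m}, \code{f}, the unconstrained solution,
#'   and the residual sum of squares.
#' @export
sex_bias_solve <- function(autosomal, x_linked, tol = 0.05) {
  stopifnot(length(autosomal) == length(x_linked),
            abs(sum(autosomal) - 1) < 1e-6, abs(sum(x_linked) - 1) < 1e-6)
  a <- autosomal; x <- x_linked[names(autosomal)]
  m0 <- 4 * a - 3 * x
  f0 <- 3 * x - 2 * a
  if (all(m0 >= 0 & m0 <= 1) && all(f0 >= 0 & f0 <= 1)) {
    return(list(m = m0, f = f0, unconstrained = list(m = m0, f = f0),
                rss = 0))
  }
  K <- length(a)
  obj <- function(par) {
    m <- par[seq_len(K)]; f <- par[K + seq_len(K)]
    sum((a - (m + f) / 2)^2 + (x - (m + 2 * f) / 3)^2) +
      1e6 * ((sum(m) - 1)^2 + (sum(f) - 1)^2)
  }
  par0 <- c(pmin(pmax(m0, 0), 1), pmin(pmax(f0, 0), 1))
  opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = rep(0, 2 * K), upper = rep(1, 2 * K),
                      control = list(maxit = 1000, factr = 1e4))
  m <- stats::setNames(opt$par[seq_len(K)], names(a))
  f <- stats::setNames(opt$par[K + seq_len(K)], names(a))
  rss <- sum((a - (m + f) / 2)^2 + (x - (m + 2 * f) / 3)^2)
  if (rss > tol)
    stop("no feasible contributor fractions; residual sum of squares ",
         signif(rss, 3), " exceeds ", tol)
  list(m = m, f = f, unconstrained = list(m = m0, f = f0), rss = rss)
}

#' Two-sample bootstrap test for a difference in mean ancestry
#'
#' Resamples each of two disjoint groups with replacement and reports a
#' two-sided bootstrap p-value for the difference in mean ancestry
#' proportion: twice the smaller tail fraction of resampled differences at or
#' crossing zero, capped at 1.
#'
#' @param group_a,group_b numeric ancestry proportions, disjoint sets of
#'   individuals.
#' @param reps bootstrap replicates.
#' @param seed RNG seed.
#' @return List with \code{difference} (mean a - mean b), \code{p_value},
#'   \code{reps}.
#' @export
ancestry_difference_test <- function(group_a, group_b, reps = 1e4,
                                     seed = NULL) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  if (length(group_a) < 2L || length(group_b) < 2L)
    warning("singleton group: bootstrap p-value will be uninformative")
  d_obs <- mean(group_a) - mean(group_b)
  d <- with_seed(seed, vapply(seq_len(reps), function(r)
    mean(sample(group_a, replace = TRUE)) -
      mean(sample(group_b, replace = TRUE)), 0))
  p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  list(difference = d_obs, p_value = p, reps = reps)
}
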