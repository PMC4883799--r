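#' Diffusion model parameters
#'
#' @param n effective diploid population density, 1/km^2.
#' @param D diffusion constant, km^2/generation.
#' @param b background IBD (distance-independent sharing), cM.
#' @return List of class \code{diffusion_params}.
#' @export
diffusion_params <- function(n, D, b = 0) {
  stopifnot(n > 0, D > 0, b >= 0)
  structure(list(n = n, D = D, b = b), class = "diffusion_params")
}

#' Gaussian lineage dispersal kernel
#'
#' Probability density (1/km^2) that a lineage sits a given planar
#' displacement away from its position \code{t} generations later, under
#' isotropic diffusion: \code{exp(-r^2 / 4Dt) / (4 pi D t)}. Integrates to 1
#' over the plane; the mean squared radial displacement is \code{4Dt}.
#'
#' @param displacement radial displacement, km (vectorized).
#' @param t elapsed time, generations (> 0).
#' @param D diffusion constant, km^2/generation.
#' @export
lineage_kernel <- function(displacement, t, D) {
  if (any(t <= 0)) stop("t must be positive")
  exp(-displacement^2 / (4 * D * t)) / (4 * pi * D * t)
}

#' Coalescence-time density for two lineages a distance R apart
#'
#' Convolving two dispersal kernels and applying the local coalescence rate
#' \code{1/(2 n dA)} gives \code{p(t | R) = exp(-R^2 / 8Dt) / (16 pi n D t)}:
#' the (improper over t) density of the pairwise coalescence time under planar
#' diffusion at constant diploid density n.
#'
#' @param t time, generations (> 0, vectorized).
#' @param R separation, km (>= 0).
#' @param n diploid population density, 1/km^2.
#' @param D diffusion constant, km^2/generation.
#' @export
coalescence_time_density <- function(t, R, n, D) {
  stopifnot(all(t > 0), R >= 0)
  exp(-R^2 / (8 * D * t)) / (16 * pi * n * D * t)
}

# Length density of the IBD segment spanning a locus whose lineages coalesce
# t generations ago (infinite genome): length-biased exponential on the
# Morgan scale with rate 2t.
ibd_length_density <- function(l, t) (2 * t)^2 * l * exp(-2 * t * l)

#' Expected IBD fraction at separation R for a segment-length window
#'
#' Expected fraction of the genome two individuals a distance \code{R} apart
#' share through IBD segments with length in \code{[l_min, l_max]} Morgans.
#' Defined by the double integral of the segment-length density against the
#' coalescence-time density; the closed form is
#' \deqn{\frac{1}{16\pi n D}\Big[2 K_0(R/r_{min}) - 2 K_0(R/r_{max}) +
#'   \frac{R}{r_{min}} K_1(R/r_{min}) - \frac{R}{r_{max}} K_1(R/r_{max})\Big]}
#' with \eqn{r_i = \sqrt{D / l_i}}, obtained from the antiderivative
#' \eqn{\int u K_2(u)\,du = -u K_1(u) - 2 K_0(u)}. At \code{R = 0} it reduces
#' to \eqn{\log(l_{max}/l_{min}) / (16\pi n D)}.
#'
#' @param l_min,l_max length window bounds, Morgans (0 < l_min < l_max).
#' @param R separation, km (>= 0, vectorized for the closed form).
#' @param n diploid population density, 1/km^2.
#' @param D diffusion constant, km^2/generation.
#' @param method \code{"closed"} (Bessel form) or \code{"numeric"} (adaptive
#'   double quadrature of the defining integral; the oracle).
#' @param rel_tol quadrature tolerance for the numeric method.
#' @return Dimensionless expected fraction.
#' @export
expected_ibd_fraction <- function(l_min, l_max, R, n, D,
                                  method = c("closed", "numeric"),
                                  rel_tol = 1e-10) {
  method <- match.arg(method)
  stopifnot(l_min > 0, l_max > l_min, all(R >= 0), n > 0, D > 0)
  if (method == "closed") {
    pref <- 1 / (16 * pi * n * D)
    vapply(R, function(r) {
      if (r == 0) return(pref * log(l_max / l_min))
      umin <- r * sqrt(l_min / D)
      umax <- r * sqrt(l_max / D)
      bes <- function(u) {
        if (u > 650) return(0) # K0, K1 underflow; term is ~exp(-u)
        2 * besselK(u, 0) + u * besselK(u, 1)
      }
      pref * (bes(umin) - bes(umax))
    }, 0)
  } else {
    vapply(R, function(r) {
      inner <- function(l) {
        vapply(l, function(li) {
          stats::integrate(function(t)
            ibd_length_density(li, t) * coalescence_time_density(t, r, n, D),
            lower = 0, upper = Inf, rel.tol = rel_tol,
            abs.tol = 0)$value
        }, 0)
      }
      out <- stats::integrate(inner, l_min, l_max, rel.tol = rel_tol,
                              abs.tol = 0)
      if (out$message != "OK") stop("quadrature failed: ", out$message)
      out$value
    }, 0)
  }
}

#' Expected total shared IBD length versus distance
#'
#' Sums the per-chromosome expected shared fraction over the genome,
#' \code{b + sum_c 2 L_c E_[l_min, L_c][f | R]} converted to cM, where the
#' window's upper bound on chromosome c is its genetic length L_c. Decays to
#' the background \code{b} as R grows.
#'
#' @param params a [diffusion_params()] object.
#' @param R separations, km (vectorized).
#' @param genome named vector of chromosome lengths, Morgans.
#' @param l_min lower segment-length cutoff, Morgans.
#' @return Expected total shared length, cM.
#' @export
expected_total_ibd <- function(params, R, genome = default_genome_map(),
                               l_min = 0.18) {
  stopifnot(inherits(params, "diffusion_params"))
  genome <- validate_genome_map(genome)
  use <- genome[genome > l_min]
  tot <- rep(0, length(R))
  for (Lc in use)
    tot <- tot + 2 * Lc *
      expected_ibd_fraction(l_min, Lc, R, params$n, params$D)
  params$b + morgans_to_cm(tot)
}

#' RMS per-generation displacement implied by a diffusion constant
#'
#' For isotropic planar diffusion the mean squared parent-offspring
#' displacement over one generation is \code{4D}, so the root-mean-square
#' displacement is \code{sqrt(4D)} km/generation.
#'
#' @param D diffusion constant, km^2/generation.
#' @export
#' @examples
#' rms_displacement(88.6) # 18.8 km
rms_displacement <- function(D) {
  stopifnot(all(D > 0))
  sqrt(4 * D)
}

# Expected shared fraction of a finite chromosome of length Lc (Morgans)
# restricted to segments of length >= l_min, given coalescence at t: derived
# from the sliding-window construction (stationary Poisson breakpoints at
# rate 2t, censoring at both chromosome ends). Reduces to the infinite-genome
# tail exp(-2 t l)(1 + 2 t l) as Lc -> Inf.
finite_window_fraction <- function(t, l_min, Lc) {
  if (l_min >= Lc) return(rep(0, length(t)))
  exp(-2 * t * l_min) * (1 + 2 * t * l_min * (1 - l_min / Lc))
}

#' Expected total IBD with the finite-genome segment-length correction
#'
#' Like [expected_total_ibd()] but using the window-corrected segment-length
#' distribution on each finite chromosome (segments observed on a chromosome
#' are the intersection of the infinite-genome segment process with
#' \code{[0, L_c]}) and integrating the coalescence-time density numerically
#' from \code{t_min} (excluding the unphysical immediate-coalescence region).
#'
#' @param params a [diffusion_params()] object.
#' @param R separations, km (vectorized).
#' @param genome named vector of chromosome lengths, Morgans.
#' @param l_min lower segment-length cutoff, Morgans.
#' @param t_min lower integration bound, generations (>= as used, default 1).
#' @param rel_tol quadrature tolerance.
#' @return Expected total shared length, cM.
#' @export
finite_genome_ibd <- function(params, R, genome = default_genome_map(),
                              l_min = 0.18, t_min = 1, rel_tol = 1e-9) {
  stopifnot(inherits(params, "diffusion_params"), t_min > 0)
  genome <- validate_genome_map(genome)
  use <- genome[genome > l_min]
  vapply(R, function(r) {
    tot <- 0
    for (Lc in use) {
      out <- stats::integrate(function(t)
        finite_window_fraction(t, l_min, Lc) *
          coalescence_time_density(t, r, params$n, params$D),
        lower = t_min, upper = Inf, rel.tol = rel_tol, abs.tol = 0)
      if (out$message != "OK") stop("quadrature failed: ", out$message)
      tot <- tot + 2 * Lc * out$value
    }
    params$b + morgans_to_cm(tot)
  }, 0)
}

#' Fit the diffusion isolation-by-distance model to a decay curve
#'
#' Weighted least squares (weights 1/SE^2 on the linear scale by default; a
#' log-scale objective is available) between binned mean pairwise IBD and the
#' model expectation, over (n, D, b). Initialization scans logarithmic grids
#' (n in [0.1, 100]/km^2, D in [1, 1000] km^2/gen, b in [0, max(curve)]),
#' followed by Nelder-Mead refinement; deterministic. When \code{fixed}
#' supplies (n, D), only the background b is fit (the cross-window prediction
#' mode), which has a closed-form weighted-mean solution.
#'
#' @param curve a [distance_decay_curve()] result (or data.frame with columns
#'   \code{midpoint_km}, \code{mean_cM}, optionally \code{se_cM}).
#' @param genome named vector of chromosome lengths, Morgans.
#' @param l_min lower segment-length cutoff, Morgans.
#' @param fit_background fit b (TRUE) or pin it to 0.
#' @param fixed optional list with \code{n} and \code{D} to hold fixed.
#' @param objective \code{"linear"} or \code{"log"} residual scale.
#' @param model \code{"infinite"} (closed form) or \code{"finite"}
#'   (finite-genome correction, numeric).
#' @param t_min integration lower bound for the finite model.
#' @return List of class \code{diffusion_fit}: \code{params}
#'   ([diffusion_params()]), \code{objective} (weighted SSR), \code{fitted},
#'   \code{convergence}, \code{grid_best}.
#' @export
fit_decay <- function(curve, genome = default_genome_map(), l_min = 0.18,
                      fit_background = TRUE, fixed = NULL,
                      objective = c("linear", "log"),
                      model = c("infinite", "finite"), t_min = 1) {
  objective <- match.arg(objective)
  model <- match.arg(model)
  ok <- is.finite(curve$mean_cM)
  Rv <- curve$midpoint_km[ok]
  y <- curve$mean_cM[ok]
  se <- if ("se_cM" %in% names(curve)) curve$se_cM[ok] else rep(NA_real_,
                                                               length(y))
  w <- ifelse(is.finite(se) & se > 0, 1 / se^2, NA_real_)
  if (anyNA(w)) w <- rep(1, length(y))
  if (is.null(fixed) && length(y) < 4L)
    stop("need at least 4 informative bins to fit (n, D, b)")

  predict_nd <- function(n, D) {
    p <- diffusion_params(n, D, 0)
    if (model == "infinite") expected_total_ibd(p, Rv, genome, l_min)
    else finite_genome_ibd(p, Rv, genome, l_min, t_min)
  }
  loss <- function(mu) {
    if (objective == "linear") sum(w * (y - mu)^2)
    else {
      if (any(mu <= 0) || any(y <= 0)) return(Inf)
      sum(w * (log(y) - log(mu))^2)
    }
  }
  best_b <- function(mu0) {
    if (!fit_background) return(0)
    if (objective == "linear") max(0, sum(w * (y - mu0)) / sum(w))
    else { # 1-d search on the log scale
      stats::optimize(function(b) loss(mu0 + b), c(0, max(y)))$minimum
    }
  }

  if (!is.null(fixed)) {
    mu0 <- predict_nd(fixed$n, fixed$D)
    b <- best_b(mu0)
    fitted <- mu0 + b
    return(structure(list(
      params = diffusion_params(fixed$n, fixed$D, b),
      objective = loss(fitted), fitted = fitted, convergence = 0L,
      grid_best = NULL), class = "diffusion_fit"))
  }

  n_grid <- 10^seq(-1, 2, length.out = 8)
  D_grid <- 10^seq(0, 3, length.out = 8)
  best <- NULL
  for (n0 in n_grid) for (D0 in D_grid) {
    mu0 <- predict_nd(n0, D0)
    b0 <- best_b(mu0)
    v <- loss(mu0 + b0)
    if (is.null(best) || v < best$value)
      best <- list(n = n0, D = D0, b = b0, value = v)
  }
  obj <- function(par) {
    n0 <- exp(par[1L]); D0 <- exp(par[2L])
    b0 <- if (fit_background) par[3L] else 0
    if (b0 < 0 || n0 > 1e4 || D0 > 1e6) return(1e30)
    loss(predict_nd(n0, D0) + b0)
  }
  par0 <- c(log(best$n), log(best$D), if (fit_background) best$b)
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (opt$value > best$value) { # refinement failed; report the grid point
    warning("local refinement did not improve on the grid initialization")
    opt <- list(par = par0, value = best$value, convergence = 1L)
  }
  n_hat <- exp(opt$par[1L]); D_hat <- exp(opt$par[2L])
  b_hat <- if (fit_background) max(0, opt$par[3L]) else 0
  params <- diffusion_params(n_hat, D_hat, b_hat)
  fitted <- predict_nd(n_hat, D_hat) + b_hat
  structure(list(params = params, objective = opt$value, fitted = fitted,
                 convergence = opt$convergence, grid_best = best),
            class = "diffusion_fit")
}

#' Expected TMRCA given an observed IBD segment length
#'
#' Under the length-biased exponential segment-length model and an
#' exponential(1/N) coalescence-time prior, the posterior of the MRCA time g
#' given a spanning segment of length l Morgans is Gamma(3, 2l + 1/N); the
#' posterior mean (the integral ratio) is \code{3 / (2l + 1/N)}, which for
#' large N approaches the familiar \code{3/(2l)}.
#'
#' @param l segment length, Morgans (> 0, vectorized).
#' @param N constant effective haploid population size.
#' @return Expected TMRCA, generations.
#' @export
#' @examples
#' tmrca_expected(0.18, 1e6) # about 8.3 generations
tmrca_expected <- function(l, N) {
  stopifnot(all(l > 0), N > 0)
  3 / (2 * l + 1 / N)
}
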