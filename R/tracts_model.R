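#' Parse a pulse-model nomenclature string
#'
#' Migration histories are written as underscore-separated events, oldest
#' first; each event has one letter per source population, \code{p} for a
#' pulse of migrants and \code{x} for none (e.g. \code{pp_xp}: a founding
#' pulse from both populations followed by a later pulse from the second).
#' The first event must found the population (at least one \code{p}).
#'
#' @param family model string, e.g. \code{"pp"}, \code{"pp_xp"},
#'   \code{"pxp_xpx_xpx"}.
#' @param labels optional ancestry labels (default \code{pop1, pop2, ...}).
#' @return List with \code{pulse} (events x populations logical matrix),
#'   \code{n_events}, \code{n_pops}, \code{labels}, \code{multi_pulse_pops}
#'   (populations receiving more than one pulse, each contributing one free
#'   relative-contribution parameter) and \code{k} (free parameter count:
#'   one time per event plus one relative contribution per multi-pulse
#'   population, with the total ancestry proportions held fixed).
#' @export
parse_pulse_family <- function(family, labels = NULL) {
  ev <- strsplit(family, "_", fixed = TRUE)[[1L]]
  if (length(ev) < 1L || any(!grepl("^[px]+$", ev)))
    stop("cannot parse model family: ", family)
  npop <- nchar(ev[1L])
  if (any(nchar(ev) != npop))
    stop("events in ", family, " disagree on the number of populations")
  pulse <- t(vapply(strsplit(ev, ""), function(x) x == "p",
                    logical(npop)))
  pulse <- matrix(pulse, nrow = length(ev))
  if (!any(pulse[1L, ])) stop("first event of ", family, " must found the population")
  if (any(rowSums(pulse) == 0L))
    stop("event with no migration in ", family, " is not identifiable")
  if (is.null(labels)) labels <- paste0("pop", seq_len(npop))
  stopifnot(length(labels) == npop)
  colnames(pulse) <- labels
  pulses_per_pop <- colSums(pulse)
  if (any(pulses_per_pop > 2L))
    stop("at most two pulses per population are supported")
  multi <- labels[pulses_per_pop == 2L]
  list(pulse = pulse, n_events = nrow(pulse), n_pops = npop,
       labels = labels, multi_pulse_pops = multi,
       k = nrow(pulse) + length(multi))
}

#' Construct a discrete-pulse admixture model
#'
#' Given event times (continuous generations before sampling, strictly
#' decreasing from the founding event toward the present, all >= 1), the fixed
#' present-day ancestry totals, and one relative contribution per
#' double-pulsed population (the fraction of that ancestry delivered by the
#' more recent pulse), solves for the per-event migrant fractions and builds
#' the discrete per-generation migration schedule. A pulse at a fractional
#' time contributes migrants to the two adjacent integer generations with
#' linear weights.
#'
#' @param family model string (see [parse_pulse_family()]).
#' @param times numeric vector, one per event, generations before sampling.
#' @param totals named present-day ancestry proportions (sum to 1).
#' @param rel named (or positional) relative contributions in (0, 1) for
#'   double-pulsed populations; empty when none.
#' @param labels optional ancestry labels; defaults to \code{names(totals)}.
#' @return Object of class \code{pulse_model} with the event list, the
#'   discrete migration schedule \code{mig} (generations x ancestries), and
#'   the schedule-implied ancestry proportions.
#' @export
pulse_model <- function(family, times, totals, rel = numeric(0),
                        labels = names(totals)) {
  fam <- parse_pulse_family(family, labels)
  labels <- fam$labels
  stopifnot(length(times) == fam$n_events, all(times >= 1))
  if (fam$n_events > 1L && any(diff(times) >= 0))
    stop("event times must strictly decrease toward the present")
  totals <- totals[labels]
  if (anyNA(totals) || abs(sum(totals) - 1) > 1e-8)
    stop("ancestry totals must be named per label and sum to 1")
  if (length(rel) != length(fam$multi_pulse_pops))
    stop("expected ", length(fam$multi_pulse_pops),
         " relative-contribution parameter(s)")
  if (length(rel) && (any(rel <= 0) || any(rel >= 1)))
    stop("relative contributions must lie strictly inside (0, 1)")
  if (length(rel)) names(rel) <- fam$multi_pulse_pops

  # contributions of each pulse to the present-day totals
  contrib <- matrix(0, fam$n_events, fam$n_pops,
                    dimnames = list(NULL, labels))
  for (p in labels) {
    ev <- which(fam$pulse[, p])
    if (length(ev) == 1L) contrib[ev, p] <- totals[[p]]
    if (length(ev) == 2L) {
      contrib[ev[1L], p] <- (1 - rel[[p]]) * totals[[p]]
      contrib[ev[2L], p] <- rel[[p]] * totals[[p]]
    }
  }
  # back out migrant fractions: process events from most recent to oldest,
  # dividing by the survival probability past all more recent events
  m <- matrix(0, fam$n_events, fam$n_pops, dimnames = list(NULL, labels))
  surv <- 1
  for (e in rev(seq_len(fam$n_events))) {
    if (surv <= 1e-12)
      stop("model degenerate: a later pulse replaces the whole population")
    m[e, ] <- contrib[e, ] / surv
    Me <- sum(m[e, ])
    if (Me > 1 + 1e-9)
      stop("infeasible pulse fractions (event ", e, " exceeds 1)")
    surv <- surv * (1 - min(Me, 1))
  }
  if (abs(sum(m[1L, ]) - 1) > 1e-6)
    stop("founding event fractions do not sum to 1; infeasible totals")
  m[1L, ] <- m[1L, ] / sum(m[1L, ])

  mig <- discretize_schedule(times, m)
  structure(list(family = family, labels = labels, times = times,
                 totals = totals, rel = rel, m = m, mig = mig,
                 k = fam$k,
                 proportions = schedule_proportions(mig)),
            class = "pulse_model")
}

# Spread event pulses onto integer generations. The founding event places a
# complete replacement at ceiling(time) plus a same-composition replacement
# pulse of strength ceiling(time) - time at floor(time); later events split
# their strength linearly between the two adjacent generations.
discretize_schedule <- function(times, m) {
  Tmax <- as.integer(ceiling(max(times)))
  mig <- matrix(0, Tmax, ncol(m), dimnames = list(NULL, colnames(m)))
  for (e in seq_along(times)) {
    g <- times[e]
    lo <- as.integer(floor(g)); hi <- as.integer(ceiling(g))
    w_lo <- hi - g
    if (e == 1L) {
      mig[hi, ] <- m[e, ]
      if (lo < hi && w_lo > 0) mig[lo, ] <- mig[lo, ] + w_lo * m[e, ]
    } else {
      if (lo == hi) mig[hi, ] <- mig[hi, ] + m[e, ]
      else {
        mig[lo, ] <- mig[lo, ] + w_lo * m[e, ]
        mig[hi, ] <- mig[hi, ] + (1 - w_lo) * m[e, ]
      }
    }
  }
  if (any(rowSums(mig) > 1 + 1e-9)) stop("discrete schedule exceeds 1")
  mig <- pmin(mig, 1)
  mig
}

# Marginal probability that a present-day locus arrived with a generation-t
# migrant of each ancestry: mig[t, p] * prod_{s < t} (1 - M_s).
arrival_distribution <- function(mig) {
  M <- pmin(rowSums(mig), 1)
  S1 <- cumprod(1 - M)                  # S1[u] = P(arrival > u)
  before <- c(1, S1[-length(S1)])       # prod_{s < t}
  pi <- mig * before
  list(pi = pi, S1 = S1)
}

schedule_proportions <- function(mig) {
  ad <- arrival_distribution(mig)
  colSums(ad$pi)
}

# Markov generator of the ancestry-arrival process along the chromosome
# (rates per Morgan). States are (arrival generation t, ancestry p) with
# positive arrival probability. A lineage that arrived at generation t is
# interrupted at rate t - 1 (one per meiosis within the admixed pedigree);
# at an interruption at meiosis level u (uniform on 1..t-1) the new lineage's
# arrival is drawn conditionally on arrival > u. The arrival distribution is
# stationary for this generator.
tract_generator <- function(mig) {
  ad <- arrival_distribution(mig)
  idx <- which(ad$pi > 0, arr.ind = TRUE)
  states <- data.frame(t = idx[, 1L],
                       pop = colnames(mig)[idx[, 2L]],
                       pi = ad$pi[idx], stringsAsFactors = FALSE)
  o <- order(states$t, states$pop)
  states <- states[o, , drop = FALSE]
  if (abs(sum(states$pi) - 1) > 1e-9)
    stop("schedule does not fully found the population")
  ns <- nrow(states)
  invS1 <- 1 / ad$S1
  H <- c(0, cumsum(invS1))              # H[m + 1] = sum_{u=1}^m 1/S1[u]
  K <- matrix(0, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    mm <- min(states$t[i], states$t[j]) - 1L
    K[i, j] <- states$pi[j] * H[mm + 1L]
  }
  Q <- K
  diag(Q) <- diag(Q) - (states$t - 1)
  list(states = states, Q = Q)
}

# Pedigree-alternation generator for a single-pulse model at integer time g.
# State = (active-leaf ancestry, co-branch leaf ancestry at meiosis levels
# 1..g-1). A crossover at level u (rate 1 per Morgan) swaps the active leaf
# with the level-u co-branch and freshens the co-branches inside the newly
# entered subtree (levels above u); an inactive level-u co-branch is the leaf
# of a depth-(g-u) subtree and is flipped as a Markov chain at its exact
# marginal switch rate (g-u-1) * alpha. Captures the back-crossover
# (alternation) structure of the pedigree that independent-redraw models
# miss; exact at g = 2. The stationary law is the product measure.
pedigree_generator <- function(alpha, g) {
  stopifnot(abs(sum(alpha) - 1) < 1e-9, g == round(g), g >= 1)
  K <- length(alpha)
  labels <- names(alpha)
  if (g == 1L) {
    states <- data.frame(pop = labels, pi = as.numeric(alpha),
                         stringsAsFactors = FALSE)
    return(list(states = states, Q = matrix(0, K, K)))
  }
  coords <- as.matrix(expand.grid(rep(list(seq_len(K)), g)))[, , drop = FALSE]
  ns <- nrow(coords)
  pw <- K^(seq_len(g) - 1L)
  idx_of <- function(cc) 1L + drop((cc - 1L) %*% pw)
  pi_s <- apply(coords, 1L, function(cc) prod(alpha[cc]))
  Q <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    cc <- coords[i, ]
    for (u in seq_len(g - 1L)) {
      # crossover at level u: swap coords 1 and u+1, freshen coords > u+1
      base <- cc
      tmp <- base[1L]; base[1L] <- base[u + 1L]; base[u + 1L] <- tmp
      fresh <- if (u + 2L <= g) seq(u + 2L, g) else integer(0)
      if (length(fresh) == 0L) {
        j <- idx_of(base)
        Q[i, j] <- Q[i, j] + 1
      } else {
        combos <- as.matrix(expand.grid(rep(list(seq_len(K)),
                                            length(fresh))))
        for (r in seq_len(nrow(combos))) {
          dest <- base
          dest[fresh] <- combos[r, ]
          w <- prod(alpha[combos[r, ]])
          j <- idx_of(dest)
          Q[i, j] <- Q[i, j] + w
        }
      }
      # inactive co-branch at level u evolves at its marginal switch rate
      depth_rate <- g - u - 1L
      if (depth_rate > 0L) for (p2 in seq_len(K)) {
        if (p2 == cc[u + 1L]) next
        dest <- cc
        dest[u + 1L] <- p2
        j <- idx_of(dest)
        Q[i, j] <- Q[i, j] + depth_rate * alpha[p2]
      }
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  states <- data.frame(pop = labels[coords[, 1L]], pi = pi_s,
                       stringsAsFactors = FALSE)
  list(states = states, Q = Q)
}

build_tract_generator <- function(model, engine = c("markov", "pedigree")) {
  engine <- match.arg(engine)
  if (engine == "markov") {
    gen <- tract_generator(model$mig)
    gen$states <- gen$states[, c("pop", "pi")]
    return(gen)
  }
  if (length(model$times) != 1L || model$times != round(model$times))
    stop("the pedigree engine supports single-pulse models at integer times")
  alpha <- model$m[1L, ]
  pedigree_generator(alpha, as.integer(model$times))
}

# Matrix-exponential integrals of the sub-generator T:
# E(l) = expm(T l), F1(l) = int_0^l E(s) ds, and int_0^l (l-s)^k/k! E(s) ds
# for k = 1, 2, via one augmented block exponential. Handles singular T.
phase_integrals <- function(Tm, lens) {
  m <- nrow(Tm)
  A <- matrix(0, 4L * m, 4L * m)
  A[seq_len(m), seq_len(m)] <- Tm
  for (blk in 1:3) {
    rows <- (blk - 1L) * m + seq_len(m)
    cols <- blk * m + seq_len(m)
    A[cbind(rows, cols)] <- 1
  }
  lapply(lens, function(l) {
    E <- as.matrix(Matrix::expm(A * l))
    list(E = E[seq_len(m), seq_len(m), drop = FALSE],
         F1 = E[seq_len(m), m + seq_len(m), drop = FALSE],
         F2 = E[seq_len(m), 2L * m + seq_len(m), drop = FALSE],
         F3 = E[seq_len(m), 3L * m + seq_len(m), drop = FALSE])
  })
}

#' Expected ancestry tract-length histogram under a pulse model
#'
#' Computes, for each ancestry and each length bin, the expected number of
#' observed tracts per \code{n_haplotypes} haploid genomes on a finite
#' chromosome set: tract lengths follow the phase-type distribution of the
#' arrival Markov process along the chromosome, with censoring at both
#' chromosome ends (tracts overlapping an end are observed at their clipped
#' length, and an uninterrupted chromosome contributes one full-length
#' tract). Expected counts are linear in \code{n_haplotypes}.
#'
#' Two engines are available. \code{"markov"} (default) is the classical
#' arrival-epoch Markov approximation: a lineage that arrived with a
#' generation-t migrant is interrupted at rate t - 1 per Morgan and redraws an
#' independent lineage; it supports arbitrary multi-pulse schedules and is
#' fast, but under-counts short tracts because a second crossover at the same
#' meiosis level returns to the \emph{previous} lineage rather than an
#' independent one. \code{"pedigree"} tracks that alternation explicitly
#' (state = active-leaf ancestry plus the co-branch ancestry at every meiosis
#' level); it is exact at g = 2, much closer to forward Wright-Fisher
#' simulations at all g, and is restricted to single-pulse models at integer
#' times.
#'
#' @param model a [pulse_model()].
#' @param genome named chromosome lengths, Morgans.
#' @param n_haplotypes number of haploid genomes.
#' @param bin_edges histogram bin edges in cM (default [default_tract_bins()]).
#' @param engine \code{"markov"} or \code{"pedigree"} (see Details).
#' @return Matrix of expected counts, \code{length(bin_edges) - 1} rows, one
#'   column per ancestry.
#' @export
expected_tract_histogram <- function(model, genome = default_genome_map(),
                                     n_haplotypes = 1,
                                     bin_edges = default_tract_bins(genome),
                                     engine = c("markov", "pedigree")) {
  stopifnot(inherits(model, "pulse_model"))
  genome <- validate_genome_map(genome)
  gen <- build_tract_generator(model, engine)
  states <- gen$states
  Q <- gen$Q
  edges_M <- cm_to_morgans(bin_edges)
  nb <- length(edges_M) - 1L
  out <- matrix(0, nb, length(model$labels),
                dimnames = list(NULL, model$labels))
  for (p in model$labels) {
    sel <- states$pop == p
    if (!any(sel)) next
    Tm <- Q[sel, sel, drop = FALSE]
    exit <- -rowSums(Tm)                      # rates out of ancestry p
    pi_p <- states$pi[sel]
    # entry flow from other-ancestry states
    nu <- colSums(Q[!sel, sel, drop = FALSE] * states$pi[!sel])
    rho <- sum(nu)
    beta <- if (rho > 0) nu / rho else rep(0, sum(sel))
    # evaluate the matrix-exponential integrals once per distinct length
    lens <- sort(unique(c(as.vector(vapply(genome, function(C)
      pmin(edges_M, C), edges_M)), unname(genome))))
    ints <- phase_integrals(Tm, lens)
    at <- function(l) ints[[match(l, lens)]]
    for (ci in seq_along(genome)) {
      C <- genome[[ci]]
      cl <- pmin(edges_M, C)
      atom_bin <- min(max(which(edges_M < C + 1e-12)), nb)
      for (b in seq_len(nb)) {
        i_lo <- at(cl[b]); i_hi <- at(cl[b + 1L])
        dF1 <- i_hi$F1 - i_lo$F1
        dG <- (cl[b + 1L] * i_hi$F1 - i_hi$F2) -
          (cl[b] * i_lo$F1 - i_lo$F2)       # int_a^b s E(s) ds
        interior <- if (rho > 0)
          rho * (C * drop(beta %*% dF1 %*% exit) -
                   drop(beta %*% dG %*% exit)) else 0
        left <- drop(pi_p %*% dF1 %*% exit)
        right <- if (rho > 0) rho * sum(beta %*% dF1) else 0
        cnt <- interior + left + right
        if (b == atom_bin) cnt <- cnt + sum(pi_p %*% at(C)$E)
        out[b, p] <- out[b, p] + cnt
      }
    }
  }
  out * n_haplotypes
}

#' Default tract-length histogram bins
#'
#' Equal-width bins (5.85 cM by default, at least 50 of them) from 0 cM to
#' past the longest chromosome, so that the sub-11.7 cM false-positive
#' exclusion corresponds exactly to the first two bins.
#'
#' @param genome named chromosome lengths, Morgans.
#' @param width bin width, cM.
#' @export
default_tract_bins <- function(genome = default_genome_map(), width = 5.85) {
  n_bins <- max(50L, ceiling(morgans_to_cm(max(genome)) / width))
  seq(0, by = width, length.out = n_bins + 1L)
}

# Expected total tract length per ancestry from the tract decomposition
# (interior + censored + whole-chromosome pieces); used to verify length
# conservation against the stationary proportions.
expected_tract_total_length <- function(model, genome = default_genome_map(),
                                        engine = "markov") {
  genome <- validate_genome_map(genome)
  gen <- build_tract_generator(model, engine)
  states <- gen$states
  Q <- gen$Q
  out <- stats::setNames(numeric(length(model$labels)), model$labels)
  for (p in model$labels) {
    sel <- states$pop == p
    if (!any(sel)) next
    Tm <- Q[sel, sel, drop = FALSE]
    exit <- -rowSums(Tm)
    pi_p <- states$pi[sel]
    nu <- colSums(Q[!sel, sel, drop = FALSE] * states$pi[!sel])
    rho <- sum(nu)
    beta <- if (rho > 0) nu / rho else rep(0, sum(sel))
    for (C in genome) {
      ii <- phase_integrals(Tm, C)[[1L]]
      G <- C * ii$F1 - ii$F2                   # int_0^C s E(s) ds
      S2 <- 2 * ii$F3 - 2 * C * ii$F2 + C^2 * ii$F1 # int_0^C s^2 E(s) ds
      interior <- if (rho > 0)
        rho * (C * drop(beta %*% G %*% exit) -
                 drop(beta %*% S2 %*% exit)) else 0
      left <- drop(pi_p %*% G %*% exit)
      right <- if (rho > 0) rho * sum(beta %*% G) else 0
      whole <- C * sum(pi_p %*% ii$E)
      out[p] <- out[p] + interior + left + right + whole
    }
  }
  out
}
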