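# Pairwise IBD segment generator. Segments between a pair at separation R are
# a Poisson process over (coalescence time t, segment length l): per
# chromosome the count intensity is
#   nu_c(t) = 2 L_c p(t|R) 2t (exp(-2t a) - exp(-2t b_c)),  b_c = min(b, L_c)
# (segments per Morgan with length in the window, given t), and lengths given
# t are window-truncated exponentials with rate 2t. The total expected shared
# length then equals the analytic expectation exactly; higher moments are a
# property of this construction, not of the model. Background sharing is a
# separate distance-independent Poisson channel calibrated to mean b.
ibd_pair_process <- function(params, R, genome, window = c(18, Inf),
                             n_grid = 4096L) {
  stopifnot(inherits(params, "diffusion_params"))
  genome <- validate_genome_map(genome)
  a <- cm_to_morgans(window[1L])
  b_full <- cm_to_morgans(window[2L])
  stopifnot(a > 0, b_full > a)
  t_star <- max(R / (4 * sqrt(a * params$D)), 1e-3)
  t_hi <- max(30 / (2 * a), 10 * t_star)
  tg <- exp(seq(log(1e-6), log(t_hi), length.out = n_grid))
  chroms <- list()
  for (cn in names(genome)) {
    Lc <- genome[[cn]]
    b_c <- min(b_full, Lc)
    if (a >= b_c) next
    nu <- function(t) 2 * Lc *
      coalescence_time_density(t, R, params$n, params$D) *
      2 * t * (exp(-2 * t * a) - exp(-2 * t * b_c))
    lambda <- stats::integrate(nu, 0, Inf, rel.tol = 1e-10,
                               abs.tol = 0)$value
    dens <- nu(tg)
    cdf <- cumsum((dens[-1L] + dens[-n_grid]) / 2 * diff(tg))
    cdf <- c(0, cdf / cdf[n_grid - 1L])
    keep <- c(TRUE, diff(cdf) > 0)   # strictly increasing for inversion
    cdf <- cdf[keep]
    # background channel: old/false-positive sharing, distance-independent
    lam_b <- 2 / a
    zb <- exp(-lam_b * a) - exp(-lam_b * b_c)
    mean_len_b <- (stats::integrate(function(l) l * lam_b * exp(-lam_b * l),
                                    a, b_c)$value) / zb
    chroms[[cn]] <- list(Lc = Lc, a = a, b = b_c, lambda = lambda,
                         tg = tg[keep], cdf = cdf, lam_b = lam_b,
                         mean_len_b = mean_len_b)
  }
  share <- vapply(chroms, `[[`, 0, "Lc")
  share <- share / sum(share)
  b_M <- cm_to_morgans(params$b)
  for (i in seq_along(chroms))
    chroms[[i]]$kappa_b <- share[i] * b_M / chroms[[i]]$mean_len_b
  structure(list(chroms = chroms, params = params, R = R, window = window),
            class = "ibd_pair_process")
}

# draw all segments for n_pairs independent pairs; returns pair index,
# chromosome, length (Morgans) and a spurious/background flag
sample_pair_segments <- function(process, n_pairs) {
  out <- list()
  for (cn in names(process$chroms)) {
    ch <- process$chroms[[cn]]
    k_model <- stats::rpois(n_pairs, ch$lambda)
    k_bg <- stats::rpois(n_pairs, ch$kappa_b)
    if (sum(k_model) > 0L) {
      t <- stats::approx(ch$cdf, ch$tg, xout = stats::runif(sum(k_model)),
                         rule = 2)$y
      u <- stats::runif(sum(k_model))
      ea <- exp(-2 * t * ch$a); eb <- exp(-2 * t * ch$b)
      l <- -log(ea - u * (ea - eb)) / (2 * t)
      out[[length(out) + 1L]] <-
        data.frame(pair = rep(seq_len(n_pairs), k_model), chrom = cn,
                   l = l, background = FALSE)
    }
    if (sum(k_bg) > 0L) {
      u <- stats::runif(sum(k_bg))
      ea <- exp(-ch$lam_b * ch$a); eb <- exp(-ch$lam_b * ch$b)
      l <- -log(ea - u * (ea - eb)) / ch$lam_b
      out[[length(out) + 1L]] <-
        data.frame(pair = rep(seq_len(n_pairs), k_bg), chrom = cn,
                   l = l, background = TRUE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(pair = integer(0), chrom = character(0), l = numeric(0),
                      background = logical(0)))
  do.call(rbind, out)
}

#' Simulate IBD segments for one pair of individuals
#'
#' Draws the IBD segments shared by two individuals a distance \code{R} apart
#' under the diffusion isolation-by-distance model plus a distance-independent
#' background channel. Over many replicate pairs, the mean total shared
#' length in the window converges to [expected_total_ibd()].
#'
#' @param params a [diffusion_params()].
#' @param R separation, km.
#' @param genome named chromosome lengths, Morgans.
#' @param window segment-length window, cM.
#' @param seed RNG seed.
#' @param ids the two individual identifiers.
#' @return An IBD segment table; attribute \code{background} flags segments
#'   from the background channel.
#' @export
simulate_pair_ibd <- function(params, R, genome = default_genome_map(),
                              window = c(18, Inf), seed = NULL,
                              ids = c("A", "B")) {
  proc <- ibd_pair_process(params, R, genome, window)
  with_seed(seed, {
    seg <- sample_pair_segments(proc, 1L)
    if (nrow(seg) == 0L) return(ibd_segments())
    start <- vapply(seq_len(nrow(seg)), function(i) {
      Lc <- proc$chroms[[seg$chrom[i]]]$Lc
      stats::runif(1L, 0, max(Lc - seg$l[i], 0))
    }, 0)
    out <- ibd_segments(ids[1L], ids[2L], seg$chrom,
                        morgans_to_cm(start),
                        morgans_to_cm(start + seg$l))
    attr(out, "background") <- seg$background
    out
  })
}

#' Simulate per-pair total IBD sharing for many pairs
#'
#' Vectorized batch form of [simulate_pair_ibd()] returning only the total
#' shared length (cM) per pair; used for decay-curve construction and
#' parameter-recovery experiments.
#'
#' @inheritParams simulate_pair_ibd
#' @param n_pairs number of independent pairs.
#' @return Numeric vector of length \code{n_pairs}, cM.
#' @export
simulate_pair_totals <- function(params, R, genome = default_genome_map(),
                                 window = c(18, Inf), n_pairs = 1L,
                                 seed = NULL) {
  proc <- ibd_pair_process(params, R, genome, window)
  with_seed(seed, {
    seg <- sample_pair_segments(proc, n_pairs)
    tot <- numeric(n_pairs)
    if (nrow(seg)) {
      agg <- rowsum(seg$l, seg$pair)
      tot[as.integer(rownames(agg))] <- agg[, 1L]
    }
    morgans_to_cm(tot)
  })
}

#' Simulate a spatially sampled IBD cohort
#'
#' Places individuals at clinics with known km-projected coordinates and
#' draws pairwise IBD segments for every pair from the diffusion model at the
#' inter-clinic distance (0 for same-clinic pairs), producing a full input
#' bundle for the relatedness pipeline alongside its generating truth.
#'
#' @param clinics data.frame with columns \code{name}, \code{x}, \code{y}
#'   (km) and \code{n} (individuals per clinic).
#' @param params a [diffusion_params()].
#' @param genome named chromosome lengths, Morgans.
#' @param window segment-length window, cM.
#' @param seed RNG seed.
#' @return List with \code{segments}, \code{cohort} (an [cohort()]), and
#'   \code{truth}.
#' @export
simulate_cohort_ibd <- function(clinics, params,
                                genome = default_genome_map(),
                                window = c(18, Inf), seed = NULL) {
  stopifnot(all(c("name", "x", "y", "n") %in% names(clinics)))
  inds <- do.call(rbind, lapply(seq_len(nrow(clinics)), function(i) {
    if (clinics$n[i] == 0L) return(NULL)
    data.frame(id = paste0(clinics$name[i], "_", seq_len(clinics$n[i])),
               region = clinics$name[i], x = clinics$x[i], y = clinics$y[i])
  }))
  if (is.null(inds))
    return(list(segments = ibd_segments(), cohort = cohort(
      data.frame(id = character(0), region = character(0),
                 x = numeric(0), y = numeric(0))),
      truth = list(params = params, window = window)))
  ch <- cohort(inds)
  with_seed(seed, {
    segs <- list()
    nc <- nrow(clinics)
    for (i in seq_len(nc)) for (j in i:nc) {
      R <- sqrt((clinics$x[i] - clinics$x[j])^2 +
                  (clinics$y[i] - clinics$y[j])^2)
      ids_i <- inds$id[inds$region == clinics$name[i]]
      ids_j <- inds$id[inds$region == clinics$name[j]]
      if (i == j) {
        if (length(ids_i) < 2L) next
        prs <- utils::combn(ids_i, 2L)
      } else {
        if (length(ids_i) == 0L || length(ids_j) == 0L) next
        prs <- rbind(rep(ids_i, each = length(ids_j)),
                     rep(ids_j, times = length(ids_i)))
      }
      proc <- ibd_pair_process(params, R, genome, window)
      seg <- sample_pair_segments(proc, ncol(prs))
      if (nrow(seg) == 0L) next
      start <- vapply(seq_len(nrow(seg)), function(k) {
        Lc <- proc$chroms[[seg$chrom[k]]]$Lc
        stats::runif(1L, 0, max(Lc - seg$l[k], 0))
      }, 0)
      segs[[length(segs) + 1L]] <-
        ibd_segments(prs[1L, seg$pair], prs[2L, seg$pair], seg$chrom,
                     morgans_to_cm(start), morgans_to_cm(start + seg$l))
    }
    segments <- if (length(segs)) do.call(rbind, segs) else ibd_segments()
    list(segments = segments, cohort = ch,
         truth = list(params = params, window = window))
  })
}

# --- forward Wright-Fisher admixture simulation ---------------------------

# haplotype representation per chromosome: list(ends, anc) where ends are
# cumulative tract endpoints in Morgans (last == Lc) and anc integer codes
extract_piece <- function(h, lo, hi) {
  e <- h$ends
  i0 <- which(e > lo + 1e-12)[1L]
  i1 <- which(e >= hi - 1e-12)[1L]
  list(ends = pmin(e[i0:i1], hi), anc = h$anc[i0:i1])
}

meiosis_chrom <- function(hA, hB, Lc) {
  k <- stats::rpois(1L, Lc)
  first <- sample(2L, 1L)
  if (k == 0L) return(if (first == 1L) hA else hB)
  cuts <- c(0, sort(stats::runif(k, 0, Lc)), Lc)
  ends <- numeric(0); anc <- integer(0)
  src <- first
  for (j in seq_len(k + 1L)) {
    h <- if (src == 1L) hA else hB
    piece <- extract_piece(h, cuts[j], cuts[j + 1L])
    ends <- c(ends, piece$ends)
    anc <- c(anc, piece$anc)
    src <- 3L - src
  }
  keep <- c(anc[-1L] != anc[-length(anc)], TRUE)
  list(ends = ends[keep], anc = anc[keep])
}

pure_haplotype <- function(genome, code)
  lapply(genome, function(Lc) list(ends = Lc, anc = code))

#' Forward Wright-Fisher simulation of admixture tracts
#'
#' Simulates a randomly mating diploid population of constant size under a
#' discrete-pulse admixture schedule: founders enter as unadmixed migrants,
#' each meiosis recombines at a Poisson rate of 1 per Morgan per chromosome,
#' and migrants at later generations replace a binomial fraction of the
#' population (monoecious mating, selfing excluded). Sampled haplotypes'
#' ancestry tracts tile each chromosome exactly.
#'
#' @param N diploid population size.
#' @param model a [pulse_model()]; its discrete schedule drives migration.
#' @param genome named chromosome lengths, Morgans.
#' @param n_sample number of diploid individuals sampled (<= N).
#' @param seed RNG seed.
#' @return Tract table: \code{id}, \code{haplotype}, \code{chrom},
#'   \code{start}, \code{end} (cM), \code{ancestry}.
#' @export
simulate_wf_admixture_tracts <- function(N, model,
                                         genome = default_genome_map(),
                                         n_sample = N, seed = NULL) {
  stopifnot(inherits(model, "pulse_model"), N >= 2, n_sample <= N)
  genome <- validate_genome_map(genome)
  mig <- model$mig
  Tmax <- nrow(mig)
  labels <- model$labels
  with_seed(seed, {
    top <- mig[Tmax, ] / sum(mig[Tmax, ])
    pop <- lapply(seq_len(N), function(i) {
      code <- sample.int(length(labels), 1L, prob = top)
      list(pure_haplotype(genome, code), pure_haplotype(genome, code))
    })
    for (d in seq(Tmax - 1L, 0L)) {
      newpop <- vector("list", N)
      for (i in seq_len(N)) {
        par <- sample.int(N, 2L, replace = FALSE)
        h1 <- mapply(function(a, b, Lc) meiosis_chrom(a, b, Lc),
                     pop[[par[1L]]][[1L]], pop[[par[1L]]][[2L]], genome,
                     SIMPLIFY = FALSE)
        h2 <- mapply(function(a, b, Lc) meiosis_chrom(a, b, Lc),
                     pop[[par[2L]]][[1L]], pop[[par[2L]]][[2L]], genome,
                     SIMPLIFY = FALSE)
        newpop[[i]] <- list(h1, h2)
      }
      if (d >= 1L) {
        Md <- sum(mig[d, ])
        if (Md > 0) {
          mask <- stats::runif(N) < Md
          for (i in which(mask)) {
            code <- sample.int(length(labels), 1L, prob = mig[d, ] / Md)
            newpop[[i]] <- list(pure_haplotype(genome, code),
                                pure_haplotype(genome, code))
          }
        }
      }
      pop <- newpop
    }
    rows <- list()
    for (i in seq_len(n_sample)) for (hap in 1:2) {
      h <- pop[[i]][[hap]]
      for (cn in names(genome)) {
        e <- h[[cn]]$ends
        rows[[length(rows) + 1L]] <-
          data.frame(id = paste0("ind", i), haplotype = hap - 1L, chrom = cn,
                     start = morgans_to_cm(c(0, e[-length(e)])),
                     end = morgans_to_cm(e),
                     ancestry = labels[h[[cn]]$anc])
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate generation-stratified census migration tables
#'
#' Draws weighted migration counts per generation from Poisson intensities
#' per origin-destination route, plus external inflow, retaining the ground
#' truth for tests of the census relatedness pipeline.
#'
#' @param regions region names.
#' @param intensity expected weighted count matrix (origin x destination), or
#'   a list of one matrix per generation.
#' @param external expected external inflow per destination (scalar or
#'   vector).
#' @param generations generation indices (default 1:3).
#' @param pop_sizes region population sizes (returned with the truth).
#' @param seed RNG seed.
#' @return List with \code{counts} (list of \code{migration_counts}),
#'   \code{pop_sizes} and \code{truth}.
#' @export
simulate_census_tables <- function(regions, intensity, external = 0,
                                   generations = 1:3, pop_sizes = NULL,
                                   seed = NULL) {
  k <- length(regions)
  ints <- if (is.list(intensity)) intensity else
    rep(list(intensity), length(generations))
  stopifnot(length(ints) == length(generations),
            all(vapply(ints, function(m) all(dim(m) == k), TRUE)),
            all(unlist(ints) >= 0))
  ext <- rep(external, length.out = k)
  with_seed(seed, {
    counts <- lapply(seq_along(generations), function(gi) {
      m <- matrix(stats::rpois(k * k, as.vector(ints[[gi]])), k, k,
                  dimnames = list(regions, regions))
      m_out <- stats::setNames(stats::rpois(k, ext), regions)
      structure(list(m = m, m_out = m_out, regions = regions,
                     generation = generations[gi]),
                class = "migration_counts")
    })
    list(counts = counts, pop_sizes = pop_sizes,
         truth = list(intensity = ints, external = ext))
  })
}

#' Plant a false-positive IBD hotspot
#'
#' Appends short spurious segments, each covering a fixed interval on one
#' chromosome (with small random overhangs), between randomly chosen pairs of
#' individuals; mimics the pile-ups produced by IBD callers at problem loci.
#'
#' @param segments an IBD segment table.
#' @param chrom chromosome label.
#' @param interval length-2 cM interval to cover.
#' @param extra_count number of spurious segments to add.
#' @param ids pool of individual identifiers to pair up.
#' @param seed RNG seed.
#' @param max_overhang maximum random overhang on each side, cM.
#' @return Segment table with the spurious rows appended; attribute
#'   \code{injected} flags them.
#' @export
inject_hotspot <- function(segments, chrom, interval, extra_count, ids,
                           seed = NULL, max_overhang = 0.5) {
  segments <- validate_ibd_segments(segments)
  stopifnot(length(interval) == 2L, interval[1L] < interval[2L],
            length(ids) >= 2L)
  if (extra_count == 0L) {
    attr(segments, "injected") <- rep(FALSE, nrow(segments))
    return(segments)
  }
  with_seed(seed, {
    a <- matrix(NA_character_, extra_count, 2L)
    for (i in seq_len(extra_count)) a[i, ] <- sample(ids, 2L)
    lo <- interval[1L] - stats::runif(extra_count, 0, max_overhang)
    hi <- interval[2L] + stats::runif(extra_count, 0, max_overhang)
    extra <- ibd_segments(a[, 1L], a[, 2L], chrom, lo, hi)
    out <- rbind(segments, extra)
    attr(out, "injected") <- c(rep(FALSE, nrow(segments)),
                               rep(TRUE, extra_count))
    out
  })
}

#' Simulate birth-year-stratified admixture-time estimates
#'
#' Groups born later lie further from the admixture onset:
#' \code{g = 1 + (mean_year - T0) / tau} plus optional Gaussian noise
#' (clamped at 1 generation). Supports recovery tests of
#' [generation_time_fit()].
#'
#' @param tau generation time, years.
#' @param T0 calendar year of admixture onset.
#' @param mean_years group mean birth years.
#' @param noise_sd Gaussian noise on g, generations.
#' @param seed RNG seed.
#' @return data.frame with \code{mean_year} and \code{g}.
#' @export
simulate_birth_year_admixture <- function(tau, T0, mean_years,
                                          noise_sd = 0, seed = NULL) {
  stopifnot(tau > 0, all(mean_years > T0))
  with_seed(seed, {
    g <- 1 + (mean_years - T0) / tau +
      stats::rnorm(length(mean_years), 0, noise_sd)
    data.frame(mean_year = mean_years, g = pmax(g, 1))
  })
}
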