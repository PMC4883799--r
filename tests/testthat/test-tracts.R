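totals2 <- c(AFR = 0.75, EUR = 0.25)
totals3 <- c(AFR = 0.80, EUR = 0.17, NAT = 0.03)

test_that("model nomenclature parses with the documented parameter counts", {
  cases <- list(list("pp", 2, 1), list("pp_xp", 2, 3),
                list("pxp_xpx", 3, 2), list("ppp_xpx", 3, 3),
                list("pxp_xpx_xpx", 3, 4), list("xpp_pxx_xpx", 3, 4))
  for (cs in cases) {
    fam <- parse_pulse_family(cs[[1]])
    expect_equal(fam$n_pops, cs[[2]], info = cs[[1]])
    expect_equal(fam$k, cs[[3]], info = cs[[1]])
  }
  expect_error(parse_pulse_family("zp"), "parse")
  expect_error(parse_pulse_family("xx_pp"), "found")
})

test_that("pulse models honor fixed totals and reject infeasible histories", {
  m <- pulse_model("pp_xp", c(9, 4), totals2, rel = 0.5)
  expect_equal(unname(m$proportions), unname(totals2), tolerance = 1e-9)
  m3 <- pulse_model("pxp_xpx_xpx", c(12, 7, 3), totals3, rel = 0.4)
  expect_equal(unname(m3$proportions), unname(totals3), tolerance = 1e-9)
  expect_error(pulse_model("pp", c(5, 2), totals2), "length")
  expect_error(pulse_model("pp_xp", c(2, 5), totals2, rel = 0.5),
               "decrease")
  expect_error(pulse_model("pp_xp", c(9, 4), totals2, rel = 1.2),
               "inside")
})

test_that("tract generators are stationary and conserve ancestry lengths", {
  genome <- toy_genome()
  models <- list(
    list(pulse_model("pp", 6, totals2), "markov"),
    list(pulse_model("pp", 6, totals2), "pedigree"),
    list(pulse_model("pp", 5.3, totals2), "markov"),
    list(pulse_model("pp_xp", c(8.3, 3.8), totals2, rel = 0.45), "markov"),
    list(pulse_model("pxp_xpx", c(11, 6), totals3), "markov"))
  for (case in models) {
    m <- case[[1]]; engine <- case[[2]]
    gen <- ibdgeo:::build_tract_generator(m, engine)
    expect_equal(max(abs(rowSums(gen$Q))), 0, tolerance = 1e-10)
    expect_equal(max(abs(gen$states$pi %*% gen$Q)), 0, tolerance = 1e-10)
    tot <- ibdgeo:::expected_tract_total_length(m, genome, engine)
    target <- if (engine == "pedigree") m$m[1, ] else m$proportions
    expect_equal(tot / sum(genome), target[names(tot)], tolerance = 1e-6)
  }
})

test_that("first-generation admixture yields whole-chromosome tracts only", {
  m <- pulse_model("pp", 1, c(AFR = 0.6, EUR = 0.4))
  edges <- seq(0, 100, by = 10)
  mu <- expected_tract_histogram(m, c("1" = 1.0), 10, edges)
  expect_equal(unname(colSums(mu)), c(6, 4))
  expect_equal(unname(mu[10, ]), c(6, 4)) # all mass in the terminal bin
  tr <- simulate_wf_admixture_tracts(40, m, toy_genome(), seed = 2)
  expect_true(all(tr$start == 0))
  lens <- morgans_to_cm(toy_genome())[as.character(tr$chrom)]
  expect_equal(tr$end, unname(lens))
})

test_that("expected histogram is linear in the number of haplotypes", {
  m <- pulse_model("pp", 4, totals2)
  edges <- seq(0, 100, 20)
  expect_equal(expected_tract_histogram(m, toy_genome(), 200, edges),
               2 * expected_tract_histogram(m, toy_genome(), 100, edges))
})

test_that("pedigree engine reproduces the exact two-generation law", {
  # at g = 2 a haplotype alternates between the parent's two pure haplotypes:
  # P(uninterrupted chromosome of ancestry p) = a_p^2 + a_p(1-a_p) e^{-L}
  a <- 0.5; L <- 1
  m <- pulse_model("pp", 2, c(AFR = a, EUR = a))
  mu <- expected_tract_histogram(m, c("1" = L), 1, seq(0, 100, 50),
                                 engine = "pedigree")
  atom <- a^2 + a * (1 - a) * exp(-L)
  expect_gte(mu[2, "AFR"], atom)      # terminal bin contains the atom
  tot <- ibdgeo:::expected_tract_total_length(m, c("1" = L), "pedigree")
  expect_equal(unname(tot), c(a * L, a * L), tolerance = 1e-9)
})

test_that("WF-simulated histograms match the pedigree-engine expectation", {
  gen1 <- c("1" = 1.0)
  m <- pulse_model("pp", 2, c(AFR = 0.5, EUR = 0.5))
  tr <- simulate_wf_admixture_tracts(1200, m, gen1, seed = 31)
  edges <- seq(0, 100, by = 10)
  h <- tract_histogram(tr, gen1, edges)
  mu <- expected_tract_histogram(m, gen1, h$n_haplotypes, edges,
                                 engine = "pedigree")
  obs <- h$counts[, colnames(mu)]
  se <- pmax(sqrt(mu), 1)
  expect_lt(max(abs(obs - mu) / se), 3.5)
})

test_that("global ancestry proportions are length ratios and require tiling", {
  genome <- c("1" = 1.0)
  tr <- data.frame(id = "i1", haplotype = 0L, chrom = "1",
                   start = c(0, 60), end = c(60, 100),
                   ancestry = c("AFR", "EUR"))
  ga <- global_ancestry(tr, genome)
  expect_equal(ga$AFR, 0.6)
  expect_equal(ga$EUR, 0.4)
  solid <- data.frame(id = "i2", haplotype = 0L, chrom = "1",
                      start = 0, end = 100, ancestry = "AFR")
  expect_equal(global_ancestry(solid, genome)$AFR, 1)
  gap <- tr; gap$end[1] <- 55
  expect_error(global_ancestry(gap, genome), "tile")
})

test_that("WF ancestry proportions recover the planted admixture fraction", {
  # drift makes individuals within one population correlated, so the MC
  # error is taken across independent replicate populations
  m <- pulse_model("pp", 8, c(AFR = 0.7496, EUR = 0.2504))
  means <- vapply(1:8, function(r) {
    tr <- simulate_wf_admixture_tracts(50, m, toy_genome(), seed = 50 + r)
    mean(global_ancestry(tr, toy_genome())$AFR)
  }, 0)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.7496), 3 * se)
})

test_that("histogram exclusion masks exactly the sub-11.7 cM default bins", {
  m <- pulse_model("pp", 6, totals2)
  tr <- simulate_wf_admixture_tracts(30, m, toy_genome(), seed = 6)
  h <- tract_histogram(tr, toy_genome())
  expect_equal(sum(h$excluded), 2L)
  expect_equal(h$bin_edges[3], 11.7)
  expect_equal(h$n_haplotypes, 60)
  expect_equal(sum(h$counts), nrow(tr))
})

test_that("single-pulse fits recover the generating time", {
  genome <- default_genome_map()[seq(1, 22, 2)]
  m <- pulse_model("pp", 6, totals2)
  edges <- default_tract_bins(genome)
  mu <- expected_tract_histogram(m, genome, 2000, edges)
  ok <- 0
  reps <- 12
  for (r in seq_len(reps)) {
    set.seed(300 + r)
    counts <- matrix(stats::rpois(length(mu), mu), nrow(mu),
                     dimnames = dimnames(mu))
    h <- structure(list(bin_edges = edges, counts = counts,
                        n_haplotypes = 2000,
                        excluded = edges[-1] <= 11.7),
                   class = "tract_histogram")
    fit <- fit_pulse_model(h, "pp", totals2, genome,
                           time_grid = seq(2, 12, 0.5))
    if (fit$times >= 5.5 && fit$times <= 6.5) ok <- ok + 1
  }
  expect_gte(ok, ceiling(0.9 * reps))
})

test_that("true generating model beats time-perturbed alternatives", {
  genome <- toy_genome()
  m <- pulse_model("pp", 6, totals2)
  edges <- seq(0, 100, 5)
  mu <- expected_tract_histogram(m, genome, 5e4, edges)
  ll <- function(g) {
    mm <- pulse_model("pp", g, totals2)
    mu_g <- expected_tract_histogram(mm, genome, 5e4, edges)
    sum(stats::dpois(round(mu), pmax(mu_g, 1e-12), log = TRUE))
  }
  expect_gt(ll(6), ll(4.5))
  expect_gt(ll(6), ll(7.5))
})

test_that("non-identifiable all-one-ancestry histograms are rejected", {
  h <- structure(list(bin_edges = seq(0, 100, 10),
                      counts = matrix(5L, 10, 2,
                                      dimnames = list(NULL, c("AFR", "EUR"))),
                      n_haplotypes = 10, excluded = rep(FALSE, 10)),
                 class = "tract_histogram")
  expect_error(fit_pulse_model(h, "pp", c(AFR = 1, EUR = 0)),
               "not identifiable")
})

test_that("information criteria use the free-parameter counts", {
  # two-pulse fit beats single pulse by 631 log-likelihood units, n = 100
  tab <- model_selection(data.frame(family = c("pp", "pp_xp"),
                                    k = c(1, 3),
                                    loglik = c(-1631, -1000)),
                         n_points = 100)
  expect_equal(tab$family[1], "pp_xp") # preferred by AIC ordering
  expect_true(tab$BIC[tab$family == "pp_xp"] <
                tab$BIC[tab$family == "pp"])
  # equal likelihoods: the smaller model wins on both criteria
  tie <- model_selection(data.frame(family = c("pp", "pp_xp"),
                                    k = c(1, 3), loglik = c(-500, -500)),
                         n_points = 100)
  expect_equal(tie$family[1], "pp")
})

test_that("generation-time regression inverts the birth-year gradient", {
  years <- c(1915, 1925, 1935, 1945, 1955)
  exact <- simulate_birth_year_admixture(27.4, 1800, years)
  fit <- suppressWarnings(generation_time_fit(exact)) # r^2 = 1 exactly
  expect_equal(fit$tau, 27.4, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_false(fit$degenerate)
  two <- suppressWarnings(generation_time_fit(exact[1:2, ]))
  expect_true(two$degenerate)
  expect_equal(two$tau, 27.4, tolerance = 1e-9)
  flipped <- exact; flipped$g <- rev(flipped$g)
  expect_error(generation_time_fit(flipped), "slope")
})

test_that("generation time is recovered from noisy cohorts", {
  # decadal birth-year groups; per-group noise of ~0.12 generations matches
  # the sampling error of a tract fit on a few hundred individuals
  years <- seq(1900, 1970, by = 10)
  ok <- 0
  for (r in 1:20) {
    sim <- simulate_birth_year_admixture(27.4, 1800, years, noise_sd = 0.12,
                                         seed = 400 + r)
    tau <- generation_time_fit(sim)$tau
    if (abs(tau - 27.4) / 27.4 < 0.1) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("calendar-year conversion is exact and affine", {
  expect_equal(admixture_calendar_year(1939.8, 5.8, 27.4), 1808.28)
  expect_equal(admixture_calendar_year(1946.9, 6.3, 27.4), 1801.68)
  expect_equal(admixture_calendar_year(1950, 1, 27.4), 1950)
  expect_error(admixture_calendar_year(1950, 0.5, 27.4), "at least 1")
  # affine in g and tau
  a <- admixture_calendar_year(1900, 3, 20)
  expect_equal(admixture_calendar_year(1900, 4, 20), a - 20)
  expect_equal(admixture_calendar_year(1900, 3, 25), 1900 - 2 * 25)
})

test_that("bootstrap CIs are percentile-based, seeded, and degenerate on constants", {
  const <- data.frame(id = 1:20, v = 5)
  ci <- bootstrap_ci(function(d) c(mean = mean(d$v)), const, ids = const$id,
                     reps = 50, seed = 1)
  expect_equal(unname(ci$ci[1, ]), 5)
  expect_equal(unname(ci$ci[2, ]), 5)
  set.seed(99)
  dat <- data.frame(id = 1:40, v = rnorm(40))
  c1 <- bootstrap_ci(function(d) c(mean = mean(d$v)), dat, ids = dat$id,
                     reps = 100, seed = 7)
  c2 <- bootstrap_ci(function(d) c(mean = mean(d$v)), dat, ids = dat$id,
                     reps = 100, seed = 7)
  expect_identical(c1$ci, c2$ci)
  expect_lte(c1$ci["lower", "mean"], mean(dat$v))
  expect_gte(c1$ci["upper", "mean"], mean(dat$v))
  # failing replicates are dropped with a warning
  flaky <- function(d) if (mean(d$v) > median(dat$v)) stop("no") else
    c(mean = mean(d$v))
  expect_warning(res <- bootstrap_ci(flaky, dat, ids = dat$id, reps = 60,
                                     seed = 3), "dropped")
  expect_gt(res$n_failed, 0)
  # with id_column, duplicate draws of one individual stay distinguishable
  multi <- data.frame(id = rep(letters[1:6], each = 3), v = rnorm(18))
  nid <- bootstrap_ci(function(d) c(k = length(unique(d$id))), multi,
                      id_column = "id", reps = 10, seed = 4)
  expect_true(all(nid$estimates[, "k"] == 6))
})

test_that("sex-bias solver matches the 2x2 algebra and pins infeasible males", {
  a <- c(AFR = 0.5, EUR = 0.5); x <- a
  eq <- sex_bias_solve(a, x)
  expect_equal(eq$m, a)
  expect_equal(eq$f, a)
  # autosomal 16.7% / X 12.89% European: m ~ 28.1%, f ~ 5.3% unconstrained
  auto <- c(AFR = 0.821, EUR = 0.167, NAT = 0.012)
  xs <- c(AFR = 0.8482, EUR = 0.1289, NAT = 0.0229)
  sol <- sex_bias_solve(auto / sum(auto), xs / sum(xs))
  expect_equal(unname(sol$unconstrained$m["EUR"]),
               unname(4 * (auto / sum(auto))["EUR"] -
                        3 * (xs / sum(xs))["EUR"]))
  expect_lt(sol$unconstrained$m[["NAT"]], 0)
  expect_equal(sol$m[["NAT"]], 0, tolerance = 1e-4)
  # constrained optimum stays near the unconstrained European solution
  expect_lt(abs(sol$m[["EUR"]] - 0.281), 0.03)
  expect_lt(abs(sol$f[["EUR"]] - 0.053), 0.03)
  expect_equal(sum(sol$m), 1, tolerance = 1e-3)
  expect_equal(sum(sol$f), 1, tolerance = 1e-3)
  # and does not fit worse than clipping the unconstrained solution
  clip <- function(v) pmin(pmax(v, 0), 1)
  a2 <- auto / sum(auto); x2 <- xs / sum(xs)
  rss_clip <- sum((a2 - (clip(sol$unconstrained$m) +
                           clip(sol$unconstrained$f)) / 2)^2 +
                    (x2 - (clip(sol$unconstrained$m) +
                             2 * clip(sol$unconstrained$f)) / 3)^2)
  expect_lte(sol$rss, rss_clip + 1e-9)
})

test_that("ancestry-difference bootstrap is calibrated and seeded", {
  set.seed(11)
  a <- rnorm(200, 0.8, 0.1)
  t1 <- ancestry_difference_test(a, a, reps = 2000, seed = 2)
  expect_gt(t1$p_value, 0.5)
  p1 <- ancestry_difference_test(a, a + 0.05, reps = 2000, seed = 2)$p_value
  expect_identical(
    p1, ancestry_difference_test(a, a + 0.05, reps = 2000, seed = 2)$p_value)
  # planted 3-SE shift is detected in most replicates
  ok <- 0
  for (r in 1:20) {
    set.seed(500 + r)
    g1 <- rnorm(200, 0.8, 0.1)
    g2 <- rnorm(200, 0.8 + 3 * 0.1 * sqrt(2 / 200), 0.1)
    p <- ancestry_difference_test(g1, g2, reps = 1000, seed = r)$p_value
    if (p < 0.05) ok <- ok + 1
  }
  expect_gte(ok, 18)
  expect_warning(ancestry_difference_test(0.5, c(0.4, 0.6), reps = 100,
                                          seed = 1), "singleton")
})
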