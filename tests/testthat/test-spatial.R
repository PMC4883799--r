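test_that("dispersal kernel is a proper density with variance 4Dt", {
  D <- 30; t <- 2.5
  expect_equal(lineage_kernel(0, t, D), 1 / (4 * pi * D * t))
  # polar-coordinate quadrature over the plane
  mass <- integrate(function(r) 2 * pi * r * lineage_kernel(r, t, D),
                    0, Inf, rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-6)
  msd <- integrate(function(r) 2 * pi * r^3 * lineage_kernel(r, t, D),
                   0, Inf, rel.tol = 1e-10)$value
  expect_equal(msd, 4 * D * t, tolerance = 1e-6)
  expect_error(lineage_kernel(1, 0, D), "positive")
})

test_that("coalescence-time density equals the kernel convolution", {
  n <- 1.7; D <- 40; R <- 60; t <- 5
  expect_equal(coalescence_time_density(t, 0, n, D),
               1 / (16 * pi * n * D * t))
  # Numeric convolution: integrate phi(x|0) phi(x|R) / 2n over the plane
  # (nested adaptive quadrature, y then x)
  fy <- function(x) vapply(x, function(xi) integrate(function(y)
    lineage_kernel(sqrt(xi^2 + y^2), t, D) *
      lineage_kernel(sqrt((xi - R)^2 + y^2), t, D),
    -Inf, Inf, rel.tol = 1e-11, abs.tol = 0)$value, 0)
  oracle <- integrate(fy, -Inf, Inf, rel.tol = 1e-11,
                      abs.tol = 0)$value / (2 * n)
  expect_equal(coalescence_time_density(t, R, n, D), oracle,
               tolerance = 1e-6)
})

test_that("coalescence-time density peaks at R^2/8D", {
  n <- 1; D <- 20; R <- 100
  tstar <- R^2 / (8 * D)
  ts <- tstar * c(0.2, 0.5, 0.9)
  expect_true(all(diff(coalescence_time_density(ts, R, n, D)) > 0))
  ts2 <- tstar * c(1.1, 2, 5)
  expect_true(all(diff(coalescence_time_density(ts2, R, n, D)) < 0))
})

test_that("closed-form IBD fraction has the documented zero-distance limit", {
  expect_equal(expected_ibd_fraction(0.18, 1.0, 0, 1, 1),
               log(1 / 0.18) / (16 * pi), tolerance = 1e-12)
})

test_that("closed form agrees with the numeric double integral", {
  cases <- expand.grid(n = c(1, 2.8), D = c(30, 88.6),
                       R = c(10, 51, 200), lmax = c(1, 3))
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    cl <- expected_ibd_fraction(0.18, cs$lmax, cs$R, cs$n, cs$D)
    nu <- expected_ibd_fraction(0.18, cs$lmax, cs$R, cs$n, cs$D,
                                method = "numeric")
    expect_equal(cl, nu, tolerance = 1e-6)
  }
})

test_that("small-R expansion matches: ratio of model to expansion tends to 1", {
  n <- 2.8; D <- 88.6; lmin <- 0.18; lmax <- 3
  expansion <- function(R)
    (log(lmax / lmin) - (lmax - lmin) * R^2 / (4 * D)) / (16 * pi * n * D)
  ratios <- vapply(c(0.1, 0.01, 0.001), function(R)
    expected_ibd_fraction(lmin, lmax, R, n, D) / expansion(R), 0)
  expect_equal(ratios, rep(1, 3), tolerance = 1e-5)
  err <- abs(ratios - 1)
  expect_true(all(diff(err) <= 0))
})

test_that("IBD fraction is monotone in R, additive over windows, scale-invariant", {
  n <- 2; D <- 50
  E <- expected_ibd_fraction(0.1, 2, c(50, 500), n, D)
  expect_lt(E[2], E[1])
  expect_equal(expected_ibd_fraction(0.1, 0.5, 77, n, D) +
                 expected_ibd_fraction(0.5, 2.0, 77, n, D),
               expected_ibd_fraction(0.1, 2.0, 77, n, D))
  # R -> cR, D -> c^2 D leaves E * n D invariant
  cc <- 3
  expect_equal(expected_ibd_fraction(0.1, 2, 77, n, D) * n * D,
               expected_ibd_fraction(0.1, 2, cc * 77, n, cc^2 * D) *
                 n * cc^2 * D)
})

test_that("expected total IBD reduces to the background at long range", {
  p <- diffusion_params(2.8, 88.6, 0.0389)
  expect_equal(expected_total_ibd(p, 1e6), 0.0389, tolerance = 1e-9)
  one <- c("7" = 1.5)
  direct <- 0.01 + 100 * 2 * 1.5 *
    expected_ibd_fraction(0.18, 1.5, 51, 2.8, 88.6)
  expect_equal(expected_total_ibd(diffusion_params(2.8, 88.6, 0.01), 51,
                                  one), direct)
  vals <- expected_total_ibd(p, c(51, 251))
  expect_gt(vals[1], vals[2])
})

test_that("rms displacement follows sqrt(4D)", {
  expect_equal(round(rms_displacement(88.6), 1), 18.8)
  expect_equal(rms_displacement(63.5), sqrt(4 * 63.5))
  expect_equal(rms_displacement(0.25), 1)
})

test_that("finite-genome correction recovers the infinite-genome limit", {
  p <- diffusion_params(1, 50, 0)
  huge <- c("1" = 1e4)
  expect_equal(finite_genome_ibd(p, 100, huge, 0.18, t_min = 1e-8),
               expected_total_ibd(p, 100, huge, 0.18), tolerance = 0.01)
  vals <- finite_genome_ibd(p, c(20, 80, 300), default_genome_map()[1:3],
                            0.18)
  expect_true(all(diff(vals) < 0))
})

test_that("refitting with the finite-genome model lowers the density estimate", {
  genome <- default_genome_map()[seq(1, 22, by = 4)]
  R <- c(0.5, 51, 151, 251, 401, 601)
  p <- diffusion_params(2.8, 88.6, 0.0389)
  curve <- data.frame(midpoint_km = R,
                      mean_cM = expected_total_ibd(p, R, genome),
                      se_cM = NA_real_)
  fit <- fit_decay(curve, genome, model = "finite", t_min = 1)
  # direction-level check: excluding t < 1 lowers the fitted density
  expect_lt(fit$params$n, 2.8 * 0.97)
  expect_gt(fit$params$n, 1.8)
  # and the corrected model still reproduces the curve closely
  expect_lt(max(abs(fit$fitted - curve$mean_cM) / curve$mean_cM), 0.02)
})

test_that("noiseless decay curves return the generating parameters", {
  genome <- default_genome_map()
  R <- c(0.5, 51, 151, 251, 351, 451, 551, 651, 751, 851)
  p <- diffusion_params(2.8, 88.6, 0.0389)
  curve <- data.frame(midpoint_km = R,
                      mean_cM = expected_total_ibd(p, R, genome),
                      se_cM = NA_real_)
  fit <- fit_decay(curve, genome)
  expect_equal(fit$params$n, 2.8, tolerance = 1e-3)
  expect_equal(fit$params$D, 88.6, tolerance = 1e-3)
  expect_equal(fit$params$b, 0.0389, tolerance = 1e-2)
})

test_that("with fixed (n, D) the background fit is location-equivariant", {
  genome <- default_genome_map()[1:4]
  R <- c(0.5, 51, 151, 251, 451)
  p <- diffusion_params(2.8, 88.6, 0.04)
  curve <- data.frame(midpoint_km = R,
                      mean_cM = expected_total_ibd(p, R, genome),
                      se_cM = rep(0.01, 5))
  f1 <- fit_decay(curve, genome, fixed = list(n = 2.8, D = 88.6))
  curve2 <- curve
  curve2$mean_cM <- curve2$mean_cM + 0.1
  f2 <- fit_decay(curve2, genome, fixed = list(n = 2.8, D = 88.6))
  expect_equal(f2$params$b - f1$params$b, 0.1, tolerance = 1e-9)
})

test_that("TMRCA posterior mean matches the quadrature oracle", {
  expect_equal(tmrca_expected(0.18, 1e6), 8.333, tolerance = 1e-3)
  expect_equal(tmrca_expected(0.03, 1e6), 50, tolerance = 1e-4)
  N <- 50; l <- 0.1
  post <- function(g) (2 * g)^2 * l * exp(-2 * g * l) * exp(-g / N) / N
  oracle <- integrate(function(g) g * post(g), 0, Inf, rel.tol = 1e-12)$value /
    integrate(post, 0, Inf, rel.tol = 1e-12)$value
  expect_equal(tmrca_expected(l, N), oracle, tolerance = 1e-9)
  # the gap to the asymptotic 3/(2l) is exactly 1/(2lN + 1) and vanishes
  # with growing N
  gap <- function(N) abs(tmrca_expected(l, N) - 3 / (2 * l)) / (3 / (2 * l))
  expect_equal(gap(N), 1 / (2 * l * N + 1), tolerance = 1e-9)
  expect_true(all(diff(vapply(c(50, 500, 5000), gap, 0)) < 0))
})
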