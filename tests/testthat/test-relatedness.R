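test_that("relatedness matrices match a brute-force oracle and stay symmetric", {
  ch <- toy_cohort()
  set.seed(42)
  ids <- ch$individuals$id
  prs <- t(combn(ids, 2))
  pick <- prs[sample(nrow(prs), 5, replace = TRUE), , drop = FALSE]
  start <- runif(5, 0, 50)
  seg <- ibd_segments(pick[, 1], pick[, 2], sample(c("1", "2"), 5, TRUE),
                      start, start + runif(5, 1, 30))
  mats <- build_relatedness_matrices(seg, ch, window = c(0, Inf))
  oracle <- brute_force_matrices(seg, ids, c(0, Inf))
  expect_equal(mats$L, oracle$L)
  expect_equal(mats$N + 0, oracle$N)
  expect_true(isSymmetric(mats$L))
  expect_true(all(diag(mats$L) == 0) && all(diag(mats$N) == 0))
  expect_true(all(mats$L[mats$N == 0] == 0))
})

test_that("window restriction and exclusion lists are honored", {
  ch <- toy_cohort()
  seg <- ibd_segments("A", "B", "1", 0, 20)
  mats <- build_relatedness_matrices(seg, ch, window = c(18, Inf))
  expect_equal(mats$L["A", "B"], 20)
  expect_equal(mats$N["B", "A"], 1L)
  # excluded related pair contributes nothing
  ch2 <- cohort(toy_cohort()$individuals,
                data.frame(id_a = "B", id_b = "A"))
  mats2 <- build_relatedness_matrices(seg, ch2, window = c(18, Inf))
  expect_true(all(mats2$L == 0) && all(mats2$N == 0))
  # below-window segment ignored
  mats3 <- build_relatedness_matrices(ibd_segments("A", "B", "1", 0, 17.9),
                                      ch, window = c(18, Inf))
  expect_true(all(mats3$L == 0))
  expect_error(build_relatedness_matrices(
    ibd_segments("A", "ZZ", "1", 0, 20), ch), "not in cohort")
})

test_that("cohort TSVs round-trip through read_cohort", {
  ind <- toy_cohort()$individuals
  mp <- tempfile(fileext = ".tsv"); ep <- tempfile(fileext = ".tsv")
  write.table(ind, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(id_a = "A", id_b = "B"), ep, sep = "\t",
              quote = FALSE, row.names = FALSE)
  ch <- read_cohort(mp, ep)
  expect_s3_class(ch, "ibd_cohort")
  expect_equal(ch$individuals$id, ind$id)
  expect_equal(nrow(ch$excluded_pairs), 1L)
})

test_that("regional relatedness implements the pair-count normalization", {
  ind <- data.frame(id = letters[1:5],
                    group = "AFR",
                    region = c("r1", "r1", "r2", "r2", "r2"),
                    x = 0, y = 0)
  ch <- cohort(ind)
  seg <- ibd_segments("a", "c", "1", 0, 10)
  mats <- build_relatedness_matrices(seg, ch, window = c(0, Inf))
  # distinct regions: N_pairs = n1 * n2 = 2 * 3
  expect_equal(regional_relatedness(mats, ch, list(region = "r1"),
                                    list(region = "r2")), 10 / 6)
  # same region: N_pairs = n (n - 1) / 2
  seg2 <- rbind(ibd_segments("c", "d", "1", 0, 8),
                ibd_segments("d", "e", "1", 0, 4))
  mats2 <- build_relatedness_matrices(seg2, ch, window = c(0, Inf))
  expect_equal(regional_relatedness(mats2, ch, list(region = "r2"),
                                    list(region = "r2")), 12 / 3)
  # suppression threshold
  expect_identical(regional_relatedness(mats, ch, list(region = "r1"),
                                        list(region = "r2"),
                                        min_pairs = 10000), "suppressed")
  expect_error(regional_relatedness(mats, ch, list(region = "nowhere"),
                                    list(region = "r2")), "empty")
})

test_that("a two-individual cohort reduces to the pairwise entry", {
  ch <- cohort(data.frame(id = c("A", "B"), group = "AFR",
                          region = c("r1", "r2"), x = 0, y = 0))
  seg <- ibd_segments("A", "B", "1", 0, 25)
  mats <- build_relatedness_matrices(seg, ch, window = c(18, Inf))
  expect_equal(regional_relatedness(mats, ch, list(region = "r1"),
                                    list(region = "r2")),
               mats$L["A", "B"])
})

test_that("decay curve bins pairs by distance with the documented midpoints", {
  ch <- cohort(data.frame(id = c("A", "B"), region = "r", group = "AFR",
                          x = c(0, 51), y = 0))
  seg <- ibd_segments("A", "B", "1", 0, 20)
  mats <- build_relatedness_matrices(seg, ch, window = c(18, Inf))
  curve <- distance_decay_curve(mats, ch)
  expect_equal(curve$midpoint_km[2], 51)
  expect_equal(curve$mean_cM[2], 20)
  expect_equal(curve$n_pairs[2], 1L)
  expect_true(is.na(curve$mean_cM[1]))  # empty bins flagged, not zero-filled
  expect_equal(curve$n_pairs[1], 0L)
})

test_that("decay curve agrees with brute-force binning and conserves total L", {
  set.seed(7)
  ind <- data.frame(id = paste0("i", 1:15), group = "AFR", region = "r",
                    x = runif(15, 0, 400), y = runif(15, 0, 400))
  ch <- cohort(ind)
  prs <- t(combn(ind$id, 2))
  keep <- sample(nrow(prs), 40, replace = TRUE)
  seg <- ibd_segments(prs[keep, 1], prs[keep, 2], "1",
                      st <- runif(40, 0, 50), st + runif(40, 18, 40))
  mats <- build_relatedness_matrices(seg, ch, window = c(18, Inf))
  edges <- c(0, 1, seq(101, 1001, 100))
  curve <- distance_decay_curve(mats, ch, edges)
  # brute force
  means <- rep(NA_real_, length(edges) - 1); cnt <- rep(0, length(edges) - 1)
  tot <- rep(0, length(edges) - 1)
  for (i in 1:14) for (j in (i + 1):15) {
    d <- sqrt(sum((ind[i, c("x", "y")] - ind[j, c("x", "y")])^2))
    b <- findInterval(d, edges)
    cnt[b] <- cnt[b] + 1
    tot[b] <- tot[b] + mats$L[ind$id[i], ind$id[j]]
  }
  means[cnt > 0] <- tot[cnt > 0] / cnt[cnt > 0]
  expect_equal(curve$mean_cM, means)
  expect_equal(curve$n_pairs, cnt)
  got <- sum(curve$mean_cM * curve$n_pairs, na.rm = TRUE)
  expect_equal(got, sum(mats$L) / 2)
  expect_error(distance_decay_curve(mats, cohort(
    data.frame(id = "A", region = "r", x = NA_real_, y = 1))),
    "missing coordinates")
})
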