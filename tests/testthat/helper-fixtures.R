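# Shared fixtures built in code.

toy_genome <- function() c("1" = 1.0, "2" = 0.8)

toy_cohort <- function() {
  cohort(data.frame(
    id = c("A", "B", "C", "D", "E"),
    group = c("AFR", "AFR", "AFR", "EUR", "EUR"),
    region = c("south", "south", "north", "north", "south"),
    x = c(0, 0, 30, 30, 51),
    y = c(0, 0, 40, 40, 0)))
}

# write a canonical IBD TSV and return its path
write_canonical_fixture <- function(df, dir = tempdir()) {
  path <- tempfile("ibd", fileext = ".tsv", tmpdir = dir)
  write_ibd_segments(df, path)
  path
}

# independent brute-force pairwise aggregation used as an oracle against
# build_relatedness_matrices
brute_force_matrices <- function(segments, ids, window) {
  n <- length(ids)
  L <- matrix(0, n, n, dimnames = list(ids, ids))
  N <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(segments))) {
    len <- segments$length[k]
    if (len < window[1] || len >= window[2]) next
    i <- segments$id_a[k]; j <- segments$id_b[k]
    L[i, j] <- L[i, j] + len; L[j, i] <- L[j, i] + len
    N[i, j] <- N[i, j] + 1; N[j, i] <- N[j, i] + 1
  }
  list(L = L, N = N)
}

# exhaustive element-permutation Mantel oracle: plain loop over permutations
# generated independently of the implementation (recursive insertion)
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- oracle_perms(n - 1L)
  out <- list()
  for (p in smaller) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

oracle_mantel_p <- function(A, B) {
  a <- as.vector(A); b <- as.vector(B)
  obs <- cor(a, b)
  stats <- vapply(oracle_perms(length(b)), function(p) cor(a, b[p]), 0)
  mean(stats >= obs - 1e-12)
}
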