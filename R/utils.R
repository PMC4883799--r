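#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Interval algebra on matrices with columns start, end (half-open [start, end)).
# Input need not be sorted; output is sorted, disjoint, with gaps > gap merged
# away (intervals closer than `gap` are fused).
merge_intervals <- function(iv, gap = 0) {
  if (is.null(iv) || nrow(iv) == 0L) return(matrix(numeric(0), 0L, 2L))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- matrix(NA_real_, nrow(iv), 2L)
  k <- 1L
  out[1L, ] <- iv[1L, ]
  if (nrow(iv) > 1L) for (i in 2L:nrow(iv)) {
    if (iv[i, 1L] - out[k, 2L] < gap) {
      out[k, 2L] <- max(out[k, 2L], iv[i, 2L])
    } else {
      k <- k + 1L
      out[k, ] <- iv[i, ]
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# Total length of [s, e) not covered by the (sorted, disjoint) intervals in iv,
# split into maximal contiguous uncovered pieces; returns the piece lengths.
uncovered_extents <- function(s, e, iv) {
  if (nrow(iv) == 0L) return(e - s)
  keep <- iv[, 2L] > s & iv[, 1L] < e
  iv <- iv[keep, , drop = FALSE]
  if (nrow(iv) == 0L) return(e - s)
  pieces <- numeric(0)
  cur <- s
  for (i in seq_len(nrow(iv))) {
    if (iv[i, 1L] > cur) pieces <- c(pieces, iv[i, 1L] - cur)
    cur <- max(cur, iv[i, 2L])
  }
  if (cur < e) pieces <- c(pieces, e - cur)
  if (length(pieces) == 0L) 0 else pieces
}

# All permutations of seq_len(n) as an n! x n integer matrix.
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 10L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}
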