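# Independent brute-force oracles used to cross-check the fast kernels.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force perfect-SSR scan: tests every (start, period) pair by whole-unit
# substring comparison; a vectorized prefilter skips starts whose first unit
# does not repeat, the per-candidate logic stays naive
ssr_oracle <- function(seq, max_period = 6, min_mono = 8, min_multi = 5) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  rows <- list()
  for (p in seq_len(max_period)) {
    if (2L * p > n) break
    idx <- seq_len(n - p)
    m <- ch[idx] == ch[idx + p] & ch[idx] != "N"
    cs <- cumsum(c(0L, m))
    cand <- idx[idx <= n - 2L * p + 1L]
    cand <- cand[cs[cand + p] - cs[cand] == p]   # first unit repeats fully
    for (st in cand) {
      motif <- substr(seq, st, st + p - 1L)
      prim <- TRUE
      if (p > 1L) for (d in seq_len(p - 1L)) {
        if (p %% d == 0L &&
            paste(rep(substr(motif, 1, d), p / d), collapse = "") == motif) {
          prim <- FALSE; break
        }
      }
      if (!prim) next
      u <- 1L
      while (st + (u + 1L) * p - 1L <= n &&
             substr(seq, st + u * p, st + (u + 1L) * p - 1L) == motif)
        u <- u + 1L
      thr <- if (p == 1L) min_mono else min_multi
      if (u < thr) next
      # leftmost maximal: the previous position must not continue the period
      if (st > 1L && st - 1L + p <= n && ch[st - 1L] != "N" &&
          ch[st - 1L] == ch[st - 1L + p]) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, period = p, unit_count = u,
        start = st - 1L, end = st - 1L + p * u, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(motif = character(), period = integer(),
                      unit_count = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# column-by-column event classifier for a pairwise alignment (two gapped rows)
events_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A)
  keep <- rep(TRUE, n)
  repeat {                      # leading terminal gap runs
    idx <- which(keep)
    if (!length(idx)) break
    f <- idx[1]
    if (A[f] == "-") { j <- f; while (j <= n && A[j] == "-") { keep[j] <- FALSE; j <- j + 1L } }
    else if (B[f] == "-") { j <- f; while (j <= n && B[j] == "-") { keep[j] <- FALSE; j <- j + 1L } }
    else break
  }
  repeat {                      # trailing terminal gap runs
    idx <- which(keep)
    if (!length(idx)) break
    l <- idx[length(idx)]
    if (A[l] == "-") { j <- l; while (j >= 1L && A[j] == "-") { keep[j] <- FALSE; j <- j - 1L } }
    else if (B[l] == "-") { j <- l; while (j >= 1L && B[j] == "-") { keep[j] <- FALSE; j <- j - 1L } }
    else break
  }
  A <- A[keep]; B <- B[keep]
  M <- 0L; C <- 0L; I <- 0L
  bases <- c("A", "C", "G", "T")
  for (t in seq_along(A)) {
    if (A[t] == "-" && (t == 1L || A[t - 1L] != "-")) I <- I + 1L
    if (B[t] == "-" && (t == 1L || B[t - 1L] != "-")) I <- I + 1L
    if (A[t] %in% bases && B[t] %in% bases) {
      if (A[t] == B[t]) C <- C + 1L else M <- M + 1L
    }
  }
  c(M = M, I = I, C = C)
}

# all strings of length n over an alphabet
all_strings <- function(n, alphabet = c("A", "T")) {
  if (n == 0L) return("")
  grid <- do.call(expand.grid, rep(list(alphabet), n))
  apply(grid, 1, paste, collapse = "")
}

# tiny GenBank text fixture written to a temp file
write_toy_genbank <- function(lines) {
  path <- tempfile(fileext = ".gb")
  writeLines(lines, path)
  path
}
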