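# Independent brute-force oracles used to freeze expected values. These
# deliberately avoid the package's own code paths.

# Pairwise-comparison AUC: mean over all (positive, negative) pairs of
# 1/0/0.5 for win/lose/tie.
oracle_auc <- function(is_pos, scores) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Plug-in MI (bits) straight from the empirical 4x4 joint table.
oracle_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  s <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (pa[i] * pb[j]))
  }
  unname(s)
}

# All-windows max-median slope, written as literally as possible.
oracle_slope <- function(time, value, gap, window) {
  s <- sapply(seq_len(length(time) - gap), function(i) {
    (value[i] - value[i + gap]) / (time[i] - time[i + gap])
  })
  best <- -Inf
  for (w in seq_len(length(s) - window + 1)) {
    best <- max(best, median(s[w:(w + window - 1)]))
  }
  best
}

# Independent Nussinov pair-count oracle: plain-R O(n^3) DP, no traceback.
oracle_nussinov_pairs <- function(rna, min_loop = 3) {
  pairs_ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  ch <- strsplit(chartr("T", "U", rna), NULL)[[1]]
  n <- length(ch)
  if (n < min_loop + 2) return(0L)
  M <- matrix(0L, n, n)
  for (len in (min_loop + 2):n) {
    for (i in 1:(n - len + 1)) {
      j <- i + len - 1
      best <- M[i + 1, j]
      for (k in (i + min_loop + 1):j) {
        if (pairs_ok(ch[i], ch[k])) {
          v <- 1L + (if (k > i + 1) M[i + 1, k - 1] else 0L) +
            (if (k < j) M[k + 1, j] else 0L)
          best <- max(best, v)
        }
      }
      M[i, j] <- best
    }
  }
  M[1, n]
}

random_seqs <- function(n, L, probs = rep(0.25, 4)) {
  apply(matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                      prob = probs), n, L),
        1, paste, collapse = "")
}
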