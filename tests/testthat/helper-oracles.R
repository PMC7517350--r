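# Independent brute-force oracles used to validate the package's
# implementations.  These deliberately re-derive each quantity from first
# principles (no Lance-Williams updates, no incremental bookkeeping).

# Agglomerative clustering that recomputes every inter-cluster distance from
# the original node-vector distances at every step (O(N^3)), with the same
# deterministic tie rule: smallest distance, then lexicographically smallest
# (id, id) pair.
naive_agglomerate <- function(vectors, linkage = "single") {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  d0 <- as.matrix(dist(vectors))
  clusters <- lapply(seq_len(n), identity)   # leaf index sets
  ids <- seq_len(n)
  merges <- NULL
  for (s in seq_len(n - 1L)) {
    best <- NULL
    for (a in seq_along(clusters)[-length(clusters)]) {
      for (b in (a + 1L):length(clusters)) {
        pairs <- d0[clusters[[a]], clusters[[b]], drop = FALSE]
        d <- switch(linkage, single = min(pairs), complete = max(pairs),
                    average = mean(pairs))
        pr <- sort(c(ids[a], ids[b]))
        better <- is.null(best) || d < best$d - 1e-15 ||
          (abs(d - best$d) <= 1e-15 &&
           (pr[1] < best$pr[1] ||
            (pr[1] == best$pr[1] && pr[2] < best$pr[2])))
        if (better) best <- list(d = d, a = a, b = b, pr = pr)
      }
    }
    merges <- rbind(merges,
                    data.frame(step = s, left = best$pr[1],
                               right = best$pr[2], new = n + s,
                               height = best$d))
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    ids[best$a] <- n + s
    clusters <- clusters[-best$b]
    ids <- ids[-best$b]
  }
  merges
}

# Direct double-sum evaluation of weighted modularity.
brute_modularity <- function(A, membership) {
  m2 <- sum(A)
  if (m2 <= 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(A)))
      if (membership[i] == membership[j])
        q <- q + A[i, j] - k[i] * k[j] / m2
  unname(q / m2)
}

# Exact two-sided rank-sum p by enumerating every group assignment of the
# pooled midranks.
brute_ranksum_p <- function(a, b) {
  n1 <- length(a)
  n <- n1 + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- combn(n, n1)
  u_all <- apply(picks, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# Random valid connectivity matrix (symmetric, zero diagonal, [0, 1]).
random_connectivity <- function(n, seed, labels = paste0("V", seq_len(n))) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  connectivity_matrix(m, labels)
}

# A 5-leaf one-attribute instance whose dendrogram is a chain: leaves at
# 0, 1, 3, 7, 15 merge as (1,2) -> +3 -> +4 -> +5.
chain_instance <- function() {
  v <- matrix(c(0, 1, 3, 7, 15), ncol = 1)
  rownames(v) <- paste0("N", 1:5)
  v
}

sine_recording <- function(freqs, fs = 500, seconds = 8,
                           labels = paste0("ch", seq_along(freqs))) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  eeg_recording(t(sapply(freqs, function(f) sin(2 * pi * f * t))),
                fs, labels)
}

# Fraction of a signal's periodogram power inside [lo, hi] Hz.
band_power_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  inband <- half & f >= lo & f <= hi
  sum(p[inband]) / sum(p[half])
}
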