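# Independent brute-force reference implementations used to validate the
# package's vectorized / library-backed code paths. These deliberately share
# no code with the package internals.

# Mean local clustering by exhaustive triangle counting over neighbour pairs.
oracle_clustering <- function(adj) {
  adj <- unclass(adj)
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) { vals[i] <- 0; next }
    pairs <- utils::combn(nb, 2)
    closed <- sum(apply(pairs, 2, function(p) adj[p[1], p[2]] != 0))
    vals[i] <- closed / ncol(pairs)
  }
  mean(vals)
}

# All-pairs shortest paths by naive breadth-first search; average over
# ordered reachable pairs.
oracle_path_length <- function(adj) {
  adj <- unclass(adj)
  n <- nrow(adj)
  dists <- c()
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- c()
      for (v in frontier) {
        for (w in which(adj[v, ] != 0)) {
          if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
    dists <- c(dists, d[-s])
  }
  mean(dists[is.finite(dists)])
}

# All 0/1 symmetric adjacency matrices on n nodes (n small).
enumerate_graphs <- function(n, max_graphs = Inf, seed = 1) {
  n_pairs <- n * (n - 1) / 2
  total <- 2^n_pairs
  idx <- if (total <= max_graphs) 0:(total - 1) else {
    set.seed(seed); sample.int(total, max_graphs) - 1
  }
  lapply(idx, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n_pairs)]
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- bits
    adj + t(adj)
  })
}

# Naive double-loop synchronization likelihood, mirroring the definition:
# time-delay embedding, rank-based critical distance over the Theiler
# corridor, joint recurrence counts. O(channels^2 n^2) and written for
# clarity, not speed.
oracle_sl <- function(segment, L, m, w1, w2, pref, nrec) {
  n <- nrow(segment); nc <- ncol(segment)
  nk <- n - (m - 1) * L
  emb <- lapply(seq_len(nc), function(c) {
    t(sapply(seq_len(nk), function(k) segment[k + (0:(m - 1)) * L, c]))
  })
  acc <- matrix(0, nc, nc)
  retained <- 0
  for (k in seq_len(nk)) {
    cand <- which(abs(seq_len(nk) - k) > w1 & abs(seq_len(nk) - k) <= w2)
    if (length(cand) < nrec) next
    ncrit <- ceiling(pref * length(cand))
    R <- matrix(FALSE, nc, length(cand))
    for (c in seq_len(nc)) {
      d <- sqrt(colSums((t(emb[[c]][cand, , drop = FALSE]) - emb[[c]][k, ])^2))
      eps <- sort(d)[ncrit]
      R[c, ] <- d <= eps
    }
    for (a in seq_len(nc - 1)) {
      for (b in (a + 1):nc) {
        num <- sum(R[a, ] & R[b, ])
        acc[a, b] <- acc[a, b] + num / sum(R[a, ])
        acc[b, a] <- acc[b, a] + num / sum(R[b, ])
      }
    }
    retained <- retained + 1
  }
  out <- (acc + t(acc)) / (2 * retained)
  diag(out) <- 0
  out
}

# Closed-form product-moment correlation.
oracle_pearson_r <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Exact permutation two-sided p-value for the rank-sum statistic on small
# samples (enumerates all assignments of pooled ranks to group a).
oracle_ranksum_p <- function(a, b) {
  pooled <- rank(c(a, b))
  na <- length(a)
  obs <- sum(pooled[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  stats <- apply(combos, 2, function(ix) sum(pooled[ix]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# Small parameter object for short SL test segments (full study parameters
# need w2 = 1049 which exceeds toy segment lengths).
sl_toy_params <- function(L = 3L, m = 3L, w1 = 10L, w2 = 160L,
                          pref = 0.05, nrec = 5L) {
  structure(list(L = L, m = m, w1 = w1, w2 = w2, pref = pref,
                 nrec = as.integer(nrec)), class = "sl_parameters")
}

# Band-limited test signal: white noise through the package's filter chain
# is avoided here on purpose; a raw sinusoid mixture keeps oracles
# independent.
toy_alpha_signal <- function(n, fs, freq = 10, phase = 0) {
  sin(2 * pi * freq * (0:(n - 1)) / fs + phase)
}
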