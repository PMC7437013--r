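#' Watts-Strogatz ring-lattice adjacency with random rewiring
#'
#' Starts from a ring lattice where every node connects to its `k` nearest
#' neighbours (`k/2` on each side) and rewires each lattice edge with
#' probability `beta` to a uniformly chosen new endpoint (no self-loops or
#' duplicate edges), preserving the edge count `n k / 2`. `beta = 0` keeps
#' the lattice, `beta = 1` approaches a random graph.
#'
#' @param n number of nodes.
#' @param k even neighbour count, `2 <= k <= n - 2`.
#' @param beta rewiring probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @param exact_count rewire exactly `round(beta * E)` edges instead of a
#'   binomial draw; removes count noise when `beta` is a controlled
#'   covariate.
#' @return Symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
watts_strogatz_adjacency <- function(n, k, beta, seed = NULL,
                                     exact_count = FALSE) {
  if (k %% 2 != 0 || k < 2) stop("k must be even and >= 2")
  if (k >= n - 1) stop(sprintf("k = %d must be < n - 1 = %d", k, n - 1))
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  adj <- matrix(0L, n, n)
  lattice_edges <- matrix(0L, n * k / 2, 2)
  e <- 0L
  for (i in seq_len(n)) {
    for (s in seq_len(k / 2)) {
      j <- ((i - 1 + s) %% n) + 1
      adj[i, j] <- adj[j, i] <- 1L
      e <- e + 1L
      lattice_edges[e, ] <- c(i, j)
    }
  }
  with_seed(seed, {
    n_edges <- nrow(lattice_edges)
    rewire <- if (exact_count) {
      # derandomized count: exactly round(beta * E) edges are rewired
      m <- round_half_away(beta * n_edges)
      seq_len(n_edges) %in% sample.int(n_edges, m)
    } else {
      runif(n_edges) < beta
    }
    for (e in which(rewire)) {
      i <- lattice_edges[e, 1]; j <- lattice_edges[e, 2]
      if (adj[i, j] == 0L) next
      free <- which(adj[i, ] == 0L & seq_len(n) != i)
      if (length(free)) {
        jnew <- free[sample.int(length(free), 1)]
        adj[i, j] <- adj[j, i] <- 0L
        adj[i, jnew] <- adj[jnew, i] <- 1L
      }
    }
  })
  adj
}

#' Generate coupled alpha-band multichannel signals
#'
#' Each channel carries private band-limited sources (white Gaussian noise
#' passed through the same zero-phase Butterworth design used in
#' preprocessing) plus interaction terms with known ground truth. The alpha
#' band is split at `band_split` into a lower and an upper sub-band, and
#' the two kinds of interaction seen between EEG channels are placed in
#' separate sub-bands so that each can be controlled independently:
#'
#' * lower sub-band -- zero-phase synchrony: each channel receives its
#'   structural neighbours' lower-band sources instantaneously, scaled by
#'   `zero_lag_gain` times the edge weight of `structural_adjacency`. In
#'   addition, a fraction `common_frac` of every channel's lower-band
#'   private variance is replaced by one global in-phase rhythm (a
#'   whole-array alpha generator), which raises the zero-phase dependence
#'   of every channel pair equally without changing channel power. Both
#'   terms are visible to amplitude-based measures such as squared
#'   coherence and invisible to the imaginary part of coherency.
#' * upper sub-band -- phase-shifted interaction: each edge passes its
#'   lower-indexed endpoint's upper-band source to the other endpoint
#'   delayed by `coupling_lag` samples and scaled by `coupling_gain`. The
#'   delay makes this component visible to the imaginary part of coherency
#'   with equal strength on every edge, while its contribution to
#'   coherence magnitude does not depend on the delay. The influence is
#'   one-directional because a symmetric exchange at equal lag has
#'   conjugate phase terms that cancel.
#'
#' On top sit three whole-signal effects: a global slow amplitude
#' co-modulation (`envelope_mod`; an arousal-like waxing and waning shared
#' by every channel, the kind of joint amplitude dynamics that
#' recurrence-based synchronization measures respond to), instantaneous
#' unstructured leakage (`mixing_strength`, volume-conduction-like), and
#' additive white measurement noise (applied after the envelope).
#'
#' @param n_channels number of channels (`>= 2`).
#' @param n_samples samples per channel (`> coupling_lag`).
#' @param fs sampling rate in Hz.
#' @param structural_adjacency symmetric non-negative matrix with zero
#'   diagonal; nonzero entries are edges, and entry values weight the
#'   zero-lag coupling per edge (use a 0/1 matrix for uniform coupling).
#' @param coupling_gain unitless gain `>= 0` of the directed lagged
#'   component (upper sub-band).
#' @param coupling_lag delay of the lagged component in samples (`>= 0`).
#' @param zero_lag_gain unitless gain `>= 0` scaling the symmetric
#'   instantaneous component (lower sub-band); defaults to `coupling_gain`.
#' @param common_frac fraction in `[0, 1)` of lower-band private variance
#'   replaced by the global common rhythm.
#' @param envelope_mod depth in `[0, 1)` of the global slow (~0.2 Hz)
#'   amplitude co-modulation applied to all channels.
#' @param mixing_strength instantaneous leakage in `[0, 1]`: each channel
#'   receives `mixing_strength / (n_channels - 1)` of every other private
#'   source at zero lag.
#' @param noise_sd standard deviation of additive white noise.
#' @param band alpha band edges in Hz.
#' @param band_split frequency in Hz separating the two interaction
#'   sub-bands; must lie strictly inside `band`.
#' @param filter_order Butterworth order of the source filters.
#' @param seed optional integer seed.
#' @return An [recording()] with zero-mean channels.
#' @export
generate_coupled_alpha <- function(n_channels, n_samples, fs,
                                   structural_adjacency = matrix(0, n_channels, n_channels),
                                   coupling_gain = 0, coupling_lag = 0,
                                   zero_lag_gain = coupling_gain,
                                   common_frac = 0, envelope_mod = 0,
                                   mixing_strength = 0, noise_sd = 0,
                                   band = c(8, 12), band_split = 9.4,
                                   filter_order = 4, seed = NULL) {
  stopifnot(coupling_gain >= 0, zero_lag_gain >= 0,
            common_frac >= 0, common_frac < 1,
            envelope_mod >= 0, envelope_mod < 1)
  stopifnot(n_channels >= 2)
  if (!(band_split > band[1] && band_split < band[2])) {
    stop("band_split must lie strictly inside the band")
  }
  A <- as.matrix(structural_adjacency)
  if (nrow(A) != n_channels || ncol(A) != n_channels) {
    stop("structural_adjacency must be n_channels x n_channels")
  }
  if (!isTRUE(all.equal(A, t(A))) || any(diag(A) != 0) || any(A < 0)) {
    stop("structural_adjacency must be symmetric, non-negative, zero diagonal")
  }
  if (coupling_lag < 0 || coupling_lag >= n_samples) {
    stop("coupling_lag must satisfy 0 <= lag < n_samples")
  }
  if (mixing_strength < 0 || mixing_strength > 1) {
    stop("mixing_strength must be in [0, 1]")
  }
  bf_lo <- signal::butter(filter_order, c(band[1], band_split) / (fs / 2),
                          type = "pass")
  bf_hi <- signal::butter(filter_order, c(band_split, band[2]) / (fs / 2),
                          type = "pass")
  with_seed(seed, {
    pad <- coupling_lag
    z_lo <- apply(matrix(rnorm((n_samples + pad) * n_channels),
                         n_samples + pad, n_channels), 2,
                  function(v) signal::filtfilt(bf_lo, v))
    z_hi <- apply(matrix(rnorm((n_samples + pad) * n_channels),
                         n_samples + pad, n_channels), 2,
                  function(v) signal::filtfilt(bf_hi, v))
    lo_now <- z_lo[(pad + 1):(pad + n_samples), , drop = FALSE]
    hi_now <- z_hi[(pad + 1):(pad + n_samples), , drop = FALSE]
    hi_lag <- z_hi[1:n_samples, , drop = FALSE]
    edges <- which(upper.tri(A) & A != 0, arr.ind = TRUE)

    lo_part <- lo_now
    if (common_frac > 0) {
      u <- signal::filtfilt(bf_lo, rnorm(n_samples))
      lo_part <- sqrt(1 - common_frac) * lo_now +
        sqrt(common_frac) * matrix(u, n_samples, n_channels)
    }
    if (zero_lag_gain > 0 && nrow(edges)) {
      lo_part <- lo_part + zero_lag_gain * (lo_now %*% A)
    }
    hi_part <- hi_now
    if (coupling_gain > 0 && nrow(edges)) {
      D <- matrix(0, n_channels, n_channels)  # D[i, j]: source i -> channel j
      for (e in seq_len(nrow(edges))) {
        D[edges[e, 1], edges[e, 2]] <- 1      # lower index leads
      }
      hi_part <- hi_part + coupling_gain * (hi_lag %*% D)
    }
    x <- lo_part + hi_part
    if (envelope_mod > 0) {
      b_slow <- signal::butter(2, 0.4 / (fs / 2), type = "low")
      slow <- signal::filtfilt(b_slow, rnorm(n_samples))
      slow <- slow / stats::sd(slow)
      x <- x * pmax(0.1, 1 + envelope_mod * slow)
    }
    if (mixing_strength > 0) {
      leak <- mixing_strength / (n_channels - 1)
      priv <- lo_now + hi_now
      x <- x + leak * (rowSums(priv) - priv)
    }
    if (noise_sd > 0) {
      x <- x + noise_sd * matrix(rnorm(n_samples * n_channels), n_samples,
                                 n_channels)
    }
    x <- sweep(x, 2, colMeans(x))
    recording(x, fs)
  })
}

#' Specification of a synthetic study cohort
#'
#' Defaults emulate the scale of the target study: 80 subjects, 30 channels,
#' 10 artifact-free segments of 4096 samples at 200 Hz in the 8-12 Hz band.
#'
#' Per subject, a Watts-Strogatz rewiring probability `beta_s` drawn
#' uniformly from `beta_range` sets the structural topology (lattice ->
#' small-world -> random), which is what small-worldness responds to. A
#' second per-subject quantity, the connectivity driver `d_s` in `[0, 1]`,
#' sets how strong the measured connectivity is. In `"linked"` mode `d_s`
#' is `beta_s` rescaled to `[0, 1]`, so more randomly wired subjects are
#' also more strongly connected and a negative association between mean
#' connectivity and small-worldness is built in; in `"null"` mode `d_s` is
#' an independent uniform draw and no association exists.
#'
#' The driver raises overall connectivity while leaving the ranking of
#' channel pairs -- and therefore the thresholded graph and its
#' small-worldness -- as untouched as the estimators allow. Two driver
#' pathways are used: the share of each channel's rhythm taken by the
#' global in-phase common source (`common_frac = common_frac_max * d_s`),
#' which lifts the zero-phase coherence of every pair equally (variance
#' neutral, so nothing else is diluted) and is what coherence magnitude and
#' synchronization likelihood respond to; and the directed interaction
#' delay (`coupling_lag`, interpolated from `lag_range[1]` down to
#' `lag_range[2]` samples as the driver rises), which moves the interaction
#' phase toward quadrature at the alpha carrier and so scales the imaginary
#' part of coherency while leaving coherence magnitude untouched. The
#' symmetric zero-lag coupling backbone that defines each subject's
#' edge structure stays fixed (`zero_lag_gain`, with rewired edges weighted
#' by `rewired_weight` so that long-range edges are as detectable as
#' lattice edges despite lacking shared-neighbour reinforcement).
#'
#' @param n_subjects,n_channels,n_segments,segment_len,fs cohort scale.
#' @param band alpha band in Hz.
#' @param k ring-lattice neighbour count of the structural graph.
#' @param beta_range range of per-subject rewiring probabilities.
#' @param beta_shape shape of the symmetric Beta distribution the rewiring
#'   probability is drawn from over `beta_range`; values below 1 place more
#'   subjects near the lattice and random extremes, widening the
#'   small-worldness contrast the cohort expresses.
#' @param mode `"linked"` or `"null"`.
#' @param g0 fixed directed lagged coupling gain.
#' @param zero_lag_range zero-lag backbone gain at driver 0 and driver 1;
#'   a mild rise keeps edge margins ahead of the floor lift the common
#'   rhythm produces.
#' @param rewired_weight relative zero-lag weight of rewired (non-lattice)
#'   edges.
#' @param common_frac_max common-rhythm variance fraction reached at
#'   driver 1.
#' @param envelope_max global amplitude-co-modulation depth reached at
#'   driver 1; the slow shared envelope raises every estimator's overall
#'   level, most strongly the recurrence-based one.
#' @param lag_range coupling delay in samples at driver 0 and driver 1.
#' @param band_split frequency splitting the zero-lag (lower) and lagged
#'   (upper) interaction sub-bands; see [generate_coupled_alpha()].
#' @param mixing_strength fixed unstructured leakage in `[0, 1]`.
#' @param noise_sd additive white-noise standard deviation.
#' @param seed integer seed for the whole cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 80, n_channels = 30, n_segments = 10,
                        segment_len = 4096, fs = 200, band = c(8, 12),
                        k = 8, beta_range = c(0.02, 0.8),
                        beta_shape = 0.4,
                        mode = c("linked", "null"),
                        g0 = 0.7, zero_lag_range = c(0.5, 0.5),
                        rewired_weight = 1.15, common_frac_max = 0.15,
                        envelope_max = 0.45,
                        lag_range = c(6L, 5L), band_split = 9.4,
                        mixing_strength = 0.1,
                        noise_sd = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_channels >= 2, segment_len > max(lag_range),
            beta_range[1] >= 0, beta_range[2] <= 1,
            mixing_strength >= 0, mixing_strength <= 1,
            common_frac_max >= 0, common_frac_max < 1, rewired_weight > 0)
  if (k >= n_channels) stop("k must be < n_channels")
  structure(list(n_subjects = n_subjects, n_channels = n_channels,
                 n_segments = n_segments, segment_len = segment_len, fs = fs,
                 band = band, k = k, beta_range = beta_range,
                 beta_shape = beta_shape, mode = mode,
                 g0 = g0,
                 zero_lag_range = zero_lag_range,
                 rewired_weight = rewired_weight,
                 common_frac_max = common_frac_max,
                 envelope_max = envelope_max,
                 lag_range = as.integer(lag_range), band_split = band_split,
                 mixing_strength = mixing_strength, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic study cohort with ground truth
#'
#' Draws per-subject topology (`beta_s`) and connectivity driver (`d_s`)
#' according to the [cohort_spec()] rule, builds each subject\'s structural
#' graph, and generates `n_segments` independent segments per subject.
#' Identical seeds reproduce the cohort bit for bit.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `subjects` (each
#'   a list: `segments` ([segment_set()]), `beta`, `driver`, `common_frac`,
#'   `lag`, `adjacency`) and the generating `spec`.
#' @export
generate_study_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lattice <- watts_strogatz_adjacency(spec$n_channels, spec$k, 0)
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    sseed <- child_seed(spec$seed, s)
    draws <- with_seed(sseed, runif(2))
    beta_s <- spec$beta_range[1] +
      stats::qbeta(draws[1], spec$beta_shape, spec$beta_shape) *
        (spec$beta_range[2] - spec$beta_range[1])
    driver <- if (spec$mode == "linked") draws[1] else draws[2]
    cf_s <- spec$common_frac_max * driver
    env_s <- spec$envelope_max * driver
    zl_s <- spec$zero_lag_range[1] +
      driver * (spec$zero_lag_range[2] - spec$zero_lag_range[1])
    lag_s <- as.integer(round(spec$lag_range[1] +
      driver * (spec$lag_range[2] - spec$lag_range[1])))
    adj <- watts_strogatz_adjacency(spec$n_channels, spec$k, beta_s,
                                    child_seed(sseed, 1), exact_count = TRUE)
    W <- adj * 1
    W[(adj == 1) & (lattice == 0)] <- spec$rewired_weight
    segs <- lapply(seq_len(spec$n_segments), function(g) {
      rec <- generate_coupled_alpha(
        spec$n_channels, spec$segment_len, spec$fs, W,
        coupling_gain = spec$g0, coupling_lag = lag_s,
        zero_lag_gain = zl_s,
        common_frac = cf_s, envelope_mod = env_s,
        mixing_strength = spec$mixing_strength, noise_sd = spec$noise_sd,
        band = spec$band, band_split = spec$band_split,
        seed = child_seed(sseed, 1000 + g))
      rec$data
    })
    subjects[[s]] <- list(
      subject_id = sprintf("s%03d", s),
      segments = segment_set(segs, spec$fs, sprintf("s%03d", s)),
      beta = beta_s, driver = driver, common_frac = cf_s, lag = lag_s,
      adjacency = adj)
  }
  structure(list(subjects = subjects, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%s mode), %d channels, %d x %d-sample segments @ %g Hz\n",
              length(x$subjects), x$spec$mode, x$spec$n_channels,
              x$spec$n_segments, x$spec$segment_len, x$spec$fs))
  invisible(x)
}

#' Uniform-weight random connectivity cohort
#'
#' Generates symmetric matrices with i.i.d. Uniform(0, 1) off-diagonal
#' weights and zero diagonal — the random-graph reference whose mean edge
#' weight is uncorrelated with small-worldness by construction.
#'
#' @param n_subjects number of matrices (0 allowed).
#' @param n_nodes nodes per matrix (`>= 2`).
#' @param seed optional integer seed.
#' @return List of `connectivity_matrix` objects (measure `"WEIGHT"`).
#' @export
generate_er_weight_cohort <- function(n_subjects, n_nodes, seed = NULL) {
  stopifnot(n_nodes >= 2)
  if (n_subjects == 0) return(list())
  with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    m <- matrix(0, n_nodes, n_nodes)
    m[upper.tri(m)] <- runif(n_nodes * (n_nodes - 1) / 2)
    connectivity_matrix(m + t(m), "WEIGHT")
  }))
}
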