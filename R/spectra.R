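#' Connectivity matrix container
#'
#' A symmetric channel-by-channel matrix of pairwise coupling estimates for
#' one measure, with a zero diagonal by convention.
#'
#' @param values symmetric numeric matrix.
#' @param measure one of `"MSC"`, `"ICOH"`, `"SL"`, or `"WEIGHT"` (generic
#'   weights such as the uniform random reference).
#' @param labels optional channel labels.
#' @return An object of class `connectivity_matrix` (a matrix with
#'   attributes).
#' @export
connectivity_matrix <- function(values, measure = c("MSC", "ICOH", "SL", "WEIGHT"),
                                labels = NULL) {
  measure <- match.arg(measure)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (max(abs(values - t(values))) > 1e-9) {
    stop("connectivity matrix must be symmetric (tolerance 1e-9)")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  structure(values, class = c("connectivity_matrix", "matrix", "array"),
            measure = measure)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d channels, edge range [%.4f, %.4f]\n",
              attr(x, "measure"), nrow(x),
              min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' Welch-averaged auto- and cross-spectra
#'
#' Splits each channel into Hann-tapered overlapping blocks, Fourier
#' transforms them, and averages periodograms and cross-periodograms over
#' blocks. With the defaults used for 4096-sample segments (512-sample
#' window, 50% overlap) 15 blocks are averaged.
#'
#' @param segment numeric matrix, samples x channels.
#' @param fs sampling rate in Hz.
#' @param window_len block length in samples (default 512).
#' @param overlap_fraction overlap between consecutive blocks in `[0, 1)`
#'   (default 0.5).
#' @return A list of class `spectral_estimate`: `freq` (Hz grid from 0 to
#'   fs/2), `S` (complex array `n_freq x n_ch x n_ch` with
#'   `S[f, i, j] = <X_i(f) conj(X_j(f))>`), and `n_blocks`.
#' @export
welch_spectra <- function(segment, fs, window_len = 512, overlap_fraction = 0.5) {
  segment <- as.matrix(segment)
  n <- nrow(segment)
  nc <- ncol(segment)
  if (window_len > n) {
    stop(sprintf("window_len = %d exceeds segment length %d", window_len, n))
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)")
  }
  step <- max(1L, as.integer(round(window_len * (1 - overlap_fraction))))
  starts <- seq(1L, n - window_len + 1L, by = step)
  # symmetric Hann taper
  w <- 0.5 * (1 - cos(2 * pi * (0:(window_len - 1)) / (window_len - 1)))
  nf <- window_len %/% 2 + 1L
  S <- array(0 + 0i, dim = c(nf, nc, nc))
  for (s0 in starts) {
    block <- segment[s0:(s0 + window_len - 1L), , drop = FALSE] * w
    X <- stats::mvfft(block)[seq_len(nf), , drop = FALSE]
    for (f in seq_len(nf)) {
      S[f, , ] <- S[f, , ] + outer(X[f, ], Conj(X[f, ]))
    }
  }
  S <- S / length(starts)
  structure(list(freq = (seq_len(nf) - 1L) * fs / window_len,
                 S = S, n_blocks = length(starts)),
            class = "spectral_estimate")
}

band_bins <- function(spectra, band) {
  idx <- which(spectra$freq >= band[1] & spectra$freq <= band[2])
  if (!length(idx)) stop("no frequency bins inside the requested band")
  idx
}

coherency_band <- function(spectra, band) {
  idx <- band_bins(spectra, band)
  nc <- dim(spectra$S)[2]
  auto <- vapply(seq_len(nc), function(i) Re(spectra$S[idx, i, i]),
                 numeric(length(idx)))
  auto <- matrix(auto, nrow = length(idx))
  if (any(auto <= 0)) stop("degenerate channel: zero auto-spectrum inside band")
  list(idx = idx, nc = nc, auto = auto)
}

#' Magnitude-squared coherence in a frequency band
#'
#' Per channel pair, `MSC(f) = |S_ij(f)|^2 / (S_ii(f) S_jj(f))` is computed
#' on every bin inside the band (edges inclusive) and averaged over bins.
#'
#' @param spectra a [welch_spectra()] result.
#' @param band numeric length-2, band edges in Hz (default `c(8, 12)`).
#' @param labels optional channel labels.
#' @return A `connectivity_matrix` with entries in `[0, 1]`.
#' @export
msc <- function(spectra, band = c(8, 12), labels = NULL) {
  cb <- coherency_band(spectra, band)
  out <- matrix(0, cb$nc, cb$nc)
  for (i in seq_len(cb$nc - 1L)) {
    for (j in (i + 1L):cb$nc) {
      v <- Mod(spectra$S[cb$idx, i, j])^2 / (cb$auto[, i] * cb$auto[, j])
      out[i, j] <- out[j, i] <- min(1, max(0, mean(v)))
    }
  }
  connectivity_matrix(out, "MSC", labels)
}

#' Imaginary part of coherency in a frequency band
#'
#' Per channel pair, `Imag(S_ij(f) / sqrt(S_ii(f) S_jj(f)))` is averaged over
#' band bins; the stored edge value is the absolute value of that band
#' average, so that opposite-signed bins may cancel but edge weights remain
#' non-negative for graph construction. Zero-lag (instantaneously mixed)
#' interactions have a real coherency and therefore vanish here.
#'
#' @inheritParams msc
#' @return A `connectivity_matrix` with entries in `[0, 1]`.
#' @export
icoh <- function(spectra, band = c(8, 12), labels = NULL) {
  cb <- coherency_band(spectra, band)
  out <- matrix(0, cb$nc, cb$nc)
  for (i in seq_len(cb$nc - 1L)) {
    for (j in (i + 1L):cb$nc) {
      v <- Im(spectra$S[cb$idx, i, j]) / sqrt(cb$auto[, i] * cb$auto[, j])
      out[i, j] <- out[j, i] <- min(1, abs(mean(v)))
    }
  }
  connectivity_matrix(out, "ICOH", labels)
}

#' Element-wise median across segment-level connectivity matrices
#'
#' @param matrices list of `connectivity_matrix` objects of identical shape
#'   and measure. For an even count the median is the mean of the two central
#'   values.
#' @return A single `connectivity_matrix`.
#' @export
aggregate_segments <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  measures <- vapply(matrices, function(m) attr(m, "measure"), character(1))
  if (length(unique(measures)) != 1L) {
    stop("cannot aggregate matrices of different measures: ",
         paste(unique(measures), collapse = ", "))
  }
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims != dims[, 1])) stop("matrices must share one shape")
  arr <- simplify2array(lapply(matrices, unclass))
  med <- apply(arr, c(1, 2), median)
  connectivity_matrix(med, measures[1], rownames(matrices[[1]]))
}

#' Mean connectivity over all channel pairs
#'
#' Mean of the strict upper triangle, counting each pair once.
#'
#' @param m a symmetric matrix (any `connectivity_matrix`).
#' @return Scalar mean edge value.
#' @export
mean_fc <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  mean(m[upper.tri(m)])
}
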