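#' Derive synchronization-likelihood parameters from band limits
#'
#' Applies the standard frequency-based heuristic: the embedding lag samples
#' the fastest band oscillation three times per cycle, the embedding
#' dimension spans the slowest oscillation, and the inner Theiler window
#' covers two periods of the slowest oscillation; the outer window then
#' follows from the requested number and fraction of recurrences,
#' `w2 = w1 + nrec/pref - 1`. For `fs = 200` Hz and an 8-12 Hz band with
#' `pref = 0.01`, `nrec = 10` this yields `L = 6`, `m = 6`, `w1 = 50`,
#' `w2 = 1049`.
#'
#' @param fs sampling rate in Hz.
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz < fs/2`.
#' @param pref target fraction of candidates counted as recurrences, in
#'   `(0, 1)`.
#' @param nrec target number of recurrences per reference index.
#' @return An object of class `sl_parameters`: list with integer fields
#'   `L`, `m`, `w1`, `w2` plus `pref` and `nrec`.
#' @examples
#' sl_parameters(200, 8, 12)
#' @export
sl_parameters <- function(fs, low_hz, high_hz, pref = 0.01, nrec = 10) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  if (pref <= 0 || pref >= 1) stop("pref must be in (0, 1)")
  L <- as.integer(round_half_away(fs / (3 * high_hz)))
  m <- as.integer(round_half_away(3 * high_hz / low_hz + 1))
  w1 <- as.integer(round_half_away(2 * fs / low_hz))
  w2 <- as.integer(round_half_away(w1 + nrec / pref - 1))
  if (m < 2L) stop("derived embedding dimension m < 2; band too narrow")
  if (L < 1L) stop("derived embedding lag L < 1")
  structure(list(L = L, m = m, w1 = w1, w2 = w2,
                 pref = pref, nrec = as.integer(nrec)),
            class = "sl_parameters")
}

#' @export
print.sl_parameters <- function(x, ...) {
  cat(sprintf("<sl_parameters> L = %d, m = %d, W1 = %d, W2 = %d (pref = %g, nrec = %d)\n",
              x$L, x$m, x$w1, x$w2, x$pref, x$nrec))
  invisible(x)
}

#' Synchronization likelihood between all channel pairs
#'
#' Estimates, for every channel pair, the probability that state-space
#' recurrences of one channel's time-delay embedding coincide with
#' recurrences of the other. The per-reference critical distance is chosen
#' by rank so that a fraction `pref` of the Theiler-window candidates count
#' as recurrences; for independent channels the joint recurrence rate is
#' therefore close to `pref`, while identical channels reach 1.
#'
#' @param segment numeric matrix, samples x channels.
#' @param params an [sl_parameters()] object.
#' @param labels optional channel labels.
#' @return A `connectivity_matrix` (measure `"SL"`) with entries in
#'   `[0, 1]`.
#' @export
synchronization_likelihood <- function(segment, params, labels = NULL) {
  stopifnot(inherits(params, "sl_parameters"))
  segment <- as.matrix(segment)
  storage.mode(segment) <- "double"
  if (ncol(segment) < 2L) stop("need at least 2 channels")
  n_min <- (params$m - 1L) * params$L + params$w1 + params$nrec + 1L
  if (nrow(segment) < n_min) {
    stop(sprintf("segment has %d samples; at least %d required for L=%d, m=%d, w1=%d, nrec=%d",
                 nrow(segment), n_min, params$L, params$m, params$w1, params$nrec))
  }
  out <- .sl_pairwise(segment, params$L, params$m, params$w1, params$w2,
                      params$pref, params$nrec)
  connectivity_matrix(out, "SL", labels)
}
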