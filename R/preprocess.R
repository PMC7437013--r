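#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel into `[low_hz, high_hz]` with a Butterworth band-pass
#' applied forward and backward (`signal::filtfilt`), so the pass band is
#' phase-neutral and the effective attenuation is the squared magnitude
#' response of the design.
#'
#' @param rec an [recording()] object.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth order of the underlying low/high sections
#'   (default 4, a common choice for narrow EEG bands).
#' @return A filtered `alpha_recording` at the same sampling rate.
#' @examples
#' rec <- recording(matrix(rnorm(2000), 1000, 2), fs = 200)
#' alpha <- bandpass(rec, 8, 12)
#' @export
bandpass <- function(rec, low_hz = 8, high_hz = 12, order = 4) {
  stopifnot(inherits(rec, "alpha_recording"))
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop(sprintf("band edges must satisfy 0 < %g < %g < fs/2 = %g Hz",
                 low_hz, high_hz, nyq))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- apply(rec$data, 2, function(x) signal::filtfilt(bf, x))
  recording(out, rec$fs, rec$labels)
}

#' Downsample a band-limited recording by integer decimation
#'
#' Keeps every `fs/target_fs`-th sample. No extra anti-alias filter is
#' applied: the intended use is after [bandpass()], when the signal's content
#' sits far below the new Nyquist frequency.
#'
#' @param rec an [recording()] object.
#' @param target_fs new sampling rate; `fs` must be an integer multiple.
#' @return Decimated `alpha_recording` with `fs = target_fs`.
#' @export
downsample <- function(rec, target_fs = 200) {
  stopifnot(inherits(rec, "alpha_recording"))
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop(sprintf("fs = %g is not an integer multiple of target_fs = %g",
                 rec$fs, target_fs))
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  idx <- seq(1L, nrow(rec$data), by = factor)
  recording(rec$data[idx, , drop = FALSE], target_fs, rec$labels)
}

#' Cut a recording into consecutive artifact-free segments
#'
#' Splits the recording into non-overlapping blocks of `segment_len` samples
#' (in temporal order), optionally drops blocks whose absolute amplitude
#' exceeds `max_abs` (an automatic stand-in for visual artifact screening),
#' and keeps the first `n_segments` clean blocks.
#'
#' @param rec an [recording()] object.
#' @param segment_len samples per segment (default 4096, i.e. 20.48 s at
#'   200 Hz).
#' @param n_segments number of clean segments to retain (default 10).
#' @param max_abs amplitude screen threshold in signal units; `NULL`
#'   (default) disables screening.
#' @param subject_id identifier stored on the result.
#' @return A [segment_set()] with exactly `n_segments` segments.
#' @export
segment_recording <- function(rec, segment_len = 4096, n_segments = 10,
                              max_abs = NULL, subject_id = "s01") {
  stopifnot(inherits(rec, "alpha_recording"))
  n <- nrow(rec$data)
  n_blocks <- n %/% segment_len
  if (n_blocks < 1L) {
    stop(sprintf("recording has %d samples, shorter than one %d-sample segment",
                 n, segment_len))
  }
  kept <- list()
  for (b in seq_len(n_blocks)) {
    block <- rec$data[((b - 1L) * segment_len + 1L):(b * segment_len), ,
                      drop = FALSE]
    if (!is.null(max_abs) && max(abs(block)) > max_abs) next
    kept[[length(kept) + 1L]] <- block
    if (length(kept) == n_segments) break
  }
  if (length(kept) < n_segments) {
    stop(sprintf("only %d artifact-free segments found, %d required",
                 length(kept), n_segments))
  }
  segment_set(kept, rec$fs, subject_id)
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' each output sample (row) sums to zero. This is an idempotent linear
#' projection and serves as the reference montage of the pipeline.
#'
#' @param rec an [recording()] object with at least two channels.
#' @return Re-referenced `alpha_recording`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "alpha_recording"))
  if (ncol(rec$data) < 2L) stop("re-referencing needs at least 2 channels")
  recording(rec$data - rowMeans(rec$data), rec$fs, rec$labels)
}

#' Full conditioning chain for one subject
#'
#' filter -> downsample -> segment -> re-reference, in that order.
#'
#' @inheritParams bandpass
#' @inheritParams downsample
#' @inheritParams segment_recording
#' @return A [segment_set()] of re-referenced alpha-band segments.
#' @export
preprocess <- function(rec, low_hz = 8, high_hz = 12, order = 4,
                       target_fs = 200, segment_len = 4096, n_segments = 10,
                       max_abs = NULL, subject_id = "s01") {
  rec <- bandpass(rec, low_hz, high_hz, order)
  rec <- downsample(rec, target_fs)
  ss <- segment_recording(rec, segment_len, n_segments, max_abs, subject_id)
  ss$segments <- lapply(ss$segments, function(seg) seg - rowMeans(seg))
  ss
}
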