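#' Multichannel recording container
#'
#' Bundles a numeric signal block (samples in rows, channels in columns) with
#' its sampling rate and channel labels. All pipeline stages consume and
#' return this class.
#'
#' @param data numeric matrix, samples x channels; all values finite.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels character vector of unique channel names; defaults to
#'   `ch01, ch02, ...`.
#'
#' @return An object of class `alpha_recording`: a list with elements
#'   `data`, `fs`, `labels`.
#' @examples
#' rec <- recording(matrix(rnorm(400), 200, 2), fs = 100)
#' rec
#' @export
recording <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at row %d, column %d", bad[1], bad[2]))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a positive scalar (Hz)")
  }
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(ncol(data)))
  labels <- as.character(labels)
  if (length(labels) != ncol(data)) {
    stop("number of labels (", length(labels), ") != number of channels (",
         ncol(data), ")")
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  colnames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels),
            class = "alpha_recording")
}

#' @export
print.alpha_recording <- function(x, ...) {
  cat(sprintf("<alpha_recording> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  cat("channels:", paste(head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Set of equal-length segments for one subject
#'
#' @param segments list of samples x channels matrices, all the same shape.
#' @param fs sampling rate in Hz.
#' @param subject_id identifier carried through to study tables.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(segments, fs, subject_id = "s01") {
  stopifnot(is.list(segments), length(segments) >= 1L)
  dims <- vapply(segments, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all segments must have identical dimensions")
  }
  structure(list(subject_id = subject_id, segments = segments, fs = fs),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$segments[[1]])
  cat(sprintf("<segment_set> subject %s: %d segments of %d samples x %d channels @ %g Hz\n",
              x$subject_id, length(x$segments), d[1], d[2], x$fs))
  invisible(x)
}
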