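#' Per-subject connectivity for all three measures
#'
#' Computes MSC, ICOH and SL on every segment of a subject and aggregates
#' segments by the element-wise median.
#'
#' @param segments a [segment_set()].
#' @param band band edges in Hz.
#' @param window_len,overlap_fraction Welch settings for the spectral
#'   measures.
#' @param sl_params an [sl_parameters()] object; derived from `band` and the
#'   sampling rate when `NULL`.
#' @param measures subset of `c("MSC", "ICOH", "SL")`.
#' @return Named list of `connectivity_matrix` objects, one per measure.
#' @export
subject_connectivity <- function(segments, band = c(8, 12), window_len = 512,
                                 overlap_fraction = 0.5, sl_params = NULL,
                                 measures = c("MSC", "ICOH", "SL")) {
  stopifnot(inherits(segments, "segment_set"))
  measures <- match.arg(measures, several.ok = TRUE)
  if ("SL" %in% measures && is.null(sl_params)) {
    sl_params <- sl_parameters(segments$fs, band[1], band[2])
  }
  per_measure <- list()
  spectral <- intersect(measures, c("MSC", "ICOH"))
  for (ms in measures) per_measure[[ms]] <- list()
  for (seg in segments$segments) {
    if (length(spectral)) {
      sp <- welch_spectra(seg, segments$fs, window_len, overlap_fraction)
      if ("MSC" %in% measures) {
        per_measure$MSC[[length(per_measure$MSC) + 1L]] <- msc(sp, band)
      }
      if ("ICOH" %in% measures) {
        per_measure$ICOH[[length(per_measure$ICOH) + 1L]] <- icoh(sp, band)
      }
    }
    if ("SL" %in% measures) {
      per_measure$SL[[length(per_measure$SL) + 1L]] <-
        synchronization_likelihood(seg, sl_params)
    }
  }
  lapply(per_measure, aggregate_segments)
}

#' Run the full connectivity vs small-worldness study
#'
#' End-to-end orchestration: generate (or accept) a cohort of per-subject
#' segment sets, estimate the three connectivity measures per subject,
#' threshold each subject's matrices over the density grid, compute
#' small-world metrics against Maslov-Sneppen nulls, and correlate subject
#' mean connectivity with small-worldness under Bonferroni control. The run
#' is a pure function of (configuration, seed); when `out_dir` is given all
#' per-stage artifacts are written as delimited text.
#'
#' @param cohort a `synthetic_cohort` from [generate_study_cohort()], or a
#'   plain list of [segment_set()] objects.
#' @param band band edges in Hz.
#' @param densities density grid (default 10-50% step 5%).
#' @param window_len,overlap_fraction Welch settings.
#' @param sl_params optional [sl_parameters()] override.
#' @param measures connectivity measures to run.
#' @param n_null,n_swap_factor null-model settings.
#' @param family_alpha,n_tests Bonferroni settings; `n_tests = NULL` uses
#'   measures x densities.
#' @param seed integer seed controlling every random stage (null models).
#' @param out_dir optional output directory for artifacts.
#' @return An `fc_sw_study` object (see [fc_sw_study()]) with an extra
#'   `subjects` attribute carrying per-subject mean connectivity and
#'   small-worldness tables.
#' @export
run_study <- function(cohort, band = c(8, 12),
                      densities = seq(0.10, 0.50, by = 0.05),
                      window_len = 512, overlap_fraction = 0.5,
                      sl_params = NULL, measures = c("MSC", "ICOH", "SL"),
                      n_null = 10, n_swap_factor = 10,
                      family_alpha = 0.05, n_tests = NULL,
                      seed = 1L, out_dir = NULL) {
  if (inherits(cohort, "synthetic_cohort")) {
    subjects <- lapply(cohort$subjects, `[[`, "segments")
  } else {
    subjects <- cohort
    if (!all(vapply(subjects, inherits, logical(1), "segment_set"))) {
      stop("cohort must be a synthetic_cohort or a list of segment_set objects")
    }
  }
  measures <- match.arg(measures, c("MSC", "ICOH", "SL"), several.ok = TRUE)
  n_sub <- length(subjects)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  fc_means <- sapply(measures, function(m) numeric(n_sub), simplify = FALSE)
  sw_vals <- sapply(measures, function(m)
    matrix(NA_real_, n_sub, length(densities),
           dimnames = list(NULL, densities)), simplify = FALSE)

  for (s in seq_len(n_sub)) {
    ss <- subjects[[s]]
    conn <- subject_connectivity(ss, band, window_len, overlap_fraction,
                                 sl_params, measures)
    for (mi in seq_along(measures)) {
      ms <- measures[mi]
      fc_means[[ms]][s] <- mean_fc(conn[[ms]])
      sweep_tab <- density_sweep(conn[[ms]], densities, n_null, n_swap_factor,
                                 seed = child_seed(seed, s * 100 + mi))
      sw_vals[[ms]][s, ] <- sweep_tab$SW
      if (!is.null(out_dir)) {
        write_connectivity(conn[[ms]], file.path(
          out_dir, sprintf("%s_%s.tsv", ss$subject_id, tolower(ms))))
        utils::write.csv(cbind(subject = ss$subject_id, measure = ms, sweep_tab),
                         file.path(out_dir, sprintf("%s_%s_sw.csv",
                                                    ss$subject_id, tolower(ms))),
                         row.names = FALSE)
      }
    }
  }

  study <- fc_sw_study(fc_means, sw_vals, densities, family_alpha, n_tests)
  attr(study, "subjects") <- list(fc = fc_means, sw = sw_vals)
  if (!is.null(out_dir)) {
    utils::write.csv(study$table, file.path(out_dir, "study_table.csv"),
                     row.names = FALSE)
    if (!is.null(study$comparisons)) {
      utils::write.csv(study$comparisons,
                       file.path(out_dir, "sw_comparisons.csv"),
                       row.names = FALSE)
    }
    manifest <- c(
      sprintf("package: alphasw %s", as.character(utils::packageVersion("alphasw"))),
      sprintf("seed: %d", seed),
      sprintf("subjects: %d", n_sub),
      sprintf("measures: %s", paste(measures, collapse = ",")),
      sprintf("band: %g:%g", band[1], band[2]),
      sprintf("densities: %s", paste(densities, collapse = ",")),
      sprintf("n_null: %d", n_null),
      sprintf("family_alpha: %g", family_alpha),
      sprintf("n_tests: %d", study$n_tests))
    writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  }
  study
}

#' Read a multichannel recording from delimited text
#'
#' The data file holds a samples x channels numeric matrix (whitespace- or
#' tab-delimited, no header); the manifest is a `key: value` text file
#' supplying at least `fs` and optionally `labels` (comma-separated) and
#' `subject_id`.
#'
#' @param path data file path.
#' @param manifest path to the sidecar manifest.
#' @return An [recording()] object.
#' @export
read_recording <- function(path, manifest) {
  if (!file.exists(path)) stop("data file not found: ", path)
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  meta <- read_keyvalue(manifest)
  if (is.null(meta$fs)) stop("manifest must provide 'fs'")
  dat <- as.matrix(read.table(path, header = FALSE))
  if (!is.numeric(dat)) stop("non-numeric content in ", path)
  labels <- if (!is.null(meta$labels)) {
    trimws(strsplit(meta$labels, ",")[[1]])
  } else NULL
  recording(dat, as.numeric(meta$fs), labels)
}

read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  out <- lapply(kv, function(x) trimws(x[2]))
  names(out) <- vapply(kv, function(x) trimws(x[1]), character(1))
  out
}

#' Write a recording plus its sidecar manifest
#'
#' @param rec an [recording()].
#' @param path data file path; the manifest is written to `<path>.manifest`.
#' @param extra optional named character vector of additional manifest keys
#'   (e.g. ground-truth parameters).
#' @return Invisibly, the manifest path.
#' @export
write_recording <- function(rec, path, extra = NULL) {
  stopifnot(inherits(rec, "alpha_recording"))
  write.table(rec$data, path, row.names = FALSE, col.names = FALSE, sep = "\t")
  manifest <- c(sprintf("fs: %g", rec$fs),
                sprintf("labels: %s", paste(rec$labels, collapse = ",")))
  if (!is.null(extra)) {
    manifest <- c(manifest, sprintf("%s: %s", names(extra), extra))
  }
  mpath <- paste0(path, ".manifest")
  writeLines(manifest, mpath)
  invisible(mpath)
}

#' Write a connectivity matrix as delimited text
#'
#' First line is a `# measure: <measure>` comment, followed by a header row
#' of channel labels and the numeric matrix.
#'
#' @param m a `connectivity_matrix`.
#' @param path output path.
#' @export
write_connectivity <- function(m, path) {
  stopifnot(inherits(m, "connectivity_matrix"))
  labels <- rownames(m) %||% sprintf("ch%02d", seq_len(nrow(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# measure: %s", attr(m, "measure")), con)
  writeLines(paste(labels, collapse = "\t"), con)
  write.table(unclass(m), con, row.names = FALSE, col.names = FALSE,
              sep = "\t")
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity()]
#'
#' Also accepts any square delimited numeric matrix (with or without the
#' measure comment / header). Asymmetry beyond 1e-9 is rejected; a nonzero
#' diagonal is zeroed with a warning.
#'
#' @param path input path.
#' @param measure measure to assume when the file carries no comment.
#' @return A `connectivity_matrix`.
#' @export
read_connectivity <- function(path, measure = "WEIGHT") {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "# measure:")) {
    measure <- trimws(sub("# measure:", "", lines[1], fixed = TRUE))
    lines <- lines[-1]
  }
  labels <- NULL
  first <- strsplit(trimws(lines[1]), "[\t ]+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) {
    labels <- first
    lines <- lines[-1]
  }
  dat <- do.call(rbind, lapply(strsplit(trimws(lines), "[\t ]+"),
                               as.numeric))
  if (anyNA(dat)) stop("non-numeric content in ", path)
  if (nrow(dat) != ncol(dat)) stop("matrix in ", path, " is not square")
  if (max(abs(dat - t(dat))) > 1e-9) {
    stop("matrix in ", path, " is asymmetric beyond 1e-9")
  }
  if (any(diag(dat) != 0)) {
    warning("nonzero diagonal in ", path, "; zeroing by convention")
    diag(dat) <- 0
  }
  connectivity_matrix(dat, measure, labels)
}
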