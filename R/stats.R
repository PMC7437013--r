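#' Pearson correlation with t-test p-value
#'
#' Sample product-moment correlation with the two-sided p-value from the
#' t transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length `>= 3` with non-zero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bonferroni-adjusted per-test alpha
#'
#' @param family_alpha family-wise error rate in `(0, 1)` (default 0.05).
#' @param n_tests number of tests in the family (`>= 1`).
#' @return `family_alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 27) # 0.0019 to 4 decimals
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_tests = 27) {
  stopifnot(n_tests >= 1, family_alpha > 0, family_alpha < 1)
  family_alpha / n_tests
}

#' Critical correlation magnitude for a two-sided test
#'
#' Inverts the t-test for a Pearson correlation: with `t*` the `1 - alpha/2`
#' quantile of the t distribution on `n - 2` degrees of freedom,
#' `r* = t* / sqrt(t*^2 + n - 2)`. A sample `|r| > r*` is equivalent to the
#' two-sided p-value falling below `alpha`. For `alpha = 0.05/27` and
#' `n = 80` this gives 0.34 (2 decimals).
#'
#' @param alpha_two_sided significance level of the two-sided test.
#' @param n sample size (`>= 4`).
#' @return Critical `|r|` in `(0, 1)`.
#' @export
critical_r <- function(alpha_two_sided, n) {
  stopifnot(n >= 4, alpha_two_sided > 0, alpha_two_sided < 1)
  tstar <- qt(1 - alpha_two_sided / 2, df = n - 2)
  tstar / sqrt(tstar^2 + n - 2)
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum comparison using midranks for ties, tie-corrected
#' variance and continuity correction — the standard large-sample `ranksum`
#' behaviour. Returns the rank sum of the first sample alongside the
#' p-value.
#'
#' @param a,b numeric samples, each with `>= 2` values.
#' @return List with `rank_sum` (sum of ranks of `a` in the pooled sample),
#'   `statistic` (Mann-Whitney U of `a`), and `p` (two-sided).
#' @export
ranksum <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  pooled <- rank(c(a, b))
  w <- sum(pooled[seq_along(a)])
  u <- w - length(a) * (length(a) + 1) / 2
  if (length(unique(c(a, b))) == 1L) {
    return(list(rank_sum = w, statistic = u, p = 1))
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = FALSE, correct = TRUE))
  list(rank_sum = w, statistic = u, p = wt$p.value)
}

#' Study-level correlation table between connectivity and small-worldness
#'
#' The central analysis: for every measure x density cell, the Pearson
#' correlation across subjects between mean connectivity and small-worldness
#' is computed and flagged against a Bonferroni-adjusted threshold. The
#' significance flag is derived both from `p < alpha_adjusted` and from
#' `|r| > critical_r(alpha_adjusted, n)`; the two criteria are asserted to
#' agree. Pairwise rank-sum comparisons of small-worldness between measures
#' are attached per density.
#'
#' @param fc named list (one element per measure) of numeric vectors: each
#'   subject's mean connectivity. Constant across densities by construction.
#' @param sw named list (one element per measure) of subject x density
#'   matrices of small-worldness values; columns named by density.
#' @param densities numeric vector of densities matching the columns of the
#'   `sw` matrices.
#' @param family_alpha family-wise alpha (default 0.05).
#' @param n_tests Bonferroni family size; defaults to
#'   `length(fc) * length(densities)` (27 under study defaults).
#' @return An object of class `fc_sw_study`; see [fc_sw_study] methods.
#' @export
fc_sw_study <- function(fc, sw, densities, family_alpha = 0.05,
                        n_tests = NULL) {
  measures <- names(fc)
  stopifnot(!is.null(measures), identical(sort(measures), sort(names(sw))))
  n_sub <- unique(c(vapply(fc, length, integer(1)),
                    vapply(sw, nrow, integer(1))))
  if (length(n_sub) != 1L) {
    stop("subject counts differ between measures / metrics")
  }
  for (ms in measures) {
    if (ncol(sw[[ms]]) != length(densities)) {
      stop("small-worldness columns must match the density grid")
    }
  }
  n_tests <- n_tests %||% (length(measures) * length(densities))
  alpha_adj <- bonferroni_alpha(family_alpha, n_tests)
  r_crit <- critical_r(alpha_adj, n_sub)

  cells <- list()
  for (ms in measures) {
    for (di in seq_along(densities)) {
      ct <- pearson(fc[[ms]], sw[[ms]][, di])
      sig_p <- ct$p < alpha_adj
      sig_r <- abs(ct$r) > r_crit
      if (sig_p != sig_r) {
        stop("p-value and critical-r significance criteria disagree")
      }
      cells[[length(cells) + 1L]] <- data.frame(
        measure = ms, density = densities[di], r = ct$r, p = ct$p,
        n = ct$n, critical_r = r_crit, significant = sig_p)
    }
  }
  table <- do.call(rbind, cells)

  comparisons <- NULL
  if (length(measures) >= 2L) {
    pairs <- utils::combn(measures, 2, simplify = FALSE)
    comp <- list()
    for (di in seq_along(densities)) {
      for (pr in pairs) {
        rs <- ranksum(sw[[pr[1]]][, di], sw[[pr[2]]][, di])
        comp[[length(comp) + 1L]] <- data.frame(
          density = densities[di],
          measure_pair = paste(pr, collapse = " vs "),
          rank_sum = rs$rank_sum, statistic = rs$statistic, p = rs$p)
      }
    }
    comparisons <- do.call(rbind, comp)
  }

  structure(list(table = table, comparisons = comparisons,
                 fc = fc, sw = sw, densities = densities,
                 measures = measures, n_subjects = n_sub,
                 family_alpha = family_alpha, n_tests = n_tests,
                 alpha_adjusted = alpha_adj, critical_r = r_crit),
            class = "fc_sw_study")
}

#' @export
print.fc_sw_study <- function(x, ...) {
  cat(sprintf("Connectivity vs small-worldness study: %d subjects, %d measures x %d densities = %d cells\n",
              x$n_subjects, length(x$measures), length(x$densities),
              nrow(x$table)))
  cat(sprintf("Bonferroni: alpha %.3g / %d tests = %.4g; critical |r| = %.2f\n",
              x$family_alpha, x$n_tests, x$alpha_adjusted, x$critical_r))
  nsig <- sum(x$table$significant)
  cat(sprintf("%d of %d cells significant\n", nsig, nrow(x$table)))
  invisible(x)
}

#' @export
summary.fc_sw_study <- function(object, ...) {
  tab <- object$table
  tab$r <- round(tab$r, 3)
  tab$p <- signif(tab$p, 3)
  cat(sprintf("Pearson correlations between mean connectivity and small-worldness (n = %d)\n",
              object$n_subjects))
  cat(sprintf("Significance: |r| > %.3f (two-sided p < %.4g, Bonferroni %g/%d)\n\n",
              object$critical_r, object$alpha_adjusted,
              object$family_alpha, object$n_tests))
  print(tab, row.names = FALSE)
  if (!is.null(object$comparisons)) {
    cat("\nRank-sum comparisons of small-worldness between measures:\n")
    comp <- object$comparisons
    comp$p <- signif(comp$p, 3)
    print(comp, row.names = FALSE)
  }
  invisible(object)
}

#' Correlation coefficients of a study as a measure x density matrix
#' @param object an `fc_sw_study`.
#' @param ... unused.
#' @export
coef.fc_sw_study <- function(object, ...) {
  out <- matrix(NA_real_, length(object$measures), length(object$densities),
                dimnames = list(object$measures, object$densities))
  for (i in seq_len(nrow(object$table))) {
    row <- object$table[i, ]
    out[row$measure, as.character(row$density)] <- row$r
  }
  out
}

#' Plot correlation against graph density
#'
#' One line per connectivity measure; the horizontal reference lines mark
#' the critical correlation magnitude below/above which cells are
#' significant after Bonferroni correction.
#'
#' @param x an `fc_sw_study`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fc_sw_study <- function(x, ...) {
  r <- t(coef(x))
  graphics::matplot(x$densities, r, type = "b", pch = 19, lty = 1,
                    xlab = "graph density", ylab = "Pearson r",
                    ylim = range(c(r, -x$critical_r, x$critical_r)), ...)
  graphics::abline(h = c(-x$critical_r, x$critical_r), lty = 2, col = "grey40")
  graphics::abline(h = 0, col = "grey80")
  graphics::legend("topright", legend = rownames(coef(x)), col = seq_len(nrow(coef(x))),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}
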