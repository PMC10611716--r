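fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' Pearson correlation of two qGI profiles
#'
#' Correlates the qGI scores of two screens over their shared genes. With a
#' `threshold`, the correlation is restricted to genes exceeding the absolute
#' score cut-off in both profiles (the stringent-cut-off variant used to
#' assess reproducibility of significant interactions only).
#'
#' @param a,b qGI profiles: tibbles with `gene` and `qgi` columns (e.g.
#'   `tidy(<qgi_result>)`).
#' @param threshold Optional absolute qGI cut-off applied to both profiles.
#' @param min_genes Minimum number of shared genes required (default 50).
#' @return Pearson correlation coefficient (scalar).
#' @export
profile_correlation <- function(a, b, threshold = NULL, min_genes = 50) {
  m <- dplyr::inner_join(dplyr::select(a, "gene", qgi_a = "qgi"),
                         dplyr::select(b, "gene", qgi_b = "qgi"),
                         by = "gene")
  if (!is.null(threshold)) {
    m <- dplyr::filter(m, abs(.data$qgi_a) > threshold,
                       abs(.data$qgi_b) > threshold)
  }
  if (nrow(m) < min_genes) {
    stop("only ", nrow(m), " shared genes (need >= ", min_genes, ")")
  }
  if (stats::sd(m$qgi_a) == 0 || stats::sd(m$qgi_b) == 0) {
    stop("zero variance in a profile; correlation undefined")
  }
  stats::cor(m$qgi_a, m$qgi_b)
}

#' Within-vs-between replicate correlation (WBC) score
#'
#' Quantifies the reproducibility of a query screen's qGI profile as a
#' z-score: the Fisher-z transformed correlation between its replicate
#' screens (within), standardized against the distribution of Fisher-z
#' correlations between each replicate and a panel of screens of other
#' queries (between):
#' `wbc = (z_within - mean(z_between)) / sd(z_between)`. A large positive
#' WBC means the replicates agree with each other far more than with
#' unrelated screens.
#'
#' @param replicates List of >= 2 qGI profiles (tibbles `gene, qgi`) of the
#'   same query.
#' @param panel List of >= 3 qGI profiles of other queries.
#' @param min_genes Minimum shared genes per correlation (default 50).
#' @return A `wbc_result` object: list with `wbc`, `within_r` (mean
#'   replicate-pair correlation, back-transformed from Fisher z),
#'   `between_mean_z`, `between_sd_z`, `n_replicates`, `n_panel`, and the
#'   individual `between_z` values.
#' @export
wbc_score <- function(replicates, panel, min_genes = 50) {
  if (length(replicates) < 2) stop("need >= 2 replicate profiles")
  if (length(panel) < 3) stop("need >= 3 panel profiles")
  pair_idx <- utils::combn(length(replicates), 2, simplify = FALSE)
  within_z <- vapply(pair_idx, function(ij) {
    fisher_z(profile_correlation(replicates[[ij[1]]], replicates[[ij[2]]],
                                 min_genes = min_genes))
  }, numeric(1))
  between_z <- as.vector(vapply(replicates, function(r) {
    vapply(panel, function(p) {
      fisher_z(profile_correlation(r, p, min_genes = min_genes))
    }, numeric(1))
  }, numeric(length(panel))))
  sd_b <- stats::sd(between_z)
  if (sd_b == 0) stop("between-screen correlations have zero spread")
  z_w <- mean(within_z)
  structure(
    list(
      wbc = (z_w - mean(between_z)) / sd_b,
      within_r = tanh(z_w),
      between_mean_z = mean(between_z),
      between_sd_z = sd_b,
      between_z = between_z,
      n_replicates = length(replicates),
      n_panel = length(panel)
    ),
    class = "wbc_result"
  )
}

#' @export
print.wbc_result <- function(x, ...) {
  cat("<wbc_result> WBC = ", format(x$wbc, digits = 3),
      " (within r = ", format(x$within_r, digits = 3), ", ",
      x$n_replicates, " replicates vs ", x$n_panel, " panel screens)\n",
      sep = "")
  invisible(x)
}

#' @describeIn wbc_score One row per between-panel comparison (Fisher-z).
#' @param x A `wbc_result` object.
#' @param ... Unused.
#' @method tidy wbc_result
#' @export
tidy.wbc_result <- function(x, ...) {
  tibble::tibble(
    comparison = "between",
    z = x$between_z,
    r = tanh(x$between_z)
  )
}

#' @describeIn wbc_score One-row summary of the WBC decomposition.
#' @method glance wbc_result
#' @export
glance.wbc_result <- function(x, ...) {
  tibble::tibble(
    wbc = x$wbc,
    within_r = x$within_r,
    between_mean_z = x$between_mean_z,
    between_sd_z = x$between_sd_z,
    n_replicates = x$n_replicates,
    n_panel = x$n_panel
  )
}

#' Histogram of between-screen correlations with the within mark
#'
#' @param object A `wbc_result` object.
#' @param ... Unused.
#' @return A ggplot of the between-panel Fisher-z distribution with the
#'   within-replicate value marked.
#' @method autoplot wbc_result
#' @export
autoplot.wbc_result <- function(object, ...) {
  df <- tibble::tibble(z = object$between_z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = fisher_z(object$within_r),
                        colour = "#b2182b", linewidth = 1) +
    ggplot2::labs(x = "Fisher z of profile correlation", y = "count",
                  title = sprintf("WBC = %.2f", object$wbc)) +
    ggplot2::theme_minimal()
}
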