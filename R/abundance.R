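#' Construct a protein abundance matrix with group labels
#'
#' @param values Numeric matrix (proteins x samples) of log2 intensities,
#'   `NA` for missing; must have row and column names.
#' @param groups Named character vector mapping every sample (column) to its
#'   group label.
#' @return An `abundance_matrix` object.
#' @export
abundance_matrix <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have protein rownames and sample colnames")
  }
  miss <- setdiff(colnames(values), names(groups))
  if (length(miss) > 0) {
    stop("no group label for sample(s): ", paste(miss, collapse = ", "))
  }
  structure(
    list(values = values, groups = groups[colnames(values)]),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("<abundance_matrix> ", nrow(x$values), " proteins x ",
      ncol(x$values), " samples (", sum(is.na(x$values)), " missing); ",
      "groups: ", paste(unique(x$groups), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy an abundance matrix into long format
#'
#' @param x An `abundance_matrix` object.
#' @param ... Unused.
#' @return Long tibble `protein, sample, group, value`.
#' @method tidy abundance_matrix
#' @export
tidy.abundance_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "sample",
                        values_to = "value") |>
    dplyr::mutate(group = unname(x$groups[.data$sample]),
                  .after = "sample")
}

#' Log2 transform and median-normalize raw intensities
#'
#' Log2-transforms raw (positive) intensities and, when `normalize = TRUE`,
#' subtracts each sample's median over its present values, so every sample's
#' post-normalization median is 0.
#'
#' @param raw Numeric matrix (proteins x samples) of raw intensities, `NA`
#'   for missing; or an `abundance_matrix` holding raw intensities.
#' @param groups Named group vector (required when `raw` is a bare matrix).
#' @param normalize Subtract per-sample medians (default TRUE).
#' @return An `abundance_matrix` of (normalized) log2 intensities.
#' @export
log2_and_median_normalize <- function(raw, groups = NULL, normalize = TRUE) {
  if (inherits(raw, "abundance_matrix")) {
    groups <- raw$groups
    raw <- raw$values
  }
  raw <- as.matrix(raw)
  if (any(raw[!is.na(raw)] <= 0)) {
    stop("raw intensities must be positive where present")
  }
  vals <- log2(raw)
  if (normalize) {
    med <- apply(vals, 2, stats::median, na.rm = TRUE)
    if (any(is.na(med))) {
      stop("sample(s) with no present values: ",
           paste(colnames(vals)[is.na(med)], collapse = ", "))
    }
    vals <- sweep(vals, 2, med)
  }
  abundance_matrix(vals, groups)
}

group_valid_counts <- function(m) {
  f <- factor(m$groups)
  present <- !is.na(m$values)
  t(rowsum(t(present) * 1L, f))  # proteins x groups
}

#' Remove proteins without enough valid values
#'
#' Keeps a protein if and only if at least one group quantifies it in at
#' least `min_valid` samples (Perseus' "valid values in at least one group"
#' filter).
#'
#' @param m An `abundance_matrix`.
#' @param min_valid Minimum present values in some group (default 3).
#' @return Filtered `abundance_matrix`.
#' @export
filter_valid_values <- function(m, min_valid = 3) {
  stopifnot(inherits(m, "abundance_matrix"))
  keep <- apply(group_valid_counts(m), 1, max) >= min_valid
  abundance_matrix(m$values[keep, , drop = FALSE], m$groups)
}

#' Impute missing values from a downshifted normal distribution
#'
#' Models missing intensities as left-censored at the detection limit: each
#' missing value in sample `c` is drawn from
#' `Normal(mu_c - downshift * sigma_c, (width * sigma_c)^2)`, where `mu_c`
#' and `sigma_c` are the mean and SD of that sample's present values
#' (Perseus defaults: width 0.3, downshift 1.8). Present values are never
#' changed; the draw is deterministic given `seed`.
#'
#' @param m An `abundance_matrix`.
#' @param width Imputation SD as a fraction of the sample SD (default 0.3).
#' @param downshift Center shift in sample-SD units (default 1.8).
#' @param seed Integer seed for the random draws.
#' @return `abundance_matrix` with no missing values.
#' @export
impute_lod <- function(m, width = 0.3, downshift = 1.8, seed = 1) {
  stopifnot(inherits(m, "abundance_matrix"))
  vals <- m$values
  n_present <- colSums(!is.na(vals))
  if (any(n_present < 2)) {
    stop("sample(s) with fewer than 2 present values: ",
         paste(colnames(vals)[n_present < 2], collapse = ", "))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (j in seq_len(ncol(vals))) {
    mi <- which(is.na(vals[, j]))
    if (length(mi) == 0) next
    mu <- mean(vals[, j], na.rm = TRUE)
    sigma <- stats::sd(vals[, j], na.rm = TRUE)
    vals[mi, j] <- stats::rnorm(length(mi),
                                mean = mu - downshift * sigma,
                                sd = width * sigma)
  }
  abundance_matrix(vals, m$groups)
}

#' S0-moderated two-sample t statistic
#'
#' SAM-style statistic `d = (mean_A - mean_B) / (se + s0)`: the fudge
#' constant `s0` is added to the standard-error denominator so that
#' low-variance proteins cannot reach huge statistics from tiny absolute
#' differences. `s0 = 0` recovers the ordinary two-sample t statistic.
#'
#' @param a,b Numeric vectors of (imputed) log2 intensities, length >= 2
#'   each.
#' @param s0 Fudge constant added to the standard error (default 0).
#' @param var_equal Pooled variance (default TRUE, Perseus behaviour) or
#'   Welch.
#' @return The statistic (scalar).
#' @export
s0_statistic <- function(a, b, s0 = 0, var_equal = TRUE) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values")
  if (var_equal) {
    if (na + nb - 2 < 1) stop("zero within-group degrees of freedom")
    pv <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    se <- sqrt(pv * (1 / na + 1 / nb))
  } else {
    se <- sqrt(stats::var(a) / na + stats::var(b) / nb)
  }
  (mean(a) - mean(b)) / (se + s0)
}

# vectorized per-protein group means/vars/counts for a complete matrix
row_group_stats <- function(values, f) {
  tv <- t(values)
  n <- as.vector(table(f))
  sums <- t(rowsum(tv, f))           # proteins x groups
  sqs <- t(rowsum(tv^2, f))
  means <- sweep(sums, 2, n, "/")
  vars <- sweep(sqs - sweep(means^2, 2, n, "*"), 2, pmax(n - 1, 1), "/")
  vars[vars < 0] <- 0  # numerical guard
  list(means = means, vars = vars, n = n)
}

# per-protein statistic: s0 t for 2 groups (signed), s0-F otherwise
row_s0_stats <- function(values, f, s0, form = c("auto", "anova")) {
  form <- match.arg(form)
  gs <- row_group_stats(values, f)
  k <- length(gs$n)
  if (k == 2 && form == "auto") {
    pv <- ((gs$n[1] - 1) * gs$vars[, 1] + (gs$n[2] - 1) * gs$vars[, 2]) /
      (sum(gs$n) - 2)
    se <- sqrt(pv * (1 / gs$n[1] + 1 / gs$n[2]))
    unname((gs$means[, 1] - gs$means[, 2]) / (se + s0))
  } else {
    grand <- as.vector(gs$means %*% gs$n) / sum(gs$n)
    msb <- as.vector(sweep(gs$means, 1, grand)^2 %*% gs$n) / (k - 1)
    msw <- as.vector(gs$vars %*% (gs$n - 1)) / (sum(gs$n) - k)
    msb / (sqrt(msw) + s0)^2
  }
}

#' One-way ANOVA with an S0 fudge constant
#'
#' Multi-sample test for any group difference per protein. The F statistic's
#' denominator scale is inflated by `s0`:
#' `F_s0 = MS_between / (sqrt(MS_within) + s0)^2`, so `s0 = 0` is the
#' classical one-way F (and with two groups equals the squared pooled t).
#' P-values are taken from the F reference distribution (exact at `s0 = 0`,
#' conservative otherwise); FDR is by Benjamini-Hochberg (`fdr_mode =
#' "bh"`) or label permutation (`"permutation"`, see [permutation_fdr()]).
#'
#' @param m A complete (imputed) `abundance_matrix` with >= 2 groups, each
#'   of size >= 2.
#' @param s0 Fudge constant (default 0).
#' @param fdr_mode `"bh"` or `"permutation"`.
#' @param target_fdr Significance threshold on the FDR (default 0.01).
#' @param n_perm,seed Permutation settings when `fdr_mode = "permutation"`.
#' @return An `abundance_test` object (see [diff_abundance()]).
#' @export
anova_s0 <- function(m, s0 = 0, fdr_mode = c("bh", "permutation"),
                     target_fdr = 0.01, n_perm = 250, seed = 1) {
  stopifnot(inherits(m, "abundance_matrix"))
  fdr_mode <- match.arg(fdr_mode)
  if (anyNA(m$values)) stop("matrix has missing values; impute first")
  f <- factor(m$groups)
  n <- as.vector(table(f))
  if (length(n) < 2) stop("need >= 2 groups")
  if (any(n < 2)) stop("every group needs >= 2 samples")
  if (fdr_mode == "permutation") {
    return(permutation_fdr(m, s0 = s0, n_perm = n_perm,
                           target_fdr = target_fdr, seed = seed,
                           statistic = "anova"))
  }
  k <- length(n)
  if (k == 2) {
    stat <- row_s0_stats(m$values, f, s0)
    pval <- 2 * stats::pt(-abs(stat), sum(n) - 2)
  } else {
    stat <- row_s0_stats(m$values, f, s0, form = "anova")
    pval <- stats::pf(stat, k - 1, sum(n) - k, lower.tail = FALSE)
  }
  fdr <- bh_fdr(pmin(pmax(pval, .Machine$double.xmin), 1))
  res <- tibble::tibble(
    protein = rownames(m$values),
    statistic = stat,
    pval = pval,
    fdr = fdr,
    significant = fdr < target_fdr,
    test = if (k == 2) "pairwise_s0" else "anova_s0"
  )
  new_abundance_test(res, m, list(s0 = s0, fdr_mode = "bh",
                                  target_fdr = target_fdr))
}

#' Permutation-based FDR for S0-moderated statistics
#'
#' Computes the observed S0 statistic per protein (absolute S0-t for two
#' groups, S0-F for more) and a null ensemble from `n_perm` random
#' permutations of the sample-group labels. For a symmetric threshold
#' `tau`, the estimated FDR is the mean number of null statistics >= `tau`
#' per permutation, divided by the number of observed statistics >= `tau`
#' (pi0 fixed at 1, conservative). The significant set is the largest
#' observed-statistic set whose estimated FDR is <= `target_fdr`.
#' Permutations that reproduce the observed grouping (up to group
#' relabelling) are excluded: they regenerate the observed statistics and
#' are not null draws.
#'
#' @param m A complete (imputed) `abundance_matrix`.
#' @param s0 Fudge constant (default 0.1 as used for pairwise tests).
#' @param n_perm Number of label permutations (default 250, minimum 10).
#' @param target_fdr FDR threshold (default 0.01).
#' @param seed Integer seed; the permutation set is deterministic given it.
#' @param statistic `"auto"` (t for 2 groups, ANOVA F otherwise) or
#'   `"anova"` to force the F form.
#' @return An `abundance_test` object with per-protein `statistic`,
#'   `perm_fdr` and `significant`.
#' @export
permutation_fdr <- function(m, s0 = 0.1, n_perm = 250, target_fdr = 0.01,
                            seed = 1, statistic = c("auto", "anova")) {
  stopifnot(inherits(m, "abundance_matrix"))
  statistic <- match.arg(statistic)
  if (n_perm < 10) stop("n_perm must be >= 10")
  if (anyNA(m$values)) stop("matrix has missing values; impute first")
  f <- factor(m$groups)
  if (nlevels(f) < 2) stop("need >= 2 groups")
  two_group <- nlevels(f) == 2 && statistic == "auto"
  form <- if (two_group) "auto" else "anova"
  obs <- row_s0_stats(m$values, f, s0, form = form)
  score <- if (two_group) abs(obs) else obs

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  # canonical partition id: invariant under group relabelling
  part_id <- function(g) {
    gi <- as.integer(g)
    paste(match(gi, unique(gi)), collapse = ".")
  }
  observed_part <- part_id(f)
  null_scores <- matrix(0, nrow(m$values), n_perm)
  b <- 1L
  tries <- 0L
  while (b <= n_perm && tries < 50L * n_perm) {
    tries <- tries + 1L
    fp <- sample(f)
    # a permutation reproducing the observed grouping is not a null draw
    if (part_id(fp) == observed_part) next
    s <- row_s0_stats(m$values, fp, s0, form = form)
    null_scores[, b] <- if (two_group) abs(s) else s
    b <- b + 1L
  }
  if (b <= n_perm) stop("could not generate enough distinct permutations")
  ord <- order(score, decreasing = TRUE)
  sorted <- score[ord]
  null_sorted <- sort(as.vector(null_scores), decreasing = TRUE)
  # mean null exceedances per permutation at each candidate threshold
  fp_mean <- findInterval(-sorted, -null_sorted) / n_perm
  fdr_at <- pmin(fp_mean / seq_along(sorted), 1)
  pass <- which(fdr_at <= target_fdr)
  n_sig <- if (length(pass) > 0) max(pass) else 0L
  sig <- logical(length(score))
  if (n_sig > 0) sig[ord[seq_len(n_sig)]] <- TRUE
  perm_fdr <- numeric(length(score))
  perm_fdr[ord] <- fdr_at
  res <- tibble::tibble(
    protein = rownames(m$values),
    statistic = obs,
    perm_fdr = perm_fdr,
    significant = sig,
    test = if (two_group) "pairwise_s0" else "anova_s0"
  )
  new_abundance_test(res, m, list(s0 = s0, fdr_mode = "permutation",
                                  target_fdr = target_fdr,
                                  n_perm = n_perm, seed = seed))
}

new_abundance_test <- function(results, m, settings) {
  structure(list(results = results, groups = m$groups, settings = settings),
            class = "abundance_test")
}

#' Differential protein abundance, Perseus style
#'
#' Full pipeline on a raw intensity matrix: log2 transform (optionally
#' median-normalized), valid-value filtering, downshifted-normal imputation,
#' then either a pairwise S0 t-test (2 groups) or S0 one-way ANOVA, with BH
#' or permutation-based FDR.
#'
#' @param raw Raw intensity matrix (proteins x samples, `NA` missing).
#' @param groups Named group vector over samples.
#' @param s0 Fudge constant (default 0.1, the pairwise setting; use 0 for
#'   the classical ANOVA variant).
#' @param normalize Median-normalize samples (default TRUE).
#' @param min_valid Valid-value filter threshold (default 3).
#' @param width,downshift Imputation parameters (defaults 0.3, 1.8).
#' @param fdr_mode `"bh"` or `"permutation"`.
#' @param target_fdr FDR threshold (default 0.01).
#' @param n_perm Permutations when `fdr_mode = "permutation"`.
#' @param seed Seed for imputation and permutations.
#' @return An `abundance_test` object; `tidy()` gives the per-protein table,
#'   `glance()` the run summary, `autoplot()` a volcano-style plot.
#' @examples
#' sim <- simulate_lfq(n_proteins = 80, seed = 3)
#' fit <- diff_abundance(sim$raw, sim$groups, s0 = 0.1, seed = 3)
#' glance(fit)
#' @export
diff_abundance <- function(raw, groups, s0 = 0.1, normalize = TRUE,
                           min_valid = 3, width = 0.3, downshift = 1.8,
                           fdr_mode = c("bh", "permutation"),
                           target_fdr = 0.01, n_perm = 250, seed = 1) {
  fdr_mode <- match.arg(fdr_mode)
  m <- log2_and_median_normalize(raw, groups, normalize = normalize) |>
    filter_valid_values(min_valid = min_valid) |>
    impute_lod(width = width, downshift = downshift, seed = seed)
  if (fdr_mode == "bh") {
    anova_s0(m, s0 = s0, fdr_mode = "bh", target_fdr = target_fdr)
  } else {
    permutation_fdr(m, s0 = s0, n_perm = n_perm, target_fdr = target_fdr,
                    seed = seed)
  }
}

#' @export
print.abundance_test <- function(x, ...) {
  cat("<abundance_test> ", nrow(x$results), " proteins tested (",
      x$results$test[1], ", S0 = ", x$settings$s0, ", ",
      x$settings$fdr_mode, " FDR); ", sum(x$results$significant),
      " significant at FDR ", x$settings$target_fdr, "\n", sep = "")
  invisible(x)
}

#' @describeIn diff_abundance Per-protein result table.
#' @param x An `abundance_test` object.
#' @param ... Unused.
#' @method tidy abundance_test
#' @export
tidy.abundance_test <- function(x, ...) x$results

#' @describeIn diff_abundance One-row summary of the test run.
#' @method glance abundance_test
#' @export
glance.abundance_test <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$results),
    n_significant = sum(x$results$significant),
    test = x$results$test[1],
    s0 = x$settings$s0,
    fdr_mode = x$settings$fdr_mode,
    target_fdr = x$settings$target_fdr
  )
}

#' Statistic plot of a differential abundance test
#'
#' @param object An `abundance_test` object.
#' @param ... Unused.
#' @return A ggplot of the per-protein statistics, significant calls
#'   highlighted.
#' @method autoplot abundance_test
#' @export
autoplot.abundance_test <- function(object, ...) {
  df <- dplyr::arrange(object$results, .data$statistic)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$statistic,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "protein rank", y = "S0 statistic",
                  colour = "significant") +
    ggplot2::theme_minimal()
}
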