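#' Build a wild-type control panel from replicate-averaged screens
#'
#' Pools a set of WT control screens into per-guide summary statistics: the
#' panel mean LFC (the single-mutant fitness estimate each query screen is
#' compared against) and its standard deviation across screens.
#'
#' @param wt_screens A list of guide-LFC tibbles (from [screen_lfc()] /
#'   [average_tech_reps()]) or a single stacked tibble containing several
#'   `screen_id`s.
#' @return Tibble `guide_id, gene, panel_mean, panel_sd, n_screens`;
#'   `panel_sd` is 0 where only one screen contains the guide.
#' @export
build_control_panel <- function(wt_screens) {
  if (is.data.frame(wt_screens)) wt_screens <- list(wt_screens)
  if (length(wt_screens) == 0) stop("empty control panel")
  stacked <- dplyr::bind_rows(wt_screens)
  if (nrow(stacked) == 0) stop("empty control panel")
  stacked |>
    dplyr::group_by(.data$guide_id, .data$gene) |>
    dplyr::summarise(
      panel_mean = mean(.data$lfc),
      panel_sd = ifelse(dplyr::n() > 1, stats::sd(.data$lfc), 0),
      n_screens = dplyr::n(),
      .groups = "drop"
    )
}

#' Guide-level residual fold-changes of a query screen
#'
#' Subtracts the control-panel mean LFC from the query screen's LFC on the
#' shared retained-guide set. The residual estimates the deviation of the
#' double-mutant fitness from the single-mutant expectation, i.e. the raw
#' guide-level genetic-interaction signal.
#'
#' @param query Replicate-averaged guide-LFC tibble of the query KO screen.
#' @param panel Control panel from [build_control_panel()].
#' @return Tibble `screen_id, guide_id, gene, raw_residual, panel_mean,
#'   t0_cpm` (plus `t0_raw_mean` when present in the query).
#' @export
residual_lfc <- function(query, panel) {
  shared <- dplyr::inner_join(
    query, dplyr::select(panel, "guide_id", "panel_mean"),
    by = "guide_id"
  )
  if (nrow(shared) == 0) stop("query and panel share no guides")
  out <- shared |>
    dplyr::mutate(raw_residual = .data$lfc - .data$panel_mean) |>
    dplyr::select(dplyr::any_of(c("screen_id", "guide_id", "gene",
                                  "raw_residual", "panel_mean", "t0_cpm",
                                  "t0_raw_mean")))
  out
}

#' LOESS correction of residual fold-changes
#'
#' Fits a second-degree LOESS curve of the raw residuals on the control-panel
#' mean LFC, with a span covering 40% of the guides, and subtracts its
#' predictions. This removes non-linear relationships between the treatment
#' and control screens (e.g. saturation of dropout in one screen) that would
#' otherwise masquerade as interactions.
#'
#' @param table Residual tibble from [residual_lfc()].
#' @param span Neighbourhood fraction (default 0.4).
#' @param degree Local polynomial degree (default 2).
#' @return `table` with a `loess_corrected` column added.
#' @export
loess_correct <- function(table, span = 0.4, degree = 2) {
  fitted <- loess_smooth(table$panel_mean, table$raw_residual,
                         span = span, degree = degree)
  dplyr::mutate(table, loess_corrected = .data$raw_residual - fitted)
}

#' Adjust residuals for their dependence on T0 read counts
#'
#' Guides sampled shallowly at T0 produce noisy, systematically inflated
#' fold-changes. To penalize such potential false positives, a degree-1 LOESS
#' trend of the LOESS-corrected residuals on log10 T0 cpm is estimated and
#' subtracted.
#'
#' @param table Residual tibble with `loess_corrected` and `t0_cpm` columns.
#' @param span Neighbourhood fraction (default 0.4).
#' @return `table` with a `t0_adjusted` column added.
#' @export
t0_adjust <- function(table, span = 0.4) {
  if (any(!is.finite(table$t0_cpm) | table$t0_cpm <= 0)) {
    stop("t0_cpm must be positive for all guides")
  }
  fitted <- loess_smooth(log10(table$t0_cpm), table$loess_corrected,
                         span = span, degree = 1)
  dplyr::mutate(table, t0_adjusted = .data$loess_corrected - fitted)
}

trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate empirical-Bayes variance-moderation parameters
#'
#' Models gene-wise sample variances as draws from a scaled F distribution
#' (`s^2 ~ s0_sq * F(d, d0)`) and recovers the prior degrees of freedom `d0`
#' and prior variance `s0_sq` by method of moments on `log(s^2)`, matching the
#' digamma/trigamma moments of the log scaled-F distribution. When the
#' spread of `log(s^2)` does not exceed what sampling alone explains
#' (`var(log s^2) <= trigamma(d/2)`), the prior is degenerate: `d0 = Inf` and
#' `s0_sq = mean(s^2)`.
#'
#' @param gene_variances Positive sample variances, one per gene.
#' @param residual_df Residual degrees of freedom `d` of each variance.
#' @return List with `d0` (prior df, possibly `Inf`), `s0_sq` (prior
#'   variance) and `d` (the residual df used).
#' @export
estimate_moderation <- function(gene_variances, residual_df) {
  v <- gene_variances[is.finite(gene_variances) & gene_variances > 0]
  if (length(v) < 2) stop("need at least 2 positive gene variances")
  if (length(v) < 10) {
    warning("fewer than 10 positive gene variances; moderation parameters ",
            "will be unstable")
  }
  d <- residual_df
  stopifnot(d >= 1)
  z <- log(v)
  evar <- stats::var(z) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = mean(v), d = d))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq, d = d)
}

#' Moderated one-sample t-tests of gene-level residuals
#'
#' For each gene, tests whether the mean of its guide-level adjusted
#' residuals (pooled across replicate screens) differs from zero, using the
#' empirical-Bayes posterior variance
#' `s_tilde^2 = (d0 * s0_sq + d * s^2) / (d0 + d)` in place of the raw
#' sample variance; the statistic `t = mean / (s_tilde / sqrt(n))` is
#' referred to a Student t distribution with `d0 + d` degrees of freedom.
#' `d0 = 0` recovers the ordinary one-sample t-test; `d0 = Inf` gives a
#' z-like statistic with the common prior variance.
#'
#' @param observations Tibble with columns `gene` and `value` (one row per
#'   guide-level observation).
#' @param params Moderation parameters from [estimate_moderation()], or
#'   `NULL` to estimate them from these observations (using the modal
#'   residual df).
#' @return Tibble `gene, n_obs, mean, var, t, df, pval`; genes with fewer
#'   than 2 observations are dropped and recorded in the `skipped` attribute.
#' @export
moderated_ttest <- function(observations, params = NULL) {
  stats_tbl <- observations |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      mean = mean(.data$value),
      var = ifelse(dplyr::n() > 1, stats::var(.data$value), NA_real_),
      .groups = "drop"
    )
  skipped <- stats_tbl$gene[stats_tbl$n_obs < 2]
  stats_tbl <- dplyr::filter(stats_tbl, .data$n_obs >= 2)
  if (nrow(stats_tbl) == 0) stop("no gene has 2 or more observations")
  if (is.null(params)) {
    df_mode <- as.integer(names(which.max(table(stats_tbl$n_obs - 1))))
    params <- estimate_moderation(stats_tbl$var, df_mode)
  }
  d0 <- params$d0
  s0_sq <- params$s0_sq
  d <- stats_tbl$n_obs - 1
  post_var <- if (is.infinite(d0)) {
    rep(s0_sq, nrow(stats_tbl))
  } else {
    (d0 * s0_sq + d * stats_tbl$var) / (d0 + d)
  }
  tt <- stats_tbl$mean / sqrt(post_var / stats_tbl$n_obs)
  tt[stats_tbl$mean == 0] <- 0  # degenerate 0/0 when the variance is also 0
  df_total <- d0 + d
  out <- stats_tbl |>
    dplyr::mutate(t = tt, df = df_total,
                  pval = 2 * stats::pt(-abs(tt), df_total))
  attr(out, "skipped") <- skipped
  attr(out, "params") <- params
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values controlling the FDR across one family of tests
#' (all scored genes of one query screen).
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-value (FDR) vector of the same length.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Assemble the gene-level qGI score table
#'
#' The qGI score of a gene is the mean T0-adjusted residual LFC over its
#' retained guides (pooled across replicate screens); genes with fewer than
#' two retained guides are omitted. A gene is called a negative interaction
#' when `qgi < -qgi_threshold` and `fdr < fdr_threshold`, positive when
#' `qgi > qgi_threshold` and `fdr < fdr_threshold`, otherwise none.
#'
#' @param residuals Stacked residual tibble(s) with `gene`, `guide_id` and
#'   `t0_adjusted` columns.
#' @param tests Tibble `gene, pval, fdr` (from [moderated_ttest()] +
#'   [bh_fdr()]).
#' @param qgi_threshold Absolute qGI score cut-off (default 0.3).
#' @param fdr_threshold FDR cut-off (default 0.10).
#' @return Tibble `gene, qgi, n_guides, pval, fdr, call`.
#' @export
gene_qgi <- function(residuals, tests, qgi_threshold = 0.3,
                     fdr_threshold = 0.10) {
  gene_means <- residuals |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      qgi = mean(.data$t0_adjusted),
      n_guides = dplyr::n_distinct(.data$guide_id),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_guides >= 2)
  missing_genes <- setdiff(gene_means$gene, tests$gene)
  if (length(missing_genes) > 0) {
    stop("no test result for gene(s): ",
         paste(utils::head(missing_genes, 3), collapse = ", "))
  }
  gene_means |>
    dplyr::inner_join(dplyr::select(tests, "gene", "pval", "fdr"),
                      by = "gene") |>
    dplyr::mutate(call = dplyr::case_when(
      .data$qgi < -qgi_threshold & .data$fdr < fdr_threshold ~ "negative",
      .data$qgi > qgi_threshold & .data$fdr < fdr_threshold ~ "positive",
      TRUE ~ "none"
    ))
}

#' Score quantitative genetic interactions for a query KO screen
#'
#' End-to-end qGI scoring: guide-level residuals of the query against the WT
#' control panel, LOESS correction against the panel mean, T0-dependence
#' adjustment, gene-level moderated t-tests with BH correction, and
#' significance calls at the score/FDR thresholds.
#'
#' @param query A replicate-averaged guide-LFC tibble (one screen) or a list
#'   of them (independent replicate screens of the same query); observations
#'   are pooled across screens.
#' @param panel Control panel from [build_control_panel()].
#' @param span,degree LOESS parameters for the control-trend correction.
#' @param t0_adjust Logical: apply the T0-dependence adjustment (default
#'   TRUE).
#' @param qgi_threshold,fdr_threshold Call thresholds (defaults 0.3, 0.10).
#' @return A `qgi_result` object: list with `genes` (the gene score table),
#'   `residuals` (guide-level table with all correction stages), `params`
#'   (moderation parameters) and the thresholds used.
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 60, n_wt_screens = 2,
#'                                          seed = 4))
#' wt <- lapply(wt_screen_ids(sim$counts), function(s)
#'   screen_lfc(sim$counts, s))
#' ko <- screen_lfc(sim$counts, ko_screen_ids(sim$counts)[1])
#' fit <- score_qgi(ko, build_control_panel(wt))
#' tidy(fit)
#' @export
score_qgi <- function(query, panel, span = 0.4, degree = 2,
                      t0_adjust = TRUE, qgi_threshold = 0.3,
                      fdr_threshold = 0.10) {
  if (is.data.frame(query)) query <- list(query)
  do_t0 <- t0_adjust
  resid <- purrr::map(query, function(q) {
    tbl <- residual_lfc(q, panel) |>
      loess_correct(span = span, degree = degree)
    if (do_t0) {
      qgikit::t0_adjust(tbl, span = span)
    } else {
      dplyr::mutate(tbl, t0_adjusted = .data$loess_corrected)
    }
  }) |>
    dplyr::bind_rows()
  obs <- tibble::tibble(gene = resid$gene, value = resid$t0_adjusted)
  tests <- moderated_ttest(obs)
  tests$fdr <- bh_fdr(tests$pval)
  genes <- gene_qgi(resid, tests, qgi_threshold, fdr_threshold)
  structure(
    list(genes = genes, residuals = resid,
         params = attr(tests, "params"),
         qgi_threshold = qgi_threshold, fdr_threshold = fdr_threshold),
    class = "qgi_result"
  )
}

#' @export
print.qgi_result <- function(x, ...) {
  cat("<qgi_result> ", nrow(x$genes), " genes scored; ",
      sum(x$genes$call == "negative"), " negative / ",
      sum(x$genes$call == "positive"), " positive GIs (|qGI| > ",
      x$qgi_threshold, ", FDR < ", x$fdr_threshold, ")\n", sep = "")
  invisible(x)
}

#' @describeIn score_qgi Gene score table of a fitted qGI result.
#' @param x A `qgi_result` object.
#' @param ... Unused.
#' @method tidy qgi_result
#' @export
tidy.qgi_result <- function(x, ...) x$genes

#' @describeIn score_qgi One-row summary: genes scored, calls by sign, and
#'   the moderation parameters.
#' @method glance qgi_result
#' @export
glance.qgi_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    n_negative = sum(x$genes$call == "negative"),
    n_positive = sum(x$genes$call == "positive"),
    d0 = x$params$d0,
    s0_sq = x$params$s0_sq
  )
}

#' Volcano plot of a qGI result
#'
#' @param object A `qgi_result` object.
#' @param ... Unused.
#' @return A ggplot: qGI score against -log10 FDR, calls coloured by sign.
#' @method autoplot qgi_result
#' @export
autoplot.qgi_result <- function(object, ...) {
  df <- object$genes
  ggplot2::ggplot(df, ggplot2::aes(x = .data$qgi,
                                   y = -log10(.data$fdr),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(negative = "#2166ac",
                                            none = "grey60",
                                            positive = "#b2182b")) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$qgi_threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "qGI score (log2)", y = "-log10 FDR",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' Overlap of interaction calls between two screens
#'
#' Intersects the significantly called genes of two gene score tables,
#' separately for negative and positive interactions.
#'
#' @param calls_a,calls_b Gene score tables (from [gene_qgi()] or
#'   `tidy(<qgi_result>)`).
#' @return Tibble `call, n_a, n_b, n_shared, genes` (list-column of shared
#'   gene symbols).
#' @export
overlap_calls <- function(calls_a, calls_b) {
  purrr::map_dfr(c("negative", "positive"), function(sign) {
    a <- calls_a$gene[calls_a$call == sign]
    b <- calls_b$gene[calls_b$call == sign]
    shared <- intersect(a, b)
    tibble::tibble(call = sign, n_a = length(a), n_b = length(b),
                   n_shared = length(shared), genes = list(shared))
  })
}
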