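#' Counts-per-million normalization with a 0.5 pseudocount
#'
#' Each read count is divided by its sample's total read count, multiplied by
#' one million, and a pseudocount of 0.5 is added:
#' `cpm[g, s] = count[g, s] / colsum[s] * 1e6 + 0.5`. Every normalized value
#' is therefore strictly positive and each column's values minus 0.5 sum to
#' one million.
#'
#' @param table A `screen_counts` object.
#' @return A `screen_cpm` object: list with `values` (tibble, `guide_id`,
#'   `gene`, then one cpm column per sample) and the original `samples` sheet.
#' @export
cpm_normalize <- function(table) {
  stopifnot(inherits(table, "screen_counts"))
  sample_cols <- table$samples$sample_id
  values <- table$counts
  for (s in sample_cols) {
    total <- sum(values[[s]])
    if (total <= 0) stop("sample '", s, "' has zero total reads")
    values[[s]] <- values[[s]] / total * 1e6 + 0.5
  }
  structure(list(values = values, samples = table$samples),
            class = "screen_cpm")
}

#' @export
print.screen_cpm <- function(x, ...) {
  cat("<screen_cpm> ", nrow(x$values), " guides x ", nrow(x$samples),
      " samples (cpm + 0.5)\n", sep = "")
  invisible(x)
}

t0_raw_mean_counts <- function(table, screen_id,
                               mode = c("mean", "any", "all")) {
  mode <- match.arg(mode)
  t0_ids <- table$samples$sample_id[table$samples$screen_id == screen_id &
                                      table$samples$timepoint == "T0"]
  if (length(t0_ids) == 0) {
    stop("screen '", screen_id, "' has no T0 sample")
  }
  m <- as.matrix(table$counts[, t0_ids, drop = FALSE])
  list(mean = rowMeans(m), min = apply(m, 1, min), max = apply(m, 1, max))
}

#' Filter guides on their T0 read-count abundance
#'
#' Guides whose raw (un-normalized) T0 read count lies outside
#' `[min_count, max_count]` are removed: too few T0 reads make the fold-change
#' unstable, too many indicate amplification artifacts. The default summary of
#' a screen's T0 technical replicates is their mean count (`t0_filter_mode =
#' "mean"`); `"all"` requires every replicate in range, `"any"` requires at
#' least one.
#'
#' @param table A `screen_counts` object.
#' @param screen_id Screen whose T0 samples define the filter.
#' @param min_count,max_count Inclusive bounds on the T0 count
#'   (defaults 40 and 10000).
#' @param t0_filter_mode How T0 technical replicates are summarised before
#'   applying the bounds: `"mean"` (default), `"any"`, or `"all"`.
#' @return Character vector of retained `guide_id`s, in library order.
#' @export
filter_guides_t0 <- function(table, screen_id, min_count = 40,
                             max_count = 10000,
                             t0_filter_mode = c("mean", "any", "all")) {
  stopifnot(inherits(table, "screen_counts"))
  t0_filter_mode <- match.arg(t0_filter_mode)
  if (!screen_id %in% table$samples$screen_id) {
    stop("unknown screen_id: '", screen_id, "'")
  }
  t0 <- t0_raw_mean_counts(table, screen_id)
  keep <- switch(t0_filter_mode,
    mean = t0$mean >= min_count & t0$mean <= max_count,
    all  = t0$min >= min_count & t0$max <= max_count,
    any  = t0$max >= min_count & t0$min <= max_count
  )
  table$counts$guide_id[keep]
}

#' Guide-level log2 fold-changes of one screen
#'
#' Computes `lfc[g] = log2(cpm_TEND[g] / cpm_T0[g])` for each technical
#' replicate of a screen. T0 and TEND samples are paired by their
#' `tech_rep` index; when the numbers of T0 and TEND replicates differ, each
#' TEND sample is compared against the mean T0 cpm profile (the T0 pool is
#' sequenced once and split across endpoint replicates).
#'
#' @param norm A `screen_cpm` object from [cpm_normalize()].
#' @param screen_id Screen to compute fold-changes for.
#' @param retained_guides Optional character vector restricting the output to
#'   these guides (e.g. from [filter_guides_t0()]).
#' @return Tibble with one row per guide and technical replicate:
#'   `screen_id, tech_rep, guide_id, gene, lfc, t0_cpm`.
#' @export
compute_lfc <- function(norm, screen_id, retained_guides = NULL) {
  stopifnot(inherits(norm, "screen_cpm"))
  smp <- dplyr::filter(norm$samples, .data$screen_id == !!screen_id)
  if (nrow(smp) == 0) stop("unknown screen_id: '", screen_id, "'")
  t0 <- dplyr::filter(smp, .data$timepoint == "T0")
  tend <- dplyr::filter(smp, .data$timepoint == "TEND")
  if (nrow(tend) == 0) stop("screen '", screen_id, "' has no TEND sample")
  if (nrow(t0) == 0) stop("screen '", screen_id, "' has no T0 sample")

  values <- norm$values
  if (!is.null(retained_guides)) {
    values <- dplyr::filter(values, .data$guide_id %in% retained_guides)
  }
  t0_mat <- as.matrix(values[, t0$sample_id, drop = FALSE])
  paired <- nrow(t0) == nrow(tend) &&
    setequal(t0$tech_rep, tend$tech_rep)
  t0_mean <- rowMeans(t0_mat)

  purrr::map_dfr(seq_len(nrow(tend)), function(i) {
    tend_cpm <- values[[tend$sample_id[i]]]
    if (paired) {
      j <- match(tend$tech_rep[i], t0$tech_rep)
      t0_cpm <- t0_mat[, j]
    } else {
      t0_cpm <- t0_mean
    }
    tibble::tibble(
      screen_id = screen_id,
      tech_rep = tend$tech_rep[i],
      guide_id = values$guide_id,
      gene = values$gene,
      lfc = log2(tend_cpm / t0_cpm),
      t0_cpm = t0_cpm
    )
  })
}

#' Average guide-level fold-changes across technical replicates
#'
#' Takes the per-replicate fold-changes from [compute_lfc()] and returns one
#' arithmetic-mean LFC per guide. Only guides present in every replicate (the
#' intersection of their retained sets) are kept.
#'
#' @param reps Tibble from [compute_lfc()] (all rows from one screen).
#' @return Tibble `screen_id, guide_id, gene, lfc, t0_cpm, n_reps` with one
#'   row per guide; `t0_cpm` is averaged alongside.
#' @export
average_tech_reps <- function(reps) {
  if (nrow(reps) == 0) stop("no replicate fold-changes supplied")
  if (dplyr::n_distinct(reps$screen_id) != 1) {
    stop("all replicates must come from the same screen")
  }
  n_rep <- dplyr::n_distinct(reps$tech_rep)
  reps |>
    dplyr::group_by(.data$screen_id, .data$guide_id, .data$gene) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      lfc = mean(.data$lfc),
      t0_cpm = mean(.data$t0_cpm),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_reps == n_rep) |>
    dplyr::select("screen_id", "guide_id", "gene", "lfc", "t0_cpm", "n_reps")
}

#' Screen counts to replicate-averaged guide fold-changes
#'
#' Convenience wrapper chaining [filter_guides_t0()], [cpm_normalize()],
#' [compute_lfc()] and [average_tech_reps()] for one screen.
#'
#' @inheritParams filter_guides_t0
#' @param norm Optional precomputed `screen_cpm` (avoids renormalizing when
#'   scoring many screens from one table).
#' @return Replicate-averaged guide LFC tibble (see [average_tech_reps()])
#'   with an extra `t0_raw_mean` column (mean raw T0 count per guide).
#' @export
screen_lfc <- function(table, screen_id, min_count = 40, max_count = 10000,
                       t0_filter_mode = "mean", norm = NULL) {
  retained <- filter_guides_t0(table, screen_id, min_count, max_count,
                               t0_filter_mode)
  if (is.null(norm)) norm <- cpm_normalize(table)
  raw_t0 <- tibble::tibble(
    guide_id = table$counts$guide_id,
    t0_raw_mean = t0_raw_mean_counts(table, screen_id)$mean
  )
  compute_lfc(norm, screen_id, retained_guides = retained) |>
    average_tech_reps() |>
    dplyr::left_join(raw_t0, by = "guide_id")
}
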