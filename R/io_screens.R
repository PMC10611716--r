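#' Read a guide-level count table with its sample sheet
#'
#' Reads the two canonical inputs of a pooled CRISPR knockout screen: a
#' tab-delimited count file (`guide_id`, `gene`, then one integer column per
#' sequenced sample) and a tab-delimited sample sheet describing each sample
#' column (`sample_id`, `screen_id`, `cell_line`, `timepoint`, `tech_rep`).
#'
#' @param count_path Path to the count TSV. Header must start with
#'   `guide_id` and `gene`; every remaining column is a sample.
#' @param sample_sheet_path Path to the sample sheet TSV. Every sample column
#'   of the count file must appear in its `sample_id` column.
#' @return A `screen_counts` object: a list with `counts` (tibble, one row per
#'   guide, columns `guide_id`, `gene`, then samples) and `samples` (tibble,
#'   one row per sample).
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 10, seed = 1))
#' tmp <- tempfile(); tmp2 <- tempfile()
#' write_count_table(sim$counts, tmp, tmp2)
#' sc <- read_count_table(tmp, tmp2)
#' sc
#' @export
read_count_table <- function(count_path, sample_sheet_path) {
  counts <- readr::read_tsv(count_path, col_types = readr::cols(
    guide_id = readr::col_character(),
    gene = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  samples <- readr::read_tsv(sample_sheet_path, col_types = readr::cols(
    sample_id = readr::col_character(),
    screen_id = readr::col_character(),
    cell_line = readr::col_character(),
    timepoint = readr::col_character(),
    tech_rep = readr::col_integer()
  ), progress = FALSE)
  new_screen_counts(counts, samples)
}

#' Construct and validate a screen_counts object
#'
#' @param counts Tibble with `guide_id`, `gene` and one numeric column per
#'   sample; counts must be finite non-negative integers.
#' @param samples Sample sheet tibble (`sample_id`, `screen_id`, `cell_line`,
#'   `timepoint`, `tech_rep`).
#' @return A validated `screen_counts` object.
#' @export
new_screen_counts <- function(counts, samples) {
  counts <- tibble::as_tibble(counts)
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "screen_id", "cell_line", "timepoint", "tech_rep")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(c("guide_id", "gene") %in% names(counts))) {
    stop("count table must start with columns 'guide_id' and 'gene'")
  }
  if (anyDuplicated(counts$guide_id)) {
    dup <- counts$guide_id[duplicated(counts$guide_id)][1]
    stop("duplicate guide_id: '", dup, "'")
  }
  sample_cols <- setdiff(names(counts), c("guide_id", "gene"))
  unknown <- setdiff(sample_cols, samples$sample_id)
  if (length(unknown) > 0) {
    stop("sample column(s) missing from sample sheet: ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in sample sheet")
  }
  key <- paste(samples$screen_id, samples$timepoint, samples$tech_rep)
  if (anyDuplicated(key)) {
    stop("duplicate (screen_id, timepoint, tech_rep) in sample sheet")
  }
  bad_tp <- setdiff(unique(samples$timepoint), c("T0", "TEND"))
  if (length(bad_tp) > 0) {
    stop("timepoint must be 'T0' or 'TEND', found: ",
         paste(bad_tp, collapse = ", "))
  }
  for (s in sample_cols) {
    v <- counts[[s]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop("count for guide '", counts$guide_id[bad[1]], "' in sample '", s,
           "' is not a non-negative integer (value: ", v[bad[1]], ")")
    }
  }
  # keep only sheet rows describing columns actually present
  samples <- dplyr::filter(samples, .data$sample_id %in% sample_cols)
  structure(list(counts = counts, samples = samples), class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("<screen_counts> ", nrow(x$counts), " guides x ", nrow(x$samples),
      " samples; screens: ",
      paste(unique(x$samples$screen_id), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a screen_counts object into long format
#'
#' @param x A `screen_counts` object.
#' @param ... Unused.
#' @return Long tibble `guide_id, gene, sample_id, count` joined with the
#'   sample sheet.
#' @method tidy screen_counts
#' @export
tidy.screen_counts <- function(x, ...) {
  x$counts |>
    tidyr::pivot_longer(-c("guide_id", "gene"),
                        names_to = "sample_id", values_to = "count") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

#' Write a screen_counts object back to TSV
#'
#' Inverse of [read_count_table()]: writes the count matrix and the sample
#' sheet as tab-delimited text so that reading them back reproduces the
#' object exactly.
#'
#' @param x A `screen_counts` object.
#' @param count_path,sample_sheet_path Output paths.
#' @return `x`, invisibly.
#' @export
write_count_table <- function(x, count_path, sample_sheet_path) {
  stopifnot(inherits(x, "screen_counts"))
  readr::write_tsv(x$counts, count_path, progress = FALSE)
  readr::write_tsv(x$samples, sample_sheet_path, progress = FALSE)
  invisible(x)
}

#' Write a result table to TSV
#'
#' Generic writer for the pipeline's tabular outputs (gene score tables,
#' residual tables, protein summaries, test results). Columns are written in
#' their current order; doubles are written at full precision (R's default
#' 15 significant digits) so a round-trip preserves values to at least 1e-12.
#'
#' @param table A non-empty data frame.
#' @param path Output path.
#' @return `table`, invisibly.
#' @export
write_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("refusing to write an empty table")
  }
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(table)
}

#' Report the replicate structure of each screen
#'
#' For every screen in the sample sheet, counts its T0 and TEND technical
#' replicates and flags screens that cannot yield a log fold-change because a
#' timepoint is missing entirely. Report-only: never mutates the data.
#'
#' @param table A `screen_counts` object.
#' @return Tibble `screen_id, cell_line, n_t0, n_tend, usable`.
#' @export
validate_screen_design <- function(table) {
  stopifnot(inherits(table, "screen_counts"))
  if (nrow(table$samples) == 0) {
    return(tibble::tibble(screen_id = character(), cell_line = character(),
                          n_t0 = integer(), n_tend = integer(),
                          usable = logical()))
  }
  table$samples |>
    dplyr::group_by(.data$screen_id) |>
    dplyr::summarise(
      cell_line = dplyr::first(.data$cell_line),
      n_t0 = sum(.data$timepoint == "T0"),
      n_tend = sum(.data$timepoint == "TEND"),
      .groups = "drop"
    ) |>
    dplyr::mutate(usable = .data$n_t0 >= 1L & .data$n_tend >= 1L)
}
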