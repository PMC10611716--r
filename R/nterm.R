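#' Read an N-terminal peptide quantification table
#'
#' Accepts comma- or tab-delimited files with the columns `protein_acc`,
#' `peptide_seq`, `start_pos`, `ratio_ac_acdc` (blank = not quantified),
#' `confident` (logical), `cleavage` (`tryptic`/`semi`/`other`), `rank1`
#' (logical).
#'
#' @param path Input CSV/TSV path; the delimiter is sniffed from the header.
#' @return Tibble of peptide records.
#' @export
read_nterm_peptides <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(
    protein_acc = readr::col_character(),
    peptide_seq = readr::col_character(),
    start_pos = readr::col_integer(),
    ratio_ac_acdc = readr::col_double(),
    confident = readr::col_logical(),
    cleavage = readr::col_character(),
    rank1 = readr::col_logical()
  ), progress = FALSE)
}

#' Filter peptide records down to true, quantifiable N-termini
#'
#' Keeps records that pass all of: peptide length >= `min_len` residues,
#' confidently identified spectrum, tryptic cleavage, protein start position
#' 1 or 2 (a true N-terminal peptide: initiator Met retained or cleaved), and
#' rank-1 peptide-spectrum match.
#'
#' @param records Peptide tibble (see [read_nterm_peptides()]).
#' @param min_len Minimum peptide length in residues (default 8).
#' @return Filtered tibble (possibly empty).
#' @export
filter_nterm_peptides <- function(records, min_len = 8) {
  dplyr::filter(
    records,
    nchar(.data$peptide_seq) >= min_len,
    .data$confident,
    .data$cleavage == "tryptic",
    .data$start_pos %in% c(1L, 2L),
    .data$rank1
  )
}

#' Acetylation degree from an Ac/AcDC ratio
#'
#' Converts the light/heavy (in vivo Ac / in vitro heavy-acetyl AcDC)
#' intensity ratio `r` into the percentage of molecules acetylated in vivo:
#' `Ac% = 100 * r / (r + 1)`. Strictly increasing in `r`, with limits 0%
#' (`r = 0`) and 100% (`r -> Inf`). Missing ratios propagate as `NA` (not
#' quantified), never as 0%.
#'
#' @param ratio Non-negative Ac/AcDC ratio(s); `NA` allowed.
#' @return Acetylation degree(s) in percent, in `[0, 100]`.
#' @export
acetylation_degree <- function(ratio) {
  bad <- !is.na(ratio) & (!is.finite(ratio) | ratio < 0)
  if (any(bad)) {
    stop("Ac/AcDC ratio must be finite and non-negative (got ",
         ratio[which(bad)[1]], ")")
  }
  100 * ratio / (ratio + 1)
}

#' Summarise peptide-level acetylation degrees per protein N-terminus
#'
#' Groups filtered, quantified records by protein accession and N-terminus
#' (start position plus the first two observed residues) and reports the
#' median and standard deviation of the peptide-level acetylation degrees,
#' with the supporting peptide count. Each N-terminus is also assigned a NAT
#' substrate class via [classify_nat_type()].
#'
#' @param records Filtered peptide tibble ([filter_nterm_peptides()]).
#' @return An `nterm_summary` tibble: `protein_acc, start_pos, residues,
#'   median_ac_pct, sd_ac_pct, n_peptides, nat_class`, sorted by accession.
#' @export
summarize_protein <- function(records) {
  out <- records |>
    dplyr::filter(!is.na(.data$ratio_ac_acdc)) |>
    dplyr::mutate(
      ac_pct = acetylation_degree(.data$ratio_ac_acdc),
      residues = substr(.data$peptide_seq, 1, 2)
    ) |>
    dplyr::group_by(.data$protein_acc, .data$start_pos, .data$residues) |>
    dplyr::summarise(
      median_ac_pct = stats::median(.data$ac_pct),
      sd_ac_pct = ifelse(dplyr::n() > 1, stats::sd(.data$ac_pct), 0),
      n_peptides = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(nat_class = purrr::map2_chr(.data$start_pos,
                                              .data$residues,
                                              classify_nat_type)) |>
    dplyr::arrange(.data$protein_acc, .data$start_pos)
  class(out) <- c("nterm_summary", class(out))
  out
}

# residue specificity sets of the ribosome-associated NAT complexes
nat_residue_sets <- function() {
  list(
    nata_small = c("A", "C", "G", "P", "S", "T", "V"),
    natb_acidic_amidic = c("D", "E", "N", "Q"),
    natcef_hydrophobic = c("L", "I", "F", "W", "V", "M", "Y", "K", "H")
  )
}

#' Classify an N-terminus by the NAT complex expected to acetylate it
#'
#' NAT complexes recognise the first two residues. After initiator-Met
#' cleavage (observed start position 2), small exposed residues
#' (A, C, G, P, S, T, V) are NatA-type. With the Met retained (start
#' position 1), Met followed by an acidic or amidic residue (D, E, N, Q) is
#' NatB-type; Met followed by a hydrophobic or amphipathic residue
#' (L, I, F, W, V, M, Y, K, H) is NatC/E/F-type. Valine is position
#' dependent: MV- N-termini with retained Met are NatC/E/F substrates while
#' an exposed V after Met cleavage is NatA-type. Everything else is
#' unclassified.
#'
#' @param start_pos Observed start position of the N-terminal peptide
#'   (1 = Met retained, 2 = Met cleaved).
#' @param residues First two observed residues (uppercase), e.g. `"MF"`.
#' @param residue_sets Optional override of the specificity sets (a list
#'   like [nat_residue_sets()]).
#' @return One of `"NatA"`, `"NatB"`, `"NatC/E/F"`, `"unclassified"`.
#' @export
classify_nat_type <- function(start_pos, residues,
                              residue_sets = nat_residue_sets()) {
  aa <- strsplit(residues, "")[[1]]
  if (!all(aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
    stop("invalid residue letter in '", residues, "'")
  }
  if (start_pos == 2 && aa[1] %in% residue_sets$nata_small) {
    return("NatA")
  }
  if (start_pos == 1 && aa[1] == "M" && length(aa) >= 2) {
    if (aa[2] %in% residue_sets$natb_acidic_amidic) return("NatB")
    if (aa[2] %in% residue_sets$natcef_hydrophobic) return("NatC/E/F")
  }
  "unclassified"
}

#' Bar plot of per-protein acetylation degrees by NAT class
#'
#' @param object An `nterm_summary` tibble from [summarize_protein()].
#' @param ... Unused.
#' @return A ggplot of median acetylation degree per protein, coloured by
#'   NAT class, with SD error bars.
#' @method autoplot nterm_summary
#' @export
autoplot.nterm_summary <- function(object, ...) {
  df <- dplyr::arrange(object, .data$nat_class, -.data$median_ac_pct)
  df$protein_acc <- factor(df$protein_acc, levels = unique(df$protein_acc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$protein_acc,
                                   y = .data$median_ac_pct,
                                   fill = .data$nat_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$median_ac_pct - .data$sd_ac_pct, 0),
      ymax = pmin(.data$median_ac_pct + .data$sd_ac_pct, 100)
    ), width = 0.3) +
    ggplot2::labs(x = NULL, y = "median Nt-acetylation (%)",
                  fill = "NAT class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
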