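# in-code fixtures shared across test files

# tiny screen: explicit counts, one screen, paired T0/TEND replicates
toy_counts <- function(counts = NULL, n_reps = 1) {
  if (is.null(counts)) {
    counts <- tibble::tibble(
      guide_id = c("g1", "g2"),
      gene = c("A", "A"),
      S_T0_1 = c(3, 1),
      S_TEND_1 = c(2, 2)
    )
  }
  sample_cols <- setdiff(names(counts), c("guide_id", "gene"))
  parts <- strsplit(sample_cols, "_")
  sheet <- tibble::tibble(
    sample_id = sample_cols,
    screen_id = vapply(parts, `[`, "", 1),
    cell_line = "WT",
    timepoint = vapply(parts, `[`, "", 2),
    tech_rep = as.integer(vapply(parts, `[`, "", 3))
  )
  new_screen_counts(counts, sheet)
}

# guide-LFC tibble built directly (bypasses counts) for panel/residual tests
lfc_tbl <- function(screen_id, guide_id, lfc, gene = NULL, t0_cpm = 500) {
  tibble::tibble(
    screen_id = screen_id,
    guide_id = guide_id,
    gene = if (is.null(gene)) sub("_g[0-9]+$", "", guide_id) else gene,
    lfc = lfc,
    t0_cpm = t0_cpm,
    n_reps = 1L
  )
}

# random qGI profile over shared genes
random_profile <- function(n_genes = 300, seed = 1) {
  set.seed(seed)
  tibble::tibble(gene = sprintf("gene%05d", seq_len(n_genes)),
                 qgi = rnorm(n_genes, 0, 0.2))
}

# brute-force BH step-up: smallest k-averaged bound, O(n^2)
bh_bruteforce <- function(p) {
  n <- length(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    r <- sum(p <= p[i])  # rank with ties sharing the block rank
    cand <- vapply(seq_len(n), function(j) {
      rj <- sum(p <= p[j])
      if (p[j] >= p[i]) n * p[j] / rj else Inf
    }, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  adj
}
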