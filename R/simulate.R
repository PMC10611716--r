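# evaluate code with a local RNG state so generators are reproducible
# without clobbering the caller's random stream
with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the pooled-screen simulator
#'
#' Bundles the knobs of [simulate_screen()] with defaults chosen to mimic a
#' desk-scale pooled knockout screen: 4 guides per gene, negative-binomial
#' read counts around 500 reads per guide with dispersion 0.05 across
#' technical replicates, a log-normal per-guide library-representation
#' spread (sd 0.5 log units), guide efficacies around 1 (truncated normal,
#' sd 0.2), and a fitness landscape where 15% of genes are essential.
#'
#' @param n_genes Number of genes (default 2000).
#' @param guides_per_gene Guides per gene (default 4).
#' @param n_wt_screens WT control screens in the panel (default 4).
#' @param n_ko_screens Replicate query KO screens (default 1).
#' @param n_replicates Technical replicates per screen and timepoint
#'   (default 3).
#' @param depth Expected reads per guide (default 500).
#' @param nb_dispersion Negative-binomial dispersion `alpha`
#'   (`Var = mu + alpha mu^2`; default 0.05).
#' @param librep_sd SD (log units) of the per-guide library representation
#'   (default 0.5).
#' @param guide_efficacy_sd SD of guide efficacy around 1, truncated to
#'   `[0, 2]` (default 0.2).
#' @param frac_essential Fraction of genes with a fitness defect
#'   (default 0.15).
#' @param essential_mean,essential_sd Fitness LFC of essential genes
#'   (defaults -1.2, 0.4).
#' @param neutral_sd Fitness spread of non-essential genes (default 0.1).
#' @param planted_gis Named numeric vector `gene -> delta LFC` of planted
#'   genetic interactions in the KO screens (default none).
#' @param trend_control Optional function of the guide's expected WT LFC
#'   returning an LFC bias added to the query screens only (the artifact the
#'   LOESS correction removes).
#' @param trend_t0 Optional function of `log10(expected T0 count)` returning
#'   an LFC bias added to the query screens only (the artifact the
#'   T0 adjustment removes).
#' @param seed Integer seed.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_genes = 2000, guides_per_gene = 4,
                              n_wt_screens = 4, n_ko_screens = 1,
                              n_replicates = 3, depth = 500,
                              nb_dispersion = 0.05, librep_sd = 0.5,
                              guide_efficacy_sd = 0.2,
                              frac_essential = 0.15, essential_mean = -1.2,
                              essential_sd = 0.4, neutral_sd = 0.1,
                              planted_gis = NULL, trend_control = NULL,
                              trend_t0 = NULL, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$depth <= 0) stop("depth must be positive")
  if (cfg$n_genes < 1 || cfg$guides_per_gene < 1) {
    stop("need at least one gene and one guide per gene")
  }
  if (!is.null(planted_gis)) {
    if (is.null(names(planted_gis))) stop("planted_gis must be named by gene")
  }
  structure(cfg, class = "screen_sim_config")
}

nb_draw <- function(mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(length(mu), mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate pooled CRISPR knockout screens with known ground truth
#'
#' Generates guide-level read counts for a panel of WT control screens and
#' replicate query KO screens. T0 counts are negative binomial around a
#' per-guide library representation; endpoint expected counts are the T0
#' expectation scaled by `2^(fitness x efficacy [+ GI in the KO screens])`.
#' Optional trend functions inject the non-linear control-dependent and
#' T0-count-dependent biases that the LOESS and T0-adjustment steps of the
#' scoring pipeline are designed to remove. Bit-reproducible given the
#' config seed.
#'
#' @param config A [screen_sim_config()].
#' @return List with `counts` (a `screen_counts` object covering all
#'   screens; WT screens are `WT_1..k`, query screens `KO_1..m`) and `truth`
#'   (list of `genes`: `gene, fitness, gi`; `guides`: `guide_id, gene,
#'   efficacy, librep`).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    gpg <- config$guides_per_gene
    genes <- sprintf("gene%05d", seq_len(ng))
    gene_of_guide <- rep(genes, each = gpg)
    guide_id <- paste0(gene_of_guide, "_g", rep(seq_len(gpg), ng))
    n_guides <- length(guide_id)

    essential <- stats::rbinom(ng, 1, config$frac_essential) == 1
    fitness <- ifelse(
      essential,
      stats::rnorm(ng, config$essential_mean, config$essential_sd),
      stats::rnorm(ng, 0, config$neutral_sd)
    )
    gi <- stats::setNames(numeric(ng), genes)
    if (!is.null(config$planted_gis)) {
      unknown <- setdiff(names(config$planted_gis), genes)
      if (length(unknown) > 0) {
        stop("planted_gis for unknown gene(s): ",
             paste(utils::head(unknown, 3), collapse = ", "))
      }
      gi[names(config$planted_gis)] <- config$planted_gis
    }
    efficacy <- pmin(pmax(stats::rnorm(n_guides, 1,
                                       config$guide_efficacy_sd), 0), 2)
    librep <- exp(stats::rnorm(n_guides, 0, config$librep_sd))
    t0_mu <- config$depth * librep / mean(librep)

    fitness_g <- fitness[match(gene_of_guide, genes)]
    gi_g <- gi[match(gene_of_guide, genes)]
    wt_lfc <- fitness_g * efficacy
    bias <- numeric(n_guides)
    if (!is.null(config$trend_control)) {
      bias <- bias + config$trend_control(wt_lfc)
    }
    if (!is.null(config$trend_t0)) {
      bias <- bias + config$trend_t0(log10(t0_mu))
    }

    counts <- tibble::tibble(guide_id = guide_id, gene = gene_of_guide)
    sheet <- list()
    add_screen <- function(counts, screen_id, cell_line, tend_lfc) {
      for (r in seq_len(config$n_replicates)) {
        for (tp in c("T0", "TEND")) {
          sid <- paste(screen_id, tp, r, sep = "_")
          mu <- if (tp == "T0") t0_mu else t0_mu * 2^tend_lfc
          counts[[sid]] <- nb_draw(mu, config$nb_dispersion)
          sheet[[length(sheet) + 1L]] <<- tibble::tibble(
            sample_id = sid, screen_id = screen_id, cell_line = cell_line,
            timepoint = tp, tech_rep = as.integer(r)
          )
        }
      }
      counts
    }
    for (i in seq_len(config$n_wt_screens)) {
      counts <- add_screen(counts, paste0("WT_", i), "WT", wt_lfc)
    }
    for (i in seq_len(config$n_ko_screens)) {
      counts <- add_screen(counts, paste0("KO_", i), "KO-query",
                           wt_lfc + gi_g + bias)
    }
    list(
      counts = new_screen_counts(counts, dplyr::bind_rows(sheet)),
      truth = list(
        genes = tibble::tibble(gene = genes, fitness = fitness,
                               gi = unname(gi), essential = essential),
        guides = tibble::tibble(guide_id = guide_id, gene = gene_of_guide,
                                efficacy = efficacy, librep = librep)
      )
    )
  })
}

#' Screen identifiers by cell-line role
#'
#' @param counts A `screen_counts` object.
#' @return Character vector of screen ids whose cell line is WT
#'   (`wt_screen_ids`) or a knockout (`ko_screen_ids`).
#' @export
wt_screen_ids <- function(counts) {
  unique(counts$samples$screen_id[counts$samples$cell_line == "WT"])
}

#' @rdname wt_screen_ids
#' @export
ko_screen_ids <- function(counts) {
  unique(counts$samples$screen_id[counts$samples$cell_line != "WT"])
}

#' Simulate N-terminal peptide quantifications with known degrees
#'
#' Draws a true acetylation degree per protein, emits `peptides_per_protein`
#' quantified peptide records whose Ac/AcDC ratios are log-normally
#' perturbed around `theta / (100 - theta)`, with start positions and first
#' two residues drawn to match a NAT-class mix. Optionally appends decoy
#' records violating each filtering rule (too short, non-tryptic, internal
#' start, unconfident, not rank 1).
#'
#' @param n_proteins Number of proteins (default 50).
#' @param peptides_per_protein Quantified peptides per protein (default 4).
#' @param true_degree_range Range the true degrees are drawn uniformly from,
#'   in percent (default `c(5, 95)`, open interval enforced).
#' @param ratio_noise_sd SD of the log-normal ratio perturbation in log
#'   units (default 0.2).
#' @param class_mix Named probabilities over `NatA`, `NatB`, `NatC/E/F`
#'   (default 0.4/0.3/0.3).
#' @param include_decoys Append one decoy per filter rule (default TRUE).
#' @param seed Integer seed.
#' @return List with `records` (peptide tibble, decoys flagged via the truth
#'   table's `decoy` column absence) and `truth` (`protein_acc,
#'   true_degree, nat_class, start_pos, residues`).
#' @export
simulate_nterm <- function(n_proteins = 50, peptides_per_protein = 4,
                           true_degree_range = c(5, 95),
                           ratio_noise_sd = 0.2,
                           class_mix = c(NatA = 0.4, NatB = 0.3,
                                         `NatC/E/F` = 0.3),
                           include_decoys = TRUE, seed = 1) {
  if (true_degree_range[1] <= 0 || true_degree_range[2] >= 100) {
    stop("true degrees must lie strictly inside (0, 100)")
  }
  sets <- nat_residue_sets()
  aa_all <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    acc <- sprintf("P%05d", seq_len(n_proteins))
    theta <- stats::runif(n_proteins, true_degree_range[1],
                          true_degree_range[2])
    cls <- sample(names(class_mix), n_proteins, replace = TRUE,
                  prob = class_mix)
    start_pos <- ifelse(cls == "NatA", 2L, 1L)
    residues <- vapply(cls, function(cl) {
      switch(cl,
        NatA = paste0(sample(sets$nata_small, 1), sample(aa_all, 1)),
        NatB = paste0("M", sample(sets$natb_acidic_amidic, 1)),
        `NatC/E/F` = paste0("M", sample(sets$natcef_hydrophobic, 1))
      )
    }, character(1))
    records <- purrr::map_dfr(seq_len(n_proteins), function(i) {
      len <- sample(8:15, peptides_per_protein, replace = TRUE)
      seqs <- vapply(len, function(l) {
        paste0(residues[i],
               paste(sample(aa_all, l - 2, replace = TRUE), collapse = ""))
      }, character(1))
      true_ratio <- theta[i] / (100 - theta[i])
      tibble::tibble(
        protein_acc = acc[i],
        peptide_seq = seqs,
        start_pos = start_pos[i],
        ratio_ac_acdc = true_ratio *
          exp(stats::rnorm(peptides_per_protein, 0, ratio_noise_sd)),
        confident = TRUE,
        cleavage = "tryptic",
        rank1 = TRUE
      )
    })
    if (include_decoys) {
      decoys <- tibble::tibble(
        protein_acc = paste0("DECOY", 1:5),
        peptide_seq = c("MFSHORT",            # 7 residues: too short
                        "MFAAAAAAAA", "MFAAAAAAAA", "MFAAAAAAAA",
                        "MFAAAAAAAA"),
        start_pos = c(1L, 3L, 1L, 1L, 1L),    # internal start
        ratio_ac_acdc = 1,
        confident = c(TRUE, TRUE, FALSE, TRUE, TRUE),  # unconfident
        cleavage = c("tryptic", "tryptic", "tryptic", "semi", "tryptic"),
        rank1 = c(TRUE, TRUE, TRUE, TRUE, FALSE)       # not rank 1
      )
      records <- dplyr::bind_rows(records, decoys)
    }
    list(
      records = records,
      truth = tibble::tibble(protein_acc = acc, true_degree = theta,
                             nat_class = cls, start_pos = start_pos,
                             residues = residues)
    )
  })
}

#' Simulate a label-free quantification matrix with MNAR missingness
#'
#' Log-normal protein intensities with per-replicate noise; a fraction of
#' proteins receives a group shift of `effect_size` log2 units (random
#' sign) in one randomly chosen non-reference group. Values below the
#' left-censoring threshold `lod` (log2 scale) are set missing, producing
#' the detection-limit missingness that downshifted-normal imputation
#' models.
#'
#' @param n_proteins Number of proteins (default 500).
#' @param groups Named integer vector of group sizes (default
#'   `c(WT = 4, KO = 4)`).
#' @param effect_frac Fraction of proteins with a planted shift
#'   (default 0.1).
#' @param effect_size Absolute shift in log2 units (default 2).
#' @param baseline_mean,baseline_sd Log2 intensity distribution across
#'   proteins (defaults 24, 1.5).
#' @param rep_sd Within-protein replicate SD in log2 units (default 0.3).
#' @param lod Left-censoring threshold on the log2 scale; `-Inf` disables
#'   missingness (default 21.5).
#' @param seed Integer seed.
#' @return List with `raw` (raw-intensity matrix, `NA` missing), `groups`
#'   (named sample -> group vector) and `truth` (`protein, planted, shift,
#'   shift_group`).
#' @export
simulate_lfq <- function(n_proteins = 500, groups = c(WT = 4, KO = 4),
                         effect_frac = 0.1, effect_size = 2,
                         baseline_mean = 24, baseline_sd = 1.5,
                         rep_sd = 0.3, lod = 21.5, seed = 1) {
  if (is.null(names(groups))) stop("groups must be a named vector of sizes")
  with_seed(seed, {
    prot <- sprintf("prot%04d", seq_len(n_proteins))
    sample_group <- rep(names(groups), times = groups)
    sample_id <- paste0(sample_group, "_", unlist(lapply(groups, seq_len)))
    n_s <- length(sample_id)
    baseline <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
    planted <- stats::runif(n_proteins) < effect_frac
    shift <- ifelse(planted,
                    effect_size * sample(c(-1, 1), n_proteins,
                                         replace = TRUE), 0)
    non_ref <- setdiff(names(groups), names(groups)[1])
    shift_group <- ifelse(planted,
                          sample(non_ref, n_proteins, replace = TRUE),
                          NA_character_)
    log2_vals <- matrix(baseline, n_proteins, n_s) +
      matrix(stats::rnorm(n_proteins * n_s, 0, rep_sd), n_proteins, n_s)
    for (i in which(planted)) {
      cols <- which(sample_group == shift_group[i])
      log2_vals[i, cols] <- log2_vals[i, cols] + shift[i]
    }
    log2_vals[log2_vals < lod] <- NA
    raw <- 2^log2_vals
    dimnames(raw) <- list(prot, sample_id)
    list(
      raw = raw,
      groups = stats::setNames(sample_group, sample_id),
      truth = tibble::tibble(protein = prot, planted = planted,
                             shift = shift, shift_group = shift_group)
    )
  })
}
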