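test_that("control panel pools per-guide mean and SD across WT screens", {
  one <- lfc_tbl("WT_1", c("A_g1", "A_g2"), c(-0.5, 0.2))
  panel <- build_control_panel(one)
  expect_equal(panel$panel_mean, one$lfc)
  expect_equal(panel$panel_sd, c(0, 0))

  two <- list(lfc_tbl("WT_1", "A_g1", 0), lfc_tbl("WT_2", "A_g1", 2))
  panel2 <- build_control_panel(two)
  expect_equal(panel2$panel_mean, 1)
  expect_equal(panel2$panel_sd, sqrt(2))

  # a guide absent from all screens simply is not in the panel
  expect_false("A_g9" %in% panel2$guide_id)
  expect_error(build_control_panel(list()), "empty")
})

test_that("residuals are query minus panel mean over shared guides", {
  set.seed(21)
  ids <- sprintf("G%03d_g%d", rep(1:25, each = 2), 1:2)
  wt <- lfc_tbl("WT_1", ids, rnorm(50))
  panel <- build_control_panel(wt)
  query <- lfc_tbl("KO_1", ids, wt$lfc)  # identical to the panel mean
  expect_equal(residual_lfc(query, panel)$raw_residual, rep(0, 50))

  shifted <- query
  shifted$lfc[3] <- shifted$lfc[3] - 1.0
  expect_equal(residual_lfc(shifted, panel)$raw_residual[3], -1.0)

  random_query <- lfc_tbl("KO_1", ids, rnorm(50))
  res <- residual_lfc(random_query, panel)
  expect_equal(res$raw_residual, random_query$lfc - panel$panel_mean[
    match(random_query$guide_id, panel$guide_id)], tolerance = 1e-15)

  disjoint <- lfc_tbl("KO_1", "other_g1", 0.5)
  expect_error(residual_lfc(disjoint, panel), "share no guides")
})

test_that("LOESS correction zeroes constant and exactly linear residuals", {
  set.seed(7)
  tbl <- tibble::tibble(
    screen_id = "KO_1", guide_id = sprintf("g%02d", 1:40),
    gene = "A", panel_mean = sort(runif(40, -2, 1)),
    t0_cpm = 500
  )
  const <- dplyr::mutate(tbl, raw_residual = 0.7)
  expect_lt(max(abs(loess_correct(const)$loess_corrected)), 1e-8)

  lin <- dplyr::mutate(tbl, raw_residual = 0.3 * panel_mean - 0.2)
  expect_lt(max(abs(loess_correct(lin)$loess_corrected)), 1e-8)
})

test_that("LOESS matches a per-point tricube weighted-least-squares oracle", {
  set.seed(31)
  n <- 30
  x <- runif(n)
  y <- sin(4 * x) + rnorm(n, 0, 0.3)
  mine <- loess_smooth(x, y, span = 0.4, degree = 2)
  q <- ceiling(0.4 * n)
  oracle <- vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    sel <- order(d)[1:q]
    h <- max(d[sel])
    w <- (1 - pmin(d[sel] / h, 1)^3)^3
    z <- x[sel] - x[i]
    fit <- stats::lm(y[sel] ~ z + I(z^2), weights = w)
    unname(stats::coef(fit)[1])
  }, numeric(1))
  expect_equal(mine, oracle, tolerance = 1e-8)

  expect_error(loess_smooth(x[1:5], y[1:5], span = 0.2, degree = 2),
               "fewer than degree")
})

test_that("T0 adjustment removes planted log10-T0 trends and nothing else", {
  set.seed(13)
  n <- 60
  tbl <- tibble::tibble(
    screen_id = "KO_1", guide_id = sprintf("g%02d", 1:n), gene = "A",
    panel_mean = rnorm(n), t0_cpm = 10^runif(n, 1, 4)
  )
  flat <- dplyr::mutate(tbl, loess_corrected = 0.25)
  expect_lt(max(abs(t0_adjust(flat)$t0_adjusted)), 1e-8)

  trended <- dplyr::mutate(tbl,
                           loess_corrected = 0.8 * log10(t0_cpm) - 1.2)
  expect_lt(max(abs(t0_adjust(trended)$t0_adjusted)), 1e-8)

  # row order is irrelevant: shuffling guides permutes the output identically
  shuffled <- trended[sample(n), ]
  adj <- t0_adjust(trended)
  adj_shuf <- t0_adjust(shuffled)
  expect_equal(adj_shuf$t0_adjusted[match(adj$guide_id, adj_shuf$guide_id)],
               adj$t0_adjusted, tolerance = 1e-12)

  bad <- dplyr::mutate(flat, t0_cpm = 0)
  expect_error(t0_adjust(bad), "positive")
})

test_that("moderation parameters are recovered from simulated variances and
           agree with an established empirical-Bayes fit", {
  set.seed(11)
  d0 <- 4; s0_sq <- 0.04; d <- 4; n <- 5000
  sigma2 <- s0_sq * d0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, d) / d
  est <- estimate_moderation(s2, d)
  expect_lt(abs(est$d0 - d0) / d0, 0.2)
  expect_lt(abs(est$s0_sq - s0_sq) / s0_sq, 0.1)

  skip_if_not_installed("limma")
  fd <- limma::fitFDist(s2, df1 = d)
  expect_equal(est$d0, fd$df2, tolerance = 1e-6)
  expect_equal(est$s0_sq, fd$scale, tolerance = 1e-6)
})

test_that("identical variances give an infinite prior and common posterior", {
  est <- estimate_moderation(rep(0.3, 50), 3)
  expect_identical(est$d0, Inf)
  expect_equal(est$s0_sq, 0.3)

  obs <- tibble::tibble(gene = rep(sprintf("G%02d", 1:20), each = 4),
                        value = rnorm(80))
  res <- moderated_ttest(obs, params = list(d0 = Inf, s0_sq = 0.3))
  expect_equal(res$t, res$mean / sqrt(0.3 / res$n_obs))
  expect_equal(res$pval, 2 * pnorm(-abs(res$t)))
})

test_that("moderated t with d0 = 0 is the ordinary one-sample t-test", {
  set.seed(3)
  obs <- tibble::tibble(gene = rep(sprintf("G%02d", 1:15), each = 5),
                        value = rnorm(75))
  res <- moderated_ttest(obs, params = list(d0 = 0, s0_sq = 1))
  for (g in c("G01", "G08", "G15")) {
    tt <- t.test(obs$value[obs$gene == g])
    expect_equal(res$t[res$gene == g], unname(tt$statistic),
                 tolerance = 1e-12)
    expect_equal(res$pval[res$gene == g], tt$p.value, tolerance = 1e-12)
  }
})

test_that("moderated t matches an independently coded posterior-variance
           formula on a 200-gene instance", {
  set.seed(8)
  n_genes <- 200
  obs <- tibble::tibble(gene = rep(sprintf("G%03d", 1:n_genes), each = 4),
                        value = rnorm(4 * n_genes, 0, 0.4))
  res <- moderated_ttest(obs)
  par <- attr(res, "params")
  oracle <- lapply(split(obs$value, obs$gene), function(v) {
    n <- length(v); s2 <- var(v)
    post <- (par$d0 * par$s0_sq + (n - 1) * s2) / (par$d0 + n - 1)
    t <- mean(v) / sqrt(post / n)
    c(t = t, p = 2 * pt(-abs(t), par$d0 + n - 1))
  })
  om <- do.call(rbind, oracle)
  expect_equal(res$t, unname(om[res$gene, "t"]), tolerance = 1e-10)
  expect_equal(res$pval, unname(om[res$gene, "p"]), tolerance = 1e-10)

  # a gene of exact zeros is a zero statistic, not NaN
  zeros <- dplyr::bind_rows(obs, tibble::tibble(gene = "Z", value = rep(0, 4)))
  rz <- moderated_ttest(zeros)
  expect_equal(rz$t[rz$gene == "Z"], 0)
  expect_equal(rz$pval[rz$gene == "Z"], 1)
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(17)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("gene-level qGI table applies the guide-count and call rules", {
  resid <- tibble::tibble(
    screen_id = "KO_1",
    gene = c("A", "A", "B", "C", "C"),
    guide_id = c("A_g1", "A_g2", "B_g1", "C_g1", "C_g2"),
    t0_adjusted = c(-0.4, -0.6, 1.0, 0.30, 0.32)
  )
  tests <- tibble::tibble(gene = c("A", "B", "C"),
                          pval = c(0.001, 0.2, 0.3),
                          fdr = c(0.05, 0.5, 0.5))
  out <- gene_qgi(resid, tests)
  expect_false("B" %in% out$gene)  # single remaining guide
  expect_equal(out$call[out$gene == "A"], "negative")  # qgi -0.5, fdr 0.05
  expect_equal(out$qgi[out$gene == "C"], 0.31)
  expect_equal(out$call[out$gene == "C"], "none")  # fails the FDR condition

  expect_error(gene_qgi(resid, tests[tests$gene != "A", ]), "no test result")
})

test_that("call overlaps intersect by sign", {
  a <- tibble::tibble(gene = c("A", "B", "C", "D"),
                      call = c("negative", "negative", "positive", "none"))
  b <- tibble::tibble(gene = c("A", "B", "C", "D"),
                      call = c("negative", "positive", "positive", "none"))
  ov <- overlap_calls(a, b)
  expect_equal(ov$n_shared[ov$call == "negative"], 1)
  expect_equal(ov$n_shared[ov$call == "positive"], 1)

  ov_same <- overlap_calls(a, a)
  expect_equal(ov_same$n_shared, c(2, 1))
  disjoint <- dplyr::mutate(b, gene = paste0("X", gene))
  expect_equal(overlap_calls(a, disjoint)$n_shared, c(0, 0))
})

test_that("qgi_result exposes tidy, glance and a volcano autoplot", {
  sim <- simulate_screen(screen_sim_config(n_genes = 50, n_wt_screens = 2,
                                           n_replicates = 2, seed = 12))
  wt <- lapply(wt_screen_ids(sim$counts), function(s)
    screen_lfc(sim$counts, s))
  fit <- score_qgi(screen_lfc(sim$counts, "KO_1"), build_control_panel(wt))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
  expect_s3_class(autoplot(fit), "ggplot")
})
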