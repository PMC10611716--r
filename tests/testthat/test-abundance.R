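make_raw <- function(n = 20, groups = c(WT = 3, KO = 3), seed = 1,
                     missing = 0) {
  set.seed(seed)
  sample_group <- rep(names(groups), groups)
  ids <- paste0(sample_group, "_", unlist(lapply(groups, seq_len)))
  m <- matrix(2^rnorm(n * length(ids), 24, 1), n,
              dimnames = list(sprintf("p%02d", 1:n), ids))
  if (missing > 0) m[sample(length(m), missing)] <- NA
  list(raw = m, groups = setNames(sample_group, ids))
}

test_that("log2 + median normalization zeroes each sample's median", {
  d <- make_raw(seed = 2)
  m <- log2_and_median_normalize(d$raw, d$groups)
  meds <- apply(m$values, 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(0, ncol(m$values)))

  plain <- log2_and_median_normalize(d$raw, d$groups, normalize = FALSE)
  expect_equal(plain$values, log2(d$raw))

  bad <- d$raw; bad[1, 1] <- -2
  expect_error(log2_and_median_normalize(bad, d$groups), "positive")
  empty_col <- d$raw; empty_col[, 1] <- NA
  expect_error(log2_and_median_normalize(empty_col, d$groups),
               "no present values")
})

test_that("valid-value filter keeps proteins quantified in >= min_valid
           samples of at least one group", {
  d <- make_raw(n = 3, groups = c(A = 3, B = 3), seed = 3)
  v <- log2(d$raw)
  v[1, 4:6] <- NA        # 3 valid in A, 0 in B -> kept
  v[2, c(1, 4)] <- NA    # 2 valid in each group -> removed
  m <- abundance_matrix(v, d$groups)
  kept <- filter_valid_values(m, min_valid = 3)
  expect_setequal(rownames(kept$values), c("p01", "p03"))
  expect_equal(nrow(filter_valid_values(m, min_valid = 0)$values), 3)
})

test_that("downshifted-normal imputation is seeded, leaves present values
           alone, and centres at mu - 1.8 sigma", {
  d <- make_raw(n = 40, seed = 4, missing = 25)
  m <- log2_and_median_normalize(d$raw, d$groups, normalize = FALSE)
  i1 <- impute_lod(m, seed = 42)
  i2 <- impute_lod(m, seed = 42)
  expect_identical(i1$values, i2$values)
  present <- !is.na(m$values)
  expect_equal(i1$values[present], m$values[present])
  expect_false(anyNA(i1$values))

  complete <- log2_and_median_normalize(make_raw(seed = 5)$raw,
                                        make_raw(seed = 5)$groups)
  expect_equal(impute_lod(complete, seed = 1)$values, complete$values)

  # law of large numbers on one column with many missing entries
  set.seed(6)
  big <- matrix(rnorm(11000, 20, 1), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  rownames(big) <- sprintf("p%05d", 1:5500)
  big[1:5000, 1] <- NA
  mm <- abundance_matrix(big, c(a = "A", b = "B"))
  mu <- mean(big[, 1], na.rm = TRUE); sg <- sd(big[, 1], na.rm = TRUE)
  imp <- impute_lod(mm, seed = 9)
  drawn <- imp$values[1:5000, 1]
  expect_equal(mean(drawn), mu - 1.8 * sg, tolerance = 0.05)
  expect_equal(sd(drawn), 0.3 * sg, tolerance = 0.05)
})

test_that("S0 statistic reduces to the pooled t at S0 = 0 and shrinks to 0
           for large S0", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(s0_statistic(a, b, s0 = 0), -3 / sqrt(2 / 3),
               tolerance = 1e-12)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(s0_statistic(a, b, s0 = 0), unname(tt$statistic),
               tolerance = 1e-10)
  wt <- t.test(a, b)
  expect_equal(s0_statistic(a, b, s0 = 0, var_equal = FALSE),
               unname(wt$statistic), tolerance = 1e-10)
  expect_lt(abs(s0_statistic(a, b, s0 = 1e6)), 1e-5)
  expect_error(s0_statistic(1, b), ">= 2 values")
})

test_that("S0 = 0 ANOVA is the classical one-way F; two groups give t^2", {
  d <- make_raw(n = 30, groups = c(A = 3, B = 4, C = 3), seed = 7)
  m <- log2_and_median_normalize(d$raw, d$groups)
  fit <- anova_s0(m, s0 = 0)
  res <- tidy(fit)
  for (i in c(1, 15, 30)) {
    v <- m$values[i, ]
    ow <- oneway.test(v ~ factor(d$groups), var.equal = TRUE)
    expect_equal(res$statistic[i], unname(ow$statistic), tolerance = 1e-10)
    expect_equal(res$pval[i], ow$p.value, tolerance = 1e-10)
  }

  d2 <- make_raw(n = 10, groups = c(A = 4, B = 4), seed = 8)
  m2 <- log2_and_median_normalize(d2$raw, d2$groups)
  pair <- tidy(anova_s0(m2, s0 = 0))
  f_form <- tidy(permutation_fdr(m2, s0 = 0, n_perm = 10, seed = 1,
                                 statistic = "anova"))
  expect_equal(f_form$statistic, pair$statistic^2, tolerance = 1e-10)
  for (i in c(1, 10)) {
    tt <- t.test(m2$values[i, 1:4], m2$values[i, 5:8], var.equal = TRUE)
    expect_equal(pair$statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(pair$pval[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("permutation FDR calls almost nothing on null data and recovers a
           planted strong effect", {
  called_frac <- vapply(1:5, function(s) {
    sim <- simulate_lfq(n_proteins = 200, effect_frac = 0, lod = -Inf,
                        seed = 200 + s)
    fit <- diff_abundance(sim$raw, sim$groups, s0 = 0.1,
                          fdr_mode = "permutation", n_perm = 100,
                          seed = 200 + s)
    mean(tidy(fit)$significant)
  }, numeric(1))
  expect_lte(mean(called_frac), 0.01)

  sim <- simulate_lfq(n_proteins = 500, effect_frac = 0, lod = -Inf,
                      seed = 77)
  raw <- sim$raw
  raw["prot0001", sim$groups == "KO"] <-
    raw["prot0001", sim$groups == "KO"] * 2^(10 * 0.3)
  fit <- diff_abundance(raw, sim$groups, s0 = 0.1,
                        fdr_mode = "permutation", n_perm = 100, seed = 77)
  res <- tidy(fit)
  expect_true(res$significant[res$protein == "prot0001"])

  fit2 <- diff_abundance(raw, sim$groups, s0 = 0.1,
                         fdr_mode = "permutation", n_perm = 200, seed = 77)
  expect_equal(tidy(fit2)$significant, res$significant)
  expect_error(permutation_fdr(log2_and_median_normalize(raw, sim$groups),
                               n_perm = 5), "n_perm")
})

test_that("filtering then imputing never changes present values", {
  sim <- simulate_lfq(n_proteins = 120, seed = 31)
  m <- log2_and_median_normalize(sim$raw, sim$groups)
  filtered <- filter_valid_values(m)
  imputed <- impute_lod(filtered, seed = 31)
  present <- !is.na(filtered$values)
  expect_equal(imputed$values[present], filtered$values[present])
})

test_that("abundance_test objects support tidy, glance and autoplot", {
  sim <- simulate_lfq(n_proteins = 60, seed = 2)
  fit <- diff_abundance(sim$raw, sim$groups, seed = 2)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n_proteins, nrow(tidy(fit)))
  expect_s3_class(autoplot(fit), "ggplot")
  long <- tidy(log2_and_median_normalize(sim$raw, sim$groups))
  expect_true(all(c("protein", "sample", "group", "value") %in% names(long)))
})
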