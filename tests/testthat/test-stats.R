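test_that("identical group means give adjusted p of 1", {
  g <- data.frame(group = c("a", "b", "c"), mean = 5, sd = c(1, 2, 1.5),
                  n = c(8, 8, 11))
  tk <- tukey_from_summary(g)
  expect_equal(tk$pairs$p_adjusted, rep(1, 3))
  expect_equal(tk$pairs$q_statistic, rep(0, 3))
})

test_that("summary-based Tukey matches q = |diff| / SE and the df bookkeeping", {
  g <- data.frame(group = c("a", "b"), mean = c(1, 3), sd = c(1, 2), n = c(5, 7))
  tk <- tukey_from_summary(g)
  expect_identical(tk$df_error, 10L + 0L + 0L)
  expect_equal(tk$mse, (4 * 1 + 6 * 4) / 10)
  expect_equal(tk$pairs$q_statistic,
               abs(tk$pairs$mean_difference) / tk$pairs$standard_error,
               tolerance = 1e-12)
  expect_error(tukey_from_summary(g[1, , drop = FALSE]), "2 groups")
  expect_error(tukey_from_summary(transform(g, n = c(1, 7))), "n >= 2")
})

test_that("raw-data ANOVA agrees with the summary path and with base R", {
  set.seed(51)
  for (i in 1:20) {
    ns <- sample(4:12, 3, replace = TRUE)
    vals <- list(a = rnorm(ns[1], 0), b = rnorm(ns[2], 0.5), c = rnorm(ns[3], 1))
    res <- anova_tukey(vals)
    summ <- data.frame(group = names(vals),
                       mean = vapply(vals, mean, numeric(1)),
                       sd = vapply(vals, sd, numeric(1)),
                       n = ns)
    expect_equal(res$tukey$pairs$p_adjusted,
                 tukey_from_summary(summ)$pairs$p_adjusted, tolerance = 1e-12)

    # independent oracle: base aov + TukeyHSD
    df <- data.frame(y = unlist(vals),
                     g = factor(rep(names(vals), ns)))
    fit <- stats::aov(y ~ g, data = df)
    hsd <- stats::TukeyHSD(fit)$g
    expect_equal(sort(res$tukey$pairs$p_adjusted), sort(unname(hsd[, "p adj"])),
                 tolerance = 1e-6)
    expect_equal(res$p_omnibus, summary(fit)[[1]][["Pr(>F)"]][1],
                 tolerance = 1e-9)
  }
})

test_that("Tukey p is monotone in the mean difference and in df", {
  base <- data.frame(group = c("a", "b", "c"), mean = c(0, 0, 0), sd = 1,
                     n = c(8, 8, 11))
  p_at <- function(d) {
    g <- base; g$mean[3] <- d
    tukey_from_summary(g)$pairs$p_adjusted[2]  # a vs c
  }
  ps <- vapply(c(0.5, 1, 1.5, 2), p_at, numeric(1))
  expect_true(all(diff(ps) < 0))
  # fixed q and k: p decreases as df grows
  expect_gt(stats::ptukey(4, 3, 10, lower.tail = FALSE),
            stats::ptukey(4, 3, 40, lower.tail = FALSE))
})

test_that("degenerate zero-variance input takes the warned p -> 0 path", {
  w <- capture_warnings(res <- anova_tukey(list(a = c(0, 0, 0), b = c(1, 1, 1))))
  expect_true(any(grepl("zero", w)))
  expect_equal(res$p_omnibus, 0)
  expect_equal(res$tukey$pairs$p_adjusted, 0)
})

test_that("pairwise Tukey p is super-uniform under the null", {
  set.seed(53)
  hits <- 0L
  for (i in 1:2000) {
    res <- tukey_from_summary(data.frame(
      group = c("a", "b", "c"),
      mean = c(mean(rnorm(8)), mean(rnorm(8)), mean(rnorm(11))),
      sd = c(sd(rnorm(8)), sd(rnorm(8)), sd(rnorm(11))),
      n = c(8, 8, 11)))
    hits <- hits + (res$pairs$p_adjusted[2] <= 0.05)
  }
  expect_lte(hits / 2000, 0.05 + 0.01)
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(3, 10)), "constant")
  expect_error(pearson_r(x, 1:9), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("sample correlation concentrates on the generating rho", {
  # 2000 cohorts of n = 27 with true correlation 0.53
  set.seed(54)
  n <- 27; rho <- 0.53; reps <- 2000
  x <- matrix(rnorm(n * reps), n)
  y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(n * reps), n)
  cx <- sweep(x, 2, colMeans(x)); cy <- sweep(y, 2, colMeans(y))
  r <- colSums(cx * cy) / sqrt(colSums(cx^2) * colSums(cy^2))
  expect_lt(abs(mean(r) - rho), 0.03)
  # spot-check the vectorized r against pearson_r
  expect_equal(r[1], pearson_r(x[, 1], y[, 1])$r, tolerance = 1e-12)
})

test_that("ddCt fold changes follow 2^-ddCt with the 40-cycle rule", {
  mk_ct <- function(hdc_t, pcs_t, ref = 20) {
    rows <- list()
    for (g in c("HDC", "PCS")) for (s in 1:2) for (gene in c("GAPDH", "NID1"))
      for (rep_i in 1:3) {
        ct <- if (gene == "GAPDH") ref else if (g == "HDC") hdc_t else pcs_t
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = paste0(g, s), group = g, gene = gene,
          replicate = rep_i, ct = ct)
      }
    do.call(rbind, rows)
  }
  # ddCt = 0 -> fold 1
  expect_equal(ddct_fold_change(mk_ct(25, 25), "PCS", "HDC")$fold_change, 1)
  # ddCt = 1 -> fold 0.5
  expect_equal(ddct_fold_change(mk_ct(25, 26), "PCS", "HDC")$fold_change, 0.5)

  # a 41-cycle replicate is dropped before averaging
  tab <- mk_ct(25, 25)
  i <- which(tab$gene == "NID1" & tab$sample_id == "PCS1")
  tab$ct[i] <- c(39, 41, 38)
  res <- ddct_fold_change(tab, "PCS", "HDC")
  agg <- stats::aggregate(ct ~ sample_id, data = tab[tab$gene == "NID1" & tab$ct <= 40, ], FUN = mean)
  expect_equal(agg$ct[agg$sample_id == "PCS1"], 38.5)
  expect_equal(res$delta_delta_ct, mean(c(38.5, 25)) - 25)

  # reference gene never expressed -> error
  bad <- mk_ct(25, 25, ref = 41)
  expect_error(ddct_fold_change(bad, "PCS", "HDC"), "not expressed")

  # target all above cutoff -> flagged, not an error
  tab2 <- mk_ct(41, 41)
  res2 <- ddct_fold_change(tab2, "PCS", "HDC")
  expect_false(res2$expressed)
  expect_true(is.na(res2$fold_change))
})
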