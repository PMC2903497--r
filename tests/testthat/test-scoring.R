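test_that("score stages are capped and total is their sum", {
  expect_equal(fibrosis_score(0, 0)$total, 0L)
  expect_equal(fibrosis_score(4, 2)$total, 6L)      # the scheme's maximum
  expect_equal(fibrosis_score(2, 1)$total, 3L)
  expect_error(fibrosis_score(5, 0), class = "fibromat_bad_score")
  expect_error(fibrosis_score(0, 3), class = "fibromat_bad_score")
  expect_error(fibrosis_score(-1, 0), class = "fibromat_bad_score")
  expect_error(fibrosis_score(1.5, 0), class = "fibromat_bad_score")
  for (p in 0:4) for (s in 0:2)
    expect_equal(fibrosis_score(p, s)$total, p + s)
})

test_that("per-animal integer stages reproduce the published group rows", {
  # day 14: portal stages {2,2,2,3,3}, perisinusoidal all 1
  portal <- c(2, 2, 2, 3, 3); peri <- rep(1, 5)
  totals <- mapply(function(p, s) fibrosis_score(p, s)$total, portal, peri)
  g <- group_summary(totals, "day14")
  expect_equal(g$mean, 3.40)
  expect_equal(round(g$sem, 2), 0.24)
  expect_equal(round(group_summary(portal)$mean, 2), 2.4)
  expect_equal(round(group_summary(portal)$sem, 2), 0.24)
  # day 20: portal all 3, perisinusoidal all 1
  totals20 <- mapply(function(p, s) fibrosis_score(p, s)$total,
                     rep(3, 4), rep(1, 4))
  g20 <- group_summary(totals20, "day20")
  expect_equal(g20$mean, 4.0)
  expect_equal(g20$sem, 0)
})

test_that("sample aggregation averages field indices", {
  expect_equal(suppressWarnings(aggregate_sample(rep(0.05, 10)))$sample_index,
               0.05)
  expect_warning(aggregate_sample(c(0.04, 0.06)),
                 class = "fibromat_field_count")
  s <- suppressWarnings(aggregate_sample(c(0.04, 0.06)))
  expect_equal(s$sample_index, 0.05)
  # permutation invariance
  set.seed(31)
  v <- runif(10)
  expect_equal(aggregate_sample(v)$sample_index,
               aggregate_sample(sample(v))$sample_index)
  expect_error(aggregate_sample(numeric()), class = "fibromat_bad_score")
})

test_that("group summary computes mean and SEM", {
  g <- group_summary(c(3, 3, 3))
  expect_equal(g$mean, 3); expect_equal(g$sem, 0)
  g2 <- group_summary(c(1, 2, 3))
  expect_equal(g2$mean, 2)
  expect_equal(g2$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_warning(g1 <- group_summary(5), class = "fibromat_sem_n1")
  expect_equal(g1$sem, 0)
  expect_error(group_summary(numeric()), class = "fibromat_bad_score")
  # homogeneity: scaling values scales mean and SEM
  set.seed(32)
  v <- rnorm(8)
  a <- group_summary(v); b <- group_summary(3.5 * v)
  expect_equal(b$mean, 3.5 * a$mean)
  expect_equal(b$sem, 3.5 * a$sem)
})

test_that("linear fit matches closed-form least squares", {
  f <- linear_fit(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  g <- linear_fit(c(0, 1, 2, 3), c(0, 1, 1, 2))
  expect_equal(g$slope, 0.6)
  expect_equal(g$intercept, 0.1, tolerance = 1e-12)
  expect_equal(g$r_squared, 0.9)
  expect_equal(g$n, 4L)

  expect_warning(h <- linear_fit(1:4, rep(2, 4)),
                 class = "fibromat_constant_y")
  expect_equal(h$r_squared, 0)
  expect_error(linear_fit(rep(1, 4), 1:4), class = "fibromat_bad_score")
  expect_error(linear_fit(1, 1), class = "fibromat_bad_score")

  # permutation invariance and R^2 == squared Pearson correlation
  set.seed(33)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20, 0, 0.3)
  p <- sample(20)
  f1 <- linear_fit(x, y); f2 <- linear_fit(x[p], y[p])
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$r_squared, f2$r_squared)
  expect_equal(f1$r_squared, cor(x, y)^2, tolerance = 1e-12)
})

test_that("score-index correlation is computed per score dimension", {
  mk <- function(p, s, idx) suppressWarnings(
    aggregate_sample(idx, sample_id = paste0("a", p, s),
                     score = fibrosis_score(p, s)))
  # index exactly affine in total score -> R^2 = 1 on the total dimension
  samples <- list(mk(0, 0, 0.001), mk(1, 0, 0.011), mk(2, 1, 0.031),
                  mk(3, 1, 0.041), mk(3, 2, 0.051))
  fits <- correlate_scores_with_index(samples)
  expect_equal(fits$total$r_squared, 1)
  expect_equal(fits$total$n, 5L)
  expect_named(fits, c("total", "periportal", "perisinusoidal"))

  # samples without scores are dropped with a warning; <2 left is an error
  unscored <- suppressWarnings(aggregate_sample(0.02, sample_id = "x"))
  expect_warning(correlate_scores_with_index(c(samples, list(unscored))),
                 class = "fibromat_missing_score")
  expect_error(
    suppressWarnings(correlate_scores_with_index(list(samples[[1]], unscored))),
    class = "fibromat_bad_score")

  # noise-free cohort affine in every dimension: all three at R^2 = 1
  affine <- lapply(0:2, function(k) mk(2 * k, k, 0.002 + 0.01 * k))
  fits2 <- correlate_scores_with_index(affine)
  expect_equal(fits2$total$r_squared, 1)
  expect_equal(fits2$periportal$r_squared, 1)
  expect_equal(fits2$perisinusoidal$r_squared, 1)
})

test_that("group report formats Table-style rows", {
  df <- data.frame(group = rep(c("d0", "d14"), c(3, 5)),
                   index = c(rep(0.0013, 3), rep(0.0475, 5)),
                   periportal = c(rep(0, 3), c(2, 2, 2, 3, 3)),
                   perisinusoidal = c(rep(0, 3), rep(1, 5)),
                   total = c(rep(0, 3), c(3, 3, 3, 4, 4)))
  rep_ <- group_report(df)
  expect_equal(rep_$n, c(3L, 5L))
  expect_equal(rep_$fibrosis_index_pct[1], "0.13 ± 0.00")
  expect_equal(rep_$total[2], "3.40 ± 0.24")
  expect_equal(rep_$periportal[2], "2.40 ± 0.24")
})

test_that("score files round-trip through CSV and TSV", {
  td <- withr_local_tempdir()
  df <- data.frame(sample_id = c("a", "b"), periportal = c(1L, 3L),
                   perisinusoidal = c(0L, 2L))
  csv <- file.path(td, "s.csv"); tsv <- file.path(td, "s.tsv")
  write.csv(df, csv, row.names = FALSE)
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  for (p in c(csv, tsv)) {
    sc <- read_scores(p)
    expect_equal(sc$total, c(1L, 5L))
  }
  bad <- file.path(td, "bad.csv")
  write.csv(data.frame(sample_id = "a", periportal = 9, perisinusoidal = 0),
            bad, row.names = FALSE)
  expect_error(read_scores(bad), class = "fibromat_bad_score")
})
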