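# dense-grid brute-force maximizer used as the independent oracle
grid_mle <- function(counts_row, mu_row, cox_reid = FALSE, groups = NULL,
                     range = c(1e-8, 10), n_grid = 40001) {
  la <- seq(log(range[1]), log(range[2]), length.out = n_grid)
  ll <- vapply(la, function(l) {
    alpha <- exp(l)
    v <- sum(stats::dnbinom(counts_row, size = 1 / alpha, mu = mu_row,
                            log = TRUE))
    if (cox_reid) {
      w <- mu_row / (1 + alpha * mu_row)
      for (g in groups) v <- v - 0.5 * log(sum(w[g]))
    }
    v
  }, 0)
  exp(la[which.max(ll)])
}

test_that("dispersion MLE matches dense-grid maximization on toys", {
  # single-group 2-observation toy: plain likelihood, group mean fixed at 20
  cm <- matrix(c(10L, 30L), nrow = 1, dimnames = list("g1", c("X_rep1", "X_rep2")))
  est <- estimate_dispersion_mle(cm, cox_reid = FALSE)
  oracle <- grid_mle(c(10, 30), c(20, 20))
  expect_equal(est$mle_alpha, oracle, tolerance = 1e-3)

  # two-group toy, Cox-Reid adjusted (the default)
  cm2 <- matrix(c(10L, 30L, 45L, 80L), nrow = 1,
                dimnames = list("g1", c("A_rep1", "A_rep2", "B_rep1", "B_rep2")))
  est2 <- estimate_dispersion_mle(cm2)
  mu_row <- c(20, 20, 62.5, 62.5)
  oracle2 <- grid_mle(c(10, 30, 45, 80), mu_row, cox_reid = TRUE,
                      groups = list(1:2, 3:4))
  expect_equal(est2$mle_alpha, oracle2, tolerance = 1e-3)

  # multi-gene toy: every row must match its own grid oracle
  cm3 <- matrix(c(5L, 9L, 3L, 7L,
                  120L, 80L, 95L, 140L,
                  1000L, 1100L, 900L, 1050L), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:3),
                                c("A_rep1", "A_rep2", "B_rep1", "B_rep2")))
  est3 <- estimate_dispersion_mle(cm3, cox_reid = FALSE)
  for (i in 1:3) {
    mu_row <- rep(c(mean(cm3[i, 1:2]), mean(cm3[i, 3:4])), each = 2)
    expect_equal(est3$mle_alpha[i], grid_mle(cm3[i, ], mu_row),
                 tolerance = 1e-3)
  }
})

test_that("identical replicates collapse to the lower search bound", {
  cm <- matrix(c(50L, 50L, 75L, 75L), nrow = 1,
               dimnames = list("g1", c("A_rep1", "A_rep2", "B_rep1", "B_rep2")))
  est <- estimate_dispersion_mle(cm, cox_reid = FALSE)
  expect_true(est$at_lower)
  # all-zero genes are unfit
  cm0 <- rbind(cm, g2 = c(0L, 0L, 0L, 0L))
  est0 <- estimate_dispersion_mle(cm0, cox_reid = FALSE)
  expect_false(est0$fitted[2])
  expect_true(is.na(est0$mle_alpha[2]))
  # < 2 replicates in a condition errors
  cm1 <- matrix(c(1L, 2L, 3L), nrow = 1,
                dimnames = list("g", c("A_rep1", "A_rep2", "B_rep1")))
  expect_error(estimate_dispersion_mle(cm1), "2 replicates")
})

test_that("known dispersion is recovered from 50 replicates", {
  set.seed(77)
  n_genes <- 300
  mu <- exp(stats::rnorm(n_genes, 5, 1))
  counts <- matrix(stats::rnbinom(n_genes * 50, size = 1 / 0.1,
                                  mu = rep(mu, 50)),
                   nrow = n_genes,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   c(paste0("A_rep", 1:25),
                                     paste0("B_rep", 1:25))))
  est <- estimate_dispersion_mle(counts)
  expect_lt(abs(stats::median(est$mle_alpha, na.rm = TRUE) - 0.1) / 0.1,
            0.20)
})

test_that("trend fitting recovers exact and simulated hyperparameters", {
  # noiseless: alpha_i = 0.03 + 3.5/mu_i exactly
  x <- exp(seq(log(5), log(5000), length.out = 200))
  y <- 0.03 + 3.5 / x
  fit <- fit_dispersion_trend(x, y)
  expect_equal(fit$a_hat, 0.03, tolerance = 1e-3)
  expect_equal(fit$b_hat, 3.5, tolerance = 1e-3)

  # simulation recovery at (a=.01, b=1), moderate scale
  st <- small_study(seed = 19, n_genes = 4000, replicates = 10)
  sf <- estimate_size_factors(st$ds$counts)
  mle <- estimate_dispersion_mle(st$ds$counts, st$ds$condition,
                                 size_factors = sf)
  usable <- mle$fitted & !mle$at_lower & !mle$at_upper & mle$base_mean > 0
  tr <- fit_dispersion_trend(mle$base_mean, mle$mle_alpha, usable = usable)
  expect_lt(abs(tr$a_hat - 0.01) / 0.01, 0.20)
  expect_lt(abs(tr$b_hat - 1) / 1, 0.20)

  expect_error(fit_dispersion_trend(x[1:10], y[1:10]), "usable genes")
})

test_that("removing a high-dispersion trisomic block lowers both trend parameters", {
  # mixed dataset: disomic backbone on one trend, chr21 block on a higher one
  x_dis <- exp(seq(log(10), log(3000), length.out = 500))
  x_tri <- exp(seq(log(10), log(3000), length.out = 60))
  y <- c(0.01 + 1 / x_dis, 0.05 + 30 / x_tri)
  x <- c(x_dis, x_tri)
  with_tri <- fit_dispersion_trend(x, y)
  without <- fit_dispersion_trend(x_dis, 0.01 + 1 / x_dis)
  expect_gt(with_tri$a_hat, without$a_hat)
  expect_gt(with_tri$b_hat, without$b_hat)
})

test_that("shrinkage contracts dispersions toward the trend", {
  st <- small_study(seed = 23, n_genes = 1500, replicates = 4)
  sf <- estimate_size_factors(st$ds$counts)
  fit <- estimate_dispersions(st$ds$counts, st$ds$condition,
                              size_factors = sf)
  ok <- is.finite(fit$mle_alpha) & is.finite(fit$map_alpha) &
    fit$mle_alpha > 1e-7
  # contraction on average
  expect_lte(mean(abs(log(fit$map_alpha[ok]) - log(fit$trend_alpha[ok]))),
             mean(abs(log(fit$mle_alpha[ok]) - log(fit$trend_alpha[ok]))))
  # genes with MLE below trend move up, never past the trend
  below <- ok & !fit$outlier_flag & fit$mle_alpha < fit$trend_alpha
  expect_true(all(fit$map_alpha[below] >= fit$mle_alpha[below] - 1e-8))
  expect_true(all(fit$map_alpha[below] <= fit$trend_alpha[below] * 1.01))
  # genes whose MLE sits on the trend stay there
  on_trend <- ok & abs(log(fit$mle_alpha) - log(fit$trend_alpha)) < 0.02
  expect_true(any(on_trend))
  expect_true(all(abs(log(fit$map_alpha[on_trend]) -
                        log(fit$trend_alpha[on_trend])) < 0.05))
  expect_gt(attr(fit, "prior_log_variance"), 0)
})

test_that("dispersion outliers keep their MLE", {
  st <- small_study(seed = 29, n_genes = 800, replicates = 4)
  counts <- st$ds$counts
  # inject an extreme-dispersion gene: alternate tiny and huge counts
  hot <- rep(c(2L, 900L), length.out = ncol(counts))
  counts["gene00001", ] <- hot
  sf <- estimate_size_factors(counts)
  fit <- estimate_dispersions(counts, st$ds$condition, size_factors = sf)
  row <- fit[fit$gene_id == "gene00001", ]
  expect_true(row$outlier_flag)
  expect_equal(row$final_alpha, row$mle_alpha)
})

test_that("per-gene dispersions track the reference implementation", {
  st <- small_study(seed = 31, n_genes = 1000, replicates = 3,
                    a = 0.03, b = 3.5)
  counts <- st$ds$counts
  keep <- rowSums(counts) > 0 & rowMeans(counts) >= 5
  counts <- counts[keep, ]
  fit <- estimate_dispersions(counts, st$ds$condition,
                              size_factors = estimate_size_factors(counts))
  coldata <- data.frame(condition = factor(st$ds$condition))
  dds <- DESeq2::DESeqDataSetFromMatrix(counts, coldata, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::dispersions(dds)
  ok <- is.finite(fit$final_alpha) & is.finite(ref) & fit$final_alpha > 1e-6
  expect_gt(stats::cor(log(fit$final_alpha[ok]), log(ref[ok])), 0.9)
  expect_lt(abs(stats::median(log(fit$final_alpha[ok] / ref[ok]))), 0.15)
})
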