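test_that("MLE fold change recovers the group-mean ratio at scale", {
  set.seed(101)
  n <- 500
  counts <- matrix(c(stats::rnbinom(n, size = 1 / 0.005, mu = 100),
                     stats::rnbinom(n, size = 1 / 0.005, mu = 150)),
                   nrow = 1, byrow = FALSE)
  # interleave: first n columns condition A, rest B
  counts <- matrix(as.integer(counts), nrow = 1,
                   dimnames = list("g1", c(paste0("A_rep", 1:n),
                                           paste0("B_rep", 1:n))))
  fit <- fit_lfc_mle(counts, alphas = 0.005)
  expect_equal(fit$lfc_mle, log2(1.5), tolerance = 0.03)
  expect_equal(attr(fit, "reference"), "A")
  # identical groups give exactly zero
  cm <- matrix(c(40L, 60L, 40L, 60L), nrow = 1,
               dimnames = list("g", c("A_rep1", "A_rep2", "B_rep1", "B_rep2")))
  fit0 <- fit_lfc_mle(cm, alphas = 0.1)
  expect_equal(fit0$lfc_mle, 0, tolerance = 1e-6)
})

test_that("the MLE equals the normalized group-mean ratio with unit scaling", {
  # with all scaling factors 1 the NB MLE of a group mean is the sample
  # mean, so lfc must equal log2 of the ratio of group means
  st <- small_study(seed = 41, n_genes = 300)
  counts <- st$ds$counts[rowSums(st$ds$counts) > 0, ]
  alphas <- rep(0.05, nrow(counts))
  fit <- fit_lfc_mle(counts, st$ds$condition, alphas = alphas)
  ga <- rowMeans(counts[, st$ds$condition == "D21"])
  gb <- rowMeans(counts[, st$ds$condition == "T21"])
  both <- ga > 0 & gb > 0
  expect_equal(fit$lfc_mle[both], unname(log2(gb / ga)[both]),
               tolerance = 1e-4)
})

test_that("standard errors shrink with replication", {
  ses <- vapply(c(4, 16, 64), function(m) {
    x <- draws_for(100, 0.02, 1, m, seed = 55)
    cm <- matrix(as.integer(rep(x, 2)), nrow = 1,
                 dimnames = list("g", c(paste0("A_rep", 1:m),
                                        paste0("B_rep", 1:m))))
    fit_lfc_mle(cm, alphas = 0.03)$se
  }, 0)
  expect_true(all(diff(ses) < 0))
})

test_that("an all-zero group yields a bounded, flagged estimate", {
  cm <- matrix(c(0L, 0L, 0L, 30L, 35L, 25L), nrow = 1,
               dimnames = list("g", c(paste0("A_rep", 1:3),
                                      paste0("B_rep", 1:3))))
  fit <- fit_lfc_mle(cm, alphas = 0.1)
  expect_true(fit$bounded)
  expect_true(is.finite(fit$lfc_mle))
  expect_gt(fit$lfc_mle, 0)
})

test_that("MAP shrinkage properties: center, flat limit, contraction", {
  lfc <- c(0, 1.2, -0.8, 0.3, 2.5)
  se <- c(0.2, 0.5, 1.5, 0.05, 0.9)
  sh <- shrink_lfc_map(lfc, se, prior_sd = 0.5)
  expect_equal(sh$lfc_map[1], 0)
  expect_true(all(abs(sh$lfc_map) <= abs(lfc)))
  expect_true(all(sign(sh$lfc_map) == sign(lfc) | lfc == 0))
  # flat-prior limit returns the MLE
  flat <- shrink_lfc_map(lfc, se, prior_sd = 1e6)
  expect_equal(flat$lfc_map, lfc, tolerance = 1e-6)
  # more uncertain estimates shrink harder
  sh2 <- shrink_lfc_map(c(1, 1), c(0.1, 1), prior_sd = 0.5)
  expect_gt(sh2$lfc_map[1], sh2$lfc_map[2])
  expect_error(shrink_lfc_map(lfc, se, prior_sd = -1), "positive")
  # auto width is finite and positive
  auto <- shrink_lfc_map(lfc, se)
  expect_gt(auto$prior_sd, 0)
})

test_that("shrinkage is strongest for low-count genes in a simulated study", {
  st <- small_study(seed = 61, n_genes = 3000, a = 0.03, b = 3.5)
  res <- run_analysis(st$ds, annotation = st$gen$annotation,
                      config = pipeline_config("naive", min_count = 1,
                                               quantile_filter = NULL))
  r <- res[res$passed_filters & res$chromosome == "chr21" &
             !is.na(res$lfc_mle_log2), ]
  gap <- abs(r$lfc_mle_log2 - r$lfc_map_log2)
  low <- r$base_mean <= stats::median(r$base_mean)
  expect_gt(mean(gap[low]), mean(gap[!low]))
})

test_that("Wald statistics and p-values follow the normal references", {
  w <- wald_test(0, 1, 0)
  expect_equal(w$pvalue, 1)
  w2 <- wald_test(log2(1.5), 0.37, log2(1.5))
  expect_equal(w2$wald_stat, 0)
  expect_equal(w2$pvalue, 1)
  w3 <- wald_test(1, 0.5, 0)
  expect_equal(w3$wald_stat, 2)
  expect_equal(w3$pvalue, 2 * stats::pnorm(-2), tolerance = 1e-12)
  expect_equal(round(w3$pvalue, 4), 0.0455)
  # inside the threshold band the test never rejects
  w4 <- wald_test(c(-0.3, 0.1, 0.58), 0.2, log2(1.5))
  expect_true(all(w4$pvalue == 1))
  # p-values stay in [0, 1] across a random grid
  set.seed(9)
  lfc <- stats::rnorm(200, 0, 2)
  se <- stats::runif(200, 0.01, 3)
  th <- sample(c(0, log2(1.5)), 200, replace = TRUE)
  w5 <- wald_test(lfc, se, th)
  expect_true(all(w5$pvalue >= 0 & w5$pvalue <= 1))
  expect_error(wald_test(1, 0, 0), "positive")
  expect_error(wald_test(1, 1, -1), "nonnegative")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjust_bh(0.04), 0.04)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(4)
  for (i in 1:20) {
    p <- stats::runif(sample(1:30, 1))^sample(1:3, 1)
    adj <- adjust_bh(p)
    expect_equal(adj, bh_bruteforce(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_bh(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("MAP fold changes track the reference implementation per gene", {
  st <- small_study(seed = 71, n_genes = 2000, a = 0.03, b = 3.5)
  counts <- st$ds$counts[rowSums(st$ds$counts) > 0, ]
  res <- run_analysis(counts, st$ds$condition,
                      annotation = st$gen$annotation,
                      config = pipeline_config("naive"))
  coldata <- data.frame(condition = factor(st$ds$condition,
                                           levels = c("D21", "T21")))
  dds <- DESeq2::DESeqDataSetFromMatrix(counts, coldata, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, betaPrior = TRUE, quiet = TRUE))
  ref <- DESeq2::results(dds)
  m <- match(rownames(ref), res$gene_id)
  ok <- res$passed_filters[m] & !is.na(ref$log2FoldChange) &
    !is.na(res$lfc_map_log2[m])
  expect_gt(sum(ok), 300)
  expect_gt(stats::cor(res$lfc_map_log2[m][ok], ref$log2FoldChange[ok]),
            0.98)
  big <- ok & abs(ref$log2FoldChange) > 0.3
  ratio <- stats::median(res$lfc_map_log2[m][big] / ref$log2FoldChange[big])
  expect_lt(abs(ratio - 1), 0.15)
})
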