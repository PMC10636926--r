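test_that("median-of-ratios size factors: identities and brute-force oracle", {
  cm <- matrix(c(10L, 10L, 100L, 100L, 40L, 40L), nrow = 3, byrow = TRUE,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(estimate_size_factors(cm), c(s1 = 1, s2 = 1))

  cm2 <- cm
  cm2[, 2] <- cm2[, 1] * 2L
  sf <- estimate_size_factors(cm2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  # 3-gene, 2-sample toy against an exhaustive hand computation
  toy <- matrix(c(4L, 16L, 10L, 10L, 25L, 4L), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), c("a", "b")))
  ref <- exp(rowMeans(log(toy)))            # per-gene geometric means
  expected <- apply(toy / ref, 2, stats::median)
  expect_equal(estimate_size_factors(toy), expected)
})

test_that("size-factor scaling equivariance holds on simulated data", {
  st <- small_study(seed = 14, n_genes = 500)
  counts <- st$ds$counts
  sf <- estimate_size_factors(counts)
  # scaling one sample by c scales its factor by c relative to every other
  # sample and leaves the other samples' relative factors unchanged (the
  # overall scale of size factors is arbitrary: the geometric-mean
  # reference moves with the scaled sample, so only ratios are identified)
  for (cfac in c(2L, 5L)) {
    sc <- counts
    sc[, 2] <- counts[, 2] * cfac
    sf2 <- estimate_size_factors(sc)
    expect_equal(unname(sf2[2] / sf2[1]), unname(cfac * sf[2] / sf[1]),
                 tolerance = 1e-12)
    expect_equal(unname(sf2[-2] / sf2[1]), unname(sf[-2] / sf[1]),
                 tolerance = 1e-12)
  }
})

test_that("size factors agree exactly with the reference implementation", {
  st <- small_study(seed = 15, n_genes = 300)
  sf <- estimate_size_factors(st$ds$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(st$ds$counts)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-10)
})

test_that("exclusions and degenerate inputs are handled", {
  st <- small_study(seed = 16, n_genes = 300)
  counts <- st$ds$counts
  chr21 <- st$gen$annotation$gene_id[st$gen$annotation$chromosome == "chr21"]
  sf_all <- estimate_size_factors(counts)
  sf_ex <- estimate_size_factors(counts, exclude_genes = chr21)
  expect_equal(length(sf_ex), ncol(counts))
  expect_true(all(sf_ex > 0))
  expect_false(identical(sf_all, sf_ex))
  # no all-positive gene left -> informative error
  bad <- matrix(c(0L, 5L, 7L, 0L), nrow = 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(estimate_size_factors(bad), "positive counts")
})

test_that("ploidy matrix assigns ploidy/2 per gene and sample", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    chromosome = c("chr21", "chr1", "chr21"),
                    ploidy_D21 = 2L, ploidy_T21 = c(3L, 2L, 3L),
                    repeat_flag = FALSE)
  cond <- c(a1 = "D21", a2 = "D21", b1 = "T21", b2 = "T21")
  nm <- make_ploidy_matrix(ann, cond)
  expect_equal(dim(nm), c(3, 4))
  expect_equal(unname(nm["g1", ]), c(1, 1, 1.5, 1.5))
  expect_equal(unname(nm["g2", ]), rep(1, 4))
  # all-disomic annotation -> all-ones matrix
  ann2 <- ann
  ann2$ploidy_T21 <- 2L
  expect_true(all(make_ploidy_matrix(ann2, cond) == 1))
  expect_error(make_ploidy_matrix(ann, c(x = "T18")), "ploidy")
})

test_that("count normalization arithmetic and validation", {
  cm <- matrix(c(150L, 100L), nrow = 1,
               dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(normalize_counts(cm, c(1, 1))[1, ]), c(150, 100))
  nm <- matrix(c(1.5, 1), nrow = 1, dimnames = dimnames(cm))
  expect_equal(unname(normalize_counts(cm, c(1, 1), nm)[1, ]), c(100, 100))
  expect_equal(unname(normalize_counts(cm, c(2, 1))[1, 1]), 75)
  expect_error(normalize_counts(cm, c(0, 1)), "positive")
  expect_error(normalize_counts(cm, c(1, 1), nm * 0), "positive")
  expect_error(normalize_counts(cm, 1), "per sample")
})
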