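# Orchestration of naive and trisomy-aware end-to-end analyses.

#' Pipeline configuration
#'
#' @param mode analysis mode:
#'   * `"naive"` — standard defaults: size factors over all genes, no ploidy
#'     normalization, fold-change null of 0, significance calls on MAP fold
#'     changes;
#'   * `"ploidy_norm"` — size factors computed without the trisomic genes,
#'     counts additionally normalized by the ploidy/2 matrix, null of 0;
#'     trisomic genes are then expected at fold change 1.0 and significant
#'     genes below 1.0 are candidate dosage-compensated genes;
#'   * `"threshold_null"` — no ploidy normalization; trisomic genes are
#'     tested against the dosage-informed null `|lfc| <= log2(ploidy
#'     ratio)`. MAP estimates are disallowed here because the zero-centered
#'     prior does not reflect the shifted null, so calls use MLE fold
#'     changes.
#' @param min_count minimum normalized base mean (default 30); genes below
#'   it are filtered as low-coverage false-positive risks.
#' @param quantile_filter optional base-mean quantile cutoff in (0, 1)
#'   (default 0.4, the second quintile); `NULL` disables it.
#' @param exclude_chr21_from_size_factors drop trisomic genes from the size
#'   factor calculation; default `NULL` means mode-dependent (FALSE for
#'   naive, TRUE otherwise).
#' @param drop_repeat_genes remove repeat-flagged genes before analysis
#'   (default TRUE).
#' @param alpha_level adjusted-p significance level (default 0.01).
#' @param lfc_estimator estimator used for Wald calls and reported fold
#'   changes: `"map"` or `"mle"`; default `NULL` means mode-dependent
#'   (map for naive/ploidy_norm, mle for threshold_null).
#' @param lfc_prior_sd prior width for MAP shrinkage (default `"auto"`).
#' @param prior_min_count base-mean cutoff defining the well-covered genes
#'   on which the automatic prior width is matched (default 30,
#'   independent of the reporting filters).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("naive", "ploidy_norm", "threshold_null"),
                            min_count = 30,
                            quantile_filter = 0.4,
                            exclude_chr21_from_size_factors = NULL,
                            drop_repeat_genes = TRUE,
                            alpha_level = 0.01,
                            lfc_estimator = NULL,
                            lfc_prior_sd = "auto",
                            prior_min_count = 30) {
  mode <- match.arg(mode)
  stop_if(min_count < 0, "`min_count` must be nonnegative")
  if (!is.null(quantile_filter)) {
    stop_if(quantile_filter <= 0 || quantile_filter >= 1,
            "`quantile_filter` must lie strictly between 0 and 1")
  }
  stop_if(alpha_level <= 0 || alpha_level >= 1,
          "`alpha_level` must lie strictly between 0 and 1")
  if (is.null(exclude_chr21_from_size_factors)) {
    exclude_chr21_from_size_factors <- mode != "naive"
  }
  if (is.null(lfc_estimator)) {
    lfc_estimator <- if (mode == "threshold_null") "mle" else "map"
  }
  stop_if(!lfc_estimator %in% c("mle", "map"),
          "`lfc_estimator` must be \"mle\" or \"map\"")
  stop_if(mode == "threshold_null" && lfc_estimator == "map",
          "threshold_null mode cannot use MAP fold changes: the ",
          "zero-centered prior contradicts the dosage-informed null")
  structure(list(mode = mode, min_count = min_count,
                 quantile_filter = quantile_filter,
                 exclude_chr21_from_size_factors =
                   exclude_chr21_from_size_factors,
                 drop_repeat_genes = drop_repeat_genes,
                 alpha_level = alpha_level,
                 lfc_estimator = lfc_estimator,
                 lfc_prior_sd = lfc_prior_sd,
                 prior_min_count = prior_min_count),
            class = "pipeline_config")
}

#' Low-coverage filter on normalized base means
#'
#' A gene passes iff its base mean is at least `min_count` and, when a
#' quantile filter is set, at least the given quantile (linear-interpolation
#' convention, [stats::quantile()] type 7) of all supplied base means.
#'
#' @param base_mean per-gene normalized base means.
#' @param min_count absolute cutoff.
#' @param quantile_filter quantile cutoff in (0, 1) or `NULL`.
#' @return Logical vector of passes.
#' @export
filter_low_coverage <- function(base_mean, min_count = 30,
                                quantile_filter = 0.4) {
  pass <- base_mean >= min_count
  if (!is.null(quantile_filter)) {
    stop_if(quantile_filter <= 0 || quantile_filter >= 1,
            "`quantile_filter` must lie strictly between 0 and 1")
    q <- stats::quantile(base_mean, quantile_filter, names = FALSE,
                         na.rm = TRUE)
    pass <- pass & base_mean >= q
  }
  pass
}

#' Repeat-gene filter
#'
#' List-based removal of genes flagged as overlapping genomic repeats,
#' which inflate apparent dosage compensation through multi-mapping
#' artifacts.
#'
#' @param annotation annotation with a logical `repeat_flag` column.
#' @return Character vector of passing gene ids.
#' @export
filter_repeat_genes <- function(annotation) {
  stop_if(is.null(annotation$repeat_flag), "annotation lacks `repeat_flag`")
  annotation$gene_id[!annotation$repeat_flag]
}

#' Run a full differential-expression analysis
#'
#' End-to-end: repeat-gene removal, size factors (optionally without the
#' trisomic genes), optional ploidy normalization, coverage filters,
#' dispersion estimation (MLE, trend, shrinkage) on the passing genes,
#' MLE/MAP fold changes, Wald tests with the mode's null, and BH adjustment
#' over the tested genes.
#'
#' @param counts integer matrix, genes x samples (or a `count_dataset`).
#' @param condition per-sample condition labels (ignored for a
#'   `count_dataset`; otherwise inferred from column names if `NULL`).
#' @param annotation gene annotation (must cover all count rows).
#' @param config a [pipeline_config()].
#' @param reference reference condition; default lexicographically first.
#' @return A data.frame of class `de_result` with one row per annotated
#'   gene: `gene_id`, `base_mean`, `lfc_mle_log2`, `lfc_map_log2`, `se`,
#'   `se_map`, `wald_stat`, `pvalue`, `padj`, `passed_filters`,
#'   `fold_change` (of the calling estimator), `chromosome`,
#'   `ploidy_ratio`. The run report (size factors, trend parameters, prior
#'   variances, filter tallies, effective config) is in `attr(, "report")`.
#' @export
run_analysis <- function(counts, condition = NULL, annotation, config,
                         reference = NULL) {
  if (inherits(counts, "count_dataset")) {
    condition <- counts$condition
    counts <- counts$counts
  }
  stop_if(!inherits(config, "pipeline_config"),
          "`config` must come from pipeline_config()")
  check_count_matrix(counts)
  condition <- infer_condition(counts, condition)
  conds <- unique(condition)
  stop_if(length(conds) != 2, "exactly two conditions required, got ",
          length(conds))
  reference <- reference %||% sort(conds)[1]
  other <- setdiff(conds, reference)
  stop_if(!all(rownames(counts) %in% annotation$gene_id),
          "annotation must cover every gene in the counts")
  ann <- annotation[match(rownames(counts), annotation$gene_id), ]

  ploidy_ref <- ploidy_of(ann, reference)
  ploidy_alt <- ploidy_of(ann, other)
  ploidy_ratio <- ploidy_alt / ploidy_ref
  trisomic <- ploidy_ratio != 1

  # 1. repeat genes
  if (isTRUE(config$drop_repeat_genes) && !is.null(ann$repeat_flag)) {
    kept_ids <- filter_repeat_genes(ann)
  } else {
    kept_ids <- ann$gene_id
  }
  keep <- rownames(counts) %in% kept_ids
  n_repeat_dropped <- sum(!keep)
  counts_k <- counts[keep, , drop = FALSE]
  ann_k <- ann[keep, , drop = FALSE]
  ratio_k <- ploidy_ratio[keep]
  tri_k <- trisomic[keep]

  # 2. size factors
  sf_exclude <- if (config$exclude_chr21_from_size_factors) {
    ann_k$gene_id[tri_k]
  } else NULL
  sf <- estimate_size_factors(counts_k, exclude_genes = sf_exclude)

  # 3. ploidy normalization matrix
  nm <- if (config$mode == "ploidy_norm") {
    make_ploidy_matrix(ann_k, condition)
  } else NULL

  # 4. coverage filters on normalized base means
  cmat <- scaling_matrix(counts_k, sf, nm)
  base_mean_k <- rowMeans(counts_k / cmat)
  pass <- filter_low_coverage(base_mean_k, config$min_count,
                              config$quantile_filter)
  n_coverage_dropped <- sum(!pass)
  counts_a <- counts_k[pass, , drop = FALSE]
  nm_a <- if (is.null(nm)) NULL else nm[pass, , drop = FALSE]

  # 5. dispersions on the analysis set
  disp <- estimate_dispersions(counts_a, condition, size_factors = sf,
                               norm_matrix = nm_a)
  trend <- attr(disp, "trend")

  # 6. fold changes and tests
  mle <- fit_lfc_mle(counts_a, condition, alphas = disp$final_alpha,
                     size_factors = sf, norm_matrix = nm_a,
                     reference = reference)
  # the automatic prior width is matched on well-covered genes only, so
  # that noisy low-coverage estimates cannot inflate the prior even when
  # the reporting filters are relaxed
  well_covered <- mle$base_mean >= config$prior_min_count
  map <- shrink_lfc_map(mle$lfc_mle, mle$se, prior_sd = config$lfc_prior_sd,
                        use = well_covered)
  theta <- if (config$mode == "threshold_null") {
    ifelse(tri_k[pass], abs(log2(ratio_k[pass])), 0)
  } else 0
  if (config$lfc_estimator == "map") {
    test <- wald_test(map$lfc_map, map$se_map, theta)
    fc_call <- 2^map$lfc_map
  } else {
    test <- wald_test(mle$lfc_mle, mle$se, theta)
    fc_call <- 2^mle$lfc_mle
  }
  padj <- adjust_bh(test$pvalue)

  # 7. assemble full table in input gene order
  res <- data.frame(gene_id = rownames(counts), base_mean = NA_real_,
                    lfc_mle_log2 = NA_real_, lfc_map_log2 = NA_real_,
                    se = NA_real_, se_map = NA_real_, wald_stat = NA_real_,
                    pvalue = NA_real_, padj = NA_real_,
                    passed_filters = FALSE, fold_change = NA_real_,
                    chromosome = ann$chromosome,
                    ploidy_ratio = ploidy_ratio,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$base_mean[keep] <- base_mean_k
  ai <- match(rownames(counts_a), res$gene_id)
  res$lfc_mle_log2[ai] <- mle$lfc_mle
  res$lfc_map_log2[ai] <- map$lfc_map
  res$se[ai] <- mle$se
  res$se_map[ai] <- map$se_map
  res$wald_stat[ai] <- test$wald_stat
  res$pvalue[ai] <- test$pvalue
  res$padj[ai] <- padj
  res$fold_change[ai] <- fc_call
  res$passed_filters[ai] <- TRUE

  report <- list(
    mode = config$mode,
    reference = reference,
    contrast = paste(other, "vs", reference),
    config = unclass(config),
    size_factors = as.list(sf),
    a_hat = trend$a_hat,
    b_hat = trend$b_hat,
    dispersion_prior_log_variance = attr(disp, "prior_log_variance"),
    lfc_prior_sd = map$prior_sd,
    n_genes_input = nrow(counts),
    n_repeat_dropped = n_repeat_dropped,
    n_coverage_dropped = n_coverage_dropped,
    n_tested = nrow(counts_a),
    n_dispersion_outliers = sum(disp$outlier_flag, na.rm = TRUE),
    n_trend_excluded = length(trend$excluded)
  )
  attr(res, "report") <- report
  attr(res, "config") <- config
  class(res) <- c("de_result", "data.frame")
  res
}

#' Classify candidate dosage-compensated genes
#'
#' From a trisomy-aware result table, returns the trisomic genes that passed
#' filters, are significant at `alpha_level`, and whose fold change falls
#' below the mode's dosage reference (1.0 under ploidy normalization —
#' counts are already dosage-corrected — or the ploidy ratio, e.g. 1.5,
#' under the threshold null). Significant trisomic genes above the
#' reference are attached as attribute `elevated`. Calling this on a
#' naive-mode result is an error: with the default null every trisomic gene
#' deviates by construction and the classification is meaningless.
#'
#' @param results a `de_result` from [run_analysis()].
#' @param alpha_level significance level; default: the run's configured one.
#' @return data.frame `gene_id`, `fold_change`, `padj`, `reason`; attribute
#'   `elevated` holds the above-reference significant trisomic genes.
#' @export
classify_candidates <- function(results, alpha_level = NULL) {
  config <- attr(results, "config")
  stop_if(is.null(config), "`results` must come from run_analysis()")
  stop_if(config$mode == "naive",
          "candidate classification requires a trisomy-aware mode ",
          "(ploidy_norm or threshold_null); the naive null misidentifies ",
          "candidates")
  alpha_level <- alpha_level %||% config$alpha_level
  ref_fc <- if (config$mode == "ploidy_norm") {
    rep(1, nrow(results))
  } else {
    results$ploidy_ratio
  }
  tri <- results$ploidy_ratio != 1
  sig <- tri & results$passed_filters &
    !is.na(results$padj) & results$padj < alpha_level
  below <- sig & results$fold_change < ref_fc
  above <- sig & results$fold_change > ref_fc
  out <- data.frame(gene_id = results$gene_id[below],
                    fold_change = results$fold_change[below],
                    padj = results$padj[below],
                    reason = sprintf("padj < %g and fold change below %g",
                                     alpha_level, ref_fc[below]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "elevated") <- data.frame(
    gene_id = results$gene_id[above],
    fold_change = results$fold_change[above],
    padj = results$padj[above],
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Per-chromosome median fold change summary
#'
#' For each chromosome, the median fold change (MFC) of the passing genes,
#' the fraction strictly below the chromosome's dosage expectation, and the
#' gene count. The expectation is the ploidy ratio (1.5 for a triplicated
#' chromosome) in modes without ploidy normalization and 1.0 after it.
#' Chromosomes with no passing gene are reported with `NA` MFC, not zero.
#'
#' @param results a `de_result` from [run_analysis()].
#' @return data.frame `chromosome`, `mfc`, `expected_fc`,
#'   `fraction_below_expected`, `n_genes`.
#' @export
summarize_mfc <- function(results) {
  config <- attr(results, "config")
  stop_if(is.null(config), "`results` must come from run_analysis()")
  chroms <- unique(results$chromosome)
  rows <- lapply(chroms, function(ch) {
    sel <- results$chromosome == ch & results$passed_filters &
      !is.na(results$fold_change)
    expected <- if (config$mode == "ploidy_norm") 1 else {
      max(results$ploidy_ratio[results$chromosome == ch])
    }
    if (!any(sel)) {
      return(data.frame(chromosome = ch, mfc = NA_real_,
                        expected_fc = expected,
                        fraction_below_expected = NA_real_, n_genes = 0L,
                        stringsAsFactors = FALSE))
    }
    fc <- results$fold_change[sel]
    data.frame(chromosome = ch, mfc = stats::median(fc),
               expected_fc = expected,
               fraction_below_expected = mean(fc < expected),
               n_genes = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
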