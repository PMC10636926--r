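#' Median-of-ratios size factors
#'
#' Computes one positive normalization factor per sample: the reference for
#' each gene is its geometric mean across samples (over genes with strictly
#' positive counts in all samples), and a sample's factor is the median of
#' its count-to-reference ratios. For trisomic designs the genes on the
#' triplicated chromosome can be excluded, since they are expected a priori
#' to differ between conditions and the method assumes most genes unchanged.
#'
#' @param counts integer matrix, genes x samples, gene ids as row names.
#' @param exclude_genes optional character vector of gene ids left out of
#'   the calculation (e.g. chromosome 21 genes).
#' @return Named numeric vector of size factors, one per sample.
#' @export
estimate_size_factors <- function(counts, exclude_genes = NULL) {
  check_count_matrix(counts)
  use <- counts
  if (!is.null(exclude_genes)) {
    use <- use[!rownames(use) %in% exclude_genes, , drop = FALSE]
  }
  log_counts <- log(use)
  all_pos <- rowSums(use > 0) == ncol(use)
  stop_if(!any(all_pos),
          "no gene has positive counts in every sample",
          if (!is.null(exclude_genes)) " (after exclusions)" else "",
          "; size factors undefined")
  log_ref <- rowMeans(log_counts[all_pos, , drop = FALSE])
  sf <- apply(log_counts[all_pos, , drop = FALSE], 2,
              function(lc) exp(stats::median(lc - log_ref)))
  stop_if(any(!is.finite(sf)) || any(sf <= 0), "degenerate size factor")
  sf
}

#' Ploidy normalization matrix
#'
#' Builds the genes x samples matrix of `ploidy / 2` factors: 1.0 for any
#' disomic gene, 1.5 for a ploidy-3 gene in a trisomic sample. Dividing
#' counts by this matrix puts trisomic genes on the same expected scale as
#' their disomic counterparts, so a triplicated gene expressed at full DNA
#' dosage shows a fold change of 1.0.
#'
#' @param annotation annotation with `ploidy_<condition>` columns.
#' @param condition named character vector mapping sample -> condition.
#' @return Numeric matrix (genes x samples) of positive entries.
#' @export
make_ploidy_matrix <- function(annotation, condition) {
  stop_if(is.null(names(condition)), "`condition` must be named by sample")
  cols <- vapply(condition, function(cond) ploidy_of(annotation, cond) / 2,
                 numeric(nrow(annotation)))
  nm <- matrix(cols, nrow = nrow(annotation),
               dimnames = list(annotation$gene_id, names(condition)))
  stop_if(any(nm <= 0), "ploidy matrix entries must be positive")
  nm
}

#' Normalize counts by size factors (and optionally ploidy)
#'
#' @param counts genes x samples matrix.
#' @param size_factors positive per-sample factors.
#' @param norm_matrix optional genes x samples matrix of additional
#'   per-gene, per-sample factors (e.g. from [make_ploidy_matrix()]);
#'   omitted means size-factor-only normalization.
#' @return Matrix of `count / (size_factor * norm_matrix)` values.
#' @export
normalize_counts <- function(counts, size_factors, norm_matrix = NULL) {
  stop_if(length(size_factors) != ncol(counts),
          "one size factor per sample required")
  stop_if(any(!is.finite(size_factors)) || any(size_factors <= 0),
          "size factors must be positive")
  denom <- matrix(size_factors, nrow = nrow(counts), ncol = ncol(counts),
                  byrow = TRUE)
  if (!is.null(norm_matrix)) {
    stop_if(!all(dim(norm_matrix) == dim(counts)),
            "`norm_matrix` must match the counts' dimensions")
    stop_if(any(norm_matrix <= 0), "`norm_matrix` entries must be positive")
    denom <- denom * norm_matrix
  }
  counts / denom
}

# combined per-gene, per-sample scaling c_gs = sf_s * nm_gs used as the
# offset inside every NB likelihood
scaling_matrix <- function(counts, size_factors = NULL, norm_matrix = NULL) {
  ns <- ncol(counts)
  if (is.null(size_factors)) size_factors <- rep(1, ns)
  stop_if(length(size_factors) != ns, "one size factor per sample required")
  cmat <- matrix(size_factors, nrow = nrow(counts), ncol = ns, byrow = TRUE)
  if (!is.null(norm_matrix)) cmat <- cmat * norm_matrix
  stop_if(any(!is.finite(cmat)) || any(cmat <= 0),
          "normalization factors must be positive and finite")
  dimnames(cmat) <- dimnames(counts)
  cmat
}
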