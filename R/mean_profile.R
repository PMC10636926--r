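#' Generate a synthetic per-gene mean-expression profile with annotation
#'
#' Builds the per-gene true means that seed the count simulator, standing in
#' for a mean profile averaged from replicated disomic RNA-seq libraries.
#' Means are drawn log-normal and a fraction of genes is silenced (mean 0),
#' emulating unexpressed annotations. A fraction of genes is assigned to
#' chromosome 21 and given ploidy 3 in the trisomic condition; every other
#' gene is disomic everywhere. Remaining genes are scattered uniformly over
#' the other autosomes so that disomic control chromosomes (e.g. chr22) are
#' available downstream.
#'
#' @param n_genes number of genes (>= 10).
#' @param chr21_fraction fraction of genes on chromosome 21
#'   (default 0.012, i.e. roughly 1 percent of the genome).
#' @param log_mean,log_sd parameters of the log-normal draw for expressed
#'   genes (natural-log scale).
#' @param zero_fraction fraction of genes with true mean 0.
#' @param seed integer seed; the profile is fully deterministic given it.
#' @param conditions character vector of condition labels; the first is the
#'   disomic reference.
#' @param trisomic_condition label(s) of the condition(s) in which chr21
#'   genes carry ploidy 3; set `NULL` for an all-disomic design (e.g. a
#'   disomy-vs-disomy null experiment).
#' @param repeat_fraction fraction of genes flagged as repeat-ridden
#'   (candidates for list-based removal); default 0.
#' @return A list with `profile` (data.frame `gene_id`, `mu`) and
#'   `annotation` (data.frame `gene_id`, `chromosome`, one `ploidy_<cond>`
#'   column per condition, `repeat_flag`, `true_mu`).
#' @export
generate_mean_profile <- function(n_genes = 20000,
                                  chr21_fraction = 0.012,
                                  log_mean = 4.0,
                                  log_sd = 1.6,
                                  zero_fraction = 0.3,
                                  seed = 1,
                                  conditions = c("D21", "T21"),
                                  trisomic_condition = "T21",
                                  repeat_fraction = 0) {
  stop_if(n_genes < 10, "`n_genes` must be at least 10 (degenerate profile)")
  stop_if(chr21_fraction <= 0 || chr21_fraction >= 1,
          "`chr21_fraction` must lie strictly between 0 and 1")
  stop_if(log_sd <= 0, "`log_sd` must be positive")
  stop_if(zero_fraction < 0 || zero_fraction >= 1,
          "`zero_fraction` must lie in [0, 1)")
  stop_if(length(conditions) < 1, "at least one condition label required")
  stop_if(!is.null(trisomic_condition) &&
            !all(trisomic_condition %in% conditions),
          "`trisomic_condition` must be one of `conditions`")

  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  mu <- exp(stats::rnorm(n_genes, log_mean, log_sd))
  n_zero <- round(n_genes * zero_fraction)
  if (n_zero > 0) mu[sample.int(n_genes, n_zero)] <- 0

  n21 <- round(n_genes * chr21_fraction)
  stop_if(n21 < 1, "`chr21_fraction` too small: no chr21 genes")
  chromosome <- rep(NA_character_, n_genes)
  idx21 <- sample.int(n_genes, n21)
  chromosome[idx21] <- "chr21"
  others <- paste0("chr", c(1:20, 22))
  chromosome[-idx21] <- sample(others, n_genes - n21, replace = TRUE)

  repeat_flag <- rep(FALSE, n_genes)
  n_rep <- round(n_genes * repeat_fraction)
  if (n_rep > 0) repeat_flag[sample.int(n_genes, n_rep)] <- TRUE

  annotation <- data.frame(gene_id = gene_id, chromosome = chromosome,
                           stringsAsFactors = FALSE)
  for (cond in conditions) {
    ploidy <- rep(2L, n_genes)
    if (!is.null(trisomic_condition) && cond %in% trisomic_condition) {
      ploidy[chromosome == "chr21"] <- 3L
    }
    annotation[[paste0("ploidy_", cond)]] <- ploidy
  }
  annotation$repeat_flag <- repeat_flag
  annotation$true_mu <- mu

  list(profile = data.frame(gene_id = gene_id, mu = mu,
                            stringsAsFactors = FALSE),
       annotation = annotation)
}

#' Scale a mean profile by a sequencing-depth factor
#'
#' Multiplies every gene's true mean by `depth_scale`, emulating shallower
#' (`< 1`) or deeper (`> 1`) sequencing of the same libraries. Scaling acts
#' on the mean before sampling, so dispersion (which depends on the
#' post-scaling mean) rises as depth falls.
#'
#' @param profile data.frame with columns `gene_id`, `mu`.
#' @param depth_scale positive multiplier.
#' @return The profile with `mu` scaled; order and ids untouched.
#' @export
apply_depth <- function(profile, depth_scale) {
  stop_if(!is.numeric(depth_scale) || length(depth_scale) != 1 ||
            !is.finite(depth_scale) || depth_scale <= 0,
          "`depth_scale` must be a single positive number")
  profile$mu <- profile$mu * depth_scale
  profile
}

# run code under a fixed seed, restoring the caller's RNG state afterwards
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

# ploidy of every gene under a condition, from the annotation table
ploidy_of <- function(annotation, condition) {
  col <- paste0("ploidy_", condition)
  stop_if(!col %in% names(annotation),
          "annotation has no ploidy column for condition '", condition, "'")
  p <- annotation[[col]]
  stop_if(!all(p %in% c(1L, 2L, 3L)), "ploidy must be 1, 2 or 3")
  p
}
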