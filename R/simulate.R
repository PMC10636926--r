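#' Simulation configuration
#'
#' Bundles the negative-binomial simulation parameters. Dispersion follows
#' \eqn{\alpha = a + b/\mu} evaluated at the post-scaling mean (after depth
#' and dosage multiplication). Trisomic (ploidy-3) genes may carry their own
#' hyperparameters, which is how noisier trisomic chromosomes are emulated;
#' they default to the global ones.
#'
#' @param a,b nonnegative dispersion hyperparameters for all genes
#'   (asymptotic dispersion and extra-Poisson noise).
#' @param trisomy_a,trisomy_b hyperparameters used for ploidy-3 genes in the
#'   condition where they are trisomic; default to `a` and `b`.
#' @param replicates integer >= 2, replicates per condition.
#' @param depth_scale positive sequencing-depth multiplier applied to every
#'   mean before sampling.
#' @param dosage_ratio positive multiplier applied to the means of ploidy-3
#'   genes in their trisomic condition (default 1.5, the DNA-dosage
#'   expectation for a triplicated chromosome).
#' @param seed master integer seed; per-condition/per-replicate streams are
#'   derived from it with [derive_seed()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(a = 0.01, b = 1,
                              trisomy_a = a, trisomy_b = b,
                              replicates = 3L,
                              depth_scale = 1,
                              dosage_ratio = 1.5,
                              seed = 1L) {
  stop_if(a < 0 || b < 0 || trisomy_a < 0 || trisomy_b < 0,
          "dispersion hyperparameters must be nonnegative")
  stop_if(replicates < 2, "`replicates` must be at least 2")
  stop_if(depth_scale <= 0, "`depth_scale` must be positive")
  stop_if(dosage_ratio <= 0, "`dosage_ratio` must be positive")
  structure(list(a = a, b = b, trisomy_a = trisomy_a, trisomy_b = trisomy_b,
                 replicates = as.integer(replicates),
                 depth_scale = depth_scale, dosage_ratio = dosage_ratio,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("NB simulation config: a =", x$a, " b =", x$b,
      " (trisomic genes: a =", x$trisomy_a, " b =", x$trisomy_b, ")\n",
      " replicates/condition =", x$replicates,
      " depth_scale =", x$depth_scale,
      " dosage_ratio =", x$dosage_ratio,
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Simulate a count matrix for one condition
#'
#' Draws independent negative-binomial counts per gene and replicate. Each
#' gene's effective mean is `mu * depth_scale`, further multiplied by
#' `dosage_ratio` when the gene has ploidy 3 in this condition; the
#' dispersion is evaluated at that effective mean. Genes with `mu = 0` yield
#' all-zero rows. Replicate `k` uses a seed derived from
#' `(seed, condition index, k)`, so adding replicates or simulating
#' conditions in a different order never changes earlier columns.
#'
#' @param profile mean profile (data.frame `gene_id`, `mu`).
#' @param annotation gene annotation with a `ploidy_<condition>` column.
#' @param config a [simulation_config()].
#' @param condition condition label to simulate.
#' @param dosage_override optional named numeric vector (names = gene ids)
#'   replacing `dosage_ratio` for specific ploidy-3 genes — e.g. to spike a
#'   fully dosage-compensated gene (ratio 1.0) into a trisomic background.
#' @return Integer matrix (genes x replicates) with gene ids as row names
#'   and columns `<condition>_rep<k>`.
#' @export
simulate_counts <- function(profile, annotation, config, condition,
                            dosage_override = NULL) {
  stop_if(!inherits(config, "simulation_config"),
          "`config` must come from simulation_config()")
  stop_if(!identical(profile$gene_id, annotation$gene_id),
          "profile and annotation gene ids must match")
  ploidy <- ploidy_of(annotation, condition)

  mu <- profile$mu
  tri <- ploidy == 3L
  dosage <- ifelse(tri, config$dosage_ratio, 1)
  if (!is.null(dosage_override)) {
    stop_if(is.null(names(dosage_override)),
            "`dosage_override` must be a named vector of gene ids")
    idx <- match(names(dosage_override), profile$gene_id)
    stop_if(anyNA(idx), "unknown gene id in `dosage_override`")
    keep <- tri[idx]
    dosage[idx[keep]] <- dosage_override[keep]
  }
  eff_mu <- mu * config$depth_scale * dosage
  a_vec <- ifelse(tri, config$trisomy_a, config$a)
  b_vec <- ifelse(tri, config$trisomy_b, config$b)
  alpha <- ifelse(eff_mu > 0, a_vec + b_vec / pmax(eff_mu, 1e-300), 0)

  # stable small integer fingerprint of the condition label
  cond_ix <- sum(utf8ToInt(condition) * seq_along(utf8ToInt(condition)))
  n_rep <- config$replicates
  out <- matrix(0L, nrow = length(mu), ncol = n_rep,
                dimnames = list(profile$gene_id,
                                paste0(condition, "_rep", seq_len(n_rep))))
  for (k in seq_len(n_rep)) {
    restore <- .Random.seed_guard(derive_seed(config$seed, cond_ix, k))
    out[, k] <- nb_sample(eff_mu, alpha)
    restore()
  }
  storage.mode(out) <- "integer"
  out
}

#' Simulate a two-condition (or multi-condition) experiment
#'
#' Calls [simulate_counts()] for each condition named in the annotation's
#' ploidy columns and binds the results into one genes x samples matrix.
#'
#' @inheritParams simulate_counts
#' @param conditions condition labels; default: every `ploidy_<cond>` column
#'   of the annotation, in column order.
#' @return A list of class `count_dataset` with elements `counts` (integer
#'   matrix), `condition` (named character vector per sample), `config`,
#'   and `conditions`.
#' @export
simulate_experiment <- function(profile, annotation, config,
                                conditions = NULL, dosage_override = NULL) {
  if (is.null(conditions)) {
    cols <- grep("^ploidy_", names(annotation), value = TRUE)
    stop_if(length(cols) == 0, "annotation has no ploidy_<condition> columns")
    conditions <- sub("^ploidy_", "", cols)
  }
  mats <- lapply(conditions, function(cond) {
    simulate_counts(profile, annotation, config, cond,
                    dosage_override = dosage_override)
  })
  counts <- do.call(cbind, mats)
  condition <- rep(conditions, each = config$replicates)
  names(condition) <- colnames(counts)
  structure(list(counts = counts, condition = condition,
                 config = config, conditions = conditions),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat("Simulated count dataset:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples (",
      paste(unique(x$condition), collapse = " vs "), ")\n")
  invisible(x)
}
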