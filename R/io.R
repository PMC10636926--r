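# Tab-delimited input/output, run reports, and bundled test fixtures.

#' Read a gene-count table
#'
#' Expects tab-delimited text with a `gene_id` first column and one integer
#' column per sample. Sample conditions come from an optional two-column
#' design file (`sample`, `condition`) or, by default, from the
#' `<condition>_rep<k>` column-name convention.
#'
#' @param path counts file.
#' @param design_path optional tab-delimited design file.
#' @return A `count_dataset` list with `counts` and `condition`.
#' @export
read_counts <- function(path, design_path = NULL) {
  stop_if(!file.exists(path), "counts file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  stop_if(ncol(tab) < 2, "counts file needs a gene_id column plus samples")
  stop_if(names(tab)[1] != "gene_id",
          "first column must be named `gene_id`, found `", names(tab)[1], "`")
  ids <- as.character(tab[[1]])
  dup <- ids[duplicated(ids)]
  stop_if(length(dup) > 0, "duplicate gene id(s): ",
          paste(utils::head(unique(dup), 3), collapse = ", "))
  mat <- as.matrix(tab[, -1, drop = FALSE])
  for (j in seq_len(ncol(mat))) {
    col <- suppressWarnings(as.numeric(mat[, j]))
    bad <- which(is.na(col) | col < 0 | col != round(col))
    stop_if(length(bad) > 0,
            "non-integer or negative count at line ", bad[1] + 1,
            ", column `", colnames(mat)[j], "`")
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  condition <- if (!is.null(design_path)) {
    des <- utils::read.delim(design_path, stringsAsFactors = FALSE)
    stop_if(!all(c("sample", "condition") %in% names(des)),
            "design file needs `sample` and `condition` columns")
    miss <- setdiff(colnames(mat), des$sample)
    stop_if(length(miss) > 0, "design file missing sample(s): ",
            paste(miss, collapse = ", "))
    cv <- des$condition[match(colnames(mat), des$sample)]
    names(cv) <- colnames(mat)
    cv
  } else {
    infer_condition(mat)
  }
  structure(list(counts = mat, condition = condition,
                 conditions = unique(condition)),
            class = "count_dataset")
}

#' Write a gene-count table
#'
#' @param counts integer matrix (or `count_dataset`).
#' @param path output file.
#' @export
write_counts <- function(counts, path) {
  if (inherits(counts, "count_dataset")) counts <- counts$counts
  check_count_matrix(counts)
  tab <- data.frame(gene_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-annotation table
#'
#' Tab-delimited with columns `gene_id`, `chromosome`, one `ploidy_<cond>`
#' column per condition, and optional `repeat_flag` (0/1) and `true_mu`.
#'
#' @param path annotation file.
#' @return Annotation data.frame.
#' @export
read_annotation <- function(path) {
  stop_if(!file.exists(path), "annotation file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if(!all(c("gene_id", "chromosome") %in% names(ann)),
          "annotation needs `gene_id` and `chromosome` columns")
  pcols <- grep("^ploidy_", names(ann), value = TRUE)
  stop_if(length(pcols) == 0, "annotation needs ploidy_<condition> columns")
  for (pc in pcols) {
    stop_if(!all(ann[[pc]] %in% c(1L, 2L, 3L)),
            "`", pc, "` has ploidy outside {1, 2, 3}")
  }
  if (is.null(ann$repeat_flag)) ann$repeat_flag <- FALSE
  ann$repeat_flag <- as.logical(ann$repeat_flag)
  ann
}

#' Write a gene-annotation table
#'
#' @param annotation annotation data.frame.
#' @param path output file.
#' @export
write_annotation <- function(annotation, path) {
  out <- annotation
  out$repeat_flag <- as.integer(out$repeat_flag)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run report as JSON
#'
#' Serializes a run report (effective configuration, seeds, size factors,
#' trend parameters, filter tallies, package version, timestamp) so the run
#' can be replayed exactly.
#'
#' @param report a report list (e.g. `attr(results, "report")`).
#' @param path output JSON file.
#' @param seed optional seed(s) to record.
#' @export
write_run_report <- function(report, path, seed = NULL) {
  report$seed <- seed %||% report$seed
  report$package_version <-
    as.character(utils::packageVersion("trisomyDE"))
  report$timestamp <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# fixed 5-gene toy used for brute-force oracle tests; constants, no RNG.
toy5_fixture <- function() {
  counts <- matrix(
    c(10L, 30L, 12L, 28L,
      100L, 110L, 205L, 198L,
      0L, 0L, 0L, 0L,
      55L, 61L, 48L, 52L,
      500L, 480L, 760L, 740L),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("g", 1:5),
                    c("D21_rep1", "D21_rep2", "T21_rep1", "T21_rep2")))
  annotation <- data.frame(
    gene_id = paste0("g", 1:5),
    chromosome = c("chr1", "chr21", "chr2", "chr22", "chr21"),
    ploidy_D21 = 2L, ploidy_T21 = c(2L, 3L, 2L, 2L, 3L),
    repeat_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  condition <- c(D21_rep1 = "D21", D21_rep2 = "D21",
                 T21_rep1 = "T21", T21_rep2 = "T21")
  list(counts = counts, condition = condition, annotation = annotation)
}

#' Deterministic test fixtures
#'
#' Bundled toy datasets with known ground truth:
#' * `"toy5"` — fixed 5-gene, 2+2-sample matrix (no RNG), matching the
#'   plain-text copies under `inst/extdata/`;
#' * `"mini200"` — 200-gene simulated mini-study, 3 replicates per
#'   condition, trisomic chr21 block at 1.5x;
#' * `"spiked"` — 2000-gene study with 10 replicates in which exactly one
#'   high-expression chr21 gene (`spike_gene` in the returned list) is
#'   simulated fully dosage-compensated (ratio 1.0) among 1.5x neighbours.
#'
#' @param kind fixture name.
#' @param seed integer seed (ignored by `"toy5"`).
#' @return List with `counts`, `condition`, `annotation`, plus ground-truth
#'   extras depending on the kind.
#' @export
make_fixture <- function(kind = c("toy5", "mini200", "spiked"), seed = 1) {
  kind <- tryCatch(match.arg(kind), error = function(e)
    stop("unknown fixture kind; available: toy5, mini200, spiked",
         call. = FALSE))
  if (kind == "toy5") return(toy5_fixture())
  if (kind == "mini200") {
    gen <- generate_mean_profile(n_genes = 200, chr21_fraction = 0.1,
                                 zero_fraction = 0.2, seed = seed)
    cfg <- simulation_config(a = 0.01, b = 1, replicates = 3, seed = seed)
    ds <- simulate_experiment(gen$profile, gen$annotation, cfg)
    return(list(counts = ds$counts, condition = ds$condition,
                annotation = gen$annotation, profile = gen$profile,
                config = cfg))
  }
  # spiked: one chr21 gene forced to full compensation with a large mean
  gen <- generate_mean_profile(n_genes = 2000, chr21_fraction = 0.05,
                               zero_fraction = 0.2, seed = seed)
  chr21 <- gen$annotation$gene_id[gen$annotation$chromosome == "chr21"]
  mus <- gen$profile$mu[match(chr21, gen$profile$gene_id)]
  spike <- chr21[which.max(mus * (mus >= 500))]
  if (max(mus) < 500) { # guarantee a well-covered spike
    spike <- chr21[which.max(mus)]
    gen$profile$mu[gen$profile$gene_id == spike] <- 800
    gen$annotation$true_mu[gen$annotation$gene_id == spike] <- 800
  }
  cfg <- simulation_config(a = 0.01, b = 1, replicates = 10, seed = seed)
  ov <- stats::setNames(1.0, spike)
  ds <- simulate_experiment(gen$profile, gen$annotation, cfg,
                            dosage_override = ov)
  list(counts = ds$counts, condition = ds$condition,
       annotation = gen$annotation, profile = gen$profile,
       config = cfg, spike_gene = spike)
}

#' Write a differential-expression results table
#'
#' @param results a `de_result` from [run_analysis()].
#' @param path output file (tab-delimited).
#' @export
write_results <- function(results, path) {
  cols <- c("gene_id", "base_mean", "lfc_mle_log2", "lfc_map_log2", "se",
            "wald_stat", "pvalue", "padj", "passed_filters", "chromosome",
            "ploidy_ratio", "fold_change")
  utils::write.table(results[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
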