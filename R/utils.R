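# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a deterministic sub-seed from a master seed
#'
#' Mixes a master seed with any number of integer indices (condition index,
#' replicate index, sweep position, ...) into a new seed below 2^31, so that
#' independent simulation streams can be replayed individually: adding a
#' replicate or a grid point never perturbs the draws of an earlier one.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the stream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  # multiplier kept small enough that s * mult stays exactly representable
  for (v in idx) {
    s <- (s * 69069 + (as.double(v) %% 2147483647) * 10007 + 1) %% 2147483647
  }
  as.integer(s)
}

# Vectorized golden-section maximizer: maximizes f over [lower, upper]
# independently for each element. f takes a vector of points (one per
# element) and returns the objective at those points. Used for all per-gene
# 1-D likelihood maximizations (dispersion, group means); ~50 iterations
# shrink a 20-log-unit bracket below 1e-7.
golden_max <- function(f, lower, upper, iter = 52L, n = NULL) {
  gr <- (sqrt(5) - 1) / 2
  if (is.null(n)) n <- max(length(lower), length(upper))
  a <- rep_len(lower, n)
  b <- rep_len(upper, n)
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- f(x1)
  f2 <- f(x2)
  for (i in seq_len(iter)) {
    up <- f1 < f2 # maximum lies in [x1, b]
    a[up] <- x1[up]
    x1[up] <- x2[up]
    f1[up] <- f2[up]
    x2[up] <- a[up] + gr * (b[up] - a[up])
    dn <- !up
    b[dn] <- x2[dn]
    x2[dn] <- x1[dn]
    f2[dn] <- f1[dn]
    x1[dn] <- b[dn] - gr * (b[dn] - a[dn])
    xn <- ifelse(up, x2, x1)
    fn <- f(xn)
    f1[dn] <- fn[dn]
    f2[up] <- fn[up]
  }
  (a + b) / 2
}

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

# condition labels of a count matrix's samples, from an explicit vector or
# from `<condition>_rep<k>` column names
infer_condition <- function(counts, condition = NULL) {
  if (!is.null(condition)) {
    stop_if(length(condition) != ncol(counts),
            "`condition` must have one entry per sample (column)")
    cn <- as.character(condition)
    names(cn) <- colnames(counts)
    return(cn)
  }
  cn <- colnames(counts)
  stop_if(is.null(cn), "counts matrix has no column names and no `condition` given")
  m <- regmatches(cn, regexec("^(.*)_rep[0-9]+$", cn))
  bad <- vapply(m, length, 1L) != 2L
  stop_if(any(bad), "cannot infer condition from sample name(s): ",
          paste(cn[bad], collapse = ", "),
          " (expected `<condition>_rep<k>` or an explicit `condition` vector)")
  out <- vapply(m, `[`, "", 2L)
  names(out) <- cn
  out
}

check_count_matrix <- function(counts) {
  stop_if(!is.matrix(counts) || !is.numeric(counts),
          "counts must be a numeric matrix (genes x samples)")
  stop_if(anyNA(counts), "counts must not contain missing values")
  stop_if(any(counts < 0), "counts must be nonnegative")
  stop_if(any(counts != round(counts)), "counts must be integers")
  stop_if(is.null(rownames(counts)), "counts must carry gene ids as row names")
  stop_if(anyDuplicated(rownames(counts)) > 0, "duplicate gene ids in counts")
  invisible(counts)
}
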