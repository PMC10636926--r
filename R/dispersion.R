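# Gene-wise NB dispersion estimation: maximum likelihood, asymptotic trend
# fitting, and empirical-Bayes shrinkage toward the trend.

# Build the per-gene profile log-likelihood of log(alpha): group means are
# fixed at the condition averages of normalized counts, the likelihood is
# evaluated on the raw counts with fitted means c_gs * qbar_g(cond). With
# `cox_reid = TRUE` the Cox-Reid adjustment -0.5 * sum_groups log(sum w)
# corrects the downward bias caused by plugging in estimated means.
disp_objective <- function(counts, cmat, group_idx, cox_reid = TRUE) {
  norm <- counts / cmat
  mu_hat <- matrix(0, nrow(counts), ncol(counts))
  for (g in group_idx) {
    qbar <- rowMeans(norm[, g, drop = FALSE])
    mu_hat[, g] <- cmat[, g, drop = FALSE] * qbar
  }
  mu_safe <- pmax(mu_hat, 1e-10)
  function(log_alpha) {
    alpha <- exp(log_alpha)
    ll <- rowSums(stats::dnbinom(counts, size = 1 / alpha, mu = mu_safe,
                                 log = TRUE))
    if (cox_reid) {
      w <- mu_hat / (1 + alpha * mu_hat)
      for (g in group_idx) {
        ll <- ll - 0.5 * log(pmax(rowSums(w[, g, drop = FALSE]), 1e-10))
      }
    }
    ll[!is.finite(ll)] <- -1e300
    ll
  }
}

group_indices <- function(condition) {
  idx <- split(seq_along(condition), condition)
  small <- vapply(idx, length, 1L) < 2L
  stop_if(any(small), "every condition needs at least 2 replicates (",
          paste(names(idx)[small], collapse = ", "), ")")
  idx
}

#' Gene-wise maximum-likelihood dispersion
#'
#' For every gene, fixes the fitted means at the per-condition averages of
#' normalized counts and maximizes the negative-binomial likelihood over a
#' bounded log-scale search for the dispersion. By default the Cox-Reid
#' adjusted (restricted) likelihood is maximized, which removes most of the
#' downward bias incurred by estimating the group means from the same data;
#' `cox_reid = FALSE` gives the plain profile MLE.
#'
#' @param counts integer matrix, genes x samples.
#' @param condition per-sample condition labels (named vector or inferred
#'   from `<condition>_rep<k>` column names).
#' @param size_factors optional per-sample size factors (default all 1).
#' @param norm_matrix optional genes x samples normalization matrix.
#' @param cox_reid use the Cox-Reid adjusted likelihood (default TRUE).
#' @param alpha_range search bounds for the dispersion (default
#'   `c(1e-8, 10)`); genes whose estimate collapses onto a bound are flagged
#'   and excluded from trend fitting.
#' @return data.frame with `gene_id`, `base_mean` (mean normalized count),
#'   `mle_alpha`, `at_lower`, `at_upper`, `fitted` (FALSE for all-zero
#'   genes, whose dispersion is undefined).
#' @export
estimate_dispersion_mle <- function(counts, condition = NULL,
                                    size_factors = NULL, norm_matrix = NULL,
                                    cox_reid = TRUE,
                                    alpha_range = c(1e-8, 10)) {
  check_count_matrix(counts)
  condition <- infer_condition(counts, condition)
  groups <- group_indices(condition)
  cmat <- scaling_matrix(counts, size_factors, norm_matrix)
  base_mean <- rowMeans(counts / cmat)
  fitted <- rowSums(counts) > 0

  obj <- disp_objective(counts, cmat, groups, cox_reid = cox_reid)
  la <- golden_max(obj, log(alpha_range[1]), log(alpha_range[2]),
                   n = nrow(counts))
  alpha <- exp(la)
  tol <- 1e-2 # log-units: golden search collapses far below this
  at_lower <- fitted & (la - log(alpha_range[1]) < tol)
  at_upper <- fitted & (log(alpha_range[2]) - la < tol)
  alpha[!fitted] <- NA_real_
  data.frame(gene_id = rownames(counts), base_mean = base_mean,
             mle_alpha = alpha, at_lower = at_lower, at_upper = at_upper,
             fitted = fitted, stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the asymptotic dispersion trend y = a + b/x
#'
#' Fits the mean-dispersion trend `alpha = a_hat + b_hat / base_mean` by
#' minimizing a gamma-style relative-error objective
#' (`mean(alpha/pred + log(pred))`, whose pointwise minimum is `pred =
#' alpha`), with iterative exclusion of genes whose log-ratio to the current
#' trend exceeds `outlier_log_ratio`. Both parameters are constrained
#' nonnegative by optimizing on the log scale.
#'
#' @param base_mean per-gene mean normalized counts.
#' @param mle_alpha per-gene dispersion estimates.
#' @param usable optional logical mask of genes to fit on (default: finite
#'   positive dispersion and positive mean); genes at the search bounds
#'   should be excluded by the caller.
#' @param min_genes minimum usable genes (default 50).
#' @param outlier_log_ratio exclusion cutoff on `|log(alpha/trend)|`
#'   (default 2).
#' @param max_iter maximum refit iterations (default 10).
#' @return List with `a_hat`, `b_hat`, `used` (logical mask of genes kept in
#'   the final fit), `excluded` (gene indices dropped as trend outliers),
#'   `iterations`.
#' @export
fit_dispersion_trend <- function(base_mean, mle_alpha, usable = NULL,
                                 min_genes = 50, outlier_log_ratio = 2,
                                 max_iter = 10) {
  if (is.null(usable)) {
    usable <- is.finite(mle_alpha) & mle_alpha > 0 &
      is.finite(base_mean) & base_mean > 0
  }
  stop_if(sum(usable) < min_genes,
          "only ", sum(usable), " usable genes for trend fitting (minimum ",
          min_genes, ")")
  x_all <- base_mean
  y_all <- mle_alpha
  keep <- usable

  fit_once <- function(x, y) {
    # moment start from a linear fit of alpha on 1/x, clipped positive
    cf <- tryCatch(stats::coef(stats::lm(y ~ I(1 / x))),
                   error = function(e) c(stats::median(y), 1))
    start <- log(pmax(c(cf[1], cf[2]), c(1e-6, 1e-4)))
    objfun <- function(p) {
      pred <- exp(p[1]) + exp(p[2]) / x
      mean(y / pred + log(pred))
    }
    opt <- stats::optim(start, objfun, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 5000))
    exp(opt$par)
  }

  par <- c(NA, NA)
  for (it in seq_len(max_iter)) {
    new_par <- fit_once(x_all[keep], y_all[keep])
    pred <- new_par[1] + new_par[2] / x_all
    ratio <- log(y_all / pred)
    new_keep <- usable & abs(ratio) <= outlier_log_ratio
    converged <- all(is.finite(par)) &&
      all(abs(new_par - par) <= 1e-4 * pmax(par, 1e-8))
    par <- new_par
    if (sum(new_keep) >= min_genes) keep <- new_keep
    if (converged) break
  }
  list(a_hat = unname(par[1]), b_hat = unname(par[2]),
       used = keep, excluded = which(usable & !keep), iterations = it)
}

#' Shrink gene-wise dispersions toward the fitted trend
#'
#' Performs the second estimation round: each gene's final dispersion
#' maximizes its (Cox-Reid adjusted) NB likelihood plus a log-normal prior
#' centered at the trend value, with prior variance estimated from the
#' spread of the log MLE residuals around the trend minus the expected
#' sampling variance of a log dispersion estimate, floored at `prior_floor`.
#' Genes whose log MLE lies more than `outlier_mult` prior standard
#' deviations above the trend are flagged dispersion outliers and keep their
#' MLE (they are not shrunk down, which would overstate significance).
#'
#' @inheritParams estimate_dispersion_mle
#' @param mle_fit output of [estimate_dispersion_mle()].
#' @param trend output of [fit_dispersion_trend()] (or a list with `a_hat`,
#'   `b_hat`).
#' @param prior_floor lower bound on the prior log-variance (default 0.25).
#' @param outlier_mult outlier cutoff in prior standard deviations above the
#'   trend (default 2).
#' @return data.frame (`gene_id`, `base_mean`, `mle_alpha`, `trend_alpha`,
#'   `map_alpha`, `final_alpha`, `outlier_flag`) with attributes `a_hat`,
#'   `b_hat`, `prior_log_variance`.
#' @export
shrink_dispersion <- function(counts, condition = NULL, mle_fit, trend,
                              size_factors = NULL, norm_matrix = NULL,
                              cox_reid = TRUE, alpha_range = c(1e-8, 10),
                              prior_floor = 0.25, outlier_mult = 2) {
  check_count_matrix(counts)
  condition <- infer_condition(counts, condition)
  groups <- group_indices(condition)
  cmat <- scaling_matrix(counts, size_factors, norm_matrix)

  trend_alpha <- trend$a_hat + trend$b_hat / pmax(mle_fit$base_mean, 1e-10)
  usable <- mle_fit$fitted & !mle_fit$at_lower & !mle_fit$at_upper &
    is.finite(mle_fit$mle_alpha)
  log_resid <- log(mle_fit$mle_alpha[usable]) - log(trend_alpha[usable])
  var_log <- stats::mad(log_resid, na.rm = TRUE)^2
  m <- ncol(counts)
  p <- length(groups)
  samp_var <- if (m - p > 0) trigamma((m - p) / 2) else 0
  prior_var <- max(prior_floor, var_log - samp_var)

  obj <- disp_objective(counts, cmat, groups, cox_reid = cox_reid)
  log_trend <- log(trend_alpha)
  post <- function(la) {
    obj(la) + stats::dnorm(la, mean = log_trend, sd = sqrt(prior_var),
                           log = TRUE)
  }
  la_map <- golden_max(post, log(alpha_range[1]), log(alpha_range[2]),
                       n = nrow(counts))
  map_alpha <- exp(la_map)
  map_alpha[!mle_fit$fitted] <- NA_real_

  outlier <- mle_fit$fitted & is.finite(mle_fit$mle_alpha) &
    (log(mle_fit$mle_alpha) - log_trend > outlier_mult * sqrt(prior_var))
  final_alpha <- ifelse(outlier, mle_fit$mle_alpha, map_alpha)

  out <- data.frame(gene_id = mle_fit$gene_id,
                    base_mean = mle_fit$base_mean,
                    mle_alpha = mle_fit$mle_alpha,
                    trend_alpha = trend_alpha,
                    map_alpha = map_alpha,
                    final_alpha = final_alpha,
                    outlier_flag = outlier,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "a_hat") <- trend$a_hat
  attr(out, "b_hat") <- trend$b_hat
  attr(out, "prior_log_variance") <- prior_var
  out
}

#' One-call dispersion workflow: MLE, trend, shrinkage
#'
#' @inheritParams estimate_dispersion_mle
#' @param ... passed to [fit_dispersion_trend()].
#' @return The [shrink_dispersion()] table, with the trend fit attached as
#'   attribute `trend`.
#' @export
estimate_dispersions <- function(counts, condition = NULL,
                                 size_factors = NULL, norm_matrix = NULL,
                                 cox_reid = TRUE, alpha_range = c(1e-8, 10),
                                 ...) {
  mle <- estimate_dispersion_mle(counts, condition, size_factors,
                                 norm_matrix, cox_reid, alpha_range)
  usable <- mle$fitted & !mle$at_lower & !mle$at_upper & mle$base_mean > 0
  trend <- fit_dispersion_trend(mle$base_mean, mle$mle_alpha,
                                usable = usable, ...)
  fit <- shrink_dispersion(counts, condition, mle, trend, size_factors,
                           norm_matrix, cox_reid, alpha_range)
  attr(fit, "trend") <- trend
  fit
}
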