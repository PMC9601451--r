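# Two-sample MR estimators, written directly from the estimating
# equations. All take a harmonized instrument table (columns
# beta_exposure, se_exposure, beta_outcome, se_outcome, rsid) and return
# an `mr_result` list.

mr_columns <- function(instruments) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!all(need %in% names(instruments)))
    stopf("instrument table needs columns %s", paste(need, collapse = ", "))
  list(bx = instruments$beta_exposure, sx = instruments$se_exposure,
       by = instruments$beta_outcome, sy = instruments$se_outcome,
       rsid = if ("rsid" %in% names(instruments)) instruments$rsid
       else paste0("snp", seq_len(nrow(instruments))))
}

mr_result <- function(method, estimate, se, pvalue, n_snps,
                      Q = NA_real_, Q_pvalue = NA_real_, ...) {
  structure(list(method = method, estimate = estimate, se = se,
                 pvalue = pvalue,
                 ci95 = c(estimate - 1.96 * se, estimate + 1.96 * se),
                 n_snps = n_snps, Q = Q, Q_pvalue = Q_pvalue, ...),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.4g (se %.4g), p = %.3g, %d SNPs\n",
              x$method, x$estimate, x$se, x$pvalue, x$n_snps))
  if (!is.na(x$Q))
    cat(sprintf("  heterogeneity Q = %.4g (p = %.3g)\n", x$Q, x$Q_pvalue))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept %.4g (se %.4g, p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_p))
  invisible(x)
}

#' Inverse-variance-weighted MR estimate
#'
#' Combines per-SNP ratio estimates `theta_j = beta_Yj / beta_Xj` with
#' weights `w_j = beta_Xj^2 / se_Yj^2` — equivalently a zero-intercept
#' weighted regression of outcome on exposure effects with weights
#' `1/se_Yj^2`. The default multiplicative random-effects model inflates
#' the fixed-effect standard error by `max(1, sqrt(Q/(n-1)))` and refers
#' the test statistic to a t distribution on `n - 1` df; the
#' fixed-effect model uses the normal reference.
#'
#' @param instruments Harmonized instrument table.
#' @param model `"random"` (default) or `"fixed"`.
#' @return An `mr_result` with heterogeneity Q and its p-value.
#' @export
mr_ivw <- function(instruments, model = c("random", "fixed")) {
  model <- match.arg(model)
  d <- mr_columns(instruments)
  n <- length(d$bx)
  if (n < 1) stopf("at least one instrument required")
  zero <- d$bx == 0
  if (any(zero))
    stopf("zero exposure effect for instrument(s): %s",
          paste(d$rsid[zero], collapse = ", "))
  theta <- d$by / d$bx
  w <- d$bx^2 / d$sy^2
  est <- sum(w * theta) / sum(w)
  if (n == 1) {
    se <- d$sy[[1]] / abs(d$bx[[1]])
    p <- 2 * stats::pnorm(-abs(est / se))
    return(mr_result("ivw_ratio", est, se, p, 1L))
  }
  Q <- sum(w * (theta - est)^2)
  Qp <- stats::pchisq(Q, df = n - 1, lower.tail = FALSE)
  se_fixed <- sqrt(1 / sum(w))
  if (model == "fixed") {
    se <- se_fixed
    p <- 2 * stats::pnorm(-abs(est / se))
  } else {
    se <- se_fixed * max(1, sqrt(Q / (n - 1)))
    p <- 2 * stats::pt(-abs(est / se), df = n - 1)
  }
  mr_result(paste0("ivw_", model), est, se, p, n, Q, Qp)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure
#' effects with a free intercept, every instrument oriented so its
#' exposure effect is positive. The slope estimates the causal effect;
#' the intercept estimates directional pleiotropy. Multiplicative
#' random-effects standard errors (inflation floored at 1), t reference
#' on `n - 2` df.
#'
#' @param instruments Harmonized instrument table (>= 3 rows).
#' @param intercept Fit the free intercept (the Egger model). With
#'   `FALSE` the regression is constrained through the origin, which
#'   reproduces the IVW estimator with the same weights.
#' @return An `mr_result` with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p` when `intercept = TRUE`.
#' @export
mr_egger <- function(instruments, intercept = TRUE) {
  d <- mr_columns(instruments)
  n <- length(d$bx)
  if (intercept && n < 3) stopf("MR-Egger requires at least 3 instruments")
  flip <- d$bx < 0
  bx <- abs(d$bx)
  by <- ifelse(flip, -d$by, d$by)
  w <- 1 / d$sy^2
  X <- if (intercept) cbind(1, bx) else cbind(bx)
  XtWX <- crossprod(X, X * w)
  XtWy <- crossprod(X, by * w)
  coef <- solve(XtWX, XtWy)[, 1]
  fitted <- as.vector(X %*% coef)
  k <- ncol(X)
  Q <- sum(w * (by - fitted)^2)
  Qp <- if (n > k) stats::pchisq(Q, df = n - k, lower.tail = FALSE) else NA
  inflation <- if (n > k) max(1, sqrt(Q / (n - k))) else 1
  cov_fixed <- solve(XtWX)
  ses <- sqrt(diag(cov_fixed)) * inflation
  slope_i <- k
  est <- coef[[slope_i]]
  se <- ses[[slope_i]]
  p <- 2 * stats::pt(-abs(est / se), df = max(n - k, 1))
  extra <- list()
  if (intercept) {
    extra <- list(
      egger_intercept = coef[[1]], egger_intercept_se = ses[[1]],
      egger_intercept_p = 2 * stats::pt(-abs(coef[[1]] / ses[[1]]),
                                        df = n - k))
  }
  do.call(mr_result,
          c(list(if (intercept) "mr_egger" else "wls_no_intercept",
                 est, se, p, n, Q, Qp), extra))
}

#' Weighted-median MR estimate
#'
#' Orders per-SNP ratio estimates and takes the inverse-variance-weighted
#' median: with standardized cumulative weights
#' `s_j = (sum_{i<=j} w_i - w_j/2) / sum(w)` the estimate interpolates
#' theta linearly at `s = 0.5`. Consistent when at least half the total
#' instrument weight comes from valid instruments. The standard error is
#' the SD of the estimator over `n_boot` parametric bootstrap draws of
#' the summary statistics.
#'
#' @param instruments Harmonized instrument table (>= 3 rows).
#' @param n_boot Parametric bootstrap replicates for the SE.
#' @param seed RNG seed for the bootstrap.
#' @param second_order Use the second-order ratio SE
#'   `sqrt(se_Y^2/bx^2 + by^2 se_X^2 / bx^4)` for the weights instead of
#'   the first-order `se_Y/|bx|`.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 1,
                               second_order = FALSE) {
  d <- mr_columns(instruments)
  n <- length(d$bx)
  if (n < 3) stopf("weighted median requires at least 3 instruments")
  if (any(d$bx == 0))
    stopf("zero exposure effect for instrument(s): %s",
          paste(d$rsid[d$bx == 0], collapse = ", "))
  point <- weighted_median_point(d$bx, d$by, d$sx, d$sy, second_order)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(n, d$bx, d$sx)
      by <- stats::rnorm(n, d$by, d$sy)
      bx[bx == 0] <- .Machine$double.eps
      weighted_median_point(bx, by, d$sx, d$sy, second_order)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(point / se))
  mr_result("weighted_median", point, se, p, n, n_boot = n_boot,
            seed = seed)
}

weighted_median_point <- function(bx, by, sx, sy, second_order = FALSE) {
  theta <- by / bx
  se_theta <- if (second_order)
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4) else sy / abs(bx)
  w <- 1 / se_theta^2
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[[1]] >= 0.5) return(theta[[1]])
  if (s[[length(s)]] <= 0.5) return(theta[[length(theta)]])
  below <- max(which(s < 0.5))
  # Linear interpolation between the bracketing order statistics.
  theta[[below]] + (theta[[below + 1]] - theta[[below]]) *
    (0.5 - s[[below]]) / (s[[below + 1]] - s[[below]])
}

#' Run all MR estimators on one instrument table
#'
#' @param instruments Harmonized instrument table.
#' @param n_boot Bootstrap replicates for the weighted median.
#' @param n_sim MR-PRESSO simulation replicates.
#' @param seed RNG seed shared by the stochastic methods.
#' @return List with `ivw`, `weighted_median`, `egger` (`NULL` when too
#'   few instruments), `presso` (`NULL` below 4 instruments), and a
#'   per-method summary data.frame `table`.
#' @export
mr_all <- function(instruments, n_boot = 1000, n_sim = 1000, seed = 1) {
  n <- nrow(instruments)
  res <- list(ivw = mr_ivw(instruments))
  res$weighted_median <- if (n >= 3)
    mr_weighted_median(instruments, n_boot = n_boot, seed = seed) else NULL
  res$egger <- if (n >= 3) mr_egger(instruments) else NULL
  res$presso <- if (n >= 4)
    mr_presso(instruments, n_sim = n_sim, seed = seed) else NULL
  rows <- list()
  add <- function(r) if (!is.null(r))
    rows[[length(rows) + 1]] <<- data.frame(
      method = r$method, estimate = r$estimate, se = r$se, pvalue = r$pvalue,
      ci_low = r$ci95[[1]], ci_high = r$ci95[[2]], n_snps = r$n_snps,
      stringsAsFactors = FALSE)
  add(res$ivw); add(res$weighted_median); add(res$egger)
  if (!is.null(res$presso)) {
    add(res$presso$estimate_all)
    if (!is.null(res$presso$estimate_outlier_corrected))
      add(res$presso$estimate_outlier_corrected)
  }
  res$table <- do.call(rbind, rows)
  res
}
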