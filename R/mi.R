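# Multiple imputation of missing day-90 KCCQ-TSS, stratified by arm and
# on/off-treatment status, with Rubin pooling of win-ratio results.
#
# Within each (arm x on/off-treatment) cell a normal linear model of the
# day-90 score on baseline score plus the configured covariates is fitted to
# the observed records; missing values are filled by posterior-predictive
# draws (sigma^2 from the scaled inverse chi-square, beta from its normal
# posterior, then a residual draw), clipped to the instrument's [0, 100]
# range.  Cells too small to support the regression fall back to a mean/SD
# draw.  Observed values are never altered.

#' Imputation configuration
#'
#' @param m Number of imputations (default 100, the trial convention; tests
#'   scale this down).
#' @param seed Master seed; imputation `i` uses the substream seed
#'   `seed + i` so that increasing `m` extends, rather than reshuffles,
#'   earlier draws.
#' @param model_covariates Names of covariate columns (besides
#'   `kccq_baseline`, always included) used in the imputation model;
#'   defaults to every `cov_`-prefixed column present.
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(m = 100, seed = 20260101,
                              model_covariates = NULL) {
  stopifnot(m >= 2, is.numeric(seed), length(seed) == 1)
  if (seed + m >= 2^31) stop("seed too large for substream derivation",
                             call. = FALSE)
  structure(list(m = as.integer(m), seed = as.integer(seed),
                 model_covariates = model_covariates),
            class = "imputation_config")
}

# Posterior-predictive draw for the missing entries of one cell.
impute_cell <- function(y_obs, X_obs, X_mis) {
  n <- length(y_obs); p <- ncol(X_obs)
  if (n >= p + 2 && qr(X_obs)$rank == p) {
    fit <- stats::lm.fit(X_obs, y_obs)
    df <- n - p
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / stats::rchisq(1, df)
    XtX_inv <- chol2inv(chol(crossprod(X_obs)))
    beta <- fit$coefficients +
      drop(t(chol(sigma2 * XtX_inv)) %*% stats::rnorm(p))
    mu <- drop(X_mis %*% beta)
    list(values = mu + stats::rnorm(nrow(X_mis), 0, sqrt(sigma2)),
         fallback = FALSE)
  } else {
    # too few observed records for the regression: mean/SD draw
    mu <- mean(y_obs)
    sd0 <- if (n >= 2) stats::sd(y_obs) else 0
    sigma <- sd0 * sqrt(stats::rchisq(1, max(n - 1, 1)) / max(n - 1, 1))
    list(values = stats::rnorm(nrow(X_mis), mu, max(sigma, 1e-8)),
         fallback = TRUE)
  }
}

#' Multiply impute missing day-90 KCCQ-TSS values
#'
#' Produces `m` completed copies of the dataset.  Records with an
#' `off_treatment_day` are grouped as off treatment, the rest as on
#' treatment; imputation cells are the four (arm x status) combinations.
#'
#' @param data A `trial_dataset` (some or no `kccq_day90` missing).
#' @param cfg An [imputation_config()].
#' @return List of `m` complete `trial_dataset` objects.  If nothing is
#'   missing, `m` copies of the input.
#' @export
impute_kccq <- function(data, cfg = imputation_config()) {
  stopifnot(inherits(data, "trial_dataset"),
            inherits(cfg, "imputation_config"))
  s <- data$subjects
  mis <- is.na(s$kccq_day90)
  if (!any(mis)) return(replicate(cfg$m, data, simplify = FALSE))

  covs <- cfg$model_covariates
  if (is.null(covs)) covs <- grep("^cov_", names(s), value = TRUE)
  absent <- setdiff(covs, names(s))
  if (length(absent)) {
    stop("imputation covariate(s) not in subjects table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  off <- !is.na(s$off_treatment_day)
  cell <- interaction(s$arm, ifelse(off, "off", "on"), drop = TRUE)
  X <- as.matrix(cbind(1, s[, c("kccq_baseline", covs), drop = FALSE]))
  storage.mode(X) <- "double"

  fallback_warned <- FALSE
  out <- vector("list", cfg$m)
  for (i in seq_len(cfg$m)) {
    set.seed(cfg$seed + i)
    filled <- s$kccq_day90
    for (g in levels(cell)) {
      in_cell <- cell == g
      obs <- in_cell & !mis
      need <- in_cell & mis
      if (!any(need)) next
      if (!any(obs)) {
        # empty cell: borrow from the whole arm
        arm_g <- s$arm[which(in_cell)[1]]
        obs <- s$arm == arm_g & !mis
        if (!any(obs)) stop("no observed day-90 KCCQ-TSS in arm ", arm_g,
                            "; cannot impute", call. = FALSE)
      }
      dr <- impute_cell(s$kccq_day90[obs], X[obs, , drop = FALSE],
                        X[need, , drop = FALSE])
      if (dr$fallback && !fallback_warned) {
        warning("imputation cell '", g, "' too small for the regression ",
                "model; using mean/SD draws", call. = FALSE)
        fallback_warned <- TRUE
      }
      filled[need] <- pmin(pmax(dr$values, 0), 100)
    }
    si <- s
    si$kccq_day90 <- filled
    out[[i]] <- trial_dataset(si, data$events, data$visits,
                              horizon_days = data$horizon_days,
                              metadata = c(data$metadata,
                                           list(imputation = i)),
                              validate = FALSE)
  }
  out
}

#' Pool win-ratio results across imputations (Rubin's rules)
#'
#' Pools on the log win-ratio scale: the pooled log estimate is the mean of
#' the per-imputation log estimates; the total variance is the mean
#' within-imputation variance plus `(1 + 1/m)` times the between-imputation
#' variance; the interval and p-value use a t reference with the
#' Barnard-Rubin-style degrees of freedom `(m-1) (1 + W/((1+1/m) B))^2`
#' (normal when the between-imputation variance is zero).  Win, loss and tie
#' percentages are pooled as plain means and may be fractional.
#'
#' @param results List of `m >= 2` `win_ratio_result` objects from
#'   identically configured analyses.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A pooled `win_ratio_result` with attributes `m`,
#'   `var_within`, `var_between` and `df` attached.
#' @export
pool_win_ratios <- function(results, alpha = 0.05) {
  m <- length(results)
  if (m < 2) stop("pooling requires at least 2 imputations", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "win_ratio_result")))
  logr <- vapply(results, function(r) log(r$estimate), numeric(1))
  se2 <- vapply(results, function(r) r$se_log^2, numeric(1))
  if (anyNA(logr) || anyNA(se2)) {
    stop("cannot pool: some imputations have undefined estimate or variance",
         call. = FALSE)
  }
  qbar <- mean(logr)
  W <- mean(se2)
  B <- if (m > 1) stats::var(logr) else 0
  Tv <- W + (1 + 1 / m) * B
  se <- sqrt(Tv)
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  q <- if (is.finite(df)) stats::qt(1 - alpha / 2, df) else
    stats::qnorm(1 - alpha / 2)
  p <- if (is.finite(df)) 2 * stats::pt(-abs(qbar) / se, df) else
    2 * stats::pnorm(-abs(qbar) / se)

  mean_of <- function(field) {
    Reduce(`+`, lapply(results, `[[`, field)) / m
  }
  res <- win_ratio_result(
    estimate = exp(qbar), se_log = se,
    ci_lower = exp(qbar - q * se), ci_upper = exp(qbar + q * se),
    p_two_sided = p,
    pct_wins_treated = mean_of("pct_wins_treated"),
    pct_wins_control = mean_of("pct_wins_control"),
    pct_ties = mean_of("pct_ties"),
    weights = results[[1]]$weights, alpha = alpha,
    method = sprintf("stratified win ratio, pooled over %d imputations", m))
  attr(res, "m") <- m
  attr(res, "var_within") <- W
  attr(res, "var_between") <- B
  attr(res, "df") <- df
  res
}

#' Primary analysis under multiple imputation
#'
#' Convenience wrapper: imputes missing day-90 KCCQ-TSS, runs the stratified
#' win ratio with U-statistic inference on each completed dataset, and pools
#' with Rubin's rules.
#'
#' @param data A `trial_dataset`.
#' @param rules A [comparison_rules()] object (missing-value policy is
#'   irrelevant post-imputation).
#' @param cfg An [imputation_config()].
#' @param alpha Two-sided significance level.
#' @return A pooled `win_ratio_result`.
#' @export
analyze_mi <- function(data, rules = comparison_rules(),
                       cfg = imputation_config(), alpha = 0.05) {
  completed <- impute_kccq(data, cfg)
  results <- lapply(completed, ustat_inference, rules = rules, alpha = alpha)
  pool_win_ratios(results, alpha = alpha)
}
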