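# Stratified win ratio over the hierarchical composite.
#
# All treated x control pairs are formed within each randomization stratum
# and classified by the pairwise engine; per-stratum win/loss proportions
# are combined with Mantel-Haenszel-analogous weights
#   w_k  proportional to  n1k * n0k / (n1k + n0k)
# and the estimate is R = P_win / P_loss on the weighted-proportion scale.
# Inference treats the win and loss indicators as kernels of two-sample
# U-statistics: the variance of each weighted proportion (and their
# covariance) is estimated from the empirical variance of the per-subject
# projection means (row means over controls for treated subjects, column
# means over treated for controls), and the delta method on
# log R = log(P_win) - log(P_loss) yields the log-scale standard error.
#
# For speed, pair classification is vectorized as n1 x n0 matrices per
# stratum; tests check this path against the scalar engine and against an
# independently coded brute-force enumerator.

HIER_LEVELS <- c("death", "hfe_count", "hfe_first_time", "kccq")

# Classify every treated x control pair of one stratum in matrix form.
# Returns n1 x n0 logical matrices W (treated wins) and L (control wins) and
# an integer matrix LEV of deciding levels (1..4; 5 = all-tie).
classify_stratum <- function(sub, ev_by_id, rules) {
  ti <- which(sub$arm == "treated")
  ci <- which(sub$arm == "control")
  n1 <- length(ti); n0 <- length(ci)
  cens_t <- sub$censor_day[ti]; cens_c <- sub$censor_day[ci]
  tau <- outer(cens_t, cens_c, pmin)

  eff_time <- function(days, tau, rows) {
    # matrix of the time if it falls within tau, else Inf
    m <- if (rows) matrix(days, nrow(tau), ncol(tau))
         else matrix(days, nrow(tau), ncol(tau), byrow = TRUE)
    m[m > tau] <- Inf
    m
  }
  d_t <- ifelse(is.na(sub$death_day[ti]), Inf, sub$death_day[ti])
  d_c <- ifelse(is.na(sub$death_day[ci]), Inf, sub$death_day[ci])
  Et <- eff_time(d_t, tau, rows = TRUE)
  Ec <- eff_time(d_c, tau, rows = FALSE)
  win_t <- Et > Ec          # control died earlier within tau -> treated wins
  win_c <- Ec > Et
  LEV <- matrix(5L, n1, n0)
  LEV[win_t | win_c] <- 1L
  W <- win_t; L <- win_c

  ev_t <- ev_by_id[sub$subject_id[ti]]
  ev_c <- ev_by_id[sub$subject_id[ci]]
  cnt_t <- matrix(0, n1, n0); cnt_c <- matrix(0, n1, n0)
  for (i in seq_len(n1)) {
    e <- ev_t[[i]]
    if (length(e)) cnt_t[i, ] <- findInterval(tau[i, ], e)
  }
  for (j in seq_len(n0)) {
    e <- ev_c[[j]]
    if (length(e)) cnt_c[, j] <- findInterval(tau[, j], e)
  }
  open <- LEV == 5L
  win_t <- cnt_t < cnt_c; win_c <- cnt_c < cnt_t
  m <- open & (win_t | win_c)
  LEV[m] <- 2L; W[m] <- win_t[m]; L[m] <- win_c[m]

  f_t <- vapply(ev_t, function(e) if (length(e)) e[1] else Inf, numeric(1))
  f_c <- vapply(ev_c, function(e) if (length(e)) e[1] else Inf, numeric(1))
  Ft <- eff_time(f_t, tau, rows = TRUE)
  Fc <- eff_time(f_c, tau, rows = FALSE)
  open <- LEV == 5L
  win_t <- Ft > Fc          # earlier first HFE within tau loses
  win_c <- Fc > Ft
  m <- open & (win_t | win_c)
  LEV[m] <- 3L; W[m] <- win_t[m]; L[m] <- win_c[m]

  ch_t <- sub$kccq_day90[ti] - sub$kccq_baseline[ti]
  ch_c <- sub$kccq_day90[ci] - sub$kccq_baseline[ci]
  D <- outer(ch_t, ch_c, "-")
  open <- LEV == 5L
  na_open <- open & is.na(D)
  if (any(na_open)) {
    if (rules$kccq_missing == "strict") {
      bad_t <- sub$subject_id[ti][row(D)[na_open]]
      bad_c <- sub$subject_id[ci][col(D)[na_open]]
      stop("missing day-90 KCCQ-TSS reached at the KCCQ level for ",
           sum(na_open), " pair(s) (e.g. ", bad_t[1], " vs ", bad_c[1],
           "); run impute_kccq() or use comparison_rules(kccq_missing = ",
           "\"complete_case\")", call. = FALSE)
    }
    warning(sum(na_open), " pair(s) with missing day-90 KCCQ-TSS scored ",
            "as ties at the KCCQ level (complete-case rules)", call. = FALSE)
  }
  win_t <- !is.na(D) & D >= rules$kccq_margin
  win_c <- !is.na(D) & D <= -rules$kccq_margin
  m <- open & (win_t | win_c)
  LEV[m] <- 4L; W[m] <- win_t[m]; L[m] <- win_c[m]

  list(n1 = n1, n0 = n0, W = W, L = L, LEV = LEV,
       treated_ids = sub$subject_id[ti], control_ids = sub$subject_id[ci])
}

pair_matrices <- function(data, rules = comparison_rules()) {
  stopifnot(inherits(data, "trial_dataset"))
  s <- data$subjects
  ev_by_id <- split(data$events$event_day, data$events$subject_id)
  ev_by_id <- lapply(ev_by_id, sort)
  out <- list()
  for (k in STRATUM_LEVELS) {
    sub <- s[s$stratum == k, , drop = FALSE]
    if (!nrow(sub)) next
    if (!all(ARM_LEVELS %in% sub$arm)) {
      warning("stratum ", k, " lacks patients in one arm; contributes ",
              "zero pairs", call. = FALSE)
      next
    }
    out[[k]] <- classify_stratum(sub, ev_by_id, rules)
  }
  if (!length(out)) {
    stop("no stratum has patients in both arms", call. = FALSE)
  }
  out
}

#' Tally all within-stratum between-arm pairwise comparisons
#'
#' Enumerates every treated x control pair within each stratum, classifies
#' it through the hierarchy, and returns per-stratum, per-level win/loss/tie
#' counts.  For each stratum, wins + losses + ties equals
#' `n_treated * n_control`.
#'
#' @param data A `trial_dataset`.
#' @param rules A [comparison_rules()] object.
#' @return An object of class `pair_counts`: a list with one element per
#'   contributing stratum carrying `n1`, `n0`, named per-level `wins` and
#'   `losses` vectors, and `ties`.
#' @export
count_pairs <- function(data, rules = comparison_rules()) {
  counts_from_matrices(pair_matrices(data, rules))
}

counts_from_matrices <- function(mats) {
  counts <- lapply(mats, function(m) {
    wins <- vapply(1:4, function(l) sum(m$W & m$LEV == l), numeric(1))
    losses <- vapply(1:4, function(l) sum(m$L & m$LEV == l), numeric(1))
    names(wins) <- names(losses) <- HIER_LEVELS
    list(n1 = m$n1, n0 = m$n0, wins = wins, losses = losses,
         ties = sum(m$LEV == 5L))
  })
  structure(counts, class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  for (k in names(x)) {
    ck <- x[[k]]
    cat(k, ": ", ck$n1, "x", ck$n0, " pairs; wins ",
        sum(ck$wins), ", losses ", sum(ck$losses), ", ties ", ck$ties,
        "\n", sep = "")
  }
  invisible(x)
}

#' Mantel-Haenszel-analogous stratum weights
#'
#' Computes `w_k` proportional to `n1k * n0k / (n1k + n0k)`, normalized to
#' sum to one — the standard weighting for combining per-stratum win/loss
#' proportions in a stratified win ratio.
#'
#' @param counts A `pair_counts` object.
#' @return Named numeric vector of weights summing to 1.
#' @export
mh_weights <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  if (!length(counts)) stop("no strata with pairs", call. = FALSE)
  w <- vapply(counts, function(ck) ck$n1 * ck$n0 / (ck$n1 + ck$n0),
              numeric(1))
  w / sum(w)
}

win_ratio_result <- function(estimate, se_log = NA_real_,
                             ci_lower = NA_real_, ci_upper = NA_real_,
                             p_two_sided = NA_real_,
                             pct_wins_treated, pct_wins_control, pct_ties,
                             weights, counts = NULL, alpha = 0.05,
                             method = "stratified win ratio",
                             problems = character()) {
  structure(
    list(estimate = estimate, log_estimate = log(estimate), se_log = se_log,
         ci_lower = ci_lower, ci_upper = ci_upper,
         p_two_sided = p_two_sided,
         pct_wins_treated = pct_wins_treated,
         pct_wins_control = pct_wins_control, pct_ties = pct_ties,
         weights = weights, counts = counts, alpha = alpha, method = method,
         problems = problems),
    class = "win_ratio_result")
}

#' @export
print.win_ratio_result <- function(x, digits = 2, ...) {
  cat("<win_ratio_result> ", x$method, "\n", sep = "")
  if (length(x$problems)) {
    cat("  problems: ", paste(x$problems, collapse = "; "), "\n", sep = "")
  }
  cat("  win ratio ", format(round(x$estimate, digits), nsmall = digits),
      if (!is.na(x$ci_lower))
        paste0(" (", 100 * (1 - x$alpha), "% CI ",
               format(round(x$ci_lower, digits), nsmall = digits), "-",
               format(round(x$ci_upper, digits), nsmall = digits), ")"),
      if (!is.na(x$p_two_sided))
        paste0(", two-sided P = ", signif(x$p_two_sided, 3)),
      "\n", sep = "")
  tab <- rbind(treated = round(x$pct_wins_treated, 2),
               control = round(x$pct_wins_control, 2))
  cat("  % wins by level (treated / control):\n")
  print(tab)
  cat("  % ties: ", round(x$pct_ties, 2), "\n", sep = "")
  invisible(x)
}

weighted_proportions <- function(counts, weights) {
  pw <- pl <- stats::setNames(numeric(4), HIER_LEVELS)
  pt <- 0
  for (k in names(counts)) {
    ck <- counts[[k]]
    np <- ck$n1 * ck$n0
    pw <- pw + weights[[k]] * ck$wins / np
    pl <- pl + weights[[k]] * ck$losses / np
    pt <- pt + weights[[k]] * ck$ties / np
  }
  list(pw = pw, pl = pl, pt = pt)
}

#' Stratified win ratio point estimate
#'
#' Combines per-stratum win and loss proportions with the supplied weights:
#' `R = sum_k w_k W_k/(n1k n0k) / sum_k w_k L_k/(n1k n0k)`.  The reported
#' per-level win percentages are the same weighted proportions times 100,
#' so the estimate equals the ratio of total win to total loss percentage.
#'
#' @param counts A `pair_counts` object from [count_pairs()].
#' @param weights Stratum weights (default [mh_weights()]).
#' @return A `win_ratio_result` carrying the point estimate and the win /
#'   loss / tie percentage decomposition (no inference; see
#'   [ustat_inference()]).
#' @export
stratified_win_ratio <- function(counts, weights = mh_weights(counts)) {
  stopifnot(inherits(counts, "pair_counts"))
  stopifnot(setequal(names(weights), names(counts)))
  p <- weighted_proportions(counts, weights)
  Pw <- sum(p$pw); Pl <- sum(p$pl)
  problems <- character()
  est <- if (Pl <= 0) {
    problems <- "zero weighted loss proportion: win ratio undefined"
    NA_real_
  } else Pw / Pl
  win_ratio_result(estimate = est,
                   pct_wins_treated = 100 * p$pw,
                   pct_wins_control = 100 * p$pl,
                   pct_ties = 100 * p$pt,
                   weights = weights, counts = counts,
                   problems = problems)
}

# Per-stratum U-statistic moments: win/loss proportions, their variances and
# covariance from the empirical variance of per-subject projection means.
stratum_umoments <- function(m) {
  n1 <- m$n1; n0 <- m$n0
  W <- m$W; L <- m$L
  theta_w <- mean(W); theta_l <- mean(L)
  rw <- rowMeans(W); cw <- colMeans(W)
  rl <- rowMeans(L); cl <- colMeans(L)
  vw <- stats::var(rw) / n1 + stats::var(cw) / n0
  vl <- stats::var(rl) / n1 + stats::var(cl) / n0
  cwl <- stats::cov(rw, rl) / n1 + stats::cov(cw, cl) / n0
  list(theta_w = theta_w, theta_l = theta_l, vw = vw, vl = vl, cwl = cwl)
}

#' Stratified win ratio with asymptotic U-statistic inference
#'
#' Computes the stratified win ratio and its log-scale standard error from
#' the two-sample U-statistic projection variances of the win and loss
#' proportions, combined across strata, with a delta-method interval on
#' `log R` and a two-sided normal p-value.
#'
#' @param data A `trial_dataset`.
#' @param rules A [comparison_rules()] object.
#' @param weights Optional stratum weights (default [mh_weights()] of the
#'   dataset's pair counts).
#' @param alpha Two-sided significance level (default 0.05, i.e. 95% CI).
#' @return A `win_ratio_result` with estimate, `se_log`, CI, two-sided p,
#'   per-level win percentages for both arms, tie percentage, and weights.
#'   If every pair is decided identically the variance is degenerate:
#'   inference fields are `NA` and a problem message is attached, but the
#'   point estimate is still returned.
#' @export
ustat_inference <- function(data, rules = comparison_rules(), weights = NULL,
                            alpha = 0.05) {
  mats <- pair_matrices(data, rules)
  counts <- counts_from_matrices(mats)
  if (is.null(weights)) weights <- mh_weights(counts)
  res <- stratified_win_ratio(counts, weights)
  if (is.na(res$estimate)) return(res)

  Pw <- sum(res$pct_wins_treated) / 100
  Pl <- sum(res$pct_wins_control) / 100
  var_pw <- var_pl <- cov_wl <- 0
  for (k in names(mats)) {
    um <- stratum_umoments(mats[[k]])
    wk <- weights[[k]]
    var_pw <- var_pw + wk^2 * um$vw
    var_pl <- var_pl + wk^2 * um$vl
    cov_wl <- cov_wl + wk^2 * um$cwl
  }
  var_log <- var_pw / Pw^2 + var_pl / Pl^2 - 2 * cov_wl / (Pw * Pl)
  if (!is.finite(var_log) || var_log <= 0) {
    res$problems <- c(res$problems,
                      "degenerate U-statistic variance: inference unavailable")
    res$alpha <- alpha
    return(res)
  }
  se <- sqrt(var_log)
  z <- stats::qnorm(1 - alpha / 2)
  lr <- log(res$estimate)
  res$se_log <- se
  res$ci_lower <- exp(lr - z * se)
  res$ci_upper <- exp(lr + z * se)
  res$p_two_sided <- 2 * stats::pnorm(-abs(lr) / se)
  res$alpha <- alpha
  res
}

#' Subset a trial dataset by subject id
#'
#' @param data A `trial_dataset`.
#' @param subject_ids Character vector of ids to keep.
#' @return A `trial_dataset` restricted to those subjects (events and visits
#'   filtered accordingly).
#' @export
subset_trial <- function(data, subject_ids) {
  stopifnot(inherits(data, "trial_dataset"))
  keep <- data$subjects$subject_id %in% subject_ids
  trial_dataset(data$subjects[keep, , drop = FALSE],
                data$events[data$events$subject_id %in% subject_ids, ,
                            drop = FALSE],
                data$visits[data$visits$subject_id %in% subject_ids, ,
                            drop = FALSE],
                horizon_days = data$horizon_days, metadata = data$metadata,
                validate = FALSE)
}

#' Per-subgroup stratified win ratios
#'
#' Computes one stratified win ratio (with inference) per subgroup, with the
#' randomization strata nested within subgroup.  No multiplicity adjustment
#' is applied.  Subgroups with an empty arm (or fewer than two patients per
#' arm) are flagged and skipped.
#'
#' @param data A `trial_dataset`.
#' @param subgroup Character/factor vector of subgroup labels, one per row of
#'   `data$subjects`, or the name of a column of `data$subjects`.
#' @param rules A [comparison_rules()] object.
#' @param alpha Two-sided significance level.
#' @return Named list of `win_ratio_result` objects (skipped subgroups
#'   absent, with a warning naming them).
#' @export
subgroup_win_ratios <- function(data, subgroup, rules = comparison_rules(),
                                alpha = 0.05) {
  s <- data$subjects
  if (is.character(subgroup) && length(subgroup) == 1 &&
      subgroup %in% names(s)) {
    subgroup <- s[[subgroup]]
  }
  stopifnot(length(subgroup) == nrow(s))
  out <- list()
  for (g in unique(as.character(subgroup))) {
    ids <- s$subject_id[as.character(subgroup) == g]
    sub <- s[s$subject_id %in% ids, , drop = FALSE]
    n_by_arm <- table(factor(sub$arm, ARM_LEVELS))
    if (any(n_by_arm < 2)) {
      warning("subgroup '", g, "' skipped: fewer than 2 patients in an arm",
              call. = FALSE)
      next
    }
    out[[g]] <- ustat_inference(subset_trial(data, ids), rules, alpha = alpha)
  }
  out
}

#' Swap the arm labels of a trial dataset
#'
#' Utility for symmetry checks: relabels treated as control and vice versa,
#' which maps the win ratio R to 1/R exactly.
#'
#' @param data A `trial_dataset`.
#' @return The relabeled `trial_dataset`.
#' @export
swap_arms <- function(data) {
  s <- data$subjects
  s$arm <- ifelse(s$arm == "treated", "control", "treated")
  trial_dataset(s, data$events, data$visits, horizon_days = data$horizon_days,
                metadata = data$metadata, validate = FALSE)
}
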