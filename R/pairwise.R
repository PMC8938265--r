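# Pairwise comparison engine for the four-level hierarchical composite:
# time to all-cause death, number of HFEs, time to first HFE, change from
# baseline in KCCQ-TSS.  All time-to-event levels are restricted to the
# common follow-up tau = min(censor_day_a, censor_day_b) of the pair, so a
# patient is never credited for events that the shorter follow-up of the
# other patient could not have observed.

PAIR_LEVELS <- c("death", "hfe_count", "hfe_first_time", "kccq", "none")

#' Comparison rules for the hierarchical composite
#'
#' @param kccq_margin Win margin delta for the KCCQ-TSS change level, in
#'   points; a between-patient difference in change of at least this margin
#'   is a win (default 5, the primary-endpoint margin).
#' @param kccq_day Day index of the KCCQ assessment (default 90).
#' @param kccq_missing How a missing day-90 KCCQ-TSS is handled when a pair
#'   reaches the KCCQ level: `"strict"` errors and directs the caller to the
#'   multiple-imputation module; `"complete_case"` scores the level as a tie
#'   (with a warning at aggregation time).
#' @return An object of class `comparison_rules`.
#' @export
comparison_rules <- function(kccq_margin = 5, kccq_day = 90,
                             kccq_missing = c("strict", "complete_case")) {
  stopifnot(is.numeric(kccq_margin), length(kccq_margin) == 1,
            kccq_margin > 0)
  structure(list(kccq_margin = kccq_margin, kccq_day = kccq_day,
                 kccq_missing = match.arg(kccq_missing)),
            class = "comparison_rules")
}

pair_result <- function(winner, level, margin = NA_real_) {
  structure(list(winner = winner, level = level, margin = margin),
            class = "pair_result")
}

#' @export
print.pair_result <- function(x, ...) {
  cat("<pair_result> winner=", x$winner, " level=", x$level,
      if (!is.na(x$margin)) paste0(" margin=", signif(x$margin, 4)), "\n",
      sep = "")
  invisible(x)
}

winner_of <- function(a_wins, b_wins, a, b) {
  if (a_wins) a$arm else if (b_wins) b$arm else "tie"
}

#' Compare two patients on time to death
#'
#' Within the common follow-up `tau = min(censor_day)`: if exactly one
#' patient died on or before `tau`, the survivor wins; if both died, the
#' later death wins; equal death days, or no death decidable within `tau`,
#' tie at this level.
#'
#' @param a,b `patient_record` objects from opposite arms.
#' @return A `pair_result` with `level = "death"` (or a tie).
#' @export
compare_death <- function(a, b) {
  tau <- min(a$censor_day, b$censor_day)
  da <- if (!is.na(a$death_day) && a$death_day <= tau) a$death_day else Inf
  db <- if (!is.na(b$death_day) && b$death_day <= tau) b$death_day else Inf
  if (da == db) return(pair_result("tie", "death"))
  pair_result(winner_of(da > db, db > da, a, b), "death",
              margin = if (is.finite(da) && is.finite(db)) da - db else NA_real_)
}

#' Compare two patients on HFE frequency
#'
#' Counts HFEs up to the earlier of the two censoring times; the patient
#' with fewer events wins; equal counts tie.
#'
#' @inheritParams compare_death
#' @return A `pair_result` with `level = "hfe_count"`.
#' @export
compare_hfe_count <- function(a, b) {
  tau <- min(a$censor_day, b$censor_day)
  na <- sum(a$hfe_days <= tau)
  nb <- sum(b$hfe_days <= tau)
  if (na == nb) return(pair_result("tie", "hfe_count"))
  pair_result(winner_of(na < nb, nb < na, a, b), "hfe_count", margin = na - nb)
}

#' Compare two patients on time to first HFE
#'
#' Within the common follow-up: if exactly one patient has a first HFE on or
#' before `tau`, that patient loses; if both do, the later first event wins;
#' same-day first events, or neither within `tau`, tie.
#'
#' @inheritParams compare_death
#' @return A `pair_result` with `level = "hfe_first_time"`.
#' @export
compare_hfe_time <- function(a, b) {
  tau <- min(a$censor_day, b$censor_day)
  fa <- if (length(a$hfe_days) && min(a$hfe_days) <= tau) min(a$hfe_days) else Inf
  fb <- if (length(b$hfe_days) && min(b$hfe_days) <= tau) min(b$hfe_days) else Inf
  if (fa == fb) return(pair_result("tie", "hfe_first_time"))
  pair_result(winner_of(fa > fb, fb > fa, a, b), "hfe_first_time",
              margin = if (is.finite(fa) && is.finite(fb)) fa - fb else NA_real_)
}

#' Compare two patients on KCCQ-TSS change from baseline
#'
#' Computes each patient's change from baseline to day 90 and declares a win
#' for the patient whose change exceeds the other's by at least the margin
#' (default 5 points, boundary inclusive); smaller differences tie.
#'
#' @inheritParams compare_death
#' @param rules A [comparison_rules()] object.
#' @return A `pair_result` with `level = "kccq"`.
#' @export
compare_kccq <- function(a, b, rules = comparison_rules()) {
  if (is.na(a$kccq_day90) || is.na(b$kccq_day90)) {
    if (rules$kccq_missing == "strict") {
      stop("missing day-90 KCCQ-TSS for pair (", a$subject_id, ", ",
           b$subject_id, "); impute first (see impute_kccq) or use ",
           "complete_case rules", call. = FALSE)
    }
    return(pair_result("tie", "kccq"))
  }
  delta <- (a$kccq_day90 - a$kccq_baseline) - (b$kccq_day90 - b$kccq_baseline)
  if (abs(delta) < rules$kccq_margin) return(pair_result("tie", "kccq"))
  pair_result(winner_of(delta > 0, delta < 0, a, b), "kccq", margin = delta)
}

#' Compare a between-arm patient pair through the full hierarchy
#'
#' Applies the four levels in order (death, HFE count, time to first HFE,
#' KCCQ-TSS change) and returns the first non-tied level; if all four tie,
#' the pair is a tie with `level = "none"`.
#'
#' @inheritParams compare_kccq
#' @return A `pair_result`.
#' @export
compare_pair <- function(a, b, rules = comparison_rules()) {
  if (a$arm == b$arm) {
    stop("compare_pair requires patients from opposite arms", call. = FALSE)
  }
  if (a$stratum != b$stratum) {
    stop("pairs are formed within strata; got ", a$stratum, " vs ",
         b$stratum, call. = FALSE)
  }
  for (f in list(compare_death, compare_hfe_count, compare_hfe_time)) {
    r <- f(a, b)
    if (r$winner != "tie") return(r)
  }
  r <- compare_kccq(a, b, rules)
  if (r$winner != "tie") return(r)
  pair_result("tie", "none")
}
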