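# Bespoke secondary endpoints: loop-diuretic dose standardization and
# diuretic response, days alive and out of hospital (DAOH), trapezoidal AUC
# of change from baseline in log NT-proBNP, and KCCQ-TSS responder status.

DIURETIC_DRUGS <- c("furosemide", "torasemide", "bumetanide")

# mg of iv-furosemide equivalent per mg of drug:
#   40 mg iv furosemide = 80 mg oral furosemide = 20 mg torasemide
#                       = 1 mg bumetanide
EQUIV_FACTOR <- list(
  furosemide = c(iv = 1, oral = 0.5),
  torasemide = c(iv = 2, oral = 2),
  bumetanide = c(iv = 40, oral = 40))

#' Convert a loop diuretic dose to iv-furosemide equivalents
#'
#' Standardizes doses so that 40 mg i.v. furosemide, 80 mg oral furosemide,
#' 20 mg torasemide and 1 mg bumetanide are all equivalent (torasemide and
#' bumetanide carry no route split).
#'
#' @param drug `"furosemide"`, `"torasemide"` or `"bumetanide"` (vectorized).
#' @param dose_mg Dose in mg (non-negative).
#' @param route `"iv"` or `"oral"`.
#' @return Dose in mg of i.v. furosemide equivalent.
#' @export
furosemide_iv_equivalents <- function(drug, dose_mg, route = "iv") {
  n <- max(length(drug), length(dose_mg), length(route))
  drug <- rep_len(as.character(drug), n)
  dose_mg <- rep_len(dose_mg, n)
  route <- rep_len(as.character(route), n)
  bad <- !drug %in% DIURETIC_DRUGS
  if (any(bad)) {
    stop("unknown loop diuretic: ", paste(unique(drug[bad]), collapse = ", "),
         call. = FALSE)
  }
  bad_r <- !route %in% c("iv", "oral")
  if (any(bad_r)) {
    stop("unknown route: ", paste(unique(route[bad_r]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(dose_mg >= 0))
  fac <- mapply(function(d, r) EQUIV_FACTOR[[d]][[r]], drug, route)
  unname(fac * dose_mg)
}

#' Diuretic response over a treatment window
#'
#' Weight change divided by the mean daily loop-diuretic dose in 40
#' mg-iv-furosemide units over the window: negative values mean weight loss
#' per unit dose.  Patients taking diuretics on at most one day of the
#' window (or with zero mean dose) are excluded.
#'
#' @param weight_change_kg Weight at window end minus baseline weight (kg).
#' @param dose_records Data frame with columns `day`, `drug` (or
#'   `loop_diuretic_drug`), `dose_mg`, `route` for doses within the window.
#' @param window_days Length of the window in days (e.g. 15 or 30).
#' @return List with `response` (kg per 40 mg unit, or `NA`), `included`
#'   (logical) and `reason` (`""` when included).
#' @export
diuretic_response <- function(weight_change_kg, dose_records, window_days) {
  stopifnot(window_days >= 1)
  dr <- as.data.frame(dose_records)
  if ("loop_diuretic_drug" %in% names(dr) && !"drug" %in% names(dr)) {
    dr$drug <- dr$loop_diuretic_drug
  }
  dr <- dr[!is.na(dr$dose_mg) & dr$dose_mg > 0, , drop = FALSE]
  days_dosed <- length(unique(dr$day))
  if (days_dosed <= 1) {
    return(list(response = NA_real_, included = FALSE,
                reason = "diuretics taken on <= 1 day in window"))
  }
  total_equiv <- sum(furosemide_iv_equivalents(dr$drug, dr$dose_mg, dr$route))
  mean_daily_units <- total_equiv / window_days / 40
  if (mean_daily_units <= 0) {
    return(list(response = NA_real_, included = FALSE,
                reason = "zero mean daily dose"))
  }
  list(response = weight_change_kg / mean_daily_units, included = TRUE,
       reason = "")
}

merge_intervals <- function(intervals) {
  if (is.null(intervals) || !nrow(intervals)) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  iv <- intervals[order(intervals$start), , drop = FALSE]
  out <- iv[1, c("start", "end"), drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      last <- nrow(out)
      if (iv$start[i] <= out$end[last]) {
        out$end[last] <- max(out$end[last], iv$end[i])
      } else {
        out <- rbind(out, iv[i, c("start", "end")])
      }
    }
  }
  out
}

#' Days alive and out of hospital
#'
#' Counts the days of a window (from study-drug initiation to a fixed end
#' day) that the patient spent alive and out of hospital.  Days from death
#' (exclusive) to the window end count as not alive; in-hospital days are
#' taken from the supplied (possibly overlapping — they are merged)
#' intervals, counted only while alive, with day-count = interval length
#' (admission day inclusive, discharge day exclusive).
#'
#' @param death_day Day of death, or `NA` if alive through the window.
#' @param hospital_intervals Data frame with columns `start`, `end` (days),
#'   or `NULL`.
#' @param window_start Day of study-drug initiation (default 0).
#' @param window_end Window end day (e.g. 90).
#' @return List with `days` and `percent`.
#' @export
days_alive_out_of_hospital <- function(death_day = NA, hospital_intervals = NULL,
                                       window_start = 0, window_end) {
  stopifnot(window_end > window_start)
  len <- window_end - window_start
  alive_end <- if (!is.na(death_day)) {
    min(max(death_day, window_start), window_end)
  } else window_end
  dead_days <- window_end - alive_end
  iv <- merge_intervals(hospital_intervals)
  hosp <- 0
  if (nrow(iv)) {
    # clip to the alive portion of the window
    s <- pmax(iv$start, window_start)
    e <- pmin(iv$end, alive_end)
    hosp <- sum(pmax(e - s, 0))
  }
  days <- len - dead_days - hosp
  days <- max(min(days, len), 0)
  list(days = days, percent = 100 * days / len)
}

#' Trapezoidal AUC of change from baseline in log NT-proBNP
#'
#' Builds the change series `c(t) = log(NTproBNP(t)) - log(baseline)` with
#' `c(0) = 0` and integrates it over `[0, through_day]` with the linear
#' trapezoidal rule (natural log).  Gaps between visits are spanned by a
#' single trapezoid; a series extending past `through_day` is linearly
#' interpolated at the boundary, and a series ending earlier is integrated
#' only to its last visit.
#'
#' @param days Visit days (sorted, positive).
#' @param ntprobnp Concentrations at those days (pg/ml, positive).
#' @param baseline_ntprobnp Baseline concentration (pg/ml, positive).
#' @param through_day Upper integration limit (default 30).
#' @return AUC in log-units x days.
#' @export
ntprobnp_log_auc <- function(days, ntprobnp, baseline_ntprobnp,
                             through_day = 30) {
  stopifnot(length(days) == length(ntprobnp), length(days) >= 1)
  keep <- !is.na(ntprobnp) & !is.na(days)
  days <- days[keep]; ntprobnp <- ntprobnp[keep]
  if (!length(days)) stop("no usable NT-proBNP visits", call. = FALSE)
  if (any(ntprobnp <= 0) || baseline_ntprobnp <= 0) {
    stop("non-positive NT-proBNP concentration: log undefined", call. = FALSE)
  }
  o <- order(days)
  days <- days[o]; ntprobnp <- ntprobnp[o]
  ch <- log(ntprobnp) - log(baseline_ntprobnp)
  t <- c(0, days)
  y <- c(0, ch)
  if (max(t) > through_day) {
    y_at <- stats::approx(t, y, xout = through_day)$y
    keep <- t < through_day
    t <- c(t[keep], through_day)
    y <- c(y[keep], y_at)
  }
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' KCCQ-TSS responder flag
#'
#' @param kccq_baseline,kccq_day90 Scores in `[0, 100]` (vectorized).
#' @param threshold Improvement threshold in points (default 10, boundary
#'   inclusive).
#' @return Logical: change from baseline `>= threshold` (`NA` when the
#'   day-90 value is missing).
#' @export
kccq_responder <- function(kccq_baseline, kccq_day90, threshold = 10) {
  (kccq_day90 - kccq_baseline) >= threshold
}

#' Per-patient secondary endpoint table
#'
#' Computes, for every patient with the necessary visit data: diuretic
#' response at the given windows, DAOH days and percent over
#' `[0, horizon]`, NT-proBNP log-AUC through day 30, and the KCCQ responder
#' flag.  Patients excluded from an endpoint carry `NA` and a reason code.
#'
#' @param data A `trial_dataset` with a populated visits table.
#' @param windows Diuretic-response windows in days (default `c(15, 30)`).
#' @param hospital_intervals Optional data frame `subject_id`, `start`,
#'   `end` of in-hospital intervals; when `NULL`, each HFE day `d` is taken
#'   as a hospitalization `[d, d + 5)` capped at the censoring day (a
#'   stated convention for data without admission records).
#' @return Data frame, one row per patient.
#' @export
secondary_endpoint_table <- function(data, windows = c(15, 30),
                                     hospital_intervals = NULL) {
  stopifnot(inherits(data, "trial_dataset"))
  s <- data$subjects
  vis <- data$visits
  out <- data.frame(subject_id = s$subject_id, arm = s$arm,
                    stratum = s$stratum, stringsAsFactors = FALSE)

  for (w in windows) {
    resp <- rep(NA_real_, nrow(s)); reason <- character(nrow(s))
    for (i in seq_len(nrow(s))) {
      vi <- vis[vis$subject_id == s$subject_id[i] & !is.na(vis$day) &
                  vis$day <= w, , drop = FALSE]
      wt <- vi$weight_kg[!is.na(vi$weight_kg)]
      base_wt <- if (length(wt)) wt[1] else NA
      end_wt <- if (length(wt)) wt[length(wt)] else NA
      if (is.na(base_wt) || is.na(end_wt) || nrow(vi) == 0) {
        reason[i] <- "no weight data in window"
        next
      }
      doses <- vi[!is.na(vi$dose_mg) & vi$dose_mg > 0, , drop = FALSE]
      r <- diuretic_response(end_wt - base_wt, doses, window_days = w)
      resp[i] <- r$response
      reason[i] <- r$reason
    }
    out[[paste0("diuretic_response_d", w)]] <- resp
    out[[paste0("diuretic_response_d", w, "_reason")]] <- reason
  }

  hosp_for <- function(id, cens) {
    if (!is.null(hospital_intervals)) {
      hospital_intervals[hospital_intervals$subject_id == id, , drop = FALSE]
    } else {
      ed <- data$events$event_day[data$events$subject_id == id]
      if (!length(ed)) return(NULL)
      data.frame(start = ed, end = pmin(ed + 5, cens))
    }
  }
  daoh_days <- daoh_pct <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    d <- days_alive_out_of_hospital(
      death_day = s$death_day[i],
      hospital_intervals = hosp_for(s$subject_id[i], s$censor_day[i]),
      window_start = 0, window_end = data$horizon_days)
    daoh_days[i] <- d$days; daoh_pct[i] <- d$percent
  }
  out$daoh_days <- daoh_days
  out$daoh_percent <- daoh_pct

  auc <- rep(NA_real_, nrow(s))
  for (i in seq_len(nrow(s))) {
    vi <- vis[vis$subject_id == s$subject_id[i] & !is.na(vis$ntprobnp_pg_ml),
              , drop = FALSE]
    base_val <- if ("cov_ntprobnp" %in% names(s)) s$cov_ntprobnp[i] else NA
    if (is.na(base_val) && nrow(vi)) {
      # fall back to the earliest visit as baseline
      base_val <- vi$ntprobnp_pg_ml[1]
      vi <- vi[-1, , drop = FALSE]
    }
    if (!is.na(base_val) && nrow(vi)) {
      auc[i] <- ntprobnp_log_auc(vi$day, vi$ntprobnp_pg_ml, base_val,
                                 through_day = 30)
    }
  }
  out$ntprobnp_log_auc_d30 <- auc
  out$kccq_responder <- kccq_responder(s$kccq_baseline, s$kccq_day90)
  out$kccq_change <- s$kccq_day90 - s$kccq_baseline
  out
}
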