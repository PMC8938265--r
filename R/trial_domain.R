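# Data model for patient-level acute heart failure trial data.
#
# A trial dataset couples three delimited tables:
#   subjects: one row per randomized patient (arm, stratum, death/censoring,
#             KCCQ-TSS at baseline and day 90, off-treatment day, covariates)
#   events:   one row per heart failure event (HFE)
#   visits:   scheduled-visit measurements (KCCQ-TSS, NT-proBNP, weight,
#             loop diuretic dosing) used by the secondary endpoints.
# Time is measured in days since randomization (day 0 = randomization).
# Death terminates follow-up: for a patient who dies, censor_day equals the
# death day, which makes the "earlier of the two censoring times" rule of the
# pairwise engine well defined with a single field.

ARM_LEVELS     <- c("treated", "control")
STRATUM_LEVELS <- c("de_novo", "decompensated")

SUBJECT_COLS <- c("subject_id", "arm", "stratum", "death_day", "censor_day",
                  "kccq_baseline", "kccq_day90", "off_treatment_day")
EVENT_COLS   <- c("subject_id", "event_day")
VISIT_COLS   <- c("subject_id", "day", "kccq_tss", "ntprobnp_pg_ml",
                  "weight_kg", "loop_diuretic_drug", "dose_mg", "route")

#' Construct a trial dataset
#'
#' Bundles the subjects, events and visits tables into a validated
#' `trial_dataset` object, the container consumed by every analysis stage.
#'
#' @param subjects Data frame with columns `subject_id`, `arm`
#'   (`"treated"`/`"control"`), `stratum` (`"de_novo"`/`"decompensated"`),
#'   `death_day` (NA if alive), `censor_day`, `kccq_baseline`, `kccq_day90`
#'   (NA if missing), `off_treatment_day` (NA if never off treatment), and
#'   optional numeric covariate columns prefixed `"cov_"`.
#' @param events Data frame with columns `subject_id`, `event_day`, one row
#'   per HFE. May be `NULL` (no events).
#' @param visits Data frame with the visit schema (see [read_trial()]), or
#'   `NULL`.
#' @param horizon_days Trial follow-up horizon in days (90 per protocol).
#' @param metadata Free-form provenance list.
#' @param validate Run [validate_trial()] (default `TRUE`).
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(subjects, events = NULL, visits = NULL,
                          horizon_days = 90, metadata = list(),
                          validate = TRUE) {
  if (is.null(events)) {
    events <- data.frame(subject_id = character(), event_day = numeric())
  }
  if (is.null(visits)) {
    visits <- empty_visits()
  }
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  events   <- as.data.frame(events, stringsAsFactors = FALSE)
  visits   <- as.data.frame(visits, stringsAsFactors = FALSE)
  x <- structure(
    list(subjects = subjects, events = events, visits = visits,
         horizon_days = horizon_days, metadata = metadata),
    class = "trial_dataset")
  if (validate) validate_trial(x)
  x
}

empty_visits <- function() {
  data.frame(subject_id = character(), day = numeric(), kccq_tss = numeric(),
             ntprobnp_pg_ml = numeric(), weight_kg = numeric(),
             loop_diuretic_drug = character(), dose_mg = numeric(),
             route = character(), stringsAsFactors = FALSE)
}

#' @export
print.trial_dataset <- function(x, ...) {
  s <- x$subjects
  cat("<trial_dataset> ", nrow(s), " patients (",
      sum(s$arm == "treated"), " treated / ",
      sum(s$arm == "control"), " control), horizon ",
      x$horizon_days, " days\n", sep = "")
  cat("  strata: ", sum(s$stratum == "de_novo"), " de_novo / ",
      sum(s$stratum == "decompensated"), " decompensated; ",
      nrow(x$events), " HFEs; ", nrow(x$visits), " visit rows\n", sep = "")
  invisible(x)
}

#' Validate a trial dataset
#'
#' Enforces the structural invariants every downstream stage relies on:
#' unique subject ids; legal arm/stratum labels; `censor_day` within
#' `[0, horizon_days]`; death implies `censor_day == death_day`; HFE days
#' strictly increasing within subject and contained in `[0, censor_day]`;
#' KCCQ scores in `[0, 100]`; event and visit rows only for known subjects.
#'
#' @param x A `trial_dataset`.
#' @return `x`, invisibly; otherwise an error listing offending subjects.
#' @export
validate_trial <- function(x) {
  stopifnot(inherits(x, "trial_dataset"))
  s <- x$subjects
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)

  missing_cols <- setdiff(SUBJECT_COLS, names(s))
  if (length(missing_cols)) {
    stop("subjects table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(x$horizon_days) || length(x$horizon_days) != 1 ||
      x$horizon_days <= 0) {
    add("horizon_days must be a single positive number")
  }
  if (anyDuplicated(s$subject_id)) {
    add(paste0("duplicated subject_id: ",
               paste(unique(s$subject_id[duplicated(s$subject_id)]),
                     collapse = ", ")))
  }
  bad_arm <- !s$arm %in% ARM_LEVELS
  if (any(bad_arm)) {
    add(paste0("invalid arm for: ",
               paste(s$subject_id[bad_arm], collapse = ", ")))
  }
  bad_str <- !s$stratum %in% STRATUM_LEVELS
  if (any(bad_str)) {
    add(paste0("invalid stratum for: ",
               paste(s$subject_id[bad_str], collapse = ", ")))
  }
  bad_cens <- is.na(s$censor_day) | s$censor_day < 0 |
    s$censor_day > x$horizon_days
  if (any(bad_cens)) {
    add(paste0("censor_day missing, negative or beyond horizon for: ",
               paste(s$subject_id[bad_cens], collapse = ", ")))
  }
  dead <- !is.na(s$death_day)
  bad_death <- dead & (s$death_day != s$censor_day)
  if (any(bad_death, na.rm = TRUE)) {
    add(paste0("death_day != censor_day (death must terminate follow-up) ",
               "for: ", paste(s$subject_id[bad_death], collapse = ", ")))
  }
  for (col in c("kccq_baseline", "kccq_day90")) {
    v <- s[[col]]
    bad <- !is.na(v) & (v < 0 | v > 100)
    if (any(bad)) {
      add(paste0(col, " outside [0,100] for: ",
                 paste(s$subject_id[bad], collapse = ", ")))
    }
  }
  bad_base <- is.na(s$kccq_baseline)
  if (any(bad_base)) {
    add(paste0("kccq_baseline missing for: ",
               paste(s$subject_id[bad_base], collapse = ", ")))
  }

  ev <- x$events
  if (nrow(ev)) {
    unknown <- !ev$subject_id %in% s$subject_id
    if (any(unknown)) {
      add(paste0("events for unknown subject_id: ",
                 paste(unique(ev$subject_id[unknown]), collapse = ", ")))
    }
    known <- ev[!unknown, , drop = FALSE]
    if (nrow(known)) {
      cens <- s$censor_day[match(known$subject_id, s$subject_id)]
      bad_day <- is.na(known$event_day) | known$event_day < 0 |
        known$event_day > cens
      if (any(bad_day)) {
        add(paste0("HFE day outside [0, censor_day] for: ",
                   paste(unique(known$subject_id[bad_day]), collapse = ", ")))
      }
      by_subj <- split(known$event_day, known$subject_id)
      nondec <- vapply(by_subj, function(d) any(diff(sort(d)) == 0) ||
                         is.unsorted(d, strictly = TRUE), logical(1))
      if (any(nondec)) {
        add(paste0("HFE days not strictly increasing for: ",
                   paste(names(by_subj)[nondec], collapse = ", ")))
      }
    }
  }
  vi <- x$visits
  if (nrow(vi)) {
    unknown <- !vi$subject_id %in% s$subject_id
    if (any(unknown)) {
      add(paste0("visits for unknown subject_id: ",
                 paste(unique(vi$subject_id[unknown]), collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("trial dataset validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(x)
}

#' Single-patient record
#'
#' A `patient_record` is the per-patient view used by the scalar pairwise
#' comparison functions: identifiers, arm, stratum, death/censoring days, the
#' ordered HFE days, KCCQ-TSS values and off-treatment day.
#'
#' @param subject_id Character id.
#' @param arm `"treated"` or `"control"`.
#' @param stratum `"de_novo"` or `"decompensated"`.
#' @param censor_day End of follow-up in days (equals `death_day` if dead).
#' @param death_day Day of death or `NA`.
#' @param hfe_days Numeric vector of HFE days, strictly increasing.
#' @param kccq_baseline,kccq_day90 KCCQ-TSS scores in `[0, 100]`
#'   (`kccq_day90` may be `NA`).
#' @param off_treatment_day Day study drug was discontinued, or `NA`.
#' @param aux_covariates Named numeric vector of baseline covariates.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(subject_id, arm, stratum, censor_day,
                           death_day = NA_real_, hfe_days = numeric(),
                           kccq_baseline = NA_real_, kccq_day90 = NA_real_,
                           off_treatment_day = NA_real_,
                           aux_covariates = numeric()) {
  structure(
    list(subject_id = as.character(subject_id), arm = match.arg(arm, ARM_LEVELS),
         stratum = match.arg(stratum, STRATUM_LEVELS),
         death_day = as.numeric(death_day), censor_day = as.numeric(censor_day),
         hfe_days = as.numeric(hfe_days),
         kccq_baseline = as.numeric(kccq_baseline),
         kccq_day90 = as.numeric(kccq_day90),
         off_treatment_day = as.numeric(off_treatment_day),
         aux_covariates = aux_covariates),
    class = "patient_record")
}

#' Split a trial dataset into patient records
#'
#' @param data A `trial_dataset`.
#' @return Named list of [patient_record()] objects (by `subject_id`).
#' @export
as_patient_records <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  s <- data$subjects
  ev <- split(data$events$event_day, data$events$subject_id)
  cov_cols <- grep("^cov_", names(s), value = TRUE)
  recs <- lapply(seq_len(nrow(s)), function(i) {
    covs <- if (length(cov_cols)) {
      stats::setNames(as.numeric(s[i, cov_cols]), cov_cols)
    } else numeric()
    patient_record(
      subject_id = s$subject_id[i], arm = s$arm[i], stratum = s$stratum[i],
      censor_day = s$censor_day[i], death_day = s$death_day[i],
      hfe_days = sort(ev[[s$subject_id[i]]]),
      kccq_baseline = s$kccq_baseline[i], kccq_day90 = s$kccq_day90[i],
      off_treatment_day = s$off_treatment_day[i], aux_covariates = covs)
  })
  stats::setNames(recs, s$subject_id)
}

read_table_checked <- function(path, required, label) {
  if (!file.exists(path)) {
    stop(label, " file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a trial dataset from delimited text files
#'
#' Reads the three comma-delimited UTF-8 tables (header row mandatory; missing
#' values as empty fields) and returns a validated [trial_dataset()].
#'
#' @param subjects_path Path to `subjects.csv`.
#' @param events_path Path to `events.csv`, or `NULL` for no events.
#' @param visits_path Path to `visits.csv`, or `NULL`.
#' @param horizon_days Follow-up horizon in days (default 90).
#' @return A validated `trial_dataset`.
#' @export
read_trial <- function(subjects_path, events_path = NULL, visits_path = NULL,
                       horizon_days = 90) {
  subjects <- read_table_checked(subjects_path, SUBJECT_COLS, "subjects")
  num_cols <- c("death_day", "censor_day", "kccq_baseline", "kccq_day90",
                "off_treatment_day", grep("^cov_", names(subjects), value = TRUE))
  for (col in num_cols) subjects[[col]] <- as.numeric(subjects[[col]])
  subjects$subject_id <- as.character(subjects$subject_id)

  events <- if (!is.null(events_path)) {
    ev <- read_table_checked(events_path, EVENT_COLS, "events")
    ev$subject_id <- as.character(ev$subject_id)
    ev$event_day <- as.numeric(ev$event_day)
    ev[order(ev$subject_id, ev$event_day), , drop = FALSE]
  } else NULL

  visits <- if (!is.null(visits_path)) {
    vi <- read_table_checked(visits_path, VISIT_COLS, "visits")
    vi$subject_id <- as.character(vi$subject_id)
    for (col in c("day", "kccq_tss", "ntprobnp_pg_ml", "weight_kg", "dose_mg"))
      vi[[col]] <- as.numeric(vi[[col]])
    vi[order(vi$subject_id, vi$day), , drop = FALSE]
  } else NULL

  trial_dataset(subjects, events, visits, horizon_days = horizon_days,
                metadata = list(source = normalizePath(subjects_path)))
}

#' Write a trial dataset to delimited text files
#'
#' Emits `subjects.csv`, `events.csv` and `visits.csv` in the documented
#' schema; missing values become empty fields.  `read_trial()` of the output
#' reproduces the dataset up to column order.
#'
#' @param data A `trial_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_trial <- function(data, out_dir) {
  stopifnot(inherits(data, "trial_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(subjects = file.path(out_dir, "subjects.csv"),
             events   = file.path(out_dir, "events.csv"),
             visits   = file.path(out_dir, "visits.csv"))
  utils::write.csv(data$subjects, paths[["subjects"]], row.names = FALSE,
                   na = "")
  utils::write.csv(data$events, paths[["events"]], row.names = FALSE, na = "")
  utils::write.csv(data$visits, paths[["visits"]], row.names = FALSE, na = "")
  invisible(paths)
}
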