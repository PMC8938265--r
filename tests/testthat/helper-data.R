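# Fixture builders used across the suite.  Small random trials use integer
# days and coarse scores on purpose, so equal-day and equal-score ties occur
# often and exercise every branch of the hierarchy.

fixture_path <- function(file) {
  system.file("extdata", "fixture_trial", file, package = "hierwin")
}

read_fixture_trial <- function() {
  read_trial(fixture_path("subjects.csv"), fixture_path("events.csv"),
             fixture_path("visits.csv"))
}

make_subject <- function(id, arm, stratum = "de_novo", censor = 90,
                         death = NA, base = 50, day90 = 60, off = NA) {
  data.frame(subject_id = id, arm = arm, stratum = stratum,
             death_day = death, censor_day = censor, kccq_baseline = base,
             kccq_day90 = day90, off_treatment_day = off,
             stringsAsFactors = FALSE)
}

# Random small trial (<= max_per_arm per arm) with integer days.
random_small_trial <- function(seed, max_per_arm = 8, p_missing = 0.1) {
  set.seed(seed)
  n1 <- sample(1:max_per_arm, 1)
  n0 <- sample(1:max_per_arm, 1)
  n <- n1 + n0
  arm <- c(rep("treated", n1), rep("control", n0))
  stratum <- sample(c("de_novo", "decompensated"), n, replace = TRUE)
  stratum[c(1, n1 + 1)] <- "de_novo"  # at least one stratum with both arms
  censor <- sample(5:90, n, replace = TRUE)
  dead <- runif(n) < 0.25
  death_day <- ifelse(dead, pmax(1, round(censor * runif(n))), NA)
  censor <- ifelse(dead, death_day, censor)
  base <- sample(20:80, n, replace = TRUE)
  day90 <- pmin(pmax(base + sample(-20:40, n, replace = TRUE), 0), 100)
  day90[runif(n) < p_missing] <- NA
  subjects <- data.frame(
    subject_id = sprintf("P%02d", seq_len(n)), arm = arm, stratum = stratum,
    death_day = death_day, censor_day = censor, kccq_baseline = base,
    kccq_day90 = day90, off_treatment_day = NA_real_,
    stringsAsFactors = FALSE)
  ev <- lapply(seq_len(n), function(i) {
    k <- min(rpois(1, 0.8), censor[i])
    if (k == 0) return(NULL)
    data.frame(subject_id = subjects$subject_id[i],
               event_day = sort(sample(0:censor[i], k)))
  })
  events <- do.call(rbind, ev)
  trial_dataset(subjects, events, horizon_days = 90)
}

cc_rules <- function(margin = 5) {
  comparison_rules(kccq_margin = margin, kccq_missing = "complete_case")
}
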