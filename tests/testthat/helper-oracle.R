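# Independent brute-force pair enumerator, written as plain nested
# conditionals straight from the endpoint definition.  Deliberately shares
# no code with the package's matrix-based engine: it is the oracle the
# engine is checked against.

brute_pair <- function(sa, ea, sb, eb, margin = 5) {
  # sa/sb: one-row subject data frames; ea/eb: sorted event-day vectors.
  # Returns list(outcome = +1 (a wins) / -1 / 0, level = 1..5).
  tau <- min(sa$censor_day, sb$censor_day)

  a_dead <- !is.na(sa$death_day) && sa$death_day <= tau
  b_dead <- !is.na(sb$death_day) && sb$death_day <= tau
  if (a_dead && !b_dead) return(list(outcome = -1, level = 1L))
  if (!a_dead && b_dead) return(list(outcome = +1, level = 1L))
  if (a_dead && b_dead) {
    if (sa$death_day > sb$death_day) return(list(outcome = +1, level = 1L))
    if (sb$death_day > sa$death_day) return(list(outcome = -1, level = 1L))
  }

  ca <- length(ea[ea <= tau]); cb <- length(eb[eb <= tau])
  if (ca < cb) return(list(outcome = +1, level = 2L))
  if (cb < ca) return(list(outcome = -1, level = 2L))

  fa <- if (ca > 0) ea[ea <= tau][1] else NA
  fb <- if (cb > 0) eb[eb <= tau][1] else NA
  if (!is.na(fa) && !is.na(fb)) {
    if (fa > fb) return(list(outcome = +1, level = 3L))
    if (fb > fa) return(list(outcome = -1, level = 3L))
  } else if (!is.na(fa)) {
    return(list(outcome = -1, level = 3L))
  } else if (!is.na(fb)) {
    return(list(outcome = +1, level = 3L))
  }

  if (!is.na(sa$kccq_day90) && !is.na(sb$kccq_day90)) {
    da <- sa$kccq_day90 - sa$kccq_baseline
    db <- sb$kccq_day90 - sb$kccq_baseline
    if (da - db >= margin) return(list(outcome = +1, level = 4L))
    if (db - da >= margin) return(list(outcome = -1, level = 4L))
  }
  list(outcome = 0, level = 5L)
}

# Per-stratum win/loss/tie tallies by exhaustive double loop.
brute_counts <- function(data, margin = 5) {
  s <- data$subjects
  ev <- data$events
  out <- list()
  for (k in c("de_novo", "decompensated")) {
    trows <- which(s$stratum == k & s$arm == "treated")
    crows <- which(s$stratum == k & s$arm == "control")
    if (!length(trows) || !length(crows)) next
    wins <- losses <- rep(0, 4)
    ties <- 0
    for (i in trows) {
      ea <- sort(ev$event_day[ev$subject_id == s$subject_id[i]])
      for (j in crows) {
        eb <- sort(ev$event_day[ev$subject_id == s$subject_id[j]])
        r <- brute_pair(s[i, ], ea, s[j, ], eb, margin)
        if (r$outcome == +1) wins[r$level] <- wins[r$level] + 1
        else if (r$outcome == -1) losses[r$level] <- losses[r$level] + 1
        else ties <- ties + 1
      }
    }
    names(wins) <- names(losses) <-
      c("death", "hfe_count", "hfe_first_time", "kccq")
    out[[k]] <- list(n1 = length(trows), n0 = length(crows),
                     wins = wins, losses = losses, ties = ties)
  }
  out
}
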