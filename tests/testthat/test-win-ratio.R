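pc <- function(...) structure(list(...), class = "pair_counts")
stratum_counts <- function(n1, n0, wins, losses, ties) {
  names(wins) <- names(losses) <-
    c("death", "hfe_count", "hfe_first_time", "kccq")
  list(n1 = n1, n0 = n0, wins = wins, losses = losses, ties = ties)
}

test_that("count_pairs matches hand traces and conserves pairs", {
  # 1 vs 1 identical records: one tie
  s <- rbind(make_subject("A", "treated"), make_subject("B", "control"))
  cnt <- count_pairs(trial_dataset(s), cc_rules())
  expect_equal(cnt$de_novo$ties, 1)
  expect_equal(sum(cnt$de_novo$wins) + sum(cnt$de_novo$losses), 0)

  # 2x2 worked set from the pairwise hand trace
  s2 <- rbind(
    make_subject("A1", "treated", base = 40, day90 = 60),
    make_subject("A2", "treated", censor = 80, death = 80, base = 30,
                 day90 = 35),
    make_subject("B1", "control", base = 50, day90 = 58),
    make_subject("B2", "control", censor = 70, death = 70, base = 60,
                 day90 = 55))
  ev2 <- data.frame(subject_id = c("A2", "B1", "B2", "B2"),
                    event_day = c(50, 50, 20, 60))
  cnt2 <- count_pairs(trial_dataset(s2, ev2), cc_rules())
  expect_equal(cnt2$de_novo$wins,
               c(death = 2, hfe_count = 1, hfe_first_time = 0, kccq = 0))
  expect_equal(cnt2$de_novo$losses,
               c(death = 1, hfe_count = 0, hfe_first_time = 0, kccq = 0))
  expect_equal(cnt2$de_novo$ties, 0)

  # conservation on a random 10x10 stratum
  d <- generate_trial(trial_config(n_per_arm = 10, p_de_novo = 0,
                                   seed = 5))
  cnt3 <- suppressWarnings(count_pairs(d, cc_rules()))
  expect_equal(sum(cnt3$decompensated$wins) +
                 sum(cnt3$decompensated$losses) + cnt3$decompensated$ties,
               100)
})

test_that("count_pairs agrees with the scalar engine", {
  for (seed in c(101, 102, 103, 104)) {
    d <- random_small_trial(seed, p_missing = 0.15)
    cnt <- suppressWarnings(count_pairs(d, cc_rules()))
    recs <- as_patient_records(d)
    for (k in names(cnt)) {
      wins <- losses <- stats::setNames(rep(0, 4), names(cnt[[k]]$wins))
      ties <- 0
      for (a in recs) {
        if (a$arm != "treated" || a$stratum != k) next
        for (b in recs) {
          if (b$arm != "control" || b$stratum != k) next
          r <- suppressWarnings(compare_pair(a, b, cc_rules()))
          if (r$winner == "treated") wins[r$level] <- wins[r$level] + 1
          else if (r$winner == "control") losses[r$level] <- losses[r$level] + 1
          else ties <- ties + 1
        }
      }
      expect_equal(cnt[[k]]$wins, wins)
      expect_equal(cnt[[k]]$losses, losses)
      expect_equal(cnt[[k]]$ties, ties)
    }
  }
})

test_that("Mantel-Haenszel-analogous weights", {
  one <- pc(de_novo = stratum_counts(3, 4, rep(1, 4), rep(1, 4), 4))
  expect_equal(unname(mh_weights(one)), 1)

  two <- pc(de_novo = stratum_counts(2, 2, rep(0, 4), rep(0, 4), 4),
            decompensated = stratum_counts(2, 2, rep(0, 4), rep(0, 4), 4))
  expect_equal(unname(mh_weights(two)), c(0.5, 0.5))

  # (100,100) and (50,50): raw weights 50 and 25 -> 2/3, 1/3
  big <- pc(de_novo = stratum_counts(100, 100, rep(0, 4), rep(0, 4), 1e4),
            decompensated = stratum_counts(50, 50, rep(0, 4), rep(0, 4),
                                           2500))
  expect_equal(unname(mh_weights(big)), c(2 / 3, 1 / 3))
})

test_that("stratified point estimate and decomposition", {
  # W = L in every stratum -> R = 1
  eq <- pc(de_novo = stratum_counts(2, 5, c(2, 1, 0, 1), c(1, 1, 1, 1), 2),
           decompensated = stratum_counts(3, 3, c(1, 0, 1, 1), c(2, 1, 0, 0),
                                          3))
  expect_equal(stratified_win_ratio(eq)$estimate, 1)

  # single stratum, W=6, L=3, T=1 over 10 pairs -> R = 2, ties 10%
  single <- pc(de_novo = stratum_counts(2, 5, c(3, 2, 0, 1), c(2, 0, 0, 1),
                                        1))
  r <- stratified_win_ratio(single)
  expect_equal(r$estimate, 2)
  expect_equal(r$pct_ties, 10)
  expect_equal(sum(r$pct_wins_treated), 60)

  # identical counts in both strata: stratified equals unstratified
  dup <- pc(de_novo = stratum_counts(4, 5, c(5, 2, 1, 2), c(3, 1, 0, 2), 4),
            decompensated = stratum_counts(4, 5, c(5, 2, 1, 2),
                                           c(3, 1, 0, 2), 4))
  expect_equal(stratified_win_ratio(dup)$estimate, 10 / 6)

  # zero losses: error object, not infinity
  zl <- pc(de_novo = stratum_counts(1, 2, c(2, 0, 0, 0), rep(0, 4), 0))
  r0 <- stratified_win_ratio(zl)
  expect_true(is.na(r0$estimate))
  expect_match(r0$problems, "undefined")
})

test_that("U-statistic inference returns a coherent result", {
  d <- generate_trial(trial_config(n_per_arm = 80, seed = 31))
  res <- suppressWarnings(ustat_inference(d, cc_rules()))
  expect_true(res$ci_lower <= res$estimate && res$estimate <= res$ci_upper)
  expect_gt(res$se_log, 0)
  expect_true(res$p_two_sided > 0 && res$p_two_sided < 1)
  expect_equal(sum(res$pct_wins_treated) + sum(res$pct_wins_control) +
                 res$pct_ties, 100, tolerance = 1e-10)
  # estimate equals ratio of weighted win to loss percentages
  expect_equal(res$estimate,
               sum(res$pct_wins_treated) / sum(res$pct_wins_control),
               tolerance = 1e-12)

  # degenerate projections: a single control makes var(col means)
  # inestimable, so the point estimate survives without inference
  s <- rbind(make_subject("A1", "treated", day90 = 90, base = 20),
             make_subject("A2", "treated", day90 = 25, base = 20),
             make_subject("B1", "control", day90 = 55, base = 20))
  rd <- ustat_inference(trial_dataset(s), cc_rules())
  expect_false(is.na(rd$estimate))
  expect_match(paste(rd$problems, collapse = " "), "degenerate")
})

test_that("arm swap maps R to 1/R and preserves ties exactly", {
  for (seed in 301:310) {
    d <- random_small_trial(seed, p_missing = 0)
    r1 <- suppressWarnings(ustat_inference(d, cc_rules()))
    r2 <- suppressWarnings(ustat_inference(swap_arms(d), cc_rules()))
    if (is.na(r1$estimate) || is.na(r2$estimate) || r1$estimate == 0 ||
        r2$estimate == 0) next  # one-sided dataset: R or 1/R undefined
    expect_equal(r2$estimate, 1 / r1$estimate, tolerance = 1e-12)
    expect_equal(r2$pct_wins_treated, r1$pct_wins_control)
    expect_equal(r2$pct_ties, r1$pct_ties)
    if (!is.na(r1$se_log) && !is.na(r2$se_log)) {
      expect_equal(r2$se_log, r1$se_log, tolerance = 1e-10)
    }
  }
})

test_that("improving a treated patient's outcome never decreases R", {
  base_cfg <- trial_config(n_per_arm = 25, seed = 77)
  d <- generate_trial(base_cfg, visits = FALSE)
  r0 <- suppressWarnings(ustat_inference(d, cc_rules()))$estimate

  # raise one treated patient's day-90 KCCQ to the maximum
  d_k <- d
  i <- which(d_k$subjects$arm == "treated" &
               !is.na(d_k$subjects$kccq_day90))[1]
  d_k$subjects$kccq_day90[i] <- 100
  expect_gte(suppressWarnings(ustat_inference(d_k, cc_rules()))$estimate, r0)

  # remove one treated patient's HFEs
  d_e <- d
  tid <- intersect(d_e$subjects$subject_id[d_e$subjects$arm == "treated"],
                   d_e$events$subject_id)[1]
  d_e$events <- d_e$events[d_e$events$subject_id != tid, , drop = FALSE]
  expect_gte(suppressWarnings(ustat_inference(d_e, cc_rules()))$estimate, r0)

  # resurrect one treated death (censored at horizon instead)
  d_d <- d
  j <- which(d_d$subjects$arm == "treated" &
               !is.na(d_d$subjects$death_day))[1]
  if (!is.na(j)) {
    d_d$subjects$death_day[j] <- NA
    d_d$subjects$censor_day[j] <- d_d$horizon_days
    expect_gte(suppressWarnings(ustat_inference(d_d, cc_rules()))$estimate,
               r0)
  }
})

test_that("subgroup analyses reduce to the primary result and skip tiny groups", {
  d <- generate_trial(trial_config(n_per_arm = 40, seed = 9))
  full <- suppressWarnings(ustat_inference(d, cc_rules()))
  sg <- suppressWarnings(
    subgroup_win_ratios(d, rep("all", nrow(d$subjects)), cc_rules()))
  expect_equal(sg$all$estimate, full$estimate)
  expect_equal(sg$all$se_log, full$se_log)

  labels <- rep("big", nrow(d$subjects))
  labels[1] <- "lonely"
  w <- capture_warnings(sg2 <- subgroup_win_ratios(d, labels, cc_rules()))
  expect_true(any(grepl("lonely", w)))
  expect_named(sg2, "big")
})
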