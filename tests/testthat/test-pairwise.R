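rec <- function(id = "x", arm = "treated", stratum = "de_novo", censor = 90,
                death = NA, hfe = numeric(), base = 50, day90 = 60) {
  patient_record(id, arm, stratum, censor_day = censor, death_day = death,
                 hfe_days = hfe, kccq_baseline = base, kccq_day90 = day90)
}

test_that("death level follows the common-follow-up rule", {
  a <- rec("a", "treated", censor = 10, death = 10)
  b <- rec("b", "control", censor = 90)
  r <- compare_death(a, b)
  expect_equal(r$winner, "control")
  expect_equal(r$level, "death")

  # death outside the common follow-up is a tie at this level
  a2 <- rec("a", "treated", censor = 50, death = 50)
  b2 <- rec("b", "control", censor = 30)
  expect_equal(compare_death(a2, b2)$winner, "tie")

  # equal death days tie; both dead, later death wins
  expect_equal(compare_death(rec(censor = 20, death = 20),
                             rec(arm = "control", censor = 20,
                                 death = 20))$winner, "tie")
  r2 <- compare_death(rec(censor = 40, death = 40),
                      rec(arm = "control", censor = 20, death = 20))
  expect_equal(r2$winner, "treated")
})

test_that("HFE count level counts events up to the earlier censoring time", {
  a <- rec("a", hfe = c(5, 40))
  b <- rec("b", "control")
  expect_equal(compare_hfe_count(a, b)$winner, "control")

  # tau = 60 leaves one event each: tie (hand-traced)
  a2 <- rec("a", hfe = c(5, 80), censor = 90)
  b2 <- rec("b", "control", hfe = 10, censor = 60)
  expect_equal(compare_hfe_count(a2, b2)$winner, "tie")
  expect_equal(compare_hfe_count(rec(), rec(arm = "control"))$winner, "tie")
})

test_that("first-HFE level: earlier event within common follow-up loses", {
  a <- rec("a", hfe = 12)
  b <- rec("b", "control", hfe = 30)
  expect_equal(compare_hfe_time(a, b)$winner, "control")

  # event after the other patient's censoring cannot decide
  a2 <- rec("a", hfe = 70)
  b2 <- rec("b", "control", censor = 60)
  expect_equal(compare_hfe_time(a2, b2)$winner, "tie")
  expect_equal(compare_hfe_time(rec(), rec(arm = "control"))$winner, "tie")
})

test_that("KCCQ level wins on a 5-point-or-greater change difference", {
  mk <- function(arm, change) rec(arm = arm, base = 40, day90 = 40 + change)
  # boundary inclusive at exactly 5
  expect_equal(compare_kccq(mk("treated", 30), mk("control", 25))$winner,
               "treated")
  expect_equal(compare_kccq(mk("treated", 30), mk("control", 25.1))$winner,
               "tie")
  expect_equal(compare_kccq(mk("treated", 0), mk("control", 10))$winner,
               "control")
  # strict mode refuses missing day-90 values
  miss <- rec(arm = "control", day90 = NA)
  expect_error(compare_kccq(rec(), miss), "impute")
  expect_equal(
    compare_kccq(rec(), miss, cc_rules())$winner, "tie")
})

test_that("compare_pair applies the hierarchy and validates the pair", {
  a <- rec("a", "treated")
  expect_error(compare_pair(a, rec("b", "treated")), "opposite arms")
  expect_error(compare_pair(a, rec("b", "control",
                                   stratum = "decompensated")),
               "within strata")

  # identical records except arm tie at level none
  r <- compare_pair(a, rec("b", "control"))
  expect_equal(r$winner, "tie")
  expect_equal(r$level, "none")

  # hierarchy precedence: death trumps any number of HFEs
  dead <- rec("a", "treated", censor = 10, death = 10)
  eventful <- rec("b", "control", hfe = c(3, 5, 7))
  r2 <- compare_pair(dead, eventful)
  expect_equal(r2$winner, "control")
  expect_equal(r2$level, "death")
})

test_that("4-patient worked set matches the hand-enumerated table", {
  a1 <- rec("A1", "treated", base = 40, day90 = 60)
  a2 <- rec("A2", "treated", censor = 80, death = 80, hfe = 50,
            base = 30, day90 = 35)
  b1 <- rec("B1", "control", hfe = 50, base = 50, day90 = 58)
  b2 <- rec("B2", "control", censor = 70, death = 70, hfe = c(20, 60),
            base = 60, day90 = 55)
  # hand trace: A1B1 count 0 vs 1; A1B2 death within tau=70;
  # A2B1 A2's death at 80 <= tau=80; A2B2 tau=70 hides A2's death
  expect_equal(compare_pair(a1, b1)[c("winner", "level")],
               list(winner = "treated", level = "hfe_count"))
  expect_equal(compare_pair(a1, b2)[c("winner", "level")],
               list(winner = "treated", level = "death"))
  expect_equal(compare_pair(a2, b1)[c("winner", "level")],
               list(winner = "control", level = "death"))
  expect_equal(compare_pair(a2, b2)[c("winner", "level")],
               list(winner = "treated", level = "death"))
})

test_that("antisymmetry and precedence hold over random pairs", {
  for (seed in 1:60) {
    d <- random_small_trial(seed, max_per_arm = 2, p_missing = 0)
    recs <- as_patient_records(d)
    arms <- vapply(recs, `[[`, character(1), "arm")
    strs <- vapply(recs, `[[`, character(1), "stratum")
    for (i in which(arms == "treated")) {
      for (j in which(arms == "control")) {
        if (strs[i] != strs[j]) next
        ab <- compare_pair(recs[[i]], recs[[j]])
        ba <- compare_pair(recs[[j]], recs[[i]])
        expect_identical(ab$level, ba$level)
        expect_identical(ab$winner, ba$winner)  # winner named by arm
        d1 <- compare_death(recs[[i]], recs[[j]])
        if (d1$winner != "tie") expect_identical(ab$level, "death")
      }
    }
  }
})
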