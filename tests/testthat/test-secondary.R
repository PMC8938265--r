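test_that("loop diuretic equivalence constants", {
  expect_equal(furosemide_iv_equivalents("torasemide", 20), 40)
  expect_equal(furosemide_iv_equivalents("furosemide", 80, "oral"), 40)
  expect_equal(furosemide_iv_equivalents("bumetanide", 1), 40)
  expect_equal(furosemide_iv_equivalents("furosemide", 40, "iv"), 40)
  expect_error(furosemide_iv_equivalents("metolazone", 5), "unknown")

  # consistent ring: torasemide -> furosemide-equivalent -> bumetanide
  # equals the direct conversion for arbitrary doses
  doses <- c(5, 12.5, 20, 37)
  via_furo <- furosemide_iv_equivalents("torasemide", doses) / 40  # units
  expect_equal(via_furo * 40,
               furosemide_iv_equivalents("bumetanide", via_furo * 1))
})

test_that("diuretic response normalizes by mean daily 40 mg units", {
  daily <- function(days, drug, dose, route = "iv") {
    data.frame(day = days, drug = drug, dose_mg = dose, route = route)
  }
  # constant 40 mg iv furosemide daily for 15 days, -2 kg
  r <- diuretic_response(-2, daily(1:15, "furosemide", 40), 15)
  expect_true(r$included)
  expect_equal(r$response, -2)

  # mean daily 80 mg equivalents = 2 units
  r2 <- diuretic_response(-3, daily(1:15, "furosemide", 80), 15)
  expect_equal(r2$response, -1.5)

  # route and drug mixtures convert before averaging
  mix <- rbind(daily(1:10, "furosemide", 80, "oral"),
               daily(11:15, "torasemide", 20, "oral"))
  r3 <- diuretic_response(-2, mix, 15)
  expect_equal(r3$response, -2 / ((10 * 40 + 5 * 40) / 15 / 40))

  # exclusion: diuretics on only one day
  r4 <- diuretic_response(-2, daily(3, "furosemide", 40), 15)
  expect_false(r4$included)
  expect_match(r4$reason, "1 day")
})

test_that("days alive and out of hospital interval arithmetic", {
  # alive, never rehospitalized
  d <- days_alive_out_of_hospital(NA, NULL, 0, 90)
  expect_equal(d$days, 90)
  expect_equal(d$percent, 100)

  # dies day 45 of 90, in hospital days 0-5
  d2 <- days_alive_out_of_hospital(45, data.frame(start = 0, end = 5),
                                   0, 90)
  expect_equal(d2$days, 40)

  # hospitalized for the entire window
  d3 <- days_alive_out_of_hospital(NA, data.frame(start = 0, end = 90),
                                   0, 90)
  expect_equal(d3$days, 0)
  expect_equal(d3$percent, 0)

  # overlapping intervals merge rather than double count
  d4 <- days_alive_out_of_hospital(
    NA, data.frame(start = c(10, 15, 40), end = c(20, 25, 45)), 0, 90)
  expect_equal(d4$days, 90 - 15 - 5)

  # bounds hold over random cases
  set.seed(1)
  for (i in 1:50) {
    k <- sample(0:3, 1)
    iv <- if (k) data.frame(start = runif(k, 0, 85),
                            end = runif(k, 0, 90)) else NULL
    if (!is.null(iv)) iv$end <- pmax(iv$end, iv$start)
    dd <- days_alive_out_of_hospital(
      if (runif(1) < 0.3) runif(1, 0, 90) else NA, iv, 0, 90)
    expect_gte(dd$days, 0)
    expect_lte(dd$days, 90)
    expect_true(dd$percent >= 0 && dd$percent <= 100)
  }
})

test_that("log NT-proBNP change AUC matches closed forms", {
  base <- 2000
  conc <- function(ch) base * exp(ch)
  # constant change at all visits (including day 0) -> 30 * c
  expect_equal(
    ntprobnp_log_auc(c(0, 10, 20, 30), conc(rep(0.3, 4)), base), 9)
  # single visit at day 30: triangle from c(0) = 0
  expect_equal(ntprobnp_log_auc(30, conc(-0.4), base), -6)
  # two visits, hand trapezoid: -0.2*5/2 + (-0.2 - 0.4)/2 * 25 = -8
  expect_equal(
    ntprobnp_log_auc(c(5, 30), conc(c(-0.2, -0.4)), base), -8)
  # series past day 30 is interpolated at the boundary
  expect_equal(
    ntprobnp_log_auc(c(15, 45), conc(c(0.2, 0.2)), base),
    0.2 * 15 / 2 + 0.2 * 15)
  expect_error(ntprobnp_log_auc(10, 0, base), "non-positive")
  expect_error(ntprobnp_log_auc(10, 500, 0), "non-positive")

  # linear in the change series
  c1 <- c(-0.1, -0.3); c2 <- c(0.2, 0.05); days <- c(10, 30)
  a1 <- ntprobnp_log_auc(days, conc(c1), base)
  a2 <- ntprobnp_log_auc(days, conc(c2), base)
  a12 <- ntprobnp_log_auc(days, conc(c1 + c2), base)
  expect_equal(a12, a1 + a2, tolerance = 1e-12)
})

test_that("KCCQ responder threshold is boundary inclusive", {
  expect_true(kccq_responder(40, 50))
  expect_false(kccq_responder(40, 49.9))
  expect_false(kccq_responder(40, 35))
  expect_true(is.na(kccq_responder(40, NA)))
})

test_that("per-patient endpoint table on the packaged fixture", {
  d <- read_fixture_trial()
  tab <- secondary_endpoint_table(d)
  expect_equal(nrow(tab), 6)
  t1 <- tab[tab$subject_id == "T1", ]
  # T1: weights 84 -> 82 by day 15; doses 40 iv + 40 oral + 80 oral
  equiv <- 40 + 20 + 40
  expect_equal(t1$diuretic_response_d15, -2 / (equiv / 15 / 40))
  expect_equal(t1$daoh_days, 90)
  expect_false(is.na(t1$ntprobnp_log_auc_d30))
  expect_true(t1$kccq_responder)
  # C3 died at day 60: DAOH 60 of 90
  expect_equal(tab$daoh_days[tab$subject_id == "C3"], 60)
  # T2 dosed on only 2 visit days at day 15 window -> excluded at d15
  expect_true(is.na(tab$diuretic_response_d15[tab$subject_id == "T2"]))
})
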