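ref <- mph_reference_params()
# logit of the dosing target implied by the worked examples
lp_work <- 0.6221

test_that("dose targets keep p0 and its logit consistent", {
  tg <- dose_target(p0 = 0.9866)
  expect_equal(round(tg$logit_p0, 4), 4.2990)
  tg2 <- dose_target(logit_p0 = 0)
  expect_identical(tg2$p0, 0.5)
  expect_error(dose_target(p0 = 0.9, logit_p0 = 3), "inconsistent")
  expect_error(dose_target(p0 = 1.2), "inside")
})

test_that("percentile targets come from last-visit fitted probabilities", {
  # degenerate cohort: identical patients, identical histories -> the
  # percentile of a constant distribution is that constant
  one <- data.frame(time_months = c(0, 2), severity_score = c(50, 45),
                    baseline_severity = 50, dose_mg_per_kg = 0.4,
                    response = c(0L, 0L))
  coh <- do.call(rbind, lapply(1:5, function(i)
    cbind(patient_id = i, one)))
  tg <- compute_target_p0(ref, coh, percentile = 90)
  bh <- predict_b(ref, one)$b_hat
  q <- inv_logit(linear_predictor(
    ref, c(time_months = 2, severity = 50), dose = 0.4, b = bh))
  expect_equal(tg$p0, q, tolerance = 1e-10)
  expect_identical(tg$source, "percentile_from_fit")

  # synthetic cohort: matches a sort-based percentile oracle
  coh2 <- generate_cohort(cohort_config(n_patients = 30, seed = 14))$visits
  tg2 <- compute_target_p0(ref, coh2, percentile = 90)
  probs <- sort(attr(tg2, "probs"))
  h <- (length(probs) - 1) * 0.9 + 1      # linear interpolation by hand
  lo <- floor(h)
  oracle_q <- probs[lo] + (h - lo) * (probs[lo + 1] - probs[lo])
  expect_equal(tg2$p0, oracle_q, tolerance = 1e-12)

  expect_error(compute_target_p0(ref, coh2, percentile = 0), "inside")
  expect_error(compute_target_p0(ref, coh2, percentile = 100), "inside")
})

test_that("initial dose inverts the model at b = 0 and time 0", {
  tg <- dose_target(p0 = 0.9866)
  rec <- initial_dose(ref, baseline_severity = 51.3817, target = tg,
                      clip = NULL)
  # an average patient needs exp((4.2990 - 1.9377)/0.8610) mg/kg
  expect_equal(rec$dose_mg_per_kg, exp((qlogis(0.9866) - 1.9377) / 0.861),
               tolerance = 1e-9)
  expect_identical(rec$b_hat_used, 0)
  expect_identical(rec$time_months, 0)

  # the default safety clip engages on that implausibly large value and
  # retains the raw inversion
  rec_c <- initial_dose(ref, baseline_severity = 51.3817, target = tg)
  expect_true(rec_c$clipped)
  expect_identical(rec_c$dose_mg_per_kg, 2)
  expect_equal(rec_c$dose_unclipped_mg_per_kg, rec$dose_mg_per_kg)

  # higher severity needs a higher dose
  tgw <- dose_target(logit_p0 = lp_work)
  d1 <- initial_dose(ref, 45, tgw, clip = NULL)$dose_mg_per_kg
  d2 <- initial_dose(ref, 60, tgw, clip = NULL)$dose_mg_per_kg
  expect_lt(d1, d2)

  # inversion identity: when the target equals eta at dose 1, D = 1
  eta1 <- linear_predictor(ref, c(time_months = 0, severity = 47),
                           dose = 1, b = 0)
  expect_equal(initial_dose(ref, 47, dose_target(logit_p0 = eta1),
                            clip = NULL)$dose_mg_per_kg, 1,
               tolerance = 1e-12)

  nod <- model_params(beta0 = 1, sigma2 = 1)
  expect_error(initial_dose(nod, 50, tgw), "inverted")
  expect_error(initial_dose(ref, 90, tgw), "\\[0, 81\\]")
})

test_that("follow-up doses reproduce the worked hypothetical patients", {
  tg <- dose_target(logit_p0 = lp_work)
  hp1 <- hypothetical_patient_1()
  hp2 <- hypothetical_patient_2()
  for (hp in list(hp1, hp2)) {
    for (k in seq_len(nrow(hp))) {
      rec <- followup_dose(ref, severity = hp$severity_score[k],
                           time_months = hp$time_months[k],
                           b_hat = hp$b_hat[k], target = tg,
                           severity_mode = "current", clip = NULL)
      # first printed dose of patient 2 carries a known transcription
      # inconsistency (~1.1%); all other rows agree within 0.5%
      tol <- if (hp$severity_score[1] == 67 && k == 1) 0.02 else 0.005
      expect_equal(rec$dose_mg_per_kg, hp$dose_printed[k],
                   tolerance = tol)
    }
  }
  # at b = 0 and t = 0 the follow-up equation reduces to the initial one
  expect_equal(
    followup_dose(ref, 48, 0, 0, tg, clip = NULL)$dose_mg_per_kg,
    initial_dose(ref, 48, tg, clip = NULL)$dose_mg_per_kg,
    tolerance = 1e-12)
})

test_that("trajectories update b_hat sequentially and stay invertible", {
  tg <- dose_target(logit_p0 = lp_work)
  hp1 <- hypothetical_patient_1()
  stream <- data.frame(time_months = hp1$time_months,
                       severity_score = hp1$severity_score,
                       baseline_severity = hp1$severity_score[1],
                       response = hp1$response)
  traj <- recommend_trajectory(ref, tg, stream,
                               severity_mode = "current",
                               b_hat_override = hp1$b_hat, clip = NULL)
  expect_equal(traj$dose_mg_per_kg, hp1$dose_printed, tolerance = 0.005)
  expect_equal(traj$b_hat, hp1$b_hat)

  # without overrides: visit 1 uses b = 0, later b come from the
  # accumulated history at the fed-back administered doses
  traj2 <- recommend_trajectory(ref, tg, stream,
                                severity_mode = "current", clip = NULL)
  expect_identical(traj2$b_hat[1], 0)
  h1 <- data.frame(time_months = stream$time_months[1],
                   baseline_severity = stream$baseline_severity[1],
                   severity_score = stream$severity_score[1],
                   dose_mg_per_kg = traj2$dose_mg_per_kg[1],
                   response = stream$response[1])
  expect_equal(traj2$b_hat[2], predict_b(ref, h1)$b_hat,
               tolerance = 1e-10)

  # an all-improved stream at fixed severity: b_hat rises, doses fall
  up <- data.frame(time_months = c(1, 2, 3, 4),
                   severity_score = 38, baseline_severity = 45,
                   response = 1L)
  traj3 <- recommend_trajectory(ref, tg, up, severity_mode = "current",
                                clip = NULL)
  expect_true(all(diff(traj3$b_hat) > 0))
  expect_true(all(diff(traj3$dose_mg_per_kg) < 0))

  # round trip: every recommended dose attains exactly p0
  for (k in seq_len(nrow(traj3))) {
    eta <- linear_predictor(
      ref, c(time_months = up$time_months[k],
             severity = up$severity_score[k]),
      dose = traj3$dose_mg_per_kg[k], b = traj3$b_hat[k])
    expect_equal(inv_logit(eta), tg$p0, tolerance = 1e-12)
  }

  expect_error(recommend_trajectory(ref, tg, up[c(2, 1), ]), "ordered")

  tmp <- tempfile(fileext = ".json")
  write_trajectory_json(traj3, tmp)
  js <- jsonlite::read_json(tmp)
  expect_equal(js$target$logit_p0, lp_work)
  expect_length(js$visits, nrow(traj3))
})

test_that("dose-response surfaces follow the closed-form ratios", {
  tg <- dose_target(logit_p0 = lp_work)
  curves <- dose_response_curves(ref, tg, severity_grid = c(45, 46, 55),
                                 time_grid = c(0, 1, 6, 12))
  expect_identical(nrow(curves), 12L)
  # one extra month on treatment scales the dose by exp(-0.08/0.861)
  d45 <- curves[curves$severity == 45, ]
  expect_equal(d45$dose_mg_per_kg[d45$time_months == 1] /
                 d45$dose_mg_per_kg[d45$time_months == 0],
               exp(-0.0800 / 0.8610), tolerance = 1e-10)
  expect_equal(exp(-0.0800 / 0.8610), 0.911, tolerance = 5e-4)
  # one severity point scales it by exp(0.0512/0.861)
  t0 <- curves[curves$time_months == 0, ]
  expect_equal(t0$dose_mg_per_kg[t0$severity == 46] /
                 t0$dose_mg_per_kg[t0$severity == 45],
               exp(0.0512 / 0.8610), tolerance = 1e-10)
  expect_equal(exp(0.0512 / 0.8610), 1.061, tolerance = 5e-4)
  # monotone in both directions
  expect_true(all(diff(t0$dose_mg_per_kg) > 0))
  expect_true(all(diff(d45$dose_mg_per_kg) < 0))
  one <- dose_response_curves(ref, tg, 50, 3)
  expect_identical(nrow(one), 1L)
})

test_that("dose recommendations are monotone in severity, time and b_hat", {
  tg <- dose_target(logit_p0 = lp_work)
  base <- followup_dose(ref, 50, 6, -0.2, tg, clip = NULL)$dose_mg_per_kg
  expect_gt(followup_dose(ref, 51, 6, -0.2, tg,
                          clip = NULL)$dose_mg_per_kg, base)
  expect_lt(followup_dose(ref, 50, 7, -0.2, tg,
                          clip = NULL)$dose_mg_per_kg, base)
  expect_lt(followup_dose(ref, 50, 6, -0.1, tg,
                          clip = NULL)$dose_mg_per_kg, base)
})
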