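test_that("transport simulation honours initial and equilibrium limits", {
  spec <- sim_spec(noise_cv = 0, t_grid_s = c(0, 1800, 1e7))
  ts <- simulate_transport(spec)
  expect_equal(ts$C_receiver_uM[1], 0)             # t = 0
  expect_equal(ts$C_donor_uM[1], 10)
  c_eq <- 10 * 0.1 / 0.7
  expect_equal(ts$C_receiver_uM[3], c_eq, tolerance = 1e-9)  # t -> inf
})

test_that("noiseless dynamics conserve mass to 1e-10 relative error", {
  spec <- sim_spec(true_papp = 3e-5, noise_cv = 0,
                   t_grid_s = seq(0, 7200, by = 300))
  ts <- simulate_transport(spec)
  total <- ts$C_donor_uM * 0.1 + ts$C_receiver_uM * 0.6
  expect_true(all(abs(total - 10 * 0.1) / (10 * 0.1) <= 1e-10))
})

test_that("receiver concentration increases in time and in permeability", {
  spec <- sim_spec(noise_cv = 0, t_grid_s = seq(60, 3600, by = 60))
  ts <- simulate_transport(spec)
  expect_true(all(diff(ts$C_receiver_uM) > 0))

  papps <- c(1e-6, 5e-6, 1e-5, 5e-5)
  at_1800 <- vapply(papps, function(p) {
    simulate_transport(sim_spec(true_papp = p, noise_cv = 0,
                                t_grid_s = c(0, 1800)))$C_receiver_uM[2]
  }, numeric(1))
  expect_true(all(diff(at_1800) > 0))
})

test_that("closed form agrees with an independent ODE integration", {
  spec <- sim_spec(true_papp = 1e-5, noise_cv = 0,
                   t_grid_s = seq(0, 1800, by = 180))
  ts <- simulate_transport(spec)
  # independent route: integrate the raw two-compartment rate equations
  rate <- function(t, y, parms) {
    flux <- parms$papp * parms$S * (y[1] - y[2])   # umol/s per (uM cm2 -> nmol/s)
    list(c(-flux / parms$Vd, flux / parms$Vr))
  }
  sol <- deSolve::ode(y = c(10, 0), times = spec$t_grid_s, func = rate,
                      parms = list(papp = 1e-5, S = 0.33, Vd = 0.1,
                                   Vr = 0.6),
                      rtol = 1e-12, atol = 1e-14)
  expect_equal(ts$C_receiver_uM[-1], sol[-1, 3], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ts$C_donor_uM[-1], sol[-1, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("estimator is biased low by exactly (1 - exp(-kt))/(kt)", {
  for (papp in c(1e-6, 5e-6, 1e-5, 5e-5, 2e-4)) {
    spec <- sim_spec(true_papp = papp, noise_cv = 0,
                     t_grid_s = c(0, 1800))
    out <- recover_papp_experiment(spec, n_reps = 1)
    k <- papp * 0.33 * (1 / 0.1 + 1 / 0.6)
    expected <- (1 - exp(-k * 1800)) / (k * 1800)
    expect_equal(1 + out$rel_bias, expected, tolerance = 1e-10)
    expect_lte(out$papp$papp_mean, papp)   # never overestimates
  }
})

test_that("cohort generation is deterministic and extensible by seed", {
  s <- cohort_spec(n_drugs = 10, seed = 99)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a, b)

  # first drugs unchanged when the cohort grows
  big <- generate_cohort(cohort_spec(n_drugs = 20, seed = 99))
  expect_equal(big$truth[1:10, ], a$truth)

  other <- generate_cohort(cohort_spec(n_drugs = 10, seed = 100))
  expect_false(identical(other$truth$papp_true, a$truth$papp_true))
})

test_that("cohort truths respect their declared domains", {
  co <- generate_cohort(cohort_spec(n_drugs = 300, seed = 3),
                        emit_transport = FALSE)
  expect_true(all(co$truth$fu_brain > 0 & co$truth$fu_brain <= 1))
  expect_true(all(co$truth$papp_true > 0))
  expect_true(all(co$truth$ps_obs > 0))
  expect_equal(co$truth$ps_true,
               predict_ps(co$truth$papp_true, co$truth$fu_brain, 150))
})

test_that("perfectly predictable cohorts classify 100% successful", {
  co <- generate_cohort(cohort_spec(n_drugs = 50, ivivc_fold_sd = 0,
                                    seed = 5), emit_transport = FALSE)
  cls <- classify_fold(co$truth$ps_true, co$truth$ps_obs)
  expect_true(all(cls$within_fold))
})

test_that("success rate matches the Gaussian-tail closed form", {
  sigma <- 0.25
  co <- generate_cohort(cohort_spec(n_drugs = 2000, ivivc_fold_sd = sigma,
                                    seed = 17), emit_transport = FALSE)
  cls <- classify_fold(co$truth$ps_true, co$truth$ps_obs)
  p_expected <- 2 * pnorm(log10(2) / sigma) - 1
  se <- sqrt(p_expected * (1 - p_expected) / 2000)
  expect_lt(abs(mean(cls$within_fold) - p_expected), 3 * se)
})

test_that("synthetic TEER courses replay their generating profile", {
  prof <- peak_profile(peak_day = 6)
  teer <- generate_teer_course(prof, blank_mean_ohm = 100,
                               blank_sd_ohm = 0, seed = 21)
  # zero-SD profiles: correction recovers (mean - blank) * area exactly
  got <- summarize_teer(correct_teer_table(teer))
  mono6 <- got[got$model_id == "mono" & got$day == 6, ]
  expect_equal(mono6$teer_mean,
               (prof$mean_ohm[prof$model_id == "mono" & prof$day == 6] -
                  100) * 0.33)
  expect_equal(mono6$teer_sem, 0)
  expect_equal(select_assay_day(got), 6L)

  again <- generate_teer_course(prof, blank_mean_ohm = 100,
                                blank_sd_ohm = 0, seed = 21)
  expect_identical(teer, again)
})
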