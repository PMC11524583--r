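test_that("PS scaling reproduces hand-verified reference cells", {
  # Papp 15.24e-6 cm/s, fu 0.01 -> 13716.00 uL/min/g
  expect_equal(predict_ps(15.24e-6, 0.01), 13716.00, tolerance = 1e-9)
  expect_equal(predict_ps(8.78e-6, 0.782), 101.05, tolerance = 5e-3)
  expect_equal(predict_ps(1e-6, 1), 9.0)     # pure unit conversion
  expect_error(predict_ps(1e-6, 0), "fu_brain")
  expect_error(predict_ps(1e-6, 1.2), "fu_brain")
})

test_that("PS scaling is monotone in papp and fu", {
  papp <- seq(1e-6, 4e-5, length.out = 20)
  expect_true(all(diff(predict_ps(papp, 0.1)) > 0))
  fu <- seq(0.01, 1, length.out = 20)
  expect_true(all(diff(predict_ps(1e-5, fu)) < 0))
})

test_that("observed-PS unification is plain multiplication by VSA", {
  expect_equal(unify_ps_obs(0.774, 150), 116.1)
  expect_equal(unify_ps_obs(1, 1), 1)
  expect_equal(unify_ps_obs(2.5), 375)
})

test_that("fold classification uses inclusive predicted/observed bounds", {
  out <- classify_fold(310.22, 116.10)
  expect_equal(out$fold_ratio, 310.22 / 116.10)   # 2.672...
  expect_false(out$within_fold)

  expect_true(classify_fold(5, 5)$within_fold)          # ratio 1
  expect_true(classify_fold(10, 5)$within_fold)         # boundary 2.0
  expect_true(classify_fold(2.5, 5)$within_fold)        # boundary 0.5
  expect_false(classify_fold(10.0001, 5)$within_fold)
  expect_error(classify_fold(1, 0), "ps_obs")
})

test_that("classification is symmetric under swapping pred/obs", {
  set.seed(42)
  pre <- 10^runif(50, 0, 4); obs <- 10^runif(50, 0, 4)
  expect_equal(classify_fold(pre, obs)$within_fold,
               classify_fold(obs, pre)$within_fold)
})

test_that("model summary counts successes and computes AFE/AAFE", {
  res <- tibble::tibble(model_id = "m",
                        fold_ratio = c(1, 1, 1),
                        within_fold = TRUE)
  s <- summarize_ivivc(res)
  expect_equal(s$afe, 1); expect_equal(s$aafe, 1)
  expect_equal(s$n_success, 3L)

  res2 <- tibble::tibble(model_id = "m",
                         fold_ratio = c(2, 8),
                         within_fold = c(TRUE, FALSE))
  s2 <- summarize_ivivc(res2)
  expect_equal(s2$afe, 4)           # 10^mean(log10 c(2,8)) = 4
  expect_equal(s2$aafe, s2$afe)     # all ratios >= 1
  expect_true(s2$aafe >= 1)

  shuffled <- res2[c(2, 1), ]
  expect_equal(summarize_ivivc(shuffled), s2)
})

test_that("failure set orders drugs by absolute log fold error", {
  res <- tibble::tibble(
    drug_id = c("a", "b", "c", "d"), model_id = "m",
    fold_ratio = c(1.0, 3.0, 0.1, 2.5),
    within_fold = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(failure_set(res), c("c", "b", "d"))
  expect_equal(failure_set(res[1, ]), character(0))
})

test_that("brain/plasma ratio is elementwise and rejects zero plasma", {
  expect_equal(brain_plasma_ratio(2, 4), 0.5)
  expect_equal(brain_plasma_ratio(c(1, 2, 3), c(1, 2, 3)), c(1, 1, 1))
  expect_error(brain_plasma_ratio(1, 0), "c_plasma")
})

test_that("reference dataset reproduces published counts and failure sets", {
  rep <- reproduce_table1()
  s <- rep$summary[order(rep$summary$model_id), ]
  expect_equal(s$n_success, c(7L, 14L))
  expect_equal(s$n_total, c(18L, 18L))
  expect_setequal(rep$failures$triple,
                  c("Verapamil", "Amitriptyline", "Fluoxetine", "Clozapine"))
  # every recomputed PS cell within 0.5% of the published one
  expect_lt(rep$max_rel_dev, 0.005)
  # the exactly-reproducing cells match to 2 decimals
  r <- rep$results
  cell <- function(d, m) r$ps_pre[r$drug_id == d & r$model_id == m]
  expect_equal(round(cell("Amitriptyline", "mono"), 2), 13716.00)
  expect_equal(round(cell("Doxepin", "mono"), 2), 6076.80)
  expect_equal(round(cell("Fluoxetine", "mono"), 2), 25830.00)
  expect_equal(round(cell("Midazolam", "mono"), 2), 5060.00)
  expect_equal(round(cell("Mirtazapine", "triple"), 2), 2009.25)
})

test_that("widening the fold bounds never reduces the success count", {
  rep_default <- reproduce_table1()
  rep_wide <- reproduce_table1(fold_bounds = c(1 / 3, 3))
  expect_true(all(rep_wide$summary$n_success >=
                    rep_default$summary$n_success))
})
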