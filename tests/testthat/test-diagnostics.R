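# one rich, well-specified study (100 dogs, 11 samples each) fitted once
# and reused across the diagnostic tests
diag_data <- simulate_study(sim_config(n_per_arm = 50), seed = 211)
diag_fit <- suppressMessages(fit_saem(
  diag_data, covariates = final_covariates(), seed = 13,
  control = saem_control(K1 = 300, K2 = 150, ll_nsim = 500,
                         compute_rse = FALSE)))

test_that("individual predictions track the data and IWRES is calibrated", {
  ip <- individual_predictions(diag_fit)
  expect_equal(nrow(ip), 1100)
  expect_true(all(is.finite(ip$IWRES)))
  # standardized residuals of a well-specified model
  expect_gt(mean(ip$IWRES), -0.2)
  expect_lt(mean(ip$IWRES), 0.2)
  expect_gt(sd(ip$IWRES), 0.8)
  expect_lt(sd(ip$IWRES), 1.2)
  # individual predictions fit each subject better than population ones
  expect_lt(mean(abs(ip$DV - ip$IPRED)), mean(abs(ip$DV - ip$PRED)))
})

test_that("a model without IIV predicts identically for all and EBEs vanish", {
  d <- simulate_study(sim_config(n_per_arm = 3), seed = 2)
  fit0 <- suppressMessages(fit_saem(
    d, iiv = character(0), seed = 5,
    control = saem_control(K1 = 80, K2 = 40, ll_nsim = 100,
                           compute_rse = FALSE)))
  ip <- individual_predictions(fit0)
  expect_equal(ip$IPRED, ip$PRED, tolerance = 1e-12)
})

test_that("shrinkage is moderate for well-informed parameters", {
  sh <- shrinkage(diag_fit)
  expect_true(is.na(sh[["Q"]]))  # no IIV on Q
  expect_lt(sh[["CL"]], 30)      # rich design: 11 samples per subject
  expect_true(all(sh[!is.na(sh)] <= 100))
})

test_that("the VPC respects percentile ordering and reproducibility", {
  v <- vpc(diag_fit, n_sim = 80, seed = 3)
  b <- v$bins
  expect_equal(nrow(b), 11)
  expect_true(all(b$obs_p10 <= b$obs_p50 & b$obs_p50 <= b$obs_p90))
  expect_true(all(b$sim_p10_med <= b$sim_p50_med + 1e-12))
  expect_true(all(b$sim_p50_med <= b$sim_p90_med + 1e-12))
  expect_true(all(b$sim_p50_lo <= b$sim_p50_hi))
  v2 <- vpc(diag_fit, n_sim = 80, seed = 3)
  expect_identical(v$bins, v2$bins)
  expect_error(vpc(diag_fit, n_sim = 0), "n_sim")
})

test_that("npde on well-specified data is approximately standard normal", {
  # generator model scored against its own data: no estimation error
  nd <- npde(default_truth_model(), diag_data, n_sim = 400, seed = 7)
  expect_equal(nrow(nd), 1100)
  expect_gt(mean(nd$npde), -0.15)
  expect_lt(mean(nd$npde), 0.15)
  expect_gt(var(nd$npde), 0.8)
  expect_lt(var(nd$npde), 1.2)
  expect_error(npde(diag_fit, n_sim = 1), "n_sim")
})

test_that("bootstrap refits are deterministic on an identity resample", {
  d <- simulate_study(sim_config(n_per_arm = 2), seed = 23)
  rebuilt <- pk_dataset(as.data.frame(d))
  ctl <- saem_control(K1 = 60, K2 = 30, compute_rse = FALSE,
                      compute_ebe = FALSE, compute_ll = FALSE)
  f1 <- suppressMessages(fit_saem(d, seed = 4, control = ctl))
  f2 <- suppressMessages(fit_saem(rebuilt, seed = 4, control = ctl))
  expect_identical(f1$trace, f2$trace)
})

test_that("bootstrap summaries order their percentiles and count successes", {
  d <- simulate_study(sim_config(n_per_arm = 4), seed = 29)
  bt <- bootstrap_pk(d, n_boot = 8, seed = 2,
                     control = saem_control(K1 = 60, K2 = 30,
                                            compute_rse = FALSE,
                                            compute_ebe = FALSE,
                                            compute_ll = FALSE))
  expect_equal(nrow(bt$estimates), 8)
  expect_true(all(bt$summary$p5 <= bt$summary$median + 1e-12))
  expect_true(all(bt$summary$median <= bt$summary$p95 + 1e-12))
  expect_lte(bt$n_success, 8)
  expect_error(bootstrap_pk(d, n_boot = 0), "n_boot")
  # reproducibility
  bt2 <- bootstrap_pk(d, n_boot = 8, seed = 2,
                      control = saem_control(K1 = 60, K2 = 30,
                                             compute_rse = FALSE,
                                             compute_ebe = FALSE,
                                             compute_ll = FALSE))
  expect_identical(bt$estimates, bt2$estimates)
})

test_that("bootstrap intervals tighten as the study grows", {
  width <- function(n_per_arm) {
    d <- simulate_study(sim_config(n_per_arm = n_per_arm), seed = 37)
    bt <- bootstrap_pk(d, n_boot = 25, seed = 3, init = default_truth_model(),
                       control = saem_control(K1 = 80, K2 = 40,
                                              compute_rse = FALSE,
                                              compute_ebe = FALSE,
                                              compute_ll = FALSE))
    s <- bt$summary
    log(s$p95[s$parameter == "CL"] / s$p5[s$parameter == "CL"])
  }
  expect_lt(width(40), width(8))
})
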