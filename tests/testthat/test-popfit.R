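# shared small study for the estimation tests
pf_data <- simulate_study(sim_config(), seed = 301)

test_that("formulation covariate arithmetic matches the exponential model", {
  m <- default_truth_model()
  free <- apply_covariates(m, "FREE")
  nc <- apply_covariates(m, "NC")
  expect_equal(unname(free[c("tlag2", "V2")]), c(1.22, 0.134))
  expect_equal(unname(nc["tlag2"]), 1.22 * exp(0.74))
  expect_equal(unname(nc["V2"]), 0.134 * exp(1.11))
  # parameters without an effect are untouched
  expect_equal(nc[c("ka1", "CL", "V1", "Q")], free[c("ka1", "CL", "V1", "Q")])
  expect_error(apply_covariates(m, "IV"), "unknown formulation")
  m0 <- m; m0$beta$value[] <- 0
  expect_equal(apply_covariates(m0, "NC"), apply_covariates(m0, "FREE"))
})

test_that("individual draws follow the lognormal hierarchy", {
  m <- default_truth_model()
  # no variability: realized equals covariate-adjusted typical values
  m0 <- m; m0$omega[] <- 0
  s <- sample_individual(m0, "NC", n = 3, seed = 1)
  for (i in 1:3)
    expect_equal(unname(s$params[i, ]), unname(apply_covariates(m, "NC")))
  # the median of a lognormal equals its typical value
  s <- sample_individual(m, "FREE", n = 10000, seed = 2)
  expect_equal(median(s$params[, "ka1"]), 0.086, tolerance = 0.02)
  # random effects are centred
  expect_lt(abs(mean(log(s$params[, "CL"]) - log(0.006))), 0.01)
})

test_that("marginal likelihood without IIV equals the closed Gaussian form", {
  d1 <- simulate_study(sim_config(n_per_arm = 1), seed = 11)
  m <- default_truth_model()
  m$omega[] <- 0
  obs <- d1[d1$EVID == 0 & d1$ID == 1, ]
  p <- apply_covariates(m, "FREE")
  f <- predict_concentration(do.call(structural_params, as.list(p)),
                             0.2, obs$TIME)
  exact <- -2 * sum(dnorm(obs$DV, f, m$b * f, log = TRUE))
  d1f <- pk_dataset(d1[d1$ID == 1, ])
  expect_equal(loglikelihood(m, d1f, nsim = 100, seed = 1), exact,
               tolerance = 1e-10)
  # tiny IIV: the importance-sampled value approaches the same limit
  m$omega[setdiff(names(m$omega), "Q")] <- 1e-3
  expect_lt(abs(loglikelihood(m, d1f, nsim = 2000, seed = 1) - exact), 0.1)
})

test_that("duplicated subjects double the -2LL contribution", {
  m <- default_truth_model()
  one <- pf_data[pf_data$ID == 1, ]
  two <- one; two$ID <- 2L
  d1 <- pk_dataset(one)
  d2 <- pk_dataset(rbind(one, two))
  l1 <- loglikelihood(m, d1, nsim = 4000, seed = 5)
  l2 <- loglikelihood(m, d2, nsim = 4000, seed = 5)
  expect_equal(l2, 2 * l1, tolerance = 0.02)
})

test_that("the generating model dominates a mis-specified one in likelihood", {
  d <- simulate_study(sim_config(n_per_arm = 25), seed = 31)
  truth <- default_truth_model()
  wrong <- truth
  wrong$theta[["CL"]] <- truth$theta[["CL"]] * 3
  lt <- loglikelihood(truth, d, nsim = 1000, seed = 9)
  lw <- loglikelihood(wrong, d, nsim = 1000, seed = 9)
  expect_lt(lt, lw - 50)
})

test_that("subject relabelling leaves the Laplace -2LL unchanged", {
  m <- default_truth_model()
  sub <- pf_data[pf_data$ID %in% 1:4, ]
  relab <- sub
  relab$ID <- c(4L, 3L, 2L, 1L)[relab$ID]
  l1 <- loglikelihood(m, pk_dataset(sub), method = "laplace", seed = 2)
  l2 <- loglikelihood(m, pk_dataset(relab), method = "laplace", seed = 2)
  expect_equal(l1, l2, tolerance = 1e-4)
})

test_that("near-noiseless dense data identifies the typical values", {
  # dense schedule including the distribution phase (V1/Q are barely
  # identified without samples before 0.25 h)
  cfg <- sim_config(
    n_per_arm = 5,
    times = c(0.05, 0.1, 0.15, 0.25, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10,
              12, 16, 20, 24, 30, 36, 42, 48, 60, 72, 96),
    truth = population_model(
      theta = c(ka1 = 0.086, ka2 = 1.82, F1 = 0.85, tlag2 = 1.22,
                CL = 0.006, V1 = 0.049, Q = 0.24, V2 = 0.134),
      omega = NULL, b = 0.02))
  d <- simulate_study(cfg, seed = 41)
  init <- population_model(
    theta = c(ka1 = 0.15, ka2 = 1, F1 = 0.7, tlag2 = 2,
              CL = 0.01, V1 = 0.1, Q = 0.1, V2 = 0.3),
    omega = setNames(rep(0.1, 7), setdiff(names(cfg$truth$omega), "Q")),
    b = 0.05)
  fit <- suppressMessages(fit_saem(
    d, init = init, covariates = final_covariates(), seed = 3,
    control = saem_control(K1 = 400, K2 = 200, ll_nsim = 100,
                           compute_rse = FALSE, compute_ebe = FALSE)))
  for (p in c("ka1", "ka2", "F1", "tlag2", "CL", "V1", "Q", "V2"))
    expect_equal(fit$model$theta[[p]], cfg$truth$theta[[p]],
                 tolerance = 0.02, label = paste("estimate for", p))
  expect_equal(fit$model$b, 0.02, tolerance = 0.15)
})

test_that("SAEM runs are reproducible bit-for-bit under a fixed seed", {
  ctl <- saem_control(K1 = 60, K2 = 30, ll_nsim = 100,
                      compute_rse = FALSE, compute_ebe = FALSE)
  f1 <- suppressMessages(fit_saem(pf_data, seed = 17, control = ctl))
  f2 <- suppressMessages(fit_saem(pf_data, seed = 17, control = ctl))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$minus2ll, f2$minus2ll)
  f3 <- suppressMessages(fit_saem(pf_data, seed = 18, control = ctl))
  expect_false(identical(f1$trace, f3$trace))
})

test_that("AIC bookkeeping counts the estimated parameters", {
  ctl <- saem_control(K1 = 60, K2 = 30, ll_nsim = 100,
                      compute_rse = FALSE, compute_ebe = FALSE)
  fit <- suppressMessages(fit_saem(pf_data, covariates = final_covariates(),
                                   seed = 1, control = ctl))
  # 8 typical values + 2 betas + 7 omegas + b
  expect_equal(fit$npar, 18)
  expect_equal(fit$aic, fit$minus2ll + 2 * 18)
})

test_that("a true covariate effect clears the inclusion threshold", {
  d <- simulate_study(sim_config(n_per_arm = 25), seed = 71)
  ctl <- saem_control(K1 = 400, K2 = 150, ll_nsim = 2000,
                      compute_rse = FALSE, compute_ebe = FALSE)
  base <- suppressMessages(fit_saem(d, seed = 5, control = ctl))
  full <- suppressMessages(fit_saem(d, covariates = final_covariates(),
                                    seed = 5, control = ctl))
  expect_gt(base$minus2ll - full$minus2ll, 3.84)
})

test_that("linearized RSEs are produced for every estimated parameter", {
  fit <- suppressMessages(fit_saem(
    pf_data, covariates = final_covariates(), seed = 21,
    control = saem_control(K1 = 150, K2 = 75, ll_nsim = 200,
                           compute_ebe = FALSE)))
  rse <- fit$rse_pct
  expect_false(is.null(rse))
  expect_length(rse, 18)
  expect_true(all(is.finite(rse)))
  expect_true(all(rse > 0))
  # the residual error is the best-determined quantity in a rich design
  expect_lt(rse[["b"]], 25)
})

test_that("an empty candidate list returns the base model unchanged", {
  ctl <- saem_control(K1 = 60, K2 = 30, ll_nsim = 100,
                      compute_rse = FALSE, compute_ebe = FALSE)
  cs <- covariate_search(pf_data,
                         candidates = data.frame(param = character(),
                                                 covariate = character()),
                         seed = 2, control = ctl)
  expect_equal(nrow(cs$selected), 0)
  expect_equal(nrow(cs$log), 0)
})
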