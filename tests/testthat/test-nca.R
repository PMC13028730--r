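test_that("lambda_z recovers an exact mono-exponential decline", {
  tt <- design_times()
  conc <- 2 * exp(-0.1 * tt)
  lz <- fit_lambda_z(tt, conc)
  expect_equal(lz$lambda_z, 0.1, tolerance = 1e-10)
  expect_equal(lz$r2adj, 1, tolerance = 1e-8)
  # half-life formula
  expect_equal(log(2) / 0.0462, 15.0, tolerance = 2e-3)
})

test_that("lambda_z refuses unusable profiles", {
  expect_error(fit_lambda_z(c(1, 2), c(2, 1)), "at least 3")
  tt <- c(1, 2, 4, 8, 12)
  expect_error(fit_lambda_z(tt, c(0.1, 0.2, 0.3, 0.4, 0.5)), "at least 3")
  expect_error(fit_lambda_z(tt, c(5, 1, 1.2, 1.4, 1.6)), "negative slope")
})

test_that("trapezoidal AUC matches closed forms", {
  expect_equal(auc_trapezoid(c(0, 10), c(3, 3)), 30)
  tt <- seq(0, 100, length.out = 2000)
  expect_equal(auc_trapezoid(tt, exp(-0.1 * tt)), 10, tolerance = 1e-3)
  expect_error(auc_trapezoid(5, 1), "length")
  expect_error(auc_trapezoid(c(2, 1), c(1, 2)), "increasing")
})

test_that("per-subject NCA metrics are internally consistent", {
  p <- ref_params()
  tt <- c(seq(0.5, 24, by = 0.5), seq(25, 300, by = 2.5))
  conc <- predict_concentration(p, 0.2, tt)
  r <- nca_single(tt, conc, 0.2)
  expect_equal(r$auc_0_inf, predict_auc_inf(p, 0.2), tolerance = 0.01)
  expect_gte(r$auc_0_inf, r$auc_0_t)
  expect_equal(r$auc_ext_pct,
               100 * (r$auc_0_inf - r$auc_0_t) / r$auc_0_inf)
  expect_equal(r$t_half, log(2) / r$lambda_z)
  expect_equal(r$cl_f, 0.2 / r$auc_0_inf)
  expect_equal(r$vd_f, r$cl_f / r$lambda_z)
})

test_that("cmax/tmax use the first occurrence of the maximum", {
  tt <- c(1, 2, 4, 8, 12, 24, 36, 48)
  conc <- c(1, 1.33, 1.33, 1, 0.8, 0.5, 0.3, 0.2)
  r <- nca_single(tt, conc, 0.2)
  expect_equal(r$tmax, 2)
  expect_equal(r$cmax, 1.33)
})

test_that("extrapolated fraction shrinks as sampling extends", {
  p <- ref_params()
  tt <- design_times()
  long <- c(tt, 72, 96, 120)
  r1 <- nca_single(tt, predict_concentration(p, 0.2, tt), 0.2)
  r2 <- nca_single(long, predict_concentration(p, 0.2, long), 0.2)
  expect_lt(r2$auc_ext_pct, r1$auc_ext_pct)
})

test_that("unit rescaling scales exposure metrics and leaves rates alone", {
  tt <- design_times()
  conc <- predict_concentration(ref_params(), 0.2, tt)
  a <- nca_single(tt, conc, 0.2)
  b <- nca_single(tt, conc * 1000, 0.2)
  expect_equal(b$auc_0_inf, 1000 * a$auc_0_inf)
  expect_equal(b$cmax, 1000 * a$cmax)
  expect_equal(b$lambda_z, a$lambda_z)
  expect_equal(b$tmax, a$tmax)
})

test_that("group comparison: identical arms give p = 1 and frel = 1", {
  tt <- design_times()
  conc <- predict_concentration(ref_params(), 0.2, tt)
  profs <- lapply(1:4, function(i)
    list(times = tt, conc = conc, form = if (i <= 2) "FREE" else "NC"))
  d <- toy_dataset(profs)
  gc <- group_compare(nca_dataset(d))
  expect_equal(gc$frel, 1, tolerance = 1e-12)
  expect_true(all(gc$table$p_value > 0.999))
})

test_that("group comparison flags a known separation", {
  set.seed(7)
  tab <- data.frame(
    FORM = rep(c("FREE", "NC"), each = 9),
    auc_0_inf = c(rnorm(9, 10, 1), rnorm(9, 20, 1)))
  gc <- group_compare(tab)
  expect_lt(gc$table$p_value[gc$table$metric == "auc_0_inf"], 0.001)
  expect_error(group_compare(tab[tab$FORM == "FREE", , drop = FALSE]),
               "two arms")
})

test_that("absolute bioavailability uses the external IV reference", {
  tab <- data.frame(FORM = rep(c("FREE", "NC"), each = 3),
                    auc_0_inf = c(27, 28, 28.19, 32, 32, 32.24))
  attr(tab, "dose_per_kg") <- 0.2
  gc <- group_compare(tab, iv_ref = list(auc = 29.5, dose = 0.2))
  expect_equal(unname(gc$f_abs["FREE"]), mean(c(27, 28, 28.19)) / 29.5)
  expect_equal(unname(gc$f_abs["NC"]), mean(c(32, 32, 32.24)) / 29.5)
})
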