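#' Reference generating model for the virtual dog study
#'
#' Typical values, inter-individual variability and formulation effects
#' describing single-oral-dose meloxicam (0.2 mg/kg) kinetics in adult
#' female dogs, for a free solution (`FREE`) versus a polymeric
#' nanocapsule formulation (`NC`). The nanoformulation delays the second
#' absorption path (effect +0.74 on log Tlag2, i.e. 1.22 h -> 2.55 h) and
#' enlarges the peripheral volume (+1.11 on log V2, i.e. 0.134 -> 0.406
#' L/kg). All parameters except `Q` carry lognormal IIV; residual error is
#' proportional with b = 0.19.
#'
#' @return a [population_model()]
#' @export
default_truth_model <- function() {
  population_model(
    theta = c(ka1 = 0.086, ka2 = 1.82, F1 = 0.85, tlag2 = 1.22,
              CL = 0.006, V1 = 0.049, Q = 0.24, V2 = 0.134),
    omega = c(ka1 = 0.38, ka2 = 1.28, F1 = 0.67, tlag2 = 0.38,
              CL = 0.32, V1 = 1.44, V2 = 0.65),
    beta = data.frame(param = c("tlag2", "V2"), covariate = c("FORM", "FORM"),
                      value = c(0.74, 1.11)),
    b = 0.19
  )
}

#' Simulation configuration for a virtual two-arm dog study
#'
#' Defaults reproduce the reference parallel-group design: 9 dogs per arm
#' (FREE vs NC), one oral dose of 0.2 mg/kg at time 0, plasma samples at
#' 0.5, 1, 2, 4, 6, 8, 12, 24, 36, 48 and 60 h, body weights uniform on
#' 10.5-16.6 kg and ages uniform on 9-48 months. Weight and age are
#' carried in the dataset as candidate covariates but do not influence the
#' simulated concentrations.
#'
#' @param n_per_arm dogs per arm
#' @param dose_per_kg oral dose (mg/kg)
#' @param times sampling times (h), strictly increasing, all > 0
#' @param weight_range,age_range uniform covariate ranges (kg, months)
#' @param truth generating [population_model()]
#' @param truncate how to keep simulated concentrations positive under
#'   proportional noise: `"redraw"` (redraw eps for offending points,
#'   default) or `"none"`
#' @return a `sim_config` list
#' @export
sim_config <- function(n_per_arm = 9, dose_per_kg = 0.2,
                       times = c(0.5, 1, 2, 4, 6, 8, 12, 24, 36, 48, 60),
                       weight_range = c(10.5, 16.6),
                       age_range = c(9, 48),
                       truth = default_truth_model(),
                       truncate = c("redraw", "none")) {
  truncate <- match.arg(truncate)
  stopifnot(n_per_arm >= 1, dose_per_kg > 0, all(times > 0),
            !is.unsorted(times, strictly = TRUE),
            inherits(truth, "population_model"))
  structure(list(n_per_arm = n_per_arm, dose_per_kg = dose_per_kg,
                 times = times, weight_range = weight_range,
                 age_range = age_range, truth = truth,
                 truncate = truncate),
            class = "sim_config")
}

#' Simulate a virtual two-arm single-oral-dose study
#'
#' Per dog: draws random effects, applies the formulation covariate of its
#' arm, predicts concentrations at the sampling schedule and applies
#' proportional observation noise `y = f (1 + b eps)`. Under the default
#' truncation policy, any draw that would produce a non-positive
#' concentration has its `eps` redrawn, so all observations stay positive
#' (profiles entirely above the quantification limit). The realized
#' individual parameters are attached as `attr(, "truth")` for parameter
#' recovery studies.
#'
#' @param config a [sim_config()]
#' @param seed integer seed; the same seed reproduces the dataset exactly
#' @return a [pk_dataset()] with a `truth` attribute (data.frame of
#'   realized individual parameters and etas)
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- 2 * config$n_per_arm
  form <- rep(c("FREE", "NC"), each = config$n_per_arm)
  wt <- round(runif(n, config$weight_range[1], config$weight_range[2]), 1)
  age <- round(runif(n, config$age_range[1], config$age_range[2]))
  ind <- sample_individual(config$truth, form, n = n)
  tt <- config$times
  nt <- length(tt)
  rec <- vector("list", n)
  tr <- config$truth
  for (i in seq_len(n)) {
    p <- ind$params[i, ]
    f <- .conc_rows(tt, p[["ka1"]], p[["ka2"]], p[["F1"]], p[["tlag2"]],
                    p[["CL"]], p[["V1"]], p[["Q"]], p[["V2"]],
                    config$dose_per_kg)
    eps <- rnorm(nt)
    y <- f * (1 + tr$b * eps)
    if (config$truncate == "redraw") {
      for (guard in 1:1000) {
        bad <- y <= 0
        if (!any(bad)) break
        eps[bad] <- rnorm(sum(bad))
        y[bad] <- f[bad] * (1 + tr$b * eps[bad])
      }
      if (any(y <= 0)) stop("could not obtain positive concentrations")
    }
    rec[[i]] <- data.frame(
      ID = i,
      TIME = c(0, tt),
      AMT = c(config$dose_per_kg, rep(NA_real_, nt)),
      DV = c(NA_real_, y),
      EVID = c(1L, rep(0L, nt)),
      FORM = form[i], WT = wt[i], AGE = age[i])
  }
  data <- pk_dataset(do.call(rbind, rec))
  truth <- data.frame(ID = seq_len(n), FORM = form, ind$params,
                      setNames(as.data.frame(ind$eta),
                               paste0("eta_", .PK_PARAMS)))
  attr(data, "truth") <- truth
  attr(data, "seed") <- seed
  data
}

#' Simulate arm-typical mean concentration profiles
#'
#' Produces population-typical (`eta = 0`) profiles per arm, formatted as a
#' dataset of "mean profiles" for [external_validate()]. Optional
#' distortions: a constant relative bias and/or proportional Gaussian
#' noise, both in percent.
#'
#' @param config a [sim_config()]
#' @param n_profiles_per_arm number of replicate mean profiles per arm
#' @param times sampling times (defaults to the design schedule)
#' @param bias_pct constant relative bias applied to all concentrations (%)
#' @param noise_pct proportional Gaussian noise SD (%)
#' @param seed integer seed (used only when `noise_pct > 0`)
#' @return a [pk_dataset()] of mean profiles (one pseudo-subject each)
#' @export
simulate_external_means <- function(config = sim_config(),
                                    n_profiles_per_arm = 1,
                                    times = config$times,
                                    bias_pct = 0, noise_pct = 0, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  arms <- rep(c("FREE", "NC"), each = n_profiles_per_arm)
  nt <- length(times)
  rec <- vector("list", length(arms))
  for (i in seq_along(arms)) {
    p <- apply_covariates(config$truth, arms[i])
    f <- .conc_rows(times, p[["ka1"]], p[["ka2"]], p[["F1"]], p[["tlag2"]],
                    p[["CL"]], p[["V1"]], p[["Q"]], p[["V2"]],
                    config$dose_per_kg)
    y <- f * (1 + bias_pct / 100)
    if (noise_pct > 0) y <- y * (1 + noise_pct / 100 * rnorm(nt))
    y <- pmax(y, 1e-9)
    rec[[i]] <- data.frame(
      ID = i, TIME = c(0, times),
      AMT = c(config$dose_per_kg, rep(NA_real_, nt)),
      DV = c(NA_real_, y), EVID = c(1L, rep(0L, nt)),
      FORM = arms[i], WT = NA_real_, AGE = NA_real_)
  }
  pk_dataset(do.call(rbind, rec))
}
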