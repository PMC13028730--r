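#' Population and individual predictions with weighted residuals
#'
#' Returns, per observation, the population prediction (covariate-adjusted
#' typical parameters, random effects at zero), the individual prediction
#' (empirical Bayes etas) and the individual weighted residual
#' `IWRES = (obs - ipred) / sd(ipred)` under the fitted residual-error
#' model.
#'
#' @param fit a `pk_fit` with EBEs (the default [saem_control()] computes
#'   them)
#' @return data.frame with `ID`, `TIME`, `DV`, `PRED`, `IPRED`, `IWRES`
#' @export
individual_predictions <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  if (is.null(fit$ebes))
    stop("fit carries no EBEs; refit with compute_ebe = TRUE")
  prob <- fit$prob
  phi_typ <- .phi_typ(prob)
  pred <- .f_from_phi(prob, phi_typ)
  phi_ind <- phi_typ
  phi_ind[, fit$iiv_idx] <- phi_ind[, fit$iiv_idx] + fit$ebes
  ipred <- .f_from_phi(prob, phi_ind)
  iwres <- (prob$sp$dv - ipred) / .err_sd(ipred, prob$err)
  data.frame(ID = prob$sp$obs_id, TIME = prob$sp$time, DV = prob$sp$dv,
             PRED = pred, IPRED = ipred, IWRES = iwres)
}

#' Eta-shrinkage of the empirical Bayes estimates
#'
#' `100 * (1 - SD(eta_EBE) / omega)` per parameter with IIV; parameters
#' without IIV are reported as `NA` (shrinkage undefined).
#'
#' @param fit a `pk_fit`
#' @return named vector of shrinkage percentages for all eight parameters
#' @export
shrinkage <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  if (is.null(fit$ebes))
    stop("fit carries no EBEs; refit with compute_ebe = TRUE")
  out <- setNames(rep(NA_real_, 8), .PK_PARAMS)
  sdv <- apply(fit$ebes, 2, sd)
  out[.PK_PARAMS[fit$iiv_idx]] <-
    100 * (1 - sdv / fit$prob$omega[fit$iiv_idx])
  out
}

# simulate one replicate of the study under the fitted model, returning
# simulated DVs aligned with the observation rows
.simulate_replicate <- function(prob, iiv_idx) {
  n <- prob$sp$n
  phi_typ <- .phi_typ(prob)
  phi <- phi_typ
  for (j in iiv_idx)
    phi[, j] <- phi[, j] + rnorm(n, 0, prob$omega[j])
  f <- .f_from_phi(prob, phi)
  f + .err_sd(f, prob$err) * rnorm(length(f))
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate studies under the fitted model with the
#' original design and covariates, and compares the observed 10th/50th/90th
#' concentration percentiles per nominal sampling time with the simulated
#' distribution of the same percentiles (90% prediction interval by
#' default). Since every subject shares the design schedule, bins are the
#' exact nominal times.
#'
#' @param fit a `pk_fit` (or a [population_model()] together with `data`)
#' @param data dataset to check (defaults to the fitted data)
#' @param n_sim number of simulated replicate studies (>= 1)
#' @param seed integer seed
#' @param probs percentiles to track
#' @param pi_level width of the simulated prediction band
#' @return a `vpc_result`: data.frame `bins` with observed percentiles and
#'   simulated band limits per time bin
#' @export
vpc <- function(fit, data = NULL, n_sim = 1000, seed = 1,
                probs = c(0.1, 0.5, 0.9), pi_level = 0.9) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  fl <- .as_fitlike(fit, data)
  prob <- fl$prob
  set.seed(seed)
  tt <- prob$sp$time
  bins <- sort(unique(tt))
  bin_of <- match(tt, bins)
  obs_pct <- t(vapply(seq_along(bins), function(b)
    quantile(prob$sp$dv[bin_of == b], probs, names = FALSE),
    numeric(length(probs))))
  sim_pct <- array(NA_real_, c(n_sim, length(bins), length(probs)))
  for (s in seq_len(n_sim)) {
    y <- .simulate_replicate(prob, fl$iiv_idx)
    for (b in seq_along(bins))
      sim_pct[s, b, ] <- quantile(y[bin_of == b], probs, names = FALSE)
  }
  alpha <- (1 - pi_level) / 2
  out <- data.frame(time = bins)
  for (k in seq_along(probs)) {
    nm <- paste0("p", round(100 * probs[k]))
    out[[paste0("obs_", nm)]] <- obs_pct[, k]
    out[[paste0("sim_", nm, "_lo")]] <-
      apply(sim_pct[, , k, drop = FALSE], 2, quantile, alpha)
    out[[paste0("sim_", nm, "_med")]] <-
      apply(sim_pct[, , k, drop = FALSE], 2, quantile, 0.5)
    out[[paste0("sim_", nm, "_hi")]] <-
      apply(sim_pct[, , k, drop = FALSE], 2, quantile, 1 - alpha)
  }
  structure(list(bins = out, n_sim = n_sim, seed = seed, probs = probs,
                 pi_level = pi_level),
            class = "vpc_result")
}

#' @export
plot.vpc_result <- function(x, log_y = FALSE, ...) {
  b <- x$bins
  ylim <- range(b[, -1], na.rm = TRUE)
  plot(b$time, b$obs_p50, type = "n", xlab = "time (h)",
       ylab = "concentration (ug/mL)", ylim = ylim,
       log = if (log_y) "y" else "", ...)
  shade <- function(lo, hi, col) polygon(c(b$time, rev(b$time)),
                                         c(lo, rev(hi)), col = col,
                                         border = NA)
  shade(b$sim_p10_lo, b$sim_p10_hi, grDevices::adjustcolor("steelblue", 0.3))
  shade(b$sim_p90_lo, b$sim_p90_hi, grDevices::adjustcolor("steelblue", 0.3))
  shade(b$sim_p50_lo, b$sim_p50_hi, grDevices::adjustcolor("firebrick", 0.3))
  lines(b$time, b$obs_p10, lty = 2); lines(b$time, b$obs_p90, lty = 2)
  lines(b$time, b$obs_p50, lwd = 2)
  invisible(x)
}

# accept either a pk_fit or (population_model, data)
.as_fitlike <- function(fit, data = NULL) {
  if (inherits(fit, "pk_fit")) return(fit)
  stopifnot(inherits(fit, "population_model"), !is.null(data))
  iiv <- names(fit$omega)[fit$omega > 0]
  covs <- if (NROW(fit$beta)) fit$beta[, c("param", "covariate")] else NULL
  prob <- .build_problem(data, fit, covs, iiv, fit$error_model)
  list(prob = prob, iiv_idx = which(.PK_PARAMS %in% prob$iiv))
}

#' Normalized prediction distribution errors
#'
#' For each subject, simulates `n_sim` replicate observation vectors under
#' the model, decorrelates both the observed and the simulated vectors
#' with the simulated mean and covariance (Cholesky), and transforms the
#' rank of each decorrelated observation among its simulations through the
#' inverse normal. Under a correct model the NPDEs are approximately
#' standard normal and independent.
#'
#' @inheritParams vpc
#' @return data.frame with `ID`, `TIME`, `npde`
#' @export
npde <- function(fit, data = NULL, n_sim = 500, seed = 1) {
  if (n_sim < 2) stop("n_sim must be >= 2 (ranks undefined otherwise)")
  fl <- .as_fitlike(fit, data)
  prob <- fl$prob
  set.seed(seed)
  nobs <- length(prob$sp$dv)
  sims <- matrix(NA_real_, nobs, n_sim)
  for (s in seq_len(n_sim)) sims[, s] <- .simulate_replicate(prob, fl$iiv_idx)
  out <- numeric(nobs)
  jittered <- FALSE
  for (i in seq_len(prob$sp$n)) {
    sel <- which(prob$sp$obs_idx == i)
    Yi <- sims[sel, , drop = FALSE]
    mi <- rowMeans(Yi)
    Si <- cov(t(Yi))
    ch <- tryCatch(chol(Si), error = function(e) NULL)
    if (is.null(ch)) {
      warning("singular simulated covariance for subject ",
              prob$sp$ids[i], "; jittered")
      jittered <- TRUE
      ch <- chol(Si + diag(1e-8 * mean(diag(Si)) + 1e-12, length(sel)))
    }
    Li <- t(ch)
    dec_obs <- forwardsolve(Li, prob$sp$dv[sel] - mi)
    dec_sim <- forwardsolve(Li, Yi - mi)
    pd <- (rowSums(dec_sim < dec_obs) + 0.5) / (n_sim + 1)
    out[sel] <- qnorm(pd)
  }
  data.frame(ID = prob$sp$obs_id, TIME = prob$sp$time, npde = out)
}

#' Nonparametric bootstrap of the population estimates
#'
#' Resamples subjects with replacement (stratified by formulation arm to
#' preserve the two-arm design), refits the model on each replicate and
#' aggregates the per-parameter median and 5th/95th percentiles.
#' Replicates reuse `init` as starting values with a shortened SAEM
#' schedule; the schedule used is recorded in the result.
#'
#' @param data a [pk_dataset()]
#' @param n_boot number of bootstrap replicates (>= 1)
#' @param init starting [population_model()] (typically the final
#'   estimates); `NULL` for data-driven defaults
#' @param covariates covariate effects to estimate (as in [fit_saem()])
#' @param iiv parameters with IIV
#' @param error_model residual-error model
#' @param seed integer seed; replicate r uses `seed + r`
#' @param stratify resample within formulation arms (default TRUE)
#' @param control SAEM schedule for the refits (default: exploration 200,
#'   smoothing 100, no EBE/RSE/LL overhead)
#' @return a `bootstrap_result`: summary data.frame (median, p5, p95 per
#'   parameter), raw replicate estimates, and `n_success`
#' @export
bootstrap_pk <- function(data, n_boot = 200, init = NULL, covariates = NULL,
                         iiv = setdiff(.PK_PARAMS, "Q"),
                         error_model = "proportional", seed = 1,
                         stratify = TRUE,
                         control = saem_control(K1 = 200, K2 = 100,
                                                compute_rse = FALSE,
                                                compute_ebe = FALSE,
                                                compute_ll = FALSE)) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  stopifnot(inherits(data, "pk_dataset"))
  ids <- unique(data$ID[data$EVID == 1])
  form <- data$FORM[data$EVID == 1][match(ids, data$ID[data$EVID == 1])]
  reps <- vector("list", n_boot)
  n_success <- 0
  for (r in seq_len(n_boot)) {
    set.seed(seed + r)
    take <- if (stratify) {
      unlist(lapply(split(ids, form), function(g)
        sample(g, length(g), replace = TRUE)), use.names = FALSE)
    } else sample(ids, length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(k) {
      sub <- data[data$ID == take[k], , drop = FALSE]
      sub$ID <- k
      sub
    })
    bdat <- pk_dataset(do.call(rbind, pieces))
    fit <- suppressMessages(
      fit_saem(bdat, init = init, covariates = covariates, iiv = iiv,
               error_model = error_model, seed = seed + r,
               control = control))
    if (fit$converged) n_success <- n_success + 1
    reps[[r]] <- .current_estimates(fit$prob, error_model)
  }
  est <- do.call(rbind, reps)
  summ <- data.frame(
    parameter = colnames(est),
    median = apply(est, 2, median),
    p5 = apply(est, 2, quantile, 0.05),
    p95 = apply(est, 2, quantile, 0.95),
    row.names = NULL)
  structure(list(summary = summ, estimates = est, n_boot = n_boot,
                 n_success = n_success, seed = seed,
                 schedule = c(K1 = control$K1, K2 = control$K2)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Nonparametric bootstrap:", x$n_boot, "replicates (",
      x$n_success, "converged ), SAEM schedule",
      paste(x$schedule, collapse = "/"), "\n")
  print(transform(x$summary, median = signif(median, 4),
                  p5 = signif(p5, 4), p95 = signif(p95, 4)))
  invisible(x)
}
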