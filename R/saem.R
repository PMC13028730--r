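#' Control settings for the SAEM estimator
#'
#' Tuning parameters of the stochastic approximation EM run. The schedule
#' has two phases: `K1` exploration iterations with step size 1 (full
#' forgetting) followed by `K2` smoothing iterations with decaying step
#' `1/(k - K1)^stepsize_power`. The E-step kernel is componentwise
#' random-walk Metropolis on the individual (transformed) parameters, with
#' the proposal scale adapted during exploration toward `adapt_target`
#' acceptance, plus one independence proposal from the current population
#' distribution per sweep.
#'
#' @param K1 exploration iterations
#' @param K2 smoothing iterations
#' @param n_kernel Metropolis sweeps per iteration
#' @param stepsize_power decay exponent of the smoothing-phase step
#' @param adapt_target target acceptance rate for scale adaptation
#' @param omega_floor lower bound applied to IIV standard deviations
#' @param ll_nsim importance-sampling size for the final -2LL
#' @param ll_method `"is"` (importance sampling) or `"laplace"`
#' @param compute_rse compute relative standard errors by linearized
#'   Fisher information (adds a few seconds)
#' @param compute_ebe compute empirical Bayes modes and shrinkage
#' @param compute_ll evaluate the marginal -2LL at the final estimates
#'   (switch off in bootstrap replicates where only the estimates matter)
#' @param theta_lower,theta_upper named vectors of bounds on the typical
#'   values (natural scale). Defaults span far beyond physiological
#'   plausibility for an orally dosed small-molecule drug and exist to
#'   stop drift along flat likelihood directions (e.g. an absorption rate
#'   so fast it is indistinguishable from a bolus)
#' @return a `saem_control` list
#' @export
saem_control <- function(K1 = 500, K2 = 200, n_kernel = 2,
                         stepsize_power = 0.7, adapt_target = 0.35,
                         omega_floor = 1e-4,
                         ll_nsim = 1000, ll_method = c("is", "laplace"),
                         compute_rse = TRUE, compute_ebe = TRUE,
                         compute_ll = TRUE,
                         theta_lower = c(ka1 = 1e-4, ka2 = 1e-4, F1 = 1e-3,
                                         tlag2 = 1e-3, CL = 1e-5, V1 = 1e-3,
                                         Q = 1e-5, V2 = 1e-4),
                         theta_upper = c(ka1 = 50, ka2 = 50, F1 = 1 - 1e-3,
                                         tlag2 = 48, CL = 10, V1 = 50,
                                         Q = 50, V2 = 100)) {
  ll_method <- match.arg(ll_method)
  stopifnot(K1 >= 1, K2 >= 1, n_kernel >= 1, stepsize_power > 0.5,
            stepsize_power <= 1)
  structure(list(K1 = K1, K2 = K2, n_kernel = n_kernel,
                 stepsize_power = stepsize_power,
                 adapt_target = adapt_target, omega_floor = omega_floor,
                 ll_nsim = ll_nsim, ll_method = ll_method,
                 compute_rse = compute_rse, compute_ebe = compute_ebe,
                 compute_ll = compute_ll,
                 theta_lower = theta_lower, theta_upper = theta_upper),
            class = "saem_control")
}

# ---- internal problem representation -------------------------------------

# Build the fitting problem: per-subject split, covariate design matrices
# per parameter, initial coefficients on the transformed scale.
.build_problem <- function(data, init, covariates, iiv, error_model) {
  sp <- .split_subjects(data)
  covariates <- if (is.null(covariates) || !NROW(covariates)) {
    data.frame(param = character(), covariate = character())
  } else {
    stopifnot(all(c("param", "covariate") %in% names(covariates)))
    covariates[, c("param", "covariate")]
  }
  cov_ref <- list()
  if ("WT" %in% covariates$covariate) cov_ref$WT <- median(sp$wt)
  if ("AGE" %in% covariates$covariate) cov_ref$AGE <- median(sp$age)

  X <- XtX <- XtXi <- vector("list", 8)
  names(X) <- names(XtX) <- names(XtXi) <- .PK_PARAMS
  for (p in .PK_PARAMS) {
    cols <- covariates$covariate[covariates$param == p]
    Xp <- matrix(1, nrow = sp$n, ncol = 1 + length(cols))
    cn <- "(pop)"
    for (k in seq_along(cols)) {
      Xp[, k + 1] <- .cov_x(cols[k], sp$form, sp$wt, sp$age, cov_ref)
      cn <- c(cn, cols[k])
    }
    colnames(Xp) <- cn
    X[[p]] <- Xp
    XtX[[p]] <- crossprod(Xp)
    # pseudo-inverse fallback: a covariate column can be constant when a
    # fitted model is merely *evaluated* on a subset (e.g. one arm)
    XtXi[[p]] <- tryCatch(solve(XtX[[p]]), error = function(e) {
      s <- svd(XtX[[p]])
      pos <- s$d > 1e-10 * max(s$d)
      s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
    })
  }

  phi0 <- .to_phi(init$theta)
  coefs <- lapply(.PK_PARAMS, function(p) {
    cf <- numeric(ncol(X[[p]]))
    cf[1] <- phi0[[p]]
    # carry over matching initial covariate coefficients, if any
    if (NROW(init$beta)) {
      for (k in seq_len(ncol(X[[p]]) - 1)) {
        hit <- init$beta$param == p &
          init$beta$covariate == colnames(X[[p]])[k + 1]
        if (any(hit)) cf[k + 1] <- init$beta$value[which(hit)[1]]
      }
    }
    cf
  })
  names(coefs) <- .PK_PARAMS

  omega <- init$omega
  omega[setdiff(.PK_PARAMS, iiv)] <- 0
  omega[iiv][omega[iiv] == 0] <- 0.3  # IIV requested but no init: start moderate

  list(sp = sp, X = X, XtX = XtX, XtXi = XtXi, coefs = coefs,
       omega = omega, iiv = iiv, covariates = covariates,
       cov_ref = cov_ref, dose_obs = unname(sp$dose[sp$obs_idx]),
       err = list(error_model = error_model, a = init$a, b = init$b),
       n_obs = length(sp$dv))
}

.phi_typ <- function(prob) {
  out <- vapply(.PK_PARAMS, function(p) drop(prob$X[[p]] %*% prob$coefs[[p]]),
                numeric(prob$sp$n))
  matrix(out, nrow = prob$sp$n, dimnames = list(NULL, .PK_PARAMS))
}

.f_from_phi <- function(prob, phi) {
  th <- .from_phi_mat(phi)
  i <- prob$sp$obs_idx
  .conc_rows(prob$sp$time, th[i, "ka1"], th[i, "ka2"], th[i, "F1"],
             th[i, "tlag2"], th[i, "CL"], th[i, "V1"], th[i, "Q"],
             th[i, "V2"], prob$dose_obs)
}

.obs_ll_rows <- function(prob, f) {
  sd <- .err_sd(f, prob$err)
  dnorm(prob$sp$dv, f, sd, log = TRUE)
}

.obs_ll_subj <- function(prob, f) {
  .ll_by_group_cpp(prob$sp$dv, f, .err_sd(f, prob$err), prob$sp$obs_idx,
                   prob$sp$n)
}

# crude data-driven starting values: clearance from mean exposure, the
# rest generic mid-range values with moderate IIV
.default_init <- function(data, error_model = "proportional") {
  sp <- .split_subjects(data)
  cl0 <- tryCatch({
    aucs <- vapply(seq_len(sp$n), function(i) {
      sel <- sp$obs_idx == i
      tryCatch(
        nca_single(sp$time[sel], sp$dv[sel], sp$dose[[i]])$auc_0_inf,
        error = function(e) NA_real_)
    }, numeric(1))
    md <- median(sp$dose) / median(aucs, na.rm = TRUE)
    if (!is.finite(md) || md <= 0) stop("fallback")
    md
  }, error = function(e) 0.01)
  population_model(
    theta = c(ka1 = 0.3, ka2 = 1, F1 = 0.7, tlag2 = 2,
              CL = cl0, V1 = 0.1, Q = 0.1, V2 = 0.3),
    omega = setNames(rep(0.3, 7), setdiff(.PK_PARAMS, "Q")),
    b = 0.2, a = if (error_model == "proportional") 0 else
      0.1 * median(sp$dv),
    error_model = error_model
  )
}

# ---- the SAEM engine -----------------------------------------------------

#' Fit the population model by stochastic approximation EM
#'
#' Maximum-likelihood estimation of the hierarchical dual-absorption model.
#' The E-step runs Metropolis-within-Gibbs over each individual's
#' transformed parameters; the M-step updates typical values and covariate
#' coefficients from the conjugate (linear-Gaussian) sufficient statistics
#' of the sampled individual parameters, the IIV standard deviations from
#' the residual dispersion, the residual-error coefficient in closed form
#' (proportional and additive models) and parameters without IIV by a
#' damped one-dimensional Newton step on the complete-data likelihood.
#' Runs are reproducible bit-for-bit for a fixed `seed` and control.
#'
#' @param data a [pk_dataset()]
#' @param init starting [population_model()]; `NULL` uses crude
#'   NCA-informed defaults
#' @param covariates data.frame with columns `param`, `covariate` listing
#'   the covariate effects to estimate (e.g. formulation on `tlag2`/`V2`);
#'   `NULL` for none
#' @param iiv parameters carrying inter-individual variability (default:
#'   all except `Q`)
#' @param error_model residual-error model
#' @param seed integer seed
#' @param control a [saem_control()]
#' @return an object of class `pk_fit`: final estimates (a
#'   `population_model`), relative standard errors, `-2LL`, AIC, empirical
#'   Bayes etas, shrinkage, and the iteration trace
#' @export
fit_saem <- function(data, init = NULL, covariates = NULL,
                     iiv = setdiff(.PK_PARAMS, "Q"),
                     error_model = c("proportional", "additive", "combined"),
                     seed = 1, control = saem_control()) {
  error_model <- match.arg(error_model)
  if (is.null(init)) init <- .default_init(data, error_model)
  stopifnot(inherits(init, "population_model"))
  set.seed(seed)
  prob <- .build_problem(data, init, covariates, iiv, error_model)
  n <- prob$sp$n
  K1 <- control$K1; K2 <- control$K2; K <- K1 + K2

  phi_typ <- .phi_typ(prob)
  phi <- phi_typ + 0                   # latent individuals (forced copy:
  f <- .f_from_phi(prob, phi)          # the E-step updates phi in place)
  ll <- .obs_ll_subj(prob, f) + 0
  prop_sd <- pmax(prob$omega, 0.1) / 2 # RW proposal scales
  obs_len <- tabulate(prob$sp$obs_idx, n)
  obs_start <- c(1L, cumsum(obs_len)[-n] + 1L)
  err_code <- match(error_model, c("proportional", "additive", "combined")) - 1L
  phi_lo <- .to_phi(control$theta_lower[.PK_PARAMS])
  phi_hi <- .to_phi(control$theta_upper[.PK_PARAMS])

  iiv_idx <- which(.PK_PARAMS %in% prob$iiv)
  d <- length(iiv_idx)

  # stochastic-approximation accumulators
  s_xy <- lapply(prob$coefs, function(cf) numeric(length(cf)))
  s_phi2 <- numeric(8)
  s_err <- 0
  warned_floor <- FALSE

  # smoothing-phase posterior moments of eta (for -2LL proposal and EBEs)
  m_sum <- matrix(0, n, d)
  c_sum <- array(0, c(n, d, d))
  m_count <- 0

  trace_names <- c(.PK_PARAMS,
                   if (NROW(prob$covariates))
                     paste0("beta_", prob$covariates$param, "_",
                            prob$covariates$covariate),
                   if (length(prob$iiv)) paste0("omega_", prob$iiv),
                   switch(error_model, proportional = "b", additive = "a",
                          combined = c("a", "b")))
  trace <- matrix(NA_real_, K, length(trace_names),
                  dimnames = list(NULL, trace_names))

  for (k in seq_len(K)) {
    gamma <- if (k <= K1) 1 else 1 / (k - K1)^control$stepsize_power

    ## E-step: Metropolis-within-Gibbs on phi columns with IIV
    ## (random-walk + independence kernels, compiled)
    acc_rate <- .mh_estep_cpp(phi, ll, phi_typ, prob$omega, prop_sd,
                              iiv_idx, prob$sp$time, prob$sp$dv,
                              prob$dose_obs, obs_start, obs_len,
                              err_code, prob$err$a, prob$err$b,
                              control$n_kernel)
    if (k <= K1)
      prop_sd[iiv_idx] <- prop_sd[iiv_idx] *
        exp(0.4 / sqrt(k) * (acc_rate - control$adapt_target))

    ## M-step: stochastic approximation of sufficient statistics
    newton_cols <- setdiff(seq_len(8), iiv_idx)
    for (j in iiv_idx) {
      p <- .PK_PARAMS[j]
      s_xy[[p]] <- s_xy[[p]] + gamma * (drop(crossprod(prob$X[[p]], phi[, j])) - s_xy[[p]])
      s_phi2[j] <- s_phi2[j] + gamma * (sum(phi[, j]^2) - s_phi2[j])
      cf <- drop(prob$XtXi[[p]] %*% s_xy[[p]])
      v <- (s_phi2[j] - 2 * sum(cf * s_xy[[p]]) +
              drop(t(cf) %*% prob$XtX[[p]] %*% cf)) / n
      # simulated annealing: during exploration the IIV variance may
      # shrink by at most 5% per iteration, preventing early collapse
      if (k <= K1) v <- max(v, 0.95 * prob$omega[j]^2)
      om_new <- min(sqrt(max(v, control$omega_floor^2)), 3)
      # typical values stay inside the plausibility bounds; covariate
      # effects within +-5 log units
      cf[1] <- max(min(cf[1], phi_hi[j]), phi_lo[j])
      if (length(cf) > 1) cf[-1] <- pmax(pmin(cf[-1], 5), -5)
      if (v < control$omega_floor^2 && !warned_floor && k > K1) {
        warning("omega for ", p, " collapsed; floored at ",
                control$omega_floor)
        warned_floor <- TRUE
      }
      prob$coefs[[p]] <- cf
      prob$omega[j] <- om_new
      # a collapsed omega pins the sampled phi to the typical value, so
      # the conjugate update can no longer move the typical value; fall
      # back to the direct likelihood update for this parameter
      if (om_new <= control$omega_floor * 1.01)
        newton_cols <- c(newton_cols, j)
    }
    # parameters without IIV (and collapsed-IIV parameters): damped
    # Newton on the complete-data likelihood
    for (j in newton_cols) {
      p <- .PK_PARAMS[j]
      for (ci in seq_along(prob$coefs[[p]])) {
        h <- 1e-3
        eval_ll <- function(cval) {
          cf <- prob$coefs[[p]]; cf[ci] <- cval
          pt <- drop(prob$X[[p]] %*% cf)
          phi2 <- phi; phi2[, j] <- pt
          sum(.obs_ll_rows(prob, .f_from_phi(prob, phi2)))
        }
        c0 <- prob$coefs[[p]][ci]
        l0 <- eval_ll(c0); lm <- eval_ll(c0 - h); lp <- eval_ll(c0 + h)
        g1 <- (lp - lm) / (2 * h); g2 <- (lp - 2 * l0 + lm) / h^2
        stp <- if (is.finite(g2) && g2 < 0) g1 / (-g2) else sign(g1) * 0.05
        stp <- max(min(stp, 0.3), -0.3)
        lo <- if (ci == 1) phi_lo[j] else -5
        hi <- if (ci == 1) phi_hi[j] else 5
        prob$coefs[[p]][ci] <- max(min(c0 + gamma * stp, hi), lo)
      }
    }
    phi_typ <- .phi_typ(prob)
    for (j in newton_cols) phi[, j] <- phi_typ[, j]
    f <- .f_from_phi(prob, phi)

    # residual-error update
    if (error_model == "proportional") {
      s_err <- s_err + gamma * (sum(((prob$sp$dv - f) / f)^2) - s_err)
      b2 <- s_err / prob$n_obs
      if (k <= K1) b2 <- max(b2, 0.95 * prob$err$b^2)  # annealing
      prob$err$b <- sqrt(b2)
    } else if (error_model == "additive") {
      s_err <- s_err + gamma * (sum((prob$sp$dv - f)^2) - s_err)
      a2 <- s_err / prob$n_obs
      if (k <= K1) a2 <- max(a2, 0.95 * prob$err$a^2)
      prob$err$a <- sqrt(a2)
    } else {
      # combined a + b f: one damped Newton step per coordinate
      res <- prob$sp$dv - f
      nll <- function(ab) {
        sdv <- pmax(ab[1] + ab[2] * f, 1e-12)
        sum(log(sdv) + res^2 / (2 * sdv^2))
      }
      cur <- c(prob$err$a, prob$err$b)
      for (ci in 1:2) {
        h <- 1e-4
        up <- cur; um <- cur; up[ci] <- cur[ci] + h; um[ci] <- max(cur[ci] - h, 1e-8)
        l0 <- nll(cur); lp <- nll(up); lm <- nll(um)
        g1 <- (lp - lm) / (2 * h); g2 <- (lp - 2 * l0 + lm) / h^2
        stp <- if (is.finite(g2) && g2 > 0) -g1 / g2 else -sign(g1) * 0.01
        cur[ci] <- max(cur[ci] + gamma * max(min(stp, 0.05), -0.05), 1e-6)
      }
      prob$err$a <- cur[1]; prob$err$b <- cur[2]
    }
    ll <- .obs_ll_subj(prob, f)

    # smoothing-phase posterior moments of eta
    if (k > K1) {
      eta <- (phi - phi_typ)[, iiv_idx, drop = FALSE]
      m_sum <- m_sum + eta
      for (a_ in seq_len(d)) for (b_ in a_:d) {
        c_sum[, a_, b_] <- c_sum[, a_, b_] + eta[, a_] * eta[, b_]
        if (b_ > a_) c_sum[, b_, a_] <- c_sum[, a_, b_]
      }
      m_count <- m_count + 1
    }

    trace[k, ] <- .current_estimates(prob, error_model)
  }

  # when the estimated IIV is negligible the marginal likelihood is (to
  # first order) the fixed-effect likelihood; maximize it directly so the
  # typical values reach the optimum instead of the stochastic
  # approximation's station noise
  if (d == 0 || max(prob$omega[iiv_idx]) < 0.05)
    prob <- .polish_fixed(prob, error_model, phi_lo, phi_hi)

  eta_mean <- m_sum / m_count
  eta_cov <- c_sum / m_count
  for (a_ in seq_len(d)) for (b_ in seq_len(d))
    eta_cov[, a_, b_] <- eta_cov[, a_, b_] - eta_mean[, a_] * eta_mean[, b_]

  est <- .estimates_model(prob, error_model)
  npar <- 8 + NROW(prob$covariates) + length(iiv_idx) +
    switch(error_model, proportional = 1, additive = 1, combined = 2)

  # convergence heuristic: smoothed estimates stable over the last
  # smoothing iterations
  tail_it <- trace[(K - min(50, K2) + 1):K, , drop = FALSE]
  rel_range <- apply(tail_it, 2, function(x) {
    m <- mean(abs(x)); if (m < 1e-8) 0 else diff(range(x)) / m
  })
  converged <- all(rel_range < 0.1)
  if (!converged)
    message("estimates still drifting over the final smoothing window: ",
            paste0(names(rel_range)[rel_range >= 0.1], " (",
                   round(100 * rel_range[rel_range >= 0.1]), "%)",
                   collapse = ", "),
            "; fit flagged, consider increasing K1/K2")

  fit <- structure(list(
    model = est, prob = prob, data = data, seed = seed, control = control,
    trace = trace, converged = converged, stationarity = rel_range,
    eta_mean = eta_mean, eta_cov = eta_cov, iiv_idx = iiv_idx,
    npar = npar, minus2ll = NA_real_, aic = NA_real_,
    rse_pct = NULL, ebes = NULL, eta_shrinkage_pct = NULL
  ), class = "pk_fit")

  if (control$compute_ll) {
    fit$minus2ll <- .marginal_m2ll(fit, method = control$ll_method,
                                   nsim = control$ll_nsim, seed = seed + 10^6)
    fit$aic <- fit$minus2ll + 2 * npar
  }

  if (control$compute_ebe) {
    fit$ebes <- .ebe_modes(fit)
    sdv <- apply(fit$ebes, 2, sd)
    fit$eta_shrinkage_pct <- setNames(
      100 * (1 - sdv / prob$omega[iiv_idx]), .PK_PARAMS[iiv_idx])
  }
  if (control$compute_rse) {
    fit$rse_pct <- tryCatch(.linearized_rse(fit), error = function(e) {
      warning("RSE computation failed: ", conditionMessage(e))
      NULL
    })
  }
  fit
}

# direct maximum likelihood over the typical-value coefficients and the
# residual error, holding random effects at zero (valid when IIV is
# absent or negligible)
.polish_fixed <- function(prob, error_model, phi_lo, phi_hi) {
  lens <- vapply(prob$coefs, length, integer(1))
  pack <- function(pr) c(unlist(pr$coefs, use.names = FALSE),
                         switch(error_model,
                                proportional = log(pr$err$b),
                                additive = log(pr$err$a),
                                combined = log(c(pr$err$a, pr$err$b))))
  unpack <- function(x, pr) {
    k <- 0
    for (p in .PK_PARAMS) {
      pr$coefs[[p]] <- x[k + seq_len(lens[[p]])]
      k <- k + lens[[p]]
    }
    if (error_model == "proportional") pr$err$b <- exp(x[k + 1])
    if (error_model == "additive") pr$err$a <- exp(x[k + 1])
    if (error_model == "combined") {
      pr$err$a <- exp(x[k + 1]); pr$err$b <- exp(x[k + 2])
    }
    pr
  }
  nll <- function(x) {
    pr <- unpack(x, prob)
    ints <- vapply(pr$coefs, `[`, numeric(1), 1)
    if (any(ints < phi_lo - 1e-9) || any(ints > phi_hi + 1e-9)) return(1e10)
    v <- -sum(.obs_ll_rows(pr, .f_from_phi(pr, .phi_typ(pr))))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- optim(pack(prob), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  unpack(opt$par, prob)
}

.current_estimates <- function(prob, error_model) {
  th <- vapply(.PK_PARAMS, function(p) prob$coefs[[p]][1], numeric(1))
  th <- exp(th)
  th[["F1"]] <- plogis(prob$coefs[["F1"]][1])
  betas <- if (NROW(prob$covariates)) {
    setNames(vapply(seq_len(nrow(prob$covariates)), function(r) {
      p <- prob$covariates$param[r]; cv <- prob$covariates$covariate[r]
      prob$coefs[[p]][match(cv, colnames(prob$X[[p]]))]
    }, numeric(1)),
    paste0("beta_", prob$covariates$param, "_", prob$covariates$covariate))
  } else numeric(0)
  om <- prob$omega[.PK_PARAMS %in% prob$iiv]
  if (length(om)) names(om) <- paste0("omega_", names(om))
  c(th, betas, om,
    switch(error_model, proportional = c(b = prob$err$b),
           additive = c(a = prob$err$a),
           combined = c(a = prob$err$a, b = prob$err$b)))
}

.estimates_model <- function(prob, error_model) {
  th <- vapply(.PK_PARAMS, function(p) prob$coefs[[p]][1], numeric(1))
  theta <- exp(th); theta[["F1"]] <- plogis(th[["F1"]])
  beta <- if (NROW(prob$covariates)) {
    data.frame(param = prob$covariates$param,
               covariate = prob$covariates$covariate,
               value = vapply(seq_len(nrow(prob$covariates)), function(r) {
                 p <- prob$covariates$param[r]
                 cv <- prob$covariates$covariate[r]
                 prob$coefs[[p]][match(cv, colnames(prob$X[[p]]))]
               }, numeric(1)))
  } else NULL
  population_model(theta = theta,
                   omega = prob$omega[prob$omega > 0],
                   beta = beta,
                   b = max(prob$err$b, 1e-8), a = prob$err$a,
                   error_model = error_model,
                   cov_ref = prob$cov_ref)
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("SAEM fit (", nrow(x$trace), " iterations, seed ", x$seed, ")\n",
      sep = "")
  print(x$model)
  cat(sprintf("-2LL = %.2f   AIC = %.2f   (%d estimated parameters)\n",
              x$minus2ll, x$aic, x$npar))
  if (!is.null(x$eta_shrinkage_pct)) {
    cat("eta-shrinkage (%):\n")
    print(round(x$eta_shrinkage_pct, 1))
  }
  if (!x$converged) cat("NOTE: flagged as not converged\n")
  invisible(x)
}
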