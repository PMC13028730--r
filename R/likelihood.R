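# ---- marginal likelihood, EBEs and standard errors -----------------------

# log-sum-exp over rows of a matrix
.lse_rows <- function(m) {
  mx <- apply(m, 1, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- -Inf
  out
}

# per-subject Cholesky factors of inflated posterior covariances,
# jittered to positive definiteness
.prop_chol <- function(eta_cov, inflate = 2) {
  n <- dim(eta_cov)[1]; d <- dim(eta_cov)[2]
  L <- array(0, c(n, d, d))
  for (i in seq_len(n)) {
    C <- inflate * eta_cov[i, , ] + diag(1e-6, d)
    ch <- tryCatch(chol(C), error = function(e) chol(C + diag(0.01, d)))
    L[i, , ] <- t(ch)  # lower triangular
  }
  L
}

# importance-sampled or Laplace -2 log marginal likelihood for a fit-like
# object (prob + eta posterior moments)
.marginal_m2ll <- function(fit, method = c("is", "laplace"),
                           nsim = 1000, seed = 1) {
  method <- match.arg(method)
  prob <- fit$prob
  n <- prob$sp$n
  iiv_idx <- fit$iiv_idx
  d <- length(iiv_idx)
  phi_typ <- .phi_typ(prob)
  om <- prob$omega[iiv_idx]

  f0 <- .f_from_phi(prob, phi_typ)
  if (any(!is.finite(f0))) {
    bad <- which(!is.finite(f0))[1]
    stop("non-finite prediction for subject ", prob$sp$obs_id[bad],
         " at t = ", prob$sp$time[bad])
  }

  # no random effects: the marginal likelihood is the observation density
  # at the typical predictions, exactly
  if (d == 0) return(-2 * sum(.obs_ll_subj(prob, f0)))

  if (method == "laplace") return(.laplace_m2ll(fit))

  set.seed(seed)
  # multivariate-t proposal (df = 4) around the conditional moments:
  # heavier tails than the target keep the importance weights bounded
  L <- .prop_chol(fit$eta_cov, inflate = 1.5)
  obs_len <- tabulate(prob$sp$obs_idx, n)
  obs_start <- c(1L, cumsum(obs_len)[-n] + 1L)
  err_code <- match(prob$err$error_model,
                    c("proportional", "additive", "combined")) - 1L
  logw <- .is_logw_cpp(phi_typ, fit$eta_mean, as.vector(L),
                       prob$omega, iiv_idx, 4, nsim,
                       prob$sp$time, prob$sp$dv, prob$dose_obs,
                       obs_start, obs_len, err_code,
                       prob$err$a, prob$err$b)
  -2 * sum(.lse_rows(logw) - log(nsim))
}

# negative log joint density of one subject's data and etas
.subject_nlpost <- function(prob, phi_typ, iiv_idx, i, sel, om) {
  force(sel)
  function(eta) {
    if (any(!is.finite(eta)) || any(abs(eta) > 30)) return(1e10)
    phi_i <- phi_typ[i, ]
    phi_i[iiv_idx] <- phi_i[iiv_idx] + eta
    th <- exp(phi_i); th[["F1"]] <- plogis(phi_i[["F1"]])
    f <- .conc_rows(prob$sp$time[sel], th[["ka1"]], th[["ka2"]], th[["F1"]],
                    th[["tlag2"]], th[["CL"]], th[["V1"]], th[["Q"]],
                    th[["V2"]], prob$dose_obs[sel])
    sd <- .err_sd(f, prob$err)
    v <- -(sum(dnorm(prob$sp$dv[sel], f, sd, log = TRUE)) +
             sum(dnorm(eta, 0, om, log = TRUE)))
    if (!is.finite(v)) 1e10 else v
  }
}

# empirical Bayes estimates: per-subject conditional modes of eta
.ebe_modes <- function(fit) {
  prob <- fit$prob
  n <- prob$sp$n
  iiv_idx <- fit$iiv_idx
  d <- length(iiv_idx)
  phi_typ <- .phi_typ(prob)
  om <- prob$omega[iiv_idx]
  out <- matrix(0, n, d, dimnames = list(NULL, .PK_PARAMS[iiv_idx]))
  if (d == 0) return(out)
  for (i in seq_len(n)) {
    sel <- prob$sp$obs_idx == i
    nl <- .subject_nlpost(prob, phi_typ, iiv_idx, i, sel, om)
    st <- if (!is.null(fit$eta_mean)) fit$eta_mean[i, ] else rep(0, d)
    opt <- optim(st, nl, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-10))
    out[i, ] <- opt$par
  }
  out
}

.laplace_m2ll <- function(fit) {
  prob <- fit$prob
  n <- prob$sp$n
  iiv_idx <- fit$iiv_idx
  d <- length(iiv_idx)
  phi_typ <- .phi_typ(prob)
  om <- prob$omega[iiv_idx]
  modes <- if (!is.null(fit$ebes)) fit$ebes else .ebe_modes(fit)
  total <- 0
  for (i in seq_len(n)) {
    sel <- prob$sp$obs_idx == i
    nl <- .subject_nlpost(prob, phi_typ, iiv_idx, i, sel, om)
    m <- modes[i, ]
    H <- .num_hessian(nl, m)
    # guard: force PD by eigenvalue flooring
    ev <- eigen(H, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-8)
    ldet <- sum(log(lam))
    total <- total + (-nl(m) + d / 2 * log(2 * pi) - 0.5 * ldet)
  }
  -2 * total
}

.num_hessian <- function(fn, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- fn(x)
  hh <- pmax(h, h * abs(x))
  for (a in seq_len(d)) {
    for (b in a:d) {
      xa <- x; xa[a] <- xa[a] + hh[a]
      xb <- x; xb[b] <- xb[b] + hh[b]
      xab <- xa; xab[b] <- xab[b] + hh[b]
      H[a, b] <- H[b, a] <-
        (fn(xab) - fn(xa) - fn(xb) + f0) / (hh[a] * hh[b])
    }
  }
  H
}

#' Marginal -2 log-likelihood of a population model
#'
#' Approximates `-2 log L` of the data under a fitted or candidate model by
#' importance sampling around the conditional distribution of the random
#' effects (proposal built from posterior moments obtained by a short MCMC
#' warm-up, or reused from a fit), or by the Laplace approximation.
#'
#' @param model a [population_model()] or a `pk_fit`
#' @param data a [pk_dataset()] (ignored when `model` is a fit)
#' @param method `"is"` or `"laplace"`
#' @param nsim importance-sampling size
#' @param seed integer seed for the Monte Carlo approximation
#' @return the scalar `-2LL`
#' @export
loglikelihood <- function(model, data = NULL, method = c("is", "laplace"),
                          nsim = 1000, seed = 1) {
  method <- match.arg(method)
  if (inherits(model, "pk_fit"))
    return(.marginal_m2ll(model, method = method, nsim = nsim, seed = seed))
  stopifnot(inherits(model, "population_model"), !is.null(data))
  fitlike <- .model_as_fit(model, data, seed = seed)
  .marginal_m2ll(fitlike, method = method, nsim = nsim, seed = seed)
}

# wrap a fixed population model + data as a fit-like object: build the
# problem and obtain eta posterior moments by a short Metropolis warm-up
.model_as_fit <- function(model, data, warm = 300, seed = 1) {
  iiv <- names(model$omega)[model$omega > 0]
  covs <- if (NROW(model$beta)) model$beta[, c("param", "covariate")] else NULL
  prob <- .build_problem(data, model, covs, iiv, model$error_model)
  n <- prob$sp$n
  iiv_idx <- which(.PK_PARAMS %in% prob$iiv)
  d <- length(iiv_idx)
  set.seed(seed)
  phi_typ <- .phi_typ(prob)
  phi <- phi_typ + 0
  ll <- .obs_ll_subj(prob, .f_from_phi(prob, phi)) + 0
  prop_sd <- pmax(prob$omega, 0.05) / 2
  obs_len <- tabulate(prob$sp$obs_idx, n)
  obs_start <- c(1L, cumsum(obs_len)[-n] + 1L)
  err_code <- match(prob$err$error_model,
                    c("proportional", "additive", "combined")) - 1L
  m_sum <- matrix(0, n, d); c_sum <- array(0, c(n, d, d)); cnt <- 0
  for (k in seq_len(warm)) {
    acc_rate <- .mh_estep_cpp(phi, ll, phi_typ, prob$omega, prop_sd,
                              iiv_idx, prob$sp$time, prob$sp$dv,
                              prob$dose_obs, obs_start, obs_len,
                              err_code, prob$err$a, prob$err$b, 1L)
    if (k <= warm / 2)
      prop_sd[iiv_idx] <- prop_sd[iiv_idx] *
        exp(0.4 / sqrt(k) * (acc_rate - 0.35))
    if (k > warm / 2) {
      eta <- (phi - phi_typ)[, iiv_idx, drop = FALSE]
      m_sum <- m_sum + eta
      for (a in seq_len(d)) for (b in a:d) {
        c_sum[, a, b] <- c_sum[, a, b] + eta[, a] * eta[, b]
        if (b > a) c_sum[, b, a] <- c_sum[, a, b]
      }
      cnt <- cnt + 1
    }
  }
  em <- m_sum / cnt
  ec <- c_sum / cnt
  for (a in seq_len(d)) for (b in seq_len(d))
    ec[, a, b] <- ec[, a, b] - em[, a] * em[, b]
  list(prob = prob, eta_mean = em, eta_cov = ec, iiv_idx = iiv_idx)
}

# ---- linearized Fisher information / RSEs --------------------------------

# First-order linearization: y_i ~ N(f_i(theta), B_i D B_i' + R_i) with
# B_i = df/deta at eta = 0 and R_i the residual variance at the typical
# prediction. The FIM is assembled from central finite differences of the
# per-subject mean and covariance over all estimated parameters.
.linearized_rse <- function(fit) {
  prob <- fit$prob
  n <- prob$sp$n
  iiv_idx <- fit$iiv_idx
  d <- length(iiv_idx)
  em <- prob$err$error_model

  psi <- .pack_psi(prob, em)
  P <- length(psi$value)

  mv <- function(pv) .mean_and_cov(prob, psi, pv, iiv_idx)
  ctr <- mv(psi$value)
  Vinv <- lapply(seq_len(n), function(i) solve(ctr$V[[i]]))

  dm <- vector("list", P); dV <- vector("list", P)
  for (a in seq_len(P)) {
    h <- max(1e-4, 1e-4 * abs(psi$value[a]))
    up <- psi$value; up[a] <- up[a] + h
    dn <- psi$value; dn[a] <- dn[a] - h
    ru <- mv(up); rd <- mv(dn)
    dm[[a]] <- (ru$f - rd$f) / (2 * h)
    dV[[a]] <- lapply(seq_len(n), function(i)
      (ru$V[[i]] - rd$V[[i]]) / (2 * h))
  }

  FIM <- matrix(0, P, P)
  for (i in seq_len(n)) {
    sel <- prob$sp$obs_idx == i
    Vi <- Vinv[[i]]
    for (a in seq_len(P)) {
      da <- dm[[a]][sel]
      Wa <- Vi %*% dV[[a]][[i]]
      for (b in a:P) {
        v <- drop(t(da) %*% Vi %*% dm[[b]][sel]) +
          0.5 * sum(Wa * t(Vi %*% dV[[b]][[i]]))
        FIM[a, b] <- FIM[b, a] <- FIM[a, b] + v
      }
    }
  }
  se <- sqrt(diag(solve(FIM)))
  .psi_to_rse(psi, se, prob)
}

# flatten estimated parameters into a vector with bookkeeping
.pack_psi <- function(prob, em) {
  value <- c(); kind <- c(); label <- c()
  for (p in .PK_PARAMS) {
    cf <- prob$coefs[[p]]
    value <- c(value, cf)
    kind <- c(kind, if (p == "F1") "logit_pop" else "log_pop",
              rep("beta", length(cf) - 1))
    label <- c(label, p,
               if (length(cf) > 1)
                 paste0("beta_", p, "_", colnames(prob$X[[p]])[-1]))
  }
  for (p in .PK_PARAMS[.PK_PARAMS %in% prob$iiv]) {
    value <- c(value, prob$omega[p]); kind <- c(kind, "omega")
    label <- c(label, paste0("omega_", p))
  }
  if (em %in% c("additive", "combined")) {
    value <- c(value, prob$err$a); kind <- c(kind, "err"); label <- c(label, "a")
  }
  if (em %in% c("proportional", "combined")) {
    value <- c(value, prob$err$b); kind <- c(kind, "err"); label <- c(label, "b")
  }
  list(value = value, kind = kind, label = label)
}

# rebuild (coefs, omega, err) from a psi vector and compute per-subject
# typical mean and linearized covariance
.mean_and_cov <- function(prob, psi, pv, iiv_idx) {
  pr <- prob
  k <- 0
  for (p in .PK_PARAMS) {
    np <- length(pr$coefs[[p]])
    pr$coefs[[p]] <- pv[k + seq_len(np)]
    k <- k + np
  }
  for (p in .PK_PARAMS[.PK_PARAMS %in% prob$iiv]) {
    k <- k + 1
    pr$omega[p] <- pv[k]
  }
  if (pr$err$error_model %in% c("additive", "combined")) {
    k <- k + 1; pr$err$a <- pv[k]
  }
  if (pr$err$error_model %in% c("proportional", "combined")) {
    k <- k + 1; pr$err$b <- pv[k]
  }
  phi_typ <- .phi_typ(pr)
  f <- .f_from_phi(pr, phi_typ)
  d <- length(iiv_idx)
  # B: df/deta by central differences, one IIV column at a time
  B <- matrix(0, length(f), d)
  h <- 1e-4
  for (a in seq_len(d)) {
    j <- iiv_idx[a]
    up <- phi_typ; up[, j] <- up[, j] + h
    dn <- phi_typ; dn[, j] <- dn[, j] - h
    B[, a] <- (.f_from_phi(pr, up) - .f_from_phi(pr, dn)) / (2 * h)
  }
  D <- diag(pr$omega[iiv_idx]^2, d)
  sd <- .err_sd(f, pr$err)
  V <- lapply(seq_len(pr$sp$n), function(i) {
    sel <- pr$sp$obs_idx == i
    Bi <- B[sel, , drop = FALSE]
    Bi %*% D %*% t(Bi) + diag(sd[sel]^2, sum(sel))
  })
  list(f = f, V = V)
}

# map SEs on the internal scale to percent RSEs on the reporting scale
.psi_to_rse <- function(psi, se, prob) {
  out <- numeric(length(se))
  for (k in seq_along(se)) {
    out[k] <- switch(psi$kind[k],
      log_pop = 100 * se[k],           # delta method: RSE of exp(phi)
      logit_pop = {
        p <- plogis(psi$value[k])
        100 * se[k] * (1 - p)          # RSE of plogis(phi): se*p(1-p)/p
      },
      beta = 100 * se[k] / abs(psi$value[k]),
      omega = 100 * se[k] / psi$value[k],
      err = 100 * se[k] / psi$value[k])
  }
  setNames(out, psi$label)
}
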