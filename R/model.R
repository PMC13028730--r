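#' Hierarchical population PK model
#'
#' Defines the nonlinear mixed-effects model around the dual-absorption
#' structural model. Individual parameters follow
#' `P_i = P_pop * exp(beta * x_i) * exp(eta_i)` with `eta_i ~ N(0, omega^2)`
#' independently per parameter (lognormal inter-individual variability);
#' the absorbed fraction `F1` is handled on the logit scale so realized
#' values stay inside (0, 1). Residual error on observed concentrations is
#' proportional by default: `y = f * (1 + b * eps)`, `eps ~ N(0, 1)`.
#'
#' Covariate effects are multiplicative-exponential. For the formulation
#' factor (`FORM`), `x_i` is the indicator of the `NC` arm, so the typical
#' NC value is `P_pop * exp(beta)`. For continuous covariates (body weight
#' `WT`, age `AGE`) `x_i = log(cov_i / ref)`, i.e. a power model normalised
#' at the reference value.
#'
#' @param theta named vector of typical values for
#'   `ka1, ka2, F1, tlag2, CL, V1, Q, V2` (natural scale, canonical units)
#' @param omega named vector of inter-individual standard deviations on the
#'   transformed (log / logit) scale; parameters absent or set to 0 carry
#'   no IIV
#' @param beta data.frame with columns `param`, `covariate`, `value`
#'   (may be NULL / empty for no covariate effects)
#' @param b proportional residual-error coefficient (unitless)
#' @param a additive residual-error SD (ug/mL), used by the additive and
#'   combined error models
#' @param error_model one of `"proportional"`, `"additive"`, `"combined"`
#' @param cov_ref named list of reference values for continuous covariates
#'   (defaults filled with the data median at fit/simulation time)
#' @return an object of class `population_model`
#' @examples
#' m <- population_model(
#'   theta = c(ka1 = 0.086, ka2 = 1.82, F1 = 0.85, tlag2 = 1.22,
#'             CL = 0.006, V1 = 0.049, Q = 0.24, V2 = 0.134),
#'   omega = c(ka1 = 0.38, ka2 = 1.28, F1 = 0.67, tlag2 = 0.38,
#'             CL = 0.32, V1 = 1.44, V2 = 0.65),
#'   beta = data.frame(param = c("tlag2", "V2"), covariate = "FORM",
#'                     value = c(0.74, 1.11)),
#'   b = 0.19)
#' apply_covariates(m, "NC")["tlag2"]  # 1.22 * exp(0.74)
#' @export
population_model <- function(theta, omega = NULL, beta = NULL,
                             b = 0.2, a = 0,
                             error_model = c("proportional", "additive",
                                             "combined"),
                             cov_ref = list()) {
  error_model <- match.arg(error_model)
  if (!all(.PK_PARAMS %in% names(theta)))
    stop("theta must name all of: ", paste(.PK_PARAMS, collapse = ", "))
  theta <- theta[.PK_PARAMS]
  validate_structural_params(theta)
  om <- setNames(numeric(8), .PK_PARAMS)
  if (!is.null(omega)) {
    bad <- setdiff(names(omega), .PK_PARAMS)
    if (length(bad)) stop("unknown omega name(s): ", paste(bad, collapse = ", "))
    om[names(omega)] <- omega
  }
  if (any(om < 0)) stop("omega must be >= 0")
  if (is.null(beta) || !NROW(beta)) {
    beta <- data.frame(param = character(), covariate = character(),
                       value = numeric())
  } else {
    stopifnot(all(c("param", "covariate", "value") %in% names(beta)))
    if (!all(beta$param %in% .PK_PARAMS))
      stop("beta$param must be structural parameter names")
  }
  if (error_model == "proportional" && b <= 0) stop("b must be > 0")
  if (error_model == "additive" && a <= 0) stop("a must be > 0")
  if (error_model == "combined" && (a <= 0 || b <= 0)) stop("a and b must be > 0")
  structure(list(theta = theta, omega = om, beta = beta,
                 b = b, a = a, error_model = error_model,
                 cov_ref = cov_ref),
            class = "population_model")
}

# transforms between the natural and the internal (phi) scale:
# log for everything except F1, which is logit
.to_phi <- function(theta) {
  phi <- log(theta)
  phi["F1"] <- qlogis(theta[["F1"]])
  phi
}
.from_phi_mat <- function(phi) {
  # phi: matrix n x 8 with .PK_PARAMS columns
  out <- exp(phi)
  out[, "F1"] <- plogis(phi[, "F1"])
  out
}

# covariate value entering the linear predictor for one subject
.cov_x <- function(covariate, form, wt, age, cov_ref) {
  switch(covariate,
    FORM = as.numeric(form == "NC"),
    WT = log(wt / (cov_ref$WT %||% stats::median(wt))),
    AGE = log(age / (cov_ref$AGE %||% stats::median(age))),
    stop("unknown covariate: ", covariate)
  )
}

#' Covariate-adjusted typical parameters
#'
#' Applies the multiplicative exponential covariate model to the typical
#' values: parameters carrying a formulation effect are multiplied by
#' `exp(beta)` for the `NC` level and unchanged for `FREE`; continuous
#' covariates are evaluated at `covariates` (or left at reference).
#'
#' @param model a [population_model()]
#' @param formulation `"FREE"` or `"NC"`
#' @param covariates optional named list of continuous covariate values
#'   (e.g. `list(WT = 12)`); absent covariates sit at their reference
#' @return named vector of typical structural parameters (natural scale)
#' @export
apply_covariates <- function(model, formulation, covariates = list()) {
  if (!formulation %in% c("FREE", "NC"))
    stop("unknown formulation level: ", formulation)
  phi <- .to_phi(model$theta)
  if (NROW(model$beta)) {
    for (r in seq_len(nrow(model$beta))) {
      p <- model$beta$param[r]; cv <- model$beta$covariate[r]
      x <- if (cv == "FORM") as.numeric(formulation == "NC") else {
        val <- covariates[[cv]]
        ref <- model$cov_ref[[cv]]
        if (is.null(val) || is.null(ref)) 0 else log(val / ref)
      }
      phi[p] <- phi[p] + model$beta$value[r] * x
    }
  }
  th <- exp(phi)
  th[["F1"]] <- plogis(phi[["F1"]])
  th
}

#' Draw individual parameters from the hierarchical model
#'
#' Samples `eta ~ N(0, omega^2)` independently per parameter and returns
#' the realized parameters `P_pop * exp(beta x) * exp(eta)` (logit scale
#' for `F1`). Deterministic for a given `seed`.
#'
#' @param model a [population_model()]
#' @param formulation arm level, recycled over `n`
#' @param n number of individuals
#' @param seed optional integer seed
#' @param covariates optional data.frame of continuous covariates (n rows)
#' @return list with `eta` (n x 8 matrix, transformed scale) and
#'   `params` (n x 8 matrix, natural scale)
#' @export
sample_individual <- function(model, formulation, n = 1, seed = NULL,
                              covariates = NULL) {
  if (!is.null(seed)) set.seed(seed)
  formulation <- rep_len(formulation, n)
  eta <- sapply(.PK_PARAMS, function(p)
    if (model$omega[[p]] > 0) rnorm(n, 0, model$omega[[p]]) else numeric(n))
  eta <- matrix(eta, nrow = n, dimnames = list(NULL, .PK_PARAMS))
  phi_typ <- t(vapply(seq_len(n), function(i) {
    cov_i <- if (is.null(covariates)) list() else as.list(covariates[i, , drop = FALSE])
    .to_phi(apply_covariates(model, formulation[i], cov_i))
  }, numeric(8)))
  colnames(phi_typ) <- .PK_PARAMS
  params <- .from_phi_mat(phi_typ + eta)
  list(eta = eta, params = params)
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (two-compartment, dual first-order absorption)\n")
  cat("typical values:\n")
  print(signif(x$theta, 4))
  cat("IIV sd (transformed scale):\n")
  print(signif(x$omega[x$omega > 0], 4))
  if (NROW(x$beta)) {
    cat("covariate effects:\n")
    print(x$beta)
  }
  cat("residual error:", x$error_model,
      switch(x$error_model,
             proportional = sprintf("(b = %.4g)", x$b),
             additive = sprintf("(a = %.4g)", x$a),
             combined = sprintf("(a = %.4g, b = %.4g)", x$a, x$b)), "\n")
  invisible(x)
}

# residual-error SD as a function of predicted f
.err_sd <- function(f, model_or_err) {
  em <- model_or_err$error_model; a <- model_or_err$a; b <- model_or_err$b
  sd <- switch(em,
               proportional = b * f,
               additive = rep_len(a, length(f)),
               combined = a + b * f)
  pmax(sd, 1e-12)
}
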