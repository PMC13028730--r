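# shared fixtures: reference parameter sets and small builders

# typical structural parameters of the reference canine meloxicam model
ref_params <- function() {
  structural_params(ka1 = 0.086, ka2 = 1.82, F1 = 0.85, tlag2 = 1.22,
                    CL = 0.006, V1 = 0.049, Q = 0.24, V2 = 0.134)
}

design_times <- function() c(0.5, 1, 2, 4, 6, 8, 12, 24, 36, 48, 60)

# independent R-side reference for the single-path oral two-compartment
# solution (used as an oracle against the compiled kernel)
ref_conc_single_path <- function(t, ka, A, tlag, CL, V1, Q, V2) {
  k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
  s <- k10 + k12 + k21
  l1 <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  l2 <- (k10 * k21) / l1
  u <- t - tlag
  out <- numeric(length(t))
  pos <- u > 0
  u <- u[pos]
  c1 <- (k21 - l1) / ((ka - l1) * (l2 - l1))
  c2 <- (k21 - l2) / ((ka - l2) * (l1 - l2))
  c3 <- (k21 - ka) / ((l1 - ka) * (l2 - ka))
  out[pos] <- ka * A / V1 *
    (c1 * exp(-l1 * u) + c2 * exp(-l2 * u) + c3 * exp(-ka * u))
  out
}

# long-format dataset for hand-built profiles
toy_dataset <- function(profiles, dose = 0.2) {
  rec <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    nt <- length(p$times)
    data.frame(ID = i, TIME = c(0, p$times),
               AMT = c(dose, rep(NA_real_, nt)),
               DV = c(NA_real_, p$conc),
               EVID = c(1L, rep(0L, nt)),
               FORM = p$form %||% "FREE",
               WT = 12, AGE = 24)
  })
  pk_dataset(do.call(rbind, rec))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# covariate specification of the final model (formulation on tlag2, V2)
final_covariates <- function() {
  data.frame(param = c("tlag2", "V2"), covariate = c("FORM", "FORM"))
}
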