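#' Mean prediction error (percent)
#'
#' Signed mean relative prediction error,
#' `MPE% = 100/N * sum((Cpred - Cobs)/Cobs)`. Positive values mean
#' over-prediction.
#'
#' @param c_obs observed concentrations (all > 0)
#' @param c_pred predicted concentrations
#' @return MPE in percent
#' @export
mpe_percent <- function(c_obs, c_pred) {
  .check_pairs(c_obs, c_pred)
  mean((c_pred - c_obs) / c_obs) * 100
}

#' Root-mean-square relative prediction error (percent)
#'
#' `RMSE% = 100 * sqrt(1/N * sum(((Cpred - Cobs)/Cobs)^2))` — the square
#' root is taken over the mean squared relative error, so the metric is on
#' the same percent scale as [mpe_percent()] and always `>= |MPE|`.
#'
#' @inheritParams mpe_percent
#' @return RMSE in percent
#' @export
rmse_percent <- function(c_obs, c_pred) {
  .check_pairs(c_obs, c_pred)
  sqrt(mean(((c_pred - c_obs) / c_obs)^2)) * 100
}

.check_pairs <- function(c_obs, c_pred) {
  if (length(c_obs) != length(c_pred))
    stop("observed and predicted vectors must have equal length")
  if (!length(c_obs)) stop("empty prediction pairs")
  if (any(c_obs <= 0))
    stop("relative errors are undefined for non-positive observations")
  invisible(TRUE)
}

#' External predictive performance of a fitted model
#'
#' Predicts an external dataset (typically mean profiles digitised from
#' other studies) with the model's population parameters held fixed —
#' covariates applied, random effects at zero, no refitting — and reports
#' MPE% and RMSE%.
#'
#' @param fit a `pk_fit` or [population_model()]
#' @param data external [pk_dataset()] (doses and observation times set
#'   the prediction grid)
#' @return list with `mpe_pct`, `rmse_pct`, `n`, and the per-observation
#'   `pairs` data.frame
#' @export
external_validate <- function(fit, data) {
  model <- if (inherits(fit, "pk_fit")) fit$model else fit
  stopifnot(inherits(model, "population_model"),
            inherits(data, "pk_dataset"))
  sp <- .split_subjects(data)
  pred <- numeric(length(sp$dv))
  for (i in seq_len(sp$n)) {
    sel <- sp$obs_idx == i
    covs <- list()
    if (!is.null(model$cov_ref$WT)) covs$WT <- sp$wt[[i]]
    if (!is.null(model$cov_ref$AGE)) covs$AGE <- sp$age[[i]]
    p <- apply_covariates(model, as.character(sp$form[[i]]), covs)
    pred[sel] <- .conc_rows(sp$time[sel], p[["ka1"]], p[["ka2"]], p[["F1"]],
                            p[["tlag2"]], p[["CL"]], p[["V1"]], p[["Q"]],
                            p[["V2"]], sp$dose[[i]])
  }
  list(mpe_pct = mpe_percent(sp$dv, pred),
       rmse_pct = rmse_percent(sp$dv, pred),
       n = length(pred),
       pairs = data.frame(ID = sp$obs_id, TIME = sp$time,
                          c_obs = sp$dv, c_pred = pred))
}
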