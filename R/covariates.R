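#' Forward-inclusion / backward-elimination covariate search
#'
#' Stepwise selection of covariate effects on structural parameters by
#' changes in the objective function (-2 log-likelihood). The forward pass
#' repeatedly adds the candidate whose inclusion drops the OFV the most,
#' provided the drop exceeds `forward_threshold` (default 3.84, the 5%
#' chi-squared point on 1 df); the backward pass then removes any retained
#' effect whose removal raises the OFV by less than `backward_threshold`
#' (default 6.63, the 1% point). All fits share the same seed so Monte
#' Carlo errors in the OFV are positively correlated across nested models.
#'
#' @param data a [pk_dataset()]
#' @param candidates data.frame with columns `param`, `covariate` listing
#'   the candidate effects (e.g. `FORM` on `tlag2`)
#' @param base_covariates effects always kept in the model (NULL for none)
#' @param init optional starting [population_model()]
#' @param iiv parameters with inter-individual variability
#' @param error_model residual-error model
#' @param forward_threshold,backward_threshold OFV-change thresholds
#' @param seed integer seed shared by all fits
#' @param control a [saem_control()]; EBEs/RSEs are switched off
#'   internally for the candidate fits
#' @return list with `fit` (final refitted model), `selected` (data.frame
#'   of retained effects) and `log` (every decision with its delta-OFV)
#' @export
covariate_search <- function(data, candidates, base_covariates = NULL,
                             init = NULL, iiv = setdiff(.PK_PARAMS, "Q"),
                             error_model = "proportional",
                             forward_threshold = 3.84,
                             backward_threshold = 6.63,
                             seed = 1, control = saem_control()) {
  stopifnot(all(c("param", "covariate") %in% names(candidates)))
  control$compute_rse <- FALSE
  control$compute_ebe <- FALSE

  cache <- new.env(parent = emptyenv())
  fit_one <- function(covs) {
    covs <- if (NROW(covs)) covs[, c("param", "covariate")] else NULL
    key <- if (is.null(covs)) "(none)" else
      paste(sort(paste(covs$param, covs$covariate, sep = ":")),
            collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- suppressMessages(
      fit_saem(data, init = init, covariates = covs, iiv = iiv,
               error_model = error_model, seed = seed, control = control))
    cache[[key]] <- fit
    fit
  }
  key <- function(df) paste(df$param, df$covariate, sep = ":")

  current <- if (is.null(base_covariates)) {
    data.frame(param = character(), covariate = character())
  } else base_covariates[, c("param", "covariate")]
  candidates <- candidates[, c("param", "covariate")]
  remaining <- candidates[!key(candidates) %in% key(current), , drop = FALSE]

  log <- list()
  cur_fit <- fit_one(current)
  cur_ofv <- cur_fit$minus2ll

  # forward inclusion
  repeat {
    if (!nrow(remaining)) break
    ofvs <- vapply(seq_len(nrow(remaining)), function(r) {
      trial <- rbind(current, remaining[r, ])
      fit_one(trial)$minus2ll
    }, numeric(1))
    drops <- cur_ofv - ofvs
    best <- which.max(drops)
    log[[length(log) + 1]] <- data.frame(
      step = "forward", param = remaining$param[best],
      covariate = remaining$covariate[best], delta_ofv = drops[best],
      decision = ifelse(drops[best] > forward_threshold, "added", "stop"))
    if (drops[best] <= forward_threshold) break
    current <- rbind(current, remaining[best, ])
    cur_ofv <- ofvs[best]
    remaining <- remaining[-best, , drop = FALSE]
  }

  # backward elimination
  repeat {
    if (!nrow(current)) break
    incs <- vapply(seq_len(nrow(current)), function(r) {
      trial <- current[-r, , drop = FALSE]
      fit_one(trial)$minus2ll - cur_ofv
    }, numeric(1))
    worst <- which.min(incs)
    if (incs[worst] >= backward_threshold) break
    log[[length(log) + 1]] <- data.frame(
      step = "backward", param = current$param[worst],
      covariate = current$covariate[worst], delta_ofv = incs[worst],
      decision = "removed")
    current <- current[-worst, , drop = FALSE]
    cur_ofv <- cur_ofv + incs[worst]
  }

  final <- fit_one(current)
  list(fit = final,
       selected = current,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(step = character(), param = character(),
                    covariate = character(), delta_ofv = numeric(),
                    decision = character()))
}
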