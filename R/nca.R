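#' Terminal slope (lambda_z) estimation
#'
#' Log-linear least squares on a terminal subset of the profile. Candidate
#' subsets are the contiguous runs of 3 to `max_points` points ending at the
#' last observation and lying strictly after Tmax; the subset with the best
#' adjusted R-squared wins, ties broken toward more points. This mirrors
#' standard automatic lambda-z selection in NCA software.
#'
#' @param times observation times (h), strictly increasing
#' @param conc concentrations (ug/mL), all > 0
#' @param min_points,max_points subset size bounds (defaults 3 and 6)
#' @return list with `lambda_z` (1/h), `n_points`, `r2adj`, `intercept`
#'   (log scale)
#' @export
fit_lambda_z <- function(times, conc, min_points = 3, max_points = 6) {
  stopifnot(length(times) == length(conc))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(conc <= 0)) stop("concentrations must be positive for log-linear fit")
  imax <- which.max(conc)  # first occurrence on ties
  idx <- seq_along(times)
  elig <- idx[idx > imax]
  if (length(elig) < min_points)
    stop("need at least ", min_points, " points after Tmax for lambda_z")
  n <- length(times)
  best <- NULL
  for (k in min_points:min(max_points, length(elig))) {
    sel <- (n - k + 1):n
    y <- log(conc[sel]); x <- times[sel]
    fit <- lm(y ~ x)
    slope <- coef(fit)[["x"]]
    if (slope >= 0) next
    # noise-free profiles fit exactly; lm's "perfect fit" warning is benign
    r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    # ties (within 1e-12) resolve toward more points because k ascends
    if (is.null(best) || r2 >= best$r2adj - 1e-12)
      best <- list(lambda_z = -slope, n_points = k, r2adj = r2,
                   intercept = coef(fit)[[1]])
  }
  if (is.null(best))
    stop("no terminal subset with a negative slope; lambda_z not estimable")
  best
}

#' Linear trapezoidal AUC from first to last observation
#'
#' @param times observation times (h), strictly increasing
#' @param conc concentrations (ug/mL)
#' @param prepend_origin prepend a (0, 0) point, appropriate for
#'   single-oral-dose profiles (default TRUE; ignored if a time-0 sample
#'   is already present)
#' @param method `"linear"` (default) or `"linear-log"` (log-down on
#'   declining segments)
#' @return AUC (ug.h/mL)
#' @export
auc_trapezoid <- function(times, conc, prepend_origin = TRUE,
                          method = c("linear", "linear-log")) {
  method <- match.arg(method)
  stopifnot(length(times) == length(conc), length(times) >= 2)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (prepend_origin && times[1] > 0) {
    times <- c(0, times); conc <- c(0, conc)
  }
  dt <- diff(times)
  c1 <- conc[-length(conc)]; c2 <- conc[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "linear-log") {
    logdown <- c2 < c1 & c2 > 0 & c1 > 0
    seg[logdown] <- (c1[logdown] - c2[logdown]) /
      log(c1[logdown] / c2[logdown]) * dt[logdown]
  }
  sum(seg)
}

#' Non-compartmental analysis of one subject's profile
#'
#' Computes the standard single-oral-dose exposure metrics: Cmax and Tmax
#' from the observed maxima (first occurrence on ties), AUC0-t by the
#' linear trapezoidal rule with a zero origin point, lambda_z by
#' [fit_lambda_z()], the extrapolated tail `Clast/lambda_z`, terminal
#' half-life `log(2)/lambda_z`, apparent clearance `dose/AUC0-inf`,
#' apparent volume `CL/F / lambda_z`, and mean residence time from
#' AUMC0-inf (tail `Clast*tlast/lz + Clast/lz^2`).
#'
#' @param times observation times (h)
#' @param conc concentrations (ug/mL)
#' @param dose_per_kg administered dose (mg/kg)
#' @param ... passed to [fit_lambda_z()] and [auc_trapezoid()]
#' @return a one-row data.frame of class `nca_result`
#' @export
nca_single <- function(times, conc, dose_per_kg, ...) {
  ord <- order(times)
  times <- times[ord]; conc <- conc[ord]
  lz <- fit_lambda_z(times, conc, ...)
  imax <- which.max(conc)
  cmax <- conc[imax]; tmax <- times[imax]
  auc_t <- auc_trapezoid(times, conc)
  clast <- conc[length(conc)]; tlast <- times[length(times)]
  auc_inf <- auc_t + clast / lz$lambda_z
  # AUMC: trapezoid on t*C with the same zero origin, plus analytic tail
  aumc_t <- auc_trapezoid(times, times * conc)
  aumc_inf <- aumc_t + clast * tlast / lz$lambda_z + clast / lz$lambda_z^2
  cl_f <- dose_per_kg / auc_inf
  res <- data.frame(
    auc_0_t = auc_t,
    auc_0_inf = auc_inf,
    auc_ext_pct = 100 * (auc_inf - auc_t) / auc_inf,
    cmax = cmax,
    tmax = tmax,
    lambda_z = lz$lambda_z,
    t_half = log(2) / lz$lambda_z,
    cl_f = cl_f,
    vd_f = cl_f / lz$lambda_z,
    mrt = aumc_inf / auc_inf,
    n_lambda_points = lz$n_points,
    lambda_r2adj = lz$r2adj
  )
  class(res) <- c("nca_result", "data.frame")
  res
}

#' Per-subject NCA over a whole dataset
#'
#' @param data a [pk_dataset()]
#' @param on_error `"fail"` stops at the first subject whose terminal
#'   slope is not estimable; `"omit"` drops such subjects with a message
#'   (mirrors how NCA software flags profiles with too few terminal
#'   points)
#' @param ... passed to [nca_single()]
#' @return data.frame with one row per evaluable subject plus `ID`, `FORM`
#' @export
nca_dataset <- function(data, on_error = c("fail", "omit"), ...) {
  on_error <- match.arg(on_error)
  sp <- .split_subjects(data)
  out <- do.call(rbind, lapply(seq_len(sp$n), function(i) {
    sel <- sp$obs_idx == i
    r <- tryCatch(nca_single(sp$time[sel], sp$dv[sel], sp$dose[[i]], ...),
                  error = function(e) {
                    if (on_error == "fail")
                      stop("subject ", sp$ids[i], ": ", conditionMessage(e),
                           call. = FALSE)
                    message("NCA: omitting subject ", sp$ids[i], " (",
                            conditionMessage(e), ")")
                    NULL
                  })
    if (is.null(r)) return(NULL)
    cbind(data.frame(ID = sp$ids[i], FORM = sp$form[[i]]), r)
  }))
  if (is.null(out)) stop("no evaluable subjects for NCA")
  rownames(out) <- NULL
  dose <- unique(sp$dose)
  if (length(dose) == 1) attr(out, "dose_per_kg") <- dose
  out
}

#' Between-arm comparison of NCA metrics
#'
#' Mean and SD per arm for every metric, with a two-sided two-sample
#' t-test per metric (Welch by default; set `pooled = TRUE` for the
#' classical equal-variance test). Relative bioavailability `frel` is the
#' ratio of mean AUC0-inf, test arm over reference arm. If an intravenous
#' reference exposure is supplied, apparent absolute bioavailability per
#' arm is `(mean AUC_oral / dose_oral) / (auc_iv / dose_iv)`.
#'
#' @param nca_table output of [nca_dataset()] (needs `FORM` column)
#' @param reference reference arm level (default `"FREE"`)
#' @param pooled use pooled-variance t-test instead of Welch
#' @param iv_ref optional list `list(auc = , dose = )` with an external
#'   intravenous AUC (ug.h/mL) and its dose (mg/kg)
#' @return a list with `table` (mean, sd, p per metric and arm), `frel`,
#'   and `f_abs` (NULL without `iv_ref`)
#' @export
group_compare <- function(nca_table, reference = "FREE", pooled = FALSE,
                          iv_ref = NULL) {
  stopifnot("FORM" %in% names(nca_table))
  arms <- levels(factor(nca_table$FORM))
  if (length(arms) != 2) stop("exactly two arms required")
  test <- setdiff(arms, reference)
  metrics <- setdiff(names(nca_table), c("ID", "FORM"))
  rows <- lapply(metrics, function(m) {
    xr <- nca_table[[m]][nca_table$FORM == reference]
    xt <- nca_table[[m]][nca_table$FORM == test]
    if (length(xr) < 2 || length(xt) < 2)
      stop("need at least 2 subjects per arm")
    p <- if (sd(xr) == 0 && sd(xt) == 0 && mean(xr) == mean(xt)) 1 else
      t.test(xt, xr, var.equal = pooled)$p.value
    data.frame(metric = m,
               mean_ref = mean(xr), sd_ref = sd(xr),
               mean_test = mean(xt), sd_test = sd(xt),
               p_value = p)
  })
  tab <- do.call(rbind, rows)
  auc_ref <- tab$mean_ref[tab$metric == "auc_0_inf"]
  auc_test <- tab$mean_test[tab$metric == "auc_0_inf"]
  frel <- auc_test / auc_ref
  f_abs <- NULL
  if (!is.null(iv_ref)) {
    stopifnot(!is.null(iv_ref$auc), !is.null(iv_ref$dose))
    dose_oral <- iv_ref$dose_oral %||% attr(nca_table, "dose_per_kg")
    if (is.null(dose_oral))
      stop("supply iv_ref$dose_oral (oral dose, mg/kg) for absolute F")
    f_abs <- c((auc_ref / dose_oral) / (iv_ref$auc / iv_ref$dose),
               (auc_test / dose_oral) / (iv_ref$auc / iv_ref$dose))
    names(f_abs) <- c(reference, test)
  }
  list(table = tab, frel = frel, f_abs = f_abs,
       reference = reference, test = test)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
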