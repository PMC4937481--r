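# Phenotype analytics: growth-curve AUC and sigmoid fits, competition
# generation counting and mutant-fraction testing, and delta-delta-Ct
# fold expression.

#' Area under a growth curve
#'
#' Trapezoidal integral of baseline-normalised absorbance over time in
#' hours. Values are normalised by subtracting the curve's initial
#' value.
#'
#' @param time_min time points in minutes, strictly increasing.
#' @param od absorbance values.
#' @param normalize subtract the initial value first (default TRUE).
#' @return AUC in normalised-OD x hours.
#' @export
growth_auc <- function(time_min, od, normalize = TRUE) {
  if (length(time_min) < 2) abort("need at least 2 time points")
  if (any(diff(time_min) <= 0)) abort("time vector must be strictly increasing")
  y <- if (normalize) od - od[1] else od
  pracma::trapz(time_min / 60, y)
}

#' Fit a sigmoid growth model and extract growth parameters
#'
#' Resamples the curve to a 30-minute grid, fits logistic and Gompertz
#' models by nonlinear least squares, and reports the better (lower
#' residual) fit. Parameters follow the standard growth-curve
#' convention: A the maximum growth (asymptote), mu the maximum growth
#' rate (slope at inflection, 1/h), lambda the lag time (x-intercept of
#' the tangent at the inflection, h). When neither model converges,
#' data-derived fallback parameters are returned with `fallback = TRUE`.
#'
#' @param time_min time points in minutes.
#' @param od absorbance values.
#' @param models which models to try.
#' @return An object of class `growth_fit`: list with `auc`, `a_max`,
#'   `mu`, `lambda`, `model`, `residual`, `fallback`, `fitted`
#'   (function of time in hours) and the normalised data.
#' @export
fit_growth <- function(time_min, od, models = c("logistic", "gompertz")) {
  y_all <- od - od[1]
  auc <- growth_auc(time_min, od)
  # resample to a 30-min grid before fitting
  grid <- seq(min(time_min), max(time_min), by = 30)
  y <- stats::approx(time_min, y_all, xout = grid)$y
  t_h <- grid / 60

  # data-derived starting values
  a0 <- max(y)
  dy <- diff(y) / diff(t_h)
  mu0 <- max(dy, na.rm = TRUE)
  imax <- which.max(dy)
  lam0 <- max(0, t_h[imax] - y[imax] / max(mu0, 1e-6))

  # the data are baseline-normalised (y(t0) = 0), so the model curve is
  # fitted minus its own value at the first time point; this makes the
  # noise-free fit recover the generating parameters exactly
  fit_one <- function(model) {
    f <- switch(model, logistic = logistic_growth, gompertz = gompertz_growth)
    t0 <- t_h[1]
    tryCatch({
      fit <- minpack.lm::nlsLM(
        y ~ f(t_h, a, mu, lambda) - f(t0, a, mu, lambda),
        start = list(a = max(a0, 1e-3), mu = max(mu0, 1e-3), lambda = lam0),
        lower = c(0, 0, 0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      list(model = model, par = coef(fit),
           residual = sum(resid(fit)^2),
           fun = function(t, a, mu, lambda) {
             f(t, a, mu, lambda) - f(t0, a, mu, lambda)
           })
    }, error = function(e) NULL)
  }
  fits <- purrr::compact(purrr::map(models, fit_one))
  if (length(fits) == 0 || a0 < 1e-3) {
    return(structure(list(
      auc = auc, a_max = a0, mu = max(mu0, 0), lambda = lam0,
      model = "fallback", residual = NA_real_, fallback = TRUE,
      fitted = function(t) rep(a0, length(t)),
      time_min = time_min, od_norm = y_all), class = "growth_fit"))
  }
  best <- fits[[which.min(vapply(fits, function(f) f$residual, 1))]]
  par <- best$par
  structure(list(
    auc = auc, a_max = unname(par["a"]), mu = unname(par["mu"]),
    lambda = unname(par["lambda"]), model = best$model,
    residual = best$residual, fallback = FALSE,
    fitted = function(t) best$fun(t, par["a"], par["mu"], par["lambda"]),
    time_min = time_min, od_norm = y_all), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth_fit (%s): A = %.3f, mu = %.3f /h, lambda = %.2f h, AUC = %.2f\n",
              x$model, x$a_max, x$mu, x$lambda, x$auc))
  invisible(x)
}

#' Generations of growth over a serial-transfer schedule
#'
#' g = sum over transfers of log2(pre-dilution density / bottleneck);
#' transfers with density below the bottleneck contribute 0 with a
#' warning.
#'
#' @param pre_density vector of pre-dilution densities (cells/ml).
#' @param bottleneck dilution target density (cells/ml).
#' @return Total generations (real).
#' @export
generations <- function(pre_density, bottleneck = 2e5) {
  ratio <- pre_density / bottleneck
  if (any(ratio < 1)) {
    warn("pre-dilution density below bottleneck; clamping to 0 generations")
    ratio[ratio < 1] <- 1
  }
  sum(log2(ratio))
}

#' Test the final mutant fraction of a competition assay
#'
#' One-sample two-sided t-test of the replicate mutant fractions
#' against the expected neutral fraction.
#'
#' @param colonies_mutant,colonies_total per-replicate colony counts.
#' @param expected expected fraction under neutrality (default 0.5).
#' @return A list with `mean_fraction`, `t`, `df`, `p`, `degenerate`
#'   (TRUE when the replicate variance is 0).
#' @export
competition_test <- function(colonies_mutant, colonies_total,
                             expected = 0.5) {
  if (length(colonies_mutant) < 2) abort("need >= 2 replicates")
  frac <- colonies_mutant / colonies_total
  m <- mean(frac)
  s <- sd(frac)
  nrep <- length(frac)
  if (s < 1e-12) {
    # zero variance: p = 1 at the null, 0 (degenerate) off the null
    at_null <- abs(m - expected) < 1e-12
    return(list(mean_fraction = m, t = if (at_null) 0 else Inf,
                df = nrep - 1, p = if (at_null) 1 else 0,
                degenerate = TRUE))
  }
  tstat <- (m - expected) / (s / sqrt(nrep))
  p <- 2 * stats::pt(-abs(tstat), df = nrep - 1)
  list(mean_fraction = m, t = tstat, df = nrep - 1, p = p,
       degenerate = FALSE)
}

#' Delta-delta-Ct relative fold expression
#'
#' ddCt = (Ct_target_sample - Ct_ref_sample) -
#' (Ct_target_control - Ct_ref_control); fold = 2^(-ddCt). Replicate
#' folds are summarised as mean and standard error.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   Ct values (vectorised over replicates).
#' @return A tibble with per-replicate `ddct` and `fold`, plus
#'   attributes-free summary columns `mean_fold` and `sem_fold`
#'   repeated per row.
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_control, ct_ref_control) {
  vals <- c(ct_target_sample, ct_ref_sample, ct_target_control,
            ct_ref_control)
  if (any(!is.finite(vals))) abort("all Ct values must be finite")
  d <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  fold <- 2^(-d)
  nrep <- length(fold)
  tibble(replicate = seq_len(nrep), ddct = d, fold = fold,
         mean_fold = mean(fold),
         sem_fold = if (nrep > 1) sd(fold) / sqrt(nrep) else NA_real_)
}
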