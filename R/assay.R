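# Analysis of the experimental readouts: calcein-AM efflux normalization,
# three-parameter logistic dose-response (IC50) fitting, and
# vanadate-sensitive ATPase activity with a phosphate standard curve.

#' Slope of a background-corrected fluorescence time series
#'
#' Ordinary least-squares slope of (signal - background) against time.
#'
#' @param time seconds, strictly increasing, length >= 3
#' @param signal fluorescence (arbitrary units)
#' @param background scalar or per-point background signal (same units)
#' @return list with `slope` (a.u./s), `se`, `n`
#' @export
fluorescence_slope <- function(time, signal, background = 0) {
  if (length(time) < 3) stop("need at least 3 time points")
  if (length(signal) != length(time)) stop("time and signal differ in length")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  y <- signal - background
  fit <- lm(y ~ time)
  co <- suppressWarnings(summary(fit)$coefficients)
  se <- if (nrow(co) >= 2) co["time", "Std. Error"] else NA_real_
  if (is.nan(se)) se <- 0
  list(slope = unname(coef(fit)[["time"]]), se = unname(se), n = length(time))
}

#' Calcein-AM efflux relative to control
#'
#' The inverse of the compound/control slope ratio:
#' efflux = 1 / (m_compound / m_control) = m_control / m_compound.
#' Values above 1 indicate more efflux (less P-gp inhibition) than control.
#'
#' @param m_compound fluorescence slope under compound (a.u./s)
#' @param m_control fluorescence slope of the buffer control (a.u./s, != 0)
#' @param tol near-zero warning threshold relative to `|m_control|`
#' @return unitless efflux ratio
#' @export
calcein_efflux <- function(m_compound, m_control, tol = 1e-6) {
  if (any(m_control == 0)) stop("m_control must be non-zero")
  if (any(m_compound == 0)) {
    stop("efflux undefined: compound slope is exactly zero")
  }
  small <- abs(m_compound) < tol * abs(m_control)
  if (any(small)) {
    warning("compound slope is near zero relative to control; ",
            "efflux ratio is numerically unstable")
  }
  m_control / m_compound
}

#' Fit a three-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `Y = Bottom + (Top - Bottom) / (1 + 10^(X - LogIC50))`
#' with `X = log10(concentration in uM)` (the GraphPad three-parameter
#' form). The parameterization permits either orientation: inhibition
#' curves fit `Top > Bottom`, stimulation-shaped data fit `Top < Bottom`.
#'
#' @param concentration_uM concentrations in micromolar (> 0, >= 4 distinct)
#' @param response measured responses (finite)
#' @param max_iter iteration cap (default 500)
#' @return an object of class `dose_response_fit`: `Top`, `Bottom`,
#'   `LogIC50` (log10 uM), standard errors (`se_top`, `se_bottom`,
#'   `se_logIC50`), `ic50` (uM), `converged`, `residual_sd`
#' @export
fit_dose_response <- function(concentration_uM, response, max_iter = 500L) {
  if (any(concentration_uM <= 0)) stop("concentrations must be positive")
  if (!all(is.finite(response))) stop("responses must be finite")
  if (length(unique(concentration_uM)) < 4) {
    stop("need at least 4 distinct concentrations")
  }
  x <- log10(concentration_uM)
  top0 <- max(response); bot0 <- min(response)
  mid <- (top0 + bot0) / 2
  log0 <- x[which.min(abs(response - mid))]
  model <- function(p) p[["Bottom"]] + (p[["Top"]] - p[["Bottom"]]) /
    (1 + 10^(x - p[["LogIC50"]]))
  fit <- minpack.lm::nls.lm(
    par = c(Top = top0, Bottom = bot0, LogIC50 = log0),
    fn = function(p) response - model(p),
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-14,
                                         ptol = 1e-14))
  if (!(fit$info %in% 1:4)) {
    stop("dose-response fit failed to converge (", fit$message,
         "); best iterate: Top=", signif(fit$par[["Top"]], 4),
         ", Bottom=", signif(fit$par[["Bottom"]], 4),
         ", LogIC50=", signif(fit$par[["LogIC50"]], 4))
  }
  est <- fit$par
  n <- length(response)
  dof <- n - 3L
  rss <- sum(fit$fvec^2)
  resid_sd <- if (dof > 0) sqrt(rss / dof) else 0
  # Gauss-Newton covariance at the optimum: sigma^2 (J'J)^-1
  se <- tryCatch({
    covm <- resid_sd^2 * chol2inv(chol(fit$hessian))
    stats::setNames(sqrt(pmax(diag(covm), 0)), names(est))
  }, error = function(e) {
    if (resid_sd < 1e-10) {
      # exact fit: the covariance collapses even if the normal matrix is
      # numerically rank-deficient
      c(Top = 0, Bottom = 0, LogIC50 = 0)
    } else {
      c(Top = NA_real_, Bottom = NA_real_, LogIC50 = NA_real_)
    }
  })
  structure(list(Top = unname(est[["Top"]]), Bottom = unname(est[["Bottom"]]),
                 LogIC50 = unname(est[["LogIC50"]]),
                 se_top = unname(se[["Top"]]), se_bottom = unname(se[["Bottom"]]),
                 se_logIC50 = unname(se[["LogIC50"]]),
                 ic50 = ic50_from_log(unname(est[["LogIC50"]])),
                 converged = TRUE, residual_sd = resid_sd, n = n),
            class = "dose_response_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "dose_response_fit: Top %.4g, Bottom %.4g, LogIC50 %.4g +/- %.2g -> IC50 %.4g uM\n",
    x$Top, x$Bottom, x$LogIC50, x$se_logIC50, x$ic50))
  invisible(x)
}

#' Convert LogIC50 to IC50
#'
#' @param log_ic50 base-10 logarithm of the IC50 in micromolar
#' @return IC50 in micromolar (`10^log_ic50`)
#' @export
ic50_from_log <- function(log_ic50) 10^log_ic50

#' Predicted response of a three-parameter logistic model
#'
#' @param concentration_uM concentrations in micromolar
#' @param top,bottom,log_ic50 curve parameters
#' @return predicted responses
#' @export
dose_response_curve <- function(concentration_uM, top, bottom, log_ic50) {
  x <- log10(concentration_uM)
  bottom + (top - bottom) / (1 + 10^(x - log_ic50))
}

#' Vanadate-sensitive ATPase activity
#'
#' Converts absorbances to nmol inorganic phosphate through a linear
#' phosphate standard curve (least squares, free intercept), normalizes by
#' reaction time and protein amount, and subtracts the vanadate condition.
#'
#' @param test list/row with `absorbance`, `time_min`, `protein_mg`
#' @param vanadate_ref the matched measurement with 500 uM vanadate
#'   (`vanadate` flag must be `TRUE`)
#' @param standards data frame with columns `absorbance` and `nmol`
#'   (>= 2 points)
#' @return activity in nmol Pi / min / mg; negative values are reported
#'   as-is with a warning
#' @export
sensitive_atpase_activity <- function(test, vanadate_ref, standards) {
  stopifnot(all(c("absorbance", "nmol") %in% names(standards)),
            nrow(standards) >= 2)
  if (!isTRUE(vanadate_ref$vanadate)) {
    stop("vanadate_ref must be a measurement with vanadate = TRUE")
  }
  if (test$time_min <= 0 || test$protein_mg <= 0) {
    stop("time and protein amount must be positive")
  }
  cal <- lm(nmol ~ absorbance, data = standards)
  if (coef(cal)[["absorbance"]] <= 0) {
    stop("phosphate standard curve has non-positive slope; calibration invalid")
  }
  to_nmol <- function(a) predict(cal, newdata = data.frame(absorbance = a))
  rate_test <- to_nmol(test$absorbance) / (test$time_min * test$protein_mg)
  rate_van <- to_nmol(vanadate_ref$absorbance) /
    (vanadate_ref$time_min * vanadate_ref$protein_mg)
  out <- unname(rate_test - rate_van)
  if (out < 0) {
    warning("sensitive ATPase activity is negative (vanadate condition ",
            "exceeded the test condition); reported as-is")
  }
  out
}
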