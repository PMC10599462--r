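# Apparent Michaelis-Menten fitting under the substrate-inhibition windowing
# rule, substrate-inhibition detection by AICc model comparison, IC50
# dose-response fitting, and the mutant relative-activity helper.

lb_start <- function(S, v) {
  # Lineweaver-Burk linearization for starting values; exact on clean data.
  ok <- v > 0 & S > 0
  if (sum(ok) < 2) return(c(V = max(v), KM = stats::median(S)))
  fit <- wls_line(1 / S[ok], 1 / v[ok])
  V0 <- 1 / fit$intercept
  KM0 <- fit$slope * V0
  if (!is.finite(V0) || V0 <= 0) V0 <- max(v) * 1.2
  if (!is.finite(KM0) || KM0 <= 0) KM0 <- stats::median(S)
  c(V = V0, KM = KM0)
}

#' Fit apparent Michaelis-Menten parameters
#'
#' Nonlinear least squares of `v = V*S/(KM+S)` over the points with
#' `S <= window_max`. The default window of 0.25 mM reflects the SLA
#' dehydrogenase assay practice of truncating above the substrate-inhibition
#' onset; `window_max = "auto"` estimates the onset with
#' [detect_substrate_inhibition()] first, and `window_max = Inf` disables
#' windowing. Standard errors come from the local variance-covariance matrix
#' of the fit; the catalytic efficiency `V/KM` (or `kcat/KM` when `E0` is
#' known) carries a delta-method standard error.
#'
#' @param data Data frame with columns `S` (mM) and `v` (rate).
#' @param window_max Numeric window limit (mM), `Inf`, or `"auto"`.
#' @param method `"nls"` (default) or `"lb"` for the classical unweighted
#'   Lineweaver-Burk linear fit (retained for plots and cross-checks).
#' @param weights `"relative"` (default) iteratively reweights by the fitted
#'   rate (`w = 1/v_hat^2`), the correct error model for the roughly
#'   constant-CV scatter of spectrophotometric initial rates, and what keeps
#'   the reported standard errors calibrated; `"none"` fits unweighted.
#'   Irrelevant on noise-free data.
#' @param E0 Optional enzyme concentration (mM); enables `kcat = V/E0`.
#' @return An object of class `mm_fit`: estimates with SEs, efficiency with
#'   delta-method SE, window bookkeeping (`window_max`, `n_used`,
#'   `n_excluded`), and diagnostics (`ss`, `r_squared`, `converged`).
#' @examples
#' d <- data.frame(S = c(0.0125, 0.025, 0.05, 0.1, 0.2),
#'                 v = rate_mm(c(0.0125, 0.025, 0.05, 0.1, 0.2),
#'                             kinetic_params(V = 1, KM = 0.1)))
#' fit_mm(d)
#' @export
fit_mm <- function(data, window_max = 0.25, method = c("nls", "lb"),
                   weights = c("relative", "none"), E0 = NULL) {
  method <- match.arg(method)
  weights <- match.arg(weights)
  stopifnot(is.data.frame(data), all(c("S", "v") %in% names(data)))
  S_all <- data$S; v_all <- data$v
  check_conc(S_all, "S")
  if (any(!is.finite(v_all)) || any(v_all < 0))
    stop_bad_arg("rates must be finite and >= 0")
  auto <- identical(window_max, "auto")
  if (auto) {
    det <- detect_substrate_inhibition(data)
    window_max <- if (isTRUE(det$flag) && is.finite(det$onset)) det$onset else Inf
  }
  if (!is.numeric(window_max) || window_max <= 0)
    stop_bad_arg("`window_max` must be a positive number, Inf, or \"auto\"")
  keep <- S_all <= window_max
  S <- S_all[keep]; v <- v_all[keep]
  if (length(unique(S)) < 4)
    stop_bad_arg("fewer than 4 distinct concentrations inside the window")
  start <- lb_start(S, v)

  if (method == "lb") {
    ok <- v > 0 & S > 0
    lb <- wls_line(1 / S[ok], 1 / v[ok])
    V <- 1 / lb$intercept
    KM <- lb$slope * V
    # delta-method SEs from the linear fit's covariance structure
    se_V <- V^2 * lb$intercept_se
    se_KM <- sqrt((lb$slope_se * V)^2 + (lb$slope * se_V)^2)
    vhat <- V * S / (KM + S)
    ss <- sum((v - vhat)^2)
    cov_VK <- NA_real_
    converged <- TRUE
    fit <- NULL
  } else {
    df <- data.frame(S = S, v = v)
    fit <- minpack.lm::nlsLM(
      v ~ V * S / (KM + S), data = df,
      start = as.list(start),
      lower = c(V = .Machine$double.eps, KM = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (weights == "relative") {
      # two IRLS passes with w = 1/v_hat^2 (constant-CV error model)
      for (it in 1:2) {
        w <- 1 / pmax(stats::fitted(fit), .Machine$double.eps)^2
        fit <- minpack.lm::nlsLM(
          v ~ V * S / (KM + S), data = df,
          start = as.list(stats::coef(fit)), weights = w,
          lower = c(V = .Machine$double.eps, KM = .Machine$double.eps),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }
    cf <- stats::coef(fit)
    V <- cf[["V"]]; KM <- cf[["KM"]]
    vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
    se_V <- sqrt(vc[1, 1]); se_KM <- sqrt(vc[2, 2]); cov_VK <- vc[1, 2]
    ss <- sum((v - stats::fitted(fit))^2)
    converged <- fit$convInfo$isConv %||% TRUE
  }
  if (KM <= 0) stop_bad_arg("fit returned non-positive KM")
  eff <- V / KM
  se_eff <- if (is.finite(cov_VK)) {
    sqrt(max(0, (se_V / KM)^2 + (V * se_KM / KM^2)^2 -
               2 * V * cov_VK / KM^3))
  } else {
    sqrt((se_V / KM)^2 + (V * se_KM / KM^2)^2)
  }
  tss <- sum((v - mean(v))^2)
  out <- list(
    V = V, V_se = se_V, KM = KM, KM_se = se_KM,
    efficiency = eff, efficiency_se = se_eff,
    kcat = if (!is.null(E0)) V / E0 else NULL,
    kcat_se = if (!is.null(E0)) se_V / E0 else NULL,
    E0 = E0,
    window_max = window_max, n_used = length(S),
    n_excluded = sum(!keep),
    ss = ss, r_squared = if (tss > 0) 1 - ss / tss else 1,
    method = method, converged = converged,
    fit = if (method == "nls") fit else NULL,
    data = data.frame(S = S, v = v))
  class(out) <- "mm_fit"
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> (", x$method, ")\n", sep = "")
  cat(sprintf("  V  = %.4g +/- %.2g\n", x$V, x$V_se))
  if (!is.null(x$kcat))
    cat(sprintf("  kcat = %.4g +/- %.2g s^-1 (E0 = %g mM)\n",
                x$kcat, x$kcat_se, x$E0))
  cat(sprintf("  KM = %.4g +/- %.2g mM\n", x$KM, x$KM_se))
  cat(sprintf("  V/KM = %.4g +/- %.2g\n", x$efficiency, x$efficiency_se))
  cat(sprintf("  window <= %g mM: %d used, %d excluded; R^2 = %.5f\n",
              x$window_max, x$n_used, x$n_excluded, x$r_squared))
  invisible(x)
}

#' Confidence intervals for an mm_fit
#'
#' Profile-likelihood intervals from the stored nonlinear fit where the
#' residual variance permits profiling, otherwise Wald intervals on the
#' t-scale.
#'
#' @param object An `mm_fit`.
#' @param parm Parameters to include (default both).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Matrix of lower/upper bounds.
#' @export
confint.mm_fit <- function(object, parm = c("V", "KM"), level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  profiled <- FALSE
  if (!is.null(object$fit) && object$ss / object$n_used > 1e-20) {
    prof <- tryCatch(
      suppressWarnings(suppressMessages(
        stats::confint(object$fit, parm, level = level))),
      error = function(e) NULL)
    if (!is.null(prof)) {
      prof <- if (is.null(dim(prof))) matrix(prof, 1, 2,
                                             dimnames = list(parm, NULL))
      else prof
      if (all(is.finite(prof))) {
        out[, ] <- prof[parm, , drop = FALSE]
        profiled <- TRUE
      }
    }
  }
  if (!profiled) {
    z <- stats::qt(1 - (1 - level) / 2, df = max(1, object$n_used - 2))
    est <- c(V = object$V, KM = object$KM)[parm]
    se <- c(V = object$V_se, KM = object$KM_se)[parm]
    out[, 1] <- est - z * se
    out[, 2] <- est + z * se
  }
  attr(out, "method") <- if (profiled) "profile" else "wald"
  out
}

#' Detect substrate inhibition by model comparison
#'
#' Fits the plain Michaelis-Menten law and the uncompetitive
#' substrate-inhibition law to the same data and compares them by corrected
#' AIC. Inhibition is flagged when the inhibition model wins by
#' `delta AICc >= 2`; the onset is reported as `sqrt(KM * Ksi)`, the
#' concentration at which the inhibited rate law peaks.
#'
#' @param data Data frame with columns `S`, `v`.
#' @param delta_aicc Decision threshold (default 2).
#' @return List with `flag` (TRUE/FALSE, or NA when undetermined), `onset`
#'   (mM), `status`, and `evidence` (the model-comparison table).
#' @export
detect_substrate_inhibition <- function(data, delta_aicc = 2) {
  stopifnot(is.data.frame(data), all(c("S", "v") %in% names(data)))
  S <- data$S; v <- data$v
  if (length(unique(S)) < 6) {
    return(list(flag = NA, onset = NA_real_, status = "undetermined",
                evidence = NULL,
                reason = "fewer than 6 distinct concentrations"))
  }
  n <- length(v)
  start <- lb_start(S, v)
  fit_plain <- minpack.lm::nlsLM(
    v ~ V * S / (KM + S), data = data.frame(S = S, v = v),
    start = as.list(start),
    lower = c(.Machine$double.eps, .Machine$double.eps),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  ss_plain <- sum(stats::resid(fit_plain)^2)
  # 1/Ksi parameterization reduces smoothly to plain MM at iKsi = 0, so the
  # fit stays well-posed when the data carry no inhibition signal
  fit_si <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      v ~ V * S / (KM + S + S^2 * iKsi), data = data.frame(S = S, v = v),
      start = c(as.list(start), list(iKsi = 1 / (4 * max(S)))),
      lower = c(.Machine$double.eps, .Machine$double.eps, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) NULL)
  if (is.null(fit_si)) {
    return(list(flag = FALSE, onset = NA_real_,
                status = "no inhibition detected",
                evidence = data.frame(model = "MM", npar = 2L, ss = ss_plain,
                                      AICc = aicc(ss_plain, n, 2), dAICc = 0),
                reason = "inhibition model did not converge"))
  }
  ss_si <- sum(stats::resid(fit_si)^2)
  tab <- data.frame(
    model = c("MM", "MM_SUBSTRATE_INHIBITION"),
    npar = c(2L, 3L),
    ss = c(ss_plain, ss_si),
    AICc = c(aicc(ss_plain, n, 2), aicc(ss_si, n, 3)))
  tab$dAICc <- tab$AICc - min(tab$AICc)
  win_si <- tab$AICc[2] + delta_aicc <= tab$AICc[1]
  cf <- stats::coef(fit_si)
  Ksi <- if (cf[["iKsi"]] > 0) 1 / cf[["iKsi"]] else Inf
  onset <- if (win_si && is.finite(Ksi)) sqrt(cf[["KM"]] * Ksi) else NA_real_
  list(flag = win_si, onset = unname(onset),
       status = if (win_si) "inhibition detected" else "no inhibition detected",
       evidence = tab,
       si_params = list(V = cf[["V"]], KM = cf[["KM"]], Ksi = unname(Ksi)))
}

#' Fit an IC50 dose-response curve
#'
#' Fits `v = v0 / (1 + ([I]/IC50)^h)`, with the Hill coefficient fixed at 1 by
#' default (simple reversible binding). Requires a bracketing design: at least
#' one measured rate below half the uninhibited rate and one above.
#' Confidence intervals for the IC50 are profile-likelihood based when the
#' residual variance permits profiling, otherwise Wald.
#'
#' @param data A [dose_response()] or data frame with columns `I` (uM), `v`.
#' @param hill_fixed Fixed Hill coefficient, or `NULL` to estimate it.
#' @param level Confidence level for the IC50 interval.
#' @return List with `IC50`, `IC50_se`, `IC50_ci`, `ci_method`, `hill`,
#'   `v0`, `ss`, `converged`.
#' @examples
#' dr <- generate_dose_response(IC50 = 28, v0 = 1,
#'                              levels = 10^seq(-0.5, 3, length.out = 12))
#' fit_ic50(dr)$IC50
#' @export
fit_ic50 <- function(data, hill_fixed = 1, level = 0.95) {
  stopifnot(is.data.frame(data), all(c("I", "v") %in% names(data)))
  I <- data$I; v <- data$v
  if (length(unique(I)) < 5)
    stop_bad_arg("at least 5 distinct inhibitor levels are required")
  if (max(v) <= 0 || stats::sd(v) == 0)
    stop_bad_arg("no inhibition signal: rates are constant")
  v0_guess <- max(v)
  if (!(min(v) < v0_guess / 2 && max(v) > v0_guess / 2))
    stop_bad_arg("non-bracketing design: need points on both sides of v0/2")
  # log-parameterized IC50 keeps the search positive and stabilizes profiling
  i_half <- I[which.min(abs(v - v0_guess / 2))]
  start <- list(v0 = v0_guess, lIC50 = log(max(i_half, min(I[I > 0]))))
  df <- data.frame(I = I, v = v)
  if (is.null(hill_fixed)) {
    fit <- minpack.lm::nlsLM(
      v ~ v0 / (1 + (I / exp(lIC50))^h), data = df,
      start = c(start, list(h = 1)),
      lower = c(.Machine$double.eps, -Inf, 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    hill <- stats::coef(fit)[["h"]]
  } else {
    stopifnot(hill_fixed > 0)
    h <- hill_fixed
    fit <- minpack.lm::nlsLM(
      v ~ v0 / (1 + (I / exp(lIC50))^h), data = df,
      start = start,
      lower = c(.Machine$double.eps, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    hill <- hill_fixed
  }
  cf <- stats::coef(fit)
  IC50 <- exp(cf[["lIC50"]])
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se_l <- if (!is.null(vc)) sqrt(vc["lIC50", "lIC50"]) else NA_real_
  IC50_se <- IC50 * se_l
  ss <- sum(stats::resid(fit)^2)
  ci <- NULL; ci_method <- "none"
  if (ss / length(v) > 1e-20) {
    prof <- tryCatch(
      suppressWarnings(suppressMessages(
        stats::confint(fit, "lIC50", level = level))),
      error = function(e) NULL)
    if (!is.null(prof) && all(is.finite(prof))) {
      ci <- exp(as.numeric(prof)); ci_method <- "profile"
    }
  }
  if (is.null(ci)) {
    if (is.finite(se_l)) {
      z <- stats::qnorm(1 - (1 - level) / 2)
      ci <- exp(cf[["lIC50"]] + c(-1, 1) * z * se_l)
      ci_method <- if (ss / length(v) > 1e-20) "wald" else "degenerate"
    } else {
      ci <- c(IC50, IC50); ci_method <- "degenerate"
    }
  }
  list(IC50 = IC50, IC50_se = IC50_se, IC50_ci = ci, ci_method = ci_method,
       hill = hill, v0 = cf[["v0"]], ss = ss,
       converged = fit$convInfo$isConv %||% TRUE)
}

#' Relative activity of an enzyme variant
#'
#' Fold-reduction of a variant (e.g. an active-site mutant) relative to
#' wildtype under matched assay conditions. A variant rate of zero is
#' reported as below detection, bounded by the assay detection limit when
#' one is supplied.
#'
#' @param v_variant,v_wildtype Observed rates (matched conditions; the caller
#'   asserts comparability).
#' @param detection_limit Optional smallest detectable rate, used to bound
#'   the fold-reduction when `v_variant = 0`.
#' @return List with `fold_reduction` (`v_wt / v_var`), `relative`
#'   (`v_var / v_wt`), a formatted `label` such as `"1/120000"`, and
#'   `below_detection`.
#' @examples
#' relative_activity(1, 1.2e5)$label
#' @export
relative_activity <- function(v_variant, v_wildtype, detection_limit = NULL) {
  if (v_wildtype <= 0) stop_bad_arg("`v_wildtype` must be positive")
  if (v_variant < 0) stop_bad_arg("`v_variant` must be >= 0")
  if (v_variant == 0) {
    bound <- if (!is.null(detection_limit) && detection_limit > 0)
      v_wildtype / detection_limit else NA_real_
    return(list(fold_reduction = NA_real_, relative = 0,
                label = "below detection",
                below_detection = TRUE, fold_reduction_lower_bound = bound))
  }
  fold <- v_wildtype / v_variant
  list(fold_reduction = fold, relative = v_variant / v_wildtype,
       label = paste0("1/", format(signif(fold, 3), scientific = FALSE,
                                   trim = TRUE)),
       below_detection = FALSE, fold_reduction_lower_bound = NA_real_)
}

#' Check printed catalytic efficiencies against the kcat/KM ratio
#'
#' For a table of apparent parameters, recomputes `kcat/KM` from the point
#' estimates and flags rows whose reported efficiency disagrees with the
#' ratio beyond a relative tolerance. Published kinetic tables sometimes
#' carry independently fitted efficiencies, so disagreement is reported, not
#' reconciled.
#'
#' @param tbl Data frame with columns `KM_mM`, `kcat_s`, `efficiency_mM_s`.
#' @param rel_tol Relative tolerance (default 0.05, i.e. agreement within 5%
#'   after rounding).
#' @return `tbl` with added columns `ratio` (`kcat_s/KM_mM`) and `consistent`.
#' @export
check_efficiency_consistency <- function(tbl, rel_tol = 0.05) {
  stopifnot(all(c("KM_mM", "kcat_s", "efficiency_mM_s") %in% names(tbl)))
  tbl$ratio <- tbl$kcat_s / tbl$KM_mM
  tbl$consistent <-
    abs(tbl$ratio - tbl$efficiency_mM_s) <= rel_tol * tbl$efficiency_mM_s
  tbl
}
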