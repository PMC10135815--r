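# Critical-temperature estimation from the binodal order parameter
# P_H - P_L versus temperature: threshold rules and the power-law fit
#   P_H - P_L = A (T_cr - T)^beta   for T < T_cr, 0 above.

#' Classify phase behaviour from the order parameter
#'
#' Labels each temperature by the two published thresholds: values above
#' `obvious_threshold` (0.15) show obvious phase separation; values below
#' `disappear_threshold` (0.07) show none; values between are marginal.
#'
#' @param value P_H - P_L values.
#' @param obvious_threshold,disappear_threshold classification thresholds.
#' @return factor with levels `obvious`, `marginal`, `none`.
#' @export
#' @examples
#' classify_llps(c(0.5, 0.10, 0.05))
classify_llps <- function(value, obvious_threshold = 0.15,
                          disappear_threshold = 0.07) {
  stopifnot(disappear_threshold <= obvious_threshold)
  lab <- ifelse(value > obvious_threshold, "obvious",
                ifelse(value < disappear_threshold, "none", "marginal"))
  factor(lab, levels = c("obvious", "marginal", "none"))
}

#' Critical temperature by threshold interpolation
#'
#' Finds the first downward crossing of the order parameter through
#' `threshold` (0.07: the value below which phase separation is deemed gone)
#' and interpolates linearly in temperature between the bracketing grid
#' points.
#'
#' @param temperature strictly increasing temperatures, T0 units.
#' @param value matching P_H - P_L values.
#' @param threshold disappearance threshold.
#' @return list with `t_cr` (NA when censored) and `censored` (`"none"`,
#'   `"above"` = all values above threshold so T_cr >= max(T), `"below"`).
#' @export
#' @examples
#' tcr_threshold(c(2, 3), c(0.17, 0.02))$t_cr  # 2.667
tcr_threshold <- function(temperature, value, threshold = 0.07) {
  stopifnot(length(temperature) == length(value), length(value) >= 1L,
            all(diff(temperature) > 0))
  if (all(value >= threshold))
    return(list(t_cr = NA_real_, censored = "above",
                bound = max(temperature)))
  if (all(value < threshold))
    return(list(t_cr = NA_real_, censored = "below",
                bound = min(temperature)))
  i <- which(value >= threshold & c(value[-1L], Inf) < threshold)[1L]
  if (is.na(i))  # series starts below threshold; first point below after a rise
    stop("order parameter does not cross the threshold downward")
  t_cr <- temperature[i] + (value[i] - threshold) /
    (value[i] - value[i + 1L]) * (temperature[i + 1L] - temperature[i])
  list(t_cr = t_cr, censored = "none", bound = NA_real_)
}

#' Fit the power-law binodal
#'
#' Least-squares fit of P_H - P_L = A (T_cr - T)^beta to the points with
#' order parameter above `disappear_threshold`.  A is profiled analytically
#' for each candidate (T_cr, beta); T_cr (and beta when free) is found by a
#' deterministic multi-start search, so the fit has no random element.
#' `beta_mode = "fixed_0.325"` pins beta at the 3D Ising exponent.
#'
#' @param temperature strictly increasing temperatures, T0 units.
#' @param value matching P_H - P_L values, in `[0, 1]`.
#' @param beta_mode `"fixed_0.325"` or `"free"`.
#' @param beta the exponent used when fixed.
#' @param disappear_threshold points at or below this are excluded from the
#'   fit (they carry no binodal signal).
#' @param t_cr_max upper search bound for T_cr (default: max fitted
#'   temperature plus five grid ranges).
#' @return object of class `tcr_fit` with `coefficients` (A, t_cr, beta),
#'   `fitted`, `residuals`, `sse`, the data, and `convergence` diagnostics.
#' @export
#' @examples
#' b <- make_binodal(A = 0.5, t_cr = 3.0, beta = 0.325,
#'                   temperature = c(1, 1.5, 2, 2.25, 2.5, 2.75))
#' coef(tcr_fit(b$temperature, b$value, beta_mode = "free"))
tcr_fit <- function(temperature, value,
                    beta_mode = c("fixed_0.325", "free"), beta = 0.325,
                    disappear_threshold = 0.07, t_cr_max = NULL) {
  beta_mode <- match.arg(beta_mode)
  stopifnot(length(temperature) == length(value), all(diff(temperature) > 0),
            all(value >= 0))
  use <- value > disappear_threshold
  if (sum(use) < 3L)
    stop("need at least 3 points above the disappearance threshold; got ",
         sum(use))
  tt <- temperature[use]
  vv <- value[use]
  t_hi <- max(tt)
  if (is.null(t_cr_max)) t_cr_max <- t_hi + 5 * max(diff(range(tt)), 1)
  profile_A <- function(t_cr, b) {
    u <- pmax(t_cr - tt, 0)^b
    s <- sum(u * u)
    if (s == 0) return(0)
    max(sum(vv * u) / s, 0)
  }
  sse <- function(t_cr, b) {
    A <- profile_A(t_cr, b)
    sum((vv - A * pmax(t_cr - tt, 0)^b)^2)
  }
  eps <- 1e-8
  if (beta_mode == "fixed_0.325") {
    # deterministic multi-start: coarse scan, then refine the best bracket
    grid <- seq(t_hi + eps, t_cr_max, length.out = 200L)
    vals <- vapply(grid, sse, numeric(1), b = beta)
    i <- which.min(vals)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    op <- optimize(sse, c(lo, hi), b = beta, tol = 1e-12)
    t_cr <- op$minimum
    b_hat <- beta
    conv <- list(method = "profile-1d", objective = op$objective)
  } else {
    obj <- function(par) {
      t_cr <- t_hi + eps + exp(par[1])  # enforce t_cr > max fitted T
      b <- exp(par[2])
      sse(t_cr, b)
    }
    starts <- expand.grid(dtcr = c(0.1, 0.3, 1, 3), beta0 = c(0.25, 0.325, 0.5, 1))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      p0 <- c(log(starts$dtcr[s]), log(starts$beta0[s]))
      o <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 5000))
      o <- optim(o$par, obj, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 1000))
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (!is.finite(best$value))
      stop("power-law fit did not converge; residual objective is not finite")
    t_cr <- t_hi + eps + exp(best$par[1])
    b_hat <- exp(best$par[2])
    conv <- list(method = "profile-2d-multistart", objective = best$value,
                 optim_convergence = best$convergence)
  }
  A <- profile_A(t_cr, b_hat)
  fitted_all <- A * pmax(t_cr - temperature, 0)^b_hat
  out <- structure(list(
    coefficients = c(A = A, t_cr = t_cr, beta = b_hat),
    beta_mode = beta_mode,
    data = data.frame(temperature = temperature, value = value, used = use),
    fitted = fitted_all,
    residuals = value - fitted_all,
    sse = sse(t_cr, b_hat),
    disappear_threshold = disappear_threshold,
    convergence = conv), class = "tcr_fit")
  out
}

#' @export
print.tcr_fit <- function(x, ...) {
  cat("Power-law binodal fit: P_H - P_L = A (T_cr - T)^beta\n")
  cat(sprintf("  A = %.6g, T_cr = %.6g T0, beta = %.6g (%s)\n",
              x$coefficients["A"], x$coefficients["t_cr"],
              x$coefficients["beta"],
              if (x$beta_mode == "free") "free" else "fixed"))
  cat(sprintf("  %d of %d points fitted, SSE = %.3g\n",
              sum(x$data$used), nrow(x$data), x$sse))
  invisible(x)
}

#' @export
coef.tcr_fit <- function(object, ...) object$coefficients

#' @export
summary.tcr_fit <- function(object, ...) {
  n <- sum(object$data$used)
  p <- if (object$beta_mode == "free") 3L else 2L
  rse <- sqrt(object$sse / max(n - p, 1L))
  thr <- tcr_threshold(object$data$temperature, object$data$value,
                       object$disappear_threshold)
  structure(list(fit = object, n_fitted = n, residual_se = rse,
                 threshold_estimate = thr), class = "summary.tcr_fit")
}

#' @export
print.summary.tcr_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual SE = %.3g on %d fitted points\n",
              x$residual_se, x$n_fitted))
  if (x$threshold_estimate$censored == "none")
    cat(sprintf("  threshold-rule estimate: T_cr = %.4g T0\n",
                x$threshold_estimate$t_cr))
  else
    cat(sprintf("  threshold-rule estimate censored (%s %.4g T0)\n",
                ifelse(x$threshold_estimate$censored == "above", ">=", "<="),
                x$threshold_estimate$bound))
  invisible(x)
}

#' @export
predict.tcr_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$temperature
        else if (is.data.frame(newdata)) newdata$temperature else newdata
  co <- object$coefficients
  unname(co["A"] * pmax(co["t_cr"] - tt, 0)^co["beta"])
}

#' @export
residuals.tcr_fit <- function(object, ...) object$residuals

#' @export
plot.tcr_fit <- function(x, ...) {
  d <- x$data
  plot(d$temperature, d$value, pch = ifelse(d$used, 19, 1),
       xlab = "temperature (T0)", ylab = expression(P[H] - P[L]), ...)
  tt <- seq(min(d$temperature), max(d$temperature, x$coefficients["t_cr"]),
            length.out = 200)
  lines(tt, predict(x, tt))
  abline(h = x$disappear_threshold, lty = 3)
  abline(v = x$coefficients["t_cr"], lty = 2)
  invisible(x)
}

#' @export
simulate.tcr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- sum(object$data$used)
  p <- if (object$beta_mode == "free") 3L else 2L
  sdres <- sqrt(object$sse / max(n - p, 1L))
  tt <- object$data$temperature
  mu <- predict(object, tt)
  out <- as.data.frame(replicate(nsim, pmax(mu + rnorm(length(mu), 0, sdres), 0)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(data.frame(temperature = tt), out)
}
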