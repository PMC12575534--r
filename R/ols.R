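#' Global least-squares fit with multicollinearity diagnostics
#'
#' Fits the global (spatially stationary) counterpart of the local model:
#' ordinary least squares of the upstream-corrected EC values on the
#' land-use predictors, with an intercept.  Reports the usual coefficient
#' table, per-predictor variance inflation factors, and the information
#' criteria used for model ranking.  The parameter count entering AIC and
#' AICc is k = p + 2 (p slopes, the intercept, and the error variance);
#' AICc applies the small-sample correction
#' AICc = AIC + 2k(k+1)/(n - k - 1).
#'
#' @param X numeric matrix or data.frame of predictors (no intercept
#'   column; one column per predictor, named).
#' @param y numeric response vector (delta-EC, mS/m).
#' @return object of class `global_fit`: list with `coefficients` (table
#'   of estimate, std. error, t value, two-sided p), `vif` (named, `NA`
#'   for single-predictor models), `residuals`, `fitted`, `sigma`,
#'   `r_squared`, `adj_r_squared`, `aic`, `aicc`, `bic`, `n`, `p`, `lm`
#'   (the underlying [stats::lm] fit).
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("input error: X and y lengths differ")
  if (n <= p + 2L) {
    stop("input error: need n > p + 2 observations (n = ", n, ", p = ", p, ")")
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    dep <- colnames(Xi)[qrX$pivot[(qrX$rank + 1L):ncol(Xi)]]
    stop("singular design: column(s) ", paste(dep, collapse = ", "),
         " linearly dependent on the others")
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")               # p + 2: coefficients plus error variance
  aic <- stats::AIC(fit)
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)

  coefs <- sm$coefficients
  colnames(coefs) <- c("estimate", "std_error", "t_value", "p_value")

  structure(
    list(
      coefficients = coefs,
      vif = if (p >= 2L) vif(X) else stats::setNames(rep(NA_real_, p), colnames(X)),
      residuals = stats::residuals(fit),
      fitted = stats::fitted(fit),
      sigma = sm$sigma,
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      aic = aic, aicc = aicc, bic = stats::BIC(fit),
      n = n, p = p, k = k,
      predictors = colnames(X),
      lm = fit
    ),
    class = "global_fit"
  )
}

#' @export
print.global_fit <- function(x, digits = 4, ...) {
  cat("Global OLS fit: n =", x$n, ", p =", x$p, "\n")
  stats::printCoefmat(x$coefficients, digits = digits,
                      cs.ind = 1:2, tst.ind = 3, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("sigma =", format(x$sigma, digits = digits),
      " adj R2 =", format(x$adj_r_squared, digits = digits), "\n")
  cat("AIC =", format(x$aic, digits = 6),
      " AICc =", format(x$aicc, digits = 6),
      " BIC =", format(x$bic, digits = 6), "\n")
  if (!all(is.na(x$vif))) {
    cat("VIF:", paste(names(x$vif), format(x$vif, digits = digits),
                      sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Variance inflation factors
#'
#' VIF_j = 1/(1 - R2_j), with R2_j the coefficient of determination of
#' predictor j regressed (with intercept) on the remaining predictors.
#' Values above 5 conventionally flag multicollinearity concern.  Perfect
#' collinearity yields `Inf` rather than an error.
#'
#' @param X numeric matrix or data.frame with at least two predictor
#'   columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2L) stop("input error: VIF needs at least two predictors")
  out <- stats::setNames(numeric(p), colnames(X))
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    res <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- if (tot == 0) 1 else 1 - sum(res^2) / tot
    out[j] <- if (r2 >= 1 - 1e-14) Inf else 1 / (1 - r2)
  }
  out
}
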