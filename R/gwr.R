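#' Spatial kernel weights
#'
#' Fixed-distance kernels mapping separation (metres) to weights in
#' [0, 1]: gaussian `w = exp(-(d/b)^2 / 2)` or bisquare
#' `w = (1 - (d/b)^2)^2` for `d < b`, 0 beyond (compact support).  The
#' weight at zero distance is 1 for both families.
#'
#' @param distances non-negative numeric vector, metres.
#' @param bandwidth positive kernel bandwidth, metres.
#' @param family `"gaussian"` (default) or `"bisquare"`.
#' @return numeric weight vector.
#' @export
kernel_weights <- function(distances, bandwidth,
                           family = c("gaussian", "bisquare")) {
  family <- match.arg(family)
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("parameter error: bandwidth must be positive")
  }
  if (any(distances < 0)) stop("input error: negative distances")
  if (family == "gaussian") {
    exp(-0.5 * (distances / bandwidth)^2)
  } else {
    u <- distances / bandwidth
    ifelse(u < 1, (1 - u^2)^2, 0)
  }
}

check_coords <- function(coords, n) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) != n) {
    stop("input error: coords must be an n x 2 matrix of projected metres")
  }
  if (!all(is.finite(coords))) stop("input error: non-finite coordinates")
  if (all(abs(coords[, 1]) <= 360) && all(abs(coords[, 2]) <= 90)) {
    stop("input error: coordinates look geographic (lon/lat); ",
         "supply projected metric coordinates")
  }
  if (anyDuplicated(coords)) {
    stop("input error: duplicate coordinates at row ",
         which(duplicated(coords))[1L])
  }
  coords
}

family_code <- function(family) match(family, c("gaussian", "bisquare")) - 1L

#' Fit a geographically weighted regression
#'
#' At every observation location (u_i, v_i) a weighted least-squares
#' problem is solved with kernel weights decaying with distance from i,
#' yielding location-specific coefficients
#' \deqn{y_i = \beta_0(u_i, v_i) + \sum_j \beta_j(u_i, v_i) x_{ij} + \varepsilon_i.}
#' The hat matrix S maps y to fitted values; its trace measures the
#' effective number of parameters and enters the small-sample corrected
#' AICc,
#' \deqn{AICc = 2n\log\hat\sigma + n\log 2\pi + n\frac{n + tr(S)}{n - 2 - tr(S)},}
#' with \eqn{\hat\sigma^2 = RSS/n}.  Adjusted R2 uses the effective
#' residual degrees of freedom `n - 2 tr(S) + tr(S'S)`.
#'
#' @param X predictor matrix (no intercept column).
#' @param y response vector (delta-EC, mS/m).
#' @param coords n x 2 matrix of projected coordinates, metres.
#'   Geographic (lon/lat) input is rejected, not silently reprojected.
#' @param bandwidth fixed kernel bandwidth, metres.
#' @param family kernel family, `"gaussian"` or `"bisquare"`.
#' @param keep_projection keep the per-location projection matrices
#'   needed by [f3_test()] (memory `n^2 (p+1)` doubles).
#' @return object of class `gwr_fit`: `beta` (n x (p+1) local
#'   coefficients, intercept first), `hat` (n x n), `hat_diag`,
#'   `trace_hat`, `trace_hat2`, `effective_params`, `residuals`,
#'   `fitted`, `rss`, `sigma2`, `aicc`, `r_squared`, `adj_r_squared`,
#'   `summary` (per-coefficient five-number summary), `kernel`,
#'   `coords`, plus the design (`X` with intercept, `y`).
#' @export
fit_gwr <- function(X, y, coords, bandwidth,
                    family = c("gaussian", "bisquare"),
                    keep_projection = TRUE) {
  family <- match.arg(family)
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("parameter error: bandwidth must be positive")
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 2L) {
    stop("input error: need n > p + 2 observations (n = ", n, ", p = ", p, ")")
  }
  coords <- check_coords(coords, n)
  D <- as.matrix(stats::dist(coords))
  Xi <- cbind(`(Intercept)` = 1, X)

  core <- gwr_core_cpp(Xi, y, D, bandwidth, family_code(family),
                       keep_projection)
  beta <- core$beta
  colnames(beta) <- colnames(Xi)
  S <- core$hat
  fitted <- rowSums(Xi * beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  trS <- sum(diag(S))
  trStS <- sum(S * S)
  enp <- 2 * trS - trStS
  sigma2 <- rss / n
  if (n - 2 - trS <= 0) {
    stop("degenerate bandwidth: effective parameters tr(S) = ",
         format(trS, digits = 5), " leave no residual degrees of freedom")
  }
  aicc <- 2 * n * log(sqrt(sigma2)) + n * log(2 * pi) +
    n * (n + trS) / (n - 2 - trS)
  edf <- n - enp
  adj_r2 <- 1 - (rss / edf) / (tss / (n - 1))

  fit <- structure(
    list(
      beta = beta, hat = S, hat_diag = diag(S),
      proj = if (keep_projection) core$proj else NULL,
      residuals = resid, fitted = fitted,
      rss = rss, sigma2 = sigma2,
      trace_hat = trS, trace_hat2 = trStS, effective_params = enp,
      aicc = aicc,
      r_squared = 1 - rss / tss, adj_r_squared = adj_r2,
      kernel = list(family = family, bandwidth = bandwidth),
      coords = coords, X = Xi, y = y, n = n, p = p
    ),
    class = "gwr_fit"
  )
  fit$summary <- coefficient_summary(fit)
  fit
}

#' @export
print.gwr_fit <- function(x, digits = 4, ...) {
  cat("GWR fit: n =", x$n, ", p =", x$p,
      ", kernel =", x$kernel$family,
      ", bandwidth =", format(x$kernel$bandwidth, digits = 7), "m\n")
  cat("effective parameters tr(S) =", format(x$trace_hat, digits = digits),
      " AICc =", format(x$aicc, digits = 6),
      " adj R2 =", format(x$adj_r_squared, digits = digits), "\n")
  cat("Local coefficient summary:\n")
  print(round(x$summary, 6))
  invisible(x)
}

#' Leave-one-out cross-validation score for a bandwidth
#'
#' Sum of squared prediction errors where the prediction at each location
#' uses zero self-weight.  Degenerate bandwidths (some location with
#' fewer positively weighted neighbours than coefficients) are an error.
#'
#' @inheritParams fit_gwr
#' @return the CV score (sum of squared leave-one-out errors).
#' @export
cv_score <- function(X, y, coords, bandwidth,
                     family = c("gaussian", "bisquare")) {
  family <- match.arg(family)
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("parameter error: bandwidth must be positive")
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  coords <- check_coords(coords, length(y))
  D <- as.matrix(stats::dist(coords))
  score <- gwr_cv_cpp(cbind(1, X), y, D, bandwidth, family_code(family))
  if (!is.finite(score)) {
    stop("degenerate bandwidth: some location has too few positively ",
         "weighted neighbours at bandwidth ", format(bandwidth, digits = 6))
  }
  score
}

#' Optimize the GWR bandwidth
#'
#' Minimizes the leave-one-out CV score or the corrected AICc over fixed
#' bandwidths between the smallest positive and the largest pairwise
#' distance.  A coarse grid first brackets the minimum (the objective can
#' be multimodal), then golden-section/Brent refinement
#' ([stats::optimize]) localizes it to a tolerance of 1e-3 times the
#' bracket width.
#'
#' @inheritParams fit_gwr
#' @param criterion `"cv"` or `"aicc"`; recorded in the result for
#'   provenance.
#' @param n_grid number of coarse bracketing grid points.
#' @return list of class `bandwidth_selection`: `bandwidth`, `score`,
#'   `criterion`, `family`, `bracket`.
#' @export
optimize_bandwidth <- function(X, y, coords,
                               family = c("gaussian", "bisquare"),
                               criterion = c("cv", "aicc"),
                               n_grid = 16L) {
  family <- match.arg(family)
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  coords <- check_coords(coords, n)
  D <- as.matrix(stats::dist(coords))
  dpos <- D[upper.tri(D)]
  lo <- min(dpos[dpos > 0])
  hi <- max(dpos)
  Xi <- cbind(1, X)
  fam <- family_code(family)

  objective <- function(bw) {
    if (criterion == "cv") {
      gwr_cv_cpp(Xi, y, D, bw, fam)
    } else {
      tryCatch({
        core <- gwr_core_cpp(Xi, y, D, bw, fam, FALSE)
        rss <- sum((y - rowSums(Xi * core$beta))^2)
        trS <- sum(diag(core$hat))
        if (n - 2 - trS <= 0) return(Inf)
        2 * n * log(sqrt(rss / n)) + n * log(2 * pi) +
          n * (n + trS) / (n - 2 - trS)
      }, error = function(e) Inf)
    }
  }

  grid <- seq(lo, hi, length.out = n_grid)
  gvals <- vapply(grid, objective, numeric(1L))
  if (all(!is.finite(gvals))) {
    stop("no valid bandwidth: objective is infinite across [",
         format(lo, digits = 6), ", ", format(hi, digits = 6), "] m")
  }
  k <- which.min(gvals)
  bracket <- c(grid[max(1L, k - 1L)], grid[min(n_grid, k + 1L)])
  finite_objective <- function(bw) {   # optimize() warns on Inf values
    v <- objective(bw)
    if (is.finite(v)) v else .Machine$double.xmax
  }
  opt <- stats::optimize(finite_objective, interval = bracket,
                         tol = 1e-3 * (hi - lo))
  # keep the grid point if refinement did not improve on it
  cand_bw <- c(opt$minimum, grid[k])
  cand_sc <- c(opt$objective, gvals[k])
  best <- which.min(cand_sc)
  structure(
    list(bandwidth = cand_bw[best], score = cand_sc[best],
         criterion = criterion, family = family, bracket = c(lo, hi)),
    class = "bandwidth_selection"
  )
}

#' @export
print.bandwidth_selection <- function(x, ...) {
  cat("Optimal bandwidth ", format(x$bandwidth, digits = 7),
      " m (", x$family, " kernel), minimizing ", toupper(x$criterion),
      " score ", format(x$score, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Approximate F test for spatially varying coefficients
#'
#' Tests, per coefficient, whether the spatial variability of the local
#' estimates exceeds what a stationary model predicts (Leung, Mei and
#' Zhang 2000, test for coefficient variation).  The observed spatial
#' variance of the k-th local coefficient series is a quadratic form in
#' y, \eqn{V_k = y' B_k' (I - J/n) B_k y / n}, where row i of
#' \eqn{B_k} extracts the k-th coefficient of the location-i solve.
#' The statistic compares it to its null expectation,
#' \deqn{F_3(k) = \frac{V_k / \gamma_1}{\hat\sigma^2},}
#' with \eqn{\gamma_r = tr(Q^r)}, \eqn{Q = B_k'(I - J/n)B_k/n}, and
#' \eqn{\hat\sigma^2 = RSS/\delta_1}, \eqn{\delta_r = tr([(I-S)'(I-S)]^r)}.
#' Under stationarity it is approximately F with
#' \eqn{(\gamma_1^2/\gamma_2,\ \delta_1^2/\delta_2)} degrees of freedom.
#' p values are reported unadjusted across coefficients.  A coefficient
#' series that is numerically constant (relative spread below 1e-8, e.g.
#' in the global-model limit of a very large bandwidth) reports statistic
#' 0 and p 1.
#'
#' @param fit a `gwr_fit` with projection matrices retained
#'   (`keep_projection = TRUE`).
#' @param global optional matching [fit_ols()] fit on the same design;
#'   used only to validate that the two models share X and y.
#' @return data.frame with one row per coefficient (intercept first):
#'   `coefficient`, `statistic`, `df1`, `df2`, `p_value`.
#' @references Leung, Y., Mei, C.-L., Zhang, W.-X. (2000). Statistical
#'   tests for spatial nonstationarity based on the geographically
#'   weighted regression model. Environment and Planning A 32, 9-32.
#' @export
f3_test <- function(fit, global = NULL) {
  stopifnot(inherits(fit, "gwr_fit"))
  if (is.null(fit$proj)) {
    stop("input error: fit was built with keep_projection = FALSE; ",
         "refit with keep_projection = TRUE")
  }
  if (!is.null(global)) {
    stopifnot(inherits(global, "global_fit"))
    if (global$n != fit$n || global$p != fit$p) {
      stop("input error: global and GWR fits do not share the same design")
    }
    if (max(abs(global$lm$model$.y - fit$y)) > 0) {
      stop("input error: global and GWR fits do not share the same response")
    }
  }
  n <- fit$n
  y <- fit$y
  M <- diag(n) - fit$hat
  R <- crossprod(M)
  delta1 <- sum(diag(R))
  delta2 <- sum(R * R)
  sigma2 <- fit$rss / delta1
  if (delta1 <= 0 || delta2 <= 0) {
    stop("diagnostic error: non-positive residual trace (delta1 = ",
         format(delta1), ")")
  }

  pcols <- ncol(fit$beta)
  out <- data.frame(
    coefficient = colnames(fit$beta),
    statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
    p_value = NA_real_, stringsAsFactors = FALSE
  )
  df2 <- delta1^2 / delta2
  for (k in seq_len(pcols)) {
    bk <- fit$beta[, k]
    if (stats::sd(bk) <= 1e-8 * (1 + abs(mean(bk)))) {
      out$statistic[k] <- 0; out$df1[k] <- NA; out$df2[k] <- df2
      out$p_value[k] <- 1
      next
    }
    Bk <- t(fit$proj[k, , ])          # n x n, row i = location-i extractor
    Bc <- sweep(Bk, 2L, colMeans(Bk)) # (I - J/n) Bk
    Q <- crossprod(Bc) / n
    gamma1 <- sum(diag(Q))
    gamma2 <- sum(Q * Q)
    Vk <- sum((bk - mean(bk))^2) / n
    df1 <- gamma1^2 / gamma2
    if (!is.finite(df1) || df1 <= 0) {
      stop("diagnostic error: degenerate numerator degrees of freedom for ",
           colnames(fit$beta)[k])
    }
    out$statistic[k] <- (Vk / gamma1) / sigma2
    out$df1[k] <- df1
    out$df2[k] <- df2
    out$p_value[k] <- stats::pf(out$statistic[k], df1, df2,
                                lower.tail = FALSE)
  }
  out
}

#' Five-number summary of local coefficients
#'
#' Min, first quartile, median, third quartile and max of each local
#' coefficient series, with quartiles by the linear-interpolation
#' convention ([stats::quantile] type 7).
#'
#' @param fit a `gwr_fit`.
#' @return matrix, one row per coefficient, columns
#'   `Min.`, `1st Qu.`, `Median`, `3rd Qu.`, `Max.`.
#' @export
coefficient_summary <- function(fit) {
  stopifnot(inherits(fit, "gwr_fit"))
  out <- t(apply(fit$beta, 2L, stats::quantile,
                 probs = c(0, 0.25, 0.5, 0.75, 1), type = 7))
  colnames(out) <- c("Min.", "1st Qu.", "Median", "3rd Qu.", "Max.")
  out
}
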