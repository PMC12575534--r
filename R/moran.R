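#' Spatial weights for Moran's I
#'
#' Inverse-distance weights `w_ij = 1/d_ij` (default) or k-nearest
#' binary weights, row-standardized by default so each row sums to 1.
#' The diagonal is always zero.  Nearest-neighbour ties are broken by
#' lower node index, so the construction is deterministic.
#'
#' @param coords n x 2 matrix of projected coordinates; duplicates are an
#'   error (infinite inverse-distance weight).
#' @param scheme `"inverse_distance"` or `"knn"`.
#' @param k number of neighbours for `"knn"`.
#' @param row_standardize divide each row by its sum.
#' @return n x n matrix of class `spatial_weights`, with attributes
#'   `scheme` and `row_standardized`.
#' @export
build_weights <- function(coords, scheme = c("inverse_distance", "knn"),
                          k = 4L, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  if (anyDuplicated(coords)) {
    stop("input error: duplicate coordinates (infinite inverse-distance weight)")
  }
  n <- nrow(coords)
  if (n < 3L) stop("input error: need at least 3 locations")
  D <- as.matrix(stats::dist(coords))
  if (scheme == "inverse_distance") {
    W <- 1 / D
    diag(W) <- 0
  } else {
    if (k < 1L || k > n - 1L) stop("input error: k must be in [1, n-1]")
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      d <- D[i, ]
      d[i] <- Inf
      nb <- order(d)[seq_len(k)]  # order() breaks ties by lower index
      W[i, nb] <- 1
    }
  }
  if (row_standardize) {
    rs <- rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  structure(W, scheme = scheme, row_standardized = row_standardize,
            class = c("spatial_weights", "matrix", "array"))
}

#' Global Moran's I
#'
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},}
#' with z the mean-centered values.  The expectation under no spatial
#' autocorrelation is \eqn{-1/(n-1)}; the analytical variance uses the
#' randomisation assumption, giving a z score and two-sided normal p
#' value.  A permutation p value (values randomly reassigned to
#' locations, seeded and reproducible) can be requested in addition, with
#' \eqn{p = (1 + \#\{|I^*_{perm} - E[I]| \ge |I - E[I]|\})/(1 + n_{perm})}.
#'
#' @param values numeric vector; must not be constant.
#' @param weights a `spatial_weights` matrix (or any non-negative n x n
#'   matrix with zero diagonal).
#' @param permutations optional permutation count (>= 99).
#' @param seed seed for the permutation draw (required with
#'   `permutations`).
#' @return list of class `moran_result`: `I`, `expectation`, `variance`,
#'   `z`, `p_value` (normal approximation, two-sided), and when requested
#'   `p_permutation`, `permutations`, `seed`, `perm_I` (the permuted
#'   statistics).
#' @export
morans_i <- function(values, weights, permutations = NULL, seed = NULL) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3L) stop("input error: need at least 3 values")
  W <- unclass(weights)
  if (!is.matrix(W) || any(dim(W) != n)) {
    stop("input error: weights must be an n x n matrix")
  }
  z <- x - mean(x)
  m2 <- sum(z^2)
  if (m2 == 0) stop("zero-variance error: values are constant")
  W0 <- sum(W)
  I <- (n / W0) * sum(W * tcrossprod(z)) / m2

  # randomisation-assumption moments
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  EI <- -1 / (n - 1)
  b2 <- n * sum(z^4) / m2^2
  num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * W0^2) -
    b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * W0^2)
  VI <- num / ((n - 1) * (n - 2) * (n - 3) * W0^2) - EI^2
  zstat <- (I - EI) / sqrt(VI)
  pval <- 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)

  out <- list(I = I, expectation = EI, variance = VI, z = zstat,
              p_value = pval, n = n)
  if (!is.null(permutations)) {
    permutations <- as.integer(permutations)
    if (permutations < 99L) stop("input error: use at least 99 permutations")
    if (is.null(seed)) stop("input error: permutation test requires a seed")
    perm_I <- withr::with_seed(seed, {
      vapply(seq_len(permutations), function(b) {
        zp <- z[sample.int(n)]
        (n / W0) * sum(W * tcrossprod(zp)) / sum(zp^2)
      }, numeric(1L))
    })
    out$p_permutation <-
      (1 + sum(abs(perm_I - EI) >= abs(I - EI))) / (1 + permutations)
    out$permutations <- permutations
    out$seed <- seed
    out$perm_I <- perm_I
  }
  structure(out, class = "moran_result")
}

#' @export
print.moran_result <- function(x, digits = 4, ...) {
  cat("Global Moran's I =", format(x$I, digits = digits),
      " E[I] =", format(x$expectation, digits = digits),
      " z =", format(x$z, digits = digits),
      " p =", format(x$p_value, digits = digits), "\n")
  if (!is.null(x$p_permutation)) {
    cat("permutation p =", format(x$p_permutation, digits = digits),
        "(", x$permutations, "permutations, seed", x$seed, ")\n")
  }
  invisible(x)
}

#' Side-by-side global vs GWR comparison record
#'
#' Collects the diagnostics used to compare the stationary and the
#' locally varying model of the same design: information criteria,
#' adjusted R2, and Moran's I of each model's residuals under a common
#' spatial weights matrix.
#'
#' @param global a [fit_ols()] result.
#' @param gwr a [fit_gwr()] result on the same design.
#' @param weights a `spatial_weights` matrix over the same locations.
#' @return data.frame with rows `GLM` and `GWR` and columns `AIC`,
#'   `AICc`, `BIC`, `adj_r_squared`, `moran_I`, `moran_p`; attribute
#'   `weights_scheme` names the scheme used.
#' @export
compare_models <- function(global, gwr, weights) {
  stopifnot(inherits(global, "global_fit"), inherits(gwr, "gwr_fit"))
  if (global$n != gwr$n || global$p != gwr$p ||
      !identical(global$predictors, colnames(gwr$beta)[-1L])) {
    stop("input error: global and GWR fits use different model specifications")
  }
  m_glm <- morans_i(global$residuals, weights)
  m_gwr <- morans_i(gwr$residuals, weights)
  out <- data.frame(
    model = c("GLM", "GWR"),
    AIC = c(global$aic, NA),
    AICc = c(global$aicc, gwr$aicc),
    BIC = c(global$bic, NA),
    adj_r_squared = c(global$adj_r_squared, gwr$adj_r_squared),
    moran_I = c(m_glm$I, m_gwr$I),
    moran_p = c(m_glm$p_value, m_gwr$p_value),
    stringsAsFactors = FALSE
  )
  attr(out, "weights_scheme") <- attr(weights, "scheme")
  out
}
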