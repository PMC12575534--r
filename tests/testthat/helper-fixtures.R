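# Shared fixtures and independent oracles.  Oracles deliberately use
# plain-R loops and textbook formulas, independent of the package's
# vectorized / compiled code paths.

# Three-node confluence: headwaters A and B drain into C.
toy_records <- function() {
  data.frame(
    id = c("A", "B", "C"),
    downstream_id = c("C", "C", NA),
    area_km2 = c(1, 1, 4),
    centroid_x = c(0, 2000, 1000),
    centroid_y = c(2000, 2000, 0),
    ec_spring = c(5, 7, 6),
    stringsAsFactors = FALSE
  )
}

toy_network <- function() build_network(toy_records())

random_network <- function(n, seed) {
  generate_watershed(synthetic_config(n_nodes = n, seed = seed))
}

# random regression fixture over a ~50 km projected domain
reg_fixture <- function(n, seed, p = 2) {
  set.seed(seed)
  list(
    X = matrix(stats::rnorm(n * p), n, p,
               dimnames = list(NULL, paste0("x", seq_len(p)))),
    coords = cbind(stats::runif(n, 0, 50000), stats::runif(n, 0, 50000))
  )
}

kernel_oracle <- function(d, bw, family) {
  if (family == "gaussian") return(exp(-0.5 * (d / bw)^2))
  u <- d / bw
  ifelse(u < 1, (1 - u^2)^2, 0)
}

# per-location weighted normal-equation solve, one plain solve() per site
gwr_oracle_beta <- function(X, y, coords, bw, family = "gaussian") {
  Xi <- cbind(1, X)
  D <- as.matrix(stats::dist(coords))
  t(vapply(seq_len(nrow(Xi)), function(i) {
    w <- kernel_oracle(D[, i], bw, family)
    A <- t(Xi * w) %*% Xi
    drop(solve(A, t(Xi * w) %*% y))
  }, numeric(ncol(Xi))))
}

# leave-one-out CV by literally refitting without observation i
cv_oracle <- function(X, y, coords, bw, family = "gaussian") {
  Xi <- cbind(1, X)
  D <- as.matrix(stats::dist(coords))
  sum(vapply(seq_len(nrow(Xi)), function(i) {
    w <- kernel_oracle(D[-i, i], bw, family)
    Xm <- Xi[-i, , drop = FALSE]
    b <- drop(solve(t(Xm * w) %*% Xm, t(Xm * w) %*% y[-i]))
    (y[i] - drop(Xi[i, ] %*% b))^2
  }, numeric(1L)))
}

# stationary / gradient-slope simulation used by the F3 checks
simulate_f3_p <- function(seed, n, bw, grad = NULL, noise = 1) {
  set.seed(seed)
  coords <- cbind(stats::runif(n, 0, 50000), stats::runif(n, 0, 50000))
  X <- cbind(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  b1 <- if (is.null(grad)) rep(2, n) else {
    t <- (coords[, 1] - min(coords[, 1])) / diff(range(coords[, 1]))
    grad[1] + (grad[2] - grad[1]) * t
  }
  y <- 1 + b1 * X[, 1] - X[, 2] + stats::rnorm(n, sd = noise)
  f3_test(fit_gwr(X, y, coords, bw))$p_value
}
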