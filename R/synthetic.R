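#' Configuration for the synthetic watershed generator
#'
#' Encodes the study conditions the generator emulates: a single-outlet
#' dendritic network of ~54 sampling sites draining ~1,880 km2 laid out
#' over a ~50 x 50 km projected domain, nine land-cover categories whose
#' per-node composition is Dirichlet-distributed with forest dominant
#' (as in rural Japanese mountain watersheds), and delta-EC responses
#' generated by spatially varying linear effects plus Gaussian noise,
#' re-accumulated downstream into raw EC by area-weighted mixing.
#'
#' @param n_nodes number of sub-watersheds (>= 3).
#' @param seed mandatory integer seed; all randomness flows through it.
#' @param area_mean_km2 mean incremental drainage area (log-normal);
#'   default 1880/54 so the full catchment is about 1,880 km2 at 54
#'   nodes.
#' @param area_sdlog log-scale sd of the incremental areas.
#' @param domain_km approximate side of the square layout domain.
#' @param dirichlet named concentration vector over the nine base
#'   land-cover categories; the default puts ~3/4 of the mass on forest.
#' @param cell_km2 area of one land-cover grid cell, km2 (default 0.01,
#'   i.e. 100 m cells — a coarsened version of a 10 m product).
#' @param noise_sd sd of the Gaussian delta-EC noise, mS/m.
#' @param effect_sd target sd (mS/m) of each predictor's contribution to
#'   delta-EC; coefficient amplitudes are scaled by the predictor's
#'   count spread to reach it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 54L, seed,
                             area_mean_km2 = 1880 / 54,
                             area_sdlog = 0.6,
                             domain_km = 50,
                             dirichlet = c(WATER = 0.5, BUILTUP = 0.8,
                                           PADDY = 1.5, CROP = 0.8,
                                           GRASS = 0.5, BARE = 0.2,
                                           DBF = 5, EBF = 2.5, ENF = 4),
                             cell_km2 = 0.01,
                             noise_sd = 1,
                             effect_sd = 2) {
  if (missing(seed)) stop("input error: a seed is mandatory")
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 3L) stop("input error: n_nodes must be >= 3")
  if (area_mean_km2 <= 0 || cell_km2 <= 0 || domain_km <= 0) {
    stop("input error: areas and domain must be positive")
  }
  if (!identical(sort(names(dirichlet)), sort(landuse_categories()))) {
    stop("input error: dirichlet must name the nine base categories")
  }
  structure(
    list(n_nodes = n_nodes, seed = as.integer(seed),
         area_mean_km2 = area_mean_km2, area_sdlog = area_sdlog,
         domain_km = domain_km,
         dirichlet = dirichlet[landuse_categories()],
         cell_km2 = cell_km2, noise_sd = noise_sd, effect_sd = effect_sd),
    class = "synthetic_config"
  )
}

#' Generate a random dendritic watershed network
#'
#' Grows a single-outlet tree by random attachment, preferring nodes with
#' fewer than two upstream neighbours so confluences are mostly binary
#' (dendritic drainage).  Incremental areas are log-normal and
#' accumulated downstream; centroids come from a recursive tree embedding
#' (children fan out upstream of their parent) with uniform jitter, so
#' coordinates are distinct and the layout spans roughly the configured
#' domain.  Fully reproducible from the seed.
#'
#' @param config a [synthetic_config()].
#' @return a `watershed_network`.
#' @export
generate_watershed <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_nodes
  withr::with_seed(config$seed, {
    # topology: node 1 is the outlet; attach preferring < 2 children
    parent <- integer(n)
    n_child <- integer(n)
    for (i in 2:n) {
      open <- which(n_child[seq_len(i - 1L)] < 2L)
      pick <- if (length(open) > 0L) open else seq_len(i - 1L)
      parent[i] <- if (length(pick) == 1L) pick else sample(pick, 1L)
      n_child[parent[i]] <- n_child[parent[i]] + 1L
    }

    inc_area <- stats::rlnorm(
      n,
      meanlog = log(config$area_mean_km2) - config$area_sdlog^2 / 2,
      sdlog = config$area_sdlog
    )

    # recursive embedding: children fan out upstream with angular spread
    depth <- integer(n)
    for (i in 2:n) depth[i] <- depth[parent[i]] + 1L
    L <- config$domain_km * 1000 / (max(depth) + 1L)
    xy <- matrix(NA_real_, n, 2L)
    ang <- numeric(n)
    xy[1L, ] <- c(0, 0)
    ang[1L] <- pi / 2              # outlet points the network "up"
    for (i in 2:n) {
      sibs <- which(parent == parent[i])
      rank_i <- match(i, sibs)
      spread <- (rank_i - (length(sibs) + 1) / 2) * 0.9
      ang[i] <- ang[parent[i]] + spread + stats::runif(1L, -0.15, 0.15)
      step <- L * stats::runif(1L, 0.7, 1.3)
      xy[i, ] <- xy[parent[i], ] + step * c(cos(ang[i]), sin(ang[i]))
    }
    while (anyDuplicated(xy)) {      # vanishingly rare; jitter resolves it
      d <- which(duplicated(xy))
      xy[d, ] <- xy[d, ] + stats::runif(2L * length(d), -1, 1)
    }

    ids <- sprintf("W%02d", seq_len(n))
    records <- data.frame(
      id = ids,
      downstream_id = c(NA_character_, ids[parent[2:n]]),
      area_km2 = inc_area,
      centroid_x = xy[, 1L], centroid_y = xy[, 2L],
      stringsAsFactors = FALSE
    )
    build_network(records, areas = "incremental")
  })
}

incremental_areas <- function(network) {
  area <- stats::setNames(network$nodes$area_km2, network$nodes$id)
  vapply(network$nodes$id, function(id) {
    up <- network$upstream[[id]]
    area[[id]] - if (length(up) > 0L) sum(area[up]) else 0
  }, numeric(1L))
}

#' Generate a synthetic land-use predictor table
#'
#' Per node, category proportions are drawn from the configured Dirichlet
#' and converted to integer cell counts by a multinomial draw over the
#' node's cell budget (incremental area divided by the cell area), so
#' counts sum exactly to the budget.  Composites are filled.
#'
#' @param network a `watershed_network`.
#' @param config a [synthetic_config()]; the draw is seeded by
#'   `config$seed + 1` so it is independent of the topology draw yet
#'   reproducible.
#' @return a `predictor_table`.
#' @export
generate_landuse <- function(network, config) {
  stopifnot(inherits(network, "watershed_network"),
            inherits(config, "synthetic_config"))
  inc <- incremental_areas(network)
  budgets <- pmax(1L, as.integer(round(inc / config$cell_km2)))
  k <- length(config$dirichlet)
  withr::with_seed(config$seed + 1L, {
    counts <- t(vapply(seq_along(budgets), function(i) {
      g <- stats::rgamma(k, shape = config$dirichlet, rate = 1)
      if (sum(g) == 0) g <- rep(1, k)
      drop(stats::rmultinom(1L, budgets[i], prob = g / sum(g)))
    }, integer(k)))
  })
  colnames(counts) <- landuse_categories()
  derive_composites(data.frame(id = network$nodes$id, counts,
                               stringsAsFactors = FALSE))
}

#' Coefficient surfaces
#'
#' Descriptions of how a regression coefficient varies over the plane:
#' constant, linear gradient along a direction (interpolating between two
#' values across the span of the node coordinates), or a Gaussian bump
#' added to a base level.  Evaluated at node centroids by
#' [evaluate_surface()].
#'
#' @param value,from,to,base,amplitude coefficient values (response units
#'   per predictor unit).
#' @param angle gradient direction, radians (0 = west-to-east).
#' @param center bump centre as fractions (in [0, 1]) of the coordinate
#'   range.
#' @param radius bump radius as a fraction of the domain diagonal.
#' @return list of class `coef_surface`.
#' @name surfaces
NULL

#' @rdname surfaces
#' @export
surface_constant <- function(value) {
  structure(list(type = "constant", value = value), class = "coef_surface")
}

#' @rdname surfaces
#' @export
surface_gradient <- function(from, to, angle = 0) {
  structure(list(type = "gradient", from = from, to = to, angle = angle),
            class = "coef_surface")
}

#' @rdname surfaces
#' @export
surface_bump <- function(base, amplitude, center = c(0.5, 0.5),
                         radius = 0.25) {
  structure(list(type = "bump", base = base, amplitude = amplitude,
                 center = center, radius = radius),
            class = "coef_surface")
}

#' Evaluate a coefficient surface at locations
#'
#' @param surface a `coef_surface`.
#' @param coords n x 2 coordinate matrix.
#' @return numeric vector of coefficient values.
#' @export
evaluate_surface <- function(surface, coords) {
  stopifnot(inherits(surface, "coef_surface"))
  coords <- as.matrix(coords)
  switch(surface$type,
    constant = rep(surface$value, nrow(coords)),
    gradient = {
      proj <- cos(surface$angle) * coords[, 1L] +
        sin(surface$angle) * coords[, 2L]
      t <- if (diff(range(proj)) == 0) rep(0.5, length(proj)) else
        (proj - min(proj)) / diff(range(proj))
      surface$from + (surface$to - surface$from) * t
    },
    bump = {
      rx <- range(coords[, 1L]); ry <- range(coords[, 2L])
      cx <- rx[1L] + surface$center[1L] * diff(rx)
      cy <- ry[1L] + surface$center[2L] * diff(ry)
      r <- surface$radius * sqrt(diff(rx)^2 + diff(ry)^2)
      d2 <- (coords[, 1L] - cx)^2 + (coords[, 2L] - cy)^2
      surface$base + surface$amplitude * exp(-d2 / (2 * r^2))
    },
    stop("unknown surface type")
  )
}

#' Generate EC observations from spatially varying effects
#'
#' Builds the ground-truth local linear model
#' \eqn{\Delta EC^*_i = \beta_0(u_i,v_i) + \sum_j \beta_j(u_i,v_i) x_{ij} + \varepsilon_i}
#' with independent Gaussian noise, then converts the delta-EC values
#' into raw EC observations with [invert_delta_ec()] — area-weighted
#' downstream re-accumulation — so that running the analysis pipeline on
#' the generated EC exactly reverses the construction.  All ground truth
#' is returned for recovery tests.
#'
#' @param network a `watershed_network`.
#' @param predictors a `predictor_table` covering the network's nodes.
#' @param surfaces named list of `coef_surface` objects: an
#'   `"(Intercept)"` entry plus one entry per generating predictor code.
#' @param noise_sd Gaussian noise sd, mS/m.
#' @param seed integer seed for the noise draw.
#' @return list: `ec` (named vector, mS/m), `delta_true`,
#'   `beta_true` (n x (p+1) matrix of local coefficients),
#'   `predictors` (generating codes), `noise_sd`, `seed`.
#' @export
generate_ec <- function(network, predictors, surfaces, noise_sd, seed) {
  stopifnot(inherits(network, "watershed_network"))
  if (!"(Intercept)" %in% names(surfaces)) {
    stop("input error: surfaces must include an \"(Intercept)\" entry")
  }
  pred_codes <- setdiff(names(surfaces), "(Intercept)")
  coords <- as.matrix(network$nodes[, c("centroid_x", "centroid_y")])
  X <- predictor_matrix(predictors, pred_codes, ids = network$nodes$id)
  beta_true <- vapply(c("(Intercept)", pred_codes),
                      function(nm) evaluate_surface(surfaces[[nm]], coords),
                      numeric(nrow(coords)))
  eps <- withr::with_seed(seed,
                          stats::rnorm(nrow(coords), sd = noise_sd))
  delta_true <- beta_true[, 1L] + rowSums(X * beta_true[, -1L, drop = FALSE]) + eps
  names(delta_true) <- network$nodes$id
  ec <- invert_delta_ec(network, delta_true)
  list(ec = ec, delta_true = delta_true, beta_true = beta_true,
       predictors = pred_codes, noise_sd = noise_sd, seed = seed)
}

#' Generate a complete two-season synthetic dataset
#'
#' Convenience wrapper producing everything the pipeline consumes: a
#' dendritic network, a land-use table, and EC observations for two
#' seasons generated from different predictor sets — a paddy-driven
#' irrigation season (WATER with a negative west-east gradient, PADDY
#' with a stable positive effect) and a forest-driven non-irrigation
#' season (WATER changing sign across the domain, EBF mostly negative).
#' Coefficient amplitudes are scaled so each predictor contributes about
#' `effect_sd` mS/m of spread against `noise_sd` of noise.  The EC
#' observations are attached to the network as `ec_irrigation` and
#' `ec_nonirrigation` columns.
#'
#' @param config a [synthetic_config()].
#' @return list: `network` (with EC columns), `landuse`, `truth` (per
#'   season: output of [generate_ec()]), `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  network <- generate_watershed(config)
  landuse <- generate_landuse(network, config)

  scale_for <- function(code) {
    x <- landuse[[code]][match(network$nodes$id, landuse$id)]
    s <- stats::sd(x)
    if (s == 0) 1 else config$effect_sd / s
  }
  surf_irr <- list(
    "(Intercept)" = surface_constant(4),
    WATER = surface_gradient(-1.5 * scale_for("WATER"),
                             -0.5 * scale_for("WATER"), angle = 0),
    PADDY = surface_constant(scale_for("PADDY"))
  )
  surf_non <- list(
    "(Intercept)" = surface_constant(5),
    WATER = surface_gradient(-scale_for("WATER"), scale_for("WATER"),
                             angle = pi / 4),
    EBF = surface_gradient(-1.2 * scale_for("EBF"), 0.2 * scale_for("EBF"),
                           angle = pi / 2)
  )
  truth <- list(
    irrigation = generate_ec(network, landuse, surf_irr,
                             config$noise_sd, config$seed + 2L),
    nonirrigation = generate_ec(network, landuse, surf_non,
                                config$noise_sd, config$seed + 3L)
  )
  network$nodes$ec_irrigation <-
    as.numeric(truth$irrigation$ec[network$nodes$id])
  network$nodes$ec_nonirrigation <-
    as.numeric(truth$nonirrigation$ec[network$nodes$id])
  network$seasons <- c("irrigation", "nonirrigation")
  list(network = network, landuse = landuse, truth = truth, config = config)
}
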