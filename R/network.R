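#' Build a nested sub-watershed network
#'
#' Assembles a directed sub-watershed hierarchy from a per-node table.
#' Each sub-watershed drains to at most one downstream neighbour; the
#' upstream map is derived by inverting the downstream links.  The network
#' is validated: ids must be unique, downstream references must resolve,
#' the graph must be acyclic, catchment areas must be positive, and every
#' node's cumulative area must strictly exceed the sum of the cumulative
#' areas of its direct upstream neighbours (the incremental drainage area
#' is positive because catchments nest).
#'
#' @param records data.frame with columns `id` (character, unique),
#'   `downstream_id` (character; `NA` or `""` marks an outlet),
#'   `area_km2` (positive), `centroid_x`, `centroid_y` (projected metres),
#'   optionally `pour_x`, `pour_y`, `excluded` (logical) and any number of
#'   EC observation columns named `ec_<season>` (mS/m).
#' @param areas either `"cumulative"` (default) when `area_km2` already
#'   holds the full catchment area S at each pour point, or
#'   `"incremental"` when it holds each node's own drainage increment, in
#'   which case cumulative areas are accumulated downstream.
#' @return An object of class `watershed_network`: a list with `nodes`
#'   (the validated table, cumulative areas in `area_km2`), `upstream`
#'   (named list id -> character vector of direct upstream ids),
#'   `outlets` (ids with no downstream link) and `seasons` (season labels
#'   found among the `ec_*` columns).
#' @examples
#' toy <- data.frame(
#'   id = c("A", "B", "C"), downstream_id = c("C", "C", NA),
#'   area_km2 = c(1, 1, 4), centroid_x = c(0, 2, 1), centroid_y = c(2, 2, 0),
#'   ec_spring = c(5, 7, 6)
#' )
#' net <- build_network(toy)
#' delta_ec(net, "spring")
#' @export
build_network <- function(records, areas = c("cumulative", "incremental")) {
  areas <- match.arg(areas)
  records <- as.data.frame(records)
  required <- c("id", "downstream_id", "area_km2", "centroid_x", "centroid_y")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("input error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records$id <- as.character(records$id)
  ds <- as.character(records$downstream_id)
  ds[!is.na(ds) & ds == ""] <- NA_character_
  records$downstream_id <- ds

  if (anyDuplicated(records$id)) {
    dup <- records$id[duplicated(records$id)][1L]
    stop("input error: duplicate sub-watershed id '", dup, "'")
  }
  if (any(!is.finite(records$area_km2)) || any(records$area_km2 <= 0)) {
    bad <- records$id[!is.finite(records$area_km2) | records$area_km2 <= 0][1L]
    stop("input error: non-positive catchment area at node '", bad, "'")
  }
  if (any(!is.finite(records$centroid_x)) || any(!is.finite(records$centroid_y))) {
    stop("input error: non-finite centroid coordinates")
  }
  dangling <- setdiff(stats::na.omit(records$downstream_id), records$id)
  if (length(dangling) > 0L) {
    stop("input error: downstream_id '", dangling[1L], "' does not match any node id")
  }
  if (any(!is.na(records$downstream_id) & records$downstream_id == records$id)) {
    stop("topology error: cycle detected involving node '",
         records$id[which(!is.na(records$downstream_id) &
                          records$downstream_id == records$id)][1L], "'")
  }
  if (!"excluded" %in% names(records)) records$excluded <- FALSE
  records$excluded <- isTRUE_vec(records$excluded)

  ord <- topological_order(records$id, records$downstream_id)  # errors on cycles

  # canonical node order: topological (headwaters first), ties by id via sort
  records <- records[match(ord, records$id), , drop = FALSE]
  rownames(records) <- NULL

  upstream <- split(records$id, factor(records$downstream_id, levels = records$id))
  upstream <- lapply(upstream, as.character)

  if (areas == "incremental") {
    cum <- stats::setNames(records$area_km2, records$id)
    for (i in seq_len(nrow(records))) {       # topological order: upstream first
      id <- records$id[i]
      up <- upstream[[id]]
      if (length(up) > 0L) cum[id] <- records$area_km2[i] + sum(cum[up])
    }
    records$area_km2 <- as.numeric(cum)
  }

  # nesting invariant on cumulative areas
  area <- stats::setNames(records$area_km2, records$id)
  for (id in records$id) {
    up <- upstream[[id]]
    if (length(up) > 0L && area[id] <= sum(area[up])) {
      stop("input error: cumulative area of node '", id,
           "' does not exceed the sum of its upstream areas (non-positive increment)")
    }
  }

  net <- structure(
    list(
      nodes = records,
      upstream = upstream,
      outlets = records$id[is.na(records$downstream_id)],
      seasons = sub("^ec_", "", grep("^ec_", names(records), value = TRUE))
    ),
    class = "watershed_network"
  )
  net
}

isTRUE_vec <- function(x) {
  out <- as.logical(x)
  out[is.na(out)] <- FALSE
  out
}

# Kahn-style topological sort over downstream links; headwaters first.
# Errors naming a cycle member when the graph is not a forest of trees.
topological_order <- function(ids, downstream) {
  n <- length(ids)
  ds_idx <- match(downstream, ids)
  indeg <- tabulate(ds_idx, nbins = n)  # number of direct upstream nodes
  queue <- sort(ids[indeg == 0L])
  seen <- character(0)
  indeg_map <- stats::setNames(indeg, ids)
  ds_map <- stats::setNames(downstream, ids)
  while (length(queue) > 0L) {
    id <- queue[1L]; queue <- queue[-1L]
    seen <- c(seen, id)
    d <- ds_map[[id]]
    if (!is.na(d)) {
      indeg_map[d] <- indeg_map[d] - 1L
      if (indeg_map[d] == 0L) queue <- sort(c(queue, d))
    }
  }
  if (length(seen) < n) {
    stop("topology error: cycle detected involving node '",
         setdiff(ids, seen)[1L], "'")
  }
  seen
}

#' @export
print.watershed_network <- function(x, ...) {
  n <- nrow(x$nodes)
  cat("watershed_network:", n, "sub-watersheds,",
      length(x$outlets), "outlet(s),",
      sum(x$nodes$excluded), "excluded\n")
  cat("  seasons:", if (length(x$seasons)) paste(x$seasons, collapse = ", ") else "(none)", "\n")
  cat("  total catchment area:",
      format(max(x$nodes$area_km2), digits = 5), "km2 at outlet\n")
  invisible(x)
}

#' Flag sub-watersheds as excluded from regression
#'
#' Excluded nodes (for instance estuarine sites where tidal intrusion makes
#' EC unrepresentative of the catchment) are dropped from the set of
#' regression observations.  If an excluded node lies upstream of a
#' retained node and carries an EC observation, that observation still
#' feeds the downstream upstream-correction — water does not stop flowing
#' at an exclusion; if it lacks EC the downstream node's delta-EC is
#' flagged unavailable rather than silently imputed.
#'
#' @param network a `watershed_network`.
#' @param ids character vector of node ids to exclude; may be empty.
#' @return The network with the `excluded` flags set.
#' @export
exclude_nodes <- function(network, ids) {
  stopifnot(inherits(network, "watershed_network"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, network$nodes$id)
  if (length(unknown) > 0L) {
    stop("input error: unknown node id '", unknown[1L], "'")
  }
  network$nodes$excluded <- network$nodes$excluded | network$nodes$id %in% ids
  network
}

#' Upstream-corrected EC (delta-EC) for one season
#'
#' For a headwater node the statistic equals the observed EC.  For a node
#' with direct upstream neighbours it is the observed EC minus the
#' catchment-area weighted mixture of the upstream observations,
#' \deqn{\Delta EC_i = EC_i - \frac{\sum_{u} EC_u S_u}{S_i},}
#' where the sum runs over the direct upstream sampling sites and S is the
#' cumulative catchment area (km2).  The denominator is the downstream
#' node's full cumulative area, so the upstream weights need not sum to
#' one: the shortfall represents dilution by the node's own drainage
#' increment.  The value isolates the local sub-watershed's contribution
#' to the ionic load.
#'
#' @param network a `watershed_network` whose nodes carry an
#'   `ec_<season>` column.
#' @param season season label (e.g. `"irrigation"`).
#' @return data.frame of class `delta_ec_result` with columns `id`,
#'   `delta_ec` (mS/m) and `provenance` (`"headwater"`, `"corrected"`, or
#'   `"unavailable"` when an excluded upstream site lacks EC).  Rows cover
#'   non-excluded nodes only; attribute `season` records the label.
#' @seealso [invert_delta_ec()] for the algebraic inverse used by the
#'   synthetic generator.
#' @export
delta_ec <- function(network, season) {
  stopifnot(inherits(network, "watershed_network"))
  ec <- ec_column(network, season)
  nodes <- network$nodes
  keep <- !nodes$excluded

  miss <- keep & is.na(ec)
  if (any(miss)) {
    stop("missing EC: node '", nodes$id[miss][1L],
         "' has no EC observation for season '", season, "'")
  }

  area <- stats::setNames(nodes$area_km2, nodes$id)
  ecv <- stats::setNames(ec, nodes$id)
  out <- data.frame(
    id = nodes$id[keep],
    delta_ec = NA_real_,
    provenance = NA_character_,
    stringsAsFactors = FALSE
  )
  for (r in seq_len(nrow(out))) {
    id <- out$id[r]
    up <- network$upstream[[id]]
    if (length(up) == 0L) {
      out$delta_ec[r] <- ecv[[id]]
      out$provenance[r] <- "headwater"
    } else if (anyNA(ecv[up])) {
      # only an *excluded* upstream node can reach here without EC
      out$provenance[r] <- "unavailable"
    } else {
      out$delta_ec[r] <- ecv[[id]] - sum(ecv[up] * area[up]) / area[[id]]
      out$provenance[r] <- "corrected"
    }
  }
  structure(out, season = season, class = c("delta_ec_result", "data.frame"))
}

ec_column <- function(network, season) {
  col <- paste0("ec_", season)
  if (!col %in% names(network$nodes)) {
    stop("input error: no EC column for season '", season,
         "' (expected column '", col, "')")
  }
  as.numeric(network$nodes[[col]])
}

#' Reconstruct per-node EC from delta-EC values
#'
#' Algebraic inverse of [delta_ec()]: traversing the network in
#' topological order (headwaters first),
#' \eqn{EC_i = \Delta EC_i + (\sum_u EC_u S_u)/S_i}.  Used by the
#' synthetic generator to produce EC observations whose upstream-corrected
#' values equal a prescribed ground truth; `delta_ec()` applied to the
#' result recovers the input to floating-point accuracy.
#'
#' @param network a `watershed_network`.
#' @param delta_values named numeric vector of delta-EC values covering
#'   every node in the network.
#' @return Named numeric vector of EC values (mS/m), in node order.
#' @export
invert_delta_ec <- function(network, delta_values) {
  stopifnot(inherits(network, "watershed_network"))
  ids <- network$nodes$id
  if (!all(ids %in% names(delta_values))) {
    stop("input error: delta value missing for node '",
         setdiff(ids, names(delta_values))[1L], "'")
  }
  area <- stats::setNames(network$nodes$area_km2, ids)
  ec <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (id in ids) {  # nodes are stored in topological order
    up <- network$upstream[[id]]
    contrib <- if (length(up) > 0L) sum(ec[up] * area[up]) / area[[id]] else 0
    ec[[id]] <- delta_values[[id]] + contrib
  }
  ec
}

#' Regression observation ids of a network
#'
#' Non-excluded nodes whose delta-EC is defined for the season (excluded
#' nodes and nodes downstream of an EC-less excluded site are dropped).
#'
#' @inheritParams delta_ec
#' @return character vector of node ids.
#' @export
observation_ids <- function(network, season) {
  d <- delta_ec(network, season)
  d$id[d$provenance != "unavailable"]
}
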