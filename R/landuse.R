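#' Land-cover category codes
#'
#' The nine base land-cover categories, in canonical order, plus the three
#' forest composites.  Composite codes use `_` in place of `+` so they are
#' valid column names: `EBF_ENF` = evergreen forest, `DBF_EBF` =
#' broadleaved forest, `FOREST` = all forest (DBF + EBF + ENF).
#'
#' @return character vector of the nine base category codes.
#' @export
landuse_categories <- function() {
  c("WATER", "BUILTUP", "PADDY", "CROP", "GRASS", "BARE",
    "DBF", "EBF", "ENF")
}

forest_composites <- function() c("EBF_ENF", "DBF_EBF", "FOREST")

#' Read an Esri ASCII grid
#'
#' Minimal reader for the plain-text Esri ASCII raster dialect: a header
#' of `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize` and
#' optionally `NODATA_value`, followed by the cell values row-major from
#' the top row.
#'
#' @param path file path.
#' @return list of class `ascii_grid` with `data` (integer matrix,
#'   `NA` where nodata), `cellsize` (metres), `xllcorner`, `yllcorner`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]])) stop("input error: ASCII grid header lacks '", key, "'")
  }
  if (hdr$cellsize <= 0) stop("input error: cellsize must be positive")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("input error: expected ", hdr$ncols * hdr$nrows, " cells, got ",
         length(vals))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  structure(
    list(data = m, cellsize = hdr$cellsize,
         xllcorner = hdr$xllcorner %||% 0, yllcorner = hdr$yllcorner %||% 0),
    class = "ascii_grid"
  )
}

#' Write an Esri ASCII grid
#'
#' @param grid an `ascii_grid` (or bare matrix plus `cellsize`).
#' @param path output file path.
#' @param nodata code written for `NA` cells.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  if (is.matrix(grid)) grid <- structure(list(data = grid, cellsize = 1,
                                              xllcorner = 0, yllcorner = 0),
                                         class = "ascii_grid")
  m <- grid$data
  m[is.na(m)] <- nodata
  hdr <- c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", grid$xllcorner), paste("yllcorner", grid$yllcorner),
    paste("cellsize", grid$cellsize), paste("NODATA_value", nodata)
  )
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count land-cover cells per sub-watershed
#'
#' Zonal tally: entry (i, c) of the result is the number of cells whose
#' assignment raster names sub-watershed i and whose category raster
#' carries land-cover code c.  Nodata cells (in either raster) are
#' ignored.  Counting is exhaustive and exclusive: per node, the nine base
#' categories sum to the node's non-nodata cell count.
#'
#' @param grid `ascii_grid` of integer category codes.
#' @param assignment `ascii_grid` of integer node codes, same shape.
#' @param code_map named integer vector mapping category codes to the nine
#'   base category names; default codes 1..9 in [landuse_categories()]
#'   order.
#' @param id_map optional named vector mapping assignment codes to node
#'   ids; default uses the codes themselves as ids.
#' @return `predictor_table` data.frame: `id` plus one count column per
#'   base category, composites filled via [derive_composites()].
#' @export
count_categories <- function(grid, assignment,
                             code_map = stats::setNames(1:9, landuse_categories()),
                             id_map = NULL) {
  stopifnot(inherits(grid, "ascii_grid"), inherits(assignment, "ascii_grid"))
  if (!identical(dim(grid$data), dim(assignment$data))) {
    stop("input error: category and assignment rasters differ in shape (",
         paste(dim(grid$data), collapse = "x"), " vs ",
         paste(dim(assignment$data), collapse = "x"), ")")
  }
  lab <- as.vector(grid$data)
  node <- as.vector(assignment$data)

  unknown <- setdiff(unique(lab[!is.na(lab)]), code_map)
  if (length(unknown) > 0L) {
    stop("input error: unknown category code(s): ",
         paste(sort(unknown), collapse = ", "))
  }
  if (!is.null(id_map)) {
    bad <- setdiff(unique(node[!is.na(node)]),
                   suppressWarnings(as.numeric(names(id_map))))
    if (length(bad) > 0L) {
      stop("input error: unknown assignment code(s): ",
           paste(sort(bad), collapse = ", "))
    }
    node_id <- as.character(id_map[as.character(node)])
  } else {
    node_id <- as.character(node)
  }

  # a node assigned anywhere gets a row, even if every cell is nodata
  ids <- sort(unique(node_id[!is.na(node_id)]))
  ok <- !is.na(lab) & !is.na(node_id)
  cat_names <- names(code_map)[match(lab[ok], code_map)]
  tab <- table(factor(node_id[ok], levels = ids),
               factor(cat_names, levels = landuse_categories()))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (cat in landuse_categories()) out[[cat]] <- as.integer(tab[, cat])
  derive_composites(out)
}

#' Fill the forest composite predictors
#'
#' Adds (or recomputes) the composite columns from the base forest counts:
#' `EBF_ENF = EBF + ENF`, `DBF_EBF = DBF + EBF`,
#' `FOREST = DBF + EBF + ENF`.
#'
#' @param table data.frame with columns `DBF`, `EBF`, `ENF`.
#' @return the table with the three composite columns, classed
#'   `predictor_table`.
#' @export
derive_composites <- function(table) {
  table <- as.data.frame(table)
  missing_cols <- setdiff(c("DBF", "EBF", "ENF"), names(table))
  if (length(missing_cols) > 0L) {
    stop("input error: missing forest column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  table$EBF_ENF <- table$EBF + table$ENF
  table$DBF_EBF <- table$DBF + table$EBF
  table$FOREST <- table$DBF + table$EBF + table$ENF
  if (!inherits(table, "predictor_table")) {
    class(table) <- c("predictor_table", class(table))
  }
  table
}

#' Read a land-use count CSV
#'
#' Expects the header `id,water,builtup,paddy,crop,grass,bare,dbf,ebf,enf`
#' (case-insensitive); columns are renamed to the canonical upper-case
#' codes and the forest composites are derived.
#'
#' @param path CSV file path.
#' @return a `predictor_table`.
#' @export
read_landuse_counts <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- toupper(names(tab))
  names(tab)[names(tab) == "ID"] <- "id"
  missing_cols <- setdiff(landuse_categories(), names(tab))
  if (length(missing_cols) > 0L) {
    stop("input error: count CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$id <- as.character(tab$id)
  if (any(vapply(tab[landuse_categories()], function(x) any(x < 0), TRUE))) {
    stop("input error: negative land-use counts")
  }
  derive_composites(tab[c("id", landuse_categories())])
}

#' Accumulate predictor counts over nested catchments
#'
#' By default counts are per incremental (non-overlapping) sub-watershed
#' polygon, matching the local allocation of the upstream-corrected EC
#' statistic.  This helper instead sums each node's counts over its full
#' nested catchment (itself plus all upstream nodes), for sensitivity runs
#' where covariates should describe the whole drainage area.
#'
#' @param table a `predictor_table` of incremental counts.
#' @param network the `watershed_network` defining the nesting.
#' @return a `predictor_table` of cumulative counts.
#' @export
accumulate_counts <- function(table, network) {
  stopifnot(inherits(network, "watershed_network"))
  cols <- landuse_categories()
  idx <- match(network$nodes$id, table$id)
  if (anyNA(idx)) {
    stop("input error: no counts for node '",
         network$nodes$id[is.na(idx)][1L], "'")
  }
  cum <- as.matrix(table[idx, cols, drop = FALSE])
  rownames(cum) <- network$nodes$id
  for (id in network$nodes$id) {  # topological order: upstream first
    up <- network$upstream[[id]]
    if (length(up) > 0L) cum[id, ] <- cum[id, ] + colSums(cum[up, , drop = FALSE])
  }
  out <- data.frame(id = network$nodes$id, cum, stringsAsFactors = FALSE)
  derive_composites(out)
}

#' Predictor design matrix for a model specification
#'
#' @param table a `predictor_table`.
#' @param predictors character vector of predictor codes (base categories
#'   and/or forest composites).
#' @param ids optional node ids selecting and ordering the rows.
#' @param proportions if `TRUE`, divide each row by the node's total base
#'   cell count (counts are the default covariates; proportions are for
#'   sensitivity runs).
#' @return numeric matrix with one column per predictor, rownames = ids.
#' @export
predictor_matrix <- function(table, predictors, ids = NULL,
                             proportions = FALSE) {
  all_codes <- c(landuse_categories(), forest_composites())
  bad <- setdiff(predictors, all_codes)
  if (length(bad) > 0L) {
    stop("input error: unknown predictor code(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(ids)) ids <- table$id
  idx <- match(ids, table$id)
  if (anyNA(idx)) {
    stop("input error: no predictor row for node '", ids[is.na(idx)][1L], "'")
  }
  X <- as.matrix(table[idx, predictors, drop = FALSE])
  rownames(X) <- ids
  if (proportions) {
    tot <- rowSums(as.matrix(table[idx, landuse_categories(), drop = FALSE]))
    tot[tot == 0] <- 1
    X <- X / tot
  }
  X
}
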