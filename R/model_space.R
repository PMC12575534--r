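#' Admissible forest predictor subsets
#'
#' Forest cover can enter a model under one of four mutually exclusive
#' subdivision schemes: all three types (`DBF`, `EBF`, `ENF`),
#' deciduous/evergreen (`DBF`, `EBF_ENF`), broadleaved/coniferous
#' (`DBF_EBF`, `ENF`), or a single merged `FOREST` variable.  The
#' admissible forest subsets are all subsets (including the empty one) of
#' any single scheme, deduplicated across schemes — mixing variables from
#' different schemes (e.g. `EBF` with `DBF_EBF`) would double-count cells.
#'
#' @param schemes list of character vectors, one per subdivision scheme.
#' @return list of character vectors in canonical order; 13 entries for
#'   the default schemes.
#' @export
forest_subset_options <- function(schemes = forest_schemes()) {
  opts <- list()
  seen <- character(0)
  for (scheme in schemes) {
    for (mask in 0:(2^length(scheme) - 1L)) {
      subset <- scheme[bitwAnd(mask, 2^(seq_along(scheme) - 1L)) > 0L]
      key <- paste(sort(subset), collapse = "|")
      if (!key %in% seen) {
        seen <- c(seen, key)
        opts[[length(opts) + 1L]] <- subset
      }
    }
  }
  # canonical order: by size, then by code position in the forest code list
  canon <- c("DBF", "EBF", "ENF", "EBF_ENF", "DBF_EBF", "FOREST")
  keyfun <- function(s) {
    paste(length(s), paste(sprintf("%02d", match(s, canon)), collapse = ""))
  }
  opts[order(vapply(opts, keyfun, character(1L)))]
}

forest_schemes <- function() {
  list(
    all_types = c("DBF", "EBF", "ENF"),
    deciduous_evergreen = c("DBF", "EBF_ENF"),
    broadleaved_coniferous = c("DBF_EBF", "ENF"),
    no_division = "FOREST"
  )
}

#' Enumerate every admissible predictor combination
#'
#' Builds the full model space for one response season: the Cartesian
#' product of all subsets of the non-forest land-use variables with the
#' admissible forest subsets of [forest_subset_options()], minus the
#' single model with no predictors at all.  The intercept is always
#' included and is not enumerated.  With the default six base variables
#' and four forest schemes this yields 2^6 x 13 - 1 = 831 models.
#'
#' @param response season label the models will be fitted against.
#' @param base_vars non-forest predictor codes; default the six base
#'   land-use categories.
#' @param forest_options list of admissible forest subsets.
#' @return list of `model_spec` objects (`list(response, predictors)`),
#'   in a deterministic order: base subsets in binary order of the
#'   canonical variable list, crossed with forest options.
#' @examples
#' length(enumerate_models("irrigation"))  # 831
#' @export
enumerate_models <- function(response,
                             base_vars = setdiff(landuse_categories(),
                                                 c("DBF", "EBF", "ENF")),
                             forest_options = forest_subset_options()) {
  m <- length(base_vars)
  specs <- vector("list", 2^m * length(forest_options))
  k <- 0L
  for (mask in 0:(2^m - 1L)) {
    base <- base_vars[bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L]
    for (fo in forest_options) {
      preds <- c(base, fo)
      if (length(preds) == 0L) next
      k <- k + 1L
      specs[[k]] <- model_spec(response, preds)
    }
  }
  specs[seq_len(k)]
}

#' Construct a model specification
#'
#' @param response season label.
#' @param predictors character vector of predictor codes; must be
#'   non-empty, duplicate-free, and any forest codes present must jointly
#'   belong to a single subdivision scheme.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response, predictors) {
  predictors <- as.character(predictors)
  if (length(predictors) == 0L) stop("input error: empty predictor set")
  if (anyDuplicated(predictors)) stop("input error: duplicate predictor codes")
  forest <- intersect(predictors, c("DBF", "EBF", "ENF", forest_composites()))
  if (length(forest) > 0L) {
    ok <- any(vapply(forest_schemes(), function(s) all(forest %in% s), TRUE))
    if (!ok) {
      stop("input error: forest predictors {",
           paste(forest, collapse = ", "),
           "} do not belong to a single subdivision scheme")
    }
  }
  structure(list(response = response, predictors = predictors),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  paste0(x$response, " ~ ", paste(x$predictors, collapse = " + "))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", format(x), "\n")
  invisible(x)
}
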