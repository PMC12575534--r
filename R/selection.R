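#' Rank fitted models by AICc
#'
#' Orders a scan-results table ascending by the chosen criterion.  Failed
#' fits (non-finite criterion, e.g. singular designs) are listed last
#' with their failure reason; exact ties are broken lexicographically on
#' the predictor codes, so the ranking is stable and reproducible.
#'
#' @param fits data.frame with at least a `predictors` column (codes
#'   joined by `+`) and the criterion column.
#' @param criterion name of the column to rank on (default `gwr_aicc`,
#'   falling back to `aicc` if absent).
#' @return the table, reordered, with a `rank` column prepended.
#' @export
rank_models <- function(fits, criterion = NULL) {
  fits <- as.data.frame(fits)
  if (nrow(fits) == 0L) stop("input error: no fitted models to rank")
  if (is.null(criterion)) {
    criterion <- if ("gwr_aicc" %in% names(fits)) "gwr_aicc" else "aicc"
  }
  if (!criterion %in% names(fits)) {
    stop("input error: no column '", criterion, "' in the results table")
  }
  score <- fits[[criterion]]
  failed <- !is.finite(score)
  score[failed] <- Inf
  ord <- order(score, fits$predictors)
  out <- fits[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Codified model selection rule
#'
#' The comparison across the enumerated model space involves fit (AICc,
#' adjusted R2), multicollinearity and residual spatial autocorrelation;
#' this function codifies those considerations into one explicit,
#' reproducible rule:
#' \enumerate{
#'   \item discard models whose global fit has any VIF >= `vif_max`;
#'   \item among the survivors, prefer models whose GWR residuals show no
#'     significant spatial autocorrelation (Moran p > `moran_alpha`);
#'   \item among those, pick the minimum GWR AICc (ties broken
#'     lexicographically on predictor codes).
#' }
#' Every discarded model is logged with its reason so the scan can be
#' re-ranked under a different reading of the trade-offs.  If every model
#' is filtered out the result says so explicitly (it is not an error) and
#' carries the unfiltered top three by AICc.
#'
#' @param fits scan-results data.frame: one row per model with columns
#'   `predictors`, `max_vif`, `gwr_aicc`, `gwr_moran_p` (as produced by
#'   [run_scan()]).
#' @param vif_max VIF threshold (default 5).
#' @param moran_alpha significance level for residual autocorrelation
#'   (default 0.05).
#' @return list of class `selection_report`: `selected` (one-row
#'   data.frame or `NULL`), `admissible`, `filtered` (with `reason`),
#'   `rules`, `no_admissible`, `top3_unfiltered`.
#' @export
select_best <- function(fits, vif_max = 5, moran_alpha = 0.05) {
  fits <- as.data.frame(fits)
  if (nrow(fits) == 0L) stop("input error: empty model scan")
  needed <- c("predictors", "max_vif", "gwr_aicc", "gwr_moran_p")
  missing_cols <- setdiff(needed, names(fits))
  if (length(missing_cols) > 0L) {
    stop("input error: scan table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  reason <- rep(NA_character_, nrow(fits))
  failed <- !is.finite(fits$gwr_aicc)
  reason[failed] <- "fit failed"
  vif_bad <- !failed & !is.na(fits$max_vif) & fits$max_vif >= vif_max
  reason[vif_bad] <- sprintf("VIF %.2f >= %g", fits$max_vif[vif_bad], vif_max)

  keep <- is.na(reason)
  pool <- fits[keep, , drop = FALSE]
  clean <- pool[!is.na(pool$gwr_moran_p) & pool$gwr_moran_p > moran_alpha, ,
                drop = FALSE]
  pool_used <- if (nrow(clean) > 0L) clean else pool
  moran_note <- if (nrow(clean) > 0L) {
    sprintf("models with GWR residual Moran p > %g preferred (%d of %d)",
            moran_alpha, nrow(clean), nrow(pool))
  } else {
    "no model free of residual autocorrelation; AICc minimum over all survivors"
  }

  selected <- NULL
  if (nrow(pool_used) > 0L) {
    ord <- order(pool_used$gwr_aicc, pool_used$predictors)
    selected <- pool_used[ord[1L], , drop = FALSE]
    rownames(selected) <- NULL
  }

  top3 <- NULL
  if (is.null(selected)) {
    ord_all <- order(ifelse(is.finite(fits$gwr_aicc), fits$gwr_aicc, Inf),
                     fits$predictors)
    top3 <- fits[ord_all[seq_len(min(3L, nrow(fits)))], , drop = FALSE]
    rownames(top3) <- NULL
  }

  structure(
    list(
      selected = selected,
      admissible = pool,
      filtered = cbind(fits[!keep, , drop = FALSE],
                       reason = reason[!keep]),
      rules = list(vif_max = vif_max, moran_alpha = moran_alpha,
                   moran_note = moran_note),
      no_admissible = is.null(selected),
      top3_unfiltered = top3
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Model selection (VIF <", x$rules$vif_max,
      ", Moran alpha =", x$rules$moran_alpha, ")\n")
  cat("  ", x$rules$moran_note, "\n")
  cat("  ", nrow(x$filtered), "model(s) filtered,",
      nrow(x$admissible), "admissible\n")
  if (x$no_admissible) {
    cat("  NO ADMISSIBLE MODEL; unfiltered top 3 by AICc:\n")
    print(x$top3_unfiltered[, c("predictors", "gwr_aicc", "max_vif")])
  } else {
    cat("  selected:", x$selected$predictors,
        "(GWR AICc", format(x$selected$gwr_aicc, digits = 6), ")\n")
  }
  invisible(x)
}
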