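#' Complete-case selection on a set of variables
#'
#' Keeps the rows with no missing value in any of the listed variables
#' (the analytic-cohort rule of the subtyping analysis: patients with a
#' missing clustering score are excluded rather than imputed). Row order
#' is preserved and the number of removed rows is reported via `message()`
#' and the `"n_dropped"` attribute.
#'
#' @param table a feature data.frame.
#' @param variables character vector of column names to require.
#' @return the filtered data.frame, with attribute `n_dropped`.
#' @export
complete_cases <- function(table, variables) {
  bad <- setdiff(variables, names(table))
  if (length(bad)) pd_stop("unknown variable(s): ", paste(bad, collapse = ", "))
  keep <- stats::complete.cases(table[, variables, drop = FALSE])
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  if (any(!keep))
    message("complete_cases: removed ", sum(!keep), " of ", nrow(table),
            " rows with missing values")
  out
}

#' Fit min-max rescaling parameters
#'
#' Records the per-variable minimum and maximum over the (complete-case)
#' fit cohort. These parameters persist with the cluster model so that new
#' patients are rescaled with the *training* ranges, as the downstream
#' nearest-centroid classification rule requires. Constant columns are
#' flagged as degenerate.
#'
#' @param table a feature data.frame with no missing values in `variables`.
#' @param variables character vector of columns to fit.
#' @return object of class `minmax_params`: data.frame (`variable`, `min`,
#'   `max`, `degenerate`) with attribute `n` (fit-cohort size).
#' @export
fit_minmax <- function(table, variables) {
  if (nrow(table) < 2L) pd_stop("fit_minmax: need at least 2 rows")
  bad <- setdiff(variables, names(table))
  if (length(bad)) pd_stop("unknown variable(s): ", paste(bad, collapse = ", "))
  sub <- table[, variables, drop = FALSE]
  if (anyNA(sub)) pd_stop("fit_minmax: missing values present; run complete_cases() first")
  mins <- vapply(sub, min, numeric(1L))
  maxs <- vapply(sub, max, numeric(1L))
  out <- data.frame(variable = variables, min = unname(mins),
                    max = unname(maxs), degenerate = unname(maxs == mins),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- nrow(table)
  class(out) <- c("minmax_params", "data.frame")
  out
}

#' Apply min-max normalization
#'
#' Maps each fitted variable through `(x - min) / (max - min)`. Rows from
#' the fit cohort land in `[0, 1]`; values of *new* patients outside the
#' training range map outside `[0, 1]` and are deliberately not clipped,
#' so that centroid distances remain faithful. Degenerate (constant-range)
#' variables map to 0 with a warning.
#'
#' @param table a feature data.frame.
#' @param params a [fit_minmax()] object covering all variables to rescale.
#' @return the table with the fitted variables replaced by their
#'   normalized values.
#' @export
apply_minmax <- function(table, params) {
  bad <- setdiff(params$variable, names(table))
  if (length(bad)) pd_stop("table lacks variable(s): ", paste(bad, collapse = ", "))
  out <- table
  for (i in seq_len(nrow(params))) {
    v <- params$variable[i]
    if (params$degenerate[i]) {
      warning("apply_minmax: degenerate range for '", v, "'; mapping to 0",
              call. = FALSE)
      out[[v]] <- rep(0, nrow(table))
    } else {
      out[[v]] <- (table[[v]] - params$min[i]) / (params$max[i] - params$min[i])
    }
  }
  out
}

#' Invert min-max normalization
#'
#' Exact inverse of [apply_minmax()] for non-degenerate variables
#' (`x = min + z * (max - min)`), used to report centroids back on
#' clinical scales. Degenerate variables have no inverse; the stored
#' constant is returned with a warning.
#'
#' @inheritParams apply_minmax
#' @return the table with normalized columns mapped back to clinical units.
#' @export
invert_minmax <- function(table, params) {
  bad <- setdiff(params$variable, names(table))
  if (length(bad)) pd_stop("table lacks variable(s): ", paste(bad, collapse = ", "))
  out <- table
  for (i in seq_len(nrow(params))) {
    v <- params$variable[i]
    if (params$degenerate[i]) {
      warning("invert_minmax: degenerate range for '", v,
              "'; returning the stored constant", call. = FALSE)
      out[[v]] <- rep(params$min[i], nrow(table))
    } else {
      out[[v]] <- params$min[i] + table[[v]] * (params$max[i] - params$min[i])
    }
  }
  out
}

#' @export
print.minmax_params <- function(x, ...) {
  cat("Min-max rescaling parameters (fit n = ", attr(x, "n"), ")\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
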