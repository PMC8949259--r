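#' Min-max normalization of a single endpoint column
#'
#' Rescales raw endpoint values to \code{[0, 1]} by the min-max indicator
#' formulas used in multi-criteria composite scoring. For a positive
#' indicator (larger raw value is better, e.g. fish LC50, where a higher
#' lethal concentration means lower acute toxicity) the score is
#' \eqn{(v - min) / (max - min)}; for a negative indicator (smaller is
#' better, e.g. logBCF) it is \eqn{(max - v) / (max - min)}.
#'
#' @param values numeric vector of raw endpoint values (length >= 2).
#' @param direction \code{"positive"} or \code{"negative"}.
#' @return numeric vector in \code{[0, 1]}, with attributes \code{min},
#'   \code{max} and \code{direction} recording the provenance of the
#'   transformation.
#' @examples
#' normalize_endpoint(c(5.3, 12.5, 40.8), "positive")
#' @export
normalize_endpoint <- function(values, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (length(values) < 2L) {
    stop("need at least 2 values to normalize an endpoint column")
  }
  if (anyNA(values) || !is.numeric(values)) {
    stop("endpoint values must be numeric with no missing entries")
  }
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) {
    stop("degenerate range: max equals min, endpoint column is uninformative")
  }
  q <- if (direction == "positive") (values - lo) / (hi - lo)
       else (hi - values) / (hi - lo)
  structure(q, min = lo, max = hi, direction = direction)
}

#' Normalize integer weight ratios onto the unit simplex
#'
#' Composite-index weights are commonly quoted as integer ratios
#' (e.g. 25:23:52); this divides by their sum so they add to 1.
#'
#' @param w nonnegative numeric vector of weights or ratio parts.
#' @return numeric vector summing to 1, same names as \code{w}.
#' @export
weight_vector <- function(w) {
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be finite and nonnegative")
  }
  if (sum(w) <= 0) stop("weights must not all be zero")
  w / sum(w)
}

#' Weighted comprehensive effect values
#'
#' Aggregates a matrix of normalized indicators into one composite effect
#' value per compound, \eqn{I_j = \sum_i w_i q_{ij}}. With all
#' \eqn{q \in [0, 1]} and weights on the simplex, \eqn{I \in [0, 1]}.
#'
#' @param q matrix or data frame of normalized indicators, compounds in
#'   rows, endpoints in columns.
#' @param w weight vector aligned with the columns of \code{q}; normalized
#'   with [weight_vector()] if it does not already sum to 1.
#' @return numeric vector of composite values, named by rownames of \code{q}.
#' @export
composite_scores <- function(q, w) {
  q <- as.matrix(q)
  if (ncol(q) != length(w)) {
    stop(sprintf("dimension mismatch: %d indicator columns but %d weights",
                 ncol(q), length(w)))
  }
  if (!is.null(names(w)) && !is.null(colnames(q)) &&
      !identical(names(w), colnames(q))) {
    if (!setequal(names(w), colnames(q))) {
      stop("weight names do not match indicator columns")
    }
    w <- w[colnames(q)]
  }
  w <- weight_vector(w)
  drop(q %*% w)
}

#' Composite-index pipeline for an endpoint table
#'
#' Runs the full composite-index computation on a raw endpoint table:
#' min-max normalization of every endpoint column in its stated indicator
#' direction, optional replacement of any normalized column by externally
#' supplied values, and weighted aggregation into the comprehensive effect
#' value I. Display rounding is applied only in the report; the \code{full}
#' table keeps full precision.
#'
#' @param table data frame whose first column (or \code{compound_col})
#'   identifies compounds and whose remaining columns are raw endpoint
#'   values.
#' @param directions named character vector mapping each endpoint column to
#'   \code{"positive"} or \code{"negative"}.
#' @param weights named nonnegative vector (ratios accepted) over the same
#'   endpoints.
#' @param overrides optional named list of externally supplied normalized
#'   columns (named numeric vectors keyed by compound, or plain vectors in
#'   table order) that replace the computed normalization for an endpoint.
#' @param scale_1000 character vector of endpoint names whose normalized
#'   column is additionally reported on a x1000 display scale (3 decimals),
#'   the convention used for the toxicity indicator.
#' @param digits decimals for reported indicator and I columns.
#' @param compound_col index or name of the compound identifier column.
#' @return object of class \code{composite_result}: a list with
#'   \code{report} (rounded display table), \code{full} (full-precision
#'   normalized columns and I), \code{weights}, and \code{provenance}
#'   (per-endpoint min/max/direction or override marker).
#' @export
index_pipeline <- function(table, directions, weights, overrides = NULL,
                           scale_1000 = "lc50", digits = 2,
                           compound_col = 1L) {
  stopifnot(is.data.frame(table))
  compounds <- as.character(table[[compound_col]])
  endo <- setdiff(seq_along(table), if (is.numeric(compound_col))
    compound_col else match(compound_col, names(table)))
  endpoints <- names(table)[endo]
  if (!all(endpoints %in% names(directions))) {
    stop("every endpoint column needs a direction")
  }
  if (!all(endpoints %in% names(weights))) {
    stop("every endpoint column needs a weight")
  }
  if (!is.null(overrides) &&
      !all(names(overrides) %in% endpoints)) {
    stop("override names must be endpoint columns")
  }

  qmat <- matrix(NA_real_, nrow(table), length(endpoints),
                 dimnames = list(compounds, endpoints))
  provenance <- list()
  for (ep in endpoints) {
    if (!is.null(overrides) && ep %in% names(overrides)) {
      ov <- overrides[[ep]]
      if (!is.null(names(ov))) {
        if (!all(compounds %in% names(ov))) {
          stop("override for '", ep, "' is missing compounds: ",
               paste(setdiff(compounds, names(ov)), collapse = ", "))
        }
        if (!all(names(ov) %in% compounds)) {
          stop("override for '", ep, "' names unknown compounds")
        }
        ov <- ov[compounds]
      } else if (length(ov) != length(compounds)) {
        stop("unnamed override for '", ep, "' must match the table rows")
      }
      qmat[, ep] <- as.numeric(ov)
      provenance[[ep]] <- list(source = "override")
    } else {
      qn <- normalize_endpoint(table[[ep]], directions[[ep]])
      qmat[, ep] <- qn
      provenance[[ep]] <- list(source = "minmax",
                               direction = attr(qn, "direction"),
                               min = attr(qn, "min"), max = attr(qn, "max"))
    }
  }

  w <- weight_vector(weights[endpoints])
  i_val <- composite_scores(qmat, w)

  report <- data.frame(compound = compounds, stringsAsFactors = FALSE)
  for (ep in endpoints) {
    report[[ep]] <- if (ep %in% scale_1000) {
      round(qmat[, ep] * 1000, 3)
    } else {
      round(qmat[, ep], digits)
    }
  }
  report$I <- round(i_val, digits)

  full <- data.frame(compound = compounds, qmat, I = i_val,
                     row.names = NULL, check.names = FALSE)
  structure(list(report = report, full = full, weights = w,
                 provenance = provenance),
            class = "composite_result")
}

#' @export
print.composite_result <- function(x, ...) {
  cat("Composite-index result (", nrow(x$report), " compounds)\n", sep = "")
  cat("weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                        collapse = ", "), "\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Write a composite-index result to CSV and JSON
#'
#' The CSV mirrors the rounded report table; the JSON carries the
#' full-precision values plus the normalization provenance (direction and
#' min/max used per column, or the override marker).
#'
#' @param result a \code{composite_result} from [index_pipeline()].
#' @param csv,json output paths (either may be \code{NULL} to skip).
#' @return \code{result}, invisibly.
#' @export
write_index_report <- function(result, csv = NULL, json = NULL) {
  stopifnot(inherits(result, "composite_result"))
  if (!is.null(csv)) {
    utils::write.csv(result$report, csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(full = result$full, weights = as.list(result$weights),
           provenance = result$provenance),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
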