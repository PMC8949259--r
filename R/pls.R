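# Partial least squares regression (PLS1, NIPALS) of activities on field
# descriptors, with leave-one-out cross-validation, fit statistics, field
# contribution percentages and STDEV*COEFF contour maps. X is expected
# block-scaled (see assemble_descriptors); here X columns and y are
# centered, y is not scaled.

#' Fit a PLS regression model
#'
#' Deterministic NIPALS fit of \code{y} on \code{X} with \code{ncomp}
#' latent components. Columns of \code{X} and \code{y} are centered
#' internally; predictions are a single linear map
#' \eqn{\hat y = X b + b_0} on the original columns.
#'
#' @param X descriptor matrix (n x p), n >= 3.
#' @param y activity vector, non-constant.
#' @param ncomp number of latent components, between 1 and
#'   \code{min(n - 1, p)}.
#' @return object of class \code{pls_model}: coefficients \code{b},
#'   intercept \code{b0}, component matrices (weights \code{W}, loadings
#'   \code{P}, scores \code{Tm}, y-loadings \code{q}), centering vectors
#'   and \code{ncomp}.
#' @export
pls_train <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("need at least 3 rows to fit a PLS model")
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (stats::sd(y) == 0) stop("y has zero variance")
  cmax <- min(n - 1L, p)
  if (ncomp < 1L || ncomp > cmax) {
    stop("ncomp must be in [1, ", cmax, "]")
  }
  mx <- colMeans(X); my <- mean(y)
  E <- sweep(X, 2, mx); f <- y - my
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop("X carries no residual covariance with y at component ", a,
           "; reduce ncomp")
    }
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) stop("degenerate score vector at component ", a)
    pvec <- drop(crossprod(E, t_)) / tt
    qa <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, pvec)
    f <- f - qa * t_
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t_; q[a] <- qa
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  b0 <- my - sum(mx * b)
  structure(list(b = b, b0 = b0, W = W, P = P, Tm = Tm, q = q,
                 x_center = mx, y_center = my, ncomp = ncomp),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$b + object$b0)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d descriptors\n",
              x$ncomp, length(x$b)))
  invisible(x)
}

#' Leave-one-out cross-validation of a PLS model
#'
#' For each component count up to \code{c_max}, every sample is held out
#' in turn, the model (including X/y centering) is refit on the remaining
#' rows, and the held-out response is predicted:
#' \eqn{PRESS(c) = \sum_i (y_i - \hat y_{(-i)})^2},
#' \eqn{q^2 = 1 - PRESS / \sum_i (y_i - \bar y)^2},
#' \eqn{SEP = \sqrt{PRESS / (N - c - 1)}}.
#' The optimal component count maximizes q2 (default) or minimizes SEP;
#' ties resolve to the smallest count.
#'
#' @param X descriptor matrix, n >= 4 rows.
#' @param y activity vector, non-constant.
#' @param c_max largest component count to scan (bounded by n - 2).
#' @param selector \code{"q2"} (maximize q2) or \code{"sep"} (minimize
#'   SEP).
#' @return list of class \code{pls_cv}: \code{table} (per-c PRESS, q2,
#'   SEP), \code{optimal} component count, \code{selector}.
#' @export
loo_cv <- function(X, y, c_max, selector = c("q2", "sep")) {
  selector <- match.arg(selector)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("leave-one-out needs at least 4 rows")
  if (stats::sd(y) == 0) {
    stop("y has zero total sum of squares; q2 is undefined")
  }
  bound <- min(n - 2L, ncol(X))
  if (c_max < 1L || c_max > bound) {
    stop("c_max must be in [1, ", bound, "]")
  }
  tss <- sum((y - mean(y))^2)
  sqerr <- matrix(0, n, c_max)
  for (i in seq_len(n)) {
    for (cc in seq_len(c_max)) {
      fit <- pls_train(X[-i, , drop = FALSE], y[-i], cc)
      pred <- predict(fit, X[i, , drop = FALSE])
      sqerr[i, cc] <- (y[i] - pred)^2
    }
  }
  press <- apply(sqerr, 2, sum)
  q2 <- 1 - press / tss
  sep <- sqrt(press / (n - seq_len(c_max) - 1))
  crit <- if (selector == "q2") q2 else -sep
  optimal <- which(crit == max(crit))[1L]
  structure(list(table = data.frame(ncomp = seq_len(c_max), press = press,
                                    q2 = q2, sep = sep),
                 optimal = optimal, selector = selector),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("optimal ncomp = %d (selector: %s)\n", x$optimal, x$selector))
  invisible(x)
}

#' Non-cross-validated fit statistics
#'
#' \eqn{r^2 = 1 - RSS/TSS}, \eqn{SEE = \sqrt{RSS / (N - c - 1)}},
#' \eqn{F = (r^2 / c) / ((1 - r^2) / (N - c - 1))} — the molecular-design
#' conventions with the component count in the degrees of freedom.
#'
#' @param model a \code{pls_model}.
#' @param X,y the training data.
#' @return list with \code{r2}, \code{see}, \code{f}, \code{n},
#'   \code{ncomp}.
#' @export
fit_statistics <- function(model, X, y) {
  n <- length(y); cc <- model$ncomp
  if (n <= cc + 1L) stop("N must exceed ncomp + 1 for SEE/F")
  res <- y - predict(model, X)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  list(r2 = r2,
       see = sqrt(rss / (n - cc - 1)),
       f = (r2 / cc) / ((1 - r2) / (n - cc - 1)),
       n = n, ncomp = cc)
}

#' External-validation coefficient for a held-out test set
#'
#' \eqn{r^2_{pred} = 1 - \sum (y_{test} - \hat y_{test})^2 /
#' \sum (y_{test} - \bar y_{train})^2}: prediction error on the test set
#' relative to the naive training-mean predictor. Used with a fixed
#' train/test split of the compound set (the packaged normalized-indicator
#' table carries the published 10/4 split, with the template molecule in
#' both sets).
#'
#' @param y_test observed test-set activities.
#' @param yhat_test model predictions for the test set.
#' @param y_train training-set activities (their mean anchors the
#'   denominator).
#' @return the external-validation coefficient.
#' @export
r2_pred <- function(y_test, yhat_test, y_train) {
  stopifnot(length(y_test) == length(yhat_test), length(y_train) >= 1)
  denom <- sum((y_test - mean(y_train))^2)
  if (denom == 0) stop("test responses equal the training mean; undefined")
  1 - sum((y_test - yhat_test)^2) / denom
}

#' Field contribution percentages
#'
#' Contribution of each field kind: the sum over that kind's columns of
#' |coefficient| x column standard deviation, normalized to percentages.
#'
#' @param model a \code{pls_model} fit on \code{block$X}.
#' @param block the \code{comsia_block} the model was trained on.
#' @return named numeric vector of percentages summing to 100.
#' @export
field_contributions <- function(model, block) {
  if (length(model$b) != ncol(block$X)) {
    stop("model and block disagree on column count")
  }
  sds <- apply(block$X, 2, stats::sd)
  contrib <- abs(model$b) * sds
  tot <- tapply(contrib, factor(block$col_kind, levels = block$kinds), sum)
  tot[is.na(tot)] <- 0
  if (sum(tot) == 0) stop("all contributions are zero")
  100 * tot / sum(tot)
}

#' STDEV*COEFF contour map
#'
#' Lattice of column standard deviation x regression coefficient per field
#' kind, thresholded into favored (positive values above the
#' \code{favored_pct} percentile) and disfavored (negative values below
#' the \code{disfavored_pct} percentile) point sets. Thresholds are strict,
#' so an all-zero coefficient vector yields empty sets.
#'
#' @param model a \code{pls_model} fit on \code{block$X}.
#' @param block the training \code{comsia_block}.
#' @param favored_pct,disfavored_pct percentile levels (defaults 80/20).
#' @return list of class \code{contour_map}, per kind: \code{values}
#'   (full-lattice stdev*coeff, zeros at filtered columns), \code{favored}
#'   and \code{disfavored} lattice point indices, and the thresholds.
#' @export
contour_map <- function(model, block, favored_pct = 80, disfavored_pct = 20) {
  if (favored_pct <= disfavored_pct) {
    stop("favored percentile must exceed the disfavored percentile")
  }
  npts <- prod(block$grid$counts)
  if (npts == 0) stop("empty lattice")
  sds <- apply(block$X, 2, stats::sd)
  v <- sds * model$b
  out <- list()
  for (k in block$kinds) {
    sel <- block$col_kind == k
    vk <- v[sel]
    # columns dropped by the filter re-enter as zeros at their lattice slot
    full <- numeric(npts)
    orig <- block$keep[sel] - (match(k, block$kinds) - 1L) * npts
    full[orig] <- vk
    qf <- stats::quantile(full, favored_pct / 100, names = FALSE)
    qd <- stats::quantile(full, disfavored_pct / 100, names = FALSE)
    out[[k]] <- list(values = full,
                     favored = which(full > qf & full > 0),
                     disfavored = which(full < qd & full < 0),
                     favored_threshold = qf, disfavored_threshold = qd)
  }
  structure(list(kinds = out, grid = block$grid,
                 favored_pct = favored_pct, disfavored_pct = disfavored_pct),
            class = "contour_map")
}

#' Write model statistics as a one-row CSV
#'
#' Mirrors the usual QSAR summary layout: n, q2, r2, SEE, F and the field
#' contribution percentages.
#'
#' @param cv a \code{pls_cv}.
#' @param stats output of [fit_statistics()].
#' @param contributions output of [field_contributions()].
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
write_statistics_table <- function(cv, stats, contributions, path) {
  row <- data.frame(n = cv$optimal,
                    q2 = cv$table$q2[cv$optimal],
                    r2 = stats$r2, SEE = stats$see, F = stats$f)
  for (k in names(contributions)) row[[k]] <- contributions[[k]]
  utils::write.csv(row, path, row.names = FALSE)
  invisible(path)
}
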