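#' Greedy covariance-based variable selection (CovSel) with deflation
#'
#' Variables are selected one at a time as the column of `X` with maximal
#' squared covariance with the (current) response. After each pick both `X`
#' and `y` are deflated by projecting out the picked column, so every
#' further pick brings new information. Reported indices refer to the
#' original column positions; ties are broken by the lowest column index.
#' A column with (remaining) zero variance is skipped (criterion 0).
#'
#' `X` is expected centered (typically autoscaled) and `y` centered, as the
#' covariance criterion is computed from plain cross products.
#'
#' @param X Numeric matrix (samples x variables), centered/scaled.
#' @param y Centered response vector (one column).
#' @param nvar Number of variables to select (positive).
#' @return An object of class `covsel_selection`: list with `indices`
#'   (original column positions, in selection order) and `criterion`
#'   (squared sample covariance of each pick with the deflated response).
#' @export
#' @examples
#' set.seed(1)
#' X <- scale(matrix(rnorm(40), 10, 4))
#' y <- X[, 2] + rnorm(10, sd = .1)
#' covsel_select(X, y - mean(y), 2)$indices
covsel_select <- function(X, y, nvar) {
  sel <- covsel_engine(X, y, nvar, pad = FALSE)
  structure(sel[c("indices", "criterion")], class = "covsel_selection")
}

# Greedy engine shared by covsel_select() and fit_so_covsel(). With
# pad = TRUE, an exhausted block (every remaining column deflated to zero
# variance) fills the remaining slots with the lowest-index unpicked
# columns at criterion 0 and flags them degenerate, instead of erroring;
# their regression coefficients are forced to zero downstream.
covsel_engine <- function(X, y, nvar, pad = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) abort("X and y must have the same number of rows")
  if (nvar < 1L || nvar > p) {
    abort("`nvar` must be between 1 and the number of columns of X")
  }
  Xd <- X
  yd <- y
  idx <- integer(nvar)
  crit <- numeric(nvar)
  degen <- logical(nvar)
  for (s in seq_len(nvar)) {
    ss <- colSums(Xd^2)
    eligible <- ss > 1e-12
    eligible[idx[seq_len(s - 1L)]] <- FALSE
    if (!any(eligible)) {
      if (!pad) {
        abort(paste0("`nvar` exceeds the column rank of X: only ", s - 1L,
                     " variable(s) selectable"))
      }
      left <- setdiff(seq_len(p), idx[seq_len(s - 1L)])
      pad_n <- nvar - s + 1L
      idx[s:nvar] <- left[seq_len(pad_n)]
      crit[s:nvar] <- 0
      degen[s:nvar] <- TRUE
      break
    }
    cv <- as.numeric(crossprod(Xd, yd)) / (n - 1)
    sc <- cv^2
    cand <- which(eligible)
    j <- cand[which.max(sc[cand])]   # which.max takes the first maximum
    idx[s] <- j
    crit[s] <- sc[j]
    v <- Xd[, j] / sqrt(ss[j])
    Xd <- Xd - v %*% crossprod(v, Xd)
    yd <- yd - v * sum(v * yd)
  }
  list(indices = idx, criterion = crit, degenerate = degen)
}

#' @export
print.covsel_selection <- function(x, ...) {
  cat("<covsel_selection>", length(x$indices), "variable(s):",
      paste(x$indices, collapse = ", "), "\n")
  invisible(x)
}

#' Orthogonalize a block against previously selected variables
#'
#' Removes from `X_next` the subspace spanned by the columns of `X_sel`
#' (the variables already selected from earlier blocks), so the next block
#' contributes only new information. The projector uses a pseudo-inverse
#' (relative singular-value cutoff 1e-12) so collinear selections degrade
#' gracefully.
#'
#' @param X_next Matrix to orthogonalize (samples x variables).
#' @param X_sel Matrix of previously selected columns (may have 0 columns,
#'   in which case `X_next` is returned unchanged).
#' @return A list with `X_orth` (the orthogonalized block, satisfying
#'   `t(X_sel) %*% X_orth == 0` to numerical tolerance) and `W`
#'   (`ncol(X_sel)` x `ncol(X_next)` projection weights, such that
#'   `X_orth = X_next - X_sel %*% W`).
#' @export
orthogonalize_block <- function(X_next, X_sel) {
  X_next <- as.matrix(X_next)
  X_sel <- as.matrix(X_sel)
  if (ncol(X_sel) == 0L) {
    return(list(X_orth = X_next, W = matrix(0, 0L, ncol(X_next))))
  }
  if (nrow(X_sel) != nrow(X_next)) {
    abort("X_next and X_sel must have the same number of rows")
  }
  W <- pinv(crossprod(X_sel)) %*% crossprod(X_sel, X_next)
  list(X_orth = X_next - X_sel %*% W, W = W)
}

#' @rdname orthogonalize_block
#' @param y Response vector to orthogonalize against `X_sel`.
#' @return `orthogonalize_response()`: the orthogonalized response vector.
#' @export
orthogonalize_response <- function(y, X_sel) {
  out <- orthogonalize_block(matrix(as.numeric(y), ncol = 1L), X_sel)
  as.numeric(out$X_orth)
}
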