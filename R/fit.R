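#' Fit a sequential orthogonalized CovSel (SO-CovSel) classification model
#'
#' Blocks enter the model in `order`. Variables are selected from the first
#' block by [covsel_select()] against the centered binary response; every
#' later block, and the response, are first orthogonalized against all
#' variables already selected from earlier blocks, so each block contributes
#' only new information. Per stage, regression coefficients are fitted by
#' ordinary least squares of the current orthogonalized response on the
#' stage's selected (orthogonalized, train-centered) columns; the predicted
#' response is the sum of the stage contributions plus a fitted intercept.
#' Finally a one-dimensional LDA rule ([fit_lda()]) on the training
#' predicted response turns predictions into class labels.
#'
#' Blocks are used as given; autoscale first (see [fit_scaler()]) or pass a
#' `scaler`, which is applied before fitting and stored in the model so
#' [predict()] and [classify()] apply it to new data.
#'
#' @param ds A `multiblock` object with both classes present.
#' @param complexities Integer vector, one entry per block (named by block,
#'   or positional in `order`): the number of variables to select from each
#'   block. A block with complexity 0 contributes no stage. At least one
#'   entry must be positive.
#' @param order Character vector: permutation of the block names giving the
#'   sequential inclusion order. Default: panel order.
#' @param scaler Optional `block_scaler` applied before fitting and stored.
#' @param priors `"empirical"` (class frequencies; default) or `"equal"`.
#' @return An object of class `so_covsel` with elements `order`,
#'   `complexities`, `stages` (per stage: block, selected indices/analytes,
#'   projection weights `W`, centering means `mu`, coefficients `B`),
#'   `intercept`, `lda`, `fitted` (training predicted response), `scaler`.
#' @seealso [predict.so_covsel()], [classify()], [run_rdcv()]
#' @export
#' @examples
#' sim <- simulate_panel(synthetic_config(seed = 1, effect_size = 3))
#' ds <- apply_scaler(fit_scaler(sim$dataset), sim$dataset)
#' m <- fit_so_covsel(ds, complexities = c(2, 2, 1))
#' tidy(m)
fit_so_covsel <- function(ds, complexities, order = NULL, scaler = NULL,
                          priors = c("empirical", "equal")) {
  priors <- match.arg(priors)
  if (!is.null(scaler)) ds <- apply_scaler(scaler, ds)
  bn <- block_names(ds)
  order <- order %||% bn
  if (!setequal(order, bn) || length(order) != length(bn)) {
    abort("`order` must be a permutation of the block names")
  }
  if (is.null(names(complexities))) {
    if (length(complexities) != length(order)) {
      abort("`complexities` must have one entry per block")
    }
    complexities <- setNames(as.integer(complexities), order)
  } else {
    if (!setequal(names(complexities), bn)) {
      abort("names of `complexities` must be the block names")
    }
    complexities <- setNames(as.integer(complexities[order]), order)
  }
  if (any(complexities < 0L)) abort("complexities must be non-negative")
  if (all(complexities == 0L)) abort("at least one block complexity must be positive")
  y <- ds$y
  if (length(unique(y)) < 2L) abort("both classes must be present to fit")
  wd <- block_widths(ds)
  over <- complexities > wd[order]
  if (any(over)) {
    abort(paste0("more variables requested than available in block '",
                 order[over][1L], "'"))
  }

  n <- length(y)
  ybar <- mean(y)
  yo <- y - ybar
  S <- matrix(0, n, 0L)
  pred <- numeric(n)
  stages <- list()
  for (b in order) {
    ck <- complexities[[b]]
    if (ck == 0L) next
    X <- ds$blocks[[b]]
    if (anyNA(X)) {
      abort(paste0("block '", b, "' contains missing values; resolve them ",
                   "before fitting"))
    }
    og <- orthogonalize_block(X, S)
    sel <- covsel_engine(og$X_orth, yo, ck, pad = TRUE)
    Xo <- og$X_orth[, sel$indices, drop = FALSE]
    mu <- colMeans(Xo)
    Xc <- sweep(Xo, 2L, mu)
    # a column deflated/orthogonalized to (numerical) zero carries no new
    # information: its coefficient is pinned to 0 instead of exploding
    live <- !sel$degenerate & colSums(Xc^2) > 1e-12
    B <- numeric(ck)
    if (any(live)) {
      Xl <- Xc[, live, drop = FALSE]
      B[live] <- as.numeric(pinv(crossprod(Xl)) %*% crossprod(Xl, yo))
    }
    fitted_k <- as.numeric(Xc %*% B)
    yo <- yo - fitted_k
    pred <- pred + fitted_k
    stages[[length(stages) + 1L]] <- list(
      block = b, indices = sel$indices,
      analytes = colnames(X)[sel$indices],
      criterion = sel$criterion,
      W = og$W[, sel$indices, drop = FALSE],
      mu = mu, B = B)
    S <- cbind(S, X[, sel$indices, drop = FALSE])
  }
  intercept <- ybar - sum(vapply(stages, function(st) sum(st$mu * st$B), 0))
  yhat <- ybar + pred
  lda <- fit_lda(yhat, y, priors = priors)
  structure(
    list(order = order, complexities = complexities, stages = stages,
         intercept = intercept, lda = lda, fitted = yhat, y = y,
         scaler = scaler, block_widths = wd, priors = priors),
    class = "so_covsel")
}

#' Predict the continuous response of an SO-CovSel model
#'
#' For each new sample, later-stage selected columns are corrected with the
#' training orthogonalization weights (`x_orth = x_sel_new - x_prev %*% W`)
#' before the stage coefficients are applied; the result is the sum of stage
#' contributions plus the intercept. Deterministic and row-wise.
#'
#' @param object A fitted `so_covsel` model.
#' @param new_blocks A `multiblock` object or a named list of matrices whose
#'   widths match the training blocks (post-filter, pre-selection).
#' @param ... Unused.
#' @return Numeric vector of predicted responses, one per row.
#' @export
predict.so_covsel <- function(object, new_blocks, ...) {
  if (inherits(new_blocks, "multiblock")) {
    if (!is.null(object$scaler)) {
      new_blocks <- apply_scaler(object$scaler, new_blocks)
    }
    new_blocks <- new_blocks$blocks
  }
  wd <- vapply(new_blocks, ncol, integer(1))
  tw <- object$block_widths[names(wd)]
  if (length(wd) != length(object$block_widths) || any(wd != tw)) {
    abort("block widths of new data do not match the training blocks")
  }
  n <- nrow(new_blocks[[1L]])
  S <- matrix(0, n, 0L)
  pred <- rep(object$intercept, n)
  for (st in object$stages) {
    Xsel <- new_blocks[[st$block]][, st$indices, drop = FALSE]
    Xo <- if (ncol(S)) Xsel - S %*% st$W else Xsel
    pred <- pred + as.numeric(Xo %*% st$B)
    S <- cbind(S, Xsel)
  }
  pred
}

#' Classify new samples with a fitted SO-CovSel model
#'
#' Applies [predict.so_covsel()] then thresholds the predicted response by
#' the model's LDA rule. A sample exactly at the threshold is assigned to
#' class 1 (documented tie rule).
#'
#' @inheritParams predict.so_covsel
#' @param m A fitted `so_covsel` model.
#' @return Integer vector of predicted labels in `{1, 0}`.
#' @export
classify <- function(m, new_blocks) {
  classify_lda(m$lda, predict(m, new_blocks))
}

#' One-dimensional Gaussian LDA on a predicted response
#'
#' Fits class means, pooled within-class variance (n - 2 denominator) and
#' class priors on the training predicted response; the decision threshold
#' is the point where the two class discriminant scores are equal (with
#' equal priors, the midpoint of the class means).
#'
#' @param yhat Numeric vector of training predicted responses.
#' @param labels Training labels in `{1, 0}`, both classes present.
#' @param priors `"empirical"` (default) or `"equal"`.
#' @return An object of class `lda_rule`: class means, pooled variance,
#'   priors, threshold, and the direction of class 1.
#' @export
fit_lda <- function(yhat, labels, priors = c("empirical", "equal")) {
  priors <- match.arg(priors)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    abort("labels must contain both classes, coded 1 and 0")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  m1 <- mean(yhat[labels == 1L])
  m0 <- mean(yhat[labels == 0L])
  s2 <- (sum((yhat[labels == 1L] - m1)^2) +
         sum((yhat[labels == 0L] - m0)^2)) / (n1 + n0 - 2L)
  if (s2 <= 0) abort("zero pooled variance: predicted response is constant within classes")
  if (m1 == m0) abort("class means of the predicted response coincide")
  p1 <- if (priors == "empirical") n1 / (n1 + n0) else 0.5
  p0 <- 1 - p1
  threshold <- (m1 + m0) / 2 + s2 * log(p0 / p1) / (m1 - m0)
  structure(list(mean_case = m1, mean_control = m0, pooled_var = s2,
                 prior_case = p1, prior_control = p0,
                 threshold = threshold, direction = sign(m1 - m0)),
            class = "lda_rule")
}

# Threshold a predicted response by a fitted rule; ties go to class 1.
classify_lda <- function(rule, yhat) {
  as.integer(rule$direction * (yhat - rule$threshold) >= 0)
}

#' @export
print.so_covsel <- function(x, ...) {
  cat("<so_covsel> block order:", paste(x$order, collapse = " > "),
      "\n  complexities:", paste(x$complexities, collapse = "-"),
      "\n  selected:",
      paste(unlist(lapply(x$stages, `[[`, "analytes")), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname fit_so_covsel
#' @param x A fitted `so_covsel` model.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per selected variable (block,
#'   analyte, stage, selection step, coefficient, covariance criterion).
#' @export
tidy.so_covsel <- function(x, ...) {
  purrr::imap_dfr(x$stages, function(st, k) {
    tibble(stage = k, block = st$block, analyte = st$analytes,
           step = seq_along(st$indices), coefficient = st$B,
           criterion = st$criterion)
  })
}

#' @rdname fit_so_covsel
#' @return `glance()`: a one-row tibble with sample counts, total selected
#'   variables, the LDA threshold and the training accuracy.
#' @export
glance.so_covsel <- function(x, ...) {
  pred <- classify_lda(x$lda, x$fitted)
  tibble(n = length(x$y),
         n_case = sum(x$y == 1L), n_control = sum(x$y == 0L),
         n_selected = sum(vapply(x$stages, function(st) length(st$B), 0L)),
         threshold = x$lda$threshold,
         training_accuracy = mean(pred == x$y))
}

#' Save / reload a fitted SO-CovSel model as JSON
#'
#' The file stores the block order, per-stage selected analytes, projection
#' weights, centering means and coefficients, the intercept, the LDA rule,
#' and the scaler (if any), at 17 significant digits so the reloaded model
#' reproduces predictions exactly.
#'
#' @param m A fitted `so_covsel` model.
#' @param path Output (or input) file path.
#' @return `write_so_covsel()`: invisibly, `path`; `read_so_covsel()`: the
#'   reconstructed `so_covsel` model.
#' @export
write_so_covsel <- function(m, path) {
  ser_mat <- function(x) list(dim = dim(x), values = as.numeric(x))
  obj <- list(
    format = "so_covsel/1",
    order = m$order, complexities = as.list(m$complexities),
    intercept = m$intercept, priors = m$priors,
    block_widths = as.list(m$block_widths),
    lda = unclass(m$lda),
    stages = lapply(m$stages, function(st) {
      list(block = st$block, indices = st$indices, analytes = st$analytes,
           criterion = st$criterion, W = ser_mat(st$W), mu = st$mu,
           B = st$B)
    }),
    fitted = m$fitted, y = m$y,
    scaler = if (!is.null(m$scaler)) {
      list(n_fitted = m$scaler$n_fitted,
           blocks = lapply(m$scaler$blocks, function(b) {
             list(analytes = names(b$mean), mean = unname(b$mean),
                  sd = unname(b$sd))
           }))
    })
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_so_covsel
#' @export
read_so_covsel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$format, "so_covsel/1")) {
    abort("not a serialized so_covsel model")
  }
  de_mat <- function(l) {
    vals <- if (length(l$values)) as.numeric(unlist(l$values)) else numeric(0)
    matrix(vals, l$dim[1], l$dim[2])
  }
  stages <- lapply(obj$stages, function(st) {
    list(block = st$block, indices = as.integer(st$indices),
         analytes = as.character(st$analytes),
         criterion = as.numeric(st$criterion), W = de_mat(st$W),
         mu = as.numeric(st$mu), B = as.numeric(st$B))
  })
  scaler <- NULL
  if (!is.null(obj$scaler)) {
    scaler <- structure(list(
      blocks = lapply(obj$scaler$blocks, function(b) {
        list(mean = setNames(as.numeric(b$mean), b$analytes),
             sd = setNames(as.numeric(b$sd), b$analytes))
      }),
      n_fitted = obj$scaler$n_fitted), class = "block_scaler")
  }
  structure(
    list(order = as.character(obj$order),
         complexities = setNames(as.integer(unlist(obj$complexities)),
                                 names(obj$complexities)),
         stages = stages, intercept = as.numeric(obj$intercept),
         lda = structure(obj$lda, class = "lda_rule"),
         fitted = as.numeric(obj$fitted), y = as.integer(obj$y),
         scaler = scaler,
         block_widths = setNames(as.integer(unlist(obj$block_widths)),
                                 names(obj$block_widths)),
         priors = obj$priors),
    class = "so_covsel")
}
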