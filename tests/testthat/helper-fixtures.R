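# Small in-code fixtures and independent oracles shared across tests.

# Hand-built two-block dataset: n samples, widths as given, optional
# planted signal in the first column of the first block.
mb_fixture <- function(n = 12, widths = c(alpha = 4, beta = 3), seed = 1,
                       effect = 0) {
  set.seed(seed)
  y <- rep_len(c(1L, 0L), n)
  dat <- data.frame(class = y, check.names = FALSE)
  panel <- data.frame(
    analyte = unlist(lapply(seq_along(widths), function(k) {
      sprintf("%s_v%d", names(widths)[k], seq_len(widths[k]))
    })),
    block = rep(names(widths), widths))
  for (a in panel$analyte) dat[[a]] <- rnorm(n)
  first <- panel$analyte[1L]
  dat[[first]] <- dat[[first]] + effect * y
  multiblock(dat, panel, label_col = "class")
}

# Independent brute-force greedy CovSel oracle: per step, computes the
# squared covariance with stats::cov for every column of an explicitly
# deflated copy, then deflates X and y via lm() residuals on the picked
# column. Shares no code with covsel_select().
covsel_oracle <- function(X, y, nvar) {
  Xd <- as.matrix(X)
  yd <- as.numeric(y)
  picked <- integer(0)
  for (s in seq_len(nvar)) {
    scores <- vapply(seq_len(ncol(Xd)), function(j) {
      stats::cov(Xd[, j], yd)^2
    }, 0)
    scores[colSums(Xd^2) <= 1e-12] <- -Inf
    j <- which.max(scores)
    picked <- c(picked, j)
    p <- Xd[, j]
    Xd <- apply(Xd, 2L, function(col) stats::resid(stats::lm(col ~ p - 1)))
    yd <- stats::resid(stats::lm(yd ~ p - 1))
  }
  picked
}

# R reference for the C++ inner-loop kernel: evaluates every complexity
# tuple of one block order by composing the public scaling, fitting and
# classification functions fold by fold. Returns misclassification counts
# in the kernel's tuple indexing (stage order, first stage fastest).
grid_cv_reference <- function(ds, folds, ord, cmax, scaling = "fold",
                              priors = "empirical") {
  box <- as.matrix(do.call(expand.grid, lapply(cmax, function(m) 0:m)))
  colnames(box) <- ord
  err <- rep(NA_real_, nrow(box))
  for (t in seq_len(nrow(box))) {
    tup <- setNames(as.integer(box[t, ]), ord)
    if (sum(tup) == 0L) next
    tot <- 0L
    for (f in sort(unique(folds))) {
      te <- which(folds == f)
      tr <- which(folds != f)
      blocks_sc <- if (scaling == "fold") {
        scale_train_apply_test(ds$blocks, tr)
      } else ds$blocks
      train <- ds
      train$sample_ids <- ds$sample_ids[tr]
      train$y <- ds$y[tr]
      train$blocks <- lapply(blocks_sc, function(m) m[tr, , drop = FALSE])
      train$censored <- lapply(ds$censored, function(m) m[tr, , drop = FALSE])
      m <- fit_so_covsel(train, complexities = tup, order = ord,
                         priors = priors)
      pred <- classify(m, lapply(blocks_sc,
                                 function(x) x[te, , drop = FALSE]))
      tot <- tot + sum(pred != ds$y[te])
    }
    err[t] <- tot
  }
  err
}

# Guarded train-fit/apply autoscaling, reimplemented for the reference.
scale_train_apply_test <- function(blocks, tr) {
  lapply(blocks, function(m) {
    mu <- colMeans(m[tr, , drop = FALSE])
    s <- apply(m[tr, , drop = FALSE], 2L, stats::sd)
    s[s < 1e-12] <- 1
    sweep(sweep(m, 2L, mu), 2L, s, "/")
  })
}
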