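scale_all <- function(ds) apply_scaler(fit_scaler(ds), ds)

test_that("a single informative block yields a positively aligned prediction", {
  set.seed(21)
  n <- 14
  y <- rep_len(c(1L, 0L), n)
  d <- data.frame(class = y, sig = y + rnorm(n, sd = .2), ns = rnorm(n))
  p <- data.frame(analyte = c("sig", "ns"), block = c("b1", "b1"))
  ds <- scale_all(multiblock(d, p))
  m <- fit_so_covsel(ds, complexities = 1)
  expect_identical(m$stages[[1]]$analytes, "sig")
  expect_gt(stats::cor(m$fitted, y), 0.8)
})

test_that("a block duplicating an earlier block contributes nothing after orthogonalization", {
  set.seed(22)
  n <- 16
  y <- rep_len(c(1L, 0L), n)
  base <- matrix(rnorm(n * 3), n, 3)
  base[, 1] <- base[, 1] + 2 * y
  d <- data.frame(class = y)
  for (j in 1:3) d[[paste0("a", j)]] <- base[, j]
  d$b1 <- base[, 1]  # block 2 duplicates block 1's selected column
  p <- data.frame(analyte = c(paste0("a", 1:3), "b1"),
                  block = rep(c("first", "second"), c(3, 1)))
  ds <- scale_all(multiblock(d, p))
  m <- fit_so_covsel(ds, complexities = c(first = 1, second = 1))
  expect_identical(m$stages[[1]]$analytes, "a1")
  # stage 2 selects from a block whose information was already removed
  expect_lt(abs(m$stages[[2]]$B), 1e-8)
  expect_lt(m$stages[[2]]$criterion, 1e-8)
})

test_that("accumulated selections stay orthogonal to later stages and strong signal separates perfectly", {
  sim <- simulate_panel(synthetic_config(seed = 5, effect_size = 3))
  ds <- scale_all(sim$dataset)
  m <- fit_so_covsel(ds, complexities = c(2, 2, 1))
  expect_equal(unname(glance(m)$training_accuracy), 1)
  # rebuild the accumulated selected-column matrix stage by stage and
  # check the orthogonalized next-stage blocks against it
  S <- NULL
  for (st in m$stages) {
    X <- ds$blocks[[st$block]]
    if (!is.null(S)) {
      og <- orthogonalize_block(X, S)
      expect_lt(max(abs(crossprod(S, og$X_orth))), 1e-8)
    }
    S <- cbind(S, X[, st$indices, drop = FALSE])
  }
})

test_that("prediction is a deterministic row-wise map reproducing training values", {
  sim <- simulate_panel(synthetic_config(seed = 6, effect_size = 2))
  ds <- scale_all(sim$dataset)
  m <- fit_so_covsel(ds, complexities = c(2, 2, 1))
  expect_equal(predict(m, ds$blocks), m$fitted)
  # consistent row permutation permutes predictions identically
  perm <- sample(seq_along(ds$y))
  permuted <- lapply(ds$blocks, function(b) b[perm, , drop = FALSE])
  expect_equal(predict(m, permuted), m$fitted[perm])
  # a new sample equal to a training sample gets that sample's value
  one <- lapply(ds$blocks, function(b) b[c(3, 3), , drop = FALSE])
  expect_equal(predict(m, one), rep(m$fitted[3], 2))
  expect_error(predict(m, lapply(ds$blocks, function(b) b[, -1])),
               "width")
})

test_that("fitting is invariant to a consistent sample reordering", {
  sim <- simulate_panel(synthetic_config(seed = 7, effect_size = 2))
  ds <- scale_all(sim$dataset)
  m1 <- fit_so_covsel(ds, complexities = c(2, 1, 1))
  perm <- withr::with_seed(1, sample(seq_along(ds$y)))
  ds2 <- ds
  ds2$sample_ids <- ds$sample_ids[perm]
  ds2$y <- ds$y[perm]
  ds2$blocks <- lapply(ds$blocks, function(b) b[perm, , drop = FALSE])
  m2 <- fit_so_covsel(ds2, complexities = c(2, 1, 1))
  expect_identical(lapply(m1$stages, `[[`, "analytes"),
                   lapply(m2$stages, `[[`, "analytes"))
  expect_equal(lapply(m1$stages, `[[`, "B"),
               lapply(m2$stages, `[[`, "B"))
  expect_equal(m1$fitted[perm], m2$fitted)
})

test_that("the intercept vanishes on centered data and complexity-0 blocks are skipped", {
  sim <- simulate_panel(synthetic_config(seed = 8, effect_size = 2))
  ds <- scale_all(sim$dataset)
  m <- fit_so_covsel(ds, complexities = c(2, 0, 1))
  expect_length(m$stages, 2L)
  expect_identical(vapply(m$stages, `[[`, "", "block"),
                   c("amino_acids", "mdv"))
  # blocks are centered, so the intercept reduces to the response mean
  expect_equal(m$intercept, mean(ds$y), tolerance = 1e-8)
  expect_error(fit_so_covsel(ds, complexities = c(0, 0, 0)), "positive")
  expect_error(fit_so_covsel(ds, complexities = c(2, 2, 9)), "mdv")
})

test_that("the one-dimensional LDA rule places thresholds where discriminants are equal", {
  yhat <- c(0.9, 1.1, 1.0, 0.05, -0.05, 0)
  labels <- c(1, 1, 1, 0, 0, 0)
  rule <- fit_lda(yhat, labels, priors = "equal")
  expect_equal(rule$threshold, 0.5)
  expect_equal(rule$mean_case, 1)
  expect_equal(rule$mean_control, 0)
  # pooled variance uses the n - 2 denominator
  expect_equal(rule$pooled_var, (0.02 + 0.005) / 4)

  # unbalanced priors shift the threshold toward the rarer class's mean;
  # verify against a numeric solve of the equal-discriminant equation
  set.seed(29)
  y2 <- c(rep(1, 9), rep(0, 3))
  yh2 <- c(rnorm(9, 1, .1), rnorm(3, 0, .1))
  r2 <- fit_lda(yh2, y2, priors = "empirical")
  disc <- function(x) {
    stats::dnorm(x, r2$mean_case, sqrt(r2$pooled_var)) * r2$prior_case -
      stats::dnorm(x, r2$mean_control, sqrt(r2$pooled_var)) * r2$prior_control
  }
  root <- stats::uniroot(disc, c(r2$mean_control, r2$mean_case))$root
  expect_equal(r2$threshold, root, tolerance = 1e-6)
  expect_lt(r2$threshold, (r2$mean_case + r2$mean_control) / 2)

  # degenerate inputs
  expect_error(fit_lda(rep(1, 6), labels), "pooled variance")
  expect_error(fit_lda(yhat, rep(1, 6)), "both classes")

  # perfectly separated training predictions classify perfectly
  m_sep <- fit_lda(c(2, 2.1, 2.2, -1, -1.1, -1.2), labels)
  expect_identical(socovsel:::classify_lda(m_sep, c(2, 2.1, 2.2, -1, -1.1, -1.2)),
                   as.integer(labels))
})

test_that("classification thresholds the predicted response with ties assigned to class 1", {
  set.seed(30)
  n <- 14
  y <- rep_len(c(1L, 0L), n)
  d <- data.frame(class = y, sig = y + rnorm(n, sd = .3), ns = rnorm(n))
  p <- data.frame(analyte = c("sig", "ns"), block = c("b1", "b1"))
  ds <- scale_all(multiblock(d, p))
  m <- fit_so_covsel(ds, complexities = 1)
  expect_identical(classify(m, ds$blocks),
                   socovsel:::classify_lda(m$lda, m$fitted))

  # craft a sample whose prediction lands exactly on the threshold
  j <- m$stages[[1]]$indices
  B <- m$stages[[1]]$B
  x_star <- (m$lda$threshold - m$intercept) / B
  new <- list(b1 = matrix(c(0, 0), 1, 2,
                          dimnames = list(NULL, colnames(ds$blocks$b1))))
  new$b1[1, j] <- x_star
  expect_equal(predict(m, new), m$lda$threshold)
  expect_identical(classify(m, new), 1L)
})

test_that("a serialized model reloads to identical predictions", {
  sim <- simulate_panel(synthetic_config(seed = 9, effect_size = 2))
  sc <- fit_scaler(sim$dataset)
  m <- fit_so_covsel(sim$dataset, complexities = c(2, 2, 1), scaler = sc)
  path <- withr::local_tempfile(fileext = ".json")
  write_so_covsel(m, path)
  back <- read_so_covsel(path)
  expect_identical(back$order, m$order)
  expect_identical(lapply(back$stages, `[[`, "analytes"),
                   lapply(m$stages, `[[`, "analytes"))
  newdata <- simulate_panel(synthetic_config(seed = 10,
                                             effect_size = 2))$dataset
  expect_equal(predict(back, newdata), predict(m, newdata), tolerance = 0)
  expect_identical(classify(back, newdata), classify(m, newdata))
})

test_that("tidy and glance expose the selected panel and figures of merit", {
  sim <- simulate_panel(synthetic_config(seed = 12, effect_size = 2.5))
  ds <- scale_all(sim$dataset)
  m <- fit_so_covsel(ds, complexities = c(2, 2, 1))
  td <- tidy(m)
  expect_identical(nrow(td), 5L)
  expect_identical(names(td),
                   c("stage", "block", "analyte", "step", "coefficient",
                     "criterion"))
  g <- glance(m)
  expect_identical(g$n_selected, 5L)
  expect_true(g$threshold > min(m$fitted) && g$threshold < max(m$fitted))
  # threshold lies between the two class means of the training prediction
  expect_true(g$threshold > min(m$lda$mean_control, m$lda$mean_case) &&
              g$threshold < max(m$lda$mean_control, m$lda$mean_case))
})
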