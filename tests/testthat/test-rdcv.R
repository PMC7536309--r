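test_that("partitions are stratified, near-equal and deterministic given the seed", {
  y21 <- c(rep(1, 11), rep(0, 10))
  f <- withr::with_seed(1, make_partition(21, 21, labels = y21))
  expect_identical(sort(unique(f)), 1:21)
  expect_true(all(table(f) == 1))  # leave-one-out degeneration

  y20 <- rep(c(1, 0), each = 10)
  f5 <- withr::with_seed(2, make_partition(20, 5, labels = y20))
  expect_true(all(table(f5) == 4))
  expect_true(all(table(f5, y20) == 2))  # 2 per class in every group

  expect_identical(withr::with_seed(3, make_partition(21, 5, labels = y21)),
                   withr::with_seed(3, make_partition(21, 5, labels = y21)))
  expect_error(make_partition(4, 5), "exceed")

  # sizes differ by at most one, with or without stratification
  for (s in 1:20) {
    n <- sample(6:40, 1)
    k <- sample(2:n, 1)
    lab <- sample(0:1, n, replace = TRUE)
    f <- make_partition(n, k, labels = lab)
    expect_lte(diff(range(tabulate(f, k))), 1L)
  }
})

test_that("the grid kernel agrees exactly with an R reference built from the public fit", {
  for (scaling in c("fold", "global")) {
    for (priors in c("empirical", "equal")) {
      ds <- mb_fixture(n = 14, widths = c(alpha = 4, beta = 3), seed = 31,
                       effect = 1.2)
      if (scaling == "global") ds <- apply_scaler(fit_scaler(ds), ds)
      folds <- withr::with_seed(5, make_partition(14, 4, labels = ds$y))
      for (ord in list(c("alpha", "beta"), c("beta", "alpha"))) {
        cmax <- c(alpha = 2L, beta = 2L)[ord]
        kern <- socovsel:::grid_cv_misclass(
          unname(ds$blocks[ord]), ds$y, folds, unname(cmax),
          scaling == "fold", priors == "equal")
        ref <- grid_cv_reference(ds, folds, ord, cmax, scaling, priors)
        nz <- !is.na(ref) & !is.na(kern)
        expect_gte(sum(nz), length(ref) - 1L)  # only the all-zero tuple drops
        expect_identical(as.numeric(kern[nz]), ref[nz])
      }
    }
  }
})

test_that("inner selection prefers the true complexity and breaks ties toward parsimony", {
  # single block, informative first column: complexity 1 should win the
  # {1, 2} grid for most seeds at a strong effect
  wins <- 0L
  for (s in 1:10) {
    ds <- mb_fixture(n = 20, widths = c(alpha = 3), seed = 200 + s,
                     effect = 3)
    cfg <- rdcv_config(n_inner_groups = 5, max_complexity = 2,
                       orders = list("alpha"))
    sel <- withr::with_seed(s, inner_select(ds, cfg))
    if (sel$complexity[["alpha"]] == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 6L)

  # degenerate grid: single candidate returned without cross-validation
  ds <- mb_fixture(n = 10, widths = c(alpha = 3, beta = 2), seed = 4)
  cfg1 <- rdcv_config(orders = list(c("beta", "alpha")),
                      grid = data.frame(alpha = 2, beta = 1))
  seed_before <- withr::with_seed(9, {
    sel <- inner_select(ds, cfg1)
    sel
  })
  expect_identical(seed_before$order, c("beta", "alpha"))
  expect_identical(seed_before$complexity, c(alpha = 2L, beta = 1L))

  # pure-noise data: the tie-break lands on the smallest total complexity
  dsn <- mb_fixture(n = 16, widths = c(alpha = 3, beta = 2), seed = 77)
  cfgn <- rdcv_config(max_complexity = 2)
  seln <- withr::with_seed(13, inner_select(dsn, cfgn, keep_errors = TRUE))
  e <- seln$inner_errors
  best_err <- min(e$error)
  expect_identical(sum(seln$complexity),
                   as.integer(min(e$total[e$error == best_err])))
})

test_that("one DCV run predicts every sample exactly once with valid rates", {
  sim <- simulate_panel(synthetic_config(seed = 41, effect_size = 2))
  run <- withr::with_seed(8, run_dcv(sim$dataset, rdcv_config()))
  expect_identical(run$n_models, 21L)
  expect_identical(nrow(run$models), 21L)
  expect_identical(sort(run$predictions$sample_id),
                   sort(sim$dataset$sample_ids))
  expect_true(all(run$predictions$predicted %in% c(0L, 1L)))
  expect_true(all(c(run$rate_case, run$rate_control, run$accuracy) >= 0 &
                  c(run$rate_case, run$rate_control, run$accuracy) <= 1))
  expect_equal(run$accuracy,
               mean(run$predictions$predicted == run$predictions$y))
})

test_that("rDCV is bit-reproducible given the configuration and counts models correctly", {
  sim <- simulate_panel(synthetic_config(seed = 42, effect_size = 2))
  cfg <- rdcv_config(n_repetitions = 2, base_seed = 11)
  a <- run_rdcv(sim$dataset, cfg)
  b <- run_rdcv(sim$dataset, cfg)
  expect_identical(glance(a), glance(b))
  expect_identical(a$frequency, b$frequency)
  expect_identical(a$models, b$models)
  expect_identical(a$total_models, 2L * 21L)

  # conservation: frequency counts sum to the total number of selections
  n_sel <- sum(vapply(a$models$selected, nrow, 0L))
  expect_identical(sum(a$frequency$count), n_sel)
  expect_true(all(a$frequency$count <= a$total_models))
})

test_that("held-out samples cannot influence the model that predicts them", {
  ds <- mb_fixture(n = 12, widths = c(alpha = 4, beta = 3), seed = 55,
                   effect = 2)
  cfg <- rdcv_config(n_outer_groups = 12, n_inner_groups = 4,
                     max_complexity = 2)
  r1 <- withr::with_seed(3, run_dcv(ds, cfg))
  target <- 5L
  g <- r1$predictions$fold[target]
  ds2 <- ds
  for (b in block_names(ds2)) ds2$blocks[[b]][target, ] <-
    ds2$blocks[[b]][target, ] + 1e3  # wild perturbation of one sample
  r2 <- withr::with_seed(3, run_dcv(ds2, cfg))
  # the model fitted with that sample held out is unchanged
  expect_identical(r1$models[g, c("order", "complexity")],
                   r2$models[g, c("order", "complexity")])
  expect_identical(r1$models$selected[[g]], r2$models$selected[[g]])
})

test_that("label-permuted data yield chance-level accuracy", {
  accs <- vapply(1:8, function(s) {
    sim <- simulate_panel(synthetic_config(seed = 300 + s,
                                           effect_size = 0))
    withr::with_seed(s, run_dcv(sim$dataset,
                                rdcv_config(max_complexity = 2)))$accuracy
  }, 0)
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("the permutation p-value respects the add-one rule and its floor", {
  sim <- simulate_panel(synthetic_config(seed = 66, effect_size = 4))
  cfg <- rdcv_config(n_repetitions = 1, base_seed = 2, max_complexity = 2)
  pt <- permutation_test(sim$dataset, cfg, B = 9)
  expect_identical(pt$B, 9L)
  expect_identical(pt$p_value,
                   (1 + sum(pt$null >= pt$observed)) / (pt$B + 1))
  expect_gte(pt$p_value, 1 / (pt$B + 1))
  expect_lte(pt$p_value, 1)
  # strong signal: observed beats every null draw, hitting the floor
  expect_identical(pt$p_value, 1 / 10)
  expect_identical(pt$n_repetitions_observed, 1L)
})
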