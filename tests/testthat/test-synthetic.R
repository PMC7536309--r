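test_that("the generator is deterministic and emulates the serum panel shape", {
  a <- simulate_panel(synthetic_config(seed = 123))
  b <- simulate_panel(synthetic_config(seed = 123))
  expect_identical(a$dataset$blocks, b$dataset$blocks)
  expect_identical(a$truth, b$truth)

  ds <- a$dataset
  expect_identical(length(ds$y), 21L)
  expect_identical(sum(ds$y), 11L)
  expect_identical(unname(block_widths(ds)), c(32L, 23L, 4L))
  expect_identical(block_names(ds), c("amino_acids", "inflammation", "mdv"))
  planted <- unlist(a$truth$planted)
  expect_length(planted, 5L)
  expect_true(all(planted %in% ds$panel$analyte))
  expect_identical(lengths(a$truth$planted),
                   c(amino_acids = 2L, inflammation = 2L, mdv = 1L))
  # concentrations are positive under the lognormal family
  expect_true(all(vapply(ds$blocks, function(m) all(m > 0), TRUE)))
})

test_that("the assayed panel carries 16 fully censored analytes in a 5/8/3 split", {
  sim <- simulate_panel(synthetic_config(assayed = TRUE, seed = 3))
  ds <- sim$dataset
  expect_identical(unname(block_widths(ds)), c(37L, 31L, 7L))
  cen_cols <- lapply(ds$censored, function(m) colnames(m)[colSums(m) == nrow(m)])
  expect_identical(lengths(cen_cols),
                   c(amino_acids = 5L, inflammation = 8L, mdv = 3L))
  expect_setequal(unlist(cen_cols), lod_analytes())
  # nothing partially censored
  part <- lapply(ds$censored, function(m) {
    any(colSums(m) > 0 & colSums(m) < nrow(m))
  })
  expect_false(any(unlist(part)))
})

test_that("planted effects realize the configured standardized mean shift", {
  cfg <- synthetic_config(n_case = 1000, n_control = 1000,
                          effect_size = 4, family = "gaussian", seed = 99)
  sim <- simulate_panel(cfg)
  ds <- sim$dataset
  se <- sqrt(1 / 1000 + 1 / 1000)  # unit-variance columns
  for (b in block_names(ds)) {
    for (a in sim$truth$planted[[b]]) {
      d <- mean(ds$blocks[[b]][ds$y == 1L, a]) -
        mean(ds$blocks[[b]][ds$y == 0L, a])
      expect_lt(abs(d - 4), 3 * se)
    }
    not_planted <- setdiff(colnames(ds$blocks[[b]]),
                           sim$truth$planted[[b]])[1]
    d0 <- mean(ds$blocks[[b]][ds$y == 1L, not_planted]) -
      mean(ds$blocks[[b]][ds$y == 0L, not_planted])
    expect_lt(abs(d0), 4 * se)
  }
})

test_that("the shared latent factor induces inter-block correlation", {
  lo <- simulate_panel(synthetic_config(seed = 17, redundancy = 0,
                                        n_case = 300, n_control = 300,
                                        family = "gaussian",
                                        effect_size = 0))
  hi <- simulate_panel(synthetic_config(seed = 17, redundancy = 0.8,
                                        n_case = 300, n_control = 300,
                                        family = "gaussian",
                                        effect_size = 0))
  xcor <- function(sim) {
    mean(abs(stats::cor(sim$dataset$blocks$amino_acids[, 1:5],
                        sim$dataset$blocks$inflammation[, 1:5])))
  }
  expect_gt(xcor(hi), xcor(lo) + 0.3)
})

test_that("censoring and configuration errors name the offending field", {
  ds <- simulate_panel(synthetic_config(seed = 1))$dataset
  expect_error(censor_panel(ds, c("tryptophan", "unobtainium")),
               "unobtainium")
  expect_identical(censor_panel(ds, character(0))$blocks, ds$blocks)

  expect_error(synthetic_config(n_case = 0), "n_case")
  expect_error(synthetic_config(effect_size = -1), "effect_size")
  expect_error(synthetic_config(redundancy = 1), "redundancy")
  expect_error(synthetic_config(n_informative = c(40, 2, 1)),
               "n_informative")
})

test_that("a simulated dataset round-trips through its disk artifacts", {
  sim <- simulate_panel(synthetic_config(seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_multiblock(paths[1], paths[2], label_column = "class")
  expect_equal(back$blocks, sim$dataset$blocks, tolerance = 0)
  truth <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_setequal(unname(unlist(truth$planted)),
                  unname(unlist(sim$truth$planted)))
})

test_that("custom widths fall back to systematic analyte names", {
  sim <- simulate_panel(synthetic_config(
    block_widths = c(x = 5, y = 4), n_informative = c(1, 1), seed = 2))
  expect_identical(block_names(sim$dataset), c("x", "y"))
  expect_identical(unname(block_widths(sim$dataset)), c(5L, 4L))
  expect_match(sim$dataset$panel$analyte[1], "^x_v01$")
  expect_true(all(lengths(sim$truth$planted) == c(1L, 1L)))
})
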