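#' Configuration for repeated double cross-validation
#'
#' Defaults follow the study design the package emulates: 50 repetitions of
#' a double cross-validation with 21 cancelation groups in the outer loop
#' (leave-one-out at n = 21) and 5 in the inner loop; the inner loop picks
#' the block order (all permutations by default) and the per-block number
#' of selected variables (0..4 by default, the all-zero tuple excluded).
#'
#' @param n_repetitions Number of independent DCV repetitions (default 50).
#' @param n_outer_groups Outer cancelation groups (default 21).
#' @param n_inner_groups Inner cancelation groups (default 5).
#' @param max_complexity Per-block upper bound of selected variables
#'   (scalar or named per block; default 4, searched from 0).
#' @param orders Candidate block orders as a list of character vectors;
#'   `NULL` (default) tries all permutations. Earlier entries are preferred
#'   on ties.
#' @param grid Optional explicit complexity grid: a matrix or data frame
#'   with one column per block (canonical panel order) and one row per
#'   allowed tuple. `NULL` uses the full `0:max_complexity` box.
#' @param scaling `"fold"` (default): autoscaling refitted on the training
#'   rows of every fold, leakage-free; `"global"`: the dataset is autoscaled
#'   once on all samples before resampling (the pretreat-then-validate
#'   order used by the emulated study).
#' @param priors LDA priors, `"empirical"` or `"equal"`.
#' @param base_seed Base of the seed ladder; repetition r runs under seed
#'   `base_seed + r - 1`.
#' @return A list of class `rdcv_config`.
#' @export
rdcv_config <- function(n_repetitions = 50, n_outer_groups = 21,
                        n_inner_groups = 5, max_complexity = 4,
                        orders = NULL, grid = NULL,
                        scaling = c("fold", "global"),
                        priors = c("empirical", "equal"),
                        base_seed = 1) {
  structure(list(n_repetitions = as.integer(n_repetitions),
                 n_outer_groups = as.integer(n_outer_groups),
                 n_inner_groups = as.integer(n_inner_groups),
                 max_complexity = max_complexity,
                 orders = orders, grid = grid,
                 scaling = match.arg(scaling),
                 priors = match.arg(priors),
                 base_seed = as.integer(base_seed)),
            class = "rdcv_config")
}

#' Split samples into cross-validation cancelation groups
#'
#' Random partition into `k` groups of near-equal size (sizes differ by at
#' most 1), stratified by class where `labels` are supplied. With `k = n`
#' this degenerates to leave-one-out. Deterministic given the RNG state.
#'
#' @param n Sample count.
#' @param k Number of groups, `2 <= k <= n`.
#' @param labels Optional class labels for stratification.
#' @return Integer vector of group ids in `1:k`, one per sample.
#' @export
make_partition <- function(n, k, labels = NULL) {
  if (k > n) abort("`k` must not exceed the number of samples")
  if (k < 2L) abort("`k` must be at least 2")
  if (is.null(labels)) {
    ord <- sample.int(n)
  } else {
    if (length(labels) != n) abort("`labels` must have length n")
    labels <- as.factor(labels)
    ord <- unlist(lapply(levels(labels), function(l) {
      w <- which(labels == l)
      w[sample.int(length(w))]
    }), use.names = FALSE)
  }
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

all_orders <- function(bn) {
  if (length(bn) == 1L) return(list(bn))
  out <- list()
  for (i in seq_along(bn)) {
    for (rest in all_orders(bn[-i])) out[[length(out) + 1L]] <- c(bn[i], rest)
  }
  out
}

# Expand the per-block complexity box 0..cmax (stage order, first stage
# varying fastest) to match the C++ kernel's tuple indexing.
tuple_box <- function(cmax) {
  g <- do.call(expand.grid, lapply(cmax, function(m) 0:m))
  as.matrix(g)
}

# Allowed-tuple mask (canonical block order) from cfg$grid, or NULL for all.
grid_keys <- function(cfg, bn) {
  if (is.null(cfg$grid)) return(NULL)
  g <- as.matrix(as.data.frame(cfg$grid))
  if (is.null(colnames(g))) colnames(g) <- bn
  apply(g[, bn, drop = FALSE], 1L, paste, collapse = "-")
}

cmax_per_block <- function(cfg, ds) {
  bn <- block_names(ds)
  m <- cfg$max_complexity
  if (!is.null(cfg$grid)) {
    g <- as.data.frame(cfg$grid)
    if (is.null(names(g)) || !all(bn %in% names(g))) names(g) <- bn
    return(setNames(vapply(bn, function(b) max(g[[b]]), 0), bn))
  }
  if (length(m) == 1L) return(setNames(rep(as.integer(m), length(bn)), bn))
  if (is.null(names(m))) return(setNames(as.integer(m), bn))
  setNames(as.integer(m[bn]), bn)
}

#' Inner-loop selection of block order and per-block complexity
#'
#' Runs `n_inner_groups`-fold cross-validation on the training set for
#' every candidate (block order, complexity tuple) and returns the
#' combination with the smallest pooled misclassification count. Ties are
#' broken by fewest total selected variables, then by the order preference
#' as listed in the configuration, then lexicographically on the tuple.
#' Consumes the current RNG state (for the inner partition).
#'
#' @param train A `multiblock` training set with both classes.
#' @param cfg An [rdcv_config()].
#' @param keep_errors If `TRUE`, also return the error of every evaluated
#'   candidate (off by default: the table is rebuilt thousands of times
#'   inside [run_rdcv()]).
#' @return A list with `order` (character), `complexity` (named integer
#'   vector in canonical block order), and `inner_errors` (tibble of all
#'   evaluated candidates, or `NULL` unless `keep_errors`).
#' @export
inner_select <- function(train, cfg, keep_errors = FALSE) {
  bn <- block_names(train)
  orders <- cfg$orders %||% all_orders(bn)
  cmax <- cmax_per_block(cfg, train)
  keys <- grid_keys(cfg, bn)

  # degenerate grid: a single candidate needs no cross-validation
  if (length(orders) == 1L && !is.null(keys) && length(unique(keys)) == 1L) {
    tup <- as.integer(strsplit(keys[1L], "-", fixed = TRUE)[[1L]])
    return(list(order = orders[[1L]],
                complexity = setNames(tup, bn), inner_errors = NULL))
  }

  folds <- make_partition(length(train$y), cfg$n_inner_groups,
                          labels = train$y)
  blocks <- train$blocks
  # in global mode the dataset is expected pre-scaled by the caller
  # (run_dcv does this); in fold mode the kernel rescales per inner fold
  scale_folds <- cfg$scaling == "fold"

  err_all <- total_all <- oi_all <- integer(0)
  canon_all <- NULL
  boxes <- list()
  for (oi in seq_along(orders)) {
    ord <- orders[[oi]]
    cm <- cmax[ord]
    err <- grid_cv_misclass(unname(blocks[ord]), train$y, folds,
                            as.integer(cm), scale_folds,
                            cfg$priors == "equal")
    bkey <- paste(cm, collapse = ",")
    if (is.null(boxes[[bkey]])) boxes[[bkey]] <- tuple_box(cm)
    box <- boxes[[bkey]]  # stage order, first stage varying fastest
    canon <- box[, match(bn, ord), drop = FALSE]
    err_all <- c(err_all, err)
    total_all <- c(total_all, as.integer(rowSums(canon)))
    oi_all <- c(oi_all, rep.int(oi, nrow(canon)))
    canon_all <- rbind(canon_all, canon)
  }
  colnames(canon_all) <- bn
  keep <- total_all > 0L
  if (!is.null(keys)) {
    keep <- keep & apply(canon_all, 1L, paste, collapse = "-") %in% keys
  }
  if (!any(keep)) abort("empty complexity grid")
  e <- ifelse(is.na(err_all), Inf, err_all)[keep]
  canon <- canon_all[keep, , drop = FALSE]
  pick <- do.call(order, c(list(e, total_all[keep], oi_all[keep]),
                           lapply(seq_along(bn),
                                  function(j) canon[, j])))[1L]
  list(order = orders[[oi_all[keep][pick]]],
       complexity = setNames(as.integer(canon[pick, ]), bn),
       inner_errors = if (keep_errors) {
         dplyr::bind_cols(
           tibble(order = vapply(orders[oi_all[keep]], paste, "",
                                 collapse = ">"),
                  error = e, total = total_all[keep]),
           as_tibble(canon))
       })
}

#' One double cross-validation run
#'
#' Splits the samples into `n_outer_groups` outer cancelation groups; for
#' each group, [inner_select()] picks the block order and complexity on the
#' retained samples only, a final model is fitted on the full outer
#' training set with those settings, and the held-out group is classified.
#' Every sample is predicted exactly once. Consumes the current RNG state;
#' seed it (or use [run_rdcv()]) for reproducibility.
#'
#' With `scaling = "fold"`, autoscaling is refitted on each training set
#' (outer and inner) so held-out samples never influence the scaler; with
#' `scaling = "global"` the dataset is autoscaled once up front.
#'
#' @param ds A `multiblock` dataset with both classes and no missing cells.
#' @param cfg An [rdcv_config()].
#' @return An object of class `dcv_run`: per-segment choices and selected
#'   analytes (`models` tibble), per-sample outer predictions, and
#'   run-level figures of merit (per-class rates, overall accuracy).
#' @export
run_dcv <- function(ds, cfg = rdcv_config()) {
  viol <- validate_multiblock(ds)
  if (length(viol)) abort(paste0("invalid dataset: ", viol[1L]))
  if (any(vapply(ds$blocks, anyNA, TRUE))) {
    abort("dataset contains missing or censored cells; filter them first")
  }
  n <- length(ds$y)
  y <- ds$y
  k <- cfg$n_outer_groups
  if (cfg$scaling == "global") {
    ds <- apply_scaler(fit_scaler(ds), ds)
  }

  folds <- NULL
  for (attempt in seq_len(100L)) {
    cand <- make_partition(n, k, labels = y)
    ok <- all(vapply(seq_len(k), function(g) {
      length(unique(y[cand != g])) == 2L
    }, TRUE))
    if (ok) { folds <- cand; break }
  }
  if (is.null(folds)) abort("could not build a partition keeping both classes in every training fold")

  pred <- integer(n)
  yhat <- numeric(n)
  models <- vector("list", k)
  for (g in seq_len(k)) {
    te <- which(folds == g)
    tr <- which(folds != g)
    train <- mb_rows(ds, tr)
    sel <- inner_select(train, cfg)
    if (cfg$scaling == "fold") {
      scaled <- scale_train_apply(ds$blocks, tr)
    } else scaled <- ds$blocks
    train_sc <- train
    train_sc$blocks <- lapply(scaled, function(m) m[tr, , drop = FALSE])
    m <- fit_so_covsel(train_sc, complexities = sel$complexity,
                       order = sel$order, priors = cfg$priors)
    test_blocks <- lapply(scaled, function(x) x[te, , drop = FALSE])
    yh <- predict(m, test_blocks)
    pred[te] <- classify_lda(m$lda, yh)
    yhat[te] <- yh
    models[[g]] <- tibble(
      segment = g, order = paste(sel$order, collapse = ">"),
      complexity = paste(sel$complexity, collapse = "-"),
      selected = list(tidy(m)[, c("block", "analyte")]))
  }
  correct <- pred == y
  structure(list(
    models = dplyr::bind_rows(models),
    predictions = tibble(sample_id = ds$sample_ids, y = y, fold = folds,
                         yhat = yhat, predicted = pred),
    rate_case = mean(correct[y == 1L]),
    rate_control = mean(correct[y == 0L]),
    accuracy = mean(correct),
    n_models = k), class = "dcv_run")
}

#' Repeated double cross-validation with selection-frequency analysis
#'
#' Executes `n_repetitions` independent [run_dcv()] runs under derived
#' seeds (`base_seed + run - 1`), then aggregates figures of merit
#' (mean, SD, min, max of the per-run class-wise rates and overall
#' accuracy), tallies how often each analyte was selected across all outer
#' models, and reports the modal complexity tuple and modal block order.
#' Identical configurations (including `base_seed`) give bit-identical
#' summaries.
#'
#' @inheritParams run_dcv
#' @return An object of class `rdcv_summary`; see [tidy.rdcv_summary()]
#'   and [glance.rdcv_summary()] for tabular views.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_panel(synthetic_config(seed = 7, effect_size = 2.5))
#' cfg <- rdcv_config(n_repetitions = 2, base_seed = 7)
#' fit <- run_rdcv(sim$dataset, cfg)
#' glance(fit)
#' }
run_rdcv <- function(ds, cfg = rdcv_config()) {
  runs <- lapply(seq_len(cfg$n_repetitions), function(r) {
    withr::with_seed(cfg$base_seed + r - 1L, run_dcv(ds, cfg))
  })
  per_run <- purrr::imap_dfr(runs, function(rr, r) {
    tibble(run = r, accuracy = rr$accuracy, rate_case = rr$rate_case,
           rate_control = rr$rate_control, n_models = rr$n_models)
  })
  models <- purrr::imap_dfr(runs, function(rr, r) {
    dplyr::mutate(rr$models, run = r, .before = 1L)
  })
  total_models <- sum(per_run$n_models)
  sel_long <- tidyr::unnest(models[, c("run", "segment", "selected")],
                            "selected")
  freq <- sel_long |>
    dplyr::count(.data$block, .data$analyte, name = "count") |>
    dplyr::arrange(match(.data$block, block_names(ds)),
                   dplyr::desc(.data$count))
  modal <- function(x) names(sort(table(x), decreasing = TRUE))[1L]
  structure(list(
    per_run = per_run, models = models, frequency = freq,
    total_models = total_models,
    modal_complexity = modal(models$complexity),
    modal_order = modal(models$order),
    block_names = block_names(ds),
    config = cfg), class = "rdcv_summary")
}

#' @export
print.rdcv_summary <- function(x, ...) {
  g <- glance(x)
  cat("<rdcv_summary> ", x$total_models, " outer models (",
      nrow(x$per_run), " runs)\n", sep = "")
  cat(sprintf("  accuracy %.1f +/- %.1f%% (case %.1f +/- %.1f%%, control %.1f +/- %.1f%%)\n",
              100 * g$accuracy_mean, 100 * g$accuracy_sd,
              100 * g$rate_case_mean, 100 * g$rate_case_sd,
              100 * g$rate_control_mean, 100 * g$rate_control_sd))
  cat("  modal order:", x$modal_order,
      " modal complexity:", x$modal_complexity, "\n")
  invisible(x)
}

#' Tabular views of an rDCV summary
#'
#' `tidy()` returns the selection-frequency table: one row per analyte ever
#' selected, with its block, the number of outer models that selected it,
#' and that count as a fraction of all models. `glance()` returns a one-row
#' tibble of the figures of merit (mean, SD, min, max over runs of the
#' overall accuracy and per-class correct-classification rates), the modal
#' block order and modal complexity, and the total model count.
#'
#' @param x An `rdcv_summary` from [run_rdcv()].
#' @param ... Unused.
#' @export
tidy.rdcv_summary <- function(x, ...) {
  dplyr::mutate(x$frequency, frequency = .data$count / x$total_models)
}

#' @rdname tidy.rdcv_summary
#' @export
glance.rdcv_summary <- function(x, ...) {
  pr <- x$per_run
  tibble(n_runs = nrow(pr), total_models = x$total_models,
         accuracy_mean = mean(pr$accuracy), accuracy_sd = sd(pr$accuracy),
         accuracy_min = min(pr$accuracy), accuracy_max = max(pr$accuracy),
         rate_case_mean = mean(pr$rate_case),
         rate_case_sd = sd(pr$rate_case),
         rate_control_mean = mean(pr$rate_control),
         rate_control_sd = sd(pr$rate_control),
         modal_order = x$modal_order,
         modal_complexity = x$modal_complexity)
}

#' Permutation test of the cross-validated classification accuracy
#'
#' The observed statistic is the mean overall accuracy of a repeated
#' double cross-validation at `cfg` (use a reduced `n_repetitions` for
#' tractability; the value used is recorded in the result). For each of
#' the `B` randomizations the class labels are permuted and the same
#' statistic is recomputed with a single DCV run; the p-value uses the
#' add-one rule `p = (1 + #(null >= observed)) / (B + 1)`.
#'
#' @inheritParams run_dcv
#' @param B Number of label randomizations (at least 1).
#' @return An object of class `permutation_result`: observed statistic,
#'   null statistics, `B`, the p-value and the repetition count used for
#'   the observed statistic.
#' @export
permutation_test <- function(ds, cfg = rdcv_config(), B = 1000) {
  B <- as.integer(B)
  if (B < 1L) abort("`B` must be at least 1")
  observed <- glance(run_rdcv(ds, cfg))$accuracy_mean
  null <- vapply(seq_len(B), function(b) {
    seed_b <- (cfg$base_seed + 104729L * b) %% 2147483647L
    withr::with_seed(seed_b, {
      perm <- ds
      perm$y <- sample(ds$y)
      run_dcv(perm, cfg)$accuracy
    })
  }, 0)
  p <- (1 + sum(null >= observed)) / (B + 1)
  structure(list(observed = observed, null = null, B = B,
                 p_value = p,
                 n_repetitions_observed = cfg$n_repetitions),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed accuracy %.3f, B = %d, p = %.4g\n",
              x$observed, x$B, x$p_value))
  invisible(x)
}

#' @rdname tidy.rdcv_summary
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(draw = seq_len(x$B), null_accuracy = x$null)
}

#' @rdname tidy.rdcv_summary
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed = x$observed, B = x$B, p_value = x$p_value,
         null_mean = mean(x$null), null_sd = sd(x$null),
         n_repetitions_observed = x$n_repetitions_observed)
}

#' Reproduce the serum-panel analysis on user-supplied per-sample data
#'
#' Convenience wrapper running the full pipeline at the emulated study's
#' settings on a per-sample concentration table (e.g. one transcribed from
#' a publication supplement): read, below-detection-limit filtering,
#' global autoscaling, then 50 x (21 outer / 5 inner) repeated double
#' cross-validation.
#'
#' @inheritParams read_multiblock
#' @param base_seed Seed ladder base.
#' @return An `rdcv_summary`.
#' @export
reproduce_serum_study <- function(data_path, panel_path,
                                label_column = "class",
                                case_label = "PF&S",
                                control_label = "nonPF&S",
                                base_seed = 1) {
  ds <- read_multiblock(data_path, panel_path, label_column = label_column,
                        case_label = case_label,
                        control_label = control_label)
  ds <- filter_below_lod(ds)
  run_rdcv(ds, rdcv_config(scaling = "global", base_seed = base_seed))
}
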