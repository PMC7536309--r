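#' Drop analytes with too many below-detection-limit cells
#'
#' An analyte is removed when its detected fraction (cells not flagged as
#' censored) across all samples is below `min_detected_fraction`. At the
#' default of 1 an analyte is dropped as soon as any censoring is present,
#' which reproduces the usual practice of excluding assays reported below
#' the detection limit before modelling. The operation is a projection:
#' applying it twice equals applying it once.
#'
#' @param ds A `multiblock` object.
#' @param min_detected_fraction Minimum fraction of non-censored cells an
#'   analyte needs to be retained, in `[0, 1]`.
#' @return `ds` with the offending analytes removed; the character vector of
#'   removed analyte names (in panel order) is attached as attribute
#'   `"removed"` and also stored in `ds$meta$removed_analytes`.
#' @export
#' @examples
#' sim <- simulate_panel(synthetic_config(assayed = TRUE, seed = 1))
#' flt <- filter_below_lod(sim$dataset)
#' length(attr(flt, "removed"))  # 16 of 75 analytes censored below LOD
#' block_widths(flt)
filter_below_lod <- function(ds, min_detected_fraction = 1) {
  stopifnot(min_detected_fraction >= 0, min_detected_fraction <= 1)
  removed <- character(0)
  for (b in names(ds$blocks)) {
    cen <- ds$censored[[b]]
    det <- 1 - colMeans(cen)
    drop <- det < min_detected_fraction
    if (all(drop) && ncol(cen) > 0L) {
      abort(paste0("detection-limit filtering would empty block '", b, "'"))
    }
    removed <- c(removed, colnames(cen)[drop])
    ds$blocks[[b]] <- ds$blocks[[b]][, !drop, drop = FALSE]
    ds$censored[[b]] <- cen[, !drop, drop = FALSE]
  }
  ds$panel <- ds$panel[!ds$panel$analyte %in% removed, ]
  ds$meta$removed_analytes <- union(ds$meta$removed_analytes %||% character(0),
                                    removed)
  attr(ds, "removed") <- removed
  ds
}

#' Fit a per-block autoscaler (column means and standard deviations)
#'
#' Autoscaling subtracts from each analyte its mean and divides by its
#' standard deviation (n - 1 denominator), per block. Fitting on a row
#' subset enables leakage-free train-only scaling inside cross-validation;
#' fitting on all rows reproduces global pretreatment.
#'
#' @param ds A `multiblock` object with no censored or missing cells.
#' @param rows Integer vector of sample indices to fit on (default: all).
#' @return An object of class `block_scaler`: per block, vectors of column
#'   means and standard deviations, plus the fitted-on row count.
#' @export
fit_scaler <- function(ds, rows = seq_along(ds$sample_ids)) {
  rows <- as.integer(rows)
  if (length(rows) < 2L) abort("at least 2 rows are required to fit a scaler")
  sc <- list()
  for (b in names(ds$blocks)) {
    m <- ds$blocks[[b]][rows, , drop = FALSE]
    if (anyNA(m)) {
      abort(paste0("block '", b, "' contains missing or censored values; ",
                   "filter or resolve them before scaling"))
    }
    mu <- colMeans(m)
    s <- apply(m, 2L, sd)
    if (any(s == 0)) {
      abort(paste0("constant column over the chosen rows: '",
                   colnames(m)[which(s == 0)[1L]], "'"))
    }
    sc[[b]] <- list(mean = mu, sd = s)
  }
  structure(list(blocks = sc, n_fitted = length(rows)),
            class = "block_scaler")
}

#' Apply a fitted autoscaler to a multi-block dataset
#'
#' Each value is replaced by `(value - mean) / sd` using the scaler's
#' parameters, which may have been fitted on a different row subset
#' (train-only scaling).
#'
#' @param sc A `block_scaler` from [fit_scaler()].
#' @param ds A `multiblock` object whose block widths match the scaler.
#' @return The scaled `multiblock` object.
#' @export
apply_scaler <- function(sc, ds) {
  for (b in names(ds$blocks)) {
    p <- sc$blocks[[b]]
    if (is.null(p) || length(p$mean) != ncol(ds$blocks[[b]])) {
      abort(paste0("scaler width mismatch for block '", b, "'"))
    }
    ds$blocks[[b]] <- sweep(sweep(ds$blocks[[b]], 2L, p$mean), 2L, p$sd, "/")
  }
  ds
}

#' @export
print.block_scaler <- function(x, ...) {
  cat("<block_scaler> fitted on", x$n_fitted, "samples;",
      length(x$blocks), "blocks\n")
  invisible(x)
}

# Guarded train/apply scaling used inside the cross-validation loops: a
# column constant over the training rows is centered and left at zero (its
# sd is treated as 1), so CovSel skips it as zero-variance instead of the
# whole resampling run aborting on a degenerate fold.
scale_train_apply <- function(blocks, train_rows) {
  lapply(blocks, function(m) {
    tr <- m[train_rows, , drop = FALSE]
    mu <- colMeans(tr)
    s <- apply(tr, 2L, sd)
    s[s < 1e-12] <- 1
    sweep(sweep(m, 2L, mu), 2L, s, "/")
  })
}
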