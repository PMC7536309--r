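#' Assemble a multi-block dataset from a sample-by-analyte table
#'
#' A multi-block dataset holds one concentration matrix per measurement
#' platform ("block"), row-aligned across blocks, together with a binary
#' class vector (1 = case, 0 = control). Blocks follow the order declared in
#' the analyte panel; analytes keep their panel order within each block.
#'
#' Censored ("below detection limit") cells may be encoded either by the
#' sentinel token (in character columns) or marked later via
#' [censor_panel()]. Censored cells are kept distinct from empty cells:
#' the former are missing-by-censoring and handled by [filter_below_lod()],
#' the latter are missing-at-random and rejected by the fitting functions.
#'
#' @param data A data frame: one row per sample, one column per analyte,
#'   plus the class label column and (optionally) a sample id column.
#' @param panel A data frame with columns `analyte` and `block`, mapping
#'   every analyte column of `data` to a named block. Block order is the
#'   order of first appearance in `panel`.
#' @param label_col Name of the class label column in `data`.
#' @param case_label,control_label Values of `label_col` coding case
#'   (mapped to 1) and control (mapped to 0).
#' @param sample_col Optional name of a sample id column; if `NULL`,
#'   ids `S01, S02, ...` are generated.
#' @param lod_sentinel Token marking a below-detection-limit cell in
#'   character columns (default `"<LOD"`).
#' @param meta Free-form provenance list.
#'
#' @return An object of class `multiblock`: a list with elements
#'   `sample_ids`, `y`, `blocks` (named list of numeric matrices),
#'   `censored` (parallel logical matrices), `panel` (tibble), and `meta`.
#' @seealso [read_multiblock()], [validate_multiblock()], [simulate_panel()]
#' @export
#' @examples
#' d <- data.frame(g = c("A", "B"), x1 = c(1, 2), x2 = c(3, 4))
#' p <- data.frame(analyte = c("x1", "x2"), block = c("b1", "b1"))
#' ds <- multiblock(d, p, label_col = "g", case_label = "A", control_label = "B")
#' validate_multiblock(ds)
multiblock <- function(data, panel, label_col = "class",
                       case_label = 1, control_label = 0,
                       sample_col = NULL, lod_sentinel = "<LOD",
                       meta = list()) {
  data <- as.data.frame(data, check.names = FALSE)
  panel <- as.data.frame(panel, check.names = FALSE)
  if (!all(c("analyte", "block") %in% names(panel))) {
    abort("`panel` must have columns 'analyte' and 'block'")
  }
  panel$analyte <- as.character(panel$analyte)
  panel$block <- as.character(panel$block)
  if (anyDuplicated(panel$analyte)) {
    dup <- panel$analyte[duplicated(panel$analyte)][1L]
    abort(paste0("analyte '", dup, "' listed more than once in the panel"))
  }
  if (nrow(data) == 0L) abort("data table has no rows")
  if (!label_col %in% names(data)) {
    abort(paste0("label column '", label_col, "' not found in data"))
  }

  labels <- as.character(data[[label_col]])
  bad <- setdiff(unique(labels), as.character(c(case_label, control_label)))
  if (length(bad)) {
    abort(paste0("label column '", label_col, "' contains value(s) other ",
                 "than the configured class codes: ",
                 paste(sQuote(bad), collapse = ", ")))
  }
  y <- as.integer(labels == as.character(case_label))

  if (!is.null(sample_col)) {
    if (!sample_col %in% names(data)) {
      abort(paste0("sample column '", sample_col, "' not found in data"))
    }
    sample_ids <- as.character(data[[sample_col]])
  } else {
    sample_ids <- sprintf("S%02d", seq_len(nrow(data)))
  }

  value_cols <- setdiff(names(data), c(label_col, sample_col))
  unmapped <- setdiff(value_cols, panel$analyte)
  if (length(unmapped)) {
    abort(paste0("data column(s) not mapped to any block: ",
                 paste(sQuote(unmapped), collapse = ", ")))
  }
  missing_cols <- setdiff(panel$analyte, value_cols)
  if (length(missing_cols)) {
    abort(paste0("panel analyte(s) absent from the data table: ",
                 paste(sQuote(missing_cols), collapse = ", ")))
  }

  block_names <- unique(panel$block)
  blocks <- list()
  censored <- list()
  for (b in block_names) {
    cols <- panel$analyte[panel$block == b]
    m <- matrix(NA_real_, nrow(data), length(cols),
                dimnames = list(sample_ids, cols))
    cen <- matrix(FALSE, nrow(data), length(cols),
                  dimnames = list(sample_ids, cols))
    for (j in seq_along(cols)) {
      v <- data[[cols[j]]]
      if (is.character(v) || is.factor(v)) {
        v <- as.character(v)
        is_cen <- !is.na(v) & trimws(v) == lod_sentinel
        num <- suppressWarnings(as.numeric(ifelse(is_cen, NA, v)))
        bad_tok <- !is.na(v) & !is_cen & is.na(num) & trimws(v) != ""
        if (any(bad_tok)) {
          abort(paste0("non-numeric value '", v[bad_tok][1L],
                       "' in column '", cols[j], "' (row ",
                       which(bad_tok)[1L], ")"))
        }
        m[, j] <- num
        cen[, j] <- is_cen
      } else {
        m[, j] <- as.numeric(v)
      }
    }
    blocks[[b]] <- m
    censored[[b]] <- cen
  }

  meta$case_label <- meta$case_label %||% case_label
  meta$control_label <- meta$control_label %||% control_label
  ds <- structure(
    list(sample_ids = sample_ids, y = y, blocks = blocks,
         censored = censored,
         panel = tibble(analyte = panel$analyte, block = panel$block),
         meta = meta),
    class = "multiblock")
  # both classes are only required at fit time, so a single-class table is
  # constructable (validate_multiblock() still reports it)
  viol <- setdiff(validate_multiblock(ds), "single class present")
  if (length(viol)) abort(paste0("invalid multiblock dataset: ", viol[1L]))
  ds
}

#' Check the structural invariants of a multi-block dataset
#'
#' Reports (never throws) violations of the `multiblock` contract: aligned
#' row counts, a strictly binary class vector with both classes present,
#' and analyte names unique across blocks.
#'
#' @param ds A `multiblock` object (or anything shaped like one).
#' @return A character vector of violation descriptions; empty if valid.
#' @export
validate_multiblock <- function(ds) {
  v <- character(0)
  if (!is.list(ds) || !all(c("sample_ids", "y", "blocks") %in% names(ds))) {
    return("not a multiblock object")
  }
  n <- length(ds$sample_ids)
  if (length(ds$y) != n) v <- c(v, "class vector length differs from sample count")
  nr <- vapply(ds$blocks, nrow, integer(1))
  if (any(nr != n)) {
    v <- c(v, paste0("block(s) with row count differing from sample count: ",
                     paste(names(ds$blocks)[nr != n], collapse = ", ")))
  }
  if (length(ds$blocks) == 0L || is.null(names(ds$blocks)) ||
      anyDuplicated(names(ds$blocks)) || any(names(ds$blocks) == "")) {
    v <- c(v, "block names must be non-empty and unique")
  }
  yv <- ds$y[!is.na(ds$y)]
  if (anyNA(ds$y)) v <- c(v, "class vector contains missing values")
  if (!all(yv %in% c(0L, 1L))) {
    v <- c(v, "class vector contains values other than 0 and 1")
  } else if (length(unique(yv)) < 2L) {
    v <- c(v, "single class present")
  }
  ans <- unlist(lapply(ds$blocks, colnames))
  if (anyDuplicated(ans)) {
    v <- c(v, paste0("analyte name duplicated across blocks: ",
                     paste(unique(ans[duplicated(ans)]), collapse = ", ")))
  }
  v
}

#' Read a multi-block dataset from a data CSV and a panel CSV
#'
#' The data file is a rectangular comma-separated table with a header row:
#' samples as rows, analytes as columns, plus the class label column. The
#' panel file has columns `analyte,block` and must map every non-label,
#' non-id column. Cells equal to `lod_sentinel` are parsed as
#' missing-by-censoring; empty cells as missing-at-random.
#'
#' @inheritParams multiblock
#' @param data_path,panel_path Paths to the data and panel CSV files.
#' @param label_column Name of the class label column.
#' @return A [multiblock()] object whose blocks follow the panel's order.
#' @export
read_multiblock <- function(data_path, panel_path, label_column = "class",
                            case_label = "PF&S", control_label = "nonPF&S",
                            sample_col = NULL, lod_sentinel = "<LOD") {
  # parsing problems are surfaced as a hard error below, so readr's own
  # warning is redundant noise
  dat <- suppressWarnings(
    readr::read_csv(data_path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE))
  pb <- readr::problems(dat)
  if (nrow(pb)) {
    abort(paste0("malformed data table at row ", pb$row[1L], ": ",
                 pb$expected[1L], " expected, got ", pb$actual[1L]))
  }
  if (nrow(dat) == 0L) abort("data table has no rows")
  pan <- readr::read_csv(panel_path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (is.null(sample_col) && "sample_id" %in% names(dat) &&
      !"sample_id" %in% pan$analyte) {
    sample_col <- "sample_id"
  }
  multiblock(dat, pan, label_col = label_column,
             case_label = case_label, control_label = control_label,
             sample_col = sample_col, lod_sentinel = lod_sentinel,
             meta = list(data_path = data_path, panel_path = panel_path))
}

#' Write a multi-block dataset back to normalized data and panel CSVs
#'
#' Inverse of [read_multiblock()]: values are printed at full precision
#' (up to 15 significant digits), censored cells as the sentinel token, and
#' sample/block/analyte order is preserved, so write-then-read round-trips.
#'
#' @param ds A `multiblock` object.
#' @param data_path,panel_path Output paths.
#' @param lod_sentinel Token written for censored cells.
#' @return Invisibly, `ds`.
#' @export
write_multiblock <- function(ds, data_path, panel_path,
                             lod_sentinel = "<LOD") {
  tab <- tibble(sample_id = ds$sample_ids,
                class = ifelse(ds$y == 1L,
                               as.character(ds$meta$case_label %||% 1),
                               as.character(ds$meta$control_label %||% 0)))
  for (b in names(ds$blocks)) {
    m <- ds$blocks[[b]]
    cen <- ds$censored[[b]]
    for (j in seq_len(ncol(m))) {
      chr <- ifelse(cen[, j], lod_sentinel,
                    ifelse(is.na(m[, j]), "",
                           sprintf("%.17g", m[, j])))
      tab[[colnames(m)[j]]] <- chr
    }
  }
  readr::write_csv(tab, data_path, progress = FALSE)
  readr::write_csv(ds$panel, panel_path, progress = FALSE)
  invisible(ds)
}

#' @export
as_tibble.multiblock <- function(x, ...) {
  out <- tibble(sample_id = x$sample_ids, class = x$y)
  for (b in names(x$blocks)) {
    m <- x$blocks[[b]]
    for (j in seq_len(ncol(m))) out[[colnames(m)[j]]] <- m[, j]
  }
  out
}

#' @export
print.multiblock <- function(x, ...) {
  w <- vapply(x$blocks, ncol, integer(1))
  cat("<multiblock> ", length(x$sample_ids), " samples (",
      sum(x$y == 1L), " cases / ", sum(x$y == 0L), " controls), ",
      length(x$blocks), " blocks\n", sep = "")
  for (b in names(x$blocks)) {
    ncen <- sum(x$censored[[b]])
    cat("  ", b, ": ", w[[b]], " analytes",
        if (ncen) paste0(" (", ncen, " censored cells)") else "", "\n",
        sep = "")
  }
  invisible(x)
}

#' Block names and widths of a multi-block dataset
#' @param ds A `multiblock` object.
#' @return `block_names()`: character vector; `block_widths()`: named
#'   integer vector of analyte counts per block.
#' @export
block_names <- function(ds) names(ds$blocks)

#' @rdname block_names
#' @export
block_widths <- function(ds) vapply(ds$blocks, ncol, integer(1))

# Row subset keeping all structure (used by the cross-validation loops).
mb_rows <- function(ds, rows) {
  ds$sample_ids <- ds$sample_ids[rows]
  ds$y <- ds$y[rows]
  ds$blocks <- lapply(ds$blocks, function(m) m[rows, , drop = FALSE])
  ds$censored <- lapply(ds$censored, function(m) m[rows, , drop = FALSE])
  ds
}
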