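#' Selection-frequency chart of an rDCV summary
#'
#' One panel per block (in block order), bars giving the number of outer
#' models in which each analyte was selected — the robustness evidence for
#' a candidate biomarker panel. Blocks in which no variable was ever
#' selected appear as empty labeled panels.
#'
#' @param object An `rdcv_summary` from [run_rdcv()].
#' @param top_n Show at most this many analytes per block (by count);
#'   `Inf` shows all ever-selected analytes.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.rdcv_summary <- function(object, top_n = Inf, ...) {
  fr <- tidy(object)
  fr <- dplyr::slice_max(dplyr::group_by(fr, .data$block),
                         order_by = .data$count, n = top_n,
                         with_ties = TRUE)
  fr$block <- factor(fr$block, levels = object$block_names)
  ggplot2::ggplot(fr, ggplot2::aes(
    x = stats::reorder(.data$analyte, .data$count),
    y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$block), scales = "free_y",
                        drop = FALSE) +
    ggplot2::labs(x = NULL, y = paste0("selection count (of ",
                                       object$total_models, " models)"),
                  title = "Selection frequency across rDCV outer models") +
    ggplot2::theme_minimal()
}

#' Write the selection-frequency chart to an image file
#'
#' @param summary An `rdcv_summary`.
#' @param path Output path; the format follows the extension (`.png`,
#'   `.svg`, `.pdf`).
#' @param width,height Device size in inches.
#' @inheritParams autoplot.rdcv_summary
#' @return Invisibly, `path`.
#' @export
frequency_chart <- function(summary, path, width = 9, height = 4,
                            top_n = Inf) {
  if (nrow(summary$frequency) == 0L) abort("empty selection-frequency table")
  p <- autoplot(summary, top_n = top_n)
  ggplot2::ggsave(path, p, width = width, height = height)
  invisible(path)
}

#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$null_accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "null accuracy (label permutations)", y = "count",
                  title = sprintf("Permutation test: p = %.4g (B = %d)",
                                  object$p_value, object$B)) +
    ggplot2::theme_minimal()
}

#' Render a human-readable markdown report of an rDCV analysis
#'
#' Summarizes, in one markdown document: retained and removed analytes
#' (when the dataset went through [filter_below_lod()]), the modal block
#' order and complexity, mean +/- SD class-wise rates and overall accuracy
#' (percentages to one decimal), the top-frequency analytes per block, and
#' the permutation p-value when supplied.
#'
#' @param summary An `rdcv_summary`.
#' @param path Output file path (markdown).
#' @param ds Optional `multiblock` dataset (for panel/filtering details).
#' @param permutation Optional `permutation_result`.
#' @param top_n Analytes listed per block.
#' @return Invisibly, `path`.
#' @export
report_rdcv <- function(summary, path, ds = NULL, permutation = NULL,
                        top_n = 5) {
  g <- glance(summary)
  pct <- function(m, s) sprintf("%.1f +/- %.1f%%", 100 * m, 100 * s)
  lines <- c(
    "# Multi-block biomarker discovery report", "",
    sprintf("- Outer models: %d (%d repetitions x %d outer groups)",
            summary$total_models, g$n_runs,
            summary$config$n_outer_groups),
    sprintf("- Overall accuracy: %s", pct(g$accuracy_mean, g$accuracy_sd)),
    sprintf("- Case rate: %s", pct(g$rate_case_mean, g$rate_case_sd)),
    sprintf("- Control rate: %s",
            pct(g$rate_control_mean, g$rate_control_sd)),
    sprintf("- Modal block order: %s", g$modal_order),
    sprintf("- Modal complexity: %s", g$modal_complexity))
  if (!is.null(permutation)) {
    lines <- c(lines, sprintf(
      "- Permutation test: p = %.4g (B = %d, observed %.3f)",
      permutation$p_value, permutation$B, permutation$observed))
  }
  if (!is.null(ds)) {
    rem <- ds$meta$removed_analytes %||% character(0)
    lines <- c(lines, "", "## Analyte panel",
               sprintf("- Retained: %d analytes (%s)",
                       sum(block_widths(ds)),
                       paste(sprintf("%s: %d", names(block_widths(ds)),
                                     block_widths(ds)), collapse = ", ")),
               sprintf("- Removed below detection limit: %d%s",
                       length(rem),
                       if (length(rem)) paste0(" (", paste(rem, collapse = ", "), ")")
                       else ""))
  }
  lines <- c(lines, "", "## Top selected analytes per block", "")
  fr <- tidy(summary)
  for (b in summary$block_names) {
    fb <- utils::head(fr[fr$block == b, ], top_n)
    lines <- c(lines, sprintf("### %s", b),
               if (nrow(fb) == 0L) "(no variable ever selected)" else
                 sprintf("- %s: %d/%d (%.1f%%)", fb$analyte, fb$count,
                         summary$total_models, 100 * fb$frequency),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Serialize an rDCV summary to JSON and CSV artifacts
#'
#' Writes three files under `dir`: `<prefix>_summary.json` (figures of
#' merit, modal order/complexity, total model count, configuration),
#' `<prefix>_models.csv` (one row per outer model: run, segment, chosen
#' order and complexity, selected analytes, semicolon-separated), and
#' `<prefix>_frequency.csv` (the selection-frequency table).
#'
#' @param summary An `rdcv_summary`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default `"rdcv"`).
#' @return Invisibly, the three file paths.
#' @export
write_rdcv <- function(summary, dir, prefix = "rdcv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_summary.json", "_models.csv",
                                           "_frequency.csv")))
  g <- glance(summary)
  jsonlite::write_json(
    list(figures_of_merit = as.list(g),
         total_models = summary$total_models,
         config = unclass(summary$config)),
    paths[1], auto_unbox = TRUE, digits = NA, null = "null")
  models <- dplyr::mutate(
    summary$models,
    selected = vapply(.data$selected,
                      function(s) paste(s$analyte, collapse = ";"), ""))
  readr::write_csv(models, paths[2], progress = FALSE)
  readr::write_csv(tidy(summary), paths[3], progress = FALSE)
  invisible(paths)
}

#' Capture a reproducibility manifest for a run
#'
#' Records everything needed to re-execute an analysis bit-identically:
#' the configuration, the seed ladder, package and R versions, input file
#' digests (MD5) when paths are given, and a timestamp.
#'
#' @param cfg An [rdcv_config()].
#' @param inputs Optional character vector of input file paths to digest.
#' @param path Optional path to also write the manifest as JSON.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(cfg, inputs = character(0), path = NULL) {
  man <- list(
    package = "socovsel",
    version = as.character(utils::packageVersion("socovsel")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(cfg),
    seed_ladder = list(
      base_seed = cfg$base_seed,
      run_seeds = cfg$base_seed + seq_len(cfg$n_repetitions) - 1L,
      permutation_seed_rule = "(base_seed + 104729 * b) mod 2147483647"),
    input_digests = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else list())
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  structure(man, class = "run_manifest")
}
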