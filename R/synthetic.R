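#' The three-block serum biomarker panel vocabulary
#'
#' The full 75-analyte panel assayed across three platforms: 37 amino acids
#' and derivatives (UPLC/MS), 31 inflammatory mediators (multiplex
#' immunoassay), and 7 mitochondrial-derived-vesicle (MDV) cargo proteins
#' (immunoblot). Greek letters are transliterated (e.g. `IL1-beta`).
#'
#' @param assayed If `TRUE` (default) return all 75 assayed analytes; if
#'   `FALSE`, only the 59 analytes quantifiable above the detection limit
#'   (see [lod_analytes()]).
#' @return A tibble with columns `analyte` and `block` (blocks
#'   `amino_acids`, `inflammation`, `mdv`, in that order).
#' @export
#' @examples
#' dplyr::count(serum_panel(), block)
serum_panel <- function(assayed = TRUE) {
  aa <- c("1-methylhistidine", "3-methylhistidine", "4-hydroxyproline",
          "alpha-aminobutyric acid", "beta-alanine",
          "beta-aminobutyric acid", "gamma-aminobutyric acid", "alanine",
          "aminoadipic acid", "anserine", "arginine", "asparagine",
          "aspartic acid", "carnosine", "citrulline", "cystathionine",
          "cystine", "ethanolamine", "glutamic acid", "glycine",
          "histidine", "isoleucine", "leucine", "lysine", "methionine",
          "ornithine", "phenylalanine", "phosphoethanolamine",
          "phosphoserine", "proline", "sarcosine", "serine", "taurine",
          "threonine", "tryptophan", "tyrosine", "valine")
  infl <- c("BDNF", "CRP", "IL1-beta", "IL1-ra", "IL2", "IL4", "IL5",
            "IL6", "IL7", "IL8", "IL9", "IL10", "IL12", "IL13", "IL15",
            "IL17", "FGF basic", "FGF21", "G-CSF", "GM-CSF", "IFN-gamma",
            "MCP-1", "MIP-1alpha", "MIP-1beta", "CCL5", "CCL11", "IP-10",
            "MPO", "PDGF-BB", "TNF-alpha", "VEGF")
  mdv <- c("ATP5A", "CD63", "MTCOI", "NDUFB8", "NDUFS3", "SDHB", "UQCRC2")
  pan <- tibble(
    analyte = c(aa, infl, mdv),
    block = rep(c("amino_acids", "inflammation", "mdv"),
                c(length(aa), length(infl), length(mdv))))
  if (!assayed) pan <- pan[!pan$analyte %in% lod_analytes(), ]
  pan
}

#' Analytes reported below the detection limit
#'
#' The 16 panel analytes whose serum concentrations fall below the assay
#' detection limit in the emulated study design (5 amino acids, 8
#' inflammatory mediators, 3 MDV proteins); dropping them from the
#' 75-analyte panel leaves 59 analytes in blocks of 32/23/4.
#'
#' @return Character vector of 16 analyte names.
#' @export
lod_analytes <- function() {
  c("anserine", "carnosine", "cystathionine", "gamma-aminobutyric acid",
    "phosphoserine",
    "IL2", "IL5", "IL7", "IL10", "IL13", "IL15", "G-CSF", "VEGF",
    "MTCOI", "NDUFB8", "UQCRC2")
}

# Default planted discriminant variables at the canonical panel widths:
# 2 amino acids, 2 inflammatory mediators, 1 MDV protein.
default_planted <- function() {
  list(amino_acids = c("phosphoethanolamine", "tryptophan"),
       inflammation = c("IL1-ra", "MIP-1beta"),
       mdv = "NDUFS3")
}

#' Configuration for the synthetic multi-block generator
#'
#' Defaults emulate the study design the package targets: 21 serum samples
#' (11 cases, 10 controls) over three blocks of 32/23/4 retained analytes
#' (or 37/31/7 assayed analytes with 5/8/3 fully censored when
#' `assayed = TRUE`), with a small planted discriminant subset of 2/2/1
#' variables, a shared latent factor inducing inter-block correlation, and
#' lognormal concentration marginals.
#'
#' @param n_case,n_control Samples per class (defaults 11 and 10).
#' @param block_widths Named integer vector of retained analytes per block.
#' @param n_informative Planted discriminant variables per block.
#' @param effect_size Standardized mean shift (in SD units, on the latent
#'   scale before any exponentiation) added to cases on planted variables.
#' @param redundancy Loading in `[0, 1)` of the shared latent factor: every
#'   variable is `redundancy * z + sqrt(1 - redundancy^2) * noise`, which
#'   induces correlation both within and between blocks.
#' @param family Marginal family: `"lognormal"` (concentrations; default)
#'   or `"gaussian"`.
#' @param assayed If `TRUE`, generate the full assayed panel (37/31/7) and
#'   mark the 16 below-LOD analytes as censored, so
#'   [filter_below_lod()] reproduces the 75 -> 59 reduction.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_case = 11, n_control = 10,
                             block_widths = c(amino_acids = 32,
                                              inflammation = 23, mdv = 4),
                             n_informative = c(2, 2, 1),
                             effect_size = 1.5, redundancy = 0.3,
                             family = c("lognormal", "gaussian"),
                             assayed = FALSE, seed = 1) {
  family <- match.arg(family)
  cfg <- list(n_case = as.integer(n_case),
              n_control = as.integer(n_control),
              block_widths = block_widths,
              n_informative = as.integer(n_informative),
              effect_size = effect_size, redundancy = redundancy,
              family = family, assayed = isTRUE(assayed),
              seed = as.integer(seed))
  if (cfg$n_case < 1L || cfg$n_control < 1L) {
    abort("invalid config: n_case and n_control must be at least 1")
  }
  if (length(cfg$n_informative) != length(cfg$block_widths)) {
    abort("invalid config: n_informative must have one entry per block")
  }
  if (any(cfg$n_informative > cfg$block_widths)) {
    abort("invalid config: n_informative exceeds block_widths")
  }
  if (cfg$effect_size < 0) abort("invalid config: effect_size must be >= 0")
  if (cfg$redundancy < 0 || cfg$redundancy >= 1) {
    abort("invalid config: redundancy must be in [0, 1)")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic multi-block dataset with known ground truth
#'
#' Each sample carries a standard-normal latent factor `z` shared across
#' blocks; every variable loads on it with weight `redundancy` plus
#' independent standard-normal noise, giving unit variance on the latent
#' scale. Planted variables add `effect_size` to cases. For the lognormal
#' family, latent values are placed on plausible per-block log-concentration
#' scales and exponentiated. With `assayed = TRUE`, the 16 designated
#' below-LOD analytes are fully censored in the returned dataset.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `dataset` (a `multiblock`) and `truth`
#'   (class `synthetic_truth`: planted analyte names per block, realized
#'   effect sizes, and the latent factor loading).
#' @export
#' @examples
#' sim <- simulate_panel(synthetic_config(seed = 42))
#' sim$dataset
#' sim$truth$planted
simulate_panel <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_case + cfg$n_control
    y <- c(rep(1L, cfg$n_case), rep(0L, cfg$n_control))
    ids <- sprintf("S%02d", seq_len(n))

    bw <- cfg$block_widths
    if (cfg$assayed) bw <- c(amino_acids = 37L, inflammation = 31L, mdv = 7L)
    bnames <- names(bw) %||% paste0("block", seq_along(bw))
    names(bw) <- bnames

    use_vocab <- identical(bnames, c("amino_acids", "inflammation", "mdv")) &&
      identical(unname(as.integer(bw)),
                if (cfg$assayed) c(37L, 31L, 7L) else c(32L, 23L, 4L))
    pan <- if (use_vocab) serum_panel(assayed = cfg$assayed) else {
      tibble(analyte = unlist(lapply(seq_along(bw), function(k) {
               sprintf("%s_v%02d", bnames[k], seq_len(bw[k]))
             })),
             block = rep(bnames, bw))
    }

    # planted discriminant variables, drawn among above-LOD analytes
    censored_names <- if (cfg$assayed) lod_analytes() else character(0)
    planted <- lapply(seq_along(bw), function(k) {
      cand <- setdiff(pan$analyte[pan$block == bnames[k]], censored_names)
      k_inf <- cfg$n_informative[k]
      if (k_inf == 0L) return(character(0))
      if (use_vocab && identical(cfg$n_informative, c(2L, 2L, 1L))) {
        default_planted()[[bnames[k]]]
      } else {
        sort(sample(cand, k_inf))
      }
    })
    names(planted) <- bnames

    # plausible per-block log-concentration placements (location, spread);
    # moderate log-scale spreads keep the standardized effect size the
    # dominant determinant of class separability after exponentiation
    scales <- list(amino_acids = c(log(50), 0.3),
                   inflammation = c(log(15), 0.4),
                   mdv = c(log(1.5), 0.3))
    z <- stats::rnorm(n)
    rho <- cfg$redundancy
    blocks <- list()
    for (k in seq_along(bw)) {
      b <- bnames[k]
      p <- bw[[k]]
      eps <- matrix(stats::rnorm(n * p), n, p)
      u <- rho * z + sqrt(1 - rho^2) * eps
      cols <- pan$analyte[pan$block == b]
      colnames(u) <- cols
      u[, colnames(u) %in% planted[[b]]] <-
        u[, colnames(u) %in% planted[[b]], drop = FALSE] +
        cfg$effect_size * y
      if (cfg$family == "lognormal") {
        sc <- scales[[b]] %||% c(log(10), 0.5)
        loc <- sc[1] + stats::runif(p, -0.5, 0.5)
        u <- exp(sweep(sweep(u, 2L, rep(sc[2], p), "*"), 2L, loc, "+"))
      }
      rownames(u) <- ids
      blocks[[b]] <- u
    }

    wide <- as.data.frame(do.call(cbind, blocks))
    names(wide) <- pan$analyte
    wide <- cbind(sample_id = ids, class = ifelse(y == 1L, "PF&S", "nonPF&S"),
                  wide)
    ds <- multiblock(wide, pan, label_col = "class",
                     case_label = "PF&S", control_label = "nonPF&S",
                     sample_col = "sample_id",
                     meta = list(generator = "socovsel::simulate_panel",
                                 seed = cfg$seed,
                                 effect_size = cfg$effect_size,
                                 redundancy = cfg$redundancy,
                                 family = cfg$family))
    if (cfg$assayed) ds <- censor_panel(ds, censored_names)
    truth <- structure(
      list(planted = planted,
           effect_size = setNames(rep(cfg$effect_size,
                                      length(unlist(planted))),
                                  unlist(planted)),
           loading = rho),
      class = "synthetic_truth")
    list(dataset = ds, truth = truth)
  })
}

#' Write a simulated dataset to disk (data CSV, panel CSV, truth JSON)
#'
#' @param sim The list returned by [simulate_panel()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default `"synthetic"`).
#' @return Invisibly, the three file paths.
#' @export
write_simulation <- function(sim, dir, prefix = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_data.csv", "_panel.csv",
                                           "_truth.json")))
  write_multiblock(sim$dataset, paths[1], paths[2])
  jsonlite::write_json(unclass(sim$truth), paths[3], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Fully censor designated analytes (below-detection-limit emulation)
#'
#' Marks every cell of the named analytes as below the detection limit, so
#' that [filter_below_lod()] removes them. With the default assayed panel
#' and [lod_analytes()], this reproduces the 75 -> 59 analyte reduction.
#'
#' @param ds A `multiblock` object.
#' @param censor Character vector of analyte names to censor fully; empty
#'   leaves the dataset unchanged.
#' @return The dataset with those analytes flagged censored (values `NA`).
#' @export
censor_panel <- function(ds, censor = lod_analytes()) {
  absent <- setdiff(censor, ds$panel$analyte)
  if (length(absent)) {
    abort(paste0("censor list names analyte(s) absent from the panel: ",
                 paste(sQuote(absent), collapse = ", ")))
  }
  for (b in names(ds$blocks)) {
    hit <- colnames(ds$blocks[[b]]) %in% censor
    ds$blocks[[b]][, hit] <- NA_real_
    ds$censored[[b]][, hit] <- TRUE
  }
  ds
}
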