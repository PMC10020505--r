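# Orchestration: config -> per-regime mixed models -> correlations -> MGIDI
# -> gains -> cross-regime overlap, with CSV/JSON/markdown rendering.

fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

parse_traits_config <- function(tr) {
  if (inherits(tr, "trait_spec")) return(tr)
  if (is.null(tr)) return(maize_trait_spec())
  if (is.list(tr) && !is.data.frame(tr))
    return(trait_spec(names(tr), unlist(tr)))
  if (is.data.frame(tr)) return(trait_spec(tr$name, tr$direction))
  stop("cannot interpret trait configuration", call. = FALSE)
}

#' Assemble a pipeline configuration
#'
#' A validated, fully serializable description of one analysis run: where the
#' phenotypes come from, the trait directions, which regimes to analyze, the
#' selection intensity and model options.  A run is reproducible from the
#' configuration alone (the analysis path holds no randomness).
#'
#' @param phenotypes path to a long-format phenotype CSV/TSV (see
#'   [read_met_table()]); ignored when `data` is supplied.
#' @param data optionally, a `met_dataset` already in memory.
#' @param traits trait directions: a [trait_spec()], a named list
#'   (`trait: direction`), or `NULL` for the maize defaults.
#' @param regimes regimes to analyze (default: all present).
#' @param intensity selection intensity (default 0.15).
#' @param n_factors optional factor-count override.
#' @param lrt compute likelihood-ratio tests (default `TRUE`).
#' @param boundary_lrt use the boundary chi-square mixture p-value.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(phenotypes = NULL, data = NULL, traits = NULL,
                            regimes = NULL, intensity = 0.15,
                            n_factors = NULL, lrt = TRUE,
                            boundary_lrt = FALSE) {
  if (is.null(phenotypes) && is.null(data))
    stop("either phenotypes path or data must be given", call. = FALSE)
  structure(list(phenotypes = phenotypes, data = data,
                 traits = parse_traits_config(traits), regimes = regimes,
                 intensity = intensity, n_factors = n_factors, lrt = lrt,
                 boundary_lrt = boundary_lrt),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]: `phenotypes`, `traits`
#' (mapping trait name to `increase`/`decrease`), `regimes`, `intensity`,
#' `n_factors`, `lrt`, `boundary_lrt`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pipeline_config(phenotypes = cfg$phenotypes, traits = cfg$traits,
                  regimes = cfg$regimes,
                  intensity = if (is.null(cfg$intensity)) 0.15 else cfg$intensity,
                  n_factors = cfg$n_factors,
                  lrt = !isFALSE(cfg$lrt),
                  boundary_lrt = isTRUE(cfg$boundary_lrt))
}

#' Run the full per-regime selection pipeline
#'
#' For each requested soil-moisture regime: subset the data, fit the mixed
#' model per trait ([met_gamem()]), collect genetic parameters and LRTs,
#' build the BLUP table, compute genetic correlations, run the MGIDI chain
#' and the selection-gain table; finally intersect the selections across
#' regimes.  The analysis path is deterministic given the configuration and
#' data.
#'
#' @param config a `pipeline_config` (or a YAML path).
#' @param quiet suppress per-stage progress messages.
#' @return Object of class `run_report`: per-regime tables (`parameters`,
#'   `lrt`, `factors`, `loadings`, `index`, `gains`, `correlations`),
#'   `overlap` (for >= 2 regimes), `version` and `config_hash`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  ds <- if (!is.null(config$data)) config$data
        else read_met_table(config$phenotypes, config$traits)
  regimes <- config$regimes
  if (is.null(regimes)) regimes <- regimes_present(ds)
  sections <- list()
  selections <- list()
  for (rg in regimes) {
    t0 <- Sys.time()
    say("regime ", rg, ": fitting mixed models")
    sub <- subset_regime(ds, rg)
    fit <- met_gamem(sub, lrt = config$lrt)
    bl <- blup_table(fit)
    say("regime ", rg, ": correlations and MGIDI")
    cm <- genetic_correlations(bl)
    sel <- mgidi(bl, intensity = config$intensity,
                 n_factors = config$n_factors)
    fm <- sel$factor_model
    sections[[rg]] <- list(
      parameters = fit$parameters,
      lrt = fit$lrt,
      factors = fm$variance[seq_len(fm$f), , drop = FALSE],
      loadings = as.data.frame(fm$loadings),
      index = sel$index,
      gains = sel$gains,
      correlations = as.data.frame(unclass(cm)),
      omega = as.data.frame(sel$omega[sel$selected, , drop = FALSE]),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    selections[[rg]] <- sel$selected
    nc <- vapply(fit$fits, `[[`, TRUE, "converged")
    if (!all(nc))
      warning("regime ", rg, ": non-converged trait(s): ",
              paste(names(nc)[!nc], collapse = ", "))
  }
  overlap <- if (length(selections) >= 2) cross_regime_overlap(selections)
             else NULL
  cfg_ser <- config[setdiff(names(config), "data")]
  out <- list(regimes = sections, overlap = overlap,
              version = as.character(utils::packageVersion("metsel")),
              config = config, config_hash = fnv1a(cfg_ser))
  class(out) <- "run_report"
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("MET selection pipeline report (metsel ", x$version, ")\n", sep = "")
  for (rg in names(x$regimes)) {
    s <- x$regimes[[rg]]
    cat(sprintf("  %-12s: %d traits, %d factor(s), %d selected (%.1fs)\n",
                rg, nrow(s$parameters), nrow(s$factors),
                sum(s$index$selected), s$seconds))
  }
  if (!is.null(x$overlap))
    cat("  common across regimes:",
        if (x$overlap$n_common) paste(x$overlap$common, collapse = ", ")
        else "(none)", "\n")
  invisible(x)
}

report_tables <- function(rr) {
  out <- list()
  for (rg in names(rr$regimes)) {
    s <- rr$regimes[[rg]]
    for (tb in c("parameters", "lrt", "factors", "loadings", "index",
                 "gains", "correlations", "omega")) {
      if (!is.null(s[[tb]]))
        out[[paste(rg, tb, sep = "_")]] <- s[[tb]]
    }
  }
  if (!is.null(rr$overlap)) out$overlap_pairwise <- rr$overlap$pairwise
  out
}

md_table <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "f"))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                          " |"))
  c(hdr, sep, body)
}

#' Render a pipeline report to files
#'
#' `"csv"` writes one CSV per table; `"json"` writes a single JSON document;
#' `"markdown"` writes one page with the tables laid out for visual diffing
#' (gains tables carry the columns Trait, Factor, Sense, Goal, Xo, Xs, SD,
#' SD% in that order).  All formats carry identical numbers.
#'
#' @param rr a `run_report`.
#' @param fmt `"csv"`, `"json"` or `"markdown"`.
#' @param dir output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(rr, fmt = c("csv", "json", "markdown"),
                          dir = ".") {
  stopifnot(inherits(rr, "run_report"))
  fmt <- match.arg(fmt)
  empty_sel <- vapply(rr$regimes, function(s) !any(s$index$selected), TRUE)
  if (any(empty_sel))
    stop("report contains an empty selection for regime(s): ",
         paste(names(rr$regimes)[empty_sel], collapse = ", "), call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- report_tables(rr)
  files <- character(0)
  if (fmt == "csv") {
    for (nm in names(tabs)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(tabs[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
  } else if (fmt == "json") {
    f <- file.path(dir, "report.json")
    jsonlite::write_json(c(tabs, list(version = rr$version,
                                      config_hash = rr$config_hash)),
                         f, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
    files <- f
  } else {
    lines <- c("# MET selection report", "",
               paste0("version ", rr$version, ", config ", rr$config_hash),
               "")
    for (rg in names(rr$regimes)) {
      s <- rr$regimes[[rg]]
      lines <- c(lines, paste0("## ", rg), "")
      gains <- s$gains
      names(gains) <- c("Trait", "Factor", "Sense", "Goal", "Xo", "Xs",
                        "SD", "SD%")
      lines <- c(lines, "### Genetic parameters", "",
                 md_table(s$parameters), "",
                 "### Factors", "", md_table(s$factors), "",
                 "### Selection gains", "", md_table(gains), "")
    }
    if (!is.null(rr$overlap))
      lines <- c(lines, "## Overlap", "", md_table(rr$overlap$pairwise), "")
    f <- file.path(dir, "report.md")
    writeLines(lines, f)
    files <- f
  }
  invisible(files)
}

#' Transcribed summary tables from a published maize moisture-regime study
#'
#' Summary tables transcribed from a published multi-environment evaluation
#' of 75 tropical maize hybrids under optimal, managed-drought and
#' managed-waterlogging regimes, shipped as plain-text CSV for arithmetic
#' cross-checks of the index chain (the underlying plot data are not public).
#'
#' @param which one of `"mgidi"` (per-hybrid index values per regime),
#'   `"gains"` (selection-gain table: factor, sense, population and
#'   selected-set means), `"factors"` (eigenvalues and explained variance of
#'   the retained factors), `"parameters"` (genotypic-mean heritability and
#'   selection accuracy per trait and regime).
#' @return Data frame.
#' @export
published_trial_table <- function(which = c("mgidi", "gains", "factors",
                                            "parameters")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("maize_trial_", which, "_reported.csv"),
                   package = "metsel", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
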