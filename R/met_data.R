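#' @keywords internal
"_PACKAGE"

REGIMES <- c("optimal", "drought", "waterlogging")

#' Trait specifications
#'
#' A trait specification names each analyzed trait and states the direction of
#' desirable change: `"increase"` (e.g. grain yield) or `"decrease"` (e.g. the
#' anthesis-silking interval).  The direction drives the 0-100 rescaling that
#' defines the ideotype, and the sign convention of selection gains.
#'
#' @param name character vector of unique trait names.
#' @param direction `"increase"` or `"decrease"`, recycled to `length(name)`.
#' @param units optional free-text units, recycled.
#' @return A data frame of class `trait_spec` with columns `name`, `direction`
#'   and `units`.
#' @examples
#' trait_spec(c("GY", "ASI"), c("increase", "decrease"), c("t/ha", "days"))
#' @export
trait_spec <- function(name, direction = "increase", units = "") {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("trait names must be unique", call. = FALSE)
  direction <- match.arg(rep_len(as.character(direction), length(name)),
                         c("increase", "decrease"), several.ok = TRUE)
  direction <- rep_len(direction, length(name))
  out <- data.frame(name = name, direction = direction,
                    units = rep_len(as.character(units), length(name)),
                    stringsAsFactors = FALSE)
  class(out) <- c("trait_spec", "data.frame")
  out
}

#' Default trait specifications for the tropical maize hybrid panel
#'
#' The twelve agronomic traits routinely scored in tropical maize
#' moisture-stress screening: three phenology traits for which negative gains
#' are desired (days to 50% anthesis `D50A`, days to 50% silking `D50S`,
#' anthesis-silking interval `ASI`) and nine for which positive gains are
#' desired (plant height `PH`, ear height `EH`, chlorophyll `SPAD`, test
#' weight `TW`, ear length `EL`, ear girth `EG`, kernel rows per ear `KRE`,
#' kernels per row `KNR`, grain yield `GY`).
#'
#' @return A [trait_spec()] data frame with 12 rows.
#' @export
maize_trait_spec <- function() {
  trait_spec(
    name = c("D50A", "D50S", "ASI", "PH", "EH", "SPAD",
             "TW", "EL", "EG", "KRE", "KNR", "GY"),
    direction = c("decrease", "decrease", "decrease", "increase", "increase",
                  "increase", "increase", "increase", "increase", "increase",
                  "increase", "increase"),
    units = c("days", "days", "days", "cm", "cm", "SPAD units",
              "g", "cm", "cm", "count", "count", "t/ha")
  )
}

trait_names <- function(traits) {
  if (inherits(traits, "trait_spec") || is.data.frame(traits)) traits$name
  else as.character(traits)
}

#' Construct and validate a multi-environment trial dataset
#'
#' Bundles long-format plot records with trait specifications and design
#' metadata.  Each record is one plot: a genotype grown in one replicate
#' (complete block) of one environment, inside an incomplete block, with one
#' plot-mean value per trait (missing values allowed).
#'
#' @param data data frame with columns `genotype`, `environment`, `regime`,
#'   `replicate`, `block`, plus one numeric column per trait.
#' @param traits a [trait_spec()] (or character vector of trait names, taken
#'   as increase-direction).
#' @return An object of class `met_dataset`: the validated data frame plus the
#'   trait table, with `e` (number of environments) and `b` (replicates per
#'   environment) derivable via [design_dims()].
#' @details Validation enforces: unique `(genotype, environment, replicate,
#'   block)` plot keys per genotype within replicate (a genotype may appear
#'   once per replicate of an environment), every environment mapped to
#'   exactly one soil-moisture regime, and all configured trait columns
#'   present and numeric.
#' @seealso [read_met_table()], [subset_regime()], [simulate_met()]
#' @export
met_dataset <- function(data, traits) {
  if (is.character(traits)) traits <- trait_spec(traits)
  stopifnot(is.data.frame(data))
  keys <- c("genotype", "environment", "regime", "replicate", "block")
  miss <- setdiff(keys, names(data))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(traits$name, names(data))
  if (length(absent))
    stop("trait column(s) absent from data: ", paste(absent, collapse = ", "),
         call. = FALSE)
  data$genotype    <- as.character(data$genotype)
  data$environment <- as.character(data$environment)
  data$regime      <- as.character(data$regime)
  bad <- setdiff(unique(data$regime), REGIMES)
  if (length(bad))
    stop("unknown regime(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(REGIMES, collapse = ", "), call. = FALSE)
  data$replicate <- as.integer(data$replicate)
  if (any(data$replicate < 1L)) stop("replicate must be >= 1", call. = FALSE)
  data$block <- as.character(data$block)
  for (tr in traits$name) data[[tr]] <- as.numeric(data[[tr]])

  key <- paste(data$genotype, data$environment, data$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (genotype, environment, replicate) record: ",
         gsub("\r", " / ", d), call. = FALSE)
  }
  er <- unique(data[, c("environment", "regime")])
  if (anyDuplicated(er$environment))
    stop("environment mapped to more than one regime: ",
         paste(er$environment[duplicated(er$environment)], collapse = ", "),
         call. = FALSE)

  out <- list(data = data[, c(keys, traits$name)], traits = traits)
  class(out) <- "met_dataset"
  out
}

#' Design dimensions of a MET dataset
#'
#' @param ds a `met_dataset`.
#' @return list with `e` (number of environments), `b` (median replicate count
#'   per environment), `g` (number of genotypes), `n` (number of plot records).
#' @export
design_dims <- function(ds) {
  stopifnot(inherits(ds, "met_dataset"))
  d <- ds$data
  reps <- tapply(d$replicate, d$environment, function(r) length(unique(r)))
  list(e = length(unique(d$environment)),
       b = as.integer(stats::median(reps)),
       g = length(unique(d$genotype)),
       n = nrow(d))
}

#' @export
print.met_dataset <- function(x, ...) {
  dm <- design_dims(x)
  cat("Multi-environment trial dataset\n")
  cat(sprintf("  %d plots: %d genotypes x %d environment(s), %d replicate(s)/env\n",
              dm$n, dm$g, dm$e, dm$b))
  er <- unique(x$data[, c("environment", "regime")])
  for (rg in unique(er$regime))
    cat(sprintf("  %-12s: %s\n", rg,
                paste(sort(er$environment[er$regime == rg]), collapse = ", ")))
  cat("  traits:", paste(x$traits$name, collapse = ", "), "\n")
  invisible(x)
}

#' Read a long-format MET phenotype table
#'
#' Reads a CSV or TSV file (header row, `.` decimal separator) with columns
#' `genotype`, `environment`, `regime`, `replicate`, `block` and one column
#' per configured trait, and returns a validated [met_dataset()].  Missing
#' cells (empty or `NA`) are preserved as missing.
#'
#' @param path file path; tab-separated if the extension is `.tsv`, otherwise
#'   comma-separated.
#' @param traits a [trait_spec()] naming the trait columns to keep.
#' @return A `met_dataset`.
#' @export
read_met_table <- function(path, traits) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), check.names = FALSE)
  met_dataset(df, traits)
}

#' Write a MET dataset back to CSV/TSV
#'
#' Inverse of [read_met_table()]: a write-then-read round trip reproduces the
#' dataset exactly.
#'
#' @param ds a `met_dataset`.
#' @param path output path; `.tsv` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_met_table <- function(ds, path) {
  stopifnot(inherits(ds, "met_dataset"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  out <- ds$data
  # 17 significant digits: doubles survive the text round trip exactly
  for (tr in ds$traits$name)
    out[[tr]] <- ifelse(is.na(out[[tr]]), NA,
                        sprintf("%.17g", out[[tr]]))
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Subset a MET dataset to one soil-moisture regime
#'
#' Each regime is analyzed on its own: the subset keeps only environments of
#' that regime and recomputes the design dimensions.
#'
#' @param ds a `met_dataset`.
#' @param regime `"optimal"`, `"drought"` or `"waterlogging"`.
#' @return A `met_dataset` containing only the requested regime.
#' @export
subset_regime <- function(ds, regime) {
  stopifnot(inherits(ds, "met_dataset"))
  regime <- match.arg(regime, REGIMES)
  keep <- ds$data$regime == regime
  if (!any(keep))
    stop("no environments with regime '", regime, "' in dataset",
         call. = FALSE)
  met_dataset(ds$data[keep, , drop = FALSE], ds$traits)
}

#' Regimes present in a dataset
#' @param ds a `met_dataset`.
#' @return character vector of regimes, in canonical order.
#' @export
regimes_present <- function(ds) {
  intersect(REGIMES, unique(ds$data$regime))
}
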