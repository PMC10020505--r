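#' Genetic correlations among traits
#'
#' Pearson correlations between genotype predicted means (BLUP-based by
#' default) for every trait pair within a regime.  Correlating BLUP-based
#' genotype means removes replicate and environment noise, which is the
#' conventional "genetic correlation" of the mixed-model trial analysis
#' stack; raw genotype means are available via `method = "raw"` together with
#' a `met_dataset`.
#'
#' @param x a [blup_table()] (or any genotypes-by-traits numeric matrix).
#' @param ds optional `met_dataset`, required for `method = "raw"`.
#' @param method `"blup"` (default) correlates the supplied predicted means;
#'   `"raw"` correlates raw across-plot genotype means from `ds`.
#' @return A symmetric correlation matrix of class `genetic_correlation`
#'   (unit diagonal, entries in \[-1, 1\]); pairs involving a constant trait
#'   are reported as `NA` with a warning.
#' @export
genetic_correlations <- function(x, ds = NULL, method = c("blup", "raw")) {
  method <- match.arg(method)
  if (method == "raw") {
    stopifnot(inherits(ds, "met_dataset"))
    x <- sapply(ds$traits$name, function(tr)
      tapply(ds$data[[tr]], ds$data$genotype, mean, na.rm = TRUE))
  }
  m <- as.matrix(unclass(x))
  if (nrow(m) < 3) stop("need at least 3 genotypes", call. = FALSE)
  if (ncol(m) < 2) stop("need at least 2 traits", call. = FALSE)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  if (any(sds == 0, na.rm = TRUE)) {
    cst <- colnames(m)[sds == 0]
    warning("constant trait column(s), correlations undefined: ",
            paste(cst, collapse = ", "))
    r[cst, ] <- NA; r[, cst] <- NA
  }
  diag(r) <- 1
  class(r) <- c("genetic_correlation", "matrix", "array")
  r
}

#' Cluster traits by correlation proximity
#'
#' Hierarchical clustering of traits on the dissimilarity \eqn{1 - |r|}
#' (average linkage): traits that are strongly associated, positively or
#' negatively, end up in the same group.  This is the tabular counterpart of
#' a correlation network plot.
#'
#' @param cm a `genetic_correlation` matrix.
#' @param h cut height in \[0, 1\] for the flat grouping (default 0.5, i.e.
#'   groups linked at average \eqn{|r| > 0.5}).
#' @return List with `order` (leaf order of the dendrogram), `groups` (named
#'   integer vector of group memberships) and `hclust` (the tree).  Missing
#'   correlations fall back to pairwise-complete distances with a warning.
#' @export
correlation_clusters <- function(cm, h = 0.5) {
  m <- as.matrix(unclass(cm))
  if (anyNA(m)) {
    warning("missing correlations; using maximal dissimilarity for NA pairs")
    m[is.na(m)] <- 0
  }
  d <- stats::as.dist(1 - abs(m))
  hc <- stats::hclust(d, method = "average")
  groups <- stats::cutree(hc, h = h)
  list(order = colnames(m)[hc$order], groups = groups, hclust = hc)
}

#' Edge list of a correlation matrix
#'
#' @param cm a `genetic_correlation` matrix.
#' @return Data frame `trait_a`, `trait_b`, `r` (upper triangle), for
#'   external network drawing.
#' @export
correlation_edges <- function(cm) {
  m <- as.matrix(unclass(cm))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  data.frame(trait_a = rownames(m)[ut[, 1]], trait_b = colnames(m)[ut[, 2]],
             r = m[ut], stringsAsFactors = FALSE)
}
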