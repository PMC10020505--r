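# The MGIDI chain: 0-100 rescaling -> exploratory factor analysis with
# varimax rotation -> factor scores for genotypes and ideotype -> Euclidean
# genotype-ideotype distance -> selection, per-factor strengths/weaknesses,
# and selection gains.

#' Rescale a genotype-by-trait table to the 0-100 ideotype scale
#'
#' Linear per-trait rescaling
#' \deqn{rX_{ij} = \frac{\eta_{nj}-\varphi_{nj}}{\eta_{0j}-\varphi_{0j}}
#'   (\theta_{ij}-\eta_{0j}) + \eta_{nj}}
#' with original extrema \eqn{\eta_{0j}} (max) and \eqn{\varphi_{0j}} (min).
#' For increase-direction traits the new extrema are
#' \eqn{\eta_{nj}=100,\ \varphi_{nj}=0} (the trait maximum maps to 100); for
#' decrease-direction traits \eqn{\eta_{nj}=0,\ \varphi_{nj}=100} (the trait
#' minimum maps to 100).  After rescaling, 100 is always the desirable
#' extreme, the ideotype scores 100 on every trait, and absolute pairwise
#' trait correlations are unchanged (the map is affine).
#'
#' @param blups a [blup_table()] or genotypes-by-traits numeric matrix.
#' @param traits a [trait_spec()]; defaults to the `traits` attribute of
#'   `blups`.
#' @return Object of class `rescaled_table`: `rx` (matrix in \[0, 100\]),
#'   `extrema` (per-trait original min/max), `traits`.
#' @export
rescale_traits <- function(blups, traits = attr(blups, "traits")) {
  m <- as.matrix(unclass(blups))
  if (is.null(traits))
    stop("trait directions required (pass a trait_spec)", call. = FALSE)
  if (is.character(traits)) traits <- trait_spec(traits)
  m <- m[, traits$name, drop = FALSE]
  rx <- m
  for (j in seq_len(ncol(m))) {
    hi <- max(m[, j], na.rm = TRUE); lo <- min(m[, j], na.rm = TRUE)
    if (hi == lo)
      stop("constant trait cannot be rescaled: ", colnames(m)[j],
           call. = FALSE)
    if (traits$direction[j] == "increase") {
      eta_n <- 100; phi_n <- 0
    } else {
      eta_n <- 0; phi_n <- 100
    }
    rx[, j] <- (eta_n - phi_n) / (hi - lo) * (m[, j] - hi) + eta_n
  }
  structure(list(rx = rx,
                 extrema = data.frame(trait = colnames(m),
                                      min = apply(m, 2, min, na.rm = TRUE),
                                      max = apply(m, 2, max, na.rm = TRUE),
                                      direction = traits$direction,
                                      row.names = NULL,
                                      stringsAsFactors = FALSE),
                 traits = traits),
            class = "rescaled_table")
}

#' Explained-variance summary of factor eigenvalues
#'
#' For eigenvalues of a p-trait correlation matrix, the per-factor explained
#' variance is \eqn{100\lambda/p} and the cumulative column its running sum.
#'
#' @param eigenvalues numeric vector of eigenvalues (all of them, or only the
#'   retained ones).
#' @param p number of traits (default `length(eigenvalues)`).
#' @return Data frame `factor`, `eigenvalue`, `variance_pct`,
#'   `cumulative_pct`.
#' @export
factor_variance_summary <- function(eigenvalues, p = length(eigenvalues)) {
  v <- 100 * eigenvalues / p
  data.frame(factor = paste0("FA", seq_along(eigenvalues)),
             eigenvalue = eigenvalues, variance_pct = v,
             cumulative_pct = cumsum(v), stringsAsFactors = FALSE)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the varimax criterion, with Kaiser row
#' normalization (delegated to [stats::varimax()]).  A single-factor loading
#' matrix is returned unchanged with an identity rotation.  Rotation
#' preserves per-trait communalities.
#'
#' @param loadings numeric p-by-f matrix of initial loadings.
#' @param eps convergence tolerance of the rotation sweeps.
#' @return List with `loadings` (rotated) and `rotation` (f-by-f orthogonal
#'   matrix).
#' @export
varimax_rotate <- function(loadings, eps = 1e-10) {
  loadings <- as.matrix(loadings)
  f <- ncol(loadings)
  if (f < 1) stop("need at least one factor", call. = FALSE)
  if (f == 1)
    return(list(loadings = loadings, rotation = diag(1)))
  vr <- stats::varimax(loadings, normalize = TRUE, eps = eps)
  A <- unclass(vr$loadings)
  dimnames(A) <- dimnames(loadings)
  list(loadings = A, rotation = vr$rotmat)
}

# varimax criterion: variance of squared loadings, summed over factors
varimax_criterion <- function(A) {
  A2 <- A^2
  sum(apply(A2, 2, function(x) mean((x - mean(x))^2)))
}

#' Exploratory factor analysis of a rescaled trait table
#'
#' Principal-component extraction from the correlation matrix `R` of the
#' rescaled values: eigenvalues determine the retained factor count
#' `f = #\{lambda > 1\}` (Kaiser rule, overridable), initial loadings are
#' eigenvectors scaled by the square roots of their eigenvalues, and final
#' loadings come from varimax rotation.  Each rotated column is flipped so
#' its largest-magnitude loading is negative — a pure sign convention the
#' downstream index is invariant to.
#'
#' @param rt a [rescale_traits()] result (or genotypes-by-traits matrix).
#' @param n_factors optional override of the Kaiser retention rule; required
#'   when no eigenvalue exceeds 1.
#' @param ridge ridge added to `R` if it is numerically singular.
#' @return Object of class `factor_model`: `R`, `eigenvalues`,
#'   `variance` (full [factor_variance_summary()]), `f`, `initial_loadings`,
#'   `loadings` (rotated), `rotation`, `communalities`,
#'   `assignment` (trait -> factor with the largest absolute loading).
#' @export
fit_efa <- function(rt, n_factors = NULL, ridge = 1e-8) {
  rx <- if (inherits(rt, "rescaled_table")) rt$rx else as.matrix(rt)
  p <- ncol(rx)
  R <- stats::cor(rx)
  ev <- eigen(R, symmetric = TRUE)
  lambda <- ev$values
  f <- if (is.null(n_factors)) sum(lambda > 1) else as.integer(n_factors)
  if (f < 1)
    stop("no eigenvalue exceeds 1; pass n_factors to force retention",
         call. = FALSE)
  A0 <- ev$vectors[, seq_len(f), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(f)]), f)
  dimnames(A0) <- list(colnames(rx), paste0("FA", seq_len(f)))
  rot <- varimax_rotate(A0)
  A <- rot$loadings
  flip <- vapply(seq_len(f), function(j) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] > 0) -1 else 1
  }, 0)
  A <- sweep(A, 2, flip, "*")
  rotation <- sweep(rot$rotation, 2, flip, "*")
  if (qr(R)$rank < p) {
    warning("correlation matrix is singular; applying ridge ", ridge)
    R <- R + diag(ridge, p)
  }
  structure(list(R = R, eigenvalues = lambda,
                 variance = factor_variance_summary(lambda, p), f = f,
                 initial_loadings = A0, loadings = A, rotation = rotation,
                 communalities = rowSums(A^2),
                 assignment = apply(abs(A), 1, which.max)),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, digits = 3, ...) {
  cat(sprintf("Exploratory factor model: %d trait(s), %d factor(s) retained\n",
              nrow(x$loadings), x$f))
  v <- x$variance[seq_len(x$f), ]
  cat(sprintf("  retained variance: %s (cumulative %.2f%%)\n",
              paste(sprintf("%.2f%%", v$variance_pct), collapse = " + "),
              v$cumulative_pct[x$f]))
  print(round(x$loadings, digits))
  invisible(x)
}

#' Factor scores of genotypes and of the ideotype
#'
#' Standardizes the rescaled table column-wise (sample standard deviation,
#' n - 1) into `Z` and scores genotypes as \eqn{F = Z R^{-1} A}.  The
#' ideotype — 100 for every trait on the rescaled scale — is standardized by
#' the same column means and SDs and scored with the same weights.
#'
#' @param rt a [rescale_traits()] result.
#' @param fm a [fit_efa()] factor model.
#' @param ridge ridge added to `R` if the solve fails.
#' @return Object of class `score_table`: `Z`, `scores` (g-by-f),
#'   `ideotype_scores` (length f), `weights` (the p-by-f matrix
#'   \eqn{R^{-1}A}).
#' @export
factor_scores <- function(rt, fm, ridge = 1e-8) {
  stopifnot(inherits(fm, "factor_model"))
  rx <- if (inherits(rt, "rescaled_table")) rt$rx else as.matrix(rt)
  mu <- colMeans(rx)
  sdv <- apply(rx, 2, stats::sd)
  if (any(sdv == 0))
    stop("constant rescaled column; cannot standardize", call. = FALSE)
  Z <- sweep(sweep(rx, 2, mu), 2, sdv, "/")
  B <- tryCatch(solve(fm$R, fm$loadings), error = function(e) {
    warning("singular correlation matrix; applying ridge ", ridge)
    solve(fm$R + diag(ridge, nrow(fm$R)), fm$loadings)
  })
  Fsc <- Z %*% B
  z_id <- (100 - mu) / sdv
  gamma <- drop(z_id %*% B)
  structure(list(Z = Z, scores = Fsc, ideotype_scores = gamma, weights = B),
            class = "score_table")
}

#' Euclidean genotype-ideotype distance in factor-score space
#'
#' \deqn{MGIDI_i = \left[\sum_{j=1}^f (\gamma_{ij} - \gamma_j)^2\right]^{0.5}}
#' where \eqn{\gamma_{ij}} is genotype i's score on factor j and
#' \eqn{\gamma_j} the ideotype score.  Lower values are closer to the
#' ideotype.
#'
#' @param scores g-by-f matrix of genotype factor scores (or a
#'   [factor_scores()] result).
#' @param ideotype_scores length-f ideotype score vector (taken from `scores`
#'   when it is a `score_table`).
#' @return Named numeric vector of distances.
#' @export
ideotype_distance <- function(scores, ideotype_scores = NULL) {
  if (inherits(scores, "score_table")) {
    ideotype_scores <- scores$ideotype_scores
    scores <- scores$scores
  }
  scores <- as.matrix(scores)
  stopifnot(length(ideotype_scores) == ncol(scores))
  d <- sweep(scores, 2, ideotype_scores)
  sqrt(rowSums(d^2))
}

#' Select genotypes closest to the ideotype
#'
#' Selects the `round(g * intensity)` genotypes with the lowest index values
#' (`round` is R's round-half-to-even, so 75 genotypes at 15% intensity give
#' 11).  Ties across the cut point are broken by input order with a warning.
#'
#' @param values named numeric vector of MGIDI values (lower = better).
#' @param intensity selection intensity, a fraction in (0, 1); default 0.15.
#' @return Character vector of selected genotype identifiers, in ascending
#'   index order.
#' @export
select_genotypes <- function(values, intensity = 0.15) {
  stopifnot(is.numeric(values), intensity > 0, intensity < 1)
  g <- length(values)
  n <- round(g * intensity)
  if (n < 1) stop("selection intensity yields an empty selection",
                  call. = FALSE)
  ord <- order(values)  # stable: ties keep input order
  sel <- ord[seq_len(n)]
  if (n < g && values[ord[n]] == values[ord[n + 1]])
    warning("tie at the selection cut point; broken by input order")
  nm <- names(values)
  if (is.null(nm)) nm <- as.character(seq_len(g))
  nm[sel]
}

#' Per-factor strengths and weaknesses
#'
#' The share of a genotype's squared ideotype distance carried by each
#' factor: \eqn{\omega_{ij} = D_{ij}^2 / \sum_j D_{ij}^2} with
#' \eqn{D_{ij} = |\gamma_{ij} - \gamma_j|}.  Rows sum to one; a low
#' \eqn{\omega} marks a strength (the traits in that factor sit close to the
#' ideotype).  A genotype exactly at the ideotype has undefined shares and is
#' reported as uniform `1/f` with attribute `undefined`.
#'
#' @param st a [factor_scores()] result (or g-by-f score matrix).
#' @param ideotype_scores ideotype score vector when `st` is a plain matrix.
#' @return g-by-f matrix of shares.
#' @export
strengths_weaknesses <- function(st, ideotype_scores = NULL) {
  if (inherits(st, "score_table")) {
    ideotype_scores <- st$ideotype_scores
    scores <- st$scores
  } else scores <- as.matrix(st)
  D2 <- sweep(scores, 2, ideotype_scores)^2
  tot <- rowSums(D2)
  zero <- tot == 0
  omega <- D2 / ifelse(tot == 0, 1, tot)
  if (any(zero)) omega[zero, ] <- 1 / ncol(scores)
  attr(omega, "undefined") <- rownames(scores)[zero]
  omega
}

#' Selection differential
#'
#' Absolute and percent change of a trait mean in the selected set relative
#' to the full population: `sd = xs - xo`,
#' \eqn{\Delta S\% = 100 (X_S - X_0)/X_0}.
#'
#' @param xs mean of the selected genotypes.
#' @param xo mean of the full population.
#' @return List with `sd` and `sd_pct`.
#' @export
selection_differential <- function(xs, xo) {
  list(sd = xs - xo, sd_pct = 100 * (xs - xo) / xo)
}

#' Selection-gain table
#'
#' Per trait: population mean `xo`, selected-set mean `xs`, selection
#' differential `sd` and percent differential `sd_pct`, the factor holding
#' the trait (largest absolute rotated loading, ties to the lower factor
#' index), the desired sense, and whether the realized gain agrees with it.
#' Means are computed on the same BLUP-based two-way table that feeds the
#' index.
#'
#' @param blups a [blup_table()] (or genotypes-by-traits matrix).
#' @param selected character vector of selected genotype ids.
#' @param fm the [fit_efa()] factor model (for factor assignment); optional.
#' @param traits a [trait_spec()]; defaults to the `traits` attribute.
#' @return Data frame with one row per trait: `trait`, `factor`, `sense`,
#'   `goal_met`, `xo`, `xs`, `sd`, `sd_pct`.
#' @export
selection_gains <- function(blups, selected, fm = NULL,
                            traits = attr(blups, "traits")) {
  m <- as.matrix(unclass(blups))
  if (is.character(traits)) traits <- trait_spec(traits)
  if (is.null(traits))
    stop("trait directions required", call. = FALSE)
  selected <- as.character(selected)
  if (!length(selected)) stop("empty selection", call. = FALSE)
  if (!all(selected %in% rownames(m)))
    stop("selected ids absent from the table", call. = FALSE)
  rows <- lapply(traits$name, function(tr) {
    xo <- mean(m[, tr]); xs <- mean(m[selected, tr])
    d <- selection_differential(xs, xo)
    sense <- traits$direction[traits$name == tr]
    fa <- if (!is.null(fm)) paste0("FA", fm$assignment[[tr]]) else NA_character_
    data.frame(trait = tr, factor = fa, sense = sense,
               goal_met = if (sense == "increase") d$sd >= 0 else d$sd <= 0,
               xo = xo, xs = xs, sd = d$sd, sd_pct = d$sd_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(fm))
    out <- out[order(fm$assignment[out$trait]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-trait genotype-ideotype distance index
#'
#' Runs the full MGIDI chain on a genotype-by-trait table of predicted means:
#' 0-100 rescaling toward the ideotype ([rescale_traits()]), exploratory
#' factor analysis with varimax rotation ([fit_efa()]), factor scores for
#' genotypes and ideotype ([factor_scores()]), Euclidean genotype-ideotype
#' distance ([ideotype_distance()]), selection at the given intensity,
#' per-factor strengths/weaknesses ([strengths_weaknesses()]) and the
#' selection-gain table ([selection_gains()]).
#'
#' @param x a [blup_table()] from [met_gamem()], or any genotypes-by-traits
#'   numeric matrix, or a `met_gamem` fit (its BLUP table is used).
#' @param traits a [trait_spec()] giving directions; defaults to the table's
#'   `traits` attribute.
#' @param intensity selection intensity, default 0.15.
#' @param n_factors optional override of the Kaiser retention rule.
#' @return Object of class `mgidi`: `index` (data frame `genotype`, `mgidi`,
#'   `rank`, `selected`), `selected` (ids), `n_selected`, `intensity`,
#'   `rescaled`, `factor_model`, `scores`, `omega`, `gains`, `blups`.
#' @examples
#' sim <- simulate_met(maize_sim_config(n_genotypes = 30, seed = 7))
#' fit <- met_gamem(subset_regime(sim$dataset, "optimal"), lrt = FALSE)
#' sel <- mgidi(fit)
#' sel
#' head(sel$gains)
#' @export
mgidi <- function(x, traits = NULL, intensity = 0.15, n_factors = NULL) {
  if (inherits(x, "met_gamem")) x <- blup_table(x)
  if (is.null(traits)) traits <- attr(x, "traits")
  if (is.null(traits))
    stop("trait directions required (pass a trait_spec)", call. = FALSE)
  if (is.character(traits)) traits <- trait_spec(traits)
  m <- as.matrix(unclass(x))
  if (anyNA(m)) stop("predicted-mean table contains missing values",
                     call. = FALSE)
  rt <- rescale_traits(m, traits)
  fm <- fit_efa(rt, n_factors = n_factors)
  st <- factor_scores(rt, fm)
  d <- ideotype_distance(st)
  names(d) <- rownames(m)
  sel <- select_genotypes(d, intensity)
  omega <- strengths_weaknesses(st)
  rownames(omega) <- rownames(m)
  gains <- selection_gains(m, sel, fm, traits)
  idx <- data.frame(genotype = names(d), mgidi = unname(d),
                    rank = rank(d, ties.method = "first"),
                    selected = names(d) %in% sel, stringsAsFactors = FALSE)
  out <- list(index = idx, selected = sel, n_selected = length(sel),
              intensity = intensity, rescaled = rt, factor_model = fm,
              scores = st, omega = omega, gains = gains, blups = m,
              regime = attr(x, "regime"), call = match.call())
  class(out) <- "mgidi"
  out
}

#' @export
print.mgidi <- function(x, ...) {
  cat(sprintf("MGIDI selection: %d genotypes, %d factor(s), intensity %.0f%%\n",
              nrow(x$index), x$factor_model$f, 100 * x$intensity))
  v <- x$factor_model$variance[seq_len(x$factor_model$f), ]
  cat(sprintf("  retained variance %.2f%% cumulative\n",
              v$cumulative_pct[x$factor_model$f]))
  top <- x$index[order(x$index$rank), ][seq_len(x$n_selected), ]
  cat(sprintf("  selected (%d): %s\n", x$n_selected,
              paste(sprintf("%s (%.2f)", top$genotype, top$mgidi),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.mgidi <- function(object, ...) {
  list(selected = object$selected,
       factors = object$factor_model$variance[seq_len(object$factor_model$f), ],
       gains = object$gains)
}

#' @export
coef.mgidi <- function(object, ...) object$factor_model$loadings

#' Plot an MGIDI selection
#'
#' `type = "index"` draws genotypes in ascending index order with the
#' selection cut point (the ranking view); `type = "contribution"` draws the
#' per-factor strength/weakness shares of the selected genotypes as stacked
#' bars (the tabular counterpart of the radar view).
#'
#' @param x an `mgidi` object.
#' @param type `"index"` or `"contribution"`.
#' @param ... passed to the underlying base-graphics call.
#' @return `x`, invisibly.
#' @export
plot.mgidi <- function(x, type = c("index", "contribution"), ...) {
  type <- match.arg(type)
  if (type == "index") {
    o <- order(x$index$mgidi)
    v <- x$index$mgidi[o]
    col <- ifelse(x$index$selected[o], "firebrick", "grey40")
    graphics::plot(seq_along(v), v, pch = 19, col = col,
                   xlab = "genotype rank", ylab = "MGIDI", ...)
    graphics::abline(v = x$n_selected + 0.5, lty = 2, col = "firebrick")
  } else {
    om <- t(x$omega[x$selected, , drop = FALSE])
    graphics::barplot(om, beside = FALSE, las = 2,
                      legend.text = rownames(om),
                      ylab = "share of squared ideotype distance", ...)
  }
  invisible(x)
}

#' Overlap of selections across regimes
#'
#' Pairwise and full intersections of the genotype sets selected under each
#' soil-moisture regime — the tabular counterpart of a Venn diagram.
#'
#' @param selections named list (regime -> character vector of selected ids).
#' @return List with `sets`, `pairwise` (data frame `regime_a`, `regime_b`,
#'   `n`, `ids`), `common` (ids present in every regime) and `n_common`.
#' @export
cross_regime_overlap <- function(selections) {
  stopifnot(is.list(selections), length(selections) >= 2)
  nm <- names(selections)
  pairs <- utils::combn(nm, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ids <- intersect(selections[[a]], selections[[b]])
    data.frame(regime_a = a, regime_b = b, n = length(ids),
               ids = paste(sort(ids), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  common <- Reduce(intersect, selections)
  list(sets = selections, pairwise = pw, common = sort(common),
       n_common = length(common))
}
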