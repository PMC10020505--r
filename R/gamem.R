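#' Broad-sense heritability on a genotypic-mean basis
#'
#' \deqn{h^2_{mg} = \frac{\sigma^2_g}
#'   {\sigma^2_g + \sigma^2_{ge}/e + \sigma^2_e/(eb)}}
#' where `e` is the number of environments and `b` the number of complete
#' replicates per environment.
#'
#' @param sigma2_g,sigma2_ge,sigma2_e genotypic, genotype-by-environment and
#'   residual variance components.
#' @param e,b numbers of environments and replicates per environment.
#' @return Heritability in \[0, 1\].
#' @examples
#' heritability_mean(4, 2, 2, e = 4, b = 2)  # 4/4.75 = 0.8421
#' @export
heritability_mean <- function(sigma2_g, sigma2_ge, sigma2_e, e, b) {
  if (e <= 0 || b <= 0) stop("e and b must be positive", call. = FALSE)
  den <- sigma2_g + sigma2_ge / e + sigma2_e / (e * b)
  if (den == 0) return(0)
  sigma2_g / den
}

#' Accuracy of genotype selection
#'
#' The selection accuracy associated with genotypic-mean heritability,
#' \eqn{A_s = \sqrt{h^2_{mg}}}.
#'
#' @param h2mg heritability in \[0, 1\].
#' @return Accuracy in \[0, 1\].
#' @examples
#' selection_accuracy(0.93)  # 0.96 to two decimals
#' @export
selection_accuracy <- function(h2mg) {
  stopifnot(all(h2mg >= 0 & h2mg <= 1))
  sqrt(h2mg)
}

#' Genetic parameters of a fitted trait model
#'
#' Summarizes a [met_reml()] fit into the standard trial genetic parameters:
#' phenotypic variance \eqn{\sigma^2_p = \sigma^2_g + \sigma^2_{ge} +
#' \sigma^2_e} (the incomplete-block component is a design nuisance and is
#' excluded), the GEI determination coefficient \eqn{R^2_{ge} =
#' \sigma^2_{ge}/\sigma^2_p}, genotypic-mean heritability, selection accuracy,
#' genotypic and residual coefficients of variation (percent of the grand
#' mean), their ratio, and an approximate Wald F statistic for the
#' environment fixed effect.
#'
#' @param object a `met_reml` fit.
#' @return List of class `genetic_parameters` with elements `sigma2_g`,
#'   `sigma2_ge`, `sigma2_block`, `sigma2_e`, `sigma2_p`, `r2ge`, `h2mg`,
#'   `accuracy`, `cv_g`, `cv_r`, `cv_ratio`, `env_f`, `grand_mean`, `e`, `b`.
#' @export
genetic_parameters <- function(object) {
  stopifnot(inherits(object, "met_reml"))
  vc <- object$vc
  s2g <- unname(vc["genotype"])
  s2ge <- if ("gei" %in% names(vc)) unname(vc["gei"]) else 0
  s2b <- if ("block" %in% names(vc)) unname(vc["block"]) else 0
  s2e <- unname(vc["residual"])
  s2p <- s2g + s2ge + s2e
  h2 <- heritability_mean(s2g, s2ge, s2e, object$e, object$b)
  mu <- object$grand_mean
  if (mu == 0) stop("grand mean is zero; CV undefined", call. = FALSE)
  out <- list(sigma2_g = s2g, sigma2_ge = s2ge, sigma2_block = s2b,
              sigma2_e = s2e, sigma2_p = s2p,
              r2ge = if (s2p > 0) s2ge / s2p else 0,
              h2mg = h2, accuracy = selection_accuracy(h2),
              cv_g = 100 * sqrt(s2g) / mu, cv_r = 100 * sqrt(s2e) / mu,
              cv_ratio = sqrt(s2g) / sqrt(s2e),
              env_f = env_wald_f(object), grand_mean = mu,
              e = object$e, b = object$b)
  class(out) <- c("genetic_parameters", "list")
  out
}

# approximate Wald F for equality of environment means (fixed effect)
env_wald_f <- function(object) {
  nm <- names(object$beta)
  sel <- grepl("^env", nm) & !grepl(":", nm)
  if (!any(sel)) return(NA_real_)
  b <- object$beta[sel]
  V <- object$vc[["residual"]] *
    object$fixed_cov_unscaled[sel, sel, drop = FALSE]
  stat <- tryCatch(drop(t(b) %*% solve(V, b)) / length(b),
                   error = function(e) NA_real_)
  stat
}

#' Likelihood-ratio test for a random term
#'
#' Tests the significance of a random term by comparing the restricted
#' log-likelihood of the full model with that of the model refitted without
#' the term: \eqn{LRT = 2(\ell_{full} - \ell_{reduced})}, clipped at zero.
#' By default the p-value is taken from the upper tail of \eqn{\chi^2_1}; the
#' boundary-corrected mixture \eqn{0.5\chi^2_0 + 0.5\chi^2_1} is available
#' via `boundary = TRUE` and halves the p-value (the null variance sits on
#' the boundary of the parameter space, making the plain chi-square test
#' conservative).
#'
#' @param object a `met_reml` fit (fitted with the term present).
#' @param term `"genotype"`, `"gei"` or `"block"`.
#' @param ds the `met_dataset` the model was fitted to.
#' @param boundary use the 50:50 boundary mixture instead of \eqn{\chi^2_1}.
#' @param ... passed to [met_reml()] for the reduced fit.
#' @return List of class `lrt_result`: `term`, `statistic`, `df`, `p_value`,
#'   `loglik_full`, `loglik_reduced`.
#' @export
lrt_random_term <- function(object, term, ds, boundary = FALSE, ...) {
  stopifnot(inherits(object, "met_reml"))
  term <- match.arg(term, c("genotype", "gei", "block"))
  if (!term %in% names(object$q))
    stop("term '", term, "' not in the fitted model", call. = FALSE)
  keep <- setdiff(names(object$q), term)
  if (!length(keep))
    stop("cannot drop the only random term '", term, "'", call. = FALSE)
  red <- met_reml(ds, object$trait, random = keep,
                  include_block = "block" %in% keep,
                  tol = object$tol, max_iter = object$max_iter, ...)
  stat <- max(2 * (object$loglik - red$loglik), 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary) p <- p / 2
  structure(list(term = term, statistic = stat, df = 1L, p_value = p,
                 loglik_full = object$loglik, loglik_reduced = red$loglik),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT for random term '%s': statistic = %.4f (df = 1), p = %.4g\n",
              x$term, x$statistic, x$p_value))
  invisible(x)
}

#' Fit the MET mixed model for every trait of a regime
#'
#' Convenience wrapper running [met_reml()] trait by trait (optionally with
#' likelihood-ratio tests for the genotype and GEI terms) and collecting the
#' genetic-parameter table.
#'
#' @param ds a `met_dataset`, typically one regime.
#' @param traits trait names (default: all configured traits).
#' @param lrt compute LRTs for genotype and GEI (two reduced refits per
#'   trait); default `TRUE`.
#' @param ... passed to [met_reml()].
#' @return Object of class `met_gamem`: `fits` (named list of `met_reml`),
#'   `parameters` (data frame, one row per trait), `lrt` (data frame or
#'   `NULL`), `traits`, `regime`.
#' @examples
#' sim <- simulate_met(maize_sim_config(n_genotypes = 15, seed = 3))
#' opt <- subset_regime(sim$dataset, "optimal")
#' fit <- met_gamem(opt, traits = c("GY", "PH"), lrt = FALSE)
#' summary(fit)
#' @export
met_gamem <- function(ds, traits = NULL, lrt = TRUE, ...) {
  stopifnot(inherits(ds, "met_dataset"))
  if (is.null(traits)) traits <- ds$traits$name
  dm <- design_dims(ds)
  if (dm$e < 2)
    stop("need at least 2 environments per analyzed regime", call. = FALSE)
  fits <- lapply(traits, function(tr) met_reml(ds, tr, ...))
  names(fits) <- traits
  params <- do.call(rbind, lapply(traits, function(tr) {
    gp <- genetic_parameters(fits[[tr]])
    data.frame(trait = tr, sigma2_g = gp$sigma2_g, sigma2_ge = gp$sigma2_ge,
               sigma2_block = gp$sigma2_block, sigma2_e = gp$sigma2_e,
               sigma2_p = gp$sigma2_p, r2ge = gp$r2ge, h2mg = gp$h2mg,
               accuracy = gp$accuracy, env_f = gp$env_f, cv_g = gp$cv_g,
               cv_r = gp$cv_r, cv_ratio = gp$cv_ratio,
               grand_mean = gp$grand_mean, stringsAsFactors = FALSE)
  }))
  lrt_tab <- NULL
  if (isTRUE(lrt)) {
    lrt_tab <- do.call(rbind, lapply(traits, function(tr) {
      rows <- lapply(intersect(c("genotype", "gei"), names(fits[[tr]]$q)),
                     function(tm) {
        lt <- lrt_random_term(fits[[tr]], tm, ds)
        data.frame(trait = tr, term = tm, statistic = lt$statistic,
                   p_value = lt$p_value, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
  }
  out <- list(fits = fits, parameters = params, lrt = lrt_tab,
              traits = ds$traits[ds$traits$name %in% traits, , drop = FALSE],
              regime = intersect(REGIMES, unique(ds$data$regime)),
              e = dm$e, b = dm$b)
  class(out) <- "met_gamem"
  out
}

#' @export
print.met_gamem <- function(x, ...) {
  cat(sprintf("MET mixed-model analysis (%s): %d trait(s), e = %d, b = %d\n",
              paste(x$regime, collapse = "+"), length(x$fits), x$e, x$b))
  conv <- vapply(x$fits, `[[`, TRUE, "converged")
  if (!all(conv))
    cat("  non-converged traits:", paste(names(conv)[!conv], collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.met_gamem <- function(object, digits = 3, ...) {
  tab <- object$parameters
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  tab
}

#' Two-way genotype-by-trait table of predicted means
#'
#' Builds the genotype (rows) by trait (columns) table of BLUP-based
#' predicted means, \eqn{X_{ij} =} grand mean of trait `j` + genotype BLUP of
#' genotype `i`, that feeds the MGIDI selection index.
#'
#' @param object a `met_gamem` multi-trait fit.
#' @return Numeric matrix of class `blup_table` (genotypes x traits) with a
#'   `traits` attribute carrying the trait directions.
#' @export
blup_table <- function(object) {
  stopifnot(inherits(object, "met_gamem"))
  missing_fit <- setdiff(object$traits$name, names(object$fits))
  if (length(missing_fit))
    stop("no fit for configured trait(s): ",
         paste(missing_fit, collapse = ", "), call. = FALSE)
  cols <- lapply(object$fits, predict)
  genos <- sort(unique(unlist(lapply(cols, names))))
  out <- matrix(NA_real_, length(genos), length(cols),
                dimnames = list(genos, names(cols)))
  for (j in names(cols)) out[names(cols[[j]]), j] <- cols[[j]]
  structure(out, traits = object$traits, regime = object$regime,
            class = c("blup_table", "matrix", "array"))
}
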