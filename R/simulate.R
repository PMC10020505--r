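#' Configure a synthetic multi-environment trial
#'
#' Defines the statistical structure of a simulated alpha-lattice MET: plot
#' values are generated as
#' `trait mean + environment effect + genotype effect + GEI effect +
#'  incomplete-block effect + residual`,
#' with genotype effects drawn from a zero-mean multivariate normal whose
#' correlation structure is induced by a traits-by-factors loading matrix
#' (so downstream factor analysis has a known truth to recover), and GEI,
#' block and residual effects drawn independently per trait with the
#' configured variances.
#'
#' @param n_genotypes number of genotypes (rows of the trial).
#' @param environments data frame with columns `id` and `regime`; each
#'   environment belongs to exactly one soil-moisture regime.
#' @param n_reps complete replicates per environment.
#' @param blocks_per_rep incomplete blocks per replicate; genotypes are
#'   allocated to blocks at random within each replicate.  When
#'   `blocks_per_rep` does not divide `n_genotypes` the last block is smaller.
#' @param traits a [trait_spec()].
#' @param trait_means named numeric vector of trait means.
#' @param sigma2_g,sigma2_ge,sigma2_block,sigma2_e named non-negative numeric
#'   vectors of genotypic, genotype-by-environment, incomplete-block and
#'   residual variances per trait.
#' @param loadings traits-by-factors matrix \eqn{\Lambda} inducing the genetic
#'   correlation matrix \eqn{\Lambda\Lambda' + \Psi}, with uniquenesses
#'   \eqn{\Psi = I - diag(\Lambda\Lambda')} so the diagonal is 1; row names
#'   must match the trait names and squared row sums must not exceed 1.
#' @param env_spread half-width (in genotypic standard deviations per trait)
#'   of the fixed, evenly spaced environment main effects.
#' @param seed integer seed making the simulation reproducible.
#' @return A list of class `sim_config`.
#' @seealso [simulate_met()], [maize_sim_config()]
#' @export
sim_config <- function(n_genotypes, environments, n_reps = 2,
                       blocks_per_rep = 5, traits, trait_means,
                       sigma2_g, sigma2_ge, sigma2_block, sigma2_e,
                       loadings = NULL, env_spread = 2, seed = 1L) {
  if (is.character(traits)) traits <- trait_spec(traits)
  environments <- as.data.frame(environments)
  stopifnot(all(c("id", "regime") %in% names(environments)))
  environments$id <- as.character(environments$id)
  environments$regime <- as.character(environments$regime)
  if (anyDuplicated(environments$id))
    stop("duplicate environment ids", call. = FALSE)
  p <- nrow(traits)
  chk <- function(v, what) {
    v <- v[traits$name]
    if (anyNA(v)) stop(what, " missing for some traits", call. = FALSE)
    if (any(v < 0)) stop(what, " must be non-negative", call. = FALSE)
    v
  }
  trait_means <- trait_means[traits$name]
  if (anyNA(trait_means)) stop("trait_means missing for some traits", call. = FALSE)
  sigma2_g     <- chk(sigma2_g, "sigma2_g")
  sigma2_ge    <- chk(sigma2_ge, "sigma2_ge")
  sigma2_block <- chk(sigma2_block, "sigma2_block")
  sigma2_e     <- chk(sigma2_e, "sigma2_e")
  if (is.null(loadings)) {
    loadings <- matrix(0, p, 1, dimnames = list(traits$name, "F1"))
  }
  loadings <- as.matrix(loadings)
  if (is.null(rownames(loadings)) || !identical(rownames(loadings), traits$name))
    loadings <- loadings[traits$name, , drop = FALSE]
  if (any(rowSums(loadings^2) > 1 + 1e-10))
    stop("squared loading row sums exceed 1; no valid uniqueness exists",
         call. = FALSE)
  structure(list(n_genotypes = as.integer(n_genotypes),
                 environments = environments, n_reps = as.integer(n_reps),
                 blocks_per_rep = as.integer(blocks_per_rep), traits = traits,
                 trait_means = trait_means, sigma2_g = sigma2_g,
                 sigma2_ge = sigma2_ge, sigma2_block = sigma2_block,
                 sigma2_e = sigma2_e, loadings = loadings,
                 env_spread = env_spread, seed = as.integer(seed)),
            class = "sim_config")
}

#' Seven-environment moisture-regime layout
#'
#' The canonical test-environment layout of the tropical maize screening
#' trials: three optimal environments (E1, E4, E6), two managed-drought
#' environments (E2, E3) and two managed-waterlogging environments (E5, E7).
#'
#' @return Data frame with columns `id` and `regime`.
#' @export
maize_environments <- function() {
  data.frame(id = paste0("E", 1:7),
             regime = c("optimal", "drought", "drought", "optimal",
                        "waterlogging", "optimal", "waterlogging"),
             stringsAsFactors = FALSE)
}

#' Default simulation configuration at tropical-maize trial scale
#'
#' Study-scale defaults: 75 genotypes, the seven-environment moisture-regime
#' layout of [maize_environments()], 2 replicates, 5 incomplete blocks per
#' replicate, and the 12 maize traits of [maize_trait_spec()] with means and
#' variance components on the scale observed in multi-location tropical maize
#' hybrid screening: per trait, the genotypic, GEI and residual variances are
#' recovered by inverting the published optimal-moisture phenotypic variance,
#' GEI determination coefficient and genotypic-mean heritability at the
#' reference design (3 environments, 2 replicates); where the published
#' triple is jointly infeasible from rounding, the genotypic share is capped
#' at 95% of the non-GEI variance.  Genetic correlations follow a
#' three-factor structure: a canopy/yield factor (PH, EH, SPAD, EL, KNR, GY),
#' a phenology factor (D50A, D50S, ASI, TW) and an ear factor (EG, KRE).
#'
#' @param n_genotypes,environments,n_reps,seed overrides passed to
#'   [sim_config()].
#' @return A `sim_config`.
#' @export
maize_sim_config <- function(n_genotypes = 75,
                             environments = maize_environments(),
                             n_reps = 2, seed = 1L) {
  traits <- maize_trait_spec()
  nm <- traits$name
  means <- c(D50A = 67.18, D50S = 69.60, ASI = 2.42, PH = 170.96, EH = 90.66,
             SPAD = 48.30, TW = 29.05, EL = 18.26, EG = 4.34, KRE = 14.80,
             KNR = 33.73, GY = 7.87)
  # published optimal-regime summary statistics: phenotypic variance, GEI
  # determination coefficient, genotypic-mean heritability
  s2p <- c(D50A = 4.60, D50S = 5.80, ASI = 1.09, PH = 297.5, EH = 169.0,
           SPAD = 33.57, TW = 5.89, EL = 2.03, EG = 0.12, KRE = 1.39,
           KNR = 12.67, GY = 2.08)
  r2ge <- c(D50A = 0.12, D50S = 0.16, ASI = 0.39, PH = 0.59, EH = 0.18,
            SPAD = 0.72, TW = 0.70, EL = 0.62, EG = 0.60, KRE = 0.58,
            KNR = 0.79, GY = 0.62)
  h2 <- c(D50A = 0.93, D50S = 0.92, ASI = 0.16, PH = 0.61, EH = 0.86,
          SPAD = 0.33, TW = 0.61, EL = 0.62, EG = 0.63, KRE = 0.73,
          KNR = 0.40, GY = 0.75)
  # invert sigma2_p = g + ge + e, R2ge = ge/p and
  # h2 = g / (g + ge/e + e/(e b)) at the reference design (e = 3, b = 2);
  # where the printed triple is jointly infeasible (rounding), cap the
  # genotypic share at 95% of the non-GEI variance
  e0 <- 3; b0 <- 2
  s2ge <- r2ge * s2p
  rest <- s2p - s2ge
  s2g <- pmin(h2 * (s2ge / e0 + rest / (e0 * b0)) / (1 - h2 * (1 - 1 / (e0 * b0))),
              0.95 * rest)
  s2e <- rest - s2g
  L <- matrix(0, length(nm), 3, dimnames = list(nm, c("F1", "F2", "F3")))
  L[c("PH", "EH", "SPAD", "EL", "KNR", "GY"), 1] <-
    c(0.80, 0.75, 0.60, 0.70, 0.75, 0.70)
  L[c("D50A", "D50S", "ASI", "TW"), 2] <- c(0.85, 0.85, 0.70, 0.50)
  L["TW", 1] <- 0.30
  L[c("EG", "KRE"), 3] <- c(0.80, 0.80)
  L["GY", 3] <- 0.30
  sim_config(n_genotypes = n_genotypes, environments = environments,
             n_reps = n_reps, blocks_per_rep = 5, traits = traits,
             trait_means = means, sigma2_g = s2g, sigma2_ge = s2ge,
             sigma2_block = 0.1 * s2e, sigma2_e = s2e, loadings = L,
             seed = seed)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Draw correlated genotype effects
#'
#' Genotype effects per trait are drawn from a zero-mean multivariate normal
#' with covariance \eqn{D^{1/2}(\Lambda\Lambda' + \Psi)D^{1/2}}, where
#' \eqn{\Lambda} is the configured loading matrix, \eqn{\Psi} the diagonal
#' uniqueness matrix completing a unit diagonal, and \eqn{D} the diagonal of
#' genotypic variances.  Reproducible given the configured seed.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return List with `effects` (genotypes-by-traits matrix) and
#'   `correlation` (the target genetic correlation matrix).
#' @export
sample_genetic_effects <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$loadings
  C <- L %*% t(L)
  diag(C) <- 1
  D <- sqrt(cfg$sigma2_g)
  Sigma <- outer(D, D) * C
  g <- cfg$n_genotypes
  if (all(Sigma == 0)) {
    eff <- matrix(0, g, nrow(C))
  } else {
    ch <- tryCatch(chol(Sigma + diag(1e-12 * max(diag(Sigma)), nrow(Sigma))),
                   error = function(e)
                     stop("target genetic covariance is not positive ",
                          "semi-definite", call. = FALSE))
    eff <- with_seed(seed, {
      matrix(stats::rnorm(g * nrow(Sigma)), g) %*% ch
    })
  }
  dimnames(eff) <- list(sprintf("G%02d", seq_len(g)), cfg$traits$name)
  list(effects = eff, correlation = C)
}

#' Simulate a multi-environment trial
#'
#' Generates a long-format plot table under the configured variance structure
#' and alpha-lattice-style layout (random allocation of genotypes to equal
#' incomplete blocks within each complete replicate), together with the truth
#' used to generate it.  Environment main effects are fixed per configuration
#' (evenly spaced within `env_spread` genotypic SDs); all other effects are
#' random draws governed by `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @param missing_rate optional proportion of trait cells set missing
#'   completely at random (default 0).
#' @return List with `dataset` (a [met_dataset()]) and `truth` (genotype
#'   effects, GEI effects, environment effects, block effects and the
#'   configured variance components).
#' @export
simulate_met <- function(cfg, seed = cfg$seed, missing_rate = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  gen <- sample_genetic_effects(cfg, seed = seed)
  g <- cfg$n_genotypes
  geno_ids <- rownames(gen$effects)
  envs <- cfg$environments
  ne <- nrow(envs)
  p <- nrow(cfg$traits)
  nm <- cfg$traits$name

  # fixed environment main effects: evenly spaced per trait
  delta <- if (ne == 1) 0 else seq(-1, 1, length.out = ne) * cfg$env_spread
  env_eff <- outer(delta, sqrt(cfg$sigma2_g))
  dimnames(env_eff) <- list(envs$id, nm)

  out <- with_seed(seed + 1L, {
    gei <- array(stats::rnorm(g * ne * p), dim = c(g, ne, p),
                 dimnames = list(geno_ids, envs$id, nm))
    for (j in seq_len(p)) gei[, , j] <- gei[, , j] * sqrt(cfg$sigma2_ge[j])

    rows <- vector("list", ne * cfg$n_reps)
    block_eff <- list()
    k <- 0L
    nb <- cfg$blocks_per_rep
    bsize <- ceiling(g / nb)
    for (ei in seq_len(ne)) {
      for (r in seq_len(cfg$n_reps)) {
        k <- k + 1L
        ord <- sample.int(g)
        blk <- sprintf("B%d", rep(seq_len(nb), each = bsize)[seq_len(g)])
        beff <- matrix(stats::rnorm(nb * p), nb, p,
                       dimnames = list(sprintf("B%d", seq_len(nb)), nm))
        beff <- sweep(beff, 2, sqrt(cfg$sigma2_block), "*")
        block_eff[[paste(envs$id[ei], r, sep = ":")]] <- beff
        vals <- matrix(NA_real_, g, p, dimnames = list(NULL, nm))
        res <- matrix(stats::rnorm(g * p), g, p)
        res <- sweep(res, 2, sqrt(cfg$sigma2_e), "*")
        for (j in seq_len(p)) {
          vals[, j] <- cfg$trait_means[j] + env_eff[ei, j] +
            gen$effects[ord, j] + gei[ord, ei, j] +
            beff[blk, j] + res[, j]
        }
        rows[[k]] <- data.frame(genotype = geno_ids[ord],
                                environment = envs$id[ei],
                                regime = envs$regime[ei],
                                replicate = r, block = blk,
                                vals, stringsAsFactors = FALSE,
                                check.names = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    if (missing_rate > 0) {
      cells <- as.matrix(df[, nm])
      drop <- stats::runif(length(cells)) < missing_rate
      cells[drop] <- NA_real_
      df[, nm] <- cells
    }
    list(df = df, gei = gei, block_eff = block_eff)
  })

  truth <- list(genotype_effects = gen$effects, gei_effects = out$gei,
                env_effects = env_eff, block_effects = out$block_eff,
                genetic_correlation = gen$correlation,
                variance_components = list(sigma2_g = cfg$sigma2_g,
                                           sigma2_ge = cfg$sigma2_ge,
                                           sigma2_block = cfg$sigma2_block,
                                           sigma2_e = cfg$sigma2_e),
                spiked = character(0))
  list(dataset = met_dataset(out$df, cfg$traits), truth = truth)
}

#' Shift named genotypes toward the ideotype
#'
#' Moves every plot value of the named genotypes in each trait's desirable
#' direction: increase-traits are shifted by `+shift`, decrease-traits by
#' `-shift`.  Used to create known near-ideal genotypes for selection-power
#' checks.
#'
#' @param ds a `met_dataset`.
#' @param ids genotype identifiers present in `ds`.
#' @param shift named non-negative numeric vector (trait -> shift magnitude);
#'   traits absent from `shift` are left untouched.
#' @return The modified `met_dataset`.
#' @export
spike_ideal_genotypes <- function(ds, ids, shift) {
  stopifnot(inherits(ds, "met_dataset"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, unique(ds$data$genotype))
  if (length(unknown))
    stop("unknown genotype id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  rows <- ds$data$genotype %in% ids
  for (tr in intersect(names(shift), ds$traits$name)) {
    dir <- ds$traits$direction[ds$traits$name == tr]
    sgn <- if (dir == "decrease") -1 else 1
    ds$data[[tr]][rows] <- ds$data[[tr]][rows] + sgn * shift[[tr]]
  }
  ds
}
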