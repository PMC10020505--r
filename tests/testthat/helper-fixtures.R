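# Shared fixtures: small simulation configs and independent oracles.

# single-trait config with explicit variance components
one_trait_config <- function(g = 12, e = 3, reps = 2, s2g = 1, s2ge = 0.5,
                             s2b = 0, s2e = 1, blocks_per_rep = 1,
                             seed = 1, mean = 10, regime = "optimal") {
  sim_config(
    n_genotypes = g,
    environments = data.frame(id = paste0("E", seq_len(e)), regime = regime),
    n_reps = reps, blocks_per_rep = blocks_per_rep,
    traits = trait_spec("Y"),
    trait_means = c(Y = mean),
    sigma2_g = c(Y = s2g), sigma2_ge = c(Y = s2ge),
    sigma2_block = c(Y = s2b), sigma2_e = c(Y = s2e),
    seed = seed)
}

# balanced RCBD dataset (one block per replicate -> no incomplete-block term)
rcbd_dataset <- function(g = 12, e = 3, reps = 2, s2g = 1, s2ge = 0.5,
                         s2e = 1, seed = 1) {
  cfg <- one_trait_config(g = g, e = e, reps = reps, s2g = s2g, s2ge = s2ge,
                          s2b = 0, s2e = s2e, blocks_per_rep = 1, seed = seed)
  simulate_met(cfg)$dataset
}

# ANOVA method-of-moments estimators for the balanced RCBD MET model
anova_components <- function(ds, trait = "Y") {
  d <- ds$data
  d$env <- factor(d$environment); d$rep <- factor(d$replicate)
  d$genotype <- factor(d$genotype)
  e <- nlevels(d$env); b <- nlevels(d$rep)
  fit <- stats::aov(stats::reformulate(
    c("env", "env:rep", "genotype", "genotype:env"), trait), data = d)
  ms <- summary(fit)[[1]][, "Mean Sq"]
  names(ms) <- trimws(rownames(summary(fit)[[1]]))
  c(genotype = (ms[["genotype"]] - ms[["env:genotype"]]) / (e * b),
    gei = (ms[["env:genotype"]] - ms[["Residuals"]]) / b,
    residual = ms[["Residuals"]])
}

# independent restricted log-likelihood: direct dense V-matrix formula
direct_reml_loglik <- function(ds, trait, sig) {
  d <- ds$data[!is.na(ds$data[[trait]]), ]
  y <- d[[trait]]
  env <- factor(d$environment); rep <- factor(d$replicate)
  geno <- factor(d$genotype)
  ge <- droplevels(interaction(geno, env))
  X <- stats::model.matrix(~ env + env:rep)
  X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  Zg <- stats::model.matrix(~ 0 + geno)
  Zi <- stats::model.matrix(~ 0 + ge)
  n <- length(y); p <- ncol(X)
  V <- sig[["genotype"]] * tcrossprod(Zg) +
    sig[["gei"]] * tcrossprod(Zi) + diag(sig[["residual"]], n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi)))
}

# maximize the restricted likelihood with a general-purpose optimizer
optim_reml <- function(ds, trait, start = c(1, 1, 1)) {
  nll <- function(ls) {
    sig <- exp(ls)
    names(sig) <- c("genotype", "gei", "residual")
    -direct_reml_loglik(ds, trait, sig)
  }
  op <- stats::optim(log(start), nll, method = "L-BFGS-B",
                     control = list(factr = 1e3, maxit = 500))
  list(sig = exp(op$par), loglik = -op$value)
}
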