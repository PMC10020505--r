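test_that("EM-REML equals ANOVA moment estimators on a balanced design", {
  ds <- rcbd_dataset(g = 12, e = 3, reps = 2, seed = 21)
  fit <- met_reml(ds, "Y", tol = 1e-13, max_iter = 10000)
  mom <- anova_components(ds)
  expect_true(all(mom > 0))  # interior solution, where the equivalence holds
  expect_equal(unname(fit$vc[c("genotype", "gei", "residual")]),
               unname(mom), tolerance = 1e-6)
})

test_that("EM-REML matches a general-purpose optimizer of the same likelihood", {
  ds <- rcbd_dataset(g = 10, e = 2, reps = 2, seed = 31)
  fit <- met_reml(ds, "Y", tol = 1e-13, max_iter = 10000)
  op <- optim_reml(ds, "Y")
  expect_equal(fit$loglik, op$loglik, tolerance = 1e-6)
  expect_equal(unname(fit$vc[c("genotype", "gei", "residual")]),
               unname(op$sig), tolerance = 1e-4)
  # and the direct V-matrix likelihood agrees with the MME-based one
  expect_equal(fit$loglik, direct_reml_loglik(ds, "Y", fit$vc),
               tolerance = 1e-8)
})

test_that("EM-REML agrees with lme4 on unbalanced data with blocks", {
  skip_if_not_installed("lme4")
  cfg <- one_trait_config(g = 15, e = 3, s2b = 0.3, blocks_per_rep = 3,
                          seed = 41)
  sim <- simulate_met(cfg, missing_rate = 0.07)
  fit <- met_reml(sim$dataset, "Y", tol = 1e-12, max_iter = 5000)
  d <- sim$dataset$data[!is.na(sim$dataset$data$Y), ]
  d$rep <- factor(d$replicate)
  lf <- lme4::lmer(
    Y ~ environment + environment:rep + (1 | genotype) +
      (1 | genotype:environment) + (1 | environment:rep:block),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  get <- function(g) vc$vcov[vc$grp == g]
  expect_equal(fit$vc[["genotype"]], get("genotype"), tolerance = 1e-3)
  expect_equal(fit$vc[["gei"]], get("genotype:environment"), tolerance = 1e-3)
  expect_equal(fit$vc[["residual"]], get("Residual"), tolerance = 1e-3)
})

test_that("the restricted log-likelihood never decreases across EM steps", {
  for (s in c(2, 12, 22)) {
    sim <- simulate_met(one_trait_config(g = 10, e = 2, blocks_per_rep = 2,
                                         s2b = 0.2, seed = s))
    fit <- met_reml(sim$dataset, "Y")
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("a null genotypic variance is pushed to the boundary", {
  ds <- rcbd_dataset(g = 20, e = 2, reps = 2, s2g = 0, s2ge = 0.3, seed = 51)
  fit <- met_reml(ds, "Y")
  expect_lt(fit$vc[["genotype"]], 0.05)
  lt <- lrt_random_term(fit, "genotype", ds)
  expect_gte(lt$statistic, 0)
  expect_lt(lt$statistic, 3)
})

test_that("LRT detects strong genotypic signal and behaves as a chi-square test", {
  ds <- rcbd_dataset(g = 30, e = 3, reps = 2, s2g = 1, s2ge = 0.3, s2e = 1,
                     seed = 61)
  fit <- met_reml(ds, "Y")
  lt <- lrt_random_term(fit, "genotype", ds)
  expect_lt(lt$p_value, 1e-3)
  expect_equal(lt$statistic,
               2 * (lt$loglik_full - lt$loglik_reduced), tolerance = 1e-10)
  # boundary mixture halves the p-value
  ltb <- lrt_random_term(fit, "genotype", ds, boundary = TRUE)
  expect_equal(ltb$p_value, lt$p_value / 2)
  expect_error(lrt_random_term(fit, "block", ds), "not in the fitted model")
})

test_that("genetic parameters follow their closed forms", {
  expect_equal(heritability_mean(4, 2, 2, e = 4, b = 2), 4 / 4.75)
  expect_equal(heritability_mean(0, 2, 2, e = 4, b = 2), 0)
  expect_equal(selection_accuracy(0), 0)

  ds <- rcbd_dataset(g = 15, e = 3, reps = 2, seed = 71)
  fit <- met_reml(ds, "Y")
  gp <- genetic_parameters(fit)
  expect_gte(gp$h2mg, 0); expect_lte(gp$h2mg, 1)
  expect_equal(gp$accuracy^2, gp$h2mg)
  expect_equal(gp$sigma2_p, gp$sigma2_g + gp$sigma2_ge + gp$sigma2_e)
  expect_equal(gp$r2ge, gp$sigma2_ge / gp$sigma2_p)
  expect_equal(gp$h2mg, heritability_mean(gp$sigma2_g, gp$sigma2_ge,
                                          gp$sigma2_e, gp$e, gp$b))
  expect_equal(gp$cv_g, 100 * sqrt(gp$sigma2_g) / gp$grand_mean)
  expect_true(is.finite(gp$env_f) && gp$env_f > 0)
})

test_that("BLUP table shrinks to the mean and to raw means in the limits", {
  # genotypic variance at the boundary: predicted means collapse to the mean
  ds0 <- rcbd_dataset(g = 15, e = 3, reps = 2, s2g = 0, s2ge = 0.2,
                      s2e = 1, seed = 81)
  fit0 <- met_gamem(ds0, lrt = FALSE)
  bl0 <- blup_table(fit0)
  if (fit0$fits$Y$vc[["genotype"]] == 0)
    expect_lt(max(abs(bl0[, "Y"] - fit0$fits$Y$grand_mean)), 1e-6)
  spread0 <- stats::sd(bl0[, "Y"])

  # vanishing non-genetic variance: predicted means approach raw means
  ds1 <- rcbd_dataset(g = 15, e = 3, reps = 2, s2g = 1, s2ge = 1e-6,
                      s2e = 1e-6, seed = 81)
  fit1 <- met_gamem(ds1, lrt = FALSE)
  bl1 <- blup_table(fit1)
  raw <- tapply(ds1$data$Y, ds1$data$genotype, mean)
  expect_lt(max(abs(bl1[rownames(bl1), "Y"] - raw[rownames(bl1)])), 0.01)
  expect_gt(stats::sd(bl1[, "Y"]), spread0)

  # centering about the grand mean on balanced data
  expect_lt(abs(mean(random_effects(fit1$fits$Y, "genotype"))), 1e-8)
})

test_that("raising residual noise shrinks the BLUP spread on average", {
  spread <- function(s2e, seed) {
    ds <- rcbd_dataset(g = 12, e = 2, reps = 2, s2g = 1, s2ge = 0.2,
                       s2e = s2e, seed = seed)
    stats::sd(random_effects(met_reml(ds, "Y"), "genotype"))
  }
  seeds <- 101:105
  lo <- vapply(seeds, function(s) spread(0.25, s), 0)
  hi <- vapply(seeds, function(s) spread(4, s), 0)
  expect_gt(mean(lo), mean(hi))
})

test_that("fit accessors are mutually consistent", {
  sim <- simulate_met(one_trait_config(g = 8, e = 2, blocks_per_rep = 2,
                                       s2b = 0.2, seed = 91))
  fit <- met_reml(sim$dataset, "Y")
  expect_equal(fitted(fit) + residuals(fit), fit$y)
  expect_equal(unname(predict(fit)),
               unname(fit$grand_mean + random_effects(fit, "genotype")))
  ynew <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(ynew), c(fit$n, 2L))
  expect_s3_class(summary(fit), "summary.met_reml")
})

test_that("the multi-trait wrapper collects parameters and LRTs per trait", {
  cfg <- one_trait_config(g = 10, e = 2, blocks_per_rep = 2, s2b = 0.2,
                          seed = 201)
  ds <- simulate_met(cfg)$dataset
  fit <- suppressWarnings(met_gamem(ds, lrt = TRUE))
  expect_named(fit$fits, "Y")
  expect_equal(nrow(fit$parameters), 1)
  expect_setequal(fit$lrt$term, c("genotype", "gei"))
  expect_true(all(fit$lrt$statistic >= 0))
  expect_true(all(fit$lrt$p_value >= 0 & fit$lrt$p_value <= 1))
  expect_error(met_gamem(simulate_met(one_trait_config(g = 5, e = 1))$dataset),
               "at least 2 environments")
})
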