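test_that("simulation is seed-deterministic", {
  cfg <- maize_sim_config(n_genotypes = 10)
  a <- simulate_met(cfg, seed = 7)
  b <- simulate_met(cfg, seed = 7)
  expect_identical(a$dataset$data, b$dataset$data)
  c <- simulate_met(cfg, seed = 8)
  expect_false(identical(a$dataset$data, c$dataset$data))
})

test_that("degenerate variances reduce plots to mean plus environment effect", {
  cfg <- one_trait_config(g = 6, e = 2, s2g = 0, s2ge = 0, s2b = 0, s2e = 0)
  sim <- simulate_met(cfg)
  d <- sim$dataset$data
  for (env in unique(d$environment)) {
    v <- d$Y[d$environment == env]
    expect_equal(v, rep(10 + sim$truth$env_effects[env, "Y"], length(v)))
  }
})

test_that("genotype-mean variance follows the law of total variance", {
  # var(genotype mean) = s2g + s2ge/e + s2e/(e*reps) = 1 + 0.5/4 + 1/8
  target <- 1 + 0.5 / 4 + 1 / 8
  vars <- vapply(1:30, function(s) {
    sim <- simulate_met(one_trait_config(g = 75, e = 4, s2g = 1, s2ge = 0.5,
                                         s2b = 0, s2e = 1, seed = 100 + s))
    stats::var(tapply(sim$dataset$data$Y, sim$dataset$data$genotype, mean))
  }, 0)
  mc_se <- stats::sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - target), 3 * mc_se + 0.02)
})

test_that("missing-value injection hits the requested rate", {
  sim <- simulate_met(maize_sim_config(n_genotypes = 75, seed = 3),
                      missing_rate = 0.05)
  cells <- as.matrix(sim$dataset$data[, sim$dataset$traits$name])
  rate <- mean(is.na(cells))
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("a shared unit-loading factor drives genetic correlation to one", {
  tr <- trait_spec(c("A", "B"))
  L <- matrix(1, 2, 1, dimnames = list(c("A", "B"), "F1"))
  cfg <- sim_config(n_genotypes = 200,
                    environments = data.frame(id = "E1", regime = "optimal"),
                    traits = tr, trait_means = c(A = 0, B = 0),
                    sigma2_g = c(A = 1, B = 1), sigma2_ge = c(A = 0, B = 0),
                    sigma2_block = c(A = 0, B = 0), sigma2_e = c(A = 0, B = 0),
                    loadings = L, seed = 4)
  eff <- sample_genetic_effects(cfg)$effects
  expect_gt(stats::cor(eff[, "A"], eff[, "B"]), 0.999)
})

test_that("three-factor loadings reproduce the block correlation structure", {
  cfg <- maize_sim_config(n_genotypes = 500, seed = 9)
  gen <- sample_genetic_effects(cfg)
  realized <- stats::cor(gen$effects)
  # block structure: within- and between-block average correlations match
  # the target within +/-0.1
  L <- cfg$loadings
  grp <- apply(abs(L), 1, which.max)  # dominant factor per trait
  for (a in 1:3) for (b in a:3) {
    sel_a <- grp == a; sel_b <- grp == b
    off <- outer(sel_a, sel_b) & upper.tri(realized)
    if (any(off))
      expect_lt(abs(mean(realized[off]) - mean(gen$correlation[off])), 0.1)
  }
  expect_gt(stats::cor(realized[upper.tri(realized)],
                       gen$correlation[upper.tri(realized)]), 0.9)
  # determinism of the draw
  expect_identical(gen$effects, sample_genetic_effects(cfg)$effects)
})

test_that("spiking shifts named genotypes in the desirable direction only", {
  sim <- simulate_met(maize_sim_config(n_genotypes = 10, seed = 6))
  ds <- sim$dataset

  same <- spike_ideal_genotypes(ds, "G03", c(GY = 0))
  expect_identical(same$data, ds$data)

  up <- spike_ideal_genotypes(ds, c("G03", "G07"), c(GY = 2, D50A = 1))
  rows <- ds$data$genotype %in% c("G03", "G07")
  expect_equal(up$data$GY[rows], ds$data$GY[rows] + 2)       # increase trait
  expect_equal(up$data$D50A[rows], ds$data$D50A[rows] - 1)   # decrease trait
  expect_identical(up$data$PH, ds$data$PH)                   # untouched
  expect_identical(up$data$GY[!rows], ds$data$GY[!rows])

  expect_error(spike_ideal_genotypes(ds, "G99", c(GY = 1)), "unknown")
})

test_that("generated datasets satisfy the dataset invariants", {
  for (s in 1:3) {
    sim <- simulate_met(maize_sim_config(n_genotypes = 12, seed = s))
    expect_s3_class(met_dataset(sim$dataset$data, sim$dataset$traits),
                    "met_dataset")
  }
})
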