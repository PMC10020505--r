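test_that("rescaling maps extrema by trait direction and stays in [0, 100]", {
  m <- cbind(up = c(2, 4, 6), down = c(2, 4, 6))
  rownames(m) <- paste0("G", 1:3)
  rt <- rescale_traits(m, trait_spec(c("up", "down"),
                                     c("increase", "decrease")))
  expect_equal(unname(rt$rx[, "up"]), c(0, 50, 100))
  expect_equal(unname(rt$rx[, "down"]), c(100, 50, 0))
  expect_true(all(rt$rx >= 0 & rt$rx <= 100))
  expect_error(rescale_traits(cbind(k = rep(1, 3)), trait_spec("k")), "k")
})

test_that("rescaling preserves absolute pairwise correlations", {
  set.seed(44)
  m <- matrix(rnorm(30 * 5, 50, 10), 30,
              dimnames = list(NULL, paste0("t", 1:5)))
  dirs <- c("increase", "decrease", "increase", "decrease", "increase")
  rt <- rescale_traits(m, trait_spec(paste0("t", 1:5), dirs))
  expect_equal(abs(stats::cor(rt$rx)), abs(stats::cor(m)), tolerance = 1e-12)
})

test_that("factor retention follows the Kaiser rule and rotation is clean", {
  set.seed(54)
  base <- matrix(rnorm(60 * 2), 60)
  m <- cbind(base[, 1] + rnorm(60, 0, 0.4), base[, 1] + rnorm(60, 0, 0.4),
             base[, 2] + rnorm(60, 0, 0.4), base[, 2] + rnorm(60, 0, 0.4))
  colnames(m) <- paste0("t", 1:4)
  m <- m * 5 + 50
  rt <- rescale_traits(m, trait_spec(colnames(m)))
  fm <- fit_efa(rt)
  expect_equal(sum(fm$eigenvalues), 4, tolerance = 1e-10)        # sum(lambda)=p
  expect_equal(fm$f, sum(fm$eigenvalues > 1))
  expect_equal(crossprod(fm$rotation), diag(fm$f), tolerance = 1e-10)
  expect_equal(rowSums(fm$loadings^2), rowSums(fm$initial_loadings^2),
               tolerance = 1e-10)                                # communalities
  expect_equal(fm$variance$cumulative_pct[4], 100, tolerance = 1e-10)
  # sign convention: each column's dominant loading is negative
  for (j in seq_len(fm$f))
    expect_lt(fm$loadings[which.max(abs(fm$loadings[, j])), j], 0)
})

test_that("an identity correlation matrix leaves nothing to retain", {
  # exactly orthogonal, zero-mean columns: R is the identity
  m <- cbind(a = c(-1, 1, -1, 1), b = c(-1, -1, 1, 1), c = c(1, -1, -1, 1))
  expect_equal(stats::cor(m), diag(3), ignore_attr = TRUE)
  expect_error(fit_efa(m), "n_factors")
  expect_s3_class(fit_efa(m, n_factors = 1), "factor_model")
})

test_that("varimax rotation is identity for one factor and monotone in general", {
  A1 <- matrix(c(0.9, 0.8, 0.7), 3, 1)
  out <- varimax_rotate(A1)
  expect_identical(out$loadings, A1)
  expect_equal(out$rotation, diag(1))

  kaiser <- function(A) A / sqrt(rowSums(A^2))
  crit <- metsel:::varimax_criterion
  set.seed(74)
  ok <- vapply(1:100, function(i) {
    A <- matrix(rnorm(12 * 3, sd = 0.5), 12, 3)
    A <- A[rowSums(A^2) > 1e-4, , drop = FALSE]
    r <- varimax_rotate(A)
    expect_equal(rowSums(r$loadings^2), rowSums(A^2), tolerance = 1e-8)
    crit(kaiser(r$loadings)) >= crit(kaiser(A)) - 1e-10
  }, TRUE)
  expect_true(all(ok))
})

test_that("factor scores center correctly and admit a 1-D closed form", {
  # one genotype sits exactly at the column means -> zero score
  m <- cbind(a = c(10, 15, 20, 25, 30), b = c(26, 14, 19, 25, 11))
  rownames(m) <- paste0("G", 1:5)
  rt <- rescale_traits(m, trait_spec(c("a", "b")))
  fm <- fit_efa(rt, n_factors = 1)
  st <- factor_scores(rt, fm)
  expect_equal(unname(colMeans(st$Z)), rep(0, 2), tolerance = 1e-12)
  expect_equal(unname(apply(st$Z, 2, stats::sd)), rep(1, 2))
  expect_equal(unname(st$scores["G3", ]), rep(0, fm$f), tolerance = 1e-10)

  # g = 2, p = 1: scores are +/- 1/sqrt(2); ideotype equals the better genotype
  m1 <- matrix(c(3, 7), 2, 1, dimnames = list(c("lo", "hi"), "y"))
  rt1 <- rescale_traits(m1, trait_spec("y"))
  fm1 <- fit_efa(rt1, n_factors = 1)
  st1 <- factor_scores(rt1, fm1)
  s <- 1 / sqrt(2)
  expect_equal(abs(unname(st1$scores[, 1])), c(s, s))
  expect_equal(unname(st1$ideotype_scores), unname(st1$scores["hi", 1]))
  d <- ideotype_distance(st1)
  expect_equal(unname(d[c("lo", "hi")]), c(2 * s, 0))
})

test_that("flipping a factor's sign flips genotype and ideotype scores together", {
  sim <- simulate_met(maize_sim_config(n_genotypes = 25, seed = 84))
  fit <- met_gamem(subset_regime(sim$dataset, "optimal"),
                   traits = c("GY", "PH", "EH", "D50A", "EG", "KRE"),
                   lrt = FALSE)
  bl <- blup_table(fit)
  rt <- rescale_traits(bl)
  fm <- fit_efa(rt)
  st <- factor_scores(rt, fm)
  fm2 <- fm
  fm2$loadings[, 1] <- -fm2$loadings[, 1]
  st2 <- factor_scores(rt, fm2)
  expect_equal(st2$scores[, 1], -st$scores[, 1], tolerance = 1e-10)
  expect_equal(st2$ideotype_scores[1], -st$ideotype_scores[1],
               tolerance = 1e-10)
  expect_equal(ideotype_distance(st2), ideotype_distance(st),
               tolerance = 1e-10)
})

test_that("the index is a Euclidean ideotype distance with stable ranks", {
  sc <- rbind(at_ideal = c(1, 2), off = c(4, 6))
  d <- ideotype_distance(sc, ideotype_scores = c(1, 2))
  expect_equal(unname(d), c(0, 5))  # per-factor gaps (3, 4)

  om <- strengths_weaknesses(sc, ideotype_scores = c(1, 2))
  expect_equal(unname(om["off", ]), c(0.36, 0.64))
  expect_equal(unname(om["at_ideal", ]), c(0.5, 0.5))  # undefined -> uniform
  expect_equal(attr(om, "undefined"), "at_ideal")

  set.seed(94)
  sc2 <- matrix(rnorm(40), 20, 2)
  om2 <- strengths_weaknesses(sc2, ideotype_scores = c(0.3, -0.2))
  expect_equal(unname(rowSums(om2)), rep(1, 20), tolerance = 1e-12)
})

test_that("selection takes the round-half-to-even count of lowest values", {
  v75 <- stats::setNames(seq(5, 6, length.out = 75), paste0("H", 1:75))
  expect_length(select_genotypes(v75, 0.15), 11)

  v10 <- stats::setNames(c(3, 9, 8, 7, 6, 5, 4, 2.5, 9.5, 10), paste0("g", 1:10))
  expect_equal(select_genotypes(v10, 0.10), "g8")

  expect_error(select_genotypes(v10[1:4], 0.10), "empty")
  vt <- c(a = 1, b = 2, c = 2, d = 3, e = 4, f = 5, g = 6, h = 7, i = 8, j = 9)
  expect_warning(sel <- select_genotypes(vt, 0.2), "tie")
  expect_equal(sel, c("a", "b"))
})

test_that("a genotype at every desirable extreme gets index zero and rank one", {
  set.seed(104)
  m <- matrix(rnorm(20 * 5, 50, 8), 20, dimnames = list(paste0("G", 1:20),
                                                        paste0("t", 1:5)))
  dirs <- c("increase", "increase", "decrease", "increase", "decrease")
  best <- apply(m, 2, max); best[dirs == "decrease"] <- apply(m, 2, min)[dirs == "decrease"]
  m <- rbind(m, STAR = best)
  res <- mgidi(m, traits = trait_spec(colnames(m), dirs), intensity = 0.15)
  expect_equal(res$index$mgidi[res$index$genotype == "STAR"], 0,
               tolerance = 1e-9)
  expect_equal(res$index$rank[res$index$genotype == "STAR"], 1)
  expect_true("STAR" %in% res$selected)
  expect_equal(sort(res$index$rank), seq_len(nrow(m)))
})

test_that("selection gains report means, differentials and goal flags", {
  m <- matrix(c(1, 2, 3, 4,
                8, 6, 4, 2), 4, 2,
              dimnames = list(paste0("G", 1:4), c("up", "down")))
  g <- selection_gains(m, selected = c("G3", "G4"),
                       traits = trait_spec(c("up", "down"),
                                           c("increase", "decrease")))
  expect_equal(g$xo, c(2.5, 5))
  expect_equal(g$xs, c(3.5, 3))
  expect_equal(g$sd, c(1, -2))
  expect_equal(g$sd_pct, c(40, -40))
  expect_true(all(g$goal_met))
  expect_error(selection_gains(m, character(0),
                               traits = trait_spec(c("up", "down"))), "empty")

  d <- selection_differential(174.14, 170.96)
  expect_equal(d$sd, 3.18, tolerance = 1e-12)
  expect_equal(round(d$sd_pct, 2), 1.86)
})

test_that("cross-regime overlap mirrors set algebra", {
  same <- list(a = c("1", "2"), b = c("1", "2"), c = c("1", "2"))
  ov <- cross_regime_overlap(same)
  expect_equal(ov$common, c("1", "2"))
  disj <- list(a = "1", b = "2", c = "3")
  ov2 <- cross_regime_overlap(disj)
  expect_equal(ov2$n_common, 0)
  expect_true(all(ov2$pairwise$n == 0))
})

test_that("the mgidi object is internally consistent end to end", {
  sim <- simulate_met(maize_sim_config(n_genotypes = 40, seed = 114))
  fit <- met_gamem(subset_regime(sim$dataset, "optimal"), lrt = FALSE)
  res <- mgidi(fit)
  expect_equal(res$n_selected, round(40 * 0.15))
  expect_true(all(res$index$mgidi >= 0))
  expect_equal(sort(res$index$rank), 1:40)
  expect_equal(unname(rowSums(res$omega)), rep(1, 40), tolerance = 1e-12)
  expect_setequal(res$index$genotype[res$index$selected], res$selected)
  expect_identical(coef(res), res$factor_model$loadings)
  # gains are computed on the same table that fed the index
  gy <- res$gains[res$gains$trait == "GY", ]
  expect_equal(gy$xs, mean(res$blups[res$selected, "GY"]))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(res))
  expect_invisible(plot(res, type = "contribution"))
})
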