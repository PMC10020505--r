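# EM-REML for the per-trait MET mixed model:
#   y = env + rep%in%env (fixed) + genotype + genotype:env + block%in%rep%in%env
#       (random) + residual
# Dense MME implementation; problem sizes here (<= a few hundred random
# levels) make sparse machinery unnecessary.

build_design <- function(ds, trait, random, include_block) {
  d <- ds$data[!is.na(ds$data[[trait]]), , drop = FALSE]
  if (!nrow(d)) stop("trait '", trait, "' has no observations", call. = FALSE)
  fr <- data.frame(
    y = d[[trait]],
    env = factor(d$environment),
    rep = factor(d$replicate),
    genotype = factor(d$genotype),
    stringsAsFactors = FALSE)
  fr$ge <- droplevels(interaction(fr$genotype, fr$env, sep = ":"))
  fr$blk <- droplevels(interaction(fr$env, fr$rep, d$block, sep = ":"))
  # blocks are only a distinct stratum if some replicate holds >1 of them
  n_er <- nlevels(droplevels(interaction(fr$env, fr$rep)))
  if (is.null(include_block)) include_block <- nlevels(fr$blk) > n_er
  if (!include_block) random <- setdiff(random, "block")
  if (nlevels(fr$env) > 1) {
    X <- stats::model.matrix(~ env + env:rep, fr)
  } else {
    X <- stats::model.matrix(~ rep, fr)
  }
  qx <- qr(X)
  X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  Zl <- list()
  if ("genotype" %in% random)
    Zl$genotype <- stats::model.matrix(~ 0 + genotype, fr)
  if ("gei" %in% random && nlevels(fr$env) > 1)
    Zl$gei <- stats::model.matrix(~ 0 + ge, fr)
  if ("block" %in% random)
    Zl$block <- stats::model.matrix(~ 0 + blk, fr)
  if (!length(Zl)) stop("no random terms in model", call. = FALSE)
  list(frame = fr, X = X, Z = Zl)
}

# balanced-formula method-of-moments starting values (clipped positive)
start_moments <- function(fr, terms) {
  vy <- stats::var(fr$y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  r <- tryCatch(stats::residuals(stats::lm(y ~ env + env:rep, data = fr)),
                error = function(e) fr$y - mean(fr$y))
  cell <- interaction(fr$genotype, fr$env, drop = TRUE)
  cw <- tapply(r, cell, stats::var)
  s2e <- stats::weighted.mean(cw, tapply(r, cell, length) - 1, na.rm = TRUE)
  if (!is.finite(s2e) || s2e <= 0) s2e <- vy / 3
  e <- nlevels(fr$env)
  b <- max(tapply(fr$rep, fr$env, function(x) length(unique(x))))
  cm <- tapply(r, list(fr$genotype, fr$env), mean)
  gm <- rowMeans(cm, na.rm = TRUE)
  inter <- sweep(sweep(cm, 1, gm), 2, colMeans(cm, na.rm = TRUE) - mean(gm))
  s2ge <- max(stats::var(as.vector(inter), na.rm = TRUE) - s2e / b, vy / 50)
  s2g <- max(stats::var(gm, na.rm = TRUE) - s2ge / e - s2e / (e * b), vy / 50)
  st <- c(genotype = s2g, gei = s2ge, block = s2e / 10, residual = s2e)
  st[c(terms, "residual")]
}

restricted_loglik <- function(sig, C0, Wty, yty, n, p, idx) {
  q <- vapply(idx, length, 0L)
  lam <- sig[["residual"]] / sig[names(idx)]
  M <- C0
  for (k in names(idx)) {
    ii <- idx[[k]]
    M[cbind(p + ii, p + ii)] <- M[cbind(p + ii, p + ii)] + lam[[k]]
  }
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  theta <- drop(backsolve(ch, backsolve(ch, Wty, transpose = TRUE)))
  rss <- max(yty - sum(theta * Wty), 1e-300)
  logdet <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * ((n - p) * log(2 * pi * sig[["residual"]]) +
                sum(q * log(sig[names(idx)] / sig[["residual"]])) +
                logdet + rss / sig[["residual"]])
  list(ll = ll, theta = theta, ch = ch, rss = rss)
}

#' Fit the per-trait MET mixed model by EM-REML
#'
#' Fits, for one trait, the standard multi-environment trial mixed model with
#' fixed environment and replicate-within-environment effects and random
#' genotype, genotype-by-environment and incomplete-block
#' (block-within-replicate-within-environment) effects:
#' \deqn{y = X\beta + Zu + \varepsilon .}
#' Variance components are estimated by restricted maximum likelihood using
#' the expectation-maximization algorithm on Henderson's mixed-model
#' equations; the restricted log-likelihood is non-decreasing across EM
#' iterations and the iteration trace is stored on the fit.
#'
#' @param ds a [met_dataset()] (typically one regime, see [subset_regime()]).
#' @param trait trait name.
#' @param random random terms to include, a subset of
#'   `c("genotype", "gei", "block")`.
#' @param include_block logical; `NULL` (default) includes the block term only
#'   when some replicate contains more than one incomplete block.
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default `1e-8`).
#' @param max_iter maximum EM iterations (default 500); non-convergence
#'   returns the fit with `converged = FALSE` and a warning.
#' @param floor lower bound for variance components during iteration
#'   (default `1e-10`); components ending at the floor are reported as 0.
#' @param start optional named numeric vector of starting values
#'   (`genotype`, `gei`, `block`, `residual`); defaults to balanced-formula
#'   method-of-moments values.
#' @return An object of class `met_reml` with components `vc` (variance
#'   components), `beta`, `u` (BLUPs per term), `loglik`, `loglik_trace`,
#'   `iterations`, `converged`, `grand_mean`, design sizes, and the model
#'   frame (for refits and likelihood-ratio tests).
#' @seealso [met_gamem()], [lrt_random_term()], [genetic_parameters()]
#' @examples
#' sim <- simulate_met(maize_sim_config(n_genotypes = 20,
#'   environments = data.frame(id = c("E1", "E2"), regime = "optimal")))
#' fit <- met_reml(sim$dataset, "GY")
#' fit
#' @export
met_reml <- function(ds, trait, random = c("genotype", "gei", "block"),
                     include_block = NULL, tol = 1e-8, max_iter = 500,
                     floor = 1e-10, start = NULL) {
  stopifnot(inherits(ds, "met_dataset"))
  if (!trait %in% ds$traits$name)
    stop("unknown trait: ", trait, call. = FALSE)
  random <- match.arg(random, several.ok = TRUE)
  des <- build_design(ds, trait, random, include_block)
  frame <- des$frame
  if (nlevels(frame$genotype) < 2)
    stop("need at least 2 genotypes", call. = FALSE)
  y <- frame$y
  X <- des$X
  Z <- do.call(cbind, des$Z)
  q <- vapply(des$Z, ncol, 0L)
  idx <- split(seq_len(sum(q)), rep(names(q), q))[names(q)]
  n <- length(y); p <- ncol(X)
  W <- cbind(X, Z)
  C0 <- crossprod(W)
  Wty <- drop(crossprod(W, y))
  yty <- sum(y^2)

  sig <- if (is.null(start)) start_moments(frame, names(q)) else
    start[c(names(q), "residual")]
  sig <- pmax(sig, floor)
  names(sig) <- c(names(q), "residual")

  trace <- numeric(0)
  converged <- FALSE
  step <- 1
  ev <- restricted_loglik(sig, C0, Wty, yty, n, p, idx)
  for (it in seq_len(max_iter)) {
    trace <- c(trace, ev$ll)
    # EM updates at current parameters
    theta <- ev$theta
    s2e_new <- ev$rss / (n - p)
    dCi <- diag(chol2inv(ev$ch))
    new <- sig
    for (k in names(idx)) {
      ii <- p + idx[[k]]
      uk <- theta[ii]
      trC <- sum(dCi[ii])
      new[[k]] <- (sum(uk^2) + sig[["residual"]] * trC) / length(ii)
    }
    new[["residual"]] <- s2e_new
    new <- pmax(new, floor)
    ev_new <- restricted_loglik(new, C0, Wty, yty, n, p, idx)
    if (!is.finite(ev_new$ll)) break
    # log-scale extrapolation along the EM direction, kept only if it
    # improves the restricted likelihood (monotonicity preserved)
    active <- new > floor & sig > floor
    if (any(active)) {
      cand <- new
      cand[active] <- pmax(exp(log(new[active]) +
                                 step * (log(new[active]) - log(sig[active]))),
                           floor)
      ev_cand <- restricted_loglik(cand, C0, Wty, yty, n, p, idx)
      if (is.finite(ev_cand$ll) && ev_cand$ll > ev_new$ll) {
        new <- cand; ev_new <- ev_cand
        step <- min(step * 2, 64)
      } else step <- 1
    }
    # components drifting to the zero boundary converge sublinearly under
    # EM; snap them to the floor when that improves the likelihood
    shrink <- names(idx)[new[names(idx)] < sig[names(idx)] &
                           new[names(idx)] > floor &
                           new[names(idx)] < 5e-2 * new[["residual"]]]
    if (length(shrink)) {
      for (fac in c(0, 0.1, 0.5)) {
        cand <- new
        cand[shrink] <- pmax(fac * cand[shrink], floor)
        ev_cand <- restricted_loglik(cand, C0, Wty, yty, n, p, idx)
        if (is.finite(ev_cand$ll) && ev_cand$ll > ev_new$ll) {
          new <- cand; ev_new <- ev_cand
          break
        }
      }
    }
    dll <- ev_new$ll - ev$ll
    sig <- new; ev <- ev_new
    if (abs(dll) < tol) { converged <- TRUE; break }
  }
  trace <- c(trace, ev$ll)
  if (!converged)
    warning("EM-REML did not converge in ", max_iter,
            " iterations for trait ", trait)

  theta <- ev$theta
  beta <- theta[seq_len(p)]; names(beta) <- colnames(X)
  u <- lapply(names(idx), function(k) {
    uk <- theta[p + idx[[k]]]
    names(uk) <- colnames(des$Z[[k]])
    uk
  })
  names(u) <- names(idx)
  if ("genotype" %in% names(u)) names(u$genotype) <- levels(frame$genotype)
  if ("gei" %in% names(u))      names(u$gei)      <- levels(frame$ge)
  if ("block" %in% names(u))    names(u$block)    <- levels(frame$blk)

  vc <- sig
  vc[vc <= floor * 1.01] <- 0
  fitted <- unname(drop(W %*% theta))
  reps <- tapply(frame$rep, frame$env, function(x) length(unique(x)))

  out <- list(trait = trait, regime = unique(ds$data$regime),
              vc = vc, beta = beta, u = u,
              loglik = ev$ll, loglik_trace = trace,
              iterations = length(trace) - 1L, converged = converged,
              n = n, p = p, q = q,
              e = nlevels(frame$env), b = as.integer(stats::median(reps)),
              grand_mean = mean(drop(X %*% beta)),
              fitted = fitted, y = y,
              frame = frame,
              fixed_cov_unscaled = chol2inv(ev$ch)[seq_len(p), seq_len(p),
                                                   drop = FALSE],
              tol = tol, max_iter = max_iter, floor = floor,
              call = match.call())
  class(out) <- "met_reml"
  out
}

#' @export
print.met_reml <- function(x, digits = 4, ...) {
  cat(sprintf("EM-REML fit: trait %s (%s; %d obs, e = %d, b = %d)\n",
              x$trait, paste(x$regime, collapse = "+"), x$n, x$e, x$b))
  cat(sprintf("  restricted logLik %.4f after %d iterations (%s)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat("  variance components:\n")
  print(round(x$vc, digits))
  invisible(x)
}

#' @export
logLik.met_reml <- function(object, ...) {
  structure(object$loglik, df = length(object$vc),
            nobs = object$n - object$p, class = "logLik")
}

#' @export
coef.met_reml <- function(object, ...) object$beta

#' @export
fitted.met_reml <- function(object, ...) object$fitted

#' @export
residuals.met_reml <- function(object, ...) object$y - object$fitted

#' Random-effect predictions (BLUPs) of a fitted model
#' @param object a `met_reml` fit.
#' @param term `"genotype"`, `"gei"` or `"block"`.
#' @return Named numeric vector of BLUPs.
#' @export
random_effects <- function(object, term = "genotype") {
  stopifnot(inherits(object, "met_reml"))
  term <- match.arg(term, names(object$u))
  object$u[[term]]
}

#' Predict genotype means from a fitted model
#'
#' Predicted genotype means on the trait scale: grand mean (average fixed
#' part) plus the genotype BLUP.
#'
#' @param object a `met_reml` fit.
#' @param ... unused.
#' @return Named numeric vector, one element per genotype.
#' @export
predict.met_reml <- function(object, ...) {
  object$grand_mean + object$u$genotype
}

#' @export
simulate.met_reml <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fr <- object$frame
  xb <- object$fitted - Reduce(`+`, lapply(names(object$u), function(k) {
    f <- switch(k, genotype = fr$genotype, gei = fr$ge, block = fr$blk)
    object$u[[k]][as.character(f)]
  }))
  out <- replicate(nsim, {
    ynew <- xb
    for (k in names(object$u)) {
      f <- switch(k, genotype = fr$genotype, gei = fr$ge, block = fr$blk)
      eff <- stats::rnorm(nlevels(f), 0, sqrt(object$vc[[k]]))
      names(eff) <- levels(f)
      ynew <- ynew + eff[as.character(f)]
    }
    ynew + stats::rnorm(length(xb), 0, sqrt(object$vc[["residual"]]))
  })
  as.data.frame(out)
}

#' @export
summary.met_reml <- function(object, ...) {
  gp <- genetic_parameters(object)
  out <- list(fit = object, parameters = gp)
  class(out) <- "summary.met_reml"
  out
}

#' @export
print.summary.met_reml <- function(x, ...) {
  print(x$fit)
  cat("  genetic parameters:\n")
  print(round(unlist(x$parameters), 4))
  invisible(x)
}
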