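# Zero-inflated Poisson occurrence model.
#
# Counts y_s of independent photographs at site s follow a mixture: with
# probability 1 - q the species is absent and y_s = 0; with probability q
# it is present and y_s ~ Poisson(lambda_s), with
#   log(lambda_s) = beta_0 + Z_s beta + log(T_s),
# T_s the camera-trap days at site s (a log offset) and Z the standardized
# covariates. One q per fitted model; no covariates on the presence part.

#' Zero-inflated Poisson log-probability mass
#'
#' For y = 0: log[(1 - q) + q e^-lambda]; for y >= 1:
#' log q + y log lambda - lambda - log y!. The zero branch is evaluated by
#' log-sum-exp, stable for lambda up to at least 1e3.
#'
#' @param y non-negative integer counts (vectorized).
#' @param q presence probability in `[0, 1]`.
#' @param lambda positive Poisson mean (vectorized, recycled against y).
#' @return log-probabilities.
#' @export
zip_logpmf <- function(y, q, lambda) {
  if (any(y < 0) || any(y != floor(y))) stop("y must be non-negative integers")
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  if (any(lambda <= 0)) stop("lambda must be positive")
  n <- max(length(y), length(lambda))
  y <- rep_len(y, n); lambda <- rep_len(lambda, n)
  out <- numeric(n)
  zero <- y == 0
  if (any(zero)) {
    # log((1-q) + q*exp(-lambda)) via log-sum-exp of log(1-q) and log(q)-lambda
    la <- log1p(-q)                     # -Inf when q = 1
    lb <- log(q) - lambda[zero]         # -Inf when q = 0
    m <- pmax(la, lb)
    out[zero] <- m + log(exp(la - m) + exp(lb - m))
  }
  if (any(!zero)) {
    out[!zero] <- log(q) + stats::dpois(y[!zero], lambda[!zero], log = TRUE)
  }
  out
}

#' ZIP model log-likelihood
#'
#' @param y per-site counts of independent photographs.
#' @param trap_days per-site camera-trap days (the log offset), positive.
#' @param Z standardized covariate matrix, sites x p.
#' @param q presence probability.
#' @param beta numeric vector of length p + 1: intercept first, then one
#'   slope per column of Z.
#' @return scalar log-likelihood.
#' @export
zip_loglik <- function(y, trap_days, Z, q, beta) {
  Z <- as.matrix(Z)
  if (length(y) != nrow(Z) || length(trap_days) != nrow(Z)) {
    stop("y, trap_days and Z must have matching lengths")
  }
  if (length(beta) != ncol(Z) + 1L) {
    stop("beta must have length ncol(Z) + 1 (intercept first)")
  }
  if (any(trap_days <= 0)) stop("trap_days must be positive")
  eta <- beta[1] + drop(Z %*% beta[-1]) + log(trap_days)
  # keep exp(eta) inside the double range so optimizers can roam freely
  lambda <- exp(pmin(pmax(eta, -700), 700))
  sum(zip_logpmf(y, q, lambda))
}

.zip_logpost <- function(theta, y, trap_days, Z, prior_sd = 10) {
  q <- stats::plogis(theta[1])
  ll <- zip_loglik(y, trap_days, Z, q, theta[-1])
  # uniform(0,1) prior on q expressed on the logit scale (Jacobian), plus
  # wide normal priors on the betas
  ll + stats::dlogis(theta[1], log = TRUE) +
    sum(stats::dnorm(theta[-1], 0, prior_sd, log = TRUE))
}

#' Maximum-likelihood fit of the ZIP occurrence model
#'
#' Numerical maximization of [zip_loglik()] over (logit q, beta) by BFGS
#' with seeded multistart to guard against local optima. Serves as an
#' independent point-estimate oracle for the MCMC fit.
#'
#' @param y,trap_days,Z as in [zip_loglik()].
#' @param n_starts number of optimizer starts (at least 5 recommended).
#' @param seed integer seed for the start points.
#' @param fix_q optionally fix the presence probability (e.g. `fix_q = 1`
#'   reduces the model to a plain Poisson regression with offset).
#' @return list: q, beta, se (delta-method standard errors on (q, beta)
#'   from the numerical Hessian; NA where the curvature is degenerate),
#'   loglik, convergence (0 = clean), n_starts.
#' @export
fit_zip_mle <- function(y, trap_days, Z, n_starts = 5, seed = 1,
                        fix_q = NULL) {
  Z <- as.matrix(Z)
  if (all(y == 0)) {
    stop("all counts are zero: q and the intercept are not identifiable")
  }
  p <- ncol(Z)
  neg <- if (is.null(fix_q)) {
    function(theta) -.zip_logpost_flat(theta, y, trap_days, Z)
  } else {
    function(beta) -zip_loglik(y, trap_days, Z, fix_q, beta)
  }
  best <- NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  b0_guess <- log(sum(y) / sum(trap_days))
  for (s in seq_len(n_starts)) {
    start <- c(if (is.null(fix_q)) stats::runif(1, -1, 2),
               b0_guess + stats::rnorm(1, 0, 0.5),
               stats::rnorm(p, 0, 0.3))
    fit <- tryCatch(
      stats::optim(start, neg, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("ZIP MLE failed to converge in all starts")
  hess <- tryCatch(stats::optimHess(best$par, neg), error = function(e) NULL)
  se <- rep(NA_real_, length(best$par))
  if (!is.null(hess)) {
    cov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov)) {
      dg <- diag(cov)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  beta_names <- c("(Intercept)", colnames(Z))
  if (is.null(fix_q)) {
    qhat <- stats::plogis(best$par[1])
    se_q <- se[1] * qhat * (1 - qhat)      # delta method on the logit scale
    list(q = qhat,
         beta = stats::setNames(best$par[-1], beta_names),
         se = stats::setNames(c(se_q, se[-1]), c("q", beta_names)),
         loglik = -best$value, convergence = best$convergence,
         n_starts = n_starts)
  } else {
    list(q = fix_q,
         beta = stats::setNames(best$par, beta_names),
         se = stats::setNames(se, beta_names),
         loglik = -best$value, convergence = best$convergence,
         n_starts = n_starts)
  }
}

# flat (prior-free) objective for the MLE; kept separate from the posterior
.zip_logpost_flat <- function(theta, y, trap_days, Z) {
  q <- stats::plogis(theta[1])
  # clamp away from the boundary so the logit stays finite
  q <- min(max(q, 1e-12), 1 - 1e-12)
  zip_loglik(y, trap_days, Z, q, theta[-1])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half and the Gelman–Rubin statistic computed on
#' the resulting 2m half-chains from the between- and within-chain
#' variances. Identical constant chains return exactly 1 (the 0/0 case is
#' defined as converged).
#'
#' @param chains matrix of draws, iterations x chains (>= 2 chains, >= 10
#'   iterations), or a list of equal-length numeric vectors.
#' @return scalar R-hat.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("R-hat needs at least two chains")
  if (nrow(chains) < 10L) stop("R-hat needs at least 10 iterations per chain")
  half <- floor(nrow(chains) / 2)
  split_chains <- cbind(chains[seq_len(half), , drop = FALSE],
                        chains[(nrow(chains) - half + 1):nrow(chains), , drop = FALSE])
  n <- nrow(split_chains); m <- ncol(split_chains)
  means <- colMeans(split_chains)
  vars <- apply(split_chains, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess_basic <- function(x) {
  # initial-positive-sequence estimator on a single concatenated chain
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  acf_vals <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k <= length(acf_vals) && acf_vals[k] > 0) {
    s <- s + acf_vals[k]
    k <- k + 1
  }
  max(1, n / (1 + 2 * s))
}

#' Fit the ZIP occurrence model by MCMC
#'
#' Adaptive component-wise random-walk Metropolis on (logit q, beta) with a
#' uniform(0,1) prior on q and normal(0, 10^2) priors on each beta
#' (covariates are standardized, so these are effectively flat). Proposal
#' scales adapt during warmup toward a 44% acceptance rate and are frozen
#' afterwards, so the retained draws target the exact posterior.
#' Convergence is declared when every parameter's split R-hat is below 1.1;
#' a non-converged fit is returned flagged, never discarded.
#'
#' @param y,trap_days,Z as in [zip_loglik()].
#' @param chains number of chains (default 4).
#' @param iterations total iterations per chain (default 2000).
#' @param warmup burn-in iterations discarded per chain (default 1000).
#' @param thin thinning interval (default 1, unthinned).
#' @param seed integer seed; chain c uses seed + c.
#' @param prior_sd prior SD for the betas (default 10).
#' @return object of class `zip_posterior`: list with `draws` (array
#'   kept-iterations x chains x parameters), `rhat`, `ess`, `converged`,
#'   `settings`.
#' @export
fit_zip_mcmc <- function(y, trap_days, Z, chains = 4, iterations = 2000,
                         warmup = 1000, thin = 1, seed = 1, prior_sd = 10) {
  Z <- as.matrix(Z)
  if (chains < 2) stop("need at least 2 chains for convergence diagnostics")
  if (warmup >= iterations) stop("warmup must be smaller than iterations")
  if (thin < 1) stop("thin must be >= 1")
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  p <- ncol(Z) + 2L                      # logit q, intercept, slopes
  par_names <- c("q", "(Intercept)", colnames(Z))
  kept <- floor((iterations - warmup) / thin)
  draws <- array(NA_real_, dim = c(kept, chains, p),
                 dimnames = list(NULL, NULL, par_names))
  b0_guess <- log(sum(y) / max(sum(trap_days), 1))
  if (!is.finite(b0_guess)) b0_guess <- 0
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch)
    theta <- c(stats::runif(1, -2, 2),
               b0_guess + stats::rnorm(1, 0, 1),
               stats::rnorm(p - 2L, 0, 0.5))
    scales <- rep(0.5, p)
    lp <- .zip_logpost(theta, y, trap_days, Z, prior_sd)
    acc <- integer(p)
    batch <- 0L
    row <- 0L
    for (it in seq_len(iterations)) {
      for (j in seq_len(p)) {
        prop <- theta
        prop[j] <- prop[j] + stats::rnorm(1, 0, scales[j])
        lp_prop <- .zip_logpost(prop, y, trap_days, Z, prior_sd)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
          theta <- prop
          lp <- lp_prop
          acc[j] <- acc[j] + 1L
        }
      }
      batch <- batch + 1L
      if (it <= warmup && batch == 50L) {
        rate <- acc / 50
        scales <- scales * exp((rate - 0.44))
        scales <- pmin(pmax(scales, 1e-3), 10)
        acc <- integer(p)
        batch <- 0L
      }
      if (it > warmup && (it - warmup) %% thin == 0L) {
        row <- row + 1L
        draws[row, ch, ] <- c(stats::plogis(theta[1]), theta[-1])
      }
    }
  }
  rh <- vapply(seq_len(p), function(j) rhat(draws[, , j]), numeric(1))
  ess <- vapply(seq_len(p), function(j) .ess_basic(as.vector(draws[, , j])),
                numeric(1))
  names(rh) <- names(ess) <- par_names
  structure(list(draws = draws, rhat = rh, ess = ess,
                 converged = all(rh < 1.1),
                 settings = list(chains = chains, iterations = iterations,
                                 warmup = warmup, thin = thin, seed = seed,
                                 prior = sprintf("q ~ uniform(0,1); beta ~ normal(0, %g)",
                                                 prior_sd))),
            class = "zip_posterior")
}

#' @export
print.zip_posterior <- function(x, ...) {
  cat("ZIP posterior:", dim(x$draws)[2], "chains x", dim(x$draws)[1],
      "kept draws;", if (x$converged) "converged" else "NOT converged",
      "(max R-hat", sprintf("%.3f)", max(x$rhat)), "\n")
  invisible(x)
}

#' Posterior effect summaries
#'
#' Posterior means with equal-tailed 80% and 95% credible intervals per
#' parameter; an effect is flagged significant when its 95% interval
#' excludes zero. Parameters are reported in the fixed order slope, road,
#' settlement, water, deciduous, coniferous, other-species rate, intercept
#' (whichever are present in the fitted model), followed by q.
#'
#' @param posterior a `zip_posterior` from [fit_zip_mcmc()].
#' @return data.frame: parameter, mean, lo95, hi95, lo80, hi80,
#'   significant, rhat.
#' @export
summarize_effects <- function(posterior) {
  stopifnot(inherits(posterior, "zip_posterior"))
  par_names <- dimnames(posterior$draws)[[3]]
  preferred <- c("slope_mean_deg", "dist_road_km", "dist_settlement_km",
                 "dist_water_km", "area_decid_km2", "area_conif_km2",
                 "rate_other_species", "(Intercept)")
  ordered <- c(intersect(preferred, par_names),
               setdiff(par_names, c(preferred, "q")), "q")
  rows <- lapply(ordered, function(nm) {
    d <- as.vector(posterior$draws[, , nm])
    qs <- stats::quantile(d, c(0.025, 0.975, 0.10, 0.90), names = FALSE)
    data.frame(parameter = nm, mean = mean(d),
               lo95 = qs[1], hi95 = qs[2], lo80 = qs[3], hi80 = qs[4],
               significant = nm != "q" && (qs[1] > 0 || qs[2] < 0),
               rhat = posterior$rhat[[nm]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
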