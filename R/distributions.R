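# Internal distribution calibration helpers for the synthetic cohort
# generator. Published cohort tables report summaries (mean/SD with a hard
# age floor, median/IQR of skewed stay lengths and counts); the generator
# works with latent parametric families whose *observed* summaries must hit
# those targets, so each family gets a small deterministic solver.

# Lower-truncated normal: solve latent (mu, sigma) so that the truncated
# distribution has the requested mean and sd. Uses the closed-form truncated
# moments; the mean-to-floor distance in sd units pins down alpha.
solve_truncnorm <- function(mean, sd, lower) {
  stopifnot(mean > lower, sd > 0)
  lambda <- function(a) dnorm(a) / pnorm(a, lower.tail = FALSE)
  ratio <- function(a) {
    l <- lambda(a)
    (l - a) / sqrt(1 + a * l - l^2)
  }
  target <- (mean - lower) / sd
  if (target <= 1) {
    stop("requested mean/sd are infeasible for a lower-truncated normal")
  }
  alpha <- uniroot(function(a) ratio(a) - target, c(-8, 8), tol = 1e-10)$root
  l <- lambda(alpha)
  sigma <- sd / sqrt(1 + alpha * l - l^2)
  mu <- lower - alpha * sigma
  list(mu = mu, sigma = sigma, lower = lower)
}

# Inverse-CDF sampler for the lower-truncated normal (deterministic given
# the RNG stream, no rejection).
rtruncnorm_lower <- function(n, mu, sigma, lower) {
  p0 <- pnorm(lower, mu, sigma)
  mu + sigma * qnorm(p0 + runif(n) * (1 - p0))
}

# Log-normal truncated below at `lower` days: solve (meanlog, sdlog) by
# least squares on the reported quartiles (median weighted up, since it is
# the calibration target with the tightest tolerance).
solve_lognormal_trunc <- function(q25, q50, q75, lower = 1) {
  qfun <- function(p, meanlog, sdlog) {
    p0 <- stats::plnorm(lower, meanlog, sdlog)
    stats::qlnorm(p0 + p * (1 - p0), meanlog, sdlog)
  }
  obj <- function(par) {
    m <- par[1]
    s <- exp(par[2])
    4 * (qfun(0.5, m, s) - q50)^2 +
      (qfun(0.25, m, s) - q25)^2 +
      (qfun(0.75, m, s) - q75)^2
  }
  fit <- optim(c(log(q50), log(0.9)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]), lower = lower)
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower) {
  p0 <- stats::plnorm(lower, meanlog, sdlog)
  stats::qlnorm(p0 + runif(n) * (1 - p0), meanlog, sdlog)
}

# Negative binomial matched to a median/IQR target by grid search (quantiles
# of a discrete family are step functions, so derivative-based optimisation
# is unreliable).
solve_nbinom <- function(q25, q50, q75) {
  sizes <- seq(1.2, 9, by = 0.1)
  mus <- seq(q50 - 4, q50 + 5, by = 0.2)
  best <- NULL
  best_loss <- Inf
  for (s in sizes) {
    q <- vapply(mus, function(m) {
      qq <- qnbinom(c(0.25, 0.5, 0.75), size = s, mu = m)
      (qq[1] - q25)^2 + 3 * (qq[2] - q50)^2 + (qq[3] - q75)^2
    }, numeric(1))
    i <- which.min(q)
    if (q[i] < best_loss) {
      best_loss <- q[i]
      best <- list(size = s, mu = mus[i])
    }
  }
  best
}

# Marginal calibration under a patient-level random intercept. If the
# per-admission success probability is plogis(m + u) with u ~ N(0, sigma^2),
# the marginal rate E_u[plogis(m + u)] exceeds/shrinks plogis(m) toward 1/2,
# so hitting a target marginal rate requires solving for the location m.
# Gauss-Hermite quadrature, vectorized over eta via a spline on a fixed grid.
logit_marginal_mean <- function(m, sigma, gh) {
  # E_u plogis(m + u), u ~ N(0, sigma^2); gh = list(nodes, weights) for N(0,1)
  sapply(m, function(mm) sum(gh$w * plogis(mm + sigma * gh$x)))
}

gauss_hermite_normal <- function(k = 21) {
  # nodes/weights for E[f(Z)], Z ~ N(0,1), via Hermite polynomial roots
  i <- seq_len(k - 1)
  b <- sqrt(i / 2)
  J <- diag(0, k)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values * sqrt(2), w = e$vectors[1, ]^2)
}

# Returns a vectorized function eta -> m such that
# E_u[plogis(m + u)] = plogis(eta).
marginal_logit_adjuster <- function(sigma) {
  if (sigma <= 0) return(identity)
  gh <- gauss_hermite_normal(25)
  grid_m <- seq(-14, 14, by = 0.1)
  grid_p <- logit_marginal_mean(grid_m, sigma, gh)
  # marginal mean is strictly increasing in m; invert by spline
  inv <- splinefun(qlogis(grid_p), grid_m, method = "hyman")
  function(eta) inv(pmin(pmax(eta, qlogis(plogis(-13))), qlogis(plogis(13))))
}
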