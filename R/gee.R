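#' Clustered logistic regression via generalized estimating equations
#'
#' Fits a marginal logistic model for correlated binary outcomes (repeat
#' admissions clustered within patients) by GEE with an independence or
#' exchangeable working correlation, and reports robust (sandwich)
#' standard errors, odds ratios with 95% confidence intervals and
#' two-sided Wald p-values. With all clusters of size one (or an
#' independence working correlation) the point estimates coincide with
#' ordinary logistic maximum likelihood.
#'
#' The exchangeable correlation parameter is estimated from Pearson
#' residual cross-products at each scoring step; the compound-symmetry
#' working covariance is inverted in closed form, so the fit is a few
#' vectorized passes over the data regardless of the number of clusters.
#'
#' @param formula model formula; the response must be 0/1 (or logical).
#' @param data data frame containing the model variables.
#' @param id cluster identifier: either a vector of length `nrow(data)` or
#'   the name of a column in `data`.
#' @param working_corr `"exchangeable"` (default) or `"independence"`.
#' @param maxit,tol scoring iteration controls.
#' @return An object of class `ipp_gee` with elements `coefficients`,
#'   `robust_se`, `vcov` (robust), `or`, `ci_lower`, `ci_upper`,
#'   `p_value`, `alpha` (working correlation), `phi` (dispersion),
#'   `n_obs`, `n_clusters`, `converged`, plus the terms needed by
#'   [predict.ipp_gee()]. Non-convergence is flagged (`converged = FALSE`,
#'   estimates `NA`), not raised as an error; perfect separation is an
#'   error.
#' @export
fit_gee_logistic <- function(formula, data, id,
                             working_corr = c("exchangeable", "independence"),
                             maxit = 50, tol = 1e-8) {
  working_corr <- match.arg(working_corr)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1))) stop("response must be binary (0/1)")
  if (length(unique(y)) < 2) stop("outcome has a single class; nothing to model")
  X <- stats::model.matrix(mt, mf)
  nonconst <- apply(X[, colnames(X) != "(Intercept)", drop = FALSE], 2,
                    function(v) diff(range(v)) > 0)
  if (length(nonconst) > 0 && !all(nonconst)) {
    stop("constant covariate(s): ",
         paste(names(nonconst)[!nonconst], collapse = ", "))
  }
  if (qr(X)$rank < ncol(X)) stop("model matrix is rank deficient")

  if (is.character(id) && length(id) == 1) {
    if (!id %in% names(data)) stop("cluster column not found: ", id)
    id <- data[[id]]
  }
  if (length(id) != nrow(X)) stop("cluster id length does not match data")
  gid <- as.integer(factor(id))
  m <- tabulate(gid)
  n <- nrow(X)
  p <- ncol(X)

  beta <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = binomial())$coefficients),
    error = function(e) rep(0, p)
  )
  if (anyNA(beta)) beta <- rep(0, p)

  alpha <- 0
  phi <- 1
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    if (max(abs(eta)) > 30) {
      mu_chk <- plogis(eta)
      if (all(abs(y - mu_chk) < 1e-8)) stop("perfect separation detected")
    }
    mu <- plogis(eta)
    A <- pmax(mu * (1 - mu), 1e-12)
    w <- sqrt(A)
    r <- y - mu
    e <- r / w
    phi <- sum(e^2) / (n - p)
    if (working_corr == "exchangeable") {
      Se <- rowsum(e, gid)
      Se2 <- rowsum(e^2, gid)
      npairs <- sum(m * (m - 1)) / 2
      alpha <- if (npairs > p) {
        sum(Se^2 - Se2) / 2 / ((npairs - p) * phi)
      } else 0
      alpha <- min(max(alpha, 0), 0.95)
    }
    cm <- (alpha / (1 + (m - 1) * alpha))[gid] # per-observation cluster shrink
    s <- e # A^{-1/2} (y - mu)
    S <- rowsum(s, gid)[gid]
    z <- w * (s - cm * S) / (1 - alpha)
    WX <- X * w
    G <- rowsum(WX, gid)
    cgrp <- alpha / (1 + (m - 1) * alpha)
    H <- (crossprod(WX) - crossprod(G * sqrt(cgrp))) / (1 - alpha)
    U <- drop(crossprod(X, z))
    step <- tryCatch(solve(H, U), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }

  out <- list(
    formula = formula, terms = mt, xlevels = stats::.getXlevels(mt, mf),
    working_corr = working_corr, n_obs = n, n_clusters = length(m),
    alpha = if (working_corr == "exchangeable") alpha else 0,
    phi = phi, converged = converged
  )
  class(out) <- "ipp_gee"
  if (!converged) {
    out$coefficients <- setNames(rep(NA_real_, p), colnames(X))
    out$robust_se <- out$or <- out$ci_lower <- out$ci_upper <- out$p_value <-
      setNames(rep(NA_real_, p), colnames(X))
    return(out)
  }

  # robust sandwich variance at the solution
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  A <- pmax(mu * (1 - mu), 1e-12)
  w <- sqrt(A)
  r <- y - mu
  s <- r / w
  cm <- (alpha / (1 + (m - 1) * alpha))[gid]
  S <- rowsum(s, gid)[gid]
  z <- w * (s - cm * S) / (1 - alpha)
  WX <- X * w
  G <- rowsum(WX, gid)
  cgrp <- alpha / (1 + (m - 1) * alpha)
  H <- (crossprod(WX) - crossprod(G * sqrt(cgrp))) / (1 - alpha)
  G2 <- rowsum(X * z, gid)
  M <- crossprod(G2)
  Hinv <- solve(H)
  V <- Hinv %*% M %*% Hinv
  se <- sqrt(diag(V))

  out$coefficients <- setNames(drop(beta), colnames(X))
  out$vcov <- V
  out$robust_se <- setNames(se, colnames(X))
  zval <- out$coefficients / se
  out$p_value <- 2 * pnorm(-abs(zval))
  out$or <- exp(out$coefficients)
  out$ci_lower <- exp(out$coefficients - qnorm(0.975) * se)
  out$ci_upper <- exp(out$coefficients + qnorm(0.975) * se)
  out
}

#' @export
print.ipp_gee <- function(x, ...) {
  cat(sprintf("<ipp_gee> logistic GEE (%s working correlation)\n", x$working_corr))
  cat(sprintf("  %d observations in %d clusters; alpha = %.3f%s\n",
              x$n_obs, x$n_clusters, x$alpha,
              if (!x$converged) "; DID NOT CONVERGE" else ""))
  if (x$converged) print(tidy_gee(x), n = Inf)
  invisible(x)
}

#' Coefficient table of a GEE fit
#'
#' @param fit an `ipp_gee` object.
#' @return Tibble with `term`, `estimate` (log-odds), `robust_se`, `or`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
tidy_gee <- function(fit) {
  stopifnot(inherits(fit, "ipp_gee"))
  tibble::tibble(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    robust_se = unname(fit$robust_se),
    or = unname(fit$or),
    ci_lower = unname(fit$ci_lower),
    ci_upper = unname(fit$ci_upper),
    p_value = unname(fit$p_value)
  )
}

#' Predictions from a GEE logistic fit
#'
#' @param object an `ipp_gee` fit.
#' @param newdata data frame with the model covariates.
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.ipp_gee <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (!object$converged) stop("cannot predict from a non-converged fit")
  tt <- delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels,
                           na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)
  eta <- drop(X %*% object$coefficients[colnames(X)])
  if (type == "link") eta else plogis(eta)
}
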