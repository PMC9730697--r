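#' Prior for the spline coefficients
#'
#' Multivariate normal prior on the Ramsay-curve coefficient vector eta.
#' A diffuse prior keeps the coefficients estimable in regions of the trait
#' scale carrying little information, where the spline coefficients are
#' otherwise empirically underidentified.  The default is mean zero with
#' covariance `tau^2 * I`.
#'
#' @param m basis dimension (length of eta).
#' @param mu prior mean vector (scalar is recycled).
#' @param tau prior standard deviation when an isotropic covariance is used.
#' @param sigma full m x m covariance matrix; overrides `tau` when given.
#' @return a list with elements `mu`, `sigma`, `prec` (the precision matrix)
#'   and `isotropic` (flag used for the eta re-centering safeguard).
#' @export
etaPrior <- function(m, mu = 0, tau = 10, sigma = NULL) {
  m <- as.integer(m)
  stopifnot(m >= 1L)
  mu <- rep_len(as.numeric(mu), m)
  if (is.null(sigma)) {
    stopifnot(tau > 0)
    sigma <- diag(tau^2, m)
    prec <- diag(1 / tau^2, m)
    iso <- all(mu == mu[1])
  } else {
    sigma <- as.matrix(sigma)
    if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-12)))
      stop("`sigma` must be symmetric")
    prec <- tryCatch(chol2inv(chol(sigma)),
                     error = function(e) stop("`sigma` must be positive definite"))
    iso <- FALSE
  }
  list(mu = mu, sigma = sigma, prec = prec, isotropic = iso)
}

# log-likelihood part of the Ramsay-curve posterior from grid counts:
# sum_q n_q log g_q(eta) = n' (B eta) - N logC.  Counts may be real valued
# (they are Robbins-Monro-smoothed inside the SAEM loop).
.etaLogLik <- function(eta, counts, basis) {
  u <- drop(basis@matrix %*% eta)
  sum(counts * u) - sum(counts) * .logSumExp(u)
}

#' Log Ramsay-curve posterior
#'
#' Log posterior (up to a constant) of the spline coefficients given sampled
#' abilities summarized as per-grid-point counts: the grid-count
#' log-likelihood plus the multivariate normal log prior penalty
#' `-(eta - mu)' prec (eta - mu) / 2`.  Because every sampled ability is a
#' grid point, the count representation is exactly the sum of log densities
#' over examinees.
#'
#' @param eta coefficient vector of length m.
#' @param counts nonnegative vector of length Q (counts of sampled abilities
#'   per grid point; may be non-integer after stochastic-approximation
#'   smoothing).
#' @param basis a [SplineBasis-class].
#' @param prior an [etaPrior()] list.
#' @return scalar log posterior (up to an additive constant).
#' @export
logRCP <- function(eta, counts, basis, prior) {
  stopifnot(is(basis, "SplineBasis"))
  eta <- as.numeric(eta)
  counts <- as.numeric(counts)
  if (length(eta) != basis@m) stop("`eta` must have length m")
  if (length(counts) != basis@grid@Q) stop("`counts` must have length Q")
  d <- eta - prior$mu
  .etaLogLik(eta, counts, basis) - 0.5 * drop(crossprod(d, prior$prec %*% d))
}

#' Gradient and Hessian of the log Ramsay-curve posterior
#'
#' Analytic derivatives used by the Newton-Raphson update: the gradient is
#' `B'(n - N g) - prec (eta - mu)` and the Hessian is
#' `-N (B' diag(g) B - (B'g)(B'g)') - prec`, where `g` is the density at
#' `eta` and `N = sum(counts)`.  The likelihood part of the Hessian is the
#' negative of a covariance-form matrix and hence negative semidefinite.
#'
#' @inheritParams logRCP
#' @return list with elements `gradient` (length m) and `hessian` (m x m).
#' @export
rcpDerivatives <- function(eta, counts, basis, prior) {
  stopifnot(is(basis, "SplineBasis"))
  eta <- as.numeric(eta)
  counts <- as.numeric(counts)
  if (length(eta) != basis@m) stop("`eta` must have length m")
  if (length(counts) != basis@grid@Q) stop("`counts` must have length Q")
  B <- basis@matrix
  N <- sum(counts)
  g <- ramsayPdf(basis, eta)@mass
  Bg <- drop(crossprod(B, g))
  gradient <- drop(crossprod(B, counts - N * g)) - drop(prior$prec %*% (eta - prior$mu))
  hessian <- -N * (crossprod(B, g * B) - tcrossprod(Bg)) - prior$prec
  list(gradient = gradient, hessian = (hessian + t(hessian)) / 2)
}

#' MAP estimate of the spline coefficients
#'
#' Newton-Raphson maximization of [logRCP()] with step-halving to enforce
#' monotone ascent and a ridge fallback when the negated Hessian is not
#' positive definite.  When the prior is isotropic with a constant mean the
#' iterate is re-centered to mean zero after each accepted step (the density
#' is invariant to adding a constant to eta, and re-centering can only
#' increase the isotropic prior density).
#'
#' @inheritParams logRCP
#' @param init starting value (defaults to the prior mean).
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @param maxInner maximum number of Newton iterations.
#' @return the fitted coefficient vector.
#' @export
fitEtaMAP <- function(counts, basis, prior, init = NULL, tol = 1e-6,
                      maxInner = 50L) {
  stopifnot(is(basis, "SplineBasis"), tol > 0, maxInner >= 1)
  m <- basis@m
  eta <- if (is.null(init)) prior$mu else as.numeric(init)
  if (length(eta) != m || any(!is.finite(eta)))
    stop("`init` must be a finite vector of length m")
  recenter <- isTRUE(prior$isotropic) && all(prior$mu == 0)
  if (recenter) eta <- eta - mean(eta)
  f <- logRCP(eta, counts, basis, prior)
  for (it in seq_len(maxInner)) {
    der <- rcpDerivatives(eta, counts, basis, prior)
    nH <- -der$hessian
    step <- NULL
    ridge <- 0
    for (tries in 0:6) {
      ch <- tryCatch(chol(nH + diag(ridge, m)), error = function(e) NULL)
      if (!is.null(ch)) {
        step <- backsolve(ch, forwardsolve(t(ch), der$gradient))
        break
      }
      ridge <- if (ridge == 0) 1e-8 else ridge * 100
    }
    if (is.null(step))
      stop("Newton update failed: negated Hessian not positive definite ",
           "even after ridge regularization")
    # step-halving to enforce ascent of the posterior
    lambda <- 1
    accepted <- FALSE
    for (h in 0:20) {
      cand <- eta + lambda * step
      if (recenter) cand <- cand - mean(cand)
      fc <- logRCP(cand, counts, basis, prior)
      if (is.finite(fc) && fc >= f - 1e-12) {
        accepted <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!accepted) break  # no ascent possible: numerically converged
    delta <- max(abs(cand - eta))
    eta <- cand
    f <- fc
    if (delta < tol) break
  }
  eta
}
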