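#' Two-component normal mixture specification
#'
#' Container for `p1 N(mu1, var1) + p2 N(mu2, var2)` with `p1 + p2 = 1`,
#' the generating family for the skewed and bimodal true ability densities
#' of the first simulation design.
#'
#' @param p1 weight of the first component, in (0, 1).
#' @param mu1,var1 first component mean and variance.
#' @param mu2,var2 second component mean and variance.
#' @return a list with class fields used by the mixture helpers.
#' @export
mixtureSpec <- function(p1, mu1, var1, mu2, var2) {
  stopifnot(p1 > 0, p1 < 1, var1 > 0, var2 > 0)
  list(p = c(p1, 1 - p1), mu = c(mu1, mu2), var = c(var1, var2))
}

#' Analytic moments of a two-component normal mixture
#'
#' Closed-form mean, sd, skewness and (non-excess) kurtosis of the mixture,
#' from the central moments
#' `E(X - mu)^3 = sum p_k (d_k^3 + 3 d_k s_k^2)` and
#' `E(X - mu)^4 = sum p_k (d_k^4 + 6 d_k^2 s_k^2 + 3 s_k^4)` with
#' `d_k = mu_k - mu`.
#'
#' @param mix a [mixtureSpec()].
#' @return named numeric `(mean, sd, skewness, kurtosis)`.
#' @export
mixtureMoments <- function(mix) {
  p <- mix$p; muk <- mix$mu; v <- mix$var
  mu <- sum(p * muk)
  d <- muk - mu
  m2 <- sum(p * (d^2 + v))
  m3 <- sum(p * (d^3 + 3 * d * v))
  m4 <- sum(p * (d^4 + 6 * d^2 * v + 3 * v^2))
  c(mean = mu, sd = sqrt(m2), skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

#' Mixture density discretized on a grid
#'
#' Evaluates the two-component normal mixture at the grid points and
#' renormalizes the values to a mass vector summing to 1.
#'
#' @param mix a [mixtureSpec()].
#' @param grid a [ThetaGrid-class].
#' @return numeric mass vector of length `grid@Q`.
#' @export
mixturePdfOnGrid <- function(mix, grid) {
  stopifnot(is(grid, "ThetaGrid"))
  w <- mix$p[1] * dnorm(grid@points, mix$mu[1], sqrt(mix$var[1])) +
       mix$p[2] * dnorm(grid@points, mix$mu[2], sqrt(mix$var[2]))
  w / sum(w)
}

#' Solve the mixture weight from a target skewness
#'
#' Given the component means and variances, finds the weight `p1` at which
#' the analytic mixture skewness equals `targetSkew`, by root-finding on
#' (0.01, 0.99).  Used because the simulation designs report the skewness
#' of the generating mixture but not its weights.
#'
#' @param mu1,var1,mu2,var2 component parameters.
#' @param targetSkew target skewness.
#' @param tol root tolerance.
#' @return the solved `p1`.
#' @export
solveMixtureWeight <- function(mu1, var1, mu2, var2, targetSkew,
                               tol = 1e-9) {
  skewAt <- function(p1)
    mixtureMoments(mixtureSpec(p1, mu1, var1, mu2, var2))[["skewness"]]
  if (mu1 == mu2 && var1 == var2) {
    if (abs(targetSkew) > 1e-12)
      stop("equal components: only skewness 0 is achievable")
    warning("equal components: skewness is 0 for every weight; returning 0.5")
    return(0.5)
  }
  f <- function(p1) skewAt(p1) - targetSkew
  loVal <- f(0.01); hiVal <- f(0.99)
  if (sign(loVal) == sign(hiVal)) {
    # the skewness need not be monotone in p1; scan for a sign change
    ps <- seq(0.01, 0.99, by = 0.005)
    vals <- vapply(ps, f, numeric(1))
    ix <- which(diff(sign(vals)) != 0)
    if (!length(ix))
      stop("infeasible target: mixture skewness never crosses ", targetSkew,
           " on p1 in (0.01, 0.99)")
    lo <- ps[ix[1]]; hi <- ps[ix[1] + 1]
  } else {
    lo <- 0.01; hi <- 0.99
  }
  uniroot(f, c(lo, hi), tol = tol)$root
}

#' Fit spline coefficients to a target density
#'
#' Finds `eta` so that `ramsayPdf(basis, eta)` approximates a target mass
#' vector.  A ridge-penalized least-squares fit in log space (target floored
#' at 1e-12) provides the starting value; it is then refined by minimizing
#' the cross-entropy `-sum_q target_q log g_q(eta)` with the same Newton
#' machinery used for ability draws, which weights the fit by where the
#' target actually has mass.  An unrefined log-space fit spreads its error
#' uniformly over the grid and can miss sharp density peaks badly.
#'
#' @param basis a [SplineBasis-class].
#' @param target mass vector of length Q (nonnegative, summing to ~1).
#' @param ridge ridge penalty of the log-space initialization (also sets
#'   the scale of the diffuse prior used in the refinement).
#' @return fitted coefficient vector, centered to mean 0.
#' @export
etaFromDensity <- function(basis, target, ridge = 1e-6) {
  stopifnot(is(basis, "SplineBasis"), length(target) == basis@grid@Q,
            ridge >= 0)
  y <- log(pmax(target, 1e-12))
  y <- y - mean(y)
  B <- basis@matrix
  A <- crossprod(B) + diag(max(ridge, 1e-10), basis@m)
  eta <- tryCatch(drop(solve(A, crossprod(B, y))), error = function(e)
    stop("rank-deficient normal equations in the log-density fit"))
  # cross-entropy refinement: equivalent to a MAP fit to a large pseudo
  # sample distributed exactly as the target
  pseudo <- 1e6
  eta <- fitEtaMAP(pseudo * target / sum(target), basis,
                   etaPrior(basis@m, tau = 1e3), init = eta)
  eta - mean(eta)
}

# Two-component mixture with mean 0, variance 1 and moments near the
# requested skewness/kurtosis; used only to seed the moment-matching
# optimizer with a density of roughly the right shape.
.momentMatchedMixture <- function(targetSkew, targetKurt) {
  obj <- function(par) {
    p1 <- 1 / (1 + exp(-par[1]))
    mu1 <- par[2]
    v1 <- exp(par[3])
    mu2 <- -p1 * mu1 / (1 - p1)
    v2 <- (1 - p1 * (v1 + mu1^2)) / (1 - p1) - mu2^2
    if (!is.finite(v2) || v2 <= 1e-4) return(1e6)
    mom <- mixtureMoments(mixtureSpec(p1, mu1, v1, mu2, v2))
    (mom[["skewness"]] - targetSkew)^2 + (mom[["kurtosis"]] - targetKurt)^2
  }
  starts <- expand.grid(lp = c(-1.5, 0, 1.5), mu1 = c(-2, -1, 1, 2),
                        lv = c(log(0.2), 0))
  best <- NULL; bestVal <- Inf
  for (i in seq_len(nrow(starts))) {
    res <- optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                 control = list(maxit = 500))
    if (res$value < bestVal) { bestVal <- res$value; best <- res$par }
  }
  p1 <- 1 / (1 + exp(-best[1]))
  mu1 <- best[2]; v1 <- exp(best[3])
  mu2 <- -p1 * mu1 / (1 - p1)
  v2 <- (1 - p1 * (v1 + mu1^2)) / (1 - p1) - mu2^2
  mixtureSpec(p1, mu1, v1, mu2, max(v2, 1e-4))
}

#' Spline coefficients matching target density moments
#'
#' Constructs a Ramsay-curve density on the given basis whose first four
#' moments are (0, 1, `targetSkew`, `targetKurt`), by penalized
#' minimization of the squared moment mismatches over `eta`.  The optimizer
#' is multi-started from log-density fits of a moment-matched two-component
#' mixture and a library of reference shapes.  Errors if the achieved
#' moments miss any target by more than `tol`.
#'
#' @param basis a [SplineBasis-class].
#' @param targetSkew,targetKurt target skewness and (non-excess) kurtosis.
#' @param tol acceptance tolerance on each achieved moment.
#' @return coefficient vector `eta` with
#'   `densityMoments(ramsayPdf(basis, eta))` within `tol` of the targets.
#' @export
etaFromMoments <- function(basis, targetSkew, targetKurt, tol = 0.02) {
  stopifnot(is(basis, "SplineBasis"))
  grid <- basis@grid
  obj <- function(eta) {
    mass <- ramsayPdf(basis, eta)@mass
    mom <- tryCatch(.massMoments(mass, grid@points), error = function(e) NULL)
    if (is.null(mom)) return(1e6)
    mom[["mean"]]^2 + (mom[["sd"]] - 1)^2 +
      (mom[["skewness"]] - targetSkew)^2 +
      (mom[["kurtosis"]] - targetKurt)^2 +
      1e-8 * sum((eta - mean(eta))^2)
  }
  seeds <- list(
    mixturePdfOnGrid(.momentMatchedMixture(targetSkew, targetKurt), grid),
    normalDensityOnGrid(grid),
    mixturePdfOnGrid(mixtureSpec(0.3, -2.7, 0.2, 1.1, 1.1), grid),
    mixturePdfOnGrid(mixtureSpec(0.5, -2, 0.25, 2.5, 0.5), grid))
  starts <- c(lapply(seeds, function(s) etaFromDensity(basis, s)),
              list(rep(0, basis@m)))
  best <- NULL; bestVal <- Inf
  for (s in starts) {
    res <- optim(s, obj, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    res <- optim(res$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (res$value < bestVal) { bestVal <- res$value; best <- res$par }
  }
  eta <- best - mean(best)
  mom <- densityMoments(ramsayPdf(basis, eta))
  err <- abs(mom - c(0, 1, targetSkew, targetKurt))
  if (any(err > tol))
    stop(sprintf(paste0("moment targets infeasible for this basis: achieved ",
                        "(mean %.4f, sd %.4f, skew %.4f, kurt %.4f)"),
                 mom["mean"], mom["sd"], mom["skewness"], mom["kurtosis"]))
  eta
}

#' Grid-sample abilities from a latent density
#'
#' Draws `n` abilities i.i.d. from the discrete density over the grid
#' points (the same scheme the SAEM ability step uses), then optionally
#' standardizes the draws to sample mean 0 and sample sd 1, as the
#' simulation designs require.
#'
#' @param mass density mass vector of length Q.
#' @param grid a [ThetaGrid-class].
#' @param n number of draws (>= 2 when standardizing).
#' @param standardize affinely transform to sample mean 0 and sd 1.
#' @return numeric vector of abilities.
#' @export
sampleTheta <- function(mass, grid, n, standardize = TRUE) {
  stopifnot(is(grid, "ThetaGrid"), length(mass) == grid@Q, n >= 1)
  idx <- sample.int(grid@Q, n, replace = TRUE, prob = mass)
  th <- grid@points[idx]
  if (standardize) {
    if (n < 2) stop("standardization needs at least 2 draws")
    s <- sd(th)
    if (s < 1e-12) stop("degenerate sample: zero variance, cannot standardize")
    th <- (th - mean(th)) / s
  }
  th
}

#' Generate item parameters
#'
#' Draws item parameters from the simulation designs' generating
#' distributions: discrimination `a ~ U(1, 2.5)`, intercept `b ~ N(0, 1)`,
#' guessing `c ~ Beta(5, 17)`.
#'
#' @param J number of items.
#' @return data.frame with columns `a`, `b`, `c`.
#' @export
genItems <- function(J) {
  stopifnot(J >= 1)
  data.frame(a = runif(J, 1, 2.5), b = rnorm(J), c = rbeta(J, 5, 17))
}

#' Generate binary responses
#'
#' Draws `u_ij ~ Bernoulli(P_j(theta_i))` independently under the 3PNO
#' model.
#'
#' @param theta abilities (length N).
#' @param items data.frame with columns `a`, `b`, `c`.
#' @return integer N x J matrix with item columns named `item1..itemJ`.
#' @export
genResponses <- function(theta, items) {
  items <- .validItems(items)
  P <- sweep(pnorm(tcrossprod(theta, items$a) +
                     matrix(items$b, length(theta), nrow(items), byrow = TRUE)),
             2, items$c, function(ph, c0) c0 + (1 - c0) * ph)
  U <- (matrix(runif(length(P)), nrow(P)) < P) * 1L
  colnames(U) <- paste0("item", seq_len(ncol(U)))
  U
}

# memo cache for the study-2 true densities (deterministic to construct,
# but the moment matching is not free)
.worldCache <- new.env(parent = emptyenv())

#' True latent density of a simulation condition
#'
#' Study 1 densities are two-component normal mixtures: the skewed shape
#' has components (-2.7, 0.2) and (1.1, 1.1) with the weight solved so the
#' mixture skewness is 2.46; the bimodal shape has components (-2, 0.25)
#' and (2.5, 0.5) with skewness 1.45; the normal shape is the discretized
#' N(0, 1).  Study 2 densities are Ramsay curves on the 6-knot degree-3
#' basis: moment-matched to skewness/kurtosis (1.72, 9.16) for the skewed
#' shape and (0.95, 2.74) for the bimodal shape, with the normal shape a
#' log-space spline fit of the discretized N(0, 1).
#'
#' @param shape `"normal"`, `"skewed"` or `"bimodal"`.
#' @param study 1 or 2.
#' @param grid a [ThetaGrid-class].
#' @param knots,degree basis for the study-2 Ramsay construction.
#' @return list with `mass` (length Q) and `eta` (study 2; `NULL` for
#'   study 1 mixtures).
#' @export
trueDensity <- function(shape = c("normal", "skewed", "bimodal"),
                        study = 2, grid = buildGrid(),
                        knots = 6L, degree = 3L) {
  shape <- match.arg(shape)
  stopifnot(study %in% c(1, 2))
  key <- sprintf("s%d_%s_k%d_d%d_Q%d", study, shape, knots, degree, grid@Q)
  if (!is.null(.worldCache[[key]])) return(.worldCache[[key]])
  if (study == 1) {
    mass <- switch(shape,
      normal = normalDensityOnGrid(grid),
      skewed = {
        p1 <- solveMixtureWeight(-2.7, 0.2, 1.1, 1.1, targetSkew = 2.46)
        mixturePdfOnGrid(mixtureSpec(p1, -2.7, 0.2, 1.1, 1.1), grid)
      },
      bimodal = {
        p1 <- solveMixtureWeight(-2, 0.25, 2.5, 0.5, targetSkew = 1.45)
        mixturePdfOnGrid(mixtureSpec(p1, -2, 0.25, 2.5, 0.5), grid)
      })
    out <- list(mass = mass, eta = NULL)
  } else {
    basis <- buildBasis(grid, knots, degree)
    eta <- switch(shape,
      normal = etaFromDensity(basis, normalDensityOnGrid(grid)),
      skewed = etaFromMoments(basis, 1.72, 9.16),
      bimodal = etaFromMoments(basis, 0.95, 2.74))
    out <- list(mass = ramsayPdf(basis, eta)@mass, eta = eta)
  }
  .worldCache[[key]] <- out
  out
}

#' Simulate a complete data-generating world
#'
#' Generates one replication's truth and data: the condition's true latent
#' density, item parameters (`a ~ U(1, 2.5)`, `b ~ N(0, 1)`,
#' `c ~ Beta(5, 17)`), grid-sampled abilities standardized to sample mean 0
#' and sd 1, and Bernoulli responses.  Draw order is items, abilities,
#' responses, so the same seed reproduces the same world exactly.
#'
#' @param shape `"normal"`, `"skewed"` or `"bimodal"`.
#' @param study 1 or 2 (selects the density construction).
#' @param N number of examinees.
#' @param J number of items.
#' @param seed integer seed (`NULL` leaves the RNG state untouched).
#' @param items optional fixed item data.frame; when supplied the item draw
#'   is skipped (used to hold items fixed across replications).
#' @param grid a [ThetaGrid-class].
#' @param knots,degree study-2 basis.
#' @return list with `responses`, `items`, `theta`, `density` (mass),
#'   `etaTrue` (or `NULL`), `N`, `J`, `seed`.
#' @export
simulateWorld <- function(shape, study = 2, N = 1000, J = 30, seed = NULL,
                          items = NULL, grid = buildGrid(),
                          knots = 6L, degree = 3L) {
  truth <- trueDensity(shape, study, grid, knots, degree)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(items)) items <- genItems(J) else stopifnot(nrow(items) == J)
  theta <- sampleTheta(truth$mass, grid, N, standardize = TRUE)
  U <- genResponses(theta, items)
  list(responses = U, items = items, theta = theta, density = truth$mass,
       etaTrue = truth$eta, N = N, J = J, seed = seed)
}
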