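#' Build an equidistant quadrature grid
#'
#' Constructs the fixed grid of latent-trait values over which the
#' Ramsay-curve density is represented.  The default in Ramsay-curve IRT is
#' 121 points from -6 to 6 in steps of 0.1; that interval contains the
#' great majority of abilities encountered in testing.
#'
#' @param lo,hi interval endpoints (latent-trait units), `lo < hi`.
#' @param step spacing between points; `(hi - lo) / step` must be integral.
#' @return a [ThetaGrid-class].
#' @examples
#' buildGrid()           # 121 points on [-6, 6]
#' buildGrid(-1, 1, 1)   # points -1, 0, 1
#' @export
buildGrid <- function(lo = -6, hi = 6, step = 0.1) {
  stopifnot(is.numeric(lo), is.numeric(hi), is.numeric(step),
            length(lo) == 1, length(hi) == 1, length(step) == 1)
  if (!(lo < hi)) stop("`lo` must be less than `hi`")
  if (!(step > 0)) stop("`step` must be positive")
  span <- (hi - lo) / step
  if (abs(span - round(span)) > 1e-9)
    stop("(hi - lo) / step must be integral: grid must include both endpoints")
  Q <- as.integer(round(span)) + 1L
  points <- lo + step * (seq_len(Q) - 1)
  points[Q] <- hi  # exact endpoint despite accumulated rounding
  new("ThetaGrid", points = points, lo = lo, hi = hi, step = step, Q = Q)
}

# B-spline design matrix at arbitrary points, with the package's breakpoint
# convention: `knots` evenly spaced breakpoints on [lo, hi] including both
# endpoints, boundary knots repeated degree + 1 times.  Points are clamped to
# [lo, hi] so evaluation outside the support uses the boundary value.
.basisAt <- function(x, lo, hi, knots, degree) {
  bk <- seq(lo, hi, length.out = knots)
  interior <- if (knots > 2L) bk[-c(1L, knots)] else numeric(0)
  x <- pmin(pmax(x, lo), hi)
  B <- splines::bs(x, knots = interior, degree = degree, intercept = TRUE,
                   Boundary.knots = c(lo, hi))
  unname(B[, , drop = FALSE])
}

#' Build a B-spline basis matrix on a grid
#'
#' Evaluates the B-spline basis at every grid point, yielding the Q x m
#' matrix B* that defines the Ramsay curve.  Breakpoints are `knots` evenly
#' spaced values on `[lo, hi]` including both endpoints; with the boundary
#' knots repeated degree + 1 times the basis dimension is
#' m = degree + knots - 1, and the rows form a partition of unity.
#'
#' @param grid a [ThetaGrid-class].
#' @param knots number of breakpoints including both endpoints (>= 2);
#'   2 to 6 are the usual choices.
#' @param degree polynomial degree (>= 1); 3 or 4 are the usual choices.
#' @return a [SplineBasis-class].
#' @examples
#' basis <- buildBasis(buildGrid(), knots = 6, degree = 3)
#' basisDim(basis)  # 8
#' @export
buildBasis <- function(grid, knots, degree) {
  stopifnot(is(grid, "ThetaGrid"))
  knots <- as.integer(knots); degree <- as.integer(degree)
  if (is.na(knots) || knots < 2L) stop("`knots` must be an integer >= 2")
  if (is.na(degree) || degree < 1L) stop("`degree` must be an integer >= 1")
  m <- degree + knots - 1L
  if (m >= grid@Q)
    stop("degenerate basis: m = degree + knots - 1 must be smaller than Q")
  B <- .basisAt(grid@points, grid@lo, grid@hi, knots, degree)
  new("SplineBasis", matrix = B, knots = knots, degree = degree, m = m,
      grid = grid)
}

.logSumExp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Evaluate a Ramsay-curve density
#'
#' Computes the latent density g with mass proportional to
#' `exp(B*_q %*% eta)` at each grid point, normalized to sum to 1 over the
#' grid.  Normalization uses the log-sum-exp trick, so large coefficient
#' vectors are handled without overflow; adding a constant to `eta` leaves
#' the density unchanged because the basis rows sum to 1.
#'
#' @param basis a [SplineBasis-class].
#' @param eta numeric coefficient vector of length `basisDim(basis)`.
#' @return a [RamsayDensity-class].
#' @examples
#' basis <- buildBasis(buildGrid(), 6, 3)
#' d <- ramsayPdf(basis, rep(0, basisDim(basis)))  # uniform over the grid
#' sum(densityMass(d))
#' @export
ramsayPdf <- function(basis, eta) {
  stopifnot(is(basis, "SplineBasis"))
  eta <- as.numeric(eta)
  if (length(eta) != basis@m)
    stop(sprintf("`eta` must have length m = %d", basis@m))
  if (any(!is.finite(eta))) stop("`eta` must be finite")
  u <- drop(basis@matrix %*% eta)
  logC <- .logSumExp(u)
  # floor at the smallest normal double so extreme eta cannot underflow the
  # strictly-positive mass invariant, then renormalize away the rounding
  mass <- pmax(exp(u - logC), 2.3e-308)
  mass <- mass / sum(mass)
  new("RamsayDensity", eta = eta, mass = mass, logC = logC, basis = basis)
}

.massMoments <- function(mass, points) {
  if (any(mass < -1e-12)) stop("mass vector must be nonnegative")
  mass <- pmax(mass, 0)
  s <- sum(mass)
  if (abs(s - 1) > 1e-8) stop("mass vector must sum to 1")
  mass <- mass / s
  mu <- sum(mass * points)
  d <- points - mu
  v <- sum(mass * d^2)
  if (v <= 1e-12)
    stop("degenerate density: zero variance on the grid")
  c(mean = mu, sd = sqrt(v),
    skewness = sum(mass * d^3) / v^1.5,
    kurtosis = sum(mass * d^4) / v^2)
}

#' @rdname densityMoments
setMethod("densityMoments", signature(x = "RamsayDensity", grid = "missing"),
          function(x, grid) .massMoments(x@mass, x@basis@grid@points))

#' @rdname densityMoments
setMethod("densityMoments", signature(x = "SAEMFit", grid = "missing"),
          function(x, grid) .massMoments(x@mass, x@grid@points))

#' @rdname densityMoments
setMethod("densityMoments", signature(x = "numeric", grid = "ThetaGrid"),
          function(x, grid) {
            if (length(x) != grid@Q)
              stop("mass vector and grid have different lengths")
            .massMoments(x, grid@points)
          })

#' Discretized normal density on a grid
#'
#' Normal density evaluated at the grid points and renormalized to sum
#' to 1; used as the fixed latent density in `"normal"`-mode fits and as a
#' reference shape elsewhere.
#'
#' @param grid a [ThetaGrid-class].
#' @param mean,sd normal parameters.
#' @return numeric mass vector of length `grid@Q`.
#' @export
normalDensityOnGrid <- function(grid, mean = 0, sd = 1) {
  stopifnot(is(grid, "ThetaGrid"), sd > 0)
  w <- dnorm(grid@points, mean, sd)
  w / sum(w)
}

#' Export a density table
#'
#' Writes a two-column tab-separated table of grid points and masses with
#' header `theta` / `mass`.
#'
#' @param x a [RamsayDensity-class], [SAEMFit-class], or numeric mass vector.
#' @param path output file path.
#' @param grid required when `x` is a bare mass vector.
#' @return `path`, invisibly.
#' @export
writeDensity <- function(x, path, grid = NULL) {
  if (is(x, "RamsayDensity")) {
    tab <- data.frame(theta = x@basis@grid@points, mass = x@mass)
  } else if (is(x, "SAEMFit")) {
    tab <- data.frame(theta = x@grid@points, mass = x@mass)
  } else {
    stopifnot(is.numeric(x), is(grid, "ThetaGrid"), length(x) == grid@Q)
    tab <- data.frame(theta = grid@points, mass = x)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
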