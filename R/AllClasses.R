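#' @import methods
#' @importFrom stats dnorm pnorm qnorm rnorm runif rbeta optim uniroot sd
#' @importFrom utils read.csv write.csv head
NULL

#' Quadrature grid for the latent trait
#'
#' An equidistant grid of points on the latent-trait (theta) scale over which
#' the Ramsay-curve density is represented and all quadrature is performed.
#' The conventional grid in Ramsay-curve IRT is 121 points from -6 to 6 in
#' steps of 0.1.
#'
#' @slot points ordered, equidistant grid points including both endpoints.
#' @slot lo,hi interval endpoints.
#' @slot step spacing between adjacent points.
#' @slot Q number of grid points.
#' @seealso [buildGrid()]
#' @export
setClass("ThetaGrid",
  representation(points = "numeric", lo = "numeric", hi = "numeric",
                 step = "numeric", Q = "integer"))

setValidity("ThetaGrid", function(object) {
  msgs <- character(0)
  p <- object@points
  if (length(p) != object@Q) msgs <- c(msgs, "Q must equal length(points)")
  if (object@Q < 2L) msgs <- c(msgs, "grid needs at least 2 points")
  d <- diff(p)
  if (any(d <= 0)) msgs <- c(msgs, "points must be strictly increasing")
  if (max(abs(d - object@step)) > 1e-9)
    msgs <- c(msgs, "points must be equidistant with spacing `step`")
  if (abs(p[1] - object@lo) > 1e-12 || abs(p[length(p)] - object@hi) > 1e-12)
    msgs <- c(msgs, "points must start at lo and end at hi")
  if (length(msgs)) msgs else TRUE
})

#' B-spline basis on a quadrature grid
#'
#' The Q x m matrix of B-spline basis functions evaluated at the grid points.
#' Breakpoints are `knots` evenly spaced values on [lo, hi] including both
#' endpoints; boundary knots are repeated degree + 1 times, so the basis
#' dimension is m = degree + knots - 1 and the rows form a partition of unity.
#'
#' @slot matrix Q x m basis matrix, entries in [0, 1], rows summing to 1.
#' @slot knots number of breakpoints (including the two endpoints).
#' @slot degree polynomial degree of the basis.
#' @slot m basis dimension, degree + knots - 1.
#' @slot grid the [ThetaGrid-class] the basis is evaluated on.
#' @seealso [buildBasis()]
#' @export
setClass("SplineBasis",
  representation(matrix = "matrix", knots = "integer", degree = "integer",
                 m = "integer", grid = "ThetaGrid"))

setValidity("SplineBasis", function(object) {
  msgs <- character(0)
  B <- object@matrix
  if (nrow(B) != object@grid@Q) msgs <- c(msgs, "basis must have Q rows")
  if (ncol(B) != object@m) msgs <- c(msgs, "basis must have m columns")
  if (object@m != object@degree + object@knots - 1L)
    msgs <- c(msgs, "m must equal degree + knots - 1")
  if (any(B < -1e-12) || any(B > 1 + 1e-12))
    msgs <- c(msgs, "basis entries must lie in [0, 1]")
  if (max(abs(rowSums(B) - 1)) > 1e-10)
    msgs <- c(msgs, "basis rows must sum to 1 (partition of unity)")
  if (length(msgs)) msgs else TRUE
})

#' Ramsay-curve density on a grid
#'
#' A discrete latent-trait density g with mass g_q = exp(B*_q eta - logC) at
#' grid point x_q, where B* is a B-spline basis matrix and C normalizes the
#' masses to sum to 1.  The normalization is carried out in log space and
#' logC is stored so that large coefficient vectors do not overflow.
#'
#' @slot eta spline coefficient vector of length m.
#' @slot mass normalized mass vector of length Q (positive, sums to 1).
#' @slot logC log normalization constant, log sum_q exp(B*_q eta).
#' @slot basis the [SplineBasis-class] the density is built on.
#' @seealso [ramsayPdf()], [densityMoments()]
#' @export
setClass("RamsayDensity",
  representation(eta = "numeric", mass = "numeric", logC = "numeric",
                 basis = "SplineBasis"))

setValidity("RamsayDensity", function(object) {
  msgs <- character(0)
  if (length(object@eta) != object@basis@m)
    msgs <- c(msgs, "eta must have length m")
  if (length(object@mass) != object@basis@grid@Q)
    msgs <- c(msgs, "mass must have length Q")
  if (any(object@mass <= 0)) msgs <- c(msgs, "mass must be strictly positive")
  if (abs(sum(object@mass) - 1) > 1e-12) msgs <- c(msgs, "mass must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' Fitted RC-3PNO / 3PNO model
#'
#' Result of [runSAEM()]: item parameter estimates, the estimated latent
#' density, convergence record, marginal log-likelihood and information
#' criteria.
#'
#' @slot items data.frame with columns `a`, `b`, `c` (one row per item).
#' @slot eta estimated spline coefficients (length 0 in `"normal"` mode).
#' @slot mass estimated latent density mass vector on the grid.
#' @slot grid the quadrature [ThetaGrid-class].
#' @slot mode `"rc"` (Ramsay-curve density estimated) or `"normal"`
#'   (density fixed at the discretized standard normal).
#' @slot knots,degree spline specification used (`NA` in normal mode).
#' @slot converged whether the max-parameter-change criterion was met.
#' @slot iterations number of SAEM iterations performed.
#' @slot logLik marginal log-likelihood at the final estimates.
#' @slot nParams parameter count used by the information criteria.
#' @slot criteria named numeric: `aic`, `bic`, `hqic`.
#' @slot trajectory per-iteration maximum absolute parameter change.
#' @slot control the control list the fit was run with.
#' @seealso [runSAEM()], [informationCriteria()]
#' @export
setClass("SAEMFit",
  representation(items = "data.frame", eta = "numeric", mass = "numeric",
                 grid = "ThetaGrid", mode = "character",
                 knots = "integer", degree = "integer",
                 converged = "logical", iterations = "integer",
                 logLik = "numeric", nParams = "integer",
                 criteria = "numeric", trajectory = "numeric",
                 control = "list"))

setValidity("SAEMFit", function(object) {
  msgs <- character(0)
  if (!all(c("a", "b", "c") %in% names(object@items)))
    msgs <- c(msgs, "items must have columns a, b, c")
  if (length(object@mass) != object@grid@Q)
    msgs <- c(msgs, "mass must have length Q")
  if (!object@mode %in% c("rc", "normal"))
    msgs <- c(msgs, "mode must be 'rc' or 'normal'")
  if (length(msgs)) msgs else TRUE
})
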