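#' 3PNO response probability
#'
#' Probability of a correct response under the three-parameter normal ogive
#' model, `P(theta) = c + (1 - c) * Phi(a * theta + b)`: `a > 0` is the
#' discrimination, `b` the intercept, and `c` in (0, 1) the guessing
#' probability (the lower asymptote).
#'
#' @param theta latent trait value(s).
#' @param a,b,c item parameters (scalars).
#' @return probabilities, same length as `theta`.
#' @examples
#' probCorrect(0, a = 1, b = 0, c = 0)          # 0.5
#' probCorrect(1, a = 1.5, b = -0.5, c = 0.2)   # 0.2 + 0.8 * pnorm(1)
#' @export
probCorrect <- function(theta, a, b, c) {
  stopifnot(length(a) == 1, length(b) == 1, length(c) == 1,
            a > 0, c > 0, c < 1)
  c + (1 - c) * pnorm(a * theta + b)
}

.PROB_CLIP <- 1e-12

# J x Q table of clipped response probabilities P_j(x_q)
.itemProbTable <- function(a, b, c, points) {
  P <- c + (1 - c) * pnorm(outer(a, points) + b)
  pmin(pmax(P, .PROB_CLIP), 1 - .PROB_CLIP)
}

.validItems <- function(items) {
  stopifnot(is.data.frame(items), all(c("a", "b", "c") %in% names(items)))
  if (any(items$a <= 0)) stop("all discriminations `a` must be positive")
  if (any(items$c <= 0 | items$c >= 1)) stop("all `c` must lie in (0, 1)")
  items
}

#' Validate a binary response matrix
#'
#' Checks that a response matrix is a complete N x J matrix of 0/1 values
#' and returns it as an integer matrix.  Columns that are constant (all 0 or
#' all 1) are rejected when `rejectConstant = TRUE` because such items carry
#' no information about their parameters.
#'
#' @param U matrix or data.frame of responses.
#' @param rejectConstant reject all-0 / all-1 item columns.
#' @return integer matrix of 0/1 values.
#' @export
validateResponses <- function(U, rejectConstant = FALSE) {
  U <- as.matrix(U)
  if (!is.numeric(U)) stop("responses must be numeric 0/1")
  if (nrow(U) < 1 || ncol(U) < 1) stop("response matrix must be non-empty")
  if (anyNA(U)) stop("responses must not contain missing values")
  if (!all(U %in% c(0, 1))) stop("responses must be 0 or 1")
  if (rejectConstant) {
    cs <- colSums(U)
    bad <- which(cs == 0 | cs == nrow(U))
    if (length(bad))
      stop("item column(s) ", paste(bad, collapse = ", "),
           " are constant (all 0 or all 1)")
  }
  storage.mode(U) <- "integer"
  U
}

# internal, warning-free version used inside the SAEM loop
.loglikTable <- function(U, a, b, c, points) {
  P <- .itemProbTable(a, b, c, points)
  L1 <- log(P)
  L0 <- log1p(-P)
  U %*% (L1 - L0) + matrix(colSums(L0), nrow(U), length(points), byrow = TRUE)
}

#' Per-examinee log-likelihood over the quadrature grid
#'
#' N x Q matrix whose (i, q) entry is the conditional log-likelihood of
#' examinee i's response pattern at ability `x_q`:
#' `sum_j u_ij log P_j(x_q) + (1 - u_ij) log(1 - P_j(x_q))`.  Probabilities
#' are clipped to `[1e-12, 1 - 1e-12]` so that the logs stay finite at
#' extreme grid points; a warning is raised when clipping occurs.
#'
#' @param U binary response matrix (N x J).
#' @param items data.frame with columns `a`, `b`, `c`.
#' @param grid a [ThetaGrid-class].
#' @return N x Q numeric matrix.
#' @export
loglikTable <- function(U, items, grid) {
  U <- validateResponses(U)
  items <- .validItems(items)
  stopifnot(is(grid, "ThetaGrid"), ncol(U) == nrow(items))
  P <- c(items$c) + (1 - items$c) * pnorm(outer(items$a, grid@points) + items$b)
  if (any(P < .PROB_CLIP) || any(P > 1 - .PROB_CLIP))
    warning("response probabilities clipped to [1e-12, 1 - 1e-12] ",
            "at extreme grid points")
  .loglikTable(U, items$a, items$b, items$c, grid@points)
}

#' Marginal log-likelihood under a latent density on the grid
#'
#' Log-likelihood of the observed responses with the latent trait integrated
#' out over the discrete density: `sum_i log sum_q exp(T[i, q]) g_q`,
#' computed with the log-sum-exp trick.
#'
#' @param U binary response matrix.
#' @param items data.frame with columns `a`, `b`, `c`.
#' @param density a [RamsayDensity-class], or a numeric mass vector paired
#'   with `grid`.
#' @param grid a [ThetaGrid-class]; required when `density` is a mass vector.
#' @return scalar log-likelihood.
#' @export
marginalLoglik <- function(U, items, density, grid = NULL) {
  if (is(density, "RamsayDensity")) {
    grid <- density@basis@grid
    mass <- density@mass
  } else {
    stopifnot(is(grid, "ThetaGrid"), is.numeric(density),
              length(density) == grid@Q)
    mass <- density
  }
  U <- validateResponses(U)
  items <- .validItems(items)
  TT <- .loglikTable(U, items$a, items$b, items$c, grid@points)
  TT <- sweep(TT, 2, log(pmax(mass, 1e-300)), "+")
  rm <- apply(TT, 1, max)
  sum(rm + log(rowSums(exp(TT - rm))))
}
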