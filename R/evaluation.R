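#' Information criteria for model selection
#'
#' AIC, BIC and HQIC from a marginal log-likelihood, used to select the
#' number of knots and the degree of the spline basis:
#' `AIC = -2 logL + 2n`, `BIC = -2 logL + n log N`,
#' `HQIC = -2 logL + 2 n log(log N)` (natural logs).  `aicAsPrinted = TRUE`
#' switches AIC to the literal `-2 logL + log(N)` variant, which carries no
#' dependence on the parameter count and cannot rank models of different
#' sizes; the standard form is the default.
#'
#' @param logL marginal log-likelihood at the final estimates.
#' @param n number of free parameters (see [countParameters()]).
#' @param N sample size (>= 3 so that `log(log(N))` is positive).
#' @param aicAsPrinted use the `-2 logL + log(N)` AIC variant.
#' @return list with `logL`, `n`, `N`, `aic`, `bic`, `hqic`.
#' @examples
#' informationCriteria(-100, n = 10, N = 1000)
#' @export
informationCriteria <- function(logL, n, N, aicAsPrinted = FALSE) {
  stopifnot(is.finite(logL), n >= 1, N >= 3)
  d <- -2 * logL
  list(logL = logL, n = n, N = N,
       aic = d + if (aicAsPrinted) log(N) else 2 * n,
       bic = d + n * log(N),
       hqic = d + 2 * n * log(log(N)))
}

#' Free-parameter count of a fitted model
#'
#' `3J + (m - 1)` in rc mode — three parameters per item plus the spline
#' coefficients, of which one is unidentified because the basis spans the
#' constant vector and the density normalizes — and `3J` in normal mode.
#'
#' @param J number of items.
#' @param m spline basis dimension (rc mode).
#' @param mode `"rc"` or `"normal"`.
#' @return integer parameter count.
#' @export
countParameters <- function(J, m = NULL, mode = c("rc", "normal")) {
  mode <- match.arg(mode)
  stopifnot(J >= 1)
  if (mode == "rc") {
    stopifnot(!is.null(m), m >= 1)
    as.integer(3 * J + m - 1)
  } else {
    as.integer(3 * J)
  }
}

#' Bias, RMSE and empirical SE across replications
#'
#' Per-parameter recovery statistics over R replications:
#' `bias = mean(estimate - truth)`,
#' `rmse = sqrt(mean((estimate - truth)^2))`, and the empirical standard
#' error is the across-replication standard deviation of the estimates
#' (divisor R - 1; `NA` when R = 1).
#'
#' @param estimates R x P matrix of estimates (replications in rows).
#' @param truth length-P vector of true values.
#' @return data.frame with columns `bias`, `rmse`, `se`.
#' @export
recoveryStats <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  R <- nrow(estimates)
  if (R < 1) stop("at least one replication is required")
  stopifnot(ncol(estimates) == length(truth))
  err <- sweep(estimates, 2, truth)
  data.frame(bias = colMeans(err),
             rmse = sqrt(colMeans(err^2)),
             se = if (R > 1) apply(estimates, 2, sd) else rep(NA_real_, length(truth)))
}

#' Integrated squared error between two densities on a grid
#'
#' Discretized `1000 * integral of (ghat(theta) - gtrue(theta))^2 dtheta`:
#' masses are converted to density heights (mass / step) and the squared
#' difference is Riemann-summed with weight `step`, which makes the value
#' independent of the grid resolution.  The conventional x1000 scaling is
#' applied.
#'
#' @param gHat,gTrue mass vectors of length Q, each summing to 1.
#' @param grid a [ThetaGrid-class].
#' @return nonnegative scalar (ISE x 1000).
#' @export
ise <- function(gHat, gTrue, grid) {
  stopifnot(is(grid, "ThetaGrid"))
  if (length(gHat) != grid@Q || length(gTrue) != grid@Q)
    stop("density and grid lengths differ")
  1000 * sum((gHat - gTrue)^2) / grid@step
}

# deterministic child seed below 2^31 for (condition, replication) pairs
deriveSeed <- function(seed, ...) {
  ix <- c(...)
  v <- (seed %% 1000003) * 2147
  for (i in seq_along(ix)) v <- (v * 1009 + ix[i] * 7919 + i) %% 2147483629
  as.integer(v + 1)
}

#' Enumerate the simulation-study conditions
#'
#' Study 1 crosses the three true density shapes with ten spline
#' specifications (knots 2-6 by degree 3-4) at N = 1000, J = 30: 30
#' conditions.  Study 2 crosses the three shapes with N in (500, 1000,
#' 2000) and J in (15, 30) under the fixed 6-knot degree-3
#' generating/fitting model: 18 conditions.
#'
#' @param study 1 or 2.
#' @return data.frame with one row per condition.
#' @export
simStudyConditions <- function(study) {
  stopifnot(study %in% c(1, 2))
  shapes <- c("normal", "skewed", "bimodal")
  if (study == 1) {
    cond <- expand.grid(shape = shapes, knots = 2:6, degree = 3:4,
                        stringsAsFactors = FALSE)
    cond$N <- 1000L
    cond$J <- 30L
  } else {
    cond <- expand.grid(shape = shapes, N = c(500L, 1000L, 2000L),
                        J = c(15L, 30L), stringsAsFactors = FALSE)
    cond$knots <- 6L
    cond$degree <- 3L
  }
  cond[order(cond$shape), c("shape", "knots", "degree", "N", "J")]
}

#' Replicated parameter-recovery experiment for one condition
#'
#' Runs R replications of one simulation condition: each replication draws
#' fresh item parameters from their generating distributions, fresh
#' standardized abilities and responses, fits the model with [runSAEM()],
#' and collects the estimates.  Recovery is summarized per parameter class
#' as the across-replication average of the per-item bias and RMSE (each
#' replication contributes the mean error and root-mean-square error of its
#' own items), plus the mean density ISE.
#'
#' @param shape true density shape.
#' @param N,J examinees and items.
#' @param R number of replications.
#' @param seed master seed; replication r uses a derived child seed.
#' @param mode `"rc"` or `"normal"` fitting mode.
#' @param study simulation design (selects the true density construction).
#' @param knots,degree spline specification (generating and fitting).
#' @param control an [saemControl()] list (its seed is overridden per
#'   replication).
#' @param priors an [itemPriors()] list.
#' @return list with `summary` (per-class mean bias/rmse), `perRep`
#'   (data.frame of per-replication bias/rmse for a, b, c and ISE), and
#'   `fits`/`truths` kept as per-replication estimate and truth matrices.
#' @export
recoveryExperiment <- function(shape, N = 1000, J = 30, R = 20, seed = 1,
                               mode = "rc", study = 2, knots = 6L,
                               degree = 3L, control = saemControl(),
                               priors = itemPriors()) {
  grid <- buildGrid()
  truth <- trueDensity(shape, study, grid, knots, degree)
  perRep <- vector("list", R)
  est <- vector("list", R)
  truths <- vector("list", R)
  for (r in seq_len(R)) {
    world <- simulateWorld(shape, study, N, J, seed = deriveSeed(seed, 1L, r),
                           grid = grid, knots = knots, degree = degree)
    ctl <- control
    ctl$seed <- deriveSeed(seed, 2L, r)
    fit <- runSAEM(world$responses, knots = knots, degree = degree,
                   mode = mode, priors = priors, control = ctl, grid = grid)
    errs <- as.matrix(fit@items[c("a", "b", "c")]) -
      as.matrix(world$items[c("a", "b", "c")])
    perRep[[r]] <- data.frame(
      rep = r,
      bias_a = mean(errs[, "a"]), rmse_a = sqrt(mean(errs[, "a"]^2)),
      bias_b = mean(errs[, "b"]), rmse_b = sqrt(mean(errs[, "b"]^2)),
      bias_c = mean(errs[, "c"]), rmse_c = sqrt(mean(errs[, "c"]^2)),
      ise = ise(fit@mass, truth$mass, grid),
      converged = fit@converged, iterations = fit@iterations)
    est[[r]] <- as.matrix(fit@items[c("a", "b", "c")])
    truths[[r]] <- as.matrix(world$items[c("a", "b", "c")])
  }
  perRep <- do.call(rbind, perRep)
  summary <- data.frame(
    parameter = c("a", "b", "c"),
    bias = c(mean(perRep$bias_a), mean(perRep$bias_b), mean(perRep$bias_c)),
    rmse = c(mean(perRep$rmse_a), mean(perRep$rmse_b), mean(perRep$rmse_c)),
    row.names = NULL)
  list(summary = summary, perRep = perRep, ise = perRep$ise,
       estimates = est, truths = truths,
       condition = list(shape = shape, N = N, J = J, R = R, mode = mode,
                        study = study, knots = knots, degree = degree))
}

#' Run a full (or scaled-down) simulation study
#'
#' Drives [recoveryExperiment()] over the condition table of
#' [simStudyConditions()].  Study 1 reports per-condition mean AIC/BIC/HQIC
#' together with item bias/RMSE; study 2 reports per-class bias/RMSE and
#' mean ISE for both rc-mode and normal-mode fits.  Replication r of
#' condition i uses a child seed derived from `(seed, i, r)`, so
#' per-condition results do not depend on execution order.  The published
#' designs use 100 replications per condition; `replications` (and the
#' iteration cap through `control`) scale the study down to desk size.
#'
#' @param study 1 or 2.
#' @param replications replications per condition.
#' @param seed master seed.
#' @param conditions optional subset (row indices into the condition table).
#' @param control an [saemControl()] list.
#' @param outDir optional directory; per-condition CSV tables are written
#'   there when given.
#' @return data.frame with one row per condition (x mode for study 2).
#' @export
runSimStudy <- function(study, replications = 100, seed = 1,
                        conditions = NULL, control = saemControl(),
                        outDir = NULL) {
  cond <- simStudyConditions(study)
  if (is.null(conditions)) conditions <- seq_len(nrow(cond))
  rows <- list()
  for (ci in conditions) {
    cd <- cond[ci, ]
    modes <- if (study == 2) c("rc", "normal") else "rc"
    for (md in modes) {
      ex <- recoveryExperiment(cd$shape, N = cd$N, J = cd$J,
                               R = replications,
                               seed = deriveSeed(seed, 10L, ci),
                               mode = md, study = study,
                               knots = cd$knots, degree = cd$degree,
                               control = control)
      s <- ex$summary
      rows[[length(rows) + 1L]] <- data.frame(
        shape = cd$shape, knots = cd$knots, degree = cd$degree,
        N = cd$N, J = cd$J, mode = md, R = replications,
        bias_a = s$bias[s$parameter == "a"],
        rmse_a = s$rmse[s$parameter == "a"],
        bias_b = s$bias[s$parameter == "b"],
        rmse_b = s$rmse[s$parameter == "b"],
        bias_c = s$bias[s$parameter == "c"],
        rmse_c = s$rmse[s$parameter == "c"],
        ise = mean(ex$ise))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(outDir,
      sprintf("study%d_recovery.csv", study)), row.names = FALSE)
  }
  out
}

#' Model selection across candidate spline specifications
#'
#' Fits the ten candidate (knots, degree) combinations — knots 2 to 6 by
#' degree 3 or 4 — to one response matrix and tabulates AIC, BIC and HQIC.
#'
#' @param U binary response matrix.
#' @param knots,degree candidate values (crossed).
#' @param control an [saemControl()] list.
#' @return data.frame with one row per candidate model.
#' @export
selectModel <- function(U, knots = 2:6, degree = 3:4,
                        control = saemControl()) {
  cand <- expand.grid(knots = knots, degree = degree)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    fit <- runSAEM(U, knots = cand$knots[i], degree = cand$degree[i],
                   mode = "rc", control = control)
    data.frame(knots = cand$knots[i], degree = cand$degree[i],
               m = length(fit@eta), logL = fit@logLik,
               aic = fit@criteria[["aic"]], bic = fit@criteria[["bic"]],
               hqic = fit@criteria[["hqic"]])
  })
  do.call(rbind, rows)
}
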