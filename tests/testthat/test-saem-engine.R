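test_that("gain sequence is unit through burn-in then harmonic", {
  expect_equal(saemGain(500), 1)
  expect_equal(saemGain(1000), 1)
  expect_equal(saemGain(1001), 1)
  expect_equal(saemGain(1200), 0.005)
  expect_equal(saemGain(3, burn = 2), 1)
  k <- 1:3000
  gk <- saemGain(k)
  expect_true(all(gk > 0 & gk <= 1))
  expect_true(all(diff(gk[k > 1000]) <= 0))
})

test_that("ability sampler draws from the categorical grid posterior", {
  g <- buildGrid()
  b <- buildBasis(g, 6, 3)
  set.seed(31)
  mass <- densityMass(ramsayPdf(b, rnorm(8)))

  # flat likelihood: posterior equals the prior; chi-square GOF
  n <- 2e4
  th <- sampleThetaPosterior(matrix(0, n, g@Q), mass, g@points)
  counts <- tabulate(th$index, g@Q)
  keep <- mass * n >= 5  # merge sparse tail cells for the chi-square
  chi <- sum((counts[keep] - n * mass[keep])^2 / (n * mass[keep])) +
    (sum(counts[!keep]) - n * sum(mass[!keep]))^2 /
      max(n * sum(mass[!keep]), 1e-9)
  df <- sum(keep)
  expect_gt(pchisq(chi, df), 0.0001)  # alpha = 1e-4 two-sided guard

  # two-point grid with hand-computed posterior ratio P1 g1 : P2 g2
  g2 <- buildGrid(-1, 1, 2)
  item <- data.frame(a = 1, b = 0.2, c = 0.2)
  U1 <- matrix(1L, 5e4, 1)
  tab <- loglikTable(U1, item, g2)
  pri <- c(0.3, 0.7)
  post <- exp(tab[1, ]) * pri
  post <- post / sum(post)
  th2 <- sampleThetaPosterior(tab, pri, g2@points)
  ph <- mean(th2$index == 2)
  expect_lt(abs(ph - post[2]), 3 * sqrt(post[2] * post[1] / 5e4))

  # reproducibility under a fixed seed
  set.seed(99); d1 <- sampleThetaPosterior(tab[1:100, , drop = FALSE], pri, g2@points)
  set.seed(99); d2 <- sampleThetaPosterior(tab[1:100, , drop = FALSE], pri, g2@points)
  expect_identical(d1, d2)
})

test_that("knowledge indicator sampler respects responses and its rate", {
  items <- data.frame(a = 1, b = 0, c = 0.5)
  n <- 1e5
  set.seed(32)

  # incorrect responses can never be 'known'
  w0 <- sampleW(matrix(0L, n, 1), items, rnorm(n))
  expect_true(all(w0 == 0))

  # u = 1 at theta = 0: Phi = 0.5, c = 0.5 -> P(w = 1) = 2/3
  w1 <- sampleW(matrix(1L, n, 1), items, rep(0, n))
  expect_lt(abs(mean(w1) - 2 / 3), 3 * sqrt(2 / 9 / n))

  # c -> 0 makes knowledge certain for correct responses
  w2 <- sampleW(matrix(1L, 1000, 1),
                data.frame(a = 1, b = 0, c = 1e-12), rep(0, 1000))
  expect_true(all(w2 == 1))
})

test_that("truncated-normal draws have the right support and means", {
  items <- data.frame(a = 1, b = 0, c = 0.2)
  n <- 1e5
  set.seed(33)

  w <- matrix(1L, n, 1)
  z <- sampleZ(items, rep(0, n), w)
  expect_true(all(z > 0))
  expect_lt(abs(mean(z) - dnorm(0) / pnorm(0)), 3 * sqrt(1 / n) * 2)

  z0 <- sampleZ(items, rep(0, n), matrix(0L, n, 1))
  expect_true(all(z0 <= 0))
  expect_lt(abs(mean(z0) + dnorm(0) / pnorm(0)), 3 * sqrt(1 / n) * 2)

  # extreme mean, handled by inverse-CDF without rejection: mean ~ 5 + tiny
  items5 <- data.frame(a = 1, b = 5, c = 0.2)
  z5 <- sampleZ(items5, rep(0, 1e4), matrix(1L, 1e4, 1))
  expect_lt(abs(mean(z5) - (5 + dnorm(5) / pnorm(5))), 0.05)
  # and a far-negative mean still yields strictly positive finite draws
  zneg <- sampleZ(data.frame(a = 1, b = -12, c = 0.2),
                  rep(0, 1000), matrix(1L, 1000, 1))
  expect_true(all(zneg > 0 & is.finite(zneg)))
})

test_that("sufficient statistics match hand and loop computations", {
  th <- c(1, -1)
  z <- matrix(c(0.5, -0.2), 2, 1)
  w <- matrix(c(1L, 0L), 2, 1)
  U <- matrix(c(1L, 0L), 2, 1)
  s <- suffStats(th, z, w, U)
  expect_equal(s$S1, matrix(c(2, 0, 0, 2), 2, 2))
  expect_equal(drop(s$S2), c(0.7, 0.3))
  expect_equal(s$S3, 1)
  expect_equal(s$S4, 0)

  set.seed(34)
  N <- 17; J <- 4
  th <- rnorm(N); z <- matrix(rnorm(N * J), N, J)
  U <- matrix(rbinom(N * J, 1, 0.5), N, J)
  w <- U * matrix(rbinom(N * J, 1, 0.7), N, J)
  s <- suffStats(th, z, w, U)
  for (j in 1:J) {
    s2 <- c(sum(th * z[, j]), sum(z[, j]))
    expect_equal(s$S2[, j], s2, tolerance = 1e-14)
    expect_identical(s$S3[j], sum(1 - w[, j]))
    expect_identical(s$S4[j], sum((1 - w[, j]) * U[, j]))
  }
  expect_identical(s$S1, matrix(c(sum(th^2), sum(th), sum(th), N), 2, 2))

  allKnown <- suffStats(th, z, U, U)  # w = U means no unknowing correct
  expect_true(all(allKnown$S4 == 0))
})

test_that("SA update is a convex combination and averages draws at 1/k", {
  old <- list(S1 = matrix(0, 2, 2), S2 = matrix(0, 2, 1), S3 = 0, S4 = 0)
  new <- list(S1 = matrix(2, 2, 2), S2 = matrix(2, 2, 1), S3 = 2, S4 = 2)
  half <- saUpdate(old, new, 0.5)
  expect_equal(half$S3, 1)
  expect_equal(half$S1, matrix(1, 2, 2))
  expect_equal(saUpdate(old, new, 1), new)

  # gamma_k = 1/k from the first draw equals the running mean
  set.seed(35)
  draws <- rnorm(50)
  s <- list(S3 = draws[1])
  for (k in 2:50)
    s <- saUpdate(s, list(S3 = draws[k]), 1 / k)
  expect_equal(s$S3, mean(draws), tolerance = 1e-12)
})

test_that("item M-step reduces to OLS under flat priors and Beta mode for c", {
  set.seed(36)
  N <- 200; J <- 3
  th <- rnorm(N)
  z <- matrix(rnorm(N * J, outer(th, c(1.5, 0.8, 2)) + 0.3), N, J)
  U <- matrix(rbinom(N * J, 1, 0.7), N, J)
  w <- U
  s <- suffStats(th, z, w, U)
  est <- mstepItems(s, itemPriors(), delta = 1e-3)
  for (j in 1:J) {
    ols <- coef(lm(z[, j] ~ th))
    expect_equal(est$a[j], unname(ols[2]), tolerance = 1e-10)
    expect_equal(est$b[j], unname(ols[1]), tolerance = 1e-10)
  }

  # Beta-mode guessing update: alpha* = 25, beta* = 97 -> 24/120
  s2 <- s
  s2$S3 <- rep(100, J); s2$S4 <- rep(20, J)
  est2 <- mstepItems(s2, itemPriors(alpha = 5, beta = 17), delta = 1e-3)
  expect_equal(est2$c, rep(0.2, J))

  # non-positive discrimination floors at delta
  s3 <- s
  s3$S2[1, ] <- -s3$S2[1, ]
  est3 <- mstepItems(s3, itemPriors(), delta = 1e-3)
  expect_true(all(est3$a == 1e-3))
})

test_that("M-step maximizes the complete-data posterior on a toy set", {
  set.seed(37)
  N <- 40
  th <- rnorm(N)
  U <- matrix(rbinom(N * 2, 1, 0.6), N, 2)
  w <- U * matrix(rbinom(N * 2, 1, 0.8), N, 2)
  z <- matrix(0, N, 2)
  z[w == 1] <- abs(rnorm(sum(w == 1), 0.5))
  z[w == 0] <- -abs(rnorm(sum(w == 0), 0.5))
  s <- suffStats(th, z, w, U)
  est <- mstepItems(s, itemPriors(alpha = 5, beta = 17), delta = 1e-3)

  # complete-data log posterior (normal part for z, Bernoulli part for
  # guessing, Beta prior on c), maximized numerically per item
  for (j in 1:2) {
    f <- function(p) {
      a <- p[1]; b <- p[2]; cc <- plogis(p[3])
      -(sum(dnorm(z[, j], a * th + b, log = TRUE)) +
          s$S4[j] * log(cc) + (s$S3[j] - s$S4[j]) * log(1 - cc) +
          dbeta(cc, 5, 17, log = TRUE))
    }
    opt <- optim(c(1, 0, 0), f, control = list(reltol = 1e-14, maxit = 5000))
    expect_equal(est$a[j], opt$par[1], tolerance = 1e-4)
    expect_equal(est$b[j], opt$par[2], tolerance = 1e-4)
    expect_equal(est$c[j], plogis(opt$par[3]), tolerance = 1e-4)
  }
})

test_that("scale identification preserves response probabilities", {
  items <- data.frame(a = 2, b = 1, c = 0.2)
  expect_equal(identifyScale(items, 0, 1), items)
  tr <- identifyScale(items, 0.5, 2)
  expect_equal(tr$a, 4)
  expect_equal(tr$b, 2)
  expect_equal(tr$c, 0.2)
  # on the standardized scale theta' = (theta - mean)/sd the transformed
  # item reproduces the original probabilities
  for (th in seq(-3, 3, by = 0.5))
    expect_equal(probCorrect((th - 0.5) / 2, tr$a, tr$b, tr$c),
                 probCorrect(th, items$a, items$b, items$c),
                 tolerance = 1e-12)
  expect_error(identifyScale(items, 0, 0), "thetaSd")
})

test_that("runSAEM validates input, respects caps, and is reproducible", {
  w <- simulateWorld("normal", study = 1, N = 120, J = 8, seed = 41)
  ctl <- saemControl(maxIter = 1, burn = 0, seed = 5)
  f1 <- runSAEM(w$responses, knots = 3, degree = 3, mode = "rc",
                control = ctl)
  expect_false(f1@converged)
  expect_equal(f1@iterations, 1L)

  ctl2 <- saemControl(maxIter = 60, burn = 30, seed = 7)
  f2 <- runSAEM(w$responses, knots = 3, degree = 3, mode = "rc",
                control = ctl2)
  f3 <- runSAEM(w$responses, knots = 3, degree = 3, mode = "rc",
                control = ctl2)
  expect_identical(f2@items, f3@items)
  expect_identical(f2@mass, f3@mass)
  expect_identical(f2@logLik, f3@logLik)

  bad <- w$responses
  bad[, 3] <- 1L
  expect_error(runSAEM(bad, mode = "normal"), "constant")
  bad2 <- w$responses
  bad2[2, 2] <- 3L
  expect_error(runSAEM(bad2, mode = "normal"), "0 or 1")

  # normal mode fixes the density at the discretized standard normal
  f4 <- runSAEM(w$responses, mode = "normal",
                control = saemControl(maxIter = 40, burn = 20, seed = 8))
  expect_equal(f4@mass, normalDensityOnGrid(buildGrid()))
  expect_length(f4@eta, 0)
  expect_equal(f4@nParams, 24L)
})

test_that("a short fit keeps estimates in their parameter spaces", {
  w <- simulateWorld("skewed", study = 1, N = 300, J = 12, seed = 42)
  fit <- runSAEM(w$responses, knots = 4, degree = 3, mode = "rc",
                 control = saemControl(maxIter = 250, burn = 150, seed = 9))
  expect_true(all(fit@items$a > 0))
  expect_true(all(fit@items$c > 0 & fit@items$c < 1))
  expect_true(all(is.finite(fit@mass)) && abs(sum(fit@mass) - 1) < 1e-9)
  expect_true(is.finite(fit@logLik))
  expect_equal(fit@nParams, 3L * 12L + 5L)  # m - 1 spline parameters
  expect_length(fit@trajectory, fit@iterations)
  # the latent scale stays pinned near mean 0, sd 1
  mom <- densityMoments(fit)
  expect_lt(abs(mom[["mean"]]), 0.2)
  expect_lt(abs(mom[["sd"]] - 1), 0.2)
})
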