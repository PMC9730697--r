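# rcsaem

Joint estimation of item parameters and a non-normal latent-trait density
for the three-parameter normal ogive (3PNO) item response model, by a
stochastic approximation EM (SAEM) algorithm.

Psychometric and epidemiological traits — pathology symptoms, substance
use, ability in selected subpopulations — are often skewed or bimodal in
the population being tested.  Fitting a 3PNO model under the usual
"θ ~ N(0, 1)" assumption then biases the item parameters, most visibly
the intercepts.  This package models the latent density as a **Ramsay
curve**,

    P_j(θ) = c_j + (1 − c_j) Φ(a_j θ + b_j),
    g(x_q | η) = exp{B*(x_q) η} / Σ_q exp{B*(x_q) η},

where `B*` is a Q × m B-spline basis on a fixed grid (121 points on
[−6, 6] by default; m = degree + knots − 1), and estimates items and
density jointly.  Estimation uses probit data augmentation (a
knows-the-answer indicator W and an underlying normal variable Z), which
makes the complete-data likelihood exponential-family with closed-form
sufficient statistics; a Robbins–Monro gain sequence (unit gain for 1000
burn-in iterations, then 1/(k − 1000)) smooths the simulated statistics;
item updates are conjugate MAP formulas (ordinary least squares of Z on
(θ, 1) under the default non-informative prior, Beta-posterior mode for
the guessing parameter), and the spline coefficients are refit each
iteration by Newton–Raphson on a penalized grid-count posterior.
Audience: psychometricians and biostatisticians running item calibration
or recovery studies where latent normality is questionable.

The package also ships the surrounding study machinery: synthetic data
generators for skewed/bimodal/normal true densities (mixture-based and
moment-matched Ramsay constructions), AIC/BIC/HQIC model selection across
knot–degree candidates, and bias/RMSE/ISE recovery metrics with
replication drivers.

## Worked example

Simulate a skewed-population test (skewness 1.72, kurtosis 9.16; N = 1000
examinees, J = 30 items) and refit the generating 6-knot, degree-3 model:

```r
library(rcsaem)
world <- simulateWorld("skewed", study = 2, N = 1000, J = 30, seed = 20)
fit <- runSAEM(world$responses, knots = 6, degree = 3, mode = "rc",
               control = saemControl(seed = 21))
fit
```

```
SAEMFit (rc mode): 30 items, 97 examinee-free parameters
  spline: knots = 6, degree = 3 (m = 8)
  converged after 1096 iterations (last max change 9.91e-05)
  marginal logLik -15997.16 | AIC 32188.3  BIC 32664.4  HQIC 32369.2
```

The fit converged before the 2500-iteration cap: the largest parameter
change between successive iterations fell below 1e-4.  `97` counts
3 × 30 item parameters plus m − 1 = 7 identifiable spline coefficients;
the information criteria are computed from the marginal log-likelihood at
the final estimates and can be compared across knot–degree candidates
(`selectModel`).  The item estimates track their generating values:

```r
head(cbind(truth = world$items, estimate = itemParams(fit)), 4)
#>    truth.a     truth.b   truth.c estimate.a estimate.b estimate.c
#> 1 2.316282 -0.43742787 0.2291511  2.1240147 -0.4949903  0.2209120
#> 2 2.152800  0.97057758 0.3344403  1.7755795  1.1853938  0.1784809
#> 3 1.418445  0.02822264 0.3559548  0.9197805  0.3089758  0.2141219
#> 4 1.793746 -0.08578219 0.1901650  1.7965914 -0.1557385  0.1928514
```

and the estimated density sits close to the generating skewed shape —
the integrated squared error against the true density (scaled by 1000,
the conventional reporting scale) is

```r
ise(densityMass(fit), world$density, buildGrid())
#> [1] 1.86
```

Fitting the same data with `mode = "normal"` (density fixed at the
discretized standard normal) reproduces the bias that motivates the
method — the mean error of the intercepts is −0.312 under the normal
assumption versus −0.069 for the Ramsay-curve fit on this data set.

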