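# CanopyCarbon

Quantifying the impact of a tropical-forest blowdown on aboveground
carbon and canopy structure from repeat lidar surveys.

Wind disturbances of intermediate size — too large for plot networks to
catch, too small and too quickly overgrown for coarse satellite records —
are a blind spot in tropical carbon accounting. When two lidar surveys
bracket such an event, the questions become concrete: how much
aboveground carbon density (ACD) was lost, how did the canopy gap
structure change, what canopy would the disturbed dynamics equilibrate
to, could the event have been seen by a multispectral satellite, and how
long will regrowth take to repay the loss? CanopyCarbon is a tested,
reusable implementation of that analysis chain for forest ecologists and
remote-sensing scientists, exercised end to end on synthetic landscapes
so every estimator is validated against known truth.

## The models at the core

* **Canopy height models.** First returns (|scan angle| ≤ 15°, optionally
  thinned to a uniform density) are rasterized two ways: a Delaunay-TIN
  surface evaluated at 1.25 m pixel centres (every in-hull pixel gets a
  height, for gap work), and 5 m mean-height pixels (top-of-canopy
  height, TCH). Heights are relative to a terrain model, with per-epoch
  constant bias correction.
* **Carbon.** `AGBD = a · TCH^b + ε`, `ε ~ N(0, σ²)`, fitted by Gaussian
  maximum likelihood on field plots; ACD = 0.47 × AGBD on ~0.5-ha cells.
  Uncertainty by parametric bootstrap (1000 draws; optionally also
  sampling `(log a, b)` from the ML covariance), with epoch change from
  paired draws.
* **Gap structure.** Gaps are 8-connected components with height ≤ h for
  h = 2…20 m. Sizes k (pixels) follow the Zeta distribution
  `f(k) = k^−λ / ζ(λ)`; λ is estimated by Metropolis–Hastings (chain
  100,000, burn-in 5,000, thin 25 → 3,800 retained samples, uniform
  prior on (1.01, 5), proposal SD 0.1). Smaller λ ⇒ relatively more
  large gaps.
* **Equilibrium canopy.** A height-class transition matrix `A` (1 m
  classes, `a_ij` = pixels moving from class j to class i) is
  column-normalized; its dominant right eigenvector (`Ax = λx`, λ = 1) is
  the projected equilibrium height distribution, with a
  Dirichlet-multinomial posterior (10,000 draws) for credible envelopes.
* **Optical detection.** Linear spectral mixture analysis into
  PV/NPV/shade fractions under a hard sum-to-one constraint; ΔNPV is the
  blowdown signal (one-sample t-test, and regression of ΔNPV on ACD
  loss).
* **Recovery.** Bookkeeping brackets: loss ÷ long-term gain
  (0.49 Mg C ha⁻¹ yr⁻¹) from above, a 5-year elevated-gain phase then the
  long-term rate from below, with an optional pre-event baseline
  adjustment (0.74 Mg C ha⁻¹ yr⁻¹ over 9 years).

## Worked example

A synthetic 150 m landscape, a blowdown removing 20% of canopy volume,
and the core chain:

```r
library(CanopyCarbon)

chm  <- generateCHM(syntheticForestConfig(extentM = 150, seed = 7))
blow <- applyBlowdown(chm, severity = 0.2, seed = 8)

# allometry from 18 simulated half-hectare calibration plots
fit <- fitAllometry(generatePlots(allometrySimConfig(seed = 1)))
fit
#> AllometricFit: AGBD = 4.71 * TCH^1.206  (n = 18 plots)
#>   sigma = 17.1 Mg ha^-1, r2 = 0.929, RMSE = 8.18% of mean AGBD

# carbon change on 70 m cells, paired Monte Carlo draws
cells <- function(r) aggregateMean(r, 56L)
pre  <- monteCarloACD(fit, cells(chm), seed = 1, residualSeed = 2,
                      perturbParams = TRUE)
post <- monteCarloACD(fit, cells(blow$chm), seed = 1, residualSeed = 3,
                      perturbParams = TRUE)
acdChange(pre, post)$landscape
#> $meanPre    88.8      # Mg C ha^-1 before
#> $meanPost   66.5      # after
#> $change     -22.3     # absolute loss
#> $pctChange  -25.1     # percent loss
#> $changeCI   -34.2 -11.1   # 95% Monte Carlo interval
```

The 20% canopy-volume removal translates into a 25% ACD loss here:
carving preferentially flattens tall, carbon-dense canopy, and
`AGBD ∝ TCH^1.2` amplifies height loss. The gap exponent drops, i.e.
large gaps become relatively more common, and the two posteriors'
credible intervals do not overlap:

```r
lamPre  <- estimateLambda(gapSizes(labelGaps(chm, 8)), seed = 2)
lamPost <- estimateLambda(gapSizes(labelGaps(blow$chm, 8)), seed = 3)
lamPre
#> ZetaPosterior: lambda median 2.224 (95% CrI 2.026-2.445)
#>   3800 retained samples (chain 100000, burn-in 5000, thin 25), 155 gap sizes
lamPost
#> ZetaPosterior: lambda median 1.766 (95% CrI 1.665-1.875)
#>   3800 retained samples (chain 100000, burn-in 5000, thin 25), 215 gap sizes
compareLambda(lamPre, lamPost)$significant
#> [1] TRUE

# how long until regrowth repays the loss?
sc <- recoveryScenario(22.3, longTermGain = 0.49,
                       elevatedGains = c(2.0, 1.6, 1.3, 1.0, 0.8))
recoveryTimeLongTerm(sc)$years   # long-term trend only (over-estimate)
#> [1] 45
recoveryTimeTwoPhase(sc)$years   # fast initial phase first (under-estimate)
#> [1] 36
```

`makeDemo()` writes a complete synthetic workspace (point tables,
terrain, plots, reflectance, config) and `runPipeline()` executes every
stage — rasterization, carbon mapping, gap MCMC, equilibrium projection,
unmixing, recovery — and writes per-stage outputs plus a JSON summary:

```r
cfg <- makeDemo("demo", seed = 1)
summary <- runPipeline(cfg)
```

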