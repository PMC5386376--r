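test_that("zero-enthalpy titrations give only baseline plus noise", {
  p <- itcProtocol()
  params <- new("ITCModelParams", N = 1, Ka = 1e7, dH = 0, baseline = 0.4)
  sim <- simulateTitration(params, p)
  expect_equal(injectionHeats(sim), rep(0.4, 19), tolerance = 1e-12)
})

test_that("saturating titrations conserve total heat", {
  # huge Ka, large ligand excess: all macromolecule in the active cell
  # volume ends up bound, so the reconstructed cumulative heat equals
  # N * dH * [M]_final * V0 (the perfusion convention dilutes [M] as
  # injections displace liquid into the overflow)
  p <- itcProtocol(cellConc = 5e-6, syringeConc = 500e-6)
  params <- new("ITCModelParams", N = 1, Ka = 1e12, dH = -8000,
                baseline = 0)
  heats <- injectionHeats(simulateTitration(params, p))
  V0 <- 204.4 * 1e-6 * 1e-3            # ul -> L
  dV <- rep(2.0, 19) * 1e-6 * 1e-3
  cum <- sum(dV)
  Mfinal <- 5e-6 * (1 - cum / (2 * V0)) / (1 + cum / (2 * V0))
  expected <- -8000 * Mfinal * V0 * 1e6            # ucal
  # invert the displacement correction to recover cumulative heat
  Q <- 0
  for (i in 1:19)
    Q <- (heats[i] * 1e-6 + Q * (1 - dV[i] / (2 * V0))) /
      (1 + dV[i] / (2 * V0))
  expect_equal(Q * 1e6, expected, tolerance = 5e-3)
  # with vanishing injected volume the dilution correction disappears
  # and the limit is the textbook N * dH * M0 * V0
  tiny <- itcProtocol(cellConc = 5e-6, syringeConc = 2e-2,
                      injectionVolumes = rep(0.05, 19))
  h2 <- injectionHeats(simulateTitration(params, tiny))
  dV2 <- rep(0.05, 19) * 1e-6 * 1e-3
  Q2 <- 0
  for (i in 1:19)
    Q2 <- (h2[i] * 1e-6 + Q2 * (1 - dV2[i] / (2 * V0))) /
      (1 + dV2[i] / (2 * V0))
  expect_equal(Q2 * 1e6, -8000 * 5e-6 * V0 * 1e6, tolerance = 5e-3)
})

test_that("the titration c-value matches the protocol arithmetic", {
  # c = N * M0 / Kd for the default cell concentration at Kd = 65 nM
  expect_equal(20e-6 / 65e-9, 307.7, tolerance = 1e-3)
  # sharply sigmoidal curve: early injections near-constant, a steep
  # drop near the equivalence point, late injections near zero
  sim <- simulateTitration(itcModelParams(kdNano = 65), itcProtocol())
  h <- injectionHeats(sim)
  expect_lt(abs(h[2] - h[1]) / abs(h[1]), 0.02)
  expect_lt(abs(h[19]), 0.05 * abs(h[1]))
})

test_that("a noiseless simulation refits to the truth within 0.1%", {
  truth <- itcModelParams(N = 1, kdNano = 100, dH = -12000)
  sim <- simulateTitration(truth, itcProtocol())
  fit <- fitSingleSite(sim)
  expect_true(isConverged(fit))
  expect_false(isNoBinding(fit))
  p <- fittedParams(fit)
  expect_equal(p@N, 1, tolerance = 1e-3)
  expect_equal(kdNano(fit), 100, tolerance = 1e-3)
  expect_equal(p@dH, -12000, tolerance = 1e-3 * 12000)
})

test_that("flat thermograms earn a no-binding verdict", {
  p <- itcProtocol()
  flat <- new("ITCModelParams", N = 1, Ka = 1e6, dH = 0, baseline = 0)
  sim <- simulateTitration(flat, p, noiseSd = 0.05, seed = 9)
  fit <- fitSingleSite(sim)
  expect_true(isNoBinding(fit))
  # while a strong binder with the same noise is NOT flagged
  strong <- simulateTitration(itcModelParams(kdNano = 65), p,
                              relativeNoise = 0.02, seed = 9)
  expect_false(isNoBinding(fitSingleSite(strong)))
})

test_that("replicate aggregation computes mean and SD in nM", {
  mk <- function(kd) new("ITCFit",
    params = new("ITCModelParams", N = 1, Ka = 1e9 / kd, dH = -1e4,
                 baseline = 0),
    kdNano = kd,
    se = c(N = NA_real_, Ka = NA_real_, dH = NA_real_,
           baseline = NA_real_),
    residualNorm = 0, converged = TRUE, noBinding = FALSE)
  agg <- aggregateReplicates(list(mk(60), mk(65), mk(70)))
  expect_equal(agg$meanKd, 65)
  expect_equal(agg$sdKd, 5)
  expect_equal(agg$n, 3L)
  expect_error(aggregateReplicates(list(mk(60))), "at least 2")
})

test_that("replicate spread is of the order set by the injected noise", {
  truth <- itcModelParams(kdNano = 200, dH = -10000)
  fits <- lapply(1:3, function(s)
    fitSingleSite(simulateTitration(truth, itcProtocol(),
                                    relativeNoise = 0.02, seed = s)))
  agg <- aggregateReplicates(fits)
  expect_equal(agg$meanKd, 200, tolerance = 0.25)
  # order-of-magnitude check on the SD: nonzero but well below the mean
  expect_gt(agg$sdKd, 0)
  expect_lt(agg$sdKd, 0.5 * agg$meanKd)
})

test_that("thermogram CSV files roundtrip through the reader", {
  sim <- simulateTitration(itcModelParams(kdNano = 500), itcProtocol(),
                           relativeNoise = 0.02, seed = 4)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(injection_index = 1:19, volume_ul = 2.0,
                       heat_ucal = injectionHeats(sim)), f,
            row.names = FALSE)
  back <- readThermogram(f)
  expect_equal(injectionHeats(back), injectionHeats(sim))
  fit <- fitSingleSite(back)
  expect_equal(kdNano(fit), 500, tolerance = 0.3)
})

test_that("discarding the first injection keeps the fit consistent", {
  truth <- itcModelParams(kdNano = 80, dH = -11000)
  sim <- simulateTitration(truth, itcProtocol())
  fit <- fitSingleSite(sim, discardFirst = TRUE)
  expect_true(isConverged(fit))
  expect_equal(kdNano(fit), 80, tolerance = 0.05)
})
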