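test_that("compartment tensors have the prescribed eigenstructure", {
  expect_equal(tensorMatrix(compartmentTensor(
    fiberCompartment(c(1, 0, 0), 2, 0.5))), diag(c(2, 0.5, 0.5)),
    ignore_attr = TRUE)
  expect_equal(tensorMatrix(compartmentTensor(
    fiberCompartment(c(0.3, -0.8, 0.2), 1.4, 1.4))), 1.4 * diag(3),
    ignore_attr = TRUE)
  set.seed(2)
  for (rep in 1:10) {
    u <- randomUnitVector()
    lam <- eigen(tensorMatrix(compartmentTensor(
      fiberCompartment(u, 2, 0.4))), symmetric = TRUE)$values
    expect_equal(lam, c(2, 0.4, 0.4), tolerance = 1e-12)
  }
  expect_error(fiberCompartment(c(1, 0, 0), 0.5, 1), "d_par >= d_perp")
})

test_that("mixture cumulants are exact for known mixtures", {
  # single compartment: Gaussian, W = 0
  mc1 <- mixtureCumulants(voxelModel(fiberCompartment(c(0, 0, 1), 2, 0.4)))
  expect_equal(unname(tensorValues(mc1$W)), rep(0, 15))
  # bi-isotropic mixture: D = 2 I, W = 0.75 I4, K(n) = 0.75, KFA = 0
  mc2 <- mixtureCumulants(voxelModel(isotropicCompartment(1, 0.5),
                                     isotropicCompartment(3, 0.5)))
  expect_equal(tensorMatrix(mc2$D), 2 * diag(3), ignore_attr = TRUE)
  expect_equal(unname(tensorValues(mc2$W)),
               0.75 * unname(tensorValues(isotropicKurtosisTensor(1))))
  expect_equal(unname(apparentDK(mc2$D, mc2$W, randomUnitVector())["K"]),
               0.75, tolerance = 1e-12)
  expect_equal(kfa(mc2$W), 0)
  # three orthogonal identical fibers: isotropic D, anisotropic W
  ax <- diag(3)
  mc3 <- mixtureCumulants(voxelModel(lapply(1:3, function(i)
    fiberCompartment(ax[, i], 2, 0.4, 1 / 3))))
  expect_lt(unname(mdFA(mc3$D)["FA"]), 1e-10)
  expect_gt(kfa(mc3$W), 0.1)
})

test_that("the per-direction kurtosis identity holds on random voxels", {
  set.seed(17)
  pop <- syntheticPopulation(30L, seed = 17)
  truth <- groundTruth(pop)
  dirs <- fibonacciSphere(20L)
  for (vx in sample(30L, 10L)) {
    vm <- pop@models[[vx]]
    D <- diffusionTensor(truth$D[vx, ])
    W <- kurtosisTensor(stats::setNames(truth$W[vx, ],
                                        names(tensorValues(kurtosisTensor()))))
    parts <- DKImetrics:::.voxelParts(vm)
    for (ci in seq_len(ncol(dirs))) {
      n <- dirs[, ci]
      dcn <- vapply(parts$Dc, function(M) sum(n * (M %*% n)), numeric(1))
      dn <- sum(parts$f * dcn)
      kOracle <- 3 * (sum(parts$f * dcn^2) - dn^2) / dn^2
      expect_equal(unname(apparentDK(D, W, n)["K"]), kOracle,
                   tolerance = 1e-10)
    }
  }
})

test_that("DKI prediction is the b^2 truncation of the mixture signal", {
  set.seed(19)
  vm <- syntheticPopulation(1L, seed = 19)@models[[1L]]
  mc <- mixtureCumulants(vm)
  n <- randomUnitVector()
  err <- vapply(c(0.05, 0.5), function(b) {
    sch <- acquisitionScheme(b, matrix(n))
    abs(predictSignal(1, mc$D, mc$W, sch) -
          exactGaussianSignal(vm, sch)) / exactGaussianSignal(vm, sch)
  }, numeric(1))
  # truncation error is O(b^3): 10x in b -> ~1000x in error
  expect_lt(err[1], 1e-5)
  expect_gt(err[2] / err[1], 100)
})

test_that("signal mixing follows the alpha weighting", {
  set.seed(23)
  Sx <- stats::runif(20); Sy <- stats::runif(20); Sz <- stats::runif(20)
  expect_identical(mixSignals(Sx, Sy, Sz, 0), Sx)
  expect_equal(mixSignals(Sx, Sy, Sz, 1 / 3), (Sx + Sy + Sz) / 3)
  expect_equal(mixSignals(Sx, Sy, Sz, 0.15),
               0.7 * Sx + 0.15 * Sy + 0.15 * Sz)
  expect_error(mixSignals(Sx, Sy, Sz, 0.5), "alpha")
  expect_error(mixSignals(Sx, Sy, Sz, -0.01), "alpha")
  expect_error(mixSignals(Sx, Sy[-1], Sz, 0.1), "share")
})

test_that("volume fraction index mirrors the FA formula on fractions", {
  expect_equal(volumeFractionIndex(c(1, 0, 0)), 1)
  expect_equal(volumeFractionIndex(c(1, 1, 1) / 3), 0)
  expect_equal(volumeFractionIndex(c(1 / 2, 1 / 4, 1 / 4)), 1 / sqrt(6))
  expect_error(volumeFractionIndex(c(0, 0, 0)), "all-zero")
  expect_error(volumeFractionIndex(c(-0.1, 0.6, 0.5)), "non-negative")
})

test_that("Rician noise has the right moments and is reproducible", {
  s <- rep(0.5, 100)
  expect_identical(addRicianNoise(s, Inf), s)
  a <- addRicianNoise(s, 50, seed = 7, realization = 3)
  b <- addRicianNoise(s, 50, seed = 7, realization = 3)
  expect_identical(a, b)
  expect_false(identical(a, addRicianNoise(s, 50, seed = 7,
                                           realization = 4)))
  # zero signal: Rayleigh mean sigma * sqrt(pi/2)
  sigma <- 1 / 20
  z <- addRicianNoise(rep(0, 1e5), 20, seed = 11)
  expect_equal(mean(z), sigma * sqrt(pi / 2), tolerance = 0.02)
  # large-signal limit: mean ~ S + sigma^2/(2 S)
  s0 <- 100 * sigma
  z2 <- addRicianNoise(rep(s0, 1e5), 20, seed = 12)
  expect_equal(mean(z2), s0 + sigma^2 / (2 * s0), tolerance = 1e-4)
  expect_error(addRicianNoise(s, -5), "SNR")
})

test_that("synthetic populations match the FA segmentation bands", {
  wm <- syntheticPopulation(500L, seed = 2, profile = "wm_like")
  gm <- syntheticPopulation(500L, seed = 2, profile = "gm_like")
  expect_gte(mean(trueMetrics(wm)$FA > 0.6 & trueMetrics(wm)$FA < 1), 0.8)
  expect_gte(mean(trueMetrics(gm)$FA > 0.1 & trueMetrics(gm)$FA < 0.3), 0.8)
  expect_true(stats::median(trueMetrics(wm)$FA) > 0.6)
  expect_true(stats::median(trueMetrics(gm)$FA) > 0.1 &&
                stats::median(trueMetrics(gm)$FA) < 0.3)
  # determinism: same seed reproduces bit-identical ground truth
  wm2 <- syntheticPopulation(500L, seed = 2, profile = "wm_like")
  expect_identical(groundTruth(wm), groundTruth(wm2))
  # mixed profile spans a broad KFA range
  mx <- syntheticPopulation(400L, seed = 5)
  expect_lt(min(trueMetrics(mx)$KFA), 0.2)
  expect_gt(max(trueMetrics(mx)$KFA), 0.8)
})

test_that("the orthogonal phantom carries consistent ground truth", {
  sch <- phantomScheme()
  ph <- orthogonalPhantom(sch, voxelsPerBundle = 2L, nBackground = 4L)
  expect_equal(nrow(ph$signals), 9 * 2 + 4)
  expect_equal(sum(ph$labels$bundle == 0), 4)
  expect_setequal(unique(ph$labels$axis), c("x", "y", "z", "water"))
  # background voxels: free water MD, FA ~ 0
  bg <- ph$labels$bundle == 0
  bgD <- ph$D[bg, , drop = FALSE]
  expect_equal(DKImetrics:::.mdFromD6(bgD), rep(2.0, 4))
  expect_equal(DKImetrics:::.faFromD6(bgD), rep(0, 4))
  # noise-free bundle-voxel fit recovers the single-fiber FA; the signals
  # are exact multi-Gaussian, so the DKI fit carries a small truncation
  # bias at b <= 3.5
  fit <- fitDki(ph$signals[1, ], sch)
  faTrue <- DKImetrics:::.faFromD6(ph$D[1, , drop = FALSE])
  expect_equal(unname(mdFA(fit@D)["FA"]), faTrue, tolerance = 0.02)
})
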