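test_that("two-shell inversion is the exact inverse of the forward model", {
  # D = 1, K = 1 at b1 = 1, b2 = 2.5: y1 = -5/6, y2 = -1.45833...
  y1 <- -5 / 6
  y2 <- -2.5 + 2.5^2 / 6
  res <- twoShellDK(1, exp(y1), exp(y2), 1, 2.5)
  expect_equal(res$D, 1, tolerance = 1e-12)
  expect_equal(res$K, 1, tolerance = 1e-12)
  expect_true(res$valid)
  # Gaussian voxel: monoexponential signals give K = 0 exactly
  d <- 0.8
  res0 <- twoShellDK(2, 2 * exp(-1 * d), 2 * exp(-2.5 * d), 1, 2.5)
  expect_equal(res0$D, d)
  expect_equal(res0$K, 0)
  # random round trips through the full forward model
  set.seed(5)
  for (rep in 1:20) {
    D <- randomDiffusionTensor()
    W <- randomKurtosisTensor(scale = 0.3)
    n <- randomUnitVector()
    sch <- acquisitionScheme(c(0, 1, 2.5), cbind(0, n, n))
    s <- predictSignal(1, D, W, sch)
    res <- twoShellDK(s[1], s[2], s[3], 1, 2.5)
    dk <- apparentDK(D, W, n)
    expect_equal(res$D, unname(dk["D"]), tolerance = 1e-12)
    expect_equal(res$K, unname(dk["K"]), tolerance = 1e-10)
  }
})

test_that("degenerate two-shell inputs error or mask as specified", {
  expect_error(twoShellDK(1, 0.5, 0.3, 1, 1), "b1 = b2")
  expect_error(twoShellDK(1, 0.5, 0.3, 2.5, 1), "b1 < b2")
  # non-positive signal masks, does not throw
  res <- twoShellDK(1, 0, 0.3, 1, 2.5)
  expect_false(res$valid)
  expect_true(is.na(res$K))
  # negative apparent diffusivity masks
  res2 <- twoShellDK(1, 2, 8, 1, 2.5)
  expect_false(res2$valid)
})

test_that("the proxy is std/rms with population normalization", {
  expect_equal(kfaProxy(rep(0.7, 9)), 0)
  expect_equal(kfaProxy(rep(c(1, -1), 5)), 1)
  expect_equal(kfaProxy(rep(0, 9)), 0)
  # hand value: K = (1, 2, 3): mean 2, pop var 2/3, rms^2 = 14/3
  expect_equal(kfaProxy(c(1, 2, 3)), sqrt((2 / 3) / (14 / 3)))
  expect_error(kfaProxy(c(1, 2)), "insufficient")
  expect_error(kfaProxy(c(1, 2, NA, NA), valid = c(TRUE, TRUE, FALSE, FALSE)),
               "insufficient")
  # proxy <= 1 always (std <= rms)
  set.seed(10)
  for (rep in 1:200) {
    k <- stats::rnorm(9, sd = 2)
    p <- kfaProxy(k)
    expect_true(p <= 1 + 1e-12 && p >= 0)
  }
})

test_that("proxy from directions equals std/rms of apparent kurtosis", {
  set.seed(6)
  pop <- syntheticPopulation(5L, seed = 6)
  tss <- twoShellScheme(1, 2.5, loadDirections("86"))
  truth <- groundTruth(pop)
  for (vx in 1:5) {
    D <- diffusionTensor(truth$D[vx, ])
    W <- kurtosisTensor(stats::setNames(truth$W[vx, ],
                                        names(tensorValues(kurtosisTensor()))))
    s <- predictSignal(1, D, W, tss)
    pm <- proxyMap(s, tss)
    kvals <- apply(bVectors(tss), 2L, function(n)
      unname(apparentDK(D, W, n)["K"]))
    expect_equal(pm$proxy, kfaProxy(kvals), tolerance = 1e-10)
  }
})

test_that("proxy maps are vectorized, deterministic and permutation invariant", {
  tss <- twoShellScheme(1, 2.5, loadDirections("9"))
  pop <- syntheticPopulation(40L, seed = 3)
  truth <- groundTruth(pop)
  vol <- DKImetrics:::.predictSignalMatrix(truth$D, truth$W,
                                           asAcquisitionScheme(tss))
  pm <- proxyMap(vol, tss)
  # equals the per-voxel loop
  single <- vapply(seq_len(nrow(vol)), function(v)
    proxyMap(vol[v, ], tss)$proxy, numeric(1))
  expect_equal(pm$proxy, single, tolerance = 1e-12)
  # identical voxels -> identical proxies; Gaussian voxels -> 0
  gauss <- voxelModel(isotropicCompartment(1.0))
  sg <- exactGaussianSignal(gauss, tss)
  uni <- proxyMap(matrix(rep(sg, 5), 5, byrow = TRUE), tss)
  expect_equal(uni$proxy, rep(0, 5), tolerance = 1e-9)
  # permutation of direction labels leaves the proxy unchanged
  perm <- sample(9L)
  tssP <- twoShellScheme(1, 2.5, bVectors(tss)[, perm])
  volP <- vol[, c(1L, 1L + perm, 1L + 9L + perm)]
  expect_equal(proxyMap(volP, tssP)$proxy, pm$proxy, tolerance = 1e-12)
  # shape mismatch errors
  expect_error(proxyMap(vol[, -2], tss), "measurements")
})

test_that("noise-free proxy is approximately rotation invariant", {
  set.seed(14)
  tss <- twoShellScheme(1, 2.5, loadDirections("86"))
  pop <- syntheticPopulation(10L, seed = 14)
  truth <- groundTruth(pop)
  for (vx in 1:5) {
    D <- diffusionTensor(truth$D[vx, ])
    W <- kurtosisTensor(stats::setNames(truth$W[vx, ],
                                        names(tensorValues(kurtosisTensor()))))
    p0 <- proxyMap(predictSignal(1, D, W, tss), tss)$proxy
    R <- randomRotation()
    pR <- proxyMap(predictSignal(1, rotateTensor(D, R), rotateTensor(W, R),
                                 tss), tss)$proxy
    expect_lt(abs(p0 - pR), 0.02)
  }
})
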