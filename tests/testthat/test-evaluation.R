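test_that("pearson matches hand-computed correlations and guards input", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson(1:4, 1:5), "lengths")
  expect_error(pearson(1:2, 1:2), ">= 3")
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

test_that("RMS contrast is the std of the min-max normalized map", {
  expect_equal(rmsContrast(rep(3, 100)), 0)
  expect_equal(rmsContrast(rep(c(0, 1), 50)), 0.5)
  set.seed(4)
  m <- stats::runif(200)
  expect_equal(rmsContrast(3.2 * m + 7), rmsContrast(m), tolerance = 1e-12)
})

test_that("SNR estimation inverts the Rayleigh background", {
  set.seed(13)
  sigma <- 1
  bg <- sqrt(stats::rnorm(1e5, 0, sigma)^2 + stats::rnorm(1e5, 0, sigma)^2)
  obj <- rep(50, 100)
  img <- c(obj, bg)
  snr <- estimateSnr(img, c(rep(TRUE, 100), rep(FALSE, 1e5)),
                     c(rep(FALSE, 100), rep(TRUE, 1e5)))
  expect_equal(snr, 50, tolerance = 0.03)
  # zero-signal object: Rayleigh mean over Gaussian sigma = sqrt(pi/2)
  obj0 <- sqrt(stats::rnorm(1000, 0, sigma)^2 +
                 stats::rnorm(1000, 0, sigma)^2)
  snr0 <- estimateSnr(c(obj0, bg), c(rep(TRUE, 1000), rep(FALSE, 1e5)),
                      c(rep(FALSE, 1000), rep(TRUE, 1e5)))
  expect_equal(snr0, sqrt(pi / 2), tolerance = 0.05)
  expect_error(estimateSnr(img, rep(FALSE, length(img)),
                           rep(TRUE, length(img))), "empty mask")
  expect_error(estimateSnr(rep(1, 10), rep(TRUE, 10), rep(TRUE, 10)),
               "zero background")
})

test_that("FA segmentation applies the strict printed bands", {
  fa <- c(0.05, 0.1, 0.2, 0.3, 0.45, 0.6, 0.7, 1.0)
  seg <- faSegmentation(fa)
  expect_equal(seg$gm, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                         FALSE))
  expect_equal(seg$wm, c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                         FALSE))
  expect_false(any(seg$gm & seg$wm))
})

test_that("the fiber-mixing sweep reproduces FA collapse with KFA survival", {
  ms <- mixtureSweep()
  expect_true(all(ms$converged))
  # endpoints: single fiber has the FA and KFA maxima
  expect_equal(ms$nFA[1], 1)
  expect_equal(ms$nKFA[1], 1)
  expect_equal(ms$VI[1], 1)
  expect_equal(ms$VI[nrow(ms)], 0, tolerance = 1e-12)
  # at VI = 0 the fitted FA vanishes while KFA survives
  last <- nrow(ms)
  expect_lt(ms$nFA[last], 0.1)
  expect_gt(ms$nKFA[last], 0.4)
  # MD is flat across the mixing level
  expect_lt(max(abs(ms$MD - mean(ms$MD))) / mean(ms$MD), 0.02)
  # the nine-direction proxy decreases with complexity like KFA
  expect_lt(ms$proxy[last], ms$proxy[1])
})

test_that("average-then-fit agrees with fit-then-average on homogeneous data", {
  sch <- phantomScheme()
  vm <- defaultFiberVoxel(c(0, 1, 0), dpar = 1.2, dperp = 0.25, isoD = 0.6)
  sig <- matrix(rep(exactGaussianSignal(vm, sch), 6), 6, byrow = TRUE)
  atf <- averageThenFit(sig, rep(TRUE, 6), sch)
  expect_equal(atf$averageThenFit, atf$fitThenAverage, tolerance = 1e-8)
  expect_error(averageThenFit(sig, rep(FALSE, 6), sch), "empty mask")
})

test_that("phantom averaging collapses FA but not KFA, keeps MD and Wbar", {
  ph <- orthogonalPhantom()
  atf <- averageThenFit(ph$signals, ph$labels$bundle > 0, ph$scheme)
  a <- stats::setNames(atf$averageThenFit, atf$metric)
  f <- stats::setNames(atf$fitThenAverage, atf$metric)
  expect_lt(a[["FA"]], 0.05 * f[["FA"]])
  expect_gt(a[["KFA"]], 0.3 * f[["KFA"]])
  expect_lt(abs(a[["MD"]] - f[["MD"]]) / f[["MD"]], 0.03)
  expect_gte(a[["Wbar"]], f[["Wbar"]])
})

test_that("direction/SNR sweeps are reproducible and noise-ordered", {
  pop <- syntheticPopulation(150L, seed = 4)
  sw <- directionSnrSweep(pop, c(3, 25), c(30, Inf), nRealizations = 10L,
                          seed = 4)
  sw2 <- directionSnrSweep(pop, c(3, 25), c(30, Inf), nRealizations = 10L,
                           seed = 4)
  expect_identical(sw@meanR, sw2@meanR)
  # few directions underperform many at low SNR
  expect_lt(sw@meanR["3", "30"], sw@meanR["25", "30"])
  expect_error(directionSnrSweep(syntheticPopulation(10L, seed = 1),
                                 9, 100), ">= 50 voxels")
  tab <- sweepTable(sw)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$mean_r >= -1 & tab$mean_r <= 1))
})

test_that("the b-value grid masks b1 >= b2 and prefers a higher b2", {
  pop <- syntheticPopulation(125L, seed = 9)
  grid <- c(1, 1.2, 2.5, 5)
  sw <- bvalueGridSearch(pop, grid, grid, nDirections = 9L, snr = 100,
                         nRealizations = 10L, seed = 9)
  expect_true(all(is.na(sw@meanR[lower.tri(sw@meanR, diag = TRUE)])))
  best <- argmaxCell(sw)
  expect_gt(best$b2, best$b1)
  # a shell pair with real separation beats the nearly-degenerate one
  expect_gt(best$meanR, sw@meanR["1", "1.2"])
  expect_error(bvalueGridSearch(pop, 2, 1), "no b1 < b2")
})
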