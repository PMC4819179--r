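test_that("MD and FA match hand-evaluated eigenvalue formulas", {
  expect_equal(unname(mdFA(diffusionTensor(diag(3) * 0.7))["FA"]), 0)
  expect_equal(unname(mdFA(diffusionTensor(1, 0, 0))["FA"]), 1)
  m <- mdFA(diffusionTensor(2, 1, 1))
  expect_equal(unname(m["MD"]), 4 / 3)
  expect_equal(unname(m["FA"]), 1 / sqrt(6))
  # all-zero tensor: FA defined as 0
  expect_equal(unname(mdFA(diffusionTensor(0, 0, 0))["FA"]), 0)
  expect_error(diffusionTensor(NaN, 1, 1), "finite")
})

test_that("Wbar is the spherical average of the quartic contraction", {
  expect_equal(wbar(isotropicKurtosisTensor(1)), 1)
  expect_equal(wbar(kurtosisTensor(xxxx = 1)), 0.2)
  # brute-force spherical quadrature oracle on random tensors
  set.seed(42)
  dirs <- fibonacciSphere(4000L)
  for (rep in 1:5) {
    W <- randomKurtosisTensor()
    Warr <- tensorArray(W)
    quad <- mean(apply(dirs, 2L, function(n) bruteWContraction(Warr, n)))
    expect_equal(wbar(W), quad, tolerance = 1e-3)
  }
})

test_that("KFA matches the 81-component Frobenius-norm definition", {
  expect_equal(kfa(isotropicKurtosisTensor(3.7)), 0)
  expect_equal(kfa(isotropicKurtosisTensor(-2)), 0)
  expect_equal(kfa(kurtosisTensor(xxxx = 1, yyyy = -1)), 1)
  expect_equal(kfa(kurtosisTensor(xxxx = 1)), sqrt(0.8))
  # zero tensor convention
  expect_equal(kfa(kurtosisTensor()), 0)
  set.seed(1)
  for (rep in 1:25) {
    W <- randomKurtosisTensor()
    Warr <- tensorArray(W)
    expect_equal(kfa(W), bruteKfa(Warr), tolerance = 1e-10)
    expect_equal(wnorm(W), bruteFrobenius(Warr), tolerance = 1e-12)
    # scale invariance
    c0 <- stats::runif(1, 0.1, 9)
    expect_equal(kfa(kurtosisTensor(c0 * W@values)), kfa(W),
                 tolerance = 1e-12)
  }
})

test_that("expansion to 81 Cartesian components respects full symmetry", {
  set.seed(3)
  W <- randomKurtosisTensor()
  a <- tensorArray(W)
  idx <- expand.grid(1:3, 1:3, 1:3, 1:3)
  for (r in sample(nrow(idx), 40L)) {
    p <- as.integer(idx[r, ])
    for (perm in list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2),
                      c(4, 3, 2, 1))) {
      q <- p[perm]
      expect_identical(a[p[1], p[2], p[3], p[4]], a[q[1], q[2], q[3], q[4]])
    }
  }
})

test_that("apparent D(n) and K(n) agree with index-loop contraction", {
  # hand-computed example
  dk <- apparentDK(diffusionTensor(2, 1, 1), kurtosisTensor(xxxx = 1),
                   c(1, 0, 0))
  expect_equal(unname(dk["D"]), 2)
  expect_equal(unname(dk["K"]), 4 / 9)
  # isotropic D: K(n) reduces to the bare quartic contraction
  set.seed(9)
  W <- randomKurtosisTensor()
  n <- randomUnitVector()
  expect_equal(unname(apparentDK(diffusionTensor(diag(3) * 1.3), W, n)["K"]),
               bruteWContraction(tensorArray(W), n), tolerance = 1e-10)
  for (rep in 1:20) {
    D <- randomDiffusionTensor()
    W <- randomKurtosisTensor()
    n <- randomUnitVector()
    dk <- apparentDK(D, W, n)
    dn <- bruteDContraction(tensorMatrix(D), n)
    md <- mean(diag(tensorMatrix(D)))
    expect_equal(unname(dk["D"]), dn, tolerance = 1e-10)
    expect_equal(unname(dk["K"]),
                 md^2 / dn^2 * bruteWContraction(tensorArray(W), n),
                 tolerance = 1e-10)
  }
  expect_error(apparentDK(diffusionTensor(1, 1, 1), randomKurtosisTensor(),
                          c(2, 0, 0)), "unit")
  expect_error(apparentDK(diffusionTensor(0, 0, 0), randomKurtosisTensor(),
                          c(1, 0, 0)), "degenerate")
})

test_that("mean kurtosis reduces to Wbar for isotropic diffusion", {
  W <- isotropicKurtosisTensor(1.7)
  D <- diffusionTensor(diag(3) * 0.9)
  expect_equal(meanKurtosis(D, W), 1.7, tolerance = 1e-6)
  set.seed(4)
  Wr <- randomKurtosisTensor()
  expect_equal(meanKurtosis(D, Wr), wbar(Wr), tolerance = 1e-3)
  expect_equal(meanKurtosis(D, kurtosisTensor()), 0)
  expect_error(meanKurtosis(D, Wr, directions = fibonacciSphere(30L)),
               ">= 60")
})

test_that("scalar metrics are rotation invariant", {
  set.seed(12)
  D <- randomDiffusionTensor()
  W <- randomKurtosisTensor()
  base <- c(mdFA(D), Wbar = wbar(W), KFA = kfa(W))
  mk0 <- meanKurtosis(D, W)
  for (rep in 1:20) {
    R <- randomRotation()
    Dr <- rotateTensor(D, R)
    Wr <- rotateTensor(W, R)
    expect_equal(c(mdFA(Dr), Wbar = wbar(Wr), KFA = kfa(Wr)), base,
                 tolerance = 1e-8)
    expect_equal(meanKurtosis(Dr, Wr), mk0, tolerance = 1e-3)
  }
  # rotateTensor itself against the explicit 8-index loop
  R <- randomRotation()
  expect_equal(tensorArray(rotateTensor(W, R)),
               bruteRotateW(tensorArray(W), R), tolerance = 1e-12)
})

test_that("FA and KFA stay inside [0, 1] over random draws", {
  set.seed(77)
  for (rep in 1:2000) {
    # deliberately unconstrained draws, including indefinite D
    d <- stats::rnorm(6L, sd = 2)
    fa <- unname(mdFA(diffusionTensor(d))["FA"])
    k <- kfa(kurtosisTensor(stats::setNames(stats::rnorm(15L, sd = 3),
                                            names(tensorValues(kurtosisTensor())))))
    expect_true(fa >= 0 && fa <= 1)
    expect_true(k >= 0 && k <= 1)
  }
})
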