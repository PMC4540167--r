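test_that("kernel correlations match their closed forms", {
  ek <- expKernel(7)
  expect_equal(kernelCorrelation(c(0.3, 0.4), c(0.3, 0.4), ek), 1)
  expect_equal(kernelCorrelation(c(0, 0), c(1, 0), ek), exp(-7))
  expect_equal(kernelCorrelation(c(0, 0), c(0, 0.5), ek), exp(-3.5))
  mk <- maternKernel(phi = 0.2)
  expect_equal(kernelCorrelation(c(0, 0), c(0, 0), mk), 1)
  # at h = phi the 5/2 closed form gives (1 + 1 + 1/3) e^-1
  expect_equal(kernelCorrelation(c(0, 0), c(0.2, 0), mk), (7 / 3) * exp(-1))
  expect_error(expKernel(-1), "nu")
  expect_error(maternKernel(0), "phi")
})

test_that("Matern 5/2 closed form equals the Bessel-function form to 1e-10", {
  # independent oracle: general Matern via besselK at kappa = 5/2
  matern_bessel <- function(u, kappa)
    ifelse(u == 0, 1, u^kappa * besselK(u, kappa) / (2^(kappa - 1) * gamma(kappa)))
  phi <- 0.15
  mk <- maternKernel(phi = phi)
  u <- 10^seq(-3, 1, length.out = 60)
  got <- vapply(u, function(ui)
    kernelCorrelation(c(0, 0), c(ui * phi, 0), mk), numeric(1))
  expect_lt(max(abs(got - matern_bessel(u, 2.5))), 1e-10)
})

test_that("anisotropy transform rotates then stretches", {
  expect_equal(anisotropyTransform(c(0.3, 0.4), 0, 1), c(0.3, 0.4))
  # pure rotation preserves pairwise distances
  set.seed(1)
  pts <- matrix(runif(10), 5, 2)
  rot <- anisotropyTransform(pts, pi / 2, 1)
  expect_equal(as.matrix(dist(rot)), as.matrix(dist(pts)))
  # ratio 2 doubles distances along the second (rotated) coordinate
  a <- anisotropyTransform(c(0, 0), pi / 6, 2)
  b <- anisotropyTransform(c(0, 1), pi / 6, 2)
  R <- matrix(c(cos(pi / 6), -sin(pi / 6), sin(pi / 6), cos(pi / 6)), 2, 2,
              byrow = TRUE)
  oracle <- diag(c(1, 2)) %*% R %*% c(0, 1)   # direct matrix multiplication
  expect_equal(b - a, drop(oracle))
  expect_error(anisotropyTransform(c(1, 2, 3), 0, 1), "d = 2")
})

test_that("correlation matrices are symmetric, unit-diagonal, positive definite", {
  set.seed(42)
  for (kern in list(expKernel(7), maternKernel(0.3),
                    expKernel(4, angle = 0.5, ratio = 2))) {
    pts <- matrix(runif(10), 5, 2)
    C <- correlationMatrix(pts, kern)
    expect_equal(C, t(C))
    expect_equal(unname(diag(C)), rep(1, 5))
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_error(correlationMatrix(rbind(c(0, 0), c(0, 0)), expKernel(7)),
               "singular")
})

test_that("kriging weights interpolate, are unbiased, and have the far-field limit", {
  set.seed(7)
  m <- gpModel(expKernel(5), trend = "linear")
  pts <- matrix(runif(12), 6, 2)
  # interpolation at every design site
  for (i in seq_len(6)) {
    kw <- krigingWeights(pts[i, ], pts, m)
    e_i <- replace(numeric(6), i, 1)
    expect_equal(kw$w, e_i, tolerance = 1e-10)
    expect_lt(abs(kw$rho2), 1e-10)
  }
  # unbiasedness w'F = f(x)' for random x and kernel parameters
  for (nu in c(0.5, 3, 11)) {
    mm <- gpModel(expKernel(nu), trend = "linear")
    Fm <- trendBasis(pts, "linear")
    for (rep in 1:5) {
      x <- runif(2)
      kw <- krigingWeights(x, pts, mm)
      expect_equal(drop(crossprod(Fm, kw$w)), c(1, x), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
  # constant trend, all correlations -> 0 (mutually distant sites, far x):
  # w -> 1/n each and rho2 -> 1 + 1/n
  mc <- gpModel(expKernel(7))
  far <- as.matrix(expand.grid(c(0, 30, 60), c(0, 30)))
  kw <- krigingWeights(c(150, 150), far, mc)
  expect_equal(kw$w, rep(1 / 6, 6), tolerance = 1e-6)
  expect_equal(kw$rho2, 1 + 1 / 6, tolerance = 1e-6)
})

test_that("rho2 is invariant to rigid motions for isotropic kernels", {
  set.seed(11)
  pts <- matrix(runif(10), 5, 2)
  x <- runif(2)
  m <- gpModel(expKernel(6))
  r0 <- krigingWeights(x, pts, m)$rho2
  th <- 0.7; R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  shift <- c(2.5, -1)
  move <- function(z) sweep(z %*% t(R), 2, shift, "+")
  r1 <- krigingWeights(drop(move(rbind(x))), move(pts), m)$rho2
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("field simulation is seeded and reproduces the model moments", {
  g <- fxSmallGrid(5)
  m <- gpModel(expKernel(3), sigma2 = 1)
  Y1 <- simulateField(g, m, 50, seed = 99)
  Y2 <- simulateField(g, m, 50, seed = 99)
  expect_identical(Y1, Y2)
  Y <- simulateField(g, m, 10000, seed = 123)
  # marginal variance: sd of a variance estimate is about sqrt(2/N)
  v <- apply(Y[, c(1, 13, 25)], 2, var)
  expect_true(all(abs(v - 1) < 3 * sqrt(2 / 10000)))
  # pairwise correlation matches the kernel
  r_emp <- cor(Y[, 1], Y[, 2])
  r_true <- kernelCorrelation(g$coords[1, ], g$coords[2, ], m$kernel)
  expect_lt(abs(r_emp - r_true), 3 / sqrt(10000))
})

test_that("simulated prediction errors reproduce the kriging variance", {
  g <- fxSmallGrid(6)
  m <- gpModel(expKernel(4))
  d <- randomDesign(g, 5, seed = 3)
  site <- 15                       # off-design prediction site
  stopifnot(!(site %in% d$idx))
  kw <- krigingWeights(g$coords[site, ], d, m)
  Y <- simulateField(g, m, 100000, seed = 31)
  err <- Y[, d$idx, drop = FALSE] %*% kw$w - Y[, site]
  v_emp <- var(drop(err))
  v_true <- m$sigma2 * kw$rho2
  expect_lt(abs(v_emp - v_true), 3 * sqrt(2 / 100000) * v_true)
})
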