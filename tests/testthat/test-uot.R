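# The unbalanced entropic OT loss: perspective coefficient, cost matrices,
# solver, gradient, composite loss.

test_that("perspective coefficient is the mean of the normalized heights", {
  expect_equal(perspectiveCoeff(0.4, 0.6), 0.5)
  for (h in c(0.1, 0.37, 1)) expect_equal(perspectiveCoeff(h, h), h)
  expect_error(perspectiveCoeff(0, 0.5), "heights")
  expect_error(perspectiveCoeff(0.5, -0.1), "heights")
})

test_that("cost matrices evaluate each family as defined", {
  # coincident pixel and point at normalized height 0.5
  p <- cbind(10, 49.5)
  expect_equal(costEntries(costMatrix(p, p, "perspective",
                                      imageHeight = 100))[1, 1], 1)
  # normalized distance 0.5 at height 0.5: exp(0.5 / 0.5) = e
  q <- cbind(60, 49.5)
  expect_equal(costEntries(costMatrix(p, q, "perspective",
                                      imageHeight = 100))[1, 1],
               exp(1), tolerance = 1e-12)
  expect_equal(costEntries(costMatrix(p, q, "exp", imageHeight = 100))[1, 1],
               exp(0.5), tolerance = 1e-12)
  expect_equal(costEntries(costMatrix(p, q, "euclid"))[1, 1], 50)
  expect_equal(costEntries(costMatrix(p, q, "squared"))[1, 1], 2500)
  expect_error(costMatrix(p, q, "nonsense"), "arg")
  expect_error(costMatrix(p, q, "perspective"), "imageHeight")
})

test_that("perspective cost strictly decreases in the coefficient", {
  # fixed normalized distance, increasing heights
  L <- 0.3
  etas <- seq(0.1, 1, by = 0.1)
  costs <- exp(L / etas)
  prev <- Inf
  for (k in seq_along(etas)) {
    pj <- cbind(0, etas[k] * 100 - 0.5)
    qj <- cbind(L * 100, etas[k] * 100 - 0.5)
    v <- costEntries(costMatrix(pj, qj, "perspective", imageHeight = 100))[1, 1]
    expect_equal(v, costs[k], tolerance = 1e-12)
    expect_lt(v, prev)
    prev <- v
  }
})

test_that("solver handles degenerate masses", {
  z <- solveUot(0, 0, matrix(5, 1, 1))
  expect_equal(transportPlan(z), matrix(0, 1, 1))
  expect_equal(z@objective, 0)
  expect_true(z@converged)
  expect_error(solveUot(c(1, NA), 1, matrix(1, 2, 1)), "finite")
  expect_error(solveUot(1, 1, matrix(1, 1, 1), eps = 0), "positive")
})

test_that("1x1 solve matches the scalar grid-search oracle", {
  tp <- solveUot(1, 1, matrix(1, 1, 1), eps = 0.05, tau = 0.5)
  p <- seq(0, 2, by = 1e-5)
  f <- p - 0.05 * ifelse(p > 0, p * log(p), 0) + 0.5 * (p - 1)^2 +
    0.5 * abs(p - 1)
  expect_lt(abs(tp@objective - min(f)) / min(f), 1e-4)
})

test_that("near-diagonal costs concentrate the plan on the diagonal", {
  C <- matrix(c(1e-3, 1, 1, 1e-3), 2, 2)
  tp <- solveUot(c(1, 1), c(1, 1), C, eps = 0.01, tau = 50,
                 tol = 1e-12, maxIter = 20000)
  P <- transportPlan(tp)
  expect_lt((P[1, 2] + P[2, 1]) / sum(P), 0.05)
})

test_that("objective at the returned plan matches an R recomputation", {
  set.seed(123)
  for (i in 1:10) {
    inst <- randomUotInstance()
    tp <- solveUot(inst$a, inst$b, inst$C)
    expect_equal(tp@objective,
                 uotObjectiveR(transportPlan(tp), inst$C, inst$a, inst$b,
                               0.05, 0.5),
                 tolerance = 1e-10)
  }
})

test_that("marginal fidelity improves monotonically with tau", {
  set.seed(55)
  for (rep in 1:3) {
    a <- runif(4, 0.2, 1.5); b <- runif(3, 0.2, 1.5)
    C <- matrix(runif(12, 0.1, 2), 4, 3)
    errs <- vapply(c(0.05, 0.5, 5, 50), function(tau) {
      P <- transportPlan(solveUot(a, b, C, eps = 0.05, tau = tau,
                                  tol = 1e-11, maxIter = 30000))
      sum(abs(rowSums(P) - a)) / sum(a)
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-8))
  }
})

test_that("envelope gradient matches finite differences", {
  set.seed(77)
  for (i in 1:5) {
    a <- runif(3, 0.1, 2); b <- runif(2, 0.2, 1.5)
    C <- matrix(runif(6, 0.1, 3), 3, 2)
    g <- uotLossGrad(a, b, C, tol = 1e-12, maxIter = 50000)
    fd <- vapply(1:3, function(k) {
      e <- 1e-5
      up <- uotLossGrad(replace(a, k, a[k] + e), b, C,
                        tol = 1e-12, maxIter = 50000)$loss
      dn <- uotLossGrad(replace(a, k, a[k] - e), b, C,
                        tol = 1e-12, maxIter = 50000)$loss
      (up - dn) / (2 * e)
    }, numeric(1))
    expect_lt(max(abs(g$grad - fd) / pmax(1e-3, abs(fd))), 1e-3)
  }
})

test_that("penalty terms scale linearly in tau at a fixed plan", {
  set.seed(99)
  inst <- randomUotInstance()
  P <- transportPlan(solveUot(inst$a, inst$b, inst$C))
  base <- uotObjectiveR(P, inst$C, inst$a, inst$b, eps = 0.05, tau = 0)
  pen1 <- uotObjectiveR(P, inst$C, inst$a, inst$b, eps = 0.05, tau = 0.5) - base
  pen2 <- uotObjectiveR(P, inst$C, inst$a, inst$b, eps = 0.05, tau = 1.0) - base
  expect_equal(pen2, 2 * pen1, tolerance = 1e-12)
})

test_that("composite loss decomposes and books keep", {
  pa <- fixPoints(cbind(c(10, 30, 50), c(12, 35, 50)), 64, 64)
  gt <- downsampleDensity(renderDensity(pa, shape = c(64, 64)), 4)
  # perfect prediction: zero count loss and zero pixel term
  lb <- compositeLoss(gt, pa, gt)
  expect_equal(lb@countLoss, 0)
  expect_equal(lb@pixelMse, 0)
  expect_equal(lossTotal(lb), lb@countLoss + 0.1 * lb@otLoss,
               tolerance = 1e-12)
  # count off by 0.5: smooth-L1 quadratic zone gives 0.125
  off <- densityMap(densityGrid(gt) * (3.5 / 3), stride = 4L)
  lb2 <- compositeLoss(off, pa, gt)
  expect_equal(lb2@countLoss, 0.125, tolerance = 1e-9)
  # custom coefficients recompose exactly
  lb3 <- compositeLoss(off, pa, gt, lambda1 = 0.3, lambda2 = 0.07)
  expect_equal(lossTotal(lb3),
               lb3@countLoss + 0.3 * lb3@otLoss + 0.07 * lb3@pixelMse,
               tolerance = 1e-12)
  # shape mismatch rejected
  expect_error(compositeLoss(downsampleDensity(gt, 2), pa, gt), "shape")
})

test_that("smooth-L1 has the stated quadratic-to-linear transition", {
  expect_equal(smoothL1(0.5), 0.125)
  expect_equal(smoothL1(-0.5), 0.125)
  expect_equal(smoothL1(3), 2.5)
  expect_equal(smoothL1(1), 0.5)
})
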