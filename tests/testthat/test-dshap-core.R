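test_that("rescale multipliers follow the difference quotient and kink rules", {
  expect_equal(rescaleMultiplier("relu", 2, 0), 1)      # (2-0)/(2-0)
  expect_equal(rescaleMultiplier("relu", -1, 0), 0)     # (0-0)/(-1-0)
  expect_equal(rescaleMultiplier("relu", 0.5, 0.5), 1)  # derivative, active side
  expect_equal(rescaleMultiplier("relu", 0, 0), 0)      # subgradient 0 at kink
  expect_equal(rescaleMultiplier("relu", 3, 1), 1)
  expect_equal(rescaleMultiplier("relu", 1, -1), 0.5)   # (1-0)/(1-(-1))
  expect_equal(rescaleMultiplier("identity", 5, 2), 1)
  s <- function(z) plogis(z)
  expect_equal(rescaleMultiplier("sigmoid", 2, -1), (s(2) - s(-1)) / 3)
  expect_equal(rescaleMultiplier("sigmoid", 0.7, 0.7), s(0.7) * (1 - s(0.7)))
  expect_error(rescaleMultiplier("tanh", 1, 0), "unsupported")
})

test_that("affine models attribute in closed form and zero at the reference", {
  m <- affineModel(c(2, -1, 0), b = 5)
  a <- deepSHAP(m, c(1, 1, 1))
  expect_equal(as.numeric(attributions(a)), c(2, -1, 0))
  expect_equal(a@residual, 0)

  a0 <- deepSHAP(m, c(0, 0, 0))          # x = ref
  expect_equal(as.numeric(attributions(a0)), c(0, 0, 0))
  expect_equal(a0@residual, 0)
})

test_that("completeness holds on seeded random rectifier networks", {
  worst <- 0
  for (s in 1:200) {
    m <- randomReluNet(8, 5L, seed = s)
    set.seed(s)
    x <- rbinom(8, 1, 0.5)
    a <- deepSHAP(m, x)
    worst <- max(worst, abs(a@residual))
  }
  expect_lte(worst, 1e-6)
})

test_that("linear-activation deep networks equal the exact Shapley oracle", {
  # 2-layer network with identity activations composes to an affine map
  set.seed(10)
  W1 <- matrix(rnorm(4 * 6), 4, 6); b1 <- rnorm(4)
  W2 <- matrix(rnorm(4), 1, 4); b2 <- 0.2
  sp <- modelSpec(paste0("C", 1:6), H = 0L, hiddenDims = 4L)
  m <- handSetModel(sp, list(list(W = W1, b = b1, activation = "identity"),
                             list(W = W2, b = b2, activation = "identity")))
  x <- c(1, 0, 1, 1, 0, 1)
  d <- attributions(deepSHAP(m, x))
  e <- attributions(exactShapley(function(z) predictRisk(m, z), x))
  expect_lt(max(abs(d - e)), 1e-9)
})

test_that("the enumeration oracle satisfies additivity and symmetry", {
  g <- list(function(z) z^2, function(z) 3 * z, function(z) exp(z))
  f <- function(x) g[[1]](x[1]) + g[[2]](x[2]) + g[[3]](x[3])
  x <- c(2, 1, 0.5); ref <- c(0.5, 0, -1)
  phi <- as.numeric(attributions(exactShapley(f, x, ref)))
  expect_equal(phi, vapply(1:3, function(i) g[[i]](x[i]) - g[[i]](ref[i]),
                           numeric(1)))
  # symmetry: interchangeable inputs with equal values get equal credit
  fs <- function(x) x[1] * x[2] + x[1] + x[2]
  phiS <- as.numeric(attributions(exactShapley(fs, c(1, 1), c(0, 0))))
  expect_equal(phiS[1], phiS[2])
  expect_error(exactShapley(function(x) sum(x), rep(1, 13)), "too large")
})

test_that("a 3-input min-like function matches a hand-coded subset loop", {
  f <- function(x) min(x[1] + x[2], 2 * x[3])
  x <- c(1, 2, 0.8); ref <- c(0, 0, 0)
  # independent enumeration: loop all 8 subsets explicitly
  phiHand <- numeric(3)
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    for (s1 in c(FALSE, TRUE)) for (s2 in c(FALSE, TRUE)) {
      S <- others[c(s1, s2)]
      w <- factorial(length(S)) * factorial(3 - length(S) - 1) / factorial(3)
      xS <- ref; xS[S] <- x[S]
      xSi <- xS; xSi[i] <- x[i]
      phiHand[i] <- phiHand[i] + w * (f(xSi) - f(xS))
    }
  }
  phi <- as.numeric(attributions(exactShapley(f, x, ref)))
  expect_equal(phi, phiHand, tolerance = 1e-14)
})

test_that("dummy inputs receive exactly zero attribution", {
  set.seed(2)
  W1 <- matrix(rnorm(3 * 5), 3, 5); W1[, 4] <- 0   # input 4 disconnected
  sp <- modelSpec(paste0("C", 1:5), H = 0L, hiddenDims = 3L)
  m <- handSetModel(sp, list(list(W = W1, b = rnorm(3), activation = "relu"),
                             list(W = matrix(rnorm(3), 1), b = 0,
                                  activation = "sigmoid")))
  a <- deepSHAP(m, c(1, 1, 1, 1, 1))
  expect_identical(unname(attributions(a)[1, 4]), 0)
  e <- exactShapley(function(z) predictRisk(m, z), c(1, 1, 1, 1, 1))
  expect_equal(unname(attributions(e)[1, 4]), 0)
})

test_that("rescale attribution tracks exact Shapley on tiny rectifier nets", {
  # the rescale rule is not exact Shapley in general: assert completeness and
  # report the agreement rather than asserting equality
  devs <- numeric(100)
  for (s in 1:100) {
    m <- randomReluNet(6, 4L, seed = 1000 + s)
    set.seed(1000 + s)
    x <- rbinom(6, 1, 0.6)
    d <- deepSHAP(m, x)
    e <- exactShapley(function(z) predictRisk(m, z), x)
    expect_lte(abs(d@residual), 1e-6)
    expect_lt(abs(e@residual), 1e-12)
    devs[s] <- max(abs(attributions(d) - attributions(e)))
  }
  # the two methods explain the same output difference; per-unit deviations
  # are reported, not asserted equal (the rescale rule is an approximation)
  expect_true(all(is.finite(devs)))
  expect_lt(max(devs), 1)
  message(sprintf("rescale vs exact Shapley: median dev %.3f, max dev %.3f",
                  median(devs), max(devs)))
})

test_that("batch attribution preserves order, determinism and completeness", {
  expect_equal(nrow(attributions(attributionBatch(
    buildModel(modelSpec("A", H = 1L, hiddenDims = 2L)), list()))), 0)

  fx <- makeFixture("tiny_linear", nPatients = 100)
  co <- sampleCohort(fx$spec, seed = 3)
  ms <- modelSpec(fx$spec@catalogue$code, H = 2L, hiddenDims = 4L, initSeed = 2L)
  m <- buildModel(ms)
  cw <- cohortWindows(co, ms)
  dup <- c(cw$windows, cw$windows[1])
  a <- attributionBatch(m, dup)
  expect_equal(attributions(a)[1, ], attributions(a)[nrow(attributions(a)), ])
  expect_true(all(abs(a@residual) <= 1e-6))
  # batch equals the single-record path
  a1 <- deepSHAP(m, featurize(cw$windows[[5]], ms))
  expect_equal(attributions(a)[5, ], attributions(a1)[1, ], tolerance = 1e-12)
})

test_that("attribution tables round-trip through CSV", {
  fx <- makeFixture("tiny_linear", nPatients = 30)
  co <- sampleCohort(fx$spec, seed = 3)
  ms <- modelSpec(fx$spec@catalogue$code, H = 1L, hiddenDims = 3L, initSeed = 2L)
  m <- buildModel(ms)
  cw <- cohortWindows(co, ms)
  a <- attributionBatch(m, cw$windows)
  f <- tempfile(fileext = ".csv")
  writeAttributionCSV(a, f, meta = c(seed = "3"))
  a2 <- readAttributionCSV(f)
  expect_equal(attributions(a), attributions(a2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(a@fX, a2@fX, tolerance = 1e-8)
})
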