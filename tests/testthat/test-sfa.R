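test_that("quadratic expansion lists monomials in lexicographic order", {
  expect_equal(quadratic_expand(c(1, 2)), c(1, 2, 1, 2, 4))
  expect_equal(length(quadratic_expand(rep(1, 3))), 9)
  expect_equal(quadratic_expand(c(0, 0, 0, 0)), rep(0, 14))
  x <- c(2, 3, 5)
  expect_equal(quadratic_expand(x),
               c(2, 3, 5, 4, 6, 10, 9, 15, 25))
  X <- rbind(c(1, 2), c(3, 4))
  expect_equal(quadratic_expand(X)[2, ], quadratic_expand(c(3, 4)))
})

test_that("delta value matches the closed form for a sampled sinusoid", {
  expect_equal(delta_value(rep(3, 100)), 0)
  T_ <- 1000
  t <- 0:(T_ - 1)
  y <- sqrt(2) * sin(2 * pi * t / T_)
  # exact discrete value 4 sin^2(pi/T) ~ (2 pi / T)^2 for the unit-variance
  # sinusoid; the continuous-time limit is matched to < 1%
  expect_equal(delta_value(y), 4 * sin(pi / T_)^2, tolerance = 1e-4)
  expect_equal(delta_value(y), (2 * pi / T_)^2, tolerance = 0.01)
  y2 <- sqrt(2) * sin(2 * pi * 5 * t / T_)
  expect_gt(delta_value(y2), delta_value(y))
  expect_error(delta_value(rep(1, 50), normalize = TRUE), "constant")
  # normalization makes amplitude irrelevant
  expect_equal(delta_value(7 * y, normalize = TRUE),
               delta_value(y, normalize = TRUE))
})

test_that("training outputs satisfy the zero-mean, unit-variance, decorrelation constraints", {
  set.seed(42)
  fixtures <- list(
    linear = list(X = apply(matrix(rnorm(3000 * 6), 3000), 2, cumsum),
                  expansion = "none", noise = 0),
    quadratic = list(X = apply(matrix(rnorm(1500 * 4), 1500), 2,
                               function(c) stats::filter(c, rep(1, 20) / 20,
                                                         circular = TRUE)),
                     expansion = "quadratic", noise = 1e-5)
  )
  for (fx in fixtures) {
    m <- fit_sfa(fx$X, out_dim = 4, expansion = fx$expansion,
                 noise_sigma = fx$noise, seed = 2)
    Y <- sfa_training_outputs(m, fx$X)
    expect_lt(max(abs(colMeans(Y))), 1e-8)
    expect_lt(max(abs(colMeans(Y^2) - 1)), 1e-6)
    C <- crossprod(Y) / nrow(Y)
    expect_lt(max(abs(C[upper.tri(C)])), 1e-6)
    expect_true(all(diff(m$delta_values) >= 0))
  }
})

test_that("quadratic SFA demixes the slow source and matches the dense oracle", {
  T_ <- 2000
  t <- 0:(T_ - 1)
  s1 <- sin(2 * pi * t / T_)
  s2 <- sin(22 * pi * t / T_)
  X <- cbind(s1 + s2^2, s2)
  m <- fit_sfa(X, out_dim = 2, expansion = "quadratic", noise_sigma = 0)
  Y <- sfa_training_outputs(m, X)
  expect_gt(abs(cor(Y[, 1], s1)), 0.95)
  orc <- oracle_sfa_outputs(X, 2, "quadratic")
  for (k in 1:2) {
    expect_gt(abs(cor(Y[, k], orc$outputs[, k])), 1 - 1e-8)
  }
})

test_that("whitening-path solution equals the dense generalized-eigenproblem oracle", {
  set.seed(9)
  X <- apply(matrix(rnorm(2000 * 8), 2000), 2,
             function(c) stats::filter(c, rep(1, 8) / 8, circular = TRUE))
  m <- fit_sfa(X, out_dim = 8, expansion = "none", noise_sigma = 0)
  Y <- sfa_training_outputs(m, X)
  orc <- oracle_sfa_outputs(X, 8, "none")
  Yo <- orc$outputs
  Yo <- sweep(Yo, 2, sqrt(colMeans(Yo^2)), `/`) # oracle outputs to unit variance
  for (k in 1:8) {
    s <- sign(sum(Y[, k] * Yo[, k]))
    expect_lt(max(abs(Y[, k] - s * Yo[, k])), 1e-6)
  }
  expect_equal(m$delta_values, orc$delta, tolerance = 1e-8)
})

test_that("the first output is slower than random projections of the same data", {
  set.seed(4)
  X <- apply(matrix(rnorm(1500 * 5), 1500), 2, cumsum)
  m <- fit_sfa(X, out_dim = 3, expansion = "none")
  Y <- sfa_training_outputs(m, X)
  d1 <- delta_value(Y[, 1])
  Phi <- sweep(X, 2, colMeans(X))
  for (i in 1:100) {
    w <- rnorm(5)
    p <- Phi %*% w
    p <- (p - mean(p)) / sqrt(mean((p - mean(p))^2))
    expect_lte(d1, delta_value(drop(p)) + 1e-12)
  }
})

test_that("apply_sfa is a deterministic map that works on a single sample", {
  set.seed(1)
  X <- apply(matrix(rnorm(800 * 4), 800), 2, cumsum)
  m <- fit_sfa(X, out_dim = 2, expansion = "quadratic", noise_sigma = 1e-6)
  y1 <- apply_sfa(m, X[5, ])
  expect_equal(dim(y1), c(1, 2))
  expect_identical(apply_sfa(m, X), apply_sfa(m, X))
  expect_error(apply_sfa(m, X[, 1:3]), "expects")
})

test_that("rank-deficient data without noise raises an informative error", {
  set.seed(2)
  base <- cumsum(rnorm(500))
  X <- cbind(base, base * 2, rnorm(500)) # collinear pair
  expect_error(fit_sfa(X, out_dim = 3, expansion = "none", noise_sigma = 0),
               "noise")
  # with regularizing noise (above the whitening cutoff) the fit succeeds
  m <- fit_sfa(X, out_dim = 3, expansion = "none", noise_sigma = 0.05)
  expect_s3_class(m, "sfa_model")
})

test_that("tidy and glance summarise a fitted model", {
  set.seed(3)
  X <- apply(matrix(rnorm(600 * 3), 600), 2, cumsum)
  m <- fit_sfa(X, out_dim = 2)
  td <- tidy(m)
  expect_equal(td$component, 1:2)
  expect_equal(td$delta, m$delta_values)
  gl <- glance(m)
  expect_equal(gl$in_dim, 3L)
  expect_equal(gl$out_dim, 2L)
})
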