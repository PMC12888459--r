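test_that("PLS1 fits exactly when X spans y", {
  y <- c(1, 4, 2, 6, 3)
  fit <- pls1(cbind(v = y), y, ncomp = 1)
  expect_equal(fitted(fit), y, tolerance = 1e-10)
  expect_equal(fit$R2Y, 1, tolerance = 1e-10)

  set.seed(31)
  X <- matrix(rnorm(50), 10, 5)
  yy <- as.numeric(X %*% c(1, -2, 0.5, 3, -1))
  fit5 <- pls1(X, yy, ncomp = 5)
  expect_equal(fit5$R2Y, 1, tolerance = 1e-8)
  expect_equal(fitted(fit5), yy, tolerance = 1e-6)
  # predict on training data reproduces the fit, coef is consistent
  expect_equal(predict(fit5, X), fitted(fit5), tolerance = 1e-8)
  b <- coef(fit5)
  expect_equal(as.numeric(b[1] + X %*% b[-1]), fitted(fit5),
               tolerance = 1e-8)
})

test_that("a response orthogonal to X is left unexplained", {
  set.seed(32)
  X <- matrix(rnorm(60), 12, 5)
  y <- rnorm(12); y <- y - mean(y)
  # orthogonalise X's centred columns against y, keep a whisper of signal
  Xc <- scale(X, scale = FALSE)
  Xo <- Xc - outer(y, as.numeric(crossprod(Xc, y)) / sum(y^2))
  Xo <- Xo + 1e-8 * matrix(rnorm(60), 12)
  fit <- pls1(Xo, y, ncomp = 1, scale = FALSE)
  expect_lt(fit$R2Y, 1e-6)
})

test_that("OPLS with no orthogonal component reduces to 1-component PLS1", {
  set.seed(33)
  X <- matrix(rnorm(80), 10, 8)
  y <- rnorm(10)
  a <- opls(X, y, n_orth = 0)
  b <- pls1(X, y, ncomp = 1)
  expect_equal(fitted(a), fitted(b), tolerance = 1e-10)
  Xnew <- matrix(rnorm(24), 3, 8)
  expect_equal(predict(a, Xnew), predict(b, Xnew), tolerance = 1e-10)
})

test_that("orthogonal components are orthogonal to the predictive score", {
  set.seed(34)
  X <- matrix(rnorm(200), 20, 10)
  y <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(20, sd = 0.3))
  for (k in 1:3) {
    fit <- opls(X, y, n_orth = k)
    expect_equal(fit$n_orth, k)
    expect_true(all(abs(crossprod(fit$T, fit$To)) < 1e-8))
  }
})

test_that("an orthogonal structured block is captured as such", {
  set.seed(35)
  y <- rnorm(24); y <- as.numeric(scale(y))
  z <- rnorm(24); z <- z - y * sum(y * z) / sum(y^2)  # exactly y-orthogonal
  X <- cbind(a = y + z, b = y)
  fit <- opls(X, y, n_orth = 1, scale = FALSE)
  expect_gt(abs(cor(fit$T[, 1], y)), 0.999)
  expect_lt(abs(cor(fit$To[, 1], y)), 1e-6)
})

test_that("a fit with no orthogonal variation left stops early", {
  y <- c(1, 3, 2, 5, 4)
  expect_warning(fit <- opls(cbind(v = y, w = 2 * y), y, n_orth = 1),
                 "no orthogonal variation")
  expect_equal(fit$n_orth, 0L)
})

test_that("VIP is normalised, and separates signal from noise", {
  y <- c(1, 4, 2, 6, 3)
  expect_equal(unname(vip(pls1(cbind(v = y), y))), 1, tolerance = 1e-9)

  set.seed(36)
  y2 <- rnorm(30)
  noise <- rnorm(30); noise <- noise - y2 * sum(y2 * noise) / sum(y2^2)
  fit <- pls1(cbind(sig = y2 + rnorm(30, sd = 0.05), noise = noise),
              y2, ncomp = 1)
  v <- vip(fit)
  expect_gt(v[["sig"]], 1)
  expect_lt(v[["noise"]], 1)

  # mean-square identity across model shapes and modes
  X <- matrix(rnorm(150), 15, 10)
  yy <- rnorm(15)
  for (fit in list(pls1(X, yy, ncomp = 3), opls(X, yy, n_orth = 2))) {
    expect_equal(mean(vip(fit)^2), 1, tolerance = 1e-9)
    expect_equal(mean(vip(fit, mode = "total")^2), 1, tolerance = 1e-9)
  }
  expect_error(vip(list()), "fitted")
})

test_that("cross-validated Q2 tracks predictive power", {
  set.seed(37)
  X <- matrix(rnorm(200), 40, 5)
  y <- as.numeric(X %*% rnorm(5))         # noiseless linear signal
  expect_gt(cross_validate_q2(X, y, folds = 7, method = "pls1",
                              ncomp = 5), 0.99)

  # shuffled responses give non-positive Q2 on average
  q2s <- replicate(40, {
    yp <- sample(y)
    cross_validate_q2(X, yp, folds = 5, n_orth = 0)
  })
  expect_lt(mean(q2s), 0)

  expect_warning(q2 <- cross_validate_q2(X[1:5, ], y[1:5], folds = 10,
                                         n_orth = 0),
                 "leave-one-out")
  expect_error(cross_validate_q2(X[1:2, , drop = FALSE], y[1:2]),
               "3 observations")
  expect_error(cross_validate_q2(X, y, folds = 1), "2 folds")
})

test_that("the permutation test is seeded, reproducible and calibrated", {
  set.seed(38)
  X <- matrix(rnorm(240), 24, 10)
  y <- as.numeric(X[, 1] * 2 + rnorm(24, sd = 0.1))
  r1 <- permutation_test(X, y, n_perm = 30, seed = 99)
  r2 <- permutation_test(X, y, n_perm = 30, seed = 99)
  expect_identical(r1$q2_perm, r2$q2_perm)
  expect_identical(r1$r2y_perm, r2$r2y_perm)
  # a strongly predictive response beats every permutation
  expect_equal(r1$n_exceed, 0L, ignore_attr = TRUE)
  expect_gt(r1$q2, max(r1$q2_perm))
  expect_error(permutation_test(X, y, n_perm = 0), "n_perm")
})

test_that("OPLS-DA separates separable classes and validates labels", {
  set.seed(39)
  X <- rbind(matrix(rnorm(50, mean = 0), 10),
             matrix(rnorm(50, mean = 4), 10))
  labels <- rep(c("a", "b"), each = 10)
  fit <- oplsda(X, labels, n_orth = 1)
  t1 <- fit$T[, 1]
  expect_true(max(t1[labels == "a"]) < min(t1[labels == "b"]) ||
                max(t1[labels == "b"]) < min(t1[labels == "a"]))
  expect_error(oplsda(X, rep("a", 20)), "2 classes")

  X3 <- rbind(X, matrix(rnorm(50, mean = 8), 10))
  fit3 <- oplsda(X3, rep(c("a", "b", "c"), each = 10))
  expect_s3_class(fit3, "oplsda_multi")
  expect_named(fit3, c("a", "b", "c"))
})

test_that("NIPALS PCA matches the spectral decomposition", {
  # collinear data: one component explains everything
  t <- rnorm(9)
  line <- outer(t, c(1, 2, -1))
  p1 <- pca_nipals(line, n_comp = 1)
  expect_equal(p1$R2X[1], 1, tolerance = 1e-10)

  set.seed(40)
  X <- matrix(rnorm(40), 8, 5)
  res <- pca_nipals(X, n_comp = 4)
  expect_true(all(abs(crossprod(res$scores)[lower.tri(diag(4))]) < 1e-8))
  Xc <- scale(X, scale = FALSE)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)$values
  expect_equal(res$R2X, (ev / sum(ev))[1:4], tolerance = 1e-8)
  expect_error(pca_nipals(X, n_comp = 8), "n_comp")
})
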