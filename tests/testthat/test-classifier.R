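test_that("a duplicated training vector yields the normalized vector as rank-1 basis", {
  set.seed(1)
  u <- rcplx(6)
  X <- cbind(u, u, u)
  model <- fit_subspace(X, rcplx(6, 3), classifier_config())
  U <- model$basis$cSDH
  # basis spans u/||u||: projection of u has zero residual
  expect_equal(as.vector(Mod(U %*% (Conj(t(U)) %*% u) - u)), rep(0, 6),
               tolerance = 1e-10)
  expect_equal(sum(Mod(U)^2), 1, tolerance = 1e-10)
})

test_that("full-rank projection reproduces training vectors exactly", {
  set.seed(2)
  Xp <- rcplx(8, 3); Xn <- rcplx(8, 3)
  model <- fit_subspace(Xp, Xn, classifier_config(rank = 3))
  U <- model$basis$cSDH
  for (j in 1:3) {
    x <- Xp[, j]
    resid <- x - U %*% (Conj(t(U)) %*% x)
    expect_lt(max(Mod(resid)), 1e-10)
  }
})

test_that("rank-1 basis matches a power-iteration oracle on the class Gram matrix", {
  set.seed(3)
  Xp <- rcplx(5, 3); Xn <- rcplx(5, 3)
  model <- fit_subspace(Xp, Xn, classifier_config())
  for (k in c("cSDH", "HC")) {
    X <- if (k == "cSDH") Xp else Xn
    v <- power_leading_eigvec(X %*% Conj(t(X)))
    u <- as.vector(model$basis[[k]])
    # equal up to a unit phase
    phase <- sum(Conj(u) * v); phase <- phase / Mod(phase)
    expect_equal(u * phase, v, tolerance = 1e-8)
  }
})

test_that("subspace projection equals brute-force least squares on small instances", {
  set.seed(4)
  for (trial in 1:20) {
    d <- sample(3:8, 1)
    n <- sample(2:min(5, d - 1), 1)
    Xp <- rcplx(d, n); Xn <- rcplx(d, n)
    model <- fit_subspace(Xp, Xn, classifier_config(rank = n))
    x <- rcplx(d)
    for (k in c("cSDH", "HC")) {
      U <- model$basis[[k]]
      X <- if (k == "cSDH") Xp else Xn
      expect_equal(as.vector(U %*% (Conj(t(U)) %*% x)),
                   as.vector(ls_projection(X, x)), tolerance = 1e-10)
    }
  }
})

test_that("decision values are scale-invariant, antisymmetric under basis swap, and bounded cases hold", {
  set.seed(5)
  Xp <- rcplx(10, 4); Xn <- rcplx(10, 4)
  model <- fit_subspace(Xp, Xn, classifier_config())
  x <- rcplx(10)
  s <- decision_value(model, x)
  for (c0 in c(2 + 0i, -1 + 0i, 0.3 - 4i)) {
    expect_equal(decision_value(model, c0 * x), s, tolerance = 1e-10)
  }
  swapped <- model
  swapped$basis <- list(cSDH = model$basis$HC, HC = model$basis$cSDH)
  expect_equal(decision_value(swapped, x), -s, tolerance = 1e-12)

  # x in the positive subspace and orthogonal to the negative one scores 1
  e1 <- c(1, 0, 0, 0) + 0i; e2 <- c(0, 1, 0, 0) + 0i
  e3 <- c(0, 0, 1, 0) + 0i; e4 <- c(0, 0, 0, 1) + 0i
  m2 <- fit_subspace(cbind(e1, e1), cbind(e3, e4), classifier_config())
  expect_equal(decision_value(m2, e1), 1, tolerance = 1e-12)
})

test_that("projection residuals are non-increasing in the retained rank", {
  set.seed(6)
  Xp <- rcplx(12, 5); Xn <- rcplx(12, 5)
  x <- rcplx(12)
  d_by_rank <- vapply(1:5, function(r) {
    model <- fit_subspace(Xp, Xn, classifier_config(rank = r))
    U <- model$basis$cSDH
    sqrt(sum(Mod(x - U %*% (Conj(t(U)) %*% x))^2)) / sqrt(sum(Mod(x)^2))
  }, 1)
  expect_true(all(diff(d_by_rank) <= 1e-12))
})

test_that("training-vector order does not change decision values", {
  set.seed(7)
  Xp <- rcplx(9, 4); Xn <- rcplx(9, 4)
  x <- rcplx(9)
  cfg <- classifier_config(rank = 2)
  s1 <- decision_value(fit_subspace(Xp, Xn, cfg), x)
  s2 <- decision_value(fit_subspace(Xp[, c(3, 1, 4, 2)], Xn[, c(2, 4, 1, 3)], cfg), x)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("rank-1 scores agree between complex SVD and covariance eigen-decomposition", {
  set.seed(8)
  Xp <- rcplx(7, 4); Xn <- rcplx(7, 4)
  x <- rcplx(7)
  s_svd <- decision_value(fit_subspace(Xp, Xn, classifier_config()), x)
  resid_eig <- function(X) {
    u <- eigen(X %*% Conj(t(X)), symmetric = TRUE)$vectors[, 1]
    sqrt(sum(Mod(x - u %*% (Conj(t(u)) %*% x))^2)) / sqrt(sum(Mod(x)^2))
  }
  expect_equal(s_svd, resid_eig(Xn) - resid_eig(Xp), tolerance = 1e-8)
})

test_that("classification applies the conservative tie rule", {
  set.seed(9)
  model <- fit_subspace(rcplx(5, 2), rcplx(5, 2), classifier_config())
  x <- rcplx(5)
  s <- decision_value(model, x)
  expect_equal(classify(model, x, threshold = s - 0.1), "cSDH")
  expect_equal(classify(model, x, threshold = s), "HC")       # tie -> HC
  expect_equal(classify(model, x, threshold = -Inf), "cSDH")  # ROC endpoint
})

test_that("degenerate inputs are rejected", {
  set.seed(10)
  Xp <- rcplx(5, 3); Xn <- rcplx(5, 3)
  expect_error(fit_subspace(Xp[, 1, drop = FALSE], Xn, classifier_config()),
               "cSDH.*need >= 2")
  expect_error(fit_subspace(Xp, Xn[, 1:2], classifier_config(rank = 3)),
               "HC")
  expect_error(fit_subspace(matrix(0 + 0i, 5, 3), Xn, classifier_config()),
               "degenerate")
  model <- fit_subspace(Xp, Xn, classifier_config())
  expect_error(decision_value(model, rep(0 + 0i, 5)), "zero")
  expect_error(decision_value(model, rcplx(4)), "dimension mismatch")
})
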