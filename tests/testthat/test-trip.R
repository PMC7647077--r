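test_that("projection is the exact mode-wise contraction", {
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  I <- list(diag(4), diag(3))
  expect_equal(project_sample(X, I), X)
  expect_equal(project_sample(matrix(0, 4, 3), I), matrix(0, 4, 3))
  # rank-one X with its factors as leading projection columns
  a <- rnorm(4); a <- a / sqrt(sum(a^2))
  b <- rnorm(3); b <- b / sqrt(sum(b^2))
  C1 <- qr.Q(qr(cbind(a, rnorm(4))))
  if (sum(C1[, 1L] * a) < 0) C1 <- -C1
  C2 <- qr.Q(qr(cbind(b, rnorm(3))))
  if (sum(C2[, 1L] * b) < 0) C2 <- -C2
  Xb <- project_sample(a %*% t(b), list(C1, C2))
  expect_equal(Xb[1L, 1L], 1, tolerance = 1e-12)
  expect_lt(max(abs(Xb[-1L, ])), 1e-12)
  expect_error(project_sample(X, list(diag(3), diag(3))), "shape mismatch")
})

test_that("reconstruction error matches its brute-force expansion", {
  set.seed(2)
  X <- matrix(rnorm(12), 4, 3)
  # complete orthonormal basis reconstructs exactly
  Cfull <- list(rand_orthonormal(4, 4), rand_orthonormal(3, 3))
  expect_lt(reconstruction_error(X, Cfull), 1e-10)
  # X orthogonal to the retained mode-1 columns loses everything
  Q <- rand_orthonormal(4, 4)
  C1 <- Q[, 1:2]; Xperp <- Q[, 3:4] %*% matrix(rnorm(6), 2, 3)
  expect_equal(reconstruction_error(Xperp, list(C1, rand_orthonormal(3, 2))),
               sum(Xperp^2), tolerance = 1e-10)
  for (rep in 1:10) {
    X <- matrix(rnorm(12), 4, 3)
    C1 <- rand_orthonormal(4, 2); C2 <- rand_orthonormal(3, 2)
    expect_equal(reconstruction_error(X, list(C1, C2)),
                 recon_oracle(X, C1, C2), tolerance = 1e-12)
  }
})

test_that("reconstruction error is contractive and nested-monotone", {
  set.seed(3)
  X <- matrix(rnorm(30), 6, 5)
  C1 <- rand_orthonormal(6, 4); C2 <- rand_orthonormal(5, 4)
  for (j in 1:4) {
    e <- reconstruction_error(X, list(C1[, 1:j, drop = FALSE],
                                      C2[, 1:j, drop = FALSE]))
    expect_lte(e, sum(X^2) + 1e-12)
    if (j > 1) expect_lte(e, e_prev + 1e-12)
    e_prev <- e
  }
})

test_that("orthonormalization returns the polar factor", {
  Q <- rand_orthonormal(5, 3)
  expect_equal(orthonormalize(Q), Q, tolerance = 1e-10)
  expect_equal(orthonormalize(diag(c(3, 5))), diag(2), tolerance = 1e-12)
  set.seed(4)
  Z <- matrix(rnorm(18), 6, 3)
  C <- orthonormalize(Z)
  expect_lt(max(abs(crossprod(C) - diag(3))), 1e-10)
  # C is the closest orthonormal matrix: no random probe beats it
  dC <- sum((Z - C)^2)
  probes <- replicate(1000, sum((Z - rand_orthonormal(6, 3))^2))
  expect_true(all(dC <= probes + 1e-12))
  expect_error(orthonormalize(cbind(1:4, 2 * (1:4))), "degenerate input")
})

test_that("the objective decomposes into prediction and reconstruction terms", {
  set.seed(5)
  pt <- generate_network_tensor(10, 5, 4, planted_rank = 2, seed = 5)
  fit <- trip(pt$tensors, pt$response, J = c(2, 2), head = "linear",
              control = trip_control(max_iter = 5))
  m0 <- fit; m0$gamma <- 0
  pred_only <- trip_objective(pt$tensors, pt$response, m0)
  expect_equal(pred_only,
               mean((pt$response - predict(fit, pt$tensors))^2),
               tolerance = 1e-10)
  # two-sample hand expansion
  A <- pt$tensors[, , 1:2]; y2 <- pt$response[1:2]
  o <- trip_objective(A, y2, fit)
  by_hand <- mean(vapply(1:2, function(i) {
    yh <- sum(fit$head$W * project_sample(A[, , i], fit$projections)) + fit$head$b
    (y2[i] - yh)^2 + fit$gamma * recon_oracle(A[, , i], fit$projections[[1L]],
                                              fit$projections[[2L]])
  }, numeric(1)))
  expect_equal(o, by_hand, tolerance = 1e-10)
  bad <- fit; bad$projections[[1L]] <- bad$projections[[1L]] * 2
  expect_error(trip_objective(A, y2, bad), "not orthonormal")
})

test_that("fitting is deterministic and recovers a planted subspace", {
  pt <- generate_network_tensor(40, 10, 8, planted_rank = 2, seed = 6)
  f1 <- trip(pt$tensors, pt$response, J = c(2, 2), head = "mlp",
             control = trip_control(seed = 3))
  f2 <- trip(pt$tensors, pt$response, J = c(2, 2), head = "mlp",
             control = trip_control(seed = 3))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$projections, f2$projections)
  # noiseless rank-2 tensors are reconstructed almost exactly
  recon <- mean(vapply(1:40, function(i)
    reconstruction_error(pt$tensors[, , i], f1$projections), numeric(1)))
  expect_lt(recon, 1e-3 * mean(apply(pt$tensors, 3L, function(S) sum(S^2))))
  # objective history never increases and projections stay orthonormal
  expect_true(all(diff(f1$history$objective) <= 1e-12))
  expect_lt(max(f1$history$ortho_dev), 1e-8)
})

test_that("a linear head on noiseless planted data predicts exactly", {
  pt <- generate_network_tensor(50, 8, 6, planted_rank = 2, seed = 7)
  fit <- trip(pt$tensors, pt$response, J = c(2, 2), head = "linear")
  r2 <- 1 - sum((pt$response - fitted(fit))^2) /
    sum((pt$response - mean(pt$response))^2)
  expect_gt(r2, 0.99)
  expect_equal(residuals(fit), pt$response - fitted(fit))
})

test_that("prediction through a constant head returns the bias", {
  pt <- generate_network_tensor(12, 5, 4, planted_rank = 1, seed = 8)
  fit <- trip(pt$tensors, pt$response, J = c(2, 2), head = "linear",
              control = trip_control(max_iter = 3))
  fit$head$W[] <- 0; fit$head$b <- 1.25
  expect_equal(predict(fit, pt$tensors), rep(1.25, 12))
  expect_equal(predict(fit, array(0, c(5, 4, 3))), rep(1.25, 3))
})

test_that("degenerate fitting arguments are rejected", {
  pt <- generate_network_tensor(10, 5, 4, planted_rank = 1, seed = 9)
  expect_error(trip(pt$tensors, pt$response[1:5], J = c(2, 2)), "response length")
  expect_error(trip(pt$tensors, pt$response, J = c(6, 2)), "J must be")
  expect_warning(trip(pt$tensors, pt$response, J = c(2, 2), gamma = 0,
                      head = "linear", control = trip_control(max_iter = 3)),
                 "gamma = 0")
})

test_that("a logistic-loss head separates binary responses on planted tensors", {
  pt <- generate_network_tensor(60, 8, 6, planted_rank = 2, seed = 11)
  yb <- as.numeric(pt$response > 0)
  fit <- trip(pt$tensors, yb, J = c(2, 2), loss = "logistic", head = "linear",
              control = trip_control(seed = 11))
  pr <- predict(fit, pt$tensors, type = "response")
  expect_true(all(pr >= 0 & pr <= 1))
  expect_gt(mean((pr > 0.5) == yb), 0.9)
  expect_true(all(diff(fit$history$objective) <= 1e-12))
})

test_that("with a dominant reconstruction weight the fit stays at the HOSVD subspace", {
  pt <- generate_network_tensor(30, 8, 6, planted_rank = 2, seed = 10)
  fit <- trip(pt$tensors, pt$response, J = c(2, 2), gamma = 1e6,
              head = "linear")
  # principal angles between learned and planted spans
  for (k in 1:2) {
    planted <- if (k == 1) pt$A else pt$B
    s <- svd(crossprod(fit$projections[[k]], planted))$d
    expect_lt(max(acos(pmin(s, 1))), 0.1)
  }
})
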