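# independent reference implementations used as test oracles

# random matrix with orthonormal columns
rand_orthonormal <- function(nrow, ncol) {
  qr.Q(qr(matrix(rnorm(nrow * nrow), nrow, nrow)))[, seq_len(ncol), drop = FALSE]
}

# weighted least squares through the normal equations
wls_oracle <- function(y, X, w) {
  Z <- cbind(1, X)
  solve(t(Z) %*% diag(w) %*% Z, t(Z) %*% diag(w) %*% y)[, 1L]
}

# brute-force squared Frobenius reconstruction error
recon_oracle <- function(X, C1, C2) {
  Xbar <- t(C1) %*% X %*% C2
  sum((X - C1 %*% Xbar %*% t(C2))^2)
}

# Pearson chi-squared statistic from the textbook formula
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# independent rank-one alternating least squares on projected slices
# (same init and norm-balancing convention as the package, different code)
als_oracle <- function(Xbar, yhat, iters = 1000) {
  J1 <- dim(Xbar)[1L]; J2 <- dim(Xbar)[2L]; n <- dim(Xbar)[3L]
  V <- t(matrix(Xbar, J1 * J2, n))
  cf <- solve(crossprod(cbind(1, V)) + diag(1e-10, J1 * J2 + 1),
              crossprod(cbind(1, V), yhat))
  sv <- svd(matrix(cf[-1L], J1, J2))
  g1 <- sv$u[, 1L] * sqrt(sv$d[1L]); g2 <- sv$v[, 1L] * sqrt(sv$d[1L])
  b <- mean(yhat)
  sse_prev <- Inf
  for (it in seq_len(iters)) {
    F1 <- t(sapply(seq_len(n), function(i) Xbar[, , i] %*% g2))
    if (J1 == 1L) F1 <- t(F1)
    cf <- solve(crossprod(cbind(1, F1)), crossprod(cbind(1, F1), yhat))
    b <- cf[1L]; g1 <- cf[-1L]
    F2 <- t(sapply(seq_len(n), function(i) t(Xbar[, , i]) %*% g1))
    if (J2 == 1L) F2 <- t(F2)
    cf <- solve(crossprod(cbind(1, F2)), crossprod(cbind(1, F2), yhat))
    b <- cf[1L]; g2 <- cf[-1L]
    sse <- sum((yhat - (F2 %*% g2 + b))^2)
    s1 <- sqrt(sum(g1^2)); s2 <- sqrt(sum(g2^2))
    if (s1 > 0 && s2 > 0) { sc <- sqrt(s2 / s1); g1 <- g1 * sc; g2 <- g2 / sc }
    if (is.finite(sse_prev) &&
        abs(sse_prev - sse) <= 1e-13 * max(1, sse_prev)) break
    sse_prev <- sse
  }
  list(g1 = g1, g2 = g2, b = b, sse = sse)
}

# minimal network_tensor for interpretation tests
mk_tensor <- function(coefs, target_ids = NULL, regulator_ids = NULL,
                      sample_ids = NULL, modulator = NULL) {
  d <- dim(coefs)
  target_ids <- target_ids %||% sprintf("T%02d", seq_len(d[1L]))
  regulator_ids <- regulator_ids %||% sprintf("R%02d", seq_len(d[2L]))
  sample_ids <- sample_ids %||% sprintf("S%02d", seq_len(d[3L]))
  dimnames(coefs) <- list(target_ids, regulator_ids, sample_ids)
  structure(list(coefficients = coefs,
                 intercepts = matrix(0, d[1L], d[3L],
                                     dimnames = list(target_ids, sample_ids)),
                 modulator = modulator %||% seq(-1, 1, length.out = d[3L]),
                 target_ids = target_ids, regulator_ids = regulator_ids,
                 sample_ids = sample_ids, bandwidth = 0.2,
                 penalty = penalty_spec()),
            class = "network_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap a grn_truth into an expression_dataset (targets then regulators)
truth_to_dataset <- function(gt) {
  p <- gt$p; q <- gt$q
  expression_dataset(
    values = t(cbind(gt$Y, gt$X)),
    gene_ids = c(sprintf("TG%03d", seq_len(p)), sprintf("RG%03d", seq_len(q))),
    roles = c(rep("target", p), rep("regulator", q)),
    modulator = gt$modulator,
    sample_ids = sprintf("S%03d", seq_len(gt$n)))
}
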