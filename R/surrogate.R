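## multi-linear surrogate attribution and crucial-component extraction

#' Fit the multi-linear surrogate of a subspace model
#'
#' Approximates the fitted head by a rank-one multi-linear read-out on the
#' projected networks: finds `g1`, `g2` and bias `b` minimizing
#' `sum_i (yhat_i - (g1' Xbar_i g2 + b))^2` by alternating least squares
#' (each factor sub-problem is an ordinary linear regression). The
#' surrogate is what makes the head's attribution over the subspace
#' readable: its factors weight the latent target and regulator
#' directions.
#'
#' @param model a fitted [trip()] object.
#' @param tensors the sample tensors the model was fitted on.
#' @param max_iter,tol alternating least squares controls. After every
#'   sweep the factor norms are balanced (`||g1|| = ||g2||`), fixing the
#'   scale indeterminacy of the rank-one parametrization.
#' @return object of class `"trip_surrogate"`: list with `factors`
#'   (list of `g1`, `g2`), `bias`, `fit_gap`
#'   (`sum_i (yhat_i - yhat'_i)^2`), and the surrogate predictions
#'   `fitted`.
#' @export
fit_surrogate <- function(model, tensors, max_iter = 1000, tol = 1e-13) {
  if (!inherits(model, "trip")) stop_invalid("`model` must be a fitted trip object")
  A <- as_tensor_array(tensors)
  yhat <- predict(model, A, type = "link")
  Xbar <- project_all(A, model$projections[[1L]], model$projections[[2L]])
  J1 <- dim(Xbar)[1L]; J2 <- dim(Xbar)[2L]; n <- dim(Xbar)[3L]

  if (all(Xbar == 0)) {
    g1 <- rep(1 / sqrt(J1), J1); g2 <- rep(1 / sqrt(J2), J2)
    b <- mean(yhat)
    return(structure(list(factors = list(g1 = g1, g2 = g2), bias = b,
                          fit_gap = sum((yhat - b)^2), fitted = rep(b, n)),
                     class = "trip_surrogate"))
  }

  # initialization: rank-one truncation of the head's own read-out matrix
  # when it is linear (exact if that matrix is rank one), otherwise of the
  # ridge-stabilized least-squares read-out refitted to the predictions
  W0 <- if (model$head$type == "linear") model$head$W else {
    V <- vec_slices(Xbar)
    G <- crossprod(cbind(1, V)) + diag(1e-10, ncol(V) + 1L)
    matrix(solve(G, crossprod(cbind(1, V), yhat))[-1L], J1, J2)
  }
  sv <- svd(W0)
  g1 <- sv$u[, 1L] * sqrt(sv$d[1L])
  g2 <- sv$v[, 1L] * sqrt(sv$d[1L])
  b <- mean(yhat)

  ls_solve <- function(F, z) {
    fit <- stats::lm.fit(cbind(1, F), z)
    cf <- fit$coefficients; cf[is.na(cf)] <- 0
    cf
  }
  balance <- function() {
    s1 <- sqrt(sum(g1^2)); s2 <- sqrt(sum(g2^2))
    if (s1 > 0 && s2 > 0) {
      sc <- sqrt(s2 / s1)
      g1 <<- g1 * sc; g2 <<- g2 / sc
    }
  }
  sse <- Inf
  for (it in seq_len(max_iter)) {
    # fix g2, solve for (b, g1): features Xbar_i g2
    F1 <- t(apply(Xbar, 3L, function(S) S %*% g2))
    if (J1 == 1L) F1 <- t(F1)
    cf <- ls_solve(F1, yhat); b <- cf[1L]; g1 <- cf[-1L]
    # fix g1, solve for (b, g2)
    F2 <- t(apply(Xbar, 3L, function(S) crossprod(S, g1)))
    if (J2 == 1L) F2 <- t(F2)
    cf <- ls_solve(F2, yhat); b <- cf[1L]; g2 <- cf[-1L]
    new_sse <- sum((yhat - (F2 %*% g2 + b))^2)
    balance()                 # fix the factor scale indeterminacy
    if (is.finite(sse) && abs(sse - new_sse) <= tol * max(1, sse)) { sse <- new_sse; break }
    sse <- new_sse
  }
  fitted <- as.numeric(apply(Xbar, 3L, function(S) crossprod(g1, S %*% g2))) + b
  structure(list(factors = list(g1 = g1, g2 = g2), bias = b,
                 fit_gap = sum((yhat - fitted)^2), fitted = fitted),
            class = "trip_surrogate")
}

#' @export
print.trip_surrogate <- function(x, ...) {
  cat(sprintf("Multi-linear surrogate: rank-1 factors of length %d and %d\n",
              length(x$factors$g1), length(x$factors$g2)))
  cat(sprintf("  bias %.4g, fit gap %.4g\n", x$bias, x$fit_gap))
  invisible(x)
}

#' Extract crucial components of the learned subspace
#'
#' For mode `k = 2` computes, per sample, the vector
#' `u_i = t(C2) %*% t(X_i) %*% C1 %*% g1` (the non-`k` mode is contracted
#' with its projection and surrogate factor, then mode `k` is projected);
#' mode `k = 1` analogously with `g2`. Columns of the stacked matrix
#' `U` are normalized to unit length (all-zero vectors are kept as zero),
#' and a PCA over samples of the normalized vectors yields the crucial
#' components: axes of network variation that matter for the prediction.
#'
#' @param tensors sample tensors.
#' @param model fitted [trip()] model.
#' @param surrogate matching [fit_surrogate()] result.
#' @param k mode index, 1 (targets) or 2 (regulators).
#' @return object of class `"component_scores"`: `vectors` (J_k x n raw
#'   u vectors), `matrix` (normalized columns), `pc_scores` (samples x
#'   components), `loadings`, `variance_explained` (non-increasing,
#'   sums to 1).
#' @export
component_scores <- function(tensors, model, surrogate, k = 2) {
  if (!inherits(model, "trip")) stop_invalid("`model` must be a fitted trip object")
  if (!inherits(surrogate, "trip_surrogate"))
    stop_invalid("`surrogate` must come from fit_surrogate()")
  if (!k %in% c(1, 2)) stop_invalid("mode index k must be 1 or 2")
  A <- as_tensor_array(tensors)
  C1 <- model$projections[[1L]]; C2 <- model$projections[[2L]]
  n <- dim(A)[3L]
  U <- if (k == 2) {
    v <- C1 %*% surrogate$factors$g1                # I1 vector
    crossprod(C2, apply(A, 3L, function(X) crossprod(X, v)))
  } else {
    v <- C2 %*% surrogate$factors$g2
    crossprod(C1, apply(A, 3L, function(X) X %*% v))
  }
  U <- matrix(U, ncol = n)
  norms <- sqrt(colSums(U^2))
  Un <- U
  pos <- norms > 0
  Un[, pos] <- sweep(U[, pos, drop = FALSE], 2, norms[pos], "/")

  pca <- prcomp(t(Un), center = TRUE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  # sign convention: largest-magnitude loading of each component positive
  for (cidx in seq_len(ncol(pca$rotation))) {
    j <- which.max(abs(pca$rotation[, cidx]))
    if (pca$rotation[j, cidx] < 0) {
      pca$rotation[, cidx] <- -pca$rotation[, cidx]
      pca$x[, cidx] <- -pca$x[, cidx]
    }
  }
  structure(list(vectors = U, matrix = Un, pc_scores = pca$x,
                 loadings = pca$rotation, variance_explained = ve,
                 mode = k),
            class = "component_scores")
}

#' @export
print.component_scores <- function(x, ...) {
  cat(sprintf("Crucial components (mode %d): %d samples, %d dimensions\n",
              x$mode, ncol(x$matrix), nrow(x$matrix)))
  ve <- utils::head(x$variance_explained, 3)
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * ve), collapse = ", "),
      if (length(x$variance_explained) > 3) "..." else "", "\n")
  invisible(x)
}

#' @export
plot.component_scores <- function(x, components = c(1, 2), ...) {
  graphics::plot(x$pc_scores[, components[1L]], x$pc_scores[, components[2L]],
                 xlab = sprintf("component %d (%.1f%%)", components[1L],
                                100 * x$variance_explained[components[1L]]),
                 ylab = sprintf("component %d (%.1f%%)", components[2L],
                                100 * x$variance_explained[components[2L]]),
                 main = "Crucial component scores", ...)
  invisible(x)
}
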