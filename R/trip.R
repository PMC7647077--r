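## stage 2: supervised orthonormal tensor subspace learning

#' Closest orthonormal matrix via SVD
#'
#' Computes the polar factor `C = P Q^T` of the thin SVD `Z = P S Q^T`.
#' `C` has orthonormal columns and is the closest such matrix to `Z` in
#' Frobenius norm; it is how the orthonormality constraint on the
#' projection matrices is enforced after every latent update.
#'
#' @param Z numeric matrix with full column rank.
#' @return matrix of the same size with `t(C) %*% C = I`.
#' @export
orthonormalize <- function(Z) {
  Z <- as.matrix(Z)
  s <- svd(Z)
  tol <- max(dim(Z)) * max(s$d) * .Machine$double.eps
  if (any(s$d <= max(tol, 0))) {
    bad <- which(s$d <= tol)
    stop_invalid("degenerate input: %d of %d singular values collapse (columns span a rank-%d space)",
                 length(bad), ncol(Z), ncol(Z) - length(bad))
  }
  s$u %*% t(s$v)
}

#' Project a sample matrix onto the learned subspace
#'
#' `Xbar = t(C1) %*% X %*% C2`, the mode-wise contraction of one sample's
#' network with the projection matrices.
#'
#' @param X sample matrix (I1 x I2).
#' @param C_list list of two projection matrices (I1 x J1, I2 x J2).
#' @return projected J1 x J2 matrix.
#' @export
project_sample <- function(X, C_list) {
  X <- as.matrix(X)
  C1 <- C_list[[1L]]; C2 <- C_list[[2L]]
  if (nrow(X) != nrow(C1) || ncol(X) != nrow(C2))
    stop_invalid("shape mismatch: X is %dx%d but projections expect %dx%d",
                 nrow(X), ncol(X), nrow(C1), nrow(C2))
  crossprod(C1, X) %*% C2
}

#' Squared Frobenius reconstruction error of one sample
#'
#' `|| X - C1 %*% Xbar %*% t(C2) ||_F^2` with `Xbar` the projection of `X`;
#' zero exactly when `X` lies in the span of the projections.
#'
#' @inheritParams project_sample
#' @return nonnegative scalar.
#' @export
reconstruction_error <- function(X, C_list) {
  Xbar <- project_sample(X, C_list)
  R <- X - C_list[[1L]] %*% Xbar %*% t(C_list[[2L]])
  sum(R^2)
}

#' Optimizer control for [trip()]
#'
#' @param tol relative objective change declaring convergence.
#' @param max_iter maximum outer iterations.
#' @param patience consecutive objective increases tolerated before the
#'   optimizer aborts with a divergence diagnosis.
#' @param lr initial projection step size (adapted by backtracking).
#' @param head_steps gradient steps on the head per outer iteration (heads
#'   without a closed-form update).
#' @param seed seed for the head initialization.
#' @return list of class `"trip_control"`.
#' @export
trip_control <- function(tol = 1e-6, max_iter = 500, patience = 10,
                         lr = 0.05, head_steps = 20, seed = 0) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 patience = as.integer(patience), lr = lr,
                 head_steps = as.integer(head_steps), seed = seed),
            class = "trip_control")
}

## ---- head: scalar readout r = <W, Xbar> through a linear or MLP map ----

head_init <- function(type, J, V, y, loss, seed, width = 16L) {
  # warm start: least-squares readout weights (ridge-stabilized)
  G <- crossprod(cbind(1, V)) + diag(1e-8, ncol(V) + 1L)
  cf <- solve(G, crossprod(cbind(1, V), y))
  W <- matrix(cf[-1L], J[1L], J[2L])
  if (type == "linear")
    return(list(type = "linear", W = W, b = cf[1L]))
  with_seed(seed, {
    V1 <- rnorm(width, 0, 0.5)
    v2 <- V1 / sum(V1^2)       # v2 . V1 = 1 so the map starts near identity
    list(type = "mlp", W = W, V1 = V1, b1 = rep(0, width), v2 = v2,
         b2 = cf[1L])
  })
}

# forward pass; V is n x (J1*J2) matrix of vec(Xbar_i)
head_forward <- function(head, V) {
  r <- as.numeric(V %*% as.numeric(head$W))
  if (head$type == "linear")
    return(list(f = r + head$b, r = r))
  H <- tanh(outer(r, head$V1) + rep(head$b1, each = length(r)))  # n x width
  list(f = as.numeric(H %*% head$v2) + head$b2, r = r, H = H)
}

head_loss <- function(loss, y, f) {
  if (loss == "squared") sum((y - f)^2)
  else sum(log1p(exp(-abs(f))) + pmax(f, 0) - y * f)   # stable logistic
}

head_dloss <- function(loss, y, f) {
  if (loss == "squared") 2 * (f - y)
  else stats::plogis(f) - y
}

# gradients of sum_i L_i wrt head parameters and wrt r
head_grads <- function(head, V, y, loss, fw) {
  g <- head_dloss(loss, y, fw$f)              # dL/df per sample
  if (head$type == "linear") {
    dr <- g
    list(W = matrix(crossprod(V, dr), nrow(head$W), ncol(head$W)),
         b = sum(g), dr = dr)
  } else {
    D <- 1 - fw$H^2                            # n x width
    dr <- g * as.numeric(D %*% (head$v2 * head$V1))
    list(W = matrix(crossprod(V, dr), nrow(head$W), ncol(head$W)),
         V1 = as.numeric(crossprod(D * outer(rep(1, length(g)), head$v2) * g, fw$r)),
         b1 = as.numeric(crossprod(D, g) * head$v2),
         v2 = as.numeric(crossprod(fw$H, g)),
         b2 = sum(g), dr = dr)
  }
}

head_step <- function(head, grads, lr) {
  head$W <- head$W - lr * grads$W
  if (head$type == "linear") {
    head$b <- head$b - lr * grads$b
  } else {
    head$V1 <- head$V1 - lr * grads$V1
    head$b1 <- head$b1 - lr * grads$b1
    head$v2 <- head$v2 - lr * grads$v2
    head$b2 <- head$b2 - lr * grads$b2
  }
  head
}

## ---- tensor algebra on the stacked array ----

# Xbar array (J1, J2, n) from A (I1, I2, n)
project_all <- function(A, C1, C2) {
  d <- dim(A); I1 <- d[1L]; I2 <- d[2L]; n <- d[3L]
  J1 <- ncol(C1); J2 <- ncol(C2)
  P <- crossprod(C1, matrix(A, I1, I2 * n))          # J1 x (I2 n)
  P <- aperm(array(P, c(J1, I2, n)), c(2L, 1L, 3L))  # I2 x J1 x n
  Q <- crossprod(C2, matrix(P, I2, J1 * n))          # J2 x (J1 n)
  aperm(array(Q, c(J2, J1, n)), c(2L, 1L, 3L))       # J1 x J2 x n
}

vec_slices <- function(Xbar) {
  d <- dim(Xbar)
  t(matrix(Xbar, d[1L] * d[2L], d[3L]))              # n x (J1 J2)
}

## ---- objective and fit ----

trip_eval <- function(A, y, C1, C2, head, gamma, loss, sumX2) {
  n <- dim(A)[3L]
  Xbar <- project_all(A, C1, C2)
  V <- vec_slices(Xbar)
  fw <- head_forward(head, V)
  pred <- head_loss(loss, y, fw$f)
  # orthonormal projections: recon error = ||X||^2 - ||Xbar||^2 per slice
  recon <- sumX2 - sum(Xbar^2)
  list(objective = (pred + gamma * recon) / n, pred = pred, recon = recon,
       Xbar = Xbar, V = V, fw = fw)
}

#' Objective of a fitted or candidate subspace model
#'
#' Mean prediction loss plus `gamma` times the mean squared reconstruction
#' error of the sample networks, the quantity [trip()] minimizes.
#'
#' @param tensors 3D array (I1 x I2 x n), list of matrices, or
#'   `network_tensor`.
#' @param y response vector.
#' @param model a `"trip"` model (or list with `projections`, `head`,
#'   `gamma`, `loss_kind`).
#' @return scalar objective value.
#' @export
trip_objective <- function(tensors, y, model) {
  A <- as_tensor_array(tensors)
  C1 <- model$projections[[1L]]; C2 <- model$projections[[2L]]
  dev <- max(max(abs(crossprod(C1) - diag(ncol(C1)))),
             max(abs(crossprod(C2) - diag(ncol(C2)))))
  if (dev > 1e-6)
    stop_invalid("invalid state: projections are not orthonormal (deviation %.2g)", dev)
  sumX2 <- sum(A^2)
  trip_eval(A, y, C1, C2, model$head, model$gamma, model$loss_kind,
            sumX2)$objective
}

#' Fit the supervised orthonormal tensor subspace model
#'
#' Learns mode-wise orthonormal projection matrices `C1` (I1 x J1) and
#' `C2` (I2 x J2) together with a prediction head, by minimizing the mean
#' prediction loss plus `gamma` times the mean squared reconstruction
#' error, subject to `t(Ck) %*% Ck = I`. The constraint is enforced by
#' re-orthonormalizing the latent matrices through their SVD polar factor
#' after every gradient step; a backtracking line search keeps the
#' objective history non-increasing. Projections are initialized from the
#' mode-wise eigenvectors (HOSVD) of the mean-centred stacked networks.
#'
#' @param tensors 3D array (I1 x I2 x n), list of n matrices, or a
#'   [build_network_tensor()] result.
#' @param y numeric response, one value per sample (e.g. the modulator).
#' @param J integer pair `(J1, J2)`: subspace dimensions per mode.
#' @param gamma trade-off (> 0) between prediction and reconstruction;
#'   `gamma = 0` drops the reconstruction term (with a warning).
#' @param loss `"squared"` or `"logistic"` (y in 0/1, head output a logit).
#' @param head `"mlp"` (one hidden tanh layer of width 16 on the scalar
#'   readout) or `"linear"`.
#' @param control a [trip_control()].
#' @return an object of class `"trip"` with elements `projections`
#'   (list of C1, C2), `latents` (pre-orthonormalization Z1, Z2), `head`,
#'   `gamma`, `loss_kind`, `J`, `history` (per-iteration objective and
#'   orthonormality deviation), `fitted.values`, `converged`, `iterations`.
#' @examples
#' pt <- generate_network_tensor(40, 8, 6, planted_rank = 2, seed = 1)
#' fit <- trip(pt$tensors, pt$response, J = c(2, 2), head = "linear")
#' fit
#' @export
trip <- function(tensors, y, J = c(2, 2), gamma = 1,
                 loss = c("squared", "logistic"),
                 head = c("mlp", "linear"), control = trip_control()) {
  loss <- match.arg(loss); head_type <- match.arg(head)
  A <- as_tensor_array(tensors)
  d <- dim(A); I1 <- d[1L]; I2 <- d[2L]; n <- d[3L]
  if (n < 2) stop_invalid("need at least 2 samples")
  if (length(y) != n)
    stop_invalid("response length (%d) must equal sample count (%d)", length(y), n)
  if (length(J) != 2L || J[1L] > I1 || J[2L] > I2 || any(J < 1))
    stop_invalid("J must be a pair with 1 <= J1 <= %d, 1 <= J2 <= %d", I1, I2)
  if (gamma < 0) stop_invalid("`gamma` must be >= 0")
  if (gamma == 0)
    warning("gamma = 0: the reconstruction term is dropped; the subspace is shaped by prediction only")

  # HOSVD initialization on mean-centred slices
  Ac <- A - as.numeric(apply(A, c(1L, 2L), mean))
  M1 <- tcrossprod(matrix(Ac, I1, I2 * n))
  C1 <- eigen(M1, symmetric = TRUE)$vectors[, seq_len(J[1L]), drop = FALSE]
  M2 <- tcrossprod(matrix(aperm(Ac, c(2L, 1L, 3L)), I2, I1 * n))
  C2 <- eigen(M2, symmetric = TRUE)$vectors[, seq_len(J[2L]), drop = FALSE]
  Z1 <- C1; Z2 <- C2
  sumX2 <- sum(A^2)

  # head warm start on the initial subspace
  V0 <- vec_slices(project_all(A, C1, C2))
  hd <- head_init(head_type, J, V0, y, loss, control$seed)

  update_head <- function(hd, ev) {
    if (hd$type == "linear" && loss == "squared") {
      G <- crossprod(cbind(1, ev$V)) + diag(1e-10, ncol(ev$V) + 1L)
      cf <- solve(G, crossprod(cbind(1, ev$V), y))
      hd$W <- matrix(cf[-1L], J[1L], J[2L]); hd$b <- cf[1L]
      return(hd)
    }
    lr_h <- 0.1 / n
    cur <- head_loss(loss, y, head_forward(hd, ev$V)$f)
    for (s in seq_len(control$head_steps)) {
      fw <- head_forward(hd, ev$V)
      gr <- head_grads(hd, ev$V, y, loss, fw)
      repeat {
        cand <- head_step(hd, gr, lr_h)
        new <- head_loss(loss, y, head_forward(cand, ev$V)$f)
        if (new <= cur + 1e-12) { hd <- cand; cur <- new; lr_h <- lr_h * 1.5; break }
        lr_h <- lr_h / 2
        if (lr_h < 1e-14) break
      }
      if (lr_h < 1e-14) break
    }
    hd
  }

  ortho_dev <- function(C1, C2)
    max(sqrt(sum((crossprod(C1) - diag(J[1L]))^2)),
        sqrt(sum((crossprod(C2) - diag(J[2L]))^2)))

  hist_obj <- numeric(0); hist_dev <- numeric(0)
  lr <- control$lr
  increases <- 0L; converged <- FALSE
  ev <- trip_eval(A, y, C1, C2, hd, gamma, loss, sumX2)
  O_prev <- ev$objective

  for (iter in seq_len(control$max_iter)) {
    hd <- update_head(hd, ev)
    ev <- trip_eval(A, y, C1, C2, hd, gamma, loss, sumX2)
    O_cur <- ev$objective

    # gradient of the summed objective wrt C1, C2 through Xbar
    gr <- head_grads(hd, ev$V, y, loss, ev$fw)
    # dL/dXbar_i = dr_i * W ; reconstruction adds -2 gamma Xbar_i
    XC2 <- array(crossprod(C2, matrix(aperm(A, c(2L, 1L, 3L)), I2, I1 * n)),
                 c(J[2L], I1, n))                       # slice i: t(X_i C2)
    XtC1 <- array(crossprod(C1, matrix(A, I1, I2 * n)), c(J[1L], I2, n))
    G1 <- matrix(0, I1, J[1L]); G2 <- matrix(0, I2, J[2L])
    for (i in seq_len(n)) {
      M <- gr$dr[i] * hd$W - 2 * gamma * ev$Xbar[, , i]  # J1 x J2
      G1 <- G1 + t(XC2[, , i]) %*% t(M)
      G2 <- G2 + t(XtC1[, , i]) %*% M
    }
    G1 <- G1 / n; G2 <- G2 / n

    # polar-retraction step with backtracking
    moved <- FALSE
    while (lr >= 1e-12) {
      Z1_try <- C1 - lr * G1; Z2_try <- C2 - lr * G2
      C1_try <- tryCatch(orthonormalize(Z1_try), error = function(e) NULL)
      C2_try <- tryCatch(orthonormalize(Z2_try), error = function(e) NULL)
      if (!is.null(C1_try) && !is.null(C2_try)) {
        ev_try <- trip_eval(A, y, C1_try, C2_try, hd, gamma, loss, sumX2)
        if (ev_try$objective <= O_cur + 1e-12) {
          C1 <- C1_try; C2 <- C2_try; Z1 <- Z1_try; Z2 <- Z2_try
          ev <- ev_try; moved <- TRUE
          lr <- min(lr * 1.2, 10)
          break
        }
      }
      lr <- lr / 2
    }

    O_new <- ev$objective
    hist_obj <- c(hist_obj, O_new)
    hist_dev <- c(hist_dev, ortho_dev(C1, C2))

    if (O_new > O_cur + max(1e-8, 1e-8 * abs(O_cur))) {
      increases <- increases + 1L
      if (increases >= control$patience)
        stop_invalid(paste0("optimization failure: objective increased for %d",
                            " consecutive iterations (last %.6g -> %.6g)"),
                     increases, O_cur, O_new)
    } else increases <- 0L

    if (abs(O_prev - O_new) < control$tol * max(1, abs(O_new))) {
      converged <- TRUE
      break
    }
    O_prev <- O_new
  }

  fitted <- head_forward(hd, ev$V)$f
  if (loss == "logistic") fitted_resp <- stats::plogis(fitted) else fitted_resp <- fitted
  structure(list(
    projections = list(C1, C2), latents = list(Z1, Z2), head = hd,
    gamma = gamma, loss_kind = loss, J = J, dims = c(I1, I2, n),
    history = data.frame(iteration = seq_along(hist_obj),
                         objective = hist_obj, ortho_dev = hist_dev),
    fitted.values = fitted_resp, linear.predictors = fitted,
    y = y, converged = converged, iterations = length(hist_obj),
    control = control), class = "trip")
}

#' @export
print.trip <- function(x, ...) {
  cat(sprintf("Supervised tensor subspace model (%s head, %s loss)\n",
              x$head$type, x$loss_kind))
  cat(sprintf("  tensor %d x %d x %d -> subspace %d x %d, gamma = %.3g\n",
              x$dims[1], x$dims[2], x$dims[3], x$J[1], x$J[2], x$gamma))
  cat(sprintf("  %d iterations (%s), final objective %.6g\n",
              x$iterations, if (x$converged) "converged" else "max_iter reached",
              utils::tail(x$history$objective, 1)))
  invisible(x)
}

#' @export
summary.trip <- function(object, ...) {
  r <- object$y - object$fitted.values
  out <- list(model = object,
              r2 = 1 - sum(r^2) / sum((object$y - mean(object$y))^2),
              max_ortho_dev = max(object$history$ortho_dev),
              final_objective = utils::tail(object$history$objective, 1))
  class(out) <- "summary.trip"
  out
}

#' @export
print.summary.trip <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training R^2 = %.4f, max orthonormality deviation %.2e\n",
              x$r2, x$max_ortho_dev))
  invisible(x)
}

#' @export
coef.trip <- function(object, ...) {
  list(projections = object$projections, readout = object$head$W,
       bias = if (object$head$type == "linear") object$head$b else object$head$b2)
}

#' Predict from a fitted subspace model
#'
#' @param object a `"trip"` fit.
#' @param newdata tensors (3D array, list of matrices or network_tensor);
#'   training fitted values when omitted.
#' @param type `"response"` (probability under logistic loss) or `"link"`.
#' @param ... unused.
#' @export
predict.trip <- function(object, newdata = NULL,
                         type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    return(if (type == "response") object$fitted.values else object$linear.predictors)
  A <- as_tensor_array(newdata)
  V <- vec_slices(project_all(A, object$projections[[1L]], object$projections[[2L]]))
  f <- head_forward(object$head, V)$f
  if (object$loss_kind == "logistic" && type == "response") stats::plogis(f) else f
}

#' @export
fitted.trip <- function(object, ...) object$fitted.values

#' @export
residuals.trip <- function(object, ...) object$y - object$fitted.values

#' @export
plot.trip <- function(x, ...) {
  graphics::plot(x$history$iteration, x$history$objective, type = "l",
                 xlab = "iteration", ylab = "objective",
                 main = "Subspace learning objective", ...)
  invisible(x)
}
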