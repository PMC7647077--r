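## stage 1: sample-specific network inference by kernel-weighted elastic net

#' Construct an expression dataset
#'
#' Container for a genes x samples expression matrix with per-gene roles,
#' a per-sample scalar modulator, and optional tissue labels.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers.
#' @param roles per-gene role: `"regulator"`, `"target"` or `"both"`.
#' @param modulator numeric vector, one value per sample.
#' @param sample_ids sample identifiers; defaults to column names.
#' @param tissue optional per-sample tissue label.
#' @return an object of class `"expression_dataset"`.
#' @export
expression_dataset <- function(values, gene_ids = rownames(values), roles,
                               modulator, sample_ids = colnames(values),
                               tissue = NULL) {
  values <- as.matrix(values)
  n <- ncol(values)
  if (is.null(gene_ids)) stop_invalid("`gene_ids` are required")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  if (anyDuplicated(gene_ids))
    stop_invalid("duplicate gene IDs: %s",
                 paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (length(gene_ids) != nrow(values) || length(roles) != nrow(values))
    stop_invalid("gene_ids/roles must match the number of rows of `values`")
  if (!all(roles %in% c("regulator", "target", "both")))
    stop_invalid("roles must be 'regulator', 'target' or 'both'")
  if (length(modulator) != n)
    stop_invalid("modulator length (%d) must equal sample count (%d)",
                 length(modulator), n)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop_invalid("missing value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]])
  }
  if (!any(roles %in% c("regulator", "both")) ||
      !any(roles %in% c("target", "both")))
    stop_invalid("need at least one regulator and one target gene")
  if (!is.null(tissue) && length(tissue) != n)
    stop_invalid("tissue labels must have length %d", n)
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids, roles = roles,
                 modulator = as.numeric(modulator), sample_ids = sample_ids,
                 tissue = tissue),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes x %d samples (%d regulators, %d targets)\n",
              nrow(x$values), ncol(x$values),
              sum(x$roles %in% c("regulator", "both")),
              sum(x$roles %in% c("target", "both"))))
  cat(sprintf("  modulator range [%.3g, %.3g]%s\n",
              min(x$modulator), max(x$modulator),
              if (is.null(x$tissue)) "" else "; tissue labels present"))
  invisible(x)
}

#' Gaussian kernel weights around a target sample
#'
#' `w_i = exp(-(m_i - m_alpha)^2 / b)`. The bandwidth divides the squared
#' modulator distance directly, so it has units of squared modulator.
#'
#' @param m modulator vector.
#' @param m_alpha modulator value of the target sample.
#' @param b bandwidth (> 0).
#' @return weights in (0, 1]; the target sample itself gets weight 1.
#' @export
gaussian_kernel_weights <- function(m, m_alpha, b) {
  if (!is.numeric(b) || length(b) != 1L || b <= 0)
    stop_invalid("bandwidth `b` must be a positive scalar")
  exp(-(m - m_alpha)^2 / b)
}

#' Penalty specification for the recursive elastic net
#'
#' Round 1 fits a standard elastic net; each later round re-fits with
#' per-coefficient penalty weights `1 / (|beta| + weight_floor)` computed
#' from the previous round, so small coefficients are pushed to exact zero
#' while established edges are penalized less. `recursion_steps = 1` is the
#' plain elastic net.
#'
#' @param lambda overall penalty strength (>= 0), on the scale of the
#'   weight-normalized squared-error loss (see Details).
#' @param alpha elastic-net mixing in \[0, 1\] (1 = lasso).
#' @param recursion_steps number of fitting rounds (>= 1).
#' @param weight_floor additive floor guarding the adaptive weights.
#' @details The fit minimizes
#'   `1/(2 sum(w)) * sum_i w_i (y_i - b0 - x_i' beta)^2 +
#'    lambda * sum_j v_j (alpha |beta_j| + (1-alpha)/2 beta_j^2)`
#'   with adaptive weights `v_j` as above, regulators standardized to
#'   weighted zero mean and unit variance, and the intercept unpenalized.
#'   Coefficients are reported on the original scale.
#' @return an object of class `"penalty_spec"`.
#' @export
penalty_spec <- function(lambda = 0.05, alpha = 0.9, recursion_steps = 2,
                         weight_floor = 1e-4) {
  if (lambda < 0) stop_invalid("`lambda` must be >= 0")
  if (alpha < 0 || alpha > 1) stop_invalid("`alpha` must be in [0, 1]")
  if (recursion_steps < 1) stop_invalid("`recursion_steps` must be >= 1")
  if (weight_floor <= 0) stop_invalid("`weight_floor` must be > 0")
  structure(list(lambda = lambda, alpha = alpha,
                 recursion_steps = as.integer(recursion_steps),
                 weight_floor = weight_floor),
            class = "penalty_spec")
}

#' Fit one target gene in one sample's kernel neighbourhood
#'
#' Solves the weighted penalized regression of one target on the candidate
#' regulators, with observation weights from the Gaussian kernel. At
#' `lambda = 0` the exact weighted least-squares solution is returned.
#'
#' @param y target expression vector (length n).
#' @param X n x q regulator expression matrix.
#' @param w nonnegative observation weights, not all zero.
#' @param penalty a [penalty_spec()].
#' @return list with `coefficients` (length q, exact zeros for excluded
#'   regulators) and `intercept`.
#' @export
fit_target_sample <- function(y, X, w, penalty = penalty_spec()) {
  X <- as.matrix(X)
  n <- length(y); q <- ncol(X)
  if (nrow(X) != n || length(w) != n)
    stop_invalid("dimensions of y (%d), X (%d rows) and w (%d) disagree",
                 n, nrow(X), length(w))
  if (any(w < 0)) stop_invalid("weights must be nonnegative")
  if (all(w == 0)) stop_invalid("degenerate fit: all observation weights are zero")
  stopifnot(inherits(penalty, "penalty_spec"))

  wn <- w / sum(w)
  xm <- colSums(X * wn)
  xs <- sqrt(colSums(sweep(X, 2, xm)^2 * wn))
  keep <- which(xs > 1e-10)                     # constant regulators get 0
  beta <- numeric(q)
  if (length(keep) == 0L)                       # intercept-only fit
    return(list(coefficients = beta,
                intercept = sum(wn * y)))

  if (penalty$lambda == 0) {
    fit <- lm.wfit(cbind(`(Intercept)` = 1, X[, keep, drop = FALSE]), y, w)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    beta[keep] <- cf[-1L]
    return(list(coefficients = beta, intercept = unname(cf[1L])))
  }

  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, xm[keep]), 2, xs[keep], "/")
  # glmnet needs >= 2 columns; pad with a heavily penalized dummy
  padded <- ncol(Xs) == 1L
  if (padded) Xs <- cbind(Xs, rep_len(c(1, -1), n))
  pf <- rep(1, ncol(Xs))
  if (padded) pf[2L] <- 1e6
  bs <- NULL
  for (r in seq_len(penalty$recursion_steps)) {
    if (r > 1L) {
      pf <- 1 / (abs(bs) + penalty$weight_floor)
      if (padded) pf[2L] <- 1e6
    }
    # glmnet rescales penalty.factor to sum to nvars; rescale lambda so the
    # effective per-variable penalty is exactly lambda * pf_j
    lam <- penalty$lambda * sum(pf) / ncol(Xs)
    fit <- glmnet::glmnet(Xs, y, weights = w, alpha = penalty$alpha,
                          lambda = lam, standardize = FALSE,
                          penalty.factor = pf, thresh = 1e-9)
    bs <- as.numeric(fit$beta)
    a0 <- as.numeric(fit$a0)
  }
  if (padded) bs <- bs[1L]
  beta[keep] <- bs / xs[keep]
  intercept <- a0 - sum(bs * xm[keep] / xs[keep])
  list(coefficients = beta, intercept = intercept)
}

#' Select bandwidth and penalty by kernel-weighted cross-validation
#'
#' Evaluates every grid point (bandwidth x lambda x alpha) by K-fold
#' cross-validated, kernel-weighted squared prediction error around the
#' target sample, and returns the first grid point attaining the minimum.
#'
#' @param y,X target vector and regulator matrix as in [fit_target_sample()].
#' @param m modulator vector; `m_alpha` the target sample's value.
#' @param m_alpha modulator value of the sample being fitted.
#' @param bandwidth_grid candidate bandwidths (> 0).
#' @param lambda_grid,alpha_grid candidate penalty strengths / mixings.
#' @param penalty template [penalty_spec()] supplying recursion settings.
#' @param nfolds number of CV folds.
#' @param fold_seed seed for the fold assignment (default 0).
#' @return list with `bandwidth`, `lambda`, `alpha`, `cv_error`, and the
#'   full error table (`grid`).
#' @export
select_hyperparameters <- function(y, X, m, m_alpha, bandwidth_grid,
                                   lambda_grid, alpha_grid = 0.9,
                                   penalty = penalty_spec(), nfolds = 5,
                                   fold_seed = 0) {
  n <- length(y)
  if (length(bandwidth_grid) == 0 || length(lambda_grid) == 0 ||
      length(alpha_grid) == 0)
    stop_invalid("hyperparameter grids must be nonempty")
  if (n < nfolds) stop_invalid("fewer samples (%d) than folds (%d)", n, nfolds)
  folds <- with_seed(fold_seed, sample(rep_len(seq_len(nfolds), n)))
  grid <- expand.grid(bandwidth = bandwidth_grid, lambda = lambda_grid,
                      alpha = alpha_grid, KEEP.OUT.ATTRS = FALSE)
  errs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    w <- gaussian_kernel_weights(m, m_alpha, grid$bandwidth[g])
    pen <- penalty_spec(grid$lambda[g], grid$alpha[g],
                        penalty$recursion_steps, penalty$weight_floor)
    err <- 0
    for (k in seq_len(nfolds)) {
      test <- folds == k
      fit <- fit_target_sample(y[!test], X[!test, , drop = FALSE], w[!test], pen)
      pred <- fit$intercept + X[test, , drop = FALSE] %*% fit$coefficients
      err <- err + sum(w[test] * (y[test] - pred)^2)
    }
    errs[g] <- err
  }
  best <- which.min(errs)                        # ties: first grid point
  list(bandwidth = grid$bandwidth[best], lambda = grid$lambda[best],
       alpha = grid$alpha[best], cv_error = errs[best],
       grid = cbind(grid, cv_error = errs))
}

#' Build the sample-specific network tensor
#'
#' For every target gene and every sample, fits the kernel-weighted
#' penalized regression of the target on all candidate regulators (a gene
#' never regresses on itself) and stacks the fitted coefficient networks
#' into a targets x regulators x samples tensor.
#'
#' @param data an [expression_dataset()].
#' @param bandwidth Gaussian kernel bandwidth; `NULL` selects it (together
#'   with lambda) by kernel-weighted cross-validation at the median
#'   modulator sample.
#' @param penalty a [penalty_spec()].
#' @param bandwidth_grid,lambda_grid grids used when `bandwidth` is `NULL`.
#' @return an object of class `"network_tensor"`: list with `coefficients`
#'   (I1 x I2 x n array with dimnames), `intercepts` (I1 x n), `modulator`,
#'   `target_ids`, `regulator_ids`, `sample_ids`, `bandwidth`, `penalty`.
#' @examples
#' st <- simulate_study(n = 30, p = 6, q = 4, n_marker = 1,
#'                      targets_per_marker = 2, seed = 1)
#' nt <- build_network_tensor(st$data, bandwidth = 0.2)
#' dim(nt$coefficients)
#' @export
build_network_tensor <- function(data, bandwidth = 0.2,
                                 penalty = penalty_spec(),
                                 bandwidth_grid = c(0.05, 0.1, 0.2, 0.5, 1),
                                 lambda_grid = c(0.01, 0.05, 0.1)) {
  stopifnot(inherits(data, "expression_dataset"))
  targets <- data$gene_ids[data$roles %in% c("target", "both")]
  regulators <- data$gene_ids[data$roles %in% c("regulator", "both")]
  n <- length(data$sample_ids)
  m <- data$modulator
  vals <- data$values

  if (is.null(bandwidth)) {
    alpha_mid <- which.min(abs(m - median(m)))
    sel <- select_hyperparameters(
      y = vals[targets[1L], ], X = t(vals[regulators, , drop = FALSE]),
      m = m, m_alpha = m[alpha_mid],
      bandwidth_grid = bandwidth_grid, lambda_grid = lambda_grid,
      alpha_grid = penalty$alpha, penalty = penalty)
    bandwidth <- sel$bandwidth
    penalty <- penalty_spec(sel$lambda, sel$alpha,
                            penalty$recursion_steps, penalty$weight_floor)
  }

  I1 <- length(targets); I2 <- length(regulators)
  coefs <- array(0, dim = c(I1, I2, n),
                 dimnames = list(targets, regulators, data$sample_ids))
  intercepts <- matrix(0, I1, n, dimnames = list(targets, data$sample_ids))
  Xall <- t(vals[regulators, , drop = FALSE])    # n x I2

  for (l in seq_len(I1)) {
    self <- match(targets[l], regulators)        # structural zero self-edge
    use <- if (is.na(self)) seq_len(I2) else setdiff(seq_len(I2), self)
    y <- vals[targets[l], ]
    Xl <- Xall[, use, drop = FALSE]
    for (a in seq_len(n)) {
      w <- gaussian_kernel_weights(m, m[a], bandwidth)
      fit <- fit_target_sample(y, Xl, w, penalty)
      coefs[l, use, a] <- fit$coefficients
      intercepts[l, a] <- fit$intercept
    }
  }
  structure(list(coefficients = coefs, intercepts = intercepts,
                 modulator = m, target_ids = targets,
                 regulator_ids = regulators, sample_ids = data$sample_ids,
                 bandwidth = bandwidth, penalty = penalty),
            class = "network_tensor")
}

#' @export
print.network_tensor <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf("Network tensor: %d targets x %d regulators x %d samples\n",
              d[1L], d[2L], d[3L]))
  nz <- mean(x$coefficients != 0)
  cat(sprintf("  bandwidth %.3g, lambda %.3g, alpha %.3g; %.1f%% of edges nonzero\n",
              x$bandwidth, x$penalty$lambda, x$penalty$alpha, 100 * nz))
  invisible(x)
}

#' @export
summary.network_tensor <- function(object, ...) {
  d <- dim(object$coefficients)
  per_sample <- apply(object$coefficients != 0, 3, sum)
  out <- list(dim = d, edges_per_sample = summary(per_sample),
              coef_range = range(object$coefficients),
              bandwidth = object$bandwidth, penalty = object$penalty)
  class(out) <- "summary.network_tensor"
  out
}

#' @export
print.summary.network_tensor <- function(x, ...) {
  cat(sprintf("Network tensor %d x %d x %d\n", x$dim[1], x$dim[2], x$dim[3]))
  cat("Edges per sample network:\n"); print(x$edges_per_sample)
  cat(sprintf("Coefficient range: [%.3g, %.3g]\n",
              x$coef_range[1], x$coef_range[2]))
  invisible(x)
}

#' @export
as.array.network_tensor <- function(x, ...) x$coefficients
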