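## synthetic data: modulator-driven expression and planted network tensors

#' Draw a per-sample modulator vector
#'
#' The modulator is the scalar biological characteristic (e.g. an EMT score)
#' that indexes the varying coefficients. The default matches the uniform
#' distribution of the motivating application.
#'
#' @param n number of samples (>= 2).
#' @param dist `"uniform"` (on \[-1, 1\]) or `"gaussian"` (standard normal).
#' @param seed integer RNG seed; the global RNG state is left untouched.
#' @return numeric vector of length `n`.
#' @examples
#' m <- generate_modulator(10, seed = 1)
#' @export
generate_modulator <- function(n, dist = c("uniform", "gaussian"), seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop_invalid("`n` must be a single count >= 2, got %s", format(n))
  dist <- match.arg(dist)
  with_seed(seed, switch(dist,
    uniform  = runif(n, -1, 1),
    gaussian = rnorm(n)
  ))
}

#' Construct a coefficient profile
#'
#' A profile is the ground-truth coefficient function beta(m) of one
#' regulator-target edge as a function of the modulator m.
#'
#' @param kind `"constant"`, `"step"`, `"sigmoid"` or `"zero"`.
#' @param baseline coefficient value at low modulator.
#' @param shifted coefficient value at high modulator.
#' @param changepoint modulator value where the transition is centred.
#' @param steepness slope parameter of the sigmoid transition.
#' @return an object of class `"coef_profile"`.
#' @examples
#' pr <- coef_profile("step", baseline = 0, shifted = 2, changepoint = 0)
#' evaluate_profile(pr, c(-0.5, 0.5))
#' @export
coef_profile <- function(kind = c("constant", "step", "sigmoid", "zero"),
                         baseline = 0, shifted = baseline,
                         changepoint = 0, steepness = 10) {
  kind <- match.arg(kind)
  if (kind == "zero" && (baseline != 0 || shifted != 0))
    stop_invalid("a zero profile must have baseline = shifted = 0")
  if (kind == "constant" && baseline != shifted)
    stop_invalid("a constant profile must have baseline = shifted")
  structure(list(kind = kind, baseline = baseline, shifted = shifted,
                 changepoint = changepoint, steepness = steepness),
            class = "coef_profile")
}

#' Evaluate a coefficient profile at modulator values
#'
#' @param profile a [coef_profile()].
#' @param m numeric vector of modulator values.
#' @return numeric vector of coefficients, same length as `m`.
#' @export
evaluate_profile <- function(profile, m) {
  stopifnot(inherits(profile, "coef_profile"))
  switch(profile$kind,
    zero     = rep(0, length(m)),
    constant = rep(profile$baseline, length(m)),
    step     = ifelse(m < profile$changepoint, profile$baseline, profile$shifted),
    sigmoid  = profile$baseline + (profile$shifted - profile$baseline) *
      stats::plogis(profile$steepness * (m - profile$changepoint))
  )
}

# build the p x q true coefficient matrix at one modulator value
profile_coef_matrix <- function(profiles, p, q, m) {
  B <- matrix(0, p, q)
  for (key in names(profiles)) {
    idx <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
    B[idx[1L], idx[2L]] <- evaluate_profile(profiles[[key]], m)
  }
  B
}

#' Key for a profile map entry
#'
#' Profile maps are named lists; the name encodes the (target, regulator)
#' index pair as `"target,regulator"`.
#'
#' @param target target index (row of the coefficient matrix).
#' @param regulator regulator index (column).
#' @return character key.
#' @export
profile_key <- function(target, regulator) paste0(target, ",", regulator)

#' Generate a modulator-driven expression dataset with known coefficients
#'
#' Regulator expression is drawn i.i.d. standard normal; each target is the
#' profile-weighted linear combination of the regulators at that sample's
#' modulator value plus Gaussian noise:
#' `y_il = sum_j beta_jl(m_i) x_ij + eps_il`, `eps ~ N(0, sigma^2)`.
#'
#' @param n sample count.
#' @param q regulator count.
#' @param p target count.
#' @param profiles named list of [coef_profile()] objects keyed by
#'   [profile_key()]; pairs not in the map have true coefficient 0.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @param modulator optional pre-drawn modulator vector of length `n`;
#'   drawn uniform on \[-1, 1\] when `NULL`.
#' @return an object of class `"grn_truth"`: list with elements
#'   `X` (n x q regulator matrix), `Y` (n x p target matrix), `modulator`,
#'   `profiles`, `sigma`, and the dimensions.
#' @examples
#' pr <- list()
#' pr[[profile_key(1, 1)]] <- coef_profile("constant", 1.5)
#' gt <- generate_dataset(n = 50, q = 3, p = 2, profiles = pr,
#'                        sigma = 0, seed = 1)
#' @export
generate_dataset <- function(n, q, p, profiles = list(), sigma = 0.1, seed,
                             modulator = NULL) {
  if (sigma < 0) stop_invalid("`sigma` must be >= 0")
  if (!is.null(modulator) && length(modulator) != n)
    stop_invalid("`modulator` must have length n = %d, got %d", n, length(modulator))
  for (key in names(profiles)) {
    idx <- suppressWarnings(as.integer(strsplit(key, ",", fixed = TRUE)[[1L]]))
    if (length(idx) != 2L || anyNA(idx) || idx[1L] < 1 || idx[1L] > p ||
        idx[2L] < 1 || idx[2L] > q)
      stop_invalid("profile key '%s' does not index a valid (target, regulator) pair", key)
  }
  with_seed(seed, {
    m <- modulator %||% runif(n, -1, 1)
    X <- matrix(rnorm(n * q), n, q)
    Y <- matrix(0, n, p)
    for (i in seq_len(n)) {
      B <- profile_coef_matrix(profiles, p, q, m[i])
      Y[i, ] <- as.numeric(B %*% X[i, ])
    }
    if (sigma > 0) Y <- Y + matrix(rnorm(n * p, 0, sigma), n, p)
    structure(list(X = X, Y = Y, modulator = m, profiles = profiles,
                   sigma = sigma, n = n, q = q, p = p),
              class = "grn_truth")
  })
}

#' @export
print.grn_truth <- function(x, ...) {
  cat(sprintf("Synthetic varying-coefficient dataset: %d samples, %d regulators, %d targets\n",
              x$n, x$q, x$p))
  cat(sprintf("  %d non-null edge profiles, noise sd %.3g\n",
              length(x$profiles), x$sigma))
  invisible(x)
}

#' True coefficient tensor of a synthetic dataset
#'
#' Evaluates every edge profile at every sample's modulator value, giving
#' the ground-truth targets x regulators x samples coefficient tensor that
#' stage-1 inference tries to recover.
#'
#' @param truth a `"grn_truth"` object from [generate_dataset()].
#' @return 3D array (targets x regulators x samples).
#' @export
true_coefficient_tensor <- function(truth) {
  stopifnot(inherits(truth, "grn_truth"))
  out <- array(0, dim = c(truth$p, truth$q, truth$n))
  for (i in seq_len(truth$n))
    out[, , i] <- profile_coef_matrix(truth$profiles, truth$p, truth$q,
                                      truth$modulator[i])
  out
}

#' Generate planted low-rank network tensors with an optional response
#'
#' Each sample slice is `X_i = sum_r s_ir a_r b_r^T + noise` with
#' orthonormal planted factor sets `{a_r}` and `{b_r}`. Scores of the first
#' factor are uniform on \[-1, 1\] (modulator-like); higher factors carry a
#' constant offset plus Gaussian variation, emulating the shared regulatory
#' backbone of personalized networks. With `response_map = "linear"` the
#' response is `y_i = w^T s_i` plus noise.
#'
#' @param n sample count.
#' @param I1,I2 slice dimensions (targets, regulators).
#' @param planted_rank number of planted factors (<= min(I1, I2)).
#' @param response_map `"linear"` or `"none"` (all-zero response).
#' @param seed integer RNG seed.
#' @param noise_sd entrywise Gaussian noise sd of the slices.
#' @param score_means,score_sds per-factor mean and sd of the scores;
#'   defaults: factor 1 uniform on \[-1, 1\], factors >= 2 `N(1.5, 0.3)`.
#' @param response_weights weights `w` of the linear response; default
#'   reads the first factor only.
#' @param response_noise_sd sd of the response noise.
#' @return list with `tensors` (I1 x I2 x n array), `response`, `scores`
#'   (n x rank), `A` (I1 x rank planted factors), `B` (I2 x rank).
#' @export
generate_network_tensor <- function(n, I1, I2, planted_rank = 2,
                                    response_map = c("linear", "none"),
                                    seed, noise_sd = 0,
                                    score_means = NULL, score_sds = NULL,
                                    response_weights = NULL,
                                    response_noise_sd = 0) {
  response_map <- match.arg(response_map)
  R <- planted_rank
  if (R > min(I1, I2))
    stop_invalid("planted_rank (%d) must be <= min(I1, I2) = %d", R, min(I1, I2))
  score_means <- score_means %||% c(0, rep(1.5, max(0, R - 1L)))[seq_len(R)]
  score_sds <- score_sds %||% c(NA, rep(0.3, max(0, R - 1L)))[seq_len(R)]
  w <- response_weights %||% c(1, rep(0, R - 1L))
  with_seed(seed, {
    A <- qr.Q(qr(matrix(rnorm(I1 * I1), I1, I1)))[, seq_len(R), drop = FALSE]
    B <- qr.Q(qr(matrix(rnorm(I2 * I2), I2, I2)))[, seq_len(R), drop = FALSE]
    S <- matrix(0, n, R)
    S[, 1L] <- runif(n, -1, 1)                     # modulator-like factor
    if (R > 1L) for (r in 2:R)
      S[, r] <- rnorm(n, score_means[r], score_sds[r])
    tens <- array(0, dim = c(I1, I2, n))
    for (i in seq_len(n)) {
      slice <- A %*% (S[i, ] * t(B))
      if (noise_sd > 0) slice <- slice + matrix(rnorm(I1 * I2, 0, noise_sd), I1, I2)
      tens[, , i] <- slice
    }
    y <- if (response_map == "linear") {
      as.numeric(S %*% w[seq_len(R)]) +
        (if (response_noise_sd > 0) rnorm(n, 0, response_noise_sd) else 0)
    } else rep(0, n)
    list(tensors = tens, response = y, scores = S, A = A, B = B)
  })
}

#' Simulate a smoothly modulated network study
#'
#' Companion fixture to [simulate_study()] in which every
#' modulator-dependent edge varies *smoothly* (gentle sigmoid over the
#' modulator range) on top of a constant-edge backbone, emulating
#' personalized networks that drift continuously along a uniformly
#' distributed modulator. This is the fixture on which the leading crucial
#' component is expected to track the modulator almost perfectly.
#'
#' @param n sample count.
#' @param p target count.
#' @param q regulator count.
#' @param sigma expression noise sd.
#' @param steepness sigmoid steepness of the varying edges (gentle by
#'   default so the variation is near-linear over the modulator range).
#' @param seed integer RNG seed.
#' @return list as [simulate_study()] (without marker designations).
#' @export
simulate_smooth_study <- function(n = 100, p = 20, q = 10, sigma = 0.1,
                                  steepness = 3, seed = 1) {
  with_seed(seed, {
    profiles <- list()
    for (j in seq_len(q)) {
      tg <- sample(seq_len(p), 4)
      for (l in tg[1:2])
        profiles[[profile_key(l, j)]] <-
          coef_profile("constant", baseline = sample(c(-1.5, 1.5), 1))
      for (l in tg[3:4])
        profiles[[profile_key(l, j)]] <-
          coef_profile("sigmoid", baseline = -1, shifted = 1,
                       changepoint = 0, steepness = steepness)
    }
    inner_seed <- sample.int(2^31 - 2, 1)
    truth <- generate_dataset(n, q, p, profiles, sigma = sigma, seed = inner_seed)
    gene_ids <- c(sprintf("TG%03d", seq_len(p)), sprintf("RG%03d", seq_len(q)))
    data <- expression_dataset(
      values = t(cbind(truth$Y, truth$X)),
      gene_ids = gene_ids,
      roles = c(rep("target", p), rep("regulator", q)),
      modulator = truth$modulator,
      sample_ids = sprintf("S%03d", seq_len(n)))
    list(truth = truth, data = data, profiles = profiles)
  })
}

#' Simulate a complete desk-scale network study
#'
#' Builds the standard end-to-end fixture: a modulator-driven expression
#' dataset in which a few designated regulators carry step-profile edges
#' that switch with the modulator (the differential markers to be
#' recovered), on top of a constant-edge regulatory backbone and a sparse
#' mixture of other edge kinds. The default edge mixture is roughly 60%
#' absent, 20% constant, 10% step and 10% sigmoid among candidate edges.
#'
#' @param n sample count.
#' @param p target count.
#' @param q regulator count.
#' @param n_marker number of designated differential regulators.
#' @param targets_per_marker step-profile targets per designated regulator.
#' @param sigma expression noise sd.
#' @param seed integer RNG seed.
#' @param shifted step height of the differential edges.
#' @param backbone `"mixed"` (default): non-marker regulators carry
#'   constant plus gently sigmoidal edges, roughly a 60/20/10/10
#'   zero/constant/step/sigmoid mixture over candidate edges; or
#'   `"constant"`: every non-marker edge is constant, so the designated
#'   step edges are the only modulator-dependent structure.
#' @return list with the `"grn_truth"` dataset (`truth`), an
#'   [expression_dataset()] view (`data`), the designated marker regulator
#'   gene IDs (`marker_regulators`) and the profile map.
#' @export
simulate_study <- function(n = 120, p = 30, q = 15, n_marker = 3,
                           targets_per_marker = 8, sigma = 0.1, seed = 1,
                           shifted = 2, backbone = c("mixed", "constant")) {
  backbone <- match.arg(backbone)
  with_seed(seed, {
    profiles <- list()
    markers <- seq_len(n_marker)                 # regulator columns 1..n_marker
    # step edges of the designated markers: off below the changepoint
    for (j in markers) {
      tg <- sample(seq_len(p), targets_per_marker)
      for (l in tg)
        profiles[[profile_key(l, j)]] <-
          coef_profile("step", baseline = 0, shifted = shifted, changepoint = 0)
    }
    # backbone edges on the remaining regulators
    others <- setdiff(seq_len(q), markers)
    for (j in others) {
      n_const <- max(1L, round(0.2 * p / 2))
      tg <- sample(seq_len(p), n_const)
      for (l in tg)
        profiles[[profile_key(l, j)]] <-
          coef_profile("constant", baseline = sample(c(-1.5, 1.5), 1))
      if (backbone == "mixed") {
        tg2 <- sample(setdiff(seq_len(p), tg), max(1L, round(0.1 * p / 2)))
        for (l in tg2)
          profiles[[profile_key(l, j)]] <-
            coef_profile("sigmoid", baseline = -1, shifted = 1,
                         changepoint = 0, steepness = 5)
      }
    }
    inner_seed <- sample.int(2^31 - 2, 1)
    truth <- generate_dataset(n, q, p, profiles, sigma = sigma, seed = inner_seed)
    gene_ids <- c(sprintf("TG%03d", seq_len(p)), sprintf("RG%03d", seq_len(q)))
    data <- expression_dataset(
      values = t(cbind(truth$Y, truth$X)),
      gene_ids = gene_ids,
      roles = c(rep("target", p), rep("regulator", q)),
      modulator = truth$modulator,
      sample_ids = sprintf("S%03d", seq_len(n)))
    list(truth = truth, data = data,
         marker_regulators = sprintf("RG%03d", markers),
         profiles = profiles)
  })
}
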