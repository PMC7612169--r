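# Fixture builders shared across the suite.  Everything is generated in
# code; no stored data.

# Random well-conditioned dataset with optional planted pleiotropy.
make_dataset <- function(p = 30, K = 2, theta = seq(0.2, by = 0.1,
                                                    length.out = K),
                         sigma_y = 0.02, sigma_x = 0.01, noise = sigma_y,
                         alpha = numeric(p), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beta_x <- matrix(runif(p * K, 0.02, 0.12), p, K)
  se_x <- matrix(runif(p * K, 0.5 * sigma_x, 1.5 * sigma_x), p, K)
  se_y <- runif(p, 0.5 * sigma_y, 1.5 * sigma_y)
  beta_y <- as.numeric(beta_x %*% theta) + alpha +
    if (noise > 0) rnorm(p, 0, noise) else 0
  summary_dataset(paste0("rs", seq_len(p)), beta_x, se_x, beta_y, se_y)
}

# Exact (noiseless, pleiotropy-free) dataset: beta_y = beta_x %*% theta.
make_exact_dataset <- function(p = 12, K = 3, theta = c(0.2, -0.1, 0.4),
                               seed = 1) {
  make_dataset(p = p, K = K, theta = theta, noise = 0, seed = seed)
}

# Brute-force weighted-least-squares oracle via explicit normal equations,
# independent of the package's QR path.
wls_oracle <- function(X, y, w) {
  A <- t(X) %*% diag(w) %*% X
  as.numeric(solve(A, t(X) %*% diag(w) %*% y))
}

# Exhaustive LAD oracle: enumerate every K-subset vertex.
lad_oracle <- function(X, y, w) {
  Xs <- X * w
  ys <- y * w
  combos <- utils::combn(nrow(X), ncol(X))
  best <- Inf
  best_theta <- NULL
  for (i in seq_len(ncol(combos))) {
    idx <- combos[, i]
    th <- tryCatch(solve(Xs[idx, , drop = FALSE], ys[idx]),
                   error = function(e) NULL)
    if (is.null(th)) next
    o <- sum(abs(ys - Xs %*% th))
    if (o < best) {
      best <- o
      best_theta <- as.numeric(th)
    }
  }
  list(theta = best_theta, objective = best)
}

# Weighted-median oracle for K = 1: weighted empirical distribution of the
# per-variant ratio estimates with weights |beta_x| / se_y^2.
weighted_median_oracle <- function(beta_x, beta_y, se_y) {
  ratio <- beta_y / beta_x
  wt <- abs(beta_x) / se_y^2
  ord <- order(ratio)
  ratio <- ratio[ord]
  wt <- wt[ord] / sum(wt)
  cw <- cumsum(wt)
  unname(ratio[which(cw >= 0.5)[1]])
}
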