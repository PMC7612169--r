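# Weighted least-absolute-deviations (median / tau = 0.5 quantile)
# regression through the origin.
#
# Minimizes sum_j w_j |y_j - x_j' theta|.  Since w_j > 0, this equals the
# unweighted LAD problem on rows scaled by w_j, which is a linear program
# whose solution (for continuous data, with probability one) interpolates
# exactly K observations.  The compiled solver (src/lad.cpp) runs IRLS on
# the smoothed objective to locate the optimum's neighbourhood, then
# polishes exactly by enumerating K-subsets of the rows with the smallest
# absolute residuals, solving each square system and keeping the subset
# with the lowest objective.  The polish makes the solution an exact LP
# vertex rather than an IRLS approximation; it is exhaustive (hence the
# solver exact) whenever p <= K + polish_extra.

lad_fit <- function(X, y, weights = rep(1, length(y)),
                    max_iter = 300L, tol = 1e-12, polish_extra = 10L,
                    theta_init = NULL) {
  X <- as.matrix(X)
  p <- nrow(X)
  K <- ncol(X)
  stopifnot(length(y) == p, length(weights) == p, all(weights > 0), p >= K)
  res <- .lad_fit_cpp(X, as.numeric(y), as.numeric(weights),
                      max_iter = as.integer(max_iter), tol = tol,
                      polish_extra = as.integer(polish_extra),
                      theta_init = theta_init)
  list(theta = as.numeric(res$theta), objective = res$objective)
}
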