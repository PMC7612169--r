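# Internal helpers shared across modules.

# Weighted least squares via QR on the root-weighted design; returns
# coefficients and the unscaled covariance (X' W X)^{-1}.
wls_fit <- function(X, y, w) {
  sw <- sqrt(w)
  Xs <- X * sw
  ys <- y * sw
  qr_d <- qr(Xs)
  if (qr_d$rank < ncol(X))
    stop("rank-deficient weighted design matrix", call. = FALSE)
  coef <- qr.coef(qr_d, ys)
  R <- qr.R(qr_d)
  cov_unscaled <- chol2inv(R)
  list(coef = as.numeric(coef), cov_unscaled = cov_unscaled)
}

# Read a small YAML or JSON config file into a list (extension-dispatched,
# falling back to YAML which is a JSON superset for our purposes).
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

# Independent integer sub-seeds for n_reps replications, derived from one
# user seed; kept below 2^31.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
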