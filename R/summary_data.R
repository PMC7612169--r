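#' Construct a summary-level MVMR dataset
#'
#' The universal input to every estimator in the package: per-variant
#' associations of `p` genetic variants with `K` risk factors (exposures) and
#' with one outcome, together with their standard errors.  Associations are
#' assumed pre-harmonized (same effect allele across all traits per variant)
#' and the standard errors are treated as known without error, as is
#' conventional for summary-data Mendelian randomization.
#'
#' @param variant_ids character vector of length `p`; unique variant labels.
#' @param beta_exposure numeric `p x K` matrix of variant-exposure
#'   associations.
#' @param se_exposure numeric `p x K` matrix of strictly positive standard
#'   errors of `beta_exposure`.
#' @param beta_outcome numeric vector of length `p`; variant-outcome
#'   associations.
#' @param se_outcome numeric vector of length `p`; strictly positive standard
#'   errors of `beta_outcome`.
#' @param exposure_names optional character vector of length `K`; defaults to
#'   `x1..xK`.
#' @param orientation_reference optional integer recording the exposure the
#'   dataset has been oriented to (see [orient()]); `NA` if unoriented.
#'
#' @return An object of class `summary_dataset`.
#'
#' @details Validity requirements (violations are errors, not warnings):
#'   `p > K`; all betas and SEs finite; all SEs strictly positive; the
#'   exposure association matrix of full column rank.  The full-rank condition
#'   guarantees the multivariable model is identified when all instruments are
#'   valid.
#'
#' @seealso [read_summary_data()], [orient()]
#' @export
#' @examples
#' d <- summary_dataset(
#'   variant_ids = paste0("rs", 1:3),
#'   beta_exposure = matrix(c(0.1, 0.2, 0.3), ncol = 1),
#'   se_exposure = matrix(0.01, 3, 1),
#'   beta_outcome = c(0.02, 0.04, 0.06),
#'   se_outcome = rep(0.01, 3))
#' d
summary_dataset <- function(variant_ids, beta_exposure, se_exposure,
                            beta_outcome, se_outcome,
                            exposure_names = NULL,
                            orientation_reference = NA_integer_) {
  beta_exposure <- as.matrix(beta_exposure)
  se_exposure <- as.matrix(se_exposure)
  p <- nrow(beta_exposure)
  K <- ncol(beta_exposure)
  variant_ids <- as.character(variant_ids)
  if (is.null(exposure_names)) exposure_names <- paste0("x", seq_len(K))

  if (length(variant_ids) != p)
    stop("variant_ids has length ", length(variant_ids),
         " but beta_exposure has ", p, " rows", call. = FALSE)
  if (anyDuplicated(variant_ids))
    stop("duplicated variant ids: ",
         paste(unique(variant_ids[duplicated(variant_ids)]), collapse = ", "),
         call. = FALSE)
  if (!identical(dim(se_exposure), dim(beta_exposure)))
    stop("se_exposure must have the same dimension as beta_exposure",
         call. = FALSE)
  if (length(beta_outcome) != p || length(se_outcome) != p)
    stop("beta_outcome and se_outcome must have length p = ", p,
         call. = FALSE)
  if (length(exposure_names) != K)
    stop("exposure_names must have length K = ", K, call. = FALSE)

  num <- list(beta_exposure = beta_exposure, se_exposure = se_exposure,
              beta_outcome = beta_outcome, se_outcome = se_outcome)
  for (nm in names(num)) {
    bad <- !is.finite(num[[nm]])
    if (any(bad))
      stop("non-finite or missing values in ", nm, " (rows: ",
           paste(utils::head(which(rowSums(matrix(bad, nrow = p)) > 0), 5L),
                 collapse = ", "), ")", call. = FALSE)
  }
  bad_se_x <- which(se_exposure <= 0, arr.ind = TRUE)
  if (nrow(bad_se_x) > 0)
    stop("non-positive exposure standard error at variant '",
         variant_ids[bad_se_x[1, 1]], "', exposure ", bad_se_x[1, 2],
         call. = FALSE)
  bad_se_y <- which(se_outcome <= 0)
  if (length(bad_se_y) > 0)
    stop("non-positive outcome standard error at variant '",
         variant_ids[bad_se_y[1]], "'", call. = FALSE)

  if (p <= K)
    stop("need more variants than exposures: p = ", p, " <= K = ", K,
         call. = FALSE)
  if (qr(beta_exposure)$rank < K)
    stop("exposure association matrix is rank deficient (rank ",
         qr(beta_exposure)$rank, " < K = ", K,
         "); exposures are collinear in their genetic associations",
         call. = FALSE)

  dimnames(beta_exposure) <- list(variant_ids, exposure_names)
  dimnames(se_exposure) <- list(variant_ids, exposure_names)
  structure(list(
    variant_ids = variant_ids,
    beta_exposure = beta_exposure,
    se_exposure = se_exposure,
    beta_outcome = stats::setNames(as.numeric(beta_outcome), variant_ids),
    se_outcome = stats::setNames(as.numeric(se_outcome), variant_ids),
    exposure_names = exposure_names,
    orientation_reference = orientation_reference
  ), class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat("Summary-level MVMR dataset\n")
  cat("  variants : p =", n_variants(x), "\n")
  cat("  exposures: K =", n_exposures(x),
      paste0("(", paste(x$exposure_names, collapse = ", "), ")"), "\n")
  if (!is.na(x$orientation_reference))
    cat("  oriented to exposure", x$orientation_reference, "\n")
  invisible(x)
}

#' Number of variants / exposures in a summary dataset
#' @param data a [summary_dataset()].
#' @return integer.
#' @export
n_variants <- function(data) length(data$variant_ids)

#' @rdname n_variants
#' @export
n_exposures <- function(data) ncol(data$beta_exposure)

#' Subset a summary dataset by variant
#' @param x a [summary_dataset()].
#' @param i integer, logical or character (variant id) index.
#' @param ... unused.
#' @return a [summary_dataset()] restricted to the selected variants.
#' @export
`[.summary_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$variant_ids)
  summary_dataset(
    variant_ids = x$variant_ids[i],
    beta_exposure = x$beta_exposure[i, , drop = FALSE],
    se_exposure = x$se_exposure[i, , drop = FALSE],
    beta_outcome = x$beta_outcome[i],
    se_outcome = x$se_outcome[i],
    exposure_names = x$exposure_names,
    orientation_reference = x$orientation_reference)
}

#' Read a summary-statistics table
#'
#' Reads a delimited text file (tab or comma, auto-detected; header required)
#' with one row per variant into a [summary_dataset()].  The default column
#' layout is `snp`, `beta_x1..beta_xK`, `se_x1..se_xK`, `beta_y`, `se_y`; any
#' other layout can be mapped via `column_map`.
#'
#' @param path path to a delimited text file.
#' @param column_map optional named list overriding column names: entries
#'   `snp`, `beta_exposure` (character vector, one per exposure, in order),
#'   `se_exposure`, `beta_outcome`, `se_outcome`.  May also be a path to a
#'   YAML or JSON file holding such a list.
#' @param exposure_names optional exposure labels; defaults derive from the
#'   beta column names.
#' @return a validated [summary_dataset()]; row order preserved.
#' @export
#' @examples
#' # synthetic example shipped with the package (25 variants, 3 exposures)
#' f <- system.file("extdata", "synthetic_mvmr_summary.tsv",
#'                  package = "mvmrtools")
#' d <- read_summary_data(f)
#' mvmr_ivw(d)
read_summary_data <- function(path, column_map = NULL, exposure_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (is.character(column_map) && length(column_map) == 1L)
    column_map <- read_config_file(column_map)

  cm <- resolve_column_map(names(tab), column_map)
  missing_cols <- setdiff(unlist(cm), names(tab))
  if (length(missing_cols) > 0)
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(exposure_names))
    exposure_names <- sub("^beta[_.]?", "", cm$beta_exposure)

  summary_dataset(
    variant_ids = as.character(tab[[cm$snp]]),
    beta_exposure = as.matrix(tab[cm$beta_exposure]),
    se_exposure = as.matrix(tab[cm$se_exposure]),
    beta_outcome = tab[[cm$beta_outcome]],
    se_outcome = tab[[cm$se_outcome]],
    exposure_names = exposure_names)
}

# Default column conventions: snp, beta_x1.., se_x1.., beta_y, se_y.
resolve_column_map <- function(cols, column_map = NULL) {
  cm <- list(
    snp = "snp",
    beta_exposure = sort_by_index(grep("^beta_x[0-9]+$", cols, value = TRUE)),
    se_exposure = sort_by_index(grep("^se_x[0-9]+$", cols, value = TRUE)),
    beta_outcome = "beta_y",
    se_outcome = "se_y")
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!nm %in% names(cm))
        stop("unknown column_map entry: ", nm, call. = FALSE)
      cm[[nm]] <- unlist(column_map[[nm]])
    }
  }
  if (length(cm$beta_exposure) == 0)
    stop("no exposure beta columns found (expected beta_x1, beta_x2, ... ",
         "or an explicit column_map)", call. = FALSE)
  if (length(cm$se_exposure) != length(cm$beta_exposure))
    stop("found ", length(cm$beta_exposure), " exposure beta columns but ",
         length(cm$se_exposure), " exposure SE columns", call. = FALSE)
  cm
}

sort_by_index <- function(x) {
  if (length(x) == 0) return(x)
  x[order(as.integer(sub("^.*_x", "", x)))]
}

#' Write a summary dataset to a delimited file
#'
#' Inverse of [read_summary_data()] under the default column layout.
#'
#' @param data a [summary_dataset()].
#' @param path output path.
#' @param sep field separator; tab by default.
#' @return `path`, invisibly.
#' @export
write_summary_data <- function(data, path, sep = "\t") {
  K <- n_exposures(data)
  out <- data.frame(snp = data$variant_ids, check.names = FALSE)
  for (k in seq_len(K)) out[[paste0("beta_x", k)]] <- data$beta_exposure[, k]
  for (k in seq_len(K)) out[[paste0("se_x", k)]] <- data$se_exposure[, k]
  out$beta_y <- unname(data$beta_outcome)
  out$se_y <- unname(data$se_outcome)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Orient variants to a reference exposure
#'
#' Re-codes each genetic variant so that its association with the chosen
#' reference exposure is non-negative, flipping the sign of all K exposure
#' associations and the outcome association for any variant with a negative
#' reference association.  Standard errors are unchanged.  The effect-allele
#' choice is arbitrary in summary data, so this is a pure re-coding; IVW-type
#' estimators are unaffected, but methods that model pleiotropy through
#' intercepts (Egger, lasso) are orientation-sensitive and conventionally use
#' all-positive orientation on the primary risk factor.
#'
#' Variants whose reference association is exactly zero are left unflipped.
#'
#' @param data a [summary_dataset()].
#' @param reference exposure index in `1..K`.
#' @return an oriented [summary_dataset()] with `orientation_reference` set.
#' @export
orient <- function(data, reference) {
  stopifnot(inherits(data, "summary_dataset"))
  K <- n_exposures(data)
  if (!(is.numeric(reference) && length(reference) == 1L &&
        reference >= 1 && reference <= K))
    stop("reference must be a single exposure index in 1..", K, call. = FALSE)
  reference <- as.integer(reference)
  flip <- data$beta_exposure[, reference] < 0
  s <- ifelse(flip, -1, 1)
  summary_dataset(
    variant_ids = data$variant_ids,
    beta_exposure = data$beta_exposure * s,
    se_exposure = data$se_exposure,
    beta_outcome = data$beta_outcome * s,
    se_outcome = data$se_outcome,
    exposure_names = data$exposure_names,
    orientation_reference = reference)
}
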