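#' Registry of processing methods
#'
#' The 25 concrete processing methods evaluated by the benchmark — 4
#' transformations, 15 normalizations and 6 imputations — plus the
#' reserved identity code `NON` ("none") in every category. Each method is
#' addressed by a three-letter code; a full analysis chain is the ordered
#' triple transformation-normalization-imputation, e.g. `LOG-MED-NON`.
#'
#' @param category optional filter: `"transformation"`, `"normalization"`
#'   or `"imputation"`.
#' @param include_none keep the `NON` identity entries (default `TRUE`).
#' @return A tibble with columns `category`, `code`, `name`.
#' @examples
#' method_registry("transformation")
#' nrow(method_registry(include_none = FALSE))  # 25
#' @export
method_registry <- function(category = NULL, include_none = TRUE) {
  reg <- dplyr::bind_rows(
    tibble::tibble(
      category = "transformation",
      code = c("BOX", "CUB", "LOG", "POW", "NON"),
      name = c("Box-Cox", "Cube Root", "Log", "Power", "None")),
    tibble::tibble(
      category = "normalization",
      code = c("AUT", "CYC", "EIG", "LOW", "MEA", "MED", "MAD", "PAR",
               "PQN", "QUA", "RLR", "TIC", "TMM", "VSN", "ZSC", "NON"),
      name = c("Auto Scaling", "Cyclic Loess", "EigenMS",
               "Locally Weighted Scatterplot Smoothing", "Mean", "Median",
               "Median Absolute Deviation", "Pareto",
               "Probabilistic Quotient", "Quantile",
               "Robust Linear Regression", "Total Ion Current",
               "Trimmed Mean of M Values", "VSN", "Z-score", "None")),
    tibble::tibble(
      category = "imputation",
      code = c("BAK", "BPC", "CEN", "KNN", "SVD", "ZER", "NON"),
      name = c("Background", "Bayesian Principal Component", "Censored",
               "K-nearest Neighbor", "Singular Value Decomposition",
               "Zero", "None"))
  )
  if (!is.null(category)) {
    category <- match.arg(category,
                          c("transformation", "normalization", "imputation"))
    reg <- dplyr::filter(reg, .data$category == !!category)
  }
  if (!include_none) reg <- dplyr::filter(reg, .data$code != "NON")
  reg
}

method_codes <- function(category, include_none = TRUE) {
  method_registry(category, include_none = include_none)$code
}

check_code <- function(code, category) {
  if (!code %in% method_codes(category))
    stop_validation(sprintf("unknown %s code '%s'", category, code))
  code
}

#' Method parameter sets
#'
#' Tunable parameters for the three chain stages, with the package
#' defaults. `chain_params()` bundles all three (plus a seed fanned out to
#' seeded methods) and is accepted everywhere a sweep or chain is run.
#'
#' @param log_base logarithm base for `LOG` (default 2).
#' @param power_exponent exponent of the power transformation, in (0, 1)
#'   (default 0.5, square root).
#' @param boxcox_lambda fixed Box-Cox lambda, or `"estimate"` (default) for
#'   a per-matrix maximum-likelihood estimate pooled over all observed
#'   values.
#' @return A named list of parameters.
#' @export
transform_params <- function(log_base = 2, power_exponent = 0.5,
                             boxcox_lambda = "estimate") {
  stopifnot(log_base > 1,
            power_exponent > 0, power_exponent < 1,
            identical(boxcox_lambda, "estimate") || is.numeric(boxcox_lambda))
  list(log_base = log_base, power_exponent = power_exponent,
       boxcox_lambda = boxcox_lambda)
}

#' @rdname transform_params
#' @param loess_span loess span for `LOW` and `CYC` trend fits.
#' @param cyclic_iterations full pairwise passes of cyclic loess.
#' @param tmm_trim_m,tmm_trim_a trimmed fractions of M and A values in TMM.
#' @param vsn_max_iter,vsn_tol coordinate-descent controls for VSN.
#' @param eigenms_n_perm permutations for the EigenMS significance test.
#' @param eigenms_alpha significance level of that test.
#' @param min_overlap minimum co-observed proteins for pairwise fits
#'   (TMM reference, regression pairs).
#' @export
normalize_params <- function(loess_span = 0.7, cyclic_iterations = 3,
                             tmm_trim_m = 0.30, tmm_trim_a = 0.05,
                             vsn_max_iter = 10, vsn_tol = 1e-4,
                             eigenms_n_perm = 500, eigenms_alpha = 0.05,
                             min_overlap = 10) {
  stopifnot(loess_span > 0, loess_span <= 1,
            cyclic_iterations >= 1,
            tmm_trim_m >= 0, tmm_trim_m < 0.5,
            tmm_trim_a >= 0, tmm_trim_a < 0.5,
            eigenms_alpha > 0, eigenms_alpha < 1)
  list(loess_span = loess_span, cyclic_iterations = cyclic_iterations,
       tmm_trim_m = tmm_trim_m, tmm_trim_a = tmm_trim_a,
       vsn_max_iter = vsn_max_iter, vsn_tol = vsn_tol,
       eigenms_n_perm = eigenms_n_perm, eigenms_alpha = eigenms_alpha,
       min_overlap = min_overlap)
}

#' @rdname transform_params
#' @param knn_k neighbours for KNN imputation.
#' @param n_components rank for SVD / Bayesian PCA imputation.
#' @param max_iter iteration cap for the iterative imputers.
#' @param tol convergence threshold for the iterative imputers: RMS
#'   change on imputed cells, relative to the observed-value sd.
#' @param background_quantile per-sample quantile used by `BAK`.
#' @param seed RNG seed used by seeded imputers.
#' @export
impute_params <- function(knn_k = 10, n_components = 5, max_iter = 100,
                          tol = 1e-4, background_quantile = 0.01,
                          seed = 1L) {
  stopifnot(knn_k >= 1, n_components >= 1, max_iter >= 1, tol > 0,
            background_quantile > 0, background_quantile <= 0.5)
  list(knn_k = knn_k, n_components = n_components, max_iter = max_iter,
       tol = tol, background_quantile = background_quantile,
       seed = as.integer(seed))
}

#' @rdname transform_params
#' @param transformation,normalization,imputation the three stage
#'   parameter lists.
#' @param seed master seed fanned out to seeded sub-steps.
#' @export
chain_params <- function(transformation = transform_params(),
                         normalization = normalize_params(),
                         imputation = impute_params(),
                         seed = 1L) {
  list(transformation = transformation, normalization = normalization,
       imputation = imputation, seed = as.integer(seed))
}

# Deterministic sub-seed from a master seed and string identifiers; keeps
# parallel and serial execution identical. Stays within 32-bit range.
derive_seed <- function(seed, ...) {
  ids <- paste(c(seed, ...), collapse = "/")
  as.integer(sum(utf8ToInt(ids) * (seq_along(utf8ToInt(ids)) %% 97 + 1)) %% 2147483L +
               1000L * (seed %% 100000L)) %% 2147483647L
}
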