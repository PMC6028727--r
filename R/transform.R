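#' Apply an intensity transformation
#'
#' First stage of an analysis chain. All transformations act element-wise
#' on observed cells only; missing cells pass through untouched and the
#' missing mask is invariant.
#'
#' Methods (three-letter codes):
#' * `LOG` — logarithm to `log_base` (default 2); requires all observed
#'   values > 0.
#' * `CUB` — real cube root, `sign(x) * |x|^(1/3)`, defined for all reals.
#' * `POW` — power transform `x^power_exponent` (default square root);
#'   nonpositive values with a non-integer exponent are a domain error.
#' * `BOX` — one-parameter Box-Cox, `(x^lambda - 1) / lambda` for
#'   `lambda != 0` and `ln x` for `lambda == 0`; requires positives.
#'   `lambda` is estimated once per matrix by maximum likelihood on all
#'   pooled observed values when `boxcox_lambda = "estimate"`.
#' * `NON` — identity.
#'
#' @param x an [intensity_table()].
#' @param code three-letter transformation code.
#' @param params parameters from [transform_params()].
#' @return The transformed `intensity_table`; mask unchanged.
#' @examples
#' m <- matrix(c(4, 16, 27, 8), 2, 2, dimnames = list(NULL, c("a", "b")))
#' it <- intensity_table(m, groups = c("A", "A"))
#' apply_transformation(it, "LOG")[, ]
#' @export
apply_transformation <- function(x, code, params = transform_params()) {
  stopifnot(inherits(x, "intensity_table"))
  check_code(code, "transformation")
  v <- values_of(x)
  obs <- !is.na(v)
  out <- switch(
    code,
    NON = return(x),
    LOG = {
      if (any(v[obs] <= 0))
        stop_stage("log transformation requires strictly positive intensities",
                   "domain-error", "transformation")
      log(v, base = params$log_base)
    },
    CUB = sign(v) * abs(v)^(1 / 3),
    POW = {
      e <- params$power_exponent
      if (any(v[obs] < 0) || (any(v[obs] == 0) && e <= 0))
        stop_stage("power transformation with a fractional exponent requires nonnegative intensities",
                   "domain-error", "transformation")
      v^e
    },
    BOX = {
      if (any(v[obs] <= 0))
        stop_stage("Box-Cox transformation requires strictly positive intensities",
                   "domain-error", "transformation")
      lambda <- params$boxcox_lambda
      if (identical(lambda, "estimate")) lambda <- boxcox_lambda_mle(v[obs])
      if (abs(lambda) < 1e-12) log(v) else (v^lambda - 1) / lambda
    }
  )
  set_values(x, out)
}

#' Maximum-likelihood Box-Cox lambda for a pooled sample
#'
#' Profile log-likelihood of the one-parameter Box-Cox model for an
#' unstructured (intercept-only) sample, maximized over lambda by golden
#' section search on \[-2, 2\].
#'
#' @param x positive numeric vector (NAs dropped).
#' @param interval search interval for lambda.
#' @return The estimated lambda (scalar).
#' @export
boxcox_lambda_mle <- function(x, interval = c(-2, 2)) {
  x <- x[!is.na(x)]
  if (any(x <= 0)) stop_stage("Box-Cox requires positive values",
                              "domain-error", "transformation")
  n <- length(x)
  sum_log <- sum(log(x))
  loglik <- function(lambda) {
    y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
    -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * sum_log
  }
  stats::optimize(loglik, interval, maximum = TRUE, tol = 1e-6)$maximum
}
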