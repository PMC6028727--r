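#' Variance-stabilizing normalization (affine calibration + arsinh)
#'
#' Per-sample affine calibration followed by a generalized-log transform:
#' `h_j(x) = arsinh(a_j + b_j * x)` with `b_j > 0`. The calibration
#' parameters are chosen to maximize a profile Gaussian likelihood of the
#' per-protein deviations from per-protein means — equivalently, to
#' minimize the pooled across-sample variance of those deviations,
#' balanced by the arsinh Jacobian so the trivial "flatten everything"
#' solution is excluded. Robustness comes from a least-trimmed variance
#' pool over the middle 90% of proteins (the 5% of proteins with the
#' largest and smallest residual sums of squares are excluded from the
#' variance term each evaluation). Optimization is coordinate descent
#' over samples, each sample's `(a_j, log b_j)` refined by Nelder-Mead,
#' until the largest parameter change falls below `vsn_tol` or
#' `vsn_max_iter` sweeps.
#'
#' Non-convergence is not a chain failure: the last iterate is returned
#' with attribute `converged = FALSE` and a warning.
#'
#' @param x an [intensity_table()]; raw-scale positive values are the
#'   intended input but any reals are accepted.
#' @param params parameters from [normalize_params()].
#' @return The calibrated, arsinh-transformed `intensity_table` with
#'   attributes `vsn_coefficients` (samples x 2 matrix of `a`, `b`) and
#'   `converged`.
#' @export
vsn_normalize <- function(x, params = normalize_params()) {
  v <- values_of(x)
  p <- nrow(v); s <- ncol(v)
  obs <- !is.na(v)
  n_i <- rowSums(obs)
  if (s < 2L)
    stop_stage("VSN requires at least 2 samples", "insufficient-data",
               "normalization")

  # init: whiten each column, so arsinh starts in its linear regime
  csd <- apply(v, 2, stats::sd, na.rm = TRUE)
  csd[!is.finite(csd) | csd == 0] <- 1
  b <- 1 / csd
  a <- -colMeans(v, na.rm = TRUE) * b

  H <- asinh(sweep(sweep(v, 2, b, `*`), 2, a, `+`))

  # Row sums and sums of squares of H are maintained incrementally, so a
  # candidate (a_j, b_j) is scored in O(p): negative profile
  # log-likelihood with the variance part trimmed to the middle 90% of
  # proteins by residual SS.
  trim <- 0.05
  use <- n_i >= 2
  n_tot <- sum(n_i)
  S <- rowSums(H, na.rm = TRUE)
  Q <- rowSums(H^2, na.rm = TRUE)

  converged <- FALSE
  for (iter in seq_len(params$vsn_max_iter)) {
    max_delta <- 0
    for (j in seq_len(s)) {
      rows_j <- which(obs[, j])
      xo <- v[rows_j, j]
      h_old <- H[rows_j, j]
      S0 <- S; S0[rows_j] <- S0[rows_j] - h_old
      Q0 <- Q; Q0[rows_j] <- Q0[rows_j] - h_old^2
      nxo <- length(xo)
      fn <- function(par) {
        aj <- par[1]; bj <- exp(par[2])
        h <- asinh(aj + bj * xo)
        Sn <- S0; Sn[rows_j] <- Sn[rows_j] + h
        Qn <- Q0; Qn[rows_j] <- Qn[rows_j] + h^2
        ss <- (Qn - Sn^2 / pmax(n_i, 1))[use]
        qs <- stats::quantile(ss, c(trim, 1 - trim), names = FALSE)
        keep <- ss >= qs[1] & ss <= qs[2]
        n_eff <- sum((n_i[use])[keep] - 1)
        t_ <- aj + bj * xo
        jac <- nxo * log(bj) - 0.5 * sum(log1p(t_^2))
        # a perfect fit (all residuals zero) must stay finite
        0.5 * n_tot * log(max(sum(ss[keep]), 1e-300) / max(n_eff, 1)) - jac
      }
      opt <- stats::optim(c(a[j], log(b[j])), fn, method = "Nelder-Mead",
                          control = list(maxit = 60, reltol = 1e-8))
      delta <- max(abs(c(opt$par[1] - a[j], opt$par[2] - log(b[j]))))
      max_delta <- max(max_delta, delta)
      a[j] <- opt$par[1]; b[j] <- exp(opt$par[2])
      h_new <- asinh(a[j] + b[j] * xo)
      S[rows_j] <- S0[rows_j] + h_new
      Q[rows_j] <- Q0[rows_j] + h_new^2
      H[rows_j, j] <- h_new
    }
    if (max_delta < params$vsn_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("VSN coordinate descent did not converge; returning last iterate")
  out <- set_values(x, H)
  attr(out, "vsn_coefficients") <- cbind(a = a, b = b)
  attr(out, "converged") <- converged
  out
}
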