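#' Apply a missing-value imputation method
#'
#' Third and final stage of an analysis chain. Every method leaves
#' observed cells bit-identical and (except `NON`) returns a table with
#' no missing cells.
#'
#' * `ZER` — missing cells set to 0.
#' * `BAK` — background substitution: missing cells set to the
#'   `background_quantile` quantile of that sample's observed values.
#' * `CEN` — left-censoring substitution: missing cells set to half the
#'   protein's minimum observed value; fully missing proteins get half
#'   the matrix minimum.
#' * `KNN` — see [knn_impute()].
#' * `SVD`, `BPC` — see [lowrank_impute()].
#' * `NON` — identity; missing cells stay missing and are simply excluded
#'   from the precision assessment.
#'
#' @param x an [intensity_table()]; every sample must have at least one
#'   observed value.
#' @param code three-letter imputation code.
#' @param params parameters from [impute_params()].
#' @return The imputed `intensity_table`.
#' @export
apply_imputation <- function(x, code, params = impute_params()) {
  stopifnot(inherits(x, "intensity_table"))
  check_code(code, "imputation")
  if (code == "NON") return(x)
  v <- values_of(x)
  miss <- is.na(v)
  if (!any(miss)) return(x)
  empty <- colSums(!miss) == 0L
  if (any(empty))
    stop_stage(paste0("sample(s) with no observed values: ",
                      paste(colnames(v)[empty], collapse = ", ")),
               "insufficient-data", "imputation")
  out <- switch(
    code,
    ZER = { v[miss] <- 0; v },
    BAK = {
      q <- apply(v, 2, stats::quantile, probs = params$background_quantile,
                 na.rm = TRUE)
      idx <- which(miss, arr.ind = TRUE)
      v[idx] <- q[idx[, 2]]
      v
    },
    CEN = {
      rmin <- suppressWarnings(apply(v, 1, min, na.rm = TRUE))
      rmin[!is.finite(rmin)] <- min(v, na.rm = TRUE)  # fully missing rows
      idx <- which(miss, arr.ind = TRUE)
      v[idx] <- rmin[idx[, 1]] / 2
      v
    },
    KNN = return(knn_impute(x, params)),
    SVD = ,
    BPC = return(lowrank_impute(x, method = code, params = params))
  )
  set_values(x, out)
}

#' K-nearest-neighbour imputation over proteins
#'
#' Neighbours are proteins (rows). For each protein with missing cells,
#' the `knn_k` proteins nearest in Euclidean distance over co-observed
#' samples are located (squared distances rescaled by
#' `n_samples / n_co-observed` so sparse overlaps are comparable); each
#' missing cell is the 1/distance-weighted average of the neighbours'
#' observed values in that sample. Zero-distance neighbours get equal
#' weights (and exclude finite-distance ones). Neighbours missing in the
#' target sample are skipped; if all are missing there, the protein's own
#' observed mean is used. Proteins sharing fewer than 2 observed samples
#' with every other protein fall back to their row mean.
#'
#' @param x an [intensity_table()] with at least `knn_k + 1` proteins.
#' @param params parameters from [impute_params()].
#' @return The imputed `intensity_table`.
#' @export
knn_impute <- function(x, params = impute_params()) {
  v <- values_of(x)
  p <- nrow(v); s <- ncol(v)
  if (p < params$knn_k + 1L)
    stop_stage(sprintf("KNN needs at least %d proteins", params$knn_k + 1L),
               "insufficient-data", "imputation")
  miss <- is.na(v)
  targets <- which(rowSums(miss) > 0L)
  M <- 1 - miss          # observed indicator
  X0 <- v; X0[miss] <- 0
  X2 <- X0^2
  row_mean <- rowSums(X0) / pmax(rowSums(M), 1)

  # squared distances over co-observed cells, all targets at once:
  # sum_co (xi - xk)^2 = xi^2.Mk + Mk... assembled from three products
  A <- X2[targets, , drop = FALSE] %*% t(M)     # sum xi^2 over co-observed
  B <- M[targets, , drop = FALSE] %*% t(X2)     # sum xk^2 over co-observed
  C <- X0[targets, , drop = FALSE] %*% t(X0)    # sum xi*xk
  Nco <- M[targets, , drop = FALSE] %*% t(M)
  D2 <- pmax(A + B - 2 * C, 0)
  D2 <- D2 * (s / pmax(Nco, 1))

  out <- v
  for (ti in seq_along(targets)) {
    i <- targets[ti]
    d2 <- D2[ti, ]
    d2[i] <- Inf
    d2[Nco[ti, ] < 2L] <- Inf
    usable <- which(is.finite(d2))
    cells <- which(miss[i, ])
    if (!length(usable)) { out[i, cells] <- row_mean[i]; next }
    k <- min(params$knn_k, length(usable))
    nb <- usable[order(d2[usable], method = "radix")[seq_len(k)]]
    d <- sqrt(d2[nb])
    w <- if (any(d == 0)) as.numeric(d == 0) else 1 / d
    for (j in cells) {
      have <- !miss[nb, j]
      if (!any(have)) { out[i, j] <- row_mean[i]; next }
      ww <- w[have]
      out[i, j] <- sum(ww * v[nb[have], j]) / sum(ww)
    }
  }
  set_values(x, out)
}

#' Low-rank matrix-completion imputation (iterative SVD or Bayesian PCA)
#'
#' Missing cells are initialized with row means (matrix mean for fully
#' missing rows) and refined iteratively; only missing cells are ever
#' overwritten.
#'
#' * `SVD` — each iteration reconstructs the matrix at rank
#'   `n_components` from its SVD and overwrites the missing cells, until
#'   the RMS change on those cells drops below `tol` (relative to the
#'   observed-value sd) or `max_iter`.
#' * `BPC` — the same loop, but the low-rank model is estimated by EM for
#'   Bayesian (probabilistic) PCA with automatic-relevance-determination
#'   priors on the component loadings, so superfluous components shrink
#'   toward zero. The effective rank (components whose loading norm
#'   exceeds `1e-3` of the largest) is returned as attribute
#'   `effective_rank`.
#'
#' A growing RMS change (10x over 5 iterations) is treated as divergence.
#'
#' @param x an [intensity_table()].
#' @param method `"SVD"` or `"BPC"`.
#' @param params parameters from [impute_params()].
#' @return The imputed `intensity_table`.
#' @export
lowrank_impute <- function(x, method = c("SVD", "BPC"),
                           params = impute_params()) {
  method <- match.arg(method)
  v <- values_of(x)
  p <- nrow(v); s <- ncol(v)
  q <- min(params$n_components, p - 1L, s - 1L)
  if (q < 1L)
    stop_stage("matrix too small for low-rank imputation",
               "insufficient-data", "imputation")
  miss <- is.na(v)
  rmn <- rowMeans(v, na.rm = TRUE)
  rmn[!is.finite(rmn)] <- mean(v, na.rm = TRUE)
  filled <- v
  filled[miss] <- rmn[row(v)[miss]]

  # convergence threshold is relative to the observed-value spread, so
  # raw-scale and log-scale chains converge on comparable effort
  sd_obs <- stats::sd(v[!miss])
  tol_eff <- params$tol * if (is.finite(sd_obs) && sd_obs > 0) sd_obs else 1

  deltas <- rep(NA_real_, params$max_iter)
  eff_rank <- q

  if (method == "BPC") {
    # EM for probabilistic PCA with ARD regularization, rows = cases.
    mu <- colMeans(filled)
    Xc <- sweep(filled, 2, mu)
    sv0 <- svd(Xc, nu = 0, nv = q)
    W <- sv0$v %*% diag(sv0$d[seq_len(q)] / sqrt(p), q)   # s x q
    # start the noise variance at the rank-q SVD residual, not the total
    # variance: overestimating it shrinks real components to death
    sigma2 <- max((sum(Xc^2) - sum(sv0$d[seq_len(q)]^2)) / (p * s), 1e-12)
    alpha <- rep(1, q)
    complete_rows <- rowSums(miss) == 0L
    incomplete_rows <- which(!complete_rows)
    obs_idx <- lapply(incomplete_rows, function(i) which(!miss[i, ]))
  }

  for (iter in seq_len(params$max_iter)) {
    old_missing <- filled[miss]
    if (method == "SVD") {
      # rank-q reconstruction X V_q V_q' via the small-side eigenproblem
      if (s <= p) {
        V <- eigen(crossprod(filled), symmetric = TRUE)$vectors[, seq_len(q),
                                                               drop = FALSE]
        recon <- (filled %*% V) %*% t(V)
      } else {
        U <- eigen(tcrossprod(filled), symmetric = TRUE)$vectors[, seq_len(q),
                                                                 drop = FALSE]
        recon <- U %*% (t(U) %*% filled)
      }
    } else {
      # EM for Bayesian PCA with ARD priors. The E-step conditions each
      # row's scores on its observed cells only; conditioning on the
      # current fill would let superfluous components feed on their own
      # predictions and escape the ARD shrinkage.
      mu <- colMeans(filled)
      Xc <- sweep(filled, 2, mu)
      Minv <- inv_spd(crossprod(W) + sigma2 * diag(q))
      EZ <- Xc %*% W %*% Minv
      EZtZ_cov <- sum(complete_rows) * sigma2 * Minv
      xz_corr <- matrix(0, s, q)             # E[x_mis z'] covariance part
      for (ii in seq_along(incomplete_rows)) {
        i <- incomplete_rows[ii]
        o <- obs_idx[[ii]]
        Wo <- W[o, , drop = FALSE]
        Ai <- inv_spd(crossprod(Wo) + sigma2 * diag(q))
        EZ[i, ] <- Ai %*% crossprod(Wo, Xc[i, o])
        EZtZ_cov <- EZtZ_cov + sigma2 * Ai
        mi <- which(miss[i, ])
        xz_corr[mi, ] <- xz_corr[mi, ] +
          W[mi, , drop = FALSE] %*% (sigma2 * Ai)
      }
      EZtZ <- EZtZ_cov + crossprod(EZ)
      recon_c <- EZ %*% t(W)                 # synthesis with current W
      Xc[miss] <- recon_c[miss]              # E[x_mis] under the model
      # joint (W, alpha) fixed point of the M-step: iterating the cheap
      # pair of updates lets superfluous components collapse instead of
      # decaying by a few percent per EM step
      Cxz <- crossprod(Xc, EZ) + xz_corr
      for (mm_it in seq_len(25L)) {
        W <- Cxz %*% inv_spd(EZtZ + sigma2 * diag(alpha, q))
        wn2 <- colSums(W^2)
        alpha_new <- s / pmax(wn2, 1e-12)
        done <- all(abs(alpha_new - alpha) <= 1e-8 * alpha)
        alpha <- alpha_new
        if (done) break
      }
      recon_c <- EZ %*% t(W)
      # full M-step noise update: observed residuals plus the posterior
      # score-covariance term; without the latter the active components
      # absorb the noise and sigma2 collapses
      n_obs_cells <- sum(!miss)
      resid2 <- sum(((Xc - recon_c)[!miss])^2)
      trace_term <- sum(EZtZ_cov * crossprod(W)) * n_obs_cells / (p * s)
      sigma2 <- max((resid2 + trace_term) / n_obs_cells, 1e-12)
      recon <- sweep(recon_c, 2, mu, `+`)
      eff_rank <- sum(sqrt(wn2) > 1e-3 * sqrt(max(wn2)))
    }
    filled[miss] <- recon[miss]
    deltas[iter] <- sqrt(mean((filled[miss] - old_missing)^2))
    if (deltas[iter] < tol_eff) break
  }
  # divergence is judged on the final window: still far from converged
  # AND the change growing 10x monotonically over the last 5 iterations.
  # A transient spike when an ARD component collapses recovers and is
  # not divergence.
  if (iter >= 5L && deltas[iter] >= tol_eff * 100) {
    w5 <- deltas[(iter - 4L):iter]
    if (all(is.finite(w5)) && all(diff(w5) > 0) && w5[5L] > 10 * w5[1L])
      stop_stage("low-rank imputation diverged", "non-convergence",
                 "imputation")
  }
  out <- set_values(x, filled)
  if (method == "BPC") attr(out, "effective_rank") <- eff_rank
  out
}

# Inverse of a symmetric positive-definite matrix via Cholesky. The ridge
# is relative to each diagonal element: a collapsed ARD component whose
# prior precision has exploded must not leak regularization into the
# still-active components' blocks.
inv_spd <- function(A) {
  d <- diag(A)
  diag(A) <- d * (1 + 1e-12)
  chol2inv(chol(A))
}
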