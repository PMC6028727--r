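#' Apply a normalization method
#'
#' Second stage of an analysis chain. All statistics are computed on
#' observed cells only; missing cells pass through untouched. Methods are
#' applied to whatever scale the chain's transformation produced — there
#' is no hidden re-logging, so the 560 chains are a blind sequential
#' composition.
#'
#' Per-sample location/scale methods (column `j`, grand statistics over
#' all observed cells):
#' * `MEA` — `x * grand mean / column mean`
#' * `MED` — `x * grand median / column median`
#' * `TIC` — `x * (mean of column sums) / column sum` (total ion current)
#' * `ZSC` — `(x - column mean) / column sd`
#' * `MAD` — `(x - column median) / column MAD` (raw MAD, no consistency
#'   constant)
#' * `PQN` — probabilistic quotient: after TIC pre-scaling, each column is
#'   divided by the median over proteins of its ratio to the per-protein
#'   median reference spectrum
#' * `QUA` — quantile normalization: the k-th order statistic of every
#'   column is replaced by the mean of k-th order statistics across
#'   columns; ties receive the mean of the means over their tied ranks;
#'   with missing values, column quantiles are interpolated to a common
#'   grid of the maximum column length
#' * `TMM` — trimmed mean of M-values scale factors, see [tmm_factors()]
#'
#' Per-protein scaling methods (row `i`):
#' * `AUT` — auto scaling `(x - row mean) / row sd`
#' * `PAR` — Pareto scaling `(x - row mean) / sqrt(row sd)`
#'
#' Model-based methods: `CYC`, `LOW`, `RLR` (see [regression_normalize()]),
#' `VSN` (see [vsn_normalize()]), `EIG` (see [eigenms_normalize()]).
#' `NON` is the bit-exact identity.
#'
#' @param x an [intensity_table()] with at least 2 samples.
#' @param code three-letter normalization code.
#' @param params parameters from [normalize_params()].
#' @param seed RNG seed for the permutation test inside `EIG` (the only
#'   stochastic method).
#' @return The normalized `intensity_table`.
#' @export
apply_normalization <- function(x, code, params = normalize_params(),
                                seed = 1L) {
  stopifnot(inherits(x, "intensity_table"))
  check_code(code, "normalization")
  if (code == "NON") return(x)
  if (ncol(x) < 2L)
    stop_stage("normalization requires at least 2 samples",
               "insufficient-data", "normalization")
  v <- values_of(x)
  out <- switch(
    code,
    MEA = {
      cm <- colMeans(v, na.rm = TRUE)
      sweep_cols(v, mean(v, na.rm = TRUE) / cm, `*`, "column mean")
    },
    MED = {
      cm <- col_medians(v)
      sweep_cols(v, stats::median(v, na.rm = TRUE) / cm, `*`, "column median")
    },
    TIC = {
      cs <- colSums(v, na.rm = TRUE)
      sweep_cols(v, mean(cs) / cs, `*`, "column sum")
    },
    ZSC = {
      cm <- colMeans(v, na.rm = TRUE)
      csd <- apply(v, 2, stats::sd, na.rm = TRUE)
      if (any(!is.na(csd) & csd == 0))
        stop_stage("zero column sd in Z-score normalization",
                   "degenerate-scale", "normalization")
      sweep(sweep(v, 2, cm, `-`), 2, csd, `/`)
    },
    MAD = {
      cmed <- col_medians(v)
      cmad <- col_medians(abs(sweep(v, 2, cmed, `-`)))
      if (any(!is.na(cmad) & cmad == 0))
        stop_stage("zero column MAD in MAD normalization",
                   "degenerate-scale", "normalization")
      sweep(sweep(v, 2, cmed, `-`), 2, cmad, `/`)
    },
    AUT = row_scale(v, pareto = FALSE),
    PAR = row_scale(v, pareto = TRUE),
    PQN = pqn_normalize(v),
    QUA = qua_normalize(v),
    TMM = {
      f <- tmm_factors(x, params)
      sweep(v, 2, f, `/`)
    },
    CYC = ,
    LOW = ,
    RLR = return(regression_normalize(x, code, params)),
    VSN = return(vsn_normalize(x, params)),
    EIG = return(eigenms_normalize(x, params = params, seed = seed))
  )
  set_values(x, out)
}

# Multiply/shift columns by a per-column statistic, guarding degenerate
# (zero or missing) statistics.
sweep_cols <- function(v, stat, op, what) {
  if (any(!is.finite(stat)))
    stop_stage(paste0("degenerate ", what, " (zero or non-finite)"),
               "degenerate-scale", "normalization")
  sweep(v, 2, stat, op)
}

row_scale <- function(v, pareto) {
  n <- row_n_obs(v)
  rm_ <- rowMeans(v, na.rm = TRUE)
  rsd <- sqrt(rowSums((v - rm_)^2, na.rm = TRUE) / pmax(n - 1, 1))
  out <- v - rm_
  scale <- if (pareto) sqrt(rsd) else rsd
  ok <- n >= 2 & rsd > 0
  out[ok, ] <- out[ok, , drop = FALSE] / scale[ok]
  out[!ok, ] <- NA_real_  # single-observation or constant rows -> missing
  out
}

pqn_normalize <- function(v) {
  cs <- colSums(v, na.rm = TRUE)
  if (any(cs == 0))
    stop_stage("zero column sum in PQN pre-scaling",
               "degenerate-scale", "normalization")
  vt <- sweep(v, 2, mean(cs) / cs, `*`)
  ref <- row_medians(vt)
  q <- vt / ref
  q[!is.finite(q)] <- NA
  fac <- col_medians(q)
  if (any(!is.na(fac) & fac == 0) || anyNA(fac))
    stop_stage("degenerate quotient in PQN", "degenerate-scale",
               "normalization")
  sweep(vt, 2, fac, `/`)
}

qua_normalize <- function(v) {
  s <- ncol(v)
  counts <- colSums(!is.na(v))
  if (any(counts == 0))
    stop_stage("sample with no observed values in quantile normalization",
               "insufficient-data", "normalization")
  L <- max(counts)
  grid <- if (L == 1L) 0.5 else (seq_len(L) - 1) / (L - 1)
  curves <- vapply(seq_len(s), function(j) {
    xo <- sort(v[, j], na.last = NA)
    m <- length(xo)
    if (m == L) xo
    else stats::approx(if (m == 1L) 0.5 else (seq_len(m) - 1) / (m - 1),
                       xo, xout = grid, rule = 2)$y
  }, numeric(L))
  meanc <- rowMeans(curves)
  out <- v
  for (j in seq_len(s)) {
    idx <- which(!is.na(v[, j]))
    m <- length(idx)
    xj <- v[idx, j]
    # value at each integer rank of this column on the mean curve
    at_rank <- if (m == L) meanc
      else stats::approx(grid, meanc,
                         xout = if (m == 1L) 0.5 else (seq_len(m) - 1) / (m - 1),
                         rule = 2)$y
    cum <- c(0, cumsum(at_rank))
    rmin <- rank(xj, ties.method = "min")
    rmax <- rank(xj, ties.method = "max")
    out[idx, j] <- (cum[rmax + 1L] - cum[rmin]) / (rmax - rmin + 1L)
  }
  out
}

#' Trimmed mean of M-values scale factors
#'
#' Per-sample scale factors in the TMM style: the reference sample is the
#' column whose upper quartile is closest to the mean upper quartile; for
#' every other sample, M-values `log2(x_j / x_ref)` and A-values
#' `0.5 * log2(x_j * x_ref)` are formed over proteins observed in both,
#' the extreme `tmm_trim_m` / `tmm_trim_a` fractions of M and A are
#' dropped, and the factor is `2^` the precision-weighted mean of the
#' remaining M. Factors are rescaled to multiply to 1 and are applied as
#' division.
#'
#' @param x an [intensity_table()] with positive observed values.
#' @param params parameters from [normalize_params()].
#' @return Named numeric vector of per-sample factors (product 1).
#' @export
tmm_factors <- function(x, params = normalize_params()) {
  v <- values_of(x)
  if (any(v[!is.na(v)] <= 0))
    stop_stage("TMM requires strictly positive intensities",
               "domain-error", "normalization")
  uq <- apply(v, 2, stats::quantile, probs = 0.75, na.rm = TRUE)
  ref <- which.min(abs(uq - mean(uq)))
  xr <- v[, ref]
  colsum <- colSums(v, na.rm = TRUE)
  f <- vapply(seq_len(ncol(v)), function(j) {
    if (j == ref) return(1)
    both <- !is.na(v[, j]) & !is.na(xr)
    if (sum(both) < params$min_overlap)
      stop_stage(sprintf("only %d proteins co-observed with TMM reference",
                         sum(both)), "insufficient-overlap", "normalization")
    xj <- v[both, j]; xb <- xr[both]
    M <- log2(xj / xb)
    A <- 0.5 * log2(xj * xb)
    n <- length(M)
    loM <- floor(n * params$tmm_trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * params$tmm_trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) keep <- rep(TRUE, n)
    # asymptotic (delta-method) precision weights on the kept M values
    w <- 1 / ((colsum[j] - xj[keep]) / (colsum[j] * xj[keep]) +
                (colsum[ref] - xb[keep]) / (colsum[ref] * xb[keep]))
    2^(sum(w * M[keep]) / sum(w))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(v))
}

#' Regression-based normalization (cyclic loess, lowess, robust line)
#'
#' All three remove an intensity-dependent trend between samples, assuming
#' additive structure on the current scale:
#' * `LOW` — per sample, a loess fit (span `loess_span`) of the difference
#'   to the reference (per-protein median across samples) against the mean
#'   level, subtracted.
#' * `RLR` — same structure, but the trend is a straight line fitted by
#'   iteratively reweighted least squares with Huber weights (tuning
#'   constant 1.345).
#' * `CYC` — for every unordered sample pair, a loess fit of M
#'   (difference) on A (average); half the fitted trend is subtracted from
#'   one sample and added to the other; repeated `cyclic_iterations`
#'   times.
#'
#' Pairs (or samples) with fewer than `min_overlap` co-observed proteins
#' are skipped with a warning; if every pair is skipped that is an error.
#'
#' @param x an [intensity_table()].
#' @param method `"CYC"`, `"LOW"` or `"RLR"`.
#' @param params parameters from [normalize_params()].
#' @return The normalized `intensity_table`.
#' @export
regression_normalize <- function(x, method = c("CYC", "LOW", "RLR"),
                                 params = normalize_params()) {
  method <- match.arg(method)
  v <- values_of(x)
  s <- ncol(v)
  any_fit <- FALSE
  if (method %in% c("LOW", "RLR")) {
    ref <- row_medians(v)
    for (j in seq_len(s)) {
      ok <- !is.na(v[, j]) & !is.na(ref)
      if (sum(ok) < params$min_overlap) {
        warning(sprintf("sample %s skipped: only %d proteins co-observed with reference",
                        colnames(v)[j], sum(ok)))
        next
      }
      any_fit <- TRUE
      d <- v[ok, j] - ref[ok]
      a <- (v[ok, j] + ref[ok]) / 2
      v[ok, j] <- v[ok, j] - trend_fit(a, d, method, params)
    }
  } else {
    for (iter in seq_len(params$cyclic_iterations)) {
      for (j in seq_len(s - 1L)) for (k in (j + 1L):s) {
        ok <- !is.na(v[, j]) & !is.na(v[, k])
        if (sum(ok) < params$min_overlap) {
          if (iter == 1L)
            warning(sprintf("pair (%s, %s) skipped: %d co-observed proteins",
                            colnames(v)[j], colnames(v)[k], sum(ok)))
          next
        }
        any_fit <- TRUE
        M <- v[ok, j] - v[ok, k]
        A <- (v[ok, j] + v[ok, k]) / 2
        fit <- trend_fit(A, M, "CYC", params)
        v[ok, j] <- v[ok, j] - fit / 2
        v[ok, k] <- v[ok, k] + fit / 2
      }
    }
  }
  if (!any_fit)
    stop_stage("no sample pair had enough co-observed proteins",
               "insufficient-overlap", "normalization")
  set_values(x, v)
}

# Fitted trend of d on a, evaluated at a. Loess via the fast C lowess for
# LOW/CYC; Huber IRLS line for RLR. Degenerate spreads fall back to a
# constant (median) trend. For large protein counts the loess curve is
# fitted on a deterministic rank-stratified subsample (every k-th point
# in A order) and interpolated at the remaining points, which leaves the
# fitted trend essentially unchanged while keeping the pairwise cyclic
# variant tractable on 100+ sample datasets.
trend_fit <- function(a, d, method, params, max_fit_points = 300L) {
  if (stats::sd(a) == 0) return(rep(stats::median(d), length(d)))
  if (method == "RLR") {
    fit <- suppressWarnings(
      MASS::rlm(cbind(1, a), d, psi = MASS::psi.huber, k = 1.345,
                maxit = 100))
    return(as.vector(cbind(1, a) %*% fit$coefficients))
  }
  n <- length(a)
  if (n > max_fit_points) {
    o <- order(a, method = "radix")
    sub <- o[unique(round(seq(1L, n, length.out = max_fit_points)))]
    lw <- stats::lowess(a[sub], d[sub], f = params$loess_span, iter = 3L)
  } else {
    lw <- stats::lowess(a, d, f = params$loess_span, iter = 3L)
  }
  stats::approx(lw$x, lw$y, xout = a, rule = 2, ties = "ordered")$y
}
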