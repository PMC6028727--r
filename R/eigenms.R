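#' EigenMS-style bias trend removal
#'
#' Removes systematic (non-biological) bias trends while preserving group
#' differences:
#' 1. fixed group effects are removed per protein (group means
#'    subtracted);
#' 2. the residual matrix of complete-case proteins is decomposed by SVD;
#' 3. the number of significant bias trends is the count of leading
#'    singular values exceeding the `(1 - eigenms_alpha)` quantile of the
#'    first singular value under `eigenms_n_perm` random permutations of
#'    the residuals within rows;
#' 4. every protein's residual vector (complete or not) is projected onto
#'    the significant right-singular vectors over its observed cells and
#'    the projection subtracted;
#' 5. group means are re-added.
#'
#' With zero significant trends the input is returned unchanged, so true
#' group-mean differences are preserved exactly.
#'
#' @param x an [intensity_table()] with >= 2 groups of >= 2 samples.
#' @param groups optional group vector overriding the table annotation.
#' @param params parameters from [normalize_params()].
#' @param seed RNG seed for the permutation test.
#' @return The normalized `intensity_table` with attribute `n_trends`.
#' @export
eigenms_normalize <- function(x, groups = NULL,
                              params = normalize_params(), seed = 1L) {
  v <- values_of(x)
  g <- if (is.null(groups)) sample_groups(x) else
    stats::setNames(as.character(groups), colnames(v))
  g <- g[colnames(v)]
  tab <- table(g)
  if (length(tab) < 2L || any(tab < 2L))
    stop_stage("EigenMS requires >= 2 groups with >= 2 samples each",
               "insufficient-data", "normalization")
  s <- ncol(v)

  complete <- rowSums(is.na(v)) == 0L
  if (sum(complete) < s)
    stop_stage(sprintf("only %d complete-case proteins for %d samples",
                       sum(complete), s), "insufficient-data", "normalization")

  group_means <- function(m) {
    gm <- matrix(NA_real_, nrow(m), s, dimnames = dimnames(m))
    for (lev in names(tab)) {
      cols <- which(g == lev)
      mu <- rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
      gm[, cols] <- mu
    }
    gm
  }

  gm_all <- group_means(v)
  R_all <- v - gm_all
  Rc <- R_all[complete, , drop = FALSE]

  # observed singular values from the complete-case residuals
  cp <- crossprod(Rc)
  ev <- eigen(cp, symmetric = TRUE, only.values = TRUE)$values
  sv <- sqrt(pmax(ev, 0))

  # null distribution of the top singular value: residuals permuted
  # independently within each row, and within each group's block of
  # samples — group-mean centering constrains every row-group block to
  # sum to zero, and a permutation that mixed blocks would break that
  # structure and make the test anti-conservative
  pc <- nrow(Rc)
  col_ord <- order(g, method = "radix")
  g_sizes <- as.integer(tab[unique(g[col_ord])])
  Rc_ord <- Rc[, col_ord, drop = FALSE]
  block <- rep(seq_len(pc), times = s) +
    pc * (rep(seq_along(g_sizes), times = g_sizes * pc) - 1L)
  block_rows <- rep(g_sizes, each = pc)  # elements per (row, group) block
  null_top <- withr::with_seed(seed, {
    vapply(seq_len(params$eigenms_n_perm), function(b) {
      o <- order(block, stats::runif(pc * s), method = "radix")
      # blocks come back ordered (group, row); stack each group's p
      # blocks as an n_g x p slab -> an s x p version of the permuted
      # matrix, which shares its singular values
      Bt <- matrix(0, s, pc)
      off <- 0L
      r0 <- 0L
      for (gi in seq_along(g_sizes)) {
        n_g <- g_sizes[gi]
        Bt[(r0 + 1L):(r0 + n_g), ] <- matrix(Rc_ord[o[(off + 1L):(off + n_g * pc)]],
                                             nrow = n_g)
        off <- off + n_g * pc
        r0 <- r0 + n_g
      }
      sqrt(max(eigen(tcrossprod(Bt), symmetric = TRUE,
                     only.values = TRUE)$values))
    }, numeric(1))
  })
  threshold <- stats::quantile(null_top, 1 - params$eigenms_alpha,
                               names = FALSE)
  n_trends <- match(FALSE, sv > threshold, nomatch = length(sv) + 1L) - 1L

  if (n_trends == 0L) {
    out <- x
    attr(out, "n_trends") <- 0L
    return(out)
  }

  V <- svd(Rc, nu = 0, nv = n_trends)$v  # s x t orthonormal trend basis
  out_v <- v
  # complete rows: orthonormal projection, vectorized
  proj <- (R_all[complete, , drop = FALSE] %*% V) %*% t(V)
  out_v[complete, ] <- v[complete, , drop = FALSE] - proj
  # incomplete rows: least-squares projection over observed cells
  for (i in which(!complete)) {
    o <- which(!is.na(v[i, ]))
    if (length(o) <= n_trends) next  # too few cells to project safely
    r <- R_all[i, o]
    Vo <- V[o, , drop = FALSE]
    beta <- tryCatch(qr.solve(Vo, r), error = function(e) NULL)
    if (is.null(beta)) next
    out_v[i, o] <- v[i, o] - as.vector(Vo %*% beta)
  }
  out <- set_values(x, out_v)
  attr(out, "n_trends") <- n_trends
  out
}
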