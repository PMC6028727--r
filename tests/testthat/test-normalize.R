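test_that("TIC matches the hand-computed oracle", {
  it <- it_fix(matrix(c(1, 3, 2, 6), 2, 2), groups = c("A", "A"))
  out <- apply_normalization(it, "TIC")
  expect_equal(unclass(out)[, ], matrix(c(1.5, 4.5, 1.5, 4.5), 2, 2),
               ignore_attr = TRUE)
  expect_equal(colSums(unclass(out)), c(s1 = 6, s2 = 6))
})

test_that("location methods equalize their per-column statistic", {
  it <- random_table(p = 1000, s = 20, seed = 5)
  v_med <- unclass(apply_normalization(it, "MED"))
  med <- apply(v_med, 2, median)
  expect_lt(diff(range(med)) / med[1], 1e-12)
  v_mea <- unclass(apply_normalization(it, "MEA"))
  expect_lt(diff(range(colMeans(v_mea))) / mean(v_mea), 1e-12)
  v_tic <- unclass(apply_normalization(it, "TIC"))
  cs <- colSums(v_tic)
  expect_lt(diff(range(cs)) / cs[1], 1e-12)
})

test_that("Z-score and auto scaling standardize columns and rows", {
  it <- random_table(p = 1000, s = 20, seed = 6)
  z <- unclass(apply_normalization(it, "ZSC"))
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-12))
  a <- unclass(apply_normalization(it, "AUT"))
  expect_true(all(abs(rowMeans(a)) < 1e-12))
  expect_true(all(abs(apply(a, 1, sd) - 1) < 1e-12))
  p <- unclass(apply_normalization(it, "PAR"))
  rsd <- apply(unclass(it), 1, sd)
  expect_equal(apply(p, 1, sd), sqrt(rsd), tolerance = 1e-12)
})

test_that("degenerate column scales fail as stage errors", {
  m <- matrix(c(1, 1, 1, 2, 3, 4), 3, 2)  # first column constant
  it <- it_fix(m, groups = c("A", "A"))
  for (code in c("ZSC", "MAD")) {
    err <- tryCatch(apply_normalization(it, code), condition = identity)
    expect_s3_class(err, "pmadbench_degenerate_scale")
    expect_identical(err$stage, "normalization")
  }
})

test_that("quantile normalization matches the rank-mean oracle", {
  it <- it_fix(matrix(c(2, 6, 4, 8), 2, 2), groups = c("A", "A"))
  out <- unclass(apply_normalization(it, "QUA"))
  expect_equal(out, matrix(c(3, 7, 3, 7), 2, 2), ignore_attr = TRUE)
})

test_that("quantile normalization equalizes sorted columns and agrees with limma", {
  skip_if_not_installed("limma")
  it <- random_table(p = 1000, s = 20, seed = 7)
  out <- unclass(apply_normalization(it, "QUA"))
  sorted <- apply(out, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  ref <- limma::normalizeQuantiles(unclass(it))
  expect_equal(out, ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("quantile normalization handles missing values on a common grid", {
  it <- random_table(p = 500, s = 8, missing = 0.2, seed = 8)
  out <- unclass(apply_normalization(it, "QUA"))
  expect_identical(is.na(out), is.na(unclass(it)))
  # complete columns of the output share identical sorted values
  full <- which(colSums(is.na(out)) == 0)
  if (length(full) >= 2) {
    sorted <- apply(out[, full, drop = FALSE], 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-10))
  }
})

test_that("every per-sample method commutes with sample reordering", {
  it <- random_table(p = 200, s = 6, missing = 0.1, seed = 9)
  perm <- c(4, 1, 6, 2, 5, 3)
  permute <- function(x, perm) {
    v <- unclass(x)[, perm]
    intensity_table(v, groups = sample_groups(x)[perm])
  }
  for (code in c("MEA", "MED", "TIC", "ZSC", "MAD", "QUA", "PQN", "AUT",
                 "PAR")) {
    a <- vals(apply_normalization(permute(it, perm), code))
    b <- vals(apply_normalization(it, code))[, perm]
    expect_equal(a, b, tolerance = 1e-12, label = code)
  }
})

test_that("PQN removes per-sample dilution exactly in the pure-scaling case", {
  withr::with_seed(10, {
    base <- exp(rnorm(300, 6, 1))
    m <- cbind(base * 0.5, base, base * 2, base * 1.3)
    it <- it_fix(m, groups = c("A", "A", "B", "B"))
    out <- unclass(apply_normalization(it, "PQN"))
    expect_true(all(abs(out - out[, 1]) < 1e-9))
  })
})

test_that("TMM recovers pure scaling factors and matches a tiny trimming oracle", {
  withr::with_seed(11, {
    base <- exp(rnorm(100, 6, 1))
    it <- it_fix(cbind(base, 2 * base), groups = c("A", "A"))
    f <- tmm_factors(it)
    expect_equal(unname(f[2] / f[1]), 2, tolerance = 1e-12)
    norm <- unclass(apply_normalization(it, "TMM"))
    expect_equal(norm[, 1], norm[, 2], tolerance = 1e-12)

    ident <- it_fix(cbind(base, base, base), groups = c("A", "A", "A"))
    expect_equal(unname(tmm_factors(ident)), c(1, 1, 1), tolerance = 1e-12)
  })

  # oracle: direct exhaustive-trim reimplementation on a 50-protein table
  withr::with_seed(12, {
    base <- exp(rnorm(50, 6, 1))
    m <- cbind(base, base * 1.5)
    m[1:5, 2] <- m[1:5, 2] * 10  # 10% outlier proteins in one sample
    it <- it_fix(m, groups = c("A", "A"))
    prm <- normalize_params()
    uq <- apply(m, 2, quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
    j <- setdiff(1:2, ref)
    M <- log2(m[, j] / m[, ref]); A <- 0.5 * log2(m[, j] * m[, ref])
    n <- length(M)
    loM <- floor(n * prm$tmm_trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * prm$tmm_trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M, ties.method = "first") >= loM &
      rank(M, ties.method = "first") <= hiM &
      rank(A, ties.method = "first") >= loA &
      rank(A, ties.method = "first") <= hiA
    cs <- colSums(m)
    w <- 1 / ((cs[j] - m[keep, j]) / (cs[j] * m[keep, j]) +
                (cs[ref] - m[keep, ref]) / (cs[ref] * m[keep, ref]))
    f_raw <- c(1, 2^(sum(w * M[keep]) / sum(w)))[order(c(ref, j))]
    f_oracle <- f_raw / exp(mean(log(f_raw)))
    expect_equal(unname(tmm_factors(it)), unname(f_oracle),
                 tolerance = 0.02)
  })
})

test_that("regression normalizations leave identical columns unchanged", {
  withr::with_seed(13, {
    base <- rnorm(300, 10, 2)
    it <- it_fix(cbind(base, base), groups = c("A", "A"))
    for (code in c("CYC", "LOW", "RLR")) {
      out <- vals(apply_normalization(it, code))
      expect_equal(out, vals(it), tolerance = 1e-9, label = code)
    }
  })
})

test_that("robust linear regression removes a constant offset", {
  withr::with_seed(14, {
    base <- rnorm(400, 10, 2)
    it <- it_fix(cbind(base, base + 3), groups = c("A", "A"))
    out <- unclass(apply_normalization(it, "RLR"))
    expect_lt(max(abs(out[, 2] - out[, 1])), 1e-6)
  })
})

test_that("cyclic loess shrinks an intensity-dependent bow", {
  withr::with_seed(15, {
    a <- rnorm(500, 10, 2)
    a_scaled <- (a - mean(a)) / sd(a)
    b <- a + 0.5 * a_scaled + rnorm(500, 0, 0.05)
    it <- it_fix(cbind(a, b), groups = c("A", "A"))
    out <- unclass(apply_normalization(it, "CYC"))
    expect_lt(mean(abs(out[, 1] - out[, 2])),
              mean(abs(a - b)))
  })
})

test_that("pairs with too few co-observed proteins are skipped or fatal", {
  m <- matrix(rnorm(40), 20, 2)
  m[1:15, 2] <- NA  # only 5 co-observed
  it <- it_fix(m, groups = c("A", "A"))
  expect_error(suppressWarnings(apply_normalization(it, "CYC")),
               class = "pmadbench_insufficient_overlap")
})

test_that("VSN equalizes a pure scaling difference and is concave", {
  withr::with_seed(16, {
    base <- exp(rnorm(300, 6, 1))
    it <- it_fix(cbind(base, 3 * base), groups = c("A", "A"))
    h <- vsn_normalize(it)
    expect_lt(max(abs(unclass(h)[, 2] - unclass(h)[, 1])), 1e-3)
    b <- attr(h, "vsn_coefficients")[, "b"]
    expect_true(all(b > 0))

    ident <- it_fix(cbind(base, base), groups = c("A", "A"))
    hi <- vsn_normalize(ident)
    expect_equal(unclass(hi)[, 1], unclass(hi)[, 2], tolerance = 1e-9)
    bb <- attr(hi, "vsn_coefficients")[, "b"]
    expect_equal(bb[1], bb[2], tolerance = 1e-6, ignore_attr = TRUE)

    # arsinh grows logarithmically: concave over an equally spaced grid
    # of large inputs (where the calibrated argument is positive)
    a1 <- attr(h, "vsn_coefficients")[1, "a"]
    b1 <- attr(h, "vsn_coefficients")[1, "b"]
    grid <- seq(2 * (1 - a1) / b1, 20 * (1 - a1) / b1, length.out = 50)
    hx <- asinh(a1 + b1 * grid)
    expect_true(all(diff(diff(hx)) < 0))
  })
})

test_that("normalization requires at least two samples", {
  it <- it_fix(matrix(1:5 * 1.0, ncol = 1), groups = "A")
  expect_error(apply_normalization(it, "MED"),
               class = "pmadbench_insufficient_data")
})
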