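test_that("simple substitution rules match their definitions", {
  m <- rbind(c(4, 8, NA),
             c(5, NA, 2))
  it <- it_fix(m, groups = c("A", "A", "A"))
  z <- unclass(apply_imputation(it, "ZER"))
  expect_identical(z[1, 3], 0)
  expect_identical(z[2, 2], 0)
  expect_identical(z[1, 1], 4)  # observed cells untouched

  cen <- unclass(apply_imputation(it, "CEN"))
  expect_identical(cen[1, 3], 2)  # observed {4, 8} -> half-minimum 2
  expect_identical(cen[2, 2], 1)  # observed {5, 2} -> half-minimum 1

  # fully missing protein falls back to half the matrix minimum
  m2 <- rbind(m, c(NA, NA, NA))
  it2 <- it_fix(m2, groups = c("A", "A", "A"))
  cen2 <- unclass(apply_imputation(it2, "CEN"))
  expect_identical(unname(cen2[3, ]), rep(min(m, na.rm = TRUE) / 2, 3))
})

test_that("background imputation uses a low per-sample quantile", {
  withr::with_seed(30, {
    m <- matrix(exp(rnorm(3000, 6, 1)), 1000, 3)
    m[1, 2] <- NA
    it <- it_fix(m, groups = c("A", "A", "A"))
    out <- unclass(apply_imputation(it, "BAK"))
    expect_equal(out[1, 2],
                 quantile(m[-1, 2], 0.01, names = FALSE),
                 tolerance = 1e-6)
    expect_lt(out[1, 2], quantile(m[-1, 2], 0.02))
  })
})

test_that("KNN copies a zero-distance neighbour and averages equidistant ones", {
  # target row identical to a complete row on all co-observed cells, k = 1
  m <- rbind(c(1, 2, 3, NA),
             c(1, 2, 3, 9),
             c(50, 60, 70, 80),
             c(5, 5, 5, 5))
  it <- it_fix(m, groups = c("A", "A", "B", "B"))
  out <- unclass(apply_imputation(it, "KNN", impute_params(knn_k = 1)))
  expect_identical(out[1, 4], 9)

  # three equidistant neighbours holding {2, 4, 6}
  m2 <- rbind(c(0, 10, NA),
              c(3, 10, 2),
              c(-3, 10, 4),
              c(0, 13, 6),
              c(100, 200, 300))
  it2 <- it_fix(m2, groups = c("A", "A", "A"))
  out2 <- unclass(apply_imputation(it2, "KNN", impute_params(knn_k = 3)))
  expect_equal(out2[1, 3], 4)
})

test_that("KNN recovers planted rank-1 structure from MCAR holes", {
  withr::with_seed(31, {
    pattern <- exp(rnorm(10, 0, 0.5))
    coef <- runif(400, 0.5, 2)
    m <- outer(coef, pattern)
    holes <- matrix(runif(length(m)) < 0.05, nrow(m))
    mm <- m; mm[holes] <- NA
    it <- it_fix(mm, groups = rep(c("A", "B"), each = 5))
    out <- unclass(apply_imputation(it, "KNN"))
    rmse <- sqrt(mean((out[holes] - m[holes])^2))
    expect_lt(rmse, 0.05 * sd(m))
  })
})

test_that("rank-1 completion is exact for SVD and BPC", {
  pattern <- c(1, 2, 4, 8)
  coef <- c(3, 5, 7, 11, 13)
  m <- outer(coef, pattern)
  m[2, 3] <- NA
  it <- it_fix(m, groups = c("A", "A", "B", "B"))
  for (method in c("SVD", "BPC")) {
    out <- unclass(apply_imputation(it, method,
                                    impute_params(n_components = 1,
                                                  max_iter = 500,
                                                  tol = 1e-10)))
    expect_lt(abs(out[2, 3] - 5 * 4), 1e-6)
  }
})

test_that("ARD shrinkage finds the true rank of noisy low-rank data", {
  hits <- 0L
  for (seed in 1:10) {
    withr::with_seed(seed, {
      W <- matrix(rnorm(8 * 2), 8, 2)
      Z <- matrix(rnorm(300 * 2), 300, 2)
      m <- Z %*% t(W) * 3 + matrix(rnorm(300 * 8, 0, 0.1), 300, 8)
      m[matrix(runif(length(m)) < 0.05, 300)] <- NA
      it <- it_fix(m, groups = rep(c("A", "B"), each = 4))
      # tight tolerance lets the ARD scales reach their fixed point
      out <- apply_imputation(it, "BPC",
                              impute_params(n_components = 5, tol = 1e-6))
      if (identical(attr(out, "effective_rank"), 2L)) hits <- hits + 1L
    })
  }
  expect_gte(hits, 9L)
})

test_that("observed cells are never modified and no missing cells remain", {
  it <- random_table(p = 60, s = 8, missing = 0.15, seed = 32)
  obs <- !missing_mask(it)
  for (code in c("ZER", "BAK", "CEN", "KNN", "SVD", "BPC")) {
    out <- apply_imputation(it, code)
    expect_identical(unclass(out)[obs], unclass(it)[obs], label = code)
    expect_false(anyNA(unclass(out)), label = code)
  }
  non <- apply_imputation(it, "NON")
  expect_identical(unclass(non)[, ], unclass(it)[, ])
})

test_that("a sample with no observed values is an imputation failure", {
  m <- matrix(c(1, 2, NA, NA, 3, 4), 3, 2)
  m[, 2] <- NA
  it <- it_fix(m, groups = c("A", "A"))
  err <- tryCatch(apply_imputation(it, "ZER"), condition = identity)
  expect_s3_class(err, "pmadbench_insufficient_data")
  expect_identical(err$stage, "imputation")
})
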