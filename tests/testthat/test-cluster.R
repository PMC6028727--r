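test_that("performance matrix keeps only complete vectors", {
  a <- tibble::tibble(
    dataset_id = rep(c("D1", "D2"), each = 8),
    chain = rep(paste0("C", 1:8), 2),
    pmad = c(runif(8, 0.1, 0.5), c(runif(6, 0.1, 0.5), NA, NA)),
    failure_stage = c(rep(NA, 14), "imputation", "normalization"),
    failure_class = c(rep(NA, 14), "non-convergence", "degenerate-scale"))
  pm <- performance_matrix(a)
  expect_identical(dim(pm$matrix), c(6L, 2L))
  expect_identical(sort(pm$excluded$chain), c("C7", "C8"))
  expect_identical(nrow(pm$matrix) + nrow(pm$excluded), 8L)
  expect_error(performance_matrix(a[a$dataset_id == "D1", ]),
               class = "pmadbench_validation_error")
})

test_that("Euclidean distance follows the summation formula", {
  expect_identical(chain_distance(c(0, 0), c(3, 4)), 5)
  expect_identical(chain_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  withr::with_seed(60, {
    for (i in 1:10) {
      a <- rnorm(7); b <- rnorm(7)
      manual <- 0
      for (k in 1:7) manual <- manual + (a[k] - b[k])^2
      expect_equal(chain_distance(a, b), sqrt(manual), tolerance = 1e-12)
    }
  })
  expect_error(chain_distance(1:3, 1:4), class = "pmadbench_validation_error")
  expect_error(chain_distance(c(1, NA), c(1, 2)),
               class = "pmadbench_validation_error")
})

test_that("Ward merges match the exhaustive variance-increase oracle", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      X <- matrix(rnorm(n * 7), n, 7)
      rownames(X) <- paste0("C", seq_len(n))
      tree <- ward_cluster(X, distance_space = "raw")
      oracle <- ward_oracle(X)
      for (k in 2:(n - 1)) {
        expect_identical(cutree_partition(tree, k),
                         canon_partition(oracle$partitions[[n - k]]))
      }
      expect_equal(sort(tree$height), sort(sqrt(2 * oracle$increases)),
                   tolerance = 1e-9)
      expect_true(all(diff(tree$height) > -1e-12))
    }
  })
})

test_that("clear cluster structure is recovered at the right cut", {
  withr::with_seed(62, {
    triad1 <- matrix(rnorm(3 * 2, 0, 0.1), 3, 2)
    triad2 <- matrix(rnorm(3 * 2, 100, 0.1), 3, 2)
    X <- rbind(triad1, triad2)
    rownames(X) <- paste0("C", 1:6)
    tree <- ward_cluster(X, distance_space = "raw")
    p <- cutree_partition(tree, 2)
    expect_identical(p, canon_partition(list(1:3, 4:6)))
  })
})

test_that("partitions are named best to worst by mean log10 PMAD", {
  withr::with_seed(63, {
    m <- rbind(matrix(10^runif(12, -3, -2), 6, 2),   # best chains
               matrix(10^runif(12, 0, 1), 6, 2),     # middling
               matrix(10^runif(12, 3, 4), 6, 2))     # worst
    rownames(m) <- paste0("C", 1:18)
    colnames(m) <- c("D1", "D2")
    tree <- ward_cluster(m)
    parts <- cut_partitions(tree, k = 3, pmad_matrix = m)
    lab <- parts$labels
    expect_identical(unname(as.character(lab[paste0("C", 1:6)])),
                     rep("P1", 6))
    expect_identical(unname(as.character(lab[paste0("C", 13:18)])),
                     rep("P3", 6))
    expect_identical(sum(parts$partition_summary$n_chains), 18L)

    parts6 <- cut_partitions(tree, k = 6, pmad_matrix = m)
    expect_identical(levels(parts6$labels),
                     c("A1", "A2", "A3", "B", "C", "D"))
    expect_identical(length(cut_partitions(tree, k = 18)$labels), 18L)
    expect_error(cut_partitions(tree, k = 1),
                 class = "pmadbench_validation_error")
  })
})

test_that("CWPAC flags follow the strict and partition rules", {
  pmads <- tibble::tibble(
    dataset_id = rep(c("D1", "D2", "D3"), each = 4),
    chain = rep(c("W1", "W2", "B1", "B2"), 3),
    pmad = c(0.1, 0.2, 5, 6,
             0.2, 0.9, 7, 8,
             0.05, 0.3, 9, 10),
    failure_stage = NA_character_, failure_class = NA_character_)
  m <- matrix(pmads$pmad, 4)[, ]
  dimnames(m) <- list(c("W1", "W2", "B1", "B2"), c("D1", "D2", "D3"))
  tree <- ward_cluster(m)
  parts <- cut_partitions(tree, k = 2, pmad_matrix = m)
  cw <- identify_cwpacs(parts, pmads)
  cw <- cw[match(c("W1", "W2", "B1", "B2"), cw$chain), ]
  expect_identical(cw$strict, c(TRUE, FALSE, FALSE, FALSE))
  # W-partition: 5/6 PMADs <= 0.7 -> 0.833 < 0.9 default
  expect_identical(cw$partition_based, c(FALSE, FALSE, FALSE, FALSE))
  cw2 <- identify_cwpacs(parts, pmads, partition_frac = 0.8)
  cw2 <- cw2[match(c("W1", "W2"), cw2$chain), ]
  expect_identical(cw2$partition_based, c(TRUE, TRUE))
})

test_that("method contributions count per category and sum to 100", {
  contrib <- method_contribution(c("LOG-TIC-ZER", "LOG-MED-ZER"))
  tr <- contrib[contrib$category == "transformation", ]
  expect_identical(tr$code, "LOG")
  expect_identical(tr$percentage, 100)
  no <- contrib[contrib$category == "normalization", ]
  expect_setequal(no$percentage, c(50, 50))
  for (cat_ in unique(contrib$category))
    expect_equal(sum(contrib$percentage[contrib$category == cat_]), 100,
                 tolerance = 1e-9)
  single <- method_contribution("POW-TMM-ZER")
  expect_true(all(single$percentage == 100))
  expect_error(method_contribution(character(0)),
               class = "pmadbench_validation_error")
})

test_that("dendrogram exports as readable Newick with chain labels", {
  withr::with_seed(64, {
    m <- matrix(10^rnorm(20), 10, 2,
                dimnames = list(paste0("LOG-ME", 1:10), c("D1", "D2")))
    tree <- ward_cluster(m)
    f <- withr::local_tempfile(fileext = ".nwk")
    export_newick(tree, f)
    phy <- ape::read.tree(f)
    expect_setequal(phy$tip.label, rownames(m))
  })
})

test_that("tidy and glance summarize partitions", {
  withr::with_seed(65, {
    m <- matrix(10^runif(24, -2, 2), 12, 2,
                dimnames = list(paste0("C", 1:12), c("D1", "D2")))
    parts <- cut_partitions(ward_cluster(m), k = 3, pmad_matrix = m)
    td <- tidy(parts)
    expect_identical(nrow(td), 12L)
    expect_setequal(td$chain, rownames(m))
    gl <- glance(parts)
    expect_identical(gl$k, 3)
    expect_identical(gl$n_chains, 12L)
  })
})
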