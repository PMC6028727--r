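# Small fixtures and independent oracles shared across test files.

# quick two-group intensity table from a matrix; ids always regenerated
it_fix <- function(m, groups = NULL, ...) {
  dimnames(m) <- list(paste0("P", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  if (is.null(groups))
    groups <- rep(c("A", "B"), length.out = ncol(m))
  intensity_table(m, groups = groups, ...)
}

# bare value matrix without table attributes, for exact comparisons
vals <- function(x) {
  v <- unclass(x)
  attr(v, "groups") <- NULL
  attr(v, "dataset_id") <- NULL
  v
}

# random positive table with optional missingness, fixed seed
random_table <- function(p = 50, s = 6, missing = 0, seed = 42,
                         groups = rep(c("A", "B"), each = s / 2)) {
  withr::with_seed(seed, {
    m <- matrix(exp(rnorm(p * s, 6, 1)), p, s)
    if (missing > 0) m[runif(p * s) < missing] <- NA
    it_fix(m, groups = groups)
  })
}

# brute-force Ward clustering: at every step recompute the within-cluster
# variance (ESS) increase of every candidate merge and take the minimum.
# Returns the partition (set of sets) after each merge and the per-step
# ESS increases.
ward_oracle <- function(X) {
  n <- nrow(X)
  ess <- function(idx) {
    if (length(idx) == 1L) return(0)
    sub <- X[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  cur <- lapply(seq_len(n), identity)
  partitions <- list()
  increases <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- NULL
    best_inc <- Inf
    for (ai in seq_along(cur)) for (bi in seq_along(cur)) if (ai < bi) {
      inc <- ess(c(cur[[ai]], cur[[bi]])) - ess(cur[[ai]]) - ess(cur[[bi]])
      if (inc < best_inc - 1e-12) {
        best_inc <- inc
        best <- c(ai, bi)
      }
    }
    cur[[best[1]]] <- c(cur[[best[1]]], cur[[best[2]]])
    cur[[best[2]]] <- NULL
    increases[step] <- best_inc
    partitions[[step]] <- lapply(cur, sort)
  }
  list(partitions = partitions, increases = increases)
}

# canonical form of a partition (set of sets) for comparison
canon_partition <- function(sets) {
  s <- lapply(sets, sort)
  s[order(vapply(s, `[`, numeric(1), 1))]
}

# partition of 1..n induced by cutree at k, as set of sets
cutree_partition <- function(tree, k) {
  cl <- stats::cutree(tree, k = k)
  canon_partition(unname(split(seq_along(cl), cl)))
}
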