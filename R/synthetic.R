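#' Ground-truth parameters for a synthetic SWATH-like dataset
#'
#' Describes a two-group (or multi-group) label-free intensity matrix the
#' way the benchmark's real datasets are structured: log-normal protein
#' abundances, per-sample multiplicative scaling biases (total-ion-current
#' variation), additive Gaussian noise on the log scale, a fraction of
#' truly differential proteins, and a mixture of intensity-dependent
#' (MNAR, logistic in log intensity) and completely random (MCAR)
#' missingness.
#'
#' @param n_proteins number of proteins.
#' @param group_sizes named integer vector, replicates per group (each
#'   >= 2).
#' @param base_mean,base_sd mean and sd of per-protein true log
#'   (natural) intensities.
#' @param scale_range range of per-sample multiplicative biases; scales
#'   are drawn log-uniformly from it.
#' @param noise_sd additive noise sd on the log scale.
#' @param frac_differential fraction of proteins with a between-group
#'   log-fold-change.
#' @param effect_size that log-fold-change (natural-log units).
#' @param mnar_steepness,mnar_midpoint logistic missingness parameters on
#'   log intensity; steepness 0 disables MNAR.
#' @param mcar_rate uniform missingness probability.
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(n_proteins = 1000,
                            group_sizes = c(A = 5L, B = 5L),
                            base_mean = 14, base_sd = 2,
                            scale_range = c(0.5, 2),
                            noise_sd = 0.1,
                            frac_differential = 0.1,
                            effect_size = 1,
                            mnar_steepness = 0.8,
                            mnar_midpoint = 11.5,
                            mcar_rate = 0.02,
                            seed = 1L) {
  if (any(group_sizes < 2L))
    stop_validation("every group needs at least 2 replicates")
  for (r in c(frac_differential, mcar_rate))
    if (r < 0 || r > 1) stop_validation("rates must lie in [0, 1]")
  if (any(scale_range <= 0)) stop_validation("sample scales must be positive")
  if (noise_sd < 0 || mnar_steepness < 0)
    stop_validation("noise_sd and mnar_steepness must be nonnegative")
  structure(list(
    n_proteins = as.integer(n_proteins), group_sizes = group_sizes,
    base_mean = base_mean, base_sd = base_sd, scale_range = scale_range,
    noise_sd = noise_sd, frac_differential = frac_differential,
    effect_size = effect_size, mnar_steepness = mnar_steepness,
    mnar_midpoint = mnar_midpoint, mcar_rate = mcar_rate,
    seed = as.integer(seed)), class = "synthetic_truth")
}

#' Generate a synthetic intensity dataset with known ground truth
#'
#' Raw-scale intensities are
#' `x_ij = exp(base_i + effect_i * 1[group(j) = last group] + log(scale_j) + eps_ij)`
#' with `eps_ij ~ Normal(0, noise_sd^2)`. Each cell is then set missing
#' with probability
#' `mcar_rate + (1 - mcar_rate) * plogis(-steepness * (log x_ij - midpoint))`.
#'
#' @param truth a [synthetic_truth()].
#' @param dataset_id identifier attached to the table.
#' @return A list with elements `table` (the [intensity_table()]) and
#'   `truth` (the input, augmented with the realized `base_abundance`,
#'   `sample_scale`, `differential` flags and `true_matrix`).
#' @export
generate_dataset <- function(truth = synthetic_truth(), dataset_id = "D1") {
  stopifnot(inherits(truth, "synthetic_truth"))
  withr::with_seed(truth$seed, {
    p <- truth$n_proteins
    gs <- truth$group_sizes
    if (is.null(names(gs))) names(gs) <- LETTERS[seq_along(gs)]
    groups <- rep(names(gs), times = gs)
    s <- length(groups)
    sample_ids <- paste0("s", seq_len(s))

    base <- stats::rnorm(p, truth$base_mean, truth$base_sd)
    diff_idx <- seq_len(floor(truth$frac_differential * p))
    effect <- numeric(p)
    effect[diff_idx] <- truth$effect_size
    scale_j <- exp(stats::runif(s, log(truth$scale_range[1]),
                                log(truth$scale_range[2])))
    in_last <- as.numeric(groups == names(gs)[length(gs)])

    log_x <- outer(base, rep(1, s)) +
      outer(effect, in_last) +
      matrix(log(scale_j), p, s, byrow = TRUE) +
      matrix(stats::rnorm(p * s, 0, truth$noise_sd), p, s)
    x <- exp(log_x)

    p_mnar <- if (truth$mnar_steepness > 0)
      stats::plogis(-truth$mnar_steepness * (log_x - truth$mnar_midpoint))
    else matrix(0, p, s)
    p_miss <- truth$mcar_rate + (1 - truth$mcar_rate) * p_mnar
    x[matrix(stats::runif(p * s), p, s) < p_miss] <- NA_real_

    dimnames(x) <- list(paste0("P", seq_len(p)), sample_ids)
    tbl <- intensity_table(x, groups = stats::setNames(groups, sample_ids),
                           dataset_id = dataset_id)
    truth$base_abundance <- base
    truth$sample_scale <- stats::setNames(scale_j, sample_ids)
    truth$differential <- seq_len(p) %in% diff_idx
    truth$true_matrix <- exp(log_x)
    list(table = tbl, truth = truth)
  })
}

#' Generate a multi-dataset benchmark suite
#'
#' Returns `n_datasets` synthetic tables with heterogeneous group sizes
#' and per-sample biases. The default profile mimics the benchmark's
#' seven two-group datasets with total sample counts
#' 6, 12, 20, 36, 36, 40 and 116 (3 to 58 replicates per group).
#'
#' @param n_datasets number of datasets (>= 2; performance vectors need
#'   at least 2 dimensions).
#' @param truths optional list of [synthetic_truth()] objects, one per
#'   dataset, overriding the default profile.
#' @param n_proteins,noise_sd,scale_range,seed convenience overrides
#'   applied to the default profile.
#' @return Named list of [intensity_table()]s (`"D1"`, `"D2"`, ...), with
#'   the matching truths in attribute `truths`.
#' @export
generate_benchmark_suite <- function(n_datasets = 7, truths = NULL,
                                     n_proteins = 1000, noise_sd = 0.1,
                                     scale_range = c(0.5, 2), seed = 1L) {
  if (n_datasets < 2L)
    stop_validation("a benchmark suite needs at least 2 datasets")
  if (is.null(truths)) {
    default_groups <- list(
      c(A = 3L, B = 3L), c(A = 6L, B = 6L), c(A = 10L, B = 10L),
      c(A = 18L, B = 18L), c(A = 18L, B = 18L), c(A = 20L, B = 20L),
      c(A = 58L, B = 58L))
    gs <- rep(default_groups, length.out = n_datasets)
    truths <- lapply(seq_len(n_datasets), function(d)
      synthetic_truth(n_proteins = n_proteins, group_sizes = gs[[d]],
                      noise_sd = noise_sd, scale_range = scale_range,
                      seed = derive_seed(seed, "dataset", d)))
  }
  if (length(truths) != n_datasets)
    stop_validation("need one truth per dataset")
  ids <- paste0("D", seq_len(n_datasets))
  gen <- purrr::map2(truths, ids, generate_dataset)
  out <- stats::setNames(purrr::map(gen, "table"), ids)
  attr(out, "truths") <- stats::setNames(purrr::map(gen, "truth"), ids)
  out
}
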