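#' Pooled intragroup median absolute deviation (PMAD)
#'
#' The precision metric of the benchmark: for each group `g` with at
#' least 2 samples and each protein `i` with at least 2 observed
#' replicate values in `g`,
#' `MAD_ig = median_j | x_ij - median_j'(x_ij') |` over the observed
#' replicates `j` in `g` (raw MAD — no 1.4826 consistency factor). The
#' group score is the mean of `MAD_ig` over eligible proteins, and PMAD
#' is the mean of the group scores. Lower PMAD means less variation among
#' replicates, i.e. better technical precision. PMAD is computed on the
#' chain's own output scale; no back-transformation is applied.
#'
#' @param x an [intensity_table()]; at least one group must have >= 2
#'   samples and contain a protein with >= 2 observed values.
#' @return Nonnegative scalar.
#' @examples
#' m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("P1", c("a", "b", "c")))
#' compute_pmad(intensity_table(m, groups = c("G", "G", "G")))  # 1
#' @export
compute_pmad <- function(x) {
  stopifnot(inherits(x, "intensity_table"))
  v <- values_of(x)
  g <- sample_groups(x)
  tab <- table(g)
  use_groups <- names(tab)[tab >= 2L]
  if (!length(use_groups))
    stop_stage("PMAD needs at least one group with >= 2 samples",
               "assessment-error", "assessment")
  scores <- numeric(0)
  for (lev in use_groups) {
    sub <- v[, g == lev, drop = FALSE]
    n_i <- row_n_obs(sub)
    eligible <- n_i >= 2L
    if (!any(eligible)) next
    mads <- row_mads(sub[eligible, , drop = FALSE])
    scores <- c(scores, mean(mads))
  }
  if (!length(scores))
    stop_stage("no protein has >= 2 observed replicates in any group",
               "assessment-error", "assessment")
  mean(scores)
}

#' Precision category from a PMAD value
#'
#' The conventional cutoffs: `<= 0.3` superior, `> 0.3 & <= 0.7` good,
#' `> 0.7` poor; an unavailable PMAD (failed chain) maps to `failed`.
#'
#' @param pmad numeric vector of PMAD values (`NA` = unavailable).
#' @return Factor with levels `superior`, `good`, `poor`, `failed`.
#' @examples
#' classify_precision(c(0.25, 0.7, 0.700001, NA))
#' @export
classify_precision <- function(pmad) {
  if (any(!is.na(pmad) & pmad < 0))
    rlang::abort("negative PMAD", class = "pmadbench_internal_error")
  out <- dplyr::case_when(
    is.na(pmad) ~ "failed",
    pmad <= 0.3 ~ "superior",
    pmad <= 0.7 ~ "good",
    TRUE ~ "poor")
  factor(out, levels = c("superior", "good", "poor", "failed"))
}

#' Assess and rank swept chains
#'
#' Adds `log10_pmad`, the precision `category` and the per-dataset `rank`
#' (1 = smallest PMAD; ascending PMAD, ties broken by chain label; failed
#' chains are unranked) to a sweep result.
#'
#' @param sweep_result `chain_sweep` tibble from [sweep_chains()].
#' @return An assessment tibble (class `chain_assessment`).
#' @export
assess_chains <- function(sweep_result) {
  out <- dplyr::mutate(
    dplyr::group_by(tibble::as_tibble(sweep_result), .data$dataset_id),
    log10_pmad = log10(.data$pmad),
    category = classify_precision(.data$pmad),
    rank = rank_available(.data$pmad, .data$chain))
  out <- dplyr::ungroup(out)
  class(out) <- c("chain_assessment", class(out))
  out
}

# ranks of available PMADs: ascending value, ties by chain label; NA for
# unavailable
rank_available <- function(pmad, chain) {
  r <- rep(NA_integer_, length(pmad))
  avail <- which(!is.na(pmad))
  o <- avail[order(pmad[avail], chain[avail], method = "radix")]
  r[o] <- seq_along(o)
  r
}

#' Rank the chains of one dataset
#'
#' @param assessments assessment rows for a single dataset (tibble with
#'   `chain` and `pmad`).
#' @return The tibble sorted ranked-first (failed chains listed last),
#'   with a `rank` column.
#' @export
rank_chains <- function(assessments) {
  stopifnot(length(unique(assessments$dataset_id)) <= 1L)
  if (all(is.na(assessments$pmad)))
    stop_stage("no available PMAD to rank", "assessment-error", "assessment")
  out <- dplyr::mutate(assessments,
                       rank = rank_available(.data$pmad, .data$chain))
  dplyr::arrange(out, is.na(.data$rank), .data$rank)
}
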