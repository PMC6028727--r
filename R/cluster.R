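#' Chain-by-dataset performance matrix
#'
#' Builds the clustering input: one row per chain whose PMAD is available
#' on every dataset (a complete performance vector); chains with at least
#' one unavailable value are excluded and listed with their failure
#' stages.
#'
#' @param assessments assessment tibble from [assess_chains()] (a plain
#'   sweep tibble also works).
#' @return List with `matrix` (chains x datasets PMAD matrix) and
#'   `excluded` (tibble: chain, datasets failed on, stages).
#' @export
performance_matrix <- function(assessments) {
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(assessments), "chain", "dataset_id",
                  "pmad"),
    names_from = "dataset_id", values_from = "pmad")
  if (ncol(wide) < 3L)
    stop_validation("performance vectors need at least 2 datasets")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$chain
  complete <- rowSums(is.na(m)) == 0L
  if (sum(complete) < 2L)
    stop_stage("fewer than 2 chains with complete performance vectors",
               "insufficient-data", "assessment")
  failed <- dplyr::filter(tibble::as_tibble(assessments),
                          !is.na(.data$failure_stage))
  excluded <- dplyr::summarise(
    dplyr::group_by(failed[failed$chain %in% rownames(m)[!complete], ],
                    .data$chain),
    datasets = paste(.data$dataset_id, collapse = ","),
    stages = paste(unique(.data$failure_stage), collapse = ","),
    .groups = "drop")
  # chains excluded for unscored (NA without failure) values still count
  excl_all <- tibble::tibble(chain = rownames(m)[!complete])
  excluded <- dplyr::left_join(excl_all, excluded, by = "chain")
  list(matrix = m[complete, , drop = FALSE], excluded = excluded)
}

#' Euclidean distance between two performance vectors
#'
#' `sqrt(sum_i (a_i - b_i)^2)` over the per-dataset PMAD entries.
#'
#' @param a,b complete numeric vectors of equal length.
#' @return Nonnegative scalar; zero iff `a == b`.
#' @export
chain_distance <- function(a, b) {
  if (length(a) != length(b))
    stop_validation("performance vectors differ in dimension")
  if (anyNA(a) || anyNA(b))
    stop_validation("performance vectors must be complete")
  sqrt(sum((a - b)^2))
}

#' Ward clustering of chain performance vectors
#'
#' Agglomerative clustering by the Lance-Williams recurrence with Ward
#' coefficients applied to Euclidean distances under the
#' squared-distance updating convention (`hclust` method `"ward.D2"`),
#' i.e. each merge minimizes the increase in total within-cluster
#' variance. Distances are computed on log10 PMAD by default, since raw
#' PMADs span many orders of magnitude and raw-space distances would be
#' dominated by the worst chains; zero PMADs are floored at `1e-16`
#' before taking logs.
#'
#' @param m chains x datasets PMAD matrix from [performance_matrix()].
#' @param distance_space `"log10"` (default) or `"raw"`.
#' @return An `hclust` tree with chain labels, plus attribute
#'   `distance_space` and the clustered coordinate matrix in
#'   attribute `coordinates`.
#' @export
ward_cluster <- function(m, distance_space = c("log10", "raw")) {
  distance_space <- match.arg(distance_space)
  if (nrow(m) < 2L)
    stop_validation("clustering needs at least 2 complete vectors")
  coords <- if (distance_space == "log10") log10(pmax(m, 1e-16)) else m
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  attr(hc, "distance_space") <- distance_space
  attr(hc, "coordinates") <- coords
  hc
}

#' Cut the Ward tree into ordered partitions
#'
#' Cuts the dendrogram into exactly `k` clusters and renames them best to
#' worst by ascending mean log10 PMAD of their member chains. At the
#' default `k = 6` the partitions are named `A1, A2, A3, B, C, D`;
#' otherwise `P1 ... Pk`.
#'
#' @param tree `hclust` tree from [ward_cluster()].
#' @param k number of partitions (2 <= k <= n).
#' @param pmad_matrix the PMAD matrix the tree was built from; defaults
#'   to the coordinates stored on the tree.
#' @return A `chain_partitions` object: list with `tree`, `k`, `labels`
#'   (named chain -> partition factor), `partition_summary` tibble and
#'   the log10 PMAD matrix.
#' @export
cut_partitions <- function(tree, k = 6, pmad_matrix = NULL) {
  n <- length(tree$labels)
  if (k < 2 || k > n) stop_validation("k must lie in [2, n]")
  cl <- stats::cutree(tree, k = k)
  log_m <- attr(tree, "coordinates")
  if (identical(attr(tree, "distance_space"), "raw"))
    log_m <- log10(pmax(log_m, 1e-16))
  if (!is.null(pmad_matrix)) log_m <- log10(pmax(pmad_matrix, 1e-16))
  mean_lp <- vapply(seq_len(k), function(ci)
    mean(log_m[names(cl)[cl == ci], , drop = FALSE]), numeric(1))
  ord <- order(mean_lp)
  nm <- if (k == 6) c("A1", "A2", "A3", "B", "C", "D")
        else paste0("P", seq_len(k))
  new_names <- character(k)
  new_names[ord] <- nm
  labels <- factor(new_names[cl], levels = nm)
  names(labels) <- names(cl)
  summary <- tibble::tibble(
    partition = nm,
    n_chains = as.integer(table(labels)[nm]),
    mean_log10_pmad = sort(mean_lp))
  structure(list(tree = tree, k = k, labels = labels,
                 partition_summary = summary, log10_matrix = log_m),
            class = "chain_partitions")
}

#' @export
print.chain_partitions <- function(x, ...) {
  cat(sprintf("<chain_partitions> %d chains in %d partitions (best -> worst)\n",
              length(x$labels), x$k))
  print(x$partition_summary)
  invisible(x)
}

#' @rdname cut_partitions
#' @param x a `chain_partitions` object.
#' @param ... unused.
#' @export
tidy.chain_partitions <- function(x, ...) {
  tibble::tibble(chain = names(x$labels),
                 partition = as.character(x$labels),
                 mean_log10_pmad = rowMeans(x$log10_matrix[names(x$labels), ,
                                                           drop = FALSE]))
}

#' @rdname cut_partitions
#' @export
glance.chain_partitions <- function(x, ...) {
  tibble::tibble(k = x$k, n_chains = length(x$labels),
                 n_datasets = ncol(x$log10_matrix),
                 best_partition_size = x$partition_summary$n_chains[1],
                 max_height = max(x$tree$height))
}

#' Identify consistently well-performed analysis chains (CWPACs)
#'
#' Two flags per clustered chain:
#' * `strict` — PMAD `<= cutoff` (default 0.7) on every dataset;
#' * `partition_based` — member of a partition in which the fraction of
#'   member PMAD values `<= cutoff` is at least `partition_frac`
#'   (default 0.9).
#'
#' @param partitions `chain_partitions` from [cut_partitions()].
#' @param assessments assessment tibble covering the clustered chains.
#' @param cutoff good-precision PMAD cutoff.
#' @param partition_frac minimum within-partition fraction of PMADs
#'   meeting the cutoff.
#' @return Tibble: `chain`, `partition`, `strict`, `partition_based`.
#' @export
identify_cwpacs <- function(partitions, assessments, cutoff = 0.7,
                            partition_frac = 0.9) {
  a <- dplyr::filter(tibble::as_tibble(assessments),
                     .data$chain %in% names(partitions$labels))
  per_chain <- dplyr::summarise(
    dplyr::group_by(a, .data$chain),
    strict = all(!is.na(.data$pmad) & .data$pmad <= cutoff),
    .groups = "drop")
  per_chain$partition <- as.character(partitions$labels[per_chain$chain])
  frac <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(a,
      partition = as.character(partitions$labels[.data$chain])),
      .data$partition),
    frac_good = mean(.data$pmad <= cutoff, na.rm = TRUE),
    .groups = "drop")
  out <- dplyr::left_join(per_chain, frac, by = "partition")
  dplyr::select(
    dplyr::mutate(out, partition_based = .data$frac_good >= partition_frac),
    "chain", "partition", "strict", "partition_based", "frac_good")
}

#' Per-method contribution within a chain set
#'
#' For a set of chains (e.g. the union of the best partitions), the
#' percentage of chains using each method of a category. Percentages
#' within one category sum to 100.
#'
#' @param chains character vector of chain labels, or anything with a
#'   `chain` column.
#' @param category optional single category to restrict to.
#' @return Tibble: `category`, `code`, `n`, `percentage`.
#' @export
method_contribution <- function(chains, category = NULL) {
  if (!is.character(chains)) chains <- chains$chain
  if (!length(chains))
    stop_validation("empty chain set")
  parsed <- parse_chain(chains)
  long <- tidyr::pivot_longer(parsed, -"chain", names_to = "category",
                              values_to = "code")
  out <- dplyr::summarise(dplyr::group_by(long, .data$category, .data$code),
                          n = dplyr::n(), .groups = "drop_last")
  out <- dplyr::ungroup(dplyr::mutate(out,
                                      percentage = 100 * .data$n / sum(.data$n)))
  if (!is.null(category))
    out <- dplyr::filter(out, .data$category == !!category)
  dplyr::arrange(out, .data$category, dplyr::desc(.data$percentage))
}

#' Export the chain dendrogram as Newick
#'
#' Writes the Ward tree with chain labels as a Newick file (suitable for
#' external tree viewers).
#'
#' @param x a `chain_partitions` object or an `hclust` tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_newick <- function(x, path) {
  hc <- if (inherits(x, "chain_partitions")) x$tree else x
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
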