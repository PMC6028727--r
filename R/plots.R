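#' Ranked precision curves per dataset
#'
#' One panel per dataset: chains ordered by ascending PMAD on the x axis,
#' log10 PMAD on the y axis, with the good-precision cutoffs (0.3, 0.7)
#' as horizontal reference lines. Optionally highlights selected chains.
#'
#' @param assessments assessment tibble from [assess_chains()].
#' @param highlight character vector of chain labels drawn as points.
#' @return A ggplot object.
#' @export
plot_chain_ranking <- function(assessments, highlight = NULL) {
  a <- dplyr::filter(tibble::as_tibble(assessments), !is.na(.data$rank))
  p <- ggplot2::ggplot(a, ggplot2::aes(x = .data$rank,
                                       y = .data$log10_pmad)) +
    ggplot2::geom_line(linewidth = 0.4, colour = "grey30") +
    ggplot2::geom_hline(yintercept = log10(c(0.3, 0.7)),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::facet_wrap(~dataset_id, scales = "free_x") +
    ggplot2::labs(x = "chain rank (ascending PMAD)",
                  y = expression(log[10] ~ PMAD))
  if (!is.null(highlight)) {
    hl <- dplyr::filter(a, .data$chain %in% highlight)
    p <- p + ggplot2::geom_point(data = hl, colour = "red", size = 2)
  }
  p
}

#' Precision-category map for selected chains
#'
#' Chains against datasets, with point size encoding the precision
#' category (smaller = better), in the style of a circle-category
#' overview of representative chains.
#'
#' @param assessments assessment tibble from [assess_chains()].
#' @param chains chains to display (default: 20 chains spread across the
#'   overall ranking).
#' @return A ggplot object.
#' @export
plot_precision_map <- function(assessments, chains = NULL) {
  a <- tibble::as_tibble(assessments)
  if (is.null(chains)) {
    med <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(a, !is.na(.data$pmad)), .data$chain),
      m = stats::median(.data$pmad), .groups = "drop")
    med <- dplyr::arrange(med, .data$m)
    chains <- med$chain[unique(pmax(1, round(seq(1, nrow(med),
                                                 length.out = 20))))]
  }
  a <- dplyr::filter(a, .data$chain %in% chains)
  a$chain <- factor(a$chain, levels = rev(chains))
  ggplot2::ggplot(a, ggplot2::aes(x = .data$dataset_id, y = .data$chain,
                                  size = .data$category,
                                  colour = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_manual(
      values = c(superior = 2, good = 4, poor = 6, failed = 1),
      drop = FALSE) +
    ggplot2::scale_colour_manual(
      values = c(superior = "#1b7837", good = "#fdb863",
                 poor = "#b2182b", failed = "grey60"),
      drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Heatmap of clustered chain performances
#'
#' The partitioned chains against datasets, coloured by log10 PMAD with
#' a diverging blue/white/orange scale centred at the good-precision
#' cutoff (PMAD = 0.7) and saturating at log10 PMAD of +/- `clamp`.
#' Chains are ordered by the dendrogram; partition boundaries are drawn.
#'
#' @param object a `chain_partitions` object from [cut_partitions()].
#' @param clamp saturation for `|log10 PMAD|` (default 5).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.chain_partitions <- function(object, clamp = 5, ...) {
  m <- pmin(pmax(object$log10_matrix, -clamp), clamp)
  ord <- object$tree$labels[object$tree$order]
  df <- tibble::tibble(
    chain = factor(rep(rownames(m), ncol(m)), levels = ord),
    dataset_id = rep(colnames(m), each = nrow(m)),
    log10_pmad = as.vector(m),
    partition = rep(as.character(object$labels[rownames(m)]), ncol(m)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset_id, y = .data$chain,
                                   fill = .data$log10_pmad)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#e08214",
                                  midpoint = log10(0.7),
                                  limits = c(-clamp, clamp),
                                  name = expression(log[10] ~ PMAD)) +
    ggplot2::facet_grid(partition ~ ., scales = "free_y",
                        space = "free_y") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "analysis chain")
}

#' Method contribution bars
#'
#' Percentage of chains in a set using each processing method, one panel
#' per category.
#'
#' @param contributions tibble from [method_contribution()], or a list of
#'   them named by chain-set (e.g. `"A1"`, `"A1+A2"`), shown as dodged
#'   bars.
#' @return A ggplot object.
#' @export
plot_method_contribution <- function(contributions) {
  if (!is.data.frame(contributions))
    contributions <- dplyr::bind_rows(contributions, .id = "set")
  aes <- if ("set" %in% names(contributions))
    ggplot2::aes(x = .data$code, y = .data$percentage, fill = .data$set)
  else
    ggplot2::aes(x = .data$code, y = .data$percentage)
  ggplot2::ggplot(contributions, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~category, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "% of chains in set")
}
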