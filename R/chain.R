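#' Enumerate analysis chains
#'
#' The full Cartesian product of the registry's transformation,
#' normalization and imputation codes (including the `NON` identity in
#' every category) in deterministic lexicographic order by the registry's
#' code lists. The full registry yields 5 x 16 x 7 = 560 chains.
#'
#' @param transformations,normalizations,imputations code vectors;
#'   default the full registry.
#' @return Tibble with columns `chain` (the `TTT-NNN-III` label),
#'   `transformation`, `normalization`, `imputation`.
#' @examples
#' nrow(enumerate_chains())  # 560
#' @export
enumerate_chains <- function(transformations = method_codes("transformation"),
                             normalizations = method_codes("normalization"),
                             imputations = method_codes("imputation")) {
  stopifnot("NON" %in% transformations, "NON" %in% normalizations,
            "NON" %in% imputations)
  grid <- expand.grid(imputation = imputations,
                      normalization = normalizations,
                      transformation = transformations,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, 3:1]
  tibble::tibble(
    chain = paste(grid$transformation, grid$normalization, grid$imputation,
                  sep = "-"),
    transformation = grid$transformation,
    normalization = grid$normalization,
    imputation = grid$imputation)
}

#' Parse a chain label into its three stage codes
#'
#' @param label chain label(s) like `"LOG-MED-NON"`.
#' @return Tibble with columns `chain`, `transformation`, `normalization`,
#'   `imputation`; unknown codes are a validation error.
#' @export
parse_chain <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop_validation(paste0("malformed chain label: ", label[bad][1]))
  tf <- vapply(parts, `[[`, "", 1L)
  no <- vapply(parts, `[[`, "", 2L)
  im <- vapply(parts, `[[`, "", 3L)
  for (x in tf) check_code(x, "transformation")
  for (x in no) check_code(x, "normalization")
  for (x in im) check_code(x, "imputation")
  tibble::tibble(chain = label, transformation = tf, normalization = no,
                 imputation = im)
}

#' Apply one analysis chain to one dataset
#'
#' Applies the three stages strictly in the order transformation ->
#' normalization -> imputation. Any stage's domain / degenerate /
#' convergence error is caught and converted into a structured failure —
#' a chain failure never crashes a sweep. Missing cells propagate through
#' stages 1–2 untouched and are resolved (or kept, for `NON`) at stage 3.
#'
#' @param x an [intensity_table()].
#' @param chain a chain label (`"LOG-MED-NON"`) or one-row tibble from
#'   [enumerate_chains()].
#' @param params parameters from [chain_params()].
#' @return A `chain_result`: list with `chain`, `dataset_id`, `table`
#'   (the processed table, or `NULL` on failure), `failure_stage` and
#'   `failure_class` (`NA` on success).
#' @export
apply_chain <- function(x, chain, params = chain_params()) {
  if (is.character(chain)) chain <- parse_chain(chain)
  stopifnot(nrow(chain) == 1L)
  ds <- dataset_id(x)
  res <- list(chain = chain$chain, dataset_id = ds, table = NULL,
              failure_stage = NA_character_, failure_class = NA_character_,
              message = NA_character_)
  out <- tryCatch({
    t1 <- apply_transformation(x, chain$transformation,
                               params$transformation)
    t2 <- apply_normalization(
      t1, chain$normalization, params$normalization,
      seed = derive_seed(params$seed, ds, chain$transformation,
                         chain$normalization))
    apply_imputation(t2, chain$imputation, params$imputation)
  }, pmadbench_stage_error = function(e) e)
  if (inherits(out, "condition")) {
    res$failure_stage <- out$stage
    res$failure_class <- out$failure_class
    res$message <- conditionMessage(out)
  } else {
    res$table <- out
  }
  structure(res, class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  if (is.null(x$table))
    cat(sprintf("<chain_result> %s on %s: FAILED at %s (%s)\n", x$chain,
                x$dataset_id, x$failure_stage, x$failure_class))
  else
    cat(sprintf("<chain_result> %s on %s: ok (%d x %d)\n", x$chain,
                x$dataset_id, nrow(x$table), ncol(x$table)))
  invisible(x)
}

#' Sweep chains over datasets
#'
#' Evaluates every (chain, dataset) pair, reusing shared stage prefixes:
#' each transformation is computed once per dataset and each
#' transformation+normalization pair once, then fanned out over the
#' imputation methods. Results are identical to calling [apply_chain()]
#' pair by pair; evaluation order does not matter.
#'
#' The pooled-MAD precision of each successful chain output is computed
#' immediately (so processed matrices need not be retained) unless
#' `score = FALSE`.
#'
#' @param datasets a named list of [intensity_table()]s, or a single
#'   table.
#' @param chains tibble from [enumerate_chains()] (default: all 560) or a
#'   character vector of labels.
#' @param params parameters from [chain_params()].
#' @param score compute PMAD per successful chain (default `TRUE`).
#' @param progress print per-dataset progress lines.
#' @return A `chain_sweep` tibble: `dataset_id`, `chain`,
#'   `transformation`, `normalization`, `imputation`, `pmad` (`NA` when
#'   failed or unscored), `failure_stage`, `failure_class`.
#' @export
sweep_chains <- function(datasets, chains = enumerate_chains(),
                         params = chain_params(), score = TRUE,
                         progress = FALSE) {
  if (inherits(datasets, "intensity_table")) datasets <- list(datasets)
  if (is.null(names(datasets)))
    names(datasets) <- vapply(seq_along(datasets), function(i) {
      id <- dataset_id(datasets[[i]])
      if (is.na(id)) paste0("D", i) else id
    }, character(1))
  if (is.character(chains)) chains <- parse_chain(chains)

  rows <- vector("list", length(datasets))
  for (di in seq_along(datasets)) {
    ds <- names(datasets)[di]
    x <- datasets[[di]]
    attr(x, "dataset_id") <- ds
    n_chain <- nrow(chains)
    pmad <- rep(NA_real_, n_chain)
    fstage <- rep(NA_character_, n_chain)
    fclass <- rep(NA_character_, n_chain)

    for (tf in unique(chains$transformation)) {
      sel_t <- which(chains$transformation == tf)
      t1 <- tryCatch(
        apply_transformation(x, tf, params$transformation),
        pmadbench_stage_error = function(e) e)
      if (inherits(t1, "condition")) {
        fstage[sel_t] <- t1$stage; fclass[sel_t] <- t1$failure_class
        next
      }
      for (no in unique(chains$normalization[sel_t])) {
        sel_n <- sel_t[chains$normalization[sel_t] == no]
        t2 <- tryCatch(
          apply_normalization(t1, no, params$normalization,
                              seed = derive_seed(params$seed, ds, tf, no)),
          pmadbench_stage_error = function(e) e)
        if (inherits(t2, "condition")) {
          fstage[sel_n] <- t2$stage; fclass[sel_n] <- t2$failure_class
          next
        }
        for (ii in seq_along(sel_n)) {
          idx <- sel_n[ii]
          t3 <- tryCatch(
            apply_imputation(t2, chains$imputation[idx], params$imputation),
            pmadbench_stage_error = function(e) e)
          if (inherits(t3, "condition")) {
            fstage[idx] <- t3$stage; fclass[idx] <- t3$failure_class
            next
          }
          if (score) {
            pm <- tryCatch(compute_pmad(t3),
                           pmadbench_stage_error = function(e) e)
            if (inherits(pm, "condition")) {
              fstage[idx] <- "assessment"; fclass[idx] <- pm$failure_class
            } else pmad[idx] <- pm
          }
        }
      }
      if (progress)
        message(sprintf("dataset %s: transformation %s done", ds, tf))
    }
    rows[[di]] <- tibble::tibble(
      dataset_id = ds, chain = chains$chain,
      transformation = chains$transformation,
      normalization = chains$normalization,
      imputation = chains$imputation,
      pmad = pmad, failure_stage = fstage, failure_class = fclass)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("chain_sweep", class(out))
  out
}

#' Summarize a sweep
#'
#' @param x a `chain_sweep` tibble from [sweep_chains()].
#' @param ... unused.
#' @return One row per dataset: chains evaluated, succeeded, failed.
#' @export
glance.chain_sweep <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$dataset_id),
    n_chains = dplyr::n(),
    n_success = sum(is.na(.data$failure_class)),
    n_failed = sum(!is.na(.data$failure_class)),
    .groups = "drop")
}
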