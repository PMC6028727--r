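#' Protein intensity table
#'
#' The container every chain stage maps to itself: a numeric matrix with
#' proteins in rows and samples in columns, missing cells stored as `NA`,
#' plus a sample-to-group annotation. Raw (untransformed) intensities are
#' nonnegative or missing; after a transformation values may be any real.
#'
#' @param values numeric matrix, proteins in rows and samples in columns.
#'   Row names are taken as protein ids and column names as sample ids
#'   unless `protein_ids` / `sample_ids` are given. `NA` marks a missing
#'   (unobserved) cell.
#' @param groups sample-to-group assignment: either a character vector of
#'   length `ncol(values)` (optionally named by sample id) or a data frame
#'   with columns `sample_id` and `group`.
#' @param protein_ids,sample_ids optional explicit id vectors overriding
#'   the dimnames of `values`.
#' @param dataset_id optional identifier carried through sweeps and reports.
#'
#' @return An object of class `intensity_table`: the validated matrix with
#'   a `groups` attribute (named character vector) and optional
#'   `dataset_id`.
#' @examples
#' m <- matrix(c(4, 16, 2, NA), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' it <- intensity_table(m, groups = c(s1 = "A", s2 = "A"))
#' missing_mask(it)
#' @export
intensity_table <- function(values, groups, protein_ids = NULL,
                            sample_ids = NULL, dataset_id = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("`values` must be a numeric matrix (proteins x samples)")
  if (!is.null(protein_ids)) rownames(values) <- protein_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)))
    rownames(values) <- paste0("protein_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop_validation("sample ids are required (column names of `values` or `sample_ids`)")

  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups)))
      stop_validation("`groups` data frame needs columns `sample_id` and `group`")
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample_id))
  }
  groups <- stats::setNames(as.character(groups),
                            if (is.null(names(groups))) colnames(values) else names(groups))

  x <- structure(values,
                 groups = groups,
                 dataset_id = dataset_id,
                 class = c("intensity_table", "matrix", "array"))
  validate_intensity_table(x)
}

#' Validate an intensity table
#'
#' Checks the structural invariants: unique protein and sample ids,
#' dimensions matching the id lists, and exactly one group label per
#' sample. Validation rejects, it never repairs.
#'
#' @param x an `intensity_table`.
#' @return `x`, invisibly unchanged, if valid; otherwise a validation
#'   error is signalled.
#' @export
validate_intensity_table <- function(x) {
  if (anyDuplicated(rownames(x)))
    stop_validation("duplicate protein ids")
  if (anyDuplicated(colnames(x)))
    stop_validation("duplicate sample ids")
  g <- attr(x, "groups")
  if (is.null(g) || anyDuplicated(names(g)))
    stop_validation("group map must assign each sample exactly once")
  missing_samples <- setdiff(colnames(x), names(g))
  if (length(missing_samples))
    stop_validation(paste0("samples without a group label: ",
                           paste(missing_samples, collapse = ", ")))
  if (anyNA(g[colnames(x)]))
    stop_validation("group labels may not be NA")
  attr(x, "groups") <- g[colnames(x)]
  x
}

#' @rdname intensity_table
#' @param x an `intensity_table`.
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "intensity_table"))
  is.na(unclass(x))
}

#' @rdname intensity_table
#' @export
sample_groups <- function(x) {
  stopifnot(inherits(x, "intensity_table"))
  attr(x, "groups")
}

#' @rdname intensity_table
#' @export
dataset_id <- function(x) {
  id <- attr(x, "dataset_id")
  if (is.null(id)) NA_character_ else id
}

# Replace the value matrix, keeping annotation. Internal workhorse used by
# every stage so attributes survive arithmetic on the bare matrix.
set_values <- function(x, values) {
  stopifnot(identical(dim(values), dim(x)))
  dimnames(values) <- dimnames(x)
  structure(values,
            groups = attr(x, "groups"),
            dataset_id = attr(x, "dataset_id"),
            class = class(x))
}

values_of <- function(x) {
  v <- unclass(x)
  attr(v, "groups") <- NULL
  attr(v, "dataset_id") <- NULL
  v
}

#' @export
print.intensity_table <- function(x, ...) {
  g <- sample_groups(x)
  cat(sprintf("<intensity_table> %d proteins x %d samples (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s: n=%d", names(table(g)), table(g)),
                    collapse = ", ")))
  cat(sprintf("missing: %d cells (%.1f%%)\n", sum(is.na(x)),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Tidy an intensity table into long form
#'
#' @param x an `intensity_table`.
#' @param ... unused.
#' @return A tibble with one row per cell: `protein_id`, `sample_id`,
#'   `group`, `intensity` (`NA` when missing), `missing`.
#' @export
tidy.intensity_table <- function(x, ...) {
  g <- sample_groups(x)
  tibble::tibble(
    protein_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    group = rep(unname(g), each = nrow(x)),
    intensity = as.vector(unclass(x)),
    missing = as.vector(is.na(unclass(x)))
  )
}
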