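#' Read a protein intensity matrix from delimited text
#'
#' Expects the fixed layout used throughout the package: first column
#' protein ids, header row sample ids, proteins in rows. Readers never
#' auto-transpose. The group annotation comes either from a second header
#' row (`groups = "inline"`) or from a two-column side file
#' (sample_id, group).
#'
#' @param path path to the matrix file.
#' @param groups `"inline"` for a second header row of group labels, or a
#'   path to a tab-separated annotation file with columns
#'   `sample_id`, `group` (header optional).
#' @param delim field delimiter, default tab.
#' @param missing_tokens character vector of cell contents treated as
#'   missing (default empty string and `"NA"`).
#' @param zero_as_missing treat exact 0 as missing (common in OpenSWATH
#'   style exports); off by default.
#' @param dataset_id optional dataset identifier to attach.
#' @return An [intensity_table()].
#' @export
read_intensity_table <- function(path, groups, delim = "\t",
                                 missing_tokens = c("", "NA"),
                                 zero_as_missing = FALSE,
                                 dataset_id = NULL) {
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  lines <- readLines(path)
  if (!length(lines)) stop_parse("empty file")
  split_row <- function(l) strsplit(l, delim, fixed = TRUE)[[1]]
  header <- split_row(lines[[1]])
  sample_ids <- header[-1]
  inline <- identical(groups, "inline")
  if (inline) {
    if (length(lines) < 2L) stop_parse("inline group row missing")
    grow <- split_row(lines[[2]])
    group_vec <- stats::setNames(grow[-1], sample_ids)
    body <- lines[-(1:2)]
  } else {
    ann <- utils::read.table(groups, sep = "\t", header = FALSE,
                             colClasses = "character",
                             col.names = c("sample_id", "group"))
    if (identical(tolower(ann$sample_id[1]), "sample_id")) ann <- ann[-1, ]
    group_vec <- stats::setNames(ann$group, ann$sample_id)
    body <- lines[-1]
  }
  body <- body[nzchar(body)]
  cells <- lapply(body, split_row)
  protein_ids <- vapply(cells, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, length(protein_ids), length(sample_ids),
                 dimnames = list(protein_ids, sample_ids))
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    row <- c(row, rep("", length(sample_ids) + 1L - length(row)))[-1L]
    miss <- row %in% missing_tokens
    num <- suppressWarnings(as.numeric(row))
    bad <- !miss & is.na(num)
    if (any(bad))
      stop_parse(sprintf("non-numeric cell at protein '%s', sample '%s': '%s'",
                         protein_ids[i], sample_ids[which(bad)[1]],
                         row[which(bad)[1]]))
    num[miss] <- NA_real_
    if (zero_as_missing) num[!is.na(num) & num == 0] <- NA_real_
    vals[i, ] <- num
  }
  tbl_groups <- group_vec[sample_ids]
  if (anyNA(tbl_groups))
    stop_validation(paste0("samples without a group label: ",
                           paste(sample_ids[is.na(tbl_groups)], collapse = ", ")))
  names(tbl_groups) <- sample_ids
  intensity_table(vals, groups = tbl_groups, dataset_id = dataset_id)
}

#' Write an intensity table as delimited text
#'
#' Same layout the reader expects; missing cells are emitted as the
#' configured token. With `groups = "inline"` a second header row carries
#' the group labels so the file round-trips through
#' [read_intensity_table()] alone.
#'
#' @param x an [intensity_table()].
#' @param path output path.
#' @param delim field delimiter.
#' @param missing_token string written for missing cells (default `"NA"`).
#' @param groups `"inline"` or a path for a separate sample annotation TSV.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path, delim = "\t",
                                  missing_token = "NA", groups = "inline") {
  stopifnot(inherits(x, "intensity_table"))
  fmt <- function(v) {
    out <- vapply(v, function(z) format(z, digits = 17, scientific = FALSE,
                                        trim = TRUE), character(1))
    out[is.na(v)] <- missing_token
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("protein_id", colnames(x)), collapse = delim), con)
  if (identical(groups, "inline")) {
    writeLines(paste(c("group", unname(sample_groups(x))), collapse = delim), con)
  } else {
    utils::write.table(
      data.frame(sample_id = colnames(x), group = unname(sample_groups(x))),
      groups, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  v <- values_of(x)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], fmt(v[i, ])), collapse = delim), con)
  invisible(path)
}

#' Write the standard result files of a benchmarking run
#'
#' Writes, into `out_dir`: per-dataset chain ranking tables
#' (`ranking_<dataset>.tsv`), the partition membership table
#' (`partitions.tsv`), the clamped log10-PMAD heatmap matrix
#' (`heatmap_log10_pmad.tsv`), the per-method contribution table
#' (`method_contributions.tsv`), a Newick dendrogram
#' (`chains.nwk`) and optionally processed matrices.
#'
#' @param assessments assessment tibble from [assess_chains()].
#' @param partitions optional `chain_partitions` object from
#'   [cut_partitions()].
#' @param contributions optional tibble from [method_contribution()].
#' @param tables optional named list of processed [intensity_table()]s to
#'   write alongside.
#' @param out_dir output directory, created if absent.
#' @param heatmap_clamp symmetric clamp applied to log10 PMAD in the
#'   heatmap matrix (default 5, i.e. values capped to \[-5, 5\] as in the
#'   blue/orange colour scale convention).
#' @return Tibble manifest: `file`, `kind`.
#' @export
write_results <- function(assessments, partitions = NULL,
                          contributions = NULL, tables = NULL,
                          out_dir, heatmap_clamp = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  add <- function(file, kind) written[[length(written) + 1L]] <<-
    tibble::tibble(file = file, kind = kind)

  for (ds in unique(assessments$dataset_id)) {
    f <- file.path(out_dir, paste0("ranking_", ds, ".tsv"))
    readr::write_tsv(
      dplyr::arrange(dplyr::filter(assessments, .data$dataset_id == ds),
                     is.na(.data$rank), .data$rank),
      f)
    add(f, "ranking")
  }
  if ("category" %in% names(assessments)) {
    # chain x dataset precision categories (the circle-size overview)
    f <- file.path(out_dir, "categories.tsv")
    readr::write_tsv(tidyr::pivot_wider(
      dplyr::transmute(assessments, .data$chain, .data$dataset_id,
                       category = as.character(.data$category)),
      names_from = "dataset_id", values_from = "category"), f)
    add(f, "categories")
  }
  if (!is.null(partitions)) {
    f <- file.path(out_dir, "partitions.tsv")
    readr::write_tsv(tidy(partitions), f)
    add(f, "partitions")
    hm <- heatmap_matrix(assessments, clamp = heatmap_clamp)
    f <- file.path(out_dir, "heatmap_log10_pmad.tsv")
    readr::write_tsv(tibble::as_tibble(hm, rownames = "chain"), f)
    add(f, "heatmap")
    f <- file.path(out_dir, "chains.nwk")
    export_newick(partitions, f)
    add(f, "newick")
  }
  if (!is.null(contributions)) {
    f <- file.path(out_dir, "method_contributions.tsv")
    readr::write_tsv(contributions, f)
    add(f, "contributions")
  }
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0("table_", nm, ".tsv"))
    write_intensity_table(tables[[nm]], f)
    add(f, "table")
  }
  dplyr::bind_rows(written)
}

#' Chain-by-dataset log10 PMAD matrix for heatmap display
#'
#' @param assessments assessment tibble from [assess_chains()].
#' @param clamp cap for `|log10 PMAD|`; values outside are clamped so a
#'   diverging colour scale saturates at the extremes.
#' @return numeric matrix, chains in rows, datasets in columns; `NA` for
#'   failed chain-dataset pairs.
#' @export
heatmap_matrix <- function(assessments, clamp = 5) {
  wide <- tidyr::pivot_wider(
    dplyr::transmute(assessments, .data$chain, .data$dataset_id,
                     v = pmin(pmax(.data$log10_pmad, -clamp), clamp)),
    names_from = "dataset_id", values_from = "v")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$chain
  m
}
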