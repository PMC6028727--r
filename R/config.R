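#' Read a pipeline run configuration from a plain text file
#'
#' Simple `key = value` format, one pair per line; `#` starts a comment.
#' Pipeline-level keys (`datasets`, `chains`, `n_datasets`, `n_proteins`,
#' `k`, `distance_space`, `cwpac_cutoff`, `cwpac_partition_frac`, `seed`,
#' `out_dir`) map to the arguments of [run_pipeline()]; any other key must
#' name a method parameter of [transform_params()], [normalize_params()]
#' or [impute_params()] (e.g. `loess_span = 0.5`, `knn_k = 6`) and is
#' routed into the right stage's parameter list. `chains` is either `all`
#' or a comma-separated list of labels.
#'
#' @param path path to the configuration file.
#' @return A named list of arguments for [run_pipeline()].
#' @examples
#' cfg <- tempfile()
#' writeLines(c("n_datasets = 2", "n_proteins = 80", "k = 2",
#'              "chains = LOG-MED-ZER,NON-NON-NON", "knn_k = 4"), cfg)
#' args <- read_run_config(cfg)
#' args$params$imputation$knn_k
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("config file not found: ", path))
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop_parse(paste0("malformed config line: ", lines[bad][1]))
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  if (anyDuplicated(keys))
    stop_parse("duplicate config keys")

  parse_val <- function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }

  pipeline_keys <- c("datasets", "chains", "n_datasets", "n_proteins", "k",
                     "distance_space", "cwpac_cutoff",
                     "cwpac_partition_frac", "seed", "out_dir")
  stage_defaults <- list(transformation = transform_params(),
                         normalization = normalize_params(),
                         imputation = impute_params())

  args <- list()
  params <- stage_defaults
  seed <- 1L
  for (i in seq_along(keys)) {
    key <- keys[i]
    val <- parse_val(vals[i])
    if (key %in% pipeline_keys) {
      if (key == "chains" && !identical(val, "all"))
        val <- trimws(strsplit(as.character(val), ",", fixed = TRUE)[[1]])
      if (key %in% c("n_datasets", "n_proteins", "k", "seed"))
        val <- as.integer(val)
      if (key == "seed") seed <- val
      args[[key]] <- val
    } else {
      hit <- FALSE
      for (stage in names(params)) {
        if (key %in% names(params[[stage]])) {
          params[[stage]][[key]] <- val
          hit <- TRUE
        }
      }
      if (!hit) stop_parse(paste0("unknown config key: ", key))
    }
  }
  args$params <- chain_params(transformation = params$transformation,
                              normalization = params$normalization,
                              imputation = params$imputation,
                              seed = seed)
  args
}
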