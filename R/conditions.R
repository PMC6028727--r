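# Classed conditions used across the chain stages. Every recoverable
# processing failure carries the stage it occurred at and a short failure
# class drawn from a fixed taxonomy, so the chain engine can convert it
# into a structured failure record instead of crashing a sweep.

.failure_classes <- c(
  "domain-error", "degenerate-scale", "insufficient-overlap",
  "insufficient-data", "non-convergence", "assessment-error"
)

stop_stage <- function(message, class, stage) {
  stopifnot(class %in% .failure_classes)
  rlang::abort(
    message,
    class = c(paste0("pmadbench_", gsub("-", "_", class)), "pmadbench_stage_error"),
    failure_class = class,
    stage = stage
  )
}

stop_validation <- function(message) {
  rlang::abort(message, class = "pmadbench_validation_error")
}

stop_parse <- function(message) {
  rlang::abort(message, class = "pmadbench_parse_error")
}
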