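# Internal helpers shared across modules.

# Condition constructors so the CLI can map error classes to exit codes:
# validation problems (bad config, missing files, malformed input) exit 1,
# runtime failures exit 2.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("trfbin_validation_error", "error")))
}

stop_runtime <- function(...) {
  stop(errorCondition(paste0(...), class = c("trfbin_runtime_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
geometric_mean <- function(x) exp(mean(log(x)))

# Region labels in 5'->3' transcriptional order.
REGION_LABELS <- c("5-Pre", "5tRF", "D-loop", "A-loop", "T-loop", "3tRF", "3-Pre")

is_nonempty_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}

# Write a TSV without quoting or row names (the package's on-disk table
# convention throughout).
write_tsv <- function(df, file) {
  utils::write.table(df, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(file, ...) {
  utils::read.delim(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
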