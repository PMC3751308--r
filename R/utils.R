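# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic child seed for a named simulation stage.
#'
#' One master seed drives the whole generator; each stage (reference,
#' abundances, each library, qPCR, abscission) draws from its own stream so
#' that stages are independently reproducible. The child seed is a simple
#' deterministic hash of (seed, stage label) kept inside 32-bit integer range.
#' @noRd
child_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((as.numeric(seed) %% 65011 + 1) * 32611 + h) %% 2147483629L
}

#' @noRd
stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

#' @noRd
check_fraction <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    stop_config(field, "must be a single number in [0, 1]")
  }
  as.numeric(value)
}

#' @noRd
check_count <- function(value, field, min = 1) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < min || value != floor(value)) {
    stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  as.numeric(value)
}

#' @noRd
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

DNA_BASES <- c("A", "C", "G", "T")
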