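`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Check that a value is a single finite number
#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Coerce pair input to a two-column character data.frame
#'
#' Accepts a data.frame whose first two columns are domain and disease
#' labels (extra columns ignored), or a character matrix with two columns.
#' @noRd
as_pair_frame <- function(pairs) {
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!is.data.frame(pairs) || ncol(pairs) < 2L)
    stopf("pairs must be a data.frame (or matrix) with at least two columns")
  out <- data.frame(domain  = as.character(pairs[[1L]]),
                    disease = as.character(pairs[[2L]]),
                    stringsAsFactors = FALSE)
  nm <- names(pairs)
  if (all(c("domain", "disease") %in% nm))
    out <- data.frame(domain  = as.character(pairs[["domain"]]),
                      disease = as.character(pairs[["disease"]]),
                      stringsAsFactors = FALSE)
  out
}

#' Deterministic child seed from a base seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @noRd
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% .Machine$integer.max)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
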