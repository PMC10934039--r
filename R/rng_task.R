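# Task-performance statistic for the 100-digit random number generation
# task performed during the Task state.

#' Randomness index of a generated digit sequence
#'
#' The default is the digram-redundancy index: with `n_ij` the count of the
#' ordered adjacent pair (i, j) and `n_i.` its row sum,
#' `RNG = sum(n_ij * ln n_ij) / sum(n_i. * ln n_i.)`.
#' It is 0 when every adjacent ordered pair is distinct and 1 for a
#' maximally repetitive sequence (a single repeated digram); human
#' sequences of length 100 typically score in the 0.25-0.45 range.
#' `method = "repeat_frequency"` gives the naive fraction of adjacent
#' pairs whose two digits are equal (expectation 0.1 under uniform
#' randomness), retained as an alternative definition.
#'
#' @param digits integer vector of digits 0-9 (or a single string of
#'   digit characters), length >= 2.
#' @param method `"digram_redundancy"` (default) or `"repeat_frequency"`.
#' @return score in `[0, 1]`.
#' @export
rng_index <- function(digits, method = c("digram_redundancy", "repeat_frequency")) {
  method <- match.arg(method)
  digits <- .as_digits(digits)
  n <- length(digits)
  if (n < 2L) stop("need at least 2 digits", call. = FALSE)
  if (method == "repeat_frequency") {
    return(mean(digits[-1] == digits[-n]))
  }
  pairs <- paste(digits[-n], digits[-1], sep = ":")
  nij <- table(pairs)
  ni <- table(digits[-n])
  den <- sum(ni * log(ni))
  if (den == 0) return(0)
  sum(nij * log(nij)) / den
}

.as_digits <- function(digits) {
  if (is.character(digits)) {
    digits <- if (length(digits) == 1L) strsplit(digits, "")[[1]] else digits
    if (any(!digits %in% as.character(0:9))) {
      stop("non-digit symbol in sequence: ",
           paste(unique(digits[!digits %in% as.character(0:9)]), collapse = ", "),
           call. = FALSE)
    }
    digits <- as.integer(digits)
  }
  if (any(is.na(digits)) || any(digits != round(digits)) ||
      any(digits < 0) || any(digits > 9)) {
    stop("digits must be integers 0-9", call. = FALSE)
  }
  as.integer(digits)
}

#' Validate a digit sequence against the task protocol
#'
#' Report-only check: flags a length different from the expected 100
#' vocalized digits and any non-digit symbols; never alters the input.
#'
#' @param digits character string or vector of symbols.
#' @param expected_len nominal sequence length (default 100).
#' @return list with `length_ok`, `symbols_ok`, `n`, `bad_symbols`.
#' @export
validate_sequence <- function(digits, expected_len = 100) {
  if (is.character(digits) && length(digits) == 1L) digits <- strsplit(digits, "")[[1]]
  symbols <- as.character(digits)
  bad <- unique(symbols[!symbols %in% as.character(0:9)])
  list(length_ok = length(symbols) == expected_len,
       symbols_ok = length(bad) == 0L,
       n = length(symbols),
       bad_symbols = bad)
}

#' Read a digit sequence from a one-line text file
#'
#' @param path file whose first non-empty line is the digit string.
#' @return integer vector of digits.
#' @export
read_digits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("parse error: ", path, " is empty", call. = FALSE)
  .as_digits(lines[1])
}
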