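#' Read a truth table from CSV
#'
#' The format is one column per input variable plus a final output column:
#' a header row of names followed by exactly 2^n data rows of 0/1 in
#' canonical row order (first variable most significant).  Validation is
#' strict and errors report the offending line number.
#'
#' @param file path to a CSV file.
#' @return a [truth_table()].
#' @export
read_truth_table <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2)
    config_error(sprintf("%s: need a header and at least 2 data rows", file))
  header <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  if (length(header) < 2)
    config_error(sprintf("%s line 1: need at least one input column and one output column", file))
  n <- length(header) - 1
  vars <- header[seq_len(n)]
  name <- header[n + 1]
  nrows <- length(lines) - 1
  if (nrows != 2^n)
    config_error(sprintf("%s: expected %d data rows for %d inputs, found %d",
                         file, 2^n, n, nrows))
  outputs <- integer(nrows)
  for (r in seq_len(nrows)) {
    ln <- r + 1
    fields <- trimws(strsplit(lines[ln], ",", fixed = TRUE)[[1]])
    if (length(fields) != n + 1)
      config_error(sprintf("%s line %d: expected %d fields, found %d",
                           file, ln, n + 1, length(fields)))
    if (!all(fields %in% c("0", "1")))
      config_error(sprintf("%s line %d: entries must be 0 or 1", file, ln))
    bits <- as.integer(fields[seq_len(n)])
    expected <- (r - 1) %/% 2^(n - seq_len(n)) %% 2
    if (!all(bits == expected))
      config_error(sprintf(
        "%s line %d: minterm (%s) out of canonical row order (expected %s)",
        file, ln, paste(bits, collapse = ""), paste(expected, collapse = "")))
    outputs[r] <- as.integer(fields[n + 1])
  }
  truth_table(outputs, vars = vars, name = name)
}

#' Write a truth table to CSV
#'
#' @param tt a [truth_table()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_truth_table <- function(tt, file) {
  stopifnot(inherits(tt, "truth_table"))
  bits <- minterm_matrix(tt$n)
  lines <- c(
    paste(c(tt$vars, tt$name), collapse = ","),
    vapply(seq_len(nrow(bits)), function(r)
      paste(c(bits[r, ], tt$outputs[r]), collapse = ","), character(1))
  )
  writeLines(lines, file)
  invisible(file)
}
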