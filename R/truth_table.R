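#' Construct a truth table
#'
#' A truth table specifies an n-input combinational logic function by listing
#' its output bit for every minterm (complete 0/1 assignment to the inputs).
#' Rows are in canonical order: row index ascends as a binary integer with the
#' FIRST listed variable as the most significant bit, so for variables
#' `(a, b)` the rows are 00, 01, 10, 11.
#'
#' @param outputs vector of 2^n values, each exactly 0 or 1, in canonical
#'   row order.
#' @param vars character vector of n input variable names.  Defaults to
#'   `x1 ... xn`.
#' @param name name of the output/function column (also used for the output
#'   species pair when compiling).
#' @return an object of class `truth_table` with fields `vars`, `n`,
#'   `outputs` (integer vector) and `name`.
#' @examples
#' truth_table(c(1, 0, 0, 0), vars = c("a", "b"), name = "c")  # NOR
#' @seealso [gate_table()], [xor3_table()], [tt_to_polynomial()]
#' @export
truth_table <- function(outputs, vars = NULL, name = "F") {
  if (length(outputs) < 2)
    config_error("a truth table needs at least one input variable (2 rows)")
  n <- log2(length(outputs))
  if (n != round(n))
    config_error(sprintf("number of outputs (%d) is not a power of two",
                         length(outputs)))
  n <- as.integer(round(n))
  if (is.null(vars)) vars <- paste0("x", seq_len(n))
  vars <- as.character(vars)
  if (length(vars) != n)
    config_error(sprintf("expected %d variable names, got %d", n, length(vars)))
  if (anyDuplicated(vars))
    config_error("variable names must be unique")
  bad <- !grepl("^[A-Za-z][A-Za-z0-9.]*$", vars)
  if (any(bad))
    config_error(paste0("invalid variable name(s): ",
                        paste(vars[bad], collapse = ", ")))
  name <- as.character(name)[1]
  if (name %in% vars)
    config_error(sprintf("output name '%s' clashes with an input variable", name))
  out <- suppressWarnings(as.numeric(outputs))
  if (anyNA(out) || !all(out %in% c(0, 1)))
    config_error("every output must be exactly 0 or 1")
  structure(
    list(vars = vars, n = n, outputs = as.integer(out), name = name),
    class = "truth_table"
  )
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("Truth table: %s(%s), %d rows\n",
              x$name, paste(x$vars, collapse = ", "), length(x$outputs)))
  bits <- minterm_matrix(x$n)
  df <- as.data.frame(bits)
  names(df) <- x$vars
  df[[x$name]] <- x$outputs
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
format.truth_table <- function(x, ...) {
  sprintf("truth_table(%s -> %s; outputs %s)",
          paste(x$vars, collapse = ","), x$name,
          paste(x$outputs, collapse = ""))
}

#' @method all.equal truth_table
#' @export
all.equal.truth_table <- function(target, current, ...) {
  ok <- identical(target$vars, current$vars) &&
    identical(target$outputs, current$outputs) &&
    identical(target$name, current$name)
  if (ok) TRUE else "truth tables differ"
}

# All minterms of n variables as a 2^n x n 0/1 matrix in canonical row order
# (first variable most significant).
minterm_matrix <- function(n) {
  rows <- 0:(2^n - 1)
  m <- vapply(seq_len(n), function(i) (rows %/% 2^(n - i)) %% 2, numeric(2^n))
  matrix(as.integer(m), nrow = 2^n, ncol = n)
}

# Canonical 0-based row index of a minterm bit vector.
minterm_index <- function(bits) {
  n <- length(bits)
  sum(bits * 2^((n - 1):0))
}

#' Standard logic-gate truth tables
#'
#' Returns the truth table of a basic logic gate, with inputs `a` (and `b`)
#' and output `b` (for NOT) or `c`.  The stochastic function of each gate is
#' its multilinear polynomial: NOT gives 1 - a, AND gives ab, OR gives
#' a + b - ab, XOR gives a + b - 2ab, and NAND/NOR/XNOR their complements.
#'
#' @param gate one of `"NOT"`, `"AND"`, `"OR"`, `"NAND"`, `"NOR"`, `"XOR"`,
#'   `"XNOR"` (case-insensitive).
#' @return a [truth_table()].
#' @examples
#' tt_to_polynomial(gate_table("OR"))   # a + b - a*b
#' @export
gate_table <- function(gate) {
  g <- toupper(as.character(gate)[1])
  spec <- list(
    NOT  = list(out = c(1L, 0L), vars = "a", name = "b"),
    AND  = list(out = c(0L, 0L, 0L, 1L), vars = c("a", "b"), name = "c"),
    OR   = list(out = c(0L, 1L, 1L, 1L), vars = c("a", "b"), name = "c"),
    NAND = list(out = c(1L, 1L, 1L, 0L), vars = c("a", "b"), name = "c"),
    NOR  = list(out = c(1L, 0L, 0L, 0L), vars = c("a", "b"), name = "c"),
    XOR  = list(out = c(0L, 1L, 1L, 0L), vars = c("a", "b"), name = "c"),
    XNOR = list(out = c(1L, 0L, 0L, 1L), vars = c("a", "b"), name = "c")
  )
  if (!g %in% names(spec))
    config_error(sprintf("unknown gate '%s' (expected one of %s)",
                         gate, paste(names(spec), collapse = ", ")))
  s <- spec[[g]]
  truth_table(s$out, vars = s$vars, name = s$name)
}

#' Three-input XOR (odd parity) truth table
#'
#' The balanced 3-input parity function, whose stochastic closed form is
#' x + y + z - 2xy - 2xz - 2yz + 4xyz.  Because its table has equal numbers
#' of 0 and 1 outputs it is the most sensitive standard function to
#' rate-constant variation, and is the subject of the robustness sweeps in
#' [error_cube()].
#'
#' @return a [truth_table()] with variables `x`, `y`, `z` and output `f`.
#' @export
xor3_table <- function() {
  truth_table(c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L),
              vars = c("x", "y", "z"), name = "f")
}

#' Three-input worked-example truth table
#'
#' A small asymmetric 3-input function used throughout the documentation,
#' with stochastic closed form (1-x2)x3 + x2 x3 + x1 x2 (1-x3).
#'
#' @return a [truth_table()] with variables `x1`, `x2`, `x3` and output `F`.
#' @export
demo3_table <- function() {
  truth_table(c(0L, 1L, 0L, 1L, 0L, 1L, 1L, 1L),
              vars = c("x1", "x2", "x3"), name = "F")
}
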