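#' Probability of a single minterm
#'
#' Under the stochastic-logic model each input variable is an independent
#' Bernoulli random variable with Pr(Xi = 1) = x_i.  The probability of a
#' minterm (one truth-table row) is the product over variables of x_i where
#' the row bit is 1 and (1 - x_i) where it is 0.
#'
#' @param assignment named numeric vector of probabilities in \[0, 1\], one
#'   per variable.
#' @param minterm 0/1 vector, one bit per variable.
#' @param vars variable names corresponding to `minterm`, in order.  Defaults
#'   to `names(assignment)`.
#' @return the row probability, a value in \[0, 1\].
#' @examples
#' minterm_probability(c(a = 0.7, b = 0.6), c(1, 1))  # 0.42
#' @export
minterm_probability <- function(assignment, minterm, vars = names(assignment)) {
  check_assignment(assignment, vars)
  if (length(minterm) != length(vars))
    config_error("minterm length does not match number of variables")
  if (!all(minterm %in% c(0, 1)))
    config_error("minterm bits must be 0 or 1")
  x <- assignment[vars]
  prod(ifelse(minterm == 1, x, 1 - x))
}

check_assignment <- function(assignment, vars) {
  if (is.null(names(assignment)) && length(assignment) == length(vars)) {
    # unnamed vectors are accepted positionally via the caller's `vars`
    names(assignment) <- vars
  }
  missing <- setdiff(vars, names(assignment))
  if (length(missing))
    config_error(paste0("assignment is missing variable(s): ",
                        paste(missing, collapse = ", ")))
  x <- assignment[vars]
  if (anyNA(x) || any(x < 0) || any(x > 1))
    domain_error("probabilities must lie in [0, 1]")
  invisible(x)
}

#' Resolve shared-variable bindings into a full assignment
#'
#' Univariate targets are often computed with several table columns carrying
#' the same value x.  Each column remains an independent random variable (an
#' independent species pair); the binding only records that they are
#' initialized with the same probability.
#'
#' @param values named numeric vector of probabilities keyed by alias (or
#'   directly by variable).
#' @param bindings named list: alias -> character vector of table columns
#'   sharing that value.
#' @return a named numeric vector covering all bound columns plus any
#'   directly-named variables.
#' @examples
#' bind_assignment(c(x = 0.3), list(x = c("x1", "x2", "x3")))
#' @export
bind_assignment <- function(values, bindings = list()) {
  out <- values
  for (alias in names(bindings)) {
    if (!alias %in% names(values))
      config_error(sprintf("binding alias '%s' has no value", alias))
    cols <- bindings[[alias]]
    out <- out[setdiff(names(out), alias)]
    out[cols] <- values[[alias]]
  }
  out
}

#' Evaluate the stochastic function of a truth table
#'
#' The probability that the function output is 1 equals the sum of the
#' probabilities of all minterms whose table output is 1, with each row
#' probability the product of per-variable Bernoulli factors.  This is the
#' exact closed form that a compiled CRN computes at equal rate constants.
#'
#' @param tt a [truth_table()].
#' @param assignment named numeric vector of input probabilities in \[0, 1\]
#'   (may use `bindings` aliases).
#' @param bindings optional named list passed to [bind_assignment()].
#' @return the function value, in \[0, 1\].
#' @examples
#' stoch_value(gate_table("AND"), c(a = 0.7, b = 0.6))  # 0.42
#' @export
stoch_value <- function(tt, assignment, bindings = list()) {
  stopifnot(inherits(tt, "truth_table"))
  if (length(bindings)) assignment <- bind_assignment(assignment, bindings)
  x <- check_assignment(assignment, tt$vars)
  bits <- minterm_matrix(tt$n)
  # row probabilities, vectorized over all 2^n minterms
  probs <- rep(1, nrow(bits))
  for (i in seq_len(tt$n))
    probs <- probs * ifelse(bits[, i] == 1, x[i], 1 - x[i])
  sum(probs[tt$outputs == 1L])
}

# Probabilities of all 2^n rows (canonical order); sums to 1 for any
# assignment -- the normalization that makes the fractional readout exact.
row_probabilities <- function(tt, assignment) {
  x <- check_assignment(assignment, tt$vars)
  bits <- minterm_matrix(tt$n)
  probs <- rep(1, nrow(bits))
  for (i in seq_len(tt$n))
    probs <- probs * ifelse(bits[, i] == 1, x[i], 1 - x[i])
  probs
}
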