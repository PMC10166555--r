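#' Multilinear polynomials
#'
#' The stochastic function of any truth table is a multilinear polynomial:
#' no variable appears with power above 1.  Coefficients are stored in a map
#' from variable subsets to reals; the empty subset (key `"1"`) is the
#' constant term.
#'
#' @param coeffs named numeric vector; each name is a subset key, variables
#'   joined by `"*"` in the order of `vars` (e.g. `"a*b"`), or `"1"` for the
#'   constant term.
#' @param vars character vector giving the variable universe and order.
#' @return an object of class `mlpoly`.
#' @examples
#' mlpoly(c("1" = 1, "a" = -1, "b" = -1, "a*b" = 1), vars = c("a", "b"))
#' @seealso [tt_to_polynomial()], [eval_polynomial()], [parse_polynomial()]
#' @export
mlpoly <- function(coeffs, vars) {
  vars <- as.character(vars)
  if (anyDuplicated(vars)) config_error("duplicate variable names")
  coeffs <- coeffs[coeffs != 0]
  keys <- names(coeffs)
  if (length(coeffs) && is.null(keys))
    config_error("coefficients must be named by variable subset")
  canon <- vapply(keys, function(k) canonical_key(k, vars), character(1))
  if (anyDuplicated(canon)) config_error("duplicate terms in polynomial")
  names(coeffs) <- canon
  structure(list(coeffs = coeffs, vars = vars), class = "mlpoly")
}

canonical_key <- function(key, vars) {
  if (key %in% c("", "1")) return("1")
  parts <- strsplit(key, "*", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  unknown <- setdiff(parts, vars)
  if (length(unknown))
    config_error(paste0("unknown variable(s) in term '", key, "': ",
                        paste(unknown, collapse = ", ")))
  if (anyDuplicated(parts))
    config_error(paste0("term '", key, "' is not multilinear"))
  paste(vars[vars %in% parts], collapse = "*")
}

#' Look up one coefficient of a multilinear polynomial
#'
#' @param p an [mlpoly()].
#' @param term character vector of variables in the term (possibly empty for
#'   the constant), or a single `"a*b"` style key.
#' @return the coefficient (0 if the term is absent).
#' @export
poly_coef <- function(p, term = character()) {
  stopifnot(inherits(p, "mlpoly"))
  key <- if (length(term) == 1 && grepl("\\*", term)) term
         else paste(term, collapse = "*")
  key <- canonical_key(if (length(term) == 0) "1" else key, p$vars)
  if (key %in% names(p$coeffs)) unname(p$coeffs[[key]]) else 0
}

#' Expand a truth table into its stochastic-function polynomial
#'
#' Sums, over all rows with output 1, the product of factors x_i (bit 1) or
#' (1 - x_i) (bit 0), and expands.  The expansion is computed exactly with a
#' Moebius transform over variable subsets, so coefficients of 0/1 tables are
#' integers.
#'
#' @param tt a [truth_table()].
#' @return an [mlpoly()] over the table's variables.
#' @examples
#' tt_to_polynomial(xor3_table())
#' # x + y + z - 2*x*y - 2*x*z - 2*y*z + 4*x*y*z
#' @export
tt_to_polynomial <- function(tt) {
  stopifnot(inherits(tt, "truth_table"))
  n <- tt$n
  # f(x) = sum_S c_S prod_{i in S} x_i with c_S = sum_{T subset S} (-1)^(|S\T|) F(T),
  # where subset T <-> the minterm whose bit i is 1 iff i in T.
  # Row index of that minterm: variable i has weight 2^(n-i), i.e. bit (n-i).
  f <- as.numeric(tt$outputs)        # indexed by subset mask + 1
  # in-place superset Moebius transform over bits 0..n-1
  for (b in 0:(n - 1)) {
    w <- 2^b
    for (mask in 0:(2^n - 1)) {
      if (bitwAnd(mask, w) != 0)
        f[mask + 1] <- f[mask + 1] - f[mask - w + 1]
    }
  }
  keys <- character(0); vals <- numeric(0)
  for (mask in 0:(2^n - 1)) {
    if (f[mask + 1] != 0) {
      members <- tt$vars[bitwAnd(mask, 2^(n - seq_len(n))) != 0]
      keys <- c(keys, if (length(members)) paste(members, collapse = "*") else "1")
      vals <- c(vals, f[mask + 1])
    }
  }
  mlpoly(setNames(vals, keys), vars = tt$vars)
}

#' Evaluate a multilinear polynomial
#'
#' @param p an [mlpoly()].
#' @param assignment named numeric vector covering the polynomial's variables.
#' @return the numeric value.
#' @export
eval_polynomial <- function(p, assignment) {
  stopifnot(inherits(p, "mlpoly"))
  missing <- setdiff(p$vars, names(assignment))
  if (length(missing))
    config_error(paste0("assignment is missing variable(s): ",
                        paste(missing, collapse = ", ")))
  total <- 0
  for (key in names(p$coeffs)) {
    term <- if (key == "1") 1
            else prod(assignment[strsplit(key, "*", fixed = TRUE)[[1]]])
    total <- total + p$coeffs[[key]] * term
  }
  unname(total)
}

#' Recover the truth table of a Boolean-valued multilinear polynomial
#'
#' Evaluates the polynomial at every 0/1 vertex.  If every vertex value is
#' (within `tol`) exactly 0 or 1 the polynomial is the stochastic function of
#' a single truth table, which is returned; otherwise an error of class
#' `stochcrn_not_boolean` is raised.
#'
#' @param p an [mlpoly()].
#' @param name output column name for the resulting table.
#' @param tol tolerance for the vertex Booleanness check (default 1e-9).
#' @return a [truth_table()].
#' @examples
#' polynomial_to_tt(parse_polynomial("1 - a - b + a*b"))  # the NOR table
#' @export
polynomial_to_tt <- function(p, name = "F", tol = 1e-9) {
  stopifnot(inherits(p, "mlpoly"))
  n <- length(p$vars)
  if (n == 0) stop_stochcrn("polynomial has no variables", "stochcrn_not_boolean")
  bits <- minterm_matrix(n)
  vals <- apply(bits, 1, function(row)
    eval_polynomial(p, setNames(row, p$vars)))
  rounded <- round(vals)
  if (any(abs(vals - rounded) > tol) || any(!rounded %in% c(0, 1)))
    stop_stochcrn(
      sprintf("vertex value %.6g is not 0 or 1: not implementable as a single truth table",
              vals[which.max(abs(vals - pmin(pmax(rounded, 0), 1)))]),
      "stochcrn_not_boolean")
  truth_table(as.integer(rounded), vars = p$vars, name = name)
}

#' @export
format.mlpoly <- function(x, ...) {
  if (length(x$coeffs) == 0) return("0")
  # constant first, then terms by subset size then variable order
  keys <- names(x$coeffs)
  size <- vapply(keys, function(k)
    if (k == "1") 0L else length(strsplit(k, "*", fixed = TRUE)[[1]]), integer(1))
  pos <- vapply(keys, function(k) {
    if (k == "1") return(0)
    idx <- match(strsplit(k, "*", fixed = TRUE)[[1]], x$vars)
    sum(idx * length(x$vars)^rev(seq_along(idx) - 1))
  }, numeric(1))
  ord <- order(size, pos)
  pieces <- character(0)
  for (j in ord) {
    k <- keys[j]; cf <- x$coeffs[[j]]
    mag <- abs(cf)
    coef_str <- if (mag == round(mag)) format(mag) else format(mag, digits = 12)
    body <- if (k == "1") coef_str
            else if (mag == 1) k
            else paste0(coef_str, "*", k)
    op <- if (length(pieces) == 0) (if (cf < 0) "-" else "")
          else (if (cf < 0) " - " else " + ")
    pieces <- c(pieces, paste0(op, body))
  }
  paste(pieces, collapse = "")
}

#' @export
print.mlpoly <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a polynomial from text
#'
#' Accepts the `"1 - a - b + a*b"` style emitted by [format.mlpoly()]:
#' terms joined by `+`/`-`, each term an optional numeric coefficient and
#' `*`-separated variables.  Repeating a variable within a term is rejected
#' (the representation is multilinear).
#'
#' @param text a single string.
#' @param vars optional variable universe/order; defaults to order of first
#'   appearance.
#' @return an [mlpoly()].
#' @export
parse_polynomial <- function(text, vars = NULL) {
  s <- gsub("[[:space:]]", "", as.character(text)[1])
  if (s == "") config_error("empty polynomial text")
  if (!grepl("^[+-]?[A-Za-z0-9.*+-]+$", s))
    config_error(paste0("cannot parse polynomial: ", text))
  terms <- regmatches(s, gregexpr("[+-]?[^+-]+", s))[[1]]
  keys <- character(0); vals <- numeric(0); seen_vars <- character(0)
  for (t in terms) {
    sign <- 1
    if (startsWith(t, "-")) { sign <- -1; t <- substring(t, 2) }
    else if (startsWith(t, "+")) t <- substring(t, 2)
    if (t == "") config_error(paste0("cannot parse polynomial: ", text))
    factors <- strsplit(t, "*", fixed = TRUE)[[1]]
    coef <- sign; members <- character(0)
    for (f in factors) {
      if (grepl("^[0-9.]+$", f)) coef <- coef * as.numeric(f)
      else if (grepl("^[A-Za-z][A-Za-z0-9.]*$", f)) members <- c(members, f)
      else config_error(paste0("cannot parse term '", t, "'"))
    }
    if (anyDuplicated(members))
      config_error(paste0("term '", t, "' is not multilinear"))
    seen_vars <- union(seen_vars, members)
    key <- if (length(members)) paste(members, collapse = "*") else "1"
    if (key %in% keys) vals[match(key, keys)] <- vals[match(key, keys)] + coef
    else { keys <- c(keys, key); vals <- c(vals, coef) }
  }
  if (is.null(vars)) vars <- seen_vars
  mlpoly(setNames(vals, keys), vars = vars)
}
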