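#' Construct a chemical reaction network
#'
#' A CRN is a set of species and an ordered list of irreversible mass-action
#' reactions with positive integer stoichiometry and per-reaction rate
#' constants.  Species carrying fractional values come in pairs named
#' `<var>_0` / `<var>_1`; the value is the fraction of the `_1` member
#' (see [encode_fraction()]).
#'
#' @param reactions list of reactions, each a list with fields `reactants`
#'   and `products` (named numeric vectors of positive integer stoichiometric
#'   coefficients, names are species ids) and `k` (positive rate constant).
#' @param species optional character vector of species ids; defaults to the
#'   union appearing in reactions.
#' @param input_pairs optional named list: variable -> character(2) of the
#'   `_0`/`_1` species ids.
#' @param output_pair optional character(2) for the output pair.
#' @return an object of class `crn`.
#' @seealso [compile_crn()], [simulate_crn()], [read_crn()]
#' @export
crn <- function(reactions, species = NULL, input_pairs = NULL,
                output_pair = NULL) {
  if (!length(reactions)) config_error("a CRN needs at least one reaction")
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    if (is.null(r$reactants) || is.null(r$products) ||
        !length(r$reactants) || !length(r$products))
      config_error(sprintf("reaction %d: needs at least one reactant and one product", j))
    if (is.null(names(r$reactants)) || is.null(names(r$products)))
      config_error(sprintf("reaction %d: stoichiometry vectors must be named", j))
    coefs <- c(r$reactants, r$products)
    if (any(coefs <= 0) || any(coefs != round(coefs)))
      config_error(sprintf("reaction %d: stoichiometric coefficients must be positive integers", j))
    if (is.null(r$k) || !is.finite(r$k) || r$k <= 0)
      config_error(sprintf("reaction %d: rate constant must be positive", j))
  }
  seen <- unique(unlist(lapply(reactions, function(r)
    c(names(r$reactants), names(r$products)))))
  if (is.null(species)) species <- seen
  else if (length(setdiff(seen, species)))
    config_error("reactions reference species not in the species list")
  if (anyDuplicated(species)) config_error("duplicate species ids")
  structure(
    list(species = species, reactions = reactions,
         input_pairs = input_pairs, output_pair = output_pair),
    class = "crn"
  )
}

species_id <- function(var, index) paste0(var, "_", index)

#' Compile a truth table into a chemical reaction network
#'
#' Produces the canonical network computing the table's stochastic function:
#' one reaction per minterm, in canonical row order.  Reaction j consumes one
#' molecule of `Xi_<bit>` for each input variable (bits of minterm j) and
#' produces one molecule of the output species indexed by the table output,
#' `Y_0` or `Y_1`.  The network has 2^n reactions over 2n + 2 species.  With
#' all rate constants equal, the decoded output fraction equals the
#' stochastic function of the table exactly, at any time with nonzero output.
#'
#' @param tt a [truth_table()].
#' @param k rate constant(s): a single positive value shared by all
#'   reactions (the correctness condition), or a vector of length 2^n for
#'   perturbation studies.
#' @return a [crn()] with `input_pairs` and `output_pair` set.
#' @examples
#' compile_crn(gate_table("NOR"))
#' @export
compile_crn <- function(tt, k = 100) {
  stopifnot(inherits(tt, "truth_table"))
  nr <- 2^tt$n
  if (!length(k) %in% c(1L, nr))
    config_error(sprintf("k must have length 1 or %d", nr))
  if (any(!is.finite(k)) || any(k <= 0))
    config_error("rate constants must be positive and finite")
  k <- rep_len(as.numeric(k), nr)
  bits <- minterm_matrix(tt$n)
  reactions <- vector("list", nr)
  for (j in seq_len(nr)) {
    reactants <- setNames(rep(1, tt$n),
                          species_id(tt$vars, bits[j, ]))
    products <- setNames(1, species_id(tt$name, tt$outputs[j]))
    reactions[[j]] <- list(reactants = reactants, products = products, k = k[j])
  }
  pairs <- lapply(tt$vars, function(v) c(species_id(v, 0), species_id(v, 1)))
  names(pairs) <- tt$vars
  species <- c(unlist(pairs, use.names = FALSE),
               species_id(tt$name, 0), species_id(tt$name, 1))
  crn(reactions, species = species, input_pairs = pairs,
      output_pair = c(species_id(tt$name, 0), species_id(tt$name, 1)))
}

# Pretty form: A_0 rendered A0 when the base name has no trailing digit.
pretty_species <- function(ids) {
  ok <- grepl("^[A-Za-z.][A-Za-z0-9._]*[^0-9_]_[01]$", ids) |
        grepl("^[A-Za-z.]_[01]$", ids)
  ifelse(ok, sub("_", "", ids), ids)
}

format_reaction <- function(r, pretty = FALSE) {
  side <- function(v) {
    ids <- names(v)
    if (pretty) ids <- pretty_species(ids)
    paste(ifelse(v == 1, ids, paste(v, ids)), collapse = " + ")
  }
  paste0(side(r$reactants), " -> ", side(r$products), " ; k=",
         format(r$k, digits = 15))
}

#' @export
print.crn <- function(x, ...) {
  cat(sprintf("CRN: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  for (r in x$reactions) cat(" ", format_reaction(r, pretty = TRUE), "\n")
  invisible(x)
}

#' Encode a fractional value as a species-pair concentration
#'
#' A value x in \[0, 1\] is represented by the pair (\[X0\], \[X1\]) =
#' (total (1 - x), total x), so that x = \[X1\]/(\[X0\]+\[X1\]).
#'
#' @param x value in \[0, 1\].
#' @param total total pair concentration (default 100, the convention used
#'   throughout the robustness sweeps).
#' @return numeric vector `c(X0, X1)`.
#' @examples
#' encode_fraction(0.7, 100)  # c(30, 70)
#' @export
encode_fraction <- function(x, total = 100) {
  if (!is.finite(x) || x < 0 || x > 1)
    domain_error("fractional value must lie in [0, 1]")
  if (!is.finite(total) || total <= 0)
    domain_error("pair total must be positive")
  c(total * (1 - x), total * x)
}

#' Decode a species pair into its fractional value
#'
#' @param pair numeric vector `c(X0, X1)` of nonnegative concentrations.
#'   Negative values within `-1e-9` (solver overshoot) are clipped to 0.
#' @return the fraction `X1 / (X0 + X1)`.  A zero pair total raises an error
#'   of class `stochcrn_undefined_fraction`.
#' @export
decode_fraction <- function(pair) {
  if (length(pair) != 2 || anyNA(pair))
    domain_error("pair must be two concentrations")
  if (any(pair < -1e-9))
    domain_error("concentrations must be nonnegative")
  pair <- pmax(pair, 0)
  tot <- sum(pair)
  if (tot == 0)
    stop_stochcrn("pair total is zero: fraction undefined",
                  "stochcrn_undefined_fraction")
  pair[2] / tot
}

#' Plan fan-out of one network's output to several consumers
#'
#' To feed one CRN's output into m downstream networks, its input volumes
#' are scaled up by a factor of m and the output volume is split into m equal
#' parts.  Splitting divides totals but never changes fractions.
#'
#' @param consumers number of downstream consumers (integer >= 1).
#' @param base_total pair total each consumer expects.
#' @return a list with `consumers`, `base_total`, `scaled_total`
#'   (= consumers * base_total, the total at which the producing stage's
#'   inputs must be encoded) and `split_fraction` (= 1/consumers).
#' @export
plan_fanout <- function(consumers, base_total = 100) {
  if (consumers < 1 || consumers != round(consumers))
    config_error("consumers must be a positive integer")
  if (base_total <= 0) domain_error("base_total must be positive")
  structure(list(consumers = as.integer(consumers), base_total = base_total,
                 scaled_total = consumers * base_total,
                 split_fraction = 1 / consumers),
            class = "fanout_plan")
}

#' Split an output pair volumetrically into equal parts
#'
#' @param pair numeric `c(Y0, Y1)`.
#' @param parts number of equal parts.
#' @return list of `parts` pairs, each `pair / parts` (same fraction).
#' @export
split_output <- function(pair, parts) {
  if (parts < 1 || parts != round(parts))
    config_error("parts must be a positive integer")
  replicate(parts, pair / parts, simplify = FALSE)
}

#' Write a CRN in plain-text reaction format
#'
#' One reaction per line, `A_0 + B_1 -> C_0 ; k=100`, stoichiometric
#' coefficients above 1 written as `2 X_1`.  Header comments record the
#' format version and, when present, the input variables and output pair so
#' that [read_crn()] round-trips compiled networks.
#'
#' @param x a [crn()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_crn <- function(x, file) {
  stopifnot(inherits(x, "crn"))
  header <- c("# crn-format: 1")
  if (!is.null(x$input_pairs))
    header <- c(header, paste("# inputs:", paste(names(x$input_pairs), collapse = " ")))
  if (!is.null(x$output_pair))
    header <- c(header, paste("# output:",
                              sub("_[01]$", "", x$output_pair[1])))
  writeLines(c(header, vapply(x$reactions, format_reaction, character(1))),
             file)
  invisible(file)
}

#' Read a CRN from plain-text reaction format
#'
#' @param file path written by [write_crn()] (or hand-written in the same
#'   format).
#' @return a [crn()].
#' @export
read_crn <- function(file) {
  lines <- readLines(file)
  inputs <- NULL; output <- NULL
  hdr <- grep("^#", lines, value = TRUE)
  m <- grep("^# inputs:", hdr, value = TRUE)
  if (length(m)) inputs <- strsplit(trimws(sub("^# inputs:", "", m[1])), " +")[[1]]
  m <- grep("^# output:", hdr, value = TRUE)
  if (length(m)) output <- trimws(sub("^# output:", "", m[1]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) config_error(sprintf("%s: no reactions found", file))
  parse_side <- function(txt, where) {
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    coefs <- numeric(0)
    for (t in terms) {
      mt <- regmatches(t, regexec("^([0-9]+[[:space:]]+)?([A-Za-z._][A-Za-z0-9._]*)$", t))[[1]]
      if (length(mt) == 0 || mt[3] == "")
        config_error(sprintf("%s: cannot parse species term '%s'", where, t))
      coef <- if (nzchar(trimws(mt[2]))) as.numeric(trimws(mt[2])) else 1
      id <- mt[3]
      coefs[id] <- (if (id %in% names(coefs)) coefs[id] else 0) + coef
    }
    coefs
  }
  reactions <- vector("list", length(body))
  for (j in seq_along(body)) {
    ln <- body[j]
    where <- sprintf("%s reaction %d", file, j)
    parts <- strsplit(ln, ";", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !grepl("k[[:space:]]*=", parts[2]))
      config_error(sprintf("%s: missing '; k=' clause", where))
    k <- as.numeric(trimws(sub("^[[:space:]]*k[[:space:]]*=", "", trimws(parts[2]))))
    sides <- strsplit(parts[1], "->", fixed = TRUE)[[1]]
    if (length(sides) != 2)
      config_error(sprintf("%s: expected exactly one '->'", where))
    reactions[[j]] <- list(reactants = parse_side(sides[1], where),
                           products = parse_side(sides[2], where), k = k)
  }
  pairs <- NULL
  if (!is.null(inputs)) {
    pairs <- lapply(inputs, function(v) c(species_id(v, 0), species_id(v, 1)))
    names(pairs) <- inputs
  }
  out_pair <- if (!is.null(output)) c(species_id(output, 0), species_id(output, 1))
  crn(reactions, input_pairs = pairs, output_pair = out_pair)
}
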