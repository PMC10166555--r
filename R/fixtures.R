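#' Generate truth-table fixtures with expected values
#'
#' Writes one or more truth-table CSV files plus a JSON file of expected
#' values (the polynomial text and exact stochastic-function values at a few
#' seeded random assignments), for use as test inputs or CLI examples.
#' Deterministic for a fixed seed.
#'
#' @param kind `"random_table"` (a random n-input table), `"gate"` (one of
#'   the standard gates), `"xor3"` (3-input parity) or `"examples"` (the
#'   NOR, AND, 3-input worked-example and XOR-3 tables).
#' @param dir output directory (created if needed).
#' @param n number of inputs for `random_table` (at most 8).
#' @param seed integer seed (drives the random table and the evaluation
#'   points).
#' @param gate gate name for `kind = "gate"`.
#' @return character vector of the CSV paths written, invisibly.
#' @export
generate_fixture <- function(kind = c("random_table", "gate", "xor3", "examples"),
                             dir = ".", n = 3, seed = 1, gate = "AND") {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- switch(kind,
    random_table = {
      if (n < 1 || n > 8) config_error("random_table needs 1 <= n <= 8")
      outs <- with_seed(seed, sample(0:1, 2^n, replace = TRUE))
      setNames(list(truth_table(outs, name = "F")),
               sprintf("random_n%d_seed%d", n, seed))
    },
    gate = setNames(list(gate_table(gate)), tolower(gate)),
    xor3 = list(xor3 = xor3_table()),
    examples = list(nor = gate_table("NOR"), and = gate_table("AND"),
                    demo3 = demo3_table(), xor3 = xor3_table())
  )
  paths <- character(0)
  for (nm in names(tables)) {
    tt <- tables[[nm]]
    csv <- file.path(dir, paste0(nm, ".csv"))
    write_truth_table(tt, csv)
    points <- with_seed(seed + 1, lapply(1:3, function(i)
      round(setNames(runif(tt$n), tt$vars), 4)))
    expected <- list(
      name = nm,
      vars = tt$vars,
      outputs = tt$outputs,
      polynomial = format(tt_to_polynomial(tt)),
      seed = seed,
      evaluations = lapply(points, function(p)
        list(assignment = as.list(p), value = stoch_value(tt, p)))
    )
    jsonlite::write_json(expected, file.path(dir, paste0(nm, "_expected.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, csv)
  }
  invisible(paths)
}
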