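#' Plan a cascade of compiled CRNs
#'
#' Because a compiled network's output uses the same fractional encoding as
#' its inputs, outputs can feed downstream networks.  A cascade plan is a
#' directed acyclic wiring of stages; execution is sequential (each stage
#' runs to completion before its consumers), with input volumes scaled so
#' that every stage's output can be split volumetrically among its
#' consumers without changing any fraction.
#'
#' @param stages named list of [crn()]s (each with input pairs and an output
#'   pair).
#' @param wiring list of connections, each `list(from = <stage>, to =
#'   <stage>, var = <input variable of `to`>)`.  Cyclic wiring is rejected.
#' @return an object of class `cascade_plan` with stages in topological
#'   order and the per-stage pair total required for a unit `base_total`
#'   at the sinks.
#' @examples
#' plan <- cascade_plan(
#'   list(mul = compile_crn(gate_table("AND")),
#'        inv = compile_crn(gate_table("NOT"))),
#'   list(list(from = "mul", to = "inv", var = "a")))
#' @export
cascade_plan <- function(stages, wiring = list()) {
  if (is.null(names(stages)) || any(!nzchar(names(stages))))
    config_error("stages must be a named list")
  for (s in stages) {
    stopifnot(inherits(s, "crn"))
    if (is.null(s$input_pairs) || is.null(s$output_pair))
      config_error("every stage needs input pairs and an output pair")
  }
  nm <- names(stages)
  for (w in wiring) {
    if (!all(c("from", "to", "var") %in% names(w)))
      config_error("each wiring entry needs from, to and var")
    if (!w$from %in% nm || !w$to %in% nm)
      config_error(sprintf("wiring references unknown stage '%s'",
                           setdiff(c(w$from, w$to), nm)[1]))
    if (!w$var %in% names(stages[[w$to]]$input_pairs))
      config_error(sprintf("stage '%s' has no input variable '%s'",
                           w$to, w$var))
  }
  # Kahn topological sort over stages
  edges_from <- lapply(setNames(nm, nm), function(s)
    vapply(Filter(function(w) w$from == s, wiring), `[[`, character(1), "to"))
  indeg <- setNames(integer(length(nm)), nm)
  for (w in wiring) indeg[w$to] <- indeg[w$to] + 1L
  order <- character(0)
  ready <- nm[indeg == 0]
  while (length(ready)) {
    s <- ready[1]; ready <- ready[-1]
    order <- c(order, s)
    for (t in edges_from[[s]]) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0) ready <- c(ready, t)
    }
  }
  if (length(order) != length(nm))
    config_error("cyclic wiring: cascade stages must form a DAG")
  # volumetric requirement: a stage must produce enough output total to
  # cover all its consumers, so its inputs are encoded at the summed need
  required <- setNames(rep(NA_real_, length(nm)), nm)
  for (s in rev(order)) {
    cons <- edges_from[[s]]
    required[s] <- if (!length(cons)) 1 else sum(required[cons])
  }
  structure(list(stages = stages[order], wiring = wiring,
                 order = order, required_total = required),
            class = "cascade_plan")
}

#' Execute a cascade plan
#'
#' Runs each stage to completion in topological order, decodes its output
#' fraction, splits the output volumetrically among consumers and feeds the
#' fraction (unchanged by splitting) into the wired downstream inputs.
#'
#' @param plan a [cascade_plan()].
#' @param inputs named list: stage -> named vector of fractions for that
#'   stage's externally supplied (unwired) input variables.
#' @param base_total pair total at the sink stages (default 100); upstream
#'   stages are automatically scaled up per the fan-out plan.
#' @param ... passed to [simulate_crn()].
#' @return list with `outputs` (decoded output fraction per sink stage),
#'   `stage_outputs` (all stages), `sims` and `totals` (pair totals used).
#' @examples
#' \donttest{
#' plan <- cascade_plan(
#'   list(mul = compile_crn(gate_table("AND")),
#'        inv = compile_crn(gate_table("NOT"))),
#'   list(list(from = "mul", to = "inv", var = "a")))
#' run_cascade(plan, list(mul = c(a = 0.7, b = 0.6)))$outputs  # 1 - 0.42
#' }
#' @export
run_cascade <- function(plan, inputs, base_total = 100, ...) {
  stopifnot(inherits(plan, "cascade_plan"))
  totals <- plan$required_total * base_total
  wired_vars <- lapply(setNames(plan$order, plan$order), function(s)
    vapply(Filter(function(w) w$to == s, plan$wiring), `[[`, character(1), "var"))
  stage_out <- setNames(rep(NA_real_, length(plan$order)), plan$order)
  sims <- list()
  for (s in plan$order) {
    net <- plan$stages[[s]]
    vars <- names(net$input_pairs)
    frac <- setNames(rep(NA_real_, length(vars)), vars)
    ext <- if (s %in% names(inputs)) inputs[[s]] else numeric(0)
    frac[intersect(vars, names(ext))] <- ext[intersect(vars, names(ext))]
    for (w in Filter(function(w) w$to == s, plan$wiring))
      frac[w$var] <- stage_out[w$from]
    if (anyNA(frac))
      config_error(sprintf("stage '%s': no value for input(s) %s", s,
                           paste(vars[is.na(frac)], collapse = ", ")))
    sim <- simulate_crn(net, fractions = frac, totals = unname(totals[[s]]), ...)
    sims[[s]] <- sim
    stage_out[s] <- sim$outputs[[1]]
  }
  sinks <- plan$order[vapply(plan$order, function(s)
    !any(vapply(plan$wiring, function(w) w$from == s, logical(1))), logical(1))]
  list(outputs = stage_out[sinks], stage_outputs = stage_out,
       sims = sims, totals = totals)
}
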