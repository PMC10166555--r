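stoich_matrices <- function(x) {
  stopifnot(inherits(x, "crn"))
  ns <- length(x$species); nr <- length(x$reactions)
  Rm <- matrix(0, ns, nr, dimnames = list(x$species, NULL))
  Pm <- matrix(0, ns, nr, dimnames = list(x$species, NULL))
  for (j in seq_len(nr)) {
    r <- x$reactions[[j]]
    Rm[names(r$reactants), j] <- r$reactants
    Pm[names(r$products), j] <- Pm[names(r$products), j] + r$products
  }
  list(R = Rm, P = Pm, S = Pm - Rm,
       k = vapply(x$reactions, `[[`, numeric(1), "k"))
}

#' Build the mass-action ODE right-hand side of a CRN
#'
#' Under mass-action kinetics the velocity of each reaction is its rate
#' constant times the product of reactant concentrations raised to their
#' stoichiometric coefficients; the derivative of each species is the
#' stoichiometry-weighted sum of velocities.  The returned function has the
#' `function(t, state, parms)` signature expected by [deSolve::lsoda()] and
#' returns `list(dstate)`; `state` must be ordered as `x$species`.
#'
#' @param x a [crn()].
#' @return a derivative function (closure over the stoichiometry).
#' @examples
#' net <- compile_crn(gate_table("AND"), k = 2)
#' f <- crn_ode(net)
#' f(0, c(A_0 = 1, A_1 = 2, B_0 = 3, B_1 = 4, c_0 = 0, c_1 = 0), NULL)
#' @export
crn_ode <- function(x) {
  m <- stoich_matrices(x)
  species <- rownames(m$R)
  function(t, state, parms) {
    conc <- pmax(as.numeric(state), 0)  # rate law only; state untouched
    v <- m$k
    for (s in seq_along(conc)) {
      e <- m$R[s, ]
      nz <- e != 0
      if (any(nz)) v[nz] <- v[nz] * conc[s]^e[nz]
    }
    list(setNames(as.numeric(m$S %*% v), species))
  }
}

#' Initial concentration state for a compiled CRN
#'
#' Encodes each input fraction over its species pair at the given pair total
#' and initializes the output pair (and any other species) to zero.
#'
#' @param x a [crn()] with `input_pairs`.
#' @param fractions named numeric vector of values in \[0, 1\], one per input
#'   variable.
#' @param totals pair total(s): a single value (default 100) or a named
#'   vector per variable.
#' @return named numeric state vector over `x$species`.
#' @export
initial_state <- function(x, fractions, totals = 100) {
  stopifnot(inherits(x, "crn"))
  if (is.null(x$input_pairs))
    config_error("CRN has no input pairs; supply a full state instead")
  vars <- names(x$input_pairs)
  missing <- setdiff(vars, names(fractions))
  if (length(missing))
    config_error(paste0("fractions missing for variable(s): ",
                        paste(missing, collapse = ", ")))
  if (length(totals) == 1 && is.null(names(totals)))
    totals <- setNames(rep(totals, length(vars)), vars)
  state <- setNames(numeric(length(x$species)), x$species)
  for (v in vars) {
    pair <- encode_fraction(fractions[[v]], totals[[v]])
    state[x$input_pairs[[v]]] <- pair
  }
  state
}

#' Simulate a CRN's mass-action kinetics to input exhaustion
#'
#' Integrates the mass-action ODEs with an adaptive stiff solver
#' ([deSolve::lsoda()]) over successively extended horizons until every
#' input pair total has fallen below `completion_eps` times its initial
#' value, or until the decoded output is stable to 1e-8 across a horizon
#' extension.  The initial horizon is the heuristic `10 / (kmax * total^(n-1))`
#' (the natural timescale of an n-input network), extended by
#' `horizon_factor` per chunk with geometrically spaced samples.
#'
#' @param x a [crn()].
#' @param init full named initial state (optional if `fractions` given).
#'   Output species default to 0.
#' @param fractions,totals convenience alternative to `init`, passed to
#'   [initial_state()].
#' @param rel_tol,abs_tol solver tolerances (defaults 1e-8 / 1e-10).
#' @param completion_eps relative input-depletion threshold (default 1e-6).
#' @param samples_per_chunk trajectory samples recorded per horizon chunk
#'   (default 24, giving a few hundred samples over a typical run).
#' @param horizon_factor horizon growth per chunk (default 100).
#' @param max_chunks maximum number of horizon extensions before a
#'   `stochcrn_convergence_error` (carrying the last state) is raised.
#' @param times optional explicit time grid; if supplied, the ODEs are
#'   integrated over exactly these times with no completion logic (useful
#'   for general, non-compiled networks).
#' @param engine `"compiled"` (C derivative, default) or `"R"`
#'   ([crn_ode()]); both compute identical rate laws.
#' @return an object of class `crn_sim`: list with `times`, `traj` (matrix,
#'   one column per species, negative overshoot clipped at readout),
#'   `final_state`, `outputs` (named decoded fraction, for networks with an
#'   output pair), `converged`, `criterion` (`"depletion"` or `"stability"`),
#'   `chunks` and `min_conc` (most negative raw value seen).
#' @examples
#' net <- compile_crn(gate_table("AND"))
#' sim <- simulate_crn(net, fractions = c(a = 0.7, b = 0.6))
#' sim$outputs  # c = 0.42
#' @export
simulate_crn <- function(x, init = NULL, fractions = NULL, totals = 100,
                         rel_tol = 1e-8, abs_tol = 1e-10,
                         completion_eps = 1e-6, samples_per_chunk = 24,
                         horizon_factor = 100, max_chunks = 20,
                         times = NULL, engine = c("compiled", "R")) {
  stopifnot(inherits(x, "crn"))
  engine <- match.arg(engine)
  if (is.null(init)) {
    if (is.null(fractions))
      config_error("supply either init or fractions")
    init <- initial_state(x, fractions, totals)
  } else {
    state0 <- setNames(numeric(length(x$species)), x$species)
    unknown <- setdiff(names(init), x$species)
    if (length(unknown))
      config_error(paste0("unknown species in init: ",
                          paste(unknown, collapse = ", ")))
    state0[names(init)] <- init
    init <- state0
  }
  if (any(init < 0)) domain_error("initial concentrations must be nonnegative")

  m <- stoich_matrices(x)
  ode_fun <- NULL
  if (engine == "compiled") {
    .Call(ma_set_network, unname(m$R), unname(m$S), m$k)
  } else {
    ode_fun <- crn_ode(x)
  }
  integrate_chunk <- function(state, tms) {
    out <- if (engine == "compiled")
      deSolve::lsoda(y = unname(state), times = tms, func = "ma_deriv",
                     parms = NULL, rtol = rel_tol, atol = abs_tol,
                     dllname = "stochcrn", initfunc = NULL)
    else
      deSolve::lsoda(y = state, times = tms, func = ode_fun, parms = NULL,
                     rtol = rel_tol, atol = abs_tol)
    mat <- unname(as.matrix(out[, -1, drop = FALSE]))
    colnames(mat) <- x$species
    list(times = out[, 1], states = mat)
  }

  if (!is.null(times)) {
    ch <- integrate_chunk(init, times)
    return(finish_sim(x, ch$times, ch$states, converged = NA,
                      criterion = "fixed-times", chunks = 1L))
  }

  pairs <- x$input_pairs
  if (is.null(pairs))
    config_error("CRN has no input pairs; supply an explicit `times` grid")
  pair_total <- function(state)
    vapply(pairs, function(p) sum(pmax(state[p], 0)), numeric(1))
  totals0 <- pair_total(init)
  live <- totals0 > 0
  npairs <- length(pairs)
  kmax <- max(m$k)
  tot_ref <- max(totals0, 1e-12)
  t1 <- 10 / (kmax * tot_ref^(npairs - 1))

  all_t <- 0; all_states <- matrix(init, nrow = 1,
                                   dimnames = list(NULL, x$species))
  state <- init
  t_lo <- 0
  y_prev <- NA_real_
  converged <- FALSE; criterion <- NA_character_; used <- 0L
  for (i in seq_len(max_chunks)) {
    t_hi <- t1 * horizon_factor^(i - 1)
    tms <- if (t_lo == 0)
      c(0, t_hi * exp(seq(log(1e-3), 0, length.out = samples_per_chunk)))
    else
      exp(seq(log(t_lo), log(t_hi), length.out = samples_per_chunk + 1))
    ch <- integrate_chunk(state, tms)
    all_t <- c(all_t, ch$times[-1])
    all_states <- rbind(all_states, ch$states[-1, , drop = FALSE])
    state <- ch$states[nrow(ch$states), ]
    t_lo <- t_hi
    used <- i
    tots <- pair_total(state)
    depleted <- all(tots[live] <= completion_eps * totals0[live])
    y_now <- if (!is.null(x$output_pair) && sum(pmax(state[x$output_pair], 0)) > 0)
      decode_fraction(pmax(state[x$output_pair], 0)) else NA_real_
    stable <- !is.na(y_now) && !is.na(y_prev) && abs(y_now - y_prev) < 1e-8
    y_prev <- y_now
    if (depleted || stable) {
      converged <- TRUE
      criterion <- if (depleted) "depletion" else "stability"
      break
    }
  }
  if (!converged) {
    stop_stochcrn(
      sprintf("no completion within %d horizon extensions (t = %.3g)",
              max_chunks, t_lo),
      "stochcrn_convergence_error",
      last_state = state, time = t_lo)
  }
  finish_sim(x, all_t, all_states, converged, criterion, used)
}

finish_sim <- function(x, times, states, converged, criterion, chunks) {
  min_conc <- min(states)
  traj <- pmax(states, 0)  # readout clipping only
  final <- traj[nrow(traj), ]
  outputs <- NULL
  if (!is.null(x$output_pair)) {
    var <- sub("_[01]$", "", x$output_pair[1])
    tot <- sum(final[x$output_pair])
    outputs <- setNames(if (tot > 0) decode_fraction(final[x$output_pair])
                        else NA_real_, var)
  }
  structure(
    list(times = times, traj = traj, final_state = final, outputs = outputs,
         converged = converged, criterion = criterion, chunks = chunks,
         min_conc = min_conc),
    class = "crn_sim"
  )
}

#' @export
print.crn_sim <- function(x, ...) {
  cat(sprintf("CRN simulation: %d samples to t = %.3g (%s)\n",
              length(x$times), max(x$times),
              if (isTRUE(x$converged)) paste0("completed by ", x$criterion)
              else "fixed time grid"))
  if (!is.null(x$outputs))
    cat("  decoded output:", names(x$outputs), "=",
        format(x$outputs, digits = 8), "\n")
  invisible(x)
}

#' Kinetic invariant diagnostics of a simulated run
#'
#' For compiled networks with equal rate constants the analysis of the
#' kinetics predicts three runtime invariants: each input fraction
#' p_i = \[Xi1\]/(\[Xi0\]+\[Xi1\]) is constant in time, each pair total
#' q_i = \[Xi0\]+\[Xi1\] is nonincreasing, and q_i plus the output pair total
#' is conserved (every reaction consumes one molecule of each input pair and
#' produces one output molecule).  This function computes the p, q, output
#' total and l = prod(q_i) series and flags violations.  With unequal rates
#' the p-invariance derivation fails and the flag is expected to be raised.
#'
#' @param sim a `crn_sim` from [simulate_crn()].
#' @param x the [crn()] that was simulated.
#' @param p_tol p-drift tolerance (default 1e-6).
#' @param q_floor fractions are only assessed while the pair retains at
#'   least this proportion of its initial total (default 1e-3): once a pair
#'   is essentially exhausted its ratio carries no information and is
#'   dominated by solver round-off.
#' @return an object of class `crn_diagnostics`: series `p` (matrix, one
#'   column per input), `q`, `q_out`, `l`, `conservation_residual`
#'   (relative), and flags `p_invariant`, `q_monotone`, `conservation_ok`,
#'   plus the measured `p_drift` and `conservation_drift`.
#' @export
compute_diagnostics <- function(sim, x, p_tol = 1e-6, q_floor = 1e-3) {
  stopifnot(inherits(sim, "crn_sim"), inherits(x, "crn"))
  if (is.null(x$input_pairs)) config_error("CRN has no input pairs")
  traj <- sim$traj
  vars <- names(x$input_pairs)
  q <- vapply(vars, function(v)
    rowSums(traj[, x$input_pairs[[v]], drop = FALSE]), numeric(nrow(traj)))
  p <- vapply(vars, function(v) {
    pair <- traj[, x$input_pairs[[v]], drop = FALSE]
    tot <- rowSums(pair)
    ifelse(tot > 0, pair[, 2] / tot, NA_real_)
  }, numeric(nrow(traj)))
  colnames(q) <- colnames(p) <- vars
  q_out <- if (!is.null(x$output_pair))
    rowSums(traj[, x$output_pair, drop = FALSE]) else rep(0, nrow(traj))
  l <- apply(q, 1, prod)

  p_drift <- 0
  for (v in vars) {
    alive <- q[, v] >= q_floor * q[1, v] & !is.na(p[, v])
    if (q[1, v] > 0 && any(alive))
      p_drift <- max(p_drift, max(abs(p[alive, v] - p[alive, v][1])))
  }
  q_monotone <- all(vapply(vars, function(v)
    all(diff(q[, v]) <= 1e-9 * max(q[1, v], 1)), logical(1)))
  cons <- vapply(vars, function(v) {
    c0 <- q[1, v] + q_out[1]
    if (c0 <= 0) return(0)
    max(abs(q[, v] + q_out - c0)) / c0
  }, numeric(1))
  structure(
    list(p = p, q = q, q_out = q_out, l = l,
         conservation_residual = cons,
         p_drift = p_drift, conservation_drift = max(cons),
         p_invariant = p_drift <= p_tol,
         q_monotone = q_monotone,
         conservation_ok = max(cons) <= 1e-6),
    class = "crn_diagnostics"
  )
}

#' @export
print.crn_diagnostics <- function(x, ...) {
  cat(sprintf(
    "CRN diagnostics: p drift %.3g (%s), q %s, conservation drift %.3g (%s)\n",
    x$p_drift, if (x$p_invariant) "invariant" else "NOT invariant",
    if (x$q_monotone) "nonincreasing" else "NOT monotone",
    x$conservation_drift, if (x$conservation_ok) "ok" else "violated"))
  invisible(x)
}
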