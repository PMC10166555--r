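#' Rate-constant perturbation schemes
#'
#' Three schemes describe how the per-reaction rate constants of a compiled
#' network deviate from the ideal equal-rate condition:
#' `uniform` (all reactions at `base_k`), `single_scaled` (one reaction's
#' rate multiplied by `factor`, the rest at `base_k`) and `normal_random`
#' (all rates drawn independently from Normal(`base_k`, `sigma`), with
#' nonpositive draws redrawn so every rate is strictly positive).
#'
#' @param kind one of `"uniform"`, `"single_scaled"`, `"normal_random"`.
#' @param base_k base rate constant (default 100).
#' @param reaction 1-based index (canonical row order) of the scaled
#'   reaction, for `single_scaled`.
#' @param factor multiplicative perturbation, for `single_scaled`.
#' @param sigma standard deviation, for `normal_random`.
#' @param seed integer seed, for `normal_random`.
#' @return an object of class `rate_scheme`.
#' @examples
#' make_rates(rate_scheme("single_scaled", reaction = 1, factor = 10), 8)
#' @export
rate_scheme <- function(kind = c("uniform", "single_scaled", "normal_random"),
                        base_k = 100, reaction = NULL, factor = NULL,
                        sigma = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(base_k) || base_k <= 0)
    config_error("base_k must be positive")
  if (kind == "single_scaled") {
    if (is.null(reaction) || is.null(factor))
      config_error("single_scaled needs `reaction` and `factor`")
    if (reaction < 1 || reaction != round(reaction))
      config_error("reaction must be a positive (1-based) index")
    if (!is.finite(factor) || factor <= 0)
      config_error("factor must be positive")
  }
  if (kind == "normal_random") {
    if (is.null(sigma) || is.null(seed))
      config_error("normal_random needs `sigma` and `seed`")
    if (!is.finite(sigma) || sigma < 0)
      config_error("sigma must be nonnegative")
  }
  structure(list(kind = kind, base_k = base_k,
                 reaction = if (!is.null(reaction)) as.integer(reaction),
                 factor = factor, sigma = sigma,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "rate_scheme")
}

#' @export
print.rate_scheme <- function(x, ...) {
  desc <- switch(x$kind,
    uniform = sprintf("all k = %g", x$base_k),
    single_scaled = sprintf("k = %g except reaction %d at %g",
                            x$base_k, x$reaction, x$base_k * x$factor),
    normal_random = sprintf("k ~ Normal(%g, %g), seed %d, positive draws only",
                            x$base_k, x$sigma, x$seed))
  cat("rate scheme:", desc, "\n")
  invisible(x)
}

#' Realize a rate scheme as a rate-constant vector
#'
#' @param scheme a [rate_scheme()].
#' @param n_reactions number of reactions (2^n for a compiled network).
#' @return numeric vector of `n_reactions` strictly positive rates.
#' @export
make_rates <- function(scheme, n_reactions) {
  stopifnot(inherits(scheme, "rate_scheme"))
  if (n_reactions < 1 || n_reactions != round(n_reactions))
    config_error("n_reactions must be a positive integer")
  switch(scheme$kind,
    uniform = rep(scheme$base_k, n_reactions),
    single_scaled = {
      if (scheme$reaction > n_reactions)
        config_error("reaction index exceeds number of reactions")
      k <- rep(scheme$base_k, n_reactions)
      k[scheme$reaction] <- scheme$base_k * scheme$factor
      k
    },
    normal_random = with_seed(scheme$seed, {
      k <- rnorm(n_reactions, scheme$base_k, scheme$sigma)
      while (any(k <= 0))  # negative rates are unphysical: redraw
        k[k <= 0] <- rnorm(sum(k <= 0), scheme$base_k, scheme$sigma)
      k
    })
  )
}

#' Sweep the output error of a compiled CRN over an input lattice
#'
#' Compiles the table with the scheme's rates and, at every point of the
#' regular lattice over \[0, 1\]^n (both endpoints included, so `1/step + 1`
#' points per axis), encodes the inputs at `pair_total`, simulates the
#' kinetics to completion and records the absolute difference between the
#' decoded output and the exact stochastic function value.  This is the
#' "error cube" view of rate-constant robustness: at equal rates the error
#' is solver noise, while perturbed rates distort the computation most in
#' the interior of the cube.
#'
#' @param tt a [truth_table()].
#' @param scheme a [rate_scheme()].
#' @param step lattice step; must divide 1 evenly (default 0.1, i.e. 11
#'   points per axis, 1331 for three inputs).
#' @param pair_total input pair total (default 100).
#' @param threshold exceedance threshold for the summary (default 0.1,
#'   strict inequality).
#' @param ... further arguments to [simulate_crn()] (solver tolerances etc.).
#' @return an object of class `error_cube`: list with `points` (data frame
#'   of lattice coordinates, `expected`, `simulated`, `error`), `tt`,
#'   `scheme`, `step`, `pair_total` and `summary` (from [cube_summary()]).
#' @examples
#' \donttest{
#' cube <- error_cube(xor3_table(), rate_scheme("uniform"), step = 0.5)
#' cube$summary$max_error
#' }
#' @export
error_cube <- function(tt, scheme, step = 0.1, pair_total = 100,
                       threshold = 0.1, ...) {
  stopifnot(inherits(tt, "truth_table"), inherits(scheme, "rate_scheme"))
  npts <- 1 / step + 1
  if (abs(npts - round(npts)) > 1e-9)
    config_error("step must divide 1 evenly")
  axis <- seq(0, 1, length.out = round(npts))
  rates <- make_rates(scheme, 2^tt$n)
  net <- compile_crn(tt, k = rates)
  grid <- expand.grid(rep(list(axis), tt$n), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- tt$vars
  expected <- numeric(nrow(grid))
  simulated <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    frac <- setNames(as.numeric(grid[r, ]), tt$vars)
    expected[r] <- stoch_value(tt, frac)
    sim <- tryCatch(
      simulate_crn(net, fractions = frac, totals = pair_total,
                   samples_per_chunk = 3, ...),
      stochcrn_convergence_error = function(e) {
        e$message <- sprintf("at lattice point (%s): %s",
                             paste(frac, collapse = ", "), e$message)
        stop(e)
      })
    simulated[r] <- sim$outputs[[1]]
  }
  points <- cbind(grid, expected = expected, simulated = simulated,
                  error = abs(simulated - expected))
  cube <- structure(
    list(points = points, tt = tt, scheme = scheme, step = step,
         pair_total = pair_total),
    class = "error_cube")
  cube$summary <- cube_summary(cube, threshold)
  cube
}

#' Summarize an error cube
#'
#' @param cube an [error_cube()].
#' @param threshold exceedance threshold (strict `>`; default 0.1).
#' @return list with `max_error`, `percent_exceeding` (percentage of lattice
#'   points with error strictly above the threshold), `n_points`,
#'   `threshold`.
#' @export
cube_summary <- function(cube, threshold = 0.1) {
  stopifnot(inherits(cube, "error_cube"))
  err <- cube$points$error
  if (!length(err)) config_error("empty error cube")
  list(max_error = max(err),
       percent_exceeding = 100 * sum(err > threshold) / length(err),
       n_points = length(err),
       threshold = threshold)
}

#' @export
summary.error_cube <- function(object, threshold = 0.1, ...) {
  cube_summary(object, threshold)
}

#' @export
print.error_cube <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "error cube: %d lattice points (step %g), max error %.4g, %.1f%% above %.2g\n",
    s$n_points, x$step, s$max_error, s$percent_exceeding, s$threshold))
  print(x$scheme)
  invisible(x)
}

#' Mean error on the cube faces versus its interior
#'
#' Errors are typically small when any input fraction is close to 0 or 1,
#' because one species of the pair is nearly absent and its reactions are
#' very slow or very fast regardless of rates.  This helper splits the
#' lattice into boundary points (any coordinate exactly 0 or 1) and interior
#' points and returns the mean error of each.
#'
#' @param cube an [error_cube()].
#' @return list with `face_mean` and `interior_mean`.
#' @export
cube_face_interior <- function(cube) {
  stopifnot(inherits(cube, "error_cube"))
  coords <- cube$points[, cube$tt$vars, drop = FALSE]
  on_face <- apply(coords == 0 | coords == 1, 1, any)
  list(face_mean = mean(cube$points$error[on_face]),
       interior_mean = mean(cube$points$error[!on_face]))
}
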