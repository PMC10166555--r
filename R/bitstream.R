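#' Generate a random bitstream
#'
#' In stochastic logic a value p in \[0, 1\] is carried by a stream of
#' independent random bits, each 1 with probability p.  Streams are
#' reproducible for a fixed seed and leave the caller's RNG state untouched.
#'
#' @param p bit probability, in \[0, 1\].
#' @param length number of bits.
#' @param seed integer seed.
#' @return an object of class `bitstream`: list with `bits` (integer
#'   vector), `p`, `seed`.
#' @examples
#' mean(bitstream(3 / 8, 1e4, seed = 1)$bits)
#' @export
bitstream <- function(p, length, seed) {
  if (!is.finite(p) || p < 0 || p > 1)
    domain_error("bit probability must lie in [0, 1]")
  if (length < 1 || length != round(length))
    config_error("length must be a positive integer")
  bits <- with_seed(seed, as.integer(runif(length) < p))
  structure(list(bits = bits, p = p, seed = as.integer(seed)),
            class = "bitstream")
}

#' @export
print.bitstream <- function(x, ...) {
  cat(sprintf("bitstream: %d bits, nominal p = %g, empirical mean = %g\n",
              length(x$bits), x$p, mean(x$bits)))
  invisible(x)
}

#' Apply a truth table bitwise to input bitstreams
#'
#' The sampling counterpart of [stoch_value()]: the output stream's bits are
#' the table outputs at the minterm formed by the input bits at each
#' position, and its empirical mean estimates the stochastic function value
#' with binomial error sqrt(f(1-f)/L).
#'
#' @param tt a [truth_table()].
#' @param streams list of [bitstream()]s, one per input variable in table
#'   order (or named by variable), all of equal length.
#' @return a list with `stream` (the output [bitstream()], nominal p set to
#'   the exact [stoch_value()]) and `mean` (empirical output mean).
#' @examples
#' s <- list(bitstream(0.7, 1e4, 1), bitstream(0.6, 1e4, 2))
#' eval_streams(gate_table("AND"), s)$mean  # close to 0.42
#' @export
eval_streams <- function(tt, streams) {
  stopifnot(inherits(tt, "truth_table"))
  if (length(streams) != tt$n)
    config_error(sprintf("expected %d streams, got %d", tt$n, length(streams)))
  if (!is.null(names(streams)) && all(nzchar(names(streams)))) {
    missing <- setdiff(tt$vars, names(streams))
    if (length(missing))
      config_error(paste0("streams missing for variable(s): ",
                          paste(missing, collapse = ", ")))
    streams <- streams[tt$vars]
  }
  lens <- vapply(streams, function(s) length(s$bits), integer(1))
  if (length(unique(lens)) != 1)
    config_error("bitstreams must have equal length")
  L <- lens[1]
  idx <- rep(1L, L)
  for (i in seq_len(tt$n))
    idx <- idx + streams[[i]]$bits * 2L^(tt$n - i)
  out_bits <- tt$outputs[idx]
  exact <- stoch_value(tt, setNames(vapply(streams, `[[`, numeric(1), "p"),
                                    tt$vars))
  out <- structure(list(bits = out_bits, p = exact, seed = NA_integer_),
                   class = "bitstream")
  list(stream = out, mean = mean(out_bits))
}
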