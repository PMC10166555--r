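test_that("known tables expand to their exact coefficient maps", {
  p <- tt_to_polynomial(xor3_table())
  expect_identical(poly_coef(p, "x"), 1)
  expect_identical(poly_coef(p, "y"), 1)
  expect_identical(poly_coef(p, "z"), 1)
  expect_identical(poly_coef(p, c("x", "y")), -2)
  expect_identical(poly_coef(p, c("x", "z")), -2)
  expect_identical(poly_coef(p, c("y", "z")), -2)
  expect_identical(poly_coef(p, c("x", "y", "z")), 4)
  expect_identical(poly_coef(p), 0)

  nor <- tt_to_polynomial(gate_table("NOR"))
  expect_identical(poly_coef(nor), 1)
  expect_identical(poly_coef(nor, "a"), -1)
  expect_identical(poly_coef(nor, "b"), -1)
  expect_identical(poly_coef(nor, c("a", "b")), 1)

  and <- tt_to_polynomial(gate_table("AND"))
  expect_identical(unname(and$coeffs), 1)
  expect_identical(names(and$coeffs), "a*b")
})

test_that("table -> polynomial -> table round-trips", {
  # exhaustive for n <= 3
  for (n in 1:3) {
    for (code in 0:(2^(2^n) - 1)) {
      outs <- row_bits(code, 2^n)
      if (all(outs == 0) || all(outs == 1)) next  # constant: fine too, keep
      tt <- truth_table(outs, name = "F")
      back <- polynomial_to_tt(tt_to_polynomial(tt), name = "F")
      expect_identical(back$outputs, tt$outputs)
    }
  }
  # randomized for n = 4
  for (s in 1:20) {
    tt <- random_table(4, seed = 400 + s)
    back <- polynomial_to_tt(tt_to_polynomial(tt), name = "F")
    expect_identical(back$outputs, tt$outputs)
    expect_identical(back$vars, tt$vars)
  }
})

test_that("polynomial evaluation agrees with the stochastic function", {
  for (s in 1:8) {
    n <- 1 + s %% 4
    tt <- random_table(n, seed = 500 + s)
    p <- tt_to_polynomial(tt)
    for (r in 1:25) {
      x <- random_assignment(tt$vars, seed = 1000 * s + r)
      expect_lt(abs(eval_polynomial(p, x) - stoch_value(tt, x)), 1e-10)
    }
  }
})

test_that("non-Boolean polynomials are rejected as truth tables", {
  expect_error(polynomial_to_tt(mlpoly(c("1" = 0.5), vars = "a")),
               class = "stochcrn_not_boolean")
  expect_error(polynomial_to_tt(parse_polynomial("0.3 + x")),
               class = "stochcrn_not_boolean")
  # Boolean-valued ones are accepted
  nor <- polynomial_to_tt(parse_polynomial("1 - a - b + a*b"))
  expect_identical(nor$outputs, c(1L, 0L, 0L, 0L))
  and <- polynomial_to_tt(parse_polynomial("a*b"))
  expect_identical(and$outputs, c(0L, 0L, 0L, 1L))
})

test_that("polynomial text form parses and formats consistently", {
  txts <- c("1 - a - b + a*b", "a + b - 2*a*b",
            "x + y + z - 2*x*y - 2*x*z - 2*y*z + 4*x*y*z", "0.25 + 0.5*u")
  for (txt in txts) {
    p <- parse_polynomial(txt)
    p2 <- parse_polynomial(format(p), vars = p$vars)
    keys <- union(names(p$coeffs), names(p2$coeffs))
    for (k in keys) expect_equal(poly_coef(p2, k), poly_coef(p, k), info = txt)
  }
  # repeated variables within a term violate multilinearity
  expect_error(parse_polynomial("x*x"), class = "stochcrn_config_error")
  expect_error(mlpoly(c("a*a" = 1), vars = "a"), class = "stochcrn_config_error")
  expect_error(parse_polynomial(""), class = "stochcrn_config_error")
})
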