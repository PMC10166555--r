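reaction_sig <- function(r) {
  paste(paste(sort(names(r$reactants)), collapse = "+"), "->",
        paste(names(r$products), collapse = "+"))
}

test_that("NOR, AND and XOR-3 compile reaction-for-reaction", {
  nor <- compile_crn(gate_table("NOR"))
  expect_identical(vapply(nor$reactions, reaction_sig, character(1)),
                   c("a_0+b_0 -> c_1", "a_0+b_1 -> c_0",
                     "a_1+b_0 -> c_0", "a_1+b_1 -> c_0"))
  and <- compile_crn(gate_table("AND"))
  expect_identical(vapply(and$reactions, reaction_sig, character(1)),
                   c("a_0+b_0 -> c_0", "a_0+b_1 -> c_0",
                     "a_1+b_0 -> c_0", "a_1+b_1 -> c_1"))
  x3 <- compile_crn(xor3_table())
  expect_identical(vapply(x3$reactions, reaction_sig, character(1)),
                   c("x_0+y_0+z_0 -> f_0", "x_0+y_0+z_1 -> f_1",
                     "x_0+y_1+z_0 -> f_1", "x_0+y_1+z_1 -> f_0",
                     "x_1+y_0+z_0 -> f_1", "x_1+y_0+z_1 -> f_0",
                     "x_1+y_1+z_0 -> f_0", "x_1+y_1+z_1 -> f_1"))
  expect_true(all(vapply(x3$reactions, `[[`, numeric(1), "k") == 100))
})

test_that("compiled networks have 2^n reactions, 2n+2 species, faithful indices", {
  for (n in 1:6) {
    tt <- random_table(n, seed = 600 + n)
    net <- compile_crn(tt, k = 7)
    expect_length(net$reactions, 2^n)
    expect_length(net$species, 2 * n + 2)
    for (j in seq_along(net$reactions)) {
      r <- net$reactions[[j]]
      bits <- row_bits(j - 1, n)
      expect_identical(names(r$reactants),
                       paste0(tt$vars, "_", bits))
      expect_identical(names(r$products),
                       paste0(tt$name, "_", tt$outputs[j]))
      expect_identical(unname(r$k), 7)
    }
  }
  expect_error(compile_crn(gate_table("AND"), k = -1),
               class = "stochcrn_config_error")
  expect_error(compile_crn(gate_table("AND"), k = c(1, 2)),
               class = "stochcrn_config_error")
})

test_that("fractional encode/decode are exact inverses with guarded domains", {
  expect_equal(encode_fraction(0.7, 100), c(30, 70))
  expect_equal(encode_fraction(0, 50), c(50, 0))
  expect_equal(encode_fraction(1, 50), c(0, 50))
  expect_error(encode_fraction(1.1, 100), class = "stochcrn_domain_error")
  expect_error(encode_fraction(0.5, 0), class = "stochcrn_domain_error")

  expect_equal(decode_fraction(c(58, 42)), 0.42)
  expect_equal(decode_fraction(c(0, 7)), 1)
  expect_error(decode_fraction(c(0, 0)), class = "stochcrn_undefined_fraction")
  expect_error(decode_fraction(c(-1, 2)), class = "stochcrn_domain_error")

  # dyadic fractions stay bit-exact through encode/decode
  xs <- stochcrn:::with_seed(7, sample(0:1024, 50) / 1024)
  for (x in xs)
    expect_identical(decode_fraction(encode_fraction(x, 128)), x)
  # arbitrary floats round-trip to within one ulp
  for (x in stochcrn:::with_seed(8, runif(20)))
    expect_equal(decode_fraction(encode_fraction(x, 100)), x, tolerance = 1e-15)
})

test_that("fan-out scales input totals and splitting preserves fractions", {
  plan <- plan_fanout(4, base_total = 100)
  expect_equal(plan$scaled_total, 400)
  expect_equal(plan$split_fraction, 0.25)
  expect_equal(plan_fanout(1, 100)$scaled_total, 100)

  parts <- split_output(c(116, 84), 2)
  expect_length(parts, 2)
  for (p in parts) {
    expect_equal(p, c(58, 42))
    expect_equal(decode_fraction(p), decode_fraction(c(116, 84)))
  }
  expect_error(plan_fanout(0), class = "stochcrn_config_error")
})

test_that("plain-text CRN format round-trips, including stoichiometry", {
  net <- compile_crn(xor3_table(), k = c(1:8) * 10)
  f <- withr::local_tempfile(fileext = ".crn")
  write_crn(net, f)
  back <- read_crn(f)
  expect_identical(length(back$reactions), length(net$reactions))
  for (j in seq_along(net$reactions)) {
    expect_identical(reaction_sig(back$reactions[[j]]),
                     reaction_sig(net$reactions[[j]]))
    expect_equal(back$reactions[[j]]$k, net$reactions[[j]]$k)
  }
  expect_identical(names(back$input_pairs), names(net$input_pairs))
  expect_identical(back$output_pair, net$output_pair)

  # general stoichiometry: `3 X_3 + X_4 -> X_1` style
  writeLines(c("# crn-format: 1",
               "X_1 + X_2 -> X_3 ; k=2",
               "X_2 + X_3 -> 2 X_4 ; k=2",
               "3 X_3 + X_4 -> X_1 ; k=2"), f)
  toy <- read_crn(f)
  expect_equal(toy$reactions[[3]]$reactants, c(X_3 = 3, X_4 = 1))
  expect_equal(toy$reactions[[2]]$products, c(X_4 = 2))
  # malformed lines are rejected
  writeLines("A_0 + B_0 -> C_1", f)
  expect_error(read_crn(f), class = "stochcrn_config_error")
})
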