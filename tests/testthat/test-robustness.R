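test_that("rate schemes realize the intended rate vectors", {
  k <- make_rates(rate_scheme("single_scaled", reaction = 1, factor = 10), 8)
  expect_equal(k, c(1000, rep(100, 7)))
  expect_equal(make_rates(rate_scheme("uniform"), 8), rep(100, 8))

  sch <- rate_scheme("normal_random", sigma = 70, seed = 5)
  k1 <- make_rates(sch, 8)
  expect_length(k1, 8)
  expect_true(all(k1 > 0))
  expect_identical(k1, make_rates(sch, 8))  # reproducible per seed
  expect_false(identical(k1, make_rates(
    rate_scheme("normal_random", sigma = 70, seed = 6), 8)))

  # with small sigma truncation is negligible and the draw mean is base_k
  big <- make_rates(rate_scheme("normal_random", sigma = 10, seed = 11), 2000)
  expect_lt(abs(mean(big) - 100), 1)
  # heavy truncation keeps strict positivity
  big70 <- make_rates(rate_scheme("normal_random", sigma = 70, seed = 12), 2000)
  expect_true(all(big70 > 0))

  expect_error(rate_scheme("single_scaled", factor = 10),
               class = "stochcrn_config_error")
  expect_error(make_rates(rate_scheme("single_scaled", reaction = 9,
                                      factor = 2), 8),
               class = "stochcrn_config_error")
})

test_that("error-cube summaries compute max and strict exceedance", {
  fake <- structure(list(points = data.frame(error = c(0.05, 0.15, 0.2, 0.05))),
                    class = "error_cube")
  s <- cube_summary(fake)
  expect_equal(s$max_error, 0.2)
  expect_equal(s$percent_exceeding, 50)
  # strict inequality at the threshold
  at <- structure(list(points = data.frame(error = c(0.1, 0.1))),
                  class = "error_cube")
  expect_equal(cube_summary(at)$percent_exceeding, 0)
  expect_equal(cube_summary(at, threshold = 0.099)$percent_exceeding, 100)
  expect_error(error_cube(xor3_table(), rate_scheme("uniform"), step = 0.3),
               class = "stochcrn_config_error")
})

test_that("equal-rate sweeps have vanishing error and both lattice endpoints", {
  cube <- error_cube(xor3_table(), rate_scheme("uniform"), step = 0.5)
  expect_equal(cube$summary$n_points, 27)
  expect_lt(cube$summary$max_error, 1e-3)
  expect_setequal(unique(cube$points$x), c(0, 0.5, 1))
})

test_that("perturbed sweeps are reproducible and show the known structure", {
  fast <- error_cube(xor3_table(),
                     rate_scheme("single_scaled", reaction = 1, factor = 10),
                     step = 0.25)
  slow <- error_cube(xor3_table(),
                     rate_scheme("single_scaled", reaction = 1, factor = 0.1),
                     step = 0.25)
  # one slow reaction hurts less than one fast reaction
  expect_lte(slow$summary$max_error, fast$summary$max_error)
  # errors are milder near the cube faces than in the interior
  fi <- cube_face_interior(fast)
  expect_lte(fi$face_mean, fi$interior_mean)
  # deterministic trials are bit-reproducible
  again <- error_cube(xor3_table(),
                      rate_scheme("single_scaled", reaction = 1, factor = 10),
                      step = 0.25)
  expect_identical(fast$points$error, again$points$error)
  # random trials reproduce per seed
  r1 <- error_cube(xor3_table(),
                   rate_scheme("normal_random", sigma = 10, seed = 3),
                   step = 0.5)
  r2 <- error_cube(xor3_table(),
                   rate_scheme("normal_random", sigma = 10, seed = 3),
                   step = 0.5)
  expect_identical(r1$points$error, r2$points$error)
})
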