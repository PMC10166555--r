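test_that("mass-action derivatives match hand-computed rate equations", {
  # two-input product network: d[A0]/dt = -k [A0]([B0]+[B1])
  net <- compile_crn(gate_table("AND"), k = 2)
  f <- crn_ode(net)
  state <- c(a_0 = 1, a_1 = 2, b_0 = 3, b_1 = 4, c_0 = 0, c_1 = 0)
  d <- f(0, state, NULL)[[1]]
  expect_equal(d[["a_0"]], -2 * 1 * (3 + 4))
  expect_equal(d[["a_1"]], -2 * 2 * (3 + 4))
  expect_equal(d[["b_0"]], -2 * 3 * (1 + 2))
  expect_equal(d[["b_1"]], -2 * 4 * (1 + 2))
  expect_equal(d[["c_0"]], 2 * (1 * 3 + 1 * 4 + 2 * 3))
  expect_equal(d[["c_1"]], 2 * 2 * 4)

  # single bimolecular reaction at (2, 3), k = 1
  r1 <- crn(list(list(reactants = c(X_1 = 1, X_2 = 1),
                      products = c(X_3 = 1), k = 1)))
  d1 <- crn_ode(r1)(0, c(X_1 = 2, X_2 = 3, X_3 = 0), NULL)[[1]]
  expect_equal(unname(d1), c(-6, -6, 6))

  # all-zero state has all-zero derivatives
  expect_true(all(crn_ode(net)(0, state * 0, NULL)[[1]] == 0))

  # general stoichiometry: velocities use conc^coefficient
  toy <- crn(list(
    list(reactants = c(X1 = 1, X2 = 1), products = c(X3 = 1), k = 1),
    list(reactants = c(X2 = 1, X3 = 1), products = c(X4 = 2), k = 1),
    list(reactants = c(X3 = 3, X4 = 1), products = c(X1 = 1), k = 1)))
  dt <- crn_ode(toy)(0, c(X1 = 1, X2 = 2, X3 = 3, X4 = 4), NULL)[[1]]
  v <- c(1 * 2, 2 * 3, 3^3 * 4)
  expect_equal(unname(dt), c(-v[1] + v[3], -v[1] - v[2],
                             v[1] - v[2] - 3 * v[3], 2 * v[2] - v[3]))
})

test_that("compiled and pure-R derivative engines agree", {
  net <- compile_crn(xor3_table(), k = c(1000, rep(100, 7)))
  frac <- c(x = 0.3, y = 0.8, z = 0.5)
  s1 <- simulate_crn(net, fractions = frac, engine = "compiled")
  s2 <- simulate_crn(net, fractions = frac, engine = "R")
  expect_equal(s1$outputs, s2$outputs, tolerance = 1e-8)
})

test_that("equal-rate networks compute the stochastic function", {
  and <- compile_crn(gate_table("AND"))
  sim <- simulate_crn(and, fractions = c(a = 0.7, b = 0.6))
  expect_true(sim$converged)
  expect_lt(abs(sim$outputs[["c"]] - 0.42), 1e-3)

  # saturated inputs: only one reaction can fire
  sim1 <- simulate_crn(and, fractions = c(a = 1, b = 1))
  expect_equal(sim1$outputs[["c"]], 1)

  # perturbed fourth reaction at 2k biases the product upward
  and2 <- compile_crn(gate_table("AND"), k = c(100, 100, 100, 200))
  sim2 <- simulate_crn(and2, fractions = c(a = 0.7, b = 0.6))
  expect_lt(abs(sim2$outputs[["c"]] - 0.462), 0.005)

  # small oracle-equivalence sweep across random tables
  for (s in 1:12) {
    n <- 1 + s %% 4
    tt <- random_table(n, seed = 700 + s)
    x <- random_assignment(tt$vars, seed = 800 + s)
    sim <- simulate_crn(compile_crn(tt), fractions = x,
                        samples_per_chunk = 4)
    expect_lt(abs(sim$outputs[[1]] - stoch_value(tt, x)), 1e-3)
  }
})

test_that("decoded output is readable at any time, not only in the limit", {
  net <- compile_crn(xor3_table())
  frac <- c(x = 0.35, y = 0.7, z = 0.55)
  sim <- simulate_crn(net, fractions = frac)
  expected <- stoch_value(xor3_table(), frac)
  tot0 <- 100
  out_tot <- rowSums(sim$traj[, net$output_pair])
  readable <- out_tot > 0.01 * tot0
  y <- sim$traj[readable, net$output_pair[2]] / out_tot[readable]
  expect_true(all(abs(y - expected) < 1e-3))
})

test_that("kinetic invariants hold at equal rates and fail when rates differ", {
  and <- compile_crn(gate_table("AND"))
  sim <- simulate_crn(and, fractions = c(a = 0.7, b = 0.6))
  diag <- compute_diagnostics(sim, and)
  expect_true(diag$p_invariant)
  expect_lt(max(abs(diag$p[diag$q[, "a"] >= 0.1, "a"] - 0.7)), 1e-6)
  expect_true(diag$q_monotone)
  expect_true(diag$conservation_ok)
  expect_gt(sim$min_conc, -1e-9)
  # l = prod of pair totals starts at the product of initial totals
  expect_equal(diag$l[1], 100 * 100)

  # unequal rates break the p-invariance derivation
  net <- compile_crn(xor3_table(), k = c(1000, rep(100, 7)))
  simu <- simulate_crn(net, fractions = c(x = 0.5, y = 0.5, z = 0.5))
  diagu <- compute_diagnostics(simu, net)
  expect_false(diagu$p_invariant)
  # but per-pair conservation still holds (1 molecule of each pair per firing)
  expect_true(diagu$conservation_ok)
  expect_true(diagu$q_monotone)
})

test_that("initial-state construction and input validation", {
  net <- compile_crn(gate_table("AND"))
  st <- initial_state(net, c(a = 0.7, b = 0.6), totals = 100)
  expect_equal(st[["a_0"]], 30)
  expect_equal(st[["a_1"]], 70)
  expect_equal(st[["b_1"]], 60)
  expect_equal(st[["c_0"]], 0)
  expect_error(initial_state(net, c(a = 0.7)), class = "stochcrn_config_error")
  expect_error(simulate_crn(net, init = c(bogus = 1)),
               class = "stochcrn_config_error")
  expect_error(simulate_crn(net, init = c(a_0 = -5, a_1 = 1, b_0 = 1, b_1 = 1)),
               class = "stochcrn_domain_error")
})
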