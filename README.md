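# stochcrn

Computing mathematical functions with abstract chemical reactions via
stochastic logic.

Stochastic logic represents a real value x ∈ [0, 1] as a random bitstream in
which each bit is 1 with probability x; logic gates then transform
probabilities (an AND gate multiplies, x·y; a NOT gate complements, 1 − x).
`stochcrn` carries this idea into molecular systems: a value is encoded
*fractionally* by a pair of chemical species,

    x = [X1] / ([X0] + [X1]),

and any n-input Boolean truth table F compiles into a chemical reaction
network (CRN) with one reaction per minterm,

    X1,v1 + X2,v2 + … + Xn,vn  →k  Y_F(V)          (one per row V of F)

over 2n + 2 species and 2^n reactions. When all rate constants k are equal,
deterministic mass-action kinetics drives the output pair to the exact
stochastic function of the table — the multilinear polynomial

    f(x1, …, xn) = Σ_{V : F(V)=1}  Π_i  c_{i,v_i},   c_{i,1} = x_i,  c_{i,0} = 1 − x_i

— and the input fractions are invariants of the motion, so the output can be
read at any time, not only in the limit. Equality of the rate constants is
the correctness condition; the package quantifies what happens when it is
violated.

The package is for researchers in molecular programming and DNA computing
who want to design, simulate and stress-test such networks. It provides:

- **Truth tables and closed forms** — construction, gate library, CSV I/O,
  exact expansion to/from multilinear polynomials (`truth_table()`,
  `gate_table()`, `tt_to_polynomial()`, `polynomial_to_tt()`).
- **Compilation** — `compile_crn()` produces the canonical network;
  a plain-text reaction format round-trips via `read_crn()`/`write_crn()`;
  outputs can be fanned out and cascaded (`plan_fanout()`, `cascade_plan()`,
  `run_cascade()`).
- **Kinetics** — mass-action ODE generation (`crn_ode()`, with a fast
  compiled equivalent) and stiff adaptive integration to input exhaustion
  (`simulate_crn()`, via deSolve/LSODA), plus runtime checks of the
  analytical invariants (`compute_diagnostics()`).
- **Sampling oracle** — a randomized-bitstream simulator
  (`bitstream()`, `eval_streams()`) that estimates the same function by
  direct Monte Carlo, independently of the kinetics.
- **Robustness sweeps** — `error_cube()` maps |simulated − expected| over a
  lattice of input fractions under rate-constant perturbation schemes
  (`rate_scheme()`), with summary statistics (`cube_summary()`).

## Worked example

Three-input parity (XOR-3), the most rate-sensitive standard function
because its table is balanced between 0s and 1s:

```r
library(stochcrn)

tt <- xor3_table()
tt_to_polynomial(tt)
#> x + y + z - 2*x*y - 2*x*z - 2*y*z + 4*x*y*z

net <- compile_crn(tt, k = 100)
net
#> CRN: 8 species, 8 reactions
#>   x0 + y0 + z0 -> f0 ; k=100
#>   x0 + y0 + z1 -> f1 ; k=100
#>   x0 + y1 + z0 -> f1 ; k=100
#>   x0 + y1 + z1 -> f0 ; k=100
#>   x1 + y0 + z0 -> f1 ; k=100
#>   x1 + y0 + z1 -> f0 ; k=100
#>   x1 + y1 + z0 -> f0 ; k=100
#>   x1 + y1 + z1 -> f1 ; k=100

sim <- simulate_crn(net, fractions = c(x = 0.2, y = 0.7, z = 0.9))
sim
#> CRN simulation: 49 samples to t = 0.001 (completed by stability)
#>   decoded output: f = 0.404
stoch_value(tt, c(x = 0.2, y = 0.7, z = 0.9))
#> [1] 0.404
```

The simulated fraction equals the closed form exactly, and the kinetic
invariants hold to solver precision:

```r
compute_diagnostics(sim, net)
#> CRN diagnostics: p drift 1.11e-15 (invariant), q nonincreasing, conservation drift 1.99e-15 (ok)
```

Making the first reaction ten times faster than the others breaks the
equal-rate condition and biases the output (here 0.343 instead of 0.404):

```r
k <- make_rates(rate_scheme("single_scaled", reaction = 1, factor = 10), 8)
simulate_crn(compile_crn(tt, k = k), fractions = c(x = 0.2, y = 0.7, z = 0.9))
#> CRN simulation: 169 samples to t = 1e+06 (completed by depletion)
#>   decoded output: f = 0.34344183

error_cube(tt, rate_scheme("single_scaled", reaction = 1, factor = 10),
           step = 0.25)
#> error cube: 125 lattice points (step 0.25), max error 0.3109, 34.4% above 0.1
#> rate scheme: k = 100 except reaction 1 at 1000
```

The error cube reports the worst-case absolute output error over the input
lattice and the share of input combinations whose error exceeds 0.1.

A thin command-line interface wraps the same functions
(`inst/cli/stochcrn.R`; subcommands `compile`, `simulate`, `bitstream`,
`errorcube`, `fixtures`).

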