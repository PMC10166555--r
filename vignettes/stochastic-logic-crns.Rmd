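---
title: "Stochastic logic with chemical reaction networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic logic with chemical reaction networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochcrn)
```

## The model

### Values as fractions of species pairs

A real value $x \in [0,1]$ is carried by two molecular species
$\mathbf{X}_0$ and $\mathbf{X}_1$ through the fractional encoding

$$x = \frac{[\mathbf{X}_1]}{[\mathbf{X}_0] + [\mathbf{X}_1]},$$

the molecular analogue of a random bitstream in which each bit is 1 with
probability $x$: the `_1` species plays the role of the 1-bits, the `_0`
species of the 0-bits, and the concentration ratio plays the role of the
bit frequency. `encode_fraction(x, total)` realizes a value at a chosen
pair total; `decode_fraction()` inverts it and treats a zero total as an
error distinct from a domain violation, because an empty pair carries no
value at all.

### The stochastic function of a truth table

An $n$-input Boolean function $F$ applied to independent Bernoulli inputs
with $\Pr(X_i = 1) = x_i$ outputs 1 with probability

$$f(x_1,\dots,x_n) \;=\; \sum_{V:\,F(V)=1} \;\prod_{i=1}^{n} c_{i,v_i},
\qquad c_{i,1} = x_i,\; c_{i,0} = 1 - x_i,$$

the sum of the probabilities of the minterms (truth-table rows) that map to
1. Since the row probabilities of *all* $2^n$ rows sum to 1 for any
assignment, $f$ always lands in $[0,1]$. Expanding the products gives a
multilinear polynomial — no variable ever appears squared — and every
multilinear polynomial obtained this way takes the table's 0/1 value at
each 0/1 vertex. `stoch_value()` computes the sum directly;
`tt_to_polynomial()` performs the expansion exactly (a Möbius transform
over variable subsets, so 0/1 tables give integer coefficients); and
`polynomial_to_tt()` inverts it, rejecting polynomials whose vertex values
are not Boolean to within $10^{-9}$.

```{r}
tt_to_polynomial(gate_table("NOR"))
stoch_value(gate_table("AND"), c(a = 0.7, b = 0.6))
```

### Compilation

`compile_crn()` emits one irreversible reaction per table row, in canonical
row order, each consuming one molecule of $\mathbf{X}_{i,v_i}$ for every
input $i$ and producing one molecule of the output species indexed by the
row's output bit:

$$\mathbf{X}_{1,v_1} + \cdots + \mathbf{X}_{n,v_n}
  \;\xrightarrow{\;k\;}\; \mathbf{Y}_{F(V)}.$$

The network has $2^n$ reactions over $2n + 2$ species. With all rate
constants equal, the mass-action kinetics have three exact invariants, which
the package computes as runtime diagnostics (`compute_diagnostics()`):

* each input fraction $p_i = [\mathbf{X}_{i,1}]/q_i$ is constant in time
  ($\dot p_i = 0$), because both members of a pair are consumed at rates
  proportional to their own concentrations with a shared factor;
* each pair total $q_i = [\mathbf{X}_{i,0}] + [\mathbf{X}_{i,1}]$ is
  nonincreasing, with $\dot q_i = -k \prod_h q_h$;
* $q_i + q_{\text{out}}$ is conserved for every $i$, since each firing
  removes one molecule of every input pair and adds one output molecule.

Because the output accrues 1-indexed molecules in proportion to the summed
probability of the 1-rows and 0-indexed molecules in proportion to the
rest, the decoded output equals $f$ at *any* time with nonzero output
total, not only asymptotically — the package's test suite checks this
"any-time readout" property on random networks. Equality of the rate
constants is the sole correctness condition; everything in the robustness
module quantifies departures from it.

## Numerical design

### Integration and the meaning of "completion"

`simulate_crn()` integrates the mass-action ODEs with LSODA
(`deSolve::lsoda`), a stiff-capable adaptive method, at `rel_tol = 1e-8`,
`abs_tol = 1e-10` by default. The compiled networks decay by power laws
(for $n$ equal pair totals, $q \sim t^{-1/(n-1)}$), so no finite horizon is
"obviously enough". The run is therefore organized in geometrically growing
horizon chunks, starting from the natural timescale heuristic
$t_1 = 10 / (k_{\max}\,q_0^{\,n-1})$ and extending by a factor of 100 per
chunk, until either

1. **depletion** — every input pair total has fallen below
   `completion_eps` ($10^{-6}$ by default) of its initial value, or
2. **stability** — the decoded output changed by less than $10^{-8}$
   across a horizon extension (which, by the conservation law, bounds the
   error of stopping by the undelivered input mass).

Equal-rate runs typically stop by stability after two chunks (the output is
exact from the start); strongly perturbed networks run to depletion,
reaching horizons around $10^6$–$10^{13}$ time units without difficulty
because LSODA's steps grow with the dynamics. If neither criterion is met
within `max_chunks` extensions, a diagnostic error carrying the last state
is raised rather than returning a silently unconverged value.

Reported quantities are *completion* values. For strongly slowed
perturbations (one rate two orders of magnitude low) the error cube keeps
creeping upward on long tails, so summaries at any fixed finite horizon are
slightly smaller than at completion; we take the completion limit as the
well-defined quantity. Negative solver overshoot is clipped to zero at
readout only — inside the rate law evaluation, never in the integrator
state — and the most negative raw value seen is recorded (`min_conc`,
always above $-10^{-9}$ in practice).

For speed, the derivative is evaluated in C (a generic mass-action kernel
staged with the network's stoichiometry, following deSolve's compiled-model
pattern); `crn_ode()` builds the identical derivative in pure R and the two
are cross-checked in the tests. A full 1331-point lattice sweep takes a few
seconds on one core.

### Conventions and tie-breaks

* **Row order.** Rows ascend as binary integers with the *first* listed
  variable as the most significant bit. Compiled reaction order, CSV files
  and the perturbation index all inherit this convention.
* **Perturbation index.** `rate_scheme("single_scaled", reaction = 1, ...)`
  uses 1-based indexing (R idiom); reaction 1 is the all-zeros minterm
  $\mathbf{X}_0 + \mathbf{Y}_0 + \mathbf{Z}_0 \to \mathbf{F}_0$.
* **Species naming.** `<var>_<index>` in files (`a_0`); printed as `a0`
  when the variable name does not itself end in a digit.
* **Shared inputs.** For univariate targets computed with replicated
  columns, each column remains an independent species pair initialized at
  the same fraction (`bind_assignment()`): stochastic logic assumes
  independent input streams, and collapsing replicated columns into one
  pair would correlate them.
* **Cascades.** Stages run to completion sequentially; the volumetric
  requirement of each stage is the sum of its consumers' requirements, so
  an output can be split into equal parts that preserve the fraction.
  Concurrent one-pot operation of several stages is not modeled — the
  sequential semantics is the one with a clean correctness argument.
* **Degenerate inputs.** Zero-input tables are rejected; a fraction is
  undefined on an exhausted pair, and fraction diagnostics are only
  assessed while a pair retains at least $10^{-3}$ of its initial total
  (`q_floor`), below which the ratio of two near-zero concentrations is
  dominated by solver round-off rather than kinetics.

## The robustness study

`error_cube()` measures how the computation degrades when rates are not
equal. The study design:

* **Function under test:** three-input parity (XOR-3,
  $f = x + y + z - 2xy - 2xz - 2yz + 4xyz$). Its table is balanced between
  0s and 1s, making it maximally sensitive to rate variation; unbalanced
  functions such as AND mask errors by over-producing their majority
  output.
* **Input lattice:** all combinations of $x, y, z \in \{0, 0.1, \dots,
  1.0\}$ — both endpoints included, $11^3 = 1331$ points — with every pair
  total at 100 concentration units.
* **Error:** $|\,\hat f_{\text{CRN}} - f\,|$ at each lattice point, with
  $\hat f_{\text{CRN}}$ the decoded output at completion and $f$ the exact
  closed form.
* **Summaries:** the maximum error over the lattice and the percentage of
  points with error strictly above 0.1.
* **Schemes:** one rate scaled by $10^{\pm 1}$ or $10^{\pm 2}$
  (`single_scaled`), or all eight rates drawn from
  $\mathcal N(100, \sigma)$ with $\sigma = 10$ or $70$ (`normal_random`).
  Nonpositive normal draws are redrawn rather than truncated at a floor;
  for $\sigma = 10$ this leaves the mean essentially at 100, while for
  $\sigma = 70$ conditioning on positivity raises the realized mean by
  roughly 10%, a bias inherent to any positivity rule.

Reproducible patterns (asserted in the test suite): a single *slow*
reaction harms less than an equally *fast* one (the fast reaction distorts
the early consumption ratios of every pair it touches, while a slow one
mostly just delays its own minterm's contribution); small normal spread
($\sigma = 10$) keeps the maximum error below the exceedance threshold
everywhere; and errors concentrate in the cube interior — on the faces,
where some input is exactly 0 or 1, one species of a pair is absent and
entire blocks of reactions cannot fire at all, leaving less room for rate
imbalance to bias the outcome.

## The bitstream oracle

`bitstream()` and `eval_streams()` estimate the same stochastic function by
direct sampling: one independent seeded Bernoulli stream per variable,
table lookup per bit position, empirical output mean. The estimate carries
binomial error $\sqrt{f(1-f)/L}$ (default $L = 10^5$), so agreement with
`stoch_value()` within a few standard errors is an implementation-independent
check on both the closed form and the kinetics — the three routes
(enumeration, ODE, sampling) share no code. The NOT gate is exactly
mean-complementary per stream, a useful deterministic identity. Correlated
streams and low-discrepancy deterministic bitstreams are out of scope.

## What the synthetic conditions do and do not show

All tests run on programmatically generated inputs: random truth tables
(up to $n = 4$ for kinetic properties, $n = 6$ for structural ones),
random assignments, and the XOR-3 lattice above. These exercise the
mathematics of the method — exactness at equal rates, the kinetic
invariants, the perturbation response — under ideal mass-action
determinism. They deliberately do not model what a wet implementation
would add: stochastic fluctuations at low copy number (no Gillespie
simulation; the analysis is purely deterministic), reversible reactions,
leak reactions, crosstalk between species, temperature or volume effects,
or the strand-displacement machinery that would realize the abstract
reactions in DNA. Passing tests therefore validate the compilation theory
and its numerical treatment, not the feasibility of any particular
chemistry.

## Problem sizes used by the test suite

Chosen as the package's standard verification workload: 50 random
equal-rate networks for the correctness and invariant properties; the four
deterministic single-rate sweeps at the full 1331-point lattice; 20 seeds
per normal-perturbation scheme for the ordering properties; $L = 10^5$ bits
per stream with 80 table/assignment combinations for the sampling oracle.
The complete suite runs in about four minutes on one core; the acceptance
script in about half a minute.

## Known limitations

* Reaction count is exponential in the number of inputs ($2^n$); the
  design targets the small tables (up to 6 inputs) for which stochastic
  logic yields compact function approximations, and the compiler does not
  attempt logic minimization.
* Only single truth tables and their polynomials are represented; there is
  no gate-netlist intermediate form, and no automatic synthesis of a
  best-approximating table for an arbitrary target function.
* Completion values for strongly slowed perturbations converge on long
  power-law tails; comparisons against finite-horizon simulations of the
  same networks can differ by a few hundredths in maximum error.
* Duplicate-reactant collapsing (e.g. $2\mathbf{A}_1 \to \dots$) is not
  performed: replicated variables stay distinct species pairs.
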