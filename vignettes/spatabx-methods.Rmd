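---
title: "Methods: spatial competition between antibiotic producers, cheaters, sensitive and resistant bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial competition between antibiotic producers, cheaters, sensitive and resistant bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`spatabx` simulates two bacterial species competing on an `L x L` torus.
Species 1 consists of producer strains that secrete a bacteriostatic
antibiotic at a per-strain rate $a$; the strain with $a = 0$ is the
non-producing cheater N. Species 2 consists of sensitive cells S, whose
birth rate is reduced by the local antibiotic, and resistant cells R,
which are immune but pay a fixed growth cost. Per-capita growth rates are

$$r_P = r_1 - ac, \qquad r_N = r_1, \qquad r_S = r_2 - A_{loc}, \qquad
  r_R = r_2 - c_R,$$

with $r_2 > r_1$ so that, absent antibiotic, the sensitive species
outgrows both producer strains. Production at rate $a$ and decay at rate
$b$ are fast compared with cell division, so the antibiotic is at local
quasi-steady state: on the lattice

$$A_{loc} = \frac{\sum_i a_i}{9b},$$

the sum running over the 9-site Moore neighbourhood (the focal site plus
its 8 neighbours). For a single producer strain this is the familiar
$a\,n_P/9b$ with $n_P$ the neighbourhood producer count; with multiple
strains each producer contributes its own rate, which is the unique
additive extension of the single-strain rule (production is linear in the
producer configuration).

This is a rock–paper–scissors structure mediated by a public bad: P
suppresses S, S outgrows N, and N outgrows P by dodging the production
cost.

## Well-mixed (mean-field) counterpart

With densities $P, N, S$ and $T = P + N + S$, death rate 1:

$$\dot P = (r_1 - ac)\,P(1-T) - P, \quad
  \dot N = r_1 N(1-T) - N, \quad
  \dot S = (r_2 - aP/b)\,S(1-T) - S.$$

Single-type equilibria are $1 - 1/r$ for the respective net rate $r$
(`single_species_equilibrium()`). With P and S only, growth rates balance
at $P_0 = b\!\left((r_2-r_1)/a + c\right)$ and
$S_0 = 1 - 1/(r_1 - ac) - P_0$; the point $(P_0, 0, S_0)$ is an unstable
fixed point that exists only when $S_0 > 0$
(`unstable_coexistence_point()`). Setting $S_0(a) = 0$ yields the window
$(a_{\min}, a_{\max})$ of production rates within which a sufficiently
common producer can exclude the sensitive species
(`production_rate_window()`). Below $a_{\min}$ too little antibiotic is
made; above $a_{\max}$ the cost exceeds the benefit. With all three types
present the only stable fixed point is S-only: the well-mixed model
predicts that cheater invasion always destroys antibiotic production.
Coexistence in this package is therefore a genuinely spatial phenomenon,
and the global-dispersal switch of `run_lattice()` turns that claim into
an executable control: with offspring placed on uniformly random sites,
the three-type start fixes to a single species.

One nuance is worth spelling out. The *deterministic* ODE ends S-only
from any interior start, but it does so by letting S recover from
astronomically small densities after the initial producer boom has driven
the antibiotic far above $r_2$. A finite well-mixed population cannot do
that: zero is absorbing, so at high production rates the sensitive
species genuinely goes extinct during the boom and the cheater then
displaces the producer (N-only fixation). Which single species survives
under global dispersal therefore depends on parameters and noise; what is
invariant — and what the property tests assert — is that mixing forbids
coexistence while local dispersal sustains it.

The classical bactericidal colicin system (kill term $-\sigma P S$) is
included as `rhs_colicin()` for comparison; from any interior start with
$r_P < r_N < r_S$ it also collapses to S-only.

# The stochastic lattice algorithm

One sweep advances time by $\delta t$ and visits every site exactly once
in a fresh uniform random permutation. At an occupied site the cell
reproduces with probability $\max(0, r_i)\,\delta t$ into a uniformly
chosen Moore neighbour — the birth is discarded if the target is occupied
— and then, independently, dies with probability $v\,\delta t$. Updates
are applied immediately (asynchronous dynamics), so a newborn that lands
on a not-yet-visited site may act later within the same sweep. At each
birth, the offspring mutates with probability $u$: a species-1 offspring
redraws its production rate uniformly from the other currently active
rates (for two strains this is the P↔N flip), a species-2 offspring
toggles S↔R when resistance mutation is enabled. Mutation never crosses
the species boundary.

Choices the underlying description leaves open, and how this package
settles them:

* **Boundary**: periodic (torus). Standard for pattern-forming lattice
  models; avoids edge artifacts.
* **Birth before death, same visit**: reproduction is evaluated first,
  then the death draw, and both may fire in one visit (independent
  events). Any alternative ordering differs at $O(\delta t^2)$.
* **Newborns act within their birth sweep** if their site has not yet
  been visited; again an $O(\delta t^2)$ effect at $\delta t = 0.01$.
* **Negative growth rates** clamp the birth probability to 0. The
  antibiotic is bacteriostatic: it never adds mortality beyond $v$.
* **Antibiotic field**: the per-site Moore production sums are maintained
  incrementally at every producer birth and death and rebuilt from the
  grid at every recording boundary. Because the quasi-steady-state field
  is a deterministic function of the instantaneous configuration, this is
  exactly the same as recomputing the local field at each birth attempt,
  only cheaper.
* **Early termination**: a run stops once a single cell type remains and
  no enabled mutation channel could restore diversity. This extends the
  "single type and $u = 0$" stopping rule to equivalent absorbing cases
  (e.g. S-only with only P↔N mutation enabled) and cannot change any
  outcome.

## Parameters

| symbol | meaning | default | notes |
|---|---|---|---|
| $r_1$ | species-1 intrinsic growth rate (per time unit) | 2 | |
| $r_2$ | species-2 intrinsic growth rate | 2.5 | must exceed $r_1$ for the cheater dilemma |
| $b$ | antibiotic decay rate | 10 | sets the field scale $a/b$ |
| $c$ | metabolic cost per unit production | 0.001 | fixed property of the pathway |
| $v$ | death rate, all types | 1 | one time unit = one mean lifetime |
| $u$ | mutation probability per birth | 0 | experiments switch to $10^{-4}$ |
| $c_R$ | growth cost of resistance | 0 | $r_R = r_2 - c_R$ |
| $\delta t$ | sweep time step | 0.01 | $\max(r_1, r_2)\delta t \le 1$, $v\,\delta t \le 1$ enforced |
| $L$ | lattice side | 256 | 1024 at full scale |

The default initial condition of the classic experiment is 5% P, 5% N,
5% S, 85% vacant, placed independently per site.

# Determinism and random numbers

The sweep kernel uses a self-contained xoshiro256++ generator seeded via
splitmix64 from the run seed; its state is threaded through between
kernel calls, so identical `(seed, params, composition)` give
bit-identical trajectories. The kernel consumes roughly $10^{10}$
uniforms in a full-scale run, which is why it does not draw from R's RNG
stream; lattice initialisation uses R's RNG under `set.seed(seed)`.
Replicate ensembles derive child seeds as `seed_base + i`.

# Numerical choices

* **ODE integration**: adaptive Dormand–Prince RK5(4), defaults
  `rtol = 1e-10`, `atol = 1e-12`, with states clipped at zero after each
  accepted step (solver undershoot of a density is unphysical).
  Trajectories pass slowly near the axes (quasi-heteroclinic segments),
  which is also why outcome classification refuses to name a winner until
  $\lVert \dot x \rVert_\infty < 10^{-9}$: at looser solver tolerances the
  numerical fixed point itself sits about $10^{-9}$ from the true one,
  so the tolerances were chosen one order tighter than that declaration.
* **Window root-finding**: $S_0(a)$ is scanned on a logarithmic grid over
  $(10^{-3}, (r_1-1)/c)$ — the upper end is the pole where the producer
  becomes non-viable — and each sign change is refined by bracketed
  root-finding to relative tolerance $10^{-9}$. More than two roots is
  reported as anomalous rather than silently truncated.
* **Outcome classification** on the lattice is exact: the surviving set
  is read off non-zero type counts. Tie-breaks in replicate majorities
  use a fixed label order and are flagged.
* **Degenerate inputs**: empty compositions give an all-vacant lattice
  (which is absorbing); production rates outside `allowed_a` are rejected
  at composition time, not during the run.

# What the synthetic world does and does not establish

All experiments are self-generating; there is no external data. The
generator's stated world is the parameter set above. Where results in
this package are produced at desk scale, simulations are scaled down —
lattices of 128–256 instead of 1024, horizons of 2,000–10,000 time units,
ensembles of 10–20 instead of 100 — and this changes what a green test
means:

* Patch sizes in the coexistence regime are tens of sites across, so a
  256² lattice holds enough patches for the cyclic P→S→N→P dominance to
  stabilise at moderate-to-high production rates (e.g. $a = 150$), and
  desk-scale replicate ensembles there reproduce the full-scale outcome
  frequencies.
* Closer to the window boundaries (e.g. $a = 110$), concentration
  oscillations during the initial transient are large relative to a small
  lattice, and a type can be lost by chance where the 1024² system would
  coexist. Desk-scale runs at such parameters show a minority of
  collapsed outcomes that are a finite-size effect, not a property of the
  full-scale model. The staged resistance protocol is therefore run at
  256² with a shared burn-in (see below) rather than at 128².
* Quantities defined as long-run averages (strain distributions,
  equilibrium concentrations) are computed over the trailing half of each
  run; at desk scale the remaining fluctuation is a few percent absolute.
* Slow observables need the full-scale horizon. In the multi-strain
  evolution protocol the total sensitive concentration equilibrates within
  a few thousand time units, but the *position* of the dominant producer
  strain drifts toward its long-run location (a ≈ 100–110) on a timescale
  set by the mutation supply; at a tenth of the full horizon it still
  remembers the initial strain. Likewise, the cheater N is a 1–4% type
  whose ratio to P carries large relative noise and an extinction bias on
  small lattices, so trends in N:P across production rates are not
  resolvable at desk scale even though the coarser trends (total species-1
  fraction falling with a, producer concentration maximal at the smallest
  coexisting a) are.

The generator emulates demographic stochasticity, local dispersal and
mutation. It does not emulate features of real plates or soils:
explicit antibiotic diffusion beyond the Moore neighbourhood, cell
motility independent of reproduction, nutrient competition, plasmid
transfer, or antibiotic-degrading enzymes are all out of scope.

# Staged protocols

`staged_protocol()` (and the `hooks` argument of `run_lattice()`) changes
parameters at scheduled times: switching mutation on after a burn-in,
activating additional production rates, or enabling the S↔R channel. The
strain coding is fixed by `allowed_a` for the whole run; stages activate
rates, they do not invent them. Two ambiguities in the source experiment
descriptions are settled as: the multi-strain evolution protocol's
"1000 time-steps without mutation" is read as 1000 time *units* (all
other durations are given in time units), and the two-strain introduction
experiment's stage time is 5,000 (the main description) rather than 6,000
(the figure caption); both are plain arguments and can be set otherwise.

The resistance sweep varies $r_R = r_2 - c_R$ holding everything else at
the defaults with $a = 110$ ($r_P = 1.89$). Because $c_R$ is inert until
R cells exist, and no R exists before mutation is switched on, all sweep
points share identical burn-in dynamics; the test suite exploits this by
reusing one burn-in lattice across the sweep, which saves most of the
runtime without changing any distribution.

# Known limitations

* Desk-scale lattices under-resolve the coexistence region near its
  boundaries (finite-size extinctions, above).
* The uniform-redraw mutation kernel among production rates is the
  stated model; biologically, small rate changes are presumably more
  likely than jumps, and the evolved strain distribution's low-rate tail
  may depend on that choice.
* The antibiotic field is a quasi-steady-state of nearest-neighbour
  production; explicitly diffusing antibiotic changes patch sizes and is
  deliberately not modelled.
* One lattice site is the effective interaction range of the antibiotic;
  physical length scales enter only through that identification.
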