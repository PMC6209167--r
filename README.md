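# spatabx

Stochastic spatial simulation of competition between antibiotic-producing
bacteria, non-producing cheaters, sensitive cells and resistant cells,
together with the corresponding well-mixed ODE models.

## The problem

Antibiotic production is a costly public good. A producer strain P secretes
antibiotic at rate *a* and pays a growth cost *a·c*; cheater mutants N keep
the benefit of their neighbours' antibiotic without paying, and a faster
growing sensitive species S is inhibited only where antibiotic is present.
In a well-mixed culture this ends badly for everyone but S: cheaters
overgrow producers, and sensitives overgrow cheaters. On a surface,
however, the three types chase each other in patches — P displaces S, S
displaces N, N displaces P — and this cyclic dominance can sustain all
three indefinitely. `spatabx` is for researchers in microbial ecology and
evolutionary dynamics who want a fast, reproducible implementation of this
model class: the lattice engine, its mean-field counterpart, and drivers
for outcome phase diagrams, production-rate evolution and the fate of
resistance mutants R within the sensitive species.

## The model

Growth rates (per unit time, death rate *v* = 1 for everyone):

| type | rate | |
|---|---|---|
| producer strain with rate *a* | *r*₁ − *a·c* | cost of production |
| non-producer N (*a* = 0) | *r*₁ | |
| sensitive S | *r*₂ − *A*loc | bacteriostatic inhibition |
| resistant R | *r*₂ − *c*R | immune, pays a fixed cost |

The antibiotic equilibrates fast, so its local concentration is the
production/decay balance over the 9-site Moore neighbourhood:
*A*loc = Σᵢ *a*ᵢ / 9*b*. Each sweep (time step δ*t*) visits every lattice
site once in fresh random order; an occupied site reproduces into a random
neighbour with probability max(0, *r*ᵢ)·δ*t* (discarded if the target is
occupied) and dies with probability *v*·δ*t*. Offspring mutate with
probability *u*: producer strains redraw *a* among the active rates
(P↔N for two strains), and S↔R when resistance mutation is enabled.

The well-mixed ODEs (with quasi-steady-state antibiotic *A* = *aP*/*b*)
admit closed-form single-species equilibria 1 − 1/*r*, an unstable P/S
balance point *P*₀ = *b*((*r*₂−*r*₁)/*a* + *c*),
*S*₀ = 1 − 1/(*r*₁−*ac*) − *P*₀, and a window (*a*min, *a*max) of
production rates — the roots of *S*₀(*a*) = 0 — inside which producers can
exclude sensitives. With cheaters present the well-mixed ODE always
collapses to S-only; coexistence is a spatial effect, and the package
exposes a global-dispersal switch under which the lattice likewise fixes
to a single species.

## Worked example

```r
library(spatabx)

# mean-field analysis at the default parameters (r1=2, r2=2.5, b=10, c=0.001)
production_rate_window(model_params())
#> production-rate window: a_min = 10.258, a_max = 984.691
unstable_coexistence_point(model_params(), a = 110)
#> unstable P/S point: P0 = 0.0554545, S0 = 0.415445 (exists: TRUE)

# a lattice run: 96x96 torus, 5% each of P(a=150), N, S
p <- model_params(L = 96, allowed_a = c(0, 150), seed = 42)
r <- run_lattice(p, lattice_composition(P150 = .05, N = .05, S = .05),
                 t_end = 300)
round(tail(r$series, 3), 4)
#>    time vacant      N   P150      S R
#> 29  280 0.4619 0.0105 0.0507 0.4769 0
#> 30  290 0.4752 0.0022 0.0528 0.4698 0
#> 31  300 0.4652 0.0014 0.0519 0.4816 0
classify_outcome(r)
#> outcome: coexist_PNS  (surviving: N, P150, S)
```

The window says producers can only hold their own for production rates
between about 10 and 985; the lattice run shows all three types alive at
*t* = 300 with sensitives and vacancy dominating and the cheater rare —
the patchy steady state, not a frozen pattern. Identical
`(seed, params, composition)` give bit-identical trajectories.

Higher-level drivers: `replicate_outcomes()` (outcome frequencies over an
ensemble), `phase_diagram()` (majority outcome over an *a*×*c* grid),
`evolve_production_rates()` (multi-strain mutation among rates 0–200),
`resistance_sweep()` (equilibrium concentrations as the resistant growth
rate varies), `staged_protocol()` (parameter changes at scheduled times),
and snapshot/time-series I/O in plain text. A command-line interface is
available via `abx_cli()` or `inst/cli/spatabx.R`:

```sh
Rscript -e 'spatabx::abx_cli()' ode window --c 0.001
Rscript -e 'spatabx::abx_cli()' replicates --a 150 --c 0.001 --n 10 --L 256
```

## Scope

Antibiotic diffusion beyond the Moore neighbourhood, independent cell
motility, plasmid transfer and antibiotic-degrading enzymes are out of
scope. See the methods vignette (`vignettes/spatabx-methods.Rmd`) for
assumptions, numerical choices and desk-scale limitations.
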