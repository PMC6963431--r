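# mtswarm

Agent-based simulation of microtubule substructure self-assembly in R.

Microtubules grow from α/β-tubulin heterodimers that polymerize into
protofilaments, rings and sheets, under the control of guanosine nucleotides:
GTP binding activates dimers for polymerization, and hydrolysis to GDP
weakens bonds and drives depolymerization. `mtswarm` models the earliest
stages of this hierarchy as a swarm of disc-shaped agents in a bounded 2D
tray. Tubulins and nucleotides diffuse under impulsive random forcing
(components uniform on \[-F<sub>max</sub>, F<sub>max</sub>\] every 0.1 s) and
interact through local, per-agent rules:

1. **Dimerization** — a free α and a free β tubulin whose complementary
   bonding sites (A↔B) meet inside a trigger zone bond into an inactive
   heterodimer.
2. **Activation** — an inactive dimer whose two members each have a free GTP
   in range activates on a single draw P<sub>random</sub> ≤ P<sub>GTP</sub>,
   consuming both GTPs (one per tubulin).
3. **Polymerization** — active dimers bond end-to-end at complementary free
   termini: straight protofilaments, or — when activation displaces the
   bond azimuths by θ = 30° per junction — circular arcs that close into
   rings of exactly 360°/θ = 12 members.
4. **Extended rules** — a terminal dimer of an open chain of length L breaks
   off with probability 1 − (1 − P<sub>break</sub>)<sup>L</sup>, releasing
   its nucleotides as free GDP (hydrolysis); a free GDP recovers to GTP
   after Limit<sub>GDP</sub> = 3 s (300 iterations).

Per-iteration analytics (dimer counts, free GTP/GDP, chain statistics, ring
counts) and a moving-average GTP consumption rate support the analysis of
how GTP population density — more than bonding probability — controls
polymerization. The intended audience is anyone studying rule-based
self-organization: the package is a laboratory for bonding-rule design, not
a molecular-dynamics code.

## Worked example

A desk-scale variant of the first reference experiment (populations scaled
to 0.1, tray side shrunk by √0.1 so number density is preserved): 30 α + 30 β
tubulins, 60 GTPs, P<sub>GTP</sub> = 1, three trials of 20,000 iterations.

```r
library(mtswarm)

cfg <- mt_config("sim1", scale = 0.1, iterations = 20000, trials = 3, seed = 42)
run <- mt_run(cfg)
run
#> <mtswarm_run> preset sim1: 3 trial(s), 20000 iterations each
#>   trial 1 (seed 43): 18 active / 3 inactive dimers, 5 chains, max length 4, 0 ring(s)
#>   trial 2 (seed 44): 13 active / 2 inactive dimers, 4 chains, max length 2, 0 ring(s)
#>   trial 3 (seed 45): 13 active / 4 inactive dimers, 3 chains, max length 5, 0 ring(s)
```

Each trial starts from randomly placed agents (seed + trial), so by 20,000
iterations 13–18 of the 30 possible dimers are GTP-activated (consuming
26–36 of the 60 GTPs) and the first short protofilaments (2–5 dimers) have
polymerized. `tidy(run)` returns the full per-iteration counts table,
`glance(run)` one row per trial, `autoplot(run)` the population curves, and
`mt_summarize(run)` per-combination means over trials:

```r
mt_summarize(run)$combinations[, c("trials", "final_active", "final_free_gtp", "max_chain_length")]
#>   trials final_active final_free_gtp max_chain_length
#> 1      3     14.66667       30.66667         3.666667
```

Ring mode (`mt_config("sim3", ...)`) bends chains 30° per junction;
`mt_run_until()` runs until a condition — such as the first closed ring —
is met:

```r
out <- mt_run_until(mt_config("sim3", scale = 0.2, seed = 20),
                    function(w) mt_snapshot(w)$closed_ring_count >= 1,
                    max_iterations = 400000)
chain_statistics(out$world)$length_histogram  # closed rings have 12 members
```

A command-line driver installs to `exec/`:

```sh
mtswarm run --preset sim1 --gtp 600 --iterations 120000 --trials 3 --seed 42 --out runs/
mtswarm summarize runs/trial-1 runs/trial-2 runs/trial-3
mtswarm plot runs/trial-1 --out counts.pdf
```

## Package layout

| file | contents |
| --- | --- |
| `R/geometry.R` | agent geometry, bonding sites, ring bond-angle displacement |
| `R/physics.R` + `src/kernels.cpp` | forcing, rigid-cluster integration, collision resolution |
| `R/rules.R` | dimerization, activation, polymerization, recovery, breakage |
| `R/analytics.R` | per-iteration counts, chain statistics, consumption rate |
| `R/config.R`, `R/run.R` | presets (sim1–sim4), trial orchestration, manifests, summaries |
| `R/cli.R`, `exec/mtswarm` | command-line driver |
| `vignettes/mtswarm-methods.Rmd` | model assumptions, parameter choices, limitations |
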