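---
title: "Methods: rule-based self-assembly of microtubule substructures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based self-assembly of microtubule substructures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mtswarm is an agent-based ("swarm engineering") simulator of the earliest
stages of microtubule self-organization: free α- and β-tubulin monomers in a
bounded two-dimensional tray form heterodimers, heterodimers are activated by
discrete GTP particles, and activated dimers polymerize into protofilaments
or — with displaced bonding angles — into closed rings. An extended rule set
adds the reverse path: length-dependent breakage of terminal dimers with
hydrolysis (release of the bound nucleotides as GDP) and timed GDP→GTP
recovery. The model is deliberately coarse: agents are rigid discs with
behavioural rules, not molecules with force fields. What the simulator is for
is studying how *population densities and bonding probabilities* shape
polymerization kinetics and chain-length distributions, not for reproducing
molecular detail.

## Agents and geometry

Every tubulin is a disc of radius $r$ (default 0.03 tray units) with a
primary axis and two bonding sites, A and B, on the rim at azimuths $0$ and
$\pi$ relative to that axis. An α tubulin's A site can bond only a β
tubulin's B site and vice versa; the intra-dimer bond is fixed to the
α-A↔β-B pairing, which leaves the α's B site and the β's A site as the
outward termini that inter-dimer (polymerization) bonds use. Because every
site holds at most one bond, chains are automatically simple paths or simple
cycles: branching cannot be expressed.

Bonding is initiated inside *trigger zones*: a bonding rule is evaluated
when the relevant sites (tubulin–tubulin bonds) or bodies (GTP binding) are
within the trigger radius, default $2r$. The default is deliberately larger
than contact distance, since a rule evaluated exactly at contact would
almost never fire in discrete time.

When a bond forms, the geometry is snapped: the joining cluster is rotated
and translated rigidly so the two sites coincide and face each other. In
protofilament mode the free-site azimuths stay at $0/\pi$, so snapped chains
are straight. In ring mode, activation displaces the two free sites
symmetrically by $\pm\theta/2$ off the primary axis (default
$\theta = 30°$). With the facing-site constraint this turns each junction by
exactly $\theta$ in a consistent rotational sense, so the cumulative bend
reaches one full turn — and the two chain termini geometrically coincide —
after $360°/\theta$ dimers: 12 members at 30°, 8 at 45°. Two conventions
hide here and both were genuinely open:

* the $\pm\theta/2$ split (rather than $\pm\theta$) is what makes the
  junction bend equal $\theta$; a $\pm\theta$ displacement would bend
  junctions by $2\theta$ and close rings at half the stated membership,
  contradicting the 12-member/30° design point;
* all junctions bend in the same (counter-clockwise) sense; the symmetric
  alternative would produce zig-zag chains that never close.

In ring mode a merge of two chains is refused when the combined length would
exceed the ring capacity $\mathrm{round}(360/\theta)$ — a rigid chain bent
past one full turn would self-overlap — and a cycle-closing bond is accepted
only at exactly the capacity, which is also the only length at which the
termini can be inside one another's trigger zones. Closed rings have no free
sites and no terminal dimers, so they accept no bonds and never break:
rings are terminal products here.

## Physics

The tray is a $3\times3$-unit rectangle with reflecting walls. Motion is a
damped semi-implicit update at a fixed timestep $dt = 0.01$ s. Brownian-like
agitation comes from impulsive random forces: every $T = 0.1$ s (10 steps)
each free agent and each constituent tubulin of a bonded cluster receives an
independent force with components uniform on $[-F_{\max}, F_{\max}]$;
between kicks the force is zero. For a bonded cluster the member forces
accumulate into a net force and a net torque about the centroid, so chains
translate and tumble rigidly; cluster geometry is exact (rotation matrices
about the centroid), so internal distances are preserved to machine
precision over arbitrarily long runs.

Parameters that the model's sources leave open, fixed here once:

* $F_{\max} = 1$ force unit (reported in every manifest); tubulin mass 1,
  nucleotide mass 0.5, so nucleotides diffuse faster than tubulins;
* damping 0.98 per step — impulsive kicks without damping accumulate energy
  without bound; with damping the speed distribution reaches a stationary
  state within ~0.5 s of simulated time;
* collisions are resolved positionally: overlapping discs of different
  clusters are pushed apart along their centre line, the correction split
  inversely by cluster mass and applied to whole clusters, over up to
  `collision_passes` (default 4) Gauss–Seidel passes per step. This is a
  standard position-based-dynamics treatment; it exchanges no momentum, which
  is acceptable because the kicks dominate transport.
* bond formation is perfectly inelastic: the merged cluster takes the
  mass-weighted mean velocity and zero angular velocity.

## Interaction rules

Within each iteration, after the physics step, rules are applied in a fixed
order: GDP→GTP recovery, heterodimer formation, GTP activation,
dimer–dimer polymerization, then (extended rules only, at check iterations)
terminal breakage. Candidate pairs are enumerated by trigger-zone proximity
and processed nearest-first, ties broken by lower agent index; each bonding
site and each nucleotide takes part in at most one topology change per
iteration. The fixed order plus deterministic tie-breaks make a run a pure
function of its configuration and seed.

**Heterodimer formation** is deterministic on contact: a free α and a free β
with complementary free sites inside the trigger zone bond into an
*inactive* dimer.

**Activation** is stochastic and atomic at the dimer level. An inactive
dimer whose two members each have a *distinct* free GTP inside their body
trigger zones activates on a single uniform draw $P_{random} \le P_{GTP}$,
binding both GTPs simultaneously (free GDPs never qualify). Atomicity is a
deliberate design decision, not an omission. With sequential one-at-a-time
binding, irreversibly bound single GTPs strand in half-loaded dimers — in
GTP-limited runs the active-dimer count then saturates well *below* the
GTP-limited level, and the bookkeeping identity
$\mathrm{freeGTP} + \mathrm{freeGDP} + 2\,\mathrm{active} = \mathrm{total}$
fails transiently. The dimer-level activation condition with its single
random draw, the saturation of active dimers at the GTP-limited ceiling, and
that conservation identity are all restored by atomic binding, and the
requirement of two GTPs — one per member tubulin — is still honoured in the
consumption accounting.

**Polymerization** bonds two dimers at complementary free termini inside the
trigger zone. By default both dimers must be active; the weaker reading in
which only the initiating dimer must be active is available as
`require_partner_active = FALSE`.

**Recovery**: a free GDP flips back to GTP once it has spent
`limit_gdp` seconds (default 3 s = 300 iterations) in the GDP state — a
duration function standing in for re-phosphorylation, so that explicit water
agents are unnecessary.

**Terminal breakage** (extended rules): at every `break_check_interval`-th
iteration (default 100, i.e. once per simulated second) each terminal dimer
of an open chain of length $L$ breaks off with probability
$1-(1-P_{break})^L$ — equal to $P_{break}$ at $L=1$ and increasing in $L$,
so long protofilaments shed ends faster. Both ends of a chain are judged
against the same pre-check length. A detached dimer keeps its internal α–β
bond but turns inactive, releasing its two nucleotides as free GDP at the
break site (the model's representation of hydrolysis); in ring mode its
displaced bond angles reset. The check cadence matters: the printed
$P_{break}$ values (0.1–0.5) applied at every 0.01-s frame would make any
chain growth impossible, so breakage is evaluated on a slower clock than
bonding; the cadence is configurable and logged.

## Analytics

Each iteration logs inactive dimers, active dimers (chained dimers
included), free GTP, free GDP, maximum chain length, chain count, closed
ring count and bound-nucleotide count. A *chain* is a connected dimer
component of at least two dimers — lone dimers are not chains. The GTP
consumption rate is the successive difference of a trailing moving average
(default window 1000 points) of the free-GTP series; the trailing window was
chosen so the rate at iteration $i$ uses only data up to $i$, and a centered
variant is available. More negative rate = faster consumption. Two
conservation identities hold at every logged row: tubulin accounting
($2(\mathrm{active}+\mathrm{inactive}) + \mathrm{monomers} =
\mathrm{total\ tubulins}$) and nucleotide accounting
($\mathrm{freeGTP}+\mathrm{freeGDP}+\mathrm{bound} = \mathrm{initial\
nucleotides}$).

## Experiments and desk scale

The four presets reproduce the reference experiment grid: protofilament
formation across GTP populations 200–1200 at $P_{GTP}=1$ (sim1), bonding
probabilities 0.05/0.5/1 at 600 GTP (sim2), rings (sim3), and extended-rule
runs started from GDP with $P_{break} \in \{0,\dots,0.5\}$ (sim4); 300 α +
300 β tubulins throughout, 120,000 iterations (100,000 for sim4), three
trials per combination, trial $t$ seeded with `seed` $+ t$.

`scale` produces desk-scale variants: populations multiply by `scale` and
the tray side shrinks by $\sqrt{\mathrm{scale}}$, preserving number density
— and therefore encounter kinetics — rather than the tray itself. With the
tray held fixed, a tenth of the population would take roughly ten times as
long to find partners, which defeats the purpose of scaling down. Scaled
runs default to 20,000 iterations; the package's own test-suite mostly uses
scale 0.1 (60 tubulins), with run lengths from 20,000 up to several hundred
thousand iterations depending on how rare the awaited event is. Ring
closure is the exception: at scale 0.1 there is material for only two and a
half 12-member rings, and the dimers routinely fragment into three or four
mid-length chains whose lengths cannot combine to exactly 12 within any
reasonable time — an artifact of under-supplying the scaled run, not of the
rules. Ring-closure runs therefore use scale 0.2 (120 tubulins at the same
density), at which enough chains grow in parallel for one of them to reach
the 12-member capacity within a few hundred thousand iterations.

## What the generator does and does not emulate

The synthetic dynamics emulate crowding, diffusive transport, stochastic
binding and the GTP/GDP cycle of the modelled system, and they support the
qualitative claims the analytics are designed for: GTP-population-limited
saturation of activation, density-dependent polymerization rate, and
breakage-probability-dependent chain lengths. They do not emulate real
tubulin biochemistry — no lateral protofilament contacts, no sheets or
tubes, no GTP cap or catastrophe/rescue asymmetry, no MAPs beyond the
nucleotide rules, no hydrodynamics, and elevation angles are absent because
the motion is planar. Passing tests therefore show the *rule system* behaves
as designed at desk scale; they do not validate the model against
experimental microtubule data.

## Numerical and degenerate-input choices

* Timestep, kick interval and recovery limit interact as integer ratios
  (`kick_interval/dt`, `limit_gdp/dt`); the configuration validator enforces
  the first and the recovery rule uses iteration arithmetic, so there is no
  floating-point drift in event timing.
* Overlap resolution stops at `collision_tol` (1e-4) or the pass budget;
  it is best-effort by design, and a dense random initialisation is instead
  prevented up front by rejection-sampling non-overlapping positions (up to
  10,000 attempts per agent before a crowding error).
* Coincident disc centres (distance 0) push apart along a fixed direction to
  keep the correction deterministic.
* A world with no agents, no GTPs, or `P_GTP = 0` passes through every rule
  as a no-op; `P_break = 1` empties every open chain at each check;
  `limit_gdp = 0` converts GDP on the next rule sweep; `theta = 0` is the
  straight-chain limit of the ring transformation.
* Orientations are kept bounded by wrapping snap rotations to $(-\pi,\pi]$,
  so long runs do not accumulate large orientation magnitudes.

## Known limitations

Chain transport slows with cluster size (net kick force grows as
$\sqrt{n}$, mass as $n$), so late-stage assembly — especially the last
member of a ring — is diffusion-limited and can take hundreds of thousands
of iterations at desk scale; `mt_run_until()` therefore runs a trial until a
caller-supplied condition (for example, the first closed ring) is met.
Moreover, because ring-mode chains only ever grow, a trial's chain
inventory can *deadlock* — no subset of open-chain lengths plus unchained
dimers sums to the ring capacity — after which no ring can ever close;
`ring_completion_possible()` detects this so that rare-event protocols can
abandon dead trials and reseed instead of burning their iteration budget. The collision model is positional
rather than impulse-based; momentum is not conserved through contacts. And
the extended rules apply to protofilament-mode chains; closed rings are
immortal by construction, matching the modelled scope in which breakage
rules were introduced for protofilaments only.
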