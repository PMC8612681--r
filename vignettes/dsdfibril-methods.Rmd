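---
title: "Models and methods behind dsdfibril"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dsdfibril}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsdfibril)
```

## The system

dsdfibril simulates a toehold-mediated DNA strand-displacement (DSD) circuit
that cross-regulates the polymerization of two self-sorting DNA-origami
species: hollow nanocylinders that polymerize into transient nanotubes, and
nanocuboids that polymerize into persistent fibrils. The circuit implements a
negative feedback loop. An external **input** strand displaces a
quencher-bearing **activator** from the cylinder connector `c1` (toehold 5,
8 nb), simultaneously arming the cylinder for polymerization (the displaced
input presents the bridging domain 9\*, which captures the opposite-face
connector `c1*`) and unquenching the cylinder's Cy5 reporter. The freed
activator invades the cuboid gate `c2/inhibitor` through the mismatched,
loop-presented toehold 6' (4 nb effective), releasing the **inhibitor**,
arming the cuboid bridge (domain 8\* captures `c2*`) and unquenching Cy3.
The released inhibitor closes the loop: entering at toehold 1 (9 nb) it
displaces the input from the bright cylinder complex, quenching Cy5 and
disarming the nanotube — the negative feedback that makes the nanotubes
transient while the cuboid fibrils persist.

Two optional modules modulate the loop. The **amplifier** fuels displace the
activator from the cuboid bridge through toehold 10 (7 nb): fuel A
(`10* 7* 8*`) replaces the bridge and keeps fibrils intact, fuel B
(`10* 7*`) cannot bridge and breaks them; both replenish free activator and
so sharpen the negative feedback. The **threshold** gate presents a fully
complementary toehold 6 and acts as a competitive activator sink that delays
the downstream reactions.

## Domain-level representation and enumeration

Species are complexes: multisets of strands joined by bonds between
complementary named domains, with at most one bond per domain instance, a
connected strand–bond graph, and no pseudoknots (some strand ordering and
per-strand direction draws every bond without crossings; strands are written
template-parallel in the library). Canonical identity is the lexicographic
minimum of the complex serialization over strand orderings, so enumeration
never duplicates isomorphic species.

The reachable network is the breadth-first closure of the initial species
under three moves:

* **bind** — bimolecular association at any free complementary domain pair.
  Long domains (the 16-nb migration cores and bridges) bind at the saturated
  rate; this is how the polymer bridges 9:9\* and 8:8\* form.
* **unbind** — dissociation of a toehold-length bond whose removal splits
  the complex, at the standard rate $u_0$. An isolated two-strand duplex
  held by a single *bridging* bond (domains 8/9) is additionally treated as
  metastable and frays at `u_bridge_solo` (default $u_0$); this is what
  releases the activator after fuel B breaks a fibril bridge. Internal
  fraying that does not split a complex re-anneals fast and is not
  enumerated.
* **migrate** — an irreversible maximal 3-way branch-migration run from an
  anchored toehold at rate `k_migrate`, transferring the incumbent's
  contiguous holds (and zipping free template domains) and splitting off any
  strand left without bonds. A second flavour, the *anchored takeover*,
  models the fuel pathways: an invader bound only by a toehold **on** the
  incumbent strand assumes every template bond whose domain it carries a
  free copy of, and the incumbent's remaining toehold-length holds are
  released in the same event.

Hairpin loops are treated kinetically, not structurally. Each declaration
lists protected domains, a guard domain and a mode: the activator's
`{6*, 7*, 8*}` are inert while its gate anchor `2*` is bound, the
inhibitor's `{1*, 2*, 5*}` while its `7*` is bound, and the threshold's `7`
until its toehold `6` is bound. This realizes the steric protection that
keeps the resting circuit leak-free — without input, the closure of the
initial species contains no reactions at all, matching the experimental
leak check. The loop toehold proper (activator `6*`, inhibitor `1*`)
additionally carries the kinetic factor $h$ when it initiates a bind; the
stem-adjacent segments react at full rate once the strand leaves its gate.

One deliberate feature of the packaged strand layout: the inhibitor spans
`7* 1* 2* 5*`, so after full branch migration the final `c1/inhibitor`
complex buries **every** entry toehold on `c1`. Completion of the negative
feedback is therefore structurally irreversible rather than a kinetic
accident, which is what lets the Cy5 proxy decay to a few percent of its
peak instead of equilibrating at a bright mixture.

## Rate model

The rate-determining step of a displacement is toehold binding. With
effective toehold length $n_\mathrm{eff}$ (length minus mismatched bases;
the connector toehold 6' has $8-4=4$):

$$k = k_\mathrm{max}\, 10^{-\sigma\,\max(0,\; n_\mathrm{sat}-n_\mathrm{eff})}
      \cdot h^{[\mathrm{loop}]} \cdot \rho^{\#\mathrm{tethered}}$$

with defaults $n_\mathrm{sat} = 6$ nb and $\sigma = 0.5$ per missing base,
so the 4-nb mismatched toehold runs 10× slower than a saturated one.
Unbinding uses the standard rate $u_0 = 0.012\,\mathrm{s^{-1}}$ for duplexes
up to $n_\mathrm{sat}+4$ nb; longer duplexes are non-dissociating on the
18-h horizon. Displacement is two elementary steps: reversible toehold
association, then irreversible migration at `k_migrate` (0.1 s⁻¹). The
origami factor $\rho$ multiplies a bimolecular rate once per
origami-tethered reactant complex and models the crowded, slowly diffusing
connector patches at the origami tips.

### Calibration

The sequence-level binding rates of the laboratory system are not available,
so the free constants are fixed in three ordered stages against printed
milestones (see `calibrate()`); later stages never touch earlier parameters.

* **Stage 1** (free strands, $\rho = 1$): $k_\mathrm{max}$ and $h$ against
  the Cy5 peak within 10 min, circuit completion near 2 h, and the quenched
  Cy5 endpoint. Packaged: $k_\mathrm{max} = 10^{-3}\,
  \mathrm{nM^{-1}s^{-1}}$ ($\approx 10^6\,\mathrm{M^{-1}s^{-1}}$, the
  textbook saturated toehold rate), $h = 0.08$. The completion time is
  governed by the second-order tail of the activator→cuboid step
  ($k_\mathrm{max}\cdot 10^{-1}\cdot h$), which pins the product
  $k_\mathrm{max} h$; the Cy5 peak only bounds $k_\mathrm{max}$ from below.
* **Stage 2** (origami circuit): $\rho$ against the origami Cy5 peak within
  30 min and a ~3-fold (±50%) peak delay relative to the free strands.
  Packaged: $\rho = 0.35$, which places the origami peak about 4× later
  than the free-strand one.
* **Stage 3** (coupled assembly): `k_bond`, `k_frag0`, `k_break` against
  the cylinder transient maximum ($\bar X_n = 3.5$), the cuboid 18-h
  plateau ($\bar X_n = 3.5$) and near-complete nanotube depolymerization at
  18 h. The modulated conditions (fuel A, threshold, 8-connector cuboids at
  doubled concentration) are **never** fitted; they are run with preset
  changes only and serve as cross-condition checks.

The brightness context factors (below) keep their 0.8 defaults; the
milestones constrain them only weakly.

## Fluorescence proxies

Quenching is declared per complex: a fluorophore is dark when a
quencher-bearing strand is bound in the same complex, with one structural
exception — the activator bound to `c2` via its `6*/7*` end leaves its
quencher-modified `2*` end dangling away from the Cy3, so activator-bound
cuboid species stay bright. Two context factors model partial Cy3 quenching
inside three-strand complexes: `b_cy3_fuelA_triplex` (Cy3 in
`c2/c2*/fuelA`) and `b_cy3_activator_triplex` (Cy3 in `c2/c2*/activator`,
origami mode only; the sub-100% plateau this models has no reported numeric
value, so 0.8 is a free default). The channel proxy is the
brightness-weighted species sum divided by the channel's total fluorophore
concentration, so the all-unquenched reference state reads exactly 1. No
distance-based FRET efficiency is modelled.

## Coupled fibril assembly

The strand-level trajectory drives assembly by operator splitting: the
connector pool is well mixed, fibril topology does not feed back, and
bridge-species consumption by bonding is neglected. For each monomer type we
derive the **arming fraction** $a(t)$ — the share of connectors sitting in
complexes that contain a bridging strand (cylinder: input; cuboid: activator
or fuel A) and no disarming strand — and the **disarm hazard** $d(t)$, the
flux of armed-pool-reducing reactions divided by the armed concentration.

Assembly is a Gillespie simulation over the fibril length multiset of each
type separately (self-sorting is structural; mixed bonds do not exist).
Fibrils $i,j$ join end-to-end with propensity

$$k_\mathrm{bond}\,\frac{c_\mathrm{monomer}}{N}\; a(t)^{m_\mathrm{arm}}\,
  (L_i L_j)^{-\gamma},$$

and every internal bond breaks at

$$k_\mathrm{break}\, d(t)\, (1-a(t))^{\theta_\mathrm{break}} + k_\mathrm{frag0}.$$

$\gamma = 0.5$ (geometric-mean $1/L$ kernel) stands in for the reduced
diffusion and end-encounter rate of longer colloidal fibrils; $m_\mathrm{arm}
= 2$ because both faces of a new bond must be armed; $\theta_\mathrm{break}
= 2$ makes scission cooperative in the disarmed fraction of the multivalent
(8/16-connector) interface, instead of tracking per-connector state. The
baseline scission rate `k_frag0` is a deliberate model choice: with
disarm-driven breaking alone, armed cuboid fibrils grow without bound,
whereas the observed cuboid population plateaus from about 2 h — a dynamic
growth/fragmentation equilibrium. A single small constant rate produces that
plateau and simultaneously explains why the cylinder transient maximum and
the cuboid plateau sit at the same $\bar X_n$: both are the same equilibrium,
read out at different arming levels. Pre-existing base-stacking dimers seed
the cuboid population (10% of monomers, cylinders 0%).

Time-varying propensities are handled by holding $a$ and $d$
piecewise-constant on the trajectory grid and running exact SSA within each
interval. Monomer counts are conserved exactly at every event, and the
number-average degree of polymerization $\bar X_n = \sum L\,c_L / \sum c_L$
is reported as mean ± sd over replicate seeds, because the TEM statistics it
is compared against were themselves counted from ~200 objects per sample.

## Numerical choices

* ODE integration: `lsoda` with rtol $10^{-8}$, atol $10^{-12}$ nM (the
  network is mildly stiff: rates span $u_0$ to $k_\mathrm{max}\times 160$
  nM); output on 1,000 geometric points from 1 s to 18 h plus $t=0$, which
  resolves both the 10-min and the 18-h features. Strand totals are
  conserved to $<10^{-6}$ relative along every trajectory.
* SSA: exact direct method on copy numbers with a dependency-graph
  propensity update; the default volume scale (625 copies/nM, i.e. $10^5$
  copies at 160 nM) keeps runs in seconds while making stochastic noise
  visible. Trajectories are reproducible per seed.
* Enumeration caps: at most 4 strands per complex (polymer bridges are
  truncated at the dimer-bridge level and handed to the assembly module as
  arming statistics) and 500 species; exceeding the species cap raises an
  enumeration-overflow error naming the runaway species.
* Ties in `peak_time()` resolve to the earliest grid point;
  `completion_time(level)` is the first time from which a trace stays
  within `level` of its final value.
* Problem sizes used by the packaged checks: assembly statistics use 20
  seeds × 5,000 monomers per type; the stochastic-vs-deterministic
  comparison uses 100 replicates at $10^4$ copies per species; the
  mean-field aggregation check uses 8 replicates of 2,000 monomers against
  a 200-term truncated Smoluchowski solution.

## What the simulator does and does not capture

The synthetic conditions are the published ones: 160/320 nM free-strand
mixtures, 10–20 nM origami with 8 or 16 connectors per face (connector
pools = monomer concentration × connectors), 37 °C, 18-h horizon, and the
reported fuel/threshold concentrations (three different fuel A
concentrations are reported for different experiments; each is a named
preset). Passing
checks show that the calibrated reaction network reproduces the *kinetic
anatomy* (peak/completion times, qualitative trace shapes) and the
*population statistics* ($\bar X_n$ at the TEM checkpoints) of the
laboratory system under these presets. They do not show sequence-level
fidelity: binding rates derive from toehold lengths rather than melting
thermodynamics, quenching is per-complex rather than geometric, salt and
temperature enter only through the calibrated constants, and the assembly
model is zero-dimensional (no bending, stacking geometry, or cyclization).

Known limitations worth flagging. The threshold gate is modelled as a pure
competitive sink, as designed: a faster, fully complementary toehold with no
downstream escape. With the threshold equimolar to the activator this
soaks up nearly the whole activator pool, so the simulated cuboid
population under the threshold preset stays much shorter at 18 h than the
measured one — the experiment evidently recovers activator from the
threshold complex through some pathway (partial reversibility, gate
consumption or leak) that 3-way displacement semantics do not provide. The
delay side of the threshold behaviour (longer nanotube lifetime, higher
transient Cy5, higher cylinder $\bar X_n$ at 30 min) is reproduced. Fuel B
end-point behaviour, by contrast, is captured through the metastable-bridge
rule described above.
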