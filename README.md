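# dsdfibril

Simulator for DNA strand-displacement (DSD) reaction networks that
cross-regulate two self-sorting DNA-origami fibril species: nanocylinders
that polymerize into *transient* nanotubes under negative feedback, and
nanocuboids whose fibrils persist — plus the amplifier (fuel A/B) and
threshold modules that reshape the feedback. It is aimed at people building
or analysing dynamic DNA-origami circuits who want a strand-level kinetic
model coupled to the colloidal polymerization it controls, without
sequence-level design.

The package covers the whole chain:

1. **Domain-level species** — strands as ordered named domains with
   fluorophore/quencher labels and kinetic hairpin-protection declarations;
   complexes with canonical identity, so enumeration never duplicates
   isomorphic species.
2. **Reaction enumeration** — breadth-first closure under toehold binding,
   toehold unbinding and irreversible 3-way branch migration (including the
   anchored fuel takeover pathways), producing a mass-action CRN exportable
   to SBML L3 and CSV.
3. **Rate model** — toehold-limited kinetics
   `k = k_max · 10^(−σ·max(0, n_sat − n_eff))` with hairpin factor `h`,
   origami crowding factor `ρ`, standard unbinding rate `u₀ = 0.012 s⁻¹`,
   and two-step (bind-then-migrate) displacement semantics.
4. **Kinetics** — stiff ODE integration (`deSolve::lsoda`) or exact
   Gillespie SSA (Rcpp core), with normalized Cy3/Cy5 fluorescence proxies
   (a fluorophore is dark when a quencher strand shares its complex).
5. **Coupled assembly** — the connector arming fraction `a(t)` and disarm
   hazard `d(t)` drive a stochastic reversible step-growth simulation of
   each monomer population; join kernel
   `k_bond · a(t)^m_arm · (L_i·L_j)^(−γ)`, per-bond scission
   `k_break · d(t) · (1−a(t))^θ + k_frag0`. Length distributions and the
   number-average degree of polymerization
   `X̄n = Σ(L·count)/Σ(count)` come out at the TEM checkpoint times.
6. **Presets & calibration** — the published experimental conditions as
   named presets (`dsd_presets()`), and the staged calibration that fixed
   the packaged rate constants (`calibrate()`).

## Worked example

Simulate the free-strand negative-feedback circuit at 160 nM and read off
the kinetic milestones:

```r
library(dsdfibril)

circ <- build_circuit("freestrand-160")
crn  <- circuit_crn(circ)
glance(crn)
#> # A tibble: 1 × 6
#>   n_species n_reactions n_bind n_unbind n_migrate origami_mode
#>       <int>       <int>  <int>    <int>     <int> <lgl>
#> 1        24          45     19       14        12 FALSE

tc <- simulate_ode(crn, circ$conc)
f5 <- fluorescence_trace(tc, "Cy5", crn = crn)
peak_time(f5) / 60          # minutes to the unquenched-Cy5 maximum
#> [1] 2.17
completion_time(tibble::tibble(time_s = tc$time_s,
                               value = tc$`c1/inhibitor`), 0.10) / 3600
#> [1] 2.14                  # hours to the completed feedback loop
```

The Cy5 proxy rises within minutes as the input invades the cylinder gates,
peaks, and then decays as the released inhibitor closes the loop; the final
`c1/inhibitor` complex forms on the two-hour scale set by the slow,
mismatched activator→cuboid step. The origami version of the same circuit
(`"origami-basic-10"`, 10 nM of each origami with 16 connectors) runs
~4× slower through the crowding factor `ρ` and couples into assembly:

```r
fib <- simulate_fibrils("origami-basic-10", seeds = 1:20)
xn_summary(fib) |> dplyr::filter(time_h %in% c(0.5, 18))
#> # A tibble: 4 × 6
#>   species  time_h xn_mean   xn_sd n_seeds max_length
#>   <chr>     <dbl>   <dbl>   <dbl>   <int>      <int>
#> 1 cuboid      0.5    1.39 0.0103       20          8
#> 2 cuboid     18      3.71 0.0564       20         27
#> 3 cylinder    0.5    3.27 0.0453       20         24
#> 4 cylinder   18      1.07 0.00461      20          4
```

Cylinder nanotubes grow to a transient maximum (`X̄n ≈ 3.3` here, with
maximum lengths around 20 monomers) in the 30 min–2 h window and then
depolymerize to monomers by 18 h, while the cuboid fibrils grow into a
persistent `X̄n ≈ 3.7` plateau — the two coupled, oppositely fated
polymerizations the circuit is designed to produce. `autoplot(fib)` draws
the checkpoint length histograms (most-abundant = 100 normalization);
`plot_fluorescence(add_fluorescence(tc, crn))` draws the two reporter
channels.

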