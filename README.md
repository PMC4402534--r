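# chromfiber

Quantitative analysis of single-molecule force spectroscopy on chromatin
fibers.

Magnetic tweezers stretch a single nucleosome array between a glass surface
and a superparamagnetic bead, recording extension (nm) against force (pN).
The curve encodes, per nucleosome, how the fiber unfolds: a stiff folded
fiber at low force, a broad plateau near 3.5 pN where nucleosome–nucleosome
contacts break, a metastable "extended" intermediate, and finally discrete,
hysteretic ~25 nm steps above ~9 pN as the last turn of DNA unwraps from
each histone core. chromfiber implements the full statistical-mechanics
analysis of such traces for people doing single-molecule chromatin
biophysics: forward modelling, per-fiber Levenberg–Marquardt fitting,
step detection, conformational occupancies and a seeded trace simulator.

## The model

Each of `n_fiber` nucleosomes occupies one of four conformations along a
single pathway — fiber, single wrap, extended, unwrapped. Free DNA follows
the extensible worm-like chain

    z(f, L) = L [1 − ½√(k_BT/(f A)) + f/S],   A = 50 nm, S = 1200 pN,

a fiber-folded nucleosome a Hookean element `z = f/k + z0` (per
nucleosome), and each transition costs ΔG₁ or ΔG₂ − f·z_ext (in k_BT).
States — occupation vectors over conformations — are weighted by a
pairwise-binomial degeneracy D and summed in a partition function; the
mean tether extension is

    ⟨z_tot(f)⟩ = Σ z_tot D e^(−G_tot/k_BT) / Σ D e^(−G_tot/k_BT).

Fitting this to the reversible regime (0.5 pN up to the first rupture)
yields ΔG₁, ΔG₂, fiber stiffness `k` and the composition (`n_fiber`,
`n_unfolded` tetrasome-like particles); the high-force staircase is
analysed non-parametrically against the ladder of extended/unwrapped
states. The last transition is hysteretic, so its energy ΔG₃ is not
estimable and the unwrapped state is excluded from the equilibrium sum.

## Worked example

Simulate a full pulling experiment on a heterogeneous fiber (13 fiber
nucleosomes + 4 tetrasomes on a 15×197-bp-repeat substrate with 2 kb
handles), then run the complete analysis:

```r
library(chromfiber)

truth <- fiber_model(nrl = 197, n_fiber = 13, n_unfolded = 4, k = 0.28,
                     z0 = 1.2, z_ext = 4.6, dG1 = 20.6, dG2 = 5.5)
protocol <- pull_protocol(
  forces = c(force_ramp(0.5, 7, 60, 10), force_ramp(7.01, 27, 60, 10)),
  sample_rate = 10, noise_sigma = 5, seed = 42)
trace <- generate_full_experiment(truth, protocol)

trace <- align_offset(trace, total_contour = 2000 + 17 * 197)
steps <- find_steps(trace, window = 10)
steps <- steps[steps$force_pN >= 7, ]          # high-force ruptures
nrow(steps)                                     # 13 detected steps

init <- fiber_model(nrl = 197, n_fiber = nrow(steps), n_unfolded = 1,
                    k = 0.22, z0 = 1.2, z_ext = 4.6, dG1 = 19, dG2 = 4.4)
fit <- fit_equilibrium(trace, init,
                       free = c("n_fiber", "n_unfolded", "dG1", "dG2", "k",
                                "offset"))
fit
#> Equilibrium force-extension fit (725 points, 0.50-11.15 pN)
#>              estimate    std_error
#> n_fiber    12.9877409  0.086175252
#> n_unfolded  3.9277261  0.652336065
#> dG1        20.6480799  0.057600224
#> dG2         5.5836811  0.048539227
#> k           0.2841593  0.003417698
#> offset      2.1775435 22.735304541
#> Residual sd: 5.18 nm; converged: TRUE

stability_report(fit, n_positioning_elements = 15, n_steps = nrow(steps))
#> Composition: n_fiber = 13, n_unfolded = 4 (total 17)
#> High-force steps: 13; positioning elements: 15
#> Heterogeneous composition flagged.
```

The fit recovers the generating energies (ΔG₁ = 20.6, ΔG₂ = 5.5 k_BT) and
the composition to within a tenth of a nucleosome: `n_fiber` = 12.99 → 13
fiber-folded nucleosomes plus ~4 particles that only undergo the last
unwrapping step. The report flags that step count, fitted composition and
the 15 positioning elements disagree — the signature of a heterogeneously
reconstituted fiber. `occupancies()` then gives the force-resolved
probability of each conformation, and `plot(fit)` overlays the fitted
curve on the data.

A command-line interface wraps the same functions
(`exec/chromfiber simulate|fit|steps|occupancy --config run.yml`), driven
by a YAML config; every run logs its seed and config hash.

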