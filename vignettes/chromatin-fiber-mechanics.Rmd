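---
title: "Statistical mechanics of chromatin fiber force spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical mechanics of chromatin fiber force spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromfiber)
```

## The problem

A magnetic-tweezers pull on a reconstituted nucleosome array produces a
force-extension curve with three regimes: a stiff, nearly linear response of
the folded fiber below ~3 pN, a broad plateau where the fiber unfolds into a
string of partially unwrapped nucleosomes, and, above ~9 pN, a staircase of
discrete, hysteretic steps as the last turn of DNA rips off each histone
core. chromfiber turns such traces into per-nucleosome physical quantities:
unwrapping free energies, fiber stiffness, the extension of each
conformation, and the composition of the individual fiber.

## The four-conformation model

Each nucleosomal particle is in one of four conformations along a single
unfolding pathway:

1. **fiber** — folded into the fiber, interacting with its neighbours;
2. **single wrap** — one full turn (89 bp) left on the core, linker DNA free;
3. **extended** — a metastable intermediate adding a constant extension
   `z_ext` on top of the single wrap (possibly a tetrasome-like particle
   after H2A-H2B release);
4. **unwrapped** — all nucleosomal DNA released.

Bare DNA of contour length $L$ follows the extensible worm-like chain
(WLC),

$$z_\mathrm{DNA}(f, L) = L\left[1 - \tfrac12\sqrt{\frac{k_BT}{fA}} +
\frac{f}{S}\right],\qquad
G_\mathrm{DNA}(f, L) = -L\left[f - \sqrt{\frac{f\,k_BT}{A}} +
\frac{f^2}{2S}\right],$$

with persistence length $A = 50$ nm and stretch modulus $S = 1200$ pN. A
nucleosome folded in the fiber responds as a Hookean element per
nucleosome, $z_\mathrm{fiber} = f/k + z_0$, $G_\mathrm{fiber} = -f^2/2k -
f z_0$. The per-conformation extensions and free energies combine the WLC
of the liberated DNA with transition energies $\Delta G_1$ (first
transition) and $\Delta G_2 - f\,z_\mathrm{ext}$ (second transition). The
free energies are integrals of the extensions over force, so
$-\partial G/\partial f$ reproduces every extension function — a property
the test suite verifies by finite differences.

A state of an $n$-nucleosome array is the occupation vector over
conformations. States with equal occupation numbers but different spatial
arrangement are grouped through a degeneracy factor, the product of
binomial coefficients over conformation pairs,
$D = \prod_{i<j}\binom{n_i + n_j}{n_i}$. The equilibrium extension is the
Boltzmann average over all states,

$$\langle z_\mathrm{tot}(f)\rangle = \frac{\sum_\mathrm{states}
z_\mathrm{tot}\, D\, e^{-G_\mathrm{tot}/k_BT}}{\sum_\mathrm{states} D\,
e^{-G_\mathrm{tot}/k_BT}},$$

with the DNA handles' WLC added once per tether.

```{r occupancy}
m <- fiber_model(nrl = 197, n_fiber = 15, k = 0.28, z0 = 1.2,
                 z_ext = 4.6, dG1 = 21.2, dG2 = 4.3)
round(occupancies(c(0.5, 3.5, 7), m), 3)
```

### Degeneracy modes and an over-counting caveat

Four modes are available. `degenerate` is the pairwise-binomial product
above; `non_degenerate_first` removes the (fiber, single-wrap) pair factor,
modelling arrays whose first transition proceeds cooperatively from the
fiber ends (the behaviour of 167-bp-NRL, zig-zag-folded fibers);
`fully_non_degenerate` sets $D = 1$ everywhere; `multinomial` uses the
exact ordering count $n!/\prod_i n_i!$. The pairwise product exceeds the
ordering count whenever three or more conformations are occupied at once
(counts (1,1,1) give $2^3 = 8$ versus $3! = 6$). A visible consequence is
that the extended-state occupancy computed with the pairwise product can
dip non-monotonically by order $10^{-3}$ in the hand-off region, while the
multinomial mode is monotone. The pairwise form is the package default
because it is the form the reference fitted parameters are defined
against; the multinomial mode exists for sensitivity analysis.

### Which states are in equilibrium

The last transition is strongly hysteretic, so its free energy $\Delta G_3$
is not measurable at equilibrium and the unwrapped conformation is excluded
from the equilibrium state space; it only enters the high-force ladder
analysis. Particles counted by `n_unfolded` (interpreted as tetrasomes)
do not fold into a fiber or single wrap: below their rupture they
contribute a fixed extended-conformation extension, and because their
energy is the same in every state it cancels from the Boltzmann average.
They are likewise not mixed into the degeneracy product.

## Trace processing

* **Offset alignment**: the post-last-rupture tail must follow the WLC of
  the known total contour length; the mean residual against it is
  subtracted. With no detected step the whole trace is treated as bare DNA.
* **Drift correction**: the residual against a force-interpolated reference
  trace is regressed on time and the fitted linear term removed; validity
  is judged by pull/release overlap below the rupture regime.
* **Step detection**: a two-sample pooled t statistic between the 10
  samples before and after each boundary; local maxima above a threshold
  (default: two-sided $p < 10^{-4}$ on $2\cdot10-2$ degrees of freedom,
  i.e. $|t| \gtrsim 5.0$) are steps, with non-maximum suppression within
  one window. On pure noise fewer than 0.01% of samples are falsely
  flagged at this threshold.
* **State assignment**: above the first rupture each sample is matched to
  the nearest rung of the ladder of states built from extended and
  unwrapped nucleosomes; ties break toward fewer unwrapped nucleosomes
  (the earlier pathway state). The assigned model curve is smoothed with a
  10-point median filter; the per-sample labels are reported unfiltered.
* **Ladder calibration**: `calibrate_z_ext()` scans candidate extended-state
  offsets and keeps the one minimising the total nearest-rung residual —
  this is how `z_ext` = 4.6 nm is pinned before equilibrium fitting.

## Fitting

`fit_equilibrium()` minimises the sum of squared residuals between the
measured extension and the model mean (plus a co-fitted constant offset)
with the Levenberg–Marquardt algorithm (`minpack.lm::nls.lm`), using
points between `f_min = 0.5` pN (below which bead–surface interactions
corrupt the data) and the first rupture step. Because ruptures occur above
~9 pN while the smooth unfolding plateau near 3.5 pN is itself steep
enough to trigger the step finder, the automatic window search only
considers steps at forces of at least 7 pN.

Composition parameters are continuous: the discrete state sums at the
bracketing integer counts are interpolated bilinearly in (`n_fiber`,
`n_unfolded`) — exact in the `n_unfolded` direction, which is linear by
construction. Fits from well-behaved traces land within 0.1 of an integer,
which the `fiber_fit` object reports as a clean-composition indicator.

Defaults and bounds (chosen to keep the optimiser in physical territory;
the data, not the bounds, determine good fits):

| parameter | meaning | default | bounds |
|---|---|---|---|
| `dG1` | first-transition energy | 21.2 $k_BT$ | [0, 60] |
| `dG2` | second-transition energy | 4.3 $k_BT$ | [0, 30] |
| `k`   | fiber stiffness / nucleosome | 0.28 pN/nm | (0, 5] |
| `z0`  | fiber contour / nucleosome | 1.2 nm | [0, 5] |
| `z_ext` | extended-state extra extension | 4.6 nm | [0, 15] |
| `n_fiber`, `n_unfolded` | composition | — | [0, 2×elements] |

`z0` is not separately measurable in these experiments, so it is treated as a
free, bounded parameter; its default 1.2 nm is the nucleosome line density
seen in electron micrographs of condensed fibers. Thermal energy defaults
to $k_BT = 4.10$ pN·nm (≈297 K; the working temperature is not otherwise
pinned down, so it is configurable), and DNA rise to 0.34 nm/bp.
Optimisation uses five deterministically jittered starts (multiplicative
factors on the free parameters) with the best residual kept; standard
errors come from the Gauss–Newton approximation at the optimum,
$\mathrm{cov} = \hat\sigma^2 (J^\top J)^{-1}$. Residuals are unweighted:
the extension noise of a magnetic tweezer is only weakly force-dependent
in the fitted window.

`fit_mononucleosome()` uses the same machinery with a single particle
whose state space is (wrapped, single wrap, extended), the fully wrapped
conformation (147 bp on the core) being the energy reference. The
difference between the fiber and mononucleosome `dG1` measures the
stabilisation a nucleosome gains from being embedded in a folded fiber.

## The synthetic-data generator

The generator provides ground truth for every analysis step. It emulates:

* equilibrium segments — the model's mean extension along a force ramp
  plus i.i.d. Gaussian noise (default σ = 5 nm, the scatter of unfiltered
  60 Hz bead tracking) and optional linear drift; reversible by
  construction, like the experiment below ~6 pN;
* rupture staircases — each particle draws an independent rupture force,
  by default uniform on [9, 25] pN, matching the observed range of the
  last transition; a Bell–Evans escape law under a linear ramp is
  available as an alternative (`rupture = list(family = "bell", ...)`);
* full experiments — the two regimes spliced consistently, with an
  optional release branch on which ruptured nucleosomes stay unwrapped
  until the force drops below ~3 pN, reproducing the hysteresis of the
  last transition only.

Study conditions used throughout the tests and the acceptance script:
equilibrium ramps 0.5–7 pN over 60 s sampled at 10 Hz (600 points — the
fitted information lives in the curve shape, not the frame rate),
staircase ramps 7–25 pN over 60 s at the 60 Hz camera rate (step detection
needs the full rate), noise 5 nm (equilibrium) and 3 nm (staircase),
handles 2000 bp, mononucleosome substrate 3000 bp.

What the generator does **not** emulate: force-dependent bead
fluctuations (noise shrinks as the tether stiffens in reality), camera
blur and tracking artefacts, bead–surface interactions below 0.5 pN,
torsional constraints, and gradual nucleosome loss over repeated pulls.
Passing recovery tests therefore demonstrate that the estimator is
correct and well-conditioned under realistic noise magnitudes — not that
every instrumental systematic of a real tweezers trace is handled.

## Numerical choices

* Boltzmann sums subtract the per-force minimum free energy before
  exponentiation, so arbitrarily large $\Delta G$ values are safe.
* Energies are computed in pN·nm throughout; $k_BT$ units appear only at
  the reporting boundary.
* The t statistic guards the pooled variance with machine epsilon so that
  noiseless staircases (exactly zero within-window variance) are handled.
* The WLC is the high-force extensible form; it diverges as $f \to 0$, so
  forces ≤ 0 are rejected and fitting starts at 0.5 pN. No low-force
  interpolation formula is included — the analysis window never needs it.
* `enumerate_states` is exact composition enumeration; with the default
  three-conformation space a 30-nucleosome array has only
  $\binom{32}{2} = 496$ states, so no truncation is required.

## Known limitations

* $\Delta G_3$ is bookkeeping only; nothing is fitted above the first
  rupture beyond state assignment.
* Per-fiber fitting only — no hierarchical pooling across fibers.
* The Hookean fiber element is empirical; it encodes no structural model
  of the folded fiber beyond a linear response.
* Identifiability: `n_unfolded` and the constant offset are partially
  degenerate over a narrow force window, since the extended-conformation
  extension varies slowly with force; composition fits therefore benefit
  from data spanning the full 0.5–7 pN window.
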