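---
title: "Elastic kinetic traps in lipid domain coalescence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic kinetic traps in lipid domain coalescence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rafttrap)
```

## The scientific problem

Liquid-ordered domains (LODs) in model membranes are thicker and stiffer
than the surrounding liquid-disordered phase (LDD). The hydrophobic
thickness mismatch at the phase boundary forces the lipids near the rim to
tilt, splay and compress, storing elastic energy: the mechanical component
of the line tension. Because that energy grows with boundary length,
domains should fuse until one macroscopic domain remains — yet nanoscopic
domains persist. This package implements a continuum-elastic explanation:
when two registered domains approach, the lipids in the shrinking gap are
claimed by both rims at once and must leave the configuration that
minimized each isolated rim's energy. The resulting interaction energy
profile `E(D)` has a maximum at gap widths of a few nanometres — a *kinetic
trap* that slows coalescence without forbidding it thermodynamically. The
package computes the profile, extracts the barrier, converts it to a
per-collision merger probability, and ties it to observable merge/bounce
statistics of domains containing a photoswitchable lipid (PhoDAG-1) whose
trans (near-cylindrical) and cis (cone-shaped) conformers shift the phase
compositions and their spontaneous curvatures.

## The elastic model

The membrane is a mirror-symmetric bilayer with registered domains; the
midplane is flat by symmetry, one monolayer is solved and the energy
doubled. With translational symmetry along the boundary the problem is
one-dimensional in the coordinate `x` normal to the boundary. Per unit
boundary length, the monolayer energy is

$$
W=\int \mathrm dx\;\Big[\tfrac B2(\operatorname{div}\mathbf n+J_0)^2-\tfrac B2 J_0^2
+\tfrac{K_t}2 \mathbf t^2+\tfrac{K_s}2(\alpha-\alpha_0)^2
+\tfrac{\sigma_0}2(\nabla H)^2\Big],
$$

with director in-plane projection $n(x)$ (directors point from heads to
tails), neutral-surface height $H(x)$ above the midplane, tilt
$\mathbf t = \mathbf n-\mathbf N \approx n - H'$, area strain $\alpha$, and
equilibrium stretching $\alpha_0=\sigma_0/K_a$. Splay couples to the
spontaneous curvature $J_0$; the $-BJ_0^2/2$ offset makes the unperturbed
far field the energy zero.

**Incompressibility closure.** The functional needs a relation between the
thickness and the other fields; we use linearized volumetric
incompressibility. A lipid "prism" of neutral-surface area $a$ and
thickness $h$ whose directors splay by $\operatorname{div}\mathbf n$ has
volume $a\,(h + h^2\operatorname{div}\mathbf n/2)$; holding the volume at
$a_0h_0$ and linearizing gives

$$
H = h = h_0\Big(1-\alpha-\tfrac{h_0}{2}\operatorname{div}\mathbf n\Big)
\quad\Longleftrightarrow\quad
\alpha = 1-\frac H{h_0}-\frac{h_0}2 n'.
$$

(The sign of the splay term depends on the director orientation convention;
with tails-pointing directors — the convention implied by writing the splay
energy as $(\operatorname{div}\mathbf n + J_0)^2$ with negative $J_0$ for
cones — the derivation above applies. We verified the opposite choices
numerically: flipping the tilt sign makes the boundary energy negative,
and flipping the closure sign suppresses the trans-state barriers by two
orders of magnitude; both are rejected.)

**Stretching modulus of the functional.** The published form of the
functional carries the tilt modulus $K_t$ in the stretching term even
though the area-stretching modulus $K_a$ is defined separately. We treat
this as intentional: solving with $K_s=K_t$ reproduces the published
barrier heights (e.g. 0.027 vs. 0.03 $k_BT$/nm for the trans LOD pair),
while $K_s=K_a$ roughly doubles them. `phase_params()` therefore defaults
`K_stretch` to `Kt` and leaves it configurable; $\alpha_0$ always uses
$K_a$.

**Boundary conditions.** $n$ and $H$ are continuous at the phase
boundaries (a director jump was tested and produces qualitatively wrong,
monotonic profiles); at the window edges the fields take their far-field
values $n=0$, $H=h_0(1-\alpha_0)$ of the local phase. Phase parameters are
piecewise constant: domain phase outside the gap, background phase inside.

## Numerics

The fields are linear on each grid interval and the energy is the
midpoint-rule quadrature of the density, an exactly quadratic function
$\tfrac12 u^TKu+f^Tu+c$ of the interleaved nodal unknowns
$(n_1,H_1,n_2,H_2,\dots)$ — `assemble_quadratic_form()`. Its unique
minimizer under the Dirichlet far-field clamps solves the discrete
Euler–Lagrange system; `minimize_energy()` uses a sparse banded solve
(bandwidth 3), with a dense reference route (`dense = TRUE`) agreeing to
relative $10^{-6}$ in the tests. Defaults: grid spacing 0.025 nm (halving
changes energies by $\ll 1\%$; tests assert $<1\%$), half-window 15 nm
beyond the domain edges (more than ten tilt–splay decay lengths
$\sqrt{B/K_t}\approx 1.4$ nm; the window is validated at construction).
Degenerate parameter sets surface as classed errors, not silent results.

`energy_profile()` sweeps the gap (default 0.5 nm steps to 10 nm, 2 nm
steps to 30 nm) and adds a 0.1 nm refinement pass around the coarse
maximum. The zero reference is the energy at the largest swept distance,
which tests confirm equals twice `single_boundary_energy()` to
$10^{-3}\,k_BT$/nm; the approach to the plateau is an exponentially damped
oscillation with ~1.4 nm decay length, so 30 nm is deep in the
non-interacting regime.

**Per-domain barrier convention.** `minimize_energy()` returns the energy
of the whole system: two monolayers, two interacting boundaries. The
reported boundary energy of the study is that of *each* domain, i.e. half
the system excess (equivalently: the half-problem with mirror conditions at
the gap midpoint). `find_barrier()` therefore defaults to
`per_domain = TRUE`, halving the interior-maximum excess; `per_domain =
FALSE` gives the raw system value. Ties in the maximum resolve to the
smallest gap. A profile without an interior maximum above the plateau has
zero barrier.

With the default parameters (splay moduli 20/10 $k_BT$, tilt modulus 10
$k_BT$/nm² — not published for this system; we adopt the standard value
~40 mN/m of the tilt–splay framework, which is nearly
composition-independent — stretching modulus 30 $k_BT$/nm², tension 0.1
$k_BT$/nm² per monolayer, thicknesses 1.8/1.3 nm, tabulated phase
curvatures) the barriers per domain are 0.027 (trans LOD), 0.036 (trans
LDD), 0.088 (cis LOD) and 0.115 (cis LDD) $k_BT$/nm, with maxima at 5.6,
7.8, 2.8 and 4.2 nm. The published trans LOD value (0.03, maximum at
4–6 nm), the cis LOD value (0.06) and the cis LDD total barrier (1.26
$k_BT$; ours 0.92) are reproduced within their 1–2 significant figures and
the stated elastic-parameter uncertainty (~10–15%, amplified quadratically
in barrier heights). Two published statements are *not* reproduced and are
reported as model properties rather than forced: the trans LDD barrier
(published 0.02, i.e. *smaller* than the LOD pair's 0.03; we get 0.036) —
in every faithful reading we tried, the pair whose gap is the stiffer,
thicker LOD phase has the larger barrier, as the cis pair ordering (LDD
pair > LOD pair) also shows — and the cis LOD maximum position, which falls
at 2.8 nm rather than within 3–8 nm. The orderings that carry the paper's
conclusions (cis > trans for each phase pair; cis LDD largest) all hold.

## From barrier to merger probability

For circular domains only a short arc of the rim interacts at a time; the
Derjaguin approximation gives the effective boundary length
$l_R=2\sqrt{2l_cR_0}$ (`derjaguin_length()`), ~8 nm for $R_0=8$ nm and
~60 nm for micrometre-sized domains with decay length $l_c=1$ nm. Because
observed cis/trans probability ratios stay near unity across sizes, the
study fixes $l_R=8$ nm for all sizes; that is the default policy
(`l_R_policy = "fixed"`), with the scaling form available as
`"derjaguin"`. The total barrier is $E_i=l_RE_B$
(`interaction_barrier()`) and the per-collision merger probability is
$\ln p=-E_i/k_BT+\ln A$ (`merger_probability()`), with the dimensionless
attempt prefactor $A$ obtained only by fitting: `fit_ln_A()` takes the
least-squares $\ln A$ over conditions, i.e. the mean of
$\ln\hat p_j+E_{i,j}$, and reports per-condition
$k_BT(\ln A-\ln\hat p_j)$. On the four tabulated conditions this gives
$\ln A\approx-0.33$ ($A\approx0.72$).

**Uncertainty convention.** Merge/bounce tallies are Bernoulli trials;
`estimate_p()` reports $\hat p=m/(m+b)$ with a normal-approximation band.
The headline `p_err` uses $1.96\,\mathrm{SE}$ (the normal 95% band), which
reproduces all four published uncertainties (±14, ±22, ±10, ±8 points)
after rounding; a plain $2\,\mathrm{SE}$ band (also reported, as
`p_err_2se`) gives ±23 rather than ±22 for the cis LOD condition.
Percentages are rounded half-up for display only; fractions are kept in
all outputs.

## Compositions and spontaneous curvatures

The overall 2:1:2:1 DPhPC:DPPC:Chol:PhoDAG mixture is folded onto the
ternary DPhPC/DPPC/Chol phase diagram by pooling the photolipid with its
packing analogue (DPPC in trans, DPhPC in cis; `effective_ternary()`).
Tie-line endpoints are *inputs*: the package ships
`tie_line_compositions()`, a synthetic fixture back-computed from the
published quaternary phase compositions rather than digitized from any
diagram. `quaternary_phase_composition()` splits the pooled fraction back
in the overall mixture's ratio (equal distribution coefficients), and
`mean_spontaneous_curvature()` takes the mole-fraction-weighted average of
the component curvatures (cholesterol −0.37, DPPC +0.07, DPhPC −0.2,
photolipid −0.2 trans / −1 cis, all nm⁻¹); non-additive curvature
energetics are deliberately out of scope. The cis-state phase values round
to the published −0.2 (LOD) and −0.4 (LDD) nm⁻¹. The published
*trans*-state values (−0.26, −0.25) are **not** the weighted averages of
the published trans compositions (which give −0.19 and −0.225); we flag
the discrepancy, use the published trans values as the solver's default
curvatures (they are what the published barriers were computed from), and
let the composition module report the averages it actually computes.

## Curvature frustration

`flat_monolayer_energy_density()` and `splitting_energy_delta()` implement
the argument against spontaneous-curvature control of domain size: the
frustration energy of flat registered domains,
$E_M=A_D\kappa_bJ_0^2/4$, is extensive in total area, so splitting a
domain changes it by exactly zero — for any modulus, curvature and
partition, as the property tests verify. The bending modulus and Gaussian
rigidity are not published for this system; defaults are
$\kappa_b = 2B_o$ and $\kappa_G = 0$, immaterial to the invariance result
(absolute $F_M$ values are consequently not benchmarkable).

## Synthetic data

No imaging data are deposited, so the statistical layer is exercised by
generators that reproduce the *assumed statistical structure* of the
observations, not the microscopy itself:

* `simulate_collisions()` — i.i.d. Bernoulli merge/bounce streams at a
  fixed per-collision probability, seeded and reproducible.
* `simulate_population()` — well-mixed (mass-action) pairwise coalescence:
  exponential waiting times at rate `collision_rate` per pair, each
  collision merging with `p_true`. The per-pair collision rate has no
  published anchor and is a free parameter; 0.01–0.05 s⁻¹ per pair gives
  population decays over tens of seconds, the scale of the tracked
  recordings.

Passing tests therefore validate the estimators (coverage of the
two-standard-error interval is ≈95–96% at the study's sample sizes, the
exact binomial value) — they say nothing about spatial diffusion,
size-dependent collision rates, or tracking losses in real microscopy.
Every simulated artifact records its parameters and seed
(`write_series()`).

## Reproducibility and problem sizes

`run_pipeline()` executes all stages from a single configuration
(`default_run_config()`, overridable from JSON/YAML via
`read_run_config()`) and echoes the fully resolved configuration in its
report, so every output is regenerable from the output alone; reruns are
byte-identical. The test suite uses 0.1–0.2 nm grids, for which barrier
heights are converged to well under 1%; the acceptance script uses the
production 0.025 nm grid, about 150 boundary-value solves in a few
seconds.

## Known limitations

* One-dimensional straight boundaries: no curved-rim or two-dimensional
  barrier landscapes.
* Mirror-symmetric registered domains only; no inter-leaflet boundary
  shift, anti-registration, or midplane deformation.
* Quadratic (small-deformation) elasticity; no thermal undulation forces.
* The chemical contribution to line tension is not modeled; only the
  elastic part enters the barrier.
* The trans LDD barrier and the cis LOD maximum position deviate from the
  published values as described above.
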