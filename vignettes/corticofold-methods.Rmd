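---
title: "corticofold: model, numerics, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{corticofold: model, numerics, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(corticofold)
```

This vignette is the package's own account of its science and numerics: the
coupled model, every tunable that matters, what the default configuration
emulates, the decisions taken where the design was genuinely open, and the
limits of what a green test establishes. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The coupled model

### 1.1 Mechanics with finite growth

The tissue occupies a quarter annulus in its reference state. The
deformation map carries material points to the grown, deformed state; its
gradient is split multiplicatively, `F = Fe · Fg`, into an irreversible,
stress-free growth part and an elastic part that alone generates stress.
Growth is transversely isotropic about the referential radial direction `N`:

* circumferential multiplier `θ⊥ = (1 + κ⊥ c)^α`
* radial multiplier `θ∥ = (1 + κ∥ c)^α`

driven by the *total* cell density `c` (all four species; the spec's open
question about which density drives Eq.-level growth is resolved to the
total, which is also the only reading consistent with subcortical expansion
before neurons exist). In the subcortex `κ⊥ = κ∥ = κ_s`, so growth is
isotropic there; in the cortex the pair splits as `κ_s β_κ` and `κ_s/β_κ`,
the differential growth that puts the cortical plate into circumferential
compression.

The elastic response is compressible neo-Hookean under plane strain (the
out-of-plane stretch is fixed at 1, so the trace term gains `+1` and the
Jacobian is the in-plane determinant). Stress follows from
`σ = Je⁻¹ [(λ ln Je − μ) I + μ be]`. The cortical shear modulus either
follows the local density (`varying` mode, a linear ramp between two density
thresholds, clamped to `[μ_s, μ∞]`) or sits at `μ∞` (`constant` mode); both
are blended radially into the subcortical `μ_s` with a regularized Heaviside
at the cortical boundary.

### 1.2 Cell-density fields

Each species obeys a mass balance in the deformed configuration whose flux
combines density-gated radial advection and zone-gated isotropic diffusion;
lineage couplings enter as explicit source terms `f• = Σ G[•, parent] c_parent`
evaluated at the previous converged step, with the 4 × 4 ratio matrix `G`
switching across five gestational-week phases. The advection gate
`H(c• − c₀; γ_c)` reads the *type-specific* density (adaptive transport: a
cell type migrates in bulk only once locally abundant); all radial gates
read the *reference* radius of the material point, and the OSVZ gate follows
the mitotic-somal-translocation boundary
`r_osvz(t) = min(r_osvz, r_isvz + m_mst ⟨t − t_P2⟩)`.

## 2. Parameters

All defaults are the reference parameter set of the source model
(`fold_config()` documents each key):

| parameter | default | units | role |
|---|---|---|---|
| `R, r` | 2, 0.4 | mm | outer/ventricular radii |
| `r_vz, r_isvz, r_osvz, r_cp` | 0.5, 0.8, 1.2, 1.9 | mm | zone boundaries |
| `mu_infinity` | 2.07 | kPa | adult cortical shear modulus |
| `poisson_nu` | 0.38 | – | compressibility |
| `beta_mu` | 3 | – | cortex/subcortex stiffness ratio (`μ_s = μ∞/β_μ`) |
| `c_mu_min, c_mu_max` | 200, 700 | mm⁻² | stiffening thresholds |
| `kappa_s` | 4.07e-4 | mm² | growth factor |
| `alpha` | 1.65 | – | growth exponent |
| `beta_kappa` | 1.5 | – | circumferential/radial growth ratio |
| `v_N, v_ORG, v_IP` | 5, 10, 0.025 | mm/d | migration / translocation speeds |
| `d_c, d_N` | 0.1, 0.11 | mm²/d | diffusivities |
| `c0_threshold, gamma_c` | 500, 0.008 | mm⁻², mm² | advection gate |
| `gamma_r, gamma_r_cp` | 20, 50 | 1/mm | zone-blend exponents (calibrated pair) |
| `beta_supg` | 0.1 | – | streamline stabilization constant |
| `m_mst` | 0.02 | mm/d | OSVZ boundary speed |
| `dt` | 0.25 | d | time step (timeline: `t_GW = 0.3 t + 4`) |
| `c_init` | 50 | mm⁻² | initial RG density in the VZ at GW 5 |

The initial condition (the source model is silent): at GW 5 the radial-glia
field is uniform at `c_init` inside the VZ and every other field is zero —
the neuroepithelial-to-RG transformation predates the modelled window.

## 3. The lineage ledger: a reconstructed calibration input

The full division-ratio table of the source model lives in supplementary
material that is not reproduced in its main text; only one worked example
(phase P3: each RG division yields an RG and an ORG, each IP division
ultimately an IP and two neurons) and the narrative of the five phases are
available. `source_terms()` implements the literal ratio sum and reproduces
that worked example exactly. The *default* ledger, however, had to be
reconstructed, and two things constrain it hard:

1. Taken as net per-day rates, "G = 1"-style entries make densities grow
   like `e^t` for tens of days (a factor ~e⁴⁰), which contradicts every
   reported milestone and destroys the mechanics. The published ratios are
   gross products per division; the net bookkeeping (parent consumption)
   is in the unavailable supplement.
2. The ledger API keeps the non-negativity invariant `G ≥ 0`, so parent
   consumption cannot be expressed: a species can stop being produced but
   never actively decline except by dilution.

`default_lineage_ledger()` therefore stores *net effective rates per day*
(products beyond parent replacement × divisions per day, order 0.03–0.75,
consistent with cell cycles of one to several days), calibrated — as the
source model itself states its cell-density parameters were — against the
reported chronology: RG density peaking near GW 9, ORG peaking late in its
production window, the neuron surge peaking at GW 30, and folding onset
near GW 27 for stiffness ratio 3 / growth ratio 1. The calibration was done
once, on the default mesh, and frozen. Mechanistic notes:

* The interior RG peak (GW ~9.7 rather than a phase boundary) emerges from
  competition between residual symmetric division (`G[RG,RG] = 0.1` in P2)
  and dilution by ventricular-zone expansion, which accelerates mid-P2 as
  the exponentially amplifying IP pool (`G[IP,IP] = 0.32`) inflates the
  local volume. This is the model's own mechanism, not a hand-placed peak.
* Neuron output per IP is constant through P2–P4 (0.02/d) and jumps to
  0.05/d in P5 when IPs commit exclusively to neurogenesis; this single
  switch produces both the late neuron surge and the folding onset.
* Because `G ≥ 0` forbids sinks, the IP field plateaus after GW 24 instead
  of declining, and the ORG peak locks close to a phase boundary (GW ~18)
  instead of GW 20 — both documented expected failures in the acceptance
  tests, not bugs.

The ledger ships as an editable JSON file (`write_lineage_ledger()`), so
alternative reconstructions — including gross ratios with an external
consumption convention — can be swapped in without touching code.

## 4. Numerics

* **Discretization.** Bilinear quadrilaterals, 2 × 2 Gauss quadrature,
  total-Lagrangian assembly on the reference mesh (spatial gradients via
  `F⁻ᵀ`), backward-Euler in time. The radial node layout is zone-aware:
  uniform inside each germinal zone, the intermediate zone graded
  geometrically toward the thin cortical plate so that both the stiff layer
  that buckles (≥ 3 layers across 0.1 mm) and the advective boundary layer
  beneath it are resolved. Default 24 × 48 elements, `dt = 0.25` d.
* **Conservative time term.** The discrete density balance uses the exact
  identity `(Jₙcₙ − Jₙ₋₁cₙ₋₁)/Δt`, which makes global material mass exactly
  conservative under zero-flux boundaries (the mass-drift acceptance check
  measures round-off, not scheme error). Mass lumping is available but off
  by default.
* **Explicit coupling, block-triangular tangent.** Growth multipliers, the
  stiffening law and the advection gates are evaluated at the previous
  converged step. The mechanics residual then does not depend on
  current-step densities and each transport equation is *linear* in its own
  field given the deformation: one Newton solve for the displacements
  followed by four sparse linear solves is algebraically the monolithic
  block solve, with the density–density blocks identically zero and the
  density–displacement block never needed for convergence.
* **Growth ratchet.** `θ⊥, θ∥` are per-quadrature-point monotone in time:
  growth is irreversible, so a later density decline must not shrink
  already-grown tissue. Negative density excursions (advection undershoot)
  are clipped to zero inside the growth and stiffness laws only, never in
  the transported fields.
* **SUPG.** Stabilization is a consistent streamline-upwind Petrov–Galerkin
  weighting with the classical parameter `τ = h ξ(Pe)/(2|v|)`,
  `ξ = coth Pe − 1/Pe`, plus the small isotropic artificial diffusivity
  `ν = β h |v|/2` with the stated constant `β = 0.1`. A purely isotropic
  "artificial diffusivity" reading of the stabilization (the simplest
  interpretation of the stated constant) was tried first and rejected: at
  the ORG translocation speed (10 mm/d) the cell Péclet number is far above
  1 on any tractable mesh, and the diffusivity needed to suppress the
  resulting oscillations transports real mass far past the OSVZ boundary.
  The Petrov–Galerkin form stabilizes without that artifact, and because the
  augmented test functions still sum to one it preserves exact global mass
  conservation.
* **Newton robustness.** Backtracking line search; if the full growth
  increment of a step fails to converge (typical exactly at the buckling
  bifurcation), the increment is re-applied as a staged ramp (4, then 12
  sub-increments) with warm starts — the converged state is unchanged. Time
  steps additionally bisect on failure. If the outer contour self-intersects
  (deep post-folding contact, which the model does not handle), the run
  stops with a partial-output failure report.
* **Symmetry breaking.** The source model does not say how buckling symmetry
  is broken. A seeded radial white-noise imperfection (default amplitude
  0.1% of `R`) perturbs reference nodes beyond the OSVZ boundary; straight
  edges and the inner arc stay exact. Fold *positions* depend on the seed;
  onset week and wavelength statistics do not (the acceptance script is
  stable across seeds).
* **lGI closure.** The simulated domain is an open sector, so the
  gyrification contour closes the deformed outer arc through the sector
  *centre* (a pie slice). Closing through the inner arc instead — a reading
  the interface description also admits — makes even a perfect sector score
  lGI ≈ 1.009 because the inner arc is a concave notch, destroying the
  sharp `lGI = 1` pre-buckling baseline that the onset detector
  (`lGI > 1 + 10⁻³`) relies on. Fold crests only ever form on the outer
  arc, so the closure choice adds convex segments only.
* **Fold wavelength** is reported in the material frame (reference arc
  length per detected crest): the deformed arc length itself grows with the
  growth ratio, which would mask the decreasing angular spacing of folds
  that the sweep ordering checks assert.

## 5. What the synthetic world does and does not establish

Everything is generated in code: the quarter-annulus geometry, the initial
condition, the imperfection, and the lineage ledger. The stated world
reproduces, at desk scale (coarse mesh, the published work states neither
mesh nor step size): the RG/neuron peak weeks, folding onset for
stiffness ratio 3 / growth ratio 1 within ~1 week of GW 27, a convex
(lGI = 1) surface before onset, purely neuronal cortical plate and
RG-dominated VZ at GW 18, and the sweep orderings (lGI non-decreasing, fold
wavelength decreasing with the growth ratio).

A green suite does **not** establish: quantitative density magnitudes (no
absolute scales are published), image-derived geometry, 3D folding, or
post-onset fold depths near self-contact. Three structural claims of the
source model are *knowingly unmet* and asserted as expected failures:

1. ORG temporal peak at GW 20 ± 1 (locks to the GW-18 phase boundary
   without negative division ratios);
2. the ISVZ dip of the GW-18 radial profile (the `γ_r = 20` Heaviside tails
   let RG spill ~0.15 mm into the ISVZ, flattening the dip);
3. ORG dominance of the OSVZ at GW 18 (the translocation front advances
   `~(1/γ_r) ln(γ_r v gate t)` ≈ 0.2–0.4 mm past the OSVZ cap — an
   intrinsic property of the exponential speed tail at `v_ORG = 10` mm/d —
   and the non-declining IP baseline outweighs what remains).

These are properties of the reconstructed, sign-constrained ledger and of
the stated blending exponents, not of the discretization; refining the mesh
does not change them.

## 6. Reproducibility

Runs are deterministic given the configuration and imperfection seed, and
the run summary embeds both (plus a configuration fingerprint).
`scripts/acceptance.R --seed N --out f.json` recomputes all acceptance
targets from scratch with two coarse-mesh runs.
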