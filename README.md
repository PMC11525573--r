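# corticofold

Cortical folding in the developing brain, simulated from the bottom up: a
two-dimensional multi-field finite-element model in which the proliferation,
migration and lineage progression of four neural cell types drive tissue
growth, and growth in turn drives the mechanical buckling of the cortical
plate. The package is aimed at computational biomechanics and developmental
neuroscience researchers who want a small, fully scripted model of
gyrification with cell-type resolution: enough to ask how changing a division
phase, a migration speed, or the cortex/subcortex stiffness contrast changes
when and how folds appear.

## The model

The reference domain is a quarter annulus (inner radius *r* = 0.4 mm, outer
radius *R* = 2 mm), a stylized sector of a coronal brain section subdivided
into five concentric germinal zones: ventricular zone (VZ), inner and outer
subventricular zones (ISVZ, OSVZ), intermediate zone (IZ), and cortical
plate (CP).

**Mechanics.** Finite-growth hyperelasticity under plane strain with the
multiplicative split `F = Fe · Fg`. The growth tensor is transversely
isotropic about the radial direction `N`:

    Fg = θ⊥ (I − N⊗N) + θ∥ N⊗N,   θ = (1 + κ c)^α,

so the local cell density `c` inflates the tissue, with a circumferential /
radial growth ratio `β_κ = κ⊥/κ_s = κ_s/κ∥ ≥ 1` in the cortex. The elastic
response is neo-Hookean,

    ψ(Fe) = λ/2 ln²(Je) + μ/2 (Fe:Fe − 3 − 2 ln Je),

with a cell-density-dependent cortical shear modulus
`μ_c(c) = min(μ∞, μ_s + m⟨c − c_min⟩)` blended radially into the subcortical
`μ_s = μ∞/β_μ` (a "constant stiffness" mode pins the cortex at `μ∞`
instead). Equilibrium `div σ = 0` is solved by Newton's method on a
bilinear-quadrilateral mesh.

**Cell densities.** Four advection–diffusion–reaction fields — radial glial
cells (RG), intermediate progenitors (IP), outer radial glial cells (ORG),
neurons (N) — obey

    (J̇/J) c• + ċ• = div q• + f•,   q• = −c• v̂• + (d• + ν) ∇c•,

with density-gated radial transport `v̂ = H(c• − c₀; γ_c) v(r) n/|n|`
(`n = F·N`), zone-gated diffusivities, SUPG streamline stabilization, and
lineage sources `f• = Σ G(•|parent, phase) c_parent` organised in five
gestational-week phases (symmetric RG amplification → RG→IP → RG→ORG →
ORG→IP → IP→neurons). The timeline is `t_GW = 0.3 t + 4` (t in days); the
OSVZ boundary advances by mitotic somal translocation,
`r_osvz(t) = min(r_osvz, r_isvz + m_mst⟨t − t_P2⟩)`.

**Analysis.** Outer-contour extraction, the local gyrification index
(lGI = contour length / convex-hull perimeter; exactly 1 until buckling),
fold wavelength, normalized radial density profiles, per-zone cellular
deconvolution, temporal peak detection, and a stiffness-ratio ×
growth-ratio sweep driver.

## Worked example

```r
library(corticofold)

# reference parameter set, gestational weeks 5 -> 30 (about a minute)
sim <- run_simulation(fold_config(solver = list(t_end = time_from_gw(30))))
print(sim)
#> <fold_sim>  335 recorded steps, final GW 30.00
#>   peak GW (RG/IP/ORG/N): 9.65 / 23.98 / 18.05 / 29.98
#>   folding onset GW: 20.98  final lGI: 1.3664
fold_wavelength(sim$mesh, sim$final$u)
#> [1] 0.449
```

Reading: radial-glia density peaks at GW 9.7 then dilutes away as the
ventricular zone expands; intermediate progenitors peak when their ORG
source switches off at GW 24; neurons surge to the end of the window; the
outer surface stays convex (lGI = 1) until undulations appear, and the lGI
then grows as sulci deepen. The fold wavelength is reported in the material
frame (reference arc length per crest).

Cellular deconvolution of the GW-18 state (fractions of the zone total):

```r
sn <- sim$snapshots$gw18
pr <- radial_profile(sim$mesh, sn$u, sn$c, gw = sn$gw)
deconvolution_table(pr, sim$mesh$domain)[, c("zone", "frac_RG", "frac_IP",
                                             "frac_ORG", "frac_N")]
#>   zone frac_RG frac_IP frac_ORG frac_N
#> 1   VZ   0.520   0.422    0.044  0.014
#> 2 ISVZ   0.452   0.436    0.074  0.038
#> 3 OSVZ   0.053   0.731    0.118  0.098
#> 4   IZ   0.000   0.201    0.694  0.105
#> 5   CP   0.000   0.000    0.000  1.000
```

Radial glia dominate the VZ and the cortical plate is purely neuronal; note
that the fast ORG translocation front overshoots the nominal OSVZ cap into
the inner IZ — a documented consequence of the soft zone blending (see the
vignette).

## Command line

```sh
Rscript -e 'corticofold::fold_cli()' simulate --seed 1 --out out/ \
    --stiffness-mode varying --beta-mu 3 --beta-kappa 1 --t-end-gw 30
Rscript -e 'corticofold::fold_cli()' sweep --out sweep/
Rscript -e 'corticofold::fold_cli()' fixtures --out fixtures/
```

`simulate` writes a legacy-VTK field file, a CSV time series and a JSON
summary; `sweep` runs the stiffness/growth-ratio grid (use `--paper-grid`
to enforce the reference 5 × 5 layout); `fixtures` emits an editable JSON
configuration and lineage-ledger file.

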