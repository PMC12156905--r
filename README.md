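# hbondnet

Hydrogen-bond speciation, network statistics and transport properties from
molecular-dynamics trajectories of n-octanol-like ether alcohols.

Liquids whose molecules carry one hydroxyl group and at most one ether
oxygen can hydrogen-bond in exactly three ways: intermolecular
hydroxyl-hydroxyl (OH-OH), intermolecular hydroxyl-ether (OH-OE), and
intramolecular hydroxyl-ether. The balance between these three channels —
which shifts with the number of carbons *n* separating the two oxygens —
controls packing, viscosity and self-diffusion. `hbondnet` implements the
complete analysis chain needed to quantify that balance from saved
coordinate trajectories, for researchers doing structure-property work on
associating liquids:

* **Detection and speciation.** A bond is a (donor O, donor H, acceptor O)
  triple with O···O distance ≤ 0.30 nm and an angular deviation ≤ 30°
  (acceptor–donor–hydrogen angle at the donor by default; the
  D–H···A ≥ 150° convention is selectable), evaluated under the minimum
  image convention. Hydroxyl oxygens donate and accept; ether oxygens only
  accept. Motif finders report double-hydrogen-bonded dimers (two
  molecules joined by reciprocal OH→OE bonds) and O₁→O₂→O₃ triplets.
* **Networks.** Each frame's bonds form a multigraph over molecules
  (intramolecular bonds are self-loops). Networks are components with at
  least one bond; the summary reports networks per frame, bonds per network
  with quartiles (linear interpolation), the maximum, dimer-containing
  networks and cyclic networks (rings over ≥ 3 molecules — a reciprocal
  dimer's double edge is not a ring).
* **Persistence.** Within consecutive 500-frame (5000 ps) windows each
  directed donor→acceptor pair accumulates bonded time regardless of
  continuity. The complementary cumulative distribution
  P(t) = 1 − Σᵢ≤ₜ Count(i)/TotalCount is fitted with
  P_fit(t) = C·e^(−γt); γ (ps⁻¹) measures how quickly bonds of each class
  decohere.
* **Structure.** Radial distribution functions g(r) for OH-OH and OH-OE
  pairs under periodic boundaries; the intramolecular OH-OE component is
  obtained by subtracting the intermolecular-only RDF from the all-pair RDF
  on a shared normalisation, making the subtraction exact at histogram
  level. Intramolecular OH-OE and OH-terminal-carbon distances and radii
  of gyration summarise conformation.
* **Transport.** Self-diffusion from MSD(t) = 6 D(L) t + c with an
  FFT-based all-origin MSD; the cubic-box finite-size correction
  D∞ = D(L) + k_B T ξ/(6πηL), ξ = 2.837298; Green–Kubo shear viscosity
  η = V/(k_B T)·∫⟨P_αβ(0)P_αβ(t)⟩dt from off-diagonal pressure components
  with block-averaged plateau fits; Stokes–Einstein products D·η/T and
  hydrodynamic radii; two-point Arrhenius activation energies.
* **Synthetic ground truth.** Generators produce planted bond motifs
  (monomers, bonded pairs, triplets, dimers, chains, rings, intramolecular
  conformers), Brownian tracers with known D, ideal-gas frames,
  exponential bond lifetimes with known γ, and Ornstein–Uhlenbeck stress
  series with a closed-form Green–Kubo integral — so every stage is
  verified against exact expectations without running MD.

Supported inputs: GRO coordinate files (fixed-column, nm), multi-frame XYZ
(box supplied via config), and whitespace-columnar time series with `#`/`@`
comment lines (xvg dialect). Orthorhombic boxes only.

## Worked example

Plant a scene with known content — seven double dimers, three 3-chains and
one 5-ring — then detect, speciate and summarise:

```r
library(hbondnet)

scene <- make_planted_scene(planted_scene_spec(
  seed = 42, double_dimer = 7, chain = c(3, 3, 3), ring = 5))
bonds <- detect_hbonds(scene$frame, scene$topology)
table(bonds$class)
#> inter_OH_OE inter_OH_OH
#>          14          11
```

The 14 OH-OE bonds are the seven reciprocal dimer pairs; the 11 OH-OH bonds
are the three 2-bond chains plus the 5-bond ring. The network summary
recovers the planted composition exactly:

```r
stats <- frame_network_stats(build_graph(bonds, scene$topology))
summarize_networks(list(stats))
#> hydrogen-bond networks over 1 frame(s)
#>   networks/frame: 11.00 +/- 0.00
#>   bonds/network (pooled): 2.27 +/- 0.90  [Q1 2, median 2, Q3 2, max 5]
#>   dimer-containing networks/frame: 7.000 (motifs 7.000)
#>   cyclic networks/frame: 1.000
```

Persistence analysis on 2000 synthetic bond lifetimes drawn at
γ = 2×10⁻³ ps⁻¹ recovers the decay constant from the fitted CCDF:

```r
lt <- make_lifetime_sample(2e-3, n_pairs = 2000, window_ps = 5000,
                           dt = 10, seed = 11)
fit_persistence(bond_ccdf(lt$time_bonded, dt = 10))
#> P(t) ~ C exp(-gamma t): C = 1.0158, gamma = 0.00204083 1/ps (rms 0.0032, 209 points)
```

A shell entry point wrapping the same pipeline lives at
`inst/cli/hbondnet.R` (installed under `system.file("cli", "hbondnet.R",
package = "hbondnet")`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/hbondnet.R", package="hbondnet"))')" \
    networks --config run.cfg --out results/
```

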