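---
title: "Methods: hydrogen-bond speciation, networks, persistence and transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen-bond speciation, networks, persistence and transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbondnet)
```

`hbondnet` analyses saved coordinate trajectories of liquids whose
molecules carry exactly one hydroxyl group and at most one ether oxygen.
This vignette records the models implemented, the parameters that matter,
the numerical choices made where more than one defensible option existed,
and what the synthetic generators do and do not establish about real data.

## The geometric bond model

A hydrogen bond is a (donor oxygen, donor hydrogen, acceptor oxygen)
triple passing two geometric tests under the minimum image convention:

* **distance** — the heavy-atom O···O separation is at most
  `max_da_distance` (default 0.30 nm). The heavy-atom convention, rather
  than H···O, is deliberate: it is insensitive to the constrained O–H bond
  length and matches common trajectory-analysis defaults.
* **angle** — by default (`ADH_at_donor`) the acceptor–donor–hydrogen
  angle measured *at the donor oxygen* is at most `max_angle_deviation`
  (default 30°). The alternative `DHA_deviation` convention instead
  requires the donor–hydrogen···acceptor angle at the hydrogen to be
  within 30° of linear (D–H···A ≥ 150°). For a rigid ~0.1 nm O–H bond and
  a 0.28 nm O···O separation the two conventions select nearly the same
  geometries; both are available so users can match either habit, and the
  detector is verified against an exhaustive all-triples scan under both.

Hydroxyl oxygens donate through their molecule's hydroxyl hydrogen and
also accept; ether oxygens only accept (they carry no hydrogen). No
exclusivity rule is imposed: a hydrogen satisfying the criteria for two
acceptors yields two bonds, because the geometric definition imposes none.
Intramolecular hydroxyl→ether pairs are geometry-tested like any other
pair — their absence for short oxygen separations must emerge from the
geometry, not from a rule. Speciation is then mechanical: same molecule →
`intra_OH_OE`; different molecules → `inter_OH_OE` or `inter_OH_OH` by the
acceptor's role.

Motifs build on the bond table of a single frame. A double-hydrogen-bonded
dimer is an unordered pair of molecules with reciprocal OH→OE bonds (a
closed two-molecule ring). A triplet O₁→O₂→O₃ is a middle oxygen that
accepts and donates in the same frame, with the O₁–O₃ separation measured
by minimum imaging. Dimer coexistence is required *within one saved
frame*; a tolerance window across frames would introduce a timescale the
geometric definition does not have.

## Networks

Every bond, regardless of class, is one edge of a multigraph whose
vertices are molecules; intramolecular bonds are self-loops. A *network*
is a connected component containing at least one bond — a single bond is
the smallest network, and unbonded molecules are not networks. Per frame
the package counts networks, bonds per network (self-loops count one),
dimer-containing networks, and *cyclic* networks. Cyclicity is decided on
the simplified skeleton (parallel edges collapsed, self-loops removed): a
connected component is cyclic iff it has at least as many
distinct-molecule edges as molecules, i.e. contains a ring over three or
more molecules. This deliberately excludes the reciprocal dimer's double
edge: a liquid dominated by dimers should report many dimers and zero
rings, and conflating the two would make the ring statistic redundant.

Across frames, bonds-per-network values are pooled before quartiles are
taken (quartiles of a per-frame-then-averaged quantity would not be
quartiles of anything observable); quartiles use linear interpolation
(type 7), which on integer-dominated pools returns the integers one
expects. Network counts are averaged per frame with their SD.

## Bond persistence

Saved frames undersample the making and breaking of bonds, so no attempt
is made to measure continuous lifetimes. Instead the trajectory is cut
into consecutive non-overlapping windows of `window_frames` frames
(default 500, i.e. 5000 ps at the default 10 ps spacing) and each directed
(donor O, acceptor O) pair observed in a window accumulates
`time_bonded = frames_bonded × dt`, regardless of continuity. Direction
matters: A→B and B→A track different bonds. Windows are pooled per bond
class; pooling across windows is a choice — one long window per
trajectory would be equally defensible but wastes frames whenever the
trajectory is longer than one window — and is recorded in the output
metadata.

The pooled bonded times form a histogram with bin width `dt`, converted to
the complementary cumulative distribution
P(t) = 1 − Σ_{i≤t} Count(i)/TotalCount, which is non-increasing and
reaches exactly zero at the largest observed time. P(t) is fitted with
C·e^(−γt) by nonlinear least squares *on the linear scale* (log-linear
fitting would overweight the noisy tail where P → 0), over bins with
P > 0 and at least one observation. C is a free coefficient, not pinned to
one: the first bin already absorbs all pairs shorter than one frame.
Starting values are C₀ = max P and γ₀ = 1/⟨time bonded⟩; convergence
tolerance is 10⁻¹⁰ on the objective; points are unweighted. A fit driven
to γ ≤ 0 (non-decaying input) is an error, not a result.

## Structure observables

g(r) is the frame-averaged histogram of minimum-image pair distances
between two role selections, normalised by the ideal-gas shell count
`n_pairs · 4πr²Δr/V`. Ordered pairs are counted; identical-atom pairs
never are. Defaults: bin width 0.002 nm — fine enough to resolve the
~0.28 nm bonding peaks these liquids show — and r_max = 0.45·L (never more
than L/2, where the minimum image convention breaks down).

The intramolecular OH-OE component is computed by subtraction: the
all-pair RDF minus the intermolecular-only RDF, both accumulated on the
same grid and normalised by the same total-pair denominator so that the
subtraction is exact bin by bin (normalising each variant by its own pair
count would leave a residual). The subtraction variant can therefore carry
tiny negative values only at floating-point level.

Intramolecular distances (hydroxyl O to ether O, hydroxyl O to terminal
carbon) are averaged over molecules, then frames. The radius of gyration
is computed over heavy atoms, mass-unweighted, after making each molecule
whole across the periodic boundary; role-tagged topologies carry no
masses, and for the near-homogeneous backbones of these molecules the
mass-weighted and unweighted radii differ by far less than the
conformational spread.

## Transport

**Self-diffusion.** MSD(t) is averaged over molecules and all time origins
with an FFT identity (cost O(N·F log F)); lags above 1000 are decimated
onto a logarithmic grid. The diffusive window defaults to 10–50% of the
available lags: below that, ballistic/caging transients; above, too few
origins per lag. The window is user-overridable and the fit reports a
log-log slope diagnostic (≈ 1 in a truly diffusive regime). The slope of
the ordinary least-squares line MSD = 6 D(L) t + c gives D(L) in nm²/ps,
converted to m²/s (×10⁻⁶). Wrapped input is rejected (single-step jump >
L/2) rather than silently unwrapped.

**Finite-size correction.** D∞ = D(L) + k_B T ξ/(6πηL) with ξ = 2.837298
for a cubic periodic box; inputs T (K), η (Pa·s), L (m) are echoed in the
result for provenance.

**Viscosity.** η = V/(k_B T)·∫₀^∞ ⟨P_αβ(0)P_αβ(t)⟩dt with the
autocorrelation averaged over at least three off-diagonal pressure
components (bar → Pa conversion inside). The series is split into
`n_blocks` consecutive blocks (default 5); per block the running integral
is fitted with A·(1−e^(−t/τ)) and A taken as the block's viscosity; the
block mean is reported with the per-block scatter as the uncertainty.
This plateau model is a deliberate simplification of more elaborate
time-decomposition weighting schemes: it is exact for exponentially
decaying correlations and robust to the long-time noise that makes the
bare integral wander. The autocorrelation length defaults to 5% of a
block and must comfortably contain the plateau; a fit that finds no
plateau is an error carrying the running-integral diagnostic.

**Derived quantities.** The Stokes–Einstein product D·η/T (SI units) and
the hydrodynamic radius r = k_B T/(ξ_SE π η D) for a boundary constant
ξ_SE ∈ [4, 6]. Two-point Arrhenius activation energies use
Ea = R·ln(x(T₁)/x(T₂))/(1/T₂ − 1/T₁), which is positive for a
thermally-activated property that grows with temperature (diffusion); a
`process = "viscosity"` switch flips the sign so that a viscosity falling
with temperature also reports a positive barrier.

## Synthetic generators: what they establish

The generators exist so every analysis stage has inputs with *exact*
expectations:

* **Planted scenes** place rigid pseudo ether-alcohol molecules (hydroxyl
  O and H, ether O, terminal C) into requested motifs. Intended bonds sit
  at 0.28 nm with the hydrogen aimed at the acceptor; every unintended
  oxygen pair is kept beyond 0.35 nm or at an angle of 60° or more, and
  motifs are separated by at least 1 nm — margins chosen so that
  perturbing the criteria by ±0.01 nm / ±5° cannot flip the ground truth.
  Each motif receives a random rigid rotation (seeded), which stresses
  the geometry code without changing any truth.
* **Brownian tracers** take independent Gaussian steps of per-axis
  variance 2·D·dt; unwrapped positions are emitted alongside the wrapped
  frames.
* **Ideal-gas frames** are uniform independent positions — the g(r) ≡ 1
  null model.
* **Lifetime samples** draw exponential times at a known rate, discretised
  to whole frames and truncated at the window, mirroring the windowed
  bonded-time table.
* **OU stress series** use the exact discrete-time update
  x_{t+1} = φx_t + √(C₀(1−φ²))ε with φ = e^(−dt/τ), so the autocovariance
  is C₀e^(−t/τ) exactly and the Green–Kubo target has the closed form
  V·C₀·τ/(k_B T).

Passing these tests establishes that the *analysis code* is correct: that
detection implements its geometric definition, that the network, CCDF,
MSD and Green–Kubo estimators recover known parameters at their expected
statistical accuracy. It does not establish anything about force fields,
sampling adequacy or equilibration of real simulations — planted scenes
are rigid and dilute, tracers are non-interacting, and the stress series
is Markovian, none of which is true of a dense liquid. Absolute values
from real trajectories (hundreds of networks per frame, and so on)
require real MD at production scale.

Problem sizes used in the shipped verification runs — 20 planted scenes of
up to ~200 molecules, 2000 lifetimes, a 500-particle/2000-frame tracer
ensemble, 2×10⁵ stress samples, a 1000-particle/100-frame ideal gas —
were chosen as the smallest ensembles at which the estimators' sampling
errors sit comfortably inside the recovery bands quoted in the tests
(5% for γ, 3% for D at fixed seed, 10% for η).

## Degenerate inputs and tie-breaks

* Zero-length vectors at an angle vertex, non-positive box edges,
  triclinic boxes, non-uniform frame spacing and wrapped MSD input are
  errors, not warnings.
* Distances exactly on a histogram bin edge belong to the lower bin
  (`ceiling(d/Δr)`); bond-table rows are canonically sorted by
  (donor, acceptor) so identical inputs give byte-identical outputs.
* An empty frame yields empty tables, zero network statistics, and an
  all-zero summary row (with a warning on emission) rather than NA.
* Persistence fits refuse fewer than three positive CCDF points and
  non-decaying input; the Green–Kubo estimator refuses fluctuation-free
  stress and series shorter than one block.

## Known limitations

* Orthorhombic (in practice cubic) boxes only; no triclinic support.
* Roles come from an explicit name→role map; chemistry is not inferred
  (ether vs hydroxyl oxygen cannot be distinguished by element alone).
* No energetic or topological hydrogen-bond definitions, no continuous /
  intermittent autocorrelation lifetimes, no Einstein-relation viscosity,
  no NPT observables (densities, heat capacities).
* GRO and XYZ text formats only; binary trajectory formats are out of
  scope, so long production runs should be decimated to text before
  analysis.
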