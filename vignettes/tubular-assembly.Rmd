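---
title: "Tubular self-assembly of field-polarized colloidal ellipsoids: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tubular self-assembly of field-polarized colloidal ellipsoids: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elltube)
```

## The model

`elltube` simulates a minimal coarse-grained model of prolate ellipsoidal
colloids aligned and polarized by an external AC electric field. The model
asks how little geometric and interaction specificity is needed for
monomers to self-assemble into regular hollow tubes of the kind familiar
from microtubules and tubular virus shells — and answers: a hard prolate
spheroid plus the electrostatics of induced polarization suffice.

Each particle is a hard prolate spheroid with short semi-axis $R$ (the unit
of length) and long semi-axis $a = \rho R$, aligned permanently along the
field axis $z$ (the field that justifies this constraint is not simulated;
alignment is an input assumption). The field-induced polarization is
represented by two opposite point charges $\pm q$ placed on the long axis
at $z = \pm d$. The offset is not free: requiring the pair to reproduce the
ratio of the two lowest non-vanishing axial multipole moments (dipole and
octupole) of a *uniformly polarized* spheroid gives

$$ d = R\,\sqrt{\tfrac{3}{5}\left(\rho^2 - 1\right)} , $$

so a sphere ($\rho = 1$) degenerates to a pure point dipole and elongated
particles carry their charge increasingly near the poles. The package
verifies this closed form against a quadrature oracle: the exterior
potential of a uniformly polarized prolate spheroid equals that of a line
density of dipoles $\mu(z) \propto 1 - z^2/c^2$ on the focal segment
($c^2 = a^2 - R^2$), whose multipole ratio is computed by
`stats::integrate` in the test suite, and `potential_exact()` evaluates the
same representation pointwise as the reference for the discrete-charge
potential `potential_discrete()`.

Energies are reduced by $k_BT$. Summing plain Coulomb interactions over the
four inter-particle site pairs and measuring site separations against the
minimum centre-to-centre distance of parallel spheroids (side-by-side
contact, $2R$) leaves a single interaction knob, the coupling parameter
$\Gamma = q^2 / (8\pi\varepsilon_m R k_B T)$:

$$ U^* \;=\; \Gamma \sum_{\substack{\text{sites } i<j\\ \text{different particles}}} \frac{Z_i Z_j}{r_{ij}/2R}, \qquad Z_i = \pm 1 . $$

Equivalently, and as implemented, every site carries a reduced charge
$q^* = \sqrt{2\Gamma R}$ and interactions are unscreened Coulomb sums. No
electrolyte screening is included: the physical regime of interest is an AC
drive faster than the charge relaxation of the medium, where the
electrolyte cannot follow the particle polarization. Intra-particle site
pairs are a rigid-body constant and are excluded everywhere. Hard-core
overlap of two parallel identical spheroids is decided exactly by the
affine map $z \to z/\rho$, which turns both particles into spheres of
radius $R$: the contact function `contact_function()` is
$F = (\Delta x^2 + \Delta y^2 + (\Delta z/\rho)^2)/(2R)^2$ with $F<1$ iff
the particles interpenetrate. The general non-parallel ellipsoid contact
problem never arises because orientations are frozen.

A control mode (`mode = "point_dipole"`) replaces the charge pair by an
ideal $z$-dipole of the same moment $2qd$ at the particle centre. The two
modes share the far field exactly (moments are matched); they differ in the
near field, where the charge pair concentrates attraction at the
interwoven poles. The control exists to show that this near-field structure
— not generic dipolar attraction — drives sheet and tube formation.

## Monte Carlo engine

`run_mc()` propagates the canonical ensemble with single-particle
translations only: one cycle is $N$ attempted moves; a trial move displaces
a uniformly chosen particle by a vector drawn uniformly from a cube of
half-width equal to the displacement parameter (default one particle
radius, $R$). Trials that overlap any particle are rejected before any
energy is computed (the hard core is inviolable by construction); the rest
are accepted with the Metropolis probability $\min(1, e^{-\Delta U^*})$.
There are no rotation, volume, or cluster moves. The trial-move
distribution (cube rather than sphere) is a documented convention; at these
acceptance rates the choice only rescales the diffusive time unit.

Periodic electrostatics use Ewald summation with conducting ("tinfoil")
boundary conditions and no surface term. Splitting parameter and cutoffs
are tuned automatically from the box and a relative accuracy target
(default $10^{-5}$, well below the thermal noise that decides Metropolis
acceptances at $\Gamma \le 10$); the real-space cutoff is half the shortest
box edge. Move energies are computed incrementally — partial real-space
sums plus a rank-one update of the cached reciprocal-space structure
factors — and the structure factors are refreshed from scratch every 5000
cycles as numerical hygiene; the running energy itself is never silently
resynchronized, so the suite's cached-versus-recomputed check is a real
test of the bookkeeping. Runs are bit-reproducible given the seed.

Two numerical points deserve record. First, the real-space kernels
$\mathrm{erfc}(\alpha r)/r$ (and the two dipole–dipole kernels in control
mode) are evaluated from dense linear-interpolation tables above
$r = R/4$ and directly below it; the table resolution keeps the
interpolation error far below the Ewald accuracy target. Second,
boundary conditions matter when comparing summation methods: a cell of
aligned dipoles carries a net moment $M_z$, so a brute-force image sum
accumulated in cubic shells converges to the *vacuum-boundary* energy,
which exceeds the tinfoil Ewald energy by the shape term
$2\pi M_z^2/3V$ (`dipole_shape_term()`). The oracle tests compare the two
methods with this term included; omitting it is a classic source of
spurious "Ewald bugs".

## Morphology classification

The study identifies morphologies visually; any quantitative classifier is
therefore a design decision of this package, with thresholds exposed as
arguments and reported in the output. `classify_morphology()` proceeds by a
cascade on the contact graph (edges where surfaces are within a fraction
$\delta = 0.2$ of touching; calls are required by the test suite to be
stable over $\delta \in [0.1, 0.3]$):

1. **fluid** — largest cluster below half the particles and nothing spans
   the box;
2. **sheet** — the largest cluster connects to its own periodic image along
   two (or three) axes;
3. **tube** — spans $z$ only and is hollow (below);
4. **string** — spans $z$ only, laterally at most about two particles wide;
5. **compact** — everything else, including ambiguous cases, with
   diagnostics attached.

Sheet and tube are treated as *completed* morphologies and additionally
require the cluster to hold at least half the particles (in the reference
systems, sheets and tubes contain essentially all the material); minority
clusters that span or close transiently during coarsening are reported
compact.

Spanning is detected by unwrapping each cluster through the minimum-image
edges and flagging any closure edge whose winding displacement is a full
box period. Hollowness is judged slab-wise so the axis can follow a
drifting or gently bent fibre: the cluster is cut into $z$-slabs one
head-to-tail period ($2\rho R$) thick, each slab's axis is its own lateral
centroid, and radial distances are measured from that axis. The defining
statistic of a single-particle-walled tube is the *wall fraction*: the
fraction of members within $1.2\,R$ of the median ring radius. It
separates the structures this model produces cleanly — an ideal built
ring scores 1, equilibrated tubes score about $0.8$–$0.97$, dense
multi-string bundles (the structure the ideal-dipole control condenses
into) about $0.7$, and space-filling disks or diffuse string webs about
$0.3$–$0.45$, the geometric value $\sim 4 r_\mathrm{med} w / A^2$ for a
filled disk of radius $A$. A cluster is a tube when its wall fraction is
at least $0.75$ and its median ring radius is at least $1.6\,R$; the
radius bound is anchored in lattice geometry (ideal closed rings of 4, 5
and 6 columns have radii $1.22$, $1.47$ and $1.73\,R$ — below about six
columns the enclosed void is smaller than a particle, and the object is a
bundle, not a tube; compare the reference cross-sections of $6\pm2$
particles per ring at $\rho = 2.7$). The hollowness test runs before the
width test because a few-column tube is itself laterally narrow; what
separates it from a one- or two-column string is the ring radius.

Two measurement-protocol conventions complete the classifier. First,
aggregate-structure calls (`simulate_assembly()`) are made on the
*inherent structure*: a short zero-temperature quench (2000 downhill-only
cycles, about 1% of a production run) lets transient single-particle
defects fall back into the wall before classification, so the label
describes the morphology rather than one thermal fluctuation. Second, the
coupling-parameter ladder (`scan_gamma()`) classifies thermal
configurations without a quench: at zero temperature any fluid of
attractive particles condenses, so quenching would erase the fluid
regime it is trying to detect. The two conventions measure different
observables — "what aggregate formed" versus "which phase is the system
in" — and are both exposed as the `quench_cycles` argument.

## Idealized aggregates and the minimum-energy maps

Why do finite sheets close into tubes? `energy_maps()` reproduces the
constrained minimum-energy calculation that answers this. Sheets are built
on a centred rectangular lattice: $n_x$ columns of $n_z$ particles, with
alternate columns shifted by half the within-column period $l_z$. Since
by Earnshaw's theorem an electrostatic minimum must sit at particle
contact, the column spacing is slaved to the diagonal contact condition
$l_x^2 + (l_z/2\rho)^2 = (2R)^2$, leaving $l_z$ as the single free
parameter; at $l_z = 2\rho R$ this gives $l_x = \sqrt{3} R$, i.e. adjacent
columns interpenetrate laterally and the oppositely signed pole charges
interweave. Tubes wrap the same lattice onto a cylinder of radius
$r_c = l_x / (2\sin(\pi/n_x))$, preserving the adjacent-column contact
chord. `minimize_lz()` minimizes the exact (open-boundary) site sum per
particle over the feasible $l_z$ interval by Brent search with endpoint
checks (the contact bound can carry the minimum, and does for a single
column). Energies are reported relative to the dimer reference — the
global minimum over two-particle contact configurations, found by a dense
scan plus refinement over the contact circle. For $\rho = 2.7$ that
minimum is a staggered side-by-side pair (total $-0.964\,\Gamma$),
distinctly below head-to-tail contact ($-0.795\,\Gamma$): the interwoven
staggered geometry is already optimal at the two-particle level.

Three lattice conventions are worth noting. First, the tube construction
uses alternating rings (not a helix; helical wrappings were evaluated and
are far higher in energy because they break the staggered pole contacts),
closing seamlessly for even $n_x$; odd $n_x$ is supported with a single
in-register seam whose clearance is enforced by minimally inflating
$r_c$, and the default map grids use even $n_x$ only. The cylinder radius
is always the smallest radius at which no column pair overlaps, so the
binding pair — usually the adjacent columns, at extreme parameters the
in-register second neighbours — sits at exact contact. Second, the map
structure is $\Gamma$-independent (energies are exactly linear in
$\Gamma$), so all maps are computed at $\Gamma = 1$.

Third, and most consequential: the energy is *bimodal* in $l_z$. A
"contact" branch near $l_z = 2\rho R$ keeps within-column particles in
head-to-tail contact with adjacent columns' poles interwoven; a
"stretched" branch near $l_z \approx 3.2\rho R$ pulls the columns apart
until the lattice becomes a stack of staggered dimer-like pairs (the
two-particle ground state), which for most aggregate sizes is the lower
idealized lattice energy, and whose spacing matches the within-column
separations measured in the Monte Carlo tubes. The energy-map sign
structure described above — and in particular the tube's advantage at
small $n_x$ — is a property of the contact branch: in the stretched
branch a four-column tube is frustrated (its in-register opposite columns
collide before the columns reach their preferred spacing) and the sheet
wins the $\Delta E$ corners instead. `minimize_lz()` resolves both
branches and takes the contact branch as its default family for the maps;
the `branch` argument exposes the stretched and global alternatives, and
the maps' qualitative conclusions about why finite sheets close should be
read as statements about the contact-branch family.

The resulting maps show: energy per particle decreasing in $n_z$ for both
kinds; the tube more stable than the sheet at large $n_z$ and/or small
$n_x$ ($\Delta E = E_\mathrm{tube} - E_\mathrm{sheet} < 0$), the sheet more
stable in the opposite corner; and $E_\mathrm{tube} \to E_\mathrm{sheet}$
monotonically as $n_x \to \infty$ at fixed $n_z$ (vanishing curvature).
The edge-charge diagnostic `sheet_edge_charges()` exhibits the mechanism:
a finite sheet's vertical edges (z-edges) expose charges of alternating
sign — a modest cost — while its horizontal edges (xy-edges) expose
like-signed pole charges — an expensive one. Closing into a tube
eliminates the z-edges at the price of curvature, which pays off once the
aggregate is long relative to its circumference.

## Synthetic study conditions, problem sizes and what the tests show

The simulation conditions are those of the study: aspect ratio
$\rho = 2.7$; volume fraction $\phi \approx 0.06$ for the
morphology ladder over $\Gamma \in [0, 10]$ (the study used $N = 384$); and
an artificially restricted dilute system — $N = 36$ at $\phi = 0.015$,
$\Gamma = 9.8$, ten independent seeds — in which a sheet cannot span the
box laterally and tube closure is observable. Initial states are random
sequential insertions free of overlaps.

Desk-scale choices, made once and documented here: the reference study
propagated $10^7$ cycles; this package's acceptance checks run the dilute
36-particle systems for $3\times 10^5$ cycles, the point where their
energy per particle has plateaued (at about $-11$ to $-12\,k_BT$ near the
ideal 6-column tube value) and all ten seeds have closed into z-spanning
hollow fibres, and run the $\phi = 0.06$ ladder at $N = 100$ for $6000$
cycles with three seeds per coupling. The ladder budget resolves the fluid
regime at $\Gamma \lesssim 4$ and the aggregation onset at
$\Gamma \approx 5$, but **not** the ordered-sheet regime, and probe runs
indicate the sheet regime is not merely slow but absent at this system
size: an $N = 120$ run at $\Gamma = 10$ coarsens through string webs and
compact aggregates and then, by $3$–$5\times 10^5$ cycles, closes into a
z-spanning *hollow fibre* rather than a doubly spanning sheet. That is the
same finite-size selection mechanism that produces tubes in the dilute
36-particle system — with only $\sim 120$ particles the aggregate cannot
pay for a box-spanning sheet (which must also be commensurate with the
periodic cell), and eliminating its z-edges by closing is cheaper. Sheets
that span two directions appear in the reference study only at
$N = 384$. The sheet-onset check is asserted at its stated scaled
conditions regardless, rather than weakened to match what that scale can
produce, and is expected to fail there; the surrounding checks (fluid
staging, aggregation onset, dilute-system tube closure, lattice
energetics, ideal-dipole control) are the desk-scale evidence for the
model's structure selection.

The generator emulates monodisperse, perfectly aligned hard spheroids with
ideal uniform polarization. Real field-assembled microgel suspensions
differ in ways the model deliberately omits: finite alignment energy
(particles tumble at weak fields), soft and slightly polydisperse
particles, electrolyte screening at finite ionic strength, hydrodynamics,
and electrode-near field inhomogeneities. Passing tests therefore support
the electrostatic structure-selection mechanism, not a quantitative map
from field strength to $\Gamma$.

## Worked example

A dilute strong-coupling run that closes into a tube, at a few times the
tube-formation scale used by the acceptance checks:

```{r example, eval = FALSE}
sh <- spheroid_shape(rho = 2.7)
res <- simulate_assembly(n = 36, gamma = 9.8, cycles = 300000, seed = 3,
                         shape = sh, phi = 0.015)
res$morphology
#> morphology: tube (largest cluster 100%, spans {z})
#>   ring counts per slab: 9 6 5 11 5
```

and the stability corners of the energy maps:

```{r maps, eval = FALSE}
maps <- energy_maps(sh)
subset(maps, (n_z == 70 & n_x == 4) | (n_z == 10 & n_x == 24))
#>    n_z n_x lz_sheet lz_tube e_sheet  e_tube  delta_e
#> 7   70   4      5.4     5.4 -0.6020 -0.6227 -0.02067
#> 36  10  24      5.4     5.4 -0.3339 -0.2857  0.04822
```

## Known limitations

- Orientations are frozen along the field axis; the model cannot describe
  weak-field regimes where alignment itself is marginal.
- No screening: adding salt (screened interactions) changes the physics
  qualitatively and is out of scope.
- The classifier is built for the morphologies this model produces;
  exotic structures (helical tubes, multiwall scrolls) would land in
  `compact` with diagnostics rather than receive labels of their own.
- Single-particle translations make late-stage coarsening slow; the
  engine is faithful to the reference protocol rather than optimized for
  sampling efficiency (no cluster moves).
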