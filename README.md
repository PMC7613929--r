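# protofil

Quaternary-structure geometry of actin-like protein filaments from
atomic coordinate models.

Bacterial actin homologues — FtsA, the divisome's membrane anchor, and
MreB, the elongasome's actin — work as filaments whose biology is
written in their quaternary geometry: whether protofilaments pair into
antiparallel double filaments, whether the lateral interfaces carry
local twofold (C2) symmetry, how far a subunit-to-subunit operator
twists and rises (and hence whether repeating it closes a ring or
traces a helix), how strongly a filament is bent, and how far a domain
swings between conformers when a partner peptide binds.  protofil
computes all of these from coordinates, for deposited crystal
structures and for synthetic ground-truth models alike, and adds the
practical companion analyses used to validate filament models in
vivo: Cbeta–Cbeta cysteine cross-link design and equilibrium
binding-isotherm fits.

## What it computes

Every inter-subunit operator is a rigid transform `y = R x + t`, which
Chasles' theorem reduces to a screw: a twist angle *theta* about a unique
axis plus a rise *d* along it.  From the screw, protofil derives the
filament helical parameters (twist, rise, helical radius, subunits per
turn = 360/|theta|, handedness) and predicts ring closure: a ring of n
subunits forms when |360 − n·theta| and |n·d| are both small.  Interfaces
between chains are detected from heavy-atom contacts (>= 5 residue
pairs within 4.5 Å by default), classified as longitudinal
(near-parallel subunits) or lateral (antiparallel, twist in
[150°, 180°]), assembled into a filament graph of protofilaments and
oligomer components, and tested for local C2 symmetry by chain-swap
self-superposition.  Curvature is a least-squares circle through
subunit centroids in their common plane; domain orientation is the
first principal axis of main-chain coordinates; hinge rotation is the
residual rotation of a mobile domain after superposition on fixed
domains.  Binding data are fitted to the single-site equilibrium
response `R(C) = C·Rmax/(C + Kd) + B` or to the two-step model
`F(P) = F0 + F_Lo·P/(Kd_Lo+P) + F_Hi·P/(Kd_Hi+P)` by bounded
Levenberg–Marquardt least squares.

A synthetic-data module generates pseudo-protomers on helices, rings,
arcs and antiparallel double filaments with exactly known parameters
(and exactly C2-symmetric lateral interfaces by construction), plus
isotherms drawn from the fitted models — the ground truth behind the
test suite.  See the methods vignette
(`vignettes/protofil-methods.Rmd`) for conventions, tolerances and
design rationale.

## Worked example

```r
library(protofil)

protomer <- make_protomer(96, seed = 1)

## a 13-subunit mini-ring (generator defaults), analysed blind
ring <- build_helical_filament(protomer)
hp <- helical_parameters_filament(ring$structure)
hp
#> helical_params: twist 27.692 deg, rise 0.000 A, radius 100.0 A, 13.00 subunits/turn, none-handed
predict_ring_closure(hp)
#> ring_closure: ring, best n = 13 (angle dev 0.000 deg, rise 0.000 A)
filament_diameter(ring$structure, hp$axis)$centroid_path_diameter_nm
#> [1] 20.00096

## an antiparallel double filament: topology and local C2 symmetry
df <- build_double_filament(protomer, n = 4, rise = 9)
ifaces <- find_interfaces(df$structure)
classes <- lapply(ifaces, classify_interface, s = df$structure,
                  axis = c(0, 0, 1))
build_filament_graph(ifaces, classes)
#> filament_graph: 8 subunits, 13 interfaces
#>   protofilament  : a-b-c-d
#>   protofilament  : A-B-C-D
#>  id size n_longitudinal n_lateral n_protofilaments double_filament
#>   1    8              6         7                2            TRUE
detect_c2(df$structure, c("a", "D"))
#> C2 a-D: yes (angle dev 0.00 deg, rise 0.00 A, rmsd 0.00 A)

## two-step binding isotherm (truth: Kd_Lo 0.016 uM, Kd_Hi 11 uM)
sim <- simulate_isotherm("two_step", noise_sigma = 0.002, seed = 11)
fit_fp(sim$data)
#> two_step_fit: Kd_Lo = 0.01837 uM, Kd_Hi = 12.26 uM (F0 0.09938, F_Lo 0.08334, F_Hi 0.1175), rss = 2.169e-05
```

The ring analysis reads the twist back from coordinates alone and
identifies the 13-subunit closure with a 20 nm centroid-path diameter —
the geometry of the dominant FtsA mini-ring.  The double-filament
analysis recovers two 4-subunit protofilaments joined laterally, with
every lateral interface exactly C2-symmetric.  The two-step fit
recovers both dissociation constants from a noisy 12-point titration.

A command-line wrapper over the same functions ships in
`inst/scripts/protofil` (subcommands `analyze-filament`, `hinge`,
`crosslink-scan`, `fit-binding`, `simulate`; YAML config validated by
`read_run_config()`).

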