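---
title: "protofil: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{protofil: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protofil)
```

protofil analyses the quaternary geometry of actin-like protein
filaments — FtsA, MreB and their relatives — from atomic coordinate
models.  This vignette records the models and procedures the package
implements, the conventions and tolerances it adopts where the
underlying geometry leaves genuine choices, and what its synthetic
ground-truth generators do and do not emulate.

## Coordinate models

A structure is a flat atom table (chain, author residue number,
insertion code, residue and atom names, element, coordinates in
Angstrom, occupancy, altloc) plus an identifier and an optional list of
rigid-body operators.  PDB and mmCIF files are parsed through bio3d;
on reading, hydrogens and waters are dropped (none of the analyses
implemented here use them), and alternate locations are resolved by
keeping the highest-occupancy copy, ties broken by the
lexicographically first altloc tag — a deterministic version of
standard practice.  Residue numbering is author numbering throughout;
no alignment-based residue mapping is performed, because for the FtsA
systems this package was built around the relevant positions coincide
across the analysed species.

Crystal-symmetry expansion takes *materialised* operator lists — from
PDB `REMARK 350` records, which are retained on read, or from a
plain-text file of 3x4 blocks (`read_operators()`).  Generating
operators from a space-group symbol is deliberately out of scope:
deposited mmCIF models carry their operators, and re-implementing
space-group tables would add a large error surface for no analytical
gain.  `expand_assembly()` derives deterministic chain identifiers
(`<source>.<operator>.<copy>`) so provenance of every generated subunit
is traceable; single-character relabelling is available when PDB output
(at most 62 chains) is required.

## Rigid transforms and screw geometry

Superposition uses the SVD-based Kabsch algorithm with unit weights and
the determinant correction that guarantees a proper rotation; weighting
by occupancy is not used (no analysis here calls for it).  Every
inter-subunit operator is reduced to its screw form: a twist about a
unique axis plus a rise along it.  Two conventions remove the inherent
sign ambiguity deterministically: the axis direction is chosen so the
rise is non-negative, and when the rise is numerically zero (below
1e-6 A) so the twist is non-negative; the twist is reported in
(-180, 180] degrees.  Twists below 1e-6 degrees are treated as pure
translations and flagged rather than raised as errors.  The reported
axis point is the point on the axis closest to the origin.

For noisy coordinates, per-neighbour-pair screw parameters inherit an
axis-direction error that the helical radius amplifies into the rise
and radius estimates.  `helical_parameters_filament()` therefore
composes the transform over k consecutive subunits (capped so the
composed twist stays below 175 degrees) and divides by k, reducing the
axis error roughly k-fold.  This estimator is what the recovery tests
and the acceptance script use.

## Filament topology

Two chains form an interface when at least 5 residue pairs have a
minimum heavy-atom distance of at most 4.5 A — standard
quaternary-contact practice; both numbers are configurable.  Polar
contacts are counted as inter-chain N/O–N/O pairs within 3.5 A with no
angular term: the package uses them only comparatively (counting
contacts lost between a straight and a bent interface), where an
angle-aware definition would add parameters without a testable anchor.

Interfaces are classified from the relative twist between their
subunits: below 60 degrees the subunits are near-parallel and the
contact is longitudinal; within [150, 180] degrees they are
antiparallel and the contact is lateral, the situation in an
antiparallel double filament.  Longitudinal contacts are subdivided
into tight versus loose by the number of residue pairs joining one
subunit's IIA/IIB subdomains to the next subunit's nucleotide face
(three pairs by default); the two lateral registries (i–i* versus
i–i*−1) are separated by the offset of the inter-centroid vector along
the protofilament axis, thresholded at the midpoint of
[0, longitudinal repeat / 2].

Local twofold (C2) symmetry is tested by the chain-swap
self-superposition of the dimer: both chains are mapped simultaneously
onto each other and the resulting transform is screw-decomposed.  The
interface passes when the rotation is within 5 degrees of 180, the
residual rise is below 1.5 A and the mapping RMSD below 2.0 A —
permissive tolerances, because "local" symmetry in a crystal is
approximate.  One property of this swap construction is worth
recording: a violation built by translating one chain along the
would-be axis does *not* surface as screw rise, because the swap map
would have to move the two chains in opposite directions, which no
rigid motion can do; the optimum instead splits the displacement into
mapping RMSD.  Violations are therefore rejected through the RMSD (and
angle) terms, and the tests assert exactly that.

The filament graph takes subunits as nodes and classified interfaces as
edges.  Protofilaments are the connected components of the longitudinal
subgraph, reported as ordered paths; a longitudinal cycle is reported
as a closed ring, which is a legitimate topology (mini-rings), not an
error.  A component is flagged as a double filament when it contains
exactly two protofilaments joined by at least one lateral edge per two
subunits.

## Helical parameters, rings, curvature

Subunits per turn is 360 divided by the absolute twist; handedness is
right when twist and rise share a sign under the package convention.
Ring closure scans integer subunit counts n in [3, 100] for
|360 − n·twist| within 3 degrees while |n·rise| stays below 5 A, ties
going to the smaller n.  A 360/13-degree twist with near-zero rise —
the geometry of the dominant 13-subunit FtsA mini-ring — closes at
n = 13 exactly.

Curvature of a bent filament is estimated from subunit centroids (all
polymer heavy atoms): the centroids are projected onto their
principal-component plane and a circle is fitted, algebraically first
(Kasa fit, exact on noiseless circles) and then refined by Gauss–Newton
on the orthogonal residuals.  Collinear input is reported as infinite
radius, not an error.  Radii are reported in nanometres, the unit used
for filament-scale curvature; all internal coordinates stay in
Angstrom.  Because a curvature radius measured on four tetramer
centroids is convention-dependent (which atoms, which points), the
package declares this convention rather than guessing alternatives, and
the regression test against the bent FtsA–FtsN tetramer carries a
generous 15% tolerance.

Two diameters are always reported for expanded helices: the
centroid-path diameter (twice the mean perpendicular centroid distance
from the screw axis) and the envelope diameter (twice the maximum
perpendicular atom distance).  Comparisons with ring diameters measured
on centre traces use the centroid path; the envelope is never smaller.

## Domain orientation and hinge rotation

Principal axes are the eigenvectors of the unit-mass covariance of
main-chain (N, CA, C) coordinates, ordered by descending spatial
extent.  Unit masses are used because the analyses specify only the
atom set, and for fixed atom sets mass weighting changes nothing of
interest.  Axis signs from an eigendecomposition are arbitrary, so
`domain_orientation()` anchors the first axis to sequence: its dot
product with the vector from the N-terminal-half centroid to the
C-terminal-half centroid of the domain is made non-negative.  Two
moments within 1% of each other set a degeneracy flag.

Hinge rotation between two conformers is measured by two
superpositions: conformer B is superposed onto conformer A on the
main-chain atoms of the fixed domains, and the rotation that then still
superposes the mobile domain is the hinge angle.  This deliberately
simple procedure takes the domain partition as input; it does not
segment domains from the displacement field the way dedicated
dynamic-domain tools do, so against such tools a disagreement of a
degree or so is expected, and the regression against the FtsA IC-domain
closed/open pair (13.8 degrees) uses a ±1.5 degree band.

FtsA subdomain boundaries (IA, IC, IIA, IIB) are not standardised and
are shipped as an editable YAML config
(`system.file("extdata", "ftsa_domains.yaml", package = "protofil")`)
holding an approximate assignment derived from the actin-fold
architecture: IA split between N- and C-terminus, IC inserted where
actin carries subdomain IB, IIB inserted within IIA.  Every report
states the boundary set used; analyses of other structures should
supply their own ranges.

## Cysteine cross-link design

Candidate pairs are inter-chain residue pairs ranked by Cbeta–Cbeta
distance, measured on the wild-type side chains — the beta carbon is
unchanged by mutation to cysteine, so no in-silico mutagenesis is
needed.  Glycine has no Cbeta and is skipped with a warning by default;
an ideal-tetrahedral virtual Cbeta reconstruction from N/CA/C is
available but off by default.  A pair is compatible with a linker when
its distance is at most span + tolerance (3 A default); pairs shorter
than span − tolerance are flagged separately, since a short pair may
react better with a shorter reagent.  Only the ~8 A span of BMOE is
widely quoted in running text, so linker spans ship as *required* user
configuration with a single-entry example file rather than invented
defaults.  At interfaces with local C2 symmetry, a single mutation
yields a self-pair with its symmetry mate (`c2_self_pairs()`); the
background check reports, for every candidate site, the minimum
cross-chain Cbeta distance to any endogenous cysteine over all
interfaces, flagging designs below 12 A as possible off-target
cross-linkers.

## Binding isotherms

Two response models are implemented: the single-site equilibrium
response R(C) = C·Rmax/(C + Kd) + B used for surface plasmon resonance
titrations, and the two-step model F(P) = F0 + F_Lo·P/(Kd_Lo + P) +
F_Hi·P/(Kd_Hi + P) used for fluorescence polarisation of a labelled
peptide titrated with protein, where the second transition reports
ligand-linked polymerisation.  Fitting is ordinary (unweighted)
nonlinear least squares via Levenberg–Marquardt with positivity bounds
on the dissociation constants and amplitudes, five deterministic
jittered restarts (best residual wins), and data-driven initial values.
For the two-step model the constants are labelled so Kd_Lo <= Kd_Hi; a
ratio below 10 triggers an identifiability warning, and a fitted Kd_Hi
beyond ten times the titrated range is flagged as unbounded by the
data.  Concentrations are micromolar; responses are treated as generic
(response units or anisotropy), since the fits are invariant to the
response unit.

## Synthetic ground truth

The generators provide inputs with exactly known answers for every
analysis stage.  `make_protomer()` builds a rigid pseudo-protein from a
compact confined random walk, four named atoms (N, CA, C, CB) per
pseudo-residue so that every selector used on real structures works
unchanged, anisotropically adjusted until its three principal moments
are pairwise distinct by at least 5% (well-defined principal axes).
`build_helical_filament()` places copies on an exact screw;
`build_arc_filament()` places centroids exactly on a circle;
`build_double_filament()` builds a second protofilament as an exact
180-degree rotation of the first about an axis perpendicular to the
filament, which makes every lateral interface *exactly* locally
C2-symmetric by construction (the global twofold composed with the
lattice translation is a local twofold at every registry).  Inter-
protofilament gap and, if not given, longitudinal rise are calibrated
by bisection to the most open spacing that still yields at least 10
residue pairs within 4.0 A, so the built interfaces are detectable with
margin at the 4.5 A / 5 pair defaults and remain so under the noise
levels used in the tests (sigma up to 0.3 A).  Every generator returns
a truth record sufficient to rebuild its output bit-identically and, for
double filaments, the list of built interfaces with classes and exact
C2 axes.

Default conditions mirror the FtsA systems the package was written
around: 13 subunits on a 100 A-radius ring (20 nm centroid-path
diameter) for the mini-ring generator, a 16.3 nm arc radius with 48 A
subunit spacing for the bent-filament generator, single-site Kd of
0.8 uM and a two-step pair of 0.016/11 uM for the isotherm generator,
with 2%-of-amplitude Gaussian response noise in the noisy variants.

What the generators emulate is topology, symmetry and metric geometry —
not protein realism.  There is no side-chain packing, no sterics, no
secondary structure, no crystallographic disorder, B-factors or missing
loops.  Passing the synthetic suite therefore demonstrates that the
geometric machinery is correct and noise-stable at realistic subunit
sizes, not that the contact thresholds are optimal for any particular
crystal form; the regression tests against deposited FtsA models cover
that complementary ground, and require the user to supply the
coordinate files locally (they are not redistributable inside the
package).

## Numerical choices and problem sizes

Degenerate inputs are flagged, not guessed at: pure translations in
screw decomposition, collinear point sets in superposition and
principal axes, infinite radii in curvature, unbounded Kd_Hi in
two-step fits.  Noise-recovery tests use a protein-sized protomer (396
pseudo-residues, the size of an FtsA monomer) because angular
superposition accuracy scales with subunit size; parameter-recovery
bounds quoted as percentages use a 0.05 A absolute floor for rises near
zero, where a relative bound is ill-defined.  The default test suite
keeps simulations small — six-subunit filaments, 50-draw parameter
sweeps, 200-replicate fit calibrations — which completes the whole
suite in well under a minute while leaving every bound comfortably
non-marginal.

## Known limitations

* The hinge procedure takes domain partitions as input; boundaries for
  proteins other than FtsA must be supplied, and results depend mildly
  on them.
* Interface classification assumes a filament-like geometry; arbitrary
  oligomers with twists between 60 and 150 degrees fall into `other`
  deliberately.
* Buried surface area, interface energetics and cross-linking
  efficiency are out of scope; Cbeta distance is a geometric proxy
  only.
* The curvature convention (subunit centroids, common-plane circle
  fit) is one declared choice among several defensible ones; radii
  from other conventions can differ by a few percent on short, bent
  oligomers.
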