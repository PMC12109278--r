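---
title: "Topological analysis of DNA replication intermediates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological analysis of DNA replication intermediates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnatopo)
```

## The problem

A covalently closed circular DNA molecule stores superhelical stress in
its linking number difference, $\Delta Lk = Lk - Lk_0$ with
$Lk_0 = N/10.5$ for $N$ base pairs.  While the molecule is being
replicated, the two replication forks split it into an unreplicated
parental duplex and two replicated daughter duplexes, and the stress can
live in several structurally distinct forms: twist and writhe of the
unreplicated region, wrapping of the daughter arms around the parental
duplex, interwinding of the two daughters (precatenanes), and
superhelical folding of the precatenated braid (plectonemes of
precatenanes).  `dnatopo` quantifies all of these from bare 3D
conformations, and additionally detects and classifies the
close-approach geometries (juxtapositions, "collision events") that type
II topoisomerases act on.

## The Gauss-integral machinery

Every topological quantity in the package reduces to the Gauss linking
integral between two oriented piecewise-linear curves.  For two straight
segments the double integral has a closed form: the signed solid angle
of the quadrilateral spanned by the four end-to-end vectors, divided by
$4\pi$ (the spherical-excess expression of Klenin and Langowski).
`segment_pair_charge()` evaluates it exactly; `contribution_matrix()`
tabulates it for every segment pair of two curves.  For closed polygons
the sum of all entries is the integer linking number with no
discretization error, which the test suite exploits: Hopf links, torus
links and generator fixtures must come out integer to $10^{-3}$.

For a replication intermediate the parental strands $A = a_1 \cup a_2$
and $B = b_1 \cup b_2$ are closed curves passing through both forks, and
partitioning the contribution matrix at the fork indices splits $Lk$
into three block sums.  `decompose_ri()` reads the five components off
these blocks:

* `q_unrep` $=$ (a1 x b1 block sum) $- n_\mathrm{unrep}/10.5$, split into
  Component 1 (the twist change of the unreplicated duplex about its
  axis) and Component 2 (the writhe-like remainder);
* Component 3 $=$ `q_wrap`, the two off-diagonal block sums;
* `q_rep` $=$ (a2 x b2 block sum), split into Component 4 (the
  precatenane number `Ca`, measured as the Gauss linking of the two
  daughter midpoint curves closed through their fork junctions) and
  Component 5 (the remainder, carried by plectonemes of precatenanes).

Components 1/2 and 4/5 are computed from direct geometric definitions
with the block-sum residuals, not from diagonal-band splitting, so the
five components always add up to the total linking difference exactly.
The relaxed baseline of an intermediate is $n_\mathrm{unrep}/10.5$,
i.e. the replicated parental strands are taken as unlinked when relaxed;
with the canonical stage sizes (1491 and 504 bp unreplicated) this
baseline is an exact integer.

### Discrete twist

`duplex_twist()` uses edge tangents of the axis polygon, projects the
strand offset at each vertex perpendicular to its edge, and
parallel-transports offsets across vertices with the minimal rotation
carrying one edge tangent onto the next.  With this discretization the
polygonal ribbon satisfies the Calugareanu–White identity
$Tw + Wr = Lk$ to floating-point accuracy, which the tests verify on
stochastically deformed duplexes at tolerance 0.05.  (A naive
central-difference tangent loses two orders of magnitude here.)

## The synthetic generator

The generator is first-class, tested code: it is the package's stand-in
for coarse-grained molecular-dynamics conformations and defines the
study conditions under which everything else is validated.

`make_relaxed_circle()` builds a planar circular axis with two strands
winding `round(n/10.5)` times.  `make_supercoiled_circle()` builds a
plectonemic axis carrying approximately $|\Delta Lk|$ interwound
crossings over the requested number of branches, measures its own
writhe, and sets the (integer) strand twist so the measured $\Delta Lk$
is exact; negative $\Delta Lk$ gives a right-handed interwound
superhelix, positive a left-handed one.  The superhelix radius defaults
to 4.5 nm — inside the 4–5.5 nm range observed for plasmids at
physiological superhelical density, and chosen so that opposing
segments of an interwound arm sit strictly inside the 10 nm
juxtaposition cutoff rather than exactly on it.  The arm radius
*breathes* by ±35 % once per crossing, which is what thermalized
plectonemes do; without it the distance landscape between the opposing
helices is a degenerate flat valley and juxtaposition minima are
ill-defined.

`make_ri()` lays out the unreplicated region as a plectonemic (or
plain) arc in one half-space and the replicated region as a two-daughter
braid in the other, both anchored at two fork junctions 12 nm apart.
The fraction of `q_unrep` realized as twist defaults to 0.3 (the rest is
plectonemic writhe), the braid radius to 4 nm.  Prescribed charges are
then met by a measure-and-correct loop: the generator computes its own
Gauss-block sums and adjusts the unreplicated strand twist, the braid
turns, and (when wrapping is prescribed) the wrap turns.  Two numerical
subtleties required design decisions:

* a whole crossing can sit on either side of a fork junction, so the
  block sums jump by ±1 turn as the strand phases at the forks sweep;
  the loop therefore scans the braid and unreplicated phases over a
  deterministic grid first and then applies only small, capped
  corrections, keeping the best build it has seen;
* both regions leave their forks through straight perpendicular stubs,
  so the two arcs do not crowd the junction area.

Residuals are accepted below 0.15 turns per region charge and the
build aborts above 0.3 (infeasible packing also aborts).  The in-vivo
stage configurations `ri_config_early()` (1491/509 bp, charges
$-12/0/+2$) and `ri_config_late()` (504/1506 bp, $-2/0/+12$) carry
stress confined per region, matching a pre-equilibrium in which fork
rotation is restricted; the late-stage parental length is 2010 bp
exactly as the stage sizes dictate.

## The Monte Carlo relaxer

`mc_relax()` emulates the redistribution of superhelical stress after
deproteinization.  Moves are crankshaft rotations of 4–50-site
sub-chains about the chord through their end sites, with angles uniform
in $\pm 0.5$ rad; with `forks_free = TRUE`, fork-twist moves rotate a
terminal block about the local duplex axis, transferring torsion across
a fork.  There is no energy function — acceptance is purely
constraint-based, because the goal is topology-preserving mixing, not
thermodynamics.

The constraints are the interesting part.  Strand passage is forbidden
by a hard-core guard on strand points, checked at interpolated rotation
angles (at most 0.6 nm of displacement between checks, so a block
cannot tunnel through a chain).  The guard is graded: 1.7 nm between
distal strands (enforcing the 2 nm duplex-axis clearance), 1.2 nm
between the paired strands of one duplex within a 6 bp window (their
native separation is at least 1.5 nm, and a full-size core there would
reject the native helix itself), and 0.9 nm inside the congested fork
junction zones.  The long fork-junction chords are subdivided by derived
guard points that move with the chord and are checked against the
moving block and against each other — junction chords deform rather than
move rigidly, and two chords at the same fork could otherwise slide
through one another.  A bond guard caps the deviation of every backbone
bond from its starting length at 1 nm.  Under these guards the total
linking number of a closed molecule, and the total linking difference of
an intermediate, are conserved to numerical precision over $10^5$ moves,
while per-region charges redistribute only when the forks are free.
Pseudo-time is the cumulative move count; it has no mapping to physical
time.

## Collision events

Juxtapositions are detected on reduced midpoint curves: one midpoint per
base pair, then every 10th point (about one helical turn).  A collision
is a pair of reduced segments at most 10 nm apart (the span of a protein
bridging two DNA sites) that is a strict local minimum of the
segment-distance landscape against its eight index neighbours, with ties
broken toward the lexicographically smallest pair.  Contour-near pairs
are excluded within a 147 bp window (one 50 nm persistence length),
measured through the fork junctions where the path crosses regions.

Chirality and topological sign follow the crossing-geometry criteria:
projecting both tangents onto the plane perpendicular to the
closest-approach connector, the node is left-handed when the underlying
segment's line rotates counter-clockwise by less than 90° onto the
overlying one, right-handed otherwise; the sign is negative when the
overpassing tangent aligns with the underpassed one by a (minimal)
clockwise rotation and positive otherwise.  Both are invariant under
swapping the two points and flip under mirror imaging, and the
constructions recover the canonical correspondences: negatively
supercoiled fixtures collide right-handed with negative sign, their
mirror images left-handed positive.

Types follow the region labels: 1 within the unreplicated region, 2
across regions, 3 within the precatenanes (braid-coordinate separation
at most 100 bp, about ten reduced points), 4 within the plectonemes of
precatenanes.  The 100 bp window is this package's operational
separation of "within the braid" from "braid folded onto itself".

## Matrix diagnostics

`diagonal_band_profile()` mirrors the visual reading of contribution
matrices: the main diagonal band (default half-width 15 bp) carries the
positive charge of the double helix, and plectonemic forms appear as
off-band charge.  Counting "secondary diagonals" by 2D connected
components is unstable — breathing fragments an arm's ridge and faint
inter-arm contacts bridge them — so the package projects off-band charge
onto the cyclic anti-diagonal coordinate: every contact of one arm
shares the same contour midpoint, making arms cleanly separated 1D
peaks.  Runs of the smoothed profile above 0.005 turns/bp with at least
0.3 turns of total charge are reported as secondary bands; a relaxed
circle reports none, an n-branch plectoneme reports n.

## Problem sizes and what the tests show

The validation suite runs at the canonical molecule sizes (2 kb circles
and intermediates, n × n contribution matrices with n = 2000–2010)
for the topology checks, and smaller 210 bp circles for the
Calugareanu–White ensemble checks where twenty independent relaxations
are needed.  Monte Carlo checks use $10^5$ moves ($4 \times 10^5$ for
the fork-transfer demonstration).  The oracle for the segment kernel is
nested adaptive quadrature of the Gauss integrand over 1000 random
well-separated segment pairs.

The generator emulates the statistical structure the analysis assumes —
prescribed charge partitions, interwound geometry, braid interwinding —
but not the thermodynamics of real DNA: there is no bending or
torsional energy, no sequence dependence, no salt, and equilibrium
ensembles of deproteinized molecules are out of reach of the
constraint-only sampler.  Passing tests therefore demonstrate that the
measurement machinery is exact and self-consistent and that the
generator realizes what it prescribes, not that any particular
equilibrium partition of stress would be observed for real molecules.

## Known limitations

* The fork junction is represented by bare chords between the last
  base pairs of adjacent regions; real forks have specific geometry
  that the guards only approximate with graded cores.
* `q_wrap` prescriptions are realized by winding the braid around a
  plain unreplicated arc; wrapping around a plectonemic unreplicated
  region is not supported.
* Open-region writhe depends on the fork-to-fork closure convention
  (a straight virtual segment), as any open-curve writhe must.
* Knot detection and type classification are out of scope; the Monte
  Carlo guard prevents knotting from arising but nothing verifies
  knot types of externally supplied conformations.
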