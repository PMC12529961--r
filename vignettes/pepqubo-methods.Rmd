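---
title: "Coarse-grained QUBO design of peptide binders: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained QUBO design of peptide binders: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepqubo)
```

## The problem

Designing a peptide that binds a given protein pocket means searching two
spaces at once: the chemical space of sequences (20^L for L residues) and the
conformational space of binding poses. `pepqubo` tackles the joint problem at
a coarse-grained level of resolution: one bead per residue, poses restricted
to self-avoiding walks on a cubic lattice laid through the pocket, and a
knowledge-based contact potential. The whole design problem is then written
as a Quadratic Unconstrained Binary Optimization (QUBO) — equivalently a
generalized Ising Hamiltonian — whose low-energy states are simultaneously a
pose *and* a sequence. That encoding is what makes the problem addressable
by annealing hardware; here it is solved by exact enumeration or classical
annealing, with a pluggable contract for external backends.

The selectivity principle is central: the optimal binder minimizes its
energy in the *target* pocket **relative to its average interaction with
generic protein surfaces**. Without that subtraction the optimizer simply
maximizes stickiness, which for any contact potential of this family means
"all hydrophobic". The package implements the subtraction as a mean-field
offset (below) and exposes its ablation as a switch, because the contrast
between the two is itself a documented behavior of the method.

## Energy model

The pairwise potential is built from a 20x20 residue contact-energy table
$e_{ij}$ (RT units), rescaled to Lennard-Jones well depths

$$\varepsilon_{ij} = \lambda\,(e_{ij} - e_0),\qquad
  \lambda = 0.159,\; e_0 = -2.27\,k_BT,$$

with interaction ranges $\sigma_{ij} = (\sigma_i + \sigma_j)/2$ from
per-residue vdW diameters. A pair at distance $r$ interacts through an LJ
form keyed on the sign of $\varepsilon_{ij}$: attractive pairs
($\varepsilon < 0$) follow the plain LJ curve with minimum
$-|\varepsilon_{ij}|$ at $r^0_{ij} = 2^{1/6}\sigma_{ij}$; repulsive pairs
follow a shifted LJ below $r^0$ and a mirrored tail above it, continuous at
$r^0$ with value $\varepsilon_{ij}$. All interactions are truncated to
exactly zero at 8.5 Å — the customary C$\alpha$ contact-map cutoff — without
energy shifting; the resulting discontinuity of magnitude $|u(8.5)|$ is tiny
and accepted. Energies are carried in $k_BT$ throughout; no temperature
conversion is ever applied.

The packaged $e_{ij}$, $\sigma_i$ and surface frequencies $f_j$ are
plain-text files under `inst/extdata/`, transcriptions of the commonly
redistributed tables; every entry point (`mj_model()`) accepts replacement
tables with the same layout, so a curated variant can be swapped in without
touching code.

### Reduced alphabet

Quantum and classical solvers both benefit from shrinking the 20-letter
alphabet to $D$ chemical families (5–10 recommended). `fit_cluster_map()`
minimizes $L = \sum_{ij} (e_{ij} - e'_{a(i)a(j)})^2$ over assignments
$a(i)\in\{1..D\}$, where $e'$ is the block-mean matrix. The normalizer
counts contributing ordered pairs, so singleton families reproduce $e$
exactly — the identity that anchors the tests. Small spaces are searched
exhaustively (restricted-growth enumeration, unique up to relabeling);
larger ones by seeded multi-restart annealing over single-type moves with a
greedy polish. Family labels are canonicalized by ascending self-energy, so
family `F1` is always the stickiest (hydrophobic-like) group and outputs are
reproducible across runs. Family diameters average; family frequencies
aggregate by *summation*, keeping them a probability distribution for the
mean-field offset (a mean would break normalization). At $D = 2$ the packaged table splits
{C, M, F, I, L, V, W, Y} from the rest — the classic HP bipartition, with
the known ambiguous residues (W, Y, H, P) allowed on either side.

### Mean-field offset

The average interaction of a sequence with generic protein surfaces is
estimated per residue as

$$E_0^{(k)} = \bar N_c \sum_j f_j\, \varepsilon_{kj},$$

with $f_j$ the surface composition and $\bar N_c$ the mean number of
receptor beads within the cutoff per grid site (computed from the actual
grid by default, overridable). Subtracting $E_0^{(k)}$ from the pocket field
penalizes residues that would bind *any* surface — in practice it taxes
hydrophobics by $\sim \bar N_c \cdot 0.3\,k_BT$ each — and is exactly what
makes designed sequences amphiphilic rather than uniformly greasy.

## Pocket lattice

`build_grid()` lays a cubic lattice of spacing 3.8 Å (the peptide-bond
length) with origin at the centroid of a reference region (for example the
experimentally bound peptide's C$\alpha$ trace), axes aligned with the input
frame — there is no canonical orientation rule for such a grid, so a
deterministic choice is made and documented rather than searched over. Candidate points are kept when within
7.6 Å of the reference region and farther than 1.5 Å from every receptor
bead; edges join axis-aligned nearest neighbors (6-connectivity). Anchors
$s, t$ are the grid sites nearest the two endpoint coordinates, ties going
to the lower site index.

One genuinely consequential geometric fact: 3.8 Å is far inside the
repulsive core of residue pairs whose diameters are ~6 Å, so grid sites
within ~2 lattice units of the receptor carry strongly positive fields, and
non-bonded residues on adjacent sites are heavily penalized (self-avoidance
is thereby also energetic, not only topological). The optimizer simply
avoids such sites; they are retained under the default radii for fidelity to
the stated placement rule.

## The Hamiltonian

Binary variables: $q_i^{(k)}$ (site $i$ holds family $k$), $q_{ij}$ (bond
across edge $\{i,j\}$), and ancillas $q_{ij}^{(k)} = q_i^{(k)}\wedge q_{ij}$
attached to the lower-indexed endpoint of each edge. For a full
$L_x \times L_y \times L_z$ box this totals about $L_xL_yL_z\,(4D+3)$
variables (`variable_count()` reports both the exact registry size and this
estimate). The terms:

* **external**: $(E_i^{(k)} - E_0^{(k)})\,q_i^{(k)}$, the precomputed pocket
  field minus the mean-field offset (`ablate_E0` drops the offset);
* **intrachain**: $u_{kl}(r_{ij})\,q_i^{(k)}q_j^{(l)}$ over unordered site
  pairs within the cutoff; for lattice edges the ancilla subtracts the same
  coupling, so covalently bonded neighbors do not also interact non-bonded;
* **ancilla**: the standard AND penalty
  $A\,(3q_{ij}^{(k)} + q_i^{(k)}q_{ij} - 2q_i^{(k)}q_{ij}^{(k)}
  - 2q_{ij}q_{ij}^{(k)})$, zero exactly on consistent assignments;
* **occupancy**: $A\,q_i^{(k)}q_i^{(l)}$ for $k<l$ — at most one residue per
  site;
* **path**: terminals hold exactly one residue and one bond, internal
  occupied sites exactly two bonds (squared linear forms expanded with
  $q^2 = q$); its zero set, verified exhaustively on small grids, is exactly
  the valid $s$–$t$ chains (plus detached rings on geometries large enough
  to host them — the decoder removes and reports those);
* **chain length**: $w\,(L_0 - \sum q_{ij})^2$. With
  $w = A/(L_0^2 p^2)$ the admissible lengths are $L_0(1\pm p)$; $w = A$
  pins the length.

`to_ising()` applies $\sigma = 2q - 1$, giving $h$, $J$ and an offset with
bitwise-identical energies — asserted on every bitstring of every small test
model.

### Choosing the penalty A

Hard constraints must dominate the soft physics. The configured defaults
($A = 20$, $w = A$; toy scale $A = 10$) are adequate when couplings are
$O(1)$. With the full MJ-scale potential,
however, steric couplings at one lattice spacing reach hundreds of $k_BT$,
and a penalty proportional to the *total* soft mass (the safest bound)
freezes every annealer. `A = "auto"` therefore uses 1.25 x the largest
per-variable incident soft mass: a single flip out of a feasible state can
gain at most the soft mass incident to that variable, so every single
constraint violation costs more than it can buy. Exhaustive checks on all
oracle-scale instances confirm ground-state feasibility under this rule; it
is a practical dominance bound, not a theorem for arbitrary multi-flip
excursions, which is why the oracle tests re-verify feasibility explicitly.

## Solvers

Three built-ins behind one contract (`solve_qubo()` also accepts any
function returning energies + states, the hook for external branch-and-bound
or annealing services):

* `brute_force()` — Gray-code enumeration up to 22 variables (configurable),
  returning the exact ground energy and *all* attaining states. Candidates
  are re-evaluated non-incrementally so floating-point drift cannot leak
  into the reported optimum. This is the oracle every other solver is
  measured against.
* `simulated_annealing()` — single-flip Metropolis with a geometric
  inverse-temperature schedule auto-scaled from the coefficient magnitudes,
  fixed sweep order, fully seeded. It matches the oracle reliably on small
  instances (the acceptance criterion demands 95/100 on the line instance;
  it achieves 100/100). At design scale it essentially never produces a
  feasible chain: the temperature window in which the $A$-scale constraint
  landscape is mobile closes long before the $k_BT$-scale physics can be
  explored. That failure mode is inherent to single-flip annealing on
  path-constraint encodings, and is why problems of this shape are normally
  handed to branch-and-bound or hybrid annealing machinery.
* `chain_enumeration()` — the consequence of that observation: enumerate all
  self-avoiding $s$–$t$ paths in the admissible length window (DFS pruned by
  graph distance and lattice parity), encode every family assignment, and
  score it through the assembled QUBO itself. No parallel physics, exact
  over the feasible sector, deterministic; viable while the path count is
  modest (tens of thousands of configurations in milliseconds). The design
  behavior tests run on this backend so that statements about "the ground
  state" are exact rather than stochastic.

`spectrum_stats()` summarizes repeated runs (lowest/mean minimum-energy
value, distinct solutions) — the solution-diversity lens used to compare
optimizers.

## Decoding and refinement

`decode()` reconstructs the chain by walking the bond graph from $s$:
branching, occupancy violations, ancilla inconsistencies, or failure to
reach $t$ invalidate the decode (with a diagnostic, never an exception);
bonded components disjoint from the chain are reported and removed as rings,
a known artifact of the encoding family. `chain_energy()` recomputes the
physical energy from the definitions and must equal the QUBO energy on every
valid chain — the invariant at the heart of the oracle tests.

Stage 2 freezes the geometry and re-optimizes the sequence over all 20
residues: one-hot variables per position, pocket field minus offset as
linear terms, non-bonded couplings between non-consecutive positions, and an
exactly-one penalty (the geometry is frozen, so every position must carry a
residue — at-most-one would allow holes). It is solved exactly for up to 6
positions, and by labeling-space annealing (residue swaps, one-hot preserved
by construction) beyond; bit-level annealing on the one-hot QUBO is retained
for completeness but suffers the same freezing pathology as above, and the
labeling-space route is checked against a 20^3 brute-force oracle in the
tests.

## Validation statistics

Pose side: a contact is a peptide-position/receptor-residue pair of
C$\alpha$ beads within 8.5 Å (configurable toward docking conventions);
$f_{nat}$ is the fraction of a reference complex's contacts reproduced by a
pose; poses rank-listed by an external docking tool are labelled positive
when $f_{nat} > 0.5$ *strictly* (the CAPRI-style rule — exactly 0.5 is
negative), and the ranking is scored by the area under the precision–recall
curve using the average-precision step rule: mean over positives of the
precision at their rank. That rule is deterministic, interpolation-free, and
invariant to trailing negatives — all asserted. Sequence side: designed and
reference sets of equal-length sequences are mapped through a cluster map
and compared per position; `top2_overlap()` counts positions where the
reference's modal family is among the designed set's two most frequent
families, ties broken by (-frequency, family index).

Docking itself is out of scope: the package emits FASTA + receptor + grid
provenance for the docking handoff and consumes ranked pose lists (CSV
manifest of PDB files).

## The synthetic world

`make_groove_receptor()` builds the test pocket: a dense hydrophobic floor
(bead spacing 1.9 Å, so several beads fall inside the attractive shell of
each corridor site) 7.6 Å — essentially the LJ minimum distance for ~6 Å
beads — below a reference corridor, flanked by sparse polar rim rows at
contact range of the top sites. Bead types are sampled per seed from
hydrophobic/polar pools; ground-truth "core"/"rim" labels ride along.
What it emulates: a pocket whose deep sites reward hydrophobics even after
the mean-field tax, and whose exposed sites do not. What it does *not*
emulate: real pocket geometry, side-chain packing, backbone chemistry,
solvent structure, or receptor flexibility. A green design test therefore
establishes that the encoding, offset, and solvers interact as the model
says they should — burial of the hydrophobic family, longer chains as the
length constraint relaxes through $w \in \{A, A/4, A/16\}$, greasier
sequences when the offset is ablated — not that any particular real peptide
would bind.

The behavior tests use include/exclude radii of 3.9/4.5 Å rather than the
7.6/1.5 defaults: the tighter exclusion removes the always-repulsive
sterically clashed sites and keeps the instance inside the exact solver's
reach. The defaults remain the defaults everywhere.

## Numerical choices and degenerate inputs

* Distances are Å, energies $k_BT$; site indices 0-based nowhere — R is
  1-based throughout; emitted PDB numbers residues from 1.
* Cutoff semantics: interaction support is $r < 8.5$; $r \ge 8.5$ is exactly
  zero (and $\bar N_c$ counts beads with $r <$ cutoff, consistently).
* Ties: anchor selection and top-2 family ranking break ties to the lower
  index; cluster families canonicalize by ascending self-energy.
* Degenerate inputs error early with instructions (empty grid → widen radii;
  identical anchors; empty native contact set; zero positives in a
  precision–recall list).
* Brute force refuses above its variable bound rather than running forever;
  chain enumeration caps the path count.
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state on exit.

## Known limitations

Single-flip SA is not a practical stage-1 solver at design scale (see
above); the exact enumerator covers desk-scale pockets, and real-scale
problems are the domain of the pluggable external backends. The packaged
parameter tables are transcriptions — verify against primary sources before
scientific use. No rotamers, no receptor flexibility, no solvent beyond
what the contact statistics imply, no docking integration beyond file
handoff, and no absolute binding free energies anywhere — the
precision–recall machinery exists precisely because those numbers are not
trustworthy at this resolution.
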