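---
title: "Rigidity- and conservation-based detection of critical protein residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigidity- and conservation-based detection of critical protein residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critres)
```

## Scope and model

`critres` answers one question about every residue of a protein: is it
*critical*, in the sense that substituting it would compromise the
protein's stability or function? Two signals with very different failure
modes are combined. Rigidity analysis looks for residues whose side-chain
contacts hold the fold's rigid core together; it is blind to surface
residues that matter for binding rather than stability. The conservation
score looks for residues under evolutionary constraint; it flags roughly
half of a typical chain and cannot say *why* a residue is conserved. Their
union is a deliberately permissive detector whose agreement structure — and
disagreement structure — is itself the object of interest.

### The mechanical model

Atoms and their stabilizing interactions are abstracted into a body-bar-hinge
framework:

* **Bodies.** Every atom with two or more covalent bonds anchors a body
  consisting of the atom and all bonded neighbours; bond lengths plus the
  angle constraints around the central atom leave no internal degree of
  freedom in such a group. Two bodies whose anchors are bonded share
  exactly the two bonded atoms. Terminal atoms are absorbed into the
  neighbour's body; an isolated diatomic is one body.
* **Hinges and bars.** A rotatable covalent bond between two anchored
  bodies leaves exactly one relative degree of freedom, the torsion; it is
  a hinge and contributes 5 bars to the multigraph. Locked bonds —
  peptide bonds, aromatic/planar ring bonds (His, Phe, Tyr, Trp, Pro) and
  template double bonds (carbonyl, carboxylate, amide, guanidinium) —
  contribute 6 bars. A hydrogen bond contributes `hbond_bars` (default 5,
  hinge-like) and a hydrophobic tether `hydrophobic_bars` (default 2).
  Both multiplicities are configuration keys because either reading of
  "hinges or bars" is defensible; the defaults follow the FIRST/KINARI
  lineage of rigidity tools.
* **Cap at six.** More than 6 parallel bars between one body pair are
  provably dependent in the (6,6) matroid; the excess is trimmed at graph
  construction and recorded, never silently discarded.

### Interaction detection

The detectors are geometric, chosen to work on legacy PDB entries without
hydrogens:

| parameter | default | meaning |
|---|---|---|
| `covalent_tolerance` | 0.4 Å | slack over the covalent radius sum |
| `hbond_max_da` | 3.5 Å | donor-acceptor distance cutoff |
| `hbond_min_angle` | 110° | D-H…A angle, applied only when H present |
| `min_seq_sep` | 2 | minimum donor/acceptor residue separation |
| `hydrophobic_slack` | 0.25 Å | slack over the van der Waals radius sum |
| `sasa_probe`, `sasa_points` | 1.4 Å, 960 | Shrake-Rupley probe and sphere sampling |

The sequence-separation rule deserves a note: backbone O(i)…N(i+1) pairs sit
near 2.2 Å in *any* peptide purely through covalent geometry, so without a
minimum separation every chain would be "hydrogen bonded" to itself at each
link. Donors and acceptors are classified from residue templates (backbone N
except proline, backbone O, and the usual side-chain N/O/S sites); for
unknown residue types any N is a donor and any O an acceptor, which keeps
synthetic test structures first-class inputs.

Solvent-accessible surface area uses the Shrake-Rupley construction with a
deterministic Fibonacci sphere lattice. To make the result exactly invariant
under rigid motions of the input, coordinates are first expressed in the
molecule's principal-axis frame with axis signs fixed by the skewness of the
projected coordinate — a convention intrinsic to the molecule, so rotating
or translating the file cannot change any reported area by more than
floating-point noise.

### The (6,6) pebble game

Generic rigidity of the multigraph is decided combinatorially. Every node
starts with 6 pebbles; a bar is accepted (independent) iff 7 pebbles can be
gathered on its endpoints, gathering being depth-first searches along the
directed graph with path reversal; accepting a bar consumes one pebble. The
internal degree-of-freedom count is `6n − 6 − independent` bars.

Rigid components are maintained incrementally. After each accepted bar the
game re-tests its endpoints; when 7 pebbles can no longer be gathered, the
maximal *tight* (spanned) node set containing the endpoints is, at that
moment, exactly `{u, v}` plus every pebble-free node from which no free
pebble outside `{u, v}` is reachable — computed by one reverse search from
all pebbled nodes. Because the union of two tight sets sharing a node is
tight in the (6,6) count, maximal tight sets partition the nodes and a
union-find suffices. (This is also why rigid *clusters of bodies* never
overlap, while the atom-level clusters familiar from visualizers do overlap:
neighbouring bodies share the two atoms of their common bond.)

Every rigidity claim in the package is cross-checked against an independent
oracle: each bar is realised as a generic distance constraint between random
points on its two bodies, giving one row of a rigidity matrix over 6-vector
velocity screws; the nullity minus the 6 trivial motions is the degree of
freedom count, and two bodies are mutually rigid iff their screws agree in
every nullspace vector. The construction is repeated at three seeds and the
maximal-rank outcome kept, which guards against accidental degeneracies of a
single random placement. The test suite demands *exact* agreement of both
the degree-of-freedom count and the component partition on hundreds of
random multigraphs.

### In-silico mutation

Mutation is constraint removal, not remodelling: a glycine target removes
every hydrogen bond and hydrophobic tether incident to any side-chain atom
of the residue; an alanine target removes those incident to atoms beyond
Cβ, keeping the Cβ's own contacts. Covalent bonds and atoms stay in place,
so the body topology is preserved and only the constraint set shrinks —
which is also why the scan is residue-independent and embarrassingly
order-invariant. The score is the percentage decrease of the largest rigid
body measured in **atoms** (the atom union of the largest component's
bodies), with the raw atom-count drop reported alongside. The default
criticality threshold `tau_r = 0` with a strict inequality means any
nonzero LRB change counts, matching how the benchmark panels treat the
column. Removing constraints can never grow a rigid cluster, so
`lrb_mut <= lrb_wt` is an invariant, not an observation.

### Conservation score

Evolutionary Trace ranks are read from either the ET-server dialect
(`%`-comments, whitespace columns) or a plain two-column TSV. Per chain,

$$c_i = \frac{\mu - \mathrm{rank}_i}{\sigma}$$

with the *population* standard deviation by default (the z-score
convention; the sample convention is a configuration switch — the two
differ by a factor `sqrt(n/(n-1))`, which cannot change any flag because
the threshold is zero). The score is affinely invariant in the ranks, has
zero mean and unit variance by construction, and `c_i = 0` is classified
non-critical: "above average" is read strictly, and the threshold is a
configuration key because the boundary demonstrably matters in practice.
All-equal ranks make criticality undefined and raise an error rather than
a silent all-negative profile.

### Combination and evaluation

The combined detector is the OR of the two flags. Verdicts fall in the 2×2
of the flags (`both_critical`, `both_noncritical`, `cons_only`,
`rig_only`); against experimental data a mutation is critical when its ΔΔG
lies in the destabilizing window `lo <= ddG < hi`, default (−10, 0)
kcal/mol with the upper bound exclusive so a stabilizing or neutral
mutation is a true negative. Per-protein summaries report the seven
percentages rounded half-up to one decimal — half-up, not banker's,
because that is the convention that reproduces the published digits — and
cohort summaries are unweighted means over proteins. The weighted or
ranked combination of the two continuous scores is deliberately out of
scope; the raw `(c_i, pct_decrease)` pairs are carried through the verdict
table for downstream use.

## The synthetic data generators

The package is buildable and testable without any download; the generators
are first-class, tested code.

`make_toy_structure()` emits chemically plausible polypeptides (ideal bond
lengths and angles, NeRF internal-coordinate construction) in three
geometries. `extended` is a flat strand with no non-covalent contacts —
the negative control. `helix_like` walks α-helical torsions (φ = −57°,
ψ = −47°) and receives its natural O(i)…N(i+4) ladder plus genuine Cβ
packing contacts. `two_domain_hinge` is the workhorse: an antiparallel
two-strand hairpin joined by a two-glycine turn, carrying an intrinsic
backbone hydrogen-bond ladder, with `n_tethers` hydrophobic bridges planted
from a single donor residue's side chain to partner residues on the other
strand. Three design points matter:

* The strand register, the turn arc and the tether pocket are found by
  small deterministic geometric searches (register scan maximising ladder
  rungs, a Bézier-arc walk for the turn, torsion sweeps with
  backbone-clearance checks) rather than fixed constants, so the
  construction stays clean across sizes.
* Planted tethers attach at the partners' **Cβ** but at the donor's
  **CG/CD** atoms. Under the alanine rule a partner mutation therefore
  removes nothing while the donor mutation severs every bridge — giving
  the sharp property the tests rely on: exactly one residue with a
  positive LRB decrease.
* Any other residue whose side chain could reach a planted atom is emitted
  as glycine, eliminating stray contacts by construction.

The seed only re-poses the molecule rigidly; topology is seed-invariant.
What the toys do *not* emulate: real packing density (a real core has far
more tethers), hydrogens, side-chain rotamer diversity, and the long-range
hydrogen-bond networks of real folds. Passing tests on toys therefore
validate the *machinery* — detectors, model construction, pebble game,
mutation bookkeeping — not the biological error rate of the method, which
is what the encoded benchmark panels speak to.

`random_body_bar_graph()` (Erdős–Rényi pairs, uniform multiplicities) is
the stress surface for the pebble game; `synthetic_rank_file()` plants a
conserved subset (ranks 1–5) against a well-separated background
(95–105), so the planted set is provably the recovered set;
`synthetic_ddg_table()` fills the evaluation path. The published benchmark
panels ship digit-for-digit as `benchmark_tables()`, guarded by frozen
row/column checksums in the tests.

## Numerical choices and degenerate inputs

* Oracle tolerances: rank from singular values at `1e-10` relative;
  screw-equality at `1e-8` on unit-norm nullspace vectors. Generic random
  placements put non-rigid pairs many orders of magnitude above this.
* Ties in the largest-rigid-body choice go to the component whose smallest
  body id is smallest; pebble searches and union-find are deterministic,
  so equal inputs give byte-identical outputs.
* Altloc handling keeps the highest-occupancy copy (ties → altloc "A");
  multi-model files read one model, by default the first; waters and
  HETATM groups are dropped unless requested. Unknown residue names warn
  and fall back to permissive donor/acceptor typing and hydrophobicity
  "none". Unknown elements in the covalent detector are a hard error
  naming the element.
* One published hydrophobicity column is internally inconsistent (the same
  residue type appears with two labels); the package's
  `hydrophobicity_class()` uses a fixed three-bin map (very: V I L F M W C;
  slight: A G Y) and the encoded table keeps the printed labels verbatim.

## Problem sizes

The default test run analyses toy structures of 3–14 residues, validates
the pebble game against the dense oracle on several hundred multigraphs of
up to 10 bodies, and recomputes all combination-stage statistics from the
encoded 42-protein cohort; the acceptance script repeats the oracle
comparison on 200 seeded graphs. These sizes exercise every code path —
including redundancy, overlap trimming and component merging — while the
pure-R pebble game comfortably scales to full-size single-domain proteins
(a few thousand bodies) for interactive use.

## Known limitations

* Energy-based hydrogen-bond scoring (Mayo-style) is out of scope; the
  geometric criterion overcounts weak bonds on unprotonated inputs.
* Binding-partner counts are accepted only as a pre-supplied column; no
  interface database is queried.
* The conservation side consumes rank files; running the Evolutionary
  Trace algorithm itself (homolog collection, tree construction) is not
  reimplemented, and published per-protein percentages that depend on the
  original homolog sets are treated as directional references only.
* The rigidity score is a stability proxy, not a ΔΔG predictor: a large
  buried residue with few modelled contacts can score zero while being
  experimentally critical — exactly the complementarity that motivates
  combining the two methods.
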