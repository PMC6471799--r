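---
title: "Tripeptide-database path search: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tripeptide-database path search: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripath)
```

# The model

`tripath` treats a protein backbone under the rigid-geometry
simplification: bond lengths, bond angles and the peptide torsion ω are
fixed, so a chain of n residues is determined by its φ/ψ dihedrals.
The chain is decomposed into n − 2 overlapping tripeptide state variables;
variable i covers residues i..i+2 and consecutive variables share two
residues, hence four dihedrals. The domain of a variable is the finite set
of conformations recorded for that three-residue sequence — in production
a library extracted from experimentally determined structures, in tests a
synthetic library with known geometry. A full-chain state assigns one
conformation index to every variable; residue j's angles are taken from
the variable in which j is central (ends from the terminal variables),
because for values drawn from different source structures the overlapping
copies of a shared angle agree only within a tolerance and one
representative must be chosen. The central-residue rule matches the
transition semantics: an elementary transition changes one variable and
mainly its central residue.

Distances between conformations are angular RMSDs with all differences
wrapped to the shorter arc of the circle. The raw difference of two
dihedrals is discontinuous at ±π and breaks the metric on the torus, so
wrapping is applied even though it costs a little sharpness near π; this
is the usual convention for dihedral statistics. The central distance
(residue 2 only) is normalised by the number of angles it uses (two), so
it is an RMSD in its own right; the alternative one-sixth normalisation is
available as `central_norm = "one-sixth"` for users who want the two
metrics on a common scale.

# Library structure: graphs, θ tuning, density

Each library becomes an adjacency graph: edge (v, v′) iff
d_c(v, v′) < θ and d(v, v′) < θ + ξ. ξ defaults to 0.35 rad and ζ (below)
to 0.2 rad. θ is tuned per tripeptide as the smallest value on a 0.05-rad
grid for which the graph has a single connected component: a fully
connected graph would impose no transition structure, a disconnected one
would make conformations unreachable, and the smallest connecting
threshold is the sharpest operationalisation of "connected with moderate
edge connectivity" that is decidable from the data alone. A target-degree
criterion could be substituted without changing any contract. When the
tuned θ is not above ζ (tightly clustered degenerate libraries) it is
lifted to the first grid value above ζ so the density remains defined.

The vertex density ρ(v) = 1 + #{graph neighbours of v within d < ζ}
requires both graph adjacency and the distance bound, implementing the
conjunction as stated; ρ is a population proxy for the conformation's
probability of existence (dense regions of the library are, by a Boltzmann
argument, the energetically favourable ones).

# Feasibility and the search

An elementary transition of variable i to an adjacent value v′ is feasible
iff (i) the new central angles agree with the *current* values of the two
neighbouring variables within ε — four wrapped inequalities; terminal
variables check only their existing neighbour — and (ii) the reconstructed
chain is collision-free. Checking against the neighbours' adjacent
(changeable) values as well would allow multi-variable transitions; that
richer semantics is deliberately not implemented.

The search is depth-first with chronological backtracking over complete
states, with a visited set over full assignments (canonical index-vector
hash) so no state is expanded twice. At every state the candidate set E is
the union over all variables of the graph neighbours of the current
values, ordered by

cost(v, v′) = d(v, v′) + w1·h(v′) + w2/ρ(v′),  w1 = w2 = 1,

where h is the per-variable shortest-path distance (edge weights d) to the
goal value, precomputed by Dijkstra when the problem is built. h is
admissible: the graph search relaxes the overlap and collision
constraints, so no feasible path can spend less d-length in that variable.
Vertices that cannot reach the goal value get h = ∞, which ranks them last
rather than erroring, so the search can still progress through other
variables.

Two realisation choices deserve a note. First, the candidate set: a
strictly incremental E that exposes a single variable's transitions at a
time (ascending index) degenerates in practice — the first variable's
moves monopolise the expansion and the search oscillates — so E is the
full union with the heuristic comparing candidates across variables;
feasibility is evaluated lazily in cost order at expansion time, which
explores exactly the same tree while running the expensive steric test
only on candidates actually tried. Second, the ε relaxation: a global
counter of consecutive infeasible candidates triggers ε := 0.7 rad once it
reaches f = 5; the current state's candidate queue is then rebuilt so that
strictly-rejected candidates are retried under the relaxed tolerance, and
ε resets to 0.35 after the next successful transition. Whether the counter
should be global or per-branch is not determined by the algorithm's
statement; global is the simplest reading and is the implemented default.

The search is sound — `validate_path()` independently replays adjacency,
overlap and collision checks for every step at the recorded ε — and, at
fixed ε (f = ∞), complete with respect to the adjacency graphs: the test
suite checks found ⇔ exists against an exhaustive product-space BFS on
fixtures of ≤ a few hundred states. The cost function contains no
accumulated-cost term, so the greedy expansion can wander on plateaus of
cheap lateral moves before closing in on the goal; returned paths are
correspondingly much longer than the shortest feasible path (the
states-expanded to path-steps ratio is a useful diagnostic, reported in
`$diagnostics`). The recursion limit (default 10⁶) produces a `"limit"`
status distinct from a proven `"no_path"`.

# Collision model

Atoms are backbone N, CA, C, O plus one side-chain pseudo-atom per residue
centred at the β-carbon (a virtual site for glycine). Backbone radii are
the Bondi van der Waals values (N 1.55, C 1.70, O 1.52 Å); pseudo-atom
radii are a per-residue single-sphere table shipped as plain text
(`inst/extdata/pseudo_atom_radii.tsv`) and swappable via
`collision_model()` — the table's values are size-plausible effective
radii for the one-sphere side-chain representation, and any published set
can be substituted without code changes. A pair collides when its distance
is below 65% of the radii sum. Pairs within three covalent bonds (1-2,
1-3, 1-4; the pseudo-atom bonded to its CA) are exempt — the minimal
exclusion under which ideal-geometry chains are self-consistent. The
detector offers a cell linked-list broad phase (cell edge = the largest
pair threshold) and a vectorised all-pairs scan; they agree exactly, and
`method = "auto"` picks the cell list above 150 atoms where its
bookkeeping pays off. Chain topology, radii and exclusion masks are cached
per sequence.

# Geometry

Internal-to-Cartesian reconstruction uses sequential natural-extension
(NeRF) placement with Engh–Huber-style constants (N–CA 1.458, CA–C 1.525,
C–N 1.329, C–O 1.231, CA–CB 1.521 Å; N-CA-C 111.2°, CA-C-N 116.2°,
C-N-CA 121.7°), ω fixed at π: cis peptides are not generated, although
extraction records keep an observed cis/trans label per peptide bond for
provenance. The carbonyl oxygen is placed trans to the next amide
nitrogen; the β-carbon by a fixed improper torsion (−122.6°) selecting the
L-configuration side. Torsions are computed with the standard atan2
construction under the IUPAC sign convention and wrapped to (−π, π];
terminal φ1/ψn are undefined and reported as `NA`, never fabricated. The
round trip reconstruct → measure recovers interior dihedrals to well below
10⁻⁶ rad over thousands of random chains and the geometry constants to
numerical precision.

# Extraction conventions

Structure files are parsed with bio3d. First model only; the
highest-occupancy altloc wins (ties favour "A"); waters and hetero
residues are skipped; a chain break is declared when a backbone atom is
missing or the peptide C–N distance exceeds 2.0 Å; modified residues map
to their parent type (MSE→M, SEC→C, PYL→K), otherwise the window is
skipped. These are curation conventions, not constraints of the method. A
window yields a record only when all six of its dihedrals are defined:
since φ of a chain's first residue and ψ of its last do not exist, an
isolated unbroken chain of length L has L − 2 windows of which L − 4 are
complete. Exact duplicate source windows are stored once; redundancy
control across structures (sequence/structure non-redundancy of the input
set) is the user's responsibility.

# Synthetic data: what it emulates and what it does not

`generate_synthetic_database()` draws per-residue (φ, ψ) from mixtures of
wrapped-normal basins at canonical Ramachandran centres (α −1.1/−0.8,
β −2.1/2.3, PPII −1.3/2.6 rad). Wrapped-normal rather than von Mises
sampling keeps the generator a two-line transform of `rnorm` with the
spread directly interpretable in radians; at the spreads used (≤ 0.35 rad)
the two families are practically indistinguishable.

`generate_toy_problem()` produces seeded fixtures with an exhaustive
certificate: *corridor* (conformations strung along one angular line; the
shortest path length is known by construction as n_vars × (m − 1)),
*random* (one diffuse basin whose pairwise differences straddle ε, so
reachability genuinely varies with the seed), and *split* (two separated
clusters under a fixed θ, certifying "no path"). The certificate is a
product-space BFS using the same feasibility predicate as the search but
none of its machinery. Certified problems keep f = ∞ so that search and
oracle address the same fixed-ε transition system.

`mini_chignolin_db()` builds its library the way a real one is built: by
slicing full-chain conformations into overlapping windows. The chains are
samples along an idealised turn-formation coordinate t ∈ [0, 1] for the
Chignolin sequence (residues 5–8 interpolate from β to α-like turn
angles), with small wrapped-normal jitter for structure-to-structure
variability. Keys whose central residue moves carry the full corridor;
keys where only a flank residue moves carry a half-resolution track —
their values are never constrained by the overlap inequalities (which bind
only the mover's central residue), so a dense track would hand the greedy
search an endless supply of near-free lateral moves, while a track coarser
than 2ε in the moving angle dead-ends the neighbouring variable's march;
fully static keys hold one conformation. This fixture reproduces the
qualitative folding demonstration (extended → folded with collision
checking) at desk scale. None of the synthetic generators attempt the
multimodal, neighbour-dependent Ramachandran statistics of real
tripeptides, so passing tests certify the algorithmic machinery — metric
properties, graph construction, search soundness/completeness, collision
detection — not biological realism of any particular pathway.

# Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on synthetic
fixtures chosen for exhaustive checkability: toy search problems with 2–4
variables and ≤ 7 values each (product spaces ≤ ~2400 states, 50+ seeded
instances against the BFS oracle), 500 random chains of 5–12 residues for
the collision-detector equivalence, 1000 random chains of length ≤ 20 for
the geometry round trip, and a mini-Chignolin demonstration with 15
corridor samples per moving key. Statistics at these sizes are exact
comparisons (oracle equality), not estimates, so no power analysis is
involved; the sizes were fixed as the smallest that exercise every code
path including backtracking, relaxation and unreachable goals.

# Known limitations

- Transitions change one variable at a time; coupled multi-variable moves
  (and with them some physically plausible concerted motions) are out of
  scope.
- The greedy cost has no accumulated term: path length is not optimised,
  only feasibility, continuity, goal progress and density.
- Rigid geometry ignores bond-angle relaxation and cis peptides; clashes
  are judged by a single-sphere side chain, so packing is approximate.
- Completeness is relative to the adjacency graphs: conformations absent
  from the library, or regions pruned by θ, simply do not exist for the
  search.
- The whole-chain angular RMSD is not superposition-based Cartesian RMSD;
  values are not comparable between metrics.
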