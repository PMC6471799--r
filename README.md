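# tripath

Discrete path search for the formation of protein structural elements,
driven by a tripeptide conformation database.

## The problem

Large-amplitude conformational changes — the folding of a β-hairpin, the
assembly of a helix — are expensive to reach with atomistic molecular
dynamics. `tripath` takes a discrete, database-driven route instead. A
protein backbone under the rigid-geometry simplification (fixed bond
lengths, bond angles and trans peptide torsions ω) is fully described by
its φ/ψ dihedrals. Fragments of three consecutive residues (tripeptides)
are the smallest units that carry neighbour-dependent backbone structure,
so the package models a protein of *n* residues as a sequence of *n − 2*
overlapping state variables `x_1 … x_{n−2}`, where variable *i* covers
residues *i, i+1, i+2* and its domain `D_i` is the finite set of
conformations of that tripeptide sequence observed in experimentally
determined structures (or in a synthetic library). The package is aimed at
structural bioinformaticians who want fast, qualitative folding or
transition pathways between two conformations of a peptide or protein
region, with full control over the underlying fragment library.

## The model and the algorithm

Each tripeptide conformation is the angular vector
`v = (φ1, ψ1, φ2, ψ2, φ3, ψ3)`. Two metrics compare conformations:

- distance `d(v, v′) = sqrt( 1/6 Σ_{j=1..3} (Δφ_j² + Δψ_j²) )` — the
  angular RMSD with differences wrapped to the shorter arc, and
- central distance `d_c`, the same RMSD restricted to the central
  residue's (φ2, ψ2).

Per tripeptide key, the domain is organised as an **adjacency graph**:
edge `(v, v′)` exists iff `d_c < θ` and `d < θ + ξ` (ξ = 0.35 rad; θ is
tuned per key to the smallest grid value giving a single connected
component). Each vertex carries a density
`ρ(v) = 1 + #{v′ adjacent to v with d(v, v′) < ζ}` (ζ = 0.2 rad), a proxy
for the conformation's probability of existence.

An **elementary transition** changes one state variable to an adjacent
value; it is feasible iff the new central-residue angles agree with the
current values of the two neighbouring variables within a tolerance
ε (wrapped |Δφ| and |Δψ| < ε, ε = 0.35 rad), and the reconstructed chain —
backbone N/CA/C/O plus one side-chain pseudo-atom per residue at the
β-carbon — is collision-free (pair distance < 65% of the radii sum,
checked by a cell linked-list with 1-2/1-3/1-4 exclusions).

**HDFS** (heuristically-guided depth-first search) finds a feasible path
from a start state `s0` to a goal `sg`: candidates over all variables are
ordered by the cost

```
cost(v_i, v_i′) = d(v_i, v_i′) + w1 · h(v_i′) + w2 / ρ(v_i′)
```

where `h` is the precomputed shortest-path distance (edge weights d) to
the goal value in that variable's graph — an admissible lower bound on the
remaining per-variable path length — and `w1 = w2 = 1`. The search is
depth-first with chronological backtracking, never revisits a complete
state, and relaxes ε to 0.7 rad after `f = 5` consecutive transition
failures (reset on the next success). It is sound (every returned path
revalidates step by step) and, at fixed ε, complete with respect to the
adjacency graphs.

## Worked example

A synthetic turn-formation library for Chignolin (GYDPETGTWG) and an
extended → folded pathway:

```r
library(tripath)

spec <- decompose_sequence("GYDPETGTWG")
spec
#> Protein spec: 10 residues (GYDPETGTWG), 8 state variables

db <- index_database(mini_chignolin_db(count = 13, seed = 7))
db
#> Tripeptide conformation database
#>   keys: 8   conformations: 68
#>   per-key count: min 1 / mean 8.5 / max 13
#>   indexed keys (adjacency graph + density): 8
#>   [synthetic database]

search_space_size(spec, db)$size
#> [1] "1399489"

st <- mini_chignolin_states(db)
pr <- transition_problem(spec, db, st$extended, st$folded,
                         collision_model = collision_model())
path <- hdfs_search(pr)
path
#> Transition path: success
#>   GYDPETGTWG (8 variables)
#>   steps 1500, distance 417.358 rad, density 1.89 (per state)
#>   recursions 1500, backtracks 0, relaxations 58
```

The path is a sequence of feasible elementary transitions from the fully
extended state to the state with the C-terminal turn formed: `steps` is
the number of transitions, `distance` the summed adjacency edge lengths,
and `density` the mean vertex density along the path (higher = the path
runs through better-populated, energetically more favourable regions of
the library). Intermediate snapshots at 1/10th-length steps can be written
as a multi-model PDB:

```r
inter <- select_intermediates(path, k = 10)   # 11 states incl. endpoints
chains <- lapply(inter, function(s) chain_from_state(spec, db, s))
write_chain_pdb(chains, "folding.pdb")
```

Real libraries are built from structure files instead:
`build_db_from_manifest("structures.txt")` extracts every complete
tripeptide window (standard residues, no chain breaks, all six dihedrals
defined) and `index_database()` adds graphs and densities. A thin command
line covering the same operations ships at
`system.file("cli", "tripath.R", package = "tripath")` with subcommands
`build-db`, `index-db`, `synth-db`, `sample`, `search`, `metrics`,
`stats`.

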