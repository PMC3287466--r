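---
title: "Protein-dependent rotamer libraries: model, potentials and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-dependent rotamer libraries: model, potentials and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotamrf)
```

## The problem

Side-chain conformations cluster into discrete, statistically favored
states — rotamers — described by their χ dihedral angles. Standard
backbone-dependent rotamer libraries give, for each amino acid and each
(φ, ψ) bin, the rotamers' prior probabilities and χ means. But a residue's
actual conformation depends on its *spatial* neighborhood, not just its
local backbone dihedrals. `rotamrf` conditions the library on the entire
given backbone: it models the protein as a pairwise Markov random field
(MRF) over residues and replaces each residue's bin priors with its
marginal distribution under that field. No global search is involved; the
output is a distribution per residue, which is exactly what downstream
combinatorial packers consume.

## Interaction graph

Each residue is a vertex. An edge joins two residues when **any** pair of
their Cα, Cβ and carbonyl-oxygen atoms lies strictly below the contact
threshold (default 10 Å). Notes on the contract:

* *Strict* inequality at the threshold: a pair at exactly 10 Å is not a
  contact. The boundary convention matters for reproducibility and is
  fixed, not configurable.
* Glycine has no Cβ; it participates through Cα and O only. (A virtual Cβ
  would be an alternative; we chose the simpler rule and kept it.)
* The topology depends only on backbone atoms — candidate rotamers never
  add or remove edges.
* Sequence-adjacent residues receive no special treatment; at 10 Å they
  essentially always satisfy the rule anyway.

## Potentials

States of vertex *i* are the rotamer records of the library's nearest
(φᵢ, ψᵢ) bin (nearest-bin with angular wrap-around; no interpolation, so
the bin's most probable rotamer stays well defined). At chain termini,
where φ or ψ is undefined, the candidate list falls back to the
backbone-independent marginal over that amino acid's bins and the output
flags it. Energies become potentials via the Boltzmann factor
`exp(-E / kBT)` with `kBT = 0.6` kcal/mol.

**Vertex energy.**
`E_i(r) = k_d * ln(p_max / p(r)) + E_sc_i(r)`, `k_d = 3.0`.
The first term is zero for the bin's most probable rotamer and grows as
the prior shrinks — it imports the library's statistics into the field.
Priors are floored at 1e-6 first, so a zero-probability record costs a
large but finite energy rather than breaking the model. The second term
sums the repulsive atom-pair energy between the candidate's side-chain
atoms and the backbone atoms (N, CA, C, O, and CB as pseudo-backbone,
matching common side-chain-packing practice) of every graph neighbor.
Interactions with the residue's *own* backbone are deliberately absent:
they are identical for every protein with the same local geometry and are
precisely what the library's (φ, ψ)-binned priors already encode.

**Edge energy.**
`E_ij(r, s) = E_sc_ij(r, s) + E_hb(r, s)`: all side-chain/side-chain
atom-pair repulsions, plus a hydrogen-bond term.

**Atom-pair repulsion** is the SCWRL3 piecewise linear approximation of
the repulsive branch of Lennard-Jones 12-6: zero beyond `r_ab = r_a +
r_b`, a plateau `E_max = 10` inside `k_sc * r_ab` with `k_sc = 0.8254`,
linear in between; continuous and non-increasing. Interaction radii are an
element-class table (C 1.6, N 1.3, O 1.3, S 1.7 Å) shipped as a
configurable default. There is no attractive component, no solvation, no
electrostatics — sterics plus statistics is the model.

**Hydrogen bonds.** The full ROSETTA orientation-dependent polynomial
model is out of scope here. The default `E_hb` is a documented surrogate:
for side-chain donor/acceptor heavy-atom pairs, a Gaussian well
`weight * exp(-(d - d_opt)^2 / (2 w^2))` (defaults: weight −2.0 kcal/mol,
`d_opt` 2.8 Å, `w` 0.3 Å) gated by the antecedent–donor–acceptor angle
(≥ 90°), taking the single most favorable pair per residue pair and per
direction. Only side-chain-mediated bonds enter: backbone–backbone terms
are constant given the fixed backbone and cannot move marginals. The term
is pluggable and can be disabled (`hbond_params(enabled = FALSE)`).

**Numerical hygiene.** Before exponentiation, energies are shifted by
their per-vertex / per-edge minimum. This is a pure rescaling of the
potentials — marginals are provably invariant — and prevents underflow
when clash plateaus stack up. The invariance is tested end to end.

## Inference

Four sum-product algorithms estimate the per-vertex marginals, plus an
exact-enumeration oracle used only for testing (it refuses state spaces
above a cap):

* **Loopy BP (default).** Belief: vertex potential times all incoming
  messages. Message i→j: sum over i's states of vertex potential × edge
  potential × messages into i except j's. Exact on trees; on loopy graphs
  a good estimate when it converges.
* **Mean field.** Coordinate ascent on the fully factorized
  approximation; fastest, least accurate on strongly coupled graphs.
* **TRBP.** Messages weighted by edge appearance probabilities ρ —
  computed *exactly* per connected component via the matrix-tree theorem
  (spanning trees containing an edge by contraction/deletion determinant
  ratio). At ρ ≡ 1 the update equations reduce algebraically to loopy BP;
  the implementation reproduces that identity to machine precision and a
  `rho_one` flag exposes it end to end.
* **GBP.** Parent-to-child message passing on a region graph whose outer
  regions are all triangles of the interaction graph plus uncovered edges,
  closed under intersection, with cluster-variation counting numbers (each
  vertex and edge factor counted exactly once). On triangle-free graphs
  this degenerates to the Bethe construction and matches loopy BP; a graph
  that is a single triangle (or a clique tree of triangles) is solved
  exactly. The region choice is the one genuinely open design point in the
  method; triangles are the smallest enrichment beyond Bethe and we
  document the construction as our own choice.

Shared conventions: messages start uniform (a seeded-random option exists
for reproducing randomized initializations), are normalized to sum to one
after every update, and sweeps are asynchronous in a fixed vertex order
(seeded random order optional). Convergence is declared when the
L-infinity change across all beliefs between successive sweeps falls below
`tolerance` (default 1e-6), within `max_iterations` (default 100). Optional
message damping (default off) is available as a safeguard for oscillatory
cases; results report it when used. Non-convergence is a reported state —
the marginals at the cap are still returned, flagged, and are typically
still useful. On diverging runs whose messages degenerate numerically, the
affected update is skipped and the non-converged flag tells the story; no
NaN ever reaches the output.

## Output

`rerank()` sorts each residue's candidates by marginal probability (stable
in prior order on ties — determinism over elegance) and
`write_protein_library()` emits the input library's column layout with a
leading residue-index column and a provenance header (algorithm,
convergence, residual). `predict_top1()` thresholds to each residue's
most probable rotamer; by design this is *not* guaranteed to be a
clash-free joint packing — producing a library for global packers, not a
packer, is the point.

## Evaluation

A predicted χ is correct when its wrap-around distance to the actual χ is
strictly below 40°; χ₁₊₂ requires both χ₁ and χ₂ correct, and so on
cumulatively. ALA and GLY are excluded. Besides accuracy,
`average_first_correct_rank()` (ideal value 1.0; residues with no correct
rotamer anywhere are excluded and counted separately) and
`topk_correct_probability()` (probability mass on correct rotamers among
the top k) measure ranking quality. Two deliberate conventions: the 40°
boundary itself counts as incorrect, and 180°-symmetric terminal χ angles
(PHE/TYR χ₂, ASP χ₂, GLU χ₃) are *not* folded by default — folding
materially changes accuracies, so it is an explicit, flagged option.
True χ angles are measured from the full-atom PDB with the package's own
dihedral routine.

## Synthetic fixtures: what they emulate and what they do not

All tests run on generated data; nothing is downloaded.

* `make_backbone()` builds geometrically valid chains by
  internal-coordinate (NeRF) construction: ideal helix (φ −57°, ψ −47°),
  extended strand (φ −139°, ψ 135°), or coordinate-perturbed variants
  (Gaussian σ in Å). Same spec + seed ⇒ byte-identical files.
* `make_library()` draws per-bin probabilities from a symmetric Dirichlet
  and places χ means near the canonical gauche±/trans wells (±60°/180°)
  with 8° jitter, the first three rotamers of every bin occupying three
  distinct χ₁ wells so that the 40° criterion discriminates between them.
* `make_toy_mrf()` produces chain/tree/cycle/complete models with
  log-normal potentials, small enough for the enumeration oracle.
* `make_bundle()` assembles a backbone, a library, and a full-atom truth
  structure whose side chains sit exactly at one library rotamer per
  residue ("top" or prior-sampled), so metrics have known optima. One
  deliberate refinement: real backbone-dependent priors anticorrelate with
  steric strain against the local backbone, while raw Dirichlet draws do
  not — so the bundle reorders each bin's probabilities to rank the least
  backbone-clashing candidate first. Without this, a placed "true" top
  rotamer can be one the energy model rightly rejects, and the
  self-consistency optimum the mode exists for would not exist.

What passing these tests shows: every contract of the pipeline —
geometry, graph, potentials, inference, ranking, evaluation — behaves as
specified, and inference agrees with exact enumeration wherever
enumeration is feasible. What it does not show: prediction accuracy on
real proteins. The fixtures make no attempt to mimic PDB-wide rotamer
statistics, sequence composition, or packing density; full-scale accuracy
requires user-supplied experimental structures and a real Dunbrack
library, which the same entry points accept.

## Side-chain construction

The method needs coordinates for candidate side chains (all energies are
atom-pair sums), so the package builds them from χ angles by
sequential NeRF placement over an idealized internal-coordinate table
(bond lengths/angles in `inst/extdata/sidechain_geometry.tsv`; Cβ from the
standard L-configuration improper, torsion(C, N, CA, CB) = +123°).
Aromatic and other rings are closed approximately by fixed torsions —
adequate for repulsive energies, and exact where it matters: rebuilding a
side chain and re-measuring its defining dihedrals returns the input χ to
well below 1e-4°. Hydrogens are never constructed; the energy model is
heavy-atom only, with hydrogen bonds handled on donor/acceptor heavy-atom
geometry.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `threshold` | 10 | Å | contact rule for graph edges (strict `<`) |
| `kBT` | 0.6 | kcal/mol | Boltzmann temperature factor |
| `k_d` | 3.0 | – | scale of the log-prior vertex term |
| `E_max` | 10 | – | repulsive plateau |
| `k_sc` | 0.8254 | – | fractional ramp start (of `r_ab`) |
| radii | C 1.6, N 1.3, O 1.3, S 1.7 | Å | element-class interaction radii |
| `prob_floor` | 1e-6 | – | floor on priors before the log term |
| `max_iterations` | 100 | sweeps | inference cap |
| `tolerance` | 1e-6 | – | L∞ belief-change convergence threshold |
| `damping` | 0 | – | optional message damping in [0, 1) |

The first six are the method's published operating point; the rest are
numerical policy with conservative defaults.

## Problem sizes used by the test and acceptance runs

Chosen so the full suite and the acceptance script each finish within a
few minutes on one CPU: tree-oracle comparisons use 100 random trees of
3–8 vertices and 2–4 states; edge-appearance cross-checks enumerate all
labeled connected graphs on ≤ 4 vertices exhaustively and seeded random
samples on 5–6 vertices (full enumeration at 6 vertices would be millions
of spanning-tree counts for no extra coverage); pipeline fixtures are
10–20 residue proteins with 3 rotamers per bin; the acceptance run
aggregates 10 such proteins. A 150-residue protein with a full-size
library runs end to end in minutes with LBP; GBP is the expensive option
since triangle regions multiply state spaces.

## Known limitations

* The hydrogen-bond term is a surrogate, not a ROSETTA port; users
  needing the original can plug their own pairwise term.
* No disulfide-specific energy: CYS pairs that would form S–S bonds are
  treated as ordinary sterics, so improvements on CYS are expected to be
  modest.
* Nearest-bin lookup (no (φ, ψ) interpolation), heavy atoms only, model 1
  only, standard residues only; 2010-style continuous-χ densities are
  ignored beyond means and probabilities.
* Sum-product only: no max-product/MAP variant and no free-energy
  computation — both are explicitly outside the method's goal.
* ω dihedrals are computed and reported but consumed by nothing
  downstream; they are provided for completeness.
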