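---
title: "Shape descriptors with pharmacophoric constraints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape descriptors with pharmacophoric constraints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usrcatkit)
```

## The model

Ultrafast shape recognition encodes a conformer's geometry as the first
three statistical moments of the distances from its atoms to four fixed
reference points: the atomic centroid, the atom closest to the centroid,
the atom farthest from the centroid, and the atom farthest from that
farthest atom. Twelve numbers — (μ, σ, κ) for each of the four
distributions — capture molecular extent, anisotropy and asymmetry in a
form that is invariant under rotation and translation by construction,
because only interatomic distances enter. Reflection invariance follows
too: the descriptor cannot distinguish enantiomers, which is a documented
limitation of the whole method family, not of this implementation.

The pharmacophore-typed extension appends four further 12-moment blocks,
one per feature class (hydrophobic, aromatic, hydrogen-bond acceptor,
donor). Two design facts matter:

* **Shared reference points.** Subset distributions are measured against
  the *all-atom* reference points rather than subset-specific ones. Small
  subsets (donors are scarce in drug-like molecules — often one to three
  atoms) would yield meaningless reference points of their own; anchoring
  them to the global frame both stabilises the moments and encodes *where*
  the features sit within the overall shape.
* **Empty-subset rule.** A molecule with no atoms of a class contributes
  twelve exact zeros for that block. Zeros are values, not missing data:
  two molecules both lacking donors agree perfectly on that block, and a
  molecule with donors is penalised against one without.

Similarity between 60-vectors is a Manhattan-type score
\[
S = \frac{1}{1 + \sum_b w_b \tfrac{1}{12} \sum_{l \in b} |M_l^i - M_l^j|},
\]
one nonnegative weight per block, applied at query time so that a stored
descriptor table supports any weighting without recomputation. With
`usrcat_weights(1, 0, 0, 0, 0)` the score equals classic 12-element USR
similarity exactly — the classic method is a special case, which the test
suite asserts identically rather than approximately.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `weights` (`ow,hw,rw,aw,dw`) | all 1 | block scaling in the similarity; unitless |
| `hydrogens` | `"exclude"` | heavy-atom descriptor computation; `"include"` adds H to the all-atom block |
| `probe_radius` | `NULL` (off) | half-width, in the moments' Å units, of the Chebyshev prefilter box on the all-atom block |
| `top_k` / `top_fraction` | `top_fraction = 1` | ranked-list cut, in molecules |
| `levels` | 1, 0.5, 0.25 (%) | enrichment-factor levels; retrieved set is `ceil(level/100 · M)` molecules |
| `ef_convention` | `"printed"` | `(a/d)/(A/D)`; `"standard"` gives `(a/n)/(A/N)` |

Equal weights are the sensible prior when nothing is known about the
target; raising a weight emphasises that feature class and can only lower
or preserve any pair's score (weight monotonicity, tested on seeded random
pairs). The hydrogen default reflects that the shipped SMARTS address heavy
atoms; hydrogens are nevertheless read and flagged so the choice stays
reversible downstream.

Pharmacophore typing is configuration, not code: a YAML file maps each of
the four classes to SMARTS lists (`load_pattern_set()`, CLI `--smarts`).
The shipped defaults are functional equivalents of widely used feature
definitions — carbons without polar double bonds plus halogens as
hydrophobes, `[a]` for aromatics, N–H/O–H bearers as donors, non-amide
nitrogens and most oxygens as acceptors. Tests that depend on typing pin
this shipped file. Subsets may overlap and no standardisation
(protonation, tautomers) is applied; input chemistry is taken as given.

## Screening and the probe radius

The prefilter is *defined* set-theoretically: a row passes iff every one
of its first 12 moments lies within `probe_radius` of the query's. Any
acceleration structure must return exactly this set, which the tests
enforce by comparing against a literal interval scan. Because the box
constrains only the all-atom block, a small radius makes results converge
to classic USR's neighbourhood (only globally similar shapes are scored),
while a radius exceeding the table's coordinate-wise diameter makes the
prefiltered screen byte-identical to the linear scan. In the benchmark the
level cut stays `ceil(level/100 · M)` with `M` the *full* screened-set
size, so an aggressive radius genuinely retrieves fewer molecules — this
is what makes mean EF non-decreasing in the radius.

Ranking is deterministic everywhere: descending score, ties by ascending
`(mol_id, conf_id)` in C-locale order; molecule collapse keeps the
best-scoring conformer, ties to the lowest conformer number. All-zero
weights score every pair 1.0; the screen warns and returns the pure tie
order.

## Benchmark protocol

Each active's conformer 0 — the lowest-energy conformer of a
strain-sorted ensemble — is the query; every conformer of the query
molecule is excluded from the screened set. Enrichment factors use the
printed convention `EF = (a/d)/(A/D)` with `A`, `D` the target's total
active and decoy counts; `a = 0` gives EF 0, and `d = 0` with `a > 0`
substitutes `d = 1` and raises a degeneracy flag (the formula is otherwise
undefined there; the substitution keeps EF finite and monotone in `a`).
The standard convention `(a/n)/(A/N)` is available as a switch; it is the
one under which a random ranking has expected EF exactly 1, and the
calibration test uses it for that reason. Averaging is two-stage — mean
over a target's queries, then mean over targets — so targets with many
actives do not dominate. Scaffold-hop summaries count, per query, actives
retrieved by the shape method but not by fingerprint similarity at the
same level, excluding queries where either method retrieved no actives.

Topological fingerprints come from the chemistry backend (circular/Morgan,
linear-path, branched-subgraph, and MACCS keys at 2048 bits except MACCS).
Their values are backend-specific; tests pin them as regression fixtures
rather than asserting cross-toolkit equality.

## The synthetic generator

The generator produces labelled point clouds in place of conformers so the
numerical core is testable without any chemistry toolkit. Its defaults are
the package's reference study conditions:

* **Template and actives.** One template cloud (10–25 atoms, globular
  Gaussian with 1.5 Å coordinate spread — drug-like heavy-atom counts and
  extent); 10 actives are jittered copies (σ = 0.15 Å per conformer 0,
  increasing with conformer number) that keep the template's labels.
* **Decoys.** 200 shape twins: the same jittered template coordinates with
  a label permutation verified to change the typed descriptor
  (`twin_fraction = 1`); setting it below 1 mixes in independent clouds.
* **Labels.** Per-atom Bernoulli draws at rates 0.45 / 0.30 / 0.25 / 0.15
  (hydrophobic / aromatic / acceptor / donor), mirroring the relative
  scarcity of donors in drug-like compounds.

Because twins share the actives' coordinate distribution exactly, the
classic shape descriptor performs at chance while the typed descriptor
separates actives by construction — the directional claim the acceptance
tests verify. This is deliberately a *favourable* regime: real decoy sets
are property-matched but not coordinate-matched, real actives differ in
size and conformation far more than 0.15 Å jitter, and real typing
inherits SMARTS imperfections. Passing these tests therefore demonstrates
algorithmic correctness and the direction of the typed-over-plain effect,
not the enrichment magnitudes achievable on curated screening databases.
Every generator output is a pure function of (spec, id, seed); generation
never touches the caller's RNG stream.

## Numerical choices

* **Population variance** (1/N), so a single-distance distribution gives
  σ = 0 rather than an undefined value; atom sets are complete
  populations, not samples.
* **κ as the signed cube root of the third central moment**, not
  standardised skewness: it stays finite when σ = 0 and keeps Å units.
  Third moments that are analytically zero (two-value or symmetric
  distributions) accumulate rounding noise of order 10⁻¹⁶σ³, which the
  cube root would amplify to ~10⁻⁵σ; values with |m₃| ≤ 10⁻¹²σ³ are
  therefore snapped to exact zero. The threshold is far below any genuine
  skew and keeps the descriptor reproducible to 10⁻¹⁰ across evaluation
  orders and rigid motions.
* **Tie-breaks** for the three atom-coincident reference points go to the
  lowest atom index, making descriptors deterministic under a fixed input
  order; under atom permutation descriptors are unchanged on generic
  (tie-free) inputs up to machine rounding.
* **Degenerate inputs:** a single considered atom yields twelve zeros; an
  all-hydrogen molecule under the exclude policy is an error, not a NaN;
  indistinguishable actives/decoys in a benchmark raise an `all_tied`
  flag instead of silently reporting tie-order enrichment.
* **Descriptor tables** print moments with 17 significant digits, the
  minimum that round-trips IEEE doubles bit-faithfully through text.

## Problem sizes

The shipped tests run the oracle and invariance suites on 200 random
clouds of 3–40 atoms each, the prefilter equivalence on a 10,000-row
table, the EF calibration on 500 shuffles of a 10-active/490-decoy set,
and the benchmark comparisons on the default 10 active / 200 decoy
construction with 3 conformers per molecule — sizes at which every
property is exercised meaningfully while the whole suite completes in a
few minutes on one CPU.

## Known limitations

* No chirality discrimination (mirror degeneracy is inherent).
* Global moments blur for molecules of very different sizes; screens work
  best when query and library sizes are comparable.
* Typing quality is bounded by the SMARTS configuration; the shipped set
  is a reasonable default, not a curated ontology.
* The fingerprint comparator requires the RDKit backend; without it the
  numerical core still works but typing, embedding and fingerprints
  error clearly.
* Enrichment magnitudes on the synthetic construction are not predictive
  of real-database performance (see the generator section).
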