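---
title: "Zinc-site discovery and ICP-MS stoichiometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zinc-site discovery and ICP-MS stoichiometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zincsites)
```

## Scope and model

`zincsites` predicts candidate Zn²⁺ coordination clusters on a protein
structure model and reduces ICP-MS element measurements to a molar
Zn:protein stoichiometry. The two halves share a common motivation: zinc
sites in large carrier proteins such as vitellogenin are known only
indirectly — from element analysis of the purified protein and from
conservation plus geometry on a predicted structure — so both lines of
evidence must be computed reproducibly and cross-checked.

The structural half rests on well-established empirical regularities of
zinc biochemistry rather than on a fitted model: Zn²⁺ ligates through the
side chains of His, Cys, Asp, Glu and Ser (and water, which a dry model
cannot represent); ligand donor atoms sit ~2.0–2.4 Å from the ion;
catalytic sites are partially exposed and mix H/C with D/E/S, structural
sites are buried and H/C-dominated, and four ligands is the dominant
coordination number for both; four-cysteine (ZnC4) sites interconvert with
crossed disulfide pairs under redox change; and productive sites show
*hydrophobic contrast* — a polar first shell wrapped in a hydrophobic
second shell.

## The cluster-search procedure

Given a structure model and a multiple sequence alignment containing the
reference sequence:

1. **Conservation.** Each reference position is scored by the frequency of
   its residue (or its exchange group — `{AVLIM}`, `{FYW}`, `{ST}`,
   `{DE}`, `{NQ}`, `{KR}`, `{C}`, `{H}`, `{G}`, `{P}` — in similarity
   mode) among the column's non-gap symbols, multiplied by the non-gap
   fraction. Columns with more than 50% gaps are flagged low-confidence.
   Scores are binned to grades 1–9.
2. **Seeding.** H/C residues at grade ≥ `min_grade` become primary
   candidates.
3. **Grouping.** Candidates whose minimum functional-atom distance is
   ≤ `d_pair` are connected; clusters are the connected components of this
   graph. Components are the only deterministic formalization of "inspect
   positions in 3D space"; they are computed with igraph and tested
   against a brute-force flood-fill oracle.
4. **Augmentation.** A cluster below `min_coordinators` members recruits
   *all* conserved D/E/S residues within `d_aux` of any member's
   functional atoms or within `seq_adjacency` residues in sequence. Adding
   all qualifying auxiliaries (rather than stopping at the minimum) is
   deliberate: a candidate shell is a hypothesis about a flexible
   apo-site, and arbitrarily discarding one of two equally qualified
   acidic neighbours would make the output depend on iteration order.
5. **ZnC4 screen.** Disulfides are cysteine SG pairs within 2.3 Å
   (greedy nearest-first, each Cys used once). Bridge pairs whose four SG
   atoms are mutually within `d_pair` become redox-switch-like clusters;
   when the four cysteines already belong to a conserved-seed cluster,
   that cluster is re-labelled rather than duplicated.
6. **Classification.** Sub-minimal below `min_coordinators`;
   redox-switch-like for crossed-disulfide all-Cys clusters;
   structural-like when ≥ 3 members are H/C and the mean burial proxy
   reaches `buried_min_neighbors`; catalytic-like otherwise.
7. **Domains and names.** Each cluster takes the domain window holding the
   majority of its members (ties resolve to the lowest member's domain —
   membership itself is purely geometric, so a cluster may straddle
   domains) and is named `<domain>.<ordinal>` by ascending lowest member
   position.

### Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_grade` | 7 | grade (1–9) | approximates the "conserved" band of a 9-colour conservation scale; the literature this mirrors judged conservation visually, so the cutoff is exposed rather than fixed |
| `d_pair` | 8.0 | Å | two ligands of one ion are ≤ ~4.8 Å apart when bound; an apo model needs slack for side-chain and loop rearrangement; documented range 6–12 |
| `d_aux` | 8.0 | Å | same geometry argument for auxiliaries |
| `seq_adjacency` | 2 | residues | sequence-adjacent conserved residues can reach a site through backbone flexibility |
| `min_coordinators` | 4 | residues | the dominant Zn²⁺ coordination number |
| `burial_radius`, `buried_min_neighbors` | 10 Å, 18 | — | CB-neighbour density is a cheap deterministic burial proxy; 18 neighbours within 10 Å separates core from surface in globular models |

Contrast radii default to 5 Å (inner) and 10 Å (outer) around the cluster
centroid; each residue joins its nearest shell once, by its closest
functional or CB atom. The statistic is the shell-mean difference on the
Eisenberg consensus scale, signed so that positive values mean a
hydrophobic exterior. The cited contrast formalism is reported in the
source literature only as a surface colouring, without a numeric
functional form, so the shell-mean difference was chosen as the simplest
statistic faithful to the concept; its correctness is established by
symmetry properties (rotation invariance, exact negation under
composition swap) rather than by numeric regression.

### Conservation grade binning

Grades use fixed-interval binning, `grade = 1 + floor(9·score)` capped at
9, so grade 9 demands a score ≥ 8/9. Quantile binning (the obvious
alternative, available via `binning = "quantile"`) was rejected as the
default because its top bin absorbs the most-conserved *ninth* of
positions regardless of absolute conservation: whenever truly invariant
columns are rarer than one in nine, noise columns are promoted to grade 9
and the planted-column recovery property (grade-9 set = exactly the
invariant columns) cannot hold. Interval binning is monotone,
deterministic and independent of the score distribution.

## ICP-MS reduction

Per sample: measured Zn (µg/L, instrument scale) × dilution factor →
undiluted concentration; ratio = (c(Zn)/M(Zn)) / (c(P)/M(P)). Defaults
M(protein) = 201147.7 g/mol (full-length honey bee Vg) and
M(Zn) = 65.30 g/mol; both configurable via `zn_constants()` (65.30 is kept
rather than the IUPAC 65.38 so results match the convention of the
workflow this reproduces). LOD and LOQ are 3× and 10× the blank SD
(n−1 denominator), so LOQ/LOD = 10/3 identically. Samples below LOD are
flagged and excluded from the summary by default (`below_lod = "keep"`
retains them). Identical blanks yield LOD = LOQ = 0 with a warning;
fewer than two blanks is an error.

Isobaric ⁶⁴Ni interference on ⁶⁴Zn is an instrument-side correction with
no published functional form in this context; inputs are taken as
calibrated concentrations from the mass-66 channel, and internal-standard
(Rh) normalization is likewise treated as already applied. The group
comparison is the Kruskal–Wallis rank test with tie correction
(delegated to `stats::kruskal.test`, verified in the test suite against a
hand-written rank formula; the all-ties case returns H = 0, p = 1, which
the delegate does not define).

## What the synthetic generators emulate — and what they do not

`make_structure` plants sites whose functional atoms sit exactly 2.1 Å
from a virtual ion along tetrahedral directions (ligand–ligand ~3.43 Å),
surrounds each ion with four hydrophobic shell residues at 7.5 Å, places
isolated H/C decoys ≥ 15 Å from everything (margin configurable — tests of
threshold sensitivity shrink it), and fills the remaining residues with an
alanine random walk kept ≥ 12 Å from every ion. Coordinates are rounded to
the PDB's 3-decimal precision at generation time so that writing and
re-reading is lossless. `make_msa` copies conserved columns verbatim and
substitutes the rest uniformly at a chosen rate, with no gaps.
`make_icpms` inverts the molar-ratio formula exactly and perturbs with
multiplicative Gaussian noise.

These generators define the package's testable claims: planted-site
recovery with precision = recall = 1 at default thresholds, positive
contrast on planted sites, exact ratio recovery at zero noise and
3-SE recovery under noise. They deliberately do *not* emulate real
protein backbones, rotamers, partial side-chain occupancy beyond
truncation, gapped alignments, phylogenetic correlation between records,
or instrument drift — so green tests certify the algorithms, not
performance on any real structure or instrument run. On real models the
decisive uncertainties are side-chain orientation error in predicted
structures and the absence of water-mediated coordination, neither of
which the synthetic truth represents.

Default generator conditions mirror the study design this pipeline
serves: five analyte samples at 1.2–2.8 g/L protein, five buffer blanks,
five-fold dilution, a true ratio of 3 and 5% measurement noise;
alignments of ~30 records, the scale of a curated ortholog set.

## Numerical choices and degenerate inputs

* Distances are exact Euclidean minima over functional-atom pairs; the
  fallback chain (functional atoms → most distal side-chain heavy atom →
  CA) keeps truncated models processable and is recorded per residue.
* Greedy nearest-first disulfide pairing makes bridge assignment
  order-independent; ZnC4 bridge-pair conflicts resolve by ascending
  lowest residue number.
* Empty candidate sets, windows with start > end, missing residues,
  all-gap columns, empty outer shells and all-tied rank tests all have
  defined behaviour (empty result, error, error, error, undefined-flag,
  H = 0) covered by tests.
* Cluster naming and ordering are fully determined by member positions,
  so identical inputs give byte-identical reports; the run log confines
  the timestamp to its first line to keep reruns diffable.

## Test problem sizes

The suite generates everything at run time: structures of 20–400 residues
(50-residue random clouds for the component oracle, a 400-residue model
for window censuses), alignments of 10–50 records, 200-table estimator
recovery per true ratio, and exhaustive rank-test checks for small group
sizes. These sizes were chosen as the smallest at which each property is
non-trivial — component structure with several clusters and decoys,
binomially tight conservation frequencies, sub-1% standard errors on the
ratio estimator.

## Known limitations

* Conservation is frequency-based, not phylogeny-aware: dense sampling of
  one clade inflates its residues' scores. The exchange-group mode
  mitigates, but does not remove, this.
* A single global `d_pair` cannot reproduce every manual judgment call
  made in curated site lists; the documented 6–12 Å range plus the run
  log's config echo make any calibration auditable.
* The burial proxy is a neighbour count, not solvent accessibility; it is
  adequate for the buried/exposed dichotomy the classification needs, not
  for quantitative SASA.
* C2H2 scanning matches the PROSITE-style consensus only; divergent
  fingers and profile-HMM-level sensitivity are out of scope.
* Water-mediated and backbone-carbonyl coordination are invisible to the
  functional-atom model.
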