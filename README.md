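# zincsites

Zinc-binding site discovery on protein structure models, and ICP-MS
metalloprotein stoichiometry.

## The problem

Many transport and storage proteins — vitellogenin (Vg), the major
yolk-precursor and zinc-carrying protein of egg-laying animals, is the
motivating case — bind a handful of Zn²⁺ ions at sites that have never been
resolved crystallographically. Two complementary questions arise:

1. **How many ions per molecule?** Element analysis (ICP-MS) of the
   purified protein gives total Zn and protein concentrations per sample;
   converting both to moles yields a per-sample stoichiometry
   *r* = (c(Zn)/M(Zn)) / (c(P)/M(P)), with detection limits derived from
   buffer blanks (LOD = 3·SD, LOQ = 10·SD) and a Kruskal–Wallis rank test
   against the blanks.
2. **Where on the structure?** On a predicted full-length model (e.g. an
   AlphaFold-based Vg model), candidate coordination sites can be found by
   combining evolutionary conservation with coordination-shell geometry.

`zincsites` implements both as a reusable, fully testable pipeline for
structural bioinformaticians working on metalloproteins.

## The procedure

The cluster search formalizes the classic manual workflow:

1. **Seeds** — histidines and cysteines whose per-column conservation
   grade (1–9, computed from a multiple sequence alignment of orthologs)
   reaches a threshold (default grade ≥ 7).
2. **Proximity grouping** — seeds whose side-chain *functional atoms*
   (His ND1/NE2, Cys SG) lie within `d_pair` (default 8 Å) are joined;
   clusters are the connected components of this graph.
3. **Augmentation** — Zn²⁺ typically takes ≥ 4 ligands, so clusters below
   four members recruit every conserved Asp/Glu/Ser within `d_aux` of a
   member (or ±2 residues in sequence).
4. **ZnC4 screen** — pairs of disulfide bridges whose four SG atoms are
   mutually within `d_pair` are reported as redox-switch-like ZnC4
   candidates.
5. **Classification** — buried, H/C-dominated clusters are
   *structural-like*; mixed-ligand or exposed clusters are
   *catalytic-like*; burial is a CB-neighbour count (≥ 18 within 10 Å).
6. **Hydrophobic contrast** — each cluster is scored as
   Δ = mean(outer shell) − mean(inner shell) on the Eisenberg consensus
   hydrophobicity scale (shells at 5 and 10 Å around the cluster
   centroid); Δ > 0 is the polar-core/hydrophobic-exterior signature of a
   productive site.

Sequence-level evidence is handled by a literal motif scanner, a C2H2
zinc-finger consensus scanner (`C-x(2,4)-C-x(3)-[LIVMFYWC]-x(8)-H-x(3,5)-H`),
and alignment-based mapping of finger ligand columns onto the reference
protein.

A synthetic-data module generates structures with planted tetrahedral
sites (ligand atoms 2.1 Å from a virtual ion), alignments with controlled
per-column conservation, and ICP-MS tables from a known true ratio, so
every stage is testable without downloads.

## Worked example

```r
library(zincsites)

# synthetic bundle with known truth: two planted sites, four decoys
st  <- make_structure(80, sites = list(c("C","C","C","C"), c("H","H","D","E")),
                      n_decoys = 4, seed = 11)
s   <- structure_model(st$atoms, domains = list(bb = c(1, 40), ah = c(41, 80)))
msa <- make_msa(paste(s$sequence, collapse = ""), n_seqs = 30,
                conserved_positions = c(st$truth$conserved_positions,
                                        st$truth$decoys),
                sub_rate = 0.7, seed = 12)
prof <- compute_conservation(msa$alignment, "REF")
cls  <- score_contrast(find_zinc_clusters(s, prof), s)
cluster_report(cls)
#>     id domain classification size         members min_position inner_mean outer_mean contrast
#> 1 bb.1     bb catalytic-like    4    C1,C5,C9,C13            1      0.040     0.6025   0.5625
#> 2 bb.2     bb catalytic-like    4 H34,H38,D43,E47           34     -0.535     0.6025   1.1375
#> 3 ah.1     ah    sub-minimal    1             H68           68     -0.400         NA       NA
#> 4 ah.2     ah    sub-minimal    1             C72           72      0.040         NA       NA
#> 5 ah.3     ah    sub-minimal    1             H76           76     -0.400         NA       NA
#> 6 ah.4     ah    sub-minimal    1             C80           80      0.040         NA       NA
```

Both planted sites are recovered in full (the H/H pair was augmented with
its two conserved acidic neighbours, D43/E47); the four conserved decoys
stay isolated and are reported as sub-minimal rather than dropped. Positive
contrast on both sites reflects the hydrophobic shells the generator placed
around each ion.

Stoichiometry from a synthetic table generated at a true ratio of 3:

```r
tab <- make_icpms(true_ratio = 3, seed = 13)
summarize_stoichiometry(tab)
#> Zn:protein stoichiometry over 5 sample(s): mean 3.10, range 2.96-3.27 mol/mol
#> LOD 0.656 ug/L, LOQ 2.19 ug/L (blank SD 0.219, n=5)
kruskal_wallis(list(tab$zn_ugL[tab$group == "analyte"],
                    tab$zn_ugL[tab$group == "blank"]))
#> $H [1] 6.818182   $df [1] 1   $p.value [1] 0.009023439
```

The molar conversion uses M(Vg) = 201147.7 g/mol and M(Zn) = 65.30 g/mol
by default (`zn_constants()`).

For real inputs, `run_pipeline()` drives every stage from one YAML/list
config (structure + alignment + sample table paths, domain windows, search
thresholds) and writes conservation, cluster, motif and stoichiometry
reports plus a run log that echoes the full configuration.

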