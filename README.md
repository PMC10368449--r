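# lpsmap

Phage resistance in *Escherichia coli* C usually arises through
loss-of-function mutations in the genes that build the lipopolysaccharide
(LPS) core oligosaccharide — the receptor of bacteriophage ΦX174.  Under
the standard one-gene-one-phenotype model, knocking out a biosynthesis
gene truncates the LPS at that gene's step and at every step downstream,
so the mutated gene should fully determine the mutant's LPS structure.
`lpsmap` implements that model as a testable pipeline and confronts it
with data: host ranges of evolved phages, which discriminate between LPS
structures far more finely than the model predicts.

The package is aimed at microbial genomicists and phage biologists who
want to:

* encode an LPS assembly pathway as a dependency graph (residues with
  parent links, transferase genes, precursor genes, decorations) and
  **predict mutant structures** by knockout propagation: residue *r* is
  present iff all of its transferase/precursor genes are functional and
  its parent residue is present;
* classify predicted structures as **rough** (truncations confined to
  the outer core) or **deep rough** (outer core completely lost, or
  inner-core phosphate decorations lost);
* collapse replicated spot assays into a binary host × phage
  **infection matrix** by the two-method consensus rule with plaque-assay
  tie-breaking, count distinct infectivity profiles, cluster hosts by
  UPGMA (Euclidean distance on binary vectors ≡ √Hamming, average
  linkage) and test which predicted classes form **unbroken clusters**
  in the dendrogram leaf order;
* quantify partition agreement with the **Rand and adjusted Rand
  indices**, and mine **perfect mutation–capability association rules**
  linking phage protein changes (collapsed to (protein, site) allele
  classes) to host-range gains and losses;
* generate **synthetic datasets with known ground truth** — including
  "hidden subclass" structure in which the true receptor classes refine
  the predicted ones — to validate every stage end to end.

## Worked example

```r
library(lpsmap)
report <- run_full_analysis()
report
```

```
LPS prediction vs infection-profile analysis
  predicted structures:       7
  anticipated classes:        8
  rough / deep rough strains: 10 / 20
  strain mutations:           32 unique of 36
  phage mutations:            15 unique of 40
  distinct phage profiles:    14
  unbroken multi-member classes: 3 of 6
```

Reading: the 31 resistant strains carry 36 mutations (32 unique) and are
predicted to collapse into just 7 LPS structures — 8 anticipated
phenotype classes once the *rfaH* regulator mutant, whose structure
cannot be predicted, is counted separately.  Ten strains keep a
rough-type LPS; twenty fall to deep rough.  Yet the 16 evolved phages
show **14 distinct infectivity profiles** over those hosts, and only 3
of the 6 multi-member predicted classes occupy unbroken spans of the
UPGMA dendrogram: observed phenotype diversity exceeds what the
one-gene-one-phenotype model anticipates.

The genotype–phenotype map on the phage side is mined combinatorially:

```r
report$association_rules$wt_loss
#> Association rule for capability 'wt_loss' (4 capable / 12 incapable phages)
#>   perfect site pairs: (F,103) (F,154); (F,154) (H,68)
#>   no perfect single site; nearest miss: (F,103) with counterexamples R25_T4
```

i.e. every phage that lost the ability to infect the wild type carries
both the H-protein site-68 change and a site-154 allele (Q154K/R) in the
F capsid protein; no single site is a perfect explanation.

The numbered scripts under `analysis/` run the same steps as a narrated
workflow (`01_predict_structures.R` … `05_synthetic_recovery.R`) and
write their tables under `results/`.

Note on data: the full supplementary mutation tables and infection
matrix of the underlying study are not redistributable here; the files
under `inst/extdata/` are reconstructions pinned by statements printed
in the study's results and figure legends, with unpinned entries chosen
once for consistency (each file documents this in its header).

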