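---
title: "Predicting LPS structures from knockouts and testing them with phage host ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting LPS structures from knockouts and testing them with phage host ranges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpsmap)
```

## The scientific problem

ΦX174 infects *Escherichia coli* C through the core oligosaccharide of
its rough-type LPS.  Bacteria escape by mutating LPS biosynthesis genes;
the mutated LPS is then predicted by the one-gene-one-phenotype model:
an enzyme that is gone cannot add its residue, and nothing downstream of
a missing residue can be added either.  If the model were complete, two
strains mutated in the same gene (or in genes whose loss truncates the
structure at the same point) would present the same receptor and be
infectable by the same phages.  `lpsmap` operationalizes the model and
measures how far reality departs from it, using evolved phages as
structural probes.

## The pathway model and its assumptions

The assembly graph is configured in YAML (`lps_pathway_file()`): each
backbone residue names its attachment point (`parent`), the transferase
gene(s) that attach it, and the precursor-supply genes for its
sugar nucleotide (ADP-heptose requires *gmhA/gmhB/gmhD/hldE*;
UDP-glucose requires *galU*; the galactoses additionally *galE*).
Decorations (heptose phosphates, EtNP, the third Kdo) are modification
nodes gated by their own genes.  Prediction is pure propagation:

* residue present ⟺ all its genes functional **and** parent present;
* modification present ⟺ its genes functional **and** target present.

This gives, provably on the packaged model, **monotonicity** (more
knockouts, never more residues) and **connectivity** (present residues
always form a rooted subtree); both are asserted exhaustively over all
single and double knockouts in the test suite.

Assumptions worth stating:

* **Every mutation in an LPS gene is a complete loss of function** (the
  `permissive` policy of `call_lof()`).  Confidence is tracked —
  `high` for nonsense/frameshift/IS-insertion, `assumed` for
  missense/in-frame events — and a `conservative` policy restricted to
  high-confidence effects is available.  *gmhB* illustrates the cost of
  the assumption: its loss is known to be only partially heptoseless in
  reality, but the model treats it as a full precursor loss.
* **Regulator genes are not propagated.**  A *rfaH* mutation can silence
  any subset of the operon, so regulator mutants are routed to an
  explicit `unpredicted:<gene>` class instead of a guessed structure.
* **Nonstoichiometric decorations are identity-irrelevant.**  The
  canonical key of a structure serializes backbone residues and
  stoichiometric modifications only; EtNP, the third Kdo and the
  partially occupied Hep-II phosphate never separate classes.
* The phosphorylation state of Hep-I in a *waaF* knockout is not
  experimentally established; the configuration keeps it present and
  flags it `uncertain`.

Rough vs deep-rough classification follows the structural definition:
`deep_rough` iff the outer core is completely absent or a stoichiometric
phosphate decoration present in the wild type is lost; otherwise
`rough`.  The outer core is whatever the configuration marks
`inner_core: false`, so the rule survives renaming or reordering of the
outer-core hexoses — the exact identity/order of those residues in
*E. coli* C is a transcription choice to which all class counts are
invariant (the packaged file uses Glc-I, Glc-II, Gal-I, Gal-II).

```{r}
model <- load_pathway(lps_pathway_file())
strains <- read_strain_table(lps_strain_table_file())
part <- predict_partition(model, strains)
table(part$types[part$labels])
```

## The infection matrix and clustering choices

Raw spot assays are collapsed by the consensus rule: a host is sensitive
only when *both* methods show lysis in ≥ 2 of 3 replicates; a
disagreement is decided by a plaque assay (plaques at both dilutions),
and an undecidable cell is an error, never an imputation — the pipeline
refuses incomplete matrices.

Clustering uses Euclidean distance on the binary profiles with average
linkage (UPGMA).  On 0/1 vectors the Euclidean metric is the square root
of the Hamming distance, so the topology is Hamming-driven; this is also
the documented default of the common clustered-heatmap tools, which is
why it is the headline convention.  Because the convention is a choice,
`contiguity_sensitivity()` reruns the unbroken-cluster analysis over
{euclidean, hamming} × {average, complete, single} and the workflow
reports the full grid.  Numerical determinism: equal inter-cluster
distances are resolved toward the lowest pair of cluster formation
indices, and the leaf order places the earlier-formed subtree left, so
identical inputs give identical dendrograms on every platform.  The
implementation is validated against an independent from-scratch
average-distance oracle (1,000 random binary matrices up to 10×10) and
against `stats::hclust` on tie-free data.

Partition agreement uses pair-counting Rand and adjusted Rand indices
(cross-checked against `mclust::adjustedRandIndex`); the dendrogram test
asks which predicted classes occupy contiguous leaf spans, counting only
classes with ≥ 2 members (singletons are trivially contiguous).

## Association mining

With 16 phage isolates, statistical association testing is underpowered;
the genotype–phenotype map is therefore mined by exact set logic.
Changes are first collapsed to (protein, site) allele classes (Q154K and
Q154R are one signal), then a capability — infecting a host class, or
having *lost* wild-type infectivity — is explained by a site (or site
pair) carried by every capable phage and no incapable one.  By default a
phage "has" a class-capability when it infects ≥ 1 member (`strict =
TRUE` requires all members; with classes that hide subgroups the strict
variant is vacuous at the predicted-class level, which is why permissive
is the default).  Imperfect rules are reported with their nearest-miss
sites and explicit counterexample lists rather than suppressed — on the
packaged data this is how the one phage that infects the first
heptoseless subgroup *without* the site-154 change surfaces.  A Fisher
exact p-value is attached to single-site supports as annotation only.
Both single-site and pair rules are always reported, since "a mutation
acts in isolation" cannot be distinguished from "acts in its observed
background" with so few genotypes.

## What the synthetic generator emulates — and what it does not

`simulation_config()` defaults encode the study conditions: 31 strains,
16 phages, exactly one mutation per strain (27 of the study's 31 strains
carry one; multi-mutation strains sit behind a flag), mutation types
drawn 15:13:1:3 for substitutions : deletions : duplications : IS
insertions, and noiseless assays.  Hosts get a gene uniformly over the
13 mutable pathway genes; the predicted class is the canonical key of
the knockout structure.  With probability `hidden_split_prob` a
predicted class with ≥ 2 strains is split into two nonempty true
subclasses — the generator's rendering of receptor diversity the
pathway model cannot see.  True classes always refine predicted classes
(asserted per replicate).  Phage capabilities default to
`one_per_true_class`, cycling one dedicated phage per true class plus
random extras, so every true class is discriminable and, at zero noise,
the profile partition equals the true partition and hidden splits force
the observed profile count above the predicted class count — the
study's central signature, reproduced by construction.  Assay noise is a
symmetric per-cell Bernoulli flip; real assay error is plausibly
asymmetric, but no rates are available to calibrate asymmetry, so
symmetric is the default.

What passing these tests does *not* show about real data: the generator
draws genes uniformly (real mutation targets are biased), plants clean
capability sets (real host ranges arise from molecular epistasis), and
its noise is independent across cells (real assay artifacts correlate
within plates).  It validates the machinery, not the biology.

## Problem sizes and run times

All packaged analyses are desk-scale: 31–32 hosts × 16–17 phages, a
10-residue pathway, ≤ 3,000-strain draws for the law-of-large-numbers
check, 50-replicate recovery experiments, and 1,000-case clustering
oracle sweeps — each finishing in seconds on one CPU.

## Known limitations

* The packaged tables are reconstructions pinned by printed statements,
  not the original supplementary data; entries not pinned are synthetic
  and marked as such in the file headers.  Aggregate quantities checked
  in the tests (class counts, profile counts, uniqueness tallies,
  contiguity) are pinned; individual unpinned cells are not evidential.
* No chemistry: linkage stereochemistry, sugar masses, O-antigen and
  smooth LPS, and assembly kinetics are out of scope, as are
  evolutionary dynamics of the phage populations.
* The contiguity count is convention-sensitive by nature; always read it
  together with the sensitivity grid.
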