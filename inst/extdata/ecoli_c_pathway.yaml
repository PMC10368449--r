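# E. coli C rough-type core-oligosaccharide assembly graph.
#
# Each backbone residue names its attachment point (parent), the
# glycosyltransferase gene(s) that attach it, and the gene(s) required to
# supply its sugar-nucleotide precursor (ADP-heptose: gmhA/gmhB/gmhD/hldE;
# UDP-glucose: galU; UDP-galactose additionally galE).  Decorations
# (phosphates, EtNP, the third Kdo) are modification nodes on a target
# residue.  Nonstoichiometric decorations are flagged and excluded from
# structure identity.  The exact naming/order of the outer-core hexoses is
# a transcription choice; structure-class counts do not depend on it.
#
# "?P" uncertainty: the phosphorylation state of Hep-I when Hep-II is
# missing is not established; the model keeps Hep-I-P present by default
# (uncertain: true records the flag).
name: ecoli_c_rough_lps
regulators: [rfaH]
# LPS biosynthesis genes considered mutable targets for phage resistance.
lps_genes: [waaC, waaF, waaG, waaO, waaT, waaW, waaP,
            galU, galE, gmhA, gmhB, gmhD, hldE]
residues:
  - {name: LipidA,  parent: ~,      transferases: [],     precursors: [],                       inner_core: true}
  - {name: Kdo-I,   parent: LipidA, transferases: [waaA], precursors: [],                       inner_core: true}
  - {name: Kdo-II,  parent: Kdo-I,  transferases: [waaA], precursors: [],                       inner_core: true}
  - {name: Hep-I,   parent: Kdo-I,  transferases: [waaC], precursors: [gmhA, gmhB, gmhD, hldE], inner_core: true}
  - {name: Hep-II,  parent: Hep-I,  transferases: [waaF], precursors: [gmhA, gmhB, gmhD, hldE], inner_core: true}
  - {name: Hep-III, parent: Hep-II, transferases: [waaQ], precursors: [gmhA, gmhB, gmhD, hldE], inner_core: true}
  - {name: Glc-I,   parent: Hep-II, transferases: [waaG], precursors: [galU],                   inner_core: false}
  - {name: Glc-II,  parent: Glc-I,  transferases: [waaO], precursors: [galU],                   inner_core: false}
  - {name: Gal-I,   parent: Glc-II, transferases: [waaT], precursors: [galU, galE],             inner_core: false}
  - {name: Gal-II,  parent: Gal-I,  transferases: [waaW], precursors: [galU, galE],             inner_core: false}
modifications:
  - {name: Hep-I-P,     target: Hep-I,  genes: [waaP], phosphate: true,  nonstoichiometric: false, uncertain: true}
  - {name: Hep-II-P,    target: Hep-II, genes: [waaP], phosphate: true,  nonstoichiometric: true}
  - {name: Kdo-II-EtNP, target: Kdo-II, genes: [eptB], phosphate: false, nonstoichiometric: true}
  - {name: Kdo-III,     target: Kdo-II, genes: [waaZ], phosphate: false, nonstoichiometric: true}
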