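# Reported dataset-level conservation of sites in one-to-one orthologs
# across 18 primate species: site counts and percent fully conserved,
# for ligand-binding sites (pooled and per ligand type) and background
# site classes.
class	n_sites	percent_conserved
other_sites	2588980	77.26
other_sites_within_domains	1082970	84.63
ligand_binding	67823	89.23
DNA	20105	91.22
RNA	4668	93.38
small_molecule	14134	88.96
ion	22771	87.95
peptide	12639	88.96
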