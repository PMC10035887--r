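# Small fixtures built in code.

fixtureTree4 <- function() {
  PrimatePhylogeny(ape::read.tree(
    text = "((A:0.3,B:0.5):0.2,(C:0.4,D:0.1):0.6);"))
}

fixtureTree6 <- function() {
  PrimatePhylogeny(ape::read.tree(
    text = "(((A:0.2,B:0.3):0.15,C:0.5):0.1,((D:0.25,E:0.35):0.2,F:0.4):0.3);"))
}

# an 18-species orthogroup whose columns are given explicitly;
# cols: character matrix species x columns
orthogroupFromColumns <- function(cols, id = "OGX", gene = id) {
  seqs <- apply(cols, 1, paste, collapse = "")
  Orthogroup(seqs, id = id, gene = gene)
}

# uniform alignment: every species carries the same sequence
uniformOrthogroup <- function(seq = "ARNDCQEGHIKLMFPSTWYV", species = NULL,
                              id = "OGU") {
  if (is.null(species)) species <- taxonLabels(loadReferenceTree())
  Orthogroup(setNames(rep(seq, length(species)), species), id = id)
}

# one-domain profile in which every match state is binding for `ligand`
allBindingProfile <- function(domain = "DMX", len = 10,
                              ligand = "DNA", precision = 0.9) {
  data.frame(domain_id = domain, ligand_type = ligand,
             match_state = seq_len(len),
             binding_frequency = 0.5, cv_precision = precision,
             stringsAsFactors = FALSE)
}

matchRows <- function(gene, domain, states, positions) {
  data.frame(gene = gene, domain_id = domain, match_state = states,
             human_position = positions, stringsAsFactors = FALSE)
}
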