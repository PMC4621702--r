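# Fixed molecule panel with hand-derived pharmacophore counts.
# The expected table was produced by applying the typing definitions
# (donor/acceptor/aromatic/hydrophobe/halogen/ring-methyl) to each
# molecular graph by hand, before the implementation existed:
#  - phenol: OH is donor and acceptor; one aromatic ring
#  - benzamide: NH2 donor; carbonyl O acceptor; amide N excluded from
#    acceptors (N-C=O); one ring
#  - acetic acid: OH donor; carbonyl O acceptor; acid OH excluded from
#    acceptors (O on C=O); methyl on carbon -> hydrophobe, no ring
#  - anisole: ether O acceptor; OCH3 methyl sits on O, not carbon -> no
#    hydrophobe, and not on a ring atom -> no ring-methyl
#  - aniline: NH2 both donor and acceptor (no adjacent hetero double bond)
#  - pyridine: ring N (no H) acceptor only
#  - toluene / 4-chlorotoluene: methyl on an aromatic carbon is both
#    ring-methyl and hydrophobe
panelMolecules <- function() {
  data.frame(
    name = c("phenol", "chlorobenzene", "toluene", "benzamide", "ethanol",
             "pyridine", "acetic_acid", "anisole", "aniline",
             "chlorotoluene"),
    smiles = c("Oc1ccccc1", "Clc1ccccc1", "Cc1ccccc1", "NC(=O)c1ccccc1",
               "CCO", "c1ccncc1", "CC(=O)O", "COc1ccccc1", "Nc1ccccc1",
               "Cc1ccc(Cl)cc1"),
    Donor      = c(1, 0, 0, 1, 1, 0, 1, 0, 1, 0),
    Acceptor   = c(1, 0, 0, 1, 1, 1, 1, 1, 1, 0),
    Aromatic   = c(1, 1, 1, 1, 0, 1, 0, 1, 1, 1),
    Hydrophobe = c(0, 0, 1, 0, 1, 0, 1, 0, 0, 1),
    Halogen    = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 1),
    RingMethyl = c(0, 0, 1, 0, 0, 0, 0, 0, 0, 1),
    stringsAsFactors = FALSE)
}

pharmaCountsFor <- function(smiles, name = "x") {
  ph <- detectPharmacophores(demoLigandPose(smiles, modelId = name))
  counts <- table(factor(ph$kind, levels = c("Donor", "Acceptor", "Aromatic",
                                             "Hydrophobe", "Halogen",
                                             "RingMethyl")))
  as.integer(counts)
}
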