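# Small structure fixtures built in code.

.pdbLine <- function(type, serial, name, alt, resn, chain, resno, x, y, z,
                     occ = 1, b = 0, element = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resn, chain, resno, x, y, z, occ, b,
          element)
}

# a toy chain: three glycines, two waters, one ethanol hetero group, one
# hydrogen that must be dropped
writeToyPdb <- function(path, altlocLines = FALSE, secondLigand = FALSE) {
  l <- character(0)
  s <- 0
  for (r in 1:3) {
    for (a in list(c("N", 0), c("CA", 1.5), c("C", 3))) {
      s <- s + 1
      l <- c(l, .pdbLine("ATOM", s, a[[1]], " ", "GLY", "A", r,
                         as.numeric(a[[2]]), r * 3, 0))
    }
  }
  s <- s + 1
  l <- c(l, .pdbLine("ATOM", s, "H", " ", "GLY", "A", 3, 3.5, 9, 0,
                     element = "H"))
  if (altlocLines) {
    s <- s + 1
    l <- c(l, .pdbLine("ATOM", s, "CB", "A", "GLY", "A", 3, 4, 9, 0,
                       occ = 0.6, element = "C"))
    s <- s + 1
    l <- c(l, .pdbLine("ATOM", s, "CB", "B", "GLY", "A", 3, 4.4, 9, 0,
                       occ = 0.4, element = "C"))
  }
  for (w in 1:2) {
    s <- s + 1
    l <- c(l, .pdbLine("HETATM", s, "O", " ", "HOH", "A", 100 + w,
                       10 + w, 10, 10, element = "O"))
  }
  eth <- function(resno, dz) {
    c(.pdbLine("HETATM", s + 1, "C1", " ", "ETH", "A", resno, 0, -5, dz,
               element = "C"),
      .pdbLine("HETATM", s + 2, "C2", " ", "ETH", "A", resno, 1.52, -5, dz,
               element = "C"),
      .pdbLine("HETATM", s + 3, "O1", " ", "ETH", "A", resno, 2.02, -3.66,
               dz, element = "O"))
  }
  l <- c(l, eth(200, 0)); s <- s + 3
  if (secondLigand) { l <- c(l, eth(201, 8)); s <- s + 3 }
  writeLines(c(l, "END"), path)
  path
}

writeToyManifest <- function(dir, n = 2, smiles = "CCO", badRow = NA) {
  pdbs <- character(n)
  for (i in seq_len(n)) {
    pdbs[i] <- file.path(dir, sprintf("toy%02d.pdb", i))
    writeToyPdb(pdbs[i])
  }
  df <- data.frame(pdb_path = basename(pdbs), smiles = smiles,
                   model_id = sprintf("t%02d", seq_len(n)),
                   chain = "A", stringsAsFactors = FALSE)
  if (!is.na(badRow)) df$pdb_path[badRow] <- "does_not_exist.pdb"
  manifest <- file.path(dir, "manifest.csv")
  write.csv(df, manifest, row.names = FALSE, quote = FALSE)
  manifest
}

# residue conformation helper
conf <- function(coords, names = paste0("A", seq_len(nrow(coords))),
                 resname = "ALA") {
  list(identity = c(chain = "A", resno = "1", insert = "",
                    resname = resname),
       atomNames = names, coords = coords)
}

# in-memory synthetic models/ensembles for summary-level tests
makeModel <- function(id, smiles = "Oc1ccccc1", shift = c(0, 0, 0),
                      waterPts = NULL, residues = list()) {
  pose <- demoLigandPose(smiles, modelId = id, shift = shift)
  w <- if (is.null(waterPts)) matrix(numeric(0), 0, 3)
       else matrix(waterPts, ncol = 3, byrow = TRUE)
  methods::new("StructureModel", modelId = id, chainId = "A",
               residues = residues, waters = w, ligand = pose)
}

ensembleOf <- function(...) {
  models <- list(...)
  methods::new("StructureEnsemble", models = models,
               records = data.frame(), manifestPath = NA_character_)
}
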