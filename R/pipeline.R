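# Pipeline orchestration: configuration, batch run, file outputs, the
# observation record and a minimal static HTML report.

#' Pipeline configuration
#'
#' Collects every tunable parameter with its default. The default lambda
#' values (Angstrom) are 1.5 for waters, 2.0 for pharmacophores and
#' fragments, 2.5 for residues and 5.0 for ligand sites; the ligand-water
#' contact cutoff is 1.5 Angstrom and the ligand-residue contact cutoff
#' 5.0 Angstrom. `minWaterConservation` defaults to 0 (report every
#' ligand-proximal water; presentation filters such as 0.85 are applied at
#' report level).
#'
#' @param lamWater,lamPharma,lamFragment,lamResidue,lamLigand clustering
#'   penalties, Angstrom.
#' @param waterContact,residueContact ligand-proximity cutoffs, Angstrom.
#' @param minWaterConservation strict lower bound for the site-water table.
#' @param site `"main"` or an integer site id.
#' @param order column ordering: `"chem"` (Morgan/Butina) or `"manifest"`.
#' @param butinaCutoff Tanimoto distance threshold for compound ordering.
#' @param seed optional integer seed recorded and used for any stochastic
#'   step.
#' @param verbose print progress messages.
#' @return A validated configuration list.
#' @export
runConfig <- function(lamWater = 1.5, lamPharma = 2.0, lamFragment = 2.0,
                      lamResidue = 2.5, lamLigand = 5.0,
                      waterContact = 1.5, residueContact = 5.0,
                      minWaterConservation = 0, site = "main",
                      order = c("chem", "manifest"), butinaCutoff = 0.4,
                      seed = NULL, verbose = FALSE) {
  order <- match.arg(order)
  cfg <- list(lamWater = lamWater, lamPharma = lamPharma,
              lamFragment = lamFragment, lamResidue = lamResidue,
              lamLigand = lamLigand, waterContact = waterContact,
              residueContact = residueContact,
              minWaterConservation = minWaterConservation, site = site,
              order = order, butinaCutoff = butinaCutoff, seed = seed,
              verbose = verbose)
  num <- c("lamWater", "lamPharma", "lamFragment", "lamResidue",
           "lamLigand", "waterContact", "residueContact")
  for (p in num)
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1L || cfg[[p]] <= 0)
      stop("usage error: '", p, "' must be a positive number")
  if (minWaterConservation < 0 || minWaterConservation >= 1)
    stop("usage error: 'minWaterConservation' must be in [0, 1)")
  cfg
}

.summaryToList <- function(s) {
  list(
    provenance = s@provenance,
    sites = s@sites,
    siteMembers = s@siteMembers,
    waterClusters = s@waterClusters@clusters,
    siteWaters = s@siteWaters,
    displacement = list(
      rows = rownames(s@displacement),
      columns = colnames(s@displacement),
      cells = unname(apply(s@displacement, 1L, as.logical,
                           simplify = FALSE))),
    pharmacophoreClusters = s@pharmacophoreClusters,
    presence = list(
      rows = rownames(s@presence),
      columns = colnames(s@presence),
      cells = unname(apply(s@presence, 1L, as.logical, simplify = FALSE))),
    residueRanking = s@residueRanking,
    residueAssignments = s@residueAssignments,
    fragmentClusters = s@fragmentClusters,
    compoundOrder = s@compoundOrder
  )
}

.writeMatrixCsv <- function(m, file) {
  df <- as.data.frame(m)
  df <- cbind(row = rownames(m), df)
  utils::write.csv(df, file, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes manifest parsing, structure loading (a bad row is skipped with
#' a warning), feature extraction, clustering and summarisation, and writes
#' the result tables to `outDir`: `sites.csv`, `waters.csv`,
#' `water_displacement.csv`, `pharmacophores.csv`,
#' `pharmacophore_presence.csv`, `residues.csv`, `residue_assignments.csv`,
#' `compound_order.csv`, `fragment_clusters.csv` and `summary.json` (the
#' full bundle with parameter provenance and input checksums).
#'
#' @param manifestPath path to the CSV manifest.
#' @param outDir output directory (created if needed).
#' @param config a [runConfig()] list.
#' @return The [EnsembleSummary-class], invisibly.
#' @export
runPipeline <- function(manifestPath, outDir, config = runConfig()) {
  ensemble <- readEnsemble(manifestPath, skipFailures = TRUE)
  if (config$verbose)
    message("loaded ", nModels(ensemble), " models from ", manifestPath)
  s <- summariseEnsemble(ensemble, config, siteId = config$site)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(s@sites, file.path(outDir, "sites.csv"),
                   row.names = FALSE)
  utils::write.csv(s@waterClusters@clusters,
                   file.path(outDir, "waters.csv"), row.names = FALSE)
  .writeMatrixCsv(s@displacement,
                  file.path(outDir, "water_displacement.csv"))
  utils::write.csv(s@pharmacophoreClusters,
                   file.path(outDir, "pharmacophores.csv"),
                   row.names = FALSE)
  .writeMatrixCsv(s@presence,
                  file.path(outDir, "pharmacophore_presence.csv"))
  utils::write.csv(s@residueRanking, file.path(outDir, "residues.csv"),
                   row.names = FALSE)
  utils::write.csv(s@residueAssignments,
                   file.path(outDir, "residue_assignments.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(order = seq_along(s@compoundOrder),
                              modelId = s@compoundOrder),
                   file.path(outDir, "compound_order.csv"),
                   row.names = FALSE)
  utils::write.csv(s@fragmentClusters,
                   file.path(outDir, "fragment_clusters.csv"),
                   row.names = FALSE)
  jsonlite::write_json(.summaryToList(s), file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(s)
}

#' Generate the demonstration ensemble and analyse it
#'
#' Writes the synthetic demo ensemble (see [defaultDemoSpec()]) under
#' `outDir/ensemble` and runs the full pipeline on it, writing the summary
#' tables to `outDir`. Fully deterministic for a given seed.
#'
#' @param outDir output directory.
#' @param seed integer seed for the generator.
#' @param config a [runConfig()] list.
#' @return A list: `generated` (paths + truth) and `summary` (the
#'   [EnsembleSummary-class]).
#' @export
runDemo <- function(outDir, seed = 17L, config = runConfig(seed = seed)) {
  gen <- generateEnsemble(defaultDemoSpec(seed = seed),
                          file.path(outDir, "ensemble"))
  s <- runPipeline(gen$manifest, outDir, config)
  list(generated = gen, summary = s)
}

.canonicalJson <- function(x) {
  srt <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v))) v <- v[order(names(v))]
      lapply(v, srt)
    } else v
  }
  jsonlite::toJSON(srt(x), auto_unbox = TRUE, digits = NA)
}

#' Save an observation record
#'
#' Captures a shareable observation about a summarised ensemble: author,
#' free-text comment and the view payload (model ids, cluster rows, site).
#' The record is appended to `observations.jsonl` next to the bundle; its
#' id is a content hash of the canonicalised payload, so saving the same
#' observation twice is de-duplicated.
#'
#' @param summary an [EnsembleSummary-class] (used for reference
#'   validation).
#' @param file path of the `observations.jsonl` file to append to.
#' @param author author name.
#' @param comment observation text.
#' @param models modelIds the view shows.
#' @param clusters pharmacophore/water cluster rows the view shows.
#' @param site site id of the view.
#' @return The observation record (list) with its `id`, invisibly.
#' @export
saveObservation <- function(summary, file, author, comment,
                            models = character(0), clusters = integer(0),
                            site = 1L) {
  known <- unlist(summary@siteMembers, use.names = FALSE)
  bad <- setdiff(models, known)
  if (length(bad))
    stop("validation error: unknown model id(s): ",
         paste(bad, collapse = ", "))
  if (length(site) != 1L || !site %in% summary@sites$siteId)
    stop("validation error: unknown site id: ", site)
  payload <- list(author = author, comment = comment,
                  view = list(models = as.character(models),
                              clusters = as.integer(clusters),
                              site = as.integer(site)),
                  provenance = summary@provenance$inputChecksums)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(.canonicalJson(payload)), tf)
  id <- unname(tools::md5sum(tf))
  rec <- c(list(id = id), payload,
           list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  dedup <- FALSE
  if (file.exists(file)) {
    existing <- readLines(file, warn = FALSE)
    ids <- vapply(existing, function(l)
      jsonlite::fromJSON(l)$id %||% "", character(1), USE.NAMES = FALSE)
    dedup <- id %in% ids
  }
  if (!dedup)
    cat(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)),
        "\n", sep = "", file = file, append = TRUE)
  invisible(rec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.htmlGrid <- function(m, trueColour, falseColour, highlight = character(0)) {
  if (nrow(m) == 0L) return("<p>empty</p>")
  hdr <- paste0("<tr><th></th>", paste0(
    "<th", ifelse(colnames(m) %in% highlight,
                  " style='border:2px solid red'", ""), ">",
    colnames(m), "</th>", collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(m)), function(r) {
    cells <- paste0("<td style='background:",
                    ifelse(m[r, ], trueColour, falseColour),
                    ";width:1.2em'>&nbsp;</td>", collapse = "")
    paste0("<tr><th>", rownames(m)[r], "</th>", cells, "</tr>")
  }, character(1))
  paste0("<table border='1' style='border-collapse:collapse'>", hdr,
         paste(rows, collapse = ""), "</table>")
}

.htmlTable <- function(df) {
  if (nrow(df) == 0L) return("<p>empty</p>")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  hdr <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""),
                "</tr>")
  rows <- apply(df, 1L, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0("<table border='1' style='border-collapse:collapse'>", hdr,
         paste(rows, collapse = ""), "</table>")
}

#' Render a static HTML report of a summary
#'
#' A single self-contained page with the ranked summary tables and the
#' presence/displacement grids (green = ligand presents the feature,
#' white = absent/displaced; highlighted columns outlined in red). No
#' external resources.
#'
#' @param summary an [EnsembleSummary-class].
#' @param file output HTML path.
#' @param highlight modelIds whose columns are outlined.
#' @return `file`, invisibly.
#' @export
renderReport <- function(summary, file, highlight = character(0)) {
  empty <- length(summary@compoundOrder) == 0L
  body <- if (empty) "<p>no models</p>" else paste0(
    "<h2>Binding sites</h2>", .htmlTable(summary@sites),
    "<h2>Conserved waters (ligand-proximal, conservation ranked)</h2>",
    .htmlTable(summary@siteWaters),
    "<h2>Water displacement (white = displaced)</h2>",
    .htmlGrid(!summary@displacement, "#7c7", "#fff", highlight),
    "<h2>Pharmacophore clusters (size ranked)</h2>",
    .htmlTable(summary@pharmacophoreClusters),
    "<h2>Pharmacophore presence (green = present)</h2>",
    .htmlGrid(summary@presence, "#7c7", "#fff", highlight),
    "<h2>Residue ranking (max pairwise RMSD)</h2>",
    .htmlTable(summary@residueRanking),
    "<h2>Compound order</h2>",
    "<p>", paste(summary@compoundOrder, collapse = ", "), "</p>")
  html <- paste0("<!DOCTYPE html><html><head><meta charset='utf-8'>",
                 "<title>Ensemble summary</title></head><body>",
                 "<h1>Protein-ligand ensemble summary</h1>", body,
                 "</body></html>")
  writeLines(html, file)
  invisible(file)
}
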