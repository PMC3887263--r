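## End-to-end workflows: (1) ESI peak-list annotation and (2) structure /
## energetics reporting, with serialized run configuration so any run can
## be reproduced bit-for-bit.

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the MS annotation workflow
#'
#' Enumerates candidate ions for each spectrum's polarity (plus, in
#' positive mode, the protonated glucose-oligomer fragment ions of the
#' host), assigns peaks, scores isotope profiles of rank-1 assignments
#' when intensities carry information, and optionally writes TSV/JSON
#' reports together with the resolved configuration.
#'
#' @param spectra List of [Spectrum-class] (or a single one).
#' @param species Named list of [MolecularSpecies-class] (default
#'   [defaultSpecies()]).
#' @param maxCounts,maxNa,maxZ Enumeration bounds passed to
#'   [enumerationBounds()].
#' @param tolDa,tolPpm Assignment tolerance (see [assignPeaks()]).
#' @param fragmentIons Inject glucose-oligomer fragment candidates in
#'   positive mode (default TRUE).
#' @param isotopeScores Add an `isotopeScore` column for rank-1 rows
#'   (default FALSE; needs meaningful intensities).
#' @param outDir Optional output directory for reports.
#' @return List with one element per spectrum: `assignments` (the
#'   [assignPeaks()] table), `nCandidates`, `nUnassigned`; plus `config`.
#' @export
runMsWorkflow <- function(spectra, species = defaultSpecies(),
                          maxCounts = NULL, maxNa = 4L, maxZ = 3L,
                          tolDa = 0.010, tolPpm = 15,
                          fragmentIons = TRUE, isotopeScores = FALSE,
                          outDir = NULL) {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop("need at least one spectrum")
  if (is.null(names(spectra)))
    names(spectra) <- paste0("spectrum", seq_along(spectra))
  config <- list(
    species = lapply(species, function(s) formulaString(s@formula)),
    bounds = list(maxCounts = if (is.null(maxCounts))
                    setNames(rep(4L, length(species)), names(species))
                  else maxCounts,
                  maxNa = maxNa, maxZ = maxZ),
    tolDa = tolDa, tolPpm = tolPpm, fragmentIons = fragmentIons,
    constantsVersion = constantsVersion())
  results <- list()
  for (nm in names(spectra)) {
    s <- spectra[[nm]]
    b <- enumerationBounds(species, polarity(s), maxCounts = config$bounds$maxCounts,
                           maxNa = maxNa, maxZ = maxZ)
    cand <- enumerateIons(species, b)
    if (fragmentIons && polarity(s) == "positive")
      cand <- c(cand, glucoseFragmentIons())
    asg <- assignPeaks(s, cand, tolDa = tolDa, tolPpm = tolPpm)
    if (isotopeScores) {
      asg$isotopeScore <- NA_real_
      top <- which(asg$assigned & asg$rank == 1L)
      byLabel <- setNames(cand, vapply(cand, ionLabel, character(1)))
      for (i in top)
        asg$isotopeScore[i] <- isotopeFit(s, byLabel[[asg$label[i]]],
                                          tolDa = tolDa, tolPpm = tolPpm)
    }
    nun <- sum(!asg$assigned)
    message(sprintf("%s: %d candidates, %d peaks, %d unassigned",
                    nm, length(cand), length(s), nun))
    results[[nm]] <- list(assignments = asg, nCandidates = length(cand),
                          nUnassigned = nun)
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(asg, file.path(outDir, paste0(nm, "_assignments.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      .writeJson(asg, file.path(outDir, paste0(nm, "_assignments.json")))
    }
  }
  if (!is.null(outDir))
    .writeJson(config, file.path(outDir, "run_config.json"))
  c(results, list(config = config))
}

#' Run the structure / energetics workflow
#'
#' For each orientation: detect intermolecular hydrogen bonds and compute
#' the complexation energy; with two or more orientations, rank them and
#' report pairwise energy differences.
#'
#' @param structures Named list of [StructureModel-class] objects or file
#'   paths (XYZ/PDB).
#' @param ledgers Named list of [EnergyLedger-class] objects or JSON
#'   paths, names matching `structures` (entries may be `NULL` when no
#'   energies are available for a geometry).
#' @param dRange,angleMin Hydrogen-bond criterion (see [detectHbonds()]).
#' @param outDir Optional output directory for reports.
#' @return List with `orientations` (per-name list of `hbonds`, `deltaE`)
#'   and `comparison` ([compareOrientations()] output, or `NULL` for a
#'   single orientation).
#' @export
runStructureWorkflow <- function(structures, ledgers = NULL,
                                 dRange = c(0.8, 2.8), angleMin = 120,
                                 outDir = NULL) {
  if (is(structures, "StructureModel")) structures <- list(structures)
  if (!length(structures)) stop("need at least one structure")
  if (is.null(names(structures)))
    names(structures) <- paste0("orientation", seq_along(structures))
  orientations <- list()
  for (nm in names(structures)) {
    st <- structures[[nm]]
    if (is.character(st)) st <- readStructure(st)
    hb <- detectHbonds(st, dRange = dRange, angleMin = angleMin)
    led <- ledgers[[nm]]
    if (is.character(led)) led <- readEnergyLedger(led)
    de <- if (is.null(led)) NA_real_ else deltaE(led)
    orientations[[nm]] <- list(hbonds = hb, deltaE = de)
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      writeHbondTable(hb, file.path(outDir, paste0(nm, "_hbonds.tsv")))
    }
  }
  comparison <- NULL
  withE <- Filter(function(o) !is.na(o$deltaE), orientations)
  if (length(withE) >= 2L)
    comparison <- compareOrientations(withE)
  if (!is.null(outDir)) {
    .writeJson(list(
      criterion = list(dRange = dRange, angleMin = angleMin),
      deltaE = lapply(orientations, `[[`, "deltaE"),
      nHbonds = lapply(orientations, function(o) nrow(o$hbonds)),
      comparison = if (!is.null(comparison)) comparison$table),
      file.path(outDir, "energetics_report.json"))
  }
  list(orientations = orientations, comparison = comparison)
}
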