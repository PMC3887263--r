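## Molecular structures: XYZ/PDB input, covalent-connectivity partitioning
## into molecules, and geometric hydrogen-bond detection/classification.

.distanceMatrix <- function(xyz) as.matrix(stats::dist(xyz))

## adjacency by covalent distance: bonded if d < 1.2 * (r_i + r_j)
.covalentAdjacency <- function(element, xyz) {
  d <- .distanceMatrix(xyz)
  r <- covalentRadius(element)
  cutoff <- 1.2 * outer(r, r, "+")
  adj <- d < cutoff & d > 0
  diag(adj) <- FALSE
  adj
}

.partitionMolecules <- function(element, xyz) {
  adj <- .covalentAdjacency(element, xyz)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  ## renumber contiguously in order of first appearance
  as.integer(match(memb, unique(memb)))
}

#' Build a structure model from atoms
#'
#' @param element Character vector of element symbols.
#' @param xyz n x 3 matrix of Cartesian coordinates in Angstrom.
#' @param provenance Free-text origin label.
#' @return A [StructureModel-class] with molecules partitioned by covalent
#'   connectivity (two atoms are bonded when their distance is below 1.2
#'   times the sum of their covalent radii).
#' @export
structureModel <- function(element, xyz, provenance = "in-memory") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  mol <- .partitionMolecules(element, xyz)
  new("StructureModel",
      atoms = data.frame(element = element, x = xyz[, 1], y = xyz[, 2],
                         z = xyz[, 3], molecule = mol),
      provenance = provenance)
}

#' Read a structure from an XYZ or PDB file
#'
#' XYZ: standard count/comment/element-x-y-z records. PDB: ATOM/HETATM
#' records of the first model, occupancy and altloc ignored (parsed with
#' bio3d). In both cases molecules are partitioned purely by geometry
#' (covalent connectivity), never by chain labels.
#'
#' @param path File path; format chosen by extension (`.xyz` or `.pdb`).
#' @return A [StructureModel-class].
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 3L) stop("malformed XYZ file: ", path)
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n) || n < 1L) stop("malformed XYZ atom count in ", path)
    if (length(lines) < n + 2L) stop("XYZ file truncated: ", path)
    rec <- strsplit(trimws(lines[3:(n + 2L)]), "[[:space:]]+")
    el <- vapply(rec, `[`, character(1), 1)
    xyz <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) stop("non-numeric coordinates in ", path)
    structureModel(el, xyz, provenance = basename(path))
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    at <- pdb$atom
    el <- trimws(at$elesy)
    miss <- !nzchar(el) | is.na(el)
    if (any(miss))  # fall back to the first letter of the atom name
      el[miss] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[miss])), 1, 1)
    el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
    structureModel(el, cbind(at$x, at$y, at$z), provenance = basename(path))
  } else stop("unsupported structure format: .", ext)
}

#' @rdname accessors
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("nMolecules", "StructureModel", function(x) max(x@atoms$molecule))

#' @export
setMethod("show", "StructureModel", function(object) {
  cat("StructureModel (", nrow(object@atoms), " atoms, ",
      nMolecules(object), " molecule(s); ", object@provenance, ")\n", sep = "")
})

## classify an accepted H-bond by the acceptor's chemical environment
.classifyHbond <- function(elD, elA, acceptorIdx, element, adj, d) {
  donorSide <- paste0(elD, "-H")   # e.g. "O-H"
  if (elA == "N") return(paste0("N...H-", elD))
  nb <- which(adj[acceptorIdx, ])
  pIdx <- nb[element[nb] == "P"]
  if (elA == "O" && length(pIdx)) {
    p <- pIdx[1]
    terminal <- length(nb) == 1L
    if (terminal) {
      ## among this P's terminal oxygens, the shortest P-O is taken as the
      ## formal double bond (heuristic: bond order is inferred from length)
      pnb <- which(adj[p, ])
      termO <- pnb[element[pnb] == "O" &
                   vapply(pnb, function(a) sum(adj[a, ]) == 1L, logical(1))]
      if (length(termO) && acceptorIdx == termO[which.min(d[p, termO])])
        return(paste0("P=O...H-", elD))
    }
    return(paste0("P-O...H-", elD))
  }
  paste0(donorSide, "...", elA)
}

#' Detect intermolecular hydrogen bonds by a geometric criterion
#'
#' A hydrogen bond D-H...A is reported when H is covalently bound to a
#' donor heavy atom D, D and A sit in different molecules, the H...A
#' distance lies in `dRange`, and the D-H...A angle exceeds `angleMin`.
#' Defaults follow the criterion used for cyclodextrin inclusion
#' complexes: H...A in 0.8-2.8 Angstrom and angle above 120 degrees.
#' Bonds are classified by the acceptor environment: N acceptors as
#' `"N...H-O"`; O acceptors bound to phosphorus as `"P=O...H-O"` (terminal
#' and shortest P-O of that phosphorus, a bond-length heuristic for the
#' formal double bond) or `"P-O...H-O"`; plain oxygen pairs as
#' `"O-H...O"`.
#'
#' @param structure A [StructureModel-class].
#' @param dRange Numeric length-2: allowed H...acceptor distance range in
#'   Angstrom (default `c(0.8, 2.8)`).
#' @param angleMin Minimum donor-H...acceptor angle in degrees (default
#'   120).
#' @param donorElements,acceptorElements Element sets for donor heavy
#'   atoms and acceptors (default O and N).
#' @return data.frame with one row per bond: atom indices `donor`,
#'   `hydrogen`, `acceptor`, the elements, `length` (H...A, Angstrom),
#'   `angle` (degrees), `class`, and the two molecule ids. Empty (zero
#'   rows) when nothing qualifies.
#' @export
detectHbonds <- function(structure, dRange = c(0.8, 2.8), angleMin = 120,
                         donorElements = c("O", "N"),
                         acceptorElements = c("O", "N")) {
  stopifnot(is(structure, "StructureModel"),
            length(dRange) == 2L, dRange[1] < dRange[2])
  at <- atoms(structure)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  el <- at$element
  adj <- .covalentAdjacency(el, xyz)
  d <- .distanceMatrix(xyz)
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donorElement = character(0),
                      acceptorElement = character(0), length = numeric(0),
                      angle = numeric(0), class = character(0),
                      donorMolecule = integer(0), acceptorMolecule = integer(0))
  hs <- which(el == "H")
  acc <- which(el %in% acceptorElements)
  if (!length(hs) || !length(acc)) return(empty)
  rows <- list()
  for (h in hs) {
    nb <- which(adj[h, ])
    dn <- nb[el[nb] %in% donorElements]
    if (!length(dn)) next
    dAtom <- dn[which.min(d[h, dn])]  # nearest covalent donor
    for (a in acc) {
      if (at$molecule[a] == at$molecule[dAtom]) next
      if (adj[h, a]) next
      len <- d[h, a]
      if (len < dRange[1] || len > dRange[2]) next
      v1 <- xyz[dAtom, ] - xyz[h, ]
      v2 <- xyz[a, ] - xyz[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang <= angleMin) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor = dAtom, hydrogen = h, acceptor = a,
        donorElement = el[dAtom], acceptorElement = el[a],
        length = len, angle = ang,
        class = .classifyHbond(el[dAtom], el[a], a, el, adj, d),
        donorMolecule = at$molecule[dAtom],
        acceptorMolecule = at$molecule[a])
    }
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(res$length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a hydrogen-bond table as TSV
#'
#' @param hbonds Output of [detectHbonds()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeHbondTable <- function(hbonds, path) {
  utils::write.table(hbonds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
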