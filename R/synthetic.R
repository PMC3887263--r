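## Synthetic data with known truth: simulated centroid ESI spectra (ppm
## jitter, decoy peaks) and planted hydrogen-bond geometries, so every
## analysis stage can be validated without instrument or quantum-chemistry
## output.

#' Simulate a centroided ESI spectrum with known truth
#'
#' Each ion contributes its leading isotopologues at theoretical m/z
#' perturbed by multiplicative Gaussian jitter of `jitterPpm` ppm
#' (instrument mass error is relative, so jitter is applied in ppm). Decoy
#' peaks are drawn uniformly over `decoyRange` and rejected inside an
#' exclusion zone of `max(3 * jitterPpm * 1e-6 * mz, 0.01)` Da around any
#' true isotopologue, which keeps truth labels unambiguous even at zero
#' jitter. Identical seeds give identical spectra.
#'
#' @param ions List of [IonSpecies-class], all of one polarity.
#' @param abundance Positive relative abundances, recycled to
#'   `length(ions)`.
#' @param jitterPpm Gaussian m/z jitter sigma in ppm (default 3).
#' @param nDecoys Number of decoy noise peaks (default 0).
#' @param decoyRange m/z range for decoys (default: true-peak range
#'   widened by 50 Th).
#' @param nIsotopologues Isotopologues kept per ion (default 3).
#' @param seed Integer RNG seed, recorded in the output.
#' @return List with `spectrum` (a [Spectrum-class]), `truth` (data.frame
#'   `label`, `mzTheo`, `mzObserved`, `abundance`, `isotopologue`, decoys
#'   excluded), and `seed`.
#' @export
simulateSpectrum <- function(ions, abundance = 1, jitterPpm = 3, nDecoys = 0,
                             decoyRange = NULL, nIsotopologues = 3, seed = 1) {
  stopifnot(length(ions) >= 1L, all(abundance > 0), jitterPpm >= 0)
  zs <- vapply(ions, function(i) i@z, integer(1))
  if (length(unique(sign(zs))) != 1L)
    stop("ions must share one polarity")
  pol <- if (zs[1] > 0) "positive" else "negative"
  abundance <- rep_len(abundance, length(ions))
  set.seed(seed)

  rows <- list()
  for (i in seq_along(ions)) {
    pat <- peaks(isotopePattern(ionFormula(ions[[i]])))
    k <- seq_len(min(nIsotopologues, nrow(pat)))
    mzTheo <- (pat$mass[k] - ions[[i]]@z * electronMass()) / abs(zs[i])
    mzObs <- mzTheo * (1 + stats::rnorm(length(k), 0, jitterPpm * 1e-6))
    rows[[i]] <- data.frame(label = ionLabel(ions[[i]]), mzTheo = mzTheo,
                            mzObserved = mzObs,
                            abundance = abundance[i] * pat$abundance[k],
                            isotopologue = k - 1L)
  }
  truth <- do.call(rbind, rows)

  decoyMz <- numeric(0)
  if (nDecoys > 0) {
    if (is.null(decoyRange))
      decoyRange <- range(truth$mzTheo) + c(-50, 50)
    decoyRange[1] <- max(decoyRange[1], 1)
    excl <- pmax(3 * jitterPpm * 1e-6 * truth$mzTheo, 0.01)
    tries <- 0L
    while (length(decoyMz) < nDecoys && tries < 1000L * nDecoys) {
      tries <- tries + 1L
      m <- stats::runif(1, decoyRange[1], decoyRange[2])
      if (all(abs(m - truth$mzTheo) > excl) &&
          (!length(decoyMz) || all(abs(m - decoyMz) > 0.01)))
        decoyMz <- c(decoyMz, m)
    }
    if (length(decoyMz) < nDecoys)
      stop("could not place all decoys outside exclusion zones")
  }
  decoyInt <- if (length(decoyMz))
    stats::runif(length(decoyMz), 0.01, 0.3) * max(truth$abundance) else numeric(0)

  mz <- c(truth$mzObserved, decoyMz)
  int <- c(truth$abundance, decoyInt)
  list(spectrum = newSpectrum(mz, int, pol), truth = truth, seed = seed)
}

## place one donor O-H and an acceptor group realizing an exact
## H...A distance and D-H...A angle, at a given origin
.plantUnit <- function(origin, distance, angle, class = "O-H...O") {
  if (distance <= 0 || angle <= 0 || angle > 180)
    stop("infeasible geometry request: distance ", distance,
         ", angle ", angle)
  dO <- origin
  h <- origin + c(0.96, 0, 0)          # covalent O-H bond
  phi <- pi - angle * pi / 180          # angle between H->D and H->A
  w <- c(cos(phi), sin(phi), 0)
  a <- h + distance * w
  el <- c("O", "H")
  xyz <- rbind(dO, h)
  accEl <- if (grepl("^N", class)) "N" else "O"
  el <- c(el, accEl)
  xyz <- rbind(xyz, a)
  if (grepl("^P=O", class)) {
    el <- c(el, "P")
    xyz <- rbind(xyz, a + 1.50 * w)
  } else if (grepl("^P-O", class)) {
    ## acceptor is the longer of two terminal P-O bonds, so it classifies
    ## as the formal single bond
    p <- a + 1.60 * w
    el <- c(el, "P", "O")
    xyz <- rbind(xyz, p, p + 1.48 * w)
  }
  list(element = el, xyz = unname(xyz))
}

#' Plant hydrogen-bond geometries with known truth
#'
#' For each requested bond an O-H donor group (O-H = 0.96 Angstrom) and an
#' acceptor atom (O, or N for `"N..."` classes; `"P=O"`/`"P-O"` classes
#' grow a phosphonate-like acceptor group) are placed so that the
#' H...acceptor distance and donor-H...acceptor angle are exactly the
#' requested values. Units are laid out on a grid 10 Angstrom apart so
#' they cannot interact; connectivity then puts donor and acceptor in
#' different molecules. Decoy oxygen atoms are scattered at least 3.5
#' Angstrom from every planted atom, strictly outside the detection
#' criterion. Identical seeds give identical structures.
#'
#' @param bonds data.frame with columns `distance` (Angstrom), `angle`
#'   (degrees) and optionally `class`.
#' @param nDecoys Number of decoy O atoms (default 0).
#' @param seed Integer RNG seed.
#' @return List with `structure` (a [StructureModel-class]), `truth`
#'   (data.frame `distance`, `angle`, `class`), and `seed`.
#' @examples
#' g <- plantHbondGeometry(data.frame(distance = 1.902, angle = 158.76))
#' detectHbonds(g$structure)
#' @export
plantHbondGeometry <- function(bonds, nDecoys = 0, seed = 1) {
  stopifnot(is.data.frame(bonds),
            all(c("distance", "angle") %in% names(bonds)) || nrow(bonds) == 0L)
  set.seed(seed)
  cls <- if ("class" %in% names(bonds)) bonds$class else
    rep("O-H...O", nrow(bonds))
  el <- character(0)
  xyz <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nrow(bonds))) {
    u <- .plantUnit(c(10 * (i - 1), 0, 0), bonds$distance[i], bonds$angle[i],
                    cls[i])
    el <- c(el, u$element)
    xyz <- rbind(xyz, u$xyz)
  }
  if (nDecoys > 0) {
    lo <- if (nrow(xyz)) apply(xyz, 2, min) - 6 else c(-10, -10, -10)
    hi <- if (nrow(xyz)) apply(xyz, 2, max) + 6 else c(10, 10, 10)
    placed <- 0L
    tries <- 0L
    while (placed < nDecoys && tries < 1000L * nDecoys) {
      tries <- tries + 1L
      p <- stats::runif(3, lo, hi)
      dd <- if (nrow(xyz)) sqrt(colSums((t(xyz) - p)^2)) else Inf
      if (all(dd >= 3.5)) {
        el <- c(el, "O")
        xyz <- rbind(xyz, p)
        placed <- placed + 1L
      }
    }
    if (placed < nDecoys) stop("could not place all decoy atoms")
  }
  truth <- data.frame(distance = bonds$distance,
                      angle = bonds$angle, class = cls)
  list(structure = structureModel(el, xyz, provenance = "planted"),
       truth = truth, seed = seed)
}

#' Write a structure to an XYZ file
#'
#' @param structure A [StructureModel-class].
#' @param path Output file.
#' @param comment Comment line (default: the provenance label).
#' @return `path`, invisibly.
#' @export
writeXyz <- function(structure, path, comment = structure@provenance) {
  at <- atoms(structure)
  lines <- c(nrow(at), comment,
             sprintf("%-2s %14.8f %14.8f %14.8f", at$element, at$x, at$y, at$z))
  writeLines(lines, path)
  invisible(path)
}

#' Precision/recall of a recovery run against planted truth
#'
#' Greedily matches result rows to truth rows on the `by` columns: numeric
#' columns match within the corresponding `tol`, character columns must be
#' equal. Each truth row is matched at most once (smallest summed absolute
#' deviation first).
#'
#' @param truth,result data.frames sharing the `by` columns.
#' @param by Column names to match on.
#' @param tol Numeric tolerance per `by` column (ignored for character
#'   columns; recycled).
#' @return List with `precision`, `recall`, `meanAbsError` (mean absolute
#'   deviation over matched numeric columns; NA if nothing matched),
#'   `nTruth`, `nResult`, `nMatched`.
#' @export
evaluateRecovery <- function(truth, result, by, tol = 0) {
  tol <- rep_len(tol, length(by))
  nT <- nrow(truth); nR <- nrow(result)
  if (nT == 0L && nR == 0L)
    return(list(precision = 1, recall = 1, meanAbsError = NA_real_,
                nTruth = 0L, nResult = 0L, nMatched = 0L))
  usedR <- logical(nR)
  matched <- 0L
  errs <- numeric(0)
  for (i in seq_len(nT)) {
    devs <- rep(Inf, nR)
    for (j in seq_len(nR)) {
      if (usedR[j]) next
      dev <- 0
      ok <- TRUE
      for (k in seq_along(by)) {
        tv <- truth[[by[k]]][i]; rv <- result[[by[k]]][j]
        if (is.numeric(tv)) {
          if (abs(rv - tv) > tol[k]) { ok <- FALSE; break }
          dev <- dev + abs(rv - tv)
        } else if (!identical(as.character(tv), as.character(rv))) {
          ok <- FALSE; break
        }
      }
      if (ok) devs[j] <- dev
    }
    j <- which.min(devs)
    if (length(j) && is.finite(devs[j])) {
      usedR[j] <- TRUE
      matched <- matched + 1L
      nNum <- sum(vapply(by, function(b) is.numeric(truth[[b]]), logical(1)))
      errs <- c(errs, if (nNum > 0) devs[j] / nNum else 0)
    }
  }
  list(precision = if (nR == 0L) 1 else matched / nR,
       recall = if (nT == 0L) 1 else matched / nT,
       meanAbsError = if (matched) mean(errs) else NA_real_,
       nTruth = nT, nResult = nR, nMatched = matched)
}
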