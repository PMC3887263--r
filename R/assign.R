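## Peak assignment: match observed centroids to candidate ions by exact
## mass, rank by mass error with parsimony tie-breaks, and score isotope
## profiles.

.massGate <- function(mz, tolDa, tolPpm) pmax(tolDa, tolPpm * 1e-6 * mz)

#' Assign observed peaks to candidate ions
#'
#' A peak matches a candidate when the absolute m/z error is within
#' `max(tolDa, tolPpm * 1e-6 * mz)`. Matches per peak are ranked by
#' `|delta m|`, ties broken by parsimony: fewer total stoichiometric
#' components, lower charge magnitude, fewer sodium adducts, then label.
#' Ranking depends only on m/z, never on intensity. Peaks without a match
#' are reported unassigned, with the nearest-miss candidate for diagnosis.
#'
#' @param spectrum A [Spectrum-class].
#' @param candidates List of [IonSpecies-class] sharing the spectrum's
#'   polarity.
#' @param tolDa Absolute tolerance in Da (default 0.010).
#' @param tolPpm Relative tolerance in ppm (default 15); the larger of the
#'   two gates applies.
#' @return data.frame with one row per (peak, matching candidate) plus one
#'   row per unassigned peak: `mz`, `intensity`, `assigned`, `label`,
#'   `mzTheo`, `deltaMda` (observed - theoretical, mDa), `deltaPpm`, `z`,
#'   `rank` (NA for unassigned; their `label`/`mzTheo` describe the nearest
#'   miss).
#' @examples
#' sp <- defaultSpecies()
#' cand <- enumerateIons(sp, enumerationBounds(sp, "negative"))
#' assignPeaks(newSpectrum(690.682, 100, "negative"), cand)
#' @export
assignPeaks <- function(spectrum, candidates, tolDa = 0.010, tolPpm = 15) {
  stopifnot(is(spectrum, "Spectrum"), tolDa > 0, tolPpm >= 0)
  pol <- if (polarity(spectrum) == "positive") 1L else -1L
  zs <- vapply(candidates, function(i) i@z, integer(1))
  if (any(sign(zs) != pol))
    stop("candidate polarity does not match the spectrum")
  theo <- vapply(candidates, mzOfIon, numeric(1))
  lab <- vapply(candidates, ionLabel, character(1))
  ncomp <- vapply(candidates, function(i) sum(i@counts), integer(1))
  nna <- vapply(candidates, function(i) i@nNa, integer(1))
  pk <- peaks(spectrum)
  out <- vector("list", nrow(pk))
  for (i in seq_len(nrow(pk))) {
    mz <- pk$mz[i]
    dm <- mz - theo
    gate <- .massGate(mz, tolDa, tolPpm)
    hit <- which(abs(dm) <= gate)
    if (length(hit)) {
      ## round the error to 1e-9 Da so stoichiometric multiples of one ion
      ## (identical m/z up to floating point) fall through to the
      ## parsimony tie-breaks
      ord <- hit[order(round(abs(dm[hit]), 9), ncomp[hit], abs(zs[hit]),
                       nna[hit], lab[hit])]
      out[[i]] <- data.frame(
        mz = mz, intensity = pk$intensity[i], assigned = TRUE,
        label = lab[ord], mzTheo = theo[ord], deltaMda = 1e3 * dm[ord],
        deltaPpm = 1e6 * dm[ord] / mz, z = zs[ord],
        rank = seq_along(ord))
    } else {
      near <- if (length(theo))
        order(round(abs(dm), 9), ncomp, abs(zs), nna, lab)[1] else integer(0)
      out[[i]] <- data.frame(
        mz = mz, intensity = pk$intensity[i], assigned = FALSE,
        label = if (length(near)) lab[near] else NA_character_,
        mzTheo = if (length(near)) theo[near] else NA_real_,
        deltaMda = if (length(near)) 1e3 * dm[near] else NA_real_,
        deltaPpm = if (length(near)) 1e6 * dm[near] / mz else NA_real_,
        z = if (length(near)) zs[near] else NA_integer_,
        rank = NA_integer_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Isotope-profile score of an assignment
#'
#' Cosine similarity between observed and theoretical satellite
#' isotopologue intensities (A+1 ... A+n-1) of the hypothesized ion, at the
#' theoretical positions spaced by about 1.00336/|z|. The monoisotopic peak
#' is excluded: it anchored the exact-mass match, so the satellites carry
#' all the independent isotope-profile evidence. Observed isotopologues
#' with no peak within tolerance contribute zero intensity, so a large
#' formula whose A+1 partner is absent scores near 0, and a wrong charge
#' hypothesis (wrong spacing) loses the satellites that fall between
#' observed peaks.
#'
#' @param spectrum A [Spectrum-class] with intensities.
#' @param ion The hypothesized [IonSpecies-class].
#' @param n Number of isotopologues including the monoisotopic anchor
#'   (>= 2; default 4).
#' @param tolDa,tolPpm Match tolerance for locating observed isotopologues.
#' @return Cosine similarity in [0, 1], or `NA` when the formula has no
#'   theoretical satellites above 1e-4 relative abundance (single-isotope
#'   species).
#' @export
isotopeFit <- function(spectrum, ion, n = 4L, tolDa = 0.010, tolPpm = 15) {
  stopifnot(n >= 2L)
  pat <- peaks(isotopePattern(ionFormula(ion)))
  zmag <- abs(ion@z)
  pos <- (pat$mass - ion@z * electronMass()) / zmag
  keep <- seq_len(min(n, nrow(pat)))[-1L]  # satellites only
  if (!length(keep)) return(NA_real_)
  theoI <- pat$abundance[keep]
  pk <- peaks(spectrum)
  obsI <- vapply(pos[keep], function(p) {
    gate <- .massGate(p, tolDa, tolPpm)
    sel <- abs(pk$mz - p) <= gate
    if (any(sel)) max(pk$intensity[sel]) else 0
  }, numeric(1))
  ## scale observed by the observed monoisotopic peak so intensity units drop
  gate0 <- .massGate(pos[1], tolDa, tolPpm)
  sel0 <- abs(pk$mz - pos[1]) <= gate0
  if (any(sel0)) obsI <- obsI / max(pk$intensity[sel0])
  if (all(obsI == 0)) return(0)
  sum(obsI * theoI) / sqrt(sum(obsI^2) * sum(theoI^2))
}
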