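## MS/MS interpretation: annotate product-ion spectra as chains of
## sequential neutral losses from a singly charged precursor.

#' Common neutral losses of the bisphosphonate/cyclodextrin system
#'
#' Phosphonate chemistry loses phosphorous acid (H3PO3), water (H2O) and
#' metaphosphorous acid (HPO2); cyclodextrins lose successive glucose
#' units (C6H10O5).
#'
#' @param glucose Include the glucose-unit loss (default TRUE).
#' @return Named list of [ElementalFormula-class] losses.
#' @export
defaultNeutralLosses <- function(glucose = TRUE) {
  losses <- list(H3PO3 = parseFormula("H3PO3"),
                 H2O   = parseFormula("H2O"),
                 HPO2  = parseFormula("HPO2"))
  if (glucose) losses$C6H10O5 <- parseFormula("C6H10O5")
  losses
}

#' Interpret an MS/MS spectrum as neutral-loss chains
#'
#' Breadth-first expansion of sequential single neutral losses from the
#' precursor, to `maxDepth` losses deep. Branches whose formula would go
#' negative in any element are pruned silently. Each observed peak is
#' annotated with the shortest loss chain whose theoretical m/z matches
#' within `tolDa`; chain m/z is exactly the precursor m/z minus the summed
#' loss masses (singly charged precursors only — multiply charged
#' precursors dissociate by charge splitting, which is not a neutral-loss
#' ladder).
#'
#' @param precursor An [IonSpecies-class] with `|z| == 1`.
#' @param spectrum The product-ion [Spectrum-class].
#' @param losses Named list of [ElementalFormula-class] (or Hill strings),
#'   e.g. [defaultNeutralLosses()].
#' @param tolDa Match tolerance in Da (default 0.010).
#' @param maxDepth Maximum number of sequential losses (default 4).
#' @return data.frame with one row per peak: `mz`, `intensity`, `matched`,
#'   `chain` (e.g. `"-H3PO3 -H2O"`, `""` for the intact precursor), `depth`,
#'   `mzTheo`, `deltaMda`.
#' @examples
#' pre <- ionSpecies(defaultSpecies()$AlnH, 1, nH = 1, z = 1)
#' ms2 <- newSpectrum(c(86.059, 150.031, 168.041), 1, "positive")
#' interpretMsms(pre, ms2, defaultNeutralLosses())
#' @export
interpretMsms <- function(precursor, spectrum, losses = defaultNeutralLosses(),
                          tolDa = 0.010, maxDepth = 4L) {
  stopifnot(is(precursor, "IonSpecies"), is(spectrum, "Spectrum"))
  if (abs(precursor@z) != 1L)
    stop("neutral-loss interpretation requires a singly charged precursor")
  losses <- lapply(losses, function(l) if (is.character(l)) parseFormula(l) else l)
  if (is.null(names(losses)) || !all(nzchar(names(losses))))
    stop("losses must be named")
  lossMass <- vapply(losses, monoisotopicMass, numeric(1))

  mz0 <- mzOfIon(precursor)
  f0 <- ionFormula(precursor)
  frontier <- list(list(formula = f0, chain = character(0), mz = mz0))
  states <- list(list(formula = f0, chain = character(0), mz = mz0))
  seen <- formulaString(f0)
  for (depth in seq_len(maxDepth)) {
    nxt <- list()
    for (st in frontier) {
      for (j in seq_along(losses)) {
        f <- tryCatch(st$formula - losses[[j]], error = function(e) NULL)
        if (is.null(f)) next  # loss drives an element count negative
        key <- formulaString(f)
        if (key %in% seen) next
        seen <- c(seen, key)
        nxt[[length(nxt) + 1L]] <- list(
          formula = f, chain = c(st$chain, names(losses)[j]),
          mz = st$mz - lossMass[j])
      }
    }
    if (!length(nxt)) break
    states <- c(states, nxt)
    frontier <- nxt
  }

  theo <- vapply(states, `[[`, numeric(1), "mz")
  pk <- peaks(spectrum)
  ann <- lapply(seq_len(nrow(pk)), function(i) {
    dm <- pk$mz[i] - theo
    hit <- which(abs(dm) <= tolDa)
    if (!length(hit))
      return(data.frame(mz = pk$mz[i], intensity = pk$intensity[i],
                        matched = FALSE, chain = NA_character_,
                        depth = NA_integer_, mzTheo = NA_real_,
                        deltaMda = NA_real_))
    ## states are in BFS order, so the first hit is a shortest chain;
    ## among equal depths prefer the smaller mass error
    dep <- vapply(states[hit], function(s) length(s$chain), integer(1))
    best <- hit[order(dep, abs(dm[hit]))][1]
    data.frame(mz = pk$mz[i], intensity = pk$intensity[i], matched = TRUE,
               chain = paste(paste0("-", states[[best]]$chain), collapse = " "),
               depth = length(states[[best]]$chain),
               mzTheo = theo[best], deltaMda = 1e3 * dm[best])
  })
  res <- do.call(rbind, ann)
  res$chain[res$matched & res$depth == 0L] <- ""
  res[order(res$mz), , drop = FALSE]
}
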