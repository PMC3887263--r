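## Complexation energetics: the supermolecule energy balance
## deltaE = E_complex - (E_host + E_guest), with explicit units.

#' Construct an energy ledger
#'
#' @param eComplex,eHost,eGuest Total energies of the optimized complex
#'   and of the two isolated components, all in the same unit.
#' @param unit `"kcal/mol"` (default) or `"hartree"`.
#' @return An [EnergyLedger-class].
#' @examples
#' energyLedger(-3576293.09, -2682715.79, -893503.25)
#' @export
energyLedger <- function(eComplex, eHost, eGuest, unit = c("kcal/mol", "hartree")) {
  unit <- match.arg(unit)
  new("EnergyLedger", eComplex = eComplex, eHost = eHost, eGuest = eGuest,
      unit = unit)
}

#' Read an energy ledger from JSON
#'
#' Expected keys: `e_complex`, `e_host`, `e_guest`, `unit`.
#'
#' @param path JSON file path.
#' @return An [EnergyLedger-class].
#' @export
readEnergyLedger <- function(path) {
  x <- jsonlite::fromJSON(path)
  need <- c("e_complex", "e_host", "e_guest", "unit")
  if (!all(need %in% names(x)))
    stop("ledger must contain keys: ", paste(need, collapse = ", "))
  energyLedger(x$e_complex, x$e_host, x$e_guest, unit = x$unit)
}

#' Complexation energy
#'
#' `deltaE = E_complex - (E_host + E_guest)`, reported in kcal/mol.
#' Hartree inputs are converted with 1 hartree = 627.5095 kcal/mol.
#' Negative values mean the inclusion process is thermodynamically
#' favorable; the lowest value marks the most stable orientation.
#'
#' @param ledger An [EnergyLedger-class].
#' @param ... Unused.
#' @return Complexation energy in kcal/mol.
#' @examples
#' deltaE(energyLedger(-3576293.09, -2682715.79, -893503.25))  # -74.05
#' @export
setMethod("deltaE", "EnergyLedger", function(ledger, ...) {
  f <- if (ledger@unit == "hartree") .HARTREE_KCAL else 1
  f * (ledger@eComplex - (ledger@eHost + ledger@eGuest))
})

#' @export
setMethod("show", "EnergyLedger", function(object) {
  cat(sprintf("EnergyLedger (%s): E_complex = %.4f, E_host = %.4f, E_guest = %.4f\n",
              object@unit, object@eComplex, object@eHost, object@eGuest))
  cat(sprintf("  deltaE = %.2f kcal/mol\n", deltaE(object)))
})

#' Rank inclusion orientations by complexation energy
#'
#' @param results Named list (one entry per orientation) of lists with
#'   elements `deltaE` (kcal/mol) and optionally `hbonds` (a
#'   [detectHbonds()] table or a bond count).
#' @return List with `table` (data.frame of label, deltaE, nHbonds, sorted
#'   ascending by deltaE, ties broken by label) and `differences`
#'   (data.frame of pairwise deltaE differences, later minus earlier in
#'   the ranking).
#' @examples
#' compareOrientations(list(
#'   orientation1 = list(deltaE = -74.05, hbonds = 5),
#'   orientation2 = list(deltaE = -60.85, hbonds = 1)))
#' @export
compareOrientations <- function(results) {
  if (length(results) < 2L) stop("need at least two orientations to compare")
  if (is.null(names(results)) || !all(nzchar(names(results))))
    stop("results must be a named list")
  de <- vapply(results, function(r) r$deltaE, numeric(1))
  nhb <- vapply(results, function(r) {
    hb <- r$hbonds
    if (is.null(hb)) NA_integer_
    else if (is.data.frame(hb)) nrow(hb)
    else as.integer(hb)
  }, integer(1))
  tab <- data.frame(label = names(results), deltaE = de, nHbonds = nhb)
  tab <- tab[order(tab$deltaE, tab$label), , drop = FALSE]
  rownames(tab) <- NULL
  pairs <- utils::combn(nrow(tab), 2)
  differences <- data.frame(
    from = tab$label[pairs[1, ]], to = tab$label[pairs[2, ]],
    deltaDeltaE = tab$deltaE[pairs[2, ]] - tab$deltaE[pairs[1, ]])
  list(table = tab, differences = differences)
}
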