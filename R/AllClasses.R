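#' @import methods
NULL

## ---------------------------------------------------------------------------
## Elemental formulas and isotope patterns

#' ElementalFormula: an element -> count multiset
#'
#' A chemical formula as a named integer vector of non-negative element
#' counts. Formulas support element-wise `+`, `-` and integer scaling `*`;
#' subtraction that would drive any count negative is an error.
#'
#' @slot counts Named integer vector, element symbol -> count (all >= 0,
#'   symbols restricted to the embedded constants table).
#' @seealso [parseFormula()], [monoisotopicMass()], [isotopePattern()]
#' @export
setClass("ElementalFormula", representation(counts = "integer"))

setValidity("ElementalFormula", function(object) {
  cts <- object@counts
  if (length(cts) && is.null(names(cts)))
    return("counts must be a named integer vector")
  if (any(is.na(cts)) || any(cts < 0L))
    return("element counts must be non-negative integers")
  bad <- setdiff(names(cts), knownElements())
  if (length(bad))
    return(paste("unknown element symbol(s):", paste(bad, collapse = ", ")))
  if (anyDuplicated(names(cts)))
    return("duplicated element symbols")
  TRUE
})

#' IsotopePattern: centroided isotope distribution of a formula
#'
#' @slot peaks data.frame with columns `mass` (Da, or Th after charge
#'   scaling) and `abundance`, sorted by mass, no two entries closer than the
#'   merge width used to build it.
#' @slot mode Normalization mode: `"base"` (base peak = 1) or `"sum"`
#'   (abundances sum to 1).
#' @export
setClass("IsotopePattern",
         representation(peaks = "data.frame", mode = "character"))

setValidity("IsotopePattern", function(object) {
  p <- object@peaks
  if (!all(c("mass", "abundance") %in% names(p)))
    return("peaks must have columns 'mass' and 'abundance'")
  if (any(p$abundance < 0)) return("abundances must be non-negative")
  if (is.unsorted(p$mass, strictly = TRUE)) return("peaks must be sorted by mass")
  if (!object@mode %in% c("base", "sum")) return("mode must be 'base' or 'sum'")
  TRUE
})

## ---------------------------------------------------------------------------
## Species and ions

#' MolecularSpecies: a named neutral molecule
#'
#' @slot name Short label used in ion brackets (e.g. `"bCD"`, `"AlnH"`).
#'   Must be non-empty and free of the characters `[ ] + -` and whitespace,
#'   which carry meaning in the bracket-label grammar.
#' @slot formula An [ElementalFormula-class] (non-empty).
#' @export
setClass("MolecularSpecies",
         representation(name = "character", formula = "ElementalFormula"))

setValidity("MolecularSpecies", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  if (grepl("[][ +-]", object@name))
    return("name must not contain '[', ']', '+', '-' or whitespace")
  if (sum(object@formula@counts) == 0L)
    return("species formula must be non-empty")
  TRUE
})

#' IonSpecies: a host-guest adduct ion
#'
#' An ion `a*Host + b*Guest + nH*H + nNa*Na` with net charge `z`. All charge
#' is carried by gain of H/Na or loss of H, so the bookkeeping invariant is
#' `z = nH + nNa`; deprotonation beyond the available hydrogens is rejected.
#'
#' @slot species List of [MolecularSpecies-class], the neutral building
#'   blocks (same order as `counts`).
#' @slot counts Integer vector of per-species stoichiometric counts
#'   (>= 0, not all zero).
#' @slot nH Integer number of hydrogen atoms added (negative =
#'   deprotonation).
#' @slot nNa Integer number of sodium atoms added (>= 0).
#' @slot z Integer net charge, `z = nH + nNa`, `|z| >= 1`; its sign is the
#'   polarity.
#' @export
setClass("IonSpecies",
         representation(species = "list", counts = "integer",
                        nH = "integer", nNa = "integer", z = "integer"))

setValidity("IonSpecies", function(object) {
  if (length(object@species) != length(object@counts))
    return("species and counts lengths differ")
  if (!all(vapply(object@species, is, logical(1), "MolecularSpecies")))
    return("species must be MolecularSpecies objects")
  if (any(object@counts < 0L) || sum(object@counts) == 0L)
    return("counts must be >= 0 and not all zero")
  if (object@nNa < 0L) return("nNa must be >= 0")
  if (abs(object@z) < 1L) return("|z| must be >= 1")
  if (object@z != object@nH + object@nNa)
    return("charge bookkeeping violated: z must equal nH + nNa")
  cts <- .ionCounts(object)
  if (any(cts < 0L))
    return("deprotonation drives an element count negative")
  TRUE
})

#' EnumerationBounds: the search box for candidate ions
#'
#' @slot maxCounts Named integer vector: per-species maximum stoichiometric
#'   count (e.g. `c(bCD = 4, AlnH = 4)`).
#' @slot maxNa Maximum number of sodium adducts.
#' @slot maxZ Maximum charge magnitude.
#' @slot polarity `"positive"` or `"negative"`.
#' @export
setClass("EnumerationBounds",
         representation(maxCounts = "integer", maxNa = "integer",
                        maxZ = "integer", polarity = "character"))

setValidity("EnumerationBounds", function(object) {
  if (any(object@maxCounts < 0L) || object@maxNa < 0L || object@maxZ < 0L)
    return("all bounds must be >= 0")
  if (is.null(names(object@maxCounts)))
    return("maxCounts must be named by species")
  if (!object@polarity %in% c("positive", "negative"))
    return("polarity must be 'positive' or 'negative'")
  TRUE
})

## ---------------------------------------------------------------------------
## Spectra

#' Spectrum: a centroided peak list
#'
#' @slot polarity `"positive"` or `"negative"`.
#' @slot peaks data.frame with columns `mz` (Th, > 0, strictly increasing,
#'   no duplicates within 1e-6) and `intensity` (>= 0).
#' @slot precursor For MS/MS spectra, the precursor [IonSpecies-class];
#'   otherwise `NULL`.
#' @export
setClass("Spectrum",
         representation(polarity = "character", peaks = "data.frame",
                        precursor = "ANY"))

setValidity("Spectrum", function(object) {
  if (!object@polarity %in% c("positive", "negative"))
    return("polarity must be 'positive' or 'negative'")
  p <- object@peaks
  if (!all(c("mz", "intensity") %in% names(p)))
    return("peaks must have columns 'mz' and 'intensity'")
  if (nrow(p)) {
    if (any(p$mz <= 0)) return("all m/z must be > 0")
    if (any(p$intensity < 0)) return("intensities must be >= 0")
    if (is.unsorted(p$mz)) return("peaks must be sorted by m/z")
    if (any(diff(p$mz) < 1e-6)) return("duplicate m/z within 1e-6")
  }
  if (!is.null(object@precursor) && !is(object@precursor, "IonSpecies"))
    return("precursor must be NULL or an IonSpecies")
  TRUE
})

## ---------------------------------------------------------------------------
## Structures and energies

#' StructureModel: atoms partitioned into molecules
#'
#' @slot atoms data.frame with columns `element`, `x`, `y`, `z` (Angstrom)
#'   and `molecule` (integer id assigned by covalent-connectivity
#'   partitioning, contiguous from 1).
#' @slot provenance Free-text label recording where the coordinates came
#'   from.
#' @export
setClass("StructureModel",
         representation(atoms = "data.frame", provenance = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("element", "x", "y", "z", "molecule")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("structure must contain at least one atom")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("coordinates must be finite")
  bad <- setdiff(unique(a$element), knownElements())
  if (length(bad))
    return(paste("unknown element(s):", paste(bad, collapse = ", ")))
  ids <- sort(unique(a$molecule))
  if (!identical(as.integer(ids), seq_along(ids)))
    return("molecule ids must be contiguous from 1")
  TRUE
})

#' EnergyLedger: the three total energies behind a complexation energy
#'
#' Holds the total energy of the optimized complex and of the two isolated
#' components, with an explicit unit, so that
#' `deltaE = E_complex - (E_host + E_guest)` is always computed from a
#' unit-consistent triple.
#'
#' @slot eComplex,eHost,eGuest Total energies (same unit).
#' @slot unit `"kcal/mol"` or `"hartree"`.
#' @export
setClass("EnergyLedger",
         representation(eComplex = "numeric", eHost = "numeric",
                        eGuest = "numeric", unit = "character"))

setValidity("EnergyLedger", function(object) {
  for (s in c("eComplex", "eHost", "eGuest")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      return(paste(s, "must be a single finite number"))
  }
  if (!object@unit %in% c("kcal/mol", "hartree"))
    return("unit must be 'kcal/mol' or 'hartree'")
  TRUE
})
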