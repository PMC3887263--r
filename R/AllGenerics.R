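#' @rdname monoisotopicMass
#' @export
setGeneric("monoisotopicMass", function(x, ...) standardGeneric("monoisotopicMass"))

#' @rdname isotopePattern
#' @export
setGeneric("isotopePattern", function(x, ...) standardGeneric("isotopePattern"))

#' @rdname formulaString
#' @export
setGeneric("formulaString", function(x, ...) standardGeneric("formulaString"))

#' @rdname mzOfIon
#' @export
setGeneric("mzOfIon", function(ion, ...) standardGeneric("mzOfIon"))

#' @rdname ionLabel
#' @export
setGeneric("ionLabel", function(ion, ...) standardGeneric("ionLabel"))

#' @rdname ionFormula
#' @export
setGeneric("ionFormula", function(ion, ...) standardGeneric("ionFormula"))

#' Accessors for spectra and structures
#'
#' `peaks()` returns the centroid table of a [Spectrum-class]; `polarity()`
#' its ion mode; `precursorIon()` its precursor (or `NULL`); `atoms()` the
#' atom table of a [StructureModel-class]; `nMolecules()` the number of
#' covalently connected molecules in the partition.
#'
#' @param x A `Spectrum` or `StructureModel`.
#' @return See description.
#' @aliases peaks polarity precursorIon atoms nMolecules
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setGeneric("polarity", function(x) standardGeneric("polarity"))

#' @rdname accessors
#' @export
setGeneric("precursorIon", function(x) standardGeneric("precursorIon"))

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' @rdname deltaE
#' @export
setGeneric("deltaE", function(ledger, ...) standardGeneric("deltaE"))
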