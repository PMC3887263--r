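## Host-guest ion species: construction, m/z, canonical bracket labels, and
## exhaustive enumeration within bounds.

#' Construct a named molecular species
#'
#' @param name Short label used in ion brackets (e.g. `"bCD"`).
#' @param formula Hill-notation string or [ElementalFormula-class].
#' @return A [MolecularSpecies-class].
#' @examples
#' molecularSpecies("bCD", "C42H70O35")
#' @export
molecularSpecies <- function(name, formula) {
  if (is.character(formula)) formula <- parseFormula(formula)
  new("MolecularSpecies", name = name, formula = formula)
}

#' The beta-cyclodextrin / alendronic-acid species pair
#'
#' The default host and guest of the package: beta-cyclodextrin
#' (`bCD`, C42H70O35, seven alpha-1,4-linked glucopyranose units) and
#' alendronic acid (`AlnH`, C4H13NO7P2, a bisphosphonate). Sodium salts of
#' the guest are not separate species: `AlnNa == AlnH + Na - H` is absorbed
#' into the H/Na adduct bookkeeping of [IonSpecies-class], which avoids
#' double-counting ions that can be spelled either way.
#'
#' @return A named list of two [MolecularSpecies-class] objects.
#' @export
defaultSpecies <- function() {
  list(bCD  = molecularSpecies("bCD", "C42H70O35"),
       AlnH = molecularSpecies("AlnH", "C4H13NO7P2"))
}

#' Read species definitions from a JSON config
#'
#' The config is an object mapping species name to Hill-notation formula,
#' e.g. `{"bCD": "C42H70O35", "AlnH": "C4H13NO7P2"}`.
#'
#' @param path Path to the JSON file.
#' @return Named list of [MolecularSpecies-class].
#' @export
readSpeciesConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  if (!length(cfg) || is.null(names(cfg)))
    stop("species config must map names to formula strings")
  out <- lapply(names(cfg), function(n) molecularSpecies(n, cfg[[n]]))
  names(out) <- names(cfg)
  if (anyDuplicated(names(out))) stop("species names must be unique")
  out
}

#' Construct an adduct ion
#'
#' @param species A [MolecularSpecies-class], or list of them.
#' @param counts Integer stoichiometric count per species.
#' @param nH Hydrogen atoms added (negative = deprotonation).
#' @param nNa Sodium atoms added (>= 0).
#' @param z Net charge; must equal `nH + nNa` (all charge carried by H/Na).
#' @return An [IonSpecies-class].
#' @examples
#' sp <- defaultSpecies()
#' ionSpecies(sp$AlnH, 1, nH = 1, z = 1)               # [AlnH + H]+
#' ionSpecies(sp, c(1, 1), nH = -2, z = -2)            # [bCD + AlnH - 2H]2-
#' @export
ionSpecies <- function(species, counts = 1L, nH = 0L, nNa = 0L, z = nH + nNa) {
  if (is(species, "MolecularSpecies")) species <- list(species)
  new("IonSpecies", species = species, counts = as.integer(counts),
      nH = as.integer(nH), nNa = as.integer(nNa), z = as.integer(z))
}

## element counts of the ionic formula (may be transiently negative in H;
## validity rejects that)
.ionCounts <- function(ion) {
  cts <- integer(0)
  add <- function(cts, sym, n) {
    cur <- if (sym %in% names(cts)) cts[[sym]] else 0L
    cts[[sym]] <- cur + n
    cts
  }
  for (i in seq_along(ion@species)) {
    f <- ion@species[[i]]@formula@counts
    for (s in names(f)) cts <- add(cts, s, f[[s]] * ion@counts[i])
  }
  cts <- add(cts, "H", ion@nH)
  cts <- add(cts, "Na", ion@nNa)
  cts
}

#' Elemental formula of an ion
#'
#' @param ion An [IonSpecies-class].
#' @param ... Unused.
#' @return The [ElementalFormula-class] of the intact ion (components plus
#'   H/Na adducts).
#' @export
setMethod("ionFormula", "IonSpecies", function(ion, ...) {
  .Formula(unlist(.ionCounts(ion)))
})

#' Theoretical m/z of an ion
#'
#' `m/z = (sum a_i M_i + nH m(H) + nNa m(Na) - z m_e) / |z|` with
#' monoisotopic masses. The electron mass is included: at 0.55 mDa per
#' charge it matters at the three-decimal precision of high-resolution
#' assignments.
#'
#' @param ion An [IonSpecies-class].
#' @param ... Unused.
#' @return m/z in Th (always positive).
#' @examples
#' mzOfIon(ionSpecies(defaultSpecies()$AlnH, 1, nH = 1, z = 1))  # 250.0240
#' @export
setMethod("mzOfIon", "IonSpecies", function(ion, ...) {
  m <- sum(vapply(ion@species, function(s) monoisotopicMass(s@formula),
                  numeric(1)) * ion@counts)
  m <- m + ion@nH * monoisotopicMass(parseFormula("H")) +
       ion@nNa * monoisotopicMass(parseFormula("Na")) -
       ion@z * electronMass()
  m / abs(ion@z)
})

#' Canonical bracket label of an ion
#'
#' Reproduces the field's bracket convention, e.g.
#' `"[bCD + AlnH + 2H]2+"`: components in species order with count
#' prefixes, then the H term, then the Na term; charge as `z+`/`z-` with
#' the magnitude omitted when 1. One canonical H/Na spelling per ion
#' (sodium-salt guests are never rendered as a separate species).
#' [parseIonLabel()] inverts it.
#'
#' @param ion An [IonSpecies-class].
#' @param ... Unused.
#' @return A string.
#' @export
setMethod("ionLabel", "IonSpecies", function(ion, ...) {
  parts <- character(0)
  for (i in seq_along(ion@species)) {
    n <- ion@counts[i]
    if (n > 0L)
      parts <- c(parts, paste0(if (n > 1L) n else "", ion@species[[i]]@name))
  }
  body <- paste(parts, collapse = " + ")
  term <- function(n, sym) {
    if (n == 0L) return("")
    paste0(if (n > 0L) " + " else " - ",
           if (abs(n) > 1L) abs(n) else "", sym)
  }
  body <- paste0(body, term(ion@nH, "H"), term(ion@nNa, "Na"))
  zmag <- abs(ion@z)
  paste0("[", body, "]", if (zmag > 1L) zmag else "",
         if (ion@z > 0L) "+" else "-")
})

#' Parse a canonical bracket label back to an ion
#'
#' @param label A label produced by [ionLabel()].
#' @param species Named list of [MolecularSpecies-class] resolving the
#'   component names.
#' @return An [IonSpecies-class].
#' @export
parseIonLabel <- function(label, species) {
  m <- regmatches(label, regexec("^\\[(.+)\\]([0-9]*)([+-])$", label))[[1]]
  if (length(m) != 4L) stop("malformed ion label: '", label, "'")
  zmag <- if (nzchar(m[3])) as.integer(m[3]) else 1L
  z <- if (m[4] == "+") zmag else -zmag
  toks <- strsplit(m[2], " ", fixed = TRUE)[[1]]
  sign <- 1L
  counts <- setNames(integer(length(species)), names(species))
  nH <- 0L; nNa <- 0L
  for (tk in toks) {
    if (tk == "+") { sign <- 1L; next }
    if (tk == "-") { sign <- -1L; next }
    tm <- regmatches(tk, regexec("^([0-9]*)(.+)$", tk))[[1]]
    n <- sign * (if (nzchar(tm[2])) as.integer(tm[2]) else 1L)
    name <- tm[3]
    if (name == "H") nH <- nH + n
    else if (name == "Na") nNa <- nNa + n
    else if (name %in% names(species)) counts[name] <- counts[name] + n
    else stop("unknown component '", name, "' in label '", label, "'")
  }
  ionSpecies(species, counts, nH = nH, nNa = nNa, z = z)
}

#' @export
setMethod("show", "IonSpecies", function(object) {
  cat("IonSpecies ", ionLabel(object),
      sprintf("  m/z %.4f\n", mzOfIon(object)), sep = "")
})

#' Bounds for candidate-ion enumeration
#'
#' Defaults span every stoichiometry reported for the
#' beta-cyclodextrin/alendronate system: up to 4 hosts, 4 guests, 4 sodium
#' adducts and charge 3.
#'
#' @param species Named list of [MolecularSpecies-class] (used for the
#'   default per-species maxima).
#' @param maxCounts Named integer vector of per-species maximum counts.
#' @param maxNa,maxZ Maximum sodium adducts / charge magnitude.
#' @param polarity `"positive"` or `"negative"`.
#' @return An [EnumerationBounds-class].
#' @export
enumerationBounds <- function(species, polarity = c("positive", "negative"),
                              maxCounts = NULL, maxNa = 4L, maxZ = 3L) {
  polarity <- match.arg(polarity)
  if (is.null(maxCounts))
    maxCounts <- setNames(rep(4L, length(species)), names(species))
  mc <- setNames(as.integer(maxCounts), names(maxCounts))
  new("EnumerationBounds", maxCounts = mc,
      maxNa = as.integer(maxNa), maxZ = as.integer(maxZ), polarity = polarity)
}

#' Enumerate all candidate ions within bounds
#'
#' Generates every [IonSpecies-class] whose stoichiometric counts, sodium
#' count and charge magnitude are inside `bounds`, with the charge
#' bookkeeping `z = nH + nNa` and a non-negative total hydrogen count.
#' Each valid ion appears exactly once, ordered by m/z then label.
#'
#' @param species Named list of [MolecularSpecies-class]; names must match
#'   `bounds@maxCounts`.
#' @param bounds An [EnumerationBounds-class].
#' @return List of [IonSpecies-class], sorted by m/z (ties by label).
#' @examples
#' sp <- defaultSpecies()
#' b <- enumerationBounds(sp, "positive", maxCounts = c(bCD = 1, AlnH = 0),
#'                        maxNa = 1, maxZ = 1)
#' sapply(enumerateIons(sp, b), ionLabel)
#' @export
enumerateIons <- function(species, bounds) {
  if (!length(species)) stop("empty species list")
  stopifnot(is(bounds, "EnumerationBounds"))
  mx <- bounds@maxCounts[names(species)]
  if (anyNA(mx)) stop("bounds lack maxima for some species")
  grids <- c(lapply(mx, function(m) 0:m),
             list(nNa = 0:bounds@maxNa, zmag = seq_len(bounds@maxZ)))
  if (bounds@maxZ == 0L) return(list())
  g <- do.call(expand.grid, grids)
  nsp <- length(species)
  out <- vector("list", nrow(g))
  k <- 0L
  for (i in seq_len(nrow(g))) {
    cts <- as.integer(unlist(g[i, seq_len(nsp)], use.names = FALSE))
    if (sum(cts) == 0L) next
    z <- if (bounds@polarity == "positive") g$zmag[i] else -g$zmag[i]
    nNa <- g$nNa[i]
    nH <- z - nNa
    ion <- tryCatch(ionSpecies(species, cts, nH = nH, nNa = nNa, z = z),
                    error = function(e) NULL)
    if (is.null(ion)) next
    k <- k + 1L
    out[[k]] <- ion
  }
  out <- out[seq_len(k)]
  mz <- vapply(out, mzOfIon, numeric(1))
  lab <- vapply(out, ionLabel, character(1))
  out[order(mz, lab)]
}

#' Protonated glucose-oligomer fragment ions
#'
#' In-source fragmentation of cyclodextrins produces protonated linear
#' glucose oligomers `[(C6H10O5)n + H]+`. These are injected into the
#' candidate list as explicit species (named `Glc{n}`, formula
#' `(C6H10O5)n`) rather than enumerated, since they are fragmentation
#' products of the host, not mixture components.
#'
#' @param n Integer vector of oligomer lengths (default 2:6).
#' @return List of singly protonated [IonSpecies-class].
#' @export
glucoseFragmentIons <- function(n = 2:6) {
  glc <- parseFormula("C6H10O5")
  lapply(n, function(k) {
    sp <- molecularSpecies(paste0("Glc", k), glc * k)
    ionSpecies(sp, 1L, nH = 1L, z = 1L)
  })
}
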