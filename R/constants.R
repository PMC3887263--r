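## Atomic constants: a single versioned table (monoisotopic masses, natural
## abundances, covalent radii) shipped as JSON so every mass in a report is
## reproducible bit-for-bit from one source.

.hgms <- new.env(parent = emptyenv())

.loadConstants <- function() {
  path <- system.file("extdata", "constants.json", package = "HostGuestMS")
  if (!nzchar(path)) # during load_all() / tests of a source tree
    path <- file.path("inst", "extdata", "constants.json")
  tbl <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  els <- lapply(tbl$elements, function(e) {
    iso <- e$isotopes
    m <- if (is.matrix(iso)) iso
         else matrix(unlist(iso), ncol = 2, byrow = TRUE)
    dimnames(m) <- list(NULL, c("mass", "abundance"))
    stopifnot(abs(sum(m[, "abundance"]) - 1) < 1e-6,
              !is.unsorted(m[, "mass"], strictly = TRUE))
    m
  })
  .hgms$elements <- els
  .hgms$electron_mass <- tbl$electron_mass
  .hgms$covalent_radii <- unlist(tbl$covalent_radii)
  .hgms$constants_version <- tbl$version
  invisible(tbl$version)
}

#' Atomic constants used throughout the package
#'
#' The package ships a single versioned table of isotope masses and natural
#' abundances (H, C, N, O, Na, P, S), the electron mass, and covalent radii.
#' All exact-mass, isotope-pattern and connectivity computations draw on this
#' one table so results are reproducible from a single source.
#'
#' @param symbol Element symbol, e.g. `"C"`.
#' @return `isotopeTable()` returns a two-column matrix (`mass` in Da,
#'   fractional `abundance`) with one row per stable isotope, sorted by mass.
#'   `electronMass()` returns the electron rest mass in Da. `covalentRadius()`
#'   returns the covalent radius in Angstrom. `constantsVersion()` returns the
#'   version string of the embedded table.
#' @examples
#' isotopeTable("C")
#' electronMass()
#' @export
isotopeTable <- function(symbol) {
  tbl <- .hgms$elements[[symbol]]
  if (is.null(tbl))
    stop("unknown element symbol: ", symbol)
  tbl
}

#' @rdname isotopeTable
#' @export
electronMass <- function() .hgms$electron_mass

#' @rdname isotopeTable
#' @export
covalentRadius <- function(symbol) {
  r <- .hgms$covalent_radii[symbol]
  if (anyNA(r))
    stop("no covalent radius for element(s): ",
         paste(symbol[is.na(r)], collapse = ", "))
  unname(r)
}

#' @rdname isotopeTable
#' @export
constantsVersion <- function() .hgms$constants_version

#' @rdname isotopeTable
#' @export
knownElements <- function() names(.hgms$elements)

## 1 hartree in kcal/mol
.HARTREE_KCAL <- 627.5095
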