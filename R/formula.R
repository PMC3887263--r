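## Elemental formulas: Hill-notation parsing/writing, exact masses, and
## isotope-pattern convolution. This is the numerical foundation for all m/z
## arithmetic in the package.

.Formula <- function(counts) {
  counts <- counts[counts > 0L]
  ## Hill order: C, H, then alphabetical
  sym <- names(counts)
  ord <- order(match(sym, c("C", "H"), nomatch = 3L), sym)
  new("ElementalFormula", counts = counts[ord])
}

#' Parse a Hill-notation formula string
#'
#' @param text Formula such as `"C42H70O35"`. Element symbols must be in the
#'   embedded constants table; counts are optional positive integers
#'   (default 1).
#' @return An [ElementalFormula-class].
#' @examples
#' parseFormula("C42H70O35")   # beta-cyclodextrin
#' parseFormula("C4H13NO7P2")  # alendronic acid
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula string: '", text, "'")
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  bad <- setdiff(sym, knownElements())
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  counts <- tapply(cnt, sym, sum)
  .Formula(setNames(as.integer(counts), names(counts)))
}

#' Write a formula in canonical Hill notation
#'
#' @param x An [ElementalFormula-class].
#' @param ... Unused.
#' @return A string, C first, H second, remaining elements alphabetical;
#'   `""` for the empty formula. Round-trips through [parseFormula()].
#' @export
setMethod("formulaString", "ElementalFormula", function(x, ...) {
  cts <- x@counts
  if (!length(cts)) return("")
  paste0(names(cts), ifelse(cts > 1L, cts, ""), collapse = "")
})

#' @export
setMethod("show", "ElementalFormula", function(object) {
  cat("ElementalFormula:", formulaString(object), "\n")
})

#' @export
setMethod("Arith", signature("ElementalFormula", "ElementalFormula"),
          function(e1, e2) {
  op <- .Generic
  if (!op %in% c("+", "-"))
    stop("operation '", op, "' not defined for formulas")
  sym <- union(names(e1@counts), names(e2@counts))
  a <- setNames(rep(0L, length(sym)), sym)
  a[names(e1@counts)] <- e1@counts
  b <- setNames(rep(0L, length(sym)), sym)
  b[names(e2@counts)] <- e2@counts
  out <- if (op == "+") a + b else a - b
  if (any(out < 0L))
    stop("formula subtraction would give negative count for: ",
         paste(sym[out < 0L], collapse = ", "))
  .Formula(out)
})

#' @export
setMethod("Arith", signature("ElementalFormula", "numeric"), function(e1, e2) {
  if (.Generic != "*" || e2 != as.integer(e2) || e2 < 0)
    stop("formulas can only be scaled by non-negative integers")
  .Formula(e1@counts * as.integer(e2))
})

#' @export
setMethod("Arith", signature("numeric", "ElementalFormula"), function(e1, e2) {
  callGeneric(e2, e1)
})

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the mass of the most abundant isotope.
#' Additive: `monoisotopicMass(a + b) == monoisotopicMass(a) + monoisotopicMass(b)`.
#'
#' @param x An [ElementalFormula-class] or a Hill-notation string.
#' @param ... Unused.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopicMass("C42H70O35")  # 1134.3698
#' @export
setMethod("monoisotopicMass", "ElementalFormula", function(x, ...) {
  cts <- x@counts
  if (!length(cts)) return(0)
  masses <- vapply(names(cts), function(s) {
    tbl <- isotopeTable(s)
    tbl[which.max(tbl[, "abundance"]), "mass"]
  }, numeric(1))
  sum(cts * masses)
})

#' @rdname monoisotopicMass
#' @export
setMethod("monoisotopicMass", "character", function(x, ...) {
  vapply(x, function(f) monoisotopicMass(parseFormula(f)), numeric(1),
         USE.NAMES = length(x) > 1L)
})

## ---------------------------------------------------------------------------
## Isotope-pattern convolution

## combine two centroided distributions: outer sum of masses, product of
## abundances, then merge peaks closer than mergeWidth by abundance-weighted
## centroid and drop entries below `floor` relative to the base peak
.convolvePatterns <- function(p1, p2, mergeWidth, floor = 1e-12) {
  mass <- outer(p1$mass, p2$mass, "+")
  ab <- outer(p1$abundance, p2$abundance, "*")
  .mergePeaks(data.frame(mass = as.vector(mass), abundance = as.vector(ab)),
              mergeWidth, floor)
}

.mergePeaks <- function(df, mergeWidth, floor) {
  df <- df[order(df$mass), , drop = FALSE]
  grp <- cumsum(c(1, diff(df$mass) >= mergeWidth))
  ab <- as.vector(tapply(df$abundance, grp, sum))
  mass <- as.vector(tapply(df$mass * df$abundance, grp, sum)) / ab
  keep <- ab >= floor * max(ab)
  data.frame(mass = mass[keep], abundance = ab[keep])
}

## n-fold self-convolution by binary exponentiation
.elementPattern <- function(symbol, n, mergeWidth) {
  tbl <- isotopeTable(symbol)
  base <- data.frame(mass = tbl[, "mass"], abundance = tbl[, "abundance"])
  acc <- data.frame(mass = 0, abundance = 1)
  sq <- base
  while (n > 0L) {
    if (n %% 2L == 1L) acc <- .convolvePatterns(acc, sq, mergeWidth)
    n <- n %/% 2L
    if (n > 0L) sq <- .convolvePatterns(sq, sq, mergeWidth)
  }
  acc
}

#' Isotope pattern of a formula
#'
#' Element-wise convolution of per-element natural isotope distributions.
#' Peaks closer than `mergeWidth` are merged by abundance-weighted centroid;
#' entries below `pruneThreshold` relative to the base peak are dropped; the
#' result is renormalized in the chosen mode.
#'
#' @param x An [ElementalFormula-class] or Hill-notation string.
#' @param pruneThreshold Relative abundance (vs base peak) below which peaks
#'   are dropped; in (0, 1). Default 1e-4.
#' @param mergeWidth Peaks closer than this (Da) are merged. Default 0.01,
#'   well below the assignment tolerance and above numerical noise.
#' @param mode `"base"` (base peak scaled to 1) or `"sum"` (abundances sum
#'   to 1).
#' @param ... Unused.
#' @return An [IsotopePattern-class].
#' @examples
#' isotopePattern("C")            # 13C/12C abundance ratio 0.0107/0.9893
#' isotopePattern("C42H70O35")    # A+1/A about 0.47
#' @export
setMethod("isotopePattern", "ElementalFormula",
          function(x, pruneThreshold = 1e-4, mergeWidth = 0.01,
                   mode = c("base", "sum"), ...) {
  mode <- match.arg(mode)
  stopifnot(pruneThreshold > 0, pruneThreshold < 1, mergeWidth > 0)
  cts <- x@counts
  acc <- data.frame(mass = 0, abundance = 1)
  for (s in names(cts))
    acc <- .convolvePatterns(acc, .elementPattern(s, cts[[s]], mergeWidth),
                             mergeWidth)
  acc <- acc[acc$abundance >= pruneThreshold * max(acc$abundance), , drop = FALSE]
  acc$abundance <- switch(mode,
    base = acc$abundance / max(acc$abundance),
    sum  = acc$abundance / sum(acc$abundance))
  rownames(acc) <- NULL
  new("IsotopePattern", peaks = acc, mode = mode)
})

#' @rdname isotopePattern
#' @export
setMethod("isotopePattern", "character", function(x, ...) {
  isotopePattern(parseFormula(x), ...)
})

#' @export
setMethod("show", "IsotopePattern", function(object) {
  cat("IsotopePattern (", nrow(object@peaks), " peaks, mode = ",
      object@mode, ")\n", sep = "")
  print(format(object@peaks, digits = 6), row.names = FALSE)
})

#' @rdname accessors
#' @export
setMethod("peaks", "IsotopePattern", function(x) x@peaks)
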