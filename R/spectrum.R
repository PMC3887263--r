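## Centroided spectra: construction, CSV input, accessors.

#' Construct a centroided spectrum
#'
#' @param mz Numeric vector of m/z values (Th, > 0). Sorted on input.
#' @param intensity Numeric vector of intensities (>= 0), recycled if
#'   length 1.
#' @param polarity `"positive"` or `"negative"`.
#' @param precursor Optional precursor [IonSpecies-class] for MS/MS spectra.
#' @return A [Spectrum-class].
#' @examples
#' spectrum <- newSpectrum(c(250.023, 272.005), c(100, 80), "positive")
#' peaks(spectrum)
#' @export
newSpectrum <- function(mz, intensity = 1, polarity = c("positive", "negative"),
                        precursor = NULL) {
  polarity <- match.arg(polarity)
  if (length(intensity) == 1L) intensity <- rep(intensity, length(mz))
  ord <- order(mz)
  new("Spectrum", polarity = polarity,
      peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
      precursor = precursor)
}

#' Read a centroided peak list from CSV
#'
#' Expects two columns, m/z and intensity; a header line is detected and
#' skipped. Rows with non-numeric fields are rejected with a warning that
#' names their line numbers; the result is sorted by m/z.
#'
#' @param path CSV file path.
#' @param polarity `"positive"` or `"negative"`.
#' @return A [Spectrum-class].
#' @export
readPeakList <- function(path, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty peak list: ", path)
  fields <- strsplit(lines, "[,\t]")
  num <- lapply(fields, function(f) suppressWarnings(as.numeric(f[1:2])))
  ok <- vapply(num, function(v) length(v) == 2L && !anyNA(v), logical(1))
  if (!ok[1] && length(ok) > 1L) ok[1] <- NA  # header line, skip silently
  bad <- which(!is.na(ok) & !ok)
  if (length(bad))
    warning("rejected non-numeric row(s) at line(s): ",
            paste(bad, collapse = ", "))
  keep <- which(!is.na(ok) & ok)
  if (!length(keep)) stop("no valid peak rows in ", path)
  m <- do.call(rbind, num[keep])
  if (any(duplicated(round(m[, 1], 6))))
    stop("duplicate m/z values in ", path)
  newSpectrum(m[, 1], m[, 2], polarity)
}

#' @rdname accessors
#' @export
setMethod("peaks", "Spectrum", function(x) x@peaks)

#' @rdname accessors
#' @export
setMethod("polarity", "Spectrum", function(x) x@polarity)

#' @rdname accessors
#' @export
setMethod("precursorIon", "Spectrum", function(x) x@precursor)

#' @export
setMethod("show", "Spectrum", function(object) {
  cat("Spectrum (", object@polarity, " mode, ", nrow(object@peaks),
      " peaks", sep = "")
  if (!is.null(object@precursor))
    cat(", precursor ", ionLabel(object@precursor), sep = "")
  cat(")\n")
  if (nrow(object@peaks)) {
    rng <- range(object@peaks$mz)
    cat(sprintf("  m/z range %.4f - %.4f\n", rng[1], rng[2]))
  }
})

#' @export
setMethod("length", "Spectrum", function(x) nrow(x@peaks))
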