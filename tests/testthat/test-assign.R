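negCandidates <- function() enumerateIons(SPECIES, enumerationBounds(SPECIES, "negative"))
posCandidates <- function()
  c(enumerateIons(SPECIES, enumerationBounds(SPECIES, "positive")),
    glucoseFragmentIons())

test_that("peak lists load from CSV with validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,intensity", "272.005,80", "250.023,100"), path)
  s <- readPeakList(path, "positive")
  expect_s4_class(s, "Spectrum")
  expect_equal(peaks(s)$mz, c(250.023, 272.005))  # sorted on input
  expect_equal(peaks(s)$intensity, c(100, 80))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(readPeakList(empty, "positive"), "empty")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("250.023,100", "oops,not_a_number", "260.1,5"), bad)
  expect_warning(s2 <- readPeakList(bad, "positive"), "line")
  expect_equal(length(s2), 2L)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("250.023,100", "250.023,50"), dup)
  expect_error(readPeakList(dup, "positive"), "duplicate")

  expect_error(readPeakList(file.path(tempdir(), "nope.csv"), "positive"),
               "no such file")
})

test_that("the 1:1 complex anion is the top-ranked assignment at 690.682", {
  a <- assignPeaks(newSpectrum(690.682, 100, "negative"), negCandidates())
  top <- a[!is.na(a$rank) & a$rank == 1L, ]
  expect_identical(top$label, "[bCD + AlnH - 2H]2-")
  expect_lt(abs(top$deltaMda), 10)
  expect_identical(top$z, -2L)
})

test_that("a peak at an exact theoretical m/z gets zero error and rank 1", {
  cand <- negCandidates()
  ion <- cand[[which(vapply(cand, ionLabel, character(1)) == "[AlnH - H]-")]]
  a <- assignPeaks(newSpectrum(mzOfIon(ion), 1, "negative"), cand)
  top <- a[!is.na(a$rank) & a$rank == 1L, ]
  expect_identical(top$label, "[AlnH - H]-")
  expect_equal(top$deltaMda, 0, tolerance = 1e-6)
})

test_that("the unidentified 1179.340 ion stays unassigned under default bounds", {
  a <- assignPeaks(newSpectrum(1179.340, 1, "negative"), negCandidates())
  expect_false(any(a$assigned))
  expect_false(is.na(a$label[1]))  # nearest miss still reported
})

test_that("polarity mismatch between spectrum and candidates is an error", {
  expect_error(assignPeaks(newSpectrum(250, 1, "positive"), negCandidates()),
               "polarity")
})

test_that("ranking ignores intensity rescaling", {
  sim <- simulateSpectrum(posCandidates()[c(10, 40, 80)], abundance = c(5, 1, 3),
                          jitterPpm = 2, seed = 7)
  cand <- posCandidates()
  a1 <- assignPeaks(sim$spectrum, cand)
  pk <- peaks(sim$spectrum)
  a2 <- assignPeaks(newSpectrum(pk$mz, pk$intensity * 1000, "positive"), cand)
  expect_identical(a1$label, a2$label)
  expect_identical(a1$rank, a2$rank)
})

test_that("rank-1 assignments recover the generating species under tight jitter", {
  sp <- SPECIES
  gen <- positiveSurvey()$label[1:12]
  frag <- glucoseFragmentIons()
  names(frag) <- vapply(frag, ionLabel, character(1))
  ions <- lapply(gen, function(l)
    if (l %in% names(frag)) frag[[l]] else parseIonLabel(l, sp))
  cand <- posCandidates()
  hits <- 0L; total <- 0L
  for (seed in 1:100) {
    sim <- simulateSpectrum(ions, jitterPpm = 1, nIsotopologues = 1, seed = seed)
    a <- assignPeaks(sim$spectrum, cand)
    top <- a[!is.na(a$rank) & a$rank == 1L, ]
    m <- merge(sim$truth, top, by.x = "mzObserved", by.y = "mz")
    hits <- hits + sum(m$label.x == m$label.y)
    total <- total + nrow(sim$truth)
  }
  expect_identical(hits, total)  # 100% rank-1 recovery across seeds
})

test_that("isotope fit rewards the true pattern and penalizes wrong hypotheses", {
  sp <- SPECIES
  guestIon <- ionSpecies(sp$AlnH, 1, nH = 1, z = 1)
  sim <- simulateSpectrum(list(guestIon), jitterPpm = 0, nIsotopologues = 4, seed = 1)
  ## self-match: spectrum generated from the hypothesis' own pattern
  expect_gte(isotopeFit(sim$spectrum, guestIon), 0.999)
  ## wrong charge hypothesis at the same m/z: the dominant half-integer
  ## satellite it predicts is absent from the observed envelope
  wrongZ <- ionSpecies(sp$AlnH, 2, nH = 2, z = 2)  # same m/z, z = 2 spacing
  expect_lt(isotopeFit(sim$spectrum, wrongZ), 0.5)
  ## a lone peak with no visible A+1 partner scores 0 for a large formula
  hostIon <- ionSpecies(sp$bCD, 1, nH = 1, z = 1)
  lone <- newSpectrum(mzOfIon(hostIon), 100, "positive")
  expect_equal(isotopeFit(lone, hostIon), 0)
  ## single-isotope species have no satellites to score
  pIon <- ionSpecies(molecularSpecies("P4", "P4"), 1, nNa = 1, z = 1)
  expect_true(is.na(isotopeFit(newSpectrum(150, 1, "positive"), pIon)))
})
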