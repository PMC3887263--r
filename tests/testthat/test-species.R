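test_that("theoretical m/z reproduces hand-derived adduct values", {
  sp <- SPECIES
  cases <- list(
    ## label parts: counts(bCD, AlnH), nH, nNa, z, frozen m/z (hand sums)
    list(c(0L, 1L),  1L, 0L,  1L, 250.023997),  # [AlnH + H]+
    list(c(0L, 1L),  0L, 1L,  1L, 272.005941),  # [AlnH + Na]+
    list(c(1L, 0L),  0L, 2L,  2L, 590.174105),  # [bCD + 2Na]2+
    list(c(0L, 1L), -1L, 0L, -1L, 248.009448),  # [AlnH - H]-
    list(c(1L, 1L),  2L, 0L,  2L, 692.700518),  # [bCD + AlnH + 2H]2+
    list(c(1L, 1L), -2L, 0L, -2L, 690.685976))  # [bCD + AlnH - 2H]2-
  for (cs in cases) {
    ion <- ionSpecies(sp, cs[[1]], nH = cs[[2]], nNa = cs[[3]], z = cs[[4]])
    expect_equal(mzOfIon(ion), cs[[5]], tolerance = 1e-6)
  }
})

test_that("ion invariants are enforced", {
  sp <- SPECIES
  ## z must equal nH + nNa
  expect_error(ionSpecies(sp$AlnH, 1, nH = 1, nNa = 1, z = 1), "bookkeeping")
  ## deprotonation beyond available hydrogens
  expect_error(ionSpecies(sp$AlnH, 1, nH = -14L, nNa = 13L, z = -1L),
               "negative")
  ## empty component set
  expect_error(ionSpecies(sp, c(0L, 0L), nH = 1L, z = 1L), "not all zero")
  expect_error(ionSpecies(sp$bCD, 1, nH = 0L, nNa = 0L, z = 0L), "z")
})

test_that("charge bookkeeping recovers the neutral mass for enumerated ions", {
  sp <- SPECIES
  mH <- monoisotopicMass("H"); mNa <- monoisotopicMass("Na")
  ions <- enumerateIons(sp, enumerationBounds(sp, "positive",
                        maxCounts = c(bCD = 2, AlnH = 2), maxNa = 2, maxZ = 3))
  for (ion in ions) {
    neutral <- ion@counts[1] * monoisotopicMass("C42H70O35") +
               ion@counts[2] * monoisotopicMass("C4H13NO7P2")
    back <- abs(ion@z) * mzOfIon(ion) - ion@nH * mH - ion@nNa * mNa +
            ion@z * electronMass()
    expect_equal(back, neutral, tolerance = 1e-9)
  }
})

test_that("sodiation series are spaced by (m(Na) - m(H)) / z", {
  sp <- SPECIES
  spacingTheo <- (monoisotopicMass("Na") - monoisotopicMass("H"))
  for (z in 1:3) {
    series <- lapply(0:z, function(k)
      ionSpecies(sp, c(1L, 1L), nH = z - k, nNa = k, z = z))
    mz <- vapply(series, mzOfIon, numeric(1))
    expect_equal(diff(mz), rep(spacingTheo / z, z), tolerance = 1e-9)
  }
  ## the doubly charged sodiated series of the 1:1 complex steps by ~10.991
  expect_equal(spacingTheo / 2, 10.990972, tolerance = 1e-6)
})

test_that("labels canonicalize and round-trip through the parser", {
  sp <- SPECIES
  expect_identical(ionLabel(ionSpecies(sp, c(1L, 1L), nH = 2L, z = 2L)),
                   "[bCD + AlnH + 2H]2+")
  expect_identical(ionLabel(ionSpecies(sp$AlnH, 1L, nH = -1L, z = -1L)),
                   "[AlnH - H]-")
  expect_identical(ionLabel(ionSpecies(sp, c(1L, 2L), nH = -1L, nNa = 3L, z = 2L)),
                   "[bCD + 2AlnH - H + 3Na]2+")

  for (pol in c("positive", "negative")) {
    ions <- enumerateIons(sp, enumerationBounds(sp, pol))
    for (ion in ions) {
      back <- parseIonLabel(ionLabel(ion), sp)
      expect_identical(unname(back@counts), unname(ion@counts))
      expect_identical(back@nH, ion@nH)
      expect_identical(back@nNa, ion@nNa)
      expect_identical(back@z, ion@z)
    }
  }
})

test_that("enumeration matches the brute-force Cartesian product", {
  sp <- SPECIES
  for (pol in c("positive", "negative")) {
    for (bounds in list(c(1, 0, 1, 1), c(1, 2, 3, 2), c(4, 4, 4, 3))) {
      mc <- c(bCD = bounds[1], AlnH = bounds[2])
      got <- sort(vapply(
        enumerateIons(sp, enumerationBounds(sp, pol, maxCounts = mc,
                                            maxNa = bounds[3], maxZ = bounds[4])),
        ionLabel, character(1)))
      want <- bruteForceIons(sp, mc, bounds[3], bounds[4], pol)
      expect_identical(got, want)
      expect_false(anyDuplicated(got) > 0)
    }
  }
})

test_that("enumeration respects edge-case bounds and ordering", {
  sp <- SPECIES
  ## host-only, one charge, one sodium: exactly [bCD + H]+ and [bCD + Na]+
  ions <- enumerateIons(sp, enumerationBounds(sp, "positive",
                        maxCounts = c(bCD = 1, AlnH = 0), maxNa = 1, maxZ = 1))
  expect_setequal(vapply(ions, ionLabel, character(1)),
                  c("[bCD + H]+", "[bCD + Na]+"))
  ## all component bounds zero: nothing to enumerate
  expect_length(enumerateIons(sp, enumerationBounds(sp, "positive",
                maxCounts = c(bCD = 0, AlnH = 0), maxNa = 2, maxZ = 2)), 0)
  ## deterministic order: sorted by m/z
  all <- enumerateIons(sp, enumerationBounds(sp, "negative"))
  mz <- vapply(all, mzOfIon, numeric(1))
  expect_false(is.unsorted(mz))
})

test_that("the mixed sodium-salt spelling is absorbed into H/Na bookkeeping", {
  ## [bCD + 2AlnNa + Na + H]2+ == 2 AlnH guests with nNa = 3, nH = -1
  sp <- SPECIES
  ion <- ionSpecies(sp, c(1L, 2L), nH = -1L, nNa = 3L, z = 2L)
  expect_equal(mzOfIon(ion), 850.182, tolerance = 0.010)
  ## and [bCD + 2AlnNa + 2H]2+ == 2 AlnH with nNa = 2, nH = 0
  ion2 <- ionSpecies(sp, c(1L, 2L), nH = 0L, nNa = 2L, z = 2L)
  expect_equal(mzOfIon(ion2), 839.185, tolerance = 0.010)
})

test_that("glucose fragment ions form the expected protonated ladder", {
  frags <- glucoseFragmentIons(2:6)
  mz <- vapply(frags, mzOfIon, numeric(1))
  expect_equal(diff(mz), rep(monoisotopicMass("C6H10O5"), 4), tolerance = 1e-9)
  expect_equal(mz[3], 649.2186, tolerance = 1e-4)  # [(C6H10O5)4 + H]+
  expect_identical(ionLabel(frags[[3]]), "[Glc4 + H]+")
})
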