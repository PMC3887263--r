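test_that("identical seeds reproduce spectra and geometries exactly", {
  ions <- list(ionSpecies(SPECIES$AlnH, 1, nH = 1, z = 1),
               ionSpecies(SPECIES, c(1L, 1L), nH = 2L, z = 2L))
  s1 <- simulateSpectrum(ions, jitterPpm = 5, nDecoys = 20, seed = 99)
  s2 <- simulateSpectrum(ions, jitterPpm = 5, nDecoys = 20, seed = 99)
  expect_identical(peaks(s1$spectrum), peaks(s2$spectrum))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateSpectrum(ions, jitterPpm = 5, nDecoys = 20, seed = 100)
  expect_false(identical(peaks(s1$spectrum), peaks(s3$spectrum)))

  g1 <- plantHbondGeometry(table1Hbonds(), nDecoys = 15, seed = 4)
  g2 <- plantHbondGeometry(table1Hbonds(), nDecoys = 15, seed = 4)
  expect_identical(atoms(g1$structure), atoms(g2$structure))
})

test_that("zero jitter and no decoys give peaks exactly at theory", {
  ion <- ionSpecies(SPECIES$AlnH, 1, nH = 1, z = 1)
  sim <- simulateSpectrum(list(ion), jitterPpm = 0, nIsotopologues = 3, seed = 1)
  expect_identical(length(sim$spectrum), 3L)
  expect_equal(peaks(sim$spectrum)$mz, sim$truth$mzTheo, tolerance = 1e-12)
  expect_equal(sim$truth$mzTheo[1], mzOfIon(ion), tolerance = 1e-9)
  ## isotopologue spacing near 1.00336/|z| reveals the charge state (merged
  ## fine structure shifts centroids by a few mDa)
  expect_true(all(abs(diff(sim$truth$mzTheo) - 1.00336) < 0.005))
})

test_that("decoys avoid the exclusion zone around true peaks", {
  ion <- ionSpecies(SPECIES$bCD, 1, nH = 1, z = 1)
  sim <- simulateSpectrum(list(ion), jitterPpm = 3, nDecoys = 50, seed = 5)
  pk <- peaks(sim$spectrum)
  decoys <- setdiff(round(pk$mz, 9), round(sim$truth$mzObserved, 9))
  excl <- pmax(3 * 3e-6 * sim$truth$mzTheo, 0.01)
  for (d in decoys)
    expect_true(all(abs(d - sim$truth$mzTheo) > excl))
})

test_that("assignment recovery does not improve as jitter grows", {
  sp <- SPECIES
  ions <- lapply(positiveSurvey()$label[c(1:4, 6, 11)],
                 function(l) parseIonLabel(l, sp))
  cand <- enumerateIons(sp, enumerationBounds(sp, "positive"))
  recovery <- sapply(c(0, 3, 10, 30), function(sigma) {
    mean(sapply(1:20, function(seed) {
      sim <- simulateSpectrum(ions, jitterPpm = sigma, nIsotopologues = 1,
                              seed = seed)
      a <- assignPeaks(sim$spectrum, cand)
      top <- a[!is.na(a$rank) & a$rank == 1L, ]
      m <- merge(sim$truth, top, by.x = "mzObserved", by.y = "mz")
      sum(m$label.x == m$label.y) / nrow(sim$truth)
    }))
  })
  expect_true(all(diff(recovery) <= 0))
  expect_equal(recovery[1], 1)     # exact peaks always recover
  expect_lt(recovery[4], recovery[1])  # 30 ppm blows through the 15 ppm gate
})

test_that("mis-assignments under heavy jitter sit beyond the ppm gate", {
  sp <- SPECIES
  ## heavy ions, where the 15 ppm gate (not the 0.010 Da floor) is binding
  ions <- lapply(positiveSurvey()$label[c(6, 11, 15, 16)],
                 function(l) parseIonLabel(l, sp))
  cand <- enumerateIons(sp, enumerationBounds(sp, "positive"))
  for (seed in 1:5) {
    sim <- simulateSpectrum(ions, jitterPpm = 30, nIsotopologues = 1, seed = seed)
    a <- assignPeaks(sim$spectrum, cand)
    truthPpm <- 1e6 * abs(sim$truth$mzObserved - sim$truth$mzTheo) /
      sim$truth$mzTheo
    lost <- sim$truth$mzObserved[truthPpm > 15 &
                                 sim$truth$mzTheo * 15e-6 > 0.010]
    for (mz in lost) {
      row <- a[abs(a$mz - mz) < 1e-9, ]
      expect_false(isTRUE(row$assigned) &&
                   row$label == sim$truth$label[sim$truth$mzObserved == mz])
    }
  }
})

test_that("infeasible geometry requests and decoy saturation fail loudly", {
  expect_error(plantHbondGeometry(data.frame(distance = -1, angle = 150)),
               "infeasible")
  expect_error(plantHbondGeometry(data.frame(distance = 2.0, angle = 200)),
               "infeasible")
  ## zero planted bonds with many decoys: nothing must be detected
  g <- plantHbondGeometry(data.frame(distance = numeric(0), angle = numeric(0)),
                          nDecoys = 100, seed = 6)
  expect_identical(nrow(detectHbonds(g$structure)), 0L)
})

test_that("recovery metrics count hits, misses and spurious calls", {
  perfect <- data.frame(x = 1:5)
  expect_equal(evaluateRecovery(perfect, perfect, by = "x")$precision, 1)
  expect_equal(evaluateRecovery(perfect, perfect, by = "x")$recall, 1)
  missedOne <- data.frame(x = 1:4)
  expect_equal(evaluateRecovery(perfect, missedOne, by = "x")$recall, 0.8)
  expect_equal(evaluateRecovery(perfect, missedOne, by = "x")$precision, 1)
  spurious <- data.frame(x = c(1:5, 99))
  r <- evaluateRecovery(perfect, spurious, by = "x")
  expect_equal(r$precision, 5 / 6)
  expect_equal(r$recall, 1)
  ## numeric tolerance matching reports the mean absolute deviation
  r2 <- evaluateRecovery(data.frame(x = c(1, 2)), data.frame(x = c(1.05, 2.1)),
                         by = "x", tol = 0.2)
  expect_equal(r2$meanAbsError, 0.075, tolerance = 1e-9)
})
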