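test_that("titration generator evaluates the Hill isotherm at design points", {
  des <- TitrationDesign(enzymeConcs = c(0, 0.5, 1, 2, 4, 8), dnaConc = 1.2,
                         replicates = 1L, noiseSd = 0)
  s <- makeTitration(HillParams(Kd = 1), des)
  pts <- measurements(s)
  expect_equal(pts$F[pts$E0 == 1], 0.5)            # half-saturation at E0 = Kd
  expect_equal(pts$F[pts$E0 == 0], 0)              # zero-enzyme baseline = Fu

  s2 <- makeTitration(HillParams(Kd = 2.45), TitrationDesign(noiseSd = 0))
  p2 <- measurements(s2)
  expect_equal(unique(p2$F[p2$E0 == 12.8]), 1 / (1 + 2.45 / 12.8),
               tolerance = 1e-12)
  expect_equal(unique(p2$F[p2$E0 == 12.8]), 0.8394, tolerance = 1e-4)
})

test_that("titration generator is deterministic per seed and clips noise to [0, 1]", {
  desA <- TitrationDesign(noiseSd = 0.05, seed = 7L)
  a <- makeTitration(HillParams(Kd = 2), desA)
  b <- makeTitration(HillParams(Kd = 2), desA)
  expect_identical(measurements(a), measurements(b))
  desB <- TitrationDesign(noiseSd = 0.05, seed = 8L)
  expect_false(identical(measurements(a),
                         measurements(makeTitration(HillParams(Kd = 2), desB))))
  noisy <- makeTitration(HillParams(Kd = 2, Fu = 0, Fb = 1),
                         TitrationDesign(noiseSd = 0.5, seed = 3L))
  expect_true(all(measurements(noisy)$F >= 0 & measurements(noisy)$F <= 1))
})

test_that("design invariants are enforced", {
  expect_error(TitrationDesign(enzymeConcs = c(0.4, 0.8)), "include 0")
  expect_error(TitrationDesign(enzymeConcs = c(0, 2, 1)), "increasing")
  expect_error(HillParams(Kd = -1), "Kd")
  expect_error(HillParams(Kd = 1, Fu = 0.8, Fb = 0.2), "Fu <= Fb")
})

test_that("time-course generator starts at zero, saturates at the plateau and matches the study endpoint", {
  truth <- KineticTruth(0.071, 2.45, plateau = 0.54)
  tc <- makeTimeCourse(truth, times = c(0, 30, 600, 1800, 3600))
  pts <- measurements(tc)
  expect_equal(pts$P[pts$t == 0], 0)
  expect_equal(pts$P[pts$t == 3600], 0.54, tolerance = 1e-9)
  expect_equal(pts$P[pts$t == 1800], 0.54, tolerance = 1e-4)   # 30-min endpoint

  expect_error(makeTimeCourse(truth, times = numeric(0)), "empty")
  expect_error(makeTimeCourse(truth, times = c(30, 4000)), "3600")
  expect_error(KineticTruth(0.071, 2.45, plateau = -0.1), "> 0")
})

test_that("noise-free initial numerical slope equals V0/S0 within 1%", {
  for (i in seq_len(nrow(refTruths))) {
    tr <- refTruths[i, ]
    truth <- KineticTruth(tr$kobs, tr$Kd, plateau = tr$plateau)
    tc <- makeTimeCourse(truth, times = c(0, 0.3, 30, 300, 3600))
    pts <- measurements(tc)
    slope <- diff(pts$P[1:2]) / diff(pts$t[1:2])
    V0 <- tr$kobs * esOracle(1, 1, tr$Kd)
    expect_equal(slope, V0, tolerance = 0.01)
  }
})

test_that("gel simulation round-trips through bound-fraction quantification", {
  obs <- simulateGel(0.5, scale = 100, background = 0, noiseSd = 0)
  expect_equal(obs@intensityBound, 50)
  expect_equal(obs@intensityUnbound, 50)
  obs2 <- simulateGel(0, scale = 100, background = 10, noiseSd = 0)
  expect_equal(obs2@intensityBound, 10)
  expect_equal(obs2@intensityUnbound, 110)
  obs3 <- simulateGel(0.754, scale = 1000, noiseSd = 0)
  expect_equal(obs3@intensityBound, 754)
  expect_equal(obs3@intensityUnbound, 246)
  expect_equal(boundFraction(obs3), 0.754)
  expect_error(simulateGel(0.5, scale = -1), "scale")

  ## noisy round trip: mean absolute error < 3 * noiseSd / scale
  fr <- 0.37; scale <- 500; noiseSd <- 4
  err <- vapply(1:150, function(s)
    abs(boundFraction(simulateGel(fr, scale, 20, noiseSd, seed = s)) - fr),
    numeric(1))
  expect_lt(mean(err), 3 * noiseSd / scale)
})

test_that("reporter duplexes carry the annotated lesion and restore GATC", {
  ctrl <- makeDuplex("none")
  expect_equal(ctrl@topStrand, "AGTTCAATGATCTTCAT")
  expect_equal(ctrl@label, "FAM")
  m1a <- makeDuplex("m1A")
  expect_equal(m1a@modifiedPos, 10L)
  expect_equal(substr(m1a@topStrand, 10, 10), "A")
  m3c <- makeDuplex("m3C")
  expect_equal(m3c@modifiedPos, 12L)
  ## demethylated strand equals the unmodified control strand
  expect_equal(m3c@topStrand, ctrl@topStrand)
  expect_error(makeDuplex("m5C"))
})

test_that("methylation-sensitive digestion yields a 9-nt labeled fragment only after repair", {
  for (les in c("m1A", "m3C"))
    expect_equal(digestDuplex(makeDuplex(les), demethylated = TRUE), 9L)
  expect_equal(digestDuplex(makeDuplex("m1A"), demethylated = FALSE), 17L)
  ## unmethylated control is cut regardless of the repair flag
  expect_equal(digestDuplex(makeDuplex("none"), demethylated = FALSE), 9L)
  expect_equal(digestDuplex(makeDuplex("none"), demethylated = TRUE), 9L)
})

test_that("toy-structure geometry re-measured by the all-pairs oracle matches the requested parameters", {
  ## hydrogen-bond pair: donor-acceptor heavy-atom distance
  m <- readStructure(makeToyStructure("hbond_pair", 2.9, 170))
  a <- atoms(m)
  expect_equal(nrow(unique(a[, c("resid", "resno")])), 2L)  # two residues parsed
  d <- minDistOracle(selXYZ(m, "Tyr1"), selXYZ(m, "lesion", "all_heavy"))
  expect_equal(d, 2.9, tolerance = 1e-3)

  ## stacked rings: centroid distance and coplanarity
  m2 <- readStructure(makeToyStructure("stacked_rings", 3.5, 0))
  st <- detectStacking(m2, "Phe1", "lesion")
  expect_equal(st$centroidDist, 3.5, tolerance = 1e-3)
  expect_equal(st$planeAngle, 0, tolerance = 1e-3)

  ## probe: closest approach equals the requested distance exactly
  m3 <- readStructure(makeToyStructure("probe_at_distance", 4.38))
  expect_equal(minDistOracle(selXYZ(m3, "Ile1"), selXYZ(m3, "lesion", "all_heavy")),
               4.38, tolerance = 1e-3)

  ## metal triad: all three coordinating atoms at the requested distance
  m4 <- readStructure(makeToyStructure("metal_triad", 2.2))
  ms <- checkMetalSite(m4)
  expect_equal(ms$distance, rep(2.2, 3), tolerance = 1e-3)

  expect_error(makeToyStructure("helix", 3), "arg")
})

test_that("toy-structure files are byte-identical for a fixed geometry and seed", {
  p1 <- makeToyStructure("hbond_pair", 2.9, 160, jitterSd = 0.05, seed = 11L,
                         path = tempfile(fileext = ".pdb"))
  p2 <- makeToyStructure("hbond_pair", 2.9, 160, jitterSd = 0.05, seed = 11L,
                         path = tempfile(fileext = ".pdb"))
  expect_identical(readLines(p1), readLines(p2))
  p3 <- makeToyStructure("hbond_pair", 2.9, 160, jitterSd = 0.05, seed = 12L,
                         path = tempfile(fileext = ".pdb"))
  expect_false(identical(readLines(p1), readLines(p3)))
})
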