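test_that("equilibrium complex concentration matches the brute-force root oracle", {
  ## 1000 random conditions, agreement to 1e-9 uM
  set.seed(1)
  E0 <- runif(1000, 0.05, 10)
  S0 <- runif(1000, 0.05, 10)
  Kd <- 10^runif(1000, -3, 1.7)
  for (i in seq_len(1000)) {
    x <- esEquilibrium(E0[i], S0[i], Kd[i])
    expect_equal(x, esOracle(E0[i], S0[i], Kd[i]), tolerance = 1e-9)
    ## mass conservation and back-substitution
    expect_lte(x, min(E0[i], S0[i]))
    expect_equal((E0[i] - x) * (S0[i] - x) / x, Kd[i], tolerance = 1e-9)
  }
})

test_that("equilibrium complex concentration has the right limits and reference value", {
  ## stoichiometric limit: at E0 = S0 the deviation from full complexation
  ## shrinks as sqrt(Kd), so [E.S] -> 1 with |1 - x| = sqrt(Kd) + O(Kd)
  expect_equal(esEquilibrium(1, 1, 1e-9), 1 - sqrt(1e-9), tolerance = 1e-9)
  expect_equal(esEquilibrium(1, 1, 1e-12), 1, tolerance = 1e-5)
  expect_lt(esEquilibrium(1, 1e-12, 1), 1e-11)                   # no substrate
  expect_equal(esEquilibrium(1, 1, 2.45), 0.23738, tolerance = 1e-5)
  expect_equal(esEquilibrium(AssayConditions(Kd = 2.45)), 0.2373821,
               tolerance = 1e-6)
  expect_error(esEquilibrium(-1, 1, 1), "> 0")
})

test_that("initial velocity equals the exponential model's exact t = 0 slope", {
  ## A = 0.54, lambda = V0/(A*S0) with the WT/m1A reference pair
  tc <- makeTimeCourse(KineticTruth(0.071, 2.45, plateau = 0.54))
  v <- initialVelocity(tc)
  expect_equal(v$V0, 0.0168541, tolerance = 1e-5)
  expect_equal(v$A, 0.54, tolerance = 1e-6)
  expect_equal(v$lambda, 0.031211, tolerance = 1e-4)
  expect_true("late_start" %in% v$flags)   # P(30 s) already above half-max
})

test_that("linear fallback reads the slope of an early linear series", {
  tc <- new("TimeCourse", variant = "WT", lesion = "m1A", E0 = 1, S0 = 1,
            points = data.frame(t = c(10, 20, 30, 40), P = 0.001 * c(10, 20, 30, 40)))
  v <- initialVelocity(tc, method = "linear")
  expect_equal(v$V0, 0.001, tolerance = 1e-10)

  flat <- new("TimeCourse", variant = "WT", lesion = "m1A", E0 = 1, S0 = 1,
              points = data.frame(t = c(30, 60, 90), P = c(0, 0, 0)))
  vf <- initialVelocity(flat)
  expect_equal(vf$V0, 0)
  expect_true("all_zero" %in% vf$flags)

  wobble <- new("TimeCourse", variant = "WT", lesion = "m1A", E0 = 1, S0 = 1,
                points = data.frame(t = c(30, 60, 90, 120),
                                    P = c(0.1, 0.4, 0.2, 0.45)))
  expect_true("non_monotone" %in% initialVelocity(wobble)$flags)
})

test_that("kobs is the velocity normalized by the precatalytic complex", {
  cond <- AssayConditions(Kd = 2.45)
  expect_equal(kObs(0.016854, cond), 0.071, tolerance = 1e-3)
  expect_equal(kObs(0, cond), 0)
  expect_equal(kObs(0.02, cond), 2 * kObs(0.01, cond))   # linear in V0
  ## weaker binding leaves less complex, so the same velocity implies a
  ## faster catalytic step: kobs increases with Kd at fixed V0
  expect_lt(kObs(0.01, AssayConditions(Kd = 1)), kObs(0.01, AssayConditions(Kd = 5)))
  expect_error(kObs(-1, cond), "V0")
})

test_that("Monte-Carlo kobs uncertainty propagation behaves linearly and stably", {
  expect_equal(propagateKobsSd(0.0169, 0, 2.45, 0), 0)
  ## 10% SD on V0 alone propagates to ~10% SD on kobs
  k <- kObs(0.0169, AssayConditions(Kd = 2.45))
  s <- propagateKobsSd(0.0169, 0.1 * 0.0169, 2.45, 0, nDraws = 20000L, seed = 1L)
  expect_equal(s / k, 0.10, tolerance = 0.01)
  ## seed-to-seed stability at 10,000 draws with the WT/m1A reference SDs
  ss <- vapply(1:3, function(sd)
    propagateKobsSd(0.0168541, 0.007 / 0.071 * 0.0168541, 2.45, 0.07,
                    nDraws = 10000L, seed = sd), numeric(1))
  expect_lt(diff(range(ss)) / mean(ss), 0.05)
  expect_identical(propagateKobsSd(0.017, 0.001, 2.45, 0.07, seed = 4L),
                   propagateKobsSd(0.017, 0.001, 2.45, 0.07, seed = 4L))
})

test_that("endpoint readout interpolates the 30-min product percentage", {
  tc <- makeTimeCourse(KineticTruth(0.045, 3.5, plateau = 0.754))
  expect_equal(endpointFraction(tc), 75.4, tolerance = 1e-3)  # exact grid point
  ## interpolation between bracketing points
  tc2 <- new("TimeCourse", variant = "WT", lesion = "m1A", E0 = 1, S0 = 1,
             points = data.frame(t = c(1200, 2400), P = c(0.4, 0.6)))
  expect_equal(endpointFraction(tc2), 50)
  expect_error(endpointFraction(tc2, tEnd = 3000), "outside")
  flat <- new("TimeCourse", variant = "WT", lesion = "m1A", E0 = 1, S0 = 1,
              points = data.frame(t = c(0, 1800, 3600), P = c(0, 0, 0)))
  expect_equal(endpointFraction(flat), 0)
})

test_that("fold changes reproduce the reported comparative ratios", {
  m1aKd <- refTruths$Kd[refTruths$lesion == "m1A"]
  m3cKd <- refTruths$Kd[refTruths$lesion == "m3C"]
  expect_equal(as.numeric(foldChange(m1aKd, "max_over_min", "kd")), 1.3)
  expect_equal(as.numeric(foldChange(m3cKd, "max_over_min", "kd")), 1.6)
  expect_equal(as.numeric(foldChange(c(0.071, 0.02), "wt_over_variant", "kobs")), 4)
  expect_equal(as.numeric(foldChange(c(0.045, 0.008), "wt_over_variant", "kobs")), 6)
  expect_equal(as.numeric(foldChange(c(3, 3), "max_over_min", "none")), 1)
  expect_equal(attr(foldChange(c(0.071, 0.02), "wt_over_variant", "kobs"), "raw"),
               c(0.071 / 0.02), ignore_attr = TRUE)
  expect_error(foldChange(numeric(0)), "empty")
  expect_error(foldChange(c(1, -2)), "> 0")
})

test_that("noise-free end-to-end kobs recovery is exact for every reference condition", {
  for (i in seq_len(nrow(refTruths))) {
    tr <- refTruths[i, ]
    tc <- makeTimeCourse(KineticTruth(tr$kobs, tr$Kd, plateau = tr$plateau))
    v <- initialVelocity(tc)
    khat <- kObs(v$V0, AssayConditions(Kd = tr$Kd))
    expect_equal(khat, tr$kobs, tolerance = 0.02)
  }
})

test_that("kinetic summary assembles a consistent result object", {
  tc <- makeTimeCourse(KineticTruth(0.071, 2.45, plateau = 0.54))
  res <- kineticSummary(tc, AssayConditions(Kd = 2.45), KdSd = 0.07,
                        nDraws = 2000L)
  expect_s4_class(res, "KineticResult")
  expect_equal(kobs(res), 0.071, tolerance = 1e-4)
  expect_equal(res@endpoint30, 54.0, tolerance = 1e-3)
  expect_gt(res@kobsSd, 0)
  expect_equal(res@kobs, res@V0 / res@ESeq)
})
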