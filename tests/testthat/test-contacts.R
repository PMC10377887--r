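test_that("structure reader parses toy PDB files and flags modified bases", {
  m <- readStructure(makeToyStructure("hbond_pair", 2.9, 170))
  a <- atoms(m)
  expect_equal(nrow(unique(a[, c("resid", "resno")])), 2L)
  expect_true(any(a$isLesion))
  expect_equal(unique(a$resid[a$isLesion]), "1MA")

  ## unknown het code without a mapping is an explicit error when required
  expect_error(readStructure(makeToyStructure("hbond_pair", 2.9, 170),
                             lesionCodes = "XYZ", requireLesion = TRUE),
               "lesionCodes")

  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(readStructure(empty))
})

test_that("minimum distance equals the brute-force all-pairs oracle", {
  ## simple 3-4-5 triangle
  tri <- makeModel(data.frame(
    elety = c("CB", "CB"), elem = c("C", "C"), resid = c("ALA", "GLY"),
    resno = c(1L, 2L), chain = "A",
    x = c(0, 3), y = c(0, 4), z = c(0, 0)))
  expect_equal(minDistance(tri, 1, 2), 5)
  expect_error(minDistance(tri, 1, 1), "self-distance")
  expect_error(minDistance(tri, 3, 1), "empty")

  for (geom in list(list("hbond_pair", 2.9, 170), list("stacked_rings", 3.5, 0),
                    list("probe_at_distance", 4.38, 0), list("metal_triad", 2.2, 0))) {
    m <- readStructure(makeToyStructure(geom[[1]], geom[[2]], geom[[3]]))
    a <- atoms(m)
    prot <- unique(a$resno[!a$isLesion & a$resid != "MN"])[1]
    tgt <- if (any(a$isLesion)) "lesion" else unique(a$resno)[2]
    expect_equal(minDistance(m, prot, tgt),
                 minDistOracle(selXYZ(m, prot), selXYZ(m, tgt, "all_heavy")))
  }
})

test_that("hydrogen-bond detection applies distance, angle and element criteria", {
  good <- readStructure(makeToyStructure("hbond_pair", 2.9, 170))
  hb <- detectHbond(good, "Tyr1", "lesion")
  expect_true(hb$detected)
  expect_equal(hb$distance, 2.9, tolerance = 1e-3)
  expect_equal(hb$angle, 170, tolerance = 0.1)

  far <- readStructure(makeToyStructure("hbond_pair", 5.0, 170))
  expect_false(detectHbond(far, "Tyr1", "lesion")$detected)

  bent <- readStructure(makeToyStructure("hbond_pair", 2.9, 90))
  expect_false(detectHbond(bent, "Tyr1", "lesion")$detected)

  ## carbon-only pair at 2.9 A: not donor/acceptor elements
  carbons <- makeModel(data.frame(
    elety = c("CB", "C2"), elem = c("C", "C"), resid = c("ALA", "1MA"),
    resno = c(1L, 2L), chain = "A", x = c(0, 2.9), y = 0, z = 0))
  expect_false(detectHbond(carbons, 1, "lesion")$detected)
})

test_that("stacking detection requires proximity, coplanarity and aromaticity", {
  expect_true(detectStacking(readStructure(makeToyStructure("stacked_rings", 3.5, 0)),
                             "Phe1", "lesion")$detected)
  expect_false(detectStacking(readStructure(makeToyStructure("stacked_rings", 3.5, 90)),
                              "Phe1", "lesion")$detected)
  expect_false(detectStacking(readStructure(makeToyStructure("stacked_rings", 6.0, 0)),
                              "Phe1", "lesion")$detected)
  probe <- readStructure(makeToyStructure("probe_at_distance", 4.0))
  st <- detectStacking(probe, "Ile1", "lesion")
  expect_false(st$detected)
  expect_equal(st$reason, "non_aromatic")
})

test_that("contact classification follows the category precedence", {
  hb <- readStructure(makeToyStructure("hbond_pair", 2.9, 170))
  expect_equal(classifyContact(hb, "Tyr1")@category, "hydrogen_bond")

  st <- readStructure(makeToyStructure("stacked_rings", 3.5, 0))
  expect_equal(classifyContact(st, "Phe1")@category, "stacking")

  wall <- readStructure(makeToyStructure("probe_at_distance", 4.2))
  expect_equal(classifyContact(wall, "Ile1")@category, "pocket_wall")

  coord <- readStructure(makeToyStructure("probe_at_distance", 4.38))
  rec <- classifyContact(coord, "Ile1", coordination = TRUE)
  expect_equal(rec@category, "coordination")
  expect_equal(rec@minDist, 4.38, tolerance = 1e-6)

  none <- readStructure(makeToyStructure("probe_at_distance", 8))
  expect_equal(classifyContact(none, "Ile1")@category, "none")
})

test_that("contact tables classify each residue and tolerate missing ones", {
  ## combined model: an H-bonding tyrosine and a pocket-wall isoleucine
  hb <- atoms(readStructure(makeToyStructure("hbond_pair", 2.9, 170)))
  ile <- data.frame(type = "ATOM", eleno = 100:101,
                    elety = c("CD1", "CB"), elem = c("C", "C"),
                    resid = "ILE", chain = "A", resno = 3L,
                    x = c(4.2, 5.7), y = 0, z = c(8, 8), isLesion = FALSE)
  ## place the Ile probe 4.2 A from the acceptor atom along z
  base <- hb[hb$isLesion, ]
  ile$x <- base$x[1]; ile$y <- base$y[1]
  ile$z <- base$z[1] + c(4.2, 5.73)
  comb <- makeModel(rbind(hb[, names(ile)], ile))
  ct <- contactTable(comb, residues = c("Tyr1", "Ile3", "Arg110"))
  rec <- contactRecords(ct)
  expect_equal(rec$category[rec$residue == "Tyr1"], "hydrogen_bond")
  expect_equal(rec$category[rec$residue == "Ile3"], "pocket_wall")
  expect_equal(rec$category[rec$residue == "Arg110"], "missing")
  expect_equal(nrow(rec), 3L)

  out <- tempfile(fileext = ".tsv")
  writeContactTable(ct, out)
  expect_equal(nrow(utils::read.delim(out)), 3L)
})

test_that("metal-site check reports coordination within the cutoff", {
  near <- readStructure(makeToyStructure("metal_triad", 2.2))
  ms <- checkMetalSite(near)
  expect_true(all(ms$coordinating))
  expect_equal(ms$residue, c("His171", "Asp173", "His236"))

  farm <- readStructure(makeToyStructure("metal_triad", 4.0))
  expect_false(any(checkMetalSite(farm)$coordinating))

  nometal <- readStructure(makeToyStructure("hbond_pair", 2.9, 170))
  expect_error(checkMetalSite(nometal), "no metal")
})

test_that("classification is invariant under rigid-body motion", {
  fixtures <- list(
    list(m = readStructure(makeToyStructure("hbond_pair", 2.9, 170)),
         res = "Tyr1", cat = "hydrogen_bond"),
    list(m = readStructure(makeToyStructure("stacked_rings", 3.5, 0)),
         res = "Phe1", cat = "stacking"),
    list(m = readStructure(makeToyStructure("probe_at_distance", 4.2)),
         res = "Ile1", cat = "pocket_wall"))
  for (fx in fixtures) {
    d0 <- minDistance(fx$m, fx$res)
    for (s in 1:20) {
      mt <- rigidTransform(fx$m, seed = s)
      expect_equal(classifyContact(mt, fx$res)@category, fx$cat)
      expect_equal(minDistance(mt, fx$res), d0, tolerance = 1e-9)
    }
  }
})

test_that("threshold changes act monotonically on the classification", {
  wall <- readStructure(makeToyStructure("probe_at_distance", 4.2))
  ## enlarging wallMaxDist never removes a pocket-wall call
  for (w in c(4.3, 5, 8, 20))
    expect_equal(classifyContact(wall, "Ile1",
                                 thresholds = ContactThresholds(wallMaxDist = w))@category,
                 "pocket_wall")
  ## shrinking hbondMaxDist never adds a hydrogen-bond call
  hb <- readStructure(makeToyStructure("hbond_pair", 2.9, 170))
  detected <- vapply(c(4.5, 3.5, 3.0, 2.95, 2.5, 2.0), function(d)
    classifyContact(hb, "Tyr1",
                    thresholds = ContactThresholds(hbondMaxDist = d))@category ==
      "hydrogen_bond", logical(1))
  expect_false(is.unsorted(rev(detected)))   # TRUEs only at larger cutoffs
})
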