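## Contacts module: geometric classification of active-site residue
## interactions with a flipped-out modified base.

## The eleven damaged-base-pocket residues of the ABH2 active site.
#' Active-site pocket residues of ABH2
#'
#' The eleven residues lining the damaged-base pocket, in reporting order.
#' @return character vector of residue labels
#' @export
pocketResidues <- function()
  c("Val99", "Val101", "Phe102", "Arg110", "Tyr122", "Phe124", "Ser125",
    "Ile168", "His171", "Asp173", "Glu175")

DEFAULT_LESION_CODES <- c("1MA", "MA7", "3MC", "MC3", "C3M", "EDA", "E1X")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
METAL_ELEMS <- c("MN", "FE", "ZN", "MG", "CO", "NI")

AROMATIC_RINGS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
NUCLEOBASE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records (first model of multi-model files) into a
#' [StructureModel-class]. Waters are excluded by default. Modified
#' nucleotides are recognized through a configurable residue-code map;
#' deposited het codes for methylated/etheno bases vary between entries, so
#' pass the codes used by your file when they differ from the defaults.
#'
#' @param path PDB-format file
#' @param lesionCodes residue names flagged as modified nucleotides
#' @param keepWaters keep water residues?
#' @param requireLesion error when no modified nucleotide is found?
#' @return a [StructureModel-class]
#' @export
readStructure <- function(path, lesionCodes = DEFAULT_LESION_CODES,
                          keepWaters = FALSE, requireLesion = FALSE) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot read PDB file '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  if (!keepWaters) a <- a[!a$resid %in% c("HOH", "WAT", "DOD"), ]
  if (nrow(a) == 0L) stop("empty model: no atoms in '", path, "'")
  elem <- a$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) {  # fall back to the leading letter of the atom name
    guess <- sub("^[0-9]*", "", a$elety[bad])
    elem[bad] <- substr(guess, 1, 1)
  }
  elem <- toupper(elem)
  atoms <- data.frame(type = a$type, eleno = a$eleno, elety = a$elety,
                      resid = a$resid, chain = a$chain, resno = a$resno,
                      x = a$x, y = a$y, z = a$z, elem = elem,
                      isLesion = a$resid %in% lesionCodes,
                      stringsAsFactors = FALSE)
  if (requireLesion && !any(atoms$isLesion))
    stop("no modified nucleotide found; extend 'lesionCodes' with the ",
         "het code used by this file")
  new("StructureModel", atoms = atoms, source = as.character(path),
      lesionCodes = lesionCodes)
}

## Resolve a residue/base selector to atom rows.
## `sel` may be "lesion" (all lesion-flagged residues), a residue number, or
## a label like "Tyr122".
.selectAtoms <- function(model, sel, scope = "all_heavy") {
  a <- model@atoms
  rows <- if (identical(sel, "lesion")) {
    a[a$isLesion, ]
  } else {
    p <- parseResidueLabel(sel)
    hit <- a$resno == p$resno
    if (!is.null(p$resid)) hit <- hit & a$resid == p$resid
    a[hit, ]
  }
  rows <- rows[rows$elem != "H", ]                      # heavy atoms only
  if (scope == "side_chain")
    rows <- rows[!(rows$elety %in% BACKBONE_ATOMS), ]
  rows
}

.selLabel <- function(sel) if (identical(sel, "lesion")) "lesion" else as.character(sel)

.xyz <- function(rows) as.matrix(rows[, c("x", "y", "z")])

.pairDists <- function(A, B) {
  ## |a - b| for all pairs; rows of A x rows of B
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Minimum heavy-atom distance between two selections
#'
#' Closest approach between the heavy atoms of a residue and of a base
#' (or any two residue selections). This is the package's convention for
#' the "coordination distance" of pocket residues that face the flipped-out
#' base without hydrogen bonding or stacking.
#'
#' @param model a [StructureModel-class]
#' @param residue residue selector: a number or "Tyr122"-style label
#' @param base base selector: "lesion" (default, the mapped modified
#'   nucleotide), a residue number, or a label
#' @param scope "side_chain" (default; drops protein backbone atoms of the
#'   residue selection) or "all_heavy"
#' @return minimal pairwise distance, Angstrom
#' @export
minDistance <- function(model, residue, base = "lesion",
                        scope = c("side_chain", "all_heavy")) {
  stopifnot(is(model, "StructureModel"))
  scope <- match.arg(scope)
  r <- .selectAtoms(model, residue, scope)
  b <- .selectAtoms(model, base, "all_heavy")
  if (nrow(r) == 0L) stop("empty residue selection: ", .selLabel(residue))
  if (nrow(b) == 0L) stop("empty base selection: ", .selLabel(base))
  if (identical(sort(r$eleno), sort(b$eleno)))
    stop("identical selections: self-distance is disallowed")
  min(.pairDists(.xyz(r), .xyz(b)))
}

.angleDeg <- function(v1, v2) {
  ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

#' Detect a hydrogen bond between a residue and a base
#'
#' Scans donor/acceptor heavy-atom pairs (N/O/S on the residue side against
#' N/O on the base side, and vice versa) for a pair within
#' `hbondMaxDist`. When hydrogens are present on the candidate donor the
#' D-H...A angle must also reach `hbondMinAngle`; for hydrogen-free models
#' (typical crystal structures) the criterion is distance-only.
#'
#' @param model a [StructureModel-class]
#' @param residue,base selectors as in [minDistance()]
#' @param thresholds a [ContactThresholds-class]
#' @return list with `detected` plus, when detected, `distance`, `angle`
#'   (NA without hydrogens), `donor` and `acceptor` atom names
#' @export
detectHbond <- function(model, residue, base, thresholds = ContactThresholds()) {
  stopifnot(is(model, "StructureModel"), is(thresholds, "ContactThresholds"))
  r <- .selectAtoms(model, residue, "side_chain")
  b <- .selectAtoms(model, base, "all_heavy")
  if (nrow(r) == 0L || nrow(b) == 0L) stop("empty selection")
  ## hydrogens of the two residues (for the angle criterion)
  a <- model@atoms
  hyd <- a[a$elem == "H", ]

  rDA <- r[r$elem %in% c("N", "O", "S"), ]
  bDA <- b[b$elem %in% c("N", "O"), ]
  if (nrow(rDA) == 0L || nrow(bDA) == 0L) return(list(detected = FALSE))
  D <- .pairDists(.xyz(rDA), .xyz(bDA))
  hits <- which(D <= thresholds@hbondMaxDist, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(list(detected = FALSE))
  ## examine the closest qualifying pair
  best <- hits[which.min(D[hits]), , drop = TRUE]
  don <- rDA[best[1], ]; acc <- bDA[best[2], ]
  dist <- D[best[1], best[2]]

  angle <- NA_real_
  if (nrow(hyd) > 0L) {
    ## hydrogens covalently attached to either heavy atom (either may donate)
    for (side in list(c(don = 1), c(don = 2))) {
      dAtom <- if (side[["don"]] == 1) don else acc
      aAtom <- if (side[["don"]] == 1) acc else don
      hd <- .pairDists(.xyz(hyd), .xyz(dAtom))
      att <- which(hd < 1.3)
      if (length(att) == 0L) next
      for (i in att) {
        h <- as.numeric(hyd[i, c("x", "y", "z")])
        ang <- .angleDeg(as.numeric(dAtom[, c("x", "y", "z")]) - h,
                         as.numeric(aAtom[, c("x", "y", "z")]) - h)
        if (is.na(angle) || ang > angle) angle <- ang
      }
    }
    if (!is.na(angle) && angle < thresholds@hbondMinAngle)
      return(list(detected = FALSE, distance = dist, angle = angle))
  }
  list(detected = TRUE, distance = dist, angle = angle,
       donor = don$elety, acceptor = acc$elety)
}

.ringAtoms <- function(rows) {
  resid <- rows$resid[1]
  wanted <- AROMATIC_RINGS[[resid]]
  if (is.null(wanted)) wanted <- NUCLEOBASE_RING   # treat as nucleobase
  rows[rows$elety %in% wanted, ]
}

.planeFit <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Detect pi-stacking between an aromatic residue and a base
#'
#' Reports stacking when the ring-centroid separation is at most
#' `stackMaxCentroid` and the angle between the least-squares ring planes is
#' at most `stackMaxPlaneAngle`. Aromatic rings are defined for Phe, Tyr,
#' His and Trp; the base ring from standard nucleobase atom names.
#'
#' @inheritParams detectHbond
#' @return list with `detected` and, when computable, `centroidDist` and
#'   `planeAngle` (degrees, folded to 0-90); non-aromatic residues return
#'   `detected = FALSE` with `reason = "non_aromatic"`
#' @export
detectStacking <- function(model, residue, base, thresholds = ContactThresholds()) {
  stopifnot(is(model, "StructureModel"), is(thresholds, "ContactThresholds"))
  r <- .selectAtoms(model, residue, "side_chain")
  b <- .selectAtoms(model, base, "all_heavy")
  if (nrow(r) == 0L || nrow(b) == 0L) stop("empty selection")
  if (!r$resid[1] %in% names(AROMATIC_RINGS) &&
      !any(r$elety %in% NUCLEOBASE_RING))
    return(list(detected = FALSE, reason = "non_aromatic"))
  rRing <- .ringAtoms(r); bRing <- b[b$elety %in% NUCLEOBASE_RING, ]
  if (nrow(rRing) < 3L || nrow(bRing) < 3L)
    return(list(detected = FALSE, reason = "ring_atoms_missing"))
  p1 <- .planeFit(.xyz(rRing)); p2 <- .planeFit(.xyz(bRing))
  cd <- sqrt(sum((p1$centroid - p2$centroid)^2))
  ang <- .angleDeg(p1$normal, p2$normal)
  if (ang > 90) ang <- 180 - ang
  list(detected = cd <= thresholds@stackMaxCentroid &&
                  ang <= thresholds@stackMaxPlaneAngle,
       centroidDist = cd, planeAngle = ang)
}

#' Detect intercalation of a residue between the bases flanking the lesion
#'
#' A residue of the DNA-intercalating loop is reported as intercalating
#' when its closest approach to both nucleotides flanking the everted base
#' (positions +/- 1 on the base's strand, plus the two nearest nucleotides
#' of the complementary strand when present) falls below `wallMaxDist`.
#' This is a descriptive simplification: the residue occupies the gap left
#' by base eversion.
#'
#' @inheritParams detectHbond
#' @return list with `detected`, the flanking residue ids and distances
#' @export
detectIntercalation <- function(model, residue, base = "lesion",
                                thresholds = ContactThresholds()) {
  stopifnot(is(model, "StructureModel"))
  b <- .selectAtoms(model, base, "all_heavy")
  if (nrow(b) == 0L) stop("empty base selection")
  a <- model@atoms
  chain <- b$chain[1]; resno <- b$resno[1]
  flanks <- list()
  for (dn in c(-1L, 1L)) {
    f <- a[a$chain == chain & a$resno == resno + dn, ]
    if (nrow(f)) flanks[[paste0(chain, resno + dn)]] <- f
  }
  ## nearest two nucleotides on other chains carrying nucleobase ring atoms
  other <- a[a$chain != chain & a$elety %in% NUCLEOBASE_RING, ]
  if (nrow(other)) {
    ids <- unique(paste(other$chain, other$resno))
    ctr <- colMeans(.xyz(b))
    dd <- vapply(ids, function(id) {
      rows <- other[paste(other$chain, other$resno) == id, ]
      min(sqrt(colSums((t(.xyz(rows)) - ctr)^2)))
    }, numeric(1))
    for (id in ids[order(dd)][seq_len(min(2L, length(ids)))])
      flanks[[gsub(" ", "", id)]] <-
        a[paste(a$chain, a$resno) == id, ]
  }
  if (length(flanks) == 0L)
    return(list(detected = FALSE, reason = "no_flanking_nucleotides"))
  dists <- vapply(names(flanks), function(id) {
    f <- flanks[[id]][flanks[[id]]$elem != "H", ]
    r <- .selectAtoms(model, residue, "side_chain")
    if (nrow(r) == 0L) return(NA_real_)
    min(.pairDists(.xyz(r), .xyz(f)))
  }, numeric(1))
  list(detected = all(dists <= thresholds@wallMaxDist, na.rm = FALSE) &&
         !anyNA(dists),
       flanks = names(flanks), distances = dists)
}

#' Classify the contact between a pocket residue and the flipped-out base
#'
#' Applies the category precedence hydrogen_bond > stacking > coordination
#' (when a numeric coordination distance is requested for this residue) >
#' pocket_wall (closest approach within `wallMaxDist`) > none. The record
#' always carries the minimum heavy-atom distance.
#'
#' @inheritParams detectHbond
#' @param coordination report this residue's contact as a numeric
#'   coordination distance when no hydrogen bond or stacking is found?
#' @param intercalation test for intercalation between the lesion-flanking
#'   bases first (for DNA-intercalating loop residues)?
#' @return a [ContactRecord-class]
#' @export
classifyContact <- function(model, residue, base = "lesion",
                            thresholds = ContactThresholds(),
                            coordination = FALSE, intercalation = FALSE) {
  md <- minDistance(model, residue, base)
  lbl <- .selLabel(residue)
  baseLbl <- .baseLabel(model, base)
  if (intercalation) {
    ic <- detectIntercalation(model, residue, base, thresholds)
    if (isTRUE(ic$detected))
      return(new("ContactRecord", residue = lbl, base = baseLbl,
                 category = "intercalating", minDist = md,
                 geometry = list(flankDistances = ic$distances)))
  }
  hb <- detectHbond(model, residue, base, thresholds)
  if (isTRUE(hb$detected))
    return(new("ContactRecord", residue = lbl, base = baseLbl,
               category = "hydrogen_bond", minDist = md,
               geometry = list(distance = hb$distance, angle = hb$angle,
                               donor = hb$donor, acceptor = hb$acceptor)))
  st <- detectStacking(model, residue, base, thresholds)
  if (isTRUE(st$detected))
    return(new("ContactRecord", residue = lbl, base = baseLbl,
               category = "stacking", minDist = md,
               geometry = list(centroidDist = st$centroidDist,
                               planeAngle = st$planeAngle)))
  if (coordination && md <= thresholds@wallMaxDist)
    return(new("ContactRecord", residue = lbl, base = baseLbl,
               category = "coordination", minDist = md,
               geometry = list(distance = md)))
  if (md <= thresholds@wallMaxDist)
    return(new("ContactRecord", residue = lbl, base = baseLbl,
               category = "pocket_wall", minDist = md,
               geometry = list(distance = md)))
  new("ContactRecord", residue = lbl, base = baseLbl, category = "none",
      minDist = md, geometry = list())
}

.baseLabel <- function(model, base) {
  if (!identical(base, "lesion")) return(.selLabel(base))
  b <- model@atoms[model@atoms$isLesion, ]
  if (nrow(b) == 0L) "lesion" else
    paste0(b$resid[1], b$resno[1])
}

#' Contact table for a set of pocket residues
#'
#' Classifies every residue in `residues` against the flipped-out base and
#' assembles the per-residue records into a [ContactTable-class].
#' Unresolvable residues are listed with category "missing" rather than
#' failing the table.
#'
#' @param model a [StructureModel-class]
#' @param residues residue labels (default: the eleven ABH2 pocket
#'   residues, [pocketResidues()])
#' @param base base selector, see [minDistance()]
#' @param thresholds a [ContactThresholds-class]
#' @param coordination residues whose contact is reported as a numeric
#'   coordination distance (default Arg110)
#' @param intercalating residues of the DNA-intercalating loop tested for
#'   intercalation (default Val101, Phe102)
#' @return a [ContactTable-class]
#' @export
contactTable <- function(model, residues = pocketResidues(), base = "lesion",
                         thresholds = ContactThresholds(),
                         coordination = "Arg110",
                         intercalating = c("Val101", "Phe102")) {
  stopifnot(is(model, "StructureModel"))
  recs <- lapply(residues, function(rl) {
    rec <- tryCatch(
      classifyContact(model, rl, base, thresholds,
                      coordination = rl %in% coordination,
                      intercalation = rl %in% intercalating),
      error = function(e) new("ContactRecord", residue = .selLabel(rl),
                              base = .baseLabel(model, base),
                              category = "missing", minDist = NA_real_,
                              geometry = list(error = conditionMessage(e))))
    data.frame(residue = rec@residue, base = rec@base,
               category = rec@category, minDist = rec@minDist,
               hbondDist = rec@geometry$distance %||% NA_real_,
               hbondAngle = rec@geometry$angle %||% NA_real_,
               centroidDist = rec@geometry$centroidDist %||% NA_real_,
               planeAngle = rec@geometry$planeAngle %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  new("ContactTable", records = do.call(rbind, recs),
      base = .baseLabel(model, base), source = model@source)
}

#' Check the metal-coordination triad
#'
#' Locates the catalytic metal (Mn/Fe/Zn and other common substitutes) and
#' reports, per triad residue, the closest coordinating-atom distance and
#' whether it is within `metalMaxDist`.
#'
#' @param model a [StructureModel-class]
#' @param triad residue labels of the coordinating triad
#' @param thresholds a [ContactThresholds-class]
#' @param metals element symbols accepted as the catalytic metal
#' @return data.frame with columns residue, distance, coordinating
#' @export
checkMetalSite <- function(model, triad = c("His171", "Asp173", "His236"),
                           thresholds = ContactThresholds(),
                           metals = METAL_ELEMS) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  metal <- a[a$elem %in% metals | a$resid %in% metals, ]
  if (nrow(metal) == 0L)
    stop("no metal atom (", paste(metals, collapse = "/"), ") in the model")
  M <- .xyz(metal)
  out <- lapply(triad, function(rl) {
    r <- .selectAtoms(model, rl, "side_chain")
    if (nrow(r) == 0L)
      return(data.frame(residue = rl, distance = NA_real_,
                        coordinating = NA))
    d <- min(.pairDists(.xyz(r), M))
    data.frame(residue = rl, distance = d,
               coordinating = d <= thresholds@metalMaxDist)
  })
  do.call(rbind, out)
}
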