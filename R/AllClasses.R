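## S4 classes for the binding, kinetics and contact-mapping pipeline.

VARIANTS <- c("WT", "Y122A", "I168A", "D173A")
LESIONS  <- c("m1A", "m3C")

## ---------------------------------------------------------------------------
## Hill-equation parameter set

#' Hill binding-isotherm parameters
#'
#' Parameters of the Hill equation
#' \deqn{F = F_u + (F_b - F_u) / (1 + (K_d / E_0)^h)}
#' describing the fraction of bound DNA \eqn{F} as a function of total enzyme
#' concentration \eqn{E_0}.
#'
#' @slot Kd effective dissociation constant, uM (> 0)
#' @slot h Hill coefficient, dimensionless (> 0)
#' @slot Fu baseline bound fraction at zero enzyme (0..1)
#' @slot Fb saturating bound fraction (Fu..1)
#' @seealso [hillModel()], [fitHill()]
#' @export
setClass("HillParams",
  representation(Kd = "numeric", h = "numeric", Fu = "numeric", Fb = "numeric"))

setValidity("HillParams", function(object) {
  msg <- character()
  for (s in c("Kd", "h", "Fu", "Fb"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      return(paste0("slot '", s, "' must be a single non-NA number"))
  if (object@Kd <= 0) msg <- c(msg, "Kd must be > 0")
  if (object@h <= 0) msg <- c(msg, "h must be > 0")
  if (object@Fu < 0 || object@Fb > 1 || object@Fu > object@Fb)
    msg <- c(msg, "need 0 <= Fu <= Fb <= 1")
  if (length(msg)) msg else TRUE
})

#' @param Kd,h,Fu,Fb see slots of [HillParams-class]
#' @rdname HillParams-class
#' @export
HillParams <- function(Kd, h = 1, Fu = 0, Fb = 1)
  new("HillParams", Kd = Kd, h = h, Fu = Fu, Fb = Fb)

## ---------------------------------------------------------------------------
## Titration design and series

#' EMSA titration design
#'
#' Experimental design of a gel-shift titration: the enzyme concentration
#' grid, the labeled duplex concentration, the number of technical replicates
#' and the densitometry noise level used by the synthetic generator.
#' Defaults mirror the study design: 1.2 uM FAM-labeled 17-nt duplex titrated
#' with enzyme at 0, 0.4, 0.8, 1.2, 1.6, 3.2, 6.4, 9.6 and 12.8 uM in
#' triplicate.
#'
#' @slot enzymeConcs enzyme concentrations, uM; non-negative, strictly
#'   increasing, must include 0 (the zero-enzyme baseline lane)
#' @slot dnaConc labeled duplex concentration, uM (> 0)
#' @slot replicates technical replicates (>= 1)
#' @slot noiseSd additive Gaussian s.d. on the bound-fraction scale (>= 0)
#' @slot seed RNG seed used by [makeTitration()]
#' @export
setClass("TitrationDesign",
  representation(enzymeConcs = "numeric", dnaConc = "numeric",
                 replicates = "integer", noiseSd = "numeric", seed = "integer"))

setValidity("TitrationDesign", function(object) {
  msg <- character()
  ec <- object@enzymeConcs
  if (length(ec) < 2L || any(ec < 0) || any(diff(ec) <= 0))
    msg <- c(msg, "enzymeConcs must be non-negative and strictly increasing")
  if (!any(ec == 0)) msg <- c(msg, "enzymeConcs must include 0")
  if (object@dnaConc <= 0) msg <- c(msg, "dnaConc must be > 0")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param enzymeConcs,dnaConc,replicates,noiseSd,seed see slots
#' @rdname TitrationDesign-class
#' @export
TitrationDesign <- function(enzymeConcs = c(0, 0.4, 0.8, 1.2, 1.6, 3.2, 6.4, 9.6, 12.8),
                            dnaConc = 1.2, replicates = 3L, noiseSd = 0,
                            seed = 1L)
  new("TitrationDesign", enzymeConcs = as.numeric(enzymeConcs),
      dnaConc = dnaConc, replicates = as.integer(replicates),
      noiseSd = noiseSd, seed = as.integer(seed))

#' Replicated titration measurements for one enzyme/lesion pair
#'
#' @slot variant enzyme form: one of WT, Y122A, I168A, D173A
#' @slot lesion methylated base in the duplex: m1A or m3C
#' @slot design the [TitrationDesign-class] that produced the points
#' @slot points data.frame with columns `E0` (uM), `F` (bound fraction) and
#'   `replicate`; exactly one row per (concentration, replicate) pair
#' @export
setClass("TitrationSeries",
  representation(variant = "character", lesion = "character",
                 design = "TitrationDesign", points = "data.frame"))

setValidity("TitrationSeries", function(object) {
  msg <- character()
  if (!object@variant %in% VARIANTS)
    msg <- c(msg, paste("variant must be one of", paste(VARIANTS, collapse = ", ")))
  if (!object@lesion %in% LESIONS)
    msg <- c(msg, paste("lesion must be one of", paste(LESIONS, collapse = ", ")))
  p <- object@points
  if (!all(c("E0", "F", "replicate") %in% names(p)))
    return("points needs columns E0, F, replicate")
  want <- expand.grid(E0 = object@design@enzymeConcs,
                      replicate = seq_len(object@design@replicates))
  have <- p[order(p$replicate, p$E0), c("E0", "replicate")]
  want <- want[order(want$replicate, want$E0), ]
  if (nrow(p) != nrow(want) ||
      !isTRUE(all.equal(unname(as.matrix(have)), unname(as.matrix(want)))))
    msg <- c(msg, "points must cover every (concentration, replicate) design pair exactly once")
  if (any(p$F < 0 | p$F > 1)) msg <- c(msg, "bound fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Kinetics

#' Ground-truth parameters for a synthetic demethylation time course
#'
#' @slot kobsTrue observed rate constant, 1/s
#' @slot KdTrue dissociation constant, uM
#' @slot E0,S0 total enzyme and substrate concentrations, uM
#' @slot plateau maximal product fraction (0..1]; sub-unity plateaus emulate
#'   the incomplete conversion seen in long reactions (enzyme/cofactor decay)
#' @export
setClass("KineticTruth",
  representation(kobsTrue = "numeric", KdTrue = "numeric",
                 E0 = "numeric", S0 = "numeric", plateau = "numeric"))

setValidity("KineticTruth", function(object) {
  v <- c(object@kobsTrue, object@KdTrue, object@E0, object@S0, object@plateau)
  if (any(!is.finite(v)) || any(v <= 0)) return("all parameters must be finite and > 0")
  if (object@plateau > 1) return("plateau must be <= 1")
  TRUE
})

#' @param kobsTrue,KdTrue,E0,S0,plateau see slots
#' @rdname KineticTruth-class
#' @export
KineticTruth <- function(kobsTrue, KdTrue, E0 = 1, S0 = 1, plateau = 1)
  new("KineticTruth", kobsTrue = kobsTrue, KdTrue = KdTrue,
      E0 = E0, S0 = S0, plateau = plateau)

#' Demethylation time course
#'
#' Product fraction versus time for one reaction at fixed total enzyme and
#' substrate concentrations.
#'
#' @slot variant,lesion enzyme form and lesion identity
#' @slot E0,S0 total enzyme / substrate concentrations, uM
#' @slot points data.frame with columns `t` (s, strictly increasing, >= 0)
#'   and `P` (product fraction in [0, 1])
#' @export
setClass("TimeCourse",
  representation(variant = "character", lesion = "character",
                 E0 = "numeric", S0 = "numeric", points = "data.frame"))

setValidity("TimeCourse", function(object) {
  p <- object@points
  if (!all(c("t", "P") %in% names(p))) return("points needs columns t, P")
  if (nrow(p) == 0L) return("time course has no points")
  if (any(p$t < 0) || any(diff(p$t) <= 0))
    return("times must be >= 0 and strictly increasing")
  if (any(p$P < 0 | p$P > 1)) return("product fractions must lie in [0, 1]")
  if (object@E0 <= 0 || object@S0 <= 0) return("E0 and S0 must be > 0")
  TRUE
})

#' Assay conditions entering the precatalytic-complex correction
#'
#' @slot E0,S0 total enzyme and DNA substrate concentrations, uM
#' @slot Kd equilibrium dissociation constant, uM (from the binding module)
#' @export
setClass("AssayConditions",
  representation(E0 = "numeric", S0 = "numeric", Kd = "numeric"))

setValidity("AssayConditions", function(object) {
  v <- c(object@E0, object@S0, object@Kd)
  if (any(!is.finite(v)) || any(v <= 0)) "E0, S0 and Kd must be finite and > 0" else TRUE
})

#' @param E0,S0,Kd see slots
#' @rdname AssayConditions-class
#' @export
AssayConditions <- function(E0 = 1, S0 = 1, Kd)
  new("AssayConditions", E0 = E0, S0 = S0, Kd = Kd)

#' Kinetic inference result for one enzyme/lesion pair
#'
#' @slot V0 initial velocity, uM/s, with standard deviation `V0Sd`
#' @slot V0Sd standard deviation of V0, uM/s
#' @slot ESeq equilibrium precatalytic complex concentration, uM
#' @slot kobs observed rate constant V0 / [E.S], 1/s, with `kobsSd`
#' @slot kobsSd standard deviation of kobs, 1/s
#' @slot endpoint30 product percentage at 1800 s
#' @slot method velocity estimation method used ("exponential" or "linear")
#' @slot flags diagnostic flags recorded during estimation
#' @export
setClass("KineticResult",
  representation(V0 = "numeric", V0Sd = "numeric", ESeq = "numeric",
                 kobs = "numeric", kobsSd = "numeric", endpoint30 = "numeric",
                 method = "character", flags = "character"))

setValidity("KineticResult", function(object) {
  if (object@ESeq < 0) return("ESeq must be >= 0")
  if (object@V0 < 0 || object@kobs < 0) return("V0 and kobs must be >= 0")
  if (object@ESeq > 0 &&
      abs(object@kobs - object@V0 / object@ESeq) > 1e-8 * max(object@kobs, 1e-12))
    return("kobs must equal V0 / ESeq")
  TRUE
})

## ---------------------------------------------------------------------------
## Gel observation and duplex substrate

#' Densitometry observation of a two-band gel lane
#'
#' Forward model of scanning densitometry: band intensities are a linear
#' scaling of the underlying molar fractions plus a shared background.
#' For an EMSA lane the bands are bound/unbound DNA; for the restriction
#' reporter they are product/substrate.
#'
#' @slot intensityBound bound (or product) band intensity, arbitrary units
#' @slot intensityUnbound unbound (or substrate) band intensity, same units
#' @slot background per-lane background level, same units
#' @export
setClass("GelObservation",
  representation(intensityBound = "numeric", intensityUnbound = "numeric",
                 background = "numeric"))

setValidity("GelObservation", function(object) {
  if (length(object@intensityBound) != length(object@intensityUnbound))
    return("band intensity vectors must have equal length")
  if (any(object@intensityBound < 0) || any(object@intensityUnbound < 0) ||
      any(object@background < 0))
    return("intensities must be >= 0")
  TRUE
})

#' 17-nt duplex substrate with the methylation-sensitive GATC reporter
#'
#' The study's substrates: a FAM-labeled top strand whose central GATC site
#' carries m1A (position 10) or m3C (position 12), annealed to the common
#' complementary strand. Demethylation restores the GATC site of the
#' unmodified control duplex, making repair readable by restriction
#' digestion.
#'
#' @slot topStrand top-strand sequence written with parent bases (the
#'   modified position is annotated separately), 5'->3'
#' @slot bottomStrand complementary strand, 5'->3'
#' @slot lesion "m1A", "m3C" or "none"
#' @slot modifiedPos 1-based position of the methylated base on the top
#'   strand (0 when lesion is "none")
#' @slot label 5' label on the top strand ("FAM")
#' @export
setClass("DuplexSubstrate",
  representation(topStrand = "character", bottomStrand = "character",
                 lesion = "character", modifiedPos = "integer",
                 label = "character"))

setValidity("DuplexSubstrate", function(object) {
  top <- Biostrings::DNAString(object@topStrand)
  bot <- Biostrings::DNAString(object@bottomStrand)
  if (as.character(Biostrings::reverseComplement(top)) != as.character(bot))
    return("strands must be reverse-complementary when the lesion is read as its parent base")
  if (object@lesion != "none") {
    if (object@modifiedPos < 1L || object@modifiedPos > nchar(object@topStrand))
      return("modifiedPos out of range")
    parent <- substr(object@topStrand, object@modifiedPos, object@modifiedPos)
    want <- if (object@lesion == "m1A") "A" else "C"
    if (parent != want)
      return(sprintf("lesion %s must sit on parent base %s", object@lesion, want))
  }
  ## demethylation must restore a GATC site
  if (length(Biostrings::matchPattern("GATC", top)) == 0L)
    return("demethylated top strand must contain a GATC site")
  TRUE
})

## ---------------------------------------------------------------------------
## Binding fit

#' Hill-equation fit result
#'
#' @slot params point estimates as a [HillParams-class]
#' @slot sd named per-parameter standard deviations (Kd, h, Fu, Fb); NA when
#'   the asymptotic covariance is unavailable (e.g. zero-residual fits)
#' @slot rss residual sum of squares
#' @slot nPoints number of fitted points
#' @slot converged optimizer convergence flag
#' @slot notes diagnostic messages recorded during fitting
#' @export
setClass("BindingFit",
  representation(params = "HillParams", sd = "numeric", rss = "numeric",
                 nPoints = "integer", converged = "logical",
                 notes = "character"))

setValidity("BindingFit", function(object) {
  if (object@nPoints < 4L) return("need at least 4 points (one per free parameter)")
  if (any(object@sd < 0, na.rm = TRUE)) return("standard deviations must be >= 0")
  if (object@rss < 0) return("rss must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Contacts

#' Geometric thresholds for contact classification
#'
#' Standard structural-biology heuristics; tune via the constructor when a
#' different convention is wanted.
#'
#' @slot hbondMaxDist donor-acceptor heavy-atom cutoff, Angstrom
#' @slot hbondMinAngle minimal D-H...A angle, degrees (used when hydrogens
#'   are present in the model)
#' @slot stackMaxCentroid maximal ring-centroid separation, Angstrom
#' @slot stackMaxPlaneAngle maximal inter-plane angle, degrees
#' @slot wallMaxDist pocket-wall closest-approach cutoff, Angstrom
#' @slot metalMaxDist metal-coordination cutoff, Angstrom
#' @export
setClass("ContactThresholds",
  representation(hbondMaxDist = "numeric", hbondMinAngle = "numeric",
                 stackMaxCentroid = "numeric", stackMaxPlaneAngle = "numeric",
                 wallMaxDist = "numeric", metalMaxDist = "numeric"))

setValidity("ContactThresholds", function(object) {
  v <- c(object@hbondMaxDist, object@hbondMinAngle, object@stackMaxCentroid,
         object@stackMaxPlaneAngle, object@wallMaxDist, object@metalMaxDist)
  if (any(v <= 0)) "all thresholds must be > 0" else TRUE
})

#' @param hbondMaxDist,hbondMinAngle,stackMaxCentroid,stackMaxPlaneAngle,wallMaxDist,metalMaxDist see slots
#' @rdname ContactThresholds-class
#' @export
ContactThresholds <- function(hbondMaxDist = 3.5, hbondMinAngle = 120,
                              stackMaxCentroid = 4.5, stackMaxPlaneAngle = 30,
                              wallMaxDist = 4.5, metalMaxDist = 2.6)
  new("ContactThresholds", hbondMaxDist = hbondMaxDist,
      hbondMinAngle = hbondMinAngle, stackMaxCentroid = stackMaxCentroid,
      stackMaxPlaneAngle = stackMaxPlaneAngle, wallMaxDist = wallMaxDist,
      metalMaxDist = metalMaxDist)

#' Atomic structure model
#'
#' Thin container over the ATOM/HETATM records of a PDB file, with modified
#' nucleotides flagged via a configurable residue-code map.
#'
#' @slot atoms data.frame with columns type, eleno, elety, resid, chain,
#'   resno, x, y, z, elem (element symbol), isLesion
#' @slot source file path or identifier the model was read from
#' @slot lesionCodes residue codes treated as modified nucleotides
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", source = "character",
                 lesionCodes = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z", "elem")
  if (!all(need %in% names(a)))
    return(paste("atoms needs columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("empty model (no atoms)")
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
    return("coordinates must be finite")
  TRUE
})

#' Per-residue contact classification
#'
#' @slot residue residue label (e.g. "Tyr122")
#' @slot base modified-nucleotide identifier
#' @slot category one of hydrogen_bond, stacking, pocket_wall, coordination,
#'   intercalating, none, missing
#' @slot minDist closest heavy-atom approach, Angstrom
#' @slot geometry category-specific measurements (distances, angles)
#' @export
setClass("ContactRecord",
  representation(residue = "character", base = "character",
                 category = "character", minDist = "numeric",
                 geometry = "list"))

setValidity("ContactRecord", function(object) {
  ok <- c("hydrogen_bond", "stacking", "pocket_wall", "coordination",
          "intercalating", "none", "missing")
  if (!object@category %in% ok)
    return(paste("category must be one of", paste(ok, collapse = ", ")))
  if (object@category != "missing" && isTRUE(object@minDist <= 0))
    return("minDist must be > 0")
  TRUE
})

#' Contact table (active-site residues vs a flipped-out base)
#'
#' @slot records data.frame with one row per residue: residue, base,
#'   category, minDist plus geometry summaries
#' @slot base the modified-nucleotide identifier classified against
#' @slot source structure the table derives from
#' @export
setClass("ContactTable",
  representation(records = "data.frame", base = "character",
                 source = "character"))

## ---------------------------------------------------------------------------
## Recovery report

#' Parameter-recovery report
#'
#' Result of the simulate -> fit -> compare pipeline over the reference
#' (variant, lesion) parameter grid.
#'
#' @slot table per-condition truths, estimates and relative errors
#' @slot folds fold-change summary (raw and rounded ratios)
#' @slot noiseSd generator noise used
#' @slot seed RNG seed used
#' @slot tolerances named relative tolerances used for the pass flags
#' @slot passed overall pass flag
#' @export
setClass("RecoveryReport",
  representation(table = "data.frame", folds = "data.frame",
                 noiseSd = "numeric", seed = "integer",
                 tolerances = "numeric", passed = "logical"))
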