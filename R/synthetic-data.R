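## Synthetic-data module: forward models for the EMSA titrations, the
## restriction-coupled demethylation time courses, gel densitometry and the
## reporter duplexes. All generators are deterministic for a fixed seed.

#' Default demethylation time grid
#'
#' Nine sampling times spanning the assayed window of 30 s to 1 h.
#'
#' @return numeric vector of times, s
#' @export
defaultTimeGrid <- function() c(30, 60, 120, 300, 600, 900, 1800, 2700, 3600)

#' Simulate an EMSA titration series
#'
#' Generates replicated bound fractions from the Hill isotherm
#' ([hillModel()]) on the design's enzyme-concentration grid, adds Gaussian
#' densitometry noise on the fraction scale, and clips to [0, 1]. The
#' zero-enzyme lane yields the baseline Fu (plus noise).
#'
#' @param params generating [HillParams-class]
#' @param design a [TitrationDesign-class] (grid, replicates, noise, seed)
#' @param variant,lesion labels for the series
#' @return a [TitrationSeries-class]
#' @examples
#' makeTitration(HillParams(Kd = 2.45), TitrationDesign())
#' @export
makeTitration <- function(params, design = TitrationDesign(),
                          variant = "WT", lesion = "m1A") {
  stopifnot(is(params, "HillParams"), is(design, "TitrationDesign"))
  validObject(params); validObject(design)
  grid <- expand.grid(E0 = design@enzymeConcs,
                      replicate = seq_len(design@replicates))
  mu <- hillModel(grid$E0, params)
  F <- withSeed(design@seed,
                clip01(mu + stats::rnorm(length(mu), 0, design@noiseSd)))
  new("TitrationSeries", variant = variant, lesion = lesion, design = design,
      points = data.frame(E0 = grid$E0, F = F, replicate = grid$replicate))
}

#' Simulate a demethylation time course
#'
#' Noise-free model: a single-exponential saturation
#' \deqn{P(t) = A\,(1 - e^{-\lambda t}), \qquad \lambda = V_0 / (A S_0),}
#' where the plateau \eqn{A} is the maximal product fraction and the initial
#' velocity is \eqn{V_0 = k_{obs} \cdot [E.S]} with the equilibrium
#' precatalytic-complex concentration from [esEquilibrium()]. The
#' parameterization guarantees the exact initial slope
#' \eqn{dP/dt|_0 \cdot S_0 = V_0}; the sub-unity plateau emulates the
#' incomplete conversion of long reactions. Gaussian noise is added on the
#' fraction scale and the result clipped to [0, 1].
#'
#' @param truth generating [KineticTruth-class]
#' @param times sampling times, s, within [0, 3600], strictly increasing
#' @param noiseSd Gaussian s.d. on the product-fraction scale
#' @param seed RNG seed
#' @param variant,lesion labels for the series
#' @return a [TimeCourse-class]
#' @examples
#' tc <- makeTimeCourse(KineticTruth(0.071, 2.45, plateau = 0.54))
#' measurements(tc)
#' @export
makeTimeCourse <- function(truth, times = defaultTimeGrid(), noiseSd = 0,
                           seed = 1L, variant = "WT", lesion = "m1A") {
  stopifnot(is(truth, "KineticTruth"))
  validObject(truth)
  if (length(times) == 0L) stop("empty time grid")
  if (any(times < 0) || any(times > 3600))
    stop("times must lie within [0, 3600] s")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  A <- truth@plateau
  V0 <- truth@kobsTrue * esEquilibrium(truth@E0, truth@S0, truth@KdTrue)
  lambda <- V0 / (A * truth@S0)
  P <- A * (1 - exp(-lambda * times))
  P <- withSeed(seed, clip01(P + stats::rnorm(length(P), 0, noiseSd)))
  new("TimeCourse", variant = variant, lesion = lesion,
      E0 = truth@E0, S0 = truth@S0,
      points = data.frame(t = times, P = P))
}

#' Simulate a densitometry observation of a two-band lane
#'
#' Forward model of gel scanning: each band intensity is
#' `scale * fraction + background + noise` (bound/product band) and
#' `scale * (1 - fraction) + background + noise` (unbound/substrate band),
#' with independent Gaussian noise per band, floored at zero. At zero noise
#' the observation round-trips exactly through [boundFraction()].
#'
#' @param fraction underlying molar fraction(s) in [0, 1]
#' @param scale multiplicative band scaling (> 0), arbitrary units
#' @param background additive per-lane background (>= 0)
#' @param noiseSd Gaussian s.d. on the intensity scale
#' @param seed RNG seed
#' @return a [GelObservation-class] (vectorized over `fraction`)
#' @examples
#' boundFraction(simulateGel(0.754, scale = 1000))   # 0.754
#' @export
simulateGel <- function(fraction, scale = 1000, background = 0, noiseSd = 0,
                        seed = 1L) {
  if (any(fraction < 0 | fraction > 1)) stop("fraction must lie in [0, 1]")
  if (scale <= 0) stop("scale must be > 0")
  if (background < 0) stop("background must be >= 0")
  n <- length(fraction)
  noise <- withSeed(seed, matrix(stats::rnorm(2 * n, 0, noiseSd), ncol = 2))
  new("GelObservation",
      intensityBound = pmax(scale * fraction + background + noise[, 1], 0),
      intensityUnbound = pmax(scale * (1 - fraction) + background + noise[, 2], 0),
      background = rep(background, n))
}

## Reference 17-mer sequences (parent-base spelling); the modification sits
## within the central GATC site, which is restored upon demethylation.
TOP_STRAND <- "AGTTCAATGATCTTCAT"
BOTTOM_STRAND <- "ATGAAGATCATTGAACT"

#' Construct a reporter duplex substrate
#'
#' Returns the study's 17-nt FAM-labeled duplex for a given lesion: m1A at
#' top-strand position 10, m3C at position 12, or the unmodified GATC
#' control. Strand sequences are stored with parent bases; the lesion
#' position is annotated so that demethylation corresponds to reading the
#' strand as written, restoring the methylation-sensitive GATC site.
#'
#' @param lesion "m1A", "m3C" or "none"
#' @return a [DuplexSubstrate-class]
#' @examples
#' makeDuplex("m1A")
#' @export
makeDuplex <- function(lesion = c("m1A", "m3C", "none")) {
  lesion <- match.arg(lesion)
  pos <- switch(lesion, m1A = 10L, m3C = 12L, none = 0L)
  new("DuplexSubstrate", topStrand = TOP_STRAND, bottomStrand = BOTTOM_STRAND,
      lesion = lesion, modifiedPos = pos, label = "FAM")
}

#' Methylation-sensitive restriction digestion of a reporter duplex
#'
#' Models the GATC-recognizing, methylation-sensitive endonuclease readout:
#' a duplex still carrying its methyl lesion is refractory and stays intact
#' (labeled length 17 nt); once demethylated (or for the unmodified
#' control) the GATC site is cleaved and the 5'-FAM-labeled fragment is
#' 9 nt. Cleavage is modeled as complete, with the cut placed after the
#' first base of the GATC site on the labeled strand
#' (AGTTCAATG | ATCTTCAT); only fragment lengths matter downstream.
#'
#' @param duplex a [DuplexSubstrate-class]
#' @param demethylated has the lesion been repaired? Ignored (treated as
#'   TRUE) for the unmodified control duplex.
#' @return integer vector of labeled-strand fragment length(s), nt
#' @examples
#' digestDuplex(makeDuplex("m1A"), demethylated = TRUE)    # 9
#' digestDuplex(makeDuplex("m1A"), demethylated = FALSE)   # 17
#' @export
digestDuplex <- function(duplex, demethylated = FALSE) {
  stopifnot(is(duplex, "DuplexSubstrate"))
  validObject(duplex)
  n <- nchar(duplex@topStrand)
  if (duplex@lesion == "none") demethylated <- TRUE
  if (!demethylated) return(n)
  site <- Biostrings::matchPattern("GATC", Biostrings::DNAString(duplex@topStrand))
  if (length(site) == 0L)
    stop("inconsistent substrate: no GATC site after demethylation")
  ## labeled (5') fragment ends after the first base of the recognition site
  as.integer(Biostrings::start(site)[1])
}
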