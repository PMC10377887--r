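## Published steady-state reference parameters for ABH2 wild type and the
## three alanine mutants, used as ground truths by the recovery pipeline.

#' Reference binding and kinetic parameters for ABH2 enzymes
#'
#' Published steady-state parameters for the wild-type enzyme and the
#' Y122A, I168A and D173A active-site mutants on the m1A- and
#' m3C-containing 17-nt duplexes: equilibrium dissociation constants (uM,
#' with SD), observed catalytic rate constants (1/s, with SD) and the
#' product-accumulation plateau used by the synthetic generator (fraction).
#' The wild-type plateaus (0.540 for m1A, 0.754 for m3C) and the I168A
#' plateaus (0.521, 0.50) are the reported 30-min endpoint levels; the
#' Y122A and D173A plateaus were not reported numerically and are set to
#' representative "significantly lower" values (0.30 for m1A, 0.25 for
#' m3C) that do not enter any rate-constant estimate (the initial-slope
#' readout is plateau-invariant).
#'
#' @return data.frame with columns variant, lesion, Kd, KdSd, kobs, kobsSd,
#'   plateau
#' @examples
#' abh2RefParams()
#' @export
abh2RefParams <- function() {
  data.frame(
    variant = rep(c("WT", "Y122A", "I168A", "D173A"), 2),
    lesion  = rep(c("m1A", "m3C"), each = 4),
    Kd      = c(2.45, 2.11, 2.70, 2.10,  3.50, 2.49, 4.10, 3.09),
    KdSd    = c(0.07, 0.08, 0.40, 0.09,  0.10, 0.06, 0.10, 0.07),
    kobs    = c(0.071, 0.013, 0.020, 0.010,  0.045, 0.005, 0.008, 0.0045),
    kobsSd  = c(0.007, 0.006, 0.010, 0.003,  0.007, 0.001, 0.002, 0.0009),
    plateau = c(0.540, 0.30, 0.521, 0.30,  0.754, 0.25, 0.50, 0.25),
    stringsAsFactors = FALSE)
}
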