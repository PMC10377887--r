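## Binding module: densitometry -> bound fractions -> Hill-equation fits.

#' Hill binding isotherm
#'
#' Evaluates the fraction of bound DNA as a function of total enzyme
#' concentration,
#' \deqn{F(E_0) = F_u + \frac{F_b - F_u}{1 + (K_d/E_0)^h},}
#' with the limit convention \eqn{F(0) = F_u}. At \eqn{E_0 = K_d} the curve
#' passes through the midpoint \eqn{(F_u + F_b)/2} for any Hill coefficient.
#'
#' The model treats total enzyme as free enzyme (no DNA depletion), which is
#' the convention of EMSA titration analysis when enzyme is in excess; see
#' [depletionModel()] for the quadratic-depletion alternative.
#'
#' @param E0 enzyme concentration(s), uM (>= 0)
#' @param params a [HillParams-class]
#' @return bound fraction(s), same length as `E0`
#' @examples
#' hillModel(2.45, HillParams(Kd = 2.45))   # 0.5: half-saturation at E0 = Kd
#' @export
hillModel <- function(E0, params) {
  stopifnot(is(params, "HillParams"))
  validObject(params)
  if (any(E0 < 0)) stop("E0 must be >= 0")
  F <- params@Fu + (params@Fb - params@Fu) / (1 + (params@Kd / E0)^params@h)
  F[E0 == 0] <- params@Fu
  F
}

#' Quadratic ligand-depletion isotherm (alternative model)
#'
#' Bound fraction computed from the exact equilibrium complex concentration
#' [E.S] (see [esEquilibrium()]) rather than the free-enzyme approximation:
#' \eqn{F = F_u + (F_b - F_u)\,[E.S]/S_0}. Provided as an optional
#' alternative for titrations where the labeled DNA concentration is
#' comparable to Kd; it is not the model used for the reported dissociation
#' constants.
#'
#' @param E0 enzyme concentration(s), uM
#' @param Kd dissociation constant, uM
#' @param S0 labeled DNA concentration, uM
#' @param Fu,Fb baseline and saturation bound fractions
#' @return bound fraction(s)
#' @export
depletionModel <- function(E0, Kd, S0, Fu = 0, Fb = 1) {
  es <- vapply(E0, function(e)
    if (e == 0) 0 else esEquilibrium(e, S0, Kd), numeric(1))
  Fu + (Fb - Fu) * es / S0
}

#' Bound fraction from gel band intensities
#'
#' Background-subtracted densitometry quantification
#' \eqn{F = (I_b - bg) / ((I_b - bg) + (I_u - bg))}, with negative
#' background-subtracted intensities clipped to zero and the result clipped
#' to [0, 1].
#'
#' @param bound bound-band (or product-band) intensities, or a
#'   [GelObservation-class]
#' @param unbound unbound-band (or substrate-band) intensities; ignored when
#'   `bound` is a [GelObservation-class]
#' @param background background level(s), recycled
#' @return bound fraction(s)
#' @examples
#' boundFraction(754, 246)          # 0.754
#' @export
setGeneric("boundFraction",
  function(bound, unbound, background = 0) standardGeneric("boundFraction"))

#' @rdname boundFraction
#' @export
setMethod("boundFraction", "numeric", function(bound, unbound, background = 0) {
  b <- pmax(bound - background, 0)
  u <- pmax(unbound - background, 0)
  tot <- b + u
  if (any(tot == 0))
    stop("undefined fraction: both background-subtracted intensities are zero")
  clip01(b / tot)
})

#' @rdname boundFraction
#' @export
setMethod("boundFraction", "GelObservation", function(bound, unbound, background = 0) {
  boundFraction(bound@intensityBound, bound@intensityUnbound, bound@background)
})

#' Fit the Hill equation to a titration series
#'
#' Least-squares fit of [hillModel()] over all replicate points of a
#' titration, estimating Kd, h, Fu and Fb. Box constraints and data-driven
#' initialization follow the EMSA conventions: Kd starts at the
#' concentration whose mean bound fraction is nearest half-maximal, h at 1,
#' Fu/Fb at the observed extremes. Zero-concentration points enter through
#' the E0 -> 0 limit (F = Fu).
#'
#' Parameter uncertainties in `sd` are asymptotic (from the fit covariance);
#' they are NA for zero-residual fits where the covariance degenerates. Use
#' [bootstrapHill()] for resampling-based uncertainties.
#'
#' @param series a [TitrationSeries-class]
#' @param bounds optional named list with elements `lower`/`upper`, numeric
#'   vectors over (Kd, h, Fu, Fb); defaults: Kd in (0, 10*max E0], h in
#'   (0, 6], Fu and Fb in [0, 1]
#' @param init optional [HillParams-class] overriding the default start
#' @return a [BindingFit-class]; non-convergence is reported through the
#'   `converged` flag rather than an error
#' @examples
#' s <- makeTitration(HillParams(Kd = 2.45), TitrationDesign())
#' kd(fitHill(s))
#' @export
fitHill <- function(series, bounds = NULL, init = NULL) {
  stopifnot(is(series, "TitrationSeries"))
  validObject(series)
  pts <- series@points
  E0 <- pts$E0
  F  <- pts$F
  if (length(unique(E0)) < 5L)
    stop("need at least 5 distinct enzyme concentrations")
  if (stats::sd(F) < 1e-12 || diff(range(F)) < 1e-9)
    stop("degenerate series: bound fraction does not vary across the titration")

  maxE <- max(E0)
  lower <- c(Kd = 1e-9, h = 1e-3, Fu = 0, Fb = 0)
  upper <- c(Kd = 10 * maxE, h = 6, Fu = 1, Fb = 1)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }

  if (is.null(init)) {
    mF <- tapply(F, E0, mean)
    half <- (min(mF) + max(mF)) / 2
    pos <- sort(unique(E0[E0 > 0]))
    kd0 <- pos[which.min(abs(mF[as.character(pos)] - half))]
    start <- list(Kd = unname(kd0), h = 1,
                  Fu = max(min(F), 0), Fb = min(max(F), 1))
  } else {
    start <- list(Kd = init@Kd, h = init@h, Fu = init@Fu, Fb = init@Fb)
  }

  ## raw model without class validity so derivative perturbations at the
  ## box bounds do not abort the optimizer
  hillRaw <- function(E0, Kd, h, Fu, Fb) {
    lo <- min(Fu, Fb); hi <- max(Fu, Fb)
    ifelse(E0 == 0, lo, lo + (hi - lo) / (1 + (Kd / E0)^h))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      F ~ hillRaw(E0, Kd, h, Fu, Fb),
      data = data.frame(E0 = E0, F = F),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  notes <- character()
  if (inherits(fit, "error")) {
    ## flagged result, not an exception
    return(new("BindingFit",
               params = HillParams(start$Kd, start$h, start$Fu, max(start$Fb, start$Fu)),
               sd = c(Kd = NA_real_, h = NA_real_, Fu = NA_real_, Fb = NA_real_),
               rss = sum((F - hillModel(E0, HillParams(start$Kd, start$h, start$Fu,
                                                       max(start$Fb, start$Fu))))^2),
               nPoints = length(F), converged = FALSE,
               notes = conditionMessage(fit)))
  }

  cf <- stats::coef(fit)
  Fu <- min(cf[["Fu"]], cf[["Fb"]]); Fb <- max(cf[["Fu"]], cf[["Fb"]])
  params <- HillParams(cf[["Kd"]], cf[["h"]], Fu, Fb)
  sds <- tryCatch({
    s <- summary(fit)$coefficients[, "Std. Error"]
    c(Kd = s[["Kd"]], h = s[["h"]], Fu = s[["Fu"]], Fb = s[["Fb"]])
  }, error = function(e) c(Kd = NA_real_, h = NA_real_, Fu = NA_real_, Fb = NA_real_))
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-20) {
    sds[] <- NA_real_
    notes <- c(notes, "zero-residual fit: asymptotic SDs unavailable")
  }
  conv <- if (is.null(fit$convInfo)) TRUE else isTRUE(fit$convInfo$isConv)
  new("BindingFit", params = params, sd = sds, rss = rss,
      nPoints = length(F), converged = conv, notes = notes)
}

#' Bootstrap uncertainties for a Hill fit
#'
#' Case-resampling bootstrap over replicate points: within each enzyme
#' concentration, replicate measurements are resampled with replacement and
#' the Hill fit is repeated. Returns the per-parameter standard deviations
#' of the bootstrap estimates. Deterministic for a fixed seed.
#'
#' @param series a [TitrationSeries-class] with >= 2 replicates
#' @param nBoot number of bootstrap refits (default 1000); fewer than 50
#'   records a warning in the result's attributes
#' @param seed RNG seed
#' @return named numeric vector of SDs (Kd, h, Fu, Fb) with attributes
#'   `nBoot`, `seed` and `warnings`
#' @export
bootstrapHill <- function(series, nBoot = 1000L, seed = 1L) {
  stopifnot(is(series, "TitrationSeries"))
  if (series@design@replicates < 2L)
    stop("bootstrap requires at least 2 replicates")
  warn <- character()
  if (nBoot < 50L) warn <- c(warn, "nBoot < 50: bootstrap SDs will be unstable")
  pts <- series@points
  reps <- sort(unique(pts$replicate))
  concs <- series@design@enzymeConcs
  est <- withSeed(seed, {
    out <- matrix(NA_real_, nrow = nBoot, ncol = 4,
                  dimnames = list(NULL, c("Kd", "h", "Fu", "Fb")))
    for (b in seq_len(nBoot)) {
      resampled <- do.call(rbind, lapply(concs, function(cc) {
        rows <- pts[pts$E0 == cc, ]
        rows <- rows[sample(nrow(rows), nrow(rows), replace = TRUE), ]
        rows$replicate <- seq_len(nrow(rows))
        rows
      }))
      bs <- series
      bs@points <- resampled
      fit <- tryCatch(fitHill(bs), error = function(e) NULL)
      if (!is.null(fit) && fit@converged) {
        p <- fit@params
        out[b, ] <- c(p@Kd, p@h, p@Fu, p@Fb)
      }
    }
    out
  })
  sds <- apply(est, 2, stats::sd, na.rm = TRUE)
  structure(sds, nBoot = nBoot, seed = seed, warnings = warn,
            nFailed = sum(is.na(est[, 1])))
}
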