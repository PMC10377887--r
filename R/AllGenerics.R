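#' @import methods
NULL

#' Extract the dissociation constant
#' @param object a [HillParams-class], [BindingFit-class] or
#'   [AssayConditions-class]
#' @return Kd in uM
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))

#' @rdname kd
#' @export
setMethod("kd", "HillParams", function(object) object@Kd)
#' @rdname kd
#' @export
setMethod("kd", "BindingFit", function(object) object@params@Kd)
#' @rdname kd
#' @export
setMethod("kd", "AssayConditions", function(object) object@Kd)

#' Extract the Hill coefficient
#' @param object a [HillParams-class] or [BindingFit-class]
#' @export
setGeneric("hillCoef", function(object) standardGeneric("hillCoef"))

#' @rdname hillCoef
#' @export
setMethod("hillCoef", "HillParams", function(object) object@h)
#' @rdname hillCoef
#' @export
setMethod("hillCoef", "BindingFit", function(object) object@params@h)

#' Fitted parameter set of a binding fit
#' @param object a [BindingFit-class]
#' @return the [HillParams-class] point estimates
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))

#' @rdname fitParams
#' @export
setMethod("fitParams", "BindingFit", function(object) object@params)

#' Convergence status of a fit
#' @param object a [BindingFit-class]
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname converged
#' @export
setMethod("converged", "BindingFit", function(object) object@converged)

#' Measurement points of a series
#' @param object a [TitrationSeries-class] or [TimeCourse-class]
#' @return the underlying data.frame of measurements
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @rdname measurements
#' @export
setMethod("measurements", "TitrationSeries", function(object) object@points)
#' @rdname measurements
#' @export
setMethod("measurements", "TimeCourse", function(object) object@points)

#' Observed rate constant of a kinetic result
#' @param object a [KineticResult-class]
#' @return kobs in 1/s
#' @export
setGeneric("kobs", function(object) standardGeneric("kobs"))

#' @rdname kobs
#' @export
setMethod("kobs", "KineticResult", function(object) object@kobs)

#' Atom records of a structure model
#' @param object a [StructureModel-class]
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "StructureModel", function(object) object@atoms)

#' Contact records as a data.frame
#' @param object a [ContactTable-class]
#' @export
setGeneric("contactRecords", function(object) standardGeneric("contactRecords"))

#' @rdname contactRecords
#' @export
setMethod("contactRecords", "ContactTable", function(object) object@records)

## ---------------------------------------------------------------------------
## show methods

setMethod("show", "HillParams", function(object) {
  cat(sprintf("HillParams: Kd = %.4g uM, h = %.3g, Fu = %.3g, Fb = %.3g\n",
              object@Kd, object@h, object@Fu, object@Fb))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries %s/%s: %d concentrations x %d replicates (DNA %.3g uM)\n",
              object@variant, object@lesion,
              length(object@design@enzymeConcs), object@design@replicates,
              object@design@dnaConc))
})

setMethod("show", "TimeCourse", function(object) {
  cat(sprintf("TimeCourse %s/%s: %d points, t in [%g, %g] s, E0 = %g, S0 = %g uM\n",
              object@variant, object@lesion, nrow(object@points),
              min(object@points$t), max(object@points$t),
              object@E0, object@S0))
})

setMethod("show", "BindingFit", function(object) {
  p <- object@params
  fmt <- function(v, s) if (is.na(s)) sprintf("%.4g", v) else sprintf("%.4g +/- %.2g", v, s)
  cat("Hill-equation fit (", object@nPoints, " points, ",
      if (object@converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("  Kd =", fmt(p@Kd, object@sd[["Kd"]]), "uM\n")
  cat("  h  =", fmt(p@h, object@sd[["h"]]), "\n")
  cat("  Fu =", fmt(p@Fu, object@sd[["Fu"]]),
      " Fb =", fmt(p@Fb, object@sd[["Fb"]]), "\n")
  cat(sprintf("  RSS = %.3g\n", object@rss))
})

setMethod("show", "KineticResult", function(object) {
  cat(sprintf("KineticResult (%s): V0 = %.4g +/- %.2g uM/s; [E.S] = %.4g uM\n",
              object@method, object@V0, object@V0Sd, object@ESeq))
  cat(sprintf("  kobs = %.4g +/- %.2g 1/s; 30-min endpoint = %.1f%%\n",
              object@kobs, object@kobsSd, object@endpoint30))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel '%s': %d atoms, %d residues, %d chain(s), %d lesion atom(s)\n",
              object@source, nrow(a),
              length(unique(paste(a$chain, a$resno))),
              length(unique(a$chain)), sum(a$isLesion)))
})

setMethod("show", "ContactTable", function(object) {
  cat(sprintf("ContactTable vs %s (%s): %d residues\n",
              object@base, object@source, nrow(object@records)))
  print(object@records[, c("residue", "category", "minDist")], row.names = FALSE)
})

setMethod("show", "RecoveryReport", function(object) {
  cat(sprintf("RecoveryReport: %d conditions, noiseSd = %g, seed = %d — %s\n",
              nrow(object@table), object@noiseSd, object@seed,
              if (object@passed) "PASS" else "FAIL"))
  print(object@table, row.names = FALSE, digits = 4)
  cat("Fold changes:\n")
  print(object@folds, row.names = FALSE)
})
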