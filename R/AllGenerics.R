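#' @rdname Tumor-class
#' @param object,x a `Tumor`
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @rdname Tumor-class
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname Tumor-class
#' @export
setGeneric("seedingEvents", function(x) standardGeneric("seedingEvents"))
#' @rdname Tumor-class
#' @export
setGeneric("simParamsOf", function(x) standardGeneric("simParamsOf"))
#' @rdname Tumor-class
#' @export
setGeneric("aliveIds", function(x) standardGeneric("aliveIds"))
#' @rdname Tumor-class
#' @export
setGeneric("isExtinct", function(x) standardGeneric("isExtinct"))

#' @rdname Tumor-class
#' @export
setMethod("cells", "Tumor", function(x) x@cells)
#' @rdname Tumor-class
#' @export
setMethod("variants", "Tumor", function(x) x@variants)
#' @rdname Tumor-class
#' @export
setMethod("seedingEvents", "Tumor", function(x) x@seeding)
#' @rdname Tumor-class
#' @export
setMethod("simParamsOf", "Tumor", function(x) x@params)
#' @rdname Tumor-class
#' @export
setMethod("aliveIds", "Tumor", function(x) x@aliveIds)
#' @rdname Tumor-class
#' @export
setMethod("isExtinct", "Tumor", function(x) x@extinct)

#' @describeIn Tumor-class number of cells alive at observation
#' @export
setMethod("length", "Tumor", function(x) length(x@aliveIds))

setMethod("show", "SimParams", function(object) {
  cat("SimParams: lambda0 =", object@lambda0,
      " mu =", object@mu,
      sprintf(" (rho = %.4g)", object@mu / object@lambda0), "\n")
  cat("  u =", object@u, " ub =", object@ub,
      " s ~ truncN(", object@sMean, ",", object@sSd, ")\n")
  cat("  Ns =", object@Ns, " Nfinal =", object@Nfinal,
      " rhoMet =", object@rhoMet, "\n")
})

setMethod("show", "Tumor", function(object) {
  cat(sprintf("Tumor (%s): %d cells ever born, %d alive, %d variants\n",
              object@role, nrow(object@cells), length(object@aliveIds),
              nrow(object@variants)))
  if (nrow(object@seeding))
    cat(sprintf("  %d seeding events\n", nrow(object@seeding)))
  if (object@extinct) cat("  [extinct before reaching target size]\n")
})

setMethod("show", "Genealogy", function(object) {
  cat(sprintf("Genealogy over %d cells, observation set of %d\n",
              length(object@parent), object@nObserved))
})

setMethod("show", "RegionSample", function(object) {
  cat(sprintf("RegionSample: %d spherical regions (radius %.2f), %s cells each\n",
              nrow(object@regions), object@regions$radius[1],
              paste(range(object@regions$n_cells), collapse = "-")))
})

setMethod("show", "TypeStructure", function(object) {
  cat(sprintf("TypeStructure: %d types, scenario '%s'\n",
              length(object@rho), object@scenario))
  print(data.frame(type = seq_along(object@rho) - 1L, rho = object@rho,
                   T = object@Tk, f = object@f, lambda = object@lambda))
})
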