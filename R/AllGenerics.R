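#' Number of twin pairs
#' @param x a \linkS4class{TwinDataset} or \linkS4class{GeneratingTruth}.
#' @return integer count of pairs.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' Variable labels, in model/data order
#' @param x a TwinDataset or TwinModelSpec.
#' @return character vector of variable names.
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' Zygosity of each pair
#' @param x a TwinDataset.
#' @return character vector of \code{"MZ"}/\code{"DZ"}.
#' @export
setGeneric("zygosity", function(x) standardGeneric("zygosity"))

#' Pair sex
#' @param x a TwinDataset.
#' @return character vector of \code{"M"}/\code{"F"}.
#' @export
setGeneric("pairSex", function(x) standardGeneric("pairSex"))

#' Preprocessing states applied so far
#' @param x a TwinDataset.
#' @return character subset of raw / sex_residualised / normalised.
#' @export
setGeneric("preprocessing", function(x) standardGeneric("preprocessing"))

#' Phenotype array
#' @param x a TwinDataset.
#' @return numeric array, pairs x twins x variables.
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname nPairs
#' @export
setMethod("nPairs", "TwinDataset", function(x) length(x@familyId))
#' @rdname nPairs
#' @export
setMethod("nPairs", "GeneratingTruth", function(x) x@nMZ + x@nDZ)

#' @rdname variableNames
#' @export
setMethod("variableNames", "TwinDataset", function(x) x@variableNames)
#' @rdname variableNames
#' @export
setMethod("variableNames", "TwinModelSpec", function(x) x@variableNames)

#' @rdname zygosity
#' @export
setMethod("zygosity", "TwinDataset", function(x) x@zygosity)

#' @rdname pairSex
#' @export
setMethod("pairSex", "TwinDataset", function(x) x@pairSex)

#' @rdname preprocessing
#' @export
setMethod("preprocessing", "TwinDataset", function(x) x@preprocessing)

#' @rdname phenotypes
#' @export
setMethod("phenotypes", "TwinDataset", function(x) x@phenotypes)

#' Free-parameter estimates of a fit
#' @param object a \linkS4class{TwinFit}.
#' @param ... unused.
#' @return named numeric vector of path coefficients.
#' @export
setMethod("coef", "TwinFit", function(object, ...) object@estimates)

#' Parameter covariance of a fit
#' @param object a TwinFit.
#' @param ... unused.
#' @export
setMethod("vcov", "TwinFit", function(object, ...) object@vcov)

#' Model specification of a fit
#' @param x a TwinFit or GeneratingTruth.
#' @return the \linkS4class{TwinModelSpec}.
#' @export
setGeneric("modelSpec", function(x) standardGeneric("modelSpec"))
#' @rdname modelSpec
#' @export
setMethod("modelSpec", "TwinFit", function(x) x@spec)
#' @rdname modelSpec
#' @export
setMethod("modelSpec", "GeneratingTruth", function(x) x@spec)

#' True parameters of a generating model
#' @param x a GeneratingTruth.
#' @return named numeric vector.
#' @export
setGeneric("trueParams", function(x) standardGeneric("trueParams"))
#' @rdname trueParams
#' @export
setMethod("trueParams", "GeneratingTruth", function(x) x@params)

setMethod("show", "TwinDataset", function(object) {
  cat(sprintf("TwinDataset: %d pairs, %d variables\n",
              nPairs(object), length(object@variableNames)))
  cat(sprintf("  zygosity: %d MZ / %d DZ; sex: %d M / %d F pairs\n",
              sum(object@zygosity == "MZ"), sum(object@zygosity == "DZ"),
              sum(object@pairSex == "M"), sum(object@pairSex == "F")))
  cat("  variables:", paste(object@variableNames, collapse = ", "), "\n")
  cat("  preprocessing:", paste(object@preprocessing, collapse = " -> "), "\n")
  nmiss <- sum(is.na(object@phenotypes))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
              100 * nmiss / length(object@phenotypes)))
})

setMethod("show", "TwinModelSpec", function(object) {
  cat(sprintf("TwinModelSpec: %s, %d variable(s), components {%s}\n",
              object@family, length(object@variableNames),
              paste(object@components, collapse = ",")))
  cat(sprintf("  sex limitation: %s", object@sexLimitation))
  if (length(object@scalarVariables))
    cat(sprintf(" (scalars: %s)", paste(object@scalarVariables, collapse = ",")))
  if (length(object@quantVariables))
    cat(sprintf(" (sex-specific paths: %s)",
                paste(object@quantVariables, collapse = ",")))
  cat("\n")
  cat(sprintf("  free parameters: %d", nFreeParams(object)))
  if (nrow(object@zeroConstraints))
    cat(sprintf("; %d path(s) constrained to zero", nrow(object@zeroConstraints)))
  cat("\n")
})

setMethod("show", "TwinFit", function(object) {
  cat(sprintf("TwinFit (%s): -2LL = %.4f, df = %d, AIC = %.4f\n",
              object@spec@family, object@neg2ll, object@nFree, object@aic))
  cat(sprintf("  converged: %s (%d start(s))\n",
              object@converged, object@nRestartsUsed))
  cat("  groups:", paste(sprintf("%s=%d", names(object@groups), object@groups),
                         collapse = ", "), "\n")
})

setMethod("show", "GeneratingTruth", function(object) {
  cat(sprintf("GeneratingTruth: %s model, %d MZ + %d DZ pairs, seed %d\n",
              object@spec@family, object@nMZ, object@nDZ, object@seed))
  cat(sprintf("  sex fraction (male): %.2f, missing rate: %.2f\n",
              object@sexFraction, object@missingRate))
})
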