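#' @include AllClasses.R
NULL

#' Accessors for promi classes
#'
#' Small accessor generics: \code{sampleConditions} returns the per-sample
#' condition factor of a \linkS4class{PeptideFeatureSet} or
#' \linkS4class{ImputedSet}; \code{featureMode} and \code{isLogScale} return
#' the table's analysis mode and scale flag; \code{muHat}, \code{sigmaHat}
#' and \code{muMNAR} extract imputation parameters; \code{imputations},
#' \code{imputationSeeds} and \code{imputationParams} unpack an
#' \linkS4class{ImputedSet}; \code{truthLabels} and \code{mechanismMap}
#' unpack a \linkS4class{SynthDataset}.
#'
#' @param x the object.
#' @name promi-accessors
#' @rdname promi-accessors
NULL

#' @rdname promi-accessors
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))
#' @rdname promi-accessors
#' @export
setGeneric("featureMode", function(x) standardGeneric("featureMode"))
#' @rdname promi-accessors
#' @export
setGeneric("isLogScale", function(x) standardGeneric("isLogScale"))
#' @rdname promi-accessors
#' @export
setGeneric("muHat", function(x) standardGeneric("muHat"))
#' @rdname promi-accessors
#' @export
setGeneric("sigmaHat", function(x) standardGeneric("sigmaHat"))
#' @rdname promi-accessors
#' @export
setGeneric("muMNAR", function(x) standardGeneric("muMNAR"))
#' @rdname promi-accessors
#' @export
setGeneric("imputations", function(x) standardGeneric("imputations"))
#' @rdname promi-accessors
#' @export
setGeneric("imputationSeeds", function(x) standardGeneric("imputationSeeds"))
#' @rdname promi-accessors
#' @export
setGeneric("imputationParams", function(x) standardGeneric("imputationParams"))
#' @rdname promi-accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname promi-accessors
#' @export
setGeneric("mechanismMap", function(x) standardGeneric("mechanismMap"))

#' @rdname promi-accessors
setMethod("sampleConditions", "PeptideFeatureSet",
          function(x) colData(x)$condition)
#' @rdname promi-accessors
setMethod("sampleConditions", "ImputedSet", function(x) x@condition)
#' @rdname promi-accessors
setMethod("featureMode", "PeptideFeatureSet",
          function(x) metadata(x)$mode)
#' @rdname promi-accessors
setMethod("isLogScale", "PeptideFeatureSet",
          function(x) metadata(x)$logScale)
#' @rdname promi-accessors
setMethod("muHat", "ImputationParams", function(x) x@mu)
#' @rdname promi-accessors
setMethod("sigmaHat", "ImputationParams", function(x) x@sigma)
#' @rdname promi-accessors
setMethod("muMNAR", "ImputationParams", function(x) x@muMNAR)
#' @rdname promi-accessors
setMethod("imputations", "ImputedSet", function(x) x@matrices)
#' @rdname promi-accessors
setMethod("imputationSeeds", "ImputedSet", function(x) x@seeds)
#' @rdname promi-accessors
setMethod("imputationParams", "ImputedSet", function(x) x@params)
#' @rdname promi-accessors
setMethod("truthLabels", "SynthDataset", function(x) {
    stats::setNames(x@truth, rownames(x@features))
})
#' @rdname promi-accessors
setMethod("mechanismMap", "SynthDataset", function(x) x@mechanism)
#' @rdname promi-accessors
#' @export
setGeneric("spikeFeatures", function(x) standardGeneric("spikeFeatures"))
#' @rdname promi-accessors
setMethod("spikeFeatures", "SynthDataset", function(x) x@features)

setMethod("show", "ImputationParams", function(object) {
    cat("ImputationParams\n")
    cat(sprintf("  %d features x %d conditions\n",
                nrow(object@mu), ncol(object@mu)))
    cat("  sigma (per condition):",
        paste(sprintf("%s=%.4g", names(object@sigma), object@sigma),
              collapse = ", "), "\n")
    cat(sprintf("  muMNAR (lower Tukey fence, k=%.3g): %.4g\n",
                object@k, object@muMNAR))
})

setMethod("show", "ImputedSet", function(object) {
    cat(sprintf("ImputedSet: %d imputations of a %d x %d log2 matrix (%d missing cells)\n",
                length(object@matrices), nrow(object@observed),
                ncol(object@observed), sum(is.na(object@observed))))
})

setMethod("show", "ModelFit", function(object) {
    cat(sprintf("ModelFit (%s): %d features, contrasts: %s\n",
                object@method, nrow(object@coefficients),
                paste(object@contrastNames, collapse = ", ")))
})

setMethod("show", "ModeratedResult", function(object) {
    cat(sprintf("ModeratedResult: %d features x %d contrasts (d0 = %.4g, s0^2 = %.4g)\n",
                nrow(object@lfc), ncol(object@lfc), object@d0, object@s02))
})

setMethod("show", "SynthDataset", function(object) {
    cat(sprintf("SynthDataset: %d features (%d TP, %d TN), %d samples, %d missing cells\n",
                nrow(object@features), sum(object@truth == "TP"),
                sum(object@truth == "TN"), ncol(object@features),
                sum(object@mechanism != "observed")))
})

#' Prior degrees of freedom and prior variance of a moderated fit
#' @param x a \linkS4class{ModeratedResult}.
#' @return \code{priorDf}: numeric(1), possibly \code{Inf}; \code{priorVar}:
#'   numeric(1).
#' @export
priorDf <- function(x) x@d0

#' @rdname priorDf
#' @export
priorVar <- function(x) x@s02

#' Posterior (shrunken) residual variances of a moderated fit
#' @param x a \linkS4class{ModeratedResult}.
#' @export
posteriorVar <- function(x) x@s2post
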