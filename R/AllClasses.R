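#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays rowData colData
NULL

#' PeptideFeatureSet: identifiers-by-samples abundance container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' peptide-centric feature table: one row per unique identifier (protein
#' accession + peptide sequence in global mode, accession + Cys-oxidation
#' site in PTM mode), one column per MS run. The single assay
#' \code{"abundance"} contains area-under-curve abundances (raw scale) or
#' log2 intensities; which one is recorded in \code{metadata(x)$logScale}.
#' \code{colData(x)$condition} maps every sample to its experimental
#' condition and \code{metadata(x)$mode} is \code{"global"} or \code{"ptm"}.
#' Missing measurements are \code{NA}.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; no new slots.
#' @aliases PeptideFeatureSet-class
#' @exportClass PeptideFeatureSet
setClass("PeptideFeatureSet", contains = "SummarizedExperiment")

setValidity("PeptideFeatureSet", function(object) {
    msg <- NULL
    if (is.null(rownames(object)))
        msg <- c(msg, "rownames (identifiers) must be set")
    else if (anyDuplicated(rownames(object)))
        msg <- c(msg, "identifiers (rownames) must be unique")
    if (!"condition" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'condition' column")
    else {
        cond <- colData(object)$condition
        if (anyNA(cond))
            msg <- c(msg, "every sample must map to a condition")
    }
    if (!"abundance" %in% names(assays(object)))
        msg <- c(msg, "assay 'abundance' is required")
    mode <- metadata(object)$mode
    if (is.null(mode) || !mode %in% c("global", "ptm"))
        msg <- c(msg, "metadata()$mode must be 'global' or 'ptm'")
    if (!is.logical(metadata(object)$logScale))
        msg <- c(msg, "metadata()$logScale must be TRUE or FALSE")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PeptideFeatureSet
#'
#' @param abundance numeric matrix, identifiers x samples; \code{NA} encodes a
#'   missing measurement. Must have unique rownames and colnames.
#' @param condition per-sample condition labels (coerced to factor), one per
#'   column of \code{abundance}.
#' @param rowData optional per-identifier metadata (\code{DataFrame} or
#'   data.frame): typically accession, sequence, score of the representative
#'   peptide.
#' @param mode \code{"global"} (accession + sequence identifiers) or
#'   \code{"ptm"} (accession + Cys-site identifiers).
#' @param logScale \code{TRUE} if \code{abundance} is already log2.
#' @return A \linkS4class{PeptideFeatureSet}.
#' @examples
#' m <- matrix(2^rnorm(12, 18), 3, 4,
#'             dimnames = list(paste0("P", 1:3, "_PEPTIDE"), paste0("s", 1:4)))
#' pfs <- PeptideFeatureSet(m, condition = c("A", "A", "B", "B"))
#' sampleConditions(pfs)
#' @export
PeptideFeatureSet <- function(abundance, condition, rowData = NULL,
                              mode = "global", logScale = FALSE) {
    abundance <- as.matrix(abundance)
    if (is.null(rownames(abundance)))
        stop("abundance matrix must have rownames (identifiers)")
    if (is.null(colnames(abundance)))
        colnames(abundance) <- paste0("sample", seq_len(ncol(abundance)))
    if (length(condition) != ncol(abundance))
        stop("length(condition) must equal ncol(abundance)")
    cd <- DataFrame(condition = factor(condition),
                    row.names = colnames(abundance))
    se <- SummarizedExperiment(
        assays = list(abundance = abundance),
        colData = cd,
        rowData = if (is.null(rowData)) DataFrame(row.names = rownames(abundance))
                  else DataFrame(rowData, row.names = rownames(abundance)),
        metadata = list(mode = mode, logScale = logScale))
    new("PeptideFeatureSet", se)
}

#' ImputationParams: robust parameters of the imputation model
#'
#' Parameters estimated from a log2 feature table for normal-distribution
#' imputation: per-(feature, condition) means of the observed values
#' (\code{mu}), one robust per-condition standard deviation (\code{sigma},
#' the median of sample SDs over features fully observed in that condition),
#' and the global left-censoring mean \code{muMNAR}, the lower Tukey fence
#' Q1 - k * IQR of all pooled observed log2 values.
#'
#' @slot mu numeric matrix, features x conditions; \code{NA} where a
#'   feature has no observation in a condition (the MNAR case).
#' @slot sigma named numeric, one SD per condition, all >= 0.
#' @slot muMNAR numeric(1), mean of the left-censored imputation normal.
#' @slot k numeric(1), Tukey fence multiplier used for \code{muMNAR}.
#' @slot poolQuartiles numeric(2), Q1 and Q3 of the pooled observed values
#'   (linear-interpolation quantiles), kept for provenance.
#' @aliases ImputationParams-class
#' @exportClass ImputationParams
setClass("ImputationParams",
    representation(mu = "matrix", sigma = "numeric", muMNAR = "numeric",
                   k = "numeric", poolQuartiles = "numeric"))

setValidity("ImputationParams", function(object) {
    msg <- NULL
    if (any(object@sigma < 0, na.rm = TRUE))
        msg <- c(msg, "sigma must be >= 0")
    if (length(object@muMNAR) != 1L || !is.finite(object@muMNAR))
        msg <- c(msg, "muMNAR must be a single finite number")
    if (ncol(object@mu) != length(object@sigma))
        msg <- c(msg, "ncol(mu) must equal length(sigma)")
    if (length(object@poolQuartiles) == 2L &&
        object@muMNAR > object@poolQuartiles[1] + 1e-12)
        msg <- c(msg, "muMNAR must not exceed Q1 of the pooled values")
    if (is.null(msg)) TRUE else msg
})

#' ImputedSet: an ordered collection of completed data matrices
#'
#' The result of multiple imputation: \code{n} complete log2 matrices that
#' agree exactly on all originally observed cells and differ only in the
#' cells drawn from the imputation model, together with the per-draw RNG
#' seeds and the \linkS4class{ImputationParams} used.
#'
#' @slot matrices list of complete numeric matrices (same dim as observed).
#' @slot seeds integer vector of per-imputation seeds.
#' @slot params the \linkS4class{ImputationParams} used for every draw.
#' @slot observed the input log2 matrix with \code{NA} at missing cells.
#' @slot condition per-sample condition factor.
#' @aliases ImputedSet-class
#' @exportClass ImputedSet
setClass("ImputedSet",
    representation(matrices = "list", seeds = "integer",
                   params = "ImputationParams", observed = "matrix",
                   condition = "factor"))

setValidity("ImputedSet", function(object) {
    msg <- NULL
    if (length(object@matrices) != length(object@seeds))
        msg <- c(msg, "one seed per imputed matrix required")
    obs <- object@observed
    seen <- !is.na(obs)
    for (i in seq_along(object@matrices)) {
        m <- object@matrices[[i]]
        if (!identical(dim(m), dim(obs))) {
            msg <- c(msg, sprintf("matrix %d has wrong dimensions", i))
            break
        }
        if (anyNA(m)) {
            msg <- c(msg, sprintf("matrix %d is not complete", i))
            break
        }
        if (!isTRUE(all.equal(m[seen], obs[seen], tolerance = 0))) {
            msg <- c(msg, sprintf("matrix %d alters observed cells", i))
            break
        }
    }
    if (length(object@condition) != ncol(obs))
        msg <- c(msg, "condition must have one entry per sample")
    if (is.null(msg)) TRUE else msg
})

#' ModelFit: per-feature linear model fits
#'
#' One ordinary or Huber-robust least-squares fit per feature under
#' cell-means coding (one coefficient per condition), reduced to the
#' requested condition contrasts.
#'
#' @slot coefficients numeric matrix, features x contrasts: log2 fold
#'   changes.
#' @slot s2 per-feature residual variance.
#' @slot df per-feature residual degrees of freedom.
#' @slot unscaledVar per-contrast unscaled coefficient variance
#'   (sum over conditions of c_j^2 / n_j for contrast weights c).
#' @slot method \code{"normal"} or \code{"robust"}.
#' @slot weights robust IRLS weights (samples as columns) or an empty
#'   matrix for normal fits.
#' @slot contrastNames names of the fitted contrasts.
#' @aliases ModelFit-class
#' @exportClass ModelFit
setClass("ModelFit",
    representation(coefficients = "matrix", s2 = "numeric", df = "numeric",
                   unscaledVar = "numeric", method = "character",
                   weights = "matrix", contrastNames = "character"))

#' ModeratedResult: empirical-Bayes moderated test results
#'
#' Moderated t-statistics after shrinking per-feature residual variances
#' toward an ensemble prior: the posterior variance is
#' (d0 * s0^2 + d * s^2) / (d0 + d) and the moderated t is referred to a t
#' distribution on d0 + d degrees of freedom (normal when d0 is infinite).
#'
#' @slot lfc,t,p,adjP numeric matrices, features x contrasts.
#' @slot d0 prior degrees of freedom (may be \code{Inf}).
#' @slot s02 prior variance.
#' @slot df per-feature residual degrees of freedom of the underlying fits.
#' @slot s2post per-feature posterior (shrunken) variance.
#' @aliases ModeratedResult-class
#' @exportClass ModeratedResult
setClass("ModeratedResult",
    representation(lfc = "matrix", t = "matrix", p = "matrix",
                   adjP = "matrix", d0 = "numeric", s02 = "numeric",
                   df = "numeric", s2post = "numeric"))

setValidity("ModeratedResult", function(object) {
    msg <- NULL
    if (any(object@p < 0 | object@p > 1, na.rm = TRUE))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (any(object@adjP + 1e-12 < object@p, na.rm = TRUE))
        msg <- c(msg, "adjusted p-values cannot be smaller than raw p-values")
    if (is.null(msg)) TRUE else msg
})

#' SynthDataset: synthetic spike-in benchmark with known truth
#'
#' @slot features a raw-scale \linkS4class{PeptideFeatureSet}.
#' @slot truth per-feature label, \code{"TP"} (spiked) or \code{"TN"}
#'   (background).
#' @slot trueLFC numeric matrix, features x condition pairs, expected log2
#'   fold change of each feature for every pairwise condition contrast.
#' @slot mechanism character matrix, same shape as the abundance assay:
#'   \code{"observed"}, \code{"mcar"} or \code{"mnar"} per cell.
#' @aliases SynthDataset-class
#' @exportClass SynthDataset
setClass("SynthDataset",
    representation(features = "PeptideFeatureSet", truth = "character",
                   trueLFC = "matrix", mechanism = "matrix"))

setValidity("SynthDataset", function(object) {
    msg <- NULL
    if (length(object@truth) != nrow(object@features))
        msg <- c(msg, "one truth label per feature required")
    if (!all(object@truth %in% c("TP", "TN")))
        msg <- c(msg, "truth labels must be 'TP' or 'TN'")
    miss <- is.na(assay(object@features, "abundance"))
    mech <- object@mechanism
    if (!identical(dim(mech), dim(miss)))
        msg <- c(msg, "mechanism map must match the abundance matrix")
    else if (!all((mech != "observed") == miss))
        msg <- c(msg, "mechanism map inconsistent with the missing mask")
    if (is.null(msg)) TRUE else msg
})
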