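#' @include AllClasses.R impute.R diffexpr.R decide.R evaluate.R
NULL

#' Run the multiple-imputation differential-abundance pipeline
#'
#' The full analysis chain on a raw-scale feature table: log2 transform,
#' removal of all-outlier features (pooled Tukey fences), robust parameter
#' estimation, \code{n} imputations, a moderated linear-model fit per
#' imputation, and per-imputation contrast results ready for the binomial
#' aggregation ([decideFeatures()]) or ROC evaluation ([rocGrid()]).
#' With \code{dropMissing = TRUE} the imputation step is replaced by the
#' filtering baseline: features with any missing value are removed and the
#' single complete dataset is analysed (n is forced to 1).
#'
#' @param x a raw-scale \linkS4class{PeptideFeatureSet} (use
#'   \code{logScale = TRUE} tables as-is).
#' @param contrast contrast string \code{"A-B"}; default: last condition
#'   level minus first.
#' @param n number of imputations (default 100).
#' @param seed master seed for the imputation draws.
#' @param method \code{"normal"} or \code{"robust"} regression.
#' @param k Tukey fence multiplier.
#' @param dropMissing analyse only complete features instead of imputing.
#' @param zeroAsMissing passed to [log2Transform()].
#' @return list with elements \code{results} (list of per-imputation
#'   result data.frames), \code{table} (the filtered log2
#'   \linkS4class{PeptideFeatureSet} actually analysed), \code{params}
#'   (\linkS4class{ImputationParams} or \code{NULL}), \code{contrast},
#'   \code{method}.
#' @examples
#' ds <- synthSpikeIn(synthConfig("ups1-like", nBackground = 300,
#'                                nSpike = 15), seed = 3)
#' fit <- runPipeline(spikeFeatures(ds), n = 5, seed = 11)
#' head(decideFeatures(fit$results, lfcUp = 1))
#' @export
runPipeline <- function(x, contrast = NULL, n = 100, seed = 1,
                        method = c("normal", "robust"), k = 1.5,
                        dropMissing = FALSE, zeroAsMissing = FALSE) {
    method <- match.arg(method)
    stopifnot(is(x, "PeptideFeatureSet"))
    lg <- if (isLogScale(x)) x else log2Transform(x, zeroAsMissing)
    lg <- removeAllOutlierFeatures(lg, k = k)
    cond <- sampleConditions(lg)
    lev <- levels(cond)
    if (is.null(contrast))
        contrast <- paste(lev[length(lev)], lev[1], sep = "-")
    if (dropMissing) {
        lg <- dropIncompleteFeatures(lg)
        fit <- fitLinear(assay(lg, "abundance"), cond,
                         contrasts = contrast, method = method)
        results <- list(contrastResults(ebayesModerate(fit), contrast))
        params <- NULL
    } else {
        params <- estimateImputationParams(lg, k = k)
        imp <- imputeMultiple(lg, params = params, n = n,
                              masterSeed = seed)
        results <- lapply(imputations(imp), function(m) {
            fit <- fitLinear(m, cond, contrasts = contrast,
                             method = method)
            contrastResults(ebayesModerate(fit), contrast)
        })
    }
    list(results = results, table = lg, params = params,
         contrast = contrast, method = method)
}
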