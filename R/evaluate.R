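#' @include AllClasses.R
NULL

#' Label spike-in ground truth
#'
#' Assigns \code{"TP"} to features whose accession originates from the
#' spiked proteome and \code{"TN"} to background features. Labels are a
#' function of the identifiers only, never of any decision output.
#'
#' @param x a \linkS4class{PeptideFeatureSet}, or a character vector of
#'   accessions/identifiers.
#' @param spike a predicate: either a prefix string matched against the
#'   accession (rowData column \code{accession} when present, else the
#'   identifier), or a function returning \code{TRUE} for spiked
#'   accessions.
#' @return named character vector of \code{"TP"} / \code{"TN"} labels.
#' @export
labelTruth <- function(x, spike) {
    if (is(x, "PeptideFeatureSet")) {
        acc <- if ("accession" %in% colnames(rowData(x)))
            rowData(x)$accession else rownames(x)
        ids <- rownames(x)
    } else {
        acc <- ids <- as.character(x)
    }
    hit <- if (is.function(spike)) vapply(acc, spike, NA, USE.NAMES = FALSE)
           else startsWith(acc, spike)
    stats::setNames(ifelse(hit, "TP", "TN"), ids)
}

#' Confusion counts and rates
#'
#' Cross-tabulates calls against truth labels and reports
#' \code{FPR = FP / (FP + TN)} and \code{TPR = TP / (TP + FN)}, both as
#' percentages (x100, the scale of the benchmark figures).
#'
#' @param calls named logical vector: feature -> significant.
#' @param labels named \code{"TP"}/\code{"TN"} vector over the same
#'   features (see [labelTruth()]).
#' @return one-row data.frame: \code{TP}, \code{FP}, \code{TN}, \code{FN},
#'   \code{FPR_pct}, \code{TPR_pct}.
#' @export
confusionCounts <- function(calls, labels) {
    if (!setequal(names(calls), names(labels)))
        stop("evaluation error: calls and labels cover different features")
    labels <- labels[names(calls)]
    tp <- sum(calls & labels == "TP")
    fn <- sum(!calls & labels == "TP")
    fp <- sum(calls & labels == "TN")
    tn <- sum(!calls & labels == "TN")
    data.frame(TP = tp, FP = fp, TN = tn, FN = fn,
               FPR_pct = 100 * fp / (fp + tn),
               TPR_pct = 100 * tp / (tp + fn))
}

#' Threshold grids for ROC operating points
#'
#' The benchmark protocol varies the per-imputation significance level
#' alpha from 0.05 down to 0.001 and the LFC cut-off from 0 up to 2, each
#' over ten linearly spaced values, separately or in lockstep. When only
#' LFC varies, alpha is fixed at 0.05; when only alpha varies, LFC is
#' fixed at 0.
#'
#' @param vary \code{"lfc"}, \code{"pval"} or \code{"both"}.
#' @param nPoints grid size (default 10).
#' @param alphaRange,lfcRange grid endpoints.
#' @return data.frame with columns \code{alpha}, \code{lfc_up}.
#' @export
thresholdGrid <- function(vary = c("both", "lfc", "pval"), nPoints = 10,
                          alphaRange = c(0.05, 0.001), lfcRange = c(0, 2)) {
    vary <- match.arg(vary)
    alphas <- seq(alphaRange[1], alphaRange[2], length.out = nPoints)
    lfcs <- seq(lfcRange[1], lfcRange[2], length.out = nPoints)
    switch(vary,
           both = data.frame(alpha = alphas, lfc_up = lfcs),
           lfc = data.frame(alpha = rep(alphaRange[1], nPoints),
                            lfc_up = lfcs),
           pval = data.frame(alpha = alphas,
                             lfc_up = rep(lfcRange[1], nPoints)))
}

#' ROC operating points over a threshold grid
#'
#' Evaluates a decision method at every grid cell and emits one operating
#' point per cell, in grid order. For a list of multiple-imputation
#' results the call at each cell is the right-tailed binomial vote
#' ([decideFeatures()]); for a single result table it is the direct hybrid
#' threshold ([singleDecision()]), the paper-style t-test protocol.
#' Operating points are discrete; no curve interpolation or area is
#' computed.
#'
#' @param results per-imputation result data.frames (list) or a single
#'   result data.frame.
#' @param labels named truth labels from [labelTruth()].
#' @inheritParams thresholdGrid
#' @param lfcLow lower LFC cut-off, default \code{-Inf} (spikes only
#'   increase).
#' @param decisionAlpha level of the binomial aggregation.
#' @param useAdjusted use FDR-adjusted p-values in the per-imputation
#'   conjunction.
#' @param method label copied into the output.
#' @return data.frame of ROC points: \code{alpha}, \code{lfc_up},
#'   \code{lfc_low}, \code{TP}, \code{FP}, \code{TN}, \code{FN},
#'   \code{FPR_pct}, \code{TPR_pct}, \code{method}.
#' @export
rocGrid <- function(results, labels, vary = c("both", "lfc", "pval"),
                    nPoints = 10, alphaRange = c(0.05, 0.001),
                    lfcRange = c(0, 2), lfcLow = -Inf,
                    decisionAlpha = 0.05, useAdjusted = TRUE,
                    method = "limma-normal") {
    vary <- match.arg(vary)
    grid <- thresholdGrid(vary, nPoints, alphaRange, lfcRange)
    single <- is.data.frame(results)
    rows <- lapply(seq_len(nrow(grid)), function(g) {
        a <- grid$alpha[g]; l <- grid$lfc_up[g]
        calls <- if (single) {
            singleDecision(results, alpha = a, lfcUp = l, lfcLow = lfcLow,
                           useAdjusted = useAdjusted)
        } else {
            d <- decideFeatures(results, alpha = a, lfcUp = l,
                                lfcLow = lfcLow,
                                decisionAlpha = decisionAlpha,
                                useAdjusted = useAdjusted)
            stats::setNames(d$significant, d$identifier)
        }
        cbind(data.frame(alpha = a, lfc_up = l, lfc_low = lfcLow),
              confusionCounts(calls, labels))
    })
    out <- do.call(rbind, rows)
    out$method <- method
    out
}
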