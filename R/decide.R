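#' @include AllClasses.R
NULL

## Coerce per-imputation results (data.frames from contrastResults() /
## ttestBaseline(), or ModeratedResult objects) to a common feature order,
## erroring on mismatched feature sets.
.resultList <- function(results, contrast = 1L) {
    if (is.data.frame(results)) results <- list(results)
    results <- lapply(results, function(r) {
        if (is(r, "ModeratedResult")) r <- contrastResults(r, contrast)
        r
    })
    ids <- results[[1]]$identifier
    for (i in seq_along(results)) {
        if (!identical(results[[i]]$identifier, ids))
            stop("aggregation error: imputation ", i,
                 " covers a different feature set")
    }
    results
}

#' Count per-feature successes across imputations
#'
#' A feature succeeds in one imputation when its (adjusted) p-value is
#' below \code{alpha} \emph{and} its log2 fold change is beyond a cut-off:
#' above \code{lfcUp} or below \code{lfcLow} (strict inequalities;
#' \code{lfcLow = -Inf} disables the decreasing side, the setting used
#' when all spiked features increase).
#'
#' @param results list of per-imputation result data.frames (columns
#'   \code{identifier}, \code{LFC}, \code{p}, \code{adj_p}), all covering
#'   the same features in the same order, or a list of
#'   \linkS4class{ModeratedResult} objects.
#' @param alpha per-imputation significance level.
#' @param lfcUp upper LFC cut-off (log2 units).
#' @param lfcLow lower LFC cut-off, usually \code{-Inf}.
#' @param useAdjusted test the FDR-adjusted p (default) or the raw p.
#' @param contrast contrast selector passed to [contrastResults()] when
#'   the list holds \linkS4class{ModeratedResult} objects.
#' @return named integer vector: successes k per feature, out of
#'   \code{length(results)} trials.
#' @export
countSuccesses <- function(results, alpha = 0.05, lfcUp = 1,
                           lfcLow = -Inf, useAdjusted = TRUE,
                           contrast = 1L) {
    results <- .resultList(results, contrast)
    ids <- results[[1]]$identifier
    k <- integer(length(ids))
    for (r in results) {
        p <- if (useAdjusted) r$adj_p else r$p
        k <- k + as.integer(p < alpha & (r$LFC > lfcUp | r$LFC < lfcLow))
    }
    stats::setNames(k, ids)
}

#' Right-tailed exact binomial decision
#'
#' Tests whether a feature was called significant in more imputations than
#' a fair coin would produce: exact right-tail probability
#' \code{P(X >= k)} for \code{X ~ Binomial(n, 0.5)} (the tail includes k
#' itself), significant when that probability is below
#' \code{decisionAlpha}. At n = 100 the smallest significant count is
#' k = 59.
#'
#' @param k successes per feature (vector ok), \code{0 <= k <= n}.
#' @param n number of imputations (trials).
#' @param decisionAlpha significance level of the aggregate decision.
#' @return data.frame with columns \code{k}, \code{n}, \code{binom_p},
#'   \code{significant}.
#' @export
binomialDecision <- function(k, n, decisionAlpha = 0.05) {
    if (n < 1) stop("n must be >= 1")
    if (any(k < 0 | k > n)) stop("k must lie in [0, n]")
    p <- stats::pbinom(k - 1, size = n, prob = 0.5, lower.tail = FALSE)
    data.frame(identifier = if (is.null(names(k))) NA_character_
               else names(k),
               k = as.integer(k), n = as.integer(n), binom_p = p,
               significant = p < decisionAlpha, row.names = NULL)
}

#' Aggregate multiple-imputation results into final calls
#'
#' Combines [countSuccesses()] and [binomialDecision()] and attaches the
#' mean LFC across imputations (the standard multiple-imputation pooling
#' of the point estimate). Note that with n = 1 trial the right-tail
#' probability at k = 1 is 0.5, so the binomial vote only reduces to the
#' single-dataset call when \code{decisionAlpha > 0.5}; single-dataset
#' methods such as the t-test baseline should use [singleDecision()]
#' instead.
#'
#' @inheritParams countSuccesses
#' @param decisionAlpha significance level of the binomial aggregation.
#' @return data.frame (one row per feature): \code{identifier}, \code{k},
#'   \code{n}, \code{binom_p}, \code{significant}, \code{mean_LFC},
#'   \code{alpha}, \code{lfc_up}, \code{lfc_low}.
#' @export
decideFeatures <- function(results, alpha = 0.05, lfcUp = 1,
                           lfcLow = -Inf, decisionAlpha = 0.05,
                           useAdjusted = TRUE, contrast = 1L) {
    results <- .resultList(results, contrast)
    n <- length(results)
    k <- countSuccesses(results, alpha, lfcUp, lfcLow, useAdjusted,
                        contrast)
    out <- binomialDecision(k, n, decisionAlpha)
    lfc <- rowMeans(vapply(results, `[[`, numeric(length(k)), "LFC"))
    out$mean_LFC <- lfc
    out$alpha <- alpha
    out$lfc_up <- lfcUp
    out$lfc_low <- lfcLow
    out
}

#' Single-dataset hybrid decision
#'
#' The decision rule applied to one dataset (no multiple-imputation vote):
#' a feature is called significant when its (adjusted) p-value is below
#' \code{alpha} and its LFC is beyond the cut-off — the hybrid
#' threshold used for the t-test baseline.
#'
#' @param result one result data.frame (\code{identifier}, \code{LFC},
#'   \code{p}, \code{adj_p}).
#' @inheritParams countSuccesses
#' @return named logical vector of calls.
#' @export
singleDecision <- function(result, alpha = 0.05, lfcUp = 1,
                           lfcLow = -Inf, useAdjusted = TRUE) {
    p <- if (useAdjusted) result$adj_p else result$p
    stats::setNames(p < alpha & (result$LFC > lfcUp | result$LFC < lfcLow),
                    result$identifier)
}
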