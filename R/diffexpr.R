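#' @include AllClasses.R
NULL

## Parse contrasts like "B-A" against condition levels into a weight matrix
## (levels x contrasts).
.contrastMatrix <- function(contrasts, lev) {
    if (is.matrix(contrasts)) {
        if (nrow(contrasts) != length(lev))
            stop("contrast matrix must have one row per condition")
        if (is.null(colnames(contrasts)))
            colnames(contrasts) <- paste0("contrast", seq_len(ncol(contrasts)))
        return(contrasts)
    }
    cm <- matrix(0, length(lev), length(contrasts),
                 dimnames = list(lev, contrasts))
    for (k in seq_along(contrasts)) {
        parts <- strsplit(contrasts[k], "-", fixed = TRUE)[[1]]
        if (length(parts) != 2L || !all(trimws(parts) %in% lev))
            stop("cannot parse contrast '", contrasts[k],
                 "'; use 'levelA-levelB' with existing condition levels")
        parts <- trimws(parts)
        cm[parts[1], k] <- 1
        cm[parts[2], k] <- -1
    }
    cm
}

## Per-condition (weighted) means for a features x samples matrix.
## W = NULL means ordinary means.
.groupMeans <- function(m, cond, W = NULL) {
    lev <- levels(cond)
    B <- matrix(NA_real_, nrow(m), length(lev),
                dimnames = list(rownames(m), lev))
    for (j in seq_along(lev)) {
        cols <- cond == lev[j]
        if (is.null(W)) {
            B[, j] <- rowMeans(m[, cols, drop = FALSE])
        } else {
            wj <- W[, cols, drop = FALSE]
            B[, j] <- rowSums(wj * m[, cols, drop = FALSE]) / rowSums(wj)
        }
    }
    B
}

#' Per-feature linear models under cell-means coding
#'
#' Fits one linear model per feature with one coefficient per condition.
#' \code{method = "normal"} is ordinary least squares, so each coefficient
#' is the condition mean and a contrast's log2 fold change is a difference
#' of condition means. \code{method = "robust"} is Huber M-estimation by
#' iteratively reweighted least squares: weights
#' \code{min(1, c * s / |r|)} with tuning constant \code{c = 1.345},
#' per-feature residual scale \code{s} re-estimated each iteration as the
#' median absolute deviation of the residuals (about zero, consistency
#' constant 1.4826), at most 20 iterations, converged when no coefficient
#' moves by more than 1e-6. Non-converged features keep their last iterate,
#' with a warning. When every weight is 1 the robust fit coincides exactly
#' with the ordinary fit.
#'
#' Residual variance is \code{sum(w * r^2) / (sum(w) - M)} on
#' \code{n - M} residual degrees of freedom (M conditions, n samples); for
#' the normal fit all weights are 1 and this is the usual OLS variance.
#'
#' @param m complete numeric matrix, features x samples (log2 scale).
#' @param condition per-sample condition labels (>= 2 levels).
#' @param contrasts character vector like \code{c("B-A")}, or a
#'   conditions-x-contrasts weight matrix. Default: all pairwise
#'   differences, later level minus earlier.
#' @param method \code{"normal"} or \code{"robust"}.
#' @param huberC Huber tuning constant.
#' @param maxIter,tol IRLS iteration cap and convergence tolerance.
#' @return A \linkS4class{ModelFit}.
#' @export
fitLinear <- function(m, condition, contrasts = NULL,
                      method = c("normal", "robust"), huberC = 1.345,
                      maxIter = 20L, tol = 1e-6) {
    method <- match.arg(method)
    m <- as.matrix(m)
    if (anyNA(m)) stop("matrix must be complete; impute first")
    cond <- droplevels(factor(condition))
    lev <- levels(cond)
    if (length(lev) < 2L) stop("need at least two conditions")
    nPer <- as.vector(table(cond)[lev])
    if (any(nPer == 0L)) stop("rank-deficient design")
    if (is.null(contrasts)) {
        pairs <- utils::combn(lev, 2)
        contrasts <- apply(pairs, 2, function(p) paste(p[2], p[1], sep = "-"))
    }
    cm <- .contrastMatrix(contrasts, lev)

    condIdx <- as.integer(cond)
    huberWeights <- function(B) {
        R <- m - B[, condIdx, drop = FALSE]
        s <- apply(abs(R), 1L, stats::median) * 1.4826
        s[s < .Machine$double.eps] <- .Machine$double.eps
        W <- huberC * s / abs(R)
        W[!is.finite(W) | W > 1] <- 1  # zero residual -> full weight
        W
    }
    W <- NULL
    B <- .groupMeans(m, cond)
    if (method == "robust") {
        converged <- rep(FALSE, nrow(m))
        for (it in seq_len(maxIter)) {
            Bnew <- .groupMeans(m, cond, huberWeights(B))
            converged <- apply(abs(Bnew - B), 1L, max) < tol
            B <- Bnew
            if (all(converged)) break
        }
        if (!all(converged))
            warning(sum(!converged),
                    " feature(s) did not converge in ", maxIter,
                    " IRLS iterations; using last iterate", call. = FALSE)
        W <- huberWeights(B)
    }
    R <- m - B[, condIdx, drop = FALSE]
    if (is.null(W)) {
        s2 <- rowSums(R^2) / (ncol(m) - length(lev))
    } else {
        s2 <- rowSums(W * R^2) / (rowSums(W) - length(lev))
        s2[s2 < 0] <- 0
    }
    coefs <- B %*% cm
    v <- colSums(cm^2 / nPer)
    new("ModelFit", coefficients = coefs, s2 = s2,
        df = rep(ncol(m) - length(lev), nrow(m)), unscaledVar = v,
        method = method,
        weights = if (is.null(W)) matrix(numeric(), 0, 0) else W,
        contrastNames = colnames(cm))
}

## Invert the trigamma function by Newton iteration (monotone decreasing,
## convex in 1/y, so the update converges from y0 = 0.5 + 1/x).
.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (iter in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
        y <- y + dif
        if (-dif / y < 1e-8) break
    }
    y
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Shrinks each feature's residual variance toward a common prior and
#' forms moderated t-statistics, using the scaled-F / log-variance method
#' of moments: with per-feature sample variances s^2 on d degrees of
#' freedom, set \code{e = log(s^2) - digamma(d/2) + log(d/2)}; then
#' \code{var(e) - trigamma(d/2)} estimates \code{trigamma(d0/2)}, inverted
#' numerically to give the prior degrees of freedom d0, and
#' \code{s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))} the prior
#' variance. The posterior variance is
#' \code{s2post = (d0 * s0^2 + d * s^2) / (d0 + d)} and the moderated t of
#' a contrast with unscaled variance v is \code{LFC / sqrt(s2post * v)},
#' referred to a t distribution on \code{d0 + d} degrees of freedom,
#' capped at the pooled residual df of the whole ensemble (when the moment
#' estimate gives \code{d0 = Inf}, \code{s0^2} is the mean sample
#' variance). Exact-zero sample
#' variances are offset to \code{1e-5} times the median variance before
#' taking logs. Two-sided p-values are Benjamini-Hochberg adjusted per
#' contrast.
#'
#' @param fit a \linkS4class{ModelFit}.
#' @return A \linkS4class{ModeratedResult}.
#' @export
ebayesModerate <- function(fit) {
    stopifnot(is(fit, "ModelFit"))
    s2 <- fit@s2
    d <- fit@df
    if (sum(d > 0) < 2L)
        stop("need at least two features with positive residual df")
    x <- pmax(s2, 0)
    med <- stats::median(x)
    if (med == 0) {
        warning("more than half of the residual variances are zero; ",
                "moderation unreliable", call. = FALSE)
        med <- 1
    }
    x <- pmax(x, 1e-5 * med)
    e <- log(x) - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(d / 2))
    if (evar > 0) {
        d0 <- 2 * .trigammaInverse(evar)
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s02 <- mean(x)
    }
    s2post <- if (is.finite(d0)) (d0 * s02 + d * x) / (d0 + d)
              else rep(s02, length(x))
    lfc <- fit@coefficients
    tt <- lfc / sqrt(outer(s2post, fit@unscaledVar))
    # total df capped at the pooled residual df of the ensemble, as in the
    # reference implementation of the moderated t
    dfTotal <- pmin(d0 + d, sum(d))
    p <- 2 * stats::pt(-abs(tt), df = dfTotal)
    adjP <- apply(p, 2, fdrAdjust)
    dimnames(tt) <- dimnames(p) <- dimnames(adjP) <- dimnames(lfc)
    new("ModeratedResult", lfc = lfc, t = tt, p = p,
        adjP = as.matrix(adjP), d0 = d0, s02 = s02, df = d,
        s2post = s2post)
}

#' Extract one contrast's results as a data frame
#'
#' @param x a \linkS4class{ModeratedResult}.
#' @param contrast contrast name or index (default: first).
#' @return data.frame with columns \code{identifier}, \code{LFC},
#'   \code{t}, \code{p}, \code{adj_p}.
#' @export
contrastResults <- function(x, contrast = 1L) {
    stopifnot(is(x, "ModeratedResult"))
    data.frame(identifier = rownames(x@lfc),
               LFC = x@lfc[, contrast],
               t = x@t[, contrast],
               p = x@p[, contrast],
               adj_p = x@adjP[, contrast],
               row.names = NULL)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1
#' (delegates to [stats::p.adjust()] after validating the input range).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
fdrAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Welch t-test baseline
#'
#' The comparison method: per-feature two-sample unequal-variance t-test
#' on one (imputed or complete) dataset, with BH adjustment; the log2 fold
#' change is the difference of condition means. When both group variances
#' are exactly zero the Welch statistic is undefined; the p-value is set
#' to 0 when the means differ and 1 when they are equal, with a warning
#' (this keeps the ordering of decisions well-defined on degenerate
#' synthetic data).
#'
#' @param m complete numeric matrix, features x samples (log2 scale).
#' @param condition per-sample condition labels.
#' @param contrast single contrast string \code{"A-B"} (LFC = mean(A) -
#'   mean(B)); both conditions need >= 2 replicates.
#' @return data.frame with \code{identifier}, \code{LFC}, \code{t},
#'   \code{p}, \code{adj_p}.
#' @export
ttestBaseline <- function(m, condition, contrast) {
    m <- as.matrix(m)
    if (anyNA(m)) stop("matrix must be complete; impute first")
    cond <- factor(condition)
    parts <- trimws(strsplit(contrast, "-", fixed = TRUE)[[1]])
    if (length(parts) != 2L || !all(parts %in% levels(cond)))
        stop("contrast must be 'A-B' over existing condition levels")
    for (p in parts)
        if (sum(cond == p) < 2L)
            stop("condition '", p, "' has fewer than 2 replicates")
    a <- m[, cond == parts[1], drop = FALSE]
    b <- m[, cond == parts[2], drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- rowSums((a - ma)^2) / (na - 1)
    vb <- rowSums((b - mb)^2) / (nb - 1)
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    dfW <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    pval <- 2 * stats::pt(-abs(tstat), df = dfW)
    degen <- se2 == 0
    if (any(degen)) {
        warning(sum(degen), " feature(s) with zero variance in both ",
                "groups; p set to 0 (means differ) or 1 (means equal)",
                call. = FALSE)
        pval[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
        tstat[degen] <- ifelse(ma[degen] == mb[degen], 0,
                               sign(ma - mb)[degen] * Inf)
    }
    data.frame(identifier = rownames(m), LFC = ma - mb, t = tstat,
               p = pval, adj_p = fdrAdjust(pval), row.names = NULL)
}
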