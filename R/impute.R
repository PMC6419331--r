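#' @include AllClasses.R
NULL

## Run expr with an isolated, seeded RNG stream; the caller's RNG state is
## untouched. Mersenne-Twister / inversion are pinned so that draws are
## reproducible across machines and R sessions.
.withSeed <- function(seed, expr) {
    hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hasSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hasSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    expr
}

#' Variance-stabilising log2 transform
#'
#' Replaces every present abundance by its log2; the missing mask is
#' preserved. Raw abundances must be positive: a zero or negative cell is
#' an error naming the identifier and sample, unless \code{zeroAsMissing}
#' converts exact zeros to missing first (some exports encode missingness
#' as 0).
#'
#' @param x a raw-scale \linkS4class{PeptideFeatureSet}.
#' @param zeroAsMissing convert exact zeros to \code{NA} before
#'   transforming.
#' @return the table on the log2 scale (\code{isLogScale(x)} is
#'   \code{TRUE}).
#' @export
log2Transform <- function(x, zeroAsMissing = FALSE) {
    stopifnot(is(x, "PeptideFeatureSet"))
    if (isLogScale(x)) stop("table is already on the log2 scale")
    m <- assay(x, "abundance")
    if (zeroAsMissing) m[!is.na(m) & m == 0] <- NA_real_
    bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-positive abundance for identifier '%s', sample '%s'",
                     rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    assay(x, "abundance") <- log2(m)
    metadata(x)$logScale <- TRUE
    x
}

.pooledFences <- function(m, k) {
    v <- m[!is.na(m)]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    list(lower = q[1] - k * iqr, upper = q[2] + k * iqr, q = q)
}

#' Drop features whose every observation is an outlier
#'
#' Tukey fences \code{[Q1 - k*IQR, Q3 + k*IQR]} are computed over the
#' pooled vector of all present log2 values (linear-interpolation
#' quantiles). A feature is removed if and only if every one of its present
#' observations lies strictly outside the fences; one in-fence observation
#' saves it. Values exactly on a fence are not outside, so a constant
#' matrix (IQR 0) loses nothing.
#'
#' @param x a log2-scale \linkS4class{PeptideFeatureSet}.
#' @param k Tukey fence multiplier (default 1.5).
#' @return the table without the all-outlier features.
#' @export
removeAllOutlierFeatures <- function(x, k = 1.5) {
    stopifnot(is(x, "PeptideFeatureSet"), isLogScale(x))
    m <- assay(x, "abundance")
    f <- .pooledFences(m, k)
    out <- !is.na(m) & (m < f$lower | m > f$upper)
    nObs <- rowSums(!is.na(m))
    allOut <- nObs > 0L & rowSums(out) == nObs
    x[!allOut, ]
}

#' Estimate the imputation model parameters
#'
#' Three robust estimates from a log2 table with missing values:
#' \itemize{
#'   \item \code{mu[i, j]}: mean of the present values of feature i in
#'     condition j (undefined, \code{NA}, when all replicates are missing);
#'   \item \code{sigma[j]}: median of the per-feature sample standard
#'     deviations (n-1 denominator), taken over features fully observed in
#'     condition j with at least two replicates there;
#'   \item \code{muMNAR}: lower Tukey fence \code{Q1(V) - k * (Q3(V) -
#'     Q1(V))} of the pooled vector V of all present values, the mean of
#'     the left-censored (missing-not-at-random) imputation distribution.
#' }
#' When a condition has no fully observed feature, \code{fallbackPooled}
#' substitutes the median of SDs pooled across all conditions, with a
#' warning; otherwise this is an error.
#'
#' @param x a log2-scale \linkS4class{PeptideFeatureSet}.
#' @param k Tukey fence multiplier for \code{muMNAR} (default 1.5).
#' @param fallbackPooled fall back to the cross-condition SD median for a
#'   condition with no complete feature.
#' @return An \linkS4class{ImputationParams}.
#' @export
estimateImputationParams <- function(x, k = 1.5, fallbackPooled = TRUE) {
    stopifnot(is(x, "PeptideFeatureSet"), isLogScale(x))
    m <- assay(x, "abundance")
    cond <- sampleConditions(x)
    lev <- levels(cond)
    mu <- matrix(NA_real_, nrow(m), length(lev),
                 dimnames = list(rownames(m), lev))
    sdsByCond <- vector("list", length(lev))
    names(sdsByCond) <- lev
    for (j in seq_along(lev)) {
        sub <- m[, cond == lev[j], drop = FALSE]
        r <- rowSums(!is.na(sub))
        mu[, j] <- ifelse(r > 0, rowMeans(sub, na.rm = TRUE), NA_real_)
        complete <- r == ncol(sub) & ncol(sub) >= 2L
        if (any(complete)) {
            cs <- sub[complete, , drop = FALSE]
            n <- ncol(cs)
            sdsByCond[[j]] <-
                sqrt(rowSums((cs - rowMeans(cs))^2) / (n - 1))
        } else {
            sdsByCond[[j]] <- numeric()
        }
    }
    sigma <- vapply(sdsByCond, function(s)
        if (length(s)) stats::median(s) else NA_real_, 0)
    if (anyNA(sigma)) {
        pooled <- unlist(sdsByCond, use.names = FALSE)
        if (!fallbackPooled || length(pooled) == 0L)
            stop("no fully observed feature in condition(s): ",
                 paste(lev[is.na(sigma)], collapse = ", "))
        warning("condition(s) without fully observed features: ",
                paste(lev[is.na(sigma)], collapse = ", "),
                "; using the SD median pooled across conditions",
                call. = FALSE)
        sigma[is.na(sigma)] <- stats::median(pooled)
    }
    f <- .pooledFences(m, k)
    new("ImputationParams", mu = mu, sigma = sigma, muMNAR = f$lower,
        k = k, poolQuartiles = f$q)
}

.imputeMatrix <- function(m, cond, params, seed) {
    lev <- levels(cond)
    mu <- params@mu
    .withSeed(seed, {
        for (j in seq_along(lev)) {
            cols <- which(cond == lev[j])
            sub <- m[, cols, drop = FALSE]
            missIdx <- which(is.na(sub), arr.ind = TRUE)
            if (nrow(missIdx) == 0L) next
            cellMean <- mu[missIdx[, 1], j]
            cellMean[is.na(cellMean)] <- params@muMNAR
            sub[missIdx] <- stats::rnorm(nrow(missIdx), mean = cellMean,
                                         sd = params@sigma[j])
            m[, cols] <- sub
        }
        m
    })
}

#' Draw one completed dataset from the imputation model
#'
#' Every missing cell of feature i in condition j is drawn independently
#' from \code{N(mu[i, j], sigma[j])} when the feature has at least one
#' observation in that condition (the missing-at-random model), and from
#' \code{N(muMNAR, sigma[j])} when all its replicates there are missing
#' (the left-censored missing-not-at-random model). Observed cells are
#' untouched; a given seed always reproduces the same draw, and the
#' caller's RNG state is not disturbed.
#'
#' @param x a log2-scale \linkS4class{PeptideFeatureSet}.
#' @param params an \linkS4class{ImputationParams} estimated from \code{x}.
#' @param seed integer seed for this draw.
#' @return a complete numeric matrix, same dimensions as the assay.
#' @export
imputeOnce <- function(x, params, seed) {
    stopifnot(is(x, "PeptideFeatureSet"), isLogScale(x),
              is(params, "ImputationParams"))
    .imputeMatrix(assay(x, "abundance"), sampleConditions(x), params,
                  as.integer(seed))
}

#' Multiple imputation
#'
#' Runs [imputeOnce()] \code{n} times with per-draw seeds derived
#' deterministically from \code{masterSeed} (seed i = masterSeed + i,
#' reduced modulo 2^31 - 1), recording every seed.
#'
#' @inheritParams imputeOnce
#' @param params an \linkS4class{ImputationParams}; estimated from \code{x}
#'   with defaults when \code{NULL}.
#' @param n number of imputations (>= 1; the source pipeline default is
#'   100).
#' @param masterSeed integer master seed.
#' @return An \linkS4class{ImputedSet}.
#' @export
imputeMultiple <- function(x, params = NULL, n = 100, masterSeed = 1) {
    stopifnot(is(x, "PeptideFeatureSet"), isLogScale(x))
    if (n < 1) stop("n must be >= 1")
    if (is.null(params)) params <- estimateImputationParams(x)
    seeds <- as.integer((as.numeric(masterSeed) + seq_len(n)) %%
                        (2^31 - 1))
    m <- assay(x, "abundance")
    cond <- sampleConditions(x)
    mats <- lapply(seeds, function(s) .imputeMatrix(m, cond, params, s))
    new("ImputedSet", matrices = mats, seeds = seeds, params = params,
        observed = m, condition = cond)
}

#' Drop features with any missing value
#'
#' The filtering baseline to which imputation is compared: removes every
#' feature with one or more missing cells.
#'
#' @param x a \linkS4class{PeptideFeatureSet}.
#' @return the complete-features subset.
#' @export
dropIncompleteFeatures <- function(x) {
    stopifnot(is(x, "PeptideFeatureSet"))
    keep <- rowSums(is.na(assay(x, "abundance"))) == 0L
    x[keep, ]
}

#' Serialize / restore an ImputedSet
#'
#' On-disk form: a directory of TSV matrices (\code{imputation_001.tsv},
#' ...), \code{observed.tsv} with empty cells for missing values, and
#' \code{metadata.json} carrying the seeds, the design and the imputation
#' parameters (per-condition SDs, left-censoring mean, fence multiplier).
#'
#' @param x an \linkS4class{ImputedSet}.
#' @param dir output directory (created if needed).
#' @export
writeImputedSet <- function(x, dir) {
    stopifnot(is(x, "ImputedSet"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(m, f) utils::write.table(
        data.frame(identifier = rownames(m), m, check.names = FALSE),
        file.path(dir, f), sep = "\t", quote = FALSE,
        row.names = FALSE, na = "")
    for (i in seq_along(x@matrices))
        wr(x@matrices[[i]], sprintf("imputation_%03d.tsv", i))
    wr(x@observed, "observed.tsv")
    p <- x@params
    meta <- list(seeds = x@seeds,
                 samples = colnames(x@observed),
                 condition = as.character(x@condition),
                 sigma = as.list(p@sigma), muMNAR = p@muMNAR, k = p@k,
                 poolQuartiles = p@poolQuartiles,
                 quantileConvention = "linear interpolation (type 7)")
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               file.path(dir, "metadata.json"))
    invisible(dir)
}

#' @rdname writeImputedSet
#' @export
readImputedSet <- function(dir) {
    meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
    rd <- function(f) {
        d <- utils::read.delim(file.path(dir, f), check.names = FALSE)
        m <- as.matrix(d[, -1, drop = FALSE])
        rownames(m) <- d$identifier
        m
    }
    obs <- rd("observed.tsv")
    mats <- lapply(seq_along(meta$seeds), function(i)
        rd(sprintf("imputation_%03d.tsv", i)))
    mu <- matrix(NA_real_, nrow(obs), length(meta$sigma),
                 dimnames = list(rownames(obs), names(meta$sigma)))
    cond <- factor(meta$condition, levels = unique(meta$condition))
    for (j in colnames(mu)) {
        sub <- obs[, cond == j, drop = FALSE]
        r <- rowSums(!is.na(sub))
        mu[, j] <- ifelse(r > 0, rowMeans(sub, na.rm = TRUE), NA_real_)
    }
    params <- new("ImputationParams", mu = mu,
                  sigma = unlist(meta$sigma), muMNAR = meta$muMNAR,
                  k = meta$k, poolQuartiles = meta$poolQuartiles)
    new("ImputedSet", matrices = mats, seeds = as.integer(meta$seeds),
        params = params, observed = obs, condition = cond)
}
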