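#' @include AllClasses.R impute.R
NULL

#' Configuration of the synthetic spike-in generator
#'
#' Builds benchmark datasets with known ground truth that emulate the two
#' spike-in designs used to validate the pipeline. Two presets ship:
#' \describe{
#'   \item{\code{"ups1-like"}}{a global-proteome design: 10,000 background
#'     features plus 400 spiked features at three concentrations
#'     (25/50/100, fmol-like) with four technical replicates each;
#'     sparse missingness (under 1\% of cells).}
#'   \item{\code{"yeast-ptm-like"}}{a Cys-oxidation enrichment design:
#'     1,780 background plus 450 spiked features at two concentrations
#'     (50/100, ng-like) with three replicates each; noisier and with
#'     substantially more missing data (~7\% of cells, ~20\% of
#'     features).}
#' }
#' Background features keep the same expected abundance in every
#' condition (expected LFC 0); a spiked feature's expected log2 abundance
#' is shifted by \code{log2(conc_j / conc_1)}, so its expected LFC between
#' conditions a and b is \code{log2(conc_a / conc_b)}. Baseline log2
#' abundances are drawn per feature from
#' \code{N(baselineMean, baselineSD)} — spiked features therefore span the
#' dynamic range, which makes some of them intrinsically harder to detect.
#' Missingness combines random dropout (each cell removed with probability
#' \code{mcarRate}) with left-censoring (every cell whose log2 value falls
#' below \code{mnarThreshold} is removed).
#'
#' @param preset \code{"ups1-like"} or \code{"yeast-ptm-like"}.
#' @param ... named overrides of any default listed above
#'   (\code{nBackground}, \code{nSpike}, \code{concentrations} (named
#'   numeric), \code{replicates}, \code{baselineMean}, \code{baselineSD}
#'   (log2 units), \code{noiseSD} (replicate noise, log2 units),
#'   \code{mcarRate}, \code{mnarThreshold} (log2 units; \code{-Inf}
#'   disables censoring), \code{spikePrefix}, \code{bgPrefix},
#'   \code{mode}, \code{seed}).
#' @return a validated list of class \code{"synthConfig"}.
#' @examples
#' cfg <- synthConfig("ups1-like", nBackground = 500, nSpike = 20)
#' ds <- synthSpikeIn(cfg, seed = 7)
#' ds
#' @export
synthConfig <- function(preset = c("ups1-like", "yeast-ptm-like"), ...) {
    preset <- match.arg(preset)
    cfg <- switch(preset,
        "ups1-like" = list(
            nBackground = 10000L, nSpike = 400L,
            concentrations = c("25" = 25, "50" = 50, "100" = 100),
            replicates = 4L, baselineMean = 18, baselineSD = 2.2,
            noiseSD = 0.25, mcarRate = 0.003, mnarThreshold = 12.9,
            spikePrefix = "UPS", bgPrefix = "CRE", mode = "global",
            seed = 1L),
        "yeast-ptm-like" = list(
            nBackground = 1780L, nSpike = 450L,
            concentrations = c("50" = 50, "100" = 100),
            replicates = 3L, baselineMean = 18, baselineSD = 2.2,
            noiseSD = 0.4, mcarRate = 0.015, mnarThreshold = 15.8,
            spikePrefix = "YEAST", bgPrefix = "CRE", mode = "ptm",
            seed = 1L))
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
        stop("unknown synthConfig field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
    cfg$preset <- preset
    if (any(cfg$concentrations <= 0))
        stop("concentrations must be positive")
    if (cfg$mcarRate < 0 || cfg$mcarRate > 1)
        stop("mcarRate must lie in [0, 1]")
    if (cfg$replicates < 1L || cfg$nBackground < 1L || cfg$nSpike < 0L)
        stop("counts must be positive")
    if (is.null(names(cfg$concentrations)))
        names(cfg$concentrations) <- as.character(cfg$concentrations)
    structure(cfg, class = "synthConfig")
}

#' Generate a synthetic spike-in dataset
#'
#' Draws the complete dataset described by the configuration, then injects
#' missingness ([injectMissingness()]). Abundances are emitted on the raw
#' scale (2^log2). Deterministic for a fixed seed.
#'
#' @param config a [synthConfig()].
#' @param seed integer seed (defaults to \code{config$seed}).
#' @return A \linkS4class{SynthDataset}.
#' @export
synthSpikeIn <- function(config, seed = config$seed) {
    stopifnot(inherits(config, "synthConfig"))
    conc <- config$concentrations
    lev <- names(conc)
    nC <- length(conc)
    nRep <- config$replicates
    nF <- config$nBackground + config$nSpike
    isSpike <- c(rep(TRUE, config$nSpike), rep(FALSE, config$nBackground))
    acc <- c(sprintf("%s|P%05d", config$spikePrefix, seq_len(config$nSpike)),
             sprintf("%s|G%05d", config$bgPrefix,
                     seq_len(config$nBackground)))
    ids <- paste0(acc, "_F", seq_len(nF))
    samples <- paste0("c", rep(lev, each = nRep), "_r",
                      rep(seq_len(nRep), nC))
    condition <- rep(lev, each = nRep)

    logm <- .withSeed(as.integer(seed), {
        base <- stats::rnorm(nF, config$baselineMean, config$baselineSD)
        shift <- log2(conc / conc[1])
        meanMat <- outer(base, rep(0, nC), `+`)
        meanMat[isSpike, ] <- meanMat[isSpike, , drop = FALSE] +
            matrix(shift, sum(isSpike), nC, byrow = TRUE)
        full <- meanMat[, rep(seq_len(nC), each = nRep), drop = FALSE] +
            matrix(stats::rnorm(nF * nC * nRep, 0, config$noiseSD), nF)
        dimnames(full) <- list(ids, samples)
        full
    })
    pfs <- PeptideFeatureSet(2^logm,
                             condition = factor(condition, levels = lev),
                             rowData = DataFrame(accession = acc),
                             mode = config$mode, logScale = FALSE)
    pairs <- utils::combn(seq_len(nC), 2)
    trueLFC <- matrix(0, nF, ncol(pairs),
                      dimnames = list(ids, apply(pairs, 2, function(p)
                          paste(lev[p[2]], lev[p[1]], sep = "-"))))
    for (k in seq_len(ncol(pairs)))
        trueLFC[isSpike, k] <- log2(conc[pairs[2, k]] / conc[pairs[1, k]])
    ds <- new("SynthDataset", features = pfs,
              truth = ifelse(isSpike, "TP", "TN"), trueLFC = trueLFC,
              mechanism = matrix("observed", nF, ncol(pfs),
                                 dimnames = dimnames(logm)))
    injectMissingness(ds, config$mcarRate, config$mnarThreshold,
                      seed = as.integer(seed) + 1L)
}

#' Inject missingness into a complete dataset
#'
#' Two mechanisms, applied in order: each cell is removed independently
#' with probability \code{mcarRate} (mechanism \code{"mcar"}); then every
#' remaining cell whose log2 abundance lies below \code{mnarThreshold} is
#' removed (mechanism \code{"mnar"}, left-censoring — missingness caused
#' by the value itself). Features left with no observed cell at all cannot
#' be analysed and are dropped with a message.
#'
#' @param dataset a \linkS4class{SynthDataset} (typically complete).
#' @param mcarRate per-cell random dropout probability.
#' @param mnarThreshold log2 censoring limit; \code{-Inf} disables.
#' @param seed integer seed for the random dropout.
#' @return the dataset with updated abundances and mechanism map.
#' @export
injectMissingness <- function(dataset, mcarRate, mnarThreshold,
                              seed = 1L) {
    stopifnot(is(dataset, "SynthDataset"))
    pfs <- dataset@features
    raw <- assay(pfs, "abundance")
    mech <- dataset@mechanism
    present <- !is.na(raw)
    mcar <- .withSeed(as.integer(seed),
        matrix(stats::runif(length(raw)) < mcarRate, nrow(raw)))
    mcar <- mcar & present
    mech[mcar] <- "mcar"
    mnar <- present & !mcar & log2(raw) < mnarThreshold
    mech[mnar] <- "mnar"
    raw[mcar | mnar] <- NA_real_
    empty <- rowSums(!is.na(raw)) == 0L
    if (any(empty))
        message(sum(empty),
                " feature(s) fully censored and dropped from the dataset")
    keep <- !empty
    assay(pfs, "abundance") <- raw
    new("SynthDataset", features = pfs[keep, ],
        truth = dataset@truth[keep],
        trueLFC = dataset@trueLFC[keep, , drop = FALSE],
        mechanism = mech[keep, , drop = FALSE])
}
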