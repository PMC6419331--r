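test_that("log2 transform maps present cells and preserves the missing mask", {
    m <- matrix(c(8, 1, NA, 4), 2, 2,
                dimnames = list(c("f1", "f2"), c("s1", "s2")))
    pfs <- PeptideFeatureSet(m, condition = c("A", "B"))
    lg <- log2Transform(pfs)
    expect_equal(assay(lg, "abundance"),
                 matrix(c(3, 0, NA, 2), 2, 2, dimnames = dimnames(m)))
    expect_true(isLogScale(lg))
    # zero abundance: error naming the cell, or missing when asked
    m0 <- m; m0[2, 1] <- 0
    pfs0 <- PeptideFeatureSet(m0, condition = c("A", "B"))
    expect_error(log2Transform(pfs0), "'f2', sample 's1'")
    lg0 <- log2Transform(pfs0, zeroAsMissing = TRUE)
    expect_true(is.na(assay(lg0, "abundance")[2, 1]))
})

test_that("all-outlier features are dropped, one in-fence value saves a feature", {
    # pooled bulk in [16, 20]; fences comfortably exclude 55
    set.seed(5)
    m <- matrix(runif(40 * 6, 16, 20), 40, 6,
                dimnames = list(paste0("f", 1:40), paste0("s", 1:6)))
    m[1, ] <- 55                       # all observations outside -> dropped
    m[2, ] <- c(18, 55, 55, 55, NA, 55)  # one in-fence value -> retained
    pfs <- PeptideFeatureSet(m, condition = rep(c("A", "B"), each = 3),
                             logScale = TRUE)
    out <- removeAllOutlierFeatures(pfs)
    expect_false("f1" %in% rownames(out))
    expect_true("f2" %in% rownames(out))
    expect_equal(nrow(out), 39L)
    # constant matrix: fences collapse onto the constant, nothing dropped
    cm <- matrix(7, 5, 6, dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
    cpfs <- PeptideFeatureSet(cm, condition = rep(c("A", "B"), each = 3),
                              logScale = TRUE)
    expect_equal(nrow(removeAllOutlierFeatures(cpfs)), 5L)
})

test_that("a feature inside the fences is never dropped", {
    set.seed(11)
    for (rep in 1:10) {
        m <- matrix(rnorm(30 * 8, 18, 2), 30, 8,
                    dimnames = list(paste0("f", 1:30), paste0("s", 1:8)))
        m[sample(length(m), 10)] <- NA
        pfs <- PeptideFeatureSet(m, condition = rep(c("A", "B"), each = 4),
                                 logScale = TRUE)
        f <- promi:::.pooledFences(m, 1.5)
        inside <- rowSums(!is.na(m) & (m < f$lower | m > f$upper)) == 0
        kept <- rownames(removeAllOutlierFeatures(pfs))
        expect_true(all(rownames(m)[inside] %in% kept))
    }
})

test_that("muMNAR equals the lower Tukey fence under interpolation quantiles", {
    # independent oracle: manual order-statistic interpolation on V = 1:4
    v <- c(1, 2, 3, 4)
    manualQ <- function(p) {
        h <- (length(v) - 1) * p
        lo <- floor(h) + 1
        v[lo] + (h - floor(h)) * (v[min(lo + 1, length(v))] - v[lo])
    }
    q1 <- manualQ(0.25); q3 <- manualQ(0.75)
    expect_equal(q1, 1.75)
    expect_equal(q3, 3.25)
    m <- matrix(v, 1, 4, dimnames = list("f1", paste0("s", 1:4)))
    pfs <- PeptideFeatureSet(m, condition = c("A", "A", "B", "B"),
                             logScale = TRUE)
    p <- estimateImputationParams(pfs)
    expect_equal(muMNAR(p), q1 - 1.5 * (q3 - q1))
    expect_equal(muMNAR(p), -0.5)
    # constant V: IQR 0, muMNAR is the constant
    cm <- matrix(6, 1, 4, dimnames = dimnames(m))
    cp <- estimateImputationParams(
        PeptideFeatureSet(cm, condition = c("A", "A", "B", "B"),
                          logScale = TRUE))
    expect_equal(muMNAR(cp), 6)
})

test_that("muMNAR never exceeds Q1 of the pooled values", {
    set.seed(21)
    for (rep in 1:20) {
        m <- matrix(rexp(10 * 6) + rnorm(60, 15), 10, 6,
                    dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
        pfs <- PeptideFeatureSet(m, condition = rep(c("A", "B"), each = 3),
                                 logScale = TRUE)
        p <- estimateImputationParams(pfs)
        q1 <- quantile(m, 0.25, names = FALSE)
        expect_lte(muMNAR(p), q1)
    }
})

test_that("sigma is the median SD of features complete in that condition", {
    # condition A: three complete features with sample SDs 1, 2, 9
    a <- rbind(c(17, 18, 19), c(16, 18, 20), c(9, 18, 27))
    a <- a * c(1, 1, 1)  # SDs exactly 1, 2, 9
    expect_equal(apply(a, 1, sd), c(1, 2, 9))
    b <- matrix(18, 3, 3)
    b[1, 1] <- NA  # feature 1 incomplete in B
    m <- cbind(a, b)
    dimnames(m) <- list(paste0("f", 1:3), paste0("s", 1:6))
    pfs <- PeptideFeatureSet(m, condition = rep(c("A", "B"), each = 3),
                             logScale = TRUE)
    p <- estimateImputationParams(pfs)
    expect_equal(unname(sigmaHat(p)["A"]), 2)
    # B's median over the two complete features (both constant): 0
    expect_equal(unname(sigmaHat(p)["B"]), 0)
    # mu is the mean of present values per feature and condition
    expect_equal(unname(muHat(p)["f1", ]), c(18, 18))
})

test_that("conditions without complete features fall back to pooled SDs", {
    m <- rbind(c(17, 18, 19, NA, 18, NA),
               c(16, 18, 20, 18, NA, 18))
    dimnames(m) <- list(c("f1", "f2"), paste0("s", 1:6))
    pfs <- PeptideFeatureSet(m, condition = rep(c("A", "B"), each = 3),
                             logScale = TRUE)
    expect_warning(p <- estimateImputationParams(pfs), "pooled")
    expect_equal(unname(sigmaHat(p)["B"]), median(c(1, 2)))
    expect_error(estimateImputationParams(pfs, fallbackPooled = FALSE),
                 "condition")
})

test_that("imputation preserves observed cells and is seed-deterministic", {
    set.seed(33)
    m <- matrix(rnorm(30 * 6, 18, 2), 30, 6,
                dimnames = list(paste0("f", 1:30), paste0("s", 1:6)))
    m[sample(length(m), 20)] <- NA
    m[5, 1:3] <- NA   # an all-missing condition cell (MNAR)
    pfs <- PeptideFeatureSet(m, condition = rep(c("A", "B"), each = 3),
                             logScale = TRUE)
    params <- estimateImputationParams(pfs)
    one <- imputeOnce(pfs, params, seed = 99)
    expect_false(anyNA(one))
    expect_identical(one[!is.na(m)], m[!is.na(m)])
    expect_identical(one, imputeOnce(pfs, params, seed = 99))
    expect_false(identical(one, imputeOnce(pfs, params, seed = 100)))
    # complete input: identity
    cfs <- PeptideFeatureSet(one, condition = rep(c("A", "B"), each = 3),
                             logScale = TRUE)
    expect_identical(imputeOnce(cfs, params, seed = 1), one)
    # the caller's RNG stream is not consumed
    set.seed(7); before <- rnorm(1)
    set.seed(7); invisible(imputeOnce(pfs, params, seed = 99))
    expect_identical(rnorm(1), before)
})

test_that("zero-sigma imputation returns the cell mean exactly", {
    m <- rbind(c(18, 18, 18, NA, 20, 22))
    dimnames(m) <- list("f1", paste0("s", 1:6))
    pfs <- PeptideFeatureSet(m, condition = rep(c("A", "B"), each = 3),
                             logScale = TRUE)
    params <- new("ImputationParams",
                  mu = matrix(c(18, 21), 1, 2,
                              dimnames = list("f1", c("A", "B"))),
                  sigma = c(A = 0, B = 0), muMNAR = 10, k = 1.5,
                  poolQuartiles = c(18, 22))
    out <- imputeOnce(pfs, params, seed = 1)
    expect_equal(out[1, 4], 21)
})

test_that("multiple imputation records seeds and agrees at observed cells", {
    set.seed(44)
    m <- matrix(rnorm(25 * 6, 18, 2), 25, 6,
                dimnames = list(paste0("f", 1:25), paste0("s", 1:6)))
    m[sample(length(m), 15)] <- NA
    m[3, 4:6] <- NA
    pfs <- PeptideFeatureSet(m, condition = rep(c("A", "B"), each = 3),
                             logScale = TRUE)
    imp <- imputeMultiple(pfs, n = 10, masterSeed = 7)
    expect_length(imputations(imp), 10L)
    expect_equal(imputationSeeds(imp), as.integer(7 + 1:10))
    expect_true(all(vapply(imputations(imp),
                           function(x) !anyNA(x), NA)))
    obs <- !is.na(m)
    for (x in imputations(imp)) expect_identical(x[obs], m[obs])
    # identical master seed reproduces the whole set
    imp2 <- imputeMultiple(pfs, n = 10, masterSeed = 7)
    expect_identical(imputations(imp), imputations(imp2))
    expect_error(imputeMultiple(pfs, n = 0), ">= 1")
    expect_length(imputations(imputeMultiple(pfs, n = 1, masterSeed = 1)),
                  1L)
})

test_that("imputed draws follow the fitted normal distributions", {
    # one MAR cell and one MNAR condition-cell, resampled many times
    m <- rbind(f1 = c(18.2, 17.8, NA, 19.0, 19.4, 19.2),
               f2 = c(NA, NA, NA, 18.1, 18.0, 17.9),
               f3 = c(17.0, 17.2, 17.1, 18.3, 18.5, 18.4),
               f4 = c(16.0, 16.4, 16.2, 17.6, 17.4, 17.5))
    colnames(m) <- paste0("s", 1:6)
    pfs <- PeptideFeatureSet(m, condition = rep(c("A", "B"), each = 3),
                             logScale = TRUE)
    params <- estimateImputationParams(pfs)
    imp <- imputeMultiple(pfs, params, n = 2000, masterSeed = 515)
    marDraws <- vapply(imputations(imp), function(x) x["f1", 3], 0)
    mnarDraws <- vapply(imputations(imp), function(x) x["f2", 1], 0)
    ksMar <- ks.test(marDraws, "pnorm", mean = muHat(params)["f1", "A"],
                     sd = sigmaHat(params)["A"])
    ksMnar <- ks.test(mnarDraws, "pnorm", mean = muMNAR(params),
                      sd = sigmaHat(params)["A"])
    expect_gt(ksMar$p.value, 0.01)
    expect_gt(ksMnar$p.value, 0.01)
    # law of large numbers sanity on the MNAR stream
    expect_lt(abs(mean(mnarDraws) - muMNAR(params)),
              4 * sigmaHat(params)["A"] / sqrt(2000))
})

test_that("dropIncompleteFeatures keeps exactly the fully observed rows", {
    m <- matrix(1:12, 3, 4,
                dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
    m[2, 3] <- NA
    pfs <- PeptideFeatureSet(m, condition = rep(c("A", "B"), each = 2),
                             logScale = TRUE)
    expect_equal(rownames(dropIncompleteFeatures(pfs)), c("f1", "f3"))
})

test_that("an ImputedSet round-trips through its TSV directory format", {
    set.seed(55)
    m <- matrix(round(rnorm(10 * 6, 18, 2), 6), 10, 6,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
    m[sample(length(m), 6)] <- NA
    pfs <- PeptideFeatureSet(m, condition = rep(c("A", "B"), each = 3),
                             logScale = TRUE)
    imp <- imputeMultiple(pfs, n = 3, masterSeed = 2)
    dir <- tempfile()
    writeImputedSet(imp, dir)
    back <- readImputedSet(dir)
    expect_equal(imputationSeeds(back), imputationSeeds(imp))
    expect_equal(imputations(back), imputations(imp), tolerance = 1e-12)
    expect_equal(sigmaHat(imputationParams(back)),
                 sigmaHat(imputationParams(imp)))
    expect_equal(muMNAR(imputationParams(back)),
                 muMNAR(imputationParams(imp)))
})
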