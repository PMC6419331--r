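test_that("CSV parsing yields one record per row with missing encoded as NA", {
    rows <- list(feature = paste0("F", 1:5),
                 sequence = rep("PEPTIDEK", 5),
                 mods = rep("", 5),
                 score = c(20, 30, 40, 50, 60),
                 accession = paste0("P", 1:5),
                 confidence = rep(10, 5),
                 unique_peptides = rep(1L, 5),
                 ab = matrix(seq_len(30), 5, 6))
    rows$ab[2, 3] <- NA
    path <- writeMeasurementsCSV(rows)
    rec <- readPeptideMeasurements(path, fixtureDialect())
    expect_equal(nrow(rec), 5L)
    expect_equal(ncol(rec$abundance), 6L)
    expect_true(is.na(rec$abundance[2, 3]))
    expect_equal(sum(is.na(rec$abundance)), 1L)
    expect_equal(rec$feature_id, paste0("F", 1:5))  # row order preserved
})

test_that("parser errors name the offending column or row", {
    rows <- twelveRowRecords()
    path <- writeMeasurementsCSV(rows)
    noScore <- peptideDialect(score = "MascotScore",
                              abundance = paste0("s", 1:6))
    expect_error(readPeptideMeasurements(path, noScore),
                 "missing column.*MascotScore")
    # a non-numeric, non-blank abundance cell is a parse error with row index
    txt <- readLines(path)
    txt[2] <- sub("100", "oops", txt[2])
    writeLines(txt, path)
    expect_error(readPeptideMeasurements(path, fixtureDialect()),
                 "parse error: non-numeric abundance at row 1")
})

test_that("score filter keeps the boundary and removes contaminants", {
    rec <- readPeptideMeasurements(twelveRowCSV(), fixtureDialect())
    out <- filterScoreAndContaminants(rec, minScore = 13)
    expect_equal(nrow(out), 9L)                # 12.9, 12 and CONTAM_X gone
    expect_true(all(out$score >= 13))
    expect_true(13 %in% out$score)             # boundary kept
    expect_false("CONTAM_X" %in% out$accession)
    # empty input passes through
    expect_equal(nrow(filterScoreAndContaminants(rec[0, ])), 0L)
})

test_that("parsimony resolution prefers unique peptides then confidence", {
    rec <- readPeptideMeasurements(twelveRowCSV(), fixtureDialect())
    rec <- filterScoreAndContaminants(rec)
    out <- resolveSharedAccessions(rec)
    expect_equal(nrow(out), 8L)
    expect_true("P2" %in% out$accession)       # 5 unique peptides beats 3
    expect_false("P3" %in% out$accession)
    # confidence breaks a unique-peptide tie
    tie <- rec[rec$sequence == "MCAK", ]
    tie$unique_peptides <- c(5L, 5L)
    expect_equal(resolveSharedAccessions(tie)$accession, "P3")  # conf 60 > 50
    # double tie falls back to smallest accession, with a warning
    tie$confidence <- c(50, 50)
    expect_warning(res <- resolveSharedAccessions(tie), "parsimony tie")
    expect_equal(res$accession, "P2")
    # no shared groups: identity
    solo <- rec[rec$sequence == "ACCK", ]
    expect_identical(resolveSharedAccessions(solo)$accession,
                     solo$accession)
})

test_that("duplicated features keep the highest-scoring identification", {
    rec <- readPeptideMeasurements(twelveRowCSV(), fixtureDialect())
    rec <- resolveSharedAccessions(filterScoreAndContaminants(rec))
    out <- deduplicateFeatures(rec)
    expect_equal(nrow(out), 7L)
    f06 <- out[out$feature_id == "F05", ]
    expect_equal(f06$sequence, "DCERK")        # score 35 beats 30
    # exact tie keeps the lexicographically smallest sequence
    tie <- rec[rec$feature_id %in% c("F05"), ]
    tie$score <- c(30, 30)
    expect_warning(res <- deduplicateFeatures(tie), "score tie")
    expect_equal(res$sequence, "DCERK")        # "DCERK" < "DCK"
})

test_that("oxidised-Cys filter requires an unalkylated cysteine", {
    rec <- readPeptideMeasurements(twelveRowCSV(), fixtureDialect())
    out <- ptmFilterOxidized(rec)
    expect_false("ACK" %in% out$sequence)   # only Cys carbamidomethylated
    expect_true("ACCK" %in% out$sequence)   # position-3 Cys unmodified
    expect_false("GGK" %in% out$sequence)   # no Cys at all
})

test_that("identifier construction sums contributors and tracks the best score", {
    rec <- readPeptideMeasurements(twelveRowCSV(), fixtureDialect())
    rec <- deduplicateFeatures(resolveSharedAccessions(
        filterScoreAndContaminants(rec)))
    rec <- ptmFilterOxidized(rec)
    expect_equal(nrow(rec), 5L)
    pfs <- buildIdentifiers(rec, condition = rep(c("A", "B"), each = 3),
                            mode = "ptm")
    expect_equal(nrow(pfs), 4L)                # P1_C1 binned from two rows
    expect_true(metadata(pfs)$localCysCoords)  # fixture has no Start column
    ab <- assay(pfs, "abundance")
    # [10, NA, 5, 8, 8, 8] + [5, 7, NA, 2, 2, 2]: missing sums with present
    expect_equal(unname(ab["P1_C1", ]), c(15, 7, 5, 10, 10, 10))
    expect_equal(rowData(pfs)["P1_C1", "score"], 13)
    expect_equal(rowData(pfs)["P1_C1", "n_contributors"], 2L)
    # abundance mass per sample conserved by the collapse
    expect_equal(colSums(ab, na.rm = TRUE),
                 colSums(rec$abundance, na.rm = TRUE))
})

test_that("global identifiers concatenate accession and sequence", {
    rows <- list(feature = c("F1", "F2", "F3"),
                 sequence = c("PEPK", "PEPK", "OTHERK"),
                 mods = c("", "", ""), score = c(20, 30, 40),
                 accession = c("P1", "P1", "P2"),
                 confidence = rep(10, 3), unique_peptides = rep(1L, 3),
                 ab = matrix(c(10, NA, 1, 5, 7, 1, NA, NA, 1,
                               1, 1, 1, 1, 1, 1, 1, 1, 1), 3, 6))
    rec <- readPeptideMeasurements(writeMeasurementsCSV(rows),
                                   fixtureDialect())
    pfs <- buildIdentifiers(rec, condition = rep(c("A", "B"), each = 3),
                            mode = "global")
    expect_setequal(rownames(pfs), c("P1_PEPK", "P2_OTHERK"))
    ab <- assay(pfs, "abundance")
    expect_equal(unname(ab["P1_PEPK", 1:3]), c(10, 12, NA))
    # single-contributor identifier passes through unchanged
    expect_equal(unname(ab["P2_OTHERK", ]), rep(1, 6))
})

test_that("ptm sites move to protein coordinates when a start column exists", {
    rows <- list(feature = c("F1", "F2"), sequence = c("ACK", "ACK"),
                 mods = c("", ""), score = c(20, 25),
                 accession = c("P9", "P9"), confidence = rep(10, 2),
                 unique_peptides = rep(1L, 2),
                 start = c(41, 41),
                 ab = matrix(1, 2, 6))
    rec <- readPeptideMeasurements(writeMeasurementsCSV(rows),
                                   fixtureDialect())
    pfs <- buildIdentifiers(rec, condition = rep(c("A", "B"), each = 3),
                            mode = "ptm")
    # peptide-local Cys offset 2 at protein start 41 -> site C42;
    # two charge-state-like records collapse into one identifier
    expect_equal(rownames(pfs), "P9_C42")
    expect_false(metadata(pfs)$localCysCoords)
    expect_equal(unname(assay(pfs, "abundance")[1, ]), rep(2, 6))
})

test_that("filtering is monotone and staged composition matches the chain", {
    rec <- readPeptideMeasurements(twelveRowCSV(), fixtureDialect())
    staged <- rec
    counts <- nrow(staged)
    for (f in list(function(r) filterScoreAndContaminants(r),
                   resolveSharedAccessions, deduplicateFeatures,
                   ptmFilterOxidized)) {
        staged <- f(staged)
        counts <- c(counts, nrow(staged))
    }
    expect_true(all(diff(counts) <= 0))
    expect_equal(counts, c(12L, 9L, 8L, 7L, 5L))
    # same file parsed twice gives byte-identical tables
    path <- twelveRowCSV()
    build <- function() {
        r <- readPeptideMeasurements(path, fixtureDialect())
        r <- ptmFilterOxidized(deduplicateFeatures(
            resolveSharedAccessions(filterScoreAndContaminants(r))))
        buildIdentifiers(r, condition = rep(c("A", "B"), each = 3),
                         mode = "ptm")
    }
    a <- build(); b <- build()
    expect_identical(assay(a, "abundance"), assay(b, "abundance"))
    expect_identical(as.data.frame(rowData(a)), as.data.frame(rowData(b)))
})

test_that("feature tables round-trip through the TSV format", {
    pfs <- smallLogTable(nf = 8)
    assay(pfs, "abundance")[1, 2] <- NA
    tsv <- tempfile(fileext = ".tsv"); des <- tempfile(fileext = ".tsv")
    writeFeatureTable(pfs, tsv, des)
    design <- readDesign(des)
    back <- readFeatureTable(tsv, design, logScale = TRUE)
    expect_equal(assay(back, "abundance"), assay(pfs, "abundance"))
    expect_equal(as.character(sampleConditions(back)),
                 as.character(sampleConditions(pfs)))
})
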