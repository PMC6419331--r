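# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the helpers write to
# tempdir() first.

# Standard 6-sample dialect used by the CSV fixtures.
fixtureDialect <- function(n = 6) {
    peptideDialect(abundance = paste0("s", seq_len(n)), start = "Start")
}

# Write a peptide-measurements CSV from a data.frame of records.
# `rows` needs feature, sequence, mods, score, accession, confidence,
# unique_peptides and an `ab` matrix column (NA = blank cell).
writeMeasurementsCSV <- function(rows, path = tempfile(fileext = ".csv")) {
    ab <- rows$ab
    df <- data.frame(Feature = rows$feature,
                     Sequence = rows$sequence,
                     Modifications = rows$mods,
                     Score = rows$score,
                     Accession = rows$accession,
                     Confidence = rows$confidence,
                     Unique.peptides = rows$unique_peptides,
                     Start = if (is.null(rows$start)) "" else rows$start,
                     check.names = FALSE)
    colnames(df)[colnames(df) == "Unique.peptides"] <- "Unique.peptides"
    ab_df <- as.data.frame(ab)
    colnames(ab_df) <- paste0("s", seq_len(ncol(ab)))
    utils::write.csv(cbind(df, ab_df), path, row.names = FALSE, na = "")
    path
}

# The 12-row fixture exercising every pre-processing rule, with hand
# counts asserted in the tests:
#   rows 1, 12: below the score-13 boundary        -> score filter
#   row 3:      CONTAM_ accession                  -> contaminant filter
#   rows 4, 5:  same feature F04 & (seq, mods, score), P2 vs P3  -> parsimony (P2 wins,
#               5 unique peptides vs 3)
#   rows 6, 7:  same feature F05, scores 30 vs 35  -> dedup keeps row 7
#   rows 8, 10: only alkylated Cys / no Cys        -> oxidised-Cys filter
#   rows 2, 11: same peptide CAK on P1             -> one identifier, summed
twelveRowRecords <- function() {
    ab <- matrix(100, 12, 6)
    ab[2, ] <- c(10, NA, 5, 8, 8, 8)
    ab[11, ] <- c(5, 7, NA, 2, 2, 2)
    list(feature = sprintf("F%02d", c(1, 2, 3, 4, 4, 5, 5, 6, 7, 8, 9, 10)),
         sequence = c("CAK", "CAK", "CCK", "MCAK", "MCAK", "DCK",
                      "DCERK", "ACK", "ACCK", "GGK", "CAK", "CAK"),
         mods = c("", "", "Carbamidomethyl (1)", "", "", "", "",
                  "Carbamidomethyl (2)", "Carbamidomethyl (2)", "", "", ""),
         score = c(12.9, 13, 20, 25, 25, 30, 35, 40, 40, 50, 13, 12),
         accession = c("P1", "P1", "CONTAM_X", "P2", "P3", "P4", "P4",
                       "P5", "P5", "P6", "P1", "P1"),
         confidence = c(10, 10, 10, 50, 60, 10, 10, 10, 10, 10, 10, 10),
         unique_peptides = c(1L, 1L, 1L, 5L, 3L, 1L, 1L, 1L, 1L, 1L,
                             1L, 1L),
         ab = ab)
}

twelveRowCSV <- function() writeMeasurementsCSV(twelveRowRecords())

# Small complete log2 table: nf features, two conditions x nrep.
smallLogTable <- function(nf = 20, nrep = 3, seed = 1, mean = 18,
                          sd = 1, noise = 0.3) {
    set.seed(seed)
    m <- matrix(rnorm(nf, mean, sd) + rnorm(nf * 2 * nrep, 0, noise),
                nf, 2 * nrep,
                dimnames = list(paste0("f", seq_len(nf)),
                                paste0("s", seq_len(2 * nrep))))
    PeptideFeatureSet(m, condition = rep(c("A", "B"), each = nrep),
                      logScale = TRUE)
}
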