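#' @include AllClasses.R
NULL

#' Column dialect of a peptide-measurements export
#'
#' Label-free quantitation software exports "peptide measurements" tables
#' with one row per matched MS1 feature; column headers vary between
#' versions and laboratories. A dialect names the columns this package
#' needs. \code{abundance} is the vector of per-sample abundance column
#' names; all other entries are single column names. \code{start} (1-based
#' position of the peptide in the protein sequence) is optional and only
#' used to place Cys-oxidation sites on protein coordinates in PTM mode.
#'
#' @param feature,sequence,modifications,score,accession,confidence,
#'   unique_peptides single column names.
#' @param abundance character vector of abundance column names, in sample
#'   order; these become the sample names.
#' @param start optional column with the peptide's start coordinate in the
#'   protein, or \code{NULL}.
#' @return A named list of class \code{"peptideDialect"}.
#' @examples
#' d <- peptideDialect(abundance = paste0("S", 1:6))
#' d$score
#' @export
peptideDialect <- function(feature = "Feature",
                           sequence = "Sequence",
                           modifications = "Modifications",
                           score = "Score",
                           accession = "Accession",
                           confidence = "Confidence",
                           unique_peptides = "Unique.peptides",
                           abundance = character(),
                           start = NULL) {
    structure(list(feature = feature, sequence = sequence,
                   modifications = modifications, score = score,
                   accession = accession, confidence = confidence,
                   unique_peptides = unique_peptides,
                   abundance = abundance, start = start),
              class = "peptideDialect")
}

## Modification cells are "Name (pos)" entries joined by "|", e.g.
## "Carbamidomethyl (2)|Oxidation (5)"; empty cell = unmodified peptide.
.parseMods <- function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell)))
        return(list(pos = integer(), name = character()))
    parts <- trimws(strsplit(cell, "|", fixed = TRUE)[[1]])
    m <- regmatches(parts, regexec("^(.*)\\(([0-9]+)\\)$", parts))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad))
        stop("cannot parse modification entry: ", parts[bad][1])
    list(pos = as.integer(vapply(m, `[`, "", 3L)),
         name = trimws(vapply(m, `[`, "", 2L)))
}

.formatMods <- function(pos, name) {
    if (length(pos) == 0L) return("")
    o <- order(pos)
    paste(sprintf("%s (%d)", name[o], pos[o]), collapse = "|")
}

#' Read a peptide-measurements CSV export
#'
#' Parses one record per row. Blank abundance cells become missing
#' (\code{NA}); a non-numeric, non-blank abundance cell is a parse error
#' reported with its row index. A mandatory column absent from the file is
#' a configuration error naming the column.
#'
#' @param path path to the CSV file.
#' @param dialect a [peptideDialect()] naming the columns; its
#'   \code{abundance} entry must be non-empty.
#' @return A [S4Vectors::DataFrame] with columns \code{feature_id},
#'   \code{sequence}, \code{modifications} (canonical string form),
#'   \code{score}, \code{accession}, \code{confidence},
#'   \code{unique_peptides}, \code{start} (\code{NA} if the dialect has no
#'   start column) and a matrix column \code{abundance}. Row order follows
#'   the file.
#' @export
readPeptideMeasurements <- function(path, dialect) {
    stopifnot(file.exists(path), inherits(dialect, "peptideDialect"))
    if (length(dialect$abundance) == 0L)
        stop("configuration error: dialect$abundance names no columns")
    raw <- utils::read.csv(path, check.names = FALSE,
                           colClasses = "character")
    need <- c(feature = dialect$feature, sequence = dialect$sequence,
              modifications = dialect$modifications, score = dialect$score,
              accession = dialect$accession,
              confidence = dialect$confidence,
              unique_peptides = dialect$unique_peptides,
              dialect$abundance)
    absent <- setdiff(need, colnames(raw))
    if (length(absent))
        stop("configuration error: missing column(s): ",
             paste(absent, collapse = ", "))
    ab <- as.matrix(raw[, dialect$abundance, drop = FALSE])
    blank <- is.na(ab) | !nzchar(trimws(ab))
    num <- suppressWarnings(array(as.numeric(ab), dim(ab)))
    bad <- which(!blank & is.na(num), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("parse error: non-numeric abundance at row %d, column '%s'",
                     bad[1, 1], dialect$abundance[bad[1, 2]]))
    num[blank] <- NA_real_
    colnames(num) <- dialect$abundance
    startCol <- if (!is.null(dialect$start) &&
                    dialect$start %in% colnames(raw))
        suppressWarnings(as.numeric(raw[[dialect$start]]))
    else rep(NA_real_, nrow(raw))
    mods <- vapply(raw[[dialect$modifications]], function(cell) {
        m <- .parseMods(cell)
        .formatMods(m$pos, m$name)
    }, "", USE.NAMES = FALSE)
    rec <- DataFrame(
        feature_id = raw[[dialect$feature]],
        sequence = toupper(trimws(raw[[dialect$sequence]])),
        modifications = mods,
        score = as.numeric(raw[[dialect$score]]),
        accession = raw[[dialect$accession]],
        confidence = as.numeric(raw[[dialect$confidence]]),
        unique_peptides = as.integer(raw[[dialect$unique_peptides]]),
        start = startCol)
    rec$abundance <- num
    if (any(!nzchar(rec$sequence)))
        stop("parse error: empty peptide sequence at row ",
             which(!nzchar(rec$sequence))[1])
    if (any(!is.finite(rec$score)))
        stop("parse error: non-finite score at row ",
             which(!is.finite(rec$score))[1])
    rec
}

#' Score and contaminant filtering
#'
#' Retains records with an identification score of at least \code{minScore}
#' (default 13, the conventional Mascot cutoff) whose accession does not
#' match the contaminant list. Contaminants are recognised by accession
#' prefix. Record order is preserved.
#'
#' @param records a record [S4Vectors::DataFrame] from
#'   [readPeptideMeasurements()].
#' @param minScore minimum identification score retained (boundary kept:
#'   \code{score >= minScore}).
#' @param contaminants character vector of accession prefixes flagging
#'   contaminant-database hits.
#' @return the filtered records.
#' @export
filterScoreAndContaminants <- function(records, minScore = 13,
                                       contaminants = c("CONTAM_", "sp|CON")) {
    keep <- records$score >= minScore
    if (length(contaminants)) {
        isCon <- Reduce(`|`, lapply(contaminants, function(p)
            startsWith(records$accession, p)))
        keep <- keep & !isCon
    }
    records[keep, , drop = FALSE]
}

#' Parsimony resolution of shared peptide accessions
#'
#' Duplicate rows of the same MS1 feature that are identical in
#' (sequence, modifications, score) but carry alternate protein
#' accessions are collapsed to a single record whose
#' accession is supported by the most unique peptides; ties fall back to
#' the larger protein confidence score, and a double tie keeps the
#' lexicographically smallest accession with a warning. Abundances of the
#' representative are kept unchanged and row order is preserved.
#'
#' @param records a record DataFrame.
#' @return records with one row per (sequence, modifications, score) group.
#' @export
resolveSharedAccessions <- function(records) {
    if (nrow(records) == 0L) return(records)
    key <- paste(records$feature_id, records$sequence,
                 records$modifications, records$score, sep = "\r")
    grp <- split(seq_len(nrow(records)), key)
    pick <- vapply(grp, function(idx) {
        if (length(idx) == 1L) return(idx)
        up <- records$unique_peptides[idx]
        idx <- idx[up == max(up)]
        if (length(idx) > 1L) {
            cf <- records$confidence[idx]
            idx <- idx[cf == max(cf)]
        }
        if (length(idx) > 1L) {
            warning("parsimony tie on unique peptides and confidence; ",
                    "keeping lexicographically smallest accession among: ",
                    paste(records$accession[idx], collapse = ", "),
                    call. = FALSE)
            idx <- idx[order(records$accession[idx])]
        }
        idx[1]
    }, 1L)
    records[sort(pick), , drop = FALSE]
}

#' Reduce duplicated MS1 features to their best identification
#'
#' Several peptide identifications can be matched to the same MS1 feature;
#' each feature keeps only the record with the highest identification
#' score. An exact score tie keeps the lexicographically smallest peptide
#' sequence, with a warning.
#'
#' @param records a record DataFrame.
#' @return records with one row per \code{feature_id}.
#' @export
deduplicateFeatures <- function(records) {
    if (nrow(records) == 0L) return(records)
    grp <- split(seq_len(nrow(records)), records$feature_id)
    pick <- vapply(grp, function(idx) {
        if (length(idx) == 1L) return(idx)
        sc <- records$score[idx]
        idx <- idx[sc == max(sc)]
        if (length(idx) > 1L) {
            warning("score tie within feature '",
                    records$feature_id[idx[1]],
                    "'; keeping lexicographically smallest sequence",
                    call. = FALSE)
            idx <- idx[order(records$sequence[idx])]
        }
        idx[1]
    }, 1L)
    records[sort(pick), , drop = FALSE]
}

## Positions (1-based, peptide-local) of cysteines lacking a
## carbamidomethyl modification — i.e. previously oxidised Cys sites.
.oxidisedCysOffsets <- function(sequence, modifications) {
    cys <- which(strsplit(sequence, "")[[1]] == "C")
    if (length(cys) == 0L) return(integer())
    m <- .parseMods(modifications)
    cam <- m$pos[grepl("carbamidomethyl", m$name, ignore.case = TRUE)]
    setdiff(cys, cam)
}

#' Keep peptides with at least one reversibly oxidised cysteine
#'
#' In the Cys-oxidation (PTM) workflow, reduced cysteines are alkylated
#' (carbamidomethylated) before enrichment, so a cysteine \emph{without}
#' carbamidomethylation marks a site of reversible oxidation. Retains
#' records whose sequence has at least one such cysteine; peptides without
#' cysteine, or with every cysteine alkylated, are removed.
#'
#' @param records a record DataFrame.
#' @return the filtered records.
#' @export
ptmFilterOxidized <- function(records) {
    if (nrow(records) == 0L) return(records)
    keep <- vapply(seq_len(nrow(records)), function(i)
        length(.oxidisedCysOffsets(records$sequence[i],
                                   records$modifications[i])) > 0L,
        NA)
    records[keep, , drop = FALSE]
}

#' Collapse records to unique identifiers
#'
#' Builds per-feature identifiers — accession + peptide sequence in global
#' mode, accession + Cys-oxidation site(s) in PTM mode — bins duplicate
#' identifiers (charge states, missed cleavages, additional variable
#' modifications) and sums the abundances of all contributing records per
#' sample. A cell is missing only when \emph{all} contributors are missing
#' in that sample; otherwise missing contributors are treated as absent
#' (not zero-imputed rows). Each identifier is represented by its
#' highest-scoring contributing record.
#'
#' In PTM mode Cys sites are placed on protein coordinates
#' (\code{start + offset - 1}) when the export carried a peptide start
#' column; otherwise peptide-local offsets are used and
#' \code{metadata()$localCysCoords} is set.
#'
#' @param records a record DataFrame (after filtering).
#' @param condition per-sample condition labels, one per abundance column.
#' @param mode \code{"global"} or \code{"ptm"}.
#' @return A \linkS4class{PeptideFeatureSet} on the raw abundance scale with
#'   rowData columns \code{accession}, \code{sequence}, \code{score},
#'   \code{n_contributors}.
#' @export
buildIdentifiers <- function(records, condition, mode = c("global", "ptm")) {
    mode <- match.arg(mode)
    if (nrow(records) == 0L)
        stop("no records left to build identifiers from")
    if (mode == "global") {
        ids <- paste(records$accession, records$sequence, sep = "_")
        localCoords <- FALSE
    } else {
        haveStart <- is.finite(records$start)
        localCoords <- !any(haveStart)
        ids <- vapply(seq_len(nrow(records)), function(i) {
            off <- .oxidisedCysOffsets(records$sequence[i],
                                       records$modifications[i])
            if (length(off) == 0L)
                stop("record ", i, " has no oxidised Cys site; ",
                     "run ptmFilterOxidized() first")
            site <- if (is.finite(records$start[i]))
                records$start[i] + off - 1L else off
            paste0(records$accession[i], "_",
                   paste0("C", site, collapse = "."))
        }, "")
    }
    uids <- unique(ids)
    ab <- records$abundance
    nS <- ncol(ab)
    mat <- matrix(NA_real_, length(uids), nS,
                  dimnames = list(uids, colnames(ab)))
    rep_idx <- integer(length(uids))
    ncontrib <- integer(length(uids))
    grp <- split(seq_len(nrow(records)), factor(ids, levels = uids))
    for (g in seq_along(grp)) {
        idx <- grp[[g]]
        sub <- ab[idx, , drop = FALSE]
        anyObs <- colSums(!is.na(sub)) > 0L
        s <- colSums(sub, na.rm = TRUE)
        s[!anyObs] <- NA_real_
        mat[g, ] <- s
        rep_idx[g] <- idx[which.max(records$score[idx])]
        ncontrib[g] <- length(idx)
    }
    rd <- DataFrame(accession = records$accession[rep_idx],
                    sequence = records$sequence[rep_idx],
                    modifications = records$modifications[rep_idx],
                    score = records$score[rep_idx],
                    n_contributors = ncontrib)
    out <- PeptideFeatureSet(mat, condition = condition, rowData = rd,
                             mode = mode, logScale = FALSE)
    metadata(out)$localCysCoords <- if (mode == "ptm") localCoords else FALSE
    out
}

#' Read a two-column sample-to-condition design TSV
#'
#' @param path TSV with columns \code{sample} and \code{condition} (no
#'   header required if exactly two columns; a header line with these names
#'   is also accepted).
#' @return named character vector, sample -> condition.
#' @export
readDesign <- function(path) {
    d <- utils::read.delim(path, header = FALSE, colClasses = "character")
    if (ncol(d) != 2L)
        stop("design file must have exactly two columns: sample, condition")
    if (identical(tolower(unlist(d[1, ])), c("sample", "condition")))
        d <- d[-1, , drop = FALSE]
    stats::setNames(d[[2]], d[[1]])
}

#' Write / read a feature table as TSV
#'
#' The on-disk form is a TSV with identifier and metadata columns followed
#' by one column per sample (empty string = missing), plus a two-column
#' sample/condition design file.
#'
#' @param x a \linkS4class{PeptideFeatureSet}.
#' @param path output TSV path.
#' @param designPath output design TSV path.
#' @export
writeFeatureTable <- function(x, path, designPath = NULL) {
    ab <- assay(x, "abundance")
    meta <- as.data.frame(rowData(x))
    out <- data.frame(identifier = rownames(x), meta,
                      as.data.frame(ab), check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    if (!is.null(designPath))
        utils::write.table(
            data.frame(sample = colnames(x),
                       condition = as.character(sampleConditions(x))),
            designPath, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @param design named sample -> condition vector (e.g. from
#'   [readDesign()]); its names select the sample columns of the TSV.
#' @param mode,logScale table flags, as in [PeptideFeatureSet()].
#' @export
readFeatureTable <- function(path, design, mode = "global",
                             logScale = FALSE) {
    d <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
    samples <- names(design)
    absent <- setdiff(samples, colnames(d))
    if (length(absent))
        stop("samples in design but not in table: ",
             paste(absent, collapse = ", "))
    ab <- as.matrix(d[, samples, drop = FALSE])
    ab[!nzchar(ab)] <- NA
    ab <- array(as.numeric(ab), dim(ab),
                dimnames = list(d$identifier, samples))
    metaCols <- setdiff(colnames(d), c("identifier", samples))
    rd <- if (length(metaCols)) d[, metaCols, drop = FALSE] else NULL
    if (!is.null(rd) && "score" %in% colnames(rd))
        rd$score <- as.numeric(rd$score)
    PeptideFeatureSet(ab, condition = unname(design[samples]),
                      rowData = rd, mode = mode, logScale = logScale)
}

#' Run the full pre-processing chain on an export file
#'
#' Convenience wrapper: read, score/contaminant filter, parsimony
#' resolution, feature deduplication, (PTM mode only) oxidised-Cys filter,
#' identifier construction.
#'
#' @inheritParams readPeptideMeasurements
#' @inheritParams buildIdentifiers
#' @inheritParams filterScoreAndContaminants
#' @return A \linkS4class{PeptideFeatureSet}.
#' @export
preprocessPeptides <- function(path, dialect, condition,
                               mode = c("global", "ptm"), minScore = 13,
                               contaminants = c("CONTAM_", "sp|CON")) {
    mode <- match.arg(mode)
    rec <- readPeptideMeasurements(path, dialect)
    rec <- filterScoreAndContaminants(rec, minScore, contaminants)
    rec <- resolveSharedAccessions(rec)
    rec <- deduplicateFeatures(rec)
    if (mode == "ptm") rec <- ptmFilterOxidized(rec)
    buildIdentifiers(rec, condition = condition, mode = mode)
}
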