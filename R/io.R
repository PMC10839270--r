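## Readers/writers for feature tables, sample metadata and subject tables.
## Dialect: UTF-8 CSV/TSV (by extension), one header row, empty cell = missing.
## Zero is a measured intensity, distinct from missing.

.featureMetaCols <- c("feature_id", "polarity", "mz", "rt", "adduct")
.sampleMetaCols <- c("sample_id", "subject_id", "location", "time",
                     "sample_type", "run_order")
.optionalFeatureCols <- c("metabolite", "id_level", "id_score")

.sepFor <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

.readDelim <- function(path) {
    utils::read.table(path, header = TRUE, sep = .sepFor(path),
                      na.strings = "", check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\"",
                      fileEncoding = "UTF-8", colClasses = NA)
}

#' Read a feature table and its sample metadata
#'
#' The feature table file carries the feature-metadata columns `feature_id`,
#' `polarity`, `mz`, `rt`, `adduct` (optionally `metabolite`, `id_level`,
#' `id_score`) followed by one column per sample; the metadata file maps
#' `sample_id` to `subject_id`, `location`, `time`, `sample_type` and
#' `run_order`. Empty cells are missing values; identifiers are
#' whitespace-trimmed on read.
#'
#' @param path feature table CSV/TSV path.
#' @param metaPath sample metadata CSV/TSV path.
#' @return a validated [FeatureTable-class].
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(path, metaPath) {
    tab <- .readDelim(path)
    meta <- .readDelim(metaPath)
    missm <- setdiff(.sampleMetaCols, colnames(meta))
    if (length(missm))
        stop("sample metadata lacks column(s): ", paste(missm, collapse = ", "))
    meta$sample_id <- trimws(as.character(meta$sample_id))
    missf <- setdiff(.featureMetaCols, colnames(tab))
    if (length(missf))
        stop("feature table lacks column(s): ", paste(missf, collapse = ", "))
    featCols <- intersect(c(.featureMetaCols, .optionalFeatureCols), colnames(tab))
    sampleCols <- setdiff(colnames(tab), featCols)
    unknown <- setdiff(trimws(sampleCols), meta$sample_id)
    if (length(unknown))
        stop("feature table has sample column(s) absent from metadata: ",
             paste(unknown, collapse = ", "))
    fd <- tab[, featCols, drop = FALSE]
    meta <- meta[match(trimws(sampleCols), meta$sample_id), , drop = FALSE]
    x <- as.matrix(tab[, sampleCols, drop = FALSE])
    if (!is.numeric(x)) {
        num <- matrix(suppressWarnings(as.numeric(x)), nrow(x), ncol(x),
                      dimnames = dimnames(x))
        bad <- which(is.na(num) & !is.na(x), arr.ind = TRUE)
        if (nrow(bad))
            stop(sprintf("non-numeric intensity at row %d, column '%s'",
                         bad[1L, 1L], sampleCols[bad[1L, 2L]]))
        x <- num
    }
    neg <- which(x < 0, arr.ind = TRUE)
    if (nrow(neg))
        stop(sprintf("negative intensity at feature '%s', sample '%s'",
                     trimws(as.character(fd$feature_id))[neg[1L, 1L]],
                     sampleCols[neg[1L, 2L]]))
    FeatureTable(x, fd, meta)
}

#' Write a feature table (and optionally its sample metadata)
#'
#' Inverse of [readFeatureTable()]: numeric text preserves at least 6
#' significant digits and missing cells are serialized as empty strings.
#'
#' @param table a [FeatureTable-class].
#' @param path output CSV/TSV path for the intensity table.
#' @param metaPath optional output path for the sample metadata.
#' @return invisibly, `path`.
#' @export
writeFeatureTable <- function(table, path, metaPath = NULL) {
    stopifnot(is(table, "FeatureTable"))
    fd <- as.data.frame(rowData(table))
    fd <- fd[, intersect(c(.featureMetaCols, .optionalFeatureCols),
                         colnames(fd)), drop = FALSE]
    out <- cbind(fd, as.data.frame(intensities(table), check.names = FALSE))
    utils::write.table(out, path, sep = .sepFor(path), row.names = FALSE,
                       quote = FALSE, na = "", fileEncoding = "UTF-8")
    if (!is.null(metaPath)) {
        cd <- as.data.frame(colData(table))[, .sampleMetaCols, drop = FALSE]
        utils::write.table(cd, metaPath, sep = .sepFor(metaPath),
                           row.names = FALSE, quote = FALSE, na = "",
                           fileEncoding = "UTF-8")
    }
    invisible(path)
}

#' Read a subject (cohort) table
#'
#' Expects columns `subject_id`, `sex` (Ma/Fe), `age` (years) and `sleep`
#' (hours the night before sampling); the literal string `"NA"` or an empty
#' cell marks missing sleep.
#'
#' @param path CSV/TSV path.
#' @return data.frame with one row per subject.
#' @export
readSubjectTable <- function(path) {
    tab <- .readDelim(path)
    need <- c("subject_id", "sex", "age", "sleep")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("subject table lacks column(s): ", paste(miss, collapse = ", "))
    if (!nrow(tab))
        return(data.frame(subject_id = character(), sex = character(),
                          age = integer(), sleep = numeric()))
    tab$subject_id <- trimws(as.character(tab$subject_id))
    tab$sex <- trimws(as.character(tab$sex))
    age <- suppressWarnings(as.integer(tab$age))
    if (any(is.na(age) & !is.na(tab$age)))
        stop(sprintf("unparseable age '%s' for subject '%s'",
                     tab$age[which(is.na(age) & !is.na(tab$age))[1L]],
                     tab$subject_id[which(is.na(age) & !is.na(tab$age))[1L]]))
    sleepChr <- trimws(as.character(tab$sleep))
    sleepChr[sleepChr %in% c("NA", "")] <- NA
    sleep <- suppressWarnings(as.numeric(sleepChr))
    if (any(is.na(sleep) & !is.na(sleepChr)))
        stop(sprintf("unparseable sleep '%s' for subject '%s'",
                     sleepChr[which(is.na(sleep) & !is.na(sleepChr))[1L]],
                     tab$subject_id[which(is.na(sleep) & !is.na(sleepChr))[1L]]))
    if (any(!tab$sex %in% c("Ma", "Fe")))
        stop("sex must be 'Ma' or 'Fe'")
    if (any(age <= 0, na.rm = TRUE)) stop("age must be positive")
    if (any(sleep <= 0 | sleep >= 24, na.rm = TRUE))
        stop("sleep must be in (0, 24) hours")
    data.frame(subject_id = tab$subject_id, sex = tab$sex,
               age = age, sleep = sleep)
}

#' Read a pipeline configuration
#'
#' YAML with one block per stage (`simulate`, `library`, `identify`,
#' `curate`, `stats`, `plsda`) plus `io` paths and a top-level `seed`.
#'
#' @param path YAML path.
#' @return named list of stage blocks.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$seed)) cfg$seed <- 1L
    cfg
}
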