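## Consensus spectral-library construction from replicate injections of
## authentic standards, and NIST-style MSP import/export.

#' Retention-time statistics of replicate detections
#'
#' @param rts numeric vector of retention times in minutes (nonempty).
#' @return named numeric vector: `rt_mean` (arithmetic mean) and `rt_dev`
#'   (RTmax - RTmin).
#' @examples
#' computeRtStats(c(5.0, 5.1, 4.9))  # mean 5.0, dev 0.2
#' @export
computeRtStats <- function(rts) {
    if (!length(rts)) stop("empty retention-time list")
    c(rt_mean = mean(rts), rt_dev = max(rts) - min(rts))
}

#' Build a consensus MS/MS spectrum from replicate acquisitions
#'
#' Fragments are kept only when matchable across ALL replicates within
#' `mzTol`: pooled peaks are sorted by m/z and grouped where consecutive
#' peaks are within tolerance; a group survives if every replicate
#' contributes at least one peak (the most intense peak per replicate is
#' used when a replicate contributes several). Consensus m/z and intensity
#' are the means over the matched peaks, then intensities are rescaled so the
#' base peak is 100%. Grouping is order-independent: permuting the replicates
#' yields the same consensus, and adding a replicate can only shrink it.
#'
#' @param replicates list of [MsmsSpectrum-class], same polarity.
#' @param mzTol fragment matching tolerance in Da.
#' @return two-column matrix (`mz`, `relint`) sorted by m/z; zero rows when no
#'   fragment is common to all replicates.
#' @export
buildConsensusSpectrum <- function(replicates, mzTol = 0.025) {
    if (!length(replicates)) stop("empty replicate set")
    pol <- unique(vapply(replicates, function(s) s@polarity, character(1)))
    if (length(pol) > 1L) stop("replicates mix polarities: ",
                               paste(pol, collapse = ", "))
    nRep <- length(replicates)
    pooled <- do.call(rbind, lapply(seq_len(nRep), function(i) {
        p <- replicates[[i]]@peaks
        if (!nrow(p)) return(NULL)
        cbind(p, rep = i)
    }))
    if (is.null(pooled) || !nrow(pooled)) return(.emptyConsensus())
    pooled <- pooled[order(pooled[, 1L]), , drop = FALSE]
    grp <- cumsum(c(1, diff(pooled[, 1L]) > mzTol))
    keep <- lapply(split(seq_len(nrow(pooled)), grp), function(idx) {
        sub <- pooled[idx, , drop = FALSE]
        if (length(unique(sub[, 3L])) < nRep) return(NULL)
        ## one peak per replicate: the most intense
        picked <- do.call(rbind, lapply(split(seq_len(nrow(sub)), sub[, 3L]),
                                        function(k) {
            s <- sub[k, , drop = FALSE]
            s[which.max(s[, 2L]), , drop = FALSE]
        }))
        c(mz = mean(picked[, 1L]), intensity = mean(picked[, 2L]))
    })
    keep <- do.call(rbind, keep)
    if (is.null(keep) || !nrow(keep)) return(.emptyConsensus())
    cons <- cbind(mz = keep[, 1L], relint = keep[, 2L] / max(keep[, 2L]) * 100)
    cons[order(cons[, 1L]), , drop = FALSE]
}

.emptyConsensus <- function() {
    matrix(numeric(), 0, 2, dimnames = list(NULL, c("mz", "relint")))
}

#' StandardRejection: a standard that failed the annotation rule
#'
#' @slot name standard label.
#' @slot reason short machine-readable reason (e.g. "incomplete detection").
#' @export
setClass("StandardRejection",
         representation(name = "character", reason = "character"))

setMethod("show", "StandardRejection", function(object) {
    cat(sprintf("StandardRejection: '%s' (%s)\n", object@name, object@reason))
    invisible(NULL)
})

#' Annotate one authentic standard from its replicate acquisitions
#'
#' A standard is accepted only when its precursor is detected in all
#' replicates of at least `minConcLevels` concentration levels (default: all
#' of them, i.e. the full 3 x 3 grid). RT statistics pool all accepted
#' replicates (n up to 9); the consensus spectrum uses only the
#' top-concentration replicates. A non-increasing intensity-vs-concentration
#' trend (Spearman rho <= 0 of total ion intensity against concentration)
#' flags — but does not reject — the entry as a possible system peak.
#'
#' @param name standard label.
#' @param exactMass neutral monoisotopic mass, Da.
#' @param polarity "pos" or "neg".
#' @param spectra list of [MsmsSpectrum-class]; a missing (concentration,
#'   replicate) cell means the precursor was not detected there.
#' @param adducts adduct labels to record for the entry.
#' @param concentrations expected working concentrations (ascending).
#' @param replicates expected replicates per concentration.
#' @param minConcLevels number of concentration levels that must be fully
#'   detected; `NULL` means all.
#' @param mzTol consensus fragment matching tolerance, Da.
#' @param inchikey optional InChIKey.
#' @return a [LibraryEntry-class], or a [StandardRejection-class].
#' @export
annotateStandard <- function(name, exactMass, polarity, spectra,
                             adducts = if (polarity == "pos") "[M+H]+" else "[M-H]-",
                             concentrations = c(0.25, 0.5, 1),
                             replicates = 3L, minConcLevels = NULL,
                             mzTol = 0.025, inchikey = NA_character_) {
    if (is.null(minConcLevels)) minConcLevels <- length(concentrations)
    concOf <- vapply(spectra, function(s) s@concentration, numeric(1))
    repOf <- vapply(spectra, function(s) s@replicate, integer(1))
    complete <- vapply(concentrations, function(cc) {
        all(seq_len(replicates) %in% repOf[concOf == cc])
    }, logical(1))
    if (sum(complete) < minConcLevels)
        return(new("StandardRejection", name = name,
                   reason = "incomplete detection"))
    rts <- vapply(spectra, function(s) s@rt, numeric(1))
    st <- computeRtStats(rts)
    top <- max(concentrations)
    cons <- buildConsensusSpectrum(spectra[concOf == top], mzTol = mzTol)
    notes <- character()
    tic <- vapply(spectra, function(s) sum(s@peaks[, 2L]), numeric(1))
    if (length(unique(concOf)) > 1L) {
        trend <- suppressWarnings(stats::cor(tic, concOf, method = "spearman"))
        if (is.na(trend) || trend <= 0)  # NA = perfectly flat response
            notes <- c(notes, "possible system peak")
    }
    LibraryEntry(name = name, exactMass = exactMass, polarity = polarity,
                 adducts = adducts, rtMean = unname(st["rt_mean"]),
                 rtDev = unname(st["rt_dev"]), consensus = cons,
                 inchikey = inchikey, qcNotes = notes)
}

#' Build a consensus library from simulated (or imported) standard runs
#'
#' @param standards list of ground truths as taken by [generateStandardRuns()].
#' @param runs named list of spectra per standard (e.g. the output of
#'   [generateStandardRuns()]).
#' @param ... passed to [annotateStandard()].
#' @return list with elements `entries` (list of [LibraryEntry-class]) and
#'   `rejections` (list of [StandardRejection-class]).
#' @export
buildLibrary <- function(standards, runs, ...) {
    entries <- list(); rejections <- list()
    for (std in standards) {
        res <- annotateStandard(std$name, std$exactMass, std$polarity,
                                runs[[std$name]], ...)
        if (is(res, "LibraryEntry")) entries[[std$name]] <- res
        else rejections[[std$name]] <- res
    }
    list(entries = unname(entries), rejections = unname(rejections))
}

#' Write a spectral library as NIST-style MSP
#'
#' One record per entry: `Name`, `PRECURSORMZ` (exact mass under the first
#' adduct), `PRECURSORTYPE`, `IONMODE`, `RETENTIONTIME`, a `Comment` line with
#' `RTDEV=`, `EXACTMASS=`, `ADDUCTS=` (and `INCHIKEY=`, `QCNOTES=` when
#' present) key=value pairs, `Num Peaks`, then one `mz intensity` line per
#' consensus fragment. [readMsp()] restores the entries.
#'
#' @param entries list of [LibraryEntry-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeMsp <- function(entries, path) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (e in entries) {
        comment <- sprintf("RTDEV=%.8g EXACTMASS=%.8g ADDUCTS=%s",
                           e@rtDev, e@exactMass,
                           paste(e@adducts, collapse = "|"))
        if (!is.na(e@inchikey))
            comment <- paste0(comment, " INCHIKEY=", e@inchikey)
        if (length(e@qcNotes))
            comment <- paste0(comment, " QCNOTES=",
                              paste(gsub(" ", "_", e@qcNotes), collapse = "|"))
        writeLines(c(
            paste0("Name: ", e@name),
            sprintf("PRECURSORMZ: %.8g", adductMz(e@exactMass, e@adducts[1L])),
            paste0("PRECURSORTYPE: ", e@adducts[1L]),
            paste0("IONMODE: ", if (e@polarity == "pos") "Positive" else "Negative"),
            sprintf("RETENTIONTIME: %.8g", e@rtMean),
            paste0("Comment: ", comment),
            sprintf("Num Peaks: %d", nrow(e@consensus))), con)
        if (nrow(e@consensus))
            writeLines(sprintf("%.8g %.8g", e@consensus[, 1L],
                               e@consensus[, 2L]), con)
        writeLines("", con)
    }
    invisible(path)
}

.parseComment <- function(s) {
    toks <- strsplit(s, " +")[[1]]
    kv <- toks[grepl("=", toks, fixed = TRUE)]
    parts <- strsplit(kv, "=", fixed = TRUE)
    stats::setNames(vapply(parts, function(p) paste(p[-1L], collapse = "="),
                           character(1)),
                    vapply(parts, `[[`, character(1), 1L))
}

#' Read a NIST-style MSP spectral library
#'
#' @param path MSP path written by [writeMsp()] (or compatible).
#' @return list of [LibraryEntry-class].
#' @export
readMsp <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    entries <- list()
    i <- 1L; recIdx <- 0L
    n <- length(lines)
    while (i <= n) {
        if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
        recIdx <- recIdx + 1L
        fields <- list(); peaks <- NULL
        while (i <= n && nzchar(trimws(lines[i]))) {
            line <- lines[i]
            m <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
            if (length(m) != 3L)
                stop(sprintf("malformed MSP line in record %d: '%s'", recIdx, line))
            key <- toupper(trimws(m[2]))
            val <- trimws(m[3])
            fields[[key]] <- val
            i <- i + 1L
            if (key == "NUM PEAKS") {
                np <- suppressWarnings(as.integer(val))
                if (is.na(np))
                    stop(sprintf("malformed 'Num Peaks' in record %d", recIdx))
                if (np > 0) {
                    if (i + np - 1L > n)
                        stop(sprintf("record %d truncated: expected %d peak lines",
                                     recIdx, np))
                    pk <- do.call(rbind, lapply(lines[i:(i + np - 1L)], function(l) {
                        v <- suppressWarnings(as.numeric(strsplit(trimws(l),
                                                                  "[ \t]+")[[1]]))
                        if (length(v) < 2L || anyNA(v[1:2]))
                            stop(sprintf("malformed peak line in record %d: '%s'",
                                         recIdx, l))
                        v[1:2]
                    }))
                    peaks <- pk
                    i <- i + np
                }
                break
            }
        }
        if (is.null(fields$NAME))
            stop(sprintf("record %d lacks a Name field", recIdx))
        cm <- if (is.null(fields$COMMENT)) character() else .parseComment(fields$COMMENT)
        polarity <- if (!is.null(fields$IONMODE) &&
                        grepl("^n", fields$IONMODE, ignore.case = TRUE)) "neg" else "pos"
        adducts <- if ("ADDUCTS" %in% names(cm))
            strsplit(cm[["ADDUCTS"]], "|", fixed = TRUE)[[1]]
        else if (!is.null(fields$PRECURSORTYPE)) fields$PRECURSORTYPE
        else if (polarity == "pos") "[M+H]+" else "[M-H]-"
        exactMass <- if ("EXACTMASS" %in% names(cm)) as.numeric(cm[["EXACTMASS"]])
                     else neutralMass(as.numeric(fields$PRECURSORMZ), adducts[1L])
        cons <- if (is.null(peaks)) .emptyConsensus() else {
            colnames(peaks) <- c("mz", "relint")
            if (max(peaks[, 2L]) != 100)  # normalize foreign libraries
                peaks[, 2L] <- peaks[, 2L] / max(peaks[, 2L]) * 100
            peaks[order(peaks[, 1L]), , drop = FALSE]
        }
        entries[[length(entries) + 1L]] <- LibraryEntry(
            name = fields$NAME, exactMass = exactMass, polarity = polarity,
            adducts = adducts,
            rtMean = as.numeric(fields$RETENTIONTIME),
            rtDev = if ("RTDEV" %in% names(cm)) as.numeric(cm[["RTDEV"]]) else 0,
            consensus = cons,
            inchikey = if ("INCHIKEY" %in% names(cm)) cm[["INCHIKEY"]]
                       else NA_character_,
            qcNotes = if ("QCNOTES" %in% names(cm))
                gsub("_", " ", strsplit(cm[["QCNOTES"]], "|", fixed = TRUE)[[1]])
            else character())
    }
    entries
}
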