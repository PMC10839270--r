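## Feature identification against the consensus library: exact mass + RT
## (MSI level 3) plus MS/MS similarity (level 1). Defaults follow common
## semi-targeted processing settings: mass tolerance 0.01 Da, RT tolerance
## 0.3 min, MS2 tolerance 0.05 Da, similarity cutoff 70%.

#' Square-root-weighted cosine similarity of two MS/MS spectra
#'
#' Fragments are matched greedily by nearest m/z within `mzTol`; the score is
#' the cosine of the square-root-scaled intensity vectors over the union of
#' fragments (unmatched fragments contribute zero), scaled to [0, 100].
#' Symmetric in its arguments.
#'
#' @param query,reference two-column (mz, intensity) matrices, nonempty.
#' @param mzTol fragment matching tolerance in Da.
#' @return similarity in [0, 100].
#' @examples
#' a <- cbind(mz = c(100, 200), intensity = c(100, 100))
#' spectralSimilarity(a, a)                      # 100
#' spectralSimilarity(cbind(100, 100), a)        # 70.7
#' @export
spectralSimilarity <- function(query, reference, mzTol = 0.05) {
    query <- as.matrix(query); reference <- as.matrix(reference)
    if (!nrow(query) || !nrow(reference)) stop("empty spectrum")
    q <- sqrt(query[, 2L]); r <- sqrt(reference[, 2L])
    ## greedy nearest-m/z matching: best (smallest |dmz|) pairs first
    cand <- which(abs(outer(query[, 1L], reference[, 1L], "-")) <= mzTol,
                  arr.ind = TRUE)
    dot <- 0
    if (nrow(cand)) {
        d <- abs(query[cand[, 1L], 1L] - reference[cand[, 2L], 1L])
        cand <- cand[order(d), , drop = FALSE]
        usedQ <- logical(nrow(query)); usedR <- logical(nrow(reference))
        for (k in seq_len(nrow(cand))) {
            i <- cand[k, 1L]; j <- cand[k, 2L]
            if (usedQ[i] || usedR[j]) next
            usedQ[i] <- TRUE; usedR[j] <- TRUE
            dot <- dot + q[i] * r[j]
        }
    }
    unname(100 * dot / (sqrt(sum(q^2)) * sqrt(sum(r^2))))
}

#' Match one feature against the spectral library
#'
#' Candidates are library entries of the same polarity whose exact mass is
#' within `massTol` of the feature's adduct-corrected neutral mass and whose
#' RT mean is within `rtTol` of the feature RT. With a usable query MS/MS
#' spectrum and a best candidate scoring at least `scoreCutoff`, the match is
#' MSI level 1 (chosen by score, ties by smaller |mass error|, then smaller
#' |RT error|); otherwise mass+RT alone give level 3 (chosen by smallest
#' |mass error|, ties by smaller |RT error|).
#'
#' @param mz feature m/z, Da.
#' @param rt feature RT, minutes.
#' @param polarity "pos" or "neg".
#' @param adduct declared adduct label (used to compute the neutral mass).
#' @param library list of [LibraryEntry-class].
#' @param ms2 optional two-column (mz, intensity) query spectrum.
#' @param massTol mass tolerance in Da.
#' @param rtTol RT tolerance in minutes.
#' @param ms2Tol MS2 fragment tolerance in Da.
#' @param scoreCutoff similarity cutoff in percent for level 1.
#' @return an [Identification-class], or `NULL` when nothing matches.
#' @export
matchFeature <- function(mz, rt, polarity, adduct, library, ms2 = NULL,
                         massTol = 0.01, rtTol = 0.3, ms2Tol = 0.05,
                         scoreCutoff = 70) {
    stopifnot(massTol > 0, rtTol > 0)
    neutral <- neutralMass(mz, adduct)
    cand <- Filter(function(e) {
        e@polarity == polarity &&
            abs(neutral - e@exactMass) <= massTol &&
            abs(rt - e@rtMean) <= rtTol
    }, library)
    if (!length(cand)) return(NULL)
    massErr <- vapply(cand, function(e) neutral - e@exactMass, numeric(1))
    rtErr <- vapply(cand, function(e) rt - e@rtMean, numeric(1))
    if (!is.null(ms2) && nrow(as.matrix(ms2))) {
        scores <- vapply(cand, function(e) {
            if (!nrow(e@consensus)) return(NA_real_)
            spectralSimilarity(ms2, e@consensus, mzTol = ms2Tol)
        }, numeric(1))
        ok <- which(!is.na(scores) & scores >= scoreCutoff)
        if (length(ok)) {
            ord <- ok[order(-scores[ok], abs(massErr[ok]), abs(rtErr[ok]))]
            b <- ord[1L]
            return(Identification(cand[[b]]@name, 1L, score = scores[b],
                                  massError = massErr[b], rtError = rtErr[b]))
        }
    }
    ord <- order(abs(massErr), abs(rtErr))
    b <- ord[1L]
    Identification(cand[[b]]@name, 3L, massError = massErr[b],
                   rtError = rtErr[b])
}

#' Identify all features of a table against the library
#'
#' Annotates `rowData()` with `metabolite`, `id_level` and `id_score`
#' (`NA` where no library entry matches).
#'
#' @param table a [FeatureTable-class].
#' @param library list of [LibraryEntry-class].
#' @param ms2Spectra optional named list (by feature_id) of query MS/MS
#'   spectra (two-column mz/intensity matrices).
#' @param ... tolerances passed to [matchFeature()].
#' @return the annotated [FeatureTable-class].
#' @export
identifyFeatures <- function(table, library, ms2Spectra = list(), ...) {
    rd <- rowData(table)
    met <- rep(NA_character_, nrow(table))
    lev <- rep(NA_integer_, nrow(table))
    sco <- rep(NA_real_, nrow(table))
    for (i in seq_len(nrow(table))) {
        id <- matchFeature(rd$mz[i], rd$rt[i], rd$polarity[i], rd$adduct[i],
                           library, ms2 = ms2Spectra[[rd$feature_id[i]]], ...)
        if (!is.null(id)) {
            met[i] <- id@metabolite
            lev[i] <- id@level
            sco[i] <- id@score
        }
    }
    rowData(table)$metabolite <- met
    rowData(table)$id_level <- lev
    rowData(table)$id_score <- sco
    validObject(table)
    table
}
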