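#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData rowData<- colData colData<-
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

#' Re-exported accessors
#'
#' `rowData()` and `colData()` from SummarizedExperiment, so feature and
#' sample metadata of a [FeatureTable-class] are reachable without attaching
#' that package.
#' @name reexports
#' @aliases rowData colData
#' @param ... passed through.
#' @return see [SummarizedExperiment::rowData()].
NULL

#' @rdname reexports
#' @export
rowData <- SummarizedExperiment::rowData

#' @rdname reexports
#' @export
colData <- SummarizedExperiment::colData

#' FeatureTable: an LC-MS feature-by-sample intensity container
#'
#' A `FeatureTable` extends
#' [SummarizedExperiment::SummarizedExperiment] with one assay named
#' `"intensities"` (nonnegative, `NA` = missing, zero = a measured zero),
#' per-feature metadata in `rowData()` (`feature_id`, `polarity`, `mz`, `rt`,
#' `adduct`, and after identification `metabolite`, `id_level`, `id_score`)
#' and per-sample metadata in `colData()` (`sample_id`, `subject_id`,
#' `location` in AT/BT/CK, `time` in M/A/E, `sample_type` in
#' study/qc_pool/blank, `run_order`).
#'
#' Study samples must carry subject, location and time; blanks and QC pools
#' must not. Feature and sample identifiers are unique and case-sensitive.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

.LOCATIONS <- c("AT", "BT", "CK")
.TIMES <- c("M", "A", "E")
.SAMPLE_TYPES <- c("study", "qc_pool", "blank")
.POLARITIES <- c("pos", "neg")

.validFeatureTable <- function(object) {
    msg <- character()
    if (!"intensities" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensities' is required")
    x <- SummarizedExperiment::assay(object, "intensities")
    if (any(x < 0, na.rm = TRUE)) {
        bad <- which(x < 0, arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf("negative intensity at feature '%s', sample '%s'",
                              rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
    }
    rd <- rowData(object)
    need <- c("feature_id", "polarity", "mz", "rt", "adduct")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ", paste(miss, collapse = ", ")))
    cd <- colData(object)
    needc <- c("sample_id", "subject_id", "location", "time", "sample_type", "run_order")
    missc <- setdiff(needc, colnames(cd))
    if (length(missc))
        msg <- c(msg, paste0("colData lacks column(s): ", paste(missc, collapse = ", ")))
    if (!length(msg)) {
        if (anyDuplicated(rd$feature_id))
            msg <- c(msg, sprintf("duplicate feature_id '%s'",
                                  rd$feature_id[anyDuplicated(rd$feature_id)]))
        if (anyDuplicated(cd$sample_id))
            msg <- c(msg, sprintf("duplicate sample_id '%s'",
                                  cd$sample_id[anyDuplicated(cd$sample_id)]))
        if (!all(rd$polarity %in% .POLARITIES))
            msg <- c(msg, "polarity must be 'pos' or 'neg'")
        if (any(rd$mz <= 0, na.rm = TRUE))
            msg <- c(msg, "feature m/z must be positive")
        if (!all(cd$sample_type %in% .SAMPLE_TYPES))
            msg <- c(msg, "sample_type must be study, qc_pool or blank")
        st <- cd$sample_type == "study"
        if (any(st & (is.na(cd$subject_id) | is.na(cd$location) | is.na(cd$time))))
            msg <- c(msg, sprintf(
                "study sample '%s' lacks subject, location or time",
                cd$sample_id[which(st & (is.na(cd$subject_id) | is.na(cd$location) |
                                         is.na(cd$time)))[1L]]))
        if (any(!st & (!is.na(cd$location) | !is.na(cd$time))))
            msg <- c(msg, "blank/QC samples must not carry location or time")
        if (!all(cd$location[st] %in% .LOCATIONS))
            msg <- c(msg, "location must be one of AT, BT, CK")
        if (!all(cd$time[st] %in% .TIMES))
            msg <- c(msg, "time must be one of M, A, E")
    }
    if (length(msg)) msg else TRUE
}

setValidity("FeatureTable", .validFeatureTable)

#' Construct a FeatureTable
#'
#' @param intensities numeric matrix, features x samples; `NA` = missing.
#' @param featureData data.frame/DataFrame with columns `feature_id`,
#'   `polarity`, `mz`, `rt`, `adduct` (one row per feature).
#' @param sampleData data.frame/DataFrame with columns `sample_id`,
#'   `subject_id`, `location`, `time`, `sample_type`, `run_order`
#'   (one row per sample).
#' @return a validated [FeatureTable-class] object.
#' @examples
#' fd <- data.frame(feature_id = c("f1", "f2"), polarity = "pos",
#'                  mz = c(100.1, 200.2), rt = c(1.5, 2.5), adduct = "[M+H]+")
#' sd <- data.frame(sample_id = c("s1", "s2"), subject_id = c("A", "A"),
#'                  location = c("AT", "BT"), time = c("M", "M"),
#'                  sample_type = "study", run_order = 1:2)
#' ft <- FeatureTable(matrix(1:4, 2, 2), fd, sd)
#' @export
FeatureTable <- function(intensities, featureData, sampleData) {
    featureData <- S4Vectors::DataFrame(featureData)
    sampleData <- S4Vectors::DataFrame(sampleData)
    for (col in c("feature_id", "polarity", "adduct"))
        if (col %in% colnames(featureData))
            featureData[[col]] <- trimws(as.character(featureData[[col]]))
    for (col in c("sample_id", "subject_id", "location", "time", "sample_type"))
        if (col %in% colnames(sampleData))
            sampleData[[col]] <- trimws(as.character(sampleData[[col]]))
    intensities <- as.matrix(intensities)
    storage.mode(intensities) <- "double"
    if (nrow(intensities) != nrow(featureData))
        stop("intensity matrix has ", nrow(intensities),
             " rows but featureData describes ", nrow(featureData), " features")
    if (ncol(intensities) != nrow(sampleData))
        stop("intensity matrix has ", ncol(intensities),
             " columns but sampleData describes ", nrow(sampleData), " samples")
    rownames(intensities) <- featureData$feature_id
    colnames(intensities) <- sampleData$sample_id
    rownames(featureData) <- featureData$feature_id
    rownames(sampleData) <- sampleData$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensities = intensities),
        rowData = featureData, colData = sampleData)
    new("FeatureTable", se)
}

#' @describeIn FeatureTable intensity matrix accessor.
#' @param x a FeatureTable.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname FeatureTable
#' @export
setMethod("intensities", "FeatureTable",
          function(x) SummarizedExperiment::assay(x, "intensities"))

#' @describeIn FeatureTable feature identifiers.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname FeatureTable
#' @export
setMethod("featureIds", "FeatureTable", function(x) rowData(x)$feature_id)

#' @describeIn FeatureTable sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname FeatureTable
#' @export
setMethod("sampleIds", "FeatureTable", function(x) colData(x)$sample_id)

#' @describeIn FeatureTable sample types (study/qc_pool/blank).
#' @export
setGeneric("sampleType", function(x) standardGeneric("sampleType"))

#' @rdname FeatureTable
#' @export
setMethod("sampleType", "FeatureTable", function(x) colData(x)$sample_type)

#' Subset a FeatureTable to one sample type
#'
#' @param x a FeatureTable.
#' @param type one of "study", "qc_pool", "blank".
#' @return a FeatureTable containing only samples of that type.
#' @export
subsetByType <- function(x, type = c("study", "qc_pool", "blank")) {
    type <- match.arg(type)
    x[, sampleType(x) == type]
}

setMethod("show", "FeatureTable", function(object) {
    cd <- colData(object)
    cat(sprintf("FeatureTable: %d features x %d samples (%d study, %d QC pool, %d blank)\n",
                nrow(object), ncol(object), sum(cd$sample_type == "study"),
                sum(cd$sample_type == "qc_pool"), sum(cd$sample_type == "blank")))
    if ("metabolite" %in% colnames(rowData(object)))
        cat(sprintf("  annotated features: %d\n",
                    sum(!is.na(rowData(object)$metabolite))))
    pol <- table(factor(rowData(object)$polarity, levels = .POLARITIES))
    cat(sprintf("  polarity: %d pos / %d neg\n", pol[["pos"]], pol[["neg"]]))
    invisible(NULL)
})

#' MsmsSpectrum: one acquired MS/MS spectrum of an authentic standard
#'
#' @slot precursorMz precursor m/z in Da.
#' @slot rt retention time in minutes.
#' @slot polarity "pos" or "neg".
#' @slot peaks two-column matrix (`mz`, `intensity`), sorted by m/z,
#'   intensities nonnegative.
#' @slot concentration working concentration in ug/mL.
#' @slot replicate replicate index.
#' @export
setClass("MsmsSpectrum",
         representation(precursorMz = "numeric", rt = "numeric",
                        polarity = "character", peaks = "matrix",
                        concentration = "numeric", replicate = "integer"))

setValidity("MsmsSpectrum", function(object) {
    msg <- character()
    if (!object@polarity %in% .POLARITIES)
        msg <- c(msg, "polarity must be 'pos' or 'neg'")
    p <- object@peaks
    if (ncol(p) != 2L)
        msg <- c(msg, "peaks must be a two-column (mz, intensity) matrix")
    else {
        if (nrow(p) > 1L && is.unsorted(p[, 1L]))
            msg <- c(msg, "peaks must be sorted by m/z")
        if (any(p[, 2L] < 0))
            msg <- c(msg, "peak intensities must be nonnegative")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname MsmsSpectrum-class
#' @param precursorMz,rt,polarity,peaks,concentration,replicate see slots.
#' @export
MsmsSpectrum <- function(precursorMz, rt, polarity, peaks,
                         concentration = 1, replicate = 1L) {
    peaks <- as.matrix(peaks)
    colnames(peaks) <- c("mz", "intensity")
    peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
    new("MsmsSpectrum", precursorMz = precursorMz, rt = rt,
        polarity = polarity, peaks = peaks,
        concentration = concentration, replicate = as.integer(replicate))
}

#' LibraryEntry: one authentic standard in the consensus spectral library
#'
#' @slot name metabolite label.
#' @slot exactMass neutral monoisotopic mass in Da.
#' @slot polarity "pos" or "neg".
#' @slot adducts adduct labels observed for this standard.
#' @slot rtMean mean retention time over accepted replicates, minutes.
#' @slot rtDev retention-time deviation (RTmax - RTmin), minutes.
#' @slot consensus two-column matrix (`mz`, `relint`), relative intensity in
#'   percent with base peak at 100; may have zero rows.
#' @slot inchikey optional InChIKey.
#' @slot qcNotes character vector of QC flags (e.g. "possible system peak").
#' @export
setClass("LibraryEntry",
         representation(name = "character", exactMass = "numeric",
                        polarity = "character", adducts = "character",
                        rtMean = "numeric", rtDev = "numeric",
                        consensus = "matrix", inchikey = "character",
                        qcNotes = "character"))

setValidity("LibraryEntry", function(object) {
    msg <- character()
    if (object@rtDev < 0) msg <- c(msg, "rtDev must be >= 0")
    if (!object@polarity %in% .POLARITIES)
        msg <- c(msg, "polarity must be 'pos' or 'neg'")
    cons <- object@consensus
    if (nrow(cons)) {
        if (abs(max(cons[, 2L]) - 100) > 1e-6)
            msg <- c(msg, "nonempty consensus must have base peak at 100%")
        if (any(cons[, 2L] <= 0) || any(cons[, 2L] > 100 + 1e-9))
            msg <- c(msg, "relative intensities must be in (0, 100]")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname LibraryEntry-class
#' @param name,exactMass,polarity,adducts,rtMean,rtDev,consensus,inchikey,qcNotes
#'   see slots.
#' @export
LibraryEntry <- function(name, exactMass, polarity, adducts, rtMean, rtDev,
                         consensus = matrix(numeric(), 0, 2),
                         inchikey = NA_character_, qcNotes = character()) {
    consensus <- as.matrix(consensus)
    if (!nrow(consensus)) consensus <- matrix(numeric(), 0, 2)
    colnames(consensus) <- c("mz", "relint")
    new("LibraryEntry", name = name, exactMass = exactMass,
        polarity = polarity, adducts = adducts, rtMean = rtMean,
        rtDev = rtDev, consensus = consensus, inchikey = inchikey,
        qcNotes = qcNotes)
}

setMethod("show", "LibraryEntry", function(object) {
    cat(sprintf("LibraryEntry '%s' (%s): M = %.4f Da, RT %.2f +/- %.2f min, %d consensus fragments\n",
                object@name, object@polarity, object@exactMass,
                object@rtMean, object@rtDev, nrow(object@consensus)))
    if (length(object@qcNotes))
        cat("  QC: ", paste(object@qcNotes, collapse = "; "), "\n", sep = "")
    invisible(NULL)
})

#' Identification: a feature's metabolite assignment
#'
#' MSI confidence level 1 (exact mass + RT + MS/MS match against an authentic
#' standard) or level 3 (exact mass + RT only).
#'
#' @slot metabolite metabolite label.
#' @slot level integer, 1 or 3.
#' @slot score MS/MS similarity in [0, 100]; `NA` for level 3.
#' @slot massError signed mass error in Da (neutral mass - library exact mass).
#' @slot rtError signed RT error in minutes.
#' @export
setClass("Identification",
         representation(metabolite = "character", level = "integer",
                        score = "numeric", massError = "numeric",
                        rtError = "numeric"))

#' @rdname Identification-class
#' @param metabolite,level,score,massError,rtError see slots.
#' @export
Identification <- function(metabolite, level, score = NA_real_,
                           massError = NA_real_, rtError = NA_real_) {
    new("Identification", metabolite = metabolite, level = as.integer(level),
        score = score, massError = massError, rtError = rtError)
}

setMethod("show", "Identification", function(object) {
    cat(sprintf("Identification: %s (level %d%s), mass error %.4g Da, RT error %.3g min\n",
                object@metabolite, object@level,
                if (is.na(object@score)) "" else sprintf(", score %.1f", object@score),
                object@massError, object@rtError))
    invisible(NULL)
})

#' ProcessedMatrix: log10 + per-metabolite Z-scored intensities
#'
#' @slot values metabolites x samples matrix of Z scores.
#' @slot sampleInfo DataFrame of per-sample grouping labels
#'   (location, time, sex, subject_id).
#' @export
setClass("ProcessedMatrix",
         representation(values = "matrix", sampleInfo = "DataFrame"))

setValidity("ProcessedMatrix", function(object) {
    if (ncol(object@values) != nrow(object@sampleInfo))
        "values columns and sampleInfo rows differ" else TRUE
})

setMethod("show", "ProcessedMatrix", function(object) {
    cat(sprintf("ProcessedMatrix: %d metabolites x %d samples (log10, Z-scored)\n",
                nrow(object@values), ncol(object@values)))
    invisible(NULL)
})

#' CurationReport: per-stage accounting of feature-table curation
#'
#' @slot stages data.frame with columns `stage`, `input`, `removed`, `kept`.
#' @slot removed data.frame with columns `feature_id`, `stage`, `reason`.
#' @slot provenance data.frame recording adduct summation and polarity choices
#'   (columns `metabolite`, `polarity`, `detail`).
#' @export
setClass("CurationReport",
         representation(stages = "data.frame", removed = "data.frame",
                        provenance = "data.frame"))

setValidity("CurationReport", function(object) {
    s <- object@stages
    if (nrow(s) && any(s$input != s$removed + s$kept))
        "stage accounting violated: input != removed + kept" else TRUE
})

CurationReport <- function(stages = data.frame(stage = character(),
                                               input = integer(),
                                               removed = integer(),
                                               kept = integer()),
                           removed = data.frame(feature_id = character(),
                                                stage = character(),
                                                reason = character()),
                           provenance = data.frame(metabolite = character(),
                                                   polarity = character(),
                                                   detail = character())) {
    new("CurationReport", stages = stages, removed = removed,
        provenance = provenance)
}

setMethod("show", "CurationReport", function(object) {
    cat("CurationReport\n")
    if (nrow(object@stages)) {
        for (i in seq_len(nrow(object@stages)))
            cat(sprintf("  %-14s in %4d  removed %4d  kept %4d\n",
                        object@stages$stage[i], object@stages$input[i],
                        object@stages$removed[i], object@stages$kept[i]))
    } else cat("  (empty)\n")
    invisible(NULL)
})

#' @describeIn CurationReport chain two reports (stage outputs compose).
#' @param a,b CurationReport objects.
#' @export
chainReports <- function(a, b) {
    new("CurationReport",
        stages = rbind(a@stages, b@stages),
        removed = rbind(a@removed, b@removed),
        provenance = rbind(a@provenance, b@provenance))
}

#' PlsdaModel: a fitted PLS-DA model
#'
#' NIPALS PLS2 against a one-hot class response. VIP for variable j is
#' sqrt(p * sum_a(SSY_a * w_ja^2) / sum_a(SSY_a)) with unit-norm weight
#' columns, so the mean of VIP^2 over variables is 1.
#'
#' @slot scores samples x A score matrix T.
#' @slot weights variables x A weight matrix W (unit-norm columns).
#' @slot loadings variables x A X-loading matrix P.
#' @slot yLoadings classes x A Y-loading matrix Q.
#' @slot Y samples x classes one-hot response.
#' @slot classes class labels (column order of Y).
#' @slot ssy per-component explained sum of squares of Y.
#' @slot r2y cumulative fraction of Y variance explained on training data.
#' @slot q2 cross-validated predictive ability (1 - PRESS/SSY); NA until
#'   cross-validated.
#' @slot vip per-variable VIP scores.
#' @slot permutationP permutation-test p value; NA until tested.
#' @slot xMeans,yMeans column means removed before fitting.
#' @export
setClass("PlsdaModel",
         representation(scores = "matrix", weights = "matrix",
                        loadings = "matrix", yLoadings = "matrix",
                        Y = "matrix", classes = "character", ssy = "numeric",
                        r2y = "numeric", q2 = "numeric", vip = "numeric",
                        permutationP = "numeric", xMeans = "numeric",
                        yMeans = "numeric"))

setMethod("show", "PlsdaModel", function(object) {
    cat(sprintf("PlsdaModel: %d samples, %d variables, %d classes, %d components\n",
                nrow(object@scores), nrow(object@weights),
                length(object@classes), ncol(object@scores)))
    cat(sprintf("  R2Y = %.3f%s%s\n", object@r2y,
                if (is.na(object@q2)) "" else sprintf(", Q2 = %.3f", object@q2),
                if (is.na(object@permutationP)) ""
                else sprintf(", permutation p = %.4g", object@permutationP)))
    invisible(NULL)
})
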