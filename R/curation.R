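## Feature-table curation, applied in the reported processing order:
## blank filter, QC-pool RSD filter, adduct summation (within polarity),
## dual-polarity merge keeping the lower-RSD ion form. Every stage accounts
## for its removals (input = removed + kept).

#' Per-feature QC metrics
#'
#' For every feature: `blank_mean` over blank injections (missing treated as
#' 0), `rsd_pct` = 100 * sd / mean over QC-pool injections (sample sd, n-1;
#' undefined unless >= 2 QC injections with positive mean), and
#' `frac_below_blank`, the fraction of study samples whose intensity is
#' strictly below `blank_mean` (missing counts as below).
#'
#' @param table a [FeatureTable-class] containing study samples (required)
#'   and, for full metrics, blanks and QC pools.
#' @return data.frame with columns `feature_id`, `blank_mean`, `rsd_pct`,
#'   `frac_below_blank`.
#' @export
computeQcMetrics <- function(table) {
    x <- intensities(table)
    type <- sampleType(table)
    if (!any(type == "study")) stop("table contains no study samples")
    blanks <- x[, type == "blank", drop = FALSE]
    blanks[is.na(blanks)] <- 0
    blankMean <- if (ncol(blanks)) rowMeans(blanks) else rep(0, nrow(x))
    qc <- x[, type == "qc_pool", drop = FALSE]
    rsd <- rep(NA_real_, nrow(x))
    if (ncol(qc) >= 2L) {
        qm <- rowMeans(qc, na.rm = TRUE)
        qs <- apply(qc, 1L, stats::sd, na.rm = TRUE)
        ok <- !is.na(qm) & qm > 0 & !is.na(qs)
        rsd[ok] <- 100 * qs[ok] / qm[ok]
    }
    study <- x[, type == "study", drop = FALSE]
    below <- sweep(study, 1L, blankMean, "<")
    below[is.na(below)] <- TRUE  # missing counts as below blank
    data.frame(feature_id = featureIds(table),
               blank_mean = unname(blankMean),
               rsd_pct = rsd,
               frac_below_blank = unname(rowMeans(below)),
               stringsAsFactors = FALSE)
}

.stageReport <- function(stage, table, keep, reason) {
    removedIds <- featureIds(table)[!keep]
    if (length(reason) == 1L) reason <- rep(reason, nrow(table))
    CurationReport(
        stages = data.frame(stage = stage, input = nrow(table),
                            removed = sum(!keep), kept = sum(keep)),
        removed = data.frame(feature_id = removedIds,
                             stage = rep(stage, length(removedIds)),
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Blank filter
#'
#' Removes a feature when its study-sample signal falls below the mean blank
#' signal in more than `fracThreshold` of the study samples (strict
#' inequality: a fraction of exactly 0.66 is kept). Blank and QC-pool columns
#' are retained for later stages.
#'
#' @param table a [FeatureTable-class].
#' @param metrics output of [computeQcMetrics()] on this table.
#' @param fracThreshold fraction of study samples, default 0.66.
#' @return list with elements `table` and `report`.
#' @export
blankFilter <- function(table, metrics = computeQcMetrics(table),
                        fracThreshold = 0.66) {
    stopifnot(identical(metrics$feature_id, featureIds(table)))
    keep <- !(metrics$frac_below_blank > fracThreshold)
    rep_ <- .stageReport("blank_filter", table, keep,
                         sprintf("%.0f%% of study samples below blank mean",
                                 100 * metrics$frac_below_blank))
    list(table = table[keep, ], report = rep_)
}

#' QC-pool RSD filter
#'
#' Removes a feature when its QC-pool RSD exceeds `maxRsd` percent (strict:
#' exactly 30% is kept). A feature whose RSD is undefined (fewer than two QC
#' injections or nonpositive QC mean) is removed conservatively under a
#' distinct reason code.
#'
#' @param table a [FeatureTable-class].
#' @param metrics output of [computeQcMetrics()] on this table.
#' @param maxRsd maximal RSD in percent, default 30.
#' @return list with elements `table` and `report`.
#' @export
rsdFilter <- function(table, metrics = computeQcMetrics(table), maxRsd = 30) {
    stopifnot(identical(metrics$feature_id, featureIds(table)))
    undef <- is.na(metrics$rsd_pct)
    keep <- !undef & !(metrics$rsd_pct > maxRsd)
    reason <- ifelse(undef, "rsd_undefined",
                     sprintf("QC RSD %.1f%%", metrics$rsd_pct))
    rep_ <- .stageReport("rsd_filter", table, keep, reason)
    list(table = table[keep, ], report = rep_)
}

#' Sum adducts of the same metabolite (within one polarity)
#'
#' Features annotated to the same metabolite are replaced by one row whose
#' per-sample intensity is the sum of the adduct rows (missing treated as 0
#' when at least one addend is present; an all-missing cell stays missing).
#' The representative row metadata come from the most intense adduct;
#' unannotated features pass through unchanged.
#'
#' @param table an annotated, single-polarity [FeatureTable-class].
#' @return list with elements `table` and `report` (the report's provenance
#'   records which adducts were summed).
#' @export
sumAdducts <- function(table) {
    rd <- rowData(table)
    if (!"metabolite" %in% colnames(rd))
        stop("features carry no metabolite annotations; run identifyFeatures first")
    pol <- unique(rd$polarity)
    if (length(pol) > 1L)
        stop("sumAdducts expects a single-polarity table")
    ann <- !is.na(rd$metabolite)
    groups <- split(which(ann), rd$metabolite[ann])
    multi <- names(groups)[vapply(groups, length, integer(1)) > 1L]
    x <- intensities(table)
    keepRows <- rep(TRUE, nrow(table))
    prov <- list()
    for (met in names(groups)) {
        idx <- groups[[met]]
        if (length(idx) == 1L) next
        sub <- x[idx, , drop = FALSE]
        allNA <- colSums(!is.na(sub)) == 0L
        summed <- colSums(sub, na.rm = TRUE)
        summed[allNA] <- NA_real_
        repRow <- idx[which.max(rowMeans(sub, na.rm = TRUE))]
        x[repRow, ] <- summed
        keepRows[setdiff(idx, repRow)] <- FALSE
        prov[[length(prov) + 1L]] <- data.frame(
            metabolite = met, polarity = pol,
            detail = paste0("summed ", paste(rd$adduct[idx], collapse = "+")),
            stringsAsFactors = FALSE)
    }
    assay(table, "intensities") <- x
    out <- table[keepRows, ]
    rowData(out)$adduct[!is.na(rowData(out)$metabolite) &
                        rowData(out)$metabolite %in% multi] <- "[summed]"
    report <- CurationReport(
        stages = data.frame(stage = "sum_adducts", input = nrow(table),
                            removed = sum(!keepRows), kept = sum(keepRows)),
        removed = data.frame(feature_id = featureIds(table)[!keepRows],
                             stage = rep("sum_adducts", sum(!keepRows)),
                             reason = rep("adduct summed into metabolite row",
                                          sum(!keepRows)),
                             stringsAsFactors = FALSE),
        provenance = if (length(prov)) do.call(rbind, prov) else
            data.frame(metabolite = character(), polarity = character(),
                       detail = character()))
    list(table = out, report = report)
}

#' Merge positive- and negative-mode tables
#'
#' The merged metabolite set is the union of both polarities; for a
#' metabolite observed in both, the ion form with the lower QC-pool RSD is
#' kept (ties keep positive mode). Both tables must share the same sample
#' set.
#'
#' @param pos,neg adduct-summed, annotated [FeatureTable-class] objects.
#' @param metricsPos,metricsNeg QC metrics recomputed on the summed tables.
#' @return list with elements `table` and `report`.
#' @export
mergeModes <- function(pos, neg, metricsPos = computeQcMetrics(pos),
                       metricsNeg = computeQcMetrics(neg)) {
    asym <- c(setdiff(sampleIds(pos), sampleIds(neg)),
              setdiff(sampleIds(neg), sampleIds(pos)))
    if (length(asym))
        stop("sample sets differ between polarities: ",
             paste(asym, collapse = ", "))
    neg <- neg[, sampleIds(pos)]
    metForTab <- function(tab) {
        m <- rowData(tab)$metabolite
        ifelse(is.na(m), paste0("unannotated:", featureIds(tab)), m)
    }
    mp <- metForTab(pos); mn <- metForTab(neg)
    both <- intersect(mp, mn)
    dropPos <- logical(nrow(pos)); dropNeg <- logical(nrow(neg))
    prov <- list()
    for (met in both) {
        i <- which(mp == met)[1L]; j <- which(mn == met)[1L]
        rp <- metricsPos$rsd_pct[i]; rn <- metricsNeg$rsd_pct[j]
        keepPos <- is.na(rn) || (!is.na(rp) && rp <= rn)
        if (keepPos) dropNeg[j] <- TRUE else dropPos[i] <- TRUE
        prov[[length(prov) + 1L]] <- data.frame(
            metabolite = met, polarity = if (keepPos) "pos" else "neg",
            detail = sprintf("kept %s mode (RSD %.2f%% vs %.2f%%)%s",
                             if (keepPos) "pos" else "neg",
                             if (keepPos) rp else rn,
                             if (keepPos) rn else rp,
                             if (!is.na(rp) && !is.na(rn) && rp == rn)
                                 " [tie, positive kept]" else ""),
            stringsAsFactors = FALSE)
    }
    removedIds <- c(featureIds(pos)[dropPos], featureIds(neg)[dropNeg])
    merged <- .rbindFeatureTables(pos[!dropPos, ], neg[!dropNeg, ])
    report <- CurationReport(
        stages = data.frame(stage = "merge_modes",
                            input = nrow(pos) + nrow(neg),
                            removed = length(removedIds),
                            kept = nrow(merged)),
        removed = data.frame(feature_id = removedIds,
                             stage = rep("merge_modes", length(removedIds)),
                             reason = rep("higher-RSD ion form",
                                          length(removedIds)),
                             stringsAsFactors = FALSE),
        provenance = if (length(prov)) do.call(rbind, prov) else
            data.frame(metabolite = character(), polarity = character(),
                       detail = character()))
    list(table = merged, report = report)
}

.rbindFeatureTables <- function(a, b) {
    cols <- intersect(colnames(rowData(a)), colnames(rowData(b)))
    fd <- rbind(as.data.frame(rowData(a))[, cols, drop = FALSE],
                as.data.frame(rowData(b))[, cols, drop = FALSE])
    ## ids may collide across polarities; disambiguate with the polarity
    dup <- duplicated(fd$feature_id) | duplicated(fd$feature_id,
                                                  fromLast = TRUE)
    fd$feature_id[dup] <- paste0(fd$feature_id[dup], "@", fd$polarity[dup])
    x <- rbind(intensities(a), intensities(b))
    rownames(x) <- fd$feature_id
    FeatureTable(x, fd, as.data.frame(colData(a)))
}

#' Full curation chain
#'
#' Applies, per polarity, the blank filter then the RSD filter then adduct
#' summation, then merges the two polarities; finally restricts the table to
#' annotated metabolites (unannotated features are retained through the
#' intermediate stages but dropped from the final analysis table unless
#' `keepUnannotated`). Returns the chained report.
#'
#' @param pos,neg annotated [FeatureTable-class] objects (either may have
#'   zero features).
#' @param blankFrac blank-filter threshold (fraction of study samples).
#' @param maxRsd RSD-filter threshold, percent.
#' @param keepUnannotated keep features without a metabolite annotation.
#' @return list with elements `table` and `report`.
#' @export
curateFeatures <- function(pos, neg, blankFrac = 0.66, maxRsd = 30,
                           keepUnannotated = FALSE) {
    for (tab in list(pos, neg)) {
        if (!nrow(tab)) next
        type <- sampleType(tab)
        if (!any(type == "blank") || sum(type == "qc_pool") < 2L)
            stop("curation requires blank and QC-pool columns ",
                 "(>= 1 blank and >= 2 QC pools)")
    }
    onePol <- function(tab) {
        if (!nrow(tab))
            return(list(table = tab, report = CurationReport()))
        bf <- blankFilter(tab, fracThreshold = blankFrac)
        rf <- rsdFilter(bf$table, maxRsd = maxRsd)
        sa <- sumAdducts(rf$table)
        list(table = sa$table,
             report = chainReports(chainReports(bf$report, rf$report),
                                   sa$report))
    }
    cp <- onePol(pos); cn <- onePol(neg)
    if (nrow(cp$table) && nrow(cn$table)) {
        mm <- mergeModes(cp$table, cn$table)
        merged <- mm$table
        report <- chainReports(chainReports(cp$report, cn$report), mm$report)
    } else {
        merged <- if (nrow(cp$table)) cp$table else cn$table
        report <- chainReports(cp$report, cn$report)
    }
    if (!keepUnannotated) {
        ann <- !is.na(rowData(merged)$metabolite)
        rep2 <- .stageReport("drop_unannotated", merged, ann, "unannotated")
        merged <- merged[ann, ]
        report <- chainReports(report, rep2)
    }
    ## analysis table: one row per metabolite, named by metabolite
    rn <- rowData(merged)$metabolite
    rownames(merged)[!is.na(rn)] <- rn[!is.na(rn)]
    list(table = merged, report = report)
}
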