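## End-to-end orchestration: simulate -> build-library -> identify -> curate
## -> stats -> plsda, with a file manifest and recovery scoring of planted
## effects against the simulator's ground truth.

## deterministic synthetic fragment list for a standard: the precursor ion
## plus two neutral-loss fragments (water, formic acid)
.syntheticFragments <- function(exactMass, polarity) {
    ion <- adductMz(exactMass, if (polarity == "pos") "[M+H]+" else "[M-H]-")
    frag <- cbind(mz = c(ion - 46.005, ion - 18.011, ion),
                  relint = c(30, 60, 100))
    frag[frag[, 1L] > 20, , drop = FALSE]
}

## the polarities a metabolite renders in under a config
.panelPolarities <- function(cfg, metabolite) {
    sp <- cfg@adductSplit[[metabolite]]
    if (is.null(sp)) "pos" else unique(sp$polarity)
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a cohort and feature tables from a [SynthConfig-class], builds a
#' consensus spectral library from simulated standard runs of the same panel,
#' identifies the rendered features, curates the tables, runs the
#' spatial/temporal statistics and the PLS-DA, and scores recovery of the
#' planted effects. All artifacts are written under `outDir` and listed in
#' the returned manifest with md5 checksums (identical config and seed give
#' identical checksums).
#'
#' @param config nested list of stage parameter blocks (see
#'   [readPipelineConfig()]); recognised blocks: `simulate` (`preset`:
#'   "paper-scale" or "correlation"), `library` (`mzTol`, `noiseSigma`,
#'   `dropoutProb`), `identify` (`massTol`, `rtTol`, `ms2Tol`,
#'   `scoreCutoff`), `curate` (`blankFrac`, `maxRsd`), `stats` (`alpha`,
#'   `fc`, `rhoCutoff`), `plsda` (`components`, `folds`, `permutations`,
#'   `vipCutoff`, `enabled`). Missing entries take the package defaults.
#' @param outDir output directory (created if needed).
#' @param synthCfg optionally, a ready-made [SynthConfig-class] overriding
#'   the `simulate` block.
#' @return list with `manifest` (data.frame file/stage/md5), `tables`,
#'   `library`, `stats`, `plsda` and `recovery` results.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("saliva_run_"),
                        synthCfg = NULL) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(config$seed %||% 1L)
    blk <- function(stage) config[[stage]] %||% list()
    manifest <- list()
    note <- function(file, stage)
        manifest[[length(manifest) + 1L]] <<-
            data.frame(file = basename(file), stage = stage,
                       md5 = unname(tools::md5sum(file)))

    ## -- simulate ----------------------------------------------------------
    sim <- blk("simulate")
    cfg <- synthCfg %||% switch(sim$preset %||% "paper-scale",
        "paper-scale" = paperScaleConfig(seed = seed),
        "correlation" = correlationPanelConfig(seed = seed),
        stop("unknown simulate preset: ", sim$preset))
    subjects <- generateSubjects(cfg@nSubjects, seed = cfg@seed)
    design <- generateDesign(subjects, cfg)
    truth <- generateAbundances(design, cfg)
    rendered <- renderFeatures(truth, cfg)
    f <- file.path(outDir, "subjects.tsv")
    utils::write.table(subjects, f, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA")
    note(f, "simulate")
    writeFeatureTable(rendered$pos, file.path(outDir, "features_pos.tsv"),
                      file.path(outDir, "samples.tsv"))
    writeFeatureTable(rendered$neg, file.path(outDir, "features_neg.tsv"))
    note(file.path(outDir, "features_pos.tsv"), "simulate")
    note(file.path(outDir, "features_neg.tsv"), "simulate")
    note(file.path(outDir, "samples.tsv"), "simulate")
    truthTab <- groundTruthTable(cfg)
    f <- file.path(outDir, "ground_truth.tsv")
    utils::write.table(truthTab, f, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA")
    note(f, "simulate")

    ## -- build-library -----------------------------------------------------
    lb <- blk("library")
    standards <- list()
    for (e in cfg@effects) for (pol in .panelPolarities(cfg, e@metabolite))
        standards[[length(standards) + 1L]] <- list(
            name = e@metabolite, exactMass = e@exactMass, polarity = pol,
            rt = e@rt, fragments = .syntheticFragments(e@exactMass, pol))
    byPol <- split(standards, vapply(standards, `[[`, character(1), "polarity"))
    libraries <- lapply(byPol, function(stds) {
        runs <- generateStandardRuns(
            stds, noiseSigma = lb$noiseSigma %||% 0.05,
            dropoutProb = lb$dropoutProb %||% 0, seed = seed + 10L)
        buildLibrary(stds, runs, mzTol = lb$mzTol %||% 0.025)
    })
    allEntries <- unlist(lapply(libraries, `[[`, "entries"), recursive = FALSE)
    f <- file.path(outDir, "library.msp")
    writeMsp(allEntries, f)
    note(f, "build-library")

    ## -- identify ----------------------------------------------------------
    idp <- blk("identify")
    ms2For <- function(tab) {
        rd <- rowData(tab)
        specs <- lapply(seq_len(nrow(tab)), function(i) {
            met <- sub("@.*$", "", rd$feature_id[i])
            e <- Filter(function(x) x@metabolite == met, cfg@effects)
            if (!length(e)) return(NULL)
            .syntheticFragments(e[[1]]@exactMass, rd$polarity[i])
        })
        stats::setNames(specs, rd$feature_id)
    }
    identified <- lapply(rendered, function(tab) {
        if (!nrow(tab)) return(tab)
        identifyFeatures(tab, allEntries, ms2Spectra = ms2For(tab),
                         massTol = idp$massTol %||% 0.01,
                         rtTol = idp$rtTol %||% 0.3,
                         ms2Tol = idp$ms2Tol %||% 0.05,
                         scoreCutoff = idp$scoreCutoff %||% 70)
    })

    ## -- curate ------------------------------------------------------------
    cu <- blk("curate")
    cur <- curateFeatures(identified$pos, identified$neg,
                          blankFrac = cu$blankFrac %||% 0.66,
                          maxRsd = cu$maxRsd %||% 30)
    writeFeatureTable(cur$table, file.path(outDir, "curated.tsv"))
    note(file.path(outDir, "curated.tsv"), "curate")
    f <- file.path(outDir, "curation_report.tsv")
    utils::write.table(cur$report@stages, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    note(f, "curate")

    ## -- stats -------------------------------------------------------------
    st <- blk("stats")
    alpha <- st$alpha %||% 0.05; fcThr <- st$fc %||% 2
    comparisons <- runComparisons(cur$table, alpha = alpha, fc = fcThr)
    stratified <- stratifiedTimeTests(cur$table, alpha = alpha, fc = fcThr)
    pm <- preprocessTable(cur$table)
    corr <- spearmanMatrix(pm, rhoCutoff = st$rhoCutoff %||% 0.8)
    venn <- vennCounts(comparisons$significant)
    f <- file.path(outDir, "comparisons.tsv")
    utils::write.table(do.call(rbind, comparisons$results), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    note(f, "stats")
    f <- file.path(outDir, "correlation_edges.tsv")
    utils::write.table(corr$edges, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    note(f, "stats")

    ## -- plsda -------------------------------------------------------------
    pl <- blk("plsda")
    plsda <- NULL
    if (isTRUE(pl$enabled %||% TRUE)) {
        model <- fitPlsda(pm, pm@sampleInfo$location,
                          nComponents = pl$components %||% 2L)
        vip <- vipScores(model)
        selected <- vipSelected(model, cutoff = pl$vipCutoff %||% 1.25)
        cv <- crossValidatePlsda(pm, pm@sampleInfo$location,
                                 nComponents = pl$components %||% 2L,
                                 folds = pl$folds %||% 7L, seed = seed)
        model@q2 <- unname(cv["Q2"])
        plsda <- list(model = model, vip = vip, selected = selected, cv = cv)
        if (!is.null(pl$permutations) && pl$permutations > 0) {
            pt <- permutationTestPlsda(pm, pm@sampleInfo$location,
                                       nComponents = pl$components %||% 2L,
                                       folds = pl$folds %||% 7L,
                                       nPerm = pl$permutations, seed = seed)
            model@permutationP <- pt$p
            plsda$permutation <- pt
            plsda$model <- model
        }
        f <- file.path(outDir, "vip.tsv")
        utils::write.table(
            data.frame(metabolite = names(vip), vip = as.numeric(vip)),
            f, sep = "\t", row.names = FALSE, quote = FALSE)
        note(f, "plsda")
    }

    ## -- score -------------------------------------------------------------
    recovery <- scoreRecovery(comparisons, stratified, truthTab)
    f <- file.path(outDir, "recovery.tsv")
    utils::write.table(as.data.frame(recovery[c("sensitivity", "specificity",
                                                "signAccuracy",
                                                "falsePositiveRate")]),
                       f, sep = "\t", row.names = FALSE, quote = FALSE)
    note(f, "score")

    list(manifest = do.call(rbind, manifest), config = cfg,
         tables = list(truth = truth, rendered = rendered,
                       identified = identified, curated = cur$table),
         curationReport = cur$report, library = libraries,
         stats = list(comparisons = comparisons, stratified = stratified,
                      correlation = corr, venn = venn, processed = pm),
         plsda = plsda, recovery = recovery)
}

#' Score recovery of planted effects
#'
#' Each planted effect is scored against the analysis designed to detect it:
#' location markers against the location factor of the unstratified
#' comparisons; diurnal metabolites acting in all locations against the time
#' factor; diurnal metabolites confined to a location subset against the
#' stratified time tests of those locations (recovered when significant in
#' every location they act in). Specificity counts null metabolites (no
#' planted effect) not flagged by any unstratified factor; sign accuracy
#' checks the direction of the log2 fold change of recovered effects.
#'
#' @param comparisons output of [runComparisons()].
#' @param stratified output of [stratifiedTimeTests()].
#' @param truth ground-truth data.frame from [groundTruthTable()].
#' @return list with `sensitivity`, `specificity`, `falsePositiveRate`,
#'   `signAccuracy`, and the per-metabolite `detail` data.frame.
#' @export
scoreRecovery <- function(comparisons, stratified, truth) {
    measured <- unique(unlist(lapply(comparisons$results,
                                     function(r) r$metabolite)))
    truth <- truth[truth$metabolite %in% measured, , drop = FALSE]
    if (!nrow(truth)) stop("no ground-truth metabolite was measured")
    sig <- comparisons$significant
    fcOf <- function(key, met) {
        r <- comparisons$results[[key]]
        r$log2fc[match(met, r$metabolite)]
    }
    rows <- list()
    for (i in seq_len(nrow(truth))) {
        tr <- truth[i, ]
        met <- tr$metabolite
        planted <- character(); recovered <- NA; signOk <- NA
        if (!is.na(tr$marker_location)) {
            planted <- c(planted, "location")
            recovered <- met %in% (sig$location %||% character())
            loc <- tr$marker_location
            keys <- paste0("location:",
                           vapply(.LOCATION_PAIRS, paste, character(1),
                                  collapse = "_vs_"))
            keys <- keys[grepl(loc, keys)]
            expSign <- ifelse(grepl(paste0("^location:", loc), keys), 1, -1)
            fcs <- vapply(keys, fcOf, numeric(1), met = met)
            signOk <- all(sign(fcs) == expSign)
        }
        if (isTRUE(tr$diurnal)) {
            planted <- c(planted, "time")
            locs <- strsplit(tr$diurnal_locations, "|", fixed = TRUE)[[1]]
            if (length(locs) == 3L) {
                recT <- met %in% (sig$time %||% character())
            } else {
                recT <- all(vapply(locs, function(l)
                    met %in% (stratified$significant[[l]] %||% character()),
                    logical(1)))
            }
            recovered <- if (is.na(recovered)) recT else recovered && recT
            fcMA <- fcOf("time:M_vs_A", met)
            sOk <- if (tr$diurnal_profile == "nadir_M") fcMA < 0 else fcMA > 0
            signOk <- if (is.na(signOk)) sOk else signOk && sOk
        }
        rows[[i]] <- data.frame(metabolite = met,
                                planted = paste(planted, collapse = "+"),
                                is_null = tr$is_null,
                                recovered = recovered, sign_ok = signOk,
                                stringsAsFactors = FALSE)
    }
    detail <- do.call(rbind, rows)
    flaggedAnywhere <- unique(unlist(sig))
    nulls <- detail$metabolite[detail$is_null]
    fp <- sum(nulls %in% flaggedAnywhere)
    eff <- detail[!detail$is_null & nzchar(detail$planted), , drop = FALSE]
    list(sensitivity = if (nrow(eff)) mean(eff$recovered) else NA_real_,
         specificity = if (length(nulls)) 1 - fp / length(nulls) else NA_real_,
         falsePositiveRate = if (length(nulls)) fp / length(nulls) else NA_real_,
         signAccuracy = if (any(!is.na(eff$sign_ok)))
             mean(eff$sign_ok[eff$recovered], na.rm = TRUE) else NA_real_,
         detail = detail)
}
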