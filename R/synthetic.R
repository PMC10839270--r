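## Synthetic cohort / feature-table simulator.
##
## Abundances are log10-normal: for study sample s and metabolite m,
##   log10 I = log10(base) + log10(location mult) + log10(time mult)
##             + log10(sex mult) + log10(BT dilution if BT)
##             + subject effect + noise.
## Correlated metabolite pairs share a latent Gaussian component; the residual
## correlation is solved so that the pair's total population Spearman rho hits
## the target, using the bivariate-normal relation rho_S = (6/pi) asin(rho_P/2).

#' EffectSpec: the planted behavior of one synthetic metabolite
#'
#' @slot metabolite metabolite label (unique within a panel).
#' @slot classLabel pathway-level class string.
#' @slot exactMass neutral monoisotopic mass, Da.
#' @slot rt nominal retention time, minutes.
#' @slot baseLevel geometric-mean intensity (raw scale).
#' @slot locationMultipliers named multipliers for AT/BT/CK.
#' @slot timeMultipliers named multipliers for M/A/E.
#' @slot diurnalLocations locations where the time multipliers apply
#'   (all three for a systemic diurnal metabolite, `"BT"` for a BT-only one).
#' @slot sexMultipliers named multipliers for Ma/Fe.
#' @slot correlationPartner optional label of an earlier panel metabolite this
#'   one is rank-correlated with.
#' @slot correlationRho target population Spearman rho for the pair.
#' @slot noiseSigma SD of log10 intensities (measurement noise).
#' @slot subjectSigma SD of the per-subject random effect on the log10 scale.
#' @export
setClass("EffectSpec",
         representation(metabolite = "character", classLabel = "character",
                        exactMass = "numeric", rt = "numeric",
                        baseLevel = "numeric",
                        locationMultipliers = "numeric",
                        timeMultipliers = "numeric",
                        diurnalLocations = "character",
                        sexMultipliers = "numeric",
                        correlationPartner = "character",
                        correlationRho = "numeric",
                        noiseSigma = "numeric", subjectSigma = "numeric"))

setValidity("EffectSpec", function(object) {
    msg <- character()
    if (any(object@locationMultipliers <= 0) || any(object@timeMultipliers <= 0) ||
        any(object@sexMultipliers <= 0))
        msg <- c(msg, "multipliers must be positive")
    if (!is.na(object@correlationRho) && abs(object@correlationRho) > 1)
        msg <- c(msg, "|correlation rho| must be <= 1")
    if (object@noiseSigma <= 0) msg <- c(msg, "noiseSigma must be positive")
    if (object@subjectSigma < 0) msg <- c(msg, "subjectSigma must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' @rdname EffectSpec-class
#' @param metabolite,classLabel,exactMass,rt,baseLevel,locationMultipliers,timeMultipliers,diurnalLocations,sexMultipliers,correlationPartner,correlationRho,noiseSigma,subjectSigma
#'   see slots.
#' @export
effectSpec <- function(metabolite, classLabel = "unclassified",
                       exactMass = 150, rt = 5, baseLevel = 1e5,
                       locationMultipliers = c(AT = 1, BT = 1, CK = 1),
                       timeMultipliers = c(M = 1, A = 1, E = 1),
                       diurnalLocations = c("AT", "BT", "CK"),
                       sexMultipliers = c(Ma = 1, Fe = 1),
                       correlationPartner = NA_character_,
                       correlationRho = NA_real_,
                       noiseSigma = 0.15, subjectSigma = 0.1) {
    new("EffectSpec", metabolite = metabolite, classLabel = classLabel,
        exactMass = exactMass, rt = rt, baseLevel = baseLevel,
        locationMultipliers = locationMultipliers[.LOCATIONS],
        timeMultipliers = timeMultipliers[.TIMES],
        diurnalLocations = diurnalLocations,
        sexMultipliers = sexMultipliers[c("Ma", "Fe")],
        correlationPartner = correlationPartner,
        correlationRho = correlationRho,
        noiseSigma = noiseSigma, subjectSigma = subjectSigma)
}

#' SynthConfig: full description of a synthetic study
#'
#' @slot nSubjects number of subjects.
#' @slot locations,times the factorial design levels.
#' @slot dropoutCount number of study samples discarded.
#' @slot dropoutPreset `"random"` (uniform over study samples) or
#'   `"replicate-study"` (dropout cells chosen so the surviving subset sizes
#'   are AT 56, BT 59, CK 44 and M 51, A 53, E 55 out of 180).
#' @slot effects list of [EffectSpec-class] (the metabolite panel).
#' @slot btDilution multiplier in (0, 1] applied to all BT intensities.
#' @slot blankLevel,blankSigma blank injections: level and log-normal noise SD
#'   (natural-log scale).
#' @slot nBlanks,nQcPools counts; `NA` derives both from the run-order pattern
#'   (a leading QC pool, then one QC pool and one blank after every five study
#'   samples).
#' @slot qcRsd target QC-pool relative standard deviation, percent.
#' @slot adductSplit named list (by metabolite) of data.frames with columns
#'   `polarity`, `adduct`, `fraction` (fractions sum to 1); metabolites absent
#'   from the list render as a single `[M+H]+` feature.
#' @slot rtJitter maximal RT jitter of rendered features, minutes.
#' @slot seed integer seed; identical configs produce identical outputs.
#' @export
setClass("SynthConfig",
         representation(nSubjects = "integer", locations = "character",
                        times = "character", dropoutCount = "integer",
                        dropoutPreset = "character", effects = "list",
                        btDilution = "numeric", blankLevel = "numeric",
                        blankSigma = "numeric", nBlanks = "integer",
                        nQcPools = "integer", qcRsd = "numeric",
                        adductSplit = "list", rtJitter = "numeric",
                        seed = "integer"))

setValidity("SynthConfig", function(object) {
    msg <- character()
    design <- object@nSubjects * length(object@locations) * length(object@times)
    if (object@dropoutCount > design)
        msg <- c(msg, sprintf("dropoutCount %d exceeds design size %d",
                              object@dropoutCount, design))
    if (object@btDilution <= 0 || object@btDilution > 1)
        msg <- c(msg, "btDilution must be in (0, 1]")
    mets <- vapply(object@effects, function(e) e@metabolite, character(1))
    if (anyDuplicated(mets))
        msg <- c(msg, "panel metabolites must be unique")
    for (nm in names(object@adductSplit)) {
        sp <- object@adductSplit[[nm]]
        if (abs(sum(sp$fraction) - 1) > 1e-9)
            msg <- c(msg, sprintf("adduct fractions for '%s' sum to %g, not 1",
                                  nm, sum(sp$fraction)))
    }
    for (e in object@effects)
        if (!is.na(e@correlationPartner) && !e@correlationPartner %in% mets)
            msg <- c(msg, sprintf("correlation partner '%s' of '%s' is not in the panel",
                                  e@correlationPartner, e@metabolite))
    if (length(msg)) msg else TRUE
})

#' @rdname SynthConfig-class
#' @param nSubjects,locations,times,dropoutCount,dropoutPreset,effects,btDilution,blankLevel,blankSigma,nBlanks,nQcPools,qcRsd,adductSplit,rtJitter,seed
#'   see slots.
#' @export
synthConfig <- function(nSubjects = 20L, locations = .LOCATIONS,
                        times = .TIMES, dropoutCount = 0L,
                        dropoutPreset = c("random", "replicate-study"),
                        effects = list(), btDilution = 1,
                        blankLevel = 100, blankSigma = 0.1,
                        nBlanks = NA_integer_, nQcPools = NA_integer_,
                        qcRsd = 5, adductSplit = list(), rtJitter = 0.02,
                        seed = 1L) {
    new("SynthConfig", nSubjects = as.integer(nSubjects),
        locations = locations, times = times,
        dropoutCount = as.integer(dropoutCount),
        dropoutPreset = match.arg(dropoutPreset), effects = effects,
        btDilution = btDilution, blankLevel = blankLevel,
        blankSigma = blankSigma, nBlanks = as.integer(nBlanks),
        nQcPools = as.integer(nQcPools), qcRsd = qcRsd,
        adductSplit = adductSplit, rtJitter = rtJitter,
        seed = as.integer(seed))
}

#' Generate a synthetic cohort
#'
#' Sexes alternate Ma/Fe to balance; ages are Normal(31.2, 4.7^2) rounded to
#' integer years and clipped to the recruitment range 18-45; sleep hours are
#' Normal(7.5, 0.7^2) rounded to the nearest quarter hour.
#'
#' @param n number of subjects (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns `subject_id`, `sex`, `age`, `sleep`.
#' @export
generateSubjects <- function(n, seed = 1L) {
    if (n < 0) stop("n must be >= 0")
    if (n == 0)
        return(data.frame(subject_id = character(), sex = character(),
                          age = integer(), sleep = numeric()))
    set.seed(seed)
    ids <- if (n <= 26) LETTERS[seq_len(n)] else sprintf("S%03d", seq_len(n))
    data.frame(
        subject_id = ids,
        sex = rep(c("Ma", "Fe"), length.out = n),
        age = as.integer(pmin(45, pmax(18, round(stats::rnorm(n, 31.2, 4.7))))),
        sleep = round(stats::rnorm(n, 7.5, 0.7) * 4) / 4)
}

## dropout cells (rows AT/BT/CK x cols M/A/E) reproducing the surviving
## margins printed for the original design: AT 56, BT 59, CK 44; M 51, A 53,
## E 55. The joint table is a choice consistent with both margins.
.REPLICATE_DROPOUT <- matrix(c(2, 1, 1,
                               1, 0, 0,
                               6, 6, 4), 3, 3, byrow = TRUE,
                             dimnames = list(.LOCATIONS, .TIMES))

#' Generate the sampling design (study samples, QC pools and blanks)
#'
#' Full factorial subjects x locations x times, then `dropoutCount` study
#' samples removed (uniformly at random, or per the `"replicate-study"`
#' preset), then run order assigned as a leading QC pool followed by
#' repeating blocks of five study samples, one QC pool and one blank.
#'
#' @param subjects data.frame from [generateSubjects()].
#' @param cfg a [SynthConfig-class].
#' @return data.frame of sample metadata (one row per injection) with columns
#'   `sample_id`, `subject_id`, `location`, `time`, `sample_type`,
#'   `run_order`, `sex`.
#' @export
generateDesign <- function(subjects, cfg) {
    set.seed(cfg@seed + 1L)
    grid <- expand.grid(subject_id = subjects$subject_id,
                        location = cfg@locations, time = cfg@times,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (cfg@dropoutCount > nrow(grid))
        stop("dropoutCount exceeds design size")
    if (cfg@dropoutPreset == "replicate-study") {
        if (!identical(sort(cfg@locations), sort(.LOCATIONS)) ||
            !identical(sort(cfg@times), sort(.TIMES)) ||
            cfg@dropoutCount != sum(.REPLICATE_DROPOUT))
            stop("the replicate-study preset requires the 3x3 design with dropoutCount ",
                 sum(.REPLICATE_DROPOUT))
        drop <- integer()
        for (loc in .LOCATIONS) for (tm in .TIMES) {
            cell <- which(grid$location == loc & grid$time == tm)
            k <- .REPLICATE_DROPOUT[loc, tm]
            if (k > 0) drop <- c(drop, sample(cell, k))
        }
    } else {
        drop <- if (cfg@dropoutCount > 0)
            sample(nrow(grid), cfg@dropoutCount) else integer()
    }
    if (length(drop)) grid <- grid[-drop, , drop = FALSE]
    grid$sample_id <- paste(grid$subject_id, grid$location, grid$time, sep = "_")
    grid$sample_type <- "study"
    grid$sex <- subjects$sex[match(grid$subject_id, subjects$subject_id)]
    ## randomized injection order, QC/blank interleaving
    grid <- grid[sample(nrow(grid)), , drop = FALSE]
    nStudy <- nrow(grid)
    nBlocks <- ceiling(nStudy / 5)
    nQc <- if (is.na(cfg@nQcPools)) nBlocks + 1L else cfg@nQcPools
    nBlank <- if (is.na(cfg@nBlanks)) nBlocks else cfg@nBlanks
    seq_types <- c("qc_pool", unlist(lapply(seq_len(nBlocks), function(b) {
        k <- min(5L, nStudy - (b - 1L) * 5L)
        c(rep("study", k), "qc_pool", "blank")
    })))
    ## honor explicit QC/blank counts by trimming or padding at the end
    adj <- function(types, what, target) {
        have <- sum(types == what)
        if (have > target) {
            idx <- rev(which(types == what))[seq_len(have - target)]
            types <- types[-idx]
        } else if (have < target)
            types <- c(types, rep(what, target - have))
        types
    }
    seq_types <- adj(adj(seq_types, "qc_pool", nQc), "blank", nBlank)
    out <- data.frame(sample_id = character(length(seq_types)),
                      subject_id = NA_character_, location = NA_character_,
                      time = NA_character_, sample_type = seq_types,
                      run_order = seq_along(seq_types), sex = NA_character_,
                      stringsAsFactors = FALSE)
    si <- which(seq_types == "study")
    out$sample_id[si] <- grid$sample_id
    out$subject_id[si] <- grid$subject_id
    out$location[si] <- grid$location
    out$time[si] <- grid$time
    out$sex[si] <- grid$sex
    out$sample_id[seq_types == "qc_pool"] <-
        sprintf("QC%02d", seq_len(sum(seq_types == "qc_pool")))
    out$sample_id[seq_types == "blank"] <-
        sprintf("BLK%02d", seq_len(sum(seq_types == "blank")))
    rownames(out) <- NULL
    out
}

## per-sample fixed effect (log10 scale, base level excluded) of one effect spec
.fixedEffect <- function(e, design) {
    f <- log10(e@locationMultipliers[design$location])
    diurnal <- design$location %in% e@diurnalLocations
    f <- f + ifelse(diurnal, log10(e@timeMultipliers[design$time]), 0)
    f <- f + log10(e@sexMultipliers[design$sex])
    unname(f)
}

#' Generate a ground-truth abundance table
#'
#' Produces the metabolite-level ("truth") [FeatureTable-class]: study-sample
#' intensities follow the log10-normal effect model, QC pools are the
#' per-metabolite mean of the simulated study samples with multiplicative
#' noise at the configured RSD (a true pool), and blanks sit at
#' `blankLevel`. For pairs declaring a `correlationPartner`, the shared latent
#' Gaussian component is calibrated so the pair's total population Spearman
#' rho (fixed effects included) matches the target.
#'
#' @param design data.frame from [generateDesign()].
#' @param cfg a [SynthConfig-class].
#' @return a [FeatureTable-class] with one feature per panel metabolite.
#' @export
generateAbundances <- function(design, cfg) {
    set.seed(cfg@seed + 2L)
    effects <- cfg@effects
    mets <- vapply(effects, function(e) e@metabolite, character(1))
    study <- design[design$sample_type == "study", , drop = FALSE]
    nS <- nrow(study)
    nM <- length(effects)
    subjects <- unique(study$subject_id)
    ## independent standardized draws, then copula coupling for declared pairs
    zSub <- matrix(stats::rnorm(length(subjects) * nM), length(subjects), nM,
                   dimnames = list(subjects, mets))
    zNoise <- matrix(stats::rnorm(nS * nM), nS, nM, dimnames = list(NULL, mets))
    fixed <- vapply(effects, .fixedEffect, numeric(nS), design = study)
    btTerm <- ifelse(study$location == "BT", log10(cfg@btDilution), 0)
    fixed <- fixed + btTerm  # common to every metabolite
    for (j in seq_len(nM)) {
        e <- effects[[j]]
        if (is.na(e@correlationPartner)) next
        q <- match(e@correlationPartner, mets)
        rhoTotal <- 2 * sin(pi * e@correlationRho / 6)
        sj <- sqrt(e@noiseSigma^2 + e@subjectSigma^2)
        eq <- effects[[q]]
        sq <- sqrt(eq@noiseSigma^2 + eq@subjectSigma^2)
        vfj <- stats::var(fixed[, j]) * (nS - 1) / nS
        vfq <- stats::var(fixed[, q]) * (nS - 1) / nS
        cf <- stats::cov(fixed[, j], fixed[, q]) * (nS - 1) / nS
        need <- (rhoTotal * sqrt(vfj + sj^2) * sqrt(vfq + sq^2) - cf) / (sj * sq)
        rhoR <- max(-0.999, min(0.999, need))
        if (abs(need) > 1)
            warning(sprintf("residual correlation for pair %s-%s clipped (needed %.3f)",
                            e@metabolite, e@correlationPartner, need))
        zSub[, j] <- rhoR * zSub[, q] + sqrt(1 - rhoR^2) * zSub[, j]
        zNoise[, j] <- rhoR * zNoise[, q] + sqrt(1 - rhoR^2) * zNoise[, j]
    }
    logI <- matrix(0, nM, nS, dimnames = list(mets, study$sample_id))
    subIdx <- match(study$subject_id, subjects)
    for (j in seq_len(nM)) {
        e <- effects[[j]]
        logI[j, ] <- log10(e@baseLevel) + fixed[, j] +
            e@subjectSigma * zSub[subIdx, j] + e@noiseSigma * zNoise[, j]
    }
    studyInt <- 10^logI
    ## QC pools: pool of all study samples, multiplicative noise at target RSD
    qcIds <- design$sample_id[design$sample_type == "qc_pool"]
    qcInt <- matrix(rowMeans(studyInt), nM, length(qcIds),
                    dimnames = list(mets, qcIds))
    if (length(qcIds))
        qcInt <- qcInt * exp(matrix(stats::rnorm(nM * length(qcIds), 0,
                                                 cfg@qcRsd / 100),
                                    nM, length(qcIds)))
    blkIds <- design$sample_id[design$sample_type == "blank"]
    blkInt <- matrix(cfg@blankLevel, nM, length(blkIds),
                     dimnames = list(mets, blkIds))
    if (length(blkIds))
        blkInt <- blkInt * exp(matrix(stats::rnorm(nM * length(blkIds), 0,
                                                   cfg@blankSigma),
                                      nM, length(blkIds)))
    x <- cbind(studyInt, qcInt, blkInt)[, design$sample_id, drop = FALSE]
    fd <- data.frame(
        feature_id = mets, polarity = "pos",
        mz = vapply(effects, function(e) adductMz(e@exactMass, "[M+H]+"),
                    numeric(1)),
        rt = vapply(effects, function(e) e@rt, numeric(1)),
        adduct = "[M+H]+",
        metabolite = mets,
        class_label = vapply(effects, function(e) e@classLabel, character(1)),
        stringsAsFactors = FALSE)
    FeatureTable(x, fd, design[, c("sample_id", "subject_id", "location",
                                   "time", "sample_type", "run_order", "sex")])
}

#' Render a truth table into observed positive/negative-mode feature tables
#'
#' Each metabolite's intensity is split across its configured adducts and
#' polarities by the configured fractions (conserving the per-sample total);
#' feature m/z values follow from the exact mass and standard adduct shifts,
#' and RT receives a uniform jitter bounded by `rtJitter`.
#'
#' @param truth [FeatureTable-class] from [generateAbundances()].
#' @param cfg the same [SynthConfig-class].
#' @return list with elements `pos` and `neg`, each a [FeatureTable-class]
#'   (unannotated: rendered features carry no `metabolite` column).
#' @export
renderFeatures <- function(truth, cfg) {
    set.seed(cfg@seed + 3L)
    effects <- cfg@effects
    mets <- vapply(effects, function(e) e@metabolite, character(1))
    rows <- list()
    for (j in seq_along(effects)) {
        e <- effects[[j]]
        sp <- cfg@adductSplit[[e@metabolite]]
        if (is.null(sp))
            sp <- data.frame(polarity = "pos", adduct = "[M+H]+", fraction = 1,
                             stringsAsFactors = FALSE)
        if (abs(sum(sp$fraction) - 1) > 1e-9)
            stop(sprintf("adduct fractions for '%s' do not sum to 1", e@metabolite))
        for (k in seq_len(nrow(sp))) {
            a <- .adductRow(sp$adduct[k])
            if (a$polarity != sp$polarity[k])
                stop(sprintf("adduct %s is not a %s-mode adduct",
                             sp$adduct[k], sp$polarity[k]))
            rows[[length(rows) + 1L]] <- list(
                metabolite = e@metabolite, polarity = sp$polarity[k],
                adduct = sp$adduct[k],
                mz = adductMz(e@exactMass, sp$adduct[k]),
                rt = e@rt + stats::runif(1, -cfg@rtJitter, cfg@rtJitter),
                fraction = sp$fraction[k], truthRow = j)
        }
    }
    build <- function(pol) {
        sel <- Filter(function(r) r$polarity == pol, rows)
        fd <- data.frame(
            feature_id = vapply(sel, function(r)
                paste0(r$metabolite, "@", r$adduct), character(1)),
            polarity = rep(pol, length(sel)),
            mz = vapply(sel, `[[`, numeric(1), "mz"),
            rt = vapply(sel, `[[`, numeric(1), "rt"),
            adduct = vapply(sel, `[[`, character(1), "adduct"),
            stringsAsFactors = FALSE)
        x <- matrix(0, length(sel), ncol(truth),
                    dimnames = list(fd$feature_id, colnames(truth)))
        for (i in seq_along(sel))
            x[i, ] <- intensities(truth)[sel[[i]]$truthRow, ] * sel[[i]]$fraction
        FeatureTable(x, fd, as.data.frame(colData(truth)))
    }
    list(pos = build("pos"), neg = build("neg"))
}

#' Simulate replicate MS/MS acquisitions of authentic standards
#'
#' Emulates the library-construction runs: each standard injected in
#' `replicates` replicates at each working concentration, fragment intensities
#' scaling with concentration under multiplicative log-normal noise, with
#' optional per-replicate fragment dropout and RT jitter.
#'
#' @param standards list of ground truths; each element a list with `name`,
#'   `exactMass`, `polarity`, `rt`, and `fragments` (two-column matrix of
#'   fragment m/z and true relative intensity).
#' @param concentrations working concentrations in ug/mL (ascending).
#' @param replicates replicates per concentration.
#' @param intensityScale counts for a 100%-relative fragment at the highest
#'   concentration.
#' @param noiseSigma log-normal noise SD (natural-log scale); 0 = noiseless.
#' @param dropoutProb per-fragment, per-replicate dropout probability.
#' @param rtJitter maximal RT jitter, minutes.
#' @param seed integer seed.
#' @return named list (by standard) of lists of [MsmsSpectrum-class].
#' @export
generateStandardRuns <- function(standards,
                                 concentrations = c(0.25, 0.5, 1),
                                 replicates = 3L, intensityScale = 1e4,
                                 noiseSigma = 0.05, dropoutProb = 0,
                                 rtJitter = 0.02, seed = 1L) {
    set.seed(seed)
    out <- list()
    for (std in standards) {
        frags <- as.matrix(std$fragments)
        if (!nrow(frags)) stop(sprintf("standard '%s' has an empty fragment list",
                                       std$name))
        specs <- list()
        for (conc in concentrations) for (rep in seq_len(replicates)) {
            keep <- stats::runif(nrow(frags)) >= dropoutProb
            if (!any(keep)) keep[which.max(frags[, 2L])] <- TRUE
            ints <- frags[keep, 2L] / 100 * intensityScale *
                conc / max(concentrations)
            if (noiseSigma > 0)
                ints <- ints * exp(stats::rnorm(length(ints), 0, noiseSigma))
            specs[[length(specs) + 1L]] <- MsmsSpectrum(
                precursorMz = adductMz(std$exactMass,
                                       if (std$polarity == "pos") "[M+H]+" else "[M-H]-"),
                rt = std$rt + stats::runif(1, -rtJitter, rtJitter),
                polarity = std$polarity,
                peaks = cbind(frags[keep, 1L], ints),
                concentration = conc, replicate = rep)
        }
        out[[std$name]] <- specs
    }
    out
}

#' The planted-effect ground truth of a configuration
#'
#' @param cfg a [SynthConfig-class].
#' @return data.frame with one row per panel metabolite: the planted location
#'   marker (if any), diurnal profile and locations, correlation partner, and
#'   whether the metabolite is null (no planted effect beyond the global BT
#'   dilution).
#' @export
groundTruthTable <- function(cfg) {
    do.call(rbind, lapply(cfg@effects, function(e) {
        lm <- e@locationMultipliers
        tmv <- e@timeMultipliers
        markerLoc <- if (max(lm) / min(lm) > 1) names(lm)[which.max(lm)] else NA
        diurnal <- max(tmv) / min(tmv) > 1
        profile <- if (!diurnal) NA_character_
                   else if (which.min(tmv) == 1L) "nadir_M" else "declining"
        data.frame(metabolite = e@metabolite, class_label = e@classLabel,
                   marker_location = markerLoc,
                   location_fc = max(lm) / min(lm),
                   diurnal = diurnal, diurnal_profile = profile,
                   diurnal_fc = max(tmv) / min(tmv),
                   diurnal_locations = paste(e@diurnalLocations, collapse = "|"),
                   sex_fc = max(e@sexMultipliers) / min(e@sexMultipliers),
                   correlation_partner = e@correlationPartner,
                   correlation_rho = e@correlationRho,
                   is_null = is.na(markerLoc) && !diurnal &&
                       max(e@sexMultipliers) / min(e@sexMultipliers) == 1 &&
                       is.na(e@correlationPartner),
                   stringsAsFactors = FALSE)
    }))
}

#' Study-scale simulation preset
#'
#' The panel emulates the original study conditions: 20 subjects, the 3x3
#' location-by-time design with 21/180 dropout (replicate-study margins), 100
#' metabolites of which 10 are AT markers and 10 CK markers (location fold
#' change 4), 5 are diurnal with fold change 4 (cortisol and cortisone
#' declining in all locations and rank-correlated at rho 0.94,
#' N-acetyl-tryptophan with its nadir in the morning in all locations, and
#' two BT-only declining metabolites), a BT dilution of 0.7, log10 noise SD
#' 0.15 and subject SD 0.1. About a quarter of the panel renders multi-adduct
#' or negative-mode features so curation has work to do.
#'
#' @param seed integer seed.
#' @return a [SynthConfig-class].
#' @export
paperScaleConfig <- function(seed = 1L) {
    effects <- list()
    adductSplit <- list()
    mkMass <- function(i) 100 + i * 2.5          # >> 0.01 Da apart
    mkRt <- function(i) 0.5 + (i %% 95) * 0.119  # within the 0.5-12 min window
    mkBase <- function(i) 10^(4 + (i %% 9) / 4)  # 1e4 .. 1e6 spread
    idx <- 0L
    add <- function(e) effects[[length(effects) + 1L]] <<- e
    for (i in 1:10) {
        idx <- idx + 1L
        add(effectSpec(sprintf("at_marker_%02d", i), "N-acetylated amino acids",
                       exactMass = mkMass(idx), rt = mkRt(idx),
                       baseLevel = mkBase(idx),
                       locationMultipliers = c(AT = 4, BT = 1, CK = 1)))
    }
    for (i in 1:10) {
        idx <- idx + 1L
        add(effectSpec(sprintf("ck_marker_%02d", i), "saccharides",
                       exactMass = mkMass(idx), rt = mkRt(idx),
                       baseLevel = mkBase(idx),
                       locationMultipliers = c(AT = 1, BT = 1, CK = 4)))
    }
    declining <- c(M = 4, A = 1.8, E = 1)
    idx <- idx + 1L
    add(effectSpec("cortisol", "terpenoids", exactMass = 362.2093,
                   rt = mkRt(idx), baseLevel = mkBase(idx),
                   timeMultipliers = declining))
    idx <- idx + 1L
    add(effectSpec("cortisone", "terpenoids", exactMass = 360.1937,
                   rt = mkRt(idx), baseLevel = mkBase(idx),
                   timeMultipliers = declining,
                   correlationPartner = "cortisol", correlationRho = 0.94))
    idx <- idx + 1L
    add(effectSpec("N-acetyl-tryptophan", "amino acids", exactMass = 246.1004,
                   rt = mkRt(idx), baseLevel = mkBase(idx),
                   timeMultipliers = c(M = 1, A = 4, E = 3.2)))
    idx <- idx + 1L
    add(effectSpec("valine", "amino acids", exactMass = 117.0790,
                   rt = mkRt(idx), baseLevel = mkBase(idx),
                   timeMultipliers = declining, diurnalLocations = "BT"))
    idx <- idx + 1L
    add(effectSpec("adenosine-cyclic-phosphate", "nucleotides",
                   exactMass = 329.0525, rt = mkRt(idx), baseLevel = mkBase(idx),
                   timeMultipliers = declining, diurnalLocations = "BT"))
    for (i in 1:75) {
        idx <- idx + 1L
        add(effectSpec(sprintf("null_%02d", i), "unclassified",
                       exactMass = mkMass(idx), rt = mkRt(idx),
                       baseLevel = mkBase(idx)))
    }
    mets <- vapply(effects, function(e) e@metabolite, character(1))
    for (j in seq_along(mets)) {
        if (j %% 4 == 1)
            adductSplit[[mets[j]]] <- data.frame(
                polarity = c("pos", "pos"), adduct = c("[M+H]+", "[M+Na]+"),
                fraction = c(0.7, 0.3), stringsAsFactors = FALSE)
        else if (j %% 4 == 2)
            adductSplit[[mets[j]]] <- data.frame(
                polarity = "neg", adduct = "[M-H]-", fraction = 1,
                stringsAsFactors = FALSE)
        else if (j %% 4 == 3)
            adductSplit[[mets[j]]] <- data.frame(
                polarity = c("pos", "neg"), adduct = c("[M+H]+", "[M-H]-"),
                fraction = c(0.6, 0.4), stringsAsFactors = FALSE)
        ## j %% 4 == 0: default single [M+H]+
    }
    synthConfig(nSubjects = 20L, dropoutCount = 21L,
                dropoutPreset = "replicate-study", effects = effects,
                btDilution = 0.7, blankLevel = 50, adductSplit = adductSplit,
                seed = seed)
}

#' Correlation-panel preset
#'
#' A panel for studying the Spearman correlation network in isolation: three
#' rank-correlated pairs at the magnitudes of the corticosteroid pair in each
#' location (rho 0.94, 0.92, 0.88) among otherwise-null metabolites, no
#' location or time effects, no BT dilution.
#'
#' @param nNull number of uncorrelated filler metabolites.
#' @param seed integer seed.
#' @return a [SynthConfig-class].
#' @export
correlationPanelConfig <- function(nNull = 24L, seed = 1L) {
    effects <- list(
        effectSpec("cortisol", "terpenoids", exactMass = 362.2093, rt = 8),
        effectSpec("cortisone", "terpenoids", exactMass = 360.1937, rt = 8.2,
                   correlationPartner = "cortisol", correlationRho = 0.94),
        effectSpec("leucine", "amino acids", exactMass = 131.0946, rt = 2),
        effectSpec("isoleucine", "amino acids", exactMass = 131.0946, rt = 2.3,
                   correlationPartner = "leucine", correlationRho = 0.92),
        effectSpec("caffeine", "alkaloids", exactMass = 194.0804, rt = 5),
        effectSpec("paraxanthine", "alkaloids", exactMass = 180.0647, rt = 5.2,
                   correlationPartner = "caffeine", correlationRho = 0.88))
    for (i in seq_len(nNull))
        effects[[length(effects) + 1L]] <-
            effectSpec(sprintf("null_%02d", i), exactMass = 200 + i * 3,
                       rt = 1 + i * 0.3)
    synthConfig(nSubjects = 20L, dropoutCount = 21L,
                dropoutPreset = "replicate-study", effects = effects,
                seed = seed)
}
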