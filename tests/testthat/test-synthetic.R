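test_that("cohort generation balances sexes and matches its distributions", {
    s <- generateSubjects(20, seed = 1)
    expect_equal(sum(s$sex == "Ma"), 10L)
    expect_equal(sum(s$sex == "Fe"), 10L)
    expect_true(all(s$age >= 18 & s$age <= 45))
    expect_equal(nrow(generateSubjects(0)), 0L)
    expect_error(generateSubjects(-1), ">= 0")
    ## Monte-Carlo check of the configured age distribution
    big <- generateSubjects(10000, seed = 99)
    expect_lt(abs(mean(big$age) - 31.2), 0.2)
    expect_lt(abs(sd(big$age) - 4.7), 0.3)
    expect_lt(abs(mean(big$sleep) - 7.5), 0.05)
})

test_that("design generation: factorial size, dropout, determinism", {
    subj <- generateSubjects(20, seed = 1)
    cfg0 <- synthConfig(nSubjects = 20, dropoutCount = 0, seed = 5)
    d0 <- generateDesign(subj, cfg0)
    expect_equal(sum(d0$sample_type == "study"), 180L)
    cfg21 <- synthConfig(nSubjects = 20, dropoutCount = 21, seed = 5)
    d21 <- generateDesign(subj, cfg21)
    expect_equal(sum(d21$sample_type == "study"), 159L)
    ## determinism
    expect_identical(d21, generateDesign(subj, cfg21))
    ## QC/blank interleaving: one leading QC, then one QC + one blank per
    ## block of five study samples
    expect_identical(d21$sample_type[1], "qc_pool")
    expect_equal(sum(d21$sample_type == "qc_pool"), ceiling(159 / 5) + 1)
    expect_equal(sum(d21$sample_type == "blank"), ceiling(159 / 5))
    ## dropout too large
    expect_error(generateDesign(subj, synthConfig(nSubjects = 20,
                                                  dropoutCount = 181)),
                 "exceeds design size")
})

test_that("the replicate-study preset reproduces the surviving margins", {
    subj <- generateSubjects(20, seed = 2)
    cfg <- synthConfig(nSubjects = 20, dropoutCount = 21,
                       dropoutPreset = "replicate-study", seed = 2)
    st <- generateDesign(subj, cfg)
    st <- st[st$sample_type == "study", ]
    expect_equal(nrow(st), 159L)
    expect_equal(unname(table(st$location)[c("AT", "BT", "CK")]),
                 c(56L, 59L, 44L), ignore_attr = TRUE)
    expect_equal(unname(table(st$time)[c("M", "A", "E")]),
                 c(51L, 53L, 55L), ignore_attr = TRUE)
})

test_that("degenerate noise reproduces base levels exactly", {
    subj <- generateSubjects(4, seed = 1)
    eff <- list(effectSpec("m1", baseLevel = 1000, noiseSigma = 1e-12,
                           subjectSigma = 0))
    cfg <- synthConfig(nSubjects = 4, effects = eff, seed = 3)
    d <- generateDesign(subj, cfg)
    ft <- generateAbundances(d, cfg)
    study <- intensities(subsetByType(ft, "study"))
    expect_equal(unname(study["m1", ]), rep(1000, ncol(study)),
                 tolerance = 1e-6)
})

test_that("planted location fold changes are recovered empirically", {
    subj <- generateSubjects(20, seed = 4)
    eff <- list(effectSpec("mk", locationMultipliers = c(AT = 4, BT = 1, CK = 1),
                           noiseSigma = 0.1, subjectSigma = 0.05))
    cfg <- synthConfig(nSubjects = 20, effects = eff, seed = 4)
    d <- generateDesign(subj, cfg)
    ft <- generateAbundances(d, cfg)
    st <- subsetByType(ft, "study")
    loc <- colData(st)$location
    ## geometric-mean ratio estimates the multiplicative effect
    ratio <- 10^(mean(log10(intensities(st)["mk", loc == "AT"])) -
                 mean(log10(intensities(st)["mk", loc == "CK"])))
    expect_lt(abs(ratio - 4) / 4, 0.15)
})

test_that("the correlation copula hits its Spearman target", {
    for (s in 1:3) {
        cfg <- correlationPanelConfig(seed = s)
        subj <- generateSubjects(cfg@nSubjects, seed = s)
        d <- generateDesign(subj, cfg)
        ft <- generateAbundances(d, cfg)
        st <- subsetByType(ft, "study")
        rho <- cor(intensities(st)["cortisol", ],
                   intensities(st)["cortisone", ], method = "spearman")
        expect_lt(abs(rho - 0.94), 0.05)
    }
})

test_that("QC pools are a true pool and blanks sit at blank level", {
    cfg <- synthConfig(nSubjects = 5,
                       effects = list(effectSpec("m1", baseLevel = 1e4)),
                       blankLevel = 77, blankSigma = 1e-9, qcRsd = 1e-9,
                       seed = 6)
    subj <- generateSubjects(5, seed = 6)
    ft <- generateAbundances(generateDesign(subj, cfg), cfg)
    x <- intensities(ft)
    type <- sampleType(ft)
    expect_equal(unname(x["m1", type == "qc_pool"]),
                 rep(mean(x["m1", type == "study"]),
                     sum(type == "qc_pool")), tolerance = 1e-6)
    expect_equal(unname(x["m1", type == "blank"]),
                 rep(77, sum(type == "blank")), tolerance = 1e-6)
})

test_that("rendering splits intensities by adduct fraction and conserves totals", {
    split <- list(m1 = data.frame(polarity = c("pos", "pos"),
                                  adduct = c("[M+H]+", "[M+Na]+"),
                                  fraction = c(0.7, 0.3)),
                  m2 = data.frame(polarity = "pos", adduct = "[M+H]+",
                                  fraction = 1))
    eff <- list(effectSpec("m1", baseLevel = 1000, noiseSigma = 1e-12,
                           subjectSigma = 0),
                effectSpec("m2", exactMass = 200, baseLevel = 500,
                           noiseSigma = 1e-12, subjectSigma = 0))
    cfg <- synthConfig(nSubjects = 3, effects = eff, adductSplit = split,
                       seed = 8)
    subj <- generateSubjects(3, seed = 8)
    truth <- generateAbundances(generateDesign(subj, cfg), cfg)
    r <- renderFeatures(truth, cfg)
    xp <- intensities(r$pos)
    study <- sampleType(r$pos) == "study"
    expect_equal(unname(xp["m1@[M+H]+", study][1]), 700, tolerance = 1e-6)
    expect_equal(unname(xp["m1@[M+Na]+", study][1]), 300, tolerance = 1e-6)
    ## single-adduct metabolite passes through unchanged
    expect_equal(unname(xp["m2@[M+H]+", ]),
                 unname(intensities(truth)["m2", ]))
    ## m/z follows the adduct arithmetic
    expect_equal(rowData(r$pos)["m1@[M+Na]+", "mz"],
                 adductMz(150, "[M+Na]+"))
})

test_that("rendered adduct intensities always sum to the truth (conservation)", {
    for (s in 1:5) {
        set.seed(s)
        fracs <- diff(sort(c(0, runif(2), 1)))  # three random fractions
        split <- list(mx = data.frame(
            polarity = c("pos", "pos", "neg"),
            adduct = c("[M+H]+", "[M+Na]+", "[M-H]-"),
            fraction = fracs))
        cfg <- synthConfig(nSubjects = 4,
                           effects = list(effectSpec("mx")),
                           adductSplit = split, seed = s)
        subj <- generateSubjects(4, seed = s)
        truth <- generateAbundances(generateDesign(subj, cfg), cfg)
        r <- renderFeatures(truth, cfg)
        tot <- colSums(intensities(r$pos)) + colSums(intensities(r$neg))
        expect_equal(unname(tot), unname(intensities(truth)["mx", ]),
                     tolerance = 1e-12)
    }
})

test_that("identical configs produce identical tables (determinism)", {
    cfg <- paperScaleConfig(seed = 11)
    subj <- generateSubjects(cfg@nSubjects, seed = cfg@seed)
    a <- generateAbundances(generateDesign(subj, cfg), cfg)
    b <- generateAbundances(generateDesign(subj, cfg), cfg)
    expect_identical(intensities(a), intensities(b))
})

test_that("fractions not summing to one are rejected", {
    split <- list(m1 = data.frame(polarity = "pos", adduct = "[M+H]+",
                                  fraction = 0.5))
    expect_error(synthConfig(effects = list(effectSpec("m1")),
                             adductSplit = split), "sum to 0.5")
    expect_error(synthConfig(effects = list(
        effectSpec("a", correlationPartner = "ghost",
                   correlationRho = 0.9))), "not in the panel")
})

test_that("standard runs: noiseless replicates are identical up to scaling", {
    std <- toyStandard()
    runs <- generateStandardRuns(list(std), noiseSigma = 0, dropoutProb = 0,
                                 rtJitter = 0, seed = 1)[[1]]
    expect_length(runs, 9L)
    top <- Filter(function(s) s@concentration == 1, runs)
    low <- Filter(function(s) s@concentration == 0.25, runs)
    expect_equal(top[[1]]@peaks, top[[2]]@peaks)
    expect_equal(low[[1]]@peaks[, 2L], top[[1]]@peaks[, 2L] * 0.25)
    expect_error(generateStandardRuns(list(toyStandard(
        fragments = matrix(numeric(), 0, 2)))), "empty fragment list")
})

test_that("a 12-standard mixture yields 12 precursor groups per run", {
    stds <- lapply(1:12, function(i)
        toyStandard(sprintf("std%02d", i), exactMass = 100 + i * 10))
    runs <- generateStandardRuns(stds, seed = 2)
    expect_length(runs, 12L)
    precursors <- vapply(runs, function(r) r[[1]]@precursorMz, numeric(1))
    expect_equal(length(unique(round(precursors, 3))), 12L)
})
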