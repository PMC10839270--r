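test_that("QC metrics reproduce hand-computed values", {
    ft <- qcFixture(study = rbind(c(5, 5, 5, 100), c(20, 20, 20, 20)),
                    qc = rbind(c(100, 100, 100), c(50, 100, 150)),
                    blank = rbind(c(10, 10), c(10, 10)))
    m <- computeQcMetrics(ft)
    expect_equal(m$rsd_pct, c(0, 50))          # sd 0; sd 50 on mean 100
    expect_equal(m$blank_mean, c(10, 10))
    expect_equal(m$frac_below_blank, c(0.75, 0))
    expect_error(computeQcMetrics(ft[, sampleType(ft) != "study"]),
                 "no study samples")
})

test_that("missing values count as below blank; RSD undefined without QCs", {
    ft <- qcFixture(study = matrix(c(NA, NA, 50, 50), 1),
                    qc = matrix(100, 1, 1), blank = matrix(10, 1, 2))
    m <- computeQcMetrics(ft)
    expect_equal(m$frac_below_blank, 0.5)
    expect_true(is.na(m$rsd_pct))  # a single QC injection is not enough
})

test_that("blank filter removes strictly above the threshold fraction", {
    ## 50 study samples, 33 below blank = fraction 0.66 exactly -> kept
    study <- matrix(100, 2, 50)
    study[1, 1:33] <- 1
    study[2, 1:34] <- 1   # 0.68 -> removed
    ft <- qcFixture(study, qc = matrix(100, 2, 3), blank = matrix(10, 2, 2))
    res <- blankFilter(ft)
    expect_identical(featureIds(res$table), "f001")
    expect_equal(res$report@stages$removed, 1L)
    expect_equal(res$report@removed$feature_id, "f002")
})

test_that("RSD filter: strict boundary at 30%, undefined removed distinctly", {
    qc <- rbind(c(100, 100, 100),   # RSD 0 -> kept
                c(70, 100, 130),    # RSD exactly 30 -> kept
                c(50, 100, 150),    # RSD 50 -> removed
                c(0, 0, 0))         # mean 0 -> undefined -> removed
    ft <- qcFixture(matrix(100, 4, 4), qc = qc, blank = matrix(1, 4, 2))
    m <- computeQcMetrics(ft)
    expect_equal(m$rsd_pct[2], 30)
    res <- rsdFilter(ft, m)
    expect_identical(featureIds(res$table), c("f001", "f002"))
    expect_setequal(res$report@removed$reason[res$report@removed$feature_id == "f004"],
                    "rsd_undefined")
})

test_that("adduct summation adds rows and respects missingness rules", {
    x <- rbind(c(100, NA, NA), c(50, 60, NA))
    ft <- qcFixture(x, qc = matrix(1, 2, 2), blank = matrix(1, 2, 1),
                    metabolite = c("metA", "metA"),
                    adduct = c("[M+H]+", "[M+Na]+"))
    res <- sumAdducts(ft)
    expect_equal(nrow(res$table), 1L)
    v <- unname(intensities(res$table)[1, sampleType(res$table) == "study"])
    expect_equal(v[1], 150)          # plain sum
    expect_equal(v[2], 60)           # missing treated as 0 beside a value
    expect_true(is.na(v[3]))         # all-missing stays missing
    expect_equal(res$report@stages$removed, 1L)
    ## single-adduct metabolite unchanged
    ft1 <- qcFixture(matrix(5, 1, 2), qc = matrix(1, 1, 2),
                     blank = matrix(1, 1, 1), metabolite = "metB")
    expect_equal(intensities(sumAdducts(ft1)$table), intensities(ft1))
})

test_that("summing rendered adducts recovers ground-truth intensities", {
    cfg <- paperScaleConfig(seed = 31)
    subj <- generateSubjects(cfg@nSubjects, seed = cfg@seed)
    truth <- generateAbundances(generateDesign(subj, cfg), cfg)
    rendered <- renderFeatures(truth, cfg)$pos
    rowData(rendered)$metabolite <- sub("@.*$", "", featureIds(rendered))
    summed <- sumAdducts(rendered)$table
    ## positive-mode-only metabolites must match the truth exactly
    posOnly <- names(Filter(function(sp) all(sp$polarity == "pos"),
                            cfg@adductSplit))
    posOnly <- intersect(posOnly, rowData(summed)$metabolite)
    expect_gt(length(posOnly), 10)
    for (met in posOnly[1:10]) {
        i <- which(rowData(summed)$metabolite == met)
        expect_equal(unname(intensities(summed)[i, ]),
                     unname(intensities(truth)[met, ]), tolerance = 1e-12)
    }
})

test_that("mode merge keeps the lower-RSD ion form with a positive tie-break", {
    mk <- function(qcRow, pol, met = "shared") {
        qcFixture(matrix(100, 1, 4), qc = matrix(qcRow, 1, 3),
                  blank = matrix(1, 1, 1), metabolite = met, polarity = pol,
                  adduct = if (pol == "pos") "[M+H]+" else "[M-H]-")
    }
    pos <- mk(c(95, 100, 105), "pos")     # RSD 5%
    neg <- mk(c(80, 100, 120), "neg")     # RSD 20%
    res <- mergeModes(pos, neg)
    expect_equal(nrow(res$table), 1L)
    expect_identical(rowData(res$table)$polarity, "pos")
    ## union of disjoint sets
    posB <- mk(c(95, 100, 105), "pos", met = "onlyPos")
    res2 <- mergeModes(posB, neg)
    expect_setequal(rowData(res2$table)$metabolite, c("onlyPos", "shared"))
    ## exact RSD tie keeps positive
    negTie <- mk(c(95, 100, 105), "neg")
    res3 <- mergeModes(pos, negTie)
    expect_identical(rowData(res3$table)$polarity, "pos")
    expect_match(res3$report@provenance$detail, "tie")
    ## asymmetric sample sets are rejected
    expect_error(mergeModes(pos, negTie[, 1:3]), "sample sets differ")
})

test_that("the full curation chain accounts exactly on the 20-feature fixture", {
    ft <- curationFixture()
    empty <- ft[integer(0), ]
    res <- curateFeatures(ft, empty)
    st <- res$report@stages
    expect_equal(st$input[st$stage == "blank_filter"], 20L)
    expect_equal(st$removed[st$stage == "blank_filter"], 3L)
    expect_equal(st$input[st$stage == "rsd_filter"], 17L)
    expect_equal(st$removed[st$stage == "rsd_filter"], 2L)
    expect_equal(nrow(res$table), 15L)
    ## accounting invariant at every stage, and stages chain
    expect_true(all(st$input == st$removed + st$kept))
    expect_equal(st$input[-1], st$kept[-nrow(st)])
})

test_that("curation is idempotent and demands QC columns", {
    ft <- curationFixture()
    empty <- ft[integer(0), ]
    once <- curateFeatures(ft, empty)
    twice <- curateFeatures(once$table, empty)
    expect_equal(sum(twice$report@stages$removed), 0L)
    expect_equal(intensities(twice$table), intensities(once$table))
    noQc <- ft[, sampleType(ft) != "qc_pool"]
    expect_error(curateFeatures(noQc, empty), "QC-pool")
})

test_that("clean zero-noise synthetic data passes curation untouched", {
    cfg <- synthConfig(
        nSubjects = 3,
        effects = list(effectSpec("m1", noiseSigma = 1e-9, subjectSigma = 0),
                       effectSpec("m2", exactMass = 300, noiseSigma = 1e-9,
                                  subjectSigma = 0)),
        qcRsd = 1e-9, blankLevel = 1, blankSigma = 1e-9, seed = 41)
    subj <- generateSubjects(3, seed = 41)
    truth <- generateAbundances(generateDesign(subj, cfg), cfg)
    rendered <- renderFeatures(truth, cfg)$pos
    rowData(rendered)$metabolite <- sub("@.*$", "", featureIds(rendered))
    res <- curateFeatures(rendered, rendered[integer(0), ])
    expect_equal(nrow(res$table), 2L)
    expect_equal(sum(res$report@stages$removed), 0L)
})
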