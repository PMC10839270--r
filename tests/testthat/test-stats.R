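test_that("preprocessing: half-minimum substitution, log10, Z within subset", {
    ft <- qcFixture(rbind(c(1, 10, 100), c(2, 4, 8)))
    pm <- preprocessTable(ft)
    expect_equal(unname(pm@values[1, ]), c(-1, 0, 1))  # sample sd = 1
    ## constant metabolite triggers the zero-variance warning
    cft <- qcFixture(rbind(c(1, 10, 100), c(2, 2, 2)))
    expect_warning(preprocessTable(cft), "zero-variance")
    ## rows are standardized
    ft2 <- randomTable(nf = 6, ns = 8, seed = 3, missingFrac = 0)
    pm3 <- preprocessTable(ft2)
    expect_equal(unname(rowMeans(pm3@values)), rep(0, 6), tolerance = 1e-9)
    expect_equal(unname(apply(pm3@values, 1, sd)), rep(1, 6),
                 tolerance = 1e-9)
})

test_that("preprocessing errors: all-nonpositive metabolite, tiny subsets", {
    x <- rbind(c(0, 0, NA), c(1, 2, 3))
    ft <- qcFixture(x)
    expect_error(preprocessTable(ft), "no positive value")
    ft2 <- qcFixture(matrix(1:4, 1))
    expect_error(preprocessTable(ft2, location = "BT"), "fewer than")
})

test_that("zeros and missing values get half the minimum positive value", {
    ft <- qcFixture(matrix(c(0, NA, 4, 16), 1))
    pm <- preprocessTable(ft)
    v <- unname(pm@values[1, ])
    expect_equal(v[1], v[2])  # 0 and NA both -> 2 -> same Z score
})

test_that("Spearman matrix: monotone invariance and thresholded edges", {
    set.seed(13)
    x <- matrix(rnorm(5 * 30), 5, 30,
                dimnames = list(paste0("m", 1:5), NULL))
    x[2, ] <- x[1, ]^3                       # monotone transform of m1
    x[3, ] <- -x[1, ]
    pm <- new("ProcessedMatrix", values = x,
              sampleInfo = S4Vectors::DataFrame(
                  sample_id = sprintf("s%02d", 1:30)))
    sm <- spearmanMatrix(pm, rhoCutoff = 0.8)
    expect_equal(sm$matrix["m1", "m2"], 1)
    expect_equal(sm$matrix["m1", "m3"], -1)
    expect_true(all(sm$matrix == t(sm$matrix)))
    expect_equal(unname(diag(sm$matrix)), rep(1, 5))
    ## signed cutoff: the rho = -1 pair is not an edge
    expect_true(all(sm$edges$rho > 0.8))
    expect_true(any(sm$edges$metabolite1 == "m1" & sm$edges$metabolite2 == "m2"))
})

test_that("rank correlation is unchanged by the log transform", {
    set.seed(14)
    raw <- matrix(10^runif(4 * 25, 1, 6), 4, 25,
                  dimnames = list(paste0("m", 1:4), NULL))
    mkPm <- function(v) new("ProcessedMatrix", values = v,
                            sampleInfo = S4Vectors::DataFrame(
                                sample_id = sprintf("s%02d", 1:25)))
    expect_equal(spearmanMatrix(mkPm(raw))$matrix,
                 spearmanMatrix(mkPm(log10(raw)))$matrix)
})

test_that("Ward2 clustering recovers planted clusters; heights monotone", {
    set.seed(15)
    a <- matrix(rnorm(40, 0, 0.1), 4, 10)
    b <- matrix(rnorm(40, 10, 0.1), 4, 10)
    x <- cbind(a, b)
    colnames(x) <- sprintf("s%02d", 1:20)
    rownames(x) <- paste0("m", 1:4)
    pm <- new("ProcessedMatrix", values = x,
              sampleInfo = S4Vectors::DataFrame(sample_id = colnames(x)))
    hc <- ward2Linkage(pm, axis = "samples")
    expect_identical(hc$method, "ward.D2")
    expect_true(all(diff(hc$height) >= -1e-12))
    k2 <- cutree(hc, 2)
    expect_equal(length(unique(k2[1:10])), 1L)
    expect_equal(length(unique(k2[11:20])), 1L)
    expect_false(k2[1] == k2[11])
    ## duplicated item merges first at height zero
    x2 <- x; x2[, 2] <- x2[, 1]
    pm2 <- new("ProcessedMatrix", values = x2, sampleInfo = pm@sampleInfo)
    hc2 <- ward2Linkage(pm2, axis = "samples")
    expect_equal(hc2$height[1], 0)
    expect_setequal(-hc2$merge[1, ], c(1, 2))
    one <- new("ProcessedMatrix", values = x[, 1, drop = FALSE],
               sampleInfo = S4Vectors::DataFrame(sample_id = "s01"))
    expect_error(ward2Linkage(one, axis = "samples"), "at least 2")
})

test_that("PCA: single-direction data, orthogonal scores, subset separation", {
    set.seed(16)
    dir <- rnorm(5)
    x <- outer(dir, rnorm(12))
    rownames(x) <- paste0("m", 1:5); colnames(x) <- sprintf("s%02d", 1:12)
    pm <- new("ProcessedMatrix", values = x,
              sampleInfo = S4Vectors::DataFrame(sample_id = colnames(x)))
    pc <- pcaScores(pm)
    expect_equal(pc$explained[1], 1, tolerance = 1e-9)
    y <- matrix(rnorm(6 * 20), 6, 20,
                dimnames = list(paste0("m", 1:6), sprintf("s%02d", 1:20)))
    pm2 <- new("ProcessedMatrix", values = y,
               sampleInfo = S4Vectors::DataFrame(sample_id = colnames(y)))
    sc <- pcaScores(pm2, nComponents = 4)$scores
    expect_equal(abs(crossprod(sc[, 1], sc[, 2])[1]), 0, tolerance = 1e-9)
})

test_that("PCA separates planted location clusters (silhouette > 0.3)", {
    cfg <- paperScaleConfig(seed = 17)
    subj <- generateSubjects(cfg@nSubjects, seed = cfg@seed)
    truth <- generateAbundances(generateDesign(subj, cfg), cfg)
    pm <- preprocessTable(truth)
    pc <- pcaScores(pm)
    sil <- meanSilhouette(pc$scores, pm@sampleInfo$location)
    expect_gt(sil, 0.3)
})

test_that("Wilcoxon p values match exhaustive enumeration", {
    ft <- qcFixture(matrix(c(1, 2, 3, 4, 5, 6), 1),
                    locations = c("AT", "AT", "AT", "BT", "BT", "BT"))
    r <- wilcoxonFc(ft, "location", c("AT", "BT"), mTests = 1)
    expect_equal(r$p_raw, 0.1)  # 2/20 assignments as extreme
    ## random small groups, no ties
    set.seed(18)
    for (trial in 1:10) {
        n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
        a <- sample(100, n1); b <- sample(200:300, n2)
        ft2 <- qcFixture(matrix(c(a, b), 1),
                         locations = rep(c("AT", "BT"), c(n1, n2)))
        r2 <- wilcoxonFc(ft2, "location", c("AT", "BT"), mTests = 1)
        expect_equal(r2$p_raw, enumWilcoxP(a, b), tolerance = 1e-12)
    }
})

test_that("identical groups give p 1 and zero fold change", {
    ft <- qcFixture(matrix(rep(c(5, 7, 9), 2), 1),
                    locations = rep(c("AT", "BT"), each = 3))
    r <- wilcoxonFc(ft, "location", c("AT", "BT"), mTests = 1)
    expect_equal(r$p_raw, 1)
    expect_equal(r$log2fc, 0)
    expect_false(r$significant)
    expect_error(wilcoxonFc(ft, "location", c("AT", "CK")), "empty group")
})

test_that("Bonferroni arithmetic and dominance", {
    ft <- qcFixture(matrix(c(1, 2, 3, 104, 105, 106), 1),
                    locations = rep(c("AT", "BT"), each = 3))
    r <- wilcoxonFc(ft, "location", c("AT", "BT"), mTests = 177)
    expect_equal(r$p_adj, min(1, 177 * r$p_raw))
    expect_gte(r$p_adj, r$p_raw)
    ## the documented worked product: 0.0001 * 177
    expect_equal(min(1, 177 * 1e-4), 0.0177)
})

test_that("swapping group order negates log2fc and keeps p (antisymmetry)", {
    set.seed(19)
    ft <- qcFixture(matrix(10^runif(3 * 12, 2, 5), 3),
                    locations = rep(c("AT", "CK"), each = 6),
                    metabolite = paste0("m", 1:3))
    f <- wilcoxonFc(ft, "location", c("AT", "CK"), mTests = 3)
    b <- wilcoxonFc(ft, "location", c("CK", "AT"), mTests = 3)
    expect_equal(f$log2fc, -b$log2fc, tolerance = 1e-12)
    expect_equal(f$p_raw, b$p_raw, tolerance = 1e-12)
})

test_that("planted location effects are recovered with FWER control", {
    cfg <- paperScaleConfig(seed = 23)
    subj <- generateSubjects(cfg@nSubjects, seed = cfg@seed)
    truth <- generateAbundances(generateDesign(subj, cfg), cfg)
    rc <- runComparisons(truth)
    gt <- groundTruthTable(cfg)
    markers <- gt$metabolite[!is.na(gt$marker_location)]
    nulls <- gt$metabolite[gt$is_null]
    sens <- mean(markers %in% rc$significant$location)
    expect_gte(sens, 0.9)
    flagged <- unique(unlist(rc$significant))
    expect_lte(sum(nulls %in% flagged) / length(nulls), 0.05)
})

test_that("all-null panels yield no significant calls across seeds", {
    hits <- vapply(1:5, function(s) {
        eff <- lapply(1:100, function(i)
            effectSpec(sprintf("n%03d", i), exactMass = 100 + i * 2.5))
        cfg <- synthConfig(nSubjects = 12, effects = eff, seed = 100 + s)
        subj <- generateSubjects(12, seed = 100 + s)
        truth <- generateAbundances(generateDesign(subj, cfg), cfg)
        rc <- runComparisons(truth, factors = c("location", "time"))
        length(unique(unlist(rc$significant)))
    }, numeric(1))
    expect_lte(sum(hits > 0), 1)  # family-wise control across the seed grid
})

test_that("a planted sex effect flags exactly the caffeine cluster", {
    caff <- c("caffeine", "paraxanthine", "theophylline")
    eff <- c(lapply(caff, function(m)
        effectSpec(m, "alkaloids", exactMass = 150 + match(m, caff) * 7,
                   sexMultipliers = c(Ma = 1, Fe = 5))),
        lapply(1:20, function(i)
            effectSpec(sprintf("n%02d", i), exactMass = 300 + i * 3)))
    cfg <- synthConfig(nSubjects = 20, effects = eff, seed = 77)
    subj <- generateSubjects(20, seed = 77)
    truth <- generateAbundances(generateDesign(subj, cfg), cfg)
    rc <- runComparisons(truth, factors = "sex")
    expect_setequal(rc$significant$sex, caff)
})

test_that("stratified time tests separate systemic from BT-only rhythms", {
    cfg <- paperScaleConfig(seed = 29)
    subj <- generateSubjects(cfg@nSubjects, seed = cfg@seed)
    truth <- generateAbundances(generateDesign(subj, cfg), cfg)
    strat <- stratifiedTimeTests(truth)
    ## systemic diurnal metabolites appear in every stratum
    for (m in c("cortisol", "cortisone"))
        expect_true(all(vapply(strat$significant, function(s) m %in% s,
                               logical(1))))
    ## BT-only metabolites appear in BT and nowhere else
    for (m in c("valine", "adenosine-cyclic-phosphate")) {
        expect_true(m %in% strat$significant$BT)
        expect_false(m %in% strat$significant$AT)
        expect_false(m %in% strat$significant$CK)
    }
    ## the nadir-in-M profile has a negative M-vs-A fold change
    mva <- strat$perStratum$BT$results[["time:M_vs_A"]]
    expect_lt(mva$log2fc[mva$metabolite == "N-acetyl-tryptophan"], 0)
    expect_gt(mva$log2fc[mva$metabolite == "cortisol"], 0)
})

test_that("Venn region counts match brute-force set arithmetic", {
    vc <- vennCounts(list(location = c("a", "b"), time = "b",
                          sex = character()))
    get <- function(region) vc$count[vc$region == region]
    expect_equal(get("location"), 1L)
    expect_equal(get("location+time"), 1L)
    expect_equal(sum(vc$count), 2L)
    ## identical sets put all mass in the triple intersection
    vc2 <- vennCounts(list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y")))
    expect_equal(vc2$count[vc2$region == "A+B+C"], 2L)
    expect_equal(sum(vc2$count), 2L)
    ## random sets against brute force
    set.seed(20)
    univ <- paste0("m", 1:30)
    sets <- list(A = sample(univ, 12), B = sample(univ, 8),
                 C = sample(univ, 15))
    vc3 <- vennCounts(sets)
    brute <- 0L
    for (m in univ) {
        memb <- vapply(sets, function(s) m %in% s, logical(1))
        if (any(memb)) {
            region <- paste(names(sets)[memb], collapse = "+")
            expect_true(region %in% vc3$region)
            brute <- brute + 1L
        }
    }
    expect_equal(sum(vc3$count), brute)
})

test_that("top discriminatory ranking is deterministic and effect-driven", {
    cfg <- paperScaleConfig(seed = 37)
    subj <- generateSubjects(cfg@nSubjects, seed = cfg@seed)
    truth <- generateAbundances(generateDesign(subj, cfg), cfg)
    rc <- runComparisons(truth, factors = "location")
    top <- topDiscriminatory(rc$results, k = 10)
    expect_length(top, 10L)
    gt <- groundTruthTable(cfg)
    markers <- gt$metabolite[!is.na(gt$marker_location)]
    expect_true(all(top %in% markers))
    ## permuting the comparison list leaves the ranking unchanged
    expect_identical(topDiscriminatory(rev(rc$results), k = 10), top)
    ## k beyond the panel returns everything
    expect_length(topDiscriminatory(rc$results, k = 1e6), nrow(truth))
})
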