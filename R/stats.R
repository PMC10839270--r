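## The statistical battery: log10 + Z preprocessing, Spearman correlation
## networks, Ward2 clustering, subset PCA, pairwise Wilcoxon rank-sum tests
## with Bonferroni correction and fold changes, stratified time tests and
## Venn summaries.

.LOCATION_PAIRS <- list(c("AT", "BT"), c("AT", "CK"), c("BT", "CK"))
.TIME_PAIRS <- list(c("M", "A"), c("M", "E"), c("A", "E"))

#' Log10 + per-metabolite Z-score preprocessing
#'
#' Subsets the study samples (optionally further by location/time), replaces
#' zeros and missing values by half the per-metabolite minimum positive value,
#' log10-transforms, and Z-scores each metabolite within the subset (the
#' subset-then-normalize order used for all subset analyses).
#'
#' @param table a curated [FeatureTable-class] (rows named by metabolite).
#' @param location,time optional level(s) to subset to.
#' @param minSamples minimal subset size.
#' @return a [ProcessedMatrix-class].
#' @export
preprocessTable <- function(table, location = NULL, time = NULL,
                            minSamples = 3L) {
    tab <- subsetByType(table, "study")
    cd <- colData(tab)
    keep <- rep(TRUE, ncol(tab))
    if (!is.null(location)) keep <- keep & cd$location %in% location
    if (!is.null(time)) keep <- keep & cd$time %in% time
    tab <- tab[, keep]
    if (ncol(tab) < minSamples)
        stop("fewer than ", minSamples, " samples after subsetting")
    x <- intensities(tab)
    for (i in seq_len(nrow(x))) {
        v <- x[i, ]
        pos <- v[!is.na(v) & v > 0]
        if (!length(pos))
            stop(sprintf("metabolite '%s' has no positive value in the subset",
                         rownames(x)[i]))
        v[is.na(v) | v == 0] <- min(pos) / 2
        x[i, ] <- v
    }
    x <- log10(x)
    mu <- rowMeans(x)
    sdv <- apply(x, 1L, stats::sd)
    if (any(sdv == 0))
        warning("zero-variance metabolite(s): ",
                paste(rownames(x)[sdv == 0], collapse = ", "))
    z <- (x - mu) / ifelse(sdv == 0, 1, sdv)
    info <- as.data.frame(cd[keep, c("sample_id", "subject_id", "location",
                                     "time", "sex"), drop = FALSE])
    new("ProcessedMatrix", values = z, sampleInfo = S4Vectors::DataFrame(info))
}

#' Spearman correlation matrix and thresholded edge list
#'
#' All pairwise Spearman rank correlations (average ranks for ties) between
#' metabolites, with the edge list filtered to signed rho > `rhoCutoff`.
#' P values use the large-sample t approximation on n-2 degrees of freedom.
#'
#' @param m a [ProcessedMatrix-class] (rank correlations are invariant to its
#'   monotone preprocessing).
#' @param rhoCutoff signed correlation cutoff, default 0.8.
#' @return list with `matrix` (full symmetric rho matrix) and `edges`
#'   (data.frame `metabolite1`, `metabolite2`, `rho`, `p`).
#' @export
spearmanMatrix <- function(m, rhoCutoff = 0.8) {
    x <- t(m@values)
    n <- nrow(x)
    if (n < 3L) stop("need at least 3 samples")
    rho <- stats::cor(x, method = "spearman")
    ut <- which(upper.tri(rho), arr.ind = TRUE)
    r <- rho[ut]
    tstat <- r * sqrt((n - 2) / pmax(1e-12, 1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    edges <- data.frame(metabolite1 = colnames(x)[ut[, 1L]],
                        metabolite2 = colnames(x)[ut[, 2L]],
                        rho = r, p = p, stringsAsFactors = FALSE)
    list(matrix = rho,
         edges = edges[edges$rho > rhoCutoff, , drop = FALSE])
}

#' Ward2 hierarchical clustering
#'
#' Agglomerative clustering with the Ward.D2 criterion on Euclidean
#' distances (merge heights are non-decreasing).
#'
#' @param m a [ProcessedMatrix-class].
#' @param axis cluster `"samples"` or `"metabolites"`.
#' @return an [stats::hclust] object.
#' @export
ward2Linkage <- function(m, axis = c("samples", "metabolites")) {
    axis <- match.arg(axis)
    x <- if (axis == "samples") t(m@values) else m@values
    if (nrow(x) < 2L) stop("need at least 2 items to cluster")
    stats::hclust(stats::dist(x), method = "ward.D2")
}

#' Principal component analysis of a processed subset
#'
#' Centered PCA via singular value decomposition on the samples.
#'
#' @param m a [ProcessedMatrix-class].
#' @param nComponents number of score columns returned.
#' @return list with `scores` (samples x components), `explained`
#'   (variance fractions for all components) and `sampleInfo`.
#' @export
pcaScores <- function(m, nComponents = 2L) {
    x <- t(m@values)
    if (nrow(x) < 2L) stop("need at least 2 samples")
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(nComponents, ncol(pc$x))
    list(scores = pc$x[, seq_len(k), drop = FALSE],
         explained = pc$sdev^2 / sum(pc$sdev^2),
         sampleInfo = m@sampleInfo)
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction and fold change
#'
#' Two-sided rank-sum test per metabolite on raw intensities (exact
#' enumeration when both groups have at most `exactMax` observations and no
#' ties; normal approximation with continuity and tie corrections otherwise);
#' Bonferroni adjustment `p_adj = min(1, mTests * p)`; log2 fold change from
#' raw-scale group means (group1 / group2, half-minimum-positive substitution
#' for nonpositive means). A metabolite is significant when `p_adj < alpha`
#' and `|log2fc| > log2(fc)`.
#'
#' @param table a curated [FeatureTable-class].
#' @param groupBy name of the grouping column in `colData` ("location",
#'   "time" or "sex"), or a vector of group labels per study sample.
#' @param pair character(2): the ordered group pair (group1, group2).
#' @param mTests Bonferroni family size; defaults to the metabolite count.
#' @param alpha significance level on the adjusted p value.
#' @param fc fold-change threshold on the raw scale.
#' @param exactMax largest group size for exact enumeration.
#' @param useMedians use group medians instead of means for the fold change.
#' @return data.frame: `metabolite`, `group1`, `group2`, `p_raw`, `p_adj`,
#'   `log2fc`, `significant`.
#' @export
wilcoxonFc <- function(table, groupBy, pair, mTests = nrow(table),
                       alpha = 0.05, fc = 2, exactMax = 8L,
                       useMedians = FALSE) {
    tab <- subsetByType(table, "study")
    labels <- if (is.character(groupBy) && length(groupBy) == 1L)
        colData(tab)[[groupBy]] else groupBy
    g1 <- which(labels == pair[1L]); g2 <- which(labels == pair[2L])
    if (!length(g1) || !length(g2))
        stop("empty group: ", pair[which(c(length(g1), length(g2)) == 0L)[1L]])
    x <- intensities(tab)
    center <- if (useMedians) function(v) stats::median(v, na.rm = TRUE)
              else function(v) mean(v, na.rm = TRUE)
    res <- lapply(seq_len(nrow(x)), function(i) {
        a <- x[i, g1]; b <- x[i, g2]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        exact <- length(a) <= exactMax && length(b) <= exactMax &&
            !anyDuplicated(c(a, b))
        p <- if (!length(a) || !length(b)) NA_real_ else
            suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                                correct = TRUE)$p.value)
        ma <- center(a); mb <- center(b)
        if (is.na(ma) || ma <= 0 || is.na(mb) || mb <= 0) {
            posAll <- c(a, b); posAll <- posAll[posAll > 0]
            half <- if (length(posAll)) min(posAll) / 2 else NA_real_
            if (is.na(ma) || ma <= 0) ma <- half
            if (is.na(mb) || mb <= 0) mb <- half
        }
        c(p = p, log2fc = log2(ma / mb))
    })
    res <- do.call(rbind, res)
    pAdj <- pmin(1, mTests * res[, "p"])
    data.frame(metabolite = rownames(x),
               group1 = pair[1L], group2 = pair[2L],
               p_raw = unname(res[, "p"]), p_adj = unname(pAdj),
               log2fc = unname(res[, "log2fc"]),
               significant = !is.na(pAdj) & pAdj < alpha &
                   abs(res[, "log2fc"]) > log2(fc),
               stringsAsFactors = FALSE)
}

#' Run the full battery of pairwise comparisons
#'
#' Location pairs (AT/BT, AT/CK, BT/CK), time pairs (M/A, M/E, A/E) and sex
#' (Ma/Fe), each Bonferroni-corrected with the metabolite count as family
#' size; the per-factor significant set is the union over that factor's
#' pairs.
#'
#' @param table a curated [FeatureTable-class].
#' @param factors which factors to test.
#' @inheritParams wilcoxonFc
#' @return list with `results` (named list of per-comparison data.frames) and
#'   `significant` (named list of per-factor metabolite sets).
#' @export
runComparisons <- function(table, factors = c("location", "time", "sex"),
                           alpha = 0.05, fc = 2, mTests = nrow(table)) {
    results <- list()
    sig <- list()
    addPair <- function(factor, pair) {
        key <- paste0(factor, ":", pair[1L], "_vs_", pair[2L])
        r <- wilcoxonFc(table, factor, pair, mTests = mTests,
                        alpha = alpha, fc = fc)
        results[[key]] <<- r
        sig[[factor]] <<- union(sig[[factor]] %||% character(),
                                r$metabolite[r$significant])
    }
    cd <- colData(subsetByType(table, "study"))
    if ("location" %in% factors) {
        if (anyNA(cd$location)) stop("missing location labels")
        for (p in .LOCATION_PAIRS) addPair("location", p)
    }
    if ("time" %in% factors) {
        if (anyNA(cd$time)) stop("missing time labels")
        for (p in .TIME_PAIRS) addPair("time", p)
    }
    if ("sex" %in% factors) {
        if (!"sex" %in% colnames(cd) || anyNA(cd$sex))
            stop("missing sex labels")
        addPair("sex", c("Ma", "Fe"))
    }
    list(results = results, significant = sig)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time-domain tests stratified by oral location
#'
#' Runs the pairwise time comparisons separately within each location (the
#' spatial-interference-free view of diurnal change) and reports, per
#' stratum, the significant metabolite set, plus the metabolites significant
#' in every stratum.
#'
#' @param table a curated [FeatureTable-class].
#' @inheritParams wilcoxonFc
#' @return list with `perStratum` (named list of [runComparisons()] outputs),
#'   `significant` (per-stratum metabolite sets), `counts` (named integer
#'   vector) and `allStrata` (metabolites significant in every tested
#'   stratum).
#' @export
stratifiedTimeTests <- function(table, alpha = 0.05, fc = 2,
                                mTests = nrow(table)) {
    study <- subsetByType(table, "study")
    out <- list(); sig <- list()
    for (loc in .LOCATIONS) {
        sub <- table[, sampleType(table) != "study" |
                       (!is.na(colData(table)$location) &
                        colData(table)$location == loc)]
        tms <- unique(colData(subsetByType(sub, "study"))$time)
        if (!all(.TIMES %in% tms)) {
            warning("stratum ", loc, " lacks a time group; skipped")
            next
        }
        rc <- runComparisons(sub, factors = "time", alpha = alpha, fc = fc,
                             mTests = mTests)
        out[[loc]] <- rc
        sig[[loc]] <- rc$significant$time %||% character()
    }
    counts <- vapply(sig, length, integer(1))
    allStrata <- if (length(sig)) Reduce(intersect, sig) else character()
    list(perStratum = out, significant = sig, counts = counts,
         allStrata = allStrata)
}

#' Venn region counts of per-factor significant sets
#'
#' @param sigSets named list of metabolite sets (e.g. location/time/sex).
#' @return data.frame with one row per intersection region (`region` as a
#'   `+`-joined label, `count`).
#' @export
vennCounts <- function(sigSets) {
    fac <- names(sigSets)
    all <- unique(unlist(sigSets))
    member <- vapply(sigSets, function(s) all %in% s,
                     logical(length(all)))
    if (length(all) == 1L) member <- matrix(member, nrow = 1L,
                                            dimnames = list(NULL, fac))
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(fac)),
                          KEEP.OUT.ATTRS = FALSE)
    colnames(combos) <- fac
    combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
    data.frame(
        region = apply(combos, 1L, function(r)
            paste(fac[as.logical(r)], collapse = "+")),
        count = apply(combos, 1L, function(r) {
            if (!length(all)) return(0L)
            sum(apply(member, 1L, function(mr) all(mr == as.logical(r))))
        }),
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Top discriminatory metabolites of a factor
#'
#' Ranks metabolites by their minimum adjusted p value across the factor's
#' pairwise comparisons, breaking ties by larger absolute log2 fold change,
#' then alphabetically for determinism.
#'
#' @param results named list of comparison data.frames (as in the `results`
#'   element of [runComparisons()], already restricted to one factor's pairs
#'   or not — all supplied comparisons are used).
#' @param k number of metabolites to return.
#' @return character vector of metabolite names, best first.
#' @export
topDiscriminatory <- function(results, k = 10L) {
    if (!length(results)) stop("no comparison results supplied")
    all <- do.call(rbind, results)
    agg <- do.call(rbind, lapply(split(all, all$metabolite), function(d) {
        data.frame(metabolite = d$metabolite[1L],
                   min_p_adj = suppressWarnings(min(d$p_adj, na.rm = TRUE)),
                   max_abs_fc = suppressWarnings(max(abs(d$log2fc),
                                                     na.rm = TRUE)))
    }))
    agg <- agg[order(agg$min_p_adj, -agg$max_abs_fc, agg$metabolite), ]
    utils::head(agg$metabolite, k)
}

#' Mean silhouette width of a labelling on a score matrix
#'
#' @param scores samples x dimensions matrix (e.g. PC1-PC2 scores).
#' @param labels group label per sample.
#' @return mean silhouette width over all samples.
#' @export
meanSilhouette <- function(scores, labels) {
    d <- as.matrix(stats::dist(scores))
    labels <- as.character(labels)
    s <- vapply(seq_along(labels), function(i) {
        own <- labels == labels[i]
        a <- if (sum(own) > 1L) mean(d[i, own & seq_along(labels) != i]) else 0
        b <- min(vapply(setdiff(unique(labels), labels[i]),
                        function(g) mean(d[i, labels == g]), numeric(1)))
        if (sum(own) == 1L) return(0)
        (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
}
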