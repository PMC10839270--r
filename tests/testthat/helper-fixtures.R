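## Fixture builders shared across the suite. Everything is generated in code;
## no binary fixtures.

## A feature table with explicit study/QC/blank blocks from plain matrices.
## Rows of `study` (and friends) are features; feature metadata is synthesized
## unless supplied.
qcFixture <- function(study, qc = NULL, blank = NULL,
                      locations = NULL, times = NULL, sex = NULL,
                      metabolite = NULL, polarity = "pos",
                      adduct = "[M+H]+", mz = NULL, rt = NULL) {
    study <- as.matrix(study)
    nf <- nrow(study)
    ns <- ncol(study)
    x <- study
    type <- rep("study", ns)
    if (!is.null(qc)) {
        qc <- matrix(qc, nrow = nf)
        x <- cbind(x, qc); type <- c(type, rep("qc_pool", ncol(qc)))
    }
    if (!is.null(blank)) {
        blank <- matrix(blank, nrow = nf)
        x <- cbind(x, blank); type <- c(type, rep("blank", ncol(blank)))
    }
    n <- length(type)
    st <- type == "study"
    cd <- data.frame(
        sample_id = sprintf("s%02d", seq_len(n)),
        subject_id = ifelse(st, sprintf("P%02d", seq_len(n)), NA),
        location = NA_character_, time = NA_character_,
        sample_type = type, run_order = seq_len(n),
        sex = NA_character_, stringsAsFactors = FALSE)
    cd$location[st] <- if (is.null(locations)) "AT" else locations
    cd$time[st] <- if (is.null(times)) "M" else times
    cd$sex[st] <- if (is.null(sex)) "Ma" else sex
    fd <- data.frame(
        feature_id = sprintf("f%03d", seq_len(nf)),
        polarity = polarity,
        mz = if (is.null(mz)) 100 + seq_len(nf) else mz,
        rt = if (is.null(rt)) seq_len(nf) / 10 else rt,
        adduct = adduct, stringsAsFactors = FALSE)
    if (!is.null(metabolite)) {
        fd$metabolite <- metabolite
        fd$id_level <- ifelse(is.na(metabolite), NA_integer_, 1L)
        fd$id_score <- ifelse(is.na(metabolite), NA_real_, 100)
    }
    FeatureTable(x, fd, cd)
}

## random valid feature table for round-trip properties
randomTable <- function(nf = 5, ns = 4, seed = 1, missingFrac = 0.1) {
    set.seed(seed)
    x <- matrix(10^runif(nf * ns, 2, 6), nf, ns)
    x[sample(length(x), round(missingFrac * length(x)))] <- NA
    qcFixture(x, locations = sample(c("AT", "BT", "CK"), ns, TRUE),
              times = sample(c("M", "A", "E"), ns, TRUE))
}

## toy MS/MS spectrum
spec <- function(peaks, precursorMz = 300, rt = 5, polarity = "pos",
                 concentration = 1, replicate = 1L) {
    MsmsSpectrum(precursorMz, rt, polarity, peaks,
                 concentration = concentration, replicate = replicate)
}

## random library entry for MSP round-trip properties
randomEntry <- function(i, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    nFrag <- sample(0:6, 1)
    cons <- if (nFrag > 0) {
        relint <- runif(nFrag, 1, 99)
        relint[which.max(relint)] <- 100
        mz <- sort(runif(nFrag, 50, 600))
        cbind(mz = mz, relint = relint)
    } else matrix(numeric(), 0, 2)
    LibraryEntry(name = sprintf("compound_%03d", i),
                 exactMass = runif(1, 80, 600),
                 polarity = sample(c("pos", "neg"), 1),
                 adducts = sample(c("[M+H]+", "[M-H]-", "[M+Na]+"), 1),
                 rtMean = runif(1, 0.5, 12), rtDev = runif(1, 0, 0.3),
                 consensus = cons,
                 inchikey = if (runif(1) < 0.5) NA_character_ else
                     "ABCDEFGHIJKLMN-OPQRSTUVWXYZAB-C")
}

## exhaustive two-sided rank-sum p value by enumeration over assignments
enumWilcoxP <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    pool <- c(a, b)
    r <- rank(pool)
    obsU <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- utils::combn(n1 + n2, n1)
    Us <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    min(1, 2 * min(mean(Us <= obsU), mean(Us >= obsU)))
}

## 20-feature fixture with known memberships: 3 blank-level features,
## 2 high-RSD features, 15 clean. 10 study samples, 3 QC pools, 2 blanks.
curationFixture <- function() {
    nf <- 20; ns <- 10
    study <- matrix(1000, nf, ns)
    qc <- matrix(1000, nf, 3)
    blank <- matrix(10, nf, 2)
    ## features 1-3: study signal below the blank mean everywhere
    study[1:3, ] <- 5
    qc[1:3, ] <- 5
    ## features 4-5: QC RSD 50%
    qc[4, ] <- c(50, 100, 150)
    qc[5, ] <- c(40, 80, 120)
    qcFixture(study, qc = qc, blank = blank,
              metabolite = sprintf("met%02d", 1:20))
}

## tiny ground-truth standard
toyStandard <- function(name = "std1", exactMass = 180.0634,
                        polarity = "pos", rt = 3,
                        fragments = cbind(mz = c(85, 127, 181),
                                          relint = c(20, 55, 100))) {
    list(name = name, exactMass = exactMass, polarity = polarity,
         rt = rt, fragments = fragments)
}
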