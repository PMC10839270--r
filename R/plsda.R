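## Partial least squares discriminant analysis: NIPALS PLS2 against a
## one-hot class response, VIP scoring, stratified cross-validated R2Y/Q2,
## and a permutation test on Q2.

.oneHot <- function(labels) {
    classes <- sort(unique(as.character(labels)))
    Y <- vapply(classes, function(cl) as.numeric(labels == cl),
                numeric(length(labels)))
    colnames(Y) <- classes
    Y
}

## core NIPALS PLS2 on column-centered X (n x p) and Y (n x c)
.nipals <- function(X, Y, A, tol = 1e-10, maxIter = 500L) {
    n <- nrow(X); p <- ncol(X); cc <- ncol(Y)
    Tm <- matrix(0, n, A); W <- matrix(0, p, A)
    P <- matrix(0, p, A); Q <- matrix(0, cc, A)
    ssy <- numeric(A)
    E <- X; F_ <- Y
    for (a in seq_len(A)) {
        u <- F_[, which.max(apply(F_, 2L, stats::var)), drop = TRUE]
        if (sum(u^2) < 1e-12) u <- F_[, 1L]
        t_old <- rep(Inf, n)
        for (it in seq_len(maxIter)) {
            w <- crossprod(E, u)[, 1L]
            nw <- sqrt(sum(w^2))
            if (nw < 1e-14) stop("degenerate rank: X residual is null")
            w <- w / nw
            t_ <- E %*% w
            q <- crossprod(F_, t_)[, 1L] / sum(t_^2)
            u <- F_ %*% q / sum(q^2)
            if (sum((t_ - t_old)^2) < tol * sum(t_^2)) break
            t_old <- t_
        }
        p_ <- crossprod(E, t_)[, 1L] / sum(t_^2)
        ssBefore <- sum(F_^2)
        E <- E - t_ %*% t(p_)
        F_ <- F_ - t_ %*% t(q)
        ssy[a] <- ssBefore - sum(F_^2)
        Tm[, a] <- t_; W[, a] <- w; P[, a] <- p_; Q[, a] <- q
    }
    list(scores = Tm, weights = W, loadings = P, yLoadings = Q, ssy = ssy,
         yResidual = F_)
}

#' Fit a PLS-DA model
#'
#' NIPALS PLS2 of the processed data against the one-hot class response.
#' X and Y are column-centered before fitting (the processed matrix is
#' already unit-variance per metabolite). Deterministic given the input
#' order; the fitted subspace is invariant to sample order.
#'
#' @param m a [ProcessedMatrix-class] or a samples x variables matrix.
#' @param labels class label per sample (>= 2 classes, each >= 2 samples).
#' @param nComponents number of latent components.
#' @return a [PlsdaModel-class] with training R2Y and VIP scores (Q2 and the
#'   permutation p are `NA` until [crossValidatePlsda()] /
#'   [permutationTestPlsda()] are run).
#' @export
fitPlsda <- function(m, labels, nComponents = 2L) {
    X <- if (is(m, "ProcessedMatrix")) t(m@values) else as.matrix(m)
    labels <- as.character(labels)
    if (length(labels) != nrow(X))
        stop("labels length does not match sample count")
    tabn <- table(labels)
    if (length(tabn) < 2L) stop("need at least 2 classes")
    if (any(tabn < 2L)) stop("every class needs at least 2 samples")
    Y <- .oneHot(labels)
    xm <- colMeans(X); ym <- colMeans(Y)
    Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
    fit <- .nipals(Xc, Yc, nComponents)
    rownames(fit$weights) <- rownames(fit$loadings) <- colnames(X)
    rownames(fit$yLoadings) <- colnames(Y)
    rownames(fit$scores) <- rownames(X)
    r2y <- sum(fit$ssy) / sum(Yc^2)
    model <- new("PlsdaModel", scores = fit$scores, weights = fit$weights,
                 loadings = fit$loadings, yLoadings = fit$yLoadings,
                 Y = Y, classes = colnames(Y), ssy = fit$ssy, r2y = r2y,
                 q2 = NA_real_, vip = numeric(), permutationP = NA_real_,
                 xMeans = xm, yMeans = ym)
    model@vip <- vipScores(model)
    model
}

#' Variable importance in projection (VIP) scores
#'
#' VIP_j = sqrt(p * sum_a(SSY_a * (w_ja / ||w_a||)^2) / sum_a(SSY_a)) with p
#' variables; the mean of VIP^2 over variables is 1 by construction. The
#' conventional selection set is VIP > 1.25.
#'
#' @param model a fitted [PlsdaModel-class].
#' @return named numeric vector of VIP scores.
#' @seealso [vipSelected()] for the conventional VIP > 1.25 selection set.
#' @export
vipScores <- function(model) {
    W <- model@weights
    if (!ncol(W)) stop("unfitted model")
    p <- nrow(W)
    Wn <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
    ssy <- model@ssy
    vip <- sqrt(p * as.numeric(Wn^2 %*% ssy) / sum(ssy))
    names(vip) <- rownames(W)
    vip
}

#' Metabolites above a VIP cutoff
#'
#' @param model a fitted [PlsdaModel-class].
#' @param cutoff VIP cutoff, conventionally 1.25.
#' @return character vector of selected variable names.
#' @export
vipSelected <- function(model, cutoff = 1.25) {
    vip <- vipScores(model)
    names(vip)[vip > cutoff]
}

## predict class responses for new (uncentered) X rows
.predictPlsda <- function(model, Xnew) {
    W <- model@weights; P <- model@loadings; Q <- model@yLoadings
    Bstar <- W %*% solve(crossprod(P, W)) %*% t(Q)
    pred <- sweep(sweep(Xnew, 2L, model@xMeans) %*% Bstar, 2L,
                  model@yMeans, "+")
    colnames(pred) <- model@classes
    pred
}

#' Cross-validated R2Y and Q2
#'
#' Stratified k-fold cross-validation: Q2 = 1 - PRESS / SSY where PRESS sums
#' squared one-hot prediction errors over held-out folds and SSY is the total
#' centered Y sum of squares; R2Y comes from the full-data fit.
#'
#' @param m a [ProcessedMatrix-class] or samples x variables matrix.
#' @param labels class label per sample.
#' @param nComponents number of latent components.
#' @param folds number of folds (each training fold must retain every class).
#' @param seed integer seed for the fold assignment.
#' @return named numeric vector `c(R2Y =, Q2 =)`.
#' @export
crossValidatePlsda <- function(m, labels, nComponents = 2L, folds = 7L,
                               seed = 1L) {
    X <- if (is(m, "ProcessedMatrix")) t(m@values) else as.matrix(m)
    labels <- as.character(labels)
    if (folds < 2L) stop("folds must be >= 2")
    set.seed(seed)
    ## stratified fold assignment
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    Y <- .oneHot(labels)
    press <- 0
    for (f in sort(unique(fold))) {
        test <- fold == f
        trLab <- labels[!test]
        if (length(unique(trLab)) < length(unique(labels)))
            stop("a class vanished from a training fold; reduce folds")
        fitTr <- fitPlsda(X[!test, , drop = FALSE], trLab, nComponents)
        pred <- .predictPlsda(fitTr, X[test, , drop = FALSE])
        Ytest <- Y[test, colnames(pred), drop = FALSE]
        press <- press + sum((Ytest - pred)^2)
    }
    ssy <- sum(sweep(Y, 2L, colMeans(Y))^2)
    full <- fitPlsda(X, labels, nComponents)
    c(R2Y = full@r2y, Q2 = 1 - press / ssy)
}

#' Permutation test of the PLS-DA model
#'
#' Refits and cross-validates under `nPerm` seeded label permutations;
#' p = (1 + #\{permuted Q2 >= observed Q2\}) / (nPerm + 1).
#'
#' @inheritParams crossValidatePlsda
#' @param nPerm number of permutations (>= 19).
#' @return list with `p`, `observedQ2`, `observedR2Y`, and the vectors
#'   `permutedQ2` / `permutedR2Y`.
#' @export
permutationTestPlsda <- function(m, labels, nComponents = 2L, folds = 7L,
                                 nPerm = 100L, seed = 1L) {
    if (nPerm < 19L) stop("nPerm must be >= 19")
    obs <- crossValidatePlsda(m, labels, nComponents, folds, seed = seed)
    set.seed(seed + 1L)
    perms <- replicate(nPerm, sample(as.character(labels)))
    permQ2 <- numeric(nPerm); permR2 <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
        cv <- crossValidatePlsda(m, perms[, b], nComponents, folds,
                                 seed = seed + 1L + b)
        permQ2[b] <- cv["Q2"]; permR2[b] <- cv["R2Y"]
    }
    list(p = (1 + sum(permQ2 >= obs["Q2"])) / (nPerm + 1),
         observedQ2 = unname(obs["Q2"]), observedR2Y = unname(obs["R2Y"]),
         permutedQ2 = permQ2, permutedR2Y = permR2)
}
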