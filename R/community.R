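# Permutation community statistics: Bray-Curtis with a dummy species,
# Gower principal-coordinate embedding, ANOSIM and PERMDISP.

#' Bray-Curtis dissimilarity with a dummy species
#'
#' d(a, b) = 1 - 2 sum_s min(a_s, b_s) / (sum_s a_s + sum_s b_s) over
#' non-negative (typically log(x+1)-transformed NPUE) rows. With
#' \code{addDummy} a column with constant value 1 is appended to every row
#' before computation, the standard device that keeps the dissimilarity
#' defined (and equal to 0) between two empty nets and damps dissimilarity
#' between near-empty ones.
#'
#' @param x a [CatchMatrix-class] or numeric matrix (rows = nets)
#' @param addDummy append the dummy column (default TRUE)
#' @return a \code{dist} object with entries in [0, 1]
#' @export
brayCurtis <- function(x, addDummy = TRUE) {
    m <- if (is(x, "CatchMatrix")) x@.Data else as.matrix(x)
    if (any(m < 0)) stop("Bray-Curtis requires non-negative values")
    if (addDummy) m <- cbind(m, dummy = 1)
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    rs <- rowSums(m)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        tot <- rs[i] + rs[j]
        d[i, j] <- d[j, i] <- if (tot == 0) 0 else
            1 - 2 * sum(pmin(m[i, ], m[j, ])) / tot
    }
    stats::as.dist(d)
}

#' Principal-coordinate (Gower) embedding of a dissimilarity matrix
#'
#' Double-centers -d^2/2 and eigendecomposes it. Semimetric
#' dissimilarities such as Bray-Curtis produce negative eigenvalues; axes
#' with positive and negative eigenvalues are kept separately (each scaled
#' by sqrt(|eigenvalue|)), so that squared original dissimilarities are
#' recovered as squared distance on the real axes minus squared distance
#' on the imaginary axes. Eigenvalues below \code{tol} x max|eigenvalue|
#' in magnitude are treated as zero.
#'
#' @param d a \code{dist} or symmetric matrix with zero diagonal
#' @param tol relative eigenvalue tolerance (default 1e-10)
#' @return list with \code{real} (n x p matrix), \code{imag} (n x q),
#'   \code{eigenvalues} (all, decreasing)
#' @export
pcoaEmbed <- function(d, tol = 1e-10) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m), tol = 1e-8)) stop("dissimilarity matrix must be symmetric")
    n <- nrow(m)
    a <- -0.5 * m^2
    # Gower double centering: B = (I - 11'/n) A (I - 11'/n)
    rm_ <- rowMeans(a); gm <- mean(a)
    b <- a - outer(rm_, rm_, `+`) + gm
    e <- eigen(b, symmetric = TRUE)
    thr <- tol * max(abs(e$values), 1e-300)
    pos <- e$values > thr
    neg <- e$values < -thr
    mk <- function(sel) {
        v <- e$vectors[, sel, drop = FALSE] %*%
            diag(sqrt(abs(e$values[sel])), sum(sel))
        rownames(v) <- rownames(m)
        v
    }
    list(real = mk(pos), imag = mk(neg), eigenvalues = e$values)
}

.permPvalue <- function(observed, permuted) {
    (sum(permuted >= observed - 1e-12) + 1) / (length(permuted) + 1)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based one-way test of whether between-group dissimilarities
#' exceed within-group dissimilarities:
#' R = (mean rank between - mean rank within) / (M/2), with M the number
#' of sample pairs and mid-ranks for ties. R near 1 means complete group
#' separation, near 0 none. The p-value is obtained by permuting group
#' labels: p = (b + 1)/(nPerm + 1) where b counts permuted R >= observed.
#'
#' @param d \code{dist} or symmetric dissimilarity matrix
#' @param groups group label per sample (>= 2 groups, each >= 2 members)
#' @param nPerm number of permutations (default 999)
#' @param seed RNG seed (required for reproducibility)
#' @return a [PermutationTestResult-class]
#' @export
anosim <- function(d, groups, nPerm = 999, seed) {
    m <- as.matrix(d)
    groups <- as.character(groups)
    stopifnot(length(groups) == nrow(m))
    sizes <- table(groups)
    if (length(sizes) < 2) stop("need at least 2 groups")
    if (any(sizes < 2)) stop("every group needs at least 2 members")
    n <- nrow(m)
    lower <- m[lower.tri(m)]
    rk <- rank(lower)          # mid-ranks for ties
    pairIdx <- which(lower.tri(m), arr.ind = TRUE)
    M <- length(lower)
    statFor <- function(g) {
        within <- g[pairIdx[, 1]] == g[pairIdx[, 2]]
        (mean(rk[!within]) - mean(rk[within])) / (M / 2)
    }
    observed <- statFor(groups)
    set.seed(seed)
    permuted <- vapply(seq_len(nPerm), function(i) statFor(sample(groups)), 0)
    new("PermutationTestResult", statistic = observed, statisticName = "R",
        nPerm = as.integer(nPerm), pValue = .permPvalue(observed, permuted),
        groupSizes = setNames(as.integer(sizes), names(sizes)),
        details = list(permuted = permuted))
}

.centroidDistances <- function(real, imag, groups) {
    # distance of each sample to its group centroid in the PCoA embedding,
    # with the negative-eigenvalue correction
    # z_i = sqrt(max(0, d2_real - d2_imag))
    z <- numeric(length(groups))
    for (g in unique(groups)) {
        idx <- which(groups == g)
        cr <- colMeans(real[idx, , drop = FALSE])
        d2r <- rowSums((real[idx, , drop = FALSE] -
                        rep(cr, each = length(idx)))^2)
        d2i <- 0
        if (ncol(imag) > 0) {
            ci <- colMeans(imag[idx, , drop = FALSE])
            d2i <- rowSums((imag[idx, , drop = FALSE] -
                            rep(ci, each = length(idx)))^2)
        }
        z[idx] <- sqrt(pmax(0, d2r - d2i))
    }
    z
}

.anovaF <- function(z, groups) {
    gm <- mean(z)
    means <- tapply(z, groups, mean)
    ns <- tapply(z, groups, length)
    ssb <- sum(ns * (means - gm)^2)
    ssw <- sum((z - means[groups])^2)
    dfb <- length(means) - 1
    dfw <- length(z) - length(means)
    if (ssw <= 0) return(Inf)
    (ssb / dfb) / (ssw / dfw)
}

#' Permutation test of multivariate dispersion (PERMDISP)
#'
#' Tests homogeneity of multivariate dispersion among groups: each
#' sample's distance to its group centroid is computed in the
#' principal-coordinate embedding of the dissimilarity matrix (with the
#' negative-eigenvalue correction of semimetric dissimilarities), the
#' one-way ANOVA F statistic on these distances is the test statistic,
#' and significance is assessed by permuting group labels with centroids
#' and distances recomputed for each permutation. Groups smaller than
#' \code{minGroupSize} are dropped with a warning before testing.
#'
#' @inheritParams anosim
#' @param minGroupSize smallest group retained (default 3)
#' @return a [PermutationTestResult-class]; \code{details} holds the
#'   per-sample distances \code{z}, their group means and standard
#'   deviations, and the retained sample labels.
#' @export
permdisp <- function(d, groups, nPerm = 999, seed, minGroupSize = 3) {
    m <- as.matrix(d)
    groups <- as.character(groups)
    stopifnot(length(groups) == nrow(m))
    sizes <- table(groups)
    keepG <- names(sizes)[sizes >= minGroupSize]
    if (length(keepG) < length(sizes))
        warning("dropping groups below size ", minGroupSize, ": ",
                paste(setdiff(names(sizes), keepG), collapse = ", "))
    if (length(keepG) < 2) stop("fewer than 2 eligible groups")
    keep <- groups %in% keepG
    m <- m[keep, keep, drop = FALSE]
    groups <- groups[keep]
    emb <- pcoaEmbed(m)
    z <- .centroidDistances(emb$real, emb$imag, groups)
    observed <- .anovaF(z, groups)
    set.seed(seed)
    permuted <- vapply(seq_len(nPerm), function(i) {
        g <- sample(groups)
        .anovaF(.centroidDistances(emb$real, emb$imag, g), g)
    }, 0)
    gm <- tapply(z, groups, mean)
    gs <- tapply(z, groups, sd)
    new("PermutationTestResult", statistic = observed, statisticName = "F",
        nPerm = as.integer(nPerm), pValue = .permPvalue(observed, permuted),
        groupSizes = setNames(as.integer(table(groups)),
                              names(table(groups))),
        details = list(z = setNames(z, rownames(m)), groupMeans = gm,
                       groupSD = gs, labels = groups, permuted = permuted))
}

#' Write a dissimilarity matrix as square CSV
#'
#' @param d \code{dist} or matrix
#' @param path output path (header row and first column carry the ids)
#' @export
writeDissimilarity <- function(d, path) {
    m <- as.matrix(d)
    utils::write.csv(m, path, row.names = TRUE)
    invisible(path)
}
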