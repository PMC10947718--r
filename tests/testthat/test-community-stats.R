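# Bray-Curtis with dummy, PCoA embedding, ANOSIM, PERMDISP.

test_that("Bray-Curtis matches hand arithmetic and is a bounded semimetric", {
    m <- rbind(a = c(2, 0), b = c(0, 2))
    d <- as.matrix(brayCurtis(m, addDummy = TRUE))
    # rows (2,0,1) and (0,2,1): 1 - 2*1/6
    expect_equal(d["a", "b"], 1 - 2 / 6)
    expect_equal(diag(d), c(a = 0, b = 0))
    # identical rows stay at 0 with or without the dummy
    m2 <- rbind(x = c(1, 3), y = c(1, 3))
    expect_equal(as.matrix(brayCurtis(m2))["x", "y"], 0)
    # two empty nets are identical once the dummy is added
    e <- rbind(p = c(0, 0), q = c(0, 0))
    expect_equal(as.matrix(brayCurtis(e))["p", "q"], 0)
    # bounded in [0,1], symmetric, zero diagonal on random data
    set.seed(4)
    r <- matrix(rpois(60, 2), 10, 6)
    dd <- as.matrix(brayCurtis(r))
    expect_true(all(dd >= 0 & dd <= 1))
    expect_equal(dd, t(dd))
    expect_true(all(diag(dd) == 0))
    expect_error(brayCurtis(rbind(c(-1, 2), c(0, 1))), "non-negative")
})

test_that("Bray-Curtis with dummy agrees with the vegan zero-adjusted form", {
    set.seed(7)
    m <- matrix(rpois(48, 1.5), 8, 6)
    ours <- as.matrix(brayCurtis(m, addDummy = TRUE))
    ref <- as.matrix(vegan::vegdist(cbind(m, 1), method = "bray"))
    expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("PCoA embedding reproduces Euclidean geometry and the Gower identity", {
    pts <- euclideanPoints(5, 2, seed = 3)
    d <- dist(pts)
    emb <- pcoaEmbed(d)
    # Euclidean input: no imaginary axes, pairwise distances recovered
    expect_equal(ncol(emb$imag), 0)
    expect_equal(as.matrix(dist(emb$real)), as.matrix(d),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # 3 collinear points embed on exactly one positive axis
    line <- cbind(c(0, 1, 3), 0)
    e2 <- pcoaEmbed(dist(line))
    expect_equal(sum(e2$eigenvalues > 1e-10 * max(abs(e2$eigenvalues))), 1)
    # semimetric input: squared real distance minus squared imaginary
    # distance returns the original squared dissimilarity
    set.seed(8)
    m <- matrix(rpois(36, 2), 6, 6)
    db <- brayCurtis(m)
    e3 <- pcoaEmbed(db)
    d2 <- as.matrix(dist(e3$real))^2 -
        (if (ncol(e3$imag)) as.matrix(dist(e3$imag))^2 else 0)
    expect_equal(d2, as.matrix(db)^2, tolerance = 1e-8, ignore_attr = TRUE)
    expect_error(pcoaEmbed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("ANOSIM separates, is rank-based, and matches vegan", {
    # maximal separation: every between-group dissimilarity exceeds every
    # within-group one
    g <- rep(c("A", "B"), each = 4)
    pts <- rbind(euclideanPoints(4, 2, seed = 1, sd = 0.01),
                 euclideanPoints(4, 2, seed = 2, sd = 0.01) + 100)
    d <- dist(pts)
    res <- anosim(d, g, nPerm = 99, seed = 1)
    expect_equal(res@statistic, 1)
    # invariant under monotone transformation of the dissimilarities
    res2 <- anosim(d^2, g, nPerm = 99, seed = 1)
    expect_equal(res2@statistic, res@statistic)
    # random labels: mean permuted R near 0, p not small
    set.seed(5)
    dr <- dist(matrix(rnorm(40), 10, 4))
    gr <- rep(c("A", "B"), 5)
    rr <- anosim(dr, gr, nPerm = 499, seed = 3)
    expect_lt(abs(mean(rr@details$permuted)), 0.05)
    # same seed reproduces the same p exactly
    expect_equal(anosim(dr, gr, nPerm = 99, seed = 7)@pValue,
                 anosim(dr, gr, nPerm = 99, seed = 7)@pValue)
    # statistic agrees with vegan's implementation
    vref <- vegan::anosim(dr, gr, permutations = 19)
    expect_equal(rr@statistic, unname(vref$statistic), tolerance = 1e-12)
    expect_error(anosim(dr, rep("A", 10), nPerm = 9, seed = 1), "2 groups")
    expect_error(anosim(dr, c(rep("A", 9), "B"), nPerm = 9, seed = 1),
                 "at least 2 members")
})

test_that("ANOSIM permutation p matches exhaustive enumeration on 6 samples", {
    set.seed(12)
    pts <- matrix(rnorm(12), 6, 2)
    pts[4:6, 1] <- pts[4:6, 1] + 1.2     # moderate separation
    d <- dist(pts)
    g <- rep(c("A", "B"), each = 3)
    # oracle: enumerate all choose(6,3) = 20 label assignments and count
    # statistics >= observed, computed from first principles on ranks
    m <- as.matrix(d)
    lower <- m[lower.tri(m)]
    rk <- rank(lower)
    idx <- which(lower.tri(m), arr.ind = TRUE)
    M <- length(lower)
    statFor <- function(gg) {
        within <- gg[idx[, 1]] == gg[idx[, 2]]
        (mean(rk[!within]) - mean(rk[within])) / (M / 2)
    }
    obs <- statFor(g)
    splits <- combn(6, 3)
    allR <- apply(splits, 2, function(s) {
        gg <- rep("B", 6); gg[s] <- "A"; statFor(gg)
    })
    pExact <- mean(allR >= obs - 1e-12)
    res <- anosim(d, g, nPerm = 1999, seed = 5)
    expect_equal(res@statistic, obs)
    # permuted labels sample the same 20 splits; MC error ~ 3*sqrt(p(1-p)/n)
    tol <- 3 * sqrt(pExact * (1 - pExact) / 1999) + 1 / 2000
    expect_lt(abs(res@pValue - pExact), tol + 0.01)
})

test_that("PERMDISP distances equal direct centroid geometry", {
    pts <- euclideanPoints(9, 2, seed = 10)
    g <- rep(c("A", "B", "C"), each = 3)
    res <- permdisp(dist(pts), g, nPerm = 99, seed = 1, minGroupSize = 3)
    zDirect <- numeric(9)
    for (gg in unique(g)) {
        i <- which(g == gg)
        cen <- colMeans(pts[i, ])
        zDirect[i] <- sqrt(rowSums((pts[i, ] - rep(cen, each = 3))^2))
    }
    expect_equal(unname(res@details$z), zDirect, tolerance = 1e-8)
    # a group of identical points has zero dispersion
    same <- rbind(pts, matrix(2, 3, 2))
    g2 <- c(g, rep("D", 3))
    res2 <- permdisp(dist(same), g2, nPerm = 99, seed = 1)
    expect_equal(unname(res2@details$z[res2@details$labels == "D"]),
                 rep(0, 3))
})

test_that("PERMDISP agrees with vegan::betadisper on Bray-Curtis data", {
    set.seed(20)
    m <- matrix(rpois(70, 2), 10, 7)
    g <- rep(c("A", "B"), each = 5)
    d <- brayCurtis(m)
    res <- permdisp(d, g, nPerm = 99, seed = 2)
    ref <- vegan::betadisper(d, g, type = "centroid")
    expect_equal(unname(res@details$z), unname(ref$distances),
                 tolerance = 1e-8)
    expect_equal(res@statistic, unname(anova(ref)$`F value`[1]),
                 tolerance = 1e-8)
})

test_that("PERMDISP drops undersized groups and needs 2 eligible groups", {
    pts <- euclideanPoints(8, 2, seed = 6)
    g <- c(rep("A", 3), rep("B", 3), rep("C", 2))
    expect_warning(res <- permdisp(dist(pts), g, nPerm = 49, seed = 1),
                   "dropping groups")
    expect_equal(names(res@groupSizes), c("A", "B"))
    expect_error(suppressWarnings(
        permdisp(dist(pts), c(rep("A", 6), "B", "C"), nPerm = 9, seed = 1)),
        "fewer than 2")
})

test_that("permutation p never falls below 1/(nPerm+1) and respects seeds", {
    g <- rep(c("A", "B"), each = 4)
    pts <- rbind(euclideanPoints(4, 2, seed = 1, sd = 0.01),
                 euclideanPoints(4, 2, seed = 2, sd = 0.01) + 100)
    res <- anosim(dist(pts), g, nPerm = 199, seed = 1)
    # perfect separation: p bounded below by 1/(m+1); permutations that
    # regenerate the original partition (probability 2/choose(8,4)) tie
    # the observed R, so p stays near that tie rate, not at the floor
    expect_gte(res@pValue, 1 / 200)
    expect_lt(res@pValue, 0.1)
})
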