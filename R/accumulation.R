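# Species accumulation: exact hypergeometric estimator, permutation
# method, and the minimum-net criterion for detecting a fraction of the
# observed species with a given probability.

#' Incidence (presence/absence) matrix of nets x species
#'
#' @param x a [CatchMatrix-class], a numeric nets x species matrix, or a
#'   [GillnetSurvey-class] (converted via [catchMatrix()]).
#' @param dropEmptySpecies drop species never observed (default TRUE, so
#'   every retained column has occurrence frequency >= 1)
#' @return binary matrix (1 = species present in net)
#' @export
incidenceMatrix <- function(x, dropEmptySpecies = TRUE) {
    m <- if (is(x, "GillnetSurvey")) catchMatrix(x)@.Data
         else if (is(x, "CatchMatrix")) x@.Data
         else as.matrix(x)
    inc <- (m > 0) * 1
    if (dropEmptySpecies && ncol(inc))
        inc <- inc[, colSums(inc) >= 1, drop = FALSE]
    inc
}

#' Species accumulation curve
#'
#' Expected species richness E[S(n)] as nets are accumulated in random
#' order, for n = 1..N. The exact (sample-based rarefaction) estimator is
#' \deqn{E[S(n)] = \sum_s 1 - C(N - f_s, n) / C(N, n)}
#' with f_s the number of nets in which species s occurs; binomial
#' coefficients are evaluated in log space. Its standard deviation comes
#' from the pairwise joint inclusion probabilities. The permutation
#' method averages richness over random orderings of the nets and also
#' returns permutation quantiles.
#'
#' @param m incidence matrix from [incidenceMatrix()]
#' @param method \code{"exact"} (default) or \code{"permutation"}
#' @param nPerm permutations for the permutation method (default 1000)
#' @param seed RNG seed (permutation method)
#' @return data.frame with columns \code{n}, \code{richness}, \code{sd}
#'   (and \code{q025}/\code{q975} for the permutation method); attribute
#'   \code{S_obs} holds the observed richness. E[S(N)] = S_obs exactly and
#'   the curve is non-decreasing and concave.
#' @export
accumulationCurve <- function(m, method = c("exact", "permutation"),
                              nPerm = 1000, seed = 1) {
    method <- match.arg(method)
    N <- nrow(m)
    if (N < 1 || ncol(m) < 1) stop("empty incidence matrix")
    keep <- which(colSums(m > 0) >= 1)
    f <- colSums(m > 0)[keep]
    S <- length(f)
    if (method == "exact") {
        ns <- seq_len(N)
        # log-space absence probability: P(s absent from n nets) =
        # C(N - f_s, n) / C(N, n)
        pAbs <- function(fs, n) {
            ifelse(n > N - fs, 0, exp(lchoose(N - fs, n) - lchoose(N, n)))
        }
        rich <- vapply(ns, function(n) sum(1 - pAbs(f, n)), 0)
        # exact variance from pairwise joint absence probabilities;
        # u_st = nets containing s or t, precomputed once
        inc <- (m[, keep, drop = FALSE] > 0) * 1
        both <- crossprod(inc)
        uMat <- outer(f, f, `+`) - both
        up <- uMat[upper.tri(uMat)]
        sdv <- vapply(ns, function(n) {
            pa <- pAbs(f, n)
            v <- sum(pa * (1 - pa))
            if (S > 1) {
                pBothAbs <- ifelse(n > N - up, 0,
                                   exp(lchoose(N - up, n) - lchoose(N, n)))
                papa <- outer(pa, pa)[upper.tri(uMat)]
                v <- v + 2 * sum(pBothAbs - papa)
            }
            sqrt(max(0, v))
        }, 0)
        out <- data.frame(n = ns, richness = rich, sd = sdv)
    } else {
        set.seed(seed)
        inc <- m[, keep, drop = FALSE] > 0
        acc <- matrix(0L, nPerm, N)
        for (p in seq_len(nPerm)) {
            ord <- sample.int(N)
            seen <- rep(FALSE, S)
            cnt <- integer(N)
            run <- 0L
            for (i in seq_len(N)) {
                new <- inc[ord[i], ] & !seen
                run <- run + sum(new)
                seen <- seen | new
                cnt[i] <- run
            }
            acc[p, ] <- cnt
        }
        out <- data.frame(n = seq_len(N), richness = colMeans(acc),
                          sd = apply(acc, 2, sd),
                          q025 = apply(acc, 2, quantile, 0.025),
                          q975 = apply(acc, 2, quantile, 0.975))
    }
    attr(out, "S_obs") <- S
    attr(out, "method") <- method
    out
}

.detectionTimes <- function(inc, nPerm, seed) {
    # for each random ordering: the net index at which each species is
    # first seen; species detection time = min position over its nets
    N <- nrow(inc)
    occ <- apply(inc > 0, 2, which)   # list of net indices per species
    if (is.matrix(occ)) occ <- as.list(as.data.frame(occ))
    set.seed(seed)
    t(vapply(seq_len(nPerm), function(p) {
        pos <- sample.int(N)          # pos[i] = position of net i in ordering
        vapply(occ, function(idx) min(pos[idx]), 0L)
    }, integer(length(occ))))
}

#' Minimum nets to detect a fraction of observed species
#'
#' Smallest number of nets n such that, when nets are sampled in random
#' order, the first n nets jointly contain at least
#' ceiling(targetFraction x S_obs) species with probability >=
#' \code{probability}. The default operationalizes "90% of species with
#' 50% probability" as the median of the permutation distribution of the
#' per-ordering detection threshold; \code{method = "expected"} instead
#' returns the smallest n whose exact expected richness reaches the
#' species target (the curve-crossing rule), which ignores the spread of
#' the distribution.
#'
#' @param m incidence matrix
#' @param targetFraction fraction of the observed richness to detect, in
#'   (0, 1] (default 0.9)
#' @param probability required detection probability, in (0, 1) (default
#'   0.5)
#' @param nPerm random orderings for the permutation criterion (default
#'   10000)
#' @param seed RNG seed (mandatory for reproducibility; default 1)
#' @param method \code{"permutation"} (default) or \code{"expected"}
#' @return smallest integer n (<= N)
#' @export
netsForDetection <- function(m, targetFraction = 0.9, probability = 0.5,
                             nPerm = 10000, seed = 1,
                             method = c("permutation", "expected")) {
    method <- match.arg(method)
    stopifnot(targetFraction > 0, targetFraction <= 1,
              probability > 0, probability < 1)
    inc <- m[, colSums(m > 0) >= 1, drop = FALSE]
    S <- ncol(inc)
    if (S < 1) stop("empty incidence matrix")
    target <- ceiling(targetFraction * S)
    if (method == "expected") {
        cv <- accumulationCurve(inc, method = "exact")
        return(min(cv$n[cv$richness >= target - 1e-9]))
    }
    dt <- .detectionTimes(inc, nPerm, seed)
    # per ordering, the n at which the target-th species appears is the
    # target-th smallest detection time; the answer is the `probability`
    # quantile of these thresholds
    thresholds <- apply(dt, 1, function(x) sort(x)[target])
    as.integer(quantile(thresholds, probability, type = 1))
}
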