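# CEN-vs-MOD comparison: TOST equivalence with achieved power and required
# sample size, percentage reduction summaries, catch-proportional labour.

#' Round half away from zero
#'
#' Matches the printed-integer convention of survey reports (e.g. 41.7 ->
#' 42), unlike R's banker's rounding.
#'
#' @param x numeric
#' @param digits decimal places
#' @return numeric
#' @export
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

.welch <- function(x, y) {
    nx <- length(x); ny <- length(y)
    vx <- var(x); vy <- var(y)
    se <- sqrt(vx / nx + vy / ny)
    df <- if (se == 0) nx + ny - 2 else
        (vx / nx + vy / ny)^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    list(diff = mean(y) - mean(x), se = se, df = df, nx = nx, ny = ny,
         sdPooled = sqrt(((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)))
}

#' Two one-sided tests (TOST) of equivalence between net designs
#'
#' Unpaired Welch-t TOST of the difference MOD - CEN on a per-net metric
#' (NPUE of a mesh, number of species, ...). Equivalence is accepted when
#' the 90% confidence interval of the difference lies entirely inside the
#' smallest-effect-size-of-interest bounds (-Delta, +Delta).
#'
#' Two constructions of the bounds are offered. The default,
#' \code{"fraction_of_grand_mean"}, sets Delta = fraction x pooled mean of
#' the metric over both samples, so the bound is anchored to the scale of
#' the data. \code{"fraction_of_mean_difference"} sets Delta = fraction x
#' |observed mean difference|; this bound shrinks with the observed
#' effect, which makes the criterion easier to satisfy for small observed
#' differences -- it is provided for comparability with reports that use
#' it, not recommended.
#'
#' @param cen per-net values under the reference design (>= 2 values)
#' @param mod per-net values under the alternative design (>= 2 values)
#' @param boundsMode \code{"fraction_of_grand_mean"} (default) or
#'   \code{"fraction_of_mean_difference"}
#' @param fraction positive fraction defining the bounds (0.5 or 0.2
#'   typically)
#' @param bounds optional explicit bounds: one positive number Delta for
#'   (-Delta, Delta) or \code{c(lower, upper)} with lower < 0 < upper;
#'   overrides \code{boundsMode}.
#' @param alpha one-sided level; the CI used is the (1 - 2 alpha) = 90%
#'   interval for the default 0.05.
#' @param powerTarget power level for the reported required sample size
#' @return list with \code{meanDifference}, \code{ci90}, \code{bounds},
#'   \code{equivalent}, \code{pValue} (max of the two one-sided p),
#'   \code{p1}, \code{p2}, \code{df}, \code{achievedPower} (at the
#'   realized group sizes, assuming a true difference of zero) and
#'   \code{nRequiredPower80}.
#' @export
tostEquivalence <- function(cen, mod,
                            boundsMode = c("fraction_of_grand_mean",
                                           "fraction_of_mean_difference"),
                            fraction = 0.5, bounds = NULL, alpha = 0.05,
                            powerTarget = 0.8) {
    boundsMode <- match.arg(boundsMode)
    stopifnot(length(cen) >= 2, length(mod) >= 2)
    if (is.null(bounds) && fraction <= 0)
        stop("fraction must be positive")
    w <- .welch(cen, mod)
    if (is.null(bounds)) {
        delta <- switch(boundsMode,
            fraction_of_grand_mean = fraction * mean(c(cen, mod)),
            fraction_of_mean_difference = fraction * abs(w$diff))
        bounds <- c(-delta, delta)
    } else if (length(bounds) == 1) bounds <- c(-abs(bounds), abs(bounds))
    stopifnot(bounds[1] <= 0, bounds[2] >= 0)

    degenerate <- w$se == 0
    if (degenerate) {
        warning("zero-variance samples: TOST decision from point difference")
        p1 <- as.numeric(w$diff <= bounds[1])
        p2 <- as.numeric(w$diff >= bounds[2])
        ci <- c(w$diff, w$diff)
    } else {
        t1 <- (w$diff - bounds[1]) / w$se   # H0: diff <= lower bound
        t2 <- (w$diff - bounds[2]) / w$se   # H0: diff >= upper bound
        p1 <- pt(t1, w$df, lower.tail = FALSE)
        p2 <- pt(t2, w$df, lower.tail = TRUE)
        ci <- w$diff + c(-1, 1) * qt(1 - alpha, w$df) * w$se
    }
    equivalent <- ci[1] > bounds[1] && ci[2] < bounds[2]
    nEff <- 2 / (1 / w$nx + 1 / w$ny)
    sdp <- if (w$sdPooled > 0) w$sdPooled else NA_real_
    pow <- if (is.na(sdp)) NA_real_ else
        equivalencePower(nEff, sdp, bounds, trueDifference = 0, alpha = alpha)
    nreq <- if (is.na(sdp)) NA_integer_ else
        requiredSampleSize(sdp, bounds, trueDifference = 0,
                           power = powerTarget, alpha = alpha)
    list(meanDifference = w$diff, ci90 = ci, bounds = bounds,
         equivalent = equivalent, pValue = max(p1, p2), p1 = p1, p2 = p2,
         df = w$df, achievedPower = pow, nRequiredPower80 = nreq,
         degenerate = degenerate)
}

#' Power of the TOST equivalence procedure
#'
#' Probability that both one-sided tests reject (i.e. equivalence is
#' declared) for a two-sample comparison with \code{n} per group, common
#' standard deviation \code{sd}, equivalence bounds and a given true
#' difference, via the noncentral-t expression
#' \deqn{power = F_t(-t_{1-\alpha,df}; (\delta-\Delta_U)/se) -
#'              F_t(t_{1-\alpha,df}; (\delta+\Delta_L)/se)}
#' with \eqn{se = sd\sqrt{2/n}} and df = 2(n - 1), truncated at zero.
#'
#' @param n sample size per group (>= 2; may be fractional for search)
#' @param sd common standard deviation (> 0)
#' @param bounds one positive Delta for symmetric bounds or
#'   \code{c(lower, upper)}
#' @param trueDifference assumed true group difference
#' @param alpha one-sided level of each test
#' @return power in [0, 1]
#' @export
equivalencePower <- function(n, sd, bounds, trueDifference = 0, alpha = 0.05) {
    stopifnot(n >= 2, sd > 0)
    if (length(bounds) == 1) bounds <- c(-abs(bounds), abs(bounds))
    if (bounds[1] >= 0 || bounds[2] <= 0) stop("bounds must straddle zero")
    se <- sd * sqrt(2 / n)
    df <- 2 * (n - 1)
    tcrit <- qt(1 - alpha, df)
    pow <- pt(-tcrit, df, ncp = (trueDifference - bounds[2]) / se) -
           pt(tcrit, df, ncp = (trueDifference - bounds[1]) / se)
    min(1, max(0, pow))
}

#' Smallest per-group n reaching a target TOST power
#'
#' Integer search (doubling then bisection) over [equivalencePower()];
#' returns \code{NA} with a warning when the target is unreachable (the
#' true difference lies at or beyond a bound).
#'
#' @inheritParams equivalencePower
#' @param power target power (default 0.8)
#' @return integer n per group
#' @export
requiredSampleSize <- function(sd, bounds, trueDifference = 0, power = 0.8,
                               alpha = 0.05) {
    if (length(bounds) == 1) bounds <- c(-abs(bounds), abs(bounds))
    if (trueDifference <= bounds[1] || trueDifference >= bounds[2]) {
        warning("true difference outside bounds: required n is unbounded")
        return(NA_integer_)
    }
    lo <- 2L; hi <- 2L
    while (equivalencePower(hi, sd, bounds, trueDifference, alpha) < power) {
        lo <- hi
        hi <- hi * 2L
        if (hi > 1e7) { warning("required n exceeds 1e7"); return(NA_integer_) }
    }
    while (hi - lo > 1L) {
        mid <- (lo + hi) %/% 2L
        if (equivalencePower(mid, sd, bounds, trueDifference, alpha) >= power)
            hi <- mid else lo <- mid
    }
    hi
}

#' Catch and NPUE reduction of MOD relative to CEN replicate pairs
#'
#' Restricts the survey to paired CEN/MOD deployments and reports, per
#' basin and pooled, the total specimens caught by each design and the
#' percent reduction 100 x (1 - MOD/CEN), and the same for summed per-net
#' NPUE. Comparisons are restricted to mesh sizes shared by both designs
#' (the CEN-only 5/55 mm panels are dropped) so the designs are compared
#' on common ground.
#'
#' @param survey a [GillnetSurvey-class] containing replicate pairs
#' @param sharedMeshesOnly default TRUE (see above)
#' @return data.frame with rows per basin plus a pooled \code{"all"} row
#' @export
reductionSummary <- function(survey, sharedMeshesOnly = TRUE) {
    sv <- pairedOnly(survey)
    if (nrow(deployments(sv)) == 0) stop("no replicate pairs in survey")
    d <- deployments(sv)
    cc <- catches(sv)
    if (sharedMeshesOnly && nrow(cc))
        cc <- cc[cc$mesh_mm %in% .sharedMeshes(sv), , drop = FALSE]
    npue <- netNpue(sv, sharedMeshesOnly = sharedMeshesOnly)
    one <- function(basins, label) {
        keep <- d$basin %in% basins
        tot <- function(design) {
            ids <- d$net_id[keep & d$design == design]
            c(catch = sum(cc$count[cc$net_id %in% ids]),
              npue = sum(npue[ids]))
        }
        cenT <- tot("CEN"); modT <- tot("MOD")
        pct <- function(cen, mod) if (cen == 0) NA_real_ else 100 * (1 - mod / cen)
        if (cenT["catch"] == 0)
            warning("zero CEN catch in ", label, ": reduction undefined")
        data.frame(basin = label,
                   catch_cen = cenT[["catch"]], catch_mod = modT[["catch"]],
                   catch_reduction_pct = pct(cenT[["catch"]], modT[["catch"]]),
                   npue_cen = cenT[["npue"]], npue_mod = modT[["npue"]],
                   npue_reduction_pct = pct(cenT[["npue"]], modT[["npue"]]),
                   stringsAsFactors = FALSE)
    }
    basins <- unique(d$basin)
    out <- do.call(rbind, lapply(basins, function(b) one(b, b)))
    rbind(out, one(basins, "all"))
}

#' Labour saving of MOD relative to CEN nets
#'
#' Catch-proportional labour model: the workload considered (fish
#' disentanglement and catch documentation) is proportional to the number
#' of fish, optionally weighted per mesh size (larger meshes hold larger
#' fish that take longer to free). labour(design) = sum over meshes of
#' catch x minutes-per-fish; saving = 100 x (1 - labour_MOD/labour_CEN).
#'
#' @param survey a [GillnetSurvey-class]
#' @param perFishMinutes named numeric vector of minutes per fish keyed by
#'   mesh size (character keys); unnamed meshes get weight 1; default
#'   uniform.
#' @param pairsOnly restrict to replicate pairs (default TRUE)
#' @param sharedMeshesOnly restrict to meshes shared by both designs
#'   (default TRUE)
#' @return list with \code{labour} (named by design) and
#'   \code{savingPercent}
#' @export
labourSavings <- function(survey, perFishMinutes = NULL, pairsOnly = TRUE,
                          sharedMeshesOnly = TRUE) {
    sv <- if (pairsOnly) pairedOnly(survey) else survey
    d <- deployments(sv)
    cc <- catches(sv)
    if (sharedMeshesOnly && nrow(cc))
        cc <- cc[cc$mesh_mm %in% .sharedMeshes(sv), , drop = FALSE]
    w <- function(mesh) {
        if (is.null(perFishMinutes)) return(rep(1, length(mesh)))
        v <- perFishMinutes[mesh]
        ifelse(is.na(v), 1, v)
    }
    lab <- vapply(c("CEN", "MOD"), function(des) {
        ids <- d$net_id[d$design == des]
        s <- cc[cc$net_id %in% ids, , drop = FALSE]
        sum(s$count * w(s$mesh_mm))
    }, 0)
    if (lab[["CEN"]] == 0) stop("zero CEN labour: saving undefined")
    list(labour = lab, savingPercent = 100 * (1 - lab[["MOD"]] / lab[["CEN"]]))
}
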