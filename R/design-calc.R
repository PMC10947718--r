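# Precision and prospective sample-size layer: CV precision (Degerman),
# dominant-species rule, Pringle and power-based net numbers,
# volume-proportional allocation, per-stratum max/ceiling/feasibility
# rule, and the design report.

#' Coefficient-of-variation precision of an NPUE sample
#'
#' Per-net NPUE values are log(x+1)-transformed (the monitoring
#' standard's scale) and summarized as mean, SD, SE = SD/sqrt(n) and
#' CV = SE/mean. The monitoring target CV <= 0.1 corresponds to detecting
#' a 50% abundance difference between two sampling occasions with 95%
#' certainty.
#'
#' @param npuePerNet per-net NPUE values (>= 2; one per deployed net,
#'   zero-catch nets included)
#' @param transform \code{"log1p"} (default) or \code{"none"} if values
#'   are already on the analysis scale
#' @return list with \code{n}, \code{mean}, \code{sd}, \code{se},
#'   \code{cv}
#' @seealso [cvFromStats()] for printed summary statistics
#' @export
cvPrecision <- function(npuePerNet, transform = c("log1p", "none")) {
    transform <- match.arg(transform)
    if (length(npuePerNet) < 2) stop("need at least 2 nets")
    x <- if (transform == "log1p") log1p(npuePerNet) else npuePerNet
    m <- mean(x)
    if (m <= 0) stop("mean is not positive: CV undefined")
    s <- sd(x)
    cvFromStats(m, s, length(x))
}

#' CV precision from summary statistics
#'
#' @param mean mean of per-net log(NPUE+1) (> 0)
#' @param sd standard deviation of the same values
#' @param n number of nets
#' @return list with \code{n}, \code{mean}, \code{sd}, \code{se} =
#'   sd/sqrt(n), \code{cv} = se/mean
#' @export
cvFromStats <- function(mean, sd, n) {
    stopifnot(mean > 0, sd >= 0, n >= 1)
    se <- sd / sqrt(n)
    list(n = as.integer(n), mean = mean, sd = sd, se = se, cv = se / mean)
}

#' Dominant species of a catch matrix
#'
#' Species contributing at least \code{threshold} (default 30%) of the
#' total NPUE; the boundary counts as dominant.
#'
#' @param x a [CatchMatrix-class] or nets x species matrix of
#'   untransformed NPUE
#' @param threshold dominance share (default 0.30)
#' @return data.frame of \code{species}, \code{share} (all species,
#'   decreasing) with attribute-free \code{dominant} logical column
#' @export
dominantSpecies <- function(x, threshold = 0.30) {
    m <- if (is(x, "CatchMatrix")) x@.Data else as.matrix(x)
    if (!nrow(m) || !ncol(m)) stop("empty catch matrix")
    tot <- colSums(m)
    share <- if (sum(tot) > 0) tot / sum(tot) else tot
    out <- data.frame(species = names(share), share = unname(share),
                      dominant = unname(share) >= threshold,
                      stringsAsFactors = FALSE)
    out[order(-out$share), , drop = FALSE]
}

#' Pringle net-number formula
#'
#' Required nets = SD^2 / (mean^2 x CV^2) for a target coefficient of
#' variation, on the log(NPUE+1) scale. Returned unrounded; standalone
#' quotes truncate to the integer part (\code{truncate = TRUE}) while
#' per-stratum minima apply a ceiling later (see
#' [stratumRequirement()]).
#'
#' @param mean mean per-net log(NPUE+1) (> 0)
#' @param sd standard deviation on the same scale
#' @param cvTarget target CV (default 0.1, the monitoring standard)
#' @param truncate return the integer part instead of the fractional
#'   value
#' @return required number of nets
#' @examples
#' pringleNets(0.39, 0.49)                 # 157.86...
#' pringleNets(0.39, 0.49, truncate = TRUE) # 157
#' @export
pringleNets <- function(mean, sd, cvTarget = 0.1, truncate = FALSE) {
    stopifnot(mean > 0, cvTarget > 0, sd >= 0)
    n <- sd^2 / (mean^2 * cvTarget^2)
    if (truncate) floor(n) else n
}

#' Power-based net numbers
#'
#' Two-sample two-sided t-test sample size to detect a
#' \code{differenceFraction} x mean difference in mean NPUE of the
#' dominant species between two sampling occasions, i.e. standardized
#' effect d = (differenceFraction x mean)/sd, at the given power and
#' alpha. Fractional n per occasion is returned; reports apply a ceiling.
#'
#' @param mean per-stratum mean NPUE of the dominant species (> 0)
#' @param sd standard deviation (> 0)
#' @param differenceFraction detectable difference as a fraction of the
#'   mean (default 0.5)
#' @param power target power (default 0.8)
#' @param alpha two-sided significance level (default 0.05)
#' @return fractional nets per sampling occasion (minimum 2)
#' @export
powerNets <- function(mean, sd, differenceFraction = 0.5, power = 0.8,
                      alpha = 0.05) {
    stopifnot(mean > 0, differenceFraction > 0)
    if (sd <= 0) return(2)
    delta <- differenceFraction * mean
    res <- try(stats::power.t.test(delta = delta, sd = sd, power = power,
                                   sig.level = alpha, type = "two.sample",
                                   alternative = "two.sided"), silent = TRUE)
    if (inherits(res, "try-error")) 2 else max(2, res$n)
}

#' Volume-proportional allocation of nets across strata
#'
#' allocation_i = total x v_i / sum(v); fractional values are preserved
#' so the ceiling is applied exactly once, at the stratum level.
#'
#' @param totalNets total (possibly fractional) nets for the community
#' @param volumes positive stratum volumes or relative weights
#' @return numeric allocations summing exactly to \code{totalNets}
#' @export
allocateByVolume <- function(totalNets, volumes) {
    if (any(volumes <= 0)) stop("volumes must be positive")
    totalNets * volumes / sum(volumes)
}

#' Integer minimum nets for one stratum
#'
#' The minimum is the larger of the species-detection requirement and the
#' NPUE-precision requirement, ceiled; in strata where fish density is
#' too low for abundance estimation with reasonable effort
#' (\code{feasible = FALSE}) the abundance requirement is waived and only
#' the species requirement (ceiled) applies.
#'
#' @param speciesReq fractional nets for 90% species detection
#' @param npueReq fractional nets for the NPUE precision target
#' @param feasible is an abundance estimate feasible in this stratum?
#' @return integer minimum net number
#' @examples
#' stratumRequirement(30.2, 7.8, TRUE)     # 31
#' stratumRequirement(17.0, 24.3, TRUE)    # 25
#' stratumRequirement(8.0, 139.4, FALSE)   # 8
#' @export
stratumRequirement <- function(speciesReq, npueReq, feasible = TRUE) {
    stopifnot(speciesReq >= 0, npueReq >= 0)
    as.integer(ceiling(if (feasible) max(speciesReq, npueReq) else speciesReq))
}

#' Design plan: per-stratum minima, totals and reduction vs baseline
#'
#' Applies [stratumRequirement()] to each stratum, totals per basin, and
#' reports the percent reduction relative to a baseline (e.g. the net
#' count the standard protocol would demand).
#'
#' @param strata data.frame with columns \code{basin}, \code{stratum},
#'   \code{species_req}, \code{npue_req}, \code{feasible} (logical);
#'   optional \code{volume}.
#' @param baselineNets baseline total net count for the reduction figure
#'   (optional)
#' @return list with \code{strata} (input plus \code{minimum}),
#'   \code{basinTotals}, \code{total}, \code{baselineNets},
#'   \code{reductionPercent}
#' @export
designReport <- function(strata, baselineNets = NULL) {
    need <- c("basin", "stratum", "species_req", "npue_req", "feasible")
    if (!all(need %in% names(strata)))
        stop("strata must have columns: ", paste(need, collapse = ", "))
    if (anyNA(strata[need])) stop("missing stratum inputs")
    strata$minimum <- mapply(stratumRequirement, strata$species_req,
                             strata$npue_req, strata$feasible)
    basinTotals <- c(tapply(strata$minimum, strata$basin, sum))
    total <- sum(strata$minimum)
    red <- if (is.null(baselineNets)) NA_real_ else
        100 * (1 - total / baselineNets)
    list(strata = strata, basinTotals = basinTotals, total = total,
         baselineNets = baselineNets, reductionPercent = red)
}
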