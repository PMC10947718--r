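# TOST equivalence, TOST power, reduction summaries, labour model.

test_that("TOST p-values match directly computed one-sided Welch probabilities", {
    x <- c(1.2, 0.8, 1.0, 1.4, 0.6, 1.1)
    y <- c(0.9, 1.3, 0.7, 1.2, 1.0, 0.8)
    delta <- 0.5
    res <- tostEquivalence(x, y, bounds = delta)
    # oracle: one-sided Welch t probabilities computed step by step
    nx <- 6; ny <- 6
    se <- sqrt(var(x) / nx + var(y) / ny)
    df <- (var(x) / nx + var(y) / ny)^2 /
        ((var(x) / nx)^2 / (nx - 1) + (var(y) / ny)^2 / (ny - 1))
    diff <- mean(y) - mean(x)
    p1 <- 1 - pt((diff + delta) / se, df)
    p2 <- pt((diff - delta) / se, df)
    expect_equal(res$meanDifference, diff)
    expect_equal(res$p1, p1, tolerance = 1e-12)
    expect_equal(res$p2, p2, tolerance = 1e-12)
    expect_equal(res$pValue, max(p1, p2))
    expect_equal(res$ci90, diff + c(-1, 1) * qt(0.95, df) * se)
    # decision follows the CI rule
    expect_equal(res$equivalent,
                 res$ci90[1] > -delta && res$ci90[2] < delta)
})

test_that("TOST decisions behave at the boundaries", {
    x <- c(1, 2, 3, 4, 2, 3)
    # identical samples: difference 0, equivalent once the bounds exceed
    # the CI half-width (the CI reflects sampling noise even at zero
    # observed difference)
    res <- tostEquivalence(x, x, bounds = 2)
    expect_true(res$equivalent)
    expect_equal(res$meanDifference, 0)
    # a CI wider than the bounds can never fit inside them
    set.seed(1)
    a <- rnorm(4, sd = 10); b <- rnorm(4, sd = 10)
    wide <- suppressWarnings(tostEquivalence(a, b, bounds = 0.01))
    expect_false(wide$equivalent)
    expect_error(tostEquivalence(a, b, fraction = 0), "positive")
    # label exchange with sign-flipped bounds leaves the decision unchanged
    set.seed(2)
    a <- rnorm(10, 5); b <- rnorm(10, 5.3)
    r1 <- tostEquivalence(a, b, bounds = c(-0.8, 1.2))
    r2 <- tostEquivalence(b, a, bounds = c(-1.2, 0.8))
    expect_equal(r1$equivalent, r2$equivalent)
    expect_equal(r1$meanDifference, -r2$meanDifference)
    # degenerate zero-variance samples are flagged
    expect_warning(tostEquivalence(rep(1, 3), rep(1, 3), bounds = 1),
                   "zero-variance")
})

test_that("TOST power is monotone, 1 at infinite bounds, and MC-calibrated", {
    # limits and monotonicity
    expect_gt(equivalencePower(10, 1, 1e6), 0.999)
    pows <- vapply(c(5, 10, 20, 40, 80), equivalencePower, 0,
                   sd = 1, bounds = 0.5)
    expect_true(all(diff(pows) >= -1e-12))
    # never accepted with null bounds
    expect_error(equivalencePower(10, 1, 0))
    # Monte-Carlo rejection rate at n = 100, sd = 1, bounds 0.5, diff 0
    n <- 100; nsim <- 20000
    tcrit <- qt(0.95, 2 * n - 2)
    set.seed(99)
    hits <- 0
    for (i in seq_len(nsim)) {
        x <- rnorm(n); y <- rnorm(n)
        se <- sqrt(var(x) / n + var(y) / n)
        d <- mean(y) - mean(x)
        if ((d + 0.5) / se >= tcrit && (d - 0.5) / se <= -tcrit)
            hits <- hits + 1
    }
    expect_lt(abs(equivalencePower(100, 1, 0.5) - hits / nsim), 0.02)
})

test_that("required sample size is the smallest n meeting the power target", {
    n <- requiredSampleSize(1, 0.5, power = 0.8)
    expect_gte(equivalencePower(n, 1, 0.5), 0.8)
    expect_lt(equivalencePower(n - 1, 1, 0.5), 0.8)
    expect_warning(res <- requiredSampleSize(1, 0.5, trueDifference = 0.6),
                   "unbounded")
    expect_true(is.na(res))
})

test_that("reduction summary reproduces hand arithmetic and is scale invariant", {
    sv <- toySurvey()
    r <- reductionSummary(sv)
    # shared meshes only: CEN catch 4+2+5 = 11 (5 mm ruffe excluded), MOD 4
    ulc <- r[r$basin == "ULC", ]
    expect_equal(ulc$catch_cen, 11)
    expect_equal(ulc$catch_mod, 4)
    expect_equal(ulc$catch_reduction_pct, 100 * (1 - 4 / 11))
    # NPUE: CEN (6*100/3.75 + 5*100/3.75), MOD (3*100/1.875 + 1*100/30)
    expect_equal(ulc$npue_cen, 1100 / 3.75)
    expect_equal(ulc$npue_mod, 300 / 1.875 + 100 / 30)
    # equal totals give 0%
    dep <- deployments(sv); cc <- catches(sv)[c(1, 4), ]
    cc$count <- c(3L, 3L); cc$mesh_mm <- c("10", "10")
    expect_equal(reductionSummary(gillnetSurvey(dep, cc))$catch_reduction_pct,
                 c(0, 0))
    # multiplying every count by a constant leaves percentages unchanged
    cc2 <- catches(sv); cc2$count <- cc2$count * 7L
    r2 <- reductionSummary(gillnetSurvey(dep, cc2))
    expect_equal(r2$catch_reduction_pct, r$catch_reduction_pct)
    expect_equal(r2$npue_reduction_pct, r$npue_reduction_pct)
})

test_that("labour savings follow the weighted catch ratio", {
    dep <- data.frame(net_id = c("c", "m"), design = c("CEN", "MOD"),
        basin = "B", zone = "benthic", stratum = "s", site_id = "x",
        date = "2019-09-12", replicate_pair_id = c("pp", "pp"))
    mk <- function(id, counts) data.frame(net_id = id,
        mesh_mm = c("10", "19.5", "35"), species = "sp",
        count = as.integer(counts), biomass_g = NA_real_)
    sv <- gillnetSurvey(dep, rbind(mk("c", c(10, 20, 30)), mk("m", c(5, 10, 10))))
    # uniform weights: 60 vs 25
    expect_equal(labourSavings(sv)$savingPercent, 100 * (1 - 25 / 60))
    # 1 min small meshes, 3 min large: CEN 10+20+90=120, MOD 5+10+30=45
    w <- c("10" = 1, "19.5" = 1, "35" = 3)
    expect_equal(labourSavings(sv, perFishMinutes = w)$savingPercent,
                 100 * (1 - 45 / 120))
    # MOD exactly half of CEN in every mesh: 50%
    sv2 <- gillnetSurvey(dep, rbind(mk("c", c(10, 20, 30)), mk("m", c(5, 10, 15))))
    expect_equal(labourSavings(sv2, perFishMinutes = w)$savingPercent, 50)
    # identical catches: 0%
    sv3 <- gillnetSurvey(dep, rbind(mk("c", c(10, 20, 30)), mk("m", c(10, 20, 30))))
    expect_equal(labourSavings(sv3)$savingPercent, 0)
})
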