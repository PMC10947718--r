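# Seeded catch simulator: determinism, layout, config round-trip, and
# convergence of realized means to the analytic negative-binomial means.

test_that("templates reproduce the intended deployment layouts", {
    cfg <- defaultConfig("lake_constance_like")
    sv <- simulateSurvey(cfg)
    d <- deployments(sv)
    counts <- table(d$basin, d$zone)
    expect_equal(counts["ULC", "benthic"], 310)
    expect_equal(counts["ULC", "pelagic"], 98)
    expect_equal(counts["LLC", "benthic"], 76)
    expect_equal(counts["LLC", "pelagic"], 23)
    # paired replicate subsets
    pairs <- d[!is.na(d$replicate_pair_id), ]
    np <- tapply(pairs$replicate_pair_id, paste(pairs$basin, pairs$zone),
                 function(x) length(unique(x)))
    expect_equal(as.vector(np[c("ULC benthic", "ULC pelagic",
                                "LLC benthic", "LLC pelagic")]),
                 c(81, 26, 20, 9))
    expect_equal(nrow(deployments(simulateSurvey(defaultConfig("minimal")))), 12)
    expect_error(defaultConfig("nonesuch"))
})

test_that("the same seed gives identical output; different seeds differ", {
    cfg <- defaultConfig("minimal", seed = 5)
    a <- simulateSurvey(cfg)
    b <- simulateSurvey(cfg)
    expect_identical(deployments(a), deployments(b))
    expect_identical(catches(a), catches(b))
    c_ <- simulateSurvey(defaultConfig("minimal", seed = 6))
    expect_false(identical(catches(a), catches(c_)))
})

test_that("adding deployments does not reshuffle existing nets", {
    cfg <- defaultConfig("minimal", seed = 5)
    small <- simulateSurvey(cfg)
    cfg2 <- cfg
    cfg2$deployments[[1]]$n <- 6L   # three extra unpaired CEN nets
    big <- simulateSurvey(gillnetTools:::.normalizeConfig(cfg2))
    shared <- deployments(small)$net_id
    cs <- catches(small); cb <- catches(big)
    expect_equal(cs, cb[cb$net_id %in% shared, ], ignore_attr = TRUE)
})

test_that("config serializes to YAML and reloads identically", {
    cfg <- defaultConfig("minimal", seed = 3)
    f <- withr::local_tempfile(fileext = ".yaml")
    writeConfig(cfg, f)
    expect_identical(readConfig(f), cfg)
    cfg2 <- defaultConfig("lake_constance_like", seed = 8)
    f2 <- withr::local_tempfile(fileext = ".yaml")
    writeConfig(cfg2, f2)
    expect_identical(readConfig(f2), cfg2)
})

test_that("realized panel means converge to mu and scale with panel area", {
    cfg <- bigPanelConfig(nNets = 2500, seed = 11)
    sv <- simulateSurvey(gillnetTools:::.normalizeConfig(cfg))
    d <- deployments(sv); cc <- catches(sv)
    panelMean <- function(design, mesh) {
        ids <- d$net_id[d$design == design]
        x <- cc$count[cc$net_id %in% ids & cc$mesh_mm == mesh]
        full <- c(x, rep(0, length(ids) - length(x)))  # absent rows = zero catch
        list(mean = mean(full), se = sd(full) / sqrt(length(full)))
    }
    for (mesh in c("6.25", "10")) for (des in c("CEN", "MOD")) {
        mu <- analyticPanelMean(cfg, 1, des, mesh)
        got <- panelMean(des, mesh)
        expect_lt(abs(got$mean - mu), 3 * got$se + 1e-12)
    }
    # MOD 6.25 mm expected catch is half the CEN 6.25 mm expected catch
    muC <- analyticPanelMean(cfg, 1, "CEN", "6.25")
    muM <- analyticPanelMean(cfg, 1, "MOD", "6.25")
    expect_equal(muM / muC, 0.5)
    gotC <- panelMean("CEN", "6.25"); gotM <- panelMean("MOD", "6.25")
    expect_lt(abs(gotM$mean - 0.5 * gotC$mean),
              3 * sqrt(gotM$se^2 + 0.25 * gotC$se^2))
})

test_that("a configured dominance share of 0.8 is realized within 0.05", {
    cfg <- defaultConfig("minimal", seed = 21)
    cfg$deployments <- lapply(cfg$deployments[1:2], function(d) {
        d$n <- 250L; d$n_paired <- 0L; d
    })
    cfg$strata <- cfg$strata[1]
    for (i in seq_along(cfg$species))
        cfg$species[[i]]$depth_density <- cfg$species[[i]]$depth_density[1]
    sv <- simulateSurvey(gillnetTools:::.normalizeConfig(cfg))
    m <- catchMatrix(sv)
    share <- sum(m[, "dominant"]) / sum(m)
    expect_lt(abs(share - 0.8), 0.05)
})

test_that("counts are overdispersed for finite k and near-Poisson for huge k", {
    base <- bigPanelConfig(nNets = 1500, seed = 31, k = 0.3)
    vmr <- function(cfg, mesh = "10") {
        sv <- simulateSurvey(gillnetTools:::.normalizeConfig(cfg))
        d <- deployments(sv); cc <- catches(sv)
        ids <- d$net_id[d$design == "CEN"]
        x <- cc$count[cc$net_id %in% ids & cc$mesh_mm == mesh]
        full <- c(x, rep(0, length(ids) - length(x)))
        var(full) / mean(full)
    }
    expect_gt(vmr(base), 1.5)
    nearPois <- bigPanelConfig(nNets = 1500, seed = 31, k = 1e6)
    expect_lt(abs(vmr(nearPois) - 1), 0.2)
})

test_that("zero-density species are never caught", {
    cfg <- defaultConfig("minimal", seed = 9)
    cfg$species[[2]]$depth_density <- lapply(cfg$species[[2]]$depth_density,
                                             function(x) 0)
    sv <- simulateSurvey(gillnetTools:::.normalizeConfig(cfg))
    expect_false(cfg$species[[2]]$species %in% catches(sv)$species)
})

test_that("paired replicates share site, night and pair id across designs", {
    sv <- simulateSurvey(defaultConfig("minimal", seed = 2))
    d <- deployments(sv)
    for (p in unique(d$replicate_pair_id)) {
        pair <- d[d$replicate_pair_id == p, ]
        expect_equal(nrow(pair), 2)
        expect_setequal(pair$design, c("CEN", "MOD"))
        expect_equal(length(unique(pair$site_id)), 1)
        expect_equal(length(unique(pair$date)), 1)
    }
})
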