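# Small in-code fixtures shared across tests.

toySurvey <- function() {
    # 2 CEN + 2 MOD benthic nets, paired, one basin; includes a 5 mm CEN
    # record (a mesh MOD lacks) and biomass
    dep <- data.frame(
        net_id = c("c1", "m1", "c2", "m2"),
        design = c("CEN", "MOD", "CEN", "MOD"),
        basin = "ULC", zone = "benthic", stratum = "0-2.9",
        site_id = c("s1", "s1", "s2", "s2"),
        date = "2019-09-12",
        replicate_pair_id = c("p1", "p1", "p2", "p2"),
        stringsAsFactors = FALSE)
    cat_ <- data.frame(
        net_id = c("c1", "c1", "c1", "m1", "c2", "m2"),
        mesh_mm = c("10", "10", "5", "10", "12.5", "43"),
        species = c("perch", "roach", "ruffe", "perch", "perch", "pike"),
        count = c(4L, 2L, 1L, 3L, 5L, 1L),
        biomass_g = c(40, 18, 2, 30, 55, 900),
        stringsAsFactors = FALSE)
    gillnetSurvey(dep, cat_)
}

euclideanPoints <- function(n, d = 2, seed = 1, sd = 1) {
    set.seed(seed)
    matrix(rnorm(n * d, sd = sd), n, d,
           dimnames = list(paste0("pt", seq_len(n)), NULL))
}

# a config with many unpaired nets of both designs in one stratum, one
# species with selectivity on the halved 6.25 mm panel
bigPanelConfig <- function(nNets, seed = 11, k = 0.5) {
    cfg <- defaultConfig("minimal", seed = seed)
    cfg$deployments <- lapply(cfg$deployments[1:2], function(d) {
        d$n <- as.integer(nNets); d$n_paired <- 0L; d
    })
    cfg$strata <- cfg$strata[1]
    sel <- setNames(as.list(rep(0, 12)),
                    c("5", "6.25", "8", "10", "12.5", "15.5", "19.5", "24",
                      "29", "35", "43", "55"))
    sel[["6.25"]] <- 0.4; sel[["10"]] <- 0.6
    cfg$species <- cfg$species[1]
    cfg$species[[1]]$mesh_selectivity <- sel
    cfg$species[[1]]$k <- k
    cfg$species[[1]]$depth_density <- cfg$species[[1]]$depth_density[1]
    cfg
}

analyticPanelMean <- function(cfg, speciesIdx, design, mesh) {
    # independent oracle: mu = density * selectivity * area / 100
    p <- cfg$species[[speciesIdx]]
    dens <- p$depth_density[[1]]
    sel <- p$mesh_selectivity[[mesh]]
    dens * sel * panelArea(design, mesh, zone = "benthic") / 100
}
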