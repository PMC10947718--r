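# Seeded negative-binomial catch simulator.
#
# Counts for species s in a mesh panel are drawn NB with mean
#   mu = density(s, basin.zone.stratum) * selectivity(s, mesh) * area/100
# and dispersion k (variance mu + mu^2/k), independently across panels and
# species; an optional site-level log-normal random effect (shared by the
# two nets of a replicate pair) induces pair correlation. One master seed;
# per-net and per-site substreams are derived by hashing identifiers, so
# adding deployments does not reshuffle the catches of existing nets.

.hash31 <- function(s, salt = 0L) {
    h <- as.double(salt %% 2147483647)
    for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
    as.integer(h)
}

.strKey <- function(basin, zone, stratum) paste(basin, zone, stratum, sep = ".")

.normalizeConfig <- function(cfg) {
    # canonical numeric form (12 significant digits) so that a config
    # written to YAML and reloaded is bit-identical to the original
    num <- function(x) signif(as.numeric(x), 12)
    cfg$rng_seed <- as.integer(cfg$rng_seed)
    cfg$pair_sigma <- num(cfg$pair_sigma)
    cfg$paired_replicates <- isTRUE(cfg$paired_replicates)
    cfg$deployments <- lapply(cfg$deployments, function(d) {
        d$n <- as.integer(d$n); d$n_paired <- as.integer(d$n_paired); d
    })
    cfg$strata <- lapply(cfg$strata, function(s) {
        s$depth_min <- num(s$depth_min)
        s$depth_max <- num(s$depth_max)
        s$volume <- num(s$volume); s
    })
    cfg$species <- lapply(cfg$species, function(p) {
        p$k <- num(p$k)
        p$dominance_share <- num(p$dominance_share)
        p$zone_affinity <- lapply(p$zone_affinity, num)
        p$mesh_selectivity <- lapply(p$mesh_selectivity, num)
        p$depth_density <- lapply(p$depth_density, num)
        p
    })
    cfg$biomass <- lapply(cfg$biomass, num)
    class(cfg) <- "SimulationConfig"
    cfg
}

.speciesPool <- function(zone, nOther, dominant, dominantShare, totalDensity,
                         strata, decayScale, meshWeights) {
    # constant dominance share across strata: all species share one depth
    # decay, so the realized NPUE share equals the density share
    mids <- vapply(strata, function(s) (s$depth_min + s$depth_max) / 2, 0)
    decay <- exp(-mids / decayScale)
    keys <- vapply(strata, function(s) .strKey(s$basin, s$zone, s$stratum), "")
    mk <- function(name, share) {
        dens <- totalDensity * share * decay
        list(species = name,
             zone_affinity = as.list(setNames(as.numeric(c("benthic", "pelagic") == zone),
                                              c("benthic", "pelagic"))),
             dominance_share = share,
             k = 0.3,
             mesh_selectivity = as.list(meshWeights),
             depth_density = as.list(setNames(dens, keys)))
    }
    others <- (1 - dominantShare) / nOther
    c(list(mk(dominant, dominantShare)),
      lapply(seq_len(nOther), function(i) mk(sprintf("%s_sp%02d", zone, i), others)))
}

.mergeSpecies <- function(a, b) {
    # merge depth_density/affinity for species appearing in both zones
    names(a) <- vapply(a, `[[`, "", "species")
    names(b) <- vapply(b, `[[`, "", "species")
    for (nm in names(b)) {
        if (nm %in% names(a)) {
            a[[nm]]$depth_density <- c(a[[nm]]$depth_density, b[[nm]]$depth_density)
            a[[nm]]$zone_affinity <- as.list(mapply(max, a[[nm]]$zone_affinity,
                                                    b[[nm]]$zone_affinity, SIMPLIFY = FALSE))
        } else a[[nm]] <- b[[nm]]
    }
    unname(a)
}

.lakeConstanceLayout <- function() {
    # deployment counts per basin/zone/stratum/design and paired subsets,
    # as in the Lake Constance campaign; volumes are relative weights
    # (hypsographic data are not part of the layout and are user-supplied
    # in real analyses)
    ub <- list(
        list("0-2.9", 0, 3, 9, 30, 9), list("3-5.9", 3, 6, 11, 30, 11),
        list("6-11.9", 6, 12, 12, 30, 12), list("12-19.9", 12, 20, 11, 30, 11),
        list("20-34.9", 20, 35, 10, 30, 10), list("35-49.9", 35, 50, 8, 30, 8),
        list("50-74.9", 50, 75, 9, 12, 9), list("75-99.9", 75, 100, 11, 13, 11),
        list("100-149.9", 100, 150, 0, 9, 0), list("150-199.9", 150, 200, 1, 8, 0),
        list("200-250", 200, 250, 1, 5, 0))
    up <- list(
        list("0-5.9", 0, 6, 0, 12, 0), list("6-11.9", 6, 12, 2, 12, 2),
        list("12-19.9", 12, 20, 12, 12, 12), list("20-34.9", 20, 35, 12, 12, 12),
        list("35-49.9", 35, 50, 0, 12, 0), list("50-74.9", 50, 75, 0, 12, 0))
    lb <- list(
        list("0-2.9", 0, 3, 3, 10, 3), list("3-5.9", 3, 6, 4, 10, 4),
        list("6-11.9", 6, 12, 4, 10, 4), list("12-19.9", 12, 20, 3, 10, 3),
        list("20-34.9", 20, 35, 3, 10, 3), list("35-50", 35, 50, 3, 6, 3))
    lp <- list(
        list("0-5.9", 0, 6, 0, 4, 0), list("6-11.9", 6, 12, 3, 4, 3),
        list("12-19.9", 12, 20, 4, 4, 4), list("20-34.9", 20, 35, 2, 2, 2))
    list(ULC.benthic = ub, ULC.pelagic = up, LLC.benthic = lb, LLC.pelagic = lp)
}

#' Default simulation configurations
#'
#' \code{"lake_constance_like"} reproduces the deployment layout of the
#' Lake Constance campaign (310 benthic + 98 pelagic nets in the upper
#' basin, 76 + 23 in the lower basin, with the paired CEN/MOD replicate
#' subsets) and a 25-species pool with a perch-like benthic dominant
#' (density share 0.8) and a stickleback-like pelagic dominant (share
#' 0.85), overdispersed counts (k = 0.3) and densities decaying with
#' depth. \code{"minimal"} yields 2 strata x 2 designs x 3 nets (12
#' deployments, all paired) with 3 species, for fast tests.
#'
#' @param template \code{"lake_constance_like"} or \code{"minimal"}
#' @param seed master RNG seed recorded in the config
#' @return a \code{SimulationConfig} (a structured list)
#' @seealso [simulateSurvey()], [writeConfig()]
#' @export
defaultConfig <- function(template = c("lake_constance_like", "minimal"),
                          seed = 1L) {
    template <- match.arg(template)
    cenMesh <- .CEN_MESHES
    if (template == "minimal") {
        strata <- list(
            list(basin = "B1", zone = "benthic", stratum = "0-5.9",
                 depth_min = 0, depth_max = 6, volume = 2),
            list(basin = "B1", zone = "benthic", stratum = "6-19.9",
                 depth_min = 6, depth_max = 20, volume = 1))
        dep <- list()
        for (s in strata) for (des in c("CEN", "MOD"))
            dep[[length(dep) + 1]] <- list(basin = s$basin, zone = s$zone,
                stratum = s$stratum, design = des, n = 3L, n_paired = 3L)
        w <- setNames(rep(0, length(cenMesh)), cenMesh)
        w[c("8", "10", "12.5", "15.5")] <- c(0.2, 0.4, 0.3, 0.1)
        species <- .speciesPool("benthic", 2, "dominant", 0.8, 60,
                                strata, 40, w)
        cfg <- list(template = template, rng_seed = seed, pair_sigma = 0.4,
                    paired_replicates = TRUE,
                    biomass = list(length_factor = 0.55, length_sdlog = 0.15,
                                   lw_a = 0.01, lw_b = 3.0),
                    strata = strata, deployments = dep, species = species)
        return(.normalizeConfig(cfg))
    }
    layout <- .lakeConstanceLayout()
    strata <- list(); dep <- list()
    for (key in names(layout)) {
        parts <- strsplit(key, ".", fixed = TRUE)[[1]]
        rows <- layout[[key]]
        mids <- vapply(rows, function(r) (r[[2]] + r[[3]]) / 2, 0)
        vols <- exp(-mids / 60); vols <- vols / sum(vols)
        for (i in seq_along(rows)) {
            r <- rows[[i]]
            strata[[length(strata) + 1]] <- list(basin = parts[1], zone = parts[2],
                stratum = r[[1]], depth_min = r[[2]], depth_max = r[[3]],
                volume = round(vols[i], 4))
            for (j in c(4L, 5L)) if (r[[j]] > 0)
                dep[[length(dep) + 1]] <- list(basin = parts[1], zone = parts[2],
                    stratum = r[[1]], design = c("CEN", "MOD")[j - 3L],
                    n = as.integer(r[[j]]), n_paired = as.integer(r[[6]]))
        }
    }
    isZone <- function(z) Filter(function(s) s$zone == z, strata)
    wB <- setNames(rep(0.01, length(cenMesh)), cenMesh)
    wB[c("6.25", "8", "10", "12.5", "15.5", "19.5")] <-
        c(0.05, 0.10, 0.35, 0.30, 0.08, 0.04)
    wB <- wB / sum(wB)
    wP <- setNames(rep(0.005, length(cenMesh)), cenMesh)
    wP[c("6.25", "8", "10")] <- c(0.15, 0.45, 0.30)
    wP <- wP / sum(wP)
    benth <- .speciesPool("benthic", 19, "perch_like", 0.8, 1000, isZone("benthic"),
                          40, wB)
    pelag <- .speciesPool("pelagic", 9, "stickleback_like", 0.85, 30,
                          isZone("pelagic"), 60, wP)
    species <- .mergeSpecies(benth, pelag)
    cfg <- list(template = template, rng_seed = seed, pair_sigma = 0.4,
                paired_replicates = TRUE,
                biomass = list(length_factor = 0.55, length_sdlog = 0.15,
                               lw_a = 0.01, lw_b = 3.0),
                strata = strata, deployments = dep, species = species)
    .normalizeConfig(cfg)
}

#' Write / read a simulation config as YAML
#'
#' @param config a \code{SimulationConfig}
#' @param path file path
#' @return \code{readConfig} returns the config; a written config reloads
#'   identically.
#' @export
writeConfig <- function(config, path) {
    # precision 17 so doubles survive the YAML round trip bit-exactly
    yaml::write_yaml(unclass(config), path, precision = 17)
    invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) .normalizeConfig(yaml::read_yaml(path))

.expectedPanelMean <- function(config, species, basin, zone, stratum, design, mesh) {
    # analytic mean mu for one species in one panel (oracle for tests)
    prof <- NULL
    for (p in config$species) if (p$species == species) prof <- p
    stopifnot(!is.null(prof))
    dens <- prof$depth_density[[.strKey(basin, zone, stratum)]]
    if (is.null(dens)) dens <- 0
    sel <- prof$mesh_selectivity[[.meshKey(mesh)]]
    if (is.null(sel)) sel <- 0
    area <- panelArea(design, mesh, zone)
    dens * sel * area / 100
}

#' Simulate a gillnet survey
#'
#' Draws catches for every configured deployment. Counts are negative
#' binomial around the analytic panel mean (density x mesh selectivity x
#' panel area / 100) with per-species dispersion k; paired replicates
#' share a site identifier, night and (when \code{pair_sigma > 0}) a
#' site-level log-normal effect of mean 1, so patchiness is correlated
#' within a pair. Biomass per record is the sum of individual weights from
#' a mesh-dependent log-normal length and a length-weight power law. The
#' same config (including its seed) always yields byte-identical output.
#'
#' @param config a \code{SimulationConfig} from [defaultConfig()] or
#'   [readConfig()]
#' @return a [GillnetSurvey-class]
#' @export
simulateSurvey <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    master <- config$rng_seed
    sigma <- if (isTRUE(config$paired_replicates)) config$pair_sigma else 0
    spp <- vapply(config$species, `[[`, "", "species")
    designs <- builtinDesigns()

    depRows <- list(); catRows <- list()
    for (d in config$deployments) {
        des <- designs[[.designKey(d$design, d$zone)]]
        meshes <- des@panels$mesh_mm
        areas <- des@panels$area_m2
        dens <- vapply(config$species, function(p) {
            v <- p$depth_density[[.strKey(d$basin, d$zone, d$stratum)]]
            if (is.null(v)) 0 else v
        }, 0)
        sel <- t(vapply(config$species, function(p) {
            v <- unlist(p$mesh_selectivity)[meshes]
            ifelse(is.na(v), 0, v)
        }, numeric(length(meshes))))
        kdisp <- vapply(config$species, function(p) p$k, 0)
        for (i in seq_len(d$n)) {
            paired <- i <= d$n_paired
            site <- if (paired)
                sprintf("%s_%s_%s_site%02d", d$basin, d$zone, d$stratum, i)
            else
                sprintf("%s_%s_%s_%s_solo%02d", d$basin, d$zone, d$stratum,
                        d$design, i)
            netId <- sprintf("%s_%s_%s_%s_%02d", d$basin, d$zone, d$stratum,
                             d$design, i)
            pairId <- if (paired)
                sprintf("%s_%s_%s_pair%02d", d$basin, d$zone, d$stratum, i)
            else NA_character_
            # site effect: shared by both nets of the pair (hash of site id)
            siteEff <- rep(1, length(spp))
            if (sigma > 0 && paired) {
                set.seed(.hash31(site, master))
                siteEff <- exp(rnorm(length(spp), -sigma^2 / 2, sigma))
            }
            date <- sprintf("2019-09-%02d", 12 + (i - 1) %% 4)
            depRows[[length(depRows) + 1]] <- data.frame(
                net_id = netId, design = d$design, basin = d$basin,
                zone = d$zone, stratum = d$stratum, site_id = site,
                date = date, replicate_pair_id = pairId,
                stringsAsFactors = FALSE)
            set.seed(.hash31(netId, master))
            mu <- (dens * siteEff) %o% rep(1, length(meshes)) * sel *
                rep(areas / 100, each = length(spp))
            counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                                     size = rep(kdisp, length(meshes))),
                             nrow = length(spp))
            hit <- which(counts > 0, arr.ind = TRUE)
            if (nrow(hit)) {
                n <- counts[hit]
                meshNum <- as.numeric(meshes[hit[, 2]])
                bio <- vapply(seq_along(n), function(r) {
                    L <- rlnorm(n[r], log(config$biomass$length_factor * meshNum[r]),
                                config$biomass$length_sdlog)
                    sum(config$biomass$lw_a * L^config$biomass$lw_b)
                }, 0)
                catRows[[length(catRows) + 1]] <- data.frame(
                    net_id = netId, mesh_mm = meshes[hit[, 2]],
                    species = spp[hit[, 1]], count = as.integer(n),
                    biomass_g = round(bio, 1), stringsAsFactors = FALSE)
            }
        }
    }
    dep <- do.call(rbind, depRows)
    cat_ <- if (length(catRows)) do.call(rbind, catRows) else NULL
    gillnetSurvey(dep, cat_, designs)
}
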