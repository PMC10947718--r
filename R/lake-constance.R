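# Published summary statistics of the Lake Constance gillnet campaign
# (upper basin ULC, lower basin LLC). These are inputs for worked
# examples and for recomputing the campaign's design numbers without the
# raw per-net data, which were not deposited.

#' Deployment counts of the Lake Constance campaign
#'
#' Nets deployed per basin and zone (both designs combined), and the
#' paired CEN/MOD replicate subsets used for design comparisons.
#'
#' @return data.frame with columns \code{basin}, \code{zone}, \code{cen},
#'   \code{mod}, \code{n} (total) and \code{pairs}
#' @export
lakeConstanceNetCounts <- function() {
    data.frame(
        basin = c("ULC", "ULC", "LLC", "LLC"),
        zone = c("benthic", "pelagic", "benthic", "pelagic"),
        cen = c(83L, 26L, 20L, 9L),
        mod = c(227L, 72L, 56L, 14L),
        n = c(310L, 98L, 76L, 23L),
        pairs = c(81L, 26L, 20L, 9L),
        stringsAsFactors = FALSE)
}

#' Precision summary statistics of the Lake Constance campaign
#'
#' Mean and SD of per-net log(NPUE+1), for total abundance and for the
#' dominant species, by basin and zone; \code{n} is the matching net
#' count. Feed into [cvFromStats()], [pringleNets()] and [powerNets()].
#'
#' @return data.frame with columns \code{basin}, \code{zone},
#'   \code{metric} ("total" or the dominant species), \code{mean},
#'   \code{sd}, \code{n}
#' @export
lakeConstancePrecision <- function() {
    data.frame(
        basin = rep(c("ULC", "ULC", "LLC", "LLC"), each = 2),
        zone = rep(c("benthic", "pelagic", "benthic", "pelagic"), each = 2),
        metric = c("total", "perch", "total", "stickleback",
                   "total", "perch", "total", "stickleback"),
        mean = c(1.34, 1.06, 0.48, 0.39, 1.37, 1.18, 0.39, 0.39),
        sd = c(0.95, 1.02, 0.48, 0.49, 0.89, 0.96, 0.35, 0.72),
        n = c(310L, 310L, 98L, 98L, 76L, 76L, 23L, 23L),
        stringsAsFactors = FALSE)
}

#' Mesh-level replicate catch totals of the Lake Constance campaign
#'
#' Total catch and summed NPUE per basin, zone, design and mesh size over
#' the replicate-pair nets (shared meshes only), with the replicate net
#' counts per group.
#'
#' @return data.frame with columns \code{basin}, \code{zone},
#'   \code{design}, \code{mesh_mm}, \code{total_catch}, \code{npue},
#'   \code{n_nets}
#' @export
lakeConstanceMeshTotals <- function() {
    mesh <- c("6.25", "8", "10", "12.5", "15.5", "19.5", "24", "29", "35", "43")
    mk <- function(basin, zone, design, catch, npue, nNets)
        data.frame(basin = basin, zone = zone, design = design,
                   mesh_mm = mesh, total_catch = catch, npue = npue,
                   n_nets = nNets, stringsAsFactors = FALSE)
    rbind(
        mk("ULC", "benthic", "CEN",
           c(113, 249, 1194, 1082, 307, 164, 74, 27, 21, 12),
           c(3013, 6640, 31840, 28853, 8187, 4373, 1973, 720, 560, 320), 81L),
        mk("ULC", "benthic", "MOD",
           c(69, 134, 495, 485, 273, 190, 68, 53, 66, 47),
           c(3680, 7147, 26400, 25867, 7280, 5067, 1813, 707, 440, 157), 81L),
        mk("ULC", "pelagic", "CEN",
           c(28, 151, 94, 9, 3, 1, 0, 9, 1, 2),
           c(187, 1007, 627, 60, 20, 7, 0, 60, 7, 13), 26L),
        mk("ULC", "pelagic", "MOD",
           c(7, 46, 79, 1, 2, 1, 4, 31, 10, 2),
           c(93, 613, 1053, 13, 13, 7, 27, 103, 17, 2), 26L),
        mk("LLC", "benthic", "CEN",
           c(29, 118, 185, 120, 204, 27, 8, 2, 5, 2),
           c(773, 3147, 4933, 3200, 5440, 720, 213, 53, 133, 53), 20L),
        mk("LLC", "benthic", "MOD",
           c(15, 54, 149, 56, 31, 19, 9, 4, 2, 9),
           c(800, 2880, 7947, 2987, 827, 507, 240, 53, 13, 30), 20L),
        mk("LLC", "pelagic", "CEN",
           c(58, 3, 11, 0, 0, 3, 0, 1, 0, 0),
           c(387, 20, 73, 0, 0, 20, 0, 7, 0, 0), 9L),
        mk("LLC", "pelagic", "MOD",
           c(3, 2, 0, 3, 0, 0, 0, 1, 1, 2),
           c(40, 27, 0, 40, 0, 0, 0, 3, 2, 2), 9L))
}

#' Per-stratum design inputs for the prospective Lake Constance campaign
#'
#' Fractional net requirements per benthic depth stratum: the
#' species-detection requirement (90% of species with 50% probability),
#' the precision-based (Pringle, CV target 0.1) requirement, the
#' power-based alternative, and the feasibility flag (abundance
#' estimation is infeasible below 50 m in ULC and below 20 m in LLC).
#'
#' @return data.frame with columns \code{basin}, \code{stratum},
#'   \code{species_req}, \code{npue_req}, \code{power_req},
#'   \code{feasible}
#' @export
lakeConstanceRequirements <- function() {
    data.frame(
        basin = c(rep("ULC", 11), rep("LLC", 6)),
        stratum = c("0-2.9", "3-5.9", "6-11.9", "12-19.9", "20-34.9",
                    "35-49.9", "50-74.9", "75-99.9", "100-149.9",
                    "150-199.9", "200-250",
                    "0-2.9", "3-5.9", "6-11.9", "12-19.9", "20-34.9", "35-50"),
        species_req = c(30.2, 12.9, 11.5, 11.4, 26.0, 17.0, 8.0, 6.9, 15.9,
                        10.9, 8.4,
                        9.3, 3.3, 2.6, 7.9, 12.9, 2.1),
        npue_req = c(7.8, 3.3, 3.0, 2.9, 22.6, 24.3, 139.4, 120.0, 276.8,
                     189.9, 145.9,
                     9.7, 3.5, 2.7, 8.2, 691.6, 110.7),
        power_req = c(3.9, 1.7, 1.5, 1.5, 79.7, 352.4, 81.6, 70.2, 161.9,
                      111.1, 85.4,
                      5.3, 1.9, 1.4, 4.5, 380.3, 60.9),
        feasible = c(rep(TRUE, 6), rep(FALSE, 5),
                     rep(TRUE, 4), rep(FALSE, 2)),
        stringsAsFactors = FALSE)
}

#' Baseline benthic net counts under the standard protocol
#'
#' The net numbers the standard stratified protocol (lake-morphology
#' based) would require: 605 benthic nets in ULC plus 80 in LLC.
#'
#' @return named integer vector with elements \code{ULC}, \code{LLC} and
#'   \code{total}
#' @export
lakeConstanceBaseline <- function() {
    c(ULC = 605L, LLC = 80L, total = 685L)
}
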