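# Built-in CEN (DIN EN 14757) and MOD gillnet geometries.
#
# CEN: 12 geometric mesh sizes, uniform 2.5 m panels; height 1.5 m benthic
# (3.75 m2 per panel) and 6 m pelagic (15 m2 per panel).
# MOD: drops the 5 and 55 mm meshes; small-mesh panels (6.25-12.5 mm) are
# halved, 29/35/43 mm panels enlarged 2-/4-/8-fold relative to CEN.

.CEN_MESHES <- c("5", "6.25", "8", "10", "12.5", "15.5", "19.5", "24",
                 "29", "35", "43", "55")

.MOD_MULTIPLIERS <- c("6.25" = 0.5, "8" = 0.5, "10" = 0.5, "12.5" = 0.5,
                      "15.5" = 1, "19.5" = 1, "24" = 1,
                      "29" = 2, "35" = 4, "43" = 8)

.zoneHeight <- function(zone) if (zone == "benthic") 1.5 else 6

.makeDesign <- function(name, zone, meshes, lengths) {
    h <- .zoneHeight(zone)
    new("NetDesign", name = name, zone = zone,
        panels = data.frame(mesh_mm = meshes,
                            panel_length_m = lengths,
                            height_m = h,
                            area_m2 = lengths * h,
                            stringsAsFactors = FALSE))
}

#' Built-in gillnet designs
#'
#' Returns the standard CEN net (12 mesh sizes 5-55 mm, uniform 2.5 m
#' panels) or the modified MOD net (10 mesh sizes; 5 and 55 mm dropped,
#' small-mesh panel areas halved, 29/35/43 mm panels enlarged 2-, 4- and
#' 8-fold) for the requested zone. Benthic nets are 1.5 m high, pelagic
#' nets 6 m.
#'
#' @param name \code{"CEN"} or \code{"MOD"}.
#' @param zone \code{"benthic"} or \code{"pelagic"}.
#' @return a [NetDesign-class]
#' @examples
#' builtinDesign("CEN", "benthic")   # total area 45 m2
#' builtinDesign("MOD", "benthic")   # total area 71.25 m2
#' @export
builtinDesign <- function(name = c("CEN", "MOD"), zone = c("benthic", "pelagic")) {
    name <- match.arg(name)
    zone <- match.arg(zone)
    if (name == "CEN") {
        .makeDesign("CEN", zone, .CEN_MESHES, rep(2.5, length(.CEN_MESHES)))
    } else {
        .makeDesign("MOD", zone, names(.MOD_MULTIPLIERS),
                    2.5 * unname(.MOD_MULTIPLIERS))
    }
}

#' All built-in designs keyed by "<design>.<zone>"
#' @return named list of [NetDesign-class]
#' @export
builtinDesigns <- function() {
    out <- list()
    for (n in c("CEN", "MOD")) for (z in c("benthic", "pelagic"))
        out[[paste(n, z, sep = ".")]] <- builtinDesign(n, z)
    out
}

#' Mesh sizes of a design
#' @param design a [NetDesign-class]
#' @return character vector of mesh keys (mm)
#' @export
meshSizes <- function(design) design@panels$mesh_mm

.meshKey <- function(mesh) {
    # canonical character key for a mesh size; trims fractional trailing
    # zeros so that "6.250", 6.25 and "6.25" agree (integers untouched)
    if (is.numeric(mesh)) mesh <- trimws(formatC(mesh, format = "fg", digits = 10))
    mesh <- trimws(mesh)
    frac <- grepl(".", mesh, fixed = TRUE)
    mesh[frac] <- sub("\\.$", "", sub("0+$", "", mesh[frac]))
    mesh
}

#' Standardization area of one mesh panel
#'
#' The area (m2) of the panel with the given mesh size in the given
#' design/zone; the NPUE denominator is \code{area / 100}.
#'
#' @param design a [NetDesign-class], or a design name (\code{"CEN"},
#'   \code{"MOD"}) combined with \code{zone}.
#' @param mesh mesh size in mm (numeric or character key).
#' @param zone required when \code{design} is given by name.
#' @return area in square metres
#' @examples
#' panelArea("CEN", 10, zone = "benthic")     # 3.75
#' panelArea("MOD", "6.25", zone = "benthic") # 1.875
#' panelArea("MOD", 43, zone = "benthic")     # 30
#' @export
panelArea <- function(design, mesh, zone = NULL) {
    if (is.character(design)) {
        stopifnot(!is.null(zone))
        design <- builtinDesign(design, zone)
    }
    key <- .meshKey(mesh)
    i <- match(key, design@panels$mesh_mm)
    if (is.na(i))
        stop(sprintf("mesh %s mm is not in design %s (%s)", key,
                     design@name, design@zone), call. = FALSE)
    design@panels$area_m2[i]
}

#' Read net designs from a CSV file
#'
#' Expected columns: \code{design}, \code{zone}, \code{mesh_mm},
#' \code{panel_length_m}, \code{height_m}. Returns a list keyed
#' \code{"<design>.<zone>"}.
#'
#' @param path CSV file path
#' @return named list of [NetDesign-class]
#' @export
readDesigns <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(mesh_mm = "character"))
    need <- c("design", "zone", "mesh_mm", "panel_length_m", "height_m")
    if (!all(need %in% names(d)))
        stop("designs file must have columns: ", paste(need, collapse = ", "))
    d$mesh_mm <- vapply(d$mesh_mm, .meshKey, character(1))
    out <- list()
    for (key in unique(paste(d$design, d$zone, sep = "."))) {
        sub <- d[paste(d$design, d$zone, sep = ".") == key, ]
        out[[key]] <- new("NetDesign", name = sub$design[1], zone = sub$zone[1],
            panels = data.frame(mesh_mm = sub$mesh_mm,
                                panel_length_m = sub$panel_length_m,
                                height_m = sub$height_m,
                                area_m2 = sub$panel_length_m * sub$height_m,
                                stringsAsFactors = FALSE))
    }
    out
}
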