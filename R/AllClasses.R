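#' @import methods
#' @importFrom stats pt qt quantile rlnorm rnbinom rnorm sd setNames var
NULL

#' Net design with mesh-size panels
#'
#' An S4 container for a multi-mesh gillnet design: an ordered set of
#' mesh-size panels, each with its own length, height and area. The panel
#' area is the denominator of the NPUE standardization (fish per 100 m2 of
#' panel per night), so heterogeneous designs (e.g. halved or enlarged
#' panels) remain directly comparable after standardization.
#'
#' Mesh sizes are stored as character keys (knot-to-knot bar length in mm,
#' e.g. \code{"6.25"}), never as floating point numbers, so that sizes such
#' as 6.25 and 12.5 compare exactly.
#'
#' @slot name Design name, e.g. \code{"CEN"} (the DIN EN 14757 standard
#'   net) or \code{"MOD"} (a modified design).
#' @slot zone \code{"benthic"} or \code{"pelagic"}.
#' @slot panels \code{data.frame} with columns \code{mesh_mm} (character),
#'   \code{panel_length_m}, \code{height_m}, \code{area_m2}.
#'
#' @seealso [builtinDesign()], [panelArea()]
#' @export
setClass("NetDesign",
    representation(name = "character", zone = "character", panels = "data.frame"))

setValidity("NetDesign", function(object) {
    msg <- character()
    p <- object@panels
    need <- c("mesh_mm", "panel_length_m", "height_m", "area_m2")
    if (!all(need %in% names(p)))
        return(paste("panels must have columns:", paste(need, collapse = ", ")))
    if (!is.character(p$mesh_mm))
        msg <- c(msg, "mesh_mm must be character (exact decimal keys)")
    if (anyDuplicated(p$mesh_mm))
        msg <- c(msg, "duplicate mesh sizes in design")
    if (any(p$area_m2 <= 0))
        msg <- c(msg, "panel areas must be positive")
    if (any(abs(p$area_m2 - p$panel_length_m * p$height_m) > 1e-6 * pmax(1, p$area_m2)))
        msg <- c(msg, "area_m2 must equal panel_length_m * height_m")
    if (!object@zone %in% c("benthic", "pelagic"))
        msg <- c(msg, "zone must be 'benthic' or 'pelagic'")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Gillnet survey: deployments plus sparse catch records
#'
#' An S4 container pairing a deployment table (one row per net set) with a
#' sparse catch table (one row per net x mesh x species actually caught;
#' absent combinations mean zero catch). Each deployment carries the net
#' design used, so catches can be standardized by the panel area of the
#' mesh they were taken in.
#'
#' @slot deployments \code{data.frame} with columns \code{net_id},
#'   \code{design}, \code{basin}, \code{zone}, \code{stratum},
#'   \code{site_id}, \code{date}, \code{replicate_pair_id} (\code{NA} when
#'   a net is unpaired).
#' @slot catches \code{data.frame} with columns \code{net_id},
#'   \code{mesh_mm} (character), \code{species}, \code{count} and
#'   optionally \code{biomass_g}.
#' @slot designs named list of [NetDesign-class] objects keyed
#'   \code{"<design>.<zone>"} (e.g. \code{"CEN.benthic"}).
#'
#' @seealso [gillnetSurvey()], [readSurvey()], [npueSummary()],
#'   [catchMatrix()]
#' @export
setClass("GillnetSurvey",
    representation(deployments = "data.frame", catches = "data.frame",
                   designs = "list"))

#' Standardized catch matrix (nets x species)
#'
#' A numeric matrix of per-net, per-species NPUE (fish per 100 m2 of net
#' panel area, summed over a net's panels), optionally transformed. Rows
#' are deployments (including all-zero rows for nets that caught nothing
#' -- zero catch is data, not missingness), columns are species.
#'
#' @slot transform transform applied elementwise: \code{"none"},
#'   \code{"log1p"} (log(x+1)) or \code{"log0p1"} (log(x+0.1)).
#' @slot sharedMeshesOnly whether records from meshes not shared by all
#'   designs in the survey (the 5 mm and 55 mm CEN-only panels) were
#'   excluded before standardization.
#' @seealso [catchMatrix()]
#' @export
setClass("CatchMatrix",
    contains = "matrix",
    representation(transform = "character", sharedMeshesOnly = "logical"))

#' Result of a permutation test (ANOSIM / PERMDISP)
#'
#' @slot statistic observed statistic: ANOSIM R (in [-1, 1]) or PERMDISP F
#'   (>= 0).
#' @slot statisticName \code{"R"} or \code{"F"}.
#' @slot nPerm number of label permutations.
#' @slot pValue permutation p-value, (b + 1) / (nPerm + 1) where b counts
#'   permuted statistics >= the observed one; never smaller than
#'   1 / (nPerm + 1).
#' @slot groupSizes named integer vector of group sizes used.
#' @slot details list of method-specific extras (e.g. per-sample
#'   distances to centroid and group means for PERMDISP, permuted
#'   statistics for diagnostics).
#' @export
setClass("PermutationTestResult",
    representation(statistic = "numeric", statisticName = "character",
                   nPerm = "integer", pValue = "numeric",
                   groupSizes = "integer", details = "list"))

setMethod("show", "NetDesign", function(object) {
    cat(sprintf("NetDesign '%s' (%s): %d mesh panels, total area %.2f m2\n",
        object@name, object@zone, nrow(object@panels), sum(object@panels$area_m2)))
    cat("  meshes [mm]:", paste(object@panels$mesh_mm, collapse = ", "), "\n")
})

setMethod("show", "GillnetSurvey", function(object) {
    d <- object@deployments
    cat(sprintf("GillnetSurvey: %d deployments, %d catch records, %d species\n",
        nrow(d), nrow(object@catches),
        length(unique(object@catches$species))))
    if (nrow(d)) {
        tab <- table(d$basin, d$zone, d$design)
        cat("  deployments by basin/zone/design:\n")
        print(stats::ftable(tab))
    }
})

setMethod("show", "CatchMatrix", function(object) {
    cat(sprintf("CatchMatrix: %d nets x %d species (transform=%s, shared meshes only=%s)\n",
        nrow(object), ncol(object), object@transform, object@sharedMeshesOnly))
})

setMethod("show", "PermutationTestResult", function(object) {
    cat(sprintf("%s = %.4f, P(perm) = %.4g  [%d permutations; groups: %s]\n",
        object@statisticName, object@statistic, object@pValue, object@nPerm,
        paste(sprintf("%s=%d", names(object@groupSizes), object@groupSizes),
              collapse = ", ")))
})

#' Accessors for survey components
#'
#' @param x a [GillnetSurvey-class]
#' @return \code{deployments()} and \code{catches()} return the underlying
#'   data.frames; \code{netDesigns()} the named list of
#'   [NetDesign-class] objects.
#' @export
deployments <- function(x) x@deployments

#' @rdname deployments
#' @export
catches <- function(x) x@catches

#' @rdname deployments
#' @export
netDesigns <- function(x) x@designs
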