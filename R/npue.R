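# NPUE/BPUE standardization: fish (or grams) per 100 m2 of net panel area.

.panelTable <- function(survey) {
    d <- deployments(survey)
    designs <- netDesigns(survey)
    rows <- lapply(seq_len(nrow(d)), function(i) {
        des <- designs[[.designKey(d$design[i], d$zone[i])]]
        data.frame(net_id = d$net_id[i], basin = d$basin[i], zone = d$zone[i],
                   design = d$design[i], stratum = d$stratum[i],
                   mesh_mm = des@panels$mesh_mm, area_m2 = des@panels$area_m2,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

.sharedMeshes <- function(survey) {
    d <- deployments(survey)
    keys <- unique(.designKey(d$design, d$zone))
    sets <- lapply(netDesigns(survey)[keys], meshSizes)
    Reduce(intersect, sets)
}

#' NPUE/BPUE summary table by group
#'
#' For each group (default: basin x zone x design x mesh size) returns the
#' total catch, the summed NPUE (sum over nets of count x 100 / panel
#' area), the mean and standard error of the per-net catch, and -- when
#' biomass was recorded -- the total biomass and summed BPUE. Per-net
#' total NPUE is the sum of NPUE over a net's mesh panels. Groups with no
#' deployed nets never arise from the deployment table itself; nets that
#' caught nothing contribute zeros to means and SEs.
#'
#' @param survey a [GillnetSurvey-class]
#' @param by character vector of grouping columns among \code{basin},
#'   \code{zone}, \code{design}, \code{stratum}, \code{mesh_mm}.
#' @param sharedMeshesOnly drop records from meshes not present in every
#'   design deployed (the CEN-only 5 and 55 mm panels) before summarizing.
#' @return data.frame with one row per group
#' @export
npueSummary <- function(survey, by = c("basin", "zone", "design", "mesh_mm"),
                        sharedMeshesOnly = FALSE) {
    stopifnot(all(by %in% c("basin", "zone", "design", "stratum", "mesh_mm")))
    pt <- .panelTable(survey)
    if (sharedMeshesOnly) pt <- pt[pt$mesh_mm %in% .sharedMeshes(survey), ]
    cc <- catches(survey)
    hasBio <- nrow(cc) > 0 && any(!is.na(cc$biomass_g))
    if (nrow(cc)) {
        k <- paste(cc$net_id, cc$mesh_mm, sep = "\r")
        cnt <- tapply(cc$count, k, sum)
        bio <- tapply(cc$biomass_g, k, function(x) sum(x, na.rm = TRUE))
    } else cnt <- bio <- numeric()
    pk <- paste(pt$net_id, pt$mesh_mm, sep = "\r")
    pt$count <- ifelse(pk %in% names(cnt), unname(cnt[pk]), 0)
    pt$biomass <- ifelse(pk %in% names(bio), unname(bio[pk]), 0)
    pt$npue <- pt$count * 100 / pt$area_m2
    pt$bpue <- pt$biomass * 100 / pt$area_m2

    # per-net catch within each group: sum over the net's panels in the group
    grp <- interaction(pt[by], drop = TRUE, lex.order = TRUE)
    out <- lapply(split(pt, grp), function(s) {
        pernet <- tapply(s$count, s$net_id, sum)
        res <- s[1, by, drop = FALSE]
        res$n_nets <- length(pernet)
        res$total_catch <- sum(s$count)
        res$npue <- sum(s$npue)
        res$mean_catch <- mean(pernet)
        res$se_catch <- if (length(pernet) > 1) sd(pernet) / sqrt(length(pernet)) else NA_real_
        res$total_biomass_g <- if (hasBio) sum(s$biomass) else NA_real_
        res$bpue <- if (hasBio) sum(s$bpue) else NA_real_
        res
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Standardized nets x species catch matrix
#'
#' Builds the [CatchMatrix-class] of per-net, per-species NPUE: for each
#' deployment and species, counts are standardized to fish per 100 m2 of
#' the panel they were caught in and summed over panels. Every deployment
#' yields a row -- nets with no catch give all-zero rows, since zero catch
#' is an observation. With \code{sharedMeshesOnly}, records from meshes
#' not shared by all deployed designs are excluded before standardization,
#' so catch-efficacy comparisons are not biased by panels only one design
#' carries.
#'
#' @param survey a [GillnetSurvey-class]
#' @param transform \code{"none"}, \code{"log1p"} (log(x+1), used for
#'   similarity and precision analyses) or \code{"log0p1"} (log(x+0.1)).
#' @param sharedMeshesOnly see above; default \code{FALSE}.
#' @return a [CatchMatrix-class] (rows = net ids, columns = species)
#' @export
catchMatrix <- function(survey, transform = c("none", "log1p", "log0p1"),
                        sharedMeshesOnly = FALSE) {
    transform <- match.arg(transform)
    d <- deployments(survey)
    cc <- catches(survey)
    if (sharedMeshesOnly && nrow(cc))
        cc <- cc[cc$mesh_mm %in% .sharedMeshes(survey), , drop = FALSE]
    species <- sort(unique(cc$species))
    m <- matrix(0, nrow = nrow(d), ncol = length(species),
                dimnames = list(d$net_id, species))
    if (nrow(cc)) {
        key <- .designKey(d$design, d$zone)[match(cc$net_id, d$net_id)]
        area <- mapply(function(k, mesh) panelArea(netDesigns(survey)[[k]], mesh),
                       key, cc$mesh_mm)
        npue <- cc$count * 100 / area
        for (r in seq_len(nrow(cc)))
            m[cc$net_id[r], cc$species[r]] <- m[cc$net_id[r], cc$species[r]] + npue[r]
    }
    m <- switch(transform, none = m, log1p = log1p(m), log0p1 = log(m + 0.1))
    new("CatchMatrix", m, transform = transform,
        sharedMeshesOnly = sharedMeshesOnly)
}

#' Per-net total NPUE
#'
#' Row sums of the untransformed catch matrix: each net's NPUE summed over
#' species (and panels).
#'
#' @param survey a [GillnetSurvey-class]
#' @param sharedMeshesOnly passed to [catchMatrix()]
#' @return named numeric vector (one value per deployment)
#' @export
netNpue <- function(survey, sharedMeshesOnly = FALSE) {
    m <- catchMatrix(survey, transform = "none",
                     sharedMeshesOnly = sharedMeshesOnly)
    rowSums(m@.Data)
}
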