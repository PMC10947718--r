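# Survey construction, validation and delimited-text I/O.

.DEPLOY_COLS <- c("net_id", "design", "basin", "zone", "stratum", "site_id",
                  "date", "replicate_pair_id")
.CATCH_COLS <- c("net_id", "mesh_mm", "species", "count")

.designKey <- function(design, zone) paste(design, zone, sep = ".")

#' Construct a validated gillnet survey
#'
#' Combines a deployment table and a sparse catch table into a
#' [GillnetSurvey-class], validating that every catch record references a
#' known net and a mesh size present in that net's design, that counts and
#' biomass are non-negative, and that net ids are unique. Validation
#' errors report the offending row numbers.
#'
#' @param deployments data.frame with columns \code{net_id}, \code{design},
#'   \code{basin}, \code{zone}, \code{stratum}, \code{site_id}, \code{date},
#'   \code{replicate_pair_id} (missing optional columns are filled with NA).
#' @param catches data.frame with columns \code{net_id}, \code{mesh_mm},
#'   \code{species}, \code{count} and optionally \code{biomass_g}. A
#'   zero-row data.frame is valid (nets with no catch are all-zero
#'   downstream).
#' @param designs named list of [NetDesign-class] keyed
#'   \code{"<design>.<zone>"}; defaults to the built-in CEN/MOD designs.
#' @return a [GillnetSurvey-class]
#' @export
gillnetSurvey <- function(deployments, catches = NULL, designs = builtinDesigns()) {
    deployments <- as.data.frame(deployments, stringsAsFactors = FALSE)
    for (col in setdiff(.DEPLOY_COLS, names(deployments)))
        deployments[[col]] <- NA
    deployments <- deployments[, .DEPLOY_COLS]
    if (is.null(catches) || nrow(as.data.frame(catches)) == 0) {
        catches <- data.frame(net_id = character(), mesh_mm = character(),
                              species = character(), count = integer(),
                              biomass_g = numeric(), stringsAsFactors = FALSE)
    }
    catches <- as.data.frame(catches, stringsAsFactors = FALSE)
    if (!all(.CATCH_COLS %in% names(catches)))
        stop("catches must have columns: ", paste(.CATCH_COLS, collapse = ", "))
    if (!"biomass_g" %in% names(catches)) catches$biomass_g <- NA_real_
    catches$mesh_mm <- vapply(as.character(catches$mesh_mm), .meshKey, character(1))

    errs <- character()
    dup <- duplicated(deployments$net_id)
    if (any(dup))
        errs <- c(errs, sprintf("duplicate net_id in deployments: %s (rows %s)",
            paste(unique(deployments$net_id[dup]), collapse = ", "),
            paste(which(dup), collapse = ", ")))
    key <- .designKey(deployments$design, deployments$zone)
    badkey <- !key %in% names(designs)
    if (any(badkey))
        errs <- c(errs, sprintf("unknown design/zone %s (deployment rows %s)",
            paste(unique(key[badkey]), collapse = ", "),
            paste(which(badkey), collapse = ", ")))
    if (nrow(catches)) {
        i <- match(catches$net_id, deployments$net_id)
        if (anyNA(i))
            errs <- c(errs, sprintf("unknown net_id in catches: %s (rows %s)",
                paste(unique(catches$net_id[is.na(i)]), collapse = ", "),
                paste(which(is.na(i)), collapse = ", ")))
        ok <- !is.na(i)
        ok[ok] <- !badkey[i[ok]]
        if (any(ok)) {
            meshok <- vapply(which(ok), function(r) {
                des <- designs[[key[i[r]]]]
                catches$mesh_mm[r] %in% des@panels$mesh_mm
            }, logical(1))
            if (!all(meshok))
                errs <- c(errs, sprintf("mesh not in design: %s (catch rows %s)",
                    paste(unique(sprintf("%s mm / %s", catches$mesh_mm[which(ok)[!meshok]],
                        key[i[which(ok)[!meshok]]])), collapse = ", "),
                    paste(which(ok)[!meshok], collapse = ", ")))
        }
        if (any(catches$count < 0, na.rm = TRUE))
            errs <- c(errs, sprintf("negative count (catch rows %s)",
                paste(which(catches$count < 0), collapse = ", ")))
        if (any(catches$biomass_g < 0, na.rm = TRUE))
            errs <- c(errs, sprintf("negative biomass (catch rows %s)",
                paste(which(catches$biomass_g < 0), collapse = ", ")))
    }
    # a replicate pair must link exactly one CEN-style and one MOD-style net
    # sharing site and zone
    pid <- deployments$replicate_pair_id
    has <- !is.na(pid) & pid != ""
    if (any(has)) {
        for (p in unique(pid[has])) {
            sub <- deployments[has & pid == p, ]
            if (nrow(sub) != 2 || length(unique(sub$design)) != 2 ||
                length(unique(sub$zone)) != 1 || length(unique(sub$site_id)) != 1)
                errs <- c(errs, sprintf(
                    "replicate_pair_id '%s' must link exactly one net of each design at one site/zone", p))
        }
    }
    if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
    new("GillnetSurvey", deployments = deployments, catches = catches,
        designs = designs)
}

#' Read a survey from delimited text files
#'
#' @param catchesFile CSV with columns \code{net_id, mesh_mm, species,
#'   count, biomass_g} (biomass optional; header required).
#' @param deploymentsFile CSV with columns \code{net_id, design, basin,
#'   zone, stratum, site_id, date, replicate_pair_id}.
#' @param designsFile optional CSV of panel geometries (see
#'   [readDesigns()]); built-in CEN/MOD designs are used when absent.
#' @return a validated [GillnetSurvey-class]
#' @export
readSurvey <- function(catchesFile, deploymentsFile, designsFile = NULL) {
    dep <- utils::read.csv(deploymentsFile, stringsAsFactors = FALSE,
                           colClasses = "character")
    cat_ <- utils::read.csv(catchesFile, stringsAsFactors = FALSE,
                            colClasses = c(mesh_mm = "character"))
    designs <- if (is.null(designsFile)) builtinDesigns() else readDesigns(designsFile)
    gillnetSurvey(dep, cat_, designs)
}

#' Write a survey to delimited text files
#'
#' Writes \code{deployments.csv} and \code{catches.csv} into \code{dir};
#' [readSurvey()] on the written files reproduces the records exactly.
#'
#' @param survey a [GillnetSurvey-class]
#' @param dir output directory (created if missing)
#' @return invisibly, the two file paths
#' @export
writeSurvey <- function(survey, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fd <- file.path(dir, "deployments.csv")
    fc <- file.path(dir, "catches.csv")
    utils::write.csv(deployments(survey), fd, row.names = FALSE, quote = TRUE)
    utils::write.csv(catches(survey), fc, row.names = FALSE, quote = TRUE)
    invisible(c(deployments = fd, catches = fc))
}

#' Restrict a survey to paired CEN/MOD replicate deployments
#'
#' Keeps only deployments carrying a \code{replicate_pair_id} (and their
#' catch records); design comparisons use these nets only, since pairs
#' share site and night.
#'
#' @param survey a [GillnetSurvey-class]
#' @return a [GillnetSurvey-class]
#' @export
pairedOnly <- function(survey) {
    d <- deployments(survey)
    keep <- !is.na(d$replicate_pair_id) & d$replicate_pair_id != ""
    d <- d[keep, , drop = FALSE]
    c_ <- catches(survey)
    c_ <- c_[c_$net_id %in% d$net_id, , drop = FALSE]
    new("GillnetSurvey", deployments = d, catches = c_,
        designs = netDesigns(survey))
}
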