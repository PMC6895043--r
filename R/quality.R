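## Residue-level map-model cross-correlation reporting.

#' Per-residue map-model cross-correlation
#'
#' For each residue, builds the voxel mask of points strictly closer than
#' \code{radius} (default 5 Angstrom) to any of its atoms and computes the
#' Pearson correlation between the experimental map and the model density
#' over that mask, with both means taken mask-locally.  The model density is
#' simulated from every atom of the model (\code{calcMode = "full"},
#' the whole-residue masking convention); \code{calcMode = "residue"} is a
#' diagnostic mode using only the residue's own atoms.  A positive score
#' indicates good local fit between model and map.
#'
#' Residues whose mask is empty (outside the map) are reported with
#' \code{nVoxels = 0} and \code{cc = NA} and a warning, never dropped
#' silently.  Residues whose mask has no density variation on either side
#' are reported with \code{cc = 0} and \code{degenerate = TRUE}.
#'
#' @param model an \code{AtomicModel}.
#' @param obs the experimental \code{DensityGrid}.
#' @param resolution map resolution for the model density, Angstrom.
#' @param radius mask radius, Angstrom (default 5).
#' @param calcMode \code{"full"} (default) or \code{"residue"}.
#' @param ... further arguments to \code{\link{simulateDensity}}.
#' @return a \code{\link{ResidueCCReport}}
#' @export
perResidueCC <- function(model, obs, resolution, radius = 5,
                         calcMode = c("full", "residue"), ...) {
    stopifnot(is(model, "AtomicModel"), is(obs, "DensityGrid"), radius > 0)
    calcMode <- match.arg(calcMode)
    a <- atoms(model)
    resIdx <- residueIndex(model)
    geom <- .gridGeom(obs)
    obsVals <- as.numeric(gridValues(obs))
    if (calcMode == "full")
        calcVals <- as.numeric(gridValues(
            simulateDensity(model, template = obs, resolution = resolution,
                            ...)))
    rows <- vector("list", length(resIdx))
    nEmpty <- 0L
    for (r in seq_along(resIdx)) {
        idx <- resIdx[[r]]
        first <- idx[1]
        sel <- cpp_voxel_mask(coords(model)[idx, , drop = FALSE],
                              as.integer(geom$dim), geom$origin, geom$voxel,
                              radius)
        if (length(sel) == 0L) {
            nEmpty <- nEmpty + 1L
            rows[[r]] <- data.frame(chain = a$chain[first],
                                    resseq = a$resseq[first],
                                    resname = a$resname[first],
                                    nVoxels = 0L, cc = NA_real_,
                                    degenerate = FALSE)
            next
        }
        if (calcMode == "residue") {
            sub <- .newModel(a[idx, , drop = FALSE],
                             coords(model)[idx, , drop = FALSE])
            calcVals <- as.numeric(gridValues(
                simulateDensity(sub, template = obs,
                                resolution = resolution, ...)))
        }
        x <- obsVals[sel]
        y <- calcVals[sel]
        cc <- tryCatch(.pearson(x, y), error = function(e) NA_real_)
        degen <- is.na(cc)
        if (degen) cc <- 0
        rows[[r]] <- data.frame(chain = a$chain[first],
                                resseq = a$resseq[first],
                                resname = a$resname[first],
                                nVoxels = length(sel), cc = cc,
                                degenerate = degen)
    }
    if (nEmpty == length(resIdx))
        stop("all residue masks are empty: model entirely outside the map")
    if (nEmpty > 0L)
        warning(nEmpty, " residue(s) outside the map reported with cc = NA")
    new("ResidueCCReport", table = do.call(rbind, rows),
        radius = radius, resolution = resolution)
}

#' Flag runs of poorly fitting residues
#'
#' Returns the maximal consecutive runs (per chain, in residue order) of
#' residues with \code{cc <= threshold}, sorted by decreasing length.
#' Residues reported with \code{cc = NA} (no map coverage) count as poor.
#'
#' @param report a \code{\link{ResidueCCReport}}.
#' @param threshold cc threshold (default 0: positive scores indicate good
#'   fit).
#' @return data.frame with columns \code{chain}, \code{start}, \code{end},
#'   \code{length}; zero rows when every residue scores above threshold.
#' @export
flagPoorRegions <- function(report, threshold = 0) {
    stopifnot(is(report, "ResidueCCReport"))
    tab <- ccTable(report)
    if (nrow(tab) == 0L) stop("empty report")
    out <- list()
    for (ch in unique(tab$chain)) {
        sub <- tab[tab$chain == ch, , drop = FALSE]
        poor <- is.na(sub$cc) | sub$cc <= threshold
        r <- rle(poor)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values))
            out[[length(out) + 1L]] <- data.frame(
                chain = ch, start = sub$resseq[starts[k]],
                end = sub$resseq[ends[k]], length = r$lengths[k])
    }
    if (length(out) == 0L)
        return(data.frame(chain = character(0), start = integer(0),
                          end = integer(0), length = integer(0)))
    res <- do.call(rbind, out)
    res[order(-res$length, res$chain, res$start), , drop = FALSE]
}

#' Write a per-residue CC report as TSV
#'
#' The header line echoes the mask radius and resolution.
#'
#' @param report a \code{\link{ResidueCCReport}}.
#' @param path output file path.
#' @export
writeResidueCC <- function(report, path) {
    stopifnot(is(report, "ResidueCCReport"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# per-residue CC; mask radius %g A; resolution %g A",
                       report@radius, report@resolution), con)
    utils::write.table(ccTable(report), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a model with per-residue CC in the B-factor column
#'
#' Repurposes the B-factor column to carry each residue's CC for
#' visualization; residues without a score get -1.
#'
#' @param model the scored \code{AtomicModel}.
#' @param report the matching \code{\link{ResidueCCReport}}.
#' @param path output PDB path.
#' @export
writeCCColoredPDB <- function(model, report, path) {
    tab <- ccTable(report)
    a <- atoms(model)
    key <- paste(a$chain, a$resseq)
    cc <- tab$cc[match(key, paste(tab$chain, tab$resseq))]
    cc[is.na(cc)] <- -1
    writePDBModel(model, path, bfac = round(cc, 3))
}
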