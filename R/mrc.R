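## MRC2014 density-map input/output.
##
## No installed R package reads MRC maps, so the 1024-byte header and the
## voxel block are handled directly with readBin/writeBin.  Only orthogonal
## cells (all angles 90 degrees) and modes 0/1/2 are supported; axis order
## is normalized to (x, y, z) on read using MAPC/MAPR/MAPS.

#' Construct a density grid
#'
#' @param values 3-D numeric array (x index fastest).
#' @param voxel voxel edge lengths, Angstrom; a scalar is recycled.
#' @param origin Cartesian position of the centre of voxel (0,0,0), Angstrom.
#' @return a \code{\link{DensityGrid}}
#' @export
densityGrid <- function(values, voxel, origin = c(0, 0, 0)) {
    new("DensityGrid", values = values, voxel = rep_len(as.numeric(voxel), 3L),
        origin = as.numeric(origin))
}

#' Read an MRC2014 density map
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32) with orthogonal axes.
#' The axis order recorded in MAPC/MAPR/MAPS is normalized to (x, y, z).
#' The origin is taken from the ORIGIN record when any component is nonzero,
#' otherwise from NXSTART/NYSTART/NZSTART times the voxel size.
#'
#' @param path MRC file path.
#' @return a \code{\link{DensityGrid}}
#' @export
readMRC <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "raw", n = 1024L)
    if (length(hdr) < 1024L) stop("MRC format error: truncated header")
    int1 <- function(at) readBin(hdr[at:(at + 3)], "integer", size = 4,
                                 endian = "little")
    num1 <- function(at) readBin(hdr[at:(at + 3)], "numeric", size = 4,
                                 endian = "little")
    word <- function(w) (w - 1L) * 4L + 1L
    ncrs <- vapply(1:3, function(w) int1(word(w)), integer(1))
    mode <- int1(word(4L))
    nstart <- vapply(5:7, function(w) int1(word(w)), integer(1))
    m <- vapply(8:10, function(w) int1(word(w)), integer(1))
    cella <- vapply(11:13, function(w) num1(word(w)), numeric(1))
    cellb <- vapply(14:16, function(w) num1(word(w)), numeric(1))
    mapcrs <- vapply(17:19, function(w) int1(word(w)), integer(1))
    orig <- vapply(50:52, function(w) num1(word(w)), numeric(1))
    if (any(abs(cellb - 90) > 1e-3))
        stop("unsupported geometry: non-orthogonal cell angles (",
             paste(round(cellb, 2), collapse = ", "), ")")
    if (!mode %in% c(0L, 1L, 2L))
        stop("MRC format error: unsupported mode ", mode)
    if (!all(sort(mapcrs) == 1:3))
        stop("MRC format error: invalid axis mapping (",
             paste(mapcrs, collapse = ","), ")")
    nvox <- prod(ncrs)
    vals <- switch(as.character(mode),
        "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                                 signed = TRUE, endian = "little")),
        "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                                 signed = TRUE, endian = "little")),
        "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"))
    if (length(vals) < nvox)
        stop("MRC format error: truncated data block (expected ", nvox,
             " voxels, got ", length(vals), ")")
    arr <- array(vals, dim = ncrs)
    ## axis j of the stored array runs along spatial axis mapcrs[j];
    ## NX/NY/NZ and NSTART are in column/row/section order, MX/MY/MZ and
    ## CELLA in spatial x/y/z order
    if (!all(mapcrs == 1:3)) arr <- aperm(arr, order(mapcrs))
    dimSpatial <- integer(3); dimSpatial[mapcrs] <- ncrs
    nstartSpatial <- integer(3); nstartSpatial[mapcrs] <- nstart
    m[m <= 0L] <- dimSpatial[m <= 0L]
    voxel <- cella / m
    voxel[!is.finite(voxel) | voxel <= 0] <- 1
    origin <- if (any(orig != 0)) orig else nstartSpatial * voxel
    densityGrid(arr, voxel = voxel, origin = origin)
}

.writeMRCImpl <- function(grid, path, mapcrs = 1:3) {
    v <- gridValues(grid)
    d <- dim(v)
    if (!all(mapcrs == 1:3)) {
        v <- aperm(v, mapcrs)   # stored axis j = spatial axis mapcrs[j]
        dcrs <- d[mapcrs]
    } else dcrs <- d
    stats <- c(min(v), max(v), mean(v))
    rms <- sqrt(mean((v - stats[3])^2))
    con <- file(path, "wb")
    on.exit(close(con))
    wInt <- function(x) writeBin(as.integer(x), con, size = 4,
                                 endian = "little")
    wNum <- function(x) writeBin(as.numeric(x), con, size = 4,
                                 endian = "little")
    wInt(dcrs)                       # NX NY NZ (column/row/section order)
    wInt(2L)                         # MODE 2: float32
    wInt(c(0L, 0L, 0L))              # NXSTART..
    wInt(d)                          # MX MY MZ (spatial x/y/z order)
    wNum(d * grid@voxel)             # CELLA (spatial x/y/z order)
    wNum(c(90, 90, 90))              # CELLB
    wInt(mapcrs)                     # MAPC MAPR MAPS
    wNum(stats)                      # DMIN DMAX DMEAN
    wInt(c(1L, 0L))                  # ISPG, NSYMBT
    extra <- integer(25L)
    extra[4L] <- 20140L              # NVERSION (word 28)
    wInt(extra)
    wNum(grid@origin)                # ORIGIN (x, y, z)
    writeBin(charToRaw("MAP "), con)
    writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
    wNum(rms)                        # RMS about the mean
    wInt(1L)                         # NLABL
    lab <- charToRaw(formatC("cryofit density grid", width = -80))
    writeBin(lab, con)
    writeBin(raw(720L), con)         # remaining label slots
    writeBin(as.numeric(v), con, size = 4, endian = "little")
    invisible(path)
}

#' Write a density grid as an MRC2014 map
#'
#' Mode-2 (float32) output with header min/max/mean/rms computed from the
#' values and the grid origin stored in the ORIGIN record.
#'
#' @param grid a \code{\link{DensityGrid}}.
#' @param path output file path.
#' @export
writeMRC <- function(grid, path) {
    stopifnot(is(grid, "DensityGrid"))
    .writeMRCImpl(grid, path)
}

#' Export a voxel mask as an MRC map for visual inspection
#'
#' Writes 1.0 inside the mask and 0.0 outside, on the geometry of the parent
#' grid.
#'
#' @param mask a \code{\link{GridMask}}.
#' @param grid the parent \code{\link{DensityGrid}}.
#' @param path output file path.
#' @export
writeMaskMRC <- function(mask, grid, path) {
    stopifnot(is(mask, "GridMask"), is(grid, "DensityGrid"),
              all(mask@dim == dim(gridValues(grid))))
    v <- array(0, dim = mask@dim)
    v[mask@indices] <- 1
    writeMRC(densityGrid(v, voxelSize(grid), gridOrigin(grid)), path)
}
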