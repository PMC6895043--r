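## Model-density simulation and the cross-correlation kernel shared by the
## fitting objective and the per-residue quality score.

.ATOMIC_NUMBER <- c(H = 1, C = 6, N = 7, O = 8, NA. = 11, MG = 12, P = 15,
                    S = 16, CL = 17, K = 19, CA = 20, MN = 25, FE = 26,
                    ZN = 30, SE = 34)

.atomAmplitudes <- function(model, amplitude = c("Z", "unit")) {
    amplitude <- match.arg(amplitude)
    if (amplitude == "unit") return(rep(1, nAtoms(model)))
    el <- toupper(atoms(model)$element)
    el[el == "NA"] <- "NA."
    z <- .ATOMIC_NUMBER[el]
    z[is.na(z)] <- 6   # unknown elements weighted like carbon
    as.numeric(z)
}

.gridGeom <- function(grid) {
    list(dim = dim(gridValues(grid)), voxel = voxelSize(grid),
         origin = gridOrigin(grid))
}

.sameGeometry <- function(a, b, tol = 1e-6) {
    ga <- .gridGeom(a); gb <- .gridGeom(b)
    all(ga$dim == gb$dim) && all(abs(ga$voxel - gb$voxel) < tol) &&
        all(abs(ga$origin - gb$origin) < tol)
}

#' Simulate a model density map
#'
#' Each atom contributes an isotropic Gaussian centred at its position with
#' standard deviation \code{sigmaFactor * resolution} and amplitude
#' proportional to its atomic number (or 1 with \code{amplitude = "unit"}).
#' Contributions are summed (linear superposition) and truncated beyond
#' \code{truncate} sigma; atoms farther than that from the grid support
#' contribute nothing.
#'
#' @param model a non-empty \code{AtomicModel}.
#' @param template a \code{DensityGrid} supplying the grid geometry, or NULL
#'   to derive one from the model bounding box plus \code{pad}.
#' @param resolution nominal map resolution, Angstrom; must be at least
#'   twice the largest voxel edge (Nyquist).
#' @param voxel voxel edge length(s) when no template is given.
#' @param pad padding around the model bounding box when no template is
#'   given, Angstrom.
#' @param sigmaFactor Gaussian width per unit resolution (default 0.225).
#' @param truncate truncation radius in sigmas (default 4).
#' @param amplitude \code{"Z"} (atomic number, default) or \code{"unit"}.
#' @return a \code{\link{DensityGrid}}
#' @export
simulateDensity <- function(model, template = NULL, resolution,
                            voxel = 1, pad = resolution,
                            sigmaFactor = 0.225, truncate = 4,
                            amplitude = "Z") {
    stopifnot(is(model, "AtomicModel"))
    if (nAtoms(model) == 0L) stop("empty model")
    if (is.null(template)) {
        voxel <- rep_len(as.numeric(voxel), 3L)
        xyz <- coords(model)
        lo <- apply(xyz, 2, min) - pad
        hi <- apply(xyz, 2, max) + pad
        gdim <- as.integer(ceiling((hi - lo) / voxel)) + 1L
        geom <- list(dim = gdim, voxel = voxel, origin = lo)
    } else {
        stopifnot(is(template, "DensityGrid"))
        geom <- .gridGeom(template)
    }
    if (resolution < 2 * max(geom$voxel))
        stop("sampling error: resolution (", resolution,
             " A) below the Nyquist limit of the ", max(geom$voxel),
             " A voxels")
    sigma <- sigmaFactor * resolution
    vals <- cpp_splat(coords(model), .atomAmplitudes(model, amplitude),
                      as.integer(geom$dim), geom$origin, geom$voxel,
                      sigma, truncate * sigma)
    densityGrid(array(vals, dim = geom$dim), geom$voxel, geom$origin)
}

#' Pearson cross-correlation between two density grids
#'
#' Computes the correlation over the masked voxels (all voxels when no mask
#' is given), with both means taken over the same voxel set.  The value is
#' symmetric in its arguments and invariant under positive affine rescaling
#' of either grid.
#'
#' @param obs,calc \code{DensityGrid}s on identical geometry.
#' @param mask optional \code{\link{GridMask}}; must be non-empty.
#' @return correlation coefficient in [-1, 1].
#' @export
crossCorrelation <- function(obs, calc, mask = NULL) {
    stopifnot(is(obs, "DensityGrid"), is(calc, "DensityGrid"))
    if (!.sameGeometry(obs, calc))
        stop("alignment error: grids differ in shape, voxel size or origin")
    x <- as.numeric(gridValues(obs))
    y <- as.numeric(gridValues(calc))
    if (!is.null(mask)) {
        stopifnot(is(mask, "GridMask"))
        if (!all(mask@dim == dim(gridValues(obs))))
            stop("alignment error: mask geometry does not match the grids")
        if (length(mask@indices) == 0L) stop("empty mask")
        x <- x[mask@indices]
        y <- y[mask@indices]
    }
    .pearson(x, y)
}

.pearson <- function(x, y) {
    n <- length(x)
    mx <- sum(x) / n; my <- sum(y) / n
    dx <- x - mx; dy <- y - my
    vx <- sum(dx * dx); vy <- sum(dy * dy)
    if (vx <= 0 || vy <= 0)
        stop("degenerate density: zero variance over the correlation domain")
    sum(dx * dy) / (sqrt(vx) * sqrt(vy))
}

#' Voxel mask around one residue
#'
#' Selects voxels whose centre lies strictly closer than \code{radius} to
#' any atom of the residue.
#'
#' @param grid the parent \code{DensityGrid}.
#' @param model an \code{AtomicModel}.
#' @param chain chain identifier of the residue.
#' @param resseq residue sequence number.
#' @param radius mask radius, Angstrom (default 5, the whole-residue masking
#'   distance).
#' @return a \code{\link{GridMask}}
#' @export
residueMask <- function(grid, model, chain, resseq, radius = 5) {
    stopifnot(is(grid, "DensityGrid"), is(model, "AtomicModel"), radius > 0)
    a <- atoms(model)
    idx <- which(a$chain == chain & a$resseq == resseq)
    if (length(idx) == 0L)
        stop("no such residue: ", chain, ":", resseq)
    geom <- .gridGeom(grid)
    sel <- cpp_voxel_mask(coords(model)[idx, , drop = FALSE],
                          as.integer(geom$dim), geom$origin, geom$voxel,
                          radius)
    if (length(sel) == 0L)
        stop("empty mask: residue ", chain, ":", resseq,
             " has no grid voxel within ", radius, " A")
    new("GridMask", indices = sel, dim = as.integer(geom$dim))
}

#' Voxel mask around a whole model
#'
#' Model-proximity correlation domain: voxels strictly closer than
#' \code{radius} to any atom.  Offered as an explicit alternative to the
#' default whole-grid correlation domain of \code{\link{totalEnergy}}.
#'
#' @param grid the parent \code{DensityGrid}.
#' @param model an \code{AtomicModel}.
#' @param radius mask radius, Angstrom.
#' @return a \code{\link{GridMask}}
#' @export
modelMask <- function(grid, model, radius = 5) {
    stopifnot(is(grid, "DensityGrid"), is(model, "AtomicModel"), radius > 0)
    geom <- .gridGeom(grid)
    sel <- cpp_voxel_mask(coords(model), as.integer(geom$dim), geom$origin,
                          geom$voxel, radius)
    if (length(sel) == 0L) stop("empty mask: model outside the grid")
    new("GridMask", indices = sel, dim = as.integer(geom$dim))
}
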