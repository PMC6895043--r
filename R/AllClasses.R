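#' @useDynLib cryofit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods is new validObject slot show
#' @importFrom stats rnorm runif sd
#' @importFrom utils head read.table write.table
NULL

#' AtomicModel: an atomic structure with optional nonbonded parameters
#'
#' Holds an ordered table of heavy atoms (identity, residue/chain assignment,
#' occupancy) together with their Cartesian coordinates in Angstrom and,
#' once \code{\link{assignFFParams}} has been called, a per-atom van der
#' Waals radius \code{vdw} (Angstrom) and well depth \code{eps}
#' (kcal/mol convention).
#'
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resname}, \code{chain}, \code{resseq},
#'   \code{insert}, \code{occ}, \code{bfac}.
#' @slot xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @slot vdw numeric vector of van der Waals radii (NA until assigned).
#' @slot eps numeric vector of well depths (NA until assigned).
#' @export
setClass("AtomicModel",
    representation(atoms = "data.frame", xyz = "matrix",
                   vdw = "numeric", eps = "numeric"),
    validity = function(object) {
        n <- nrow(object@atoms)
        if (nrow(object@xyz) != n || ncol(object@xyz) != 3L)
            return("xyz must be an n x 3 matrix matching the atom table")
        if (n > 0L && !all(is.finite(object@xyz)))
            return("all coordinates must be finite")
        if (length(object@vdw) != n || length(object@eps) != n)
            return("vdw/eps must have one entry per atom")
        ok <- !is.na(object@vdw)
        if (any(object@vdw[ok] <= 0))
            return("assigned van der Waals radii must be positive")
        ok <- !is.na(object@eps)
        if (any(object@eps[ok] < 0))
            return("assigned well depths must be non-negative")
        TRUE
    })

#' RigidBodyPartition: disjoint rigid bodies over a model's atoms
#'
#' @slot bodies named list of integer atom-index vectors, pairwise disjoint
#'   and non-empty.
#' @slot fixed integer vector of atom indices in no body (held immobile).
#' @slot nAtoms total atom count of the parent model, for auditing.
#' @export
setClass("RigidBodyPartition",
    representation(bodies = "list", fixed = "integer", nAtoms = "integer"),
    validity = function(object) {
        if (length(object@bodies) < 1L)
            return("at least one rigid body is required")
        if (is.null(names(object@bodies)) || anyDuplicated(names(object@bodies)))
            return("bodies must be uniquely named")
        idx <- unlist(object@bodies, use.names = FALSE)
        if (any(lengths(object@bodies) == 0L))
            return("every body must contain at least one atom")
        if (anyDuplicated(c(idx, object@fixed)))
            return("bodies and fixed set must be pairwise disjoint")
        if (length(idx) + length(object@fixed) != object@nAtoms)
            return("bodies plus fixed set must cover all atoms exactly")
        if (object@nAtoms > 0L && (min(c(idx, object@fixed)) < 1L ||
                                   max(c(idx, object@fixed)) > object@nAtoms))
            return("atom indices out of range")
        TRUE
    })

#' RigidTransform: a proper rotation plus translation about a pivot
#'
#' Maps a point x to \code{R (x - pivot) + pivot + t}, with R the rotation
#' matrix of the unit quaternion \code{q} (w, x, y, z ordering).
#'
#' @slot q unit quaternion, length 4, |q| = 1 within 1e-9.
#' @slot t translation vector, Angstrom.
#' @slot pivot rotation pivot, Angstrom.
#' @export
setClass("RigidTransform",
    representation(q = "numeric", t = "numeric", pivot = "numeric"),
    validity = function(object) {
        if (length(object@q) != 4L || length(object@t) != 3L ||
            length(object@pivot) != 3L)
            return("q must have length 4, t and pivot length 3")
        if (!all(is.finite(c(object@q, object@t, object@pivot))))
            return("transform components must be finite")
        if (abs(sqrt(sum(object@q^2)) - 1) > 1e-9)
            return("quaternion must be unit length (|q| = 1 within 1e-9)")
        TRUE
    })

#' ForceFieldTable: per-atom-class nonbonded parameters
#'
#' Lookup is by \code{(element, atom name)} with element-level fallback;
#' atom-name rows have a non-empty \code{name}, element-level rows an empty
#' one.
#'
#' @slot table data.frame with columns \code{element}, \code{name},
#'   \code{vdw}, \code{eps}.
#' @export
setClass("ForceFieldTable",
    representation(table = "data.frame"),
    validity = function(object) {
        need <- c("element", "name", "vdw", "eps")
        if (!all(need %in% names(object@table)))
            return("table needs columns element, name, vdw, eps")
        if (any(object@table$vdw <= 0.5 | object@table$vdw >= 3.0))
            return("all van der Waals radii must lie in (0.5, 3.0) Angstrom")
        if (any(object@table$eps < 0))
            return("well depths must be non-negative")
        TRUE
    })

#' DensityGrid: a 3-D scalar density field with voxel geometry
#'
#' @slot values 3-D numeric array, x index fastest.
#' @slot voxel voxel edge lengths per axis, Angstrom.
#' @slot origin Cartesian position of the centre of voxel (0,0,0), Angstrom.
#' @export
setClass("DensityGrid",
    representation(values = "array", voxel = "numeric", origin = "numeric"),
    validity = function(object) {
        if (length(dim(object@values)) != 3L)
            return("values must be a 3-D array")
        if (any(dim(object@values) < 1L))
            return("all grid dimensions must be >= 1")
        if (length(object@voxel) != 3L || any(object@voxel <= 0))
            return("voxel must be three positive edge lengths")
        if (length(object@origin) != 3L || !all(is.finite(object@origin)))
            return("origin must be a finite 3-vector")
        if (!all(is.finite(object@values)))
            return("all density values must be finite")
        TRUE
    })

#' GridMask: a voxel subset of a parent grid
#'
#' @slot indices 1-based linear voxel indices into the parent grid.
#' @slot dim dimensions of the parent grid.
#' @export
setClass("GridMask",
    representation(indices = "integer", dim = "integer"),
    validity = function(object) {
        if (length(object@dim) != 3L || any(object@dim < 1L))
            return("dim must be a valid 3-D grid shape")
        n <- prod(object@dim)
        if (length(object@indices) > 0L &&
            (min(object@indices) < 1L || max(object@indices) > n))
            return("mask indices out of parent grid range")
        TRUE
    })

#' EnergyWeights: weights of the correlation and clash terms
#'
#' Defaults w1 = 100 (correlation term) and w2 = 1 (clash term).
#'
#' @slot w1 non-negative weight on \code{1 - CC}.
#' @slot w2 non-negative weight on the 12-6 clash sum.
#' @export
setClass("EnergyWeights",
    representation(w1 = "numeric", w2 = "numeric"),
    validity = function(object) {
        if (object@w1 < 0 || object@w2 < 0) return("weights must be >= 0")
        if (object@w1 == 0 && object@w2 == 0) return("weights cannot both be zero")
        TRUE
    })

#' EnergyBreakdown: the fitted objective and its components
#'
#' @slot cc map-model cross-correlation in [-1, 1].
#' @slot ccTerm \code{w1 * (1 - cc)}.
#' @slot clashTerm \code{w2} times the 12-6 inter-body sum.
#' @slot total \code{ccTerm + clashTerm}.
#' @export
setClass("EnergyBreakdown",
    representation(cc = "numeric", ccTerm = "numeric", clashTerm = "numeric",
                   total = "numeric"),
    validity = function(object) {
        if (is.finite(object@total) &&
            abs(object@total - (object@ccTerm + object@clashTerm)) > 1e-12 *
                max(1, abs(object@total)))
            return("total must equal ccTerm + clashTerm")
        TRUE
    })

#' MCConfig: Monte Carlo sampling configuration
#'
#' @slot nMoves total number of translation + rotation proposals
#'   (default 50000).
#' @slot kT acceptance temperature in objective units (default 1).
#' @slot translationStep Gaussian sigma of translation proposals, Angstrom;
#'   0 disables the translation channel.
#' @slot rotationStep Gaussian sigma of rotation angles, degrees, about a
#'   uniformly random axis through the body centroid; 0 disables rotations.
#' @slot seed RNG seed.
#' @slot weights an \code{EnergyWeights}.
#' @slot cutoff clash cutoff, Angstrom.
#' @slot resolution map resolution used for the model density, Angstrom.
#' @slot anneal numeric(0) for constant kT, else c(start, end) for a linear
#'   kT schedule over the run.
#' @export
setClass("MCConfig",
    representation(nMoves = "integer", kT = "numeric",
                   translationStep = "numeric", rotationStep = "numeric",
                   seed = "integer", weights = "EnergyWeights",
                   cutoff = "numeric", resolution = "numeric",
                   anneal = "numeric"),
    validity = function(object) {
        if (object@nMoves < 1L) return("nMoves must be >= 1")
        if (object@kT <= 0) return("kT must be positive")
        if (object@translationStep < 0 || object@rotationStep < 0)
            return("step sizes must be >= 0")
        if (object@translationStep == 0 && object@rotationStep == 0)
            return("at least one move channel must be enabled")
        if (object@cutoff <= 0) return("cutoff must be positive")
        if (object@resolution <= 0) return("resolution must be positive")
        if (!length(object@anneal) %in% c(0L, 2L))
            return("anneal must be empty or c(start, end)")
        if (length(object@anneal) == 2L && any(object@anneal <= 0))
            return("annealed kT values must be positive")
        TRUE
    })

#' FitResult: outcome of a Monte Carlo rigid-body fit
#'
#' @slot bestTransforms named list of cumulative per-body
#'   \code{RigidTransform}s from the initial pose to the best pose.
#' @slot bestModel the best-scoring \code{AtomicModel}.
#' @slot bestEnergy \code{EnergyBreakdown} at the best pose.
#' @slot trace data.frame with one row per move: \code{move}, \code{body},
#'   \code{type}, \code{dE}, \code{accepted}, \code{E}, \code{cc}.
#' @slot acceptanceRate fraction of accepted moves.
#' @slot seed the RNG seed used.
#' @slot nOverflow proposals auto-rejected for non-finite energy.
#' @export
setClass("FitResult",
    representation(bestTransforms = "list", bestModel = "AtomicModel",
                   bestEnergy = "EnergyBreakdown", trace = "data.frame",
                   acceptanceRate = "numeric", seed = "integer",
                   nOverflow = "integer"),
    validity = function(object) {
        tr <- object@trace
        need <- c("move", "body", "type", "dE", "accepted", "E", "cc")
        if (!all(need %in% names(tr)))
            return("trace is missing required columns")
        accE <- tr$E[tr$accepted]
        if (length(accE) && object@bestEnergy@total > min(accE) + 1e-6)
            return("best energy must not exceed any accepted-state energy")
        TRUE
    })

#' ResidueCCReport: per-residue map-model cross-correlation
#'
#' @slot table data.frame with columns \code{chain}, \code{resseq},
#'   \code{resname}, \code{nVoxels}, \code{cc}, \code{degenerate}.
#' @slot radius mask radius, Angstrom.
#' @slot resolution resolution used for the model density, Angstrom.
#' @export
setClass("ResidueCCReport",
    representation(table = "data.frame", radius = "numeric",
                   resolution = "numeric"),
    validity = function(object) {
        cc <- object@table$cc
        cc <- cc[!is.na(cc)]
        if (length(cc) && any(cc < -1 - 1e-9 | cc > 1 + 1e-9))
            return("cc values must lie in [-1, 1]")
        if (object@radius <= 0) return("radius must be positive")
        TRUE
    })
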