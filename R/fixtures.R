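## Synthetic ground-truth test beds: idealized poly-alanine helices, clean
## or noisy maps simulated from them, and controlled pose perturbations.
## Everything regenerates bitwise from (spec, seed); no external data.

## One idealized poly-Ala residue shell per index: CA on a helix of radius
## 2.28 A (rise 1.5 A, 100 deg/residue, so consecutive CA-CA = 3.80 A);
## N, C, O, CB placed in the local cylindrical frame.  CB is axial so the
## maximal radial extent stays ~2.3 A.  Chemically idealized, not refined.
.helixCoords <- function(nRes) {
    rise <- 1.5; twist <- 100 * pi / 180; rCA <- 2.28
    atomsPerRes <- 5L
    xyz <- matrix(0, nRes * atomsPerRes, 3)
    for (i in seq_len(nRes)) {
        th <- (i - 1) * twist
        z <- (i - 1) * rise
        at <- function(r, dphi, dz)
            c(r * cos(th + dphi), r * sin(th + dphi), z + dz)
        row <- (i - 1) * atomsPerRes
        xyz[row + 1L, ] <- at(1.56, -26 * pi / 180, -0.90)  # N
        xyz[row + 2L, ] <- at(rCA, 0, 0)                    # CA
        xyz[row + 3L, ] <- at(1.66, 28 * pi / 180, 1.10)    # C
        xyz[row + 4L, ] <- at(1.66, 38 * pi / 180, 2.33)    # O (carbonyl,
                                                            # axial offset)
        xyz[row + 5L, ] <- at(rCA, 0, 0) + c(0, 0, -1.53)   # CB (axial)
    }
    xyz
}

.helixAtoms <- function(nRes, chain, startSerial = 1L) {
    names <- c("N", "CA", "C", "O", "CB")
    elements <- c("N", "C", "C", "O", "C")
    n <- nRes * 5L
    data.frame(
        serial = seq.int(startSerial, length.out = n),
        name = rep(names, nRes),
        element = rep(elements, nRes),
        resname = "ALA",
        chain = chain,
        resseq = rep(seq_len(nRes), each = 5L),
        insert = "",
        occ = 1,
        bfac = 0,
        stringsAsFactors = FALSE)
}

#' Generate a toy poly-alanine model with a rigid-body partition
#'
#' \code{"helix"} builds a single idealized poly-Ala alpha-helix (5 heavy
#' atoms per residue) as one body; \code{"dumbbell"} builds two such helices
#' (chains A and B, bodies \code{body1}/\code{body2}) with chain B offset
#' along x.  Construction is deterministic: the same spec always returns
#' bitwise-identical coordinates.
#'
#' @param kind \code{"helix"} or \code{"dumbbell"}.
#' @param nRes residues per helix (default 10).
#' @param offset inter-helix x offset for the dumbbell, Angstrom
#'   (default 20); offsets that make the bodies approach within 4 Angstrom
#'   are a construction error.
#' @return list with \code{model} (an \code{AtomicModel}, nonbonded
#'   parameters assigned from the built-in table) and \code{partition}
#'   (a \code{RigidBodyPartition}).
#' @export
makeToyModel <- function(kind = c("dumbbell", "helix"), nRes = 10,
                         offset = 20) {
    kind <- match.arg(kind)
    if (kind == "helix") {
        model <- .newModel(.helixAtoms(nRes, "A"), .helixCoords(nRes))
        part <- rigidBodyPartition(model, data.frame(
            body = "body1", chain = "A", first = 1L, last = nRes))
    } else {
        xyzA <- .helixCoords(nRes)
        xyzB <- .helixCoords(nRes)
        xyzB[, 1] <- xyzB[, 1] + offset
        minsep <- min(vapply(seq_len(nrow(xyzA)), function(i)
            min(sqrt(rowSums(sweep(xyzB, 2, xyzA[i, ])^2))), numeric(1)))
        if (minsep <= 4)
            stop("construction error: bodies overlap (min separation ",
                 round(minsep, 2), " A)")
        atoms <- rbind(.helixAtoms(nRes, "A"),
                       .helixAtoms(nRes, "B", startSerial = nRes * 5L + 1L))
        atoms$serial <- seq_len(nrow(atoms))
        model <- .newModel(atoms, rbind(xyzA, xyzB))
        part <- rigidBodyPartition(model, data.frame(
            body = c("body1", "body2"), chain = c("A", "B"),
            first = 1L, last = nRes))
    }
    list(model = assignFFParams(model), partition = part)
}

#' Simulate a ground-truth map from a model
#'
#' The clean map is \code{\link{simulateDensity}} on a grid padded by
#' \code{pad} on all sides; optional i.i.d. Gaussian voxel noise is added
#' with standard deviation \code{noiseSd} times the clean map's RMS.  The
#' noise realization is reproducible from \code{seed}.
#'
#' @param model an \code{AtomicModel}.
#' @param resolution map resolution, Angstrom (at least twice the voxel).
#' @param voxel voxel edge length, Angstrom.
#' @param noiseSd noise level as a fraction of the clean map RMS
#'   (default 0).
#' @param seed RNG seed for the noise.
#' @param pad padding around the model bounding box, Angstrom (default:
#'   the resolution).
#' @param ... further arguments to \code{\link{simulateDensity}}.
#' @return a \code{\link{DensityGrid}}
#' @export
makeGroundTruthMap <- function(model, resolution, voxel, noiseSd = 0,
                               seed = 1, pad = resolution, ...) {
    if (resolution < 2 * max(voxel))
        stop("sampling error: resolution below the Nyquist limit")
    if (pad < resolution)
        stop("pad must be at least the resolution")
    clean <- simulateDensity(model, resolution = resolution, voxel = voxel,
                             pad = pad, ...)
    if (noiseSd <= 0) return(clean)
    v <- gridValues(clean)
    rms <- sqrt(mean(v^2))
    set.seed(seed)
    densityGrid(v + array(rnorm(length(v), 0, noiseSd * rms), dim = dim(v)),
                voxelSize(clean), gridOrigin(clean))
}

#' Perturb one rigid body by exact translation and rotation magnitudes
#'
#' Applies a transform of exactly \code{translation} Angstrom along a
#' uniformly random direction and exactly \code{rotation} degrees about a
#' uniformly random axis through the body centroid, and returns the
#' ground-truth inverse so recovery error can be measured.
#'
#' @param model an \code{AtomicModel}.
#' @param partition a \code{RigidBodyPartition}.
#' @param body body name.
#' @param translation translation magnitude, Angstrom.
#' @param rotation rotation angle, degrees.
#' @param seed RNG seed for the random direction and axis.
#' @return list with \code{model} (perturbed), \code{applied} (the
#'   \code{RigidTransform} used) and \code{truth} (its inverse).
#' @export
perturbPose <- function(model, partition, body, translation, rotation,
                        seed = 1) {
    stopifnot(is(model, "AtomicModel"), is(partition, "RigidBodyPartition"))
    if (!body %in% names(bodies(partition)))
        stop("unknown rigid body: ", body)
    set.seed(seed)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    idx <- bodies(partition)[[body]]
    pivot <- colMeans(coords(model)[idx, , drop = FALSE])
    T <- rigidTransform(translation = translation * dir, axis = ax,
                        angle = rotation, pivot = pivot)
    list(model = applyTransform(model, T, partition, body),
         applied = T, truth = invertTransform(T))
}
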