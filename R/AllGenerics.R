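#' Atom coordinates of a model
#' @param object an \code{AtomicModel}
#' @return numeric n x 3 matrix of coordinates in Angstrom
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' Replace atom coordinates
#' @param object an \code{AtomicModel}
#' @param value an n x 3 numeric matrix
#' @export
setGeneric("coords<-", function(object, value) standardGeneric("coords<-"))

#' Number of atoms in a model
#' @param object an \code{AtomicModel}
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))

#' Atom table of a model
#' @param object an \code{AtomicModel}
#' @return the atom data.frame (identity columns only, no coordinates)
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))

#' Residue index of a model
#'
#' @param object an \code{AtomicModel}
#' @return named list mapping \code{"chain:resseq"} to atom index vectors,
#'   in order of first appearance
#' @export
setGeneric("residueIndex", function(object) standardGeneric("residueIndex"))

#' Rigid bodies of a partition
#' @param object a \code{RigidBodyPartition}
#' @export
setGeneric("bodies", function(object) standardGeneric("bodies"))

#' Fixed (immobile) atom indices of a partition
#' @param object a \code{RigidBodyPartition}
#' @export
setGeneric("fixedAtoms", function(object) standardGeneric("fixedAtoms"))

#' Grid values of a density grid
#' @param object a \code{DensityGrid}
#' @return the 3-D value array
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))

#' Voxel edge lengths of a density grid
#' @param object a \code{DensityGrid}
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' Origin (centre of voxel (0,0,0)) of a density grid
#' @param object a \code{DensityGrid}
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' Best-pose model of a fit
#' @param object a \code{FitResult}
#' @export
setGeneric("bestModel", function(object) standardGeneric("bestModel"))

#' Best-pose energy breakdown of a fit
#' @param object a \code{FitResult}
#' @export
setGeneric("bestEnergy", function(object) standardGeneric("bestEnergy"))

#' Per-move trace of a fit
#' @param object a \code{FitResult}
#' @export
setGeneric("mcTrace", function(object) standardGeneric("mcTrace"))

#' Acceptance rate of a fit
#' @param object a \code{FitResult}
#' @export
setGeneric("acceptanceRate", function(object) standardGeneric("acceptanceRate"))

#' Report table of a per-residue CC report
#' @param object a \code{ResidueCCReport}
#' @export
setGeneric("ccTable", function(object) standardGeneric("ccTable"))

#' @rdname coords
#' @export
setMethod("coords", "AtomicModel", function(object) object@xyz)

#' @rdname coords-set
#' @export
setMethod("coords<-", "AtomicModel", function(object, value) {
    stopifnot(is.matrix(value), all(dim(value) == dim(object@xyz)))
    object@xyz <- value
    validObject(object)
    object
})

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "AtomicModel", function(object) nrow(object@atoms))

#' @rdname atoms
#' @export
setMethod("atoms", "AtomicModel", function(object) object@atoms)

#' @rdname residueIndex
#' @export
setMethod("residueIndex", "AtomicModel", function(object) {
    key <- paste(object@atoms$chain, object@atoms$resseq, sep = ":")
    split(seq_len(nrow(object@atoms)), factor(key, levels = unique(key)))
})

#' @rdname bodies
#' @export
setMethod("bodies", "RigidBodyPartition", function(object) object@bodies)

#' @rdname fixedAtoms
#' @export
setMethod("fixedAtoms", "RigidBodyPartition", function(object) object@fixed)

#' @rdname gridValues
#' @export
setMethod("gridValues", "DensityGrid", function(object) object@values)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "DensityGrid", function(object) object@voxel)

#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "DensityGrid", function(object) object@origin)

#' @rdname bestModel
#' @export
setMethod("bestModel", "FitResult", function(object) object@bestModel)

#' @rdname bestEnergy
#' @export
setMethod("bestEnergy", "FitResult", function(object) object@bestEnergy)

#' @rdname mcTrace
#' @export
setMethod("mcTrace", "FitResult", function(object) object@trace)

#' @rdname acceptanceRate
#' @export
setMethod("acceptanceRate", "FitResult", function(object) object@acceptanceRate)

#' @rdname ccTable
#' @export
setMethod("ccTable", "ResidueCCReport", function(object) object@table)

setMethod("show", "AtomicModel", function(object) {
    a <- object@atoms
    nres <- length(unique(paste(a$chain, a$resseq)))
    cat(sprintf("AtomicModel: %d atoms, %d residues, %d chain(s)\n",
                nrow(a), nres, length(unique(a$chain))))
    if (all(is.na(object@vdw)))
        cat("  nonbonded parameters: not assigned\n")
    else
        cat("  nonbonded parameters: assigned\n")
})

setMethod("show", "DensityGrid", function(object) {
    d <- dim(object@values)
    cat(sprintf("DensityGrid: %d x %d x %d voxels (%.3g x %.3g x %.3g A)\n",
                d[1], d[2], d[3], object@voxel[1], object@voxel[2],
                object@voxel[3]))
    cat(sprintf("  origin (%.2f, %.2f, %.2f) A; value range [%.4g, %.4g]\n",
                object@origin[1], object@origin[2], object@origin[3],
                min(object@values), max(object@values)))
})

setMethod("show", "RigidBodyPartition", function(object) {
    cat(sprintf("RigidBodyPartition: %d bodies over %d atoms (%d fixed)\n",
                length(object@bodies), object@nAtoms, length(object@fixed)))
    for (nm in names(object@bodies))
        cat(sprintf("  %s: %d atoms\n", nm, length(object@bodies[[nm]])))
})

setMethod("show", "EnergyBreakdown", function(object) {
    cat(sprintf(
        "EnergyBreakdown: total %.6g (cc %.6f, ccTerm %.6g, clashTerm %.6g)\n",
        object@total, object@cc, object@ccTerm, object@clashTerm))
})

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult: %d moves, acceptance %.1f%%, seed %d\n",
                nrow(object@trace), 100 * object@acceptanceRate, object@seed))
    cat("  best: "); show(object@bestEnergy)
})

setMethod("show", "ResidueCCReport", function(object) {
    tab <- object@table
    cat(sprintf(
        "ResidueCCReport: %d residues (mask %.2f A, resolution %.2f A)\n",
        nrow(tab), object@radius, object@resolution))
    cc <- tab$cc[!is.na(tab$cc)]
    if (length(cc))
        cat(sprintf("  cc: min %.3f, median %.3f, max %.3f; %d below zero\n",
                    min(cc), stats::median(cc), max(cc), sum(cc <= 0)))
})
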