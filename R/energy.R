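## The fitting objective: E = w1 * (1 - CC(obs, calc)) + w2 * clash, with
## the 12-6 clash sum restricted to inter-body (and body vs fixed) atom
## pairs, plus a cached state for exact incremental re-evaluation under
## single-body moves.

#' Construct energy weights
#'
#' Defaults are w1 = 100 on the correlation term and w2 = 1 on the clash
#' term.
#'
#' @param w1,w2 non-negative weights, not both zero.
#' @return an \code{\link{EnergyWeights}}
#' @export
energyWeights <- function(w1 = 100, w2 = 1) {
    new("EnergyWeights", w1 = as.numeric(w1), w2 = as.numeric(w2))
}

.energyBreakdown <- function(cc, w1, w2, clashOrdered) {
    ccTerm <- w1 * (1 - cc)
    new("EnergyBreakdown", cc = cc, ccTerm = ccTerm,
        clashTerm = w2 * clashOrdered, total = ccTerm + w2 * clashOrdered)
}

.checkParams <- function(model) {
    if (anyNA(model@vdw) || anyNA(model@eps))
        stop("nonbonded parameters missing: run assignFFParams() first")
}

#' Inter-body 12-6 steric-clash energy
#'
#' Sums \code{eps_ij [ (r_ij/d_ij)^12 - 2 (r_ij/d_ij)^6 ]} over ordered atom
#' pairs whose members belong to different rigid bodies (or to a body and
#' the fixed set), with \code{r_ij = r_i + r_j} and
#' \code{eps_ij = sqrt(eps_i eps_j)}.  Intra-body pairs are excluded: their
#' energy is constant under rigid motion.  Pairs beyond \code{cutoff}
#' contribute zero.
#'
#' @param model an \code{AtomicModel} with parameters assigned.
#' @param partition a \code{RigidBodyPartition}.
#' @param cutoff pair cutoff, Angstrom; must be at least the largest
#'   \code{r_ij}.
#' @param orderedPairs count each pair in both orders, as in the printed
#'   double sum (default TRUE); FALSE halves the value.
#' @return the clash energy (energy units).
#' @export
clashEnergy <- function(model, partition, cutoff = 8, orderedPairs = TRUE) {
    stopifnot(is(model, "AtomicModel"), is(partition, "RigidBodyPartition"))
    .checkParams(model)
    if (cutoff < 2 * max(model@vdw))
        stop("cutoff (", cutoff, " A) smaller than the largest pair radius (",
             2 * max(model@vdw), " A)")
    xyz <- coords(model)
    groups <- c(bodies(partition),
                if (length(fixedAtoms(partition)))
                    list(.fixed = fixedAtoms(partition)))
    E <- 0
    ng <- length(groups)
    if (ng >= 2L) {
        for (i in seq_len(ng - 1L)) for (j in seq.int(i + 1L, ng)) {
            ia <- groups[[i]]; ib <- groups[[j]]
            E <- E + cpp_clash_pair(xyz[ia, , drop = FALSE], model@eps[ia],
                                    model@vdw[ia], xyz[ib, , drop = FALSE],
                                    model@eps[ib], model@vdw[ib], cutoff)
        }
    }
    if (!is.finite(E)) stop("coincident atoms: zero inter-body distance")
    if (orderedPairs) 2 * E else E
}

#' Full objective evaluation
#'
#' \code{E = w1 (1 - CC(obs, density(model))) + w2 clash}.  The correlation
#' domain defaults to the whole experimental map; pass \code{mask} to
#' restrict it explicitly.
#'
#' @param model an \code{AtomicModel} with parameters assigned.
#' @param obs the experimental \code{DensityGrid}.
#' @param partition optional \code{RigidBodyPartition}; without one the
#'   model is a single body and the clash term is zero.
#' @param weights an \code{\link{EnergyWeights}}.
#' @param resolution map resolution for the model density, Angstrom.
#' @param cutoff clash cutoff, Angstrom.
#' @param mask optional \code{\link{GridMask}} correlation domain.
#' @param orderedPairs see \code{\link{clashEnergy}}.
#' @param ... further arguments to \code{\link{simulateDensity}}.
#' @return an \code{\link{EnergyBreakdown}}
#' @export
totalEnergy <- function(model, obs, partition = NULL,
                        weights = energyWeights(), resolution, cutoff = 8,
                        mask = NULL, orderedPairs = TRUE, ...) {
    calc <- simulateDensity(model, template = obs, resolution = resolution,
                            ...)
    cc <- crossCorrelation(obs, calc, mask = mask)
    clash <- if (is.null(partition)) 0
             else clashEnergy(model, partition, cutoff = cutoff,
                              orderedPairs = orderedPairs)
    .energyBreakdown(cc, weights@w1, weights@w2, clash)
}

## ---------------------------------------------------------- cached evaluator

.ccFromSums <- function(s1, s2, sxy, so, so2, n) {
    vx <- s2 - s1 * s1 / n
    vy <- so2 - so * so / n
    if (!is.finite(vx) || vx <= 0 || vy <= 0) return(NA_real_)
    (sxy - s1 * so / n) / (sqrt(vx) * sqrt(vy))
}

#' Build a cached energy state for incremental evaluation
#'
#' Precomputes each body's density contribution, the running correlation
#' sums and the inter-body clash table, so that a single-body move can be
#' scored by updating only what that move touches.
#' \code{\link{deltaEnergy}} on this state is exact: it equals a full
#' recomputation to numerical precision.
#'
#' @inheritParams totalEnergy
#' @param partition a \code{RigidBodyPartition} (required here).
#' @param sigmaFactor,truncate,amplitude density-simulation options, as in
#'   \code{\link{simulateDensity}}.
#' @return an opaque state object for \code{\link{deltaEnergy}},
#'   \code{\link{commitMove}}, \code{\link{stateEnergy}} and
#'   \code{\link{resyncState}}.
#' @export
energyState <- function(model, obs, partition, weights = energyWeights(),
                        resolution, cutoff = 8, sigmaFactor = 0.225,
                        truncate = 4, amplitude = "Z", orderedPairs = TRUE) {
    stopifnot(is(model, "AtomicModel"), is(obs, "DensityGrid"),
              is(partition, "RigidBodyPartition"))
    .checkParams(model)
    if (resolution < 2 * max(voxelSize(obs)))
        stop("sampling error: resolution below the Nyquist limit of the map")
    st <- new.env(parent = emptyenv())
    st$atoms <- atoms(model)
    st$xyz <- coords(model)
    st$vdw <- model@vdw
    st$eps <- model@eps
    st$amp <- .atomAmplitudes(model, amplitude)
    st$bodies <- bodies(partition)
    st$fixed <- fixedAtoms(partition)
    st$geom <- .gridGeom(obs)
    st$obs <- as.numeric(gridValues(obs))
    st$n <- length(st$obs)
    st$so <- sum(st$obs)
    st$so2 <- sum(st$obs^2)
    st$w1 <- weights@w1
    st$w2 <- weights@w2
    st$factor <- if (orderedPairs) 2 else 1
    st$sigma <- sigmaFactor * resolution
    st$rcut <- truncate * st$sigma
    st$cutoff <- cutoff
    st$version <- 0L
    nb <- length(st$bodies)
    st$cum <- rep(list(.identityQT()), nb)
    names(st$cum) <- names(st$bodies)
    .resyncInternal(st)
    if (!is.finite(st$E))
        stop("degenerate starting state: non-finite energy")
    class(st) <- "cryofitEnergyState"
    st
}

.splatIdx <- function(st, idx, xyz = st$xyz) {
    cpp_splat(xyz[idx, , drop = FALSE], st$amp[idx],
              as.integer(st$geom$dim), st$geom$origin, st$geom$voxel,
              st$sigma, st$rcut)
}

.clashBetween <- function(st, xa, ia, ib) {
    cpp_clash_pair(xa, st$eps[ia], st$vdw[ia],
                   st$xyz[ib, , drop = FALSE], st$eps[ib], st$vdw[ib],
                   st$cutoff)
}

.resyncInternal <- function(st) {
    nb <- length(st$bodies)
    st$bodyDens <- lapply(st$bodies, function(idx) .splatIdx(st, idx))
    st$fixedDens <- if (length(st$fixed)) .splatIdx(st, st$fixed)
                    else numeric(st$n)
    st$calc <- Reduce(`+`, st$bodyDens, st$fixedDens)
    st$s1 <- sum(st$calc)
    st$s2 <- sum(st$calc^2)
    st$sxy <- sum(st$obs * st$calc)
    st$M <- matrix(0, nb, nb)
    st$Fv <- numeric(nb)
    for (b in seq_len(nb)) {
        ia <- st$bodies[[b]]
        xa <- st$xyz[ia, , drop = FALSE]
        if (b < nb) for (o in seq.int(b + 1L, nb)) {
            st$M[b, o] <- st$M[o, b] <- .clashBetween(st, xa, ia,
                                                      st$bodies[[o]])
        }
        if (length(st$fixed))
            st$Fv[b] <- .clashBetween(st, xa, ia, st$fixed)
    }
    st$clashU <- sum(st$M[upper.tri(st$M)]) + sum(st$Fv)
    st$cc <- .ccFromSums(st$s1, st$s2, st$sxy, st$so, st$so2, st$n)
    st$E <- if (is.na(st$cc)) Inf
            else st$w1 * (1 - st$cc) + st$w2 * st$factor * st$clashU
    invisible(st)
}

.proposeDelta <- function(st, b, q, tvec, pivot) {
    idx <- st$bodies[[b]]
    newXyz <- .applyQT(q, tvec, pivot, st$xyz[idx, , drop = FALSE])
    newDens <- cpp_splat(newXyz, st$amp[idx], as.integer(st$geom$dim),
                         st$geom$origin, st$geom$voxel, st$sigma, st$rcut)
    sums <- cpp_cc_sums(st$obs, st$calc, st$bodyDens[[b]], newDens)
    cc <- .ccFromSums(sums[1], sums[2], sums[3], st$so, st$so2, st$n)
    nb <- length(st$bodies)
    newRow <- numeric(nb)
    for (o in seq_len(nb)) if (o != b)
        newRow[o] <- .clashBetween(st, newXyz, idx, st$bodies[[o]])
    newF <- if (length(st$fixed)) .clashBetween(st, newXyz, idx, st$fixed)
            else 0
    clashU <- st$clashU - (sum(st$M[b, ]) + st$Fv[b]) + (sum(newRow) + newF)
    E <- if (is.na(cc)) Inf
         else st$w1 * (1 - cc) + st$w2 * st$factor * clashU
    list(body = b, q = q, t = tvec, pivot = pivot, xyz = newXyz,
         dens = newDens, s1 = sums[1], s2 = sums[2], sxy = sums[3],
         row = newRow, f = newF, clashU = clashU, cc = cc, E = E,
         dE = E - st$E, version = st$version)
}

.commitDelta <- function(st, p) {
    b <- p$body
    idx <- st$bodies[[b]]
    st$xyz[idx, ] <- p$xyz
    st$calc <- st$calc - st$bodyDens[[b]] + p$dens
    st$bodyDens[[b]] <- p$dens
    st$s1 <- p$s1; st$s2 <- p$s2; st$sxy <- p$sxy
    st$M[b, ] <- p$row; st$M[, b] <- p$row
    st$Fv[b] <- p$f
    st$clashU <- p$clashU
    st$cc <- p$cc
    st$E <- p$E
    st$cum[[b]] <- .composeQT(list(q = p$q, t = p$t, pivot = p$pivot),
                              st$cum[[b]])
    st$version <- st$version + 1L
    invisible(st)
}

#' Incremental energy change of a single-body move
#'
#' Scores moving \code{body} by \code{transform} against the cached state,
#' updating only that body's density contribution and its inter-body clash
#' pairs.  The returned proposal carries \code{dE}; pass it to
#' \code{\link{commitMove}} to accept the move.
#'
#' @param state a state from \code{\link{energyState}}.
#' @param body body name.
#' @param transform a \code{RigidTransform} for the move.
#' @return invisibly, a proposal list with elements \code{dE}, \code{E},
#'   \code{cc} and internal update payloads.
#' @export
deltaEnergy <- function(state, body, transform) {
    stopifnot(inherits(state, "cryofitEnergyState"),
              is(transform, "RigidTransform"))
    b <- match(body, names(state$bodies))
    if (is.na(b)) stop("unknown rigid body: ", body)
    invisible(.proposeDelta(state, b, transform@q, transform@t,
                            transform@pivot))
}

#' Commit a proposed move into the cached state
#'
#' @param state a state from \code{\link{energyState}}.
#' @param proposal the value returned by \code{\link{deltaEnergy}} for the
#'   current state; committing a proposal computed against an earlier state
#'   version is a consistency error.
#' @export
commitMove <- function(state, proposal) {
    stopifnot(inherits(state, "cryofitEnergyState"))
    if (!identical(proposal$version, state$version))
        stop("stale proposal: state has changed since deltaEnergy()")
    invisible(.commitDelta(state, proposal))
}

#' Current energy breakdown of a cached state
#'
#' @param state a state from \code{\link{energyState}}.
#' @return an \code{\link{EnergyBreakdown}}
#' @export
stateEnergy <- function(state) {
    stopifnot(inherits(state, "cryofitEnergyState"))
    .energyBreakdown(state$cc, state$w1, state$w2,
                     state$factor * state$clashU)
}

#' Recompute a cached state from scratch
#'
#' Rebuilds all density contributions, correlation sums and clash tables
#' from the current coordinates, clearing any accumulated floating-point
#' drift.
#'
#' @param state a state from \code{\link{energyState}}.
#' @export
resyncState <- function(state) {
    stopifnot(inherits(state, "cryofitEnergyState"))
    .resyncInternal(state)
    state$version <- state$version + 1L
    invisible(state)
}

#' Model snapshot of a cached state
#'
#' @param state a state from \code{\link{energyState}}.
#' @return an \code{AtomicModel} at the state's current pose.
#' @export
stateModel <- function(state) {
    stopifnot(inherits(state, "cryofitEnergyState"))
    .newModel(state$atoms, state$xyz, vdw = state$vdw, eps = state$eps)
}
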