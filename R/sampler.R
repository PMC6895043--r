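## Metropolis Monte Carlo over rigid-body poses.

#' Construct a Monte Carlo configuration
#'
#' Defaults follow the fitting protocol: 50,000 total translation/rotation
#' moves and weights w1 = 100, w2 = 1.  The temperature and step sizes are
#' implementation defaults: kT = 1 in objective units (so a one-point CC
#' change scores as \code{dE = 1} under w1 = 100), 1 Angstrom / 2 degree
#' Gaussian proposal widths.
#'
#' @param nMoves total number of moves across all bodies (default 50000).
#' @param kT acceptance temperature (default 1).
#' @param translationStep Gaussian sigma of translations, Angstrom; 0
#'   disables the channel.
#' @param rotationStep Gaussian sigma of rotation angles, degrees; 0
#'   disables the channel.
#' @param seed RNG seed.
#' @param weights an \code{\link{EnergyWeights}}.
#' @param cutoff clash cutoff, Angstrom.
#' @param resolution map resolution, Angstrom.
#' @param anneal NULL for constant kT, else \code{c(start, end)} for a
#'   linear kT schedule.
#' @return an \code{\link{MCConfig}}
#' @export
mcConfig <- function(nMoves = 50000, kT = 1, translationStep = 1,
                     rotationStep = 2, seed = 1, weights = energyWeights(),
                     cutoff = 8, resolution, anneal = NULL) {
    new("MCConfig", nMoves = as.integer(nMoves), kT = as.numeric(kT),
        translationStep = as.numeric(translationStep),
        rotationStep = as.numeric(rotationStep), seed = as.integer(seed),
        weights = weights, cutoff = as.numeric(cutoff),
        resolution = as.numeric(resolution),
        anneal = if (is.null(anneal)) numeric(0) else as.numeric(anneal))
}

## Draw one symmetric proposal from the current RNG stream: a body chosen
## uniformly, then with probability 1/2 an isotropic Gaussian translation or
## a Gaussian-angle rotation about a uniformly random axis through `pivot`.
.drawMove <- function(config, nBodies, pivotOf) {
    b <- sample.int(nBodies, 1L)
    doRot <- if (config@rotationStep <= 0) FALSE
             else if (config@translationStep <= 0) TRUE
             else runif(1) < 0.5
    if (doRot) {
        ang <- rnorm(1, 0, config@rotationStep) * pi / 180
        ax <- rnorm(3)
        nrm <- sqrt(sum(ax^2))
        if (nrm < 1e-12) { ax <- c(0, 0, 1); nrm <- 1 }
        list(body = b, type = "rotation",
             q = c(cos(ang / 2), sin(ang / 2) * ax / nrm),
             t = c(0, 0, 0), pivot = pivotOf(b))
    } else {
        list(body = b, type = "translation", q = c(1, 0, 0, 0),
             t = rnorm(3) * config@translationStep, pivot = c(0, 0, 0))
    }
}

#' Propose one rigid-body move
#'
#' The body is chosen uniformly; the move is a translation or a rotation
#' with probability 1/2 each (unless a channel is disabled).  Translations
#' are isotropic Gaussian with sigma \code{translationStep}; rotations use a
#' Gaussian angle (sigma \code{rotationStep} degrees) about a uniformly
#' random axis through the body centroid.  The proposal density is
#' symmetric, as Metropolis acceptance requires.
#'
#' @param config an \code{\link{MCConfig}}.
#' @param partition a \code{RigidBodyPartition}.
#' @param model the \code{AtomicModel} at the current pose (for centroids).
#' @return list with \code{body} (name) and \code{transform}
#'   (\code{RigidTransform}).
#' @export
proposeMove <- function(config, partition, model) {
    stopifnot(is(config, "MCConfig"), is(partition, "RigidBodyPartition"))
    bodyIdx <- bodies(partition)
    if (length(bodyIdx) == 0L) stop("configuration error: empty partition")
    xyz <- coords(model)
    mv <- .drawMove(config, length(bodyIdx),
                    function(b) colMeans(xyz[bodyIdx[[b]], , drop = FALSE]))
    list(body = names(bodyIdx)[mv$body],
         type = mv$type,
         transform = rigidTransform(translation = mv$t, pivot = mv$pivot,
                                    q = mv$q))
}

#' Metropolis acceptance rule
#'
#' Accepts when \code{dE <= 0}; otherwise accepts with probability
#' \code{exp(-dE / kT)}, consuming one uniform draw.
#'
#' @param dE energy difference of the proposed move.
#' @param kT temperature, > 0.
#' @return TRUE to accept, FALSE to reject.
#' @export
metropolisAccept <- function(dE, kT) {
    if (!is.finite(dE)) stop("numeric error: non-finite energy difference")
    stopifnot(kT > 0)
    if (dE <= 0) TRUE else runif(1) < exp(-dE / kT)
}

#' Fit rigid bodies into a density map by Metropolis Monte Carlo
#'
#' Runs exactly \code{nMoves} propose/evaluate/accept cycles over the
#' partition's bodies using the cached incremental evaluator, and returns
#' the best pose seen (plain Metropolis does not end at the minimum).
#' Proposals with non-finite energy (deep steric overlap) are auto-rejected
#' and counted rather than raising an error.  Identical seed and inputs
#' reproduce the trace bitwise; the cached energy is re-synchronized against
#' a full recomputation every 500 moves and verified at the end.
#'
#' @param model an \code{AtomicModel} with parameters assigned.
#' @param partition a \code{RigidBodyPartition}.
#' @param obs the experimental \code{DensityGrid}.
#' @param config an \code{\link{MCConfig}}.
#' @return a \code{\link{FitResult}}
#' @export
fitModel <- function(model, partition, obs, config) {
    stopifnot(is(config, "MCConfig"))
    set.seed(config@seed)
    st <- energyState(model, obs, partition, weights = config@weights,
                      resolution = config@resolution, cutoff = config@cutoff)
    bodyIdx <- st$bodies
    nb <- length(bodyIdx)
    n <- config@nMoves
    kTs <- if (length(config@anneal) == 2L)
               seq(config@anneal[1], config@anneal[2], length.out = n)
           else rep(config@kT, n)
    tBody <- character(n); tType <- character(n)
    tdE <- numeric(n); tAcc <- logical(n)
    tE <- numeric(n); tCC <- numeric(n)
    bestE <- st$E
    bestCC <- st$cc
    bestClashU <- st$clashU
    bestXyz <- st$xyz
    bestCum <- st$cum
    nAccept <- 0L
    nOverflow <- 0L
    for (m in seq_len(n)) {
        mv <- .drawMove(config, nb, function(b)
            colMeans(st$xyz[bodyIdx[[b]], , drop = FALSE]))
        p <- .proposeDelta(st, mv$body, mv$q, mv$t, mv$pivot)
        if (!is.finite(p$E)) {
            acc <- FALSE
            nOverflow <- nOverflow + 1L
        } else if (p$dE <= 0) {
            acc <- TRUE
        } else {
            acc <- runif(1) < exp(-p$dE / kTs[m])
        }
        if (acc) {
            .commitDelta(st, p)
            nAccept <- nAccept + 1L
            if (st$E < bestE) {
                bestE <- st$E
                bestCC <- st$cc
                bestClashU <- st$clashU
                bestXyz <- st$xyz
                bestCum <- st$cum
            }
        }
        tBody[m] <- names(bodyIdx)[mv$body]
        tType[m] <- mv$type
        tdE[m] <- p$dE
        tAcc[m] <- acc
        tE[m] <- st$E
        tCC[m] <- st$cc
        if (m %% 500L == 0L) {
            v <- st$version
            .resyncInternal(st)
            st$version <- v + 1L
        }
    }
    ## audit: cached energy must match a from-scratch recomputation
    Ecached <- st$E
    .resyncInternal(st)
    if (is.finite(Ecached) && abs(Ecached - st$E) > 1e-6)
        stop("internal consistency error: cached energy drifted by ",
             abs(Ecached - st$E))
    bestModelObj <- .newModel(st$atoms, bestXyz, vdw = st$vdw, eps = st$eps)
    bestBreak <- .energyBreakdown(bestCC, st$w1, st$w2,
                                  st$factor * bestClashU)
    bestCum <- lapply(bestCum, .qtToTransform)
    new("FitResult", bestTransforms = bestCum, bestModel = bestModelObj,
        bestEnergy = bestBreak,
        trace = data.frame(move = seq_len(n), body = tBody, type = tType,
                           dE = tdE, accepted = tAcc, E = tE, cc = tCC,
                           stringsAsFactors = FALSE),
        acceptanceRate = nAccept / n, seed = config@seed,
        nOverflow = nOverflow)
}

#' Write a fit trace as TSV
#'
#' @param result a \code{FitResult}.
#' @param path output file path.
#' @export
writeTrace <- function(result, path) {
    stopifnot(is(result, "FitResult"))
    utils::write.table(mcTrace(result), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Serialize a fit result as JSON
#'
#' Best transforms (quaternion + translation + pivot per body), energy
#' breakdown, acceptance rate and seed.
#'
#' @param result a \code{FitResult}.
#' @param path optional output file; with NULL the JSON string is returned.
#' @export
fitResultJSON <- function(result, path = NULL) {
    stopifnot(is(result, "FitResult"))
    be <- bestEnergy(result)
    obj <- list(
        best_transforms = lapply(result@bestTransforms, function(T)
            list(q = T@q, t = T@t, pivot = T@pivot)),
        best_energy = list(cc = be@cc, cc_term = be@ccTerm,
                           clash_term = be@clashTerm, total = be@total),
        acceptance_rate = result@acceptanceRate,
        n_overflow = result@nOverflow,
        seed = result@seed)
    js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(path)
}
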