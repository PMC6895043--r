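## Atomic-model construction, PDB I/O (via bio3d), force-field parameter
## assignment, rigid-body partitioning and rigid transforms.

.WATER_RESNAMES <- c("HOH", "WAT", "TIP", "TIP3", "H2O", "DOD", "SOL")

.newModel <- function(atoms, xyz, vdw = NULL, eps = NULL) {
    n <- nrow(atoms)
    rownames(atoms) <- NULL
    dimnames(xyz) <- NULL
    new("AtomicModel", atoms = atoms, xyz = xyz,
        vdw = if (is.null(vdw)) rep(NA_real_, n) else vdw,
        eps = if (is.null(eps)) rep(NA_real_, n) else eps)
}

.elementOf <- function(elety, elesy) {
    el <- toupper(trimws(elesy))
    miss <- is.na(el) | el == ""
    if (any(miss)) {
        nm <- toupper(trimws(elety[miss]))
        nm <- sub("^[0-9']+", "", nm)
        guess <- substr(nm, 1L, 1L)
        guess[substr(nm, 1L, 2L) == "SE"] <- "SE"
        el[miss] <- guess
    }
    el
}

#' Read an atomic model from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records through \pkg{bio3d}.  Alternate
#' locations are collapsed to the highest-occupancy conformer (ties: first
#' encountered); hydrogens and waters are dropped by default, matching the
#' heavy-atom models deposited for cryo-EM maps.
#'
#' @param path PDB file path.
#' @param keepHydrogens keep hydrogen/deuterium atoms (default FALSE).
#' @param removeWaters drop water residues (default TRUE).
#' @return an \code{\link{AtomicModel}} with coordinates in Angstrom.
#' @export
readPDBModel <- function(path, keepHydrogens = FALSE, removeWaters = TRUE) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    rec <- substr(lines, 1L, 6L)
    isAtom <- rec %in% c("ATOM  ", "HETATM")
    if (!any(isAtom)) stop("empty model: no ATOM/HETATM records in ", path)
    for (ln in which(isAtom)) {
        l <- lines[ln]
        xyzok <- nchar(l) >= 54L &&
            !anyNA(suppressWarnings(as.numeric(c(
                substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)))))
        if (!xyzok)
            stop("PDB format error at line ", ln,
                 ": unparsable coordinate fields")
    }
    pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    a <- pdb$atom
    a$element <- .elementOf(a$elety, a$elesy)
    if (removeWaters) a <- a[!(a$resid %in% .WATER_RESNAMES), , drop = FALSE]
    if (!keepHydrogens) a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
    if (nrow(a) == 0L)
        stop("empty model: no atoms left after filtering ", path)
    ## altloc: keep the highest-occupancy conformer per atom site
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
    if (anyDuplicated(key)) {
        occ <- ifelse(is.na(a$o), 1, a$o)
        keep <- unlist(lapply(split(seq_len(nrow(a)), factor(key, unique(key))),
                              function(i) i[which.max(occ[i])]),
                       use.names = FALSE)
        a <- a[sort(keep), , drop = FALSE]
    }
    atoms <- data.frame(
        serial = as.integer(a$eleno),
        name = trimws(a$elety),
        element = a$element,
        resname = trimws(a$resid),
        chain = ifelse(is.na(a$chain), " ", a$chain),
        resseq = as.integer(a$resno),
        insert = ifelse(is.na(a$insert), "", a$insert),
        occ = ifelse(is.na(a$o), 1, a$o),
        bfac = ifelse(is.na(a$b), 0, a$b),
        stringsAsFactors = FALSE)
    .newModel(atoms, cbind(a$x, a$y, a$z))
}

#' Write an atomic model to a PDB file
#'
#' Standard fixed-column records with coordinates rounded to three decimals;
#' repeated writes of the same model are byte-identical.
#'
#' @param model an \code{AtomicModel}; must be non-empty.
#' @param path output file path.
#' @param bfac optional replacement B-factor vector (e.g. per-residue CC for
#'   visualization).
#' @export
writePDBModel <- function(model, path, bfac = NULL) {
    stopifnot(is(model, "AtomicModel"))
    n <- nAtoms(model)
    if (n == 0L) stop("empty model: nothing to write")
    xyz <- coords(model)
    if (any(abs(xyz) >= 10000) || any(xyz <= -1000))
        stop("field overflow: coordinate magnitude does not fit PDB columns")
    a <- atoms(model)
    b <- if (is.null(bfac)) a$bfac else rep_len(bfac, n)
    bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                     type = rep("ATOM", n), eleno = a$serial,
                     elety = a$name, resid = a$resname, chain = a$chain,
                     resno = a$resseq, insert = ifelse(a$insert == "", NA,
                                                       a$insert),
                     o = a$occ, b = b, elesy = a$element)
    invisible(path)
}

## ---------------------------------------------------------------- forcefield

#' Built-in element-level nonbonded parameter table
#'
#' CHARMM-style van der Waals radii (half the pair minimum-energy distance)
#' and well depths, per element, read from the plain-text table shipped with
#' the package.  Pair parameters downstream combine as
#' \code{r_ij = r_i + r_j} and \code{eps_ij = sqrt(eps_i * eps_j)}.
#'
#' @return a \code{\link{ForceFieldTable}}
#' @export
defaultForceField <- function() {
    readForceField(system.file("extdata", "vdw_default.txt",
                               package = "cryofit", mustWork = TRUE))
}

#' Read a nonbonded parameter table
#'
#' Whitespace-delimited lines, either \code{element radius epsilon}
#' (element-level) or \code{element atom_name radius epsilon} (atom-name
#' override).  Lines starting with \code{#} are comments.
#'
#' @param path file path.
#' @return a \code{\link{ForceFieldTable}}
#' @export
readForceField <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    rows <- lapply(seq_along(lines), function(i) {
        f <- strsplit(lines[i], "[[:space:]]+")[[1]]
        if (length(f) == 3L)
            data.frame(element = toupper(f[1]), name = "",
                       vdw = as.numeric(f[2]), eps = as.numeric(f[3]))
        else if (length(f) == 4L)
            data.frame(element = toupper(f[1]), name = toupper(f[2]),
                       vdw = as.numeric(f[3]), eps = as.numeric(f[4]))
        else stop("force-field table: malformed line ", i, ": ", lines[i])
    })
    tab <- do.call(rbind, rows)
    if (anyNA(tab$vdw) || anyNA(tab$eps))
        stop("force-field table: non-numeric radius/epsilon")
    new("ForceFieldTable", table = tab)
}

#' Assign per-atom nonbonded parameters
#'
#' Looks each atom up by \code{(element, atom name)} with element-level
#' fallback.  The input model is not modified.
#'
#' @param model an \code{AtomicModel}.
#' @param table a \code{\link{ForceFieldTable}} (default: the shipped table).
#' @param default optional \code{c(vdw, eps)} used for atoms whose element is
#'   missing from the table; with \code{default = NULL} (the default) such
#'   atoms raise a missing-parameter error naming them.
#' @return a new \code{AtomicModel} with \code{vdw}/\code{eps} set.
#' @export
assignFFParams <- function(model, table = defaultForceField(), default = NULL) {
    stopifnot(is(model, "AtomicModel"), is(table, "ForceFieldTable"))
    tab <- table@table
    byName <- tab[tab$name != "", , drop = FALSE]
    byElem <- tab[tab$name == "", , drop = FALSE]
    a <- atoms(model)
    keyAtom <- paste(toupper(a$element), toupper(a$name))
    i <- match(keyAtom, paste(byName$element, byName$name))
    vdw <- byName$vdw[i]
    eps <- byName$eps[i]
    j <- match(toupper(a$element), byElem$element)
    useElem <- is.na(i)
    vdw[useElem] <- byElem$vdw[j[useElem]]
    eps[useElem] <- byElem$eps[j[useElem]]
    miss <- is.na(vdw)
    if (any(miss)) {
        if (is.null(default))
            stop("missing nonbonded parameters for atoms: ",
                 paste(sprintf("%s %s%d %s(%s)", a$chain[miss],
                               a$resname[miss], a$resseq[miss], a$name[miss],
                               a$element[miss]), collapse = ", "))
        vdw[miss] <- default[1]
        eps[miss] <- default[2]
    }
    .newModel(a, coords(model), vdw = vdw, eps = eps)
}

## ----------------------------------------------------------------- partition

#' Build a rigid-body partition from chain/residue ranges
#'
#' @param model an \code{AtomicModel}.
#' @param defs data.frame with columns \code{body}, \code{chain},
#'   \code{first}, \code{last} (1-based inclusive residue ranges); several
#'   rows may share a body name.
#' @return a \code{\link{RigidBodyPartition}}; atoms matched by no range go
#'   to the fixed set.
#' @export
rigidBodyPartition <- function(model, defs) {
    stopifnot(is(model, "AtomicModel"),
              all(c("body", "chain", "first", "last") %in% names(defs)))
    a <- atoms(model)
    bodyNames <- unique(as.character(defs$body))
    bodies <- lapply(bodyNames, function(nm) {
        d <- defs[defs$body == nm, , drop = FALSE]
        idx <- integer(0)
        for (r in seq_len(nrow(d)))
            idx <- c(idx, which(a$chain == d$chain[r] &
                                a$resseq >= d$first[r] &
                                a$resseq <= d$last[r]))
        sort(unique(idx))
    })
    names(bodies) <- bodyNames
    empty <- bodyNames[lengths(bodies) == 0L]
    if (length(empty))
        stop("rigid body selects no atoms: ", paste(empty, collapse = ", "))
    used <- unlist(bodies, use.names = FALSE)
    if (anyDuplicated(used))
        stop("rigid-body definitions overlap")
    new("RigidBodyPartition", bodies = bodies,
        fixed = setdiff(seq_len(nAtoms(model)), used),
        nAtoms = nAtoms(model))
}

#' Read rigid-body definitions from a plain-text file
#'
#' One body range per line: \code{body_name chain_id first_residue
#' last_residue} (1-based, inclusive); \code{#} starts a comment.
#'
#' @param model an \code{AtomicModel} the definitions apply to.
#' @param path file path.
#' @return a \code{\link{RigidBodyPartition}}
#' @export
readRigidBodies <- function(model, path) {
    defs <- utils::read.table(path, header = FALSE, comment.char = "#",
                              col.names = c("body", "chain", "first", "last"),
                              colClasses = c("character", "character",
                                             "integer", "integer"))
    rigidBodyPartition(model, defs)
}

## ---------------------------------------------------------------- transforms

.quatFromAxisAngle <- function(axis, angleRad) {
    axis <- axis / sqrt(sum(axis^2))
    c(cos(angleRad / 2), sin(angleRad / 2) * axis)
}

.quatMul <- function(a, b) {
    c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
      a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
      a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
      a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

.quatToMat <- function(q) {
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3, byrow = TRUE)
}

## x' = R (x - pivot) + pivot + t, rows of xyz
## (written as x R' + (pivot + t - R pivot) to keep the per-move cost low)
.applyQT <- function(q, t, pivot, xyz) {
    R <- .quatToMat(q)
    off <- pivot + t - as.numeric(R %*% pivot)
    z <- xyz %*% t(R)
    z[, 1] <- z[, 1] + off[1]
    z[, 2] <- z[, 2] + off[2]
    z[, 3] <- z[, 3] + off[3]
    z
}

## plain-list composition of (q, t, pivot) triples: apply m1 then m2
.composeQT <- function(m2, m1) {
    R2 <- .quatToMat(m2$q)
    list(q = .quatMul(m2$q, m1$q),
         t = as.numeric(R2 %*% (m1$pivot + m1$t - m2$pivot)) +
             m2$pivot + m2$t - m1$pivot,
         pivot = m1$pivot)
}

.identityQT <- function() list(q = c(1, 0, 0, 0), t = c(0, 0, 0),
                               pivot = c(0, 0, 0))

.qtToTransform <- function(m)
    rigidTransform(translation = m$t, pivot = m$pivot,
                   q = m$q / sqrt(sum(m$q^2)))

#' Construct a rigid transform
#'
#' The transform maps a point x to \code{R (x - pivot) + pivot + t}, where R
#' is the rotation about \code{axis} by \code{angle}.
#'
#' @param translation 3-vector, Angstrom.
#' @param axis rotation axis (any nonzero 3-vector; normalized internally).
#' @param angle rotation angle in degrees.
#' @param pivot point the rotation is applied about, Angstrom.
#' @param q optional unit quaternion (w, x, y, z) overriding axis/angle.
#' @return a \code{\link{RigidTransform}}
#' @export
rigidTransform <- function(translation = c(0, 0, 0), axis = c(0, 0, 1),
                           angle = 0, pivot = c(0, 0, 0), q = NULL) {
    if (is.null(q)) q <- .quatFromAxisAngle(axis, angle * pi / 180)
    new("RigidTransform", q = q / sqrt(sum(q^2)), t = as.numeric(translation),
        pivot = as.numeric(pivot))
}

#' Identity transform
#' @export
identityTransform <- function() rigidTransform()

#' Compose two rigid transforms (apply \code{first}, then \code{second})
#'
#' @param second,first \code{RigidTransform}s.
#' @return the composed \code{RigidTransform}, expressed about
#'   \code{first}'s pivot.
#' @export
composeTransforms <- function(second, first) {
    R2 <- .quatToMat(second@q)
    q <- .quatMul(second@q, first@q)
    tnew <- as.numeric(R2 %*% (first@pivot + first@t - second@pivot)) +
        second@pivot + second@t - first@pivot
    rigidTransform(translation = tnew, pivot = first@pivot, q = q)
}

#' Invert a rigid transform
#' @param transform a \code{RigidTransform}.
#' @return the inverse \code{RigidTransform} (same pivot).
#' @export
invertTransform <- function(transform) {
    qc <- c(transform@q[1], -transform@q[2:4])
    rigidTransform(translation = -as.numeric(.quatToMat(qc) %*% transform@t),
                   pivot = transform@pivot, q = qc)
}

#' Apply a rigid transform to a model or one of its bodies
#'
#' Only the atoms of \code{body} move (all atoms when no partition is
#' given); intra-body distances are preserved to numerical precision.
#'
#' @param model an \code{AtomicModel}.
#' @param transform a \code{RigidTransform}.
#' @param partition optional \code{RigidBodyPartition}.
#' @param body body name within \code{partition}; required when a partition
#'   is given.
#' @return a new \code{AtomicModel}.
#' @export
applyTransform <- function(model, transform, partition = NULL, body = NULL) {
    stopifnot(is(model, "AtomicModel"), is(transform, "RigidTransform"))
    xyz <- coords(model)
    if (is.null(partition)) {
        idx <- seq_len(nrow(xyz))
    } else {
        stopifnot(is(partition, "RigidBodyPartition"))
        if (is.null(body) || !body %in% names(bodies(partition)))
            stop("unknown rigid body: ", if (is.null(body)) "<none>" else body)
        idx <- bodies(partition)[[body]]
    }
    xyz[idx, ] <- .applyQT(transform@q, transform@t, transform@pivot,
                           xyz[idx, , drop = FALSE])
    .newModel(atoms(model), xyz, vdw = model@vdw, eps = model@eps)
}

#' Root-mean-square deviation between two models (no superposition)
#'
#' Atoms are matched by order over \code{selection}; the fixed-frame RMSD is
#' returned in Angstrom.
#'
#' @param a,b \code{AtomicModel}s.
#' @param selection optional integer atom indices (applied to both models).
#' @export
modelRMSD <- function(a, b, selection = NULL) {
    xa <- coords(a); xb <- coords(b)
    if (!is.null(selection)) {
        xa <- xa[selection, , drop = FALSE]
        xb <- xb[selection, , drop = FALSE]
    }
    if (nrow(xa) != nrow(xb))
        stop("selection size mismatch: ", nrow(xa), " vs ", nrow(xb), " atoms")
    sqrt(mean(rowSums((xa - xb)^2)))
}
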