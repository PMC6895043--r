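# Atomic-model data model, PDB round-trips, parameter assignment and rigid
# transforms.

polyAlaPDB <- function(path, nRes = 3) {
    toy <- makeToyModel("helix", nRes = nRes)
    writePDBModel(toy$model, path)
    path
}

test_that("PDB round-trip preserves identity and coordinates to PDB precision", {
    f <- withr::local_tempfile(fileext = ".pdb")
    toy <- makeToyModel("helix", nRes = 3)
    writePDBModel(toy$model, f)
    m <- readPDBModel(f)
    expect_equal(nAtoms(m), 15)  # 5 heavy atoms per Ala residue
    expect_identical(atoms(m)$name, atoms(toy$model)$name)
    expect_identical(atoms(m)$chain, atoms(toy$model)$chain)
    expect_identical(atoms(m)$resseq, atoms(toy$model)$resseq)
    expect_lt(max(abs(coords(m) - coords(toy$model))), 1e-3)
    # second round trip is exact, and repeated writes are byte-stable
    f2 <- withr::local_tempfile(fileext = ".pdb")
    f3 <- withr::local_tempfile(fileext = ".pdb")
    writePDBModel(m, f2)
    writePDBModel(m, f3)
    expect_identical(readBin(f2, "raw", file.size(f2)),
                     readBin(f3, "raw", file.size(f3)))
    expect_identical(coords(readPDBModel(f2)), coords(m))
})

test_that("PDB reader filters waters/hydrogens and resolves altlocs by occupancy", {
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(c(
        "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
        "ATOM      2  N  BALA A   1       1.000   0.000   0.000  0.60  0.00           N",
        "ATOM      3  CA  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
        "ATOM      4  H   ALA A   1       3.000   0.000   0.000  1.00  0.00           H",
        "HETATM    5  O   HOH A 101       4.000   0.000   0.000  1.00  0.00           O",
        "END"), f)
    m <- readPDBModel(f)
    expect_equal(nAtoms(m), 2)                 # water + hydrogen dropped
    expect_equal(coords(m)[1, 1], 1.0)         # higher-occupancy B conformer
    expect_equal(nAtoms(readPDBModel(f, keepHydrogens = TRUE)), 3)

    fw <- withr::local_tempfile(fileext = ".pdb")
    writeLines(c(
        "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
        "END"), fw)
    expect_error(readPDBModel(fw), "empty model")
    expect_error(readPDBModel(withr::local_tempfile(fileext = ".pdb")),
                 "not found")
})

test_that("malformed coordinate records and overflow coordinates error", {
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(c(
        "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
        "ATOM      2  CA  ALA A   2      xx.xxx   0.000   0.000  1.00  0.00           C"),
        f)
    expect_error(readPDBModel(f), "line 2")
    toy <- makeToyModel("helix", nRes = 2)
    far <- applyTransform(toy$model,
                          rigidTransform(translation = c(10000, 0, 0)))
    expect_error(writePDBModel(far, withr::local_tempfile(fileext = ".pdb")),
                 "overflow")
})

test_that("translation shifts written x fields by exactly the offset", {
    f1 <- withr::local_tempfile(fileext = ".pdb")
    f2 <- withr::local_tempfile(fileext = ".pdb")
    toy <- makeToyModel("helix", nRes = 2)
    writePDBModel(toy$model, f1)
    writePDBModel(applyTransform(toy$model,
                                 rigidTransform(translation = c(1, 0, 0))), f2)
    x1 <- as.numeric(substr(grep("^ATOM", readLines(f1), value = TRUE), 31, 38))
    x2 <- as.numeric(substr(grep("^ATOM", readLines(f2), value = TRUE), 31, 38))
    expect_equal(x2 - x1, rep(1, length(x1)), tolerance = 1e-9)
})

test_that("force-field assignment is a pure lookup with combination rules", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("# comment", "C 1.7 0.1", "N 1.85 0.2", "O 1.7 0.12",
                 "C CB 1.9 0.4"), f)
    tab <- readForceField(f)
    toy <- makeToyModel("helix", nRes = 2)
    m0 <- new("AtomicModel", atoms = atoms(toy$model),
              xyz = coords(toy$model),
              vdw = rep(NA_real_, nAtoms(toy$model)),
              eps = rep(NA_real_, nAtoms(toy$model)))
    m <- assignFFParams(m0, tab)
    a <- atoms(m)
    expect_equal(m@vdw[a$name == "CA"][1], 1.7)
    expect_equal(m@eps[a$name == "CA"][1], 0.1)
    expect_equal(m@vdw[a$name == "CB"][1], 1.9)   # atom-name override
    expect_equal(m@eps[a$name == "CB"][1], 0.4)
    # combination rules: eps_ij = sqrt(eps_i eps_j), r_ij = r_i + r_j
    expect_equal(sqrt(0.1 * 0.4), 0.2)
    expect_identical(m0@vdw, rep(NA_real_, nAtoms(m0)))  # input untouched

    # unknown element with defaults disabled names the offending atoms
    aSe <- atoms(m0)
    aSe$element[1] <- "SE"
    mSe <- new("AtomicModel", atoms = aSe, xyz = coords(m0),
               vdw = m0@vdw, eps = m0@eps)
    expect_error(assignFFParams(mSe, tab), "missing nonbonded.*SE")
    mDef <- assignFFParams(mSe, tab, default = c(2.0, 0.05))
    expect_equal(mDef@vdw[1], 2.0)
})

test_that("rigid transforms are isometries and compose with their inverses", {
    set.seed(11)
    toy <- makeToyModel("dumbbell", nRes = 4)
    idx <- bodies(toy$partition)$body2
    d0 <- as.matrix(dist(coords(toy$model)[idx, ]))
    for (rep in 1:20) {
        T <- rigidTransform(translation = rnorm(3, 0, 5), axis = rnorm(3),
                            angle = runif(1, -180, 180),
                            pivot = rnorm(3, 0, 10))
        m1 <- applyTransform(toy$model, T, toy$partition, "body2")
        # only the body moves
        other <- setdiff(seq_len(nAtoms(toy$model)), idx)
        expect_identical(coords(m1)[other, ], coords(toy$model)[other, ])
        # intra-body distances preserved
        expect_lt(max(abs(as.matrix(dist(coords(m1)[idx, ])) - d0)), 1e-9)
        # inverse returns the pose
        m2 <- applyTransform(m1, invertTransform(T), toy$partition, "body2")
        expect_lt(max(abs(coords(m2) - coords(toy$model))), 1e-8)
        # composition matches sequential application
        T2 <- rigidTransform(translation = rnorm(3), axis = rnorm(3),
                             angle = rnorm(1, 0, 30), pivot = rnorm(3))
        seqApplied <- applyTransform(m1, T2, toy$partition, "body2")
        composed <- applyTransform(toy$model, composeTransforms(T2, T),
                                   toy$partition, "body2")
        expect_lt(max(abs(coords(seqApplied) - coords(composed))), 1e-8)
    }
    expect_error(applyTransform(toy$model, identityTransform(),
                                toy$partition, "nope"), "unknown rigid body")
})

test_that("identity and pure-translation transforms behave analytically", {
    toy <- makeToyModel("helix", nRes = 3)
    m <- toy$model
    expect_identical(coords(applyTransform(m, identityTransform())), coords(m))
    mt <- applyTransform(m, rigidTransform(translation = c(3, 4, 0)))
    expect_equal(modelRMSD(m, mt), 5)
    # 90-degree rotation about the centroid keeps the centroid and radii
    cen <- colMeans(coords(m))
    mr <- applyTransform(m, rigidTransform(axis = c(0, 0, 1), angle = 90,
                                           pivot = cen))
    expect_lt(max(abs(colMeans(coords(mr)) - cen)), 1e-9)
    r0 <- sqrt(rowSums(sweep(coords(m), 2, cen)^2))
    r1 <- sqrt(rowSums(sweep(coords(mr), 2, cen)^2))
    expect_lt(max(abs(r0 - r1)), 1e-9)
})

test_that("rmsd matches the brute-force oracle and errors on shape mismatch", {
    set.seed(3)
    toy <- makeToyModel("helix", nRes = 2)
    m <- toy$model
    xb <- coords(m) + matrix(rnorm(nAtoms(m) * 3), ncol = 3)
    mb <- applyTransform(m, identityTransform())
    coords(mb) <- xb
    expect_equal(modelRMSD(m, mb), rmsdOracle(coords(m), xb),
                 tolerance = 1e-12)
    expect_equal(modelRMSD(m, m), 0)
    # bio3d::rmsd rounds to 3 decimals; cross-check at that precision
    expect_equal(modelRMSD(m, mb),
                 bio3d::rmsd(as.numeric(t(coords(m))), as.numeric(t(xb)),
                             fit = FALSE),
                 tolerance = 1e-3)
    small <- makeToyModel("helix", nRes = 1)$model
    expect_error(modelRMSD(m, small), "mismatch")
})

test_that("partition audit: bodies plus fixed set cover all atoms exactly", {
    toy <- makeToyModel("dumbbell", nRes = 6)
    p <- rigidBodyPartition(toy$model, data.frame(
        body = c("b1", "b2"), chain = c("A", "B"), first = c(1, 2),
        last = c(6, 5)))
    expect_equal(sum(lengths(bodies(p))) + length(fixedAtoms(p)),
                 nAtoms(toy$model))
    expect_length(fixedAtoms(p), 10)  # chain B residues 1 and 6
    expect_error(rigidBodyPartition(toy$model, data.frame(
        body = "bX", chain = "C", first = 1, last = 6)), "no atoms")
    expect_error(rigidBodyPartition(toy$model, data.frame(
        body = c("b1", "b2"), chain = "A", first = c(1, 3), last = c(4, 6))),
        "overlap")
    # file round-trip
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("# bodies", "b1 A 1 6", "b2 B 2 5"), f)
    p2 <- readRigidBodies(toy$model, f)
    expect_identical(bodies(p2), bodies(p))
})
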