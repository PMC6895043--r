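# The fitting objective: 12-6 clash term, total energy, and the cached
# incremental evaluator.

twoAtomModel <- function(d, eps = c(0.1, 0.4), vdw = c(1.7, 1.7)) {
    atoms <- data.frame(serial = 1:2, name = "CA", element = "C",
                        resname = "ALA", chain = c("A", "B"), resseq = 1L,
                        insert = "", occ = 1, bfac = 0)
    m <- new("AtomicModel", atoms = atoms,
             xyz = matrix(c(0, 0, 0, d, 0, 0), 2, byrow = TRUE),
             vdw = vdw, eps = eps)
    p <- rigidBodyPartition(m, data.frame(body = c("b1", "b2"),
                                          chain = c("A", "B"),
                                          first = 1, last = 1))
    list(model = m, partition = p)
}

test_that("the 12-6 clash term has its analytic minimum and zero crossing", {
    rij <- 1.7 + 1.7
    eij <- sqrt(0.1 * 0.4)   # 0.2 by the combination rule
    atMin <- twoAtomModel(rij)
    expect_equal(clashEnergy(atMin$model, atMin$partition, cutoff = 8),
                 2 * (-eij), tolerance = 1e-12)   # ordered-pair convention
    expect_equal(clashEnergy(atMin$model, atMin$partition, cutoff = 8,
                             orderedPairs = FALSE), -eij, tolerance = 1e-12)
    atZero <- twoAtomModel(2^(-1/6) * rij)
    expect_equal(clashEnergy(atZero$model, atZero$partition, cutoff = 8), 0,
                 tolerance = 1e-12)
    beyond <- twoAtomModel(8.5)
    expect_equal(clashEnergy(beyond$model, beyond$partition, cutoff = 8), 0)
    atOrigin <- twoAtomModel(0)
    expect_error(clashEnergy(atOrigin$model, atOrigin$partition, cutoff = 8),
                 "coincident")
})

test_that("clash energy matches the O(N^2) double-loop oracle", {
    set.seed(13)
    for (rep in 1:10) {
        n <- 20
        xyz <- matrix(runif(n * 3, 0, 10), n)
        eps <- runif(n, 0.05, 0.5)
        vdw <- runif(n, 1.2, 2.1)
        group <- rep(1:2, each = n / 2)
        atoms <- data.frame(serial = 1:n, name = "CA", element = "C",
                            resname = "ALA", chain = c("A", "B")[group],
                            resseq = rep(1:(n / 2), 2), insert = "", occ = 1,
                            bfac = 0)
        m <- new("AtomicModel", atoms = atoms, xyz = xyz, vdw = vdw,
                 eps = eps)
        p <- rigidBodyPartition(m, data.frame(body = c("b1", "b2"),
                                              chain = c("A", "B"),
                                              first = 1, last = n / 2))
        got <- clashEnergy(m, p, cutoff = 8)
        want <- clashOracle(xyz, eps, vdw, group, cutoff = 8)
        expect_equal(got, want, tolerance = 1e-10)
    }
})

test_that("clash energy is invariant under a common rigid motion", {
    toy <- toyFixture(nRes = 5, offset = 9)
    e0 <- clashEnergy(toy$model, toy$partition, cutoff = 12)
    T <- rigidTransform(translation = c(3, -2, 5), axis = c(1, 2, 3),
                        angle = 71, pivot = c(4, 4, 4))
    moved <- applyTransform(toy$model, T)
    expect_equal(clashEnergy(moved, toy$partition, cutoff = 12), e0,
                 tolerance = 1e-9)
    expect_gt(abs(e0), 0)
})

test_that("self-simulated single-body energy is zero with default weights", {
    toy <- makeToyModel("helix", nRes = 6)
    map <- makeGroundTruthMap(toy$model, resolution = 6, voxel = 2)
    e <- totalEnergy(toy$model, map, partition = toy$partition,
                     resolution = 6)
    expect_equal(e@cc, 1, tolerance = 1e-12)
    expect_equal(e@total, 0, tolerance = 1e-10)
    expect_equal(e@clashTerm, 0)
    expect_equal(e@total, e@ccTerm + e@clashTerm, tolerance = 1e-12)
})

test_that("weights act linearly on the two terms", {
    toy <- toyFixture(nRes = 5, offset = 9)
    map <- makeGroundTruthMap(toy$model, resolution = 6, voxel = 2)
    clash <- clashEnergy(toy$model, toy$partition, cutoff = 8)
    eClashOnly <- totalEnergy(toy$model, map, partition = toy$partition,
                              weights = energyWeights(0, 1), resolution = 6)
    expect_equal(eClashOnly@total, clash, tolerance = 1e-12)
    eCCOnly <- totalEnergy(toy$model, map, partition = toy$partition,
                           weights = energyWeights(100, 0), resolution = 6)
    expect_equal(eCCOnly@total, 100 * (1 - eCCOnly@cc), tolerance = 1e-12)
})

test_that("a model displaced into empty density loses its correlation", {
    toy <- makeToyModel("helix", nRes = 6)
    map <- makeGroundTruthMap(toy$model, resolution = 6, voxel = 2, pad = 10)
    shifted <- applyTransform(toy$model,
                              rigidTransform(translation = c(10, 0, 0)))
    e <- totalEnergy(shifted, map, partition = toy$partition, resolution = 6)
    ccRef <- ccOracle(as.numeric(gridValues(map)),
                      as.numeric(gridValues(simulateDensity(
                          shifted, template = map, resolution = 6))))
    expect_equal(e@cc, ccRef, tolerance = 1e-10)
    expect_equal(e@ccTerm, 100 * (1 - ccRef), tolerance = 1e-8)
    expect_equal(e@clashTerm, 0)
    expect_lt(e@cc, 0.5)
    expect_gt(e@total, totalEnergy(toy$model, map,
                                   partition = toy$partition,
                                   resolution = 6)@total)
})

test_that("incremental evaluation equals full recomputation", {
    toy <- toyFixture(nRes = 6)
    map <- makeGroundTruthMap(toy$model, resolution = 6, voxel = 2, pad = 8)
    st <- energyState(toy$model, map, toy$partition, resolution = 6)
    e0 <- stateEnergy(st)
    full0 <- totalEnergy(toy$model, map, partition = toy$partition,
                         resolution = 6)
    expect_equal(e0@total, full0@total, tolerance = 1e-10)
    # identity move: exactly zero change
    pId <- deltaEnergy(st, "body2", identityTransform())
    expect_equal(pId$dE, 0, tolerance = 1e-12)
    # random moves vs full recomputation, committing as we go
    set.seed(23)
    model <- toy$model
    for (rep in 1:40) {
        body <- sample(names(bodies(toy$partition)), 1)
        idx <- bodies(toy$partition)[[body]]
        piv <- colMeans(coords(model)[idx, , drop = FALSE])
        T <- rigidTransform(translation = rnorm(3, 0, 1), axis = rnorm(3),
                            angle = rnorm(1, 0, 10), pivot = piv)
        p <- deltaEnergy(st, body, T)
        after <- applyTransform(model, T, toy$partition, body)
        eAfter <- totalEnergy(after, map, partition = toy$partition,
                              resolution = 6)
        eBefore <- totalEnergy(model, map, partition = toy$partition,
                               resolution = 6)
        expect_equal(p$dE, eAfter@total - eBefore@total, tolerance = 1e-8)
        # move then inverse move cancels
        commitMove(st, p)
        pBack <- deltaEnergy(st, body, invertTransform(T))
        expect_equal(p$dE + pBack$dE, 0, tolerance = 1e-8)
        commitMove(st, pBack)
        expect_equal(stateEnergy(st)@total, eBefore@total, tolerance = 1e-8)
        # leave the state moved for the next iteration half the time
        if (rep %% 2 == 0) {
            p2 <- deltaEnergy(st, body, T)
            commitMove(st, p2)
            model <- after
        }
    }
})

test_that("stale proposals are rejected and resync clears drift", {
    toy <- toyFixture(nRes = 4)
    map <- makeGroundTruthMap(toy$model, resolution = 6, voxel = 2)
    st <- energyState(toy$model, map, toy$partition, resolution = 6)
    p1 <- deltaEnergy(st, "body1",
                      rigidTransform(translation = c(0.5, 0, 0)))
    commitMove(st, p1)
    expect_error(commitMove(st, p1), "stale")
    eBefore <- stateEnergy(st)@total
    resyncState(st)
    expect_equal(stateEnergy(st)@total, eBefore, tolerance = 1e-10)
    expect_error(deltaEnergy(st, "nope", identityTransform()),
                 "unknown rigid body")
})

test_that("missing nonbonded parameters are caught before scoring", {
    toy <- toyFixture(nRes = 3)
    bare <- new("AtomicModel", atoms = atoms(toy$model),
                xyz = coords(toy$model),
                vdw = rep(NA_real_, nAtoms(toy$model)),
                eps = rep(NA_real_, nAtoms(toy$model)))
    expect_error(clashEnergy(bare, toy$partition), "parameters missing")
})
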