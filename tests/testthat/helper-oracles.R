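# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the package kernels.

# Pearson correlation by explicit accumulation over a vector of voxels.
ccOracle <- function(x, y) {
    n <- length(x)
    sx <- 0; sy <- 0
    for (i in seq_len(n)) { sx <- sx + x[i]; sy <- sy + y[i] }
    mx <- sx / n; my <- sy / n
    sxy <- 0; sxx <- 0; syy <- 0
    for (i in seq_len(n)) {
        dx <- x[i] - mx; dy <- y[i] - my
        sxy <- sxy + dx * dy
        sxx <- sxx + dx * dx
        syy <- syy + dy * dy
    }
    sxy / (sqrt(sxx) * sqrt(syy))
}

# O(N^2) double-loop 12-6 inter-group sum, ordered-pair convention.
clashOracle <- function(xyz, eps, vdw, group, cutoff) {
    E <- 0
    n <- nrow(xyz)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j || group[i] == group[j]) next
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d > cutoff) next
        rij <- vdw[i] + vdw[j]
        eij <- sqrt(eps[i] * eps[j])
        E <- E + eij * ((rij / d)^12 - 2 * (rij / d)^6)
    }
    E
}

# Per-atom-pair RMSD by direct summation.
rmsdOracle <- function(xa, xb) {
    s <- 0
    for (i in seq_len(nrow(xa)))
        s <- s + sum((xa[i, ] - xb[i, ])^2)
    sqrt(s / nrow(xa))
}

# Random density grid on a given geometry.
randomGrid <- function(dim, voxel = 1.5, origin = c(0, 0, 0)) {
    densityGrid(array(rnorm(prod(dim)), dim = dim), voxel, origin)
}

# Small dumbbell fixture shared across tests.
toyFixture <- function(nRes = 10, offset = 20) makeToyModel("dumbbell", nRes, offset)
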