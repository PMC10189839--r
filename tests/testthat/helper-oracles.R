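# Independent oracles and small fixture builders used across tests.

# Horn's quaternion-eigenvector RMSD: closed-form optimal superposition
# RMSD, independent of the package's SVD-based Kabsch code path.
quaternionRmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Pc, Qc)
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]),
    nrow = 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P))
}

randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

# a tiny all-atom ensemble: two residues at controllable separation,
# used by interaction-energy and monitor-rule tests; atom 1 belongs to
# the "protein", atom 2 to the "ligand"
twoAtomEnsemble <- function(distances) {
  atoms <- data.frame(
    eleno = 1:2, elety = c("P1", "L1"), resid = c("PRO", "LIG"),
    chain = "A", resno = 1:2, element = c("C", "C"),
    stringsAsFactors = FALSE)
  xyz <- t(vapply(distances,
                  function(d) c(0, 0, 0, d, 0, 0), numeric(6)))
  trajectoryEnsemble(xyz, atoms, "toy", "GDP")
}

twoAtomParams <- function(qP = 0, qL = 0, rminHalfP = 1, rminHalfL = 1,
                          epsP = 0, epsL = 0) {
  nonbondedParams(c("P1", "L1"), c("PRO", "LIG"),
                  charge = c(qP, qL), rminHalf = c(rminHalfP, rminHalfL),
                  epsilon = c(epsP, epsL))
}

# adjusted Rand index (mclust's implementation serves as the
# label-permutation oracle for cluster recovery)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# mean silhouette width of a labelled 2D embedding (Euclidean)
meanSilhouette <- function(xy, labels) {
  D <- as.matrix(dist(xy))
  s <- vapply(seq_len(nrow(xy)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(nrow(xy)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# SD of the empirical state-II fraction of a stationary two-state
# Markov chain with P(II) = p and mean state-II dwell `d`:
# lag-1 autocorrelation rho = 1 - 1/(d(1-p)), large-n variance
# p(1-p)/n * (1+rho)/(1-rho) = p(1-p)(2d(1-p) - 1)/n; reduces to the
# binomial variance when the chain is memoryless
chainFractionSd <- function(p, d, n) {
  sqrt(p * (1 - p) * max(2 * d * (1 - p) - 1, 1) / n)
}
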