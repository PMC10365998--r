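# side-chain ring atom sets used for pi-pi stacking assessment;
# Trp uses the full 9-atom bicyclic indole system, His its 5-ring
.RING_ATOMS <- list(
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

.centroid <- function(m) colMeans(m)

# unit normal of the least-squares plane through >= 3 points
.lsPlaneNormal <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  s <- svd(m)
  n <- s$v[, 3]
  n / sqrt(sum(n^2))
}

# interplanar angle between two plane normals, folded into [0, 90] degrees
.interplanarAngle <- function(n1, n2) {
  ct <- abs(sum(n1 * n2)) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  acos(min(1, max(-1, ct))) * 180 / pi
}

# uniform random proper rotation (QR of a Gaussian matrix, det fixed to +1);
# consumes the current RNG stream
.randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid transform to the xyz columns of an atom table
.transformAtoms <- function(atoms, R, t) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + t[1]
  atoms$y <- xyz[, 2] + t[2]
  atoms$z <- xyz[, 3] + t[3]
  atoms
}

# coordinates of one residue's named atoms as a matrix (rows in `names` order),
# NULL if any is missing
.residueAtomCoords <- function(atoms, chain, resno, insert, names) {
  sel <- atoms$chain == chain & atoms$resno == resno & atoms$insert == insert &
    atoms$elety %in% names
  sub <- atoms[sel, ]
  if (!all(names %in% sub$elety)) return(NULL)
  sub <- sub[match(names, sub$elety), ]
  as.matrix(sub[, c("x", "y", "z")])
}
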