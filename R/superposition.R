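#' Pair C-alpha atoms between two structures
#'
#' Matches C-alpha atoms of polymer residues by identical
#' (chain, residue number, insertion code, residue type); unmatched
#' residues are dropped.  This reproduces the plain author-numbering
#' correspondence used when comparing ligand-bound and free forms of the
#' same construct.
#'
#' @param a,b two [StructureModel-class] objects.
#' @return list with elements \code{xa}, \code{xb} (n x 3 coordinate
#'   matrices in matched order) and \code{keys} (residue identifiers).
#' @export
pairCalpha <- function(a, b) {
  ca <- function(m) {
    at <- m@atoms
    at <- at[at$category == "polymer" & at$elety == "CA", ]
    key <- paste(at$chain, at$resno, at$insert, at$resid, sep = "\r")
    at <- at[!duplicated(key), ]
    rownames(at) <- NULL
    at
  }
  aa <- ca(a); bb <- ca(b)
  if (nrow(aa) == 0 || nrow(bb) == 0)
    stop("both models must contain polymer C-alpha atoms")
  ka <- paste(aa$chain, aa$resno, aa$insert, aa$resid, sep = "\r")
  kb <- paste(bb$chain, bb$resno, bb$insert, bb$resid, sep = "\r")
  common <- intersect(ka, kb)
  if (length(common) < 3)
    stop("insufficient correspondence: only ", length(common),
         " matched C-alpha atoms (>= 3 required)")
  ia <- match(common, ka); ib <- match(common, kb)
  list(xa = as.matrix(aa[ia, c("x", "y", "z")]),
       xb = as.matrix(bb[ib, c("x", "y", "z")]),
       keys = gsub("\r", " ", common))
}

#' Kabsch least-squares superposition
#'
#' Computes the proper rotation (reflections excluded by correcting the
#' sign of the smallest singular vector) and translation minimizing the
#' sum of squared distances mapping the mobile coordinates \code{xb} onto
#' the reference \code{xa}, and the RMSD after the transform.
#'
#' @param pairs either the list returned by [pairCalpha()] or an n x 3
#'   reference matrix (then \code{xb} must be given).
#' @param xb optional n x 3 mobile coordinate matrix.
#' @return a [SuperpositionResult-class]; \code{rotation \%*\% b +
#'   translation} maps mobile points onto the reference frame.
#' @export
kabschSuperpose <- function(pairs, xb = NULL) {
  if (is.list(pairs) && !is.null(pairs$xa)) {
    xa <- pairs$xa; xb <- pairs$xb
  } else xa <- as.matrix(pairs)
  xa <- unname(as.matrix(xa)); xb <- unname(as.matrix(xb))
  stopifnot(ncol(xa) == 3, ncol(xb) == 3, nrow(xa) == nrow(xb))
  n <- nrow(xa)
  if (n < 3) stop("at least 3 point pairs required")
  ca <- colMeans(xa); cb <- colMeans(xb)
  A <- sweep(xa, 2, ca); B <- sweep(xb, 2, cb)
  # degenerate (collinear) sets have no unique rotation
  if (svd(A)$d[2] < 1e-8 * max(1, svd(A)$d[1]))
    stop("degenerate geometry: reference points are collinear")
  H <- crossprod(B, A)            # 3x3 covariance, mobile vs reference
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(ca - R %*% cb)
  fit <- sweep(xb %*% t(R), 2, tr, "+")
  rms <- sqrt(mean(rowSums((fit - xa)^2)))
  new("SuperpositionResult", rotation = R, translation = tr,
      nPairs = as.integer(n), rmsd = rms)
}

#' Superpose two structures on their matched C-alpha atoms
#'
#' Convenience wrapper: [pairCalpha()] then [kabschSuperpose()].
#'
#' @inheritParams pairCalpha
#' @return a [SuperpositionResult-class].
#' @examples
#' s <- makeBindingSiteStructure(siteGeometry(seed = 3))$model
#' rmsd(superposeCalpha(s, s))   # 0
#' @export
superposeCalpha <- function(a, b) kabschSuperpose(pairCalpha(a, b))

#' Centroid distance between a ligand and the nearest cofactor
#'
#' Distance between the heavy-atom centroid of \code{ligand} and the
#' heavy-atom centroid of the nearest residue with component code
#' \code{otherCode} (e.g. \code{"TPP"}, operationalizing "distance to
#' the catalytic site" as distance to the thiamine-pyrophosphate
#' cofactor).
#'
#' @param model a [StructureModel-class].
#' @param ligand a [LigandInstance-class] contained in \code{model}.
#' @param otherCode component code of the second ligand/cofactor.
#' @return distance in Angstrom.
#' @export
siteDistance <- function(model, ligand, otherCode) {
  at <- model@atoms
  other <- at[at$category == "ligand" & at$resid == otherCode, ]
  if (nrow(other) == 0)
    stop("no residue with component code '", otherCode, "' in ",
         model@entryId)
  cen <- .centroid(as.matrix(ligand@atoms[, c("x", "y", "z")]))
  key <- unique(other[, c("chain", "resno", "insert")])
  dmin <- Inf
  for (i in seq_len(nrow(key))) {
    oa <- other[other$chain == key$chain[i] & other$resno == key$resno[i] &
                  other$insert == key$insert[i], ]
    d <- .dist3(cen, .centroid(as.matrix(oa[, c("x", "y", "z")])))
    dmin <- min(dmin, d)
  }
  dmin
}
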