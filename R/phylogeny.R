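#' Pairwise p-distance matrix over aligned sequences
#'
#' \eqn{d(i,j)} = mismatched columns divided by columns where neither
#' sequence has a gap.  Sequences must be pre-aligned (equal length);
#' gap-free families from the synthetic generator are trivially aligned.
#'
#' @param seqs named character vector or \code{AAStringSet} of aligned
#'   sequences (>= 2, equal lengths).
#' @return symmetric numeric matrix with zero diagonal, labelled by
#'   sequence names.
#' @export
pDistanceMatrix <- function(seqs) {
  if (inherits(seqs, "XStringSet")) seqs <- as.character(seqs)
  n <- length(seqs)
  if (n < 2) stop("at least two sequences required")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%04d", seq_len(n))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("alignment required: sequences have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  gap <- m == "-" | m == "."
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- !gap[i, ] & !gap[j, ]
    if (!any(comp))
      stop("no comparable (gap-free) columns between ", names(seqs)[i],
           " and ", names(seqs)[j])
    d <- sum(m[i, comp] != m[j, comp]) / sum(comp)
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion \eqn{Q_{ij} = (m-2) d_{ij} - r_i - r_j} is joined, with
#' branch lengths from the standard formulas.  Ties are broken by the
#' lowest (row, column) index pair, so output is deterministic.
#' Negative branch lengths are clamped to zero with the deficit
#' transferred to the sibling branch (preserving the joined pair's path
#' length).  On an additive matrix the tree's leaf-to-leaf path lengths
#' reproduce the input distances exactly.
#'
#' @param D symmetric distance matrix (>= 3 taxa, zero diagonal, no NA).
#' @param labels taxon labels; defaults to \code{rownames(D)}.
#' @return a [DistanceMatrixTree-class] holding the matrix, the unrooted
#'   \code{phylo} tree and its Newick string.
#' @examples
#' D <- matrix(c(0,2,4,4, 2,0,4,4, 4,4,0,2, 4,4,2,0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' neighborJoining(D)
#' @export
neighborJoining <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n))
  if (n < 3) stop("at least 3 taxa required")
  if (any(is.na(D)) || any(!is.finite(D)))
    stop("invalid matrix: NA or non-finite entries")
  if (max(abs(D - t(D))) > 1e-9) stop("invalid matrix: not symmetric")
  # each active node carries its newick fragment
  frag <- as.list(labels)
  Dm <- D
  bl <- function(x) sprintf("%.10g", max(0, x))
  while (nrow(Dm) > 3) {
    m <- nrow(Dm)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    i <- idx[1]; j <- idx[2]
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newFrag <- paste0("(", frag[[i]], ":", bl(li), ",",
                      frag[[j]], ":", bl(lj), ")")
    ks <- setdiff(seq_len(m), c(i, j))
    dnew <- (Dm[i, ks] + Dm[j, ks] - Dm[i, j]) / 2
    Dm <- rbind(cbind(Dm[ks, ks, drop = FALSE], pmax(dnew, 0)),
                c(pmax(dnew, 0), 0))
    frag <- c(frag[ks], list(newFrag))
  }
  # terminal 3-taxon star: closed-form branch lengths
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  nwk <- paste0("(", frag[[1]], ":", bl(l1), ",", frag[[2]], ":", bl(l2),
                ",", frag[[3]], ":", bl(l3), ");")
  tree <- ape::read.tree(text = nwk)
  new("DistanceMatrixTree", labels = labels, D = D, tree = tree,
      newick = nwk)
}
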