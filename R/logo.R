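.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Position frequency matrix around the motif anchors
#'
#' Builds residue counts for the alignment columns spanned by each motif
#' anchor plus \code{flank} residues on either side (overlapping windows
#' are merged), indexed by offset from the P anchor.  Windows truncated
#' at sequence ends (and non-standard letters) contribute gaps.
#'
#' @param seqs character vector (or \code{AAStringSet}) of unaligned
#'   sequences.
#' @param starts 1-based P-anchor position of the motif match in each
#'   sequence (same length as \code{seqs}).
#' @param spec the [MotifSpec-class] the matches came from.
#' @param flank residues on each side of each anchor (default 3).
#' @return a [PositionFrequencyMatrix-class].
#' @seealso [informationContent()]
#' @export
anchorWindows <- function(seqs, starts, spec = motifSpec(), flank = 3L) {
  if (inherits(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (length(seqs) == 0) stop("empty match list: no sequences to tally")
  stopifnot(length(starts) == length(seqs))
  offsets <- sort(unique(unlist(lapply(spec@offsets, function(o)
    (o - flank):(o + flank)))))
  K <- length(offsets)
  counts <- matrix(0L, nrow = 20L, ncol = K,
                   dimnames = list(.AA20, as.character(offsets)))
  gaps <- integer(K)
  for (i in seq_along(seqs)) {
    chars <- strsplit(toupper(seqs[[i]]), "")[[1]]
    pos <- starts[i] + offsets
    inside <- pos >= 1L & pos <= length(chars)
    letters <- rep(NA_character_, K)
    letters[inside] <- chars[pos[inside]]
    hit <- match(letters, .AA20)
    gap <- is.na(hit)
    gaps <- gaps + gap
    ok <- which(!gap)
    for (j in ok) counts[hit[j], j] <- counts[hit[j], j] + 1L
  }
  new("PositionFrequencyMatrix", counts = counts, gaps = gaps,
      offsets = as.integer(offsets), nSequences = length(seqs))
}

#' Per-column information content in bits
#'
#' \eqn{IC = \log_2 20 - H} where \eqn{H} is the Shannon entropy of the
#' column's residue frequencies against a uniform background; gaps are
#' excluded from the frequencies and no small-sample correction is
#' applied.  A perfectly conserved column scores \eqn{\log_2 20 \approx
#' 4.3219} bits, a uniform column 0 bits.  All-gap columns are reported
#' as \code{NA}.
#'
#' @param pfm a [PositionFrequencyMatrix-class].
#' @return named numeric vector of bits, one per column, in
#'   \eqn{[0, \log_2 20]}.
#' @export
informationContent <- function(pfm) {
  counts <- pfm@counts
  tot <- colSums(counts)
  ic <- vapply(seq_len(ncol(counts)), function(j) {
    if (tot[j] == 0) return(NA_real_)
    f <- counts[, j] / tot[j]
    f <- f[f > 0]
    h <- -sum(f * log2(f))
    max(0, log2(20) - h)
  }, 0)
  names(ic) <- colnames(counts)
  ic
}
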