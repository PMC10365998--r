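#' Construct the eight-anchor ATP-regulatory motif specification
#'
#' Anchors at offsets 0 (P), 1 (W), 4 (H), 8 (Y), 9 (R), 17 (H), 19 (R)
#' and 51 (R) from the leading proline, i.e. the motif
#' P W x(2) H x(3) Y R x(7) H x R x(31) R spanning 52 residues.  In the
#' reference phosphoketolase numbering the anchors fall on P702, W703,
#' H706, Y710, R711, H719, R721 and R753.
#'
#' @param fungalVariant admit lysine at the offset-9 arginine (the
#'   residue that salt-bridges the reciprocal ATP's gamma-phosphate),
#'   as in fungal homologs.
#' @param spacerSlack non-negative integer: extra residues each of the
#'   seven inter-anchor spacers may absorb (0 = exact spacing).
#' @return a [MotifSpec-class].
#' @export
motifSpec <- function(fungalVariant = FALSE, spacerSlack = 0L) {
  new("MotifSpec",
      offsets = c(0L, 1L, 4L, 8L, 9L, 17L, 19L, 51L),
      allowed = list("P", "W", "H", "Y",
                     if (fungalVariant) c("R", "K") else "R",
                     "H", "R", "R"),
      fungalVariant = fungalVariant, spacerSlack = as.integer(spacerSlack))
}

#' Scan a protein sequence for the ATP-regulatory motif
#'
#' Reports every start position at which all eight anchors match their
#' allowed residue sets at the specified offsets.  Input is uppercased
#' and \code{*} terminators are stripped; \code{X} never matches an
#' anchor.  Coordinates are 1-based.  With \code{spacerSlack > 0} each
#' inter-anchor spacer may stretch by up to that many extra residues;
#' the leftmost (smallest-stretch) anchor placement is reported per
#' start.
#'
#' @param seq amino-acid string (or an \code{AAString}).
#' @param spec a [MotifSpec-class].
#' @return data.frame with one row per match: \code{start} (position of
#'   the P anchor), \code{usedFungalVariant}, and list-columns
#'   \code{anchorPositions} / \code{anchorResidues} (length-8 each).
#' @examples
#' seq <- plantMotif(strrep("A", 800), 702)
#' scanSequence(seq, motifSpec())
#' @export
scanSequence <- function(seq, spec = motifSpec()) {
  seq <- toupper(gsub("\\*", "", as.character(seq)))
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  empty <- data.frame(start = integer(0), usedFungalVariant = logical(0))
  empty$anchorPositions <- list()
  empty$anchorResidues <- list()
  span <- spec@offsets[length(spec@offsets)]
  if (L < span + 1L) return(empty)
  if (spec@spacerSlack == 0L) {
    # vectorized fixed-offset intersection over candidate starts
    ok <- rep(TRUE, L - span)
    for (k in seq_along(spec@offsets)) {
      pos <- seq_len(L - span) + spec@offsets[k]
      ok <- ok & chars[pos] %in% spec@allowed[[k]]
    }
    starts <- which(ok)
    placements <- lapply(starts, function(s) s + spec@offsets)
  } else {
    starts <- integer(0); placements <- list()
    for (s in seq_len(L - span)) {
      pl <- .slackPlace(chars, s, spec)
      if (!is.null(pl)) {
        starts <- c(starts, s)
        placements[[length(placements) + 1L]] <- pl
      }
    }
  }
  if (length(starts) == 0) return(empty)
  out <- data.frame(start = starts,
                    usedFungalVariant = vapply(placements, function(p)
                      spec@fungalVariant && chars[p[5]] == "K", TRUE))
  out$anchorPositions <- placements
  out$anchorResidues <- lapply(placements, function(p) chars[p])
  out
}

# depth-first anchor placement with per-gap slack; returns the leftmost
# placement (smallest stretches, earlier gaps preferred) or NULL
.slackPlace <- function(chars, start, spec) {
  offs <- spec@offsets
  allowed <- spec@allowed
  slack <- spec@spacerSlack
  L <- length(chars)
  rec <- function(k, pos) {
    if (pos > L || !chars[pos] %in% allowed[[k]]) return(NULL)
    if (k == length(offs)) return(pos)
    gap <- offs[k + 1L] - offs[k]
    for (extra in 0:slack) {
      res <- rec(k + 1L, pos + gap + extra)
      if (!is.null(res)) return(c(pos, res))
    }
    NULL
  }
  rec(1L, start)
}

#' Global percent identity between two protein sequences
#'
#' Needleman-Wunsch global alignment with unit match score, zero
#' mismatch score and affine gap penalties (via
#' \code{Biostrings::pairwiseAlignment}); identity is the fraction of
#' identical columns over all aligned columns including internal gap
#' columns, times 100.
#'
#' @param a,b amino-acid strings (non-empty).
#' @param gapOpen,gapExtend affine gap penalties (defaults 10 / 0.5).
#' @return identity percentage in \eqn{[0, 100]}.
#' @export
percentIdentity <- function(a, b, gapOpen = 10, gapExtend = 0.5) {
  a <- toupper(gsub("\\*", "", as.character(a)))
  b <- toupper(gsub("\\*", "", as.character(b)))
  if (!nzchar(a) || !nzchar(b))
    stop("percent identity undefined for an empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = .unitAAMatrix(), gapOpening = gapOpen,
    gapExtension = gapExtend)
  Biostrings::pid(aln, type = "PID1")
}

# unit-match/zero-mismatch substitution matrix over the AA alphabet
.unitAAMatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      letters <- Biostrings::AA_ALPHABET
      m <- diag(1, length(letters))
      dimnames(m) <- list(letters, letters)
      cache <<- m
    }
    cache
  }
})

#' Survey a sequence family for the ATP-regulatory motif
#'
#' Filters sequences by global percent identity to a reference (the
#' local, deterministic stand-in for a similarity search) and scans each
#' passing sequence for the motif.
#'
#' @param seqs named character vector or \code{Biostrings::AAStringSet}.
#' @param reference reference amino-acid sequence (warned about if it
#'   does not itself contain the motif).
#' @param minIdentity identity threshold, percent (default 60).
#' @param spec a [MotifSpec-class].
#' @return list with \code{table} (per-sequence: id, identity,
#'   passIdentity, motifPresent, matchStart), \code{nPassIdentity},
#'   \code{nMotif} and \code{prevalence} (motif-positive fraction among
#'   identity-passing sequences).
#' @export
motifSurvey <- function(seqs, reference, minIdentity = 60,
                        spec = motifSpec()) {
  if (inherits(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  reference <- as.character(reference)
  if (nrow(scanSequence(reference, spec)) == 0)
    warning("reference sequence does not contain the motif")
  n <- length(seqs)
  identity <- numeric(n); present <- logical(n); start <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    identity[i] <- tryCatch(percentIdentity(seqs[[i]], reference),
                            error = function(e) NA_real_)
    if (!is.na(identity[i]) && identity[i] >= minIdentity) {
      m <- scanSequence(seqs[[i]], spec)
      present[i] <- nrow(m) > 0
      if (present[i]) start[i] <- m$start[1]
    }
  }
  pass <- !is.na(identity) & identity >= minIdentity
  tab <- data.frame(id = names(seqs), identity = identity,
                    passIdentity = pass, motifPresent = present,
                    matchStart = start, stringsAsFactors = FALSE)
  nMotif <- sum(present[pass])
  list(table = tab, nPassIdentity = sum(pass), nMotif = nMotif,
       prevalence = if (sum(pass) > 0) nMotif / sum(pass) else NA_real_)
}
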