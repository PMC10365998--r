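#' @import methods
NULL

# canonical atom-table columns shared by all structure code
.ATOM_COLS <- c("rectype", "chain", "resno", "insert", "resid", "category",
                "elety", "elesy", "alt", "occ", "x", "y", "z")

# the nine purine ring atoms of an adenine nucleotide, PDB naming
.PURINE_ATOMS <- c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6")

# nucleotide component codes: ATP plus the five non-hydrolyzable analogs,
# and the diphosphate/monophosphate forms admitted in criterion-1-only mode
.TRIPHOSPHATE_CODES <- c("ATP", "ANP", "ACP", "APC", "ZAN", "AGS")
.NUCLEOTIDE_CODES   <- c(.TRIPHOSPHATE_CODES, "ADP", "AMP")

.TIER_LEVELS <- c("none", "T1_pair_contact", "T2_cross_subunit",
                  "T3_dual_stacking", "T4_full")

#' StructureModel: a parsed atomic structure
#'
#' Uniform in-memory representation of one coordinate model of a PDB or
#' mmCIF file: a flat atom table annotated with residue category
#' (polymer / ligand / water).  Only the first coordinate model of
#' multi-model files is represented and hydrogens are excluded; altlocs
#' are collapsed to the highest-occupancy conformer.
#'
#' @slot entryId single structure identifier (file basename or data block).
#' @slot atoms data.frame with columns rectype, chain, resno, insert,
#'   resid, category, elety (atom name), elesy (element), alt, occ, x, y, z.
#' @slot sourceFormat one of "pdb", "mmcif", "synthetic".
#' @export
setClass("StructureModel",
         representation(entryId = "character",
                        atoms = "data.frame",
                        sourceFormat = "character"))

setValidity("StructureModel", function(object) {
  msg <- NULL
  if (length(object@entryId) != 1L) msg <- c(msg, "entryId must be length 1")
  if (!all(.ATOM_COLS %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must contain columns:",
                        paste(setdiff(.ATOM_COLS, names(object@atoms)), collapse = ", ")))
  else {
    xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
    if (nrow(xyz) > 0 && !all(is.finite(xyz)))
      msg <- c(msg, "all coordinates must be finite")
    occ <- object@atoms$occ
    if (length(occ) > 0 && (any(occ < 0, na.rm = TRUE) || any(occ > 1, na.rm = TRUE)))
      msg <- c(msg, "occupancy must lie in [0, 1]")
    if (nrow(object@atoms) > 0 &&
        !all(object@atoms$category %in% c("polymer", "ligand", "water")))
      msg <- c(msg, "category must be polymer, ligand or water")
  }
  if (!object@sourceFormat %in% c("pdb", "mmcif", "synthetic"))
    msg <- c(msg, "sourceFormat must be 'pdb', 'mmcif' or 'synthetic'")
  if (is.null(msg)) TRUE else msg
})

#' LigandInstance: one adenine-nucleotide ligand residue
#'
#' One occurrence of a nucleotide component (ATP, ANP, ACP, APC, ZAN, AGS,
#' ADP or AMP) in a structure, with its purine ring atoms and the two
#' anchor atoms of the geometric screen resolved: adenine C5 and the
#' gamma-phosphate phosphorus PG.  PG is absent for ADP and AMP.
#'
#' @slot compId 3-letter component code.
#' @slot chainId chain identifier of the ligand residue.
#' @slot seqNum author residue number.
#' @slot insert insertion code ("" if none).
#' @slot atoms data.frame of the ligand's heavy atoms (atom-table columns).
#' @slot purineAtoms character vector of purine ring atom names present.
#' @slot c5 numeric xyz of atom C5, or length-0 if absent.
#' @slot pg numeric xyz of atom PG, or length-0 if absent.
#' @export
setClass("LigandInstance",
         representation(compId = "character", chainId = "character",
                        seqNum = "integer", insert = "character",
                        atoms = "data.frame", purineAtoms = "character",
                        c5 = "numeric", pg = "numeric"))

setValidity("LigandInstance", function(object) {
  msg <- NULL
  if (!object@compId %in% .NUCLEOTIDE_CODES)
    msg <- c(msg, paste("unsupported component code:", object@compId))
  if (!length(object@c5) %in% c(0L, 3L)) msg <- c(msg, "c5 must be empty or xyz")
  if (!length(object@pg) %in% c(0L, 3L)) msg <- c(msg, "pg must be empty or xyz")
  if (object@compId %in% c("ADP", "AMP") && length(object@pg) == 3L)
    msg <- c(msg, "ADP/AMP carry no gamma-phosphate PG")
  if (is.null(msg)) TRUE else msg
})

#' ScreenCriteria: cutoffs and anchor atoms of the geometric screen
#'
#' The two distance criteria of the binding-mode screen (adenine C5 to
#' aromatic-residue CG; gamma-phosphate PG to arginine CZ; both default
#' 5 Angstrom, inclusive) plus the pi-pi stacking geometry thresholds
#' (ring-centroid distance and interplanar angle).
#'
#' @slot dAromatic C5-CG contact cutoff, Angstrom.
#' @slot dArg PG-CZ contact cutoff, Angstrom.
#' @slot aromaticSet residue codes treated as aromatic.
#' @slot aromaticAnchorAtom side-chain anchor atom name (CG).
#' @slot adenineAnchorAtom ligand anchor atom name (C5).
#' @slot gammaAtom gamma-phosphate atom name (PG).
#' @slot argAnchorAtom arginine anchor atom name (CZ).
#' @slot stackingCentroidMax max ring-centroid separation for stacking, Angstrom.
#' @slot stackingAngleMax max interplanar angle for stacking, degrees.
#' @export
setClass("ScreenCriteria",
         representation(dAromatic = "numeric", dArg = "numeric",
                        aromaticSet = "character",
                        aromaticAnchorAtom = "character",
                        adenineAnchorAtom = "character",
                        gammaAtom = "character", argAnchorAtom = "character",
                        stackingCentroidMax = "numeric",
                        stackingAngleMax = "numeric"))

setValidity("ScreenCriteria", function(object) {
  msg <- NULL
  for (s in c("dAromatic", "dArg", "stackingCentroidMax", "stackingAngleMax"))
    if (length(slot(object, s)) != 1L || slot(object, s) <= 0)
      msg <- c(msg, paste(s, "must be a single positive number"))
  if (length(object@aromaticSet) < 1L)
    msg <- c(msg, "aromaticSet must be non-empty")
  if (is.null(msg)) TRUE else msg
})

#' MotifSpec: the eight-anchor ATP-regulatory motif
#'
#' Positional specification of the phosphoketolase ATP-regulatory motif
#' P W x(2) H x(3) Y R x(7) H x R x(31) R: eight fixed-identity anchors at
#' offsets 0, 1, 4, 8, 9, 17, 19 and 51 from the leading proline.  With
#' \code{fungalVariant = TRUE} the arginine at offset 9 (the residue
#' contacting the reciprocal ATP's gamma-phosphate) may also be lysine,
#' as observed in fungal homologs.
#'
#' @slot offsets integer offsets of the anchors from the match start.
#' @slot allowed list of allowed residue sets, one per anchor.
#' @slot fungalVariant logical; lysine admitted at the offset-9 arginine.
#' @slot spacerSlack non-negative integer; extra residues each inter-anchor
#'   spacer may absorb (0 = exact spacing).
#' @export
setClass("MotifSpec",
         representation(offsets = "integer", allowed = "list",
                        fungalVariant = "logical", spacerSlack = "integer"))

setValidity("MotifSpec", function(object) {
  msg <- NULL
  if (length(object@offsets) != length(object@allowed))
    msg <- c(msg, "offsets and allowed must have equal length")
  if (is.unsorted(object@offsets, strictly = TRUE))
    msg <- c(msg, "offsets must be strictly increasing")
  if (length(object@offsets) != 8L)
    msg <- c(msg, "the motif has exactly eight anchors")
  if (object@spacerSlack < 0L) msg <- c(msg, "spacerSlack must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' PositionFrequencyMatrix: per-column residue counts around motif anchors
#'
#' Residue counts over the 20 standard amino acids for a set of alignment
#' columns indexed by offset from the motif's leading proline; positions
#' falling outside a sequence (or non-standard letters) are tallied as gaps.
#'
#' @slot counts 20 x K integer matrix, rows the standard amino acids.
#' @slot gaps integer vector of per-column gap counts.
#' @slot offsets integer column offsets from the P anchor.
#' @slot nSequences number of contributing sequences.
#' @export
setClass("PositionFrequencyMatrix",
         representation(counts = "matrix", gaps = "integer",
                        offsets = "integer", nSequences = "integer"))

setValidity("PositionFrequencyMatrix", function(object) {
  msg <- NULL
  if (nrow(object@counts) != 20L) msg <- c(msg, "counts must have 20 rows")
  if (ncol(object@counts) != length(object@offsets))
    msg <- c(msg, "one column per offset required")
  if (length(object@gaps) != length(object@offsets))
    msg <- c(msg, "one gap count per column required")
  if (ncol(object@counts) > 0 &&
      !all(colSums(object@counts) + object@gaps == object@nSequences))
    msg <- c(msg, "column counts plus gaps must equal nSequences")
  if (is.null(msg)) TRUE else msg
})

#' SuperpositionResult: optimal rigid-body superposition
#'
#' Result of a least-squares (Kabsch) superposition of matched C-alpha
#' atoms: the proper rotation and translation mapping the mobile set onto
#' the reference, the number of matched atoms, and the post-fit RMSD.
#'
#' @slot rotation 3x3 proper orthonormal matrix (determinant +1).
#' @slot translation length-3 numeric, Angstrom.
#' @slot nPairs number of matched atom pairs.
#' @slot rmsd root-mean-square deviation after superposition, Angstrom.
#' @export
setClass("SuperpositionResult",
         representation(rotation = "matrix", translation = "numeric",
                        nPairs = "integer", rmsd = "numeric"))

setValidity("SuperpositionResult", function(object) {
  msg <- NULL
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation must be proper (det +1)")
  }
  if (length(object@translation) != 3L) msg <- c(msg, "translation must be xyz")
  if (object@nPairs < 3L) msg <- c(msg, "at least 3 atom pairs required")
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' DistanceMatrixTree: p-distance matrix with its neighbor-joining tree
#'
#' Pairwise p-distances over a set of aligned sequences together with the
#' unrooted neighbor-joining tree built from them and its Newick
#' serialization.
#'
#' @slot labels sequence identifiers (tree leaf set).
#' @slot D symmetric distance matrix, zero diagonal.
#' @slot tree the tree as an \code{ape} \code{phylo} object.
#' @slot newick Newick string.
#' @export
setClass("DistanceMatrixTree",
         representation(labels = "character", D = "matrix",
                        tree = "ANY", newick = "character"))

setValidity("DistanceMatrixTree", function(object) {
  msg <- NULL
  D <- object@D
  if (nrow(D) != ncol(D)) msg <- c(msg, "D must be square")
  else {
    if (max(abs(D - t(D))) > 1e-12) msg <- c(msg, "D must be symmetric")
    if (any(diag(D) != 0)) msg <- c(msg, "D must have zero diagonal")
    if (any(D < 0)) msg <- c(msg, "distances must be non-negative")
  }
  if (length(object@labels) != nrow(D))
    msg <- c(msg, "one label per matrix row required")
  if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo")
  else if (!setequal(object@tree$tip.label, object@labels))
    msg <- c(msg, "tree leaf set must equal labels")
  if (is.null(msg)) TRUE else msg
})
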