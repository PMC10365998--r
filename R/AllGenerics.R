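#' @rdname StructureModel-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))
#' @rdname StructureModel-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname StructureModel-class
#' @export
setGeneric("sourceFormat", function(x) standardGeneric("sourceFormat"))
#' @rdname StructureModel-class
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname LigandInstance-class
#' @param x an object.
#' @export
setGeneric("compId", function(x) standardGeneric("compId"))
#' @rdname LigandInstance-class
#' @export
setGeneric("c5Coords", function(x) standardGeneric("c5Coords"))
#' @rdname LigandInstance-class
#' @export
setGeneric("pgCoords", function(x) standardGeneric("pgCoords"))

#' @rdname SuperpositionResult-class
#' @param x an object.
#' @export
setGeneric("rotationMatrix", function(x) standardGeneric("rotationMatrix"))
#' @rdname SuperpositionResult-class
#' @export
setGeneric("translationVector", function(x) standardGeneric("translationVector"))
#' @rdname SuperpositionResult-class
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
#' @rdname SuperpositionResult-class
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))

#' @rdname PositionFrequencyMatrix-class
#' @param x an object.
#' @export
setGeneric("pfmCounts", function(x) standardGeneric("pfmCounts"))
#' @rdname PositionFrequencyMatrix-class
#' @export
setGeneric("pfmFrequencies", function(x) standardGeneric("pfmFrequencies"))
#' @rdname PositionFrequencyMatrix-class
#' @export
setGeneric("pfmOffsets", function(x) standardGeneric("pfmOffsets"))
#' @rdname PositionFrequencyMatrix-class
#' @export
setGeneric("pfmGaps", function(x) standardGeneric("pfmGaps"))

#' @rdname DistanceMatrixTree-class
#' @param x an object.
#' @export
setGeneric("newick", function(x) standardGeneric("newick"))
#' @rdname DistanceMatrixTree-class
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))
#' @rdname DistanceMatrixTree-class
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))
#' @rdname DistanceMatrixTree-class
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))

#' @rdname StructureModel-class
setMethod("entryId", "StructureModel", function(x) x@entryId)
#' @rdname StructureModel-class
setMethod("atomTable", "StructureModel", function(x) x@atoms)
#' @rdname StructureModel-class
setMethod("sourceFormat", "StructureModel", function(x) x@sourceFormat)
#' @rdname StructureModel-class
setMethod("chainIds", "StructureModel", function(x)
  unique(x@atoms$chain[x@atoms$category == "polymer"]))

#' @rdname LigandInstance-class
setMethod("compId", "LigandInstance", function(x) x@compId)
#' @rdname LigandInstance-class
setMethod("c5Coords", "LigandInstance", function(x) x@c5)
#' @rdname LigandInstance-class
setMethod("pgCoords", "LigandInstance", function(x) x@pg)

#' @rdname SuperpositionResult-class
setMethod("rotationMatrix", "SuperpositionResult", function(x) x@rotation)
#' @rdname SuperpositionResult-class
setMethod("translationVector", "SuperpositionResult", function(x) x@translation)
#' @rdname SuperpositionResult-class
setMethod("nPairs", "SuperpositionResult", function(x) x@nPairs)
#' @rdname SuperpositionResult-class
setMethod("rmsd", "SuperpositionResult", function(x) x@rmsd)

#' @rdname PositionFrequencyMatrix-class
setMethod("pfmCounts", "PositionFrequencyMatrix", function(x) x@counts)
#' @rdname PositionFrequencyMatrix-class
setMethod("pfmFrequencies", "PositionFrequencyMatrix", function(x) {
  tot <- colSums(x@counts)
  sweep(x@counts, 2, ifelse(tot > 0, tot, NA_real_), "/")
})
#' @rdname PositionFrequencyMatrix-class
setMethod("pfmOffsets", "PositionFrequencyMatrix", function(x) x@offsets)
#' @rdname PositionFrequencyMatrix-class
setMethod("pfmGaps", "PositionFrequencyMatrix", function(x) x@gaps)

#' @rdname DistanceMatrixTree-class
setMethod("newick", "DistanceMatrixTree", function(x) x@newick)
#' @rdname DistanceMatrixTree-class
setMethod("distanceMatrix", "DistanceMatrixTree", function(x) x@D)
#' @rdname DistanceMatrixTree-class
setMethod("asPhylo", "DistanceMatrixTree", function(x) x@tree)
#' @rdname DistanceMatrixTree-class
setMethod("leafLabels", "DistanceMatrixTree", function(x) x@labels)

#' @rdname StructureModel-class
setMethod("show", "StructureModel", function(object) {
  at <- object@atoms
  nres <- nrow(unique(at[at$category == "polymer",
                         c("chain", "resno", "insert")]))
  nlig <- sum(at$category == "ligand" & !duplicated(
    at[, c("chain", "resno", "insert", "resid")]) & at$category == "ligand")
  lig <- unique(at[at$category == "ligand", c("chain", "resno", "resid")])
  cat("StructureModel '", object@entryId, "' (", object@sourceFormat, ")\n",
      "  ", length(unique(at$chain[at$category == "polymer"])),
      " polymer chain(s), ", nres, " residues, ", nrow(at), " atoms\n",
      "  ", nrow(lig), " non-water hetero residue(s)",
      if (nrow(lig) > 0) paste0(": ", paste(lig$resid, collapse = " ")), "\n",
      sep = "")
})

#' @rdname ScreenCriteria-class
#' @param object a \code{ScreenCriteria}.
setMethod("show", "ScreenCriteria", function(object) {
  cat("ScreenCriteria\n",
      "  C5-CG aromatic contact: <= ", object@dAromatic, " A (",
      paste(object@aromaticSet, collapse = ","), ")\n",
      "  PG-CZ arginine contact: <= ", object@dArg, " A\n",
      "  stacking: centroid <= ", object@stackingCentroidMax,
      " A, angle <= ", object@stackingAngleMax, " deg\n", sep = "")
})

#' @rdname MotifSpec-class
#' @param object a \code{MotifSpec}.
setMethod("show", "MotifSpec", function(object) {
  cat("MotifSpec: 8 anchors, span ",
      object@offsets[8] - object@offsets[1] + 1L, " residues\n  ", sep = "")
  cat(paste0(vapply(object@allowed, paste, "", collapse = "/"),
             "@", object@offsets, collapse = "  "), "\n")
  cat("  fungalVariant =", object@fungalVariant,
      "; spacerSlack =", object@spacerSlack, "\n")
})

#' @rdname SuperpositionResult-class
#' @param object a \code{SuperpositionResult}.
setMethod("show", "SuperpositionResult", function(object) {
  cat("SuperpositionResult: ", object@nPairs, " C-alpha pairs, RMSD ",
      format(object@rmsd, digits = 4), " A\n", sep = "")
})

#' @rdname PositionFrequencyMatrix-class
#' @param object a \code{PositionFrequencyMatrix}.
setMethod("show", "PositionFrequencyMatrix", function(object) {
  cat("PositionFrequencyMatrix: ", ncol(object@counts), " columns (offsets ",
      min(object@offsets), "..", max(object@offsets), "), ",
      object@nSequences, " sequences\n", sep = "")
})

#' @rdname DistanceMatrixTree-class
#' @param object a \code{DistanceMatrixTree}.
setMethod("show", "DistanceMatrixTree", function(object) {
  cat("DistanceMatrixTree: ", length(object@labels),
      " taxa, neighbor-joining\n  ", sep = "")
  nw <- object@newick
  cat(if (nchar(nw) > 70) paste0(substr(nw, 1, 67), "...") else nw, "\n")
})
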