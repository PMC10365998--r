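#' Construct screening criteria
#'
#' Defaults follow the published screen: an aromatic contact is a
#' tyrosine, tryptophan, phenylalanine or histidine whose side-chain
#' gamma-carbon CG lies within 5 Angstrom (inclusive) of the adenine C5,
#' and an arginine contact is a CZ within 5 Angstrom of the
#' gamma-phosphate phosphorus PG.  Stacking thresholds (ring-centroid
#' distance \eqn{\le} 5 Angstrom, interplanar angle \eqn{\le} 30 degrees)
#' are standard literature defaults for face-to-face pi-pi geometry.
#'
#' @param dAromatic C5-CG cutoff, Angstrom.
#' @param dArg PG-CZ cutoff, Angstrom.
#' @param aromaticSet aromatic residue codes.
#' @param stackingCentroidMax centroid-centroid stacking cutoff, Angstrom.
#' @param stackingAngleMax interplanar-angle stacking cutoff, degrees.
#' @return a [ScreenCriteria-class].
#' @export
screenCriteria <- function(dAromatic = 5, dArg = 5,
                           aromaticSet = c("TYR", "TRP", "PHE", "HIS"),
                           stackingCentroidMax = 5, stackingAngleMax = 30) {
  new("ScreenCriteria", dAromatic = dAromatic, dArg = dArg,
      aromaticSet = aromaticSet, aromaticAnchorAtom = "CG",
      adenineAnchorAtom = "C5", gammaAtom = "PG", argAnchorAtom = "CZ",
      stackingCentroidMax = stackingCentroidMax,
      stackingAngleMax = stackingAngleMax)
}

#' Find aromatic residues contacting the adenine ring
#'
#' Criterion 1 of the screen: every polymer residue of the aromatic set
#' whose CG atom lies within \code{dAromatic} (inclusive) of the ligand's
#' adenine C5.  Aromatic residues lacking a CG atom are skipped with a
#' warning.
#'
#' @param model a [StructureModel-class].
#' @param ligand a [LigandInstance-class] with C5 present.
#' @param criteria a [ScreenCriteria-class].
#' @return data.frame with one row per contact (chain, resno, insert,
#'   resid, distC5CG, stacked, stackingAngle, centroidDistance), sorted by
#'   distance; stacking columns are NA until [assessStacking()] is run.
#' @export
findAromaticContacts <- function(model, ligand, criteria = screenCriteria()) {
  if (length(ligand@c5) != 3L)
    stop("criterion inapplicable: ligand ", ligand@compId, " ",
         ligand@chainId, ligand@seqNum, " has no C5 atom")
  at <- model@atoms
  arom <- at[at$category == "polymer" & at$resid %in% criteria@aromaticSet, ]
  res <- unique(arom[, c("chain", "resno", "insert", "resid")])
  empty <- data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), resid = character(0),
                      distC5CG = numeric(0), stacked = logical(0),
                      stackingAngle = numeric(0),
                      centroidDistance = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(res) == 0) return(empty)
  cg <- arom[arom$elety == criteria@aromaticAnchorAtom, ]
  key <- paste(res$chain, res$resno, res$insert, sep = "\r")
  cgkey <- paste(cg$chain, cg$resno, cg$insert, sep = "\r")
  miss <- !(key %in% cgkey)
  if (any(miss))
    warning(sum(miss), " aromatic residue(s) lacking a ",
            criteria@aromaticAnchorAtom, " atom skipped in ", model@entryId)
  if (nrow(cg) == 0) return(empty)
  d <- sqrt((cg$x - ligand@c5[1])^2 + (cg$y - ligand@c5[2])^2 +
              (cg$z - ligand@c5[3])^2)
  keep <- d <= criteria@dAromatic
  out <- data.frame(chain = cg$chain[keep], resno = cg$resno[keep],
                    insert = cg$insert[keep], resid = cg$resid[keep],
                    distC5CG = d[keep], stacked = rep(NA, sum(keep)),
                    stackingAngle = rep(NA_real_, sum(keep)),
                    centroidDistance = rep(NA_real_, sum(keep)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$distC5CG, out$chain, out$resno), ]
  rownames(out) <- NULL
  out
}

#' Find arginines contacting the gamma-phosphate
#'
#' Criterion 2 of the screen: arginine residues whose CZ atom lies within
#' \code{dArg} (inclusive) of the ligand's gamma-phosphate phosphorus PG.
#' Ligands without a gamma-phosphate (ADP, AMP) yield an empty result.
#'
#' @inheritParams findAromaticContacts
#' @return data.frame (chain, resno, insert, resid, distPGCZ) sorted by
#'   ascending distance.
#' @export
findArginineGammaContacts <- function(model, ligand,
                                      criteria = screenCriteria()) {
  empty <- data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), resid = character(0),
                      distPGCZ = numeric(0), stringsAsFactors = FALSE)
  if (length(ligand@pg) != 3L) return(empty)
  at <- model@atoms
  cz <- at[at$category == "polymer" & at$resid == "ARG" &
             at$elety == criteria@argAnchorAtom, ]
  if (nrow(cz) == 0) return(empty)
  d <- sqrt((cz$x - ligand@pg[1])^2 + (cz$y - ligand@pg[2])^2 +
              (cz$z - ligand@pg[3])^2)
  keep <- d <= criteria@dArg
  out <- data.frame(chain = cz$chain[keep], resno = cz$resno[keep],
                    insert = cz$insert[keep], resid = cz$resid[keep],
                    distPGCZ = d[keep], stringsAsFactors = FALSE)
  out <- out[order(out$distPGCZ, out$chain, out$resno), ]
  rownames(out) <- NULL
  out
}

#' Assess pi-pi stacking for aromatic contacts
#'
#' For each contact, fits least-squares planes through the ligand's
#' 9-atom purine system and through the aromatic side-chain ring (6-ring
#' for Tyr/Phe, 5-ring for His, full 9-atom indole for Trp), and flags
#' the contact as stacked when the ring-centroid separation and the
#' interplanar angle (folded into \eqn{[0, 90]} degrees) are both within
#' the stacking thresholds.  Contacts with missing ring atoms are marked
#' not stacked.
#'
#' @inheritParams findAromaticContacts
#' @param contacts data.frame from [findAromaticContacts()].
#' @return \code{contacts} with stacked / stackingAngle / centroidDistance
#'   filled in.
#' @export
assessStacking <- function(model, ligand, contacts,
                           criteria = screenCriteria()) {
  if (nrow(contacts) == 0) return(contacts)
  lig <- ligand@atoms
  pur <- lig[lig$elety %in% .PURINE_ATOMS, ]
  purXyz <- as.matrix(pur[, c("x", "y", "z")])
  purOk <- nrow(purXyz) >= 3
  if (purOk) {
    purC <- .centroid(purXyz)
    purN <- .lsPlaneNormal(purXyz)
  }
  for (i in seq_len(nrow(contacts))) {
    ringNames <- .RING_ATOMS[[contacts$resid[i]]]
    ring <- .residueAtomCoords(model@atoms, contacts$chain[i],
                               contacts$resno[i], contacts$insert[i],
                               ringNames)
    if (is.null(ring) || !purOk) {
      contacts$stacked[i] <- FALSE
      next
    }
    cen <- .dist3(.centroid(ring), purC)
    ang <- .interplanarAngle(.lsPlaneNormal(ring), purN)
    contacts$centroidDistance[i] <- cen
    contacts$stackingAngle[i] <- ang
    contacts$stacked[i] <- cen <= criteria@stackingCentroidMax &&
      ang <= criteria@stackingAngleMax
  }
  contacts
}

#' Classify a ligand site into the screen's tiers
#'
#' Requires at least two aromatic contacts (a "pair"); the reported pair
#' is the one with the smallest summed C5-CG distance, i.e. the two
#' closest contacts.  Tiers are cumulative: \code{T1_pair_contact} = at
#' least two aromatic contacts; \code{T2_cross_subunit} = the pair spans
#' two chains; \code{T3_dual_stacking} = both pair members are stacked;
#' \code{T4_full} = additionally at least one arginine gamma-phosphate
#' contact (requires PG, so never reached by ADP/AMP).
#'
#' @param contacts stacking-assessed data.frame from [assessStacking()].
#' @param argContacts data.frame from [findArginineGammaContacts()].
#' @param ligand the screened [LigandInstance-class].
#' @return one-row data.frame (ligandComp, ligandChain, ligandSeq, tier,
#'   aromatic1, aromatic2, d1, d2, crossSubunit, nStacked, argList), or
#'   \code{NULL} if fewer than two aromatic contacts.
#' @export
classifySite <- function(contacts, argContacts, ligand) {
  if (nrow(contacts) < 2) return(NULL)
  # the minimal-sum pair is simply the two closest contacts
  contacts <- contacts[order(contacts$distC5CG, contacts$chain,
                             contacts$resno), ]
  pair <- contacts[1:2, ]
  cross <- pair$chain[1] != pair$chain[2]
  nStacked <- sum(pair$stacked, na.rm = TRUE)
  hasArg <- nrow(argContacts) > 0 && length(ligand@pg) == 3L
  tier <- "T1_pair_contact"
  if (cross) {
    tier <- "T2_cross_subunit"
    if (nStacked == 2L) {
      tier <- "T3_dual_stacking"
      if (hasArg) tier <- "T4_full"
    }
  }
  fmt <- function(r) sprintf("%s %s%d%s", r$resid, r$chain, r$resno, r$insert)
  argList <- if (nrow(argContacts) == 0) "" else
    paste(sprintf("ARG %s%d:%.2f", argContacts$chain, argContacts$resno,
                  argContacts$distPGCZ), collapse = ";")
  data.frame(ligandComp = ligand@compId, ligandChain = ligand@chainId,
             ligandSeq = ligand@seqNum, tier = tier,
             aromatic1 = fmt(pair[1, ]), aromatic2 = fmt(pair[2, ]),
             d1 = pair$distC5CG[1], d2 = pair$distC5CG[2],
             crossSubunit = cross, nStacked = nStacked, argList = argList,
             stringsAsFactors = FALSE)
}

#' Screen a library of structures for the aromatic-sandwich binding mode
#'
#' Applies the full two-criterion screen (or criterion 1 only) to every
#' nucleotide ligand instance in every file.  In \code{criterion1_only}
#' mode the admitted component codes extend to ADP and AMP and the
#' arginine criterion is skipped, so tiers are capped at
#' \code{T3_dual_stacking}.  Unreadable files produce an error row and
#' the screen continues.
#'
#' @param paths character vector of PDB/mmCIF files (or a directory).
#' @param criteria a [ScreenCriteria-class].
#' @param mode \code{"full"} or \code{"criterion1_only"}.
#' @param codes component codes to admit; defaults depend on \code{mode}.
#' @return data.frame with one row per (entry, ligand instance):
#'   entryId, ligandComp, ligandChain, ligandSeq, tier ("none" when fewer
#'   than two aromatic contacts), aromatic1/2, d1/d2, crossSubunit,
#'   nStacked, argList, error.  Rows are ordered by entryId then ligand.
#' @seealso [tierCounts()]
#' @export
screenLibrary <- function(paths, criteria = screenCriteria(),
                          mode = c("full", "criterion1_only"), codes = NULL) {
  mode <- match.arg(mode)
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(pdb|ent|cif|mmcif)$",
                        full.names = TRUE)
  if (is.null(codes))
    codes <- if (mode == "full") .TRIPHOSPHATE_CODES else .NUCLEOTIDE_CODES
  paths <- paths[order(basename(paths))]
  rows <- list()
  blank <- data.frame(ligandComp = NA_character_, ligandChain = NA_character_,
                      ligandSeq = NA_integer_, tier = NA_character_,
                      aromatic1 = NA_character_, aromatic2 = NA_character_,
                      d1 = NA_real_, d2 = NA_real_, crossSubunit = NA,
                      nStacked = NA_integer_, argList = NA_character_,
                      stringsAsFactors = FALSE)
  for (p in paths) {
    model <- tryCatch(readStructure(p), error = function(e) e)
    if (inherits(model, "error")) {
      r <- blank
      r$error <- conditionMessage(model)
      r <- cbind(entryId = tools::file_path_sans_ext(basename(p)), r,
                 stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- r
      next
    }
    ligs <- withCallingHandlers(
      extractLigands(model, codes),
      warning = function(w) invokeRestart("muffleWarning"))
    for (lig in ligs) {
      if (length(lig@c5) != 3L) next
      contacts <- suppressWarnings(findAromaticContacts(model, lig, criteria))
      contacts <- assessStacking(model, lig, contacts, criteria)
      argc <- if (mode == "full")
        findArginineGammaContacts(model, lig, criteria)
      else data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), resid = character(0),
                      distPGCZ = numeric(0))
      hit <- classifySite(contacts, argc, lig)
      if (is.null(hit)) {
        hit <- blank
        hit$ligandComp <- lig@compId
        hit$ligandChain <- lig@chainId
        hit$ligandSeq <- lig@seqNum
        hit$tier <- "none"
        hit$argList <- ""
      }
      hit$error <- NA_character_
      rows[[length(rows) + 1L]] <-
        cbind(entryId = model@entryId, hit, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    out <- cbind(entryId = character(0), blank[0, ],
                 error = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$entryId, out$ligandChain, out$ligandSeq), ]
  rownames(out) <- NULL
  out
}

#' Summarize screen hits per tier
#'
#' Counts hits at each tier, either per ligand site (one row of the hit
#' table each) or per entry, where a structure's tier is the maximum over
#' its ligand instances.
#'
#' @param hits data.frame from [screenLibrary()].
#' @param by \code{"site"} or \code{"entry"}.
#' @return named integer vector over the tiers (none, T1..T4).
#' @export
tierCounts <- function(hits, by = c("site", "entry")) {
  by <- match.arg(by)
  ok <- hits[!is.na(hits$tier), , drop = FALSE]
  if (by == "entry" && nrow(ok) > 0) {
    lv <- factor(ok$tier, levels = .TIER_LEVELS)
    mx <- tapply(as.integer(lv), ok$entryId, max)
    tiers <- .TIER_LEVELS[mx]
  } else tiers <- ok$tier
  table(factor(tiers, levels = .TIER_LEVELS))
}
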