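# ---- idealized ligand geometry -------------------------------------------

# idealized planar purine: regular hexagon (N1,C2,N3,C4,C5,C6; bond 1.39 A)
# with a regular pentagon (C4,N9,C8,N7,C5) fused on the C4-C5 edge; z = 0
.purineCoords <- function() {
  rh <- 1.39
  hexNames <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ang <- (seq_len(6) - 1) * pi / 3
  hexm <- cbind(rh * cos(ang), rh * sin(ang), 0)
  rownames(hexm) <- hexNames
  C4 <- hexm["C4", ]; C5 <- hexm["C5", ]
  M <- (C4 + C5) / 2
  u <- M / sqrt(sum(M^2))                      # away from hexagon center
  edge <- sqrt(sum((C4 - C5)^2))
  r5 <- edge / (2 * sin(pi / 5))
  a5 <- r5 * cos(pi / 5)
  cen <- M + a5 * u
  ang4 <- atan2(C4[2] - cen[2], C4[1] - cen[1])
  ang5 <- atan2(C5[2] - cen[2], C5[1] - cen[1])
  delta <- ang5 - ang4
  delta <- atan2(sin(delta), cos(delta))       # wrap to (-pi, pi]; |delta| = 72 deg
  # ring order C4 -> N9 -> C8 -> N7 -> C5 runs opposite to the C4->C5 step
  pent <- t(vapply(1:3, function(k) {
    a <- ang4 - k * delta
    cen + c(r5 * cos(a), r5 * sin(a), 0)
  }, numeric(3)))
  rownames(pent) <- c("N9", "C8", "N7")
  rbind(hexm, pent)
}

# ligand atom table: purine + a colinear phosphate tail leaving through N9
.ligandAtoms <- function(code, chain = "C", resno = 901L) {
  pur <- .purineCoords()
  p0 <- colMeans(pur)
  u <- pur["N9", ] - p0
  u <- u / sqrt(sum(u^2))
  tail <- list(PA = pur["N9", ] + 3.0 * u,
               PB = pur["N9", ] + 4.6 * u,
               PG = pur["N9", ] + 6.2 * u)
  keep <- switch(code, AMP = "PA", ADP = c("PA", "PB"),
                 c("PA", "PB", "PG"))
  coords <- rbind(pur, do.call(rbind, tail[keep]))
  data.frame(rectype = "HETATM", chain = chain, resno = resno, insert = "",
             resid = code, category = "ligand",
             elety = rownames(coords),
             elesy = ifelse(grepl("^P", rownames(coords)), "P",
                            substr(rownames(coords), 1, 1)),
             alt = "", occ = 1,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

# ---- aromatic ring placement ---------------------------------------------

# place a regular side-chain ring realizing (i) purine-centroid to
# ring-centroid distance, (ii) interplanar angle, and (iii) the C5-CG
# distance, to within 0.01 A; side = +1 above the purine plane, -1 below.
# returns the ring atom matrix with row 1 = CG.
.placeRing <- function(c5pos, p0, ringNames, radius, dC5CG, angleDeg,
                       centroidDist, side) {
  theta <- angleDeg * pi / 180
  exy <- c5pos[1:2] - p0[1:2]
  e <- if (sqrt(sum(exy^2)) > 1e-9) c(exy / sqrt(sum(exy^2)), 0) else c(1, 0, 0)
  nring <- length(ringNames)
  u1 <- c(cos(theta) * e[1], cos(theta) * e[2], -side * sin(theta))
  u2 <- c(-e[2], e[1], 0)
  ringAt <- function(a, phi) {
    h <- sqrt(max(0, centroidDist^2 - a^2))
    cen <- p0 + a * e + c(0, 0, side * h)
    ps <- phi + (seq_len(nring) - 1) * 2 * pi / nring
    sweep(outer(cos(ps), u1) + outer(sin(ps), u2), 1, radius, "*") +
      matrix(cen, nring, 3, byrow = TRUE)
  }
  # |CG - C5|^2 is sinusoidal in the ring phase, so for each lateral
  # offset a the phase solving the requested distance is closed-form;
  # scan a (nearest-to-center feasible value wins) and solve exactly
  best <- NULL
  for (a in sort(seq(-0.995, 0.995, length.out = 241)) [
    order(abs(seq(-0.995, 0.995, length.out = 241)))] * centroidDist) {
    h <- sqrt(max(0, centroidDist^2 - a^2))
    w <- p0 + a * e + c(0, 0, side * h) - c5pos
    target <- dC5CG^2 - sum(w^2) - radius^2
    B <- 2 * radius * sum(u1 * w)
    C <- 2 * radius * sum(u2 * w)
    Rm <- sqrt(B^2 + C^2)
    if (Rm >= abs(target)) {
      phi <- atan2(C, B) + acos(max(-1, min(1, target / Rm)))
      best <- c(a, phi)
      break
    }
  }
  if (is.null(best))
    stop("infeasible geometry: cannot realize C5-CG = ", dC5CG,
         " A with centroid distance ", centroidDist, " A")
  atoms <- ringAt(best[1], best[2])
  rownames(atoms) <- ringNames
  atoms
}

# full planted residue (ring + stub backbone) as atom-table rows
.aromaticResidueAtoms <- function(spec, c5pos, p0, side) {
  ringNames <- .RING_ATOMS[[spec$resid]]
  radius <- if (length(ringNames) == 5) 1.19 else 1.39
  ring <- .placeRing(c5pos, p0, ringNames, radius, spec$dC5CG, spec$angle,
                     spec$centroidDist, side)
  cen <- colMeans(ring)
  out <- cen - p0
  out <- out / sqrt(sum(out^2))
  cb <- ring["CG", ] + 1.5 * out
  ca <- cb + c(0, 1.1, 1.0 * side)
  bb <- rbind(CB = cb, CA = ca, N = ca + c(1.4, 0.4, 0),
              C = ca + c(-1.4, 0.4, 0), O = ca + c(-1.9, 1.5, 0))
  coords <- rbind(ring, bb)
  data.frame(rectype = "ATOM", chain = spec$chain, resno = spec$resno,
             insert = "", resid = spec$resid, category = "polymer",
             elety = rownames(coords),
             elesy = substr(rownames(coords), 1, 1), alt = "", occ = 1,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

# arginine with CZ at the requested distance from PG, guanidinium sketched
.arginineAtoms <- function(spec, pgpos, p0) {
  dirv <- pgpos - p0
  dirv <- dirv / sqrt(sum(dirv^2))
  cz <- pgpos + spec$dPGCZ * dirv
  perp <- c(-dirv[2], dirv[1], 0)
  if (sqrt(sum(perp^2)) < 1e-9) perp <- c(1, 0, 0)
  perp <- perp / sqrt(sum(perp^2))
  coords <- rbind(CZ = cz, NH1 = cz + 1.33 * perp, NH2 = cz - 1.33 * perp,
                  NE = cz + 1.33 * dirv, CD = cz + 2.8 * dirv,
                  CG = cz + 4.0 * dirv + c(0, 0, 1),
                  CB = cz + 5.3 * dirv + c(0, 0, 1.8),
                  CA = cz + 6.5 * dirv + c(0, 0, 2.6),
                  N = cz + 7.4 * dirv + c(0.8, 0, 2.6),
                  C = cz + 7.4 * dirv + c(-0.8, 0, 3.0),
                  O = cz + 8.2 * dirv + c(-1.2, 0, 3.6))
  data.frame(rectype = "ATOM", chain = spec$chain, resno = spec$resno,
             insert = "", resid = "ARG", category = "polymer",
             elety = rownames(coords),
             elesy = substr(rownames(coords), 1, 1), alt = "", occ = 1,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

# poly-glycine scaffold: inert backbone residues far from the site
.scaffoldAtoms <- function(chain, resnos, zoff) {
  rows <- lapply(seq_along(resnos), function(i) {
    base <- c(25 + 3.5 * (i - 1), 20, zoff)
    coords <- rbind(N = base, CA = base + c(1.2, 0.8, 0),
                    C = base + c(2.4, 0, 0), O = base + c(2.6, -1.2, 0))
    data.frame(rectype = "ATOM", chain = chain, resno = resnos[i],
               insert = "", resid = "GLY", category = "polymer",
               elety = rownames(coords),
               elesy = substr(rownames(coords), 1, 1), alt = "", occ = 1,
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- site geometry design ------------------------------------------------

#' Design a synthetic nucleotide binding site
#'
#' Describes a minimal one- or two-chain binding site: an adenine-like
#' ligand with correct atom names, two aromatic side chains at
#' parameterized C5-CG distances / interplanar angles / ring-centroid
#' offsets (one on each face of the purine), and an arginine at a
#' parameterized PG-CZ distance.  \code{decoyMode} perturbs the base
#' design to violate exactly one screen condition; the expected screen
#' tier is derived from the final fields and recorded in the label.
#'
#' @param aromatic1,aromatic2 lists with fields resid ("TYR", "PHE" or
#'   "HIS"), chain, resno, dC5CG, angle (degrees), centroidDist
#'   (Angstrom); \code{aromatic2} may be \code{NULL}.
#' @param arginine list with fields present, chain, resno, dPGCZ.
#' @param ligandCode nucleotide component code (default "ANP", the
#'   non-hydrolyzable ATP analog).
#' @param decoyMode one of "none", "far_aromatic", "single_aromatic",
#'   "same_chain", "no_stacking", "no_arginine".
#' @param seed integer seed controlling the rigid placement jitter.
#' @param rigidTransform apply a random rigid rotation + translation to
#'   the finished structure (distances unaffected).
#' @param entryId identifier for the emitted model.
#' @return a list of class \code{"SiteGeometry"} with the resolved
#'   fields and \code{expectedTier}.
#' @seealso [makeBindingSiteStructure()]
#' @export
siteGeometry <- function(aromatic1 = list(resid = "HIS", chain = "A",
                                          resno = 706L, dC5CG = 4.0,
                                          angle = 5, centroidDist = 3.6),
                         aromatic2 = list(resid = "TYR", chain = "B",
                                          resno = 710L, dC5CG = 4.5,
                                          angle = 8, centroidDist = 3.7),
                         arginine = list(present = TRUE, chain = "B",
                                         resno = 711L, dPGCZ = 3.8),
                         ligandCode = "ANP",
                         decoyMode = c("none", "far_aromatic",
                                       "single_aromatic", "same_chain",
                                       "no_stacking", "no_arginine"),
                         seed = 1L, rigidTransform = TRUE,
                         entryId = NULL) {
  decoyMode <- match.arg(decoyMode)
  stopifnot(ligandCode %in% .NUCLEOTIDE_CODES)
  bad <- function(x) !is.null(x) && (x$dC5CG <= 0 || x$centroidDist <= 0)
  if (bad(aromatic1) || bad(aromatic2) ||
      (arginine$present && arginine$dPGCZ <= 0))
    stop("infeasible geometry: distances must be positive")
  if (decoyMode == "far_aromatic") {
    for (nm in c("aromatic1", "aromatic2")) {
      a <- get(nm)
      if (!is.null(a)) { a$dC5CG <- 6.0; a$centroidDist <- 5.6 }
      assign(nm, a)
    }
  } else if (decoyMode == "single_aromatic") {
    aromatic2 <- NULL
  } else if (decoyMode == "same_chain") {
    if (!is.null(aromatic2)) aromatic2$chain <- aromatic1$chain
  } else if (decoyMode == "no_stacking") {
    aromatic1$angle <- 60; aromatic2$angle <- 60
  } else if (decoyMode == "no_arginine") {
    arginine$present <- FALSE
  }
  if (is.null(entryId)) entryId <- sprintf("SYN%s-%d", toupper(substr(
    decoyMode, 1, 3)), seed)
  g <- list(aromatic1 = aromatic1, aromatic2 = aromatic2,
            arginine = arginine, ligandCode = ligandCode,
            decoyMode = decoyMode, seed = as.integer(seed),
            rigidTransform = rigidTransform, entryId = entryId)
  g$expectedTier <- .tierFromGeometry(g)
  class(g) <- "SiteGeometry"
  g
}

# ground-truth tier implied by a geometry design under default criteria
.tierFromGeometry <- function(g, criteria = screenCriteria()) {
  aroms <- Filter(Negate(is.null), list(g$aromatic1, g$aromatic2))
  contacts <- Filter(function(a) a$dC5CG <= criteria@dAromatic, aroms)
  if (length(contacts) < 2) return("none")
  cross <- contacts[[1]]$chain != contacts[[2]]$chain
  stackedBoth <- all(vapply(contacts, function(a)
    a$angle <= criteria@stackingAngleMax &&
      a$centroidDist <= criteria@stackingCentroidMax, TRUE))
  argOk <- g$arginine$present && g$arginine$dPGCZ <= criteria@dArg &&
    g$ligandCode %in% .TRIPHOSPHATE_CODES
  if (!cross) return("T1_pair_contact")
  if (!stackedBoth) return("T2_cross_subunit")
  if (!argOk) return("T3_dual_stacking")
  "T4_full"
}

#' @export
print.SiteGeometry <- function(x, ...) {
  cat("SiteGeometry (", x$decoyMode, ") -> expected tier ", x$expectedTier,
      "\n", sep = "")
  invisible(x)
}

#' Emit a synthetic binding-site structure
#'
#' Realizes a [siteGeometry()] design as coordinates: idealized
#' adenine-nucleotide ligand, aromatic side chains placed so the planted
#' C5-CG distances, interplanar angles and ring-centroid offsets are met
#' to within 0.01 Angstrom, an arginine at the planted PG-CZ distance,
#' and inert poly-glycine scaffolds on each chain.  A seeded random
#' rigid transform is applied so fixtures are not axis-aligned.
#'
#' @param geom a \code{"SiteGeometry"} design.
#' @param dir if non-NULL, write \code{<entryId>.pdb}, \code{<entryId>.cif}
#'   and a \code{<entryId>.json} ground-truth sidecar there.
#' @return list with \code{model} (a [StructureModel-class]), \code{label}
#'   (ground-truth record: expected tier, planted distances, seed) and
#'   \code{paths} (written files, if any).
#' @export
makeBindingSiteStructure <- function(geom, dir = NULL) {
  stopifnot(inherits(geom, "SiteGeometry"))
  lig <- .ligandAtoms(geom$ligandCode)
  pur <- as.matrix(lig[lig$elety %in% .PURINE_ATOMS, c("x", "y", "z")])
  p0 <- colMeans(pur)
  c5pos <- as.numeric(lig[lig$elety == "C5", c("x", "y", "z")])
  parts <- list(lig)
  if (!is.null(geom$aromatic1))
    parts <- c(parts, list(.aromaticResidueAtoms(geom$aromatic1, c5pos,
                                                 p0, side = +1)))
  if (!is.null(geom$aromatic2))
    parts <- c(parts, list(.aromaticResidueAtoms(geom$aromatic2, c5pos,
                                                 p0, side = -1)))
  if (geom$arginine$present) {
    if (!geom$ligandCode %in% .TRIPHOSPHATE_CODES)
      warning("arginine requested but ligand ", geom$ligandCode,
              " has no gamma-phosphate; placing relative to the tail end")
    pgpos <- if ("PG" %in% lig$elety)
      as.numeric(lig[lig$elety == "PG", c("x", "y", "z")])
    else as.numeric(lig[nrow(lig), c("x", "y", "z")])
    parts <- c(parts, list(.arginineAtoms(geom$arginine, pgpos, p0)))
  }
  chains <- unique(unlist(lapply(
    Filter(Negate(is.null), list(geom$aromatic1, geom$aromatic2,
                                 if (geom$arginine$present) geom$arginine)),
    `[[`, "chain")))
  if (length(chains) == 0) chains <- "A"
  used <- do.call(rbind, lapply(parts[-1], function(p)
    unique(p[, c("chain", "resno")])))
  for (k in seq_along(chains)) {
    resnos <- setdiff(690:720, used$resno[used$chain == chains[k]])
    parts <- c(parts, list(.scaffoldAtoms(chains[k], resnos,
                                          zoff = 14 + 6 * k)))
  }
  atoms <- do.call(rbind, parts)
  if (geom$rigidTransform) {
    set.seed(geom$seed)
    R <- .randomRotation()
    tr <- stats::runif(3, -20, 20)
    atoms <- .transformAtoms(atoms, R, tr)
  }
  atoms <- atoms[order(match(atoms$chain, sort(unique(atoms$chain))),
                       atoms$resno), ]
  rownames(atoms) <- NULL
  model <- new("StructureModel", entryId = geom$entryId, atoms = atoms,
               sourceFormat = "synthetic")
  planted <- list(
    dC5CG = lapply(Filter(Negate(is.null),
                          list(geom$aromatic1, geom$aromatic2)),
                   `[[`, "dC5CG"),
    dPGCZ = if (geom$arginine$present) geom$arginine$dPGCZ else NULL)
  label <- list(entryId = geom$entryId, tier = geom$expectedTier,
                decoyMode = geom$decoyMode, ligandCode = geom$ligandCode,
                seed = geom$seed, planted = planted)
  paths <- character(0)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pdb <- file.path(dir, paste0(geom$entryId, ".pdb"))
    cif <- file.path(dir, paste0(geom$entryId, ".cif"))
    lab <- file.path(dir, paste0(geom$entryId, ".json"))
    writeStructure(model, pdb, "pdb")
    writeStructure(model, cif, "mmcif")
    jsonlite::write_json(label, lab, auto_unbox = TRUE, digits = NA)
    paths <- c(pdb = pdb, cif = cif, label = lab)
  }
  list(model = model, label = label, paths = paths)
}

#' Generate a labelled library of binding-site fixtures
#'
#' Draws \code{n} site designs over the decoy modes in \code{modeMix}
#' (default: balanced across the full site and the five decoy classes),
#' jitters the planted distances and angles within tier-preserving
#' ranges, and writes one PDB per fixture plus a \code{labels.tsv}
#' ground-truth table.
#'
#' @param n number of fixtures.
#' @param dir output directory (created if needed).
#' @param seed integer seed; the whole library is a deterministic
#'   function of it.
#' @param modeMix named numeric vector of sampling weights over decoy
#'   modes.
#' @return data.frame (entryId, path, decoyMode, tier, seed).
#' @export
makeStructureLibrary <- function(n = 20, dir, seed = 1,
                                 modeMix = c(none = 2, far_aromatic = 1,
                                             single_aromatic = 1,
                                             same_chain = 1,
                                             no_stacking = 1,
                                             no_arginine = 1)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  modes <- sample(names(modeMix), n, replace = TRUE,
                  prob = modeMix / sum(modeMix))
  subSeeds <- sample.int(.Machine$integer.max - 1L, n)
  types <- c("TYR", "PHE", "HIS")
  rows <- lapply(seq_len(n), function(i) {
    a1 <- list(resid = sample(types, 1), chain = "A", resno = 706L,
               dC5CG = stats::runif(1, 3.7, 4.8),
               angle = stats::runif(1, 0, 20),
               centroidDist = stats::runif(1, 3.4, 4.3))
    a2 <- list(resid = sample(types, 1), chain = "B", resno = 710L,
               dC5CG = stats::runif(1, 3.7, 4.8),
               angle = stats::runif(1, 0, 20),
               centroidDist = stats::runif(1, 3.4, 4.3))
    arg <- list(present = TRUE, chain = "B", resno = 711L,
                dPGCZ = stats::runif(1, 3.2, 4.8))
    g <- siteGeometry(a1, a2, arg, ligandCode = "ANP",
                      decoyMode = modes[i], seed = subSeeds[i],
                      entryId = sprintf("FIX%03d", i))
    res <- makeBindingSiteStructure(g, dir = NULL)
    path <- file.path(dir, paste0(g$entryId, ".pdb"))
    writeStructure(res$model, path, "pdb")
    data.frame(entryId = g$entryId, path = path, decoyMode = modes[i],
               tier = g$expectedTier, seed = subSeeds[i],
               stringsAsFactors = FALSE)
  })
  labels <- do.call(rbind, rows)
  # the written table uses basenames so a library is relocatable
  disk <- labels
  disk$path <- basename(disk$path)
  utils::write.table(disk, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  labels
}

# ---- sequence family generator -------------------------------------------

#' Plant the ATP-regulatory motif into a sequence
#'
#' Overwrites the eight anchor positions of \code{spec}, starting at
#' \code{start} (1-based), with P, W, H, Y, R (K if \code{fungal}), H,
#' R, R.
#'
#' @param seq background amino-acid string.
#' @param start 1-based position for the leading proline.
#' @param spec a [MotifSpec-class] (supplies the offsets).
#' @param fungal plant lysine instead of arginine at offset 9.
#' @return the modified sequence string.
#' @export
plantMotif <- function(seq, start, spec = motifSpec(), fungal = FALSE) {
  chars <- strsplit(seq, "")[[1]]
  if (start + spec@offsets[8] > length(chars))
    stop("sequence too short to plant the motif at position ", start)
  res <- c("P", "W", "H", "Y", if (fungal) "K" else "R", "H", "R", "R")
  chars[start + spec@offsets] <- res
  paste(chars, collapse = "")
}

#' Design a synthetic phosphoketolase-like sequence family
#'
#' @param nSequences family size.
#' @param length sequence length (>= anchorStart + 51).
#' @param identityRange target percent-identity band to the reference.
#' @param motifPrevalence fraction of sequences carrying an intact motif.
#' @param fungalFraction fraction of the motif-positive sequences using
#'   the lysine (fungal) variant at the offset-9 anchor.
#' @param anchorStart 1-based position of the leading proline in the
#'   reference (default 702, the reference phosphoketolase numbering).
#' @param seed integer seed.
#' @return a list of class \code{"FamilyDesign"}.
#' @export
familyDesign <- function(nSequences = 200, length = 800,
                         identityRange = c(70, 95), motifPrevalence = 0.75,
                         fungalFraction = 0, anchorStart = 702, seed = 1) {
  if (length < anchorStart + 51)
    stop("length must be at least anchorStart + 51 = ", anchorStart + 51)
  if (identityRange[1] > identityRange[2] || identityRange[2] > 100)
    stop("invalid identity range")
  maxMut <- length - 9L       # non-anchor positions minus one spare
  if (round(length * (1 - identityRange[1] / 100)) > maxMut)
    stop("identity band unreachable: too many mutations for this length")
  structure(list(nSequences = as.integer(nSequences),
                 length = as.integer(length),
                 identityRange = identityRange,
                 motifPrevalence = motifPrevalence,
                 fungalFraction = fungalFraction,
                 anchorStart = as.integer(anchorStart),
                 seed = as.integer(seed)),
            class = "FamilyDesign")
}

#' Generate a labelled sequence family
#'
#' Builds a random reference with the motif planted at
#' \code{anchorStart}, then derives each family member by mutating
#' enough non-anchor positions to land in the identity band.
#' Motif-positive members keep all eight anchors (fungal-variant members
#' substitute lysine at the offset-9 arginine); motif-negative members
#' additionally have one randomly chosen anchor destroyed.  The family
#' is a deterministic function of the design seed.
#'
#' @param design a [familyDesign()].
#' @param fasta optional path: write the family as FASTA (plus
#'   \code{<fasta>.labels.tsv}).
#' @return list with \code{sequences} (named character vector),
#'   \code{reference}, and \code{labels} (data.frame: id, motif one of
#'   canonical/fungal/absent, targetIdentity, nMutations).
#' @export
makeSequenceFamily <- function(design, fasta = NULL) {
  stopifnot(inherits(design, "FamilyDesign"))
  set.seed(design$seed)
  spec <- motifSpec()
  L <- design$length
  ref <- paste(sample(.AA20, L, replace = TRUE), collapse = "")
  ref <- plantMotif(ref, design$anchorStart, spec)
  anchorPos <- design$anchorStart + spec@offsets
  nonAnchor <- setdiff(seq_len(L), anchorPos)
  n <- design$nSequences
  nPos <- round(n * design$motifPrevalence)
  nFun <- round(nPos * design$fungalFraction)
  motif <- c(rep("fungal", nFun), rep("canonical", nPos - nFun),
             rep("absent", n - nPos))
  refChars <- strsplit(ref, "")[[1]]
  seqs <- character(n); targetId <- numeric(n); nMut <- integer(n)
  for (i in seq_len(n)) {
    u <- stats::runif(1, design$identityRange[1], design$identityRange[2])
    k <- round(L * (1 - u / 100))
    chars <- refChars
    if (motif[i] == "absent") {
      a <- sample(anchorPos, 1)
      pool <- setdiff(.AA20, c(chars[a], "P", "W", "H", "Y", "R", "K"))
      chars[a] <- sample(pool, 1)
      kRemain <- max(0, k - 1L)
    } else kRemain <- k
    if (motif[i] == "fungal") chars[design$anchorStart + 9L] <- "K"
    sites <- sample(nonAnchor, kRemain)
    for (p in sites)
      chars[p] <- sample(setdiff(.AA20, chars[p]), 1)
    seqs[i] <- paste(chars, collapse = "")
    targetId[i] <- u; nMut[i] <- k
  }
  names(seqs) <- sprintf("fam%04d_%s", seq_len(n), motif)
  labels <- data.frame(id = names(seqs), motif = motif,
                       targetIdentity = targetId, nMutations = nMut,
                       stringsAsFactors = FALSE)
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta)
    utils::write.table(labels, paste0(fasta, ".labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(sequences = seqs, reference = ref, labels = labels)
}
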