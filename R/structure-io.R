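#' Read a PDB or mmCIF structure into a StructureModel
#'
#' Parses a coordinate file (via \pkg{bio3d}) into the package's uniform
#' atom-table representation.  Only the first coordinate model of a
#' multi-model file is kept, hydrogens (and deuteriums) are dropped, and
#' alternate locations are collapsed to the highest-occupancy conformer
#' (ties broken alphabetically, so altloc "A" wins).  Waters are retained
#' but flagged with category \code{"water"}.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format \code{"auto"} (sniff from extension/content), \code{"pdb"}
#'   or \code{"mmcif"}.
#' @return a [StructureModel-class].
#' @seealso [writeStructure()], [extractLigands()]
#' @examples
#' geom <- siteGeometry(seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(makeBindingSiteStructure(geom)$model, f)
#' readStructure(f)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
    else if (ext %in% c("pdb", "ent")) "pdb"
    else if (any(grepl("^data_", lines[nzchar(lines)][1]))) "mmcif"
    else "pdb"
  }
  entry <- tools::file_path_sans_ext(basename(path))
  if (format == "pdb") {
    raw <- .firstModelPdb(lines)
    if (!any(grepl("^(ATOM|HETATM)", raw)))
      stop("empty coordinate section in PDB file: ", path)
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    writeLines(raw, tf)
    pdb <- tryCatch(
      { capture.output(p <- bio3d::read.pdb(tf, verbose = FALSE,
                                            rm.alt = FALSE)); p },
      error = function(e) stop("PDB parse error in ", path,
                               ": ", conditionMessage(e)))
    at <- pdb$atom
  } else {
    res <- .firstModelCif(lines)
    if (!is.null(res$entry)) entry <- res$entry
    tf <- tempfile(fileext = ".cif")
    on.exit(unlink(tf), add = TRUE)
    writeLines(res$lines, tf)
    pdb <- withCallingHandlers(
      tryCatch(
        { capture.output(p <- bio3d::read.cif(tf, verbose = FALSE,
                                              rm.alt = FALSE)); p },
        error = function(e) stop("mmCIF parse error in ", path,
                                 ": ", conditionMessage(e))),
      warning = function(w) {
        if (grepl("beta version|helix/sheet", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    at <- pdb$atom
    if (nrow(at) == 0) stop("empty coordinate section in mmCIF file: ", path)
  }
  .modelFromBio3d(at, entry, format)
}

# truncate PDB record lines at the first ENDMDL so only model 1 survives
.firstModelPdb <- function(lines) {
  endm <- grep("^ENDMDL", lines)
  if (length(endm) > 0) lines <- lines[seq_len(endm[1] - 1L)]
  lines
}

# keep only the first pdbx_PDB_model_num value of an atom_site loop
# (bio3d discards model numbers, so rows are filtered before parsing)
.firstModelCif <- function(lines) {
  entry <- NULL
  d <- grep("^data_", lines)
  if (length(d) > 0) entry <- sub("^data_", "", lines[d[1]])
  fields <- grep("^_atom_site\\.", lines)
  if (length(fields) == 0) return(list(lines = lines, entry = entry))
  nm <- sub("^_atom_site\\.", "", trimws(lines[fields]))
  mcol <- match("pdbx_PDB_model_num", nm)
  if (is.na(mcol)) return(list(lines = lines, entry = entry))
  first <- max(fields) + 1L
  last <- first - 1L
  while (last + 1L <= length(lines)) {
    nxt <- lines[last + 1L]
    if (grepl("^\\s*(#|loop_|_[A-Za-z]|data_)", nxt) || !nzchar(trimws(nxt))) break
    last <- last + 1L
  }
  if (last < first) return(list(lines = lines, entry = entry))
  rows <- lines[first:last]
  toks <- strsplit(trimws(rows), "\\s+")
  models <- vapply(toks, function(t) t[mcol], "")
  keep <- models == models[1]
  list(lines = c(lines[1:(first - 1L)], rows[keep],
                 if (last < length(lines)) lines[(last + 1L):length(lines)]),
       entry = entry)
}

# normalize a bio3d atom table: drop hydrogens, collapse altlocs, categorize
.modelFromBio3d <- function(at, entry, format) {
  if (nrow(at) == 0) stop("empty coordinate section")
  elesy <- at$elesy
  elesy[is.na(elesy) | !nzchar(trimws(elesy))] <-
    substr(gsub("[^A-Za-z].*", "", at$elety[is.na(elesy) | !nzchar(trimws(elesy))]), 1, 1)
  elesy <- toupper(trimws(elesy))
  keep <- !(elesy %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elesy <- elesy[keep]
  alt <- at$alt
  alt[is.na(alt)] <- ""
  ins <- at$insert
  ins[is.na(ins)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  occ <- pmin(pmax(occ, 0), 1)
  df <- data.frame(rectype = at$type, chain = as.character(at$chain),
                   resno = as.integer(at$resno), insert = ins,
                   resid = as.character(at$resid), category = "polymer",
                   elety = as.character(at$elety), elesy = elesy, alt = alt,
                   occ = occ, x = at$x, y = at$y, z = at$z,
                   stringsAsFactors = FALSE)
  df$category <- ifelse(df$resid %in% c("HOH", "WAT", "DOD"), "water",
                        ifelse(df$rectype == "HETATM", "ligand", "polymer"))
  # altloc collapse: highest occupancy first, then altloc letter
  o <- order(df$chain, df$resno, df$insert, df$resid, df$elety,
             -df$occ, df$alt)
  df <- df[o, ]
  key <- paste(df$chain, df$resno, df$insert, df$resid, df$elety, sep = "\r")
  df <- df[!duplicated(key), ]
  df <- df[order(match(df$chain, unique(df$chain)), df$resno, df$insert), ]
  rownames(df) <- NULL
  new("StructureModel", entryId = entry, atoms = df, sourceFormat = format)
}

#' Write a StructureModel to PDB or mmCIF
#'
#' PDB output goes through \code{bio3d::write.pdb}; mmCIF output is a
#' minimal \code{atom_site} loop (one coordinate model) sufficient to
#' round-trip the package's own fixtures.
#'
#' @param model a [StructureModel-class].
#' @param path output file path.
#' @param format \code{"auto"} (from extension), \code{"pdb"} or \code{"mmcif"}.
#' @return the path, invisibly.
#' @export
writeStructure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  at <- model@atoms
  if (nrow(at) == 0) stop("refusing to write an empty model")
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     type = at$rectype,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$resno, resid = at$resid,
                     chain = at$chain,
                     insert = ifelse(nzchar(at$insert), at$insert, ""),
                     alt = ifelse(nzchar(at$alt), at$alt, ""),
                     eleno = seq_len(nrow(at)), elety = at$elety,
                     o = at$occ, b = rep(0, nrow(at)), elesy = at$elesy)
  } else {
    hdr <- c(paste0("data_", model@entryId), "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
    rows <- sprintf("%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
                    at$rectype, seq_len(nrow(at)), at$elesy, at$elety,
                    ifelse(nzchar(at$alt), at$alt, "."), at$resid, at$chain,
                    at$resno, ifelse(nzchar(at$insert), at$insert, "?"),
                    at$x, at$y, at$z, at$occ, at$resno, at$resid, at$chain,
                    at$elety)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Enumerate adenine-nucleotide ligand instances in a model
#'
#' Finds every hetero residue whose component code is in \code{codes}
#' (subset of ATP, ANP, ACP, APC, ZAN, AGS, ADP, AMP) and resolves the
#' atoms the geometric screen anchors on: the nine purine ring atoms, the
#' adenine C5, and the gamma-phosphate phosphorus PG.  PG is never
#' assigned for ADP or AMP.  A nucleotide residue missing all nine purine
#' atoms is excluded with a warning.
#'
#' @param model a [StructureModel-class].
#' @param codes character vector of component codes to admit.
#' @return list of [LigandInstance-class] objects, ordered by chain then
#'   residue number.
#' @export
extractLigands <- function(model,
                           codes = .TRIPHOSPHATE_CODES) {
  stopifnot(all(codes %in% .NUCLEOTIDE_CODES))
  at <- model@atoms
  sel <- at$category == "ligand" & at$resid %in% codes
  if (!any(sel)) return(list())
  sub <- at[sel, ]
  key <- unique(sub[, c("chain", "resno", "insert", "resid")])
  key <- key[order(key$chain, key$resno, key$insert), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(key))) {
    ra <- sub[sub$chain == key$chain[i] & sub$resno == key$resno[i] &
                sub$insert == key$insert[i] & sub$resid == key$resid[i], ]
    purine <- intersect(.PURINE_ATOMS, ra$elety)
    if (length(purine) == 0) {
      warning("ligand ", key$resid[i], " ", key$chain[i], key$resno[i],
              " in ", model@entryId,
              " lacks all purine ring atoms; excluded")
      next
    }
    c5 <- if ("C5" %in% ra$elety)
      as.numeric(ra[ra$elety == "C5", c("x", "y", "z")][1, ]) else numeric(0)
    pg <- if ("PG" %in% ra$elety && !key$resid[i] %in% c("ADP", "AMP"))
      as.numeric(ra[ra$elety == "PG", c("x", "y", "z")][1, ]) else numeric(0)
    out[[length(out) + 1L]] <-
      new("LigandInstance", compId = key$resid[i], chainId = key$chain[i],
          seqNum = as.integer(key$resno[i]), insert = key$insert[i],
          atoms = ra, purineAtoms = purine, c5 = c5, pg = pg)
  }
  out
}
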