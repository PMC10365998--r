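.CONFIG_DEFAULTS <- list(
  stages = c("simulate", "screen", "scan", "logo", "tree", "superpose"),
  outDir = "allosite_run", seed = 1L, logLevel = "info",
  # simulate
  nStructures = 12L, nSequences = 60L, sequenceLength = 800L,
  prevalence = 0.75, fungalFraction = 0, anchorStart = 702L,
  # screen
  structuresDir = "", screenMode = "full",
  dAromatic = 5, dArg = 5, stackingCentroidMax = 5, stackingAngleMax = 30,
  # scan
  fastaPath = "", referencePath = "", minIdentity = 60,
  fungalVariant = FALSE, spacerSlack = 0L,
  # logo / tree
  flank = 3L, maxTreeTaxa = 60L,
  # superpose
  superposeNoise = 0.2)

#' Build a pipeline configuration
#'
#' Named-argument overrides on top of the defaults; unknown keys are
#' rejected.  Defaults match the published screen parameters (5 Angstrom
#' cutoffs, the 8-anchor motif offsets, 60 percent identity filter).
#'
#' @param ... overrides of the default keys (see
#'   [readPipelineConfig()] for the key list).
#' @return named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, over)
  bad <- setdiff(cfg$stages, .CONFIG_DEFAULTS$stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from a key=value file
#'
#' Plain-text format: one \code{key = value} per line, \code{#} comments,
#' comma-separated lists for multi-valued keys (e.g. \code{stages}).
#' Unknown keys are rejected.
#'
#' @param path configuration file.
#' @return a \code{"PipelineConfig"} list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*(.*)$",
                                  lines))
  if (any(lengths(kv) != 3))
    stop("malformed configuration line: ", lines[which(lengths(kv) != 3)[1]])
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  over <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(.CONFIG_DEFAULTS))
      stop("unknown configuration key(s): ", k)
    proto <- .CONFIG_DEFAULTS[[k]]
    v <- trimws(strsplit(vals[i], ",")[[1]])
    v <- if (is.logical(proto)) as.logical(v)
    else if (is.integer(proto)) as.integer(v)
    else if (is.numeric(proto)) as.numeric(v)
    else v
    over[[k]] <- v
  }
  do.call(pipelineConfig, over)
}

# serialize a config deterministically (echoed into every run directory)
.writeConfig <- function(cfg, path) {
  keys <- names(.CONFIG_DEFAULTS)
  lines <- vapply(keys, function(k)
    paste0(k, " = ", paste(cfg[[k]], collapse = ",")), "")
  writeLines(lines, path)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (structure
#' fixtures + sequence family), screen, scan, logo, tree, superpose —
#' writing every artifact under \code{outDir} and a
#' \code{manifest.json} listing each output with its MD5 hash.  With a
#' fixed configuration and seed the run is byte-identical, hence so is
#' the manifest.  Missing inputs for an enabled stage raise an error
#' naming the stage before any computation in it.
#'
#' @param config a [pipelineConfig()] (or path to a config file).
#' @return invisibly, a named character vector of artifact MD5 hashes
#'   (the manifest).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  cfg <- config
  log <- function(...) if (cfg$logLevel != "quiet")
    message("[allosite] ", ...)
  out <- cfg$outDir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  .writeConfig(cfg, file.path(out, "config.cfg"))
  artifacts <- file.path(out, "config.cfg")
  stages <- cfg$stages
  structPaths <- NULL; family <- NULL; reference <- NULL
  survey <- NULL; spec <- motifSpec(cfg$fungalVariant, cfg$spacerSlack)

  # stage input checks before any computation
  if ("screen" %in% stages && !"simulate" %in% stages &&
      !dir.exists(cfg$structuresDir))
    stop("stage 'screen': no structures (enable simulate or set structuresDir)")
  if ("scan" %in% stages && !"simulate" %in% stages &&
      (!file.exists(cfg$fastaPath) || !file.exists(cfg$referencePath)))
    stop("stage 'scan': no sequences (enable simulate or set fastaPath/referencePath)")
  if (any(c("logo", "tree") %in% stages) && !"scan" %in% stages)
    stop("stages 'logo'/'tree' require the scan stage")

  if ("simulate" %in% stages) {
    log("simulate: ", cfg$nStructures, " structures, ",
        cfg$nSequences, " sequences (seed ", cfg$seed, ")")
    sdir <- file.path(out, "structures")
    lib <- makeStructureLibrary(cfg$nStructures, sdir, seed = cfg$seed)
    structPaths <- lib$path
    fam <- makeSequenceFamily(
      familyDesign(nSequences = cfg$nSequences, length = cfg$sequenceLength,
                   motifPrevalence = cfg$prevalence,
                   fungalFraction = cfg$fungalFraction,
                   anchorStart = cfg$anchorStart, seed = cfg$seed),
      fasta = file.path(out, "family.fasta"))
    family <- fam$sequences; reference <- fam$reference
    writeLines(c(">reference", reference), file.path(out, "reference.fasta"))
    artifacts <- c(artifacts, file.path(sdir, "labels.tsv"), structPaths,
                   file.path(out, "family.fasta"),
                   file.path(out, "family.fasta.labels.tsv"),
                   file.path(out, "reference.fasta"))
  }

  if ("screen" %in% stages) {
    if (is.null(structPaths))
      structPaths <- list.files(cfg$structuresDir,
                                pattern = "\\.(pdb|ent|cif|mmcif)$",
                                full.names = TRUE)
    log("screen: ", length(structPaths), " structures")
    crit <- screenCriteria(cfg$dAromatic, cfg$dArg,
                           stackingCentroidMax = cfg$stackingCentroidMax,
                           stackingAngleMax = cfg$stackingAngleMax)
    hits <- screenLibrary(structPaths, crit, mode = cfg$screenMode)
    hitsPath <- file.path(out, "hits.tsv")
    utils::write.table(hits, hitsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    summ <- list(perSite = as.list(tierCounts(hits, "site")),
                 perEntry = as.list(tierCounts(hits, "entry")))
    jsonlite::write_json(summ, file.path(out, "screen_summary.json"),
                         auto_unbox = TRUE)
    artifacts <- c(artifacts, hitsPath, file.path(out, "screen_summary.json"))
  }

  if ("scan" %in% stages) {
    if (is.null(family)) {
      fam <- Biostrings::readAAStringSet(cfg$fastaPath)
      family <- as.character(fam)
      reference <- as.character(
        Biostrings::readAAStringSet(cfg$referencePath))[[1]]
    }
    log("scan: ", length(family), " sequences vs reference")
    survey <- motifSurvey(family, reference, cfg$minIdentity, spec)
    utils::write.table(survey$table, file.path(out, "survey.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(nPassIdentity = survey$nPassIdentity,
                              nMotif = survey$nMotif,
                              prevalence = survey$prevalence),
                         file.path(out, "survey_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    pos <- survey$table$id[survey$table$motifPresent]
    Biostrings::writeXStringSet(Biostrings::AAStringSet(family[pos]),
                                file.path(out, "motif_positive.fasta"))
    artifacts <- c(artifacts, file.path(out, "survey.tsv"),
                   file.path(out, "survey_summary.json"),
                   file.path(out, "motif_positive.fasta"))
  }

  if ("logo" %in% stages) {
    tabPos <- survey$table[survey$table$motifPresent, ]
    if (nrow(tabPos) == 0) stop("stage 'logo': no motif-positive sequences")
    log("logo: ", nrow(tabPos), " motif-positive sequences, flank ",
        cfg$flank)
    pfm <- anchorWindows(family[tabPos$id], tabPos$matchStart, spec,
                         cfg$flank)
    jsonlite::write_json(
      list(offsets = pfm@offsets, counts = pfm@counts,
           gaps = pfm@gaps, nSequences = pfm@nSequences,
           bits = unname(informationContent(pfm))),
      file.path(out, "logo.json"), digits = NA)
    artifacts <- c(artifacts, file.path(out, "logo.json"))
  }

  if ("tree" %in% stages) {
    tabPos <- survey$table[survey$table$motifPresent, ]
    if (nrow(tabPos) < 3) stop("stage 'tree': fewer than 3 motif-positive sequences")
    ids <- utils::head(tabPos$id, cfg$maxTreeTaxa)
    log("tree: neighbor-joining over ", length(ids), " sequences")
    D <- pDistanceMatrix(family[ids])
    tr <- neighborJoining(D)
    writeLines(tr@newick, file.path(out, "tree.nwk"))
    artifacts <- c(artifacts, file.path(out, "tree.nwk"))
  }

  if ("superpose" %in% stages) {
    log("superpose: ligand-bound vs perturbed free form")
    # bound form and a ligand-free copy with seeded coordinate noise,
    # emulating the free-vs-bound comparison
    g <- siteGeometry(seed = cfg$seed, entryId = "BOUND")
    bound <- makeBindingSiteStructure(g)$model
    freeAtoms <- bound@atoms[bound@atoms$category == "polymer", ]
    set.seed(cfg$seed + 1L)
    nz <- nrow(freeAtoms)
    freeAtoms$x <- freeAtoms$x + stats::rnorm(nz, 0, cfg$superposeNoise)
    freeAtoms$y <- freeAtoms$y + stats::rnorm(nz, 0, cfg$superposeNoise)
    freeAtoms$z <- freeAtoms$z + stats::rnorm(nz, 0, cfg$superposeNoise)
    rownames(freeAtoms) <- NULL
    free <- new("StructureModel", entryId = "FREE", atoms = freeAtoms,
                sourceFormat = "synthetic")
    sup <- superposeCalpha(bound, free)
    jsonlite::write_json(list(rotation = sup@rotation,
                              translation = sup@translation,
                              nPairs = sup@nPairs, rmsd = sup@rmsd),
                         file.path(out, "superpose.json"), digits = NA)
    artifacts <- c(artifacts, file.path(out, "superpose.json"))
  }

  manifest <- tools::md5sum(sort(unique(artifacts)))
  pref <- paste0(out, "/")
  names(manifest) <- ifelse(startsWith(names(manifest), pref),
                            substring(names(manifest), nchar(pref) + 1L),
                            names(manifest))
  jsonlite::write_json(as.list(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE)
  log("done: ", length(manifest), " artifacts in ", out)
  invisible(manifest)
}
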