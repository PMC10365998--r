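# shared oracles and fixture builders (everything generated in code)

# brute-force O(n^2) contact oracle: scan every polymer atom, no indexing
bruteAromaticContacts <- function(model, ligand, cutoff = 5,
                                  aromaticSet = c("TYR", "TRP", "PHE", "HIS")) {
  at <- atomTable(model)
  c5 <- c5Coords(ligand)
  hits <- data.frame(chain = character(0), resno = integer(0), d = numeric(0))
  for (i in seq_len(nrow(at))) {
    if (at$category[i] != "polymer") next
    if (!at$resid[i] %in% aromaticSet) next
    if (at$elety[i] != "CG") next
    d <- sqrt(sum((c(at$x[i], at$y[i], at$z[i]) - c5)^2))
    if (d <= cutoff)
      hits <- rbind(hits, data.frame(chain = at$chain[i],
                                     resno = at$resno[i], d = d))
  }
  hits[order(hits$d, hits$chain, hits$resno), , drop = FALSE]
}

bruteArgContacts <- function(model, ligand, cutoff = 5) {
  at <- atomTable(model)
  pg <- pgCoords(ligand)
  hits <- data.frame(chain = character(0), resno = integer(0), d = numeric(0))
  if (length(pg) != 3) return(hits)
  for (i in seq_len(nrow(at))) {
    if (at$category[i] != "polymer" || at$resid[i] != "ARG" ||
        at$elety[i] != "CZ") next
    d <- sqrt(sum((c(at$x[i], at$y[i], at$z[i]) - pg)^2))
    if (d <= cutoff)
      hits <- rbind(hits, data.frame(chain = at$chain[i],
                                     resno = at$resno[i], d = d))
  }
  hits[order(hits$d), , drop = FALSE]
}

# brute-force motif oracle: test every window against the anchor table
bruteMotifScan <- function(seq, fungal = FALSE) {
  chars <- strsplit(toupper(seq), "")[[1]]
  offs <- c(0, 1, 4, 8, 9, 17, 19, 51)
  allowed <- list("P", "W", "H", "Y", if (fungal) c("R", "K") else "R",
                  "H", "R", "R")
  starts <- integer(0)
  for (s in seq_len(max(0, length(chars) - 51))) {
    ok <- TRUE
    for (k in 1:8)
      if (!chars[s + offs[k]] %in% allowed[[k]]) { ok <- FALSE; break }
    if (ok) starts <- c(starts, s)
  }
  starts
}

# numerical superposition oracle: minimize RMSD over rotations directly
bruteKabschRmsd <- function(xa, xb) {
  A <- sweep(xa, 2, colMeans(xa))
  B <- sweep(xb, 2, colMeans(xb))
  rotFromAngles <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) sqrt(mean(rowSums((B %*% t(rotFromAngles(p)) - A)^2)))
  best <- Inf
  for (s in 1:8) {
    p0 <- stats::runif(3, -pi, pi)
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, fit$value)
  }
  best
}

# minimal hand-built one-chain model: a ligand C5/PG plus named atoms at
# explicit coordinates, bypassing the generator entirely
handModel <- function(rows, entryId = "HAND") {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(rectype = r$rectype, chain = r$chain, resno = r$resno,
               insert = "", resid = r$resid,
               category = if (r$rectype == "HETATM") "ligand" else "polymer",
               elety = r$elety, elesy = substr(r$elety, 1, 1), alt = "",
               occ = 1, x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  new("StructureModel", entryId = entryId, atoms = df,
      sourceFormat = "synthetic")
}

atomRow <- function(rectype, chain, resno, resid, elety, xyz)
  list(rectype = rectype, chain = chain, resno = resno, resid = resid,
       elety = elety, xyz = xyz)

tierIndex <- function(tier)
  match(tier, c("none", "T1_pair_contact", "T2_cross_subunit",
                "T3_dual_stacking", "T4_full"))
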