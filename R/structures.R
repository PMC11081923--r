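## Coordinate handling: PDB reading, amide hydrogen placement, NH bond
## vectors and Kabsch superposition.

#' Construct a ProteinStructure from an atom table
#'
#' Mostly used internally by [readStructure()] and the synthetic builder;
#' exposed so tests and users can assemble structures programmatically.
#' Gaps are inferred per chain as residue numbers between the first and
#' last observed residue that have no atoms.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`, `altloc`, `occupancy`.
#' @return a [ProteinStructure-class] object.
#' @export
proteinStructure <- function(atoms) {
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$altloc <- as.character(atoms$altloc)
  gaps <- integer(0)
  for (ch in unique(atoms$chain)) {
    rn <- sort(unique(atoms$resno[atoms$chain == ch]))
    if (length(rn) > 1)
      gaps <- union(gaps, setdiff(seq(min(rn), max(rn)), rn))
  }
  gaps <- sort(setdiff(as.integer(gaps), atoms$resno))
  firsts <- !duplicated(atoms$resno)
  sq <- stats::setNames(atoms$resname[firsts],
                        as.character(atoms$resno[firsts]))
  sq <- sq[order(as.integer(names(sq)))]
  new("ProteinStructure", atoms = atoms, sequence = sq, gaps = gaps)
}

#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM records (via bio3d), keeps the requested model, and
#' resolves alternate locations by keeping the highest-occupancy altloc
#' (ties broken alphabetically, so 'A' wins). Residue numbers follow the
#' author numbering in the file; numbering discontinuities are recorded as
#' gaps.
#'
#' @param path PDB file.
#' @param modelIndex 1-based model number for multi-model files.
#' @param keepHetatm keep HETATM records (waters, ions)? Default `FALSE`.
#' @return a [ProteinStructure-class] object.
#' @export
readStructure <- function(path, modelIndex = 1L, keepHetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (!keepHetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms in model: ", path)
  nModels <- nrow(pdb$xyz)
  if (modelIndex < 1L || modelIndex > nModels)
    stop("model_index ", modelIndex, " out of range (file has ",
         nModels, " model(s))")
  if (modelIndex > 1L) {
    xyz <- matrix(pdb$xyz[modelIndex, ], ncol = 3L, byrow = TRUE)
    keep <- which(pdb$atom$type == "ATOM" | keepHetatm)
    a$x <- xyz[keep, 1]; a$y <- xyz[keep, 2]; a$z <- xyz[keep, 3]
  }
  occ <- a$o
  occ[is.na(occ)] <- 1
  alt <- a$alt
  alt[is.na(alt)] <- ""
  df <- data.frame(chain = as.character(a$chain), resno = a$resno,
                   resname = a$resid, atom = a$elety,
                   element = ifelse(is.na(a$elesy) | a$elesy == "",
                                    substr(gsub("[0-9]", "", a$elety), 1, 1),
                                    a$elesy),
                   x = a$x, y = a$y, z = a$z,
                   altloc = alt, occupancy = occ,
                   stringsAsFactors = FALSE)
  df <- resolveAltlocs(df)
  proteinStructure(df)
}

## Highest occupancy wins; ties resolved alphabetically (blank < 'A' <
## 'B'), so the 'A' conformer is kept on a tie between lettered altlocs.
resolveAltlocs <- function(df) {
  ord <- order(df$chain, df$resno, df$atom, -df$occupancy, df$altloc)
  df <- df[ord, , drop = FALSE]
  key <- paste(df$chain, df$resno, df$atom)
  df <- df[!duplicated(key), , drop = FALSE]
  df[order(df$chain, df$resno, match(df$atom, unique(df$atom))), ,
     drop = FALSE]
}

#' Place backbone amide hydrogens
#'
#' Adds an idealised amide hydrogen to every non-proline residue that has
#' none: H lies in the C(i-1)-N(i)-CA(i) plane along the external bisector
#' of the C-N-CA angle, at `nhLength` from N. Prolines, N-terminal
#' residues (no preceding carbonyl carbon, e.g. after a chain break) and
#' residues already carrying an amide H are left untouched.
#'
#' @param s a [ProteinStructure-class].
#' @param nhLength N-H bond length in Angstrom (default 1.02).
#' @return a new [ProteinStructure-class] including the placed hydrogens.
#' @export
placeAmideHydrogens <- function(s, nhLength = 1.02) {
  a <- atoms(s)
  newRows <- list()
  for (ch in unique(a$chain)) {
    ca <- a[a$chain == ch, , drop = FALSE]
    resnos <- sort(unique(ca$resno))
    for (rn in resnos) {
      res <- ca[ca$resno == rn, , drop = FALSE]
      if (res$resname[1] == "PRO") next
      if (any(res$atom %in% c("H", "HN"))) next
      prev <- ca[ca$resno == rn - 1L, , drop = FALSE]
      nAt <- res[res$atom == "N", , drop = FALSE]
      caAt <- res[res$atom == "CA", , drop = FALSE]
      cAt <- prev[prev$atom == "C", , drop = FALSE]
      if (nrow(nAt) != 1L || nrow(caAt) != 1L) {
        if (rn != resnos[1L])
          warning("residue ", rn, ": backbone N/CA missing; H not placed")
        next
      }
      if (nrow(cAt) != 1L) {
        ## N-terminal residue (or residue after a gap): no preceding
        ## carbonyl carbon, amide H geometry undefined -> skip quietly.
        next
      }
      N <- as.numeric(nAt[, c("x", "y", "z")])
      CA <- as.numeric(caAt[, c("x", "y", "z")])
      C <- as.numeric(cAt[, c("x", "y", "z")])
      u1 <- vunit(N - C); u2 <- vunit(N - CA)
      bis <- u1 + u2
      if (vnorm(bis) < 1e-8) {
        warning("colinear C-N-CA at residue ", rn, "; H not placed")
        next
      }
      H <- N + nhLength * vunit(bis)
      newRows[[length(newRows) + 1L]] <- data.frame(
        chain = ch, resno = rn, resname = res$resname[1], atom = "H",
        element = "H", x = H[1], y = H[2], z = H[3], altloc = "",
        occupancy = 1, stringsAsFactors = FALSE)
    }
  }
  if (!length(newRows)) return(s)
  proteinStructure(rbind(a, do.call(rbind, newRows)))
}

#' Extract NH bond unit vectors
#'
#' One unit vector (N to H) per residue possessing both backbone N and an
#' amide H; residues lacking either atom are silently omitted.
#'
#' @param s a [ProteinStructure-class] (run [placeAmideHydrogens()] first
#'   if the coordinates lack hydrogens).
#' @return data.frame with columns `resno`, `x`, `y`, `z`; each row a unit
#'   vector.
#' @export
nhBondVectors <- function(s) {
  a <- atoms(s)
  nAt <- a[a$atom == "N", , drop = FALSE]
  hAt <- a[a$atom %in% c("H", "HN"), , drop = FALSE]
  common <- intersect(nAt$resno, hAt$resno)
  out <- lapply(sort(common), function(rn) {
    N <- as.numeric(nAt[match(rn, nAt$resno), c("x", "y", "z")])
    H <- as.numeric(hAt[match(rn, hAt$resno), c("x", "y", "z")])
    v <- vunit(H - N)
    data.frame(resno = rn, x = v[1], y = v[2], z = v[3])
  })
  if (!length(out))
    return(data.frame(resno = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  do.call(rbind, out)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Matches atoms between the two structures by (chain, residue number,
#' atom name) intersection -- hydrogens excluded by default -- and returns
#' the proper rotation and translation minimising the coordinate RMSD of
#' the mobile structure onto the reference. A reflection is never
#' returned.
#'
#' @param mobile,reference [ProteinStructure-class] objects.
#' @param selection which atoms enter the match: `"heavy"` (all
#'   non-hydrogen, default), `"backbone"` (N, CA, C, O), `"CA"`, or
#'   `"all"`.
#' @return a [Superposition-class]; apply as `R x + t` to mobile
#'   coordinates.
#' @export
superpose <- function(mobile, reference,
                      selection = c("heavy", "backbone", "CA", "all")) {
  selection <- match.arg(selection)
  pick <- function(a) {
    a <- switch(selection,
      heavy = a[!(a$element %in% c("H", "D")), , drop = FALSE],
      backbone = a[a$atom %in% c("N", "CA", "C", "O"), , drop = FALSE],
      CA = a[a$atom == "CA", , drop = FALSE],
      all = a)
    a$key <- paste(a$chain, a$resno, a$atom)
    a
  }
  am <- pick(atoms(mobile)); ar <- pick(atoms(reference))
  common <- intersect(am$key, ar$key)
  n <- length(common)
  if (n < 3L) stop("need at least 3 matched atom pairs, got ", n)
  X <- as.matrix(am[match(common, am$key), c("x", "y", "z")])
  Y <- as.matrix(ar[match(common, ar$key), c("x", "y", "z")])
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2, xbar); Yc <- sweep(Y, 2, ybar)
  if (min(svd(Xc)$d) < 1e-8 * max(svd(Xc)$d))
    stop("degenerate (collinear) atom selection")
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- as.numeric(ybar - R %*% xbar)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  new("Superposition", rotation = R, translation = tvec, rmsd = rmsd,
      nAtoms = as.integer(n))
}

#' Write a superposition report as TSV
#'
#' @param sp a [Superposition-class].
#' @param path output file.
#' @export
writeSuperpositionReport <- function(sp, path) {
  R <- rotationMatrix(sp)
  df <- data.frame(
    n_atoms = sp@nAtoms, rmsd_angstrom = rmsdValue(sp),
    r11 = R[1, 1], r12 = R[1, 2], r13 = R[1, 3],
    r21 = R[2, 1], r22 = R[2, 2], r23 = R[2, 3],
    r31 = R[3, 1], r32 = R[3, 2], r33 = R[3, 3],
    tx = sp@translation[1], ty = sp@translation[2], tz = sp@translation[3])
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a structure to a PDB file
#'
#' @param s a [ProteinStructure-class].
#' @param path output file.
#' @export
writeStructurePdb <- function(s, path) {
  a <- atoms(s)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, elety = a$atom,
                   chain = a$chain, o = a$occupancy)
  invisible(path)
}
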