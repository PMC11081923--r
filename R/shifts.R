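## Chemical-shift tables: parsing, assignment completeness, secondary
## shifts and titration chemical-shift perturbations.

#' Construct a ShiftTable
#'
#' @param entries data.frame with columns `resno`, `resname`, `atom`,
#'   `shift` (ppm).
#' @param sequence optional named character vector (residue number ->
#'   3-letter code) giving the full construct sequence; defaults to the
#'   residues seen in `entries`.
#' @return a [ShiftTable-class].
#' @export
shiftTable <- function(entries, sequence = NULL) {
  entries$resno <- as.integer(entries$resno)
  entries$resname <- toupper(as.character(entries$resname))
  entries$atom <- toupper(as.character(entries$atom))
  entries$shift <- as.numeric(entries$shift)
  if (is.null(sequence)) {
    firsts <- !duplicated(entries$resno)
    sequence <- stats::setNames(entries$resname[firsts],
                                as.character(entries$resno[firsts]))
  }
  sequence <- sequence[order(as.integer(names(sequence)))]
  new("ShiftTable", entries = entries, sequence = sequence)
}

#' Read assigned chemical shifts
#'
#' Accepts either an NMR-STAR file (the `_Atom_chem_shift` loop of an
#' `assigned_chemical_shifts` save frame, the BMRB deposition format) or a
#' plain 4-column TSV with header `resno`, `resname`, `atom`, `shift`.
#' The format is sniffed from the file content.
#'
#' Duplicate (residue, atom) rows and residue-name inconsistencies raise
#' errors naming the offending residue.
#'
#' @param path input file.
#' @param sequence optional full construct sequence (named character,
#'   residue number -> 3-letter code) for completeness accounting.
#' @return a [ShiftTable-class].
#' @export
readShiftTable <- function(path, sequence = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isStar <- any(grepl("_Atom_chem_shift\\.", lines))
  df <- if (isStar) parseNmrStarShifts(lines) else {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    need <- c("resno", "resname", "atom", "shift")
    if (!all(need %in% names(d)))
      stop("TSV shift table must have columns: ",
           paste(need, collapse = ", "))
    d[, need]
  }
  shiftTable(df, sequence = sequence)
}

## Minimal NMR-STAR reader for the assigned-chemical-shift loop: finds the
## loop whose tags start with _Atom_chem_shift., records the tag order and
## reads whitespace-delimited rows until stop_. No installed R package
## parses NMR-STAR, so this is done in-package.
parseNmrStarShifts <- function(lines) {
  lines <- trimws(lines)
  loopStarts <- which(lines == "loop_")
  for (ls in loopStarts) {
    tags <- character(0)
    i <- ls + 1L
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i]); i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    rows <- list()
    while (i <= length(lines) && lines[i] != "stop_") {
      if (nzchar(lines[i]) && !startsWith(lines[i], "#")) {
        f <- strsplit(lines[i], "[[:space:]]+")[[1]]
        if (length(f) == length(tags)) rows[[length(rows) + 1L]] <- f
      }
      i <- i + 1L
    }
    if (!length(rows)) stop("empty _Atom_chem_shift loop")
    m <- do.call(rbind, rows)
    colnames(m) <- sub("^_Atom_chem_shift\\.", "", tags)
    pickCol <- function(cands) {
      hit <- cands[cands %in% colnames(m)][1]
      if (is.na(hit)) stop("NMR-STAR loop lacks any of: ",
                           paste(cands, collapse = ", "))
      m[, hit]
    }
    resno <- pickCol(c("Auth_seq_ID", "Seq_ID", "Comp_index_ID"))
    ## Auth_seq_ID may be '.'; fall back to the deposition numbering
    if (any(resno %in% c(".", "?")))
      resno <- pickCol(c("Seq_ID", "Comp_index_ID"))
    return(data.frame(
      resno = as.integer(resno),
      resname = toupper(pickCol("Comp_ID")),
      atom = toupper(pickCol("Atom_ID")),
      shift = as.numeric(pickCol("Val")),
      stringsAsFactors = FALSE))
  }
  stop("no _Atom_chem_shift loop found")
}

#' Random-coil CA/CB reference shifts
#'
#' Bundled random-coil 13C chemical shifts (ppm, DSS-referenced) for the
#' twenty standard residues, from the published peptide random-coil scale
#' of Wishart and co-workers. Used as the baseline for secondary-shift
#' calculation.
#'
#' @return data.frame with columns `resname`, `CA`, `CB` (`CB` is `NA`
#'   for glycine).
#' @export
randomCoilShifts <- function() {
  data.frame(
    resname = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                "THR", "TRP", "TYR", "VAL"),
    CA = c(52.5, 56.0, 53.1, 54.2, 58.2, 55.7, 56.6, 45.1, 55.0, 61.1,
           55.1, 56.2, 55.4, 57.7, 63.3, 58.3, 61.8, 57.5, 57.9, 62.2),
    CB = c(19.1, 30.9, 38.9, 41.1, 28.0, 29.4, 29.9, NA, 29.0, 38.8,
           42.4, 33.1, 32.9, 39.6, 32.1, 63.8, 69.8, 29.6, 38.8, 32.9),
    stringsAsFactors = FALSE)
}

## Expected-atom chemistry per completeness class. Each rule returns the
## residue numbers of `sequence` for which the class is chemically
## expected, plus a predicate for "assigned".
completenessClasses <- function() {
  list(
    "HN_N" = list(
      expected = function(sq) names(sq)[sq != "PRO"],
      assigned = function(e, rn) any(e$atom %in% c("H", "HN") & e$resno == rn) &&
        any(e$atom == "N" & e$resno == rn)),
    "H" = list(
      expected = function(sq) names(sq)[sq != "PRO"],
      assigned = function(e, rn) any(e$atom %in% c("H", "HN") & e$resno == rn)),
    "N" = list(
      expected = function(sq) names(sq)[sq != "PRO"],
      assigned = function(e, rn) any(e$atom == "N" & e$resno == rn)),
    "CA" = list(
      expected = function(sq) names(sq),
      assigned = function(e, rn) any(e$atom == "CA" & e$resno == rn)),
    "C" = list(
      expected = function(sq) names(sq),
      assigned = function(e, rn) any(e$atom == "C" & e$resno == rn)),
    "HA" = list(
      expected = function(sq) names(sq),
      assigned = function(e, rn)
        any(e$atom %in% c("HA", "HA2", "HA3") & e$resno == rn)),
    "CB" = list(
      expected = function(sq) names(sq)[sq != "GLY"],
      assigned = function(e, rn) any(e$atom == "CB" & e$resno == rn)),
    "HB" = list(
      expected = function(sq) names(sq)[sq != "GLY"],
      assigned = function(e, rn)
        any(e$atom %in% c("HB", "HB1", "HB2", "HB3") & e$resno == rn)))
}

#' Assignment completeness for an atom class
#'
#' Counts residues where the atom class is chemically expected (prolines
#' have no amide H or N; glycine has no CB/HB; glycine HA counts via
#' HA2/HA3) and the fraction of those actually assigned. Percentages are
#' rounded to one decimal, matching the conventional reporting precision.
#'
#' @param t a [ShiftTable-class] whose `sequence` covers the construct.
#' @param atomClass one of `"HN_N"` (amide 1H and 15N both assigned),
#'   `"H"`, `"N"`, `"CA"`, `"C"` (carbonyl), `"HA"`, `"CB"`, `"HB"`.
#' @return list with `assigned`, `possible`, `percent`.
#' @export
assignmentCompleteness <- function(t, atomClass = "HN_N") {
  classes <- completenessClasses()
  if (!atomClass %in% names(classes))
    stop("unknown atom class '", atomClass, "'; available: ",
         paste(names(classes), collapse = ", "))
  sq <- residueSequence(t)
  if (!length(sq)) stop("shift table has no sequence")
  rule <- classes[[atomClass]]
  possible <- as.integer(rule$expected(sq))
  e <- shiftEntries(t)
  assigned <- sum(vapply(possible, function(rn) rule$assigned(e, rn),
                         logical(1)))
  list(assigned = as.integer(assigned), possible = length(possible),
       percent = round(100 * assigned / length(possible), 1))
}

#' CA/CB secondary shifts
#'
#' Secondary shift = observed shift minus the residue-type random-coil
#' value. The difference dCA - dCB is the classic secondary-structure
#' indicator: positive runs mark alpha-helix, negative runs beta-strand.
#' Glycine (no CB) contributes dCB = 0. Residues lacking an assigned CA
#' (or CB for non-glycine) are omitted.
#'
#' @param t a [ShiftTable-class].
#' @param randomCoil reference table as from [randomCoilShifts()].
#' @return data.frame with columns `resno`, `resname`, `deltaCA`,
#'   `deltaCB`, `dCaMinusDcb` (all ppm), sorted by residue.
#' @export
secondaryShifts <- function(t, randomCoil = randomCoilShifts()) {
  e <- shiftEntries(t)
  rc <- randomCoil
  out <- list()
  for (rn in sort(unique(e$resno))) {
    res <- e[e$resno == rn, , drop = FALSE]
    nm <- res$resname[1]
    i <- match(nm, rc$resname)
    if (is.na(i)) next
    caRow <- res[res$atom == "CA", , drop = FALSE]
    if (nrow(caRow) != 1L) next
    dca <- caRow$shift - rc$CA[i]
    if (nm == "GLY") {
      dcb <- 0
    } else {
      cbRow <- res[res$atom == "CB", , drop = FALSE]
      if (nrow(cbRow) != 1L) next
      dcb <- cbRow$shift - rc$CB[i]
    }
    out[[length(out) + 1L]] <- data.frame(
      resno = rn, resname = nm, deltaCA = dca, deltaCB = dcb,
      dCaMinusDcb = dca - dcb)
  }
  if (!length(out))
    return(data.frame(resno = integer(0), resname = character(0),
                      deltaCA = numeric(0), deltaCB = numeric(0),
                      dCaMinusDcb = numeric(0)))
  do.call(rbind, out)
}

#' Segment secondary structure from secondary shifts
#'
#' Simple run-length classifier: consecutive residues with dCA - dCB above
#' `helixCut` form helix candidates, below `strandCut` strand candidates;
#' candidate runs shorter than the minimum length fall back to coil.
#' Breaks in residue numbering (unassigned residues) break runs.
#'
#' @param records output of [secondaryShifts()].
#' @param helixCut ppm threshold for helix (default +0.7).
#' @param strandCut ppm threshold for strand (default -0.7).
#' @param minRunHelix,minRunStrand minimum consecutive residues for a
#'   helix (4) or strand (3) segment.
#' @return data.frame with columns `start`, `end`, `type` (one of
#'   `"helix"`, `"strand"`, `"coil"`).
#' @export
classifySecondaryStructure <- function(records, helixCut = 0.7,
                                       strandCut = -0.7,
                                       minRunHelix = 4L,
                                       minRunStrand = 3L) {
  if (!nrow(records))
    return(data.frame(start = integer(0), end = integer(0),
                      type = character(0)))
  records <- records[order(records$resno), , drop = FALSE]
  lab <- ifelse(records$dCaMinusDcb > helixCut, "helix",
                ifelse(records$dCaMinusDcb < strandCut, "strand", "coil"))
  rn <- records$resno
  ## split into consecutive-numbering blocks, then run-length filter
  block <- cumsum(c(1L, diff(rn) != 1L))
  segs <- list()
  for (b in unique(block)) {
    idx <- which(block == b)
    r <- rle(lab[idx])
    minRun <- ifelse(r$values == "helix", minRunHelix,
                     ifelse(r$values == "strand", minRunStrand, 1L))
    r$values[r$lengths < minRun] <- "coil"
    ## merge adjacent coils created by the demotion
    lab2 <- inverse.rle(r)
    r2 <- rle(lab2)
    ends <- cumsum(r2$lengths)
    starts <- ends - r2$lengths + 1L
    segs[[length(segs) + 1L]] <- data.frame(
      start = rn[idx][starts], end = rn[idx][ends], type = r2$values)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Per-residue labels from classified segments
#'
#' Convenience expansion of [classifySecondaryStructure()] output to a
#' named character vector (residue -> `"H"`/`"E"`/`"C"`), for comparison
#' against a generator's ground-truth layout.
#'
#' @param segments data.frame from [classifySecondaryStructure()].
#' @return named character vector.
#' @export
segmentLabels <- function(segments) {
  code <- c(helix = "H", strand = "E", coil = "C")
  out <- character(0)
  for (i in seq_len(nrow(segments))) {
    rng <- seq(segments$start[i], segments$end[i])
    out[as.character(rng)] <- code[[segments$type[i]]]
  }
  out
}

#' Chemical-shift perturbations between two shift tables
#'
#' Combined amide CSP per residue:
#' `combined = sqrt(dH^2 + (w * dN)^2)` with 15N weight `w` (default
#' 0.15). Residues present in only one table are omitted with a warning.
#'
#' @param reference,perturbed [ShiftTable-class] objects containing amide
#'   `H` and `N` entries.
#' @param nWeight 15N scaling weight.
#' @return data.frame with columns `resno`, `dH`, `dN`, `combined` (ppm).
#' @export
csp <- function(reference, perturbed, nWeight = 0.15) {
  getHN <- function(t) {
    e <- shiftEntries(t)
    h <- e[e$atom %in% c("H", "HN"), c("resno", "shift")]
    n <- e[e$atom == "N", c("resno", "shift")]
    m <- merge(h, n, by = "resno", suffixes = c("_h", "_n"))
    m[order(m$resno), , drop = FALSE]
  }
  a <- getHN(reference); b <- getHN(perturbed)
  common <- intersect(a$resno, b$resno)
  lost <- setdiff(union(a$resno, b$resno), common)
  if (length(lost))
    warning("residues present in only one table omitted: ",
            paste(sort(lost), collapse = " "))
  ia <- match(common, a$resno); ib <- match(common, b$resno)
  dH <- b$shift_h[ib] - a$shift_h[ia]
  dN <- b$shift_n[ib] - a$shift_n[ia]
  data.frame(resno = common, dH = dH, dN = dN,
             combined = sqrt(dH^2 + (nWeight * dN)^2))
}

#' Residues with combined CSP above a threshold
#'
#' @param records data.frame from [csp()].
#' @param threshold ppm; strictly-greater rule (default 0.1).
#' @return sorted integer vector of residue numbers.
#' @export
identifyShifted <- function(records, threshold = 0.1) {
  stopifnot(threshold > 0)
  sort(records$resno[records$combined > threshold])
}

#' Write a shift table as TSV
#'
#' @param t a [ShiftTable-class].
#' @param path output file.
#' @export
writeShiftTable <- function(t, path) {
  utils::write.table(shiftEntries(t), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
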