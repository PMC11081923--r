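#' @import methods
NULL

#' ProteinStructure: atomic coordinates with explicit gaps
#'
#' Container for a protein coordinate set read from a PDB file or built by
#' the synthetic generator. Atoms are stored in a data.frame with one row
#' per atom; residues present in the construct but absent from the
#' coordinates (no electron density, cloning artefacts) are recorded as
#' first-class `gaps` so downstream per-residue analyses can distinguish
#' "missing" from "zero". Author residue numbering is preserved end to end.
#'
#' @slot atoms data.frame with columns `chain`, `resno` (author numbering),
#'   `resname` (3-letter code), `atom`, `element`, `x`, `y`, `z` (Angstrom),
#'   `altloc`, `occupancy`.
#' @slot sequence named character vector mapping residue number to 3-letter
#'   residue name.
#' @slot gaps integer vector of residue numbers with no atoms, inferred
#'   from numbering discontinuities.
#'
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(atoms = "data.frame", sequence = "character",
                 gaps = "integer"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resname", "atom", "element",
            "x", "y", "z", "altloc", "occupancy")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("atom coordinates must be finite")
    occ <- a$occupancy[!is.na(a$occupancy)]
    if (any(occ < 0 | occ > 1))
      return("occupancy must lie in [0, 1]")
    key <- paste(a$chain, a$resno, a$atom, a$altloc)
    if (anyDuplicated(key))
      return("duplicate (chain, residue, atom, altloc) records")
    if (any(object@gaps %in% a$resno))
      return("gaps must be disjoint from residues possessing atoms")
  }
  TRUE
})

#' ShiftTable: assigned chemical shifts
#'
#' One row per assigned atom: residue number (author numbering), 3-letter
#' residue name, atom name and the chemical shift in ppm. The `sequence`
#' slot carries the full construct sequence so completeness statistics can
#' count expected-but-unassigned atoms.
#'
#' @slot entries data.frame with columns `resno`, `resname`, `atom`,
#'   `shift` (ppm).
#' @slot sequence named character vector mapping residue number to 3-letter
#'   residue name for every residue of the construct.
#'
#' @exportClass ShiftTable
setClass("ShiftTable",
  representation(entries = "data.frame", sequence = "character"))

setValidity("ShiftTable", function(object) {
  e <- object@entries
  need <- c("resno", "resname", "atom", "shift")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (!all(is.finite(e$shift)))
      return("shifts must be finite")
    if (anyDuplicated(paste(e$resno, e$atom)))
      return("one entry per (residue, atom) allowed")
    seq <- object@sequence
    if (length(seq)) {
      hit <- as.character(e$resno) %in% names(seq)
      bad <- hit & e$resname != seq[as.character(e$resno)]
      if (any(bad))
        return(paste0("residue name mismatch with sequence at residue ",
                      e$resno[which(bad)[1L]]))
    }
  }
  TRUE
})

#' AlignmentTensor: molecular alignment (Saupe order) tensor
#'
#' Symmetric, traceless 3x3 order matrix describing the weak alignment of
#' the molecule, in Hz (the dipolar interaction constant is folded in, so
#' contracting the matrix with an NH unit vector gives the residual dipolar
#' coupling directly). The conventional parameters -- axial magnitude Da,
#' rhombicity R and z-y-z Euler angles of the principal frame -- are
#' derived from the matrix via [tensorParameters()].
#'
#' @slot saupe numeric 3x3 symmetric traceless matrix, Hz.
#'
#' @exportClass AlignmentTensor
setClass("AlignmentTensor", representation(saupe = "matrix"))

setValidity("AlignmentTensor", function(object) {
  s <- object@saupe
  if (!is.numeric(s) || !all(dim(s) == c(3L, 3L)))
    return("saupe must be a numeric 3x3 matrix")
  if (!all(is.finite(s)))
    return("saupe entries must be finite")
  if (max(abs(s - t(s))) > 1e-9 * max(1, max(abs(s))))
    return("saupe must be symmetric")
  if (abs(sum(diag(s))) > 1e-9 * max(1, max(abs(s))))
    return("saupe must be traceless")
  TRUE
})

#' RdcDataset: per-residue residual dipolar couplings
#'
#' @slot records data.frame with columns `resno`, `d_exp` (Hz), `sigma`
#'   (Hz, > 0) and `domain` (label assigning the residue to a structural
#'   domain).
#' @slot description free-text provenance of the measurement.
#'
#' @exportClass RdcDataset
setClass("RdcDataset",
  representation(records = "data.frame", description = "character"))

setValidity("RdcDataset", function(object) {
  r <- object@records
  need <- c("resno", "d_exp", "sigma", "domain")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (anyDuplicated(r$resno)) return("residue numbers must be unique")
    if (any(!is.finite(r$d_exp))) return("d_exp must be finite")
    if (any(!(r$sigma > 0))) return("sigma must be > 0")
  }
  TRUE
})

#' RdcFit: result of an alignment-tensor fit
#'
#' Produced by [fitTensorSvd()] (single tensor, 5 parameters) and
#' [fitTwoDomainShared()] (shared Da/R, independent orientations, 8
#' parameters). Quality is reported as the uncertainty-weighted chi-squared
#' and as Cornilescu Q factors, overall and per domain.
#'
#' @slot tensors named list of [AlignmentTensor-class] objects, one per
#'   domain label (a single-tensor fit uses one entry named `"all"` or the
#'   pooled domain labels).
#' @slot chi2 numeric, sum of squared sigma-weighted residuals.
#' @slot nData integer, number of couplings fitted.
#' @slot nParams integer, number of free parameters.
#' @slot qPerDomain named numeric, Q factor per domain label.
#' @slot qOverall numeric, Q factor over all fitted couplings.
#' @slot residuesUsed integer vector of residue numbers fitted.
#' @slot details list of extras (back-calculated couplings, per-domain
#'   assignments, nested pooled fit for the two-domain model, optimiser
#'   diagnostics).
#'
#' @exportClass RdcFit
setClass("RdcFit",
  representation(tensors = "list", chi2 = "numeric", nData = "integer",
                 nParams = "integer", qPerDomain = "numeric",
                 qOverall = "numeric", residuesUsed = "integer",
                 details = "list"))

setValidity("RdcFit", function(object) {
  if (object@chi2 < 0) return("chi2 must be >= 0")
  if (object@nParams > object@nData)
    return("nParams must not exceed nData")
  if (any(object@qPerDomain < 0) || any(object@qOverall < 0))
    return("Q factors must be >= 0")
  if (!all(vapply(object@tensors, is, logical(1), "AlignmentTensor")))
    return("tensors must be AlignmentTensor objects")
  TRUE
})

#' Superposition: least-squares rigid-body overlay
#'
#' @slot rotation 3x3 proper orthogonal matrix applied to the mobile
#'   coordinates.
#' @slot translation length-3 numeric, Angstrom.
#' @slot rmsd numeric, Angstrom, over the matched atoms.
#' @slot nAtoms integer, number of matched atom pairs.
#'
#' @exportClass Superposition
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nAtoms = "integer"))

setValidity("Superposition", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthogonal")
  if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det = +1)")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})
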