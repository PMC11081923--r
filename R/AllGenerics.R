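#' Accessor generics
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("residueSequence", function(x) standardGeneric("residueSequence"))

#' @rdname accessors
#' @export
setGeneric("gapResidues", function(x) standardGeneric("gapResidues"))

#' @rdname accessors
#' @export
setGeneric("shiftEntries", function(x) standardGeneric("shiftEntries"))

#' @rdname accessors
#' @export
setGeneric("saupeMatrix", function(x) standardGeneric("saupeMatrix"))

#' @rdname accessors
#' @export
setGeneric("daMagnitude", function(x) standardGeneric("daMagnitude"))

#' @rdname accessors
#' @export
setGeneric("rhombicity", function(x) standardGeneric("rhombicity"))

#' @rdname accessors
#' @export
setGeneric("eulerAngles", function(x) standardGeneric("eulerAngles"))

#' @rdname accessors
#' @export
setGeneric("principalAxes", function(x) standardGeneric("principalAxes"))

#' @rdname accessors
#' @export
setGeneric("rdcRecords", function(x) standardGeneric("rdcRecords"))

#' @rdname accessors
#' @export
setGeneric("tensors", function(x) standardGeneric("tensors"))

#' @rdname accessors
#' @export
setGeneric("chiSquared", function(x) standardGeneric("chiSquared"))

#' @rdname accessors
#' @export
setGeneric("qFactors", function(x) standardGeneric("qFactors"))

#' @rdname accessors
#' @export
setGeneric("rotationMatrix", function(x) standardGeneric("rotationMatrix"))

#' @rdname accessors
#' @export
setGeneric("translationVector",
           function(x) standardGeneric("translationVector"))

#' @rdname accessors
#' @export
setGeneric("rmsdValue", function(x) standardGeneric("rmsdValue"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("residueSequence", "ProteinStructure", function(x) x@sequence)

#' @rdname accessors
#' @export
setMethod("residueSequence", "ShiftTable", function(x) x@sequence)

#' @rdname accessors
#' @export
setMethod("gapResidues", "ProteinStructure", function(x) x@gaps)

#' @rdname accessors
#' @export
setMethod("shiftEntries", "ShiftTable", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("saupeMatrix", "AlignmentTensor", function(x) x@saupe)

#' @rdname accessors
#' @export
setMethod("rdcRecords", "RdcDataset", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("tensors", "RdcFit", function(x) x@tensors)

#' @rdname accessors
#' @export
setMethod("chiSquared", "RdcFit", function(x) x@chi2)

#' @rdname accessors
#' @export
setMethod("qFactors", "RdcFit",
          function(x) c(x@qPerDomain, overall = x@qOverall))

#' @rdname accessors
#' @export
setMethod("rotationMatrix", "Superposition", function(x) x@rotation)

#' @rdname accessors
#' @export
setMethod("translationVector", "Superposition", function(x) x@translation)

#' @rdname accessors
#' @export
setMethod("rmsdValue", "Superposition", function(x) x@rmsd)

## ---- show methods --------------------------------------------------------

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat("ProteinStructure:", nrow(a), "atoms,",
      length(object@sequence), "residues")
  if (nrow(a))
    cat(" (", min(a$resno), "-", max(a$resno), ")", sep = "")
  cat("\n")
  if (length(object@gaps))
    cat("  gaps:", paste(object@gaps, collapse = " "), "\n")
})

setMethod("show", "ShiftTable", function(object) {
  cat("ShiftTable:", nrow(object@entries), "assigned shifts over",
      length(object@sequence), "residues\n")
})

setMethod("show", "AlignmentTensor", function(object) {
  p <- tensorParameters(object)
  cat(sprintf(
    "AlignmentTensor: Da = %.3f Hz, R = %.3f, Euler(zyz) = %.1f %.1f %.1f deg\n",
    p$da, p$rhombicity, p$euler[1], p$euler[2], p$euler[3]))
})

setMethod("show", "RdcDataset", function(object) {
  r <- object@records
  cat("RdcDataset:", nrow(r), "couplings")
  if (nrow(r)) {
    cat(sprintf(" [%.1f, %.1f] Hz, domains: %s",
                min(r$d_exp), max(r$d_exp),
                paste(sort(unique(as.character(r$domain))), collapse = ", ")))
  }
  cat("\n")
  if (nzchar(object@description)) cat(" ", object@description, "\n")
})

setMethod("show", "RdcFit", function(object) {
  cat(sprintf("RdcFit: %d couplings, %d parameters, chi2 = %.4g\n",
              object@nData, object@nParams, object@chi2))
  cat(sprintf("  Q overall = %.3f", object@qOverall))
  if (length(object@qPerDomain))
    cat("; per domain:",
        paste(sprintf("%s = %.3f", names(object@qPerDomain),
                      object@qPerDomain), collapse = ", "))
  cat("\n")
  for (nm in names(object@tensors)) {
    p <- tensorParameters(object@tensors[[nm]])
    cat(sprintf("  [%s] Da = %.2f Hz, R = %.3f\n", nm, p$da, p$rhombicity))
  }
})

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition: rmsd = %.3f A over %d atoms\n",
              object@rmsd, object@nAtoms))
})
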