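# Fixture builders shared across test files. Everything is generated in
# code at test time; nothing binary is stored.

# Fixed-width PDB ATOM lines from an atom table.
pdbLines <- function(df) {
  vapply(seq_len(nrow(df)), function(i) {
    name <- df$atom[i]
    name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name4, df$altloc[i] %||% " ", df$resname[i], df$chain[i],
            df$resno[i], df$x[i], df$y[i], df$z[i],
            df$occupancy[i] %||% 1, 0, df$element[i])
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-written three-residue backbone fixture (GLY-ALA-SER), residues
# 10-12, chain A. Coordinates are an arbitrary but valid backbone trace.
threeResidueAtoms <- function() {
  data.frame(
    chain = "A",
    resno = rep(10:12, each = 3L),
    resname = rep(c("GLY", "ALA", "SER"), each = 3L),
    atom = rep(c("N", "CA", "C"), 3L),
    element = rep(c("N", "C", "C"), 3L),
    x = c(0.0, 1.46, 2.0, 3.2, 4.3, 5.8, 6.4, 7.8, 8.9),
    y = c(0.0, 0.0, 1.4, 1.5, 2.6, 2.4, 3.5, 3.4, 4.5),
    z = c(0.0, 0.0, 0.1, 0.3, 0.2, 0.6, 0.4, 0.9, 0.8),
    altloc = "", occupancy = 1.0,
    stringsAsFactors = FALSE)
}

writePdbFixture <- function(df, path = tempfile(fileext = ".pdb")) {
  writeLines(c(pdbLines(df), "END"), path)
  path
}

# Minimal NMR-STAR assigned-chemical-shift loop.
writeStarFixture <- function(rows, path = tempfile(fileext = ".str")) {
  body <- apply(rows, 1, paste, collapse = " ")
  writeLines(c(
    "data_test", "", "save_assigned_chemical_shifts",
    "  loop_",
    "    _Atom_chem_shift.ID",
    "    _Atom_chem_shift.Seq_ID",
    "    _Atom_chem_shift.Comp_ID",
    "    _Atom_chem_shift.Atom_ID",
    "    _Atom_chem_shift.Val",
    paste("   ", body),
    "  stop_", "save_"), path)
  path
}

# Small shift table built directly from entries.
makeShiftTable <- function(resno, resname, atom, shift, sequence = NULL) {
  shiftTable(data.frame(resno = resno, resname = resname, atom = atom,
                        shift = shift, stringsAsFactors = FALSE),
             sequence = sequence)
}

# Random unit vectors, reproducible.
randomUnitVectors <- function(n, seed) {
  set.seed(seed)
  V <- matrix(stats::rnorm(3 * n), ncol = 3)
  V <- V / sqrt(rowSums(V^2))
  rownames(V) <- seq_len(n)
  V
}

# Closed-form H/D-exchange class implied by a decay rate: a peak is
# detected at time t iff i0 * exp(-rate t) > detectK * noiseSd (noise-free
# threshold crossing); the class is the detected prefix length.
expectedHdxClass <- function(rate, timepoints = c(15, 1440, 2880),
                             detectK = 3, noiseSd = 1e4, i0 = 1e6) {
  det <- i0 * exp(-rate * timepoints) > detectK * noiseSd
  k <- match(FALSE, det, nomatch = length(det) + 1L) - 1L
  c("unprotected", "short", "medium", "persistent")[k + 1L]
}
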