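## Synthetic-data generators: ground-truth-labelled inputs for every
## pipeline stage (coordinates, RDCs, shift tables, titrations, hetNOE
## intensity pairs, timed H/D-exchange series).

## Secondary-structure layout of one synthetic domain: an N-terminal coil
## tail, a helix, a turn, a strand and a C-terminal coil. Mixing helix
## and extended geometry keeps the NH bond-vector distribution
## orientationally diverse, which an alignment-tensor fit needs.
domainLayout <- function(n, tail = 4L) {
  stopifnot(n >= 8L)
  nHelix <- max(4L, ceiling((n - tail - 5L) * 0.55))
  nStrand <- n - tail - nHelix - 3L - 2L
  if (nStrand < 3L) { nStrand <- 3L; nHelix <- n - tail - 3L - 2L - nStrand }
  c(rep("C", tail), rep("H", nHelix), rep("C", 3L), rep("E", nStrand),
    rep("C", 2L))
}

## Backbone dihedrals per secondary-structure label.
phiPsiFor <- function(label) {
  switch(label,
         H = c(phi = -57, psi = -47),
         E = c(phi = -120, psi = 120),
         C = c(phi = -75, psi = 150))
}

## Build an N/CA/C backbone from per-residue (phi, psi) with ideal bond
## geometry, by natural extension.
buildBackbone <- function(labels, startRes, chain = "A") {
  n <- length(labels)
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7
  coords <- matrix(NA_real_, nrow = 3L * n, ncol = 3L)
  ## seed triad for residue 1 in the xy-plane
  coords[1, ] <- c(0, 0, 0)                       # N1
  coords[2, ] <- c(bNCA, 0, 0)                    # CA1
  th <- deg2rad(180 - aNCAC)
  coords[3, ] <- coords[2, ] + bCAC * c(cos(th), sin(th), 0)  # C1
  for (i in seq_len(n - 1L)) {
    Nc <- coords[3 * i - 2, ]; CAc <- coords[3 * i - 1, ]
    Cc <- coords[3 * i, ]
    psi <- phiPsiFor(labels[i])["psi"]
    phi <- phiPsiFor(labels[i + 1L])["phi"]
    Nn <- nerfPlace(Nc, CAc, Cc, bCN, aCACN, psi)      # psi(i)
    CAn <- nerfPlace(CAc, Cc, Nn, bNCA, aCNCA, 180)    # omega = 180
    Cn <- nerfPlace(Cc, Nn, CAn, bCAC, aNCAC, phi)     # phi(i+1)
    coords[3 * i + 1, ] <- Nn
    coords[3 * i + 2, ] <- CAn
    coords[3 * i + 3, ] <- Cn
  }
  resno <- rep(startRes + seq_len(n) - 1L, each = 3L)
  data.frame(chain = chain, resno = resno, resname = "ALA",
             atom = rep(c("N", "CA", "C"), n),
             element = rep(c("N", "C", "C"), n),
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             altloc = "", occupancy = 1, stringsAsFactors = FALSE)
}

#' Generate a synthetic two-domain structure with ground truth
#'
#' Builds two poly-alanine domains (each an ideal helix plus an extended
#' strand, standard bond geometry, helix dihedrals phi = -57, psi = -47)
#' joined by a 3-residue linker with no coordinates, so the linker
#' appears as a numbering gap exactly like a disordered loop without
#' electron density. Domain B is rigid-body rotated by `rotation`
#' degrees about `rotationAxis` (default the tensor's y principal axis,
#' so the principal z-axis tilts by exactly the stated angle) and
#' translated away from domain A. Amide hydrogens are placed with
#' [placeAmideHydrogens()].
#'
#' The returned ground truth records everything a consumer test needs:
#' the alignment tensor of domain A, the interdomain rotation, the
#' per-residue secondary-structure layout, the flexible N-terminal tail,
#' a 7-residue binding site, per-residue H/D-exchange rates and the
#' domain membership of every residue.
#'
#' @param nResA,nResB residues per domain (>= 8).
#' @param rotation interdomain rotation, degrees.
#' @param rotationAxis length-3 axis for the interdomain rotation.
#' @param seed stored in the ground truth (construction is
#'   deterministic).
#' @param startRes first residue number (author numbering preserved
#'   throughout).
#' @param tensor [AlignmentTensor-class] experienced by domain A (and by
#'   domain B after the interdomain rotation).
#' @return list with elements `structure` ([ProteinStructure-class]) and
#'   `truth` (list, see Details).
#' @export
makeTwoDomainStructure <- function(nResA = 60L, nResB = 60L,
                                   rotation = 0,
                                   rotationAxis = c(0, 1, 0),
                                   seed = 1L, startRes = 461L,
                                   tensor = alignmentTensor(15, 0.3)) {
  stopifnot(nResA >= 8L, nResB >= 8L)
  layA <- domainLayout(nResA, tail = min(8L, nResA %/% 4L))
  layB <- domainLayout(nResB, tail = 2L)
  startB <- startRes + nResA + 3L   # 3-residue linker without coordinates
  atomsA <- buildBackbone(layA, startRes)
  atomsB <- buildBackbone(layB, startB)
  ## rigid interdomain rotation about the domain-B centroid, then shift
  xyzB <- as.matrix(atomsB[, c("x", "y", "z")])
  ctr <- colMeans(xyzB)
  Rot <- rotationAboutAxis(rotationAxis, rotation)
  xyzB <- sweep(sweep(xyzB, 2, ctr) %*% t(Rot), 2, ctr + c(40, 0, 0), "+")
  atomsB[, c("x", "y", "z")] <- xyzB
  s <- placeAmideHydrogens(proteinStructure(rbind(atomsA, atomsB)))

  resA <- startRes + seq_len(nResA) - 1L
  resB <- startB + seq_len(nResB) - 1L
  domains <- stats::setNames(rep(c("A", "B"), c(nResA, nResB)),
                             c(resA, resB))
  layout <- stats::setNames(c(layA, layB), c(resA, resB))
  flexible <- resA[seq_len(min(8L, nResA %/% 4L))]  # disordered N-tail
  structured <- as.integer(names(layout)[layout != "C"])
  binding <- structured[structured %in% resA][round(seq(
    2, sum(structured %in% resA) - 1, length.out = 7))]
  truth <- list(
    tensor = tensor,
    interdomainRotation = list(axis = rotationAxis, degrees = rotation),
    secondaryLayout = layout,
    flexibleResidues = flexible,
    bindingSite = sort(unique(binding)),
    protectionRates = protectionRatesFromLayout(layout, flexible),
    domains = domains,
    seed = seed)
  list(structure = s, truth = truth)
}

## H/D exchange rates (1/min) by structural class, >= 10x apart so the
## three-timepoint classing is unambiguous: coil/flexible amides exchange
## within minutes, strand cores persist for days.
protectionRatesFromLayout <- function(layout, flexible) {
  rates <- stats::setNames(rep(1.0, length(layout)), names(layout))
  helix <- names(layout)[layout == "H"]
  nH <- length(helix)
  rates[helix[seq_len(nH %/% 2)]] <- 1.8e-3      # medium: gone by 48 h
  rates[helix[seq(nH %/% 2 + 1, nH)]] <- 2e-2    # short: gone by 24 h
  rates[layout == "E"] <- 1e-4                   # persistent
  rates[as.character(flexible)] <- 1.0           # unprotected tail
  rates
}

#' Simulate an RDC dataset from ground truth
#'
#' Back-calculates the coupling for every supplied NH vector under the
#' single global ground-truth alignment tensor and adds Gaussian noise.
#' The coupling reports the bond orientation in the solution state, so
#' pass the vectors of the structure that carries the interdomain
#' rotation; fitting the resulting data against a reference structure
#' built with `rotation = 0` then emulates the classic situation where
#' the solution interdomain orientation differs from the crystal model
#' (the apparent domain-B tensor is the global tensor carried into the
#' domain frame by the rotation).
#'
#' @param truth ground truth from [makeTwoDomainStructure()].
#' @param vectors NH bond vectors ([nhBondVectors()]), normally from the
#'   structure that produced `truth`.
#' @param noiseSd Gaussian noise, Hz.
#' @param seed RNG seed.
#' @return an [RdcDataset-class] (reported sigma is `noiseSd`, floored at
#'   0.5 Hz).
#' @export
simulateRdcs <- function(truth, vectors, noiseSd = 1, seed = 1L) {
  V <- asVectorMatrix(vectors)
  resno <- as.integer(rownames(V))
  dom <- truth$domains[as.character(resno)]
  if (any(is.na(dom)))
    stop("vectors contain residues outside the ground-truth construct")
  d <- calcRdc(truth$tensor, V)
  withSeed(seed, {
    dExp <- d + stats::rnorm(length(d), 0, noiseSd)
    rdcDataset(data.frame(resno = resno, d_exp = dExp,
                          sigma = rep(max(noiseSd, 0.5), length(d)),
                          domain = dom),
               description = sprintf(
                 "synthetic RDCs: noise %.2g Hz, seed %d", noiseSd, seed))
  })
}

## Secondary-shift offsets added to random-coil CA/CB per class:
## literature-scale round values.
sseOffsets <- list(H = c(CA = 3.0, CB = -0.5),
                   E = c(CA = -1.5, CB = 2.0),
                   C = c(CA = 0, CB = 0))

#' Simulate a CA/CB shift table from a secondary-structure layout
#'
#' Random-coil values plus class offsets (helix +3.0/-0.5 ppm, strand
#' -1.5/+2.0 ppm on CA/CB) plus Gaussian noise.
#'
#' @param layout named character vector (residue -> `"H"`/`"E"`/`"C"`).
#' @param noiseSd Gaussian noise per shift, ppm.
#' @param seed RNG seed.
#' @param resname residue type used for every position (default `"ALA"`).
#' @return a [ShiftTable-class] with CA and CB entries.
#' @export
simulateShiftTable <- function(layout, noiseSd = 0.2, seed = 1L,
                               resname = "ALA") {
  rc <- randomCoilShifts()
  i <- match(resname, rc$resname)
  stopifnot(!is.na(i))
  resno <- as.integer(names(layout))
  withSeed(seed, {
    offCA <- vapply(layout, function(l) sseOffsets[[l]]["CA"], numeric(1))
    offCB <- vapply(layout, function(l) sseOffsets[[l]]["CB"], numeric(1))
    n <- length(resno)
    entries <- rbind(
      data.frame(resno = resno, resname = resname, atom = "CA",
                 shift = rc$CA[i] + offCA + stats::rnorm(n, 0, noiseSd)),
      data.frame(resno = resno, resname = resname, atom = "CB",
                 shift = rc$CB[i] + offCB + stats::rnorm(n, 0, noiseSd)))
    shiftTable(entries)
  })
}

#' Simulate a fast-exchange titration shift series
#'
#' Binding-site residues shift along a fixed per-residue direction by
#' `maxCsp * [L] / (Kd + [L])` (one-site fast-exchange isotherm); all
#' other residues are static. The direction partitions the combined CSP
#' into 1H and 15N components consistent with the weighting used by
#' [csp()].
#'
#' @param truth ground truth from [makeTwoDomainStructure()].
#' @param kd dissociation constant, mM.
#' @param ligandConcs ligand concentrations, mM.
#' @param maxCsp combined CSP at saturation, ppm.
#' @param nWeight 15N weight used to partition the combined shift.
#' @param seed RNG seed (baseline shift dispersion and shift directions).
#' @return list of [ShiftTable-class], one per concentration, in order.
#' @export
simulateTitration <- function(truth, kd = 5, ligandConcs = c(0, 10, 20, 50),
                              maxCsp = 0.2, nWeight = 0.15, seed = 1L) {
  resno <- as.integer(names(truth$domains))
  n <- length(resno)
  withSeed(seed, {
    baseH <- 8.2 + stats::runif(n, -0.6, 0.6)
    baseN <- 118 + stats::runif(n, -8, 8)
    dir <- stats::runif(n, 0.2, pi / 2 - 0.2)  # CSP partition angle
    lapply(ligandConcs, function(L) {
      frac <- L / (kd + L)
      amp <- ifelse(resno %in% truth$bindingSite, frac * maxCsp, 0)
      entries <- rbind(
        data.frame(resno = resno, resname = "ALA", atom = "H",
                   shift = baseH + amp * cos(dir)),
        data.frame(resno = resno, resname = "ALA", atom = "N",
                   shift = baseN + amp * sin(dir) / nWeight))
      shiftTable(entries)
    })
  })
}

#' Simulate saturated/reference intensity pairs for hetNOE analysis
#'
#' Reference intensity fixed at 1e6; the saturated intensity is the
#' class ratio times the reference (rigid backbone vs fast-timescale
#' flexible tail). Intensities are exact; measurement noise enters via
#' the `noise_sd` column consumed by [hetNoe()]'s Monte-Carlo error
#' estimation.
#'
#' @param truth ground truth from [makeTwoDomainStructure()].
#' @param rigidRatio,flexibleRatio hetNOE ratios for rigid and flexible
#'   residues.
#' @param noiseSd baseline noise recorded per residue.
#' @param seed stored for provenance (generation is deterministic).
#' @return data.frame suitable for [hetNoe()].
#' @export
simulateHetNoe <- function(truth, rigidRatio = 0.85, flexibleRatio = 0.3,
                           noiseSd = 0, seed = 1L) {
  resno <- as.integer(names(truth$domains))
  ratio <- ifelse(resno %in% truth$flexibleResidues,
                  flexibleRatio, rigidRatio)
  iRef <- 1e6
  data.frame(resno = resno, i_sat = ratio * iRef, i_ref = iRef,
             noise_sd = noiseSd)
}

#' Simulate a timed H/D-exchange intensity series
#'
#' Exponential decay `I(t) = I0 exp(-rate t)` per residue with the
#' ground-truth exchange rates, plus Gaussian baseline noise.
#'
#' @param truth ground truth from [makeTwoDomainStructure()].
#' @param timepoints minutes after transfer into D2O (default 15 min,
#'   24 h, 48 h).
#' @param noiseSd Gaussian intensity noise (also the recorded
#'   `noise_sd`).
#' @param i0 pre-exchange intensity.
#' @param seed RNG seed.
#' @return long data.frame suitable for [hdxClassify()] / [hdxExtent()].
#' @export
simulateHdx <- function(truth, timepoints = c(15, 1440, 2880),
                        noiseSd = 1e4, i0 = 1e6, seed = 1L) {
  rates <- truth$protectionRates
  resno <- as.integer(names(rates))
  grid <- expand.grid(resno = resno, time_min = timepoints)
  grid$rate <- rates[as.character(grid$resno)]
  withSeed(seed, {
    noise <- if (noiseSd > 0)
      stats::rnorm(nrow(grid), 0, noiseSd) else 0
    data.frame(resno = grid$resno, time_min = grid$time_min,
               intensity = i0 * exp(-grid$rate * grid$time_min) + noise,
               noise_sd = noiseSd)[order(grid$resno, grid$time_min), ]
  })
}
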