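## Residual dipolar couplings: back-calculation, alignment-tensor fitting
## (single-tensor SVD and two-domain shared-magnitude fits), Q factors,
## nested-model F-test and interdomain angles.

#' Construct an alignment tensor from Da, R and Euler angles
#'
#' Builds the Saupe order matrix (Hz; the dipolar interaction constant is
#' folded in) from the axial magnitude `da`, rhombicity `rhombicity` and
#' the z-y-z Euler angles (degrees) orienting the tensor principal frame
#' in the molecular frame. The principal values are
#' `Azz = 2 Da`, `Axx = -Da (1 - 1.5 R)`, `Ayy = -Da (1 + 1.5 R)`.
#'
#' @param da axial component, Hz.
#' @param rhombicity dimensionless, in [0, 2/3].
#' @param euler numeric length-3, z-y-z Euler angles in degrees.
#' @return an [AlignmentTensor-class].
#' @export
alignmentTensor <- function(da, rhombicity = 0, euler = c(0, 0, 0)) {
  stopifnot(length(euler) == 3L, is.finite(da), rhombicity >= 0,
            rhombicity <= 2 / 3)
  pf <- diag(c(-da * (1 - 1.5 * rhombicity),
               -da * (1 + 1.5 * rhombicity),
               2 * da))
  V <- eulerToRotation(euler[1], euler[2], euler[3])
  S <- V %*% pf %*% t(V)
  S <- (S + t(S)) / 2
  S <- S - diag(rep(sum(diag(S)) / 3, 3))  # scrub numerical trace
  new("AlignmentTensor", saupe = S)
}

#' Rotate an alignment tensor
#'
#' Applies a proper rotation to the tensor (equivalently, the molecule):
#' `S' = R S R^T`.
#'
#' @param tensor an [AlignmentTensor-class].
#' @param rotation 3x3 rotation matrix.
#' @return rotated [AlignmentTensor-class].
#' @export
rotateTensor <- function(tensor, rotation) {
  S <- rotation %*% saupeMatrix(tensor) %*% t(rotation)
  new("AlignmentTensor", saupe = (S + t(S)) / 2)
}

#' Canonical tensor parameters
#'
#' Eigen-decomposes the Saupe matrix and reports the conventional
#' parameterisation: eigenvalues ordered `|Azz| >= |Ayy| >= |Axx|`,
#' `Da = Azz / 2`, `R = (2/3) (Axx - Ayy) / Azz` (the x/y assignment is
#' chosen so that R >= 0), and z-y-z Euler angles of the principal axes.
#' The frame is made right-handed; the remaining 180-degree axis-flip
#' ambiguities are inherent to the tensor.
#'
#' @param tensor an [AlignmentTensor-class].
#' @return list with `da`, `rhombicity`, `euler` (degrees), `eigenvalues`
#'   (named `Axx`, `Ayy`, `Azz`) and `axes` (3x3 matrix, columns x, y, z).
#' @export
tensorParameters <- function(tensor) {
  S <- saupeMatrix(tensor)
  ev <- eigen(S, symmetric = TRUE)
  ord <- order(abs(ev$values), decreasing = TRUE)
  vals <- ev$values[ord]          # |Azz| >= then the two minor values
  vecs <- ev$vectors[, ord, drop = FALSE]
  Azz <- vals[1]
  ## assign minor eigenvalues to (Ayy, Axx) so that R >= 0
  if ((vals[3] - vals[2]) / Azz >= 0) {
    Axx <- vals[3]; Ayy <- vals[2]
    axes <- cbind(vecs[, 3], vecs[, 2], vecs[, 1])
  } else {
    Axx <- vals[2]; Ayy <- vals[3]
    axes <- cbind(vecs[, 2], vecs[, 3], vecs[, 1])
  }
  if (det(axes) < 0) axes[, 1] <- -axes[, 1]
  colnames(axes) <- c("x", "y", "z")
  list(da = Azz / 2,
       rhombicity = if (Azz != 0) (2 / 3) * (Axx - Ayy) / Azz else 0,
       euler = rotationToEuler(axes),
       eigenvalues = c(Axx = Axx, Ayy = Ayy, Azz = Azz),
       axes = axes)
}

#' @rdname accessors
#' @export
setMethod("daMagnitude", "AlignmentTensor",
          function(x) tensorParameters(x)$da)

#' @rdname accessors
#' @export
setMethod("rhombicity", "AlignmentTensor",
          function(x) tensorParameters(x)$rhombicity)

#' @rdname accessors
#' @export
setMethod("eulerAngles", "AlignmentTensor",
          function(x) tensorParameters(x)$euler)

#' @rdname accessors
#' @export
setMethod("principalAxes", "AlignmentTensor",
          function(x) tensorParameters(x)$axes)

asVectorMatrix <- function(vectors) {
  if (is.data.frame(vectors)) {
    m <- as.matrix(vectors[, c("x", "y", "z")])
    rownames(m) <- vectors$resno
    m
  } else {
    m <- as.matrix(vectors)
    stopifnot(ncol(m) == 3L)
    m
  }
}

#' Back-calculate RDCs from a tensor
#'
#' Contraction of each unit bond vector with the Saupe matrix,
#' `D = v' S v`. Equivalent to the polar form
#' `D = Da (3 cos^2 theta - 1) + (3/2) Da R sin^2 theta cos 2 phi`
#' with (theta, phi) the vector's polar angles in the tensor principal
#' frame (see [calcRdcAngles()]).
#'
#' @param tensor an [AlignmentTensor-class].
#' @param vectors data.frame from [nhBondVectors()] (or an n x 3 matrix
#'   of unit vectors).
#' @return numeric vector of couplings, Hz (named by residue when
#'   `vectors` carries residue numbers).
#' @export
calcRdc <- function(tensor, vectors) {
  V <- asVectorMatrix(vectors)
  d <- rowSums((V %*% saupeMatrix(tensor)) * V)
  stats::setNames(as.numeric(d), rownames(V))
}

#' Back-calculate RDCs via the polar-angle form
#'
#' The explicit (Da, R, theta, phi) dipolar formula; agrees with the
#' matrix contraction in [calcRdc()] to machine precision and is kept as
#' an independent route for cross-checking.
#'
#' @inheritParams calcRdc
#' @return numeric vector of couplings, Hz.
#' @export
calcRdcAngles <- function(tensor, vectors) {
  V <- asVectorMatrix(vectors)
  p <- tensorParameters(tensor)
  vp <- V %*% p$axes                     # components in principal frame
  cosT <- vp[, 3]
  d <- p$da * (3 * cosT^2 - 1) +
    1.5 * p$da * p$rhombicity * (vp[, 1]^2 - vp[, 2]^2)
  stats::setNames(as.numeric(d), rownames(V))
}

#' Construct an RDC dataset
#'
#' @param records data.frame with columns `resno`, `d_exp` (Hz), `sigma`
#'   (Hz), `domain`.
#' @param description free-text provenance.
#' @param sigmaFloor lower bound applied to `sigma` (default 0.5 Hz);
#'   uncertainties from repeat splitting measurements can be
#'   optimistically small.
#' @return an [RdcDataset-class].
#' @export
rdcDataset <- function(records, description = "", sigmaFloor = 0.5) {
  records$resno <- as.integer(records$resno)
  records$domain <- as.character(records$domain)
  records$sigma <- pmax(records$sigma, sigmaFloor)
  new("RdcDataset", records = records, description = description)
}

#' Read an RDC table from TSV
#'
#' Expected header: `resno`, `d_exp`, `sigma`, `domain` (Hz).
#'
#' @param path input file.
#' @param ... passed to [rdcDataset()].
#' @return an [RdcDataset-class].
#' @export
readRdcTable <- function(path, ...) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("resno", "d_exp", "sigma", "domain")
  if (!all(need %in% names(d)))
    stop("RDC table must have columns: ", paste(need, collapse = ", "))
  rdcDataset(d[, need], description = paste("read from", path), ...)
}

#' Exclude flexible residues from an RDC dataset
#'
#' Couplings from residues undergoing fast internal motion do not report
#' on the overall alignment; residues with a hetNOE ratio strictly below
#' the cutoff are removed before fitting. Residues without an NOE value
#' are retained with a warning.
#'
#' @param data an [RdcDataset-class].
#' @param noe data.frame from [hetNoe()].
#' @param cutoff NOE ratio threshold (default 0.7).
#' @return filtered [RdcDataset-class].
#' @export
filterByNoe <- function(data, noe, cutoff = 0.7) {
  r <- rdcRecords(data)
  idx <- match(r$resno, noe$resno)
  noNoe <- is.na(idx)
  if (any(noNoe))
    warning("no NOE value for residues (retained): ",
            paste(r$resno[noNoe], collapse = " "))
  keep <- noNoe | noe$ratio[idx] >= cutoff
  rdcDataset(r[keep, , drop = FALSE], description = data@description,
             sigmaFloor = 0)
}

## Align RDC records with bond vectors by residue number.
matchRdcVectors <- function(data, vectors) {
  r <- rdcRecords(data)
  V <- asVectorMatrix(vectors)
  rv <- as.integer(rownames(V))
  idx <- match(r$resno, rv)
  keep <- !is.na(idx)
  list(records = r[keep, , drop = FALSE],
       V = V[idx[keep], , drop = FALSE])
}

## Saupe design matrix for unit vectors: columns multiply the independent
## components (Sxx, Syy, Sxy, Sxz, Syz); Szz = -(Sxx + Syy).
saupeDesign <- function(V) {
  cbind(V[, 1]^2 - V[, 3]^2, V[, 2]^2 - V[, 3]^2,
        2 * V[, 1] * V[, 2], 2 * V[, 1] * V[, 3], 2 * V[, 2] * V[, 3])
}

saupeFromComponents <- function(s) {
  matrix(c(s[1], s[3], s[4],
           s[3], s[2], s[5],
           s[4], s[5], -s[1] - s[2]), 3, 3)
}

rmsq <- function(x) sqrt(mean(x^2))

#' Fit a single alignment tensor by weighted SVD
#'
#' The coupling is linear in the five independent Saupe components, so
#' the sigma-weighted least-squares problem is solved directly by
#' singular value decomposition of the design matrix; the tensor
#' parameters (Da, R, Euler angles) follow from eigen-decomposition.
#' `chi2` is the sum of squared sigma-weighted residuals; `n_params` is
#' 5.
#'
#' @param data an [RdcDataset-class].
#' @param vectors NH bond vectors from [nhBondVectors()].
#' @return an [RdcFit-class] with a single tensor named `"all"`; Q
#'   factors are reported overall and per domain label present in the
#'   data.
#' @export
fitTensorSvd <- function(data, vectors) {
  mv <- matchRdcVectors(data, vectors)
  r <- mv$records; V <- mv$V
  n <- nrow(r)
  if (n < 5L)
    stop("need at least 5 couplings with matching vectors, got ", n)
  A <- saupeDesign(V)
  w <- 1 / r$sigma
  sv <- svd(A * w)
  condition <- sv$d[1] / sv$d[5]
  if (sv$d[5] < 1e-10 * sv$d[1])
    stop("rank-deficient design (condition number ",
         format(condition, digits = 3), "): vectors too degenerate")
  s <- sv$v %*% ((t(sv$u) %*% (r$d_exp * w)) / sv$d)
  S <- saupeFromComponents(as.numeric(s))
  tensor <- new("AlignmentTensor", saupe = S)
  dCalc <- calcRdc(tensor, V)
  chi2 <- sum(((r$d_exp - dCalc) / r$sigma)^2)
  qPer <- vapply(split(seq_len(n), r$domain), function(i)
    qFactor(r$d_exp[i], dCalc[i]), numeric(1))
  new("RdcFit",
      tensors = list(all = tensor), chi2 = chi2, nData = as.integer(n),
      nParams = 5L, qPerDomain = qPer,
      qOverall = qFactor(r$d_exp, dCalc),
      residuesUsed = sort(r$resno),
      details = list(dCalc = data.frame(resno = r$resno,
                                        d_exp = r$d_exp, d_calc = dCalc),
                     condition = condition))
}

## chi2 of the two-orientation model at fixed Euler angles, profiling the
## shared (Da, Da*R) magnitudes out by linear least squares.
twoDomainObjective <- function(angles, recA, VA, recB, VB,
                               returnFit = FALSE) {
  coef1 <- function(V, ang) {
    Vf <- eulerToRotation(ang[1], ang[2], ang[3])
    vp <- V %*% Vf
    cbind(3 * vp[, 3]^2 - 1, 1.5 * (vp[, 1]^2 - vp[, 2]^2))
  }
  X <- rbind(coef1(VA, angles[1:3]), coef1(VB, angles[4:6]))
  y <- c(recA$d_exp, recB$d_exp)
  w <- 1 / c(recA$sigma, recB$sigma)
  fit <- stats::lm.wfit(X, y, w^2)
  chi2 <- sum((fit$residuals * w)^2)
  if (!returnFit) return(chi2)
  list(chi2 = chi2, da = fit$coefficients[1],
       daR = fit$coefficients[2])
}

#' Fit two domains with a shared tensor magnitude
#'
#' Two-domain model for interdomain orientation analysis: a single Da and
#' R for the whole molecule (both domains experience the same alignment
#' strength) but independent tensor orientations in the two domains (8
#' parameters). The orientation parameters are optimised by Nelder-Mead
#' with the magnitudes profiled out linearly at each step; starting
#' points are the per-domain SVD solutions and the pooled single-tensor
#' solution, which also guarantees the nested-model inequality
#' `chi2(pooled) >= chi2(two-orientation)`.
#'
#' The nested 5-parameter pooled fit (one tensor for both domains) is
#' computed alongside and stored in `details(fit)$pooled` for F-testing
#' with [fTestNested()].
#'
#' @param data an [RdcDataset-class] whose records carry exactly two
#'   domain labels, each with at least 5 usable couplings.
#' @param vectors NH bond vectors from [nhBondVectors()].
#' @param maxIter optimiser iteration cap (default 10000).
#' @param tol convergence tolerance on chi2 (default 1e-8).
#' @return an [RdcFit-class] with one tensor per domain (`nParams = 8`);
#'   `@details$pooled` holds the nested pooled [RdcFit-class].
#' @export
fitTwoDomainShared <- function(data, vectors, maxIter = 10000L,
                               tol = 1e-8) {
  r <- rdcRecords(data)
  doms <- sort(unique(r$domain))
  if (length(doms) != 2L)
    stop("two-domain fit needs exactly 2 domain labels, got ",
         length(doms))
  sub <- function(d) {
    ds <- rdcDataset(r[r$domain == d, , drop = FALSE], sigmaFloor = 0)
    mv <- matchRdcVectors(ds, vectors)
    if (nrow(mv$records) < 5L)
      stop("domain '", d, "' has fewer than 5 usable couplings")
    mv
  }
  a <- sub(doms[1]); b <- sub(doms[2])

  fitA <- fitTensorSvd(rdcDataset(a$records, sigmaFloor = 0), vectors)
  fitB <- fitTensorSvd(rdcDataset(b$records, sigmaFloor = 0), vectors)
  pooled <- fitTensorSvd(data, vectors)
  eA <- eulerAngles(tensors(fitA)$all)
  eB <- eulerAngles(tensors(fitB)$all)
  eP <- eulerAngles(tensors(pooled)$all)
  starts <- list(c(eA, eB), c(eP, eP))

  obj <- function(p) twoDomainObjective(p, a$records, a$V, b$records, b$V)
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = maxIter,
                                     reltol = tol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$convergence != 0)
    stop("two-domain fit did not converge within ", maxIter,
         " iterations (best chi2 = ", format(best$value, digits = 6), ")")
  sol <- twoDomainObjective(best$par, a$records, a$V, b$records, b$V,
                            returnFit = TRUE)
  da <- as.numeric(sol$da)
  R <- as.numeric(sol$daR) / da
  mkTensor <- function(ang) {
    pf <- diag(c(-da * (1 - 1.5 * R), -da * (1 + 1.5 * R), 2 * da))
    Vf <- eulerToRotation(ang[1], ang[2], ang[3])
    S <- Vf %*% pf %*% t(Vf)
    new("AlignmentTensor", saupe = (S + t(S)) / 2)
  }
  tA <- mkTensor(best$par[1:3]); tB <- mkTensor(best$par[4:6])
  dA <- calcRdc(tA, a$V); dB <- calcRdc(tB, b$V)
  chi2 <- sum(((a$records$d_exp - dA) / a$records$sigma)^2) +
    sum(((b$records$d_exp - dB) / b$records$sigma)^2)
  n <- nrow(a$records) + nrow(b$records)
  tensorsOut <- stats::setNames(list(tA, tB), doms)
  qPer <- stats::setNames(c(qFactor(a$records$d_exp, dA),
                            qFactor(b$records$d_exp, dB)), doms)
  new("RdcFit",
      tensors = tensorsOut, chi2 = chi2, nData = as.integer(n),
      nParams = 8L, qPerDomain = qPer,
      qOverall = qFactor(c(a$records$d_exp, b$records$d_exp),
                         c(dA, dB)),
      residuesUsed = sort(c(a$records$resno, b$records$resno)),
      details = list(
        pooled = pooled,
        perDomainSvd = list(fitA, fitB),
        dCalc = data.frame(
          resno = c(a$records$resno, b$records$resno),
          domain = rep(doms, c(nrow(a$records), nrow(b$records))),
          d_exp = c(a$records$d_exp, b$records$d_exp),
          d_calc = c(dA, dB)),
        sharedDa = da, sharedR = R,
        optim = best[c("value", "counts", "convergence")]))
}

#' Cornilescu Q factor
#'
#' `Q = rms(d_exp - d_calc) / rms(d_exp)` by default. The alternative
#' normalisation by the tensor magnitude,
#' `sqrt(2 Da^2 (4 + 3 R^2) / 5)`, is available via
#' `normalization = "tensor"` (supply `da` and `rhombicity`).
#'
#' @param dExp,dCalc equal-length numeric vectors of experimental and
#'   back-calculated couplings (Hz).
#' @param normalization `"rms"` (default) or `"tensor"`.
#' @param da,rhombicity tensor parameters, used only for
#'   `normalization = "tensor"`.
#' @return dimensionless Q.
#' @export
qFactor <- function(dExp, dCalc, normalization = c("rms", "tensor"),
                    da = NULL, rhombicity = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(length(dExp) == length(dCalc), length(dExp) >= 1L)
  denom <- if (normalization == "rms") {
    if (all(dExp == 0))
      stop("Q factor undefined: all experimental couplings are zero")
    rmsq(dExp)
  } else {
    if (is.null(da) || is.null(rhombicity))
      stop("tensor normalisation needs da and rhombicity")
    sqrt(2 * da^2 * (4 + 3 * rhombicity^2) / 5)
  }
  rmsq(dExp - dCalc) / denom
}

#' F-test between nested tensor fits
#'
#' Compares a reduced fit (e.g. one pooled tensor, 5 parameters) against
#' a full fit (e.g. two orientations with shared magnitude, 8 parameters)
#' on the same data:
#' `F = ((chi2_red - chi2_full) / (p_full - p_red)) /
#'      (chi2_full / (N - p_full))`.
#' The reported probability is the F cumulative distribution at the
#' statistic, i.e. the probability that the improvement is significant.
#'
#' @param fitReduced,fitFull nested [RdcFit-class] objects over the same
#'   couplings.
#' @return list with `fValue`, `dof` (numerator, denominator) and
#'   `probability`.
#' @export
fTestNested <- function(fitReduced, fitFull) {
  if (fitFull@nParams <= fitReduced@nParams)
    stop("fits are not nested: full model must have more parameters")
  if (fitFull@nData != fitReduced@nData ||
      !identical(fitReduced@residuesUsed, fitFull@residuesUsed))
    stop("fits are not nested: different data")
  d1 <- fitFull@nParams - fitReduced@nParams
  d2 <- fitFull@nData - fitFull@nParams
  f <- ((fitReduced@chi2 - fitFull@chi2) / d1) / (fitFull@chi2 / d2)
  f <- max(0, f)
  list(fValue = f, dof = c(numerator = d1, denominator = d2),
       probability = stats::pf(f, d1, d2))
}

#' Interdomain angle between fitted tensor orientations
#'
#' Angle between the principal (z) eigenvectors of the two domain
#' tensors, folded to [0, 90] degrees because eigenvector signs are
#' arbitrary.
#'
#' @param fit an [RdcFit-class] containing exactly two tensors.
#' @return angle in degrees.
#' @export
interdomainAngle <- function(fit) {
  tl <- tensors(fit)
  if (length(tl) != 2L)
    stop("interdomain angle needs a two-domain fit, found ",
         length(tl), " tensor(s)")
  z1 <- principalAxes(tl[[1]])[, "z"]
  z2 <- principalAxes(tl[[2]])[, "z"]
  rad2deg(acos(min(1, abs(sum(z1 * z2)))))
}

#' Write an RDC fit report
#'
#' TSV of per-residue experimental and back-calculated couplings plus a
#' JSON block with tensor parameters, chi2 and Q factors.
#'
#' @param fit an [RdcFit-class].
#' @param pathTsv,pathJson output files (either may be `NULL`).
#' @export
writeRdcFitReport <- function(fit, pathTsv = NULL, pathJson = NULL) {
  if (!is.null(pathTsv))
    utils::write.table(fit@details$dCalc, pathTsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(pathJson)) {
    tens <- lapply(tensors(fit), function(t) {
      p <- tensorParameters(t)
      list(da_hz = p$da, rhombicity = p$rhombicity,
           euler_zyz_deg = p$euler)
    })
    jsonlite::write_json(
      list(tensors = tens, chi2 = fit@chi2, n_data = fit@nData,
           n_params = fit@nParams,
           q_overall = fit@qOverall,
           q_per_domain = as.list(fit@qPerDomain)),
      pathJson, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(fit)
}
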