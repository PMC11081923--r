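test_that("RDC back-calculation matches axis and magic-angle cases", {
  tz <- alignmentTensor(da = 10, rhombicity = 0)
  expect_equal(unname(calcRdc(tz, matrix(c(0, 0, 1), 1))), 20)

  tr <- alignmentTensor(da = 10, rhombicity = 2 / 3)
  expect_equal(unname(calcRdc(tr, matrix(c(1, 0, 0), 1))), 0,
               tolerance = 1e-12)

  magic <- matrix(c(1, 1, 1) / sqrt(3), 1)
  expect_equal(unname(calcRdc(tz, magic)), 0, tolerance = 1e-12)
})

test_that("matrix contraction and polar-angle formulas agree", {
  set.seed(99)
  for (i in 1:20) {
    t1 <- alignmentTensor(runif(1, 5, 25), runif(1, 0, 2 / 3),
                          runif(3, -180, 180))
    V <- randomUnitVectors(50, seed = i)
    expect_equal(calcRdc(t1, V), calcRdcAngles(t1, V), tolerance = 1e-10)
    # inversion symmetry: D(v) = D(-v)
    expect_equal(calcRdc(t1, V), calcRdc(t1, -V), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("tensor parameters round-trip through the Saupe matrix", {
  for (seed in 1:10) {
    set.seed(seed)
    da <- runif(1, 5, 25) * sample(c(-1, 1), 1)
    R <- runif(1, 0.01, 0.6)
    eu <- runif(3, -170, 170)
    t1 <- alignmentTensor(da, R, eu)
    p <- tensorParameters(t1)
    expect_equal(p$da, da, tolerance = 1e-9)
    expect_equal(p$rhombicity, R, tolerance = 1e-9)
    # rebuilt from canonical parameters, the matrix is identical
    t2 <- alignmentTensor(p$da, p$rhombicity, p$euler)
    expect_equal(saupeMatrix(t2), saupeMatrix(t1), tolerance = 1e-8)
    expect_equal(sum(diag(saupeMatrix(t1))), 0, tolerance = 1e-9)
    ev <- p$eigenvalues
    expect_true(abs(ev["Azz"]) >= abs(ev["Ayy"]) &
                  abs(ev["Ayy"]) >= abs(ev["Axx"]) - 1e-12)
    expect_gte(p$rhombicity, 0); expect_lte(p$rhombicity, 2 / 3 + 1e-12)
  }
})

test_that("SVD tensor fit recovers exact data to machine precision", {
  truth <- alignmentTensor(15, 0.3, c(25, 65, -40))
  V <- randomUnitVectors(50, seed = 3)
  d <- calcRdc(truth, V)
  data <- rdcDataset(data.frame(resno = 1:50, d_exp = d, sigma = 1,
                                domain = "A"), sigmaFloor = 0)
  fit <- fitTensorSvd(data, V)
  expect_lt(chiSquared(fit), 1e-12)
  p <- tensorParameters(tensors(fit)$all)
  expect_equal(p$da, 15, tolerance = 1e-9)
  expect_equal(p$rhombicity, 0.3, tolerance = 1e-9)
  expect_lt(fit@qOverall, 1e-9)

  # exactly five independent couplings: fully determined, chi2 ~ 0
  d5 <- rdcDataset(data.frame(resno = 1:5, d_exp = d[1:5] + c(1, -2, 0.5, 3, -1),
                              sigma = 1, domain = "A"), sigmaFloor = 0)
  expect_lt(chiSquared(fitTensorSvd(d5, V[1:5, ])), 1e-9)

  expect_error(fitTensorSvd(rdcDataset(data.frame(
    resno = 1:4, d_exp = d[1:4], sigma = 1, domain = "A"),
    sigmaFloor = 0), V), "at least 5")
})

test_that("fit chi2 equals the brute-force normal-equations solution", {
  for (seed in 1:5) {
    truth <- alignmentTensor(12 + seed, 0.2, c(10 * seed, 40, 70))
    V <- randomUnitVectors(30, seed = 100 + seed)
    set.seed(200 + seed)
    d <- calcRdc(truth, V) + rnorm(30, sd = 2)
    sig <- runif(30, 0.5, 2)
    data <- rdcDataset(data.frame(resno = 1:30, d_exp = d, sigma = sig,
                                  domain = "A"), sigmaFloor = 0)
    fit <- fitTensorSvd(data, V)
    # independent oracle: weighted normal equations solved directly
    A <- cbind(V[, 1]^2 - V[, 3]^2, V[, 2]^2 - V[, 3]^2,
               2 * V[, 1] * V[, 2], 2 * V[, 1] * V[, 3],
               2 * V[, 2] * V[, 3])
    W <- diag(1 / sig^2)
    s <- solve(t(A) %*% W %*% A, t(A) %*% W %*% d)
    res <- d - A %*% s
    expect_equal(chiSquared(fit), sum((res / sig)^2), tolerance = 1e-8)
  }
})

test_that("tensor parameters are recovered under realistic noise", {
  truth <- alignmentTensor(15, 0.3, c(30, 50, 20))
  zTrue <- principalAxes(truth)[, "z"]
  dDa <- dR <- dAx <- numeric(10)
  for (seed in 1:10) {
    V <- randomUnitVectors(50, seed = 300 + seed)
    set.seed(400 + seed)
    d <- calcRdc(truth, V) + rnorm(50, sd = 1)
    fit <- fitTensorSvd(rdcDataset(data.frame(
      resno = 1:50, d_exp = d, sigma = 1, domain = "A"),
      sigmaFloor = 0), V)
    p <- tensorParameters(tensors(fit)$all)
    dDa[seed] <- abs(p$da - 15) / 15
    dR[seed] <- abs(p$rhombicity - 0.3)
    dAx[seed] <- acos(min(1, abs(sum(p$axes[, "z"] * zTrue)))) * 180 / pi
  }
  expect_lte(median(dDa), 0.02)
  expect_lte(median(dR), 0.05)
  expect_lte(median(dAx), 3)
})

test_that("NOE filtering drops flexible residues and keeps the rest", {
  data <- rdcDataset(data.frame(resno = 1:6, d_exp = 1:6, sigma = 1,
                                domain = "A"), sigmaFloor = 0)
  noe <- data.frame(resno = 1:6, ratio = c(0.9, 0.9, 0.5, 0.7, 0.69, 0.9),
                    ratio_error = 0)
  kept <- rdcRecords(filterByNoe(data, noe))$resno
  expect_identical(kept, c(1L, 2L, 4L, 6L))

  # all rigid: unchanged
  rigid <- data.frame(resno = 1:6, ratio = 0.9, ratio_error = 0)
  expect_identical(rdcRecords(filterByNoe(data, rigid))$resno, 1:6)

  # residues without an NOE value are retained with a warning
  expect_warning(f <- filterByNoe(data, noe[1:5, ]), "no NOE value")
  expect_true(6L %in% rdcRecords(f)$resno)

  # generator round trip: exactly the seeded flexible tail is dropped
  sol <- makeTwoDomainStructure(40L, 40L, seed = 9L)
  vec <- nhBondVectors(sol$structure)
  rdc <- simulateRdcs(sol$truth, vec, noiseSd = 0, seed = 9L)
  noeS <- hetNoe(simulateHetNoe(sol$truth), nMc = 2L, seed = 1L)
  filtered <- filterByNoe(rdc, noeS)
  dropped <- setdiff(rdcRecords(rdc)$resno, rdcRecords(filtered)$resno)
  expect_setequal(dropped,
                  intersect(sol$truth$flexibleResidues,
                            rdcRecords(rdc)$resno))
})

test_that("Q factor matches its definition", {
  expect_equal(qFactor(c(10, 0), c(10, 0)), 0)
  expect_equal(qFactor(c(10, 5), c(0, 0)), 1.0)
  expect_equal(qFactor(c(10, 0), c(8, 0)), 0.2)
  expect_error(qFactor(c(0, 0), c(1, 2)), "all experimental")
  # tensor-magnitude normalisation option
  qa <- qFactor(c(10, 0), c(8, 0), normalization = "tensor",
                da = 10, rhombicity = 0)
  expect_equal(qa, sqrt(2) / sqrt(2 * 100 * 4 / 5), tolerance = 1e-12)
})

test_that("F-test reproduces the nested-model statistic", {
  mkFit <- function(chi2, p) new("RdcFit", tensors = list(), chi2 = chi2,
                                 nData = 81L, nParams = as.integer(p),
                                 qPerDomain = numeric(0), qOverall = 0,
                                 residuesUsed = 1:81, details = list())
  # equal chi2: F = 0, probability 0
  ft0 <- fTestNested(mkFit(150, 5), mkFit(150, 8))
  expect_equal(ft0$fValue, 0)
  expect_equal(ft0$probability, 0)

  # worked arithmetic example with F-distribution CDF oracle
  ft <- fTestNested(mkFit(200, 5), mkFit(150, 8))
  expect_equal(ft$fValue, (50 / 3) / (150 / 73), tolerance = 1e-12)
  expect_equal(round(ft$fValue, 2), 8.11)
  expect_equal(unname(ft$dof), c(3, 73))
  expect_equal(ft$probability, stats::pf((50 / 3) / (150 / 73), 3, 73))

  # non-nested inputs are rejected
  expect_error(fTestNested(mkFit(200, 8), mkFit(150, 5)), "not nested")
  short <- new("RdcFit", tensors = list(), chi2 = 100, nData = 40L,
               nParams = 5L, qPerDomain = numeric(0), qOverall = 0,
               residuesUsed = 1:40, details = list())
  expect_error(fTestNested(short, mkFit(90, 8)), "not nested")
})

test_that("interdomain angle folds the axis-sign degeneracy", {
  tA <- alignmentTensor(15, 0.3, c(0, 0, 0))
  mkFit <- function(t1, t2) new("RdcFit",
    tensors = list(A = t1, B = t2), chi2 = 1, nData = 20L, nParams = 8L,
    qPerDomain = numeric(0), qOverall = 0.1, residuesUsed = 1:20,
    details = list())
  expect_equal(interdomainAngle(mkFit(tA, tA)), 0)

  tB <- rotateTensor(tA, DomainNMR:::rotationAboutAxis(c(1, 0, 0), 30))
  expect_equal(interdomainAngle(mkFit(tA, tB)), 30, tolerance = 1e-9)

  # 150-degree rotation folds to 30 (z and -z are the same axis)
  tC <- rotateTensor(tA, DomainNMR:::rotationAboutAxis(c(1, 0, 0), 150))
  expect_equal(interdomainAngle(mkFit(tA, tC)), 30, tolerance = 1e-9)

  single <- new("RdcFit", tensors = list(all = tA), chi2 = 1,
                nData = 20L, nParams = 5L, qPerDomain = numeric(0),
                qOverall = 0.1, residuesUsed = 1:20, details = list())
  expect_error(interdomainAngle(single), "two-domain")
})

test_that("two-domain shared fit collapses onto the pooled model when true", {
  ref <- makeTwoDomainStructure(40L, 40L, rotation = 0, seed = 21L)
  vec <- nhBondVectors(ref$structure)
  rdc <- simulateRdcs(ref$truth, vec, noiseSd = 0, seed = 21L)
  fit <- fitTwoDomainShared(rdc, vec)
  pooled <- fit@details$pooled
  expect_lt(abs(chiSquared(fit) - chiSquared(pooled)), 1e-6)
  expect_lt(interdomainAngle(fit), 1)
  # nested monotonicity
  expect_lte(chiSquared(fit), chiSquared(pooled) + 1e-10)
  expect_equal(fit@nParams, 8L)
  expect_equal(pooled@nParams, 5L)
})

test_that("a 7-degree interdomain rotation is recovered from noisy data", {
  sol <- makeTwoDomainStructure(60L, 60L, rotation = 7, seed = 31L)
  ref <- makeTwoDomainStructure(60L, 60L, rotation = 0, seed = 31L)
  rdc <- simulateRdcs(sol$truth, nhBondVectors(sol$structure),
                      noiseSd = 1, seed = 31L)
  fit <- fitTwoDomainShared(rdc, nhBondVectors(ref$structure))
  expect_equal(interdomainAngle(fit), 7, tolerance = 1 / 7)
  ft <- fTestNested(fit@details$pooled, fit)
  expect_gt(ft$probability, 0.99)
  # shared magnitudes match the generating tensor
  expect_equal(fit@details$sharedDa, 15, tolerance = 0.05 * 15)
  expect_equal(fit@details$sharedR, 0.3, tolerance = 0.07)
  # pooled chi2 always bounds the two-orientation chi2 from above
  expect_gte(chiSquared(fit@details$pooled), chiSquared(fit))
})
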