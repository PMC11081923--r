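test_that("shift tables read from TSV and NMR-STAR", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("resno\tresname\tatom\tshift",
               "2\tALA\tCA\t52.5", "2\tALA\tCB\t19.0", "3\tGLY\tCA\t45.0"),
             tsv)
  t1 <- readShiftTable(tsv)
  expect_equal(nrow(shiftEntries(t1)), 3L)

  star <- writeStarFixture(data.frame(id = 1, seq = 2, comp = "ALA",
                                      atom = "CA", val = 52.5))
  t2 <- readShiftTable(star)
  e <- shiftEntries(t2)
  expect_equal(e$shift[e$resno == 2L & e$atom == "CA"], 52.5)

  # duplicate (residue, atom) is an error
  dup <- data.frame(resno = c(2, 2), resname = "ALA",
                    atom = c("CA", "CA"), shift = c(52, 53))
  expect_error(shiftTable(dup), "one entry per")

  # residue-name mismatch against the declared sequence names the residue
  expect_error(
    makeShiftTable(2, "ALA", "CA", 52.5, sequence = c(`2` = "GLY")),
    "mismatch.*2")
})

test_that("assignment completeness applies per-residue chemistry rules", {
  # sequence APGK with amide H/N assigned for A, G, K: proline excluded
  sq <- c(`1` = "ALA", `2` = "PRO", `3` = "GLY", `4` = "LYS")
  full <- makeShiftTable(rep(c(1, 3, 4), each = 2),
                         rep(c("ALA", "GLY", "LYS"), each = 2),
                         rep(c("H", "N"), 3), rep(c(8.2, 120), 3),
                         sequence = sq)
  r <- assignmentCompleteness(full, "HN_N")
  expect_equal(r$assigned, 3L)
  expect_equal(r$possible, 3L)
  expect_equal(r$percent, 100.0)

  # K unassigned: 2/3 = 66.7% (rounded to one decimal)
  part <- makeShiftTable(rep(c(1, 3), each = 2),
                         rep(c("ALA", "GLY"), each = 2),
                         rep(c("H", "N"), 2), rep(c(8.2, 120), 2),
                         sequence = sq)
  r2 <- assignmentCompleteness(part, "HN_N")
  expect_equal(r2$assigned, 2L)
  expect_equal(r2$possible, 3L)
  expect_equal(r2$percent, 66.7)

  # glycine is excluded from the CB denominator; proline counts for CA
  ca <- makeShiftTable(c(1, 2), c("ALA", "PRO"), c("CA", "CA"),
                       c(52.5, 63.0), sequence = sq)
  expect_equal(assignmentCompleteness(ca, "CA")$possible, 4L)
  expect_equal(assignmentCompleteness(ca, "CB")$possible, 3L)
  # glycine HA2/HA3 counts as an HA assignment
  ha <- makeShiftTable(3, "GLY", "HA2", 3.9, sequence = sq)
  expect_equal(assignmentCompleteness(ha, "HA")$assigned, 1L)

  expect_error(assignmentCompleteness(full, "XX"), "unknown atom class")
})

test_that("completeness is monotone in assignments and bounded", {
  sq <- stats::setNames(rep("ALA", 10), 1:10)
  set.seed(4)
  for (rep in 1:5) {
    picked <- sort(sample(1:10, sample(1:9, 1)))
    entries <- data.frame(resno = rep(picked, each = 2),
                          resname = "ALA",
                          atom = rep(c("H", "N"), length(picked)),
                          shift = 8)
    t0 <- shiftTable(entries, sequence = sq)
    p0 <- assignmentCompleteness(t0, "HN_N")$percent
    expect_gte(p0, 0); expect_lte(p0, 100)
    extra <- setdiff(1:10, picked)[1]
    t1 <- shiftTable(rbind(entries,
                           data.frame(resno = extra, resname = "ALA",
                                      atom = c("H", "N"), shift = 8)),
                     sequence = sq)
    expect_gte(assignmentCompleteness(t1, "HN_N")$percent, p0)
  }
})

test_that("secondary shifts subtract random-coil values", {
  rc <- randomCoilShifts()
  ala <- rc[rc$resname == "ALA", ]
  gly <- rc[rc$resname == "GLY", ]

  # shifts equal to random coil: zero secondary shift
  t0 <- makeShiftTable(c(1, 1), c("ALA", "ALA"), c("CA", "CB"),
                       c(ala$CA, ala$CB))
  expect_equal(secondaryShifts(t0)$dCaMinusDcb, 0)

  # dCA = +3.0, dCB = -0.5 gives +3.5
  t1 <- makeShiftTable(c(1, 1), c("ALA", "ALA"), c("CA", "CB"),
                       c(ala$CA + 3.0, ala$CB - 0.5))
  expect_equal(secondaryShifts(t1)$dCaMinusDcb, 3.5)

  # glycine has no CB: dCB forced to zero
  t2 <- makeShiftTable(1, "GLY", "CA", gly$CA - 1.2)
  r2 <- secondaryShifts(t2)
  expect_equal(r2$deltaCB, 0)
  expect_equal(r2$dCaMinusDcb, -1.2, tolerance = 1e-12)

  # internal consistency of the record
  expect_equal(r2$dCaMinusDcb, r2$deltaCA - r2$deltaCB)
})

test_that("secondary-structure classification applies run-length rules", {
  flat <- data.frame(resno = 1:10, resname = "ALA", deltaCA = 0,
                     deltaCB = 0, dCaMinusDcb = 0)
  seg <- classifySecondaryStructure(flat)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$type, "coil")
  expect_equal(c(seg$start, seg$end), c(1L, 10L))

  helix <- flat
  helix$dCaMinusDcb[3:8] <- 3
  seg2 <- classifySecondaryStructure(helix)
  expect_true(any(seg2$type == "helix" & seg2$start == 3 & seg2$end == 8))

  # a 3-residue positive run is below the helix minimum: demoted to coil
  short <- flat
  short$dCaMinusDcb[4:6] <- 3
  expect_false("helix" %in% classifySecondaryStructure(short)$type)
  # but 3 consecutive strand-like residues do qualify
  strand <- flat
  strand$dCaMinusDcb[4:6] <- -3
  expect_true("strand" %in% classifySecondaryStructure(strand)$type)

  # numbering gaps break runs: 6 helix-like residues split 3 + 3
  gapped <- helix[helix$resno %in% c(3, 4, 5, 7, 8, 9), ]
  gapped$dCaMinusDcb <- 3
  expect_false("helix" %in% classifySecondaryStructure(gapped)$type)
})

test_that("classifier recovers the generator layout at >= 90%", {
  hits <- 0; total <- 0
  for (seed in 1:20) {
    lay <- makeTwoDomainStructure(40L, 40L, seed = seed)$truth$secondaryLayout
    tab <- simulateShiftTable(lay, noiseSd = 0.2, seed = seed)
    lab <- segmentLabels(classifySecondaryStructure(secondaryShifts(tab)))
    structured <- names(lay)[lay != "C"]
    hits <- hits + sum(lab[structured] == lay[structured])
    total <- total + length(structured)
  }
  expect_gte(hits / total, 0.9)
})

test_that("CSP combines 1H and 15N shifts with the 0.15 weight", {
  ref <- makeShiftTable(rep(1:3, each = 2), "ALA",
                        rep(c("H", "N"), 3),
                        c(8.1, 120, 8.3, 118, 7.9, 124))

  # identical tables: all zero
  expect_equal(csp(ref, ref)$combined, rep(0, 3))

  # pure 1H change of 0.1 ppm
  p1 <- makeShiftTable(rep(1:3, each = 2), "ALA",
                       rep(c("H", "N"), 3),
                       c(8.2, 120, 8.3, 118, 7.9, 124))
  expect_equal(csp(ref, p1)$combined, c(0.1, 0, 0))

  # dH = 0.03, dN = 0.40 with weight 0.15: 0.0671 ppm
  p2 <- makeShiftTable(c(1, 1), "ALA", c("H", "N"), c(8.13, 120.40))
  r2 <- suppressWarnings(csp(ref, p2))
  expect_equal(r2$combined[r2$resno == 1], sqrt(0.03^2 + 0.06^2),
               tolerance = 1e-12)
  expect_equal(round(r2$combined[r2$resno == 1], 4), 0.0671)

  # symmetry under swapping reference and perturbed
  expect_equal(suppressWarnings(csp(p2, ref))$combined, r2$combined)

  # combined is zero iff both deltas are zero
  r <- csp(ref, p1)
  expect_identical(r$combined == 0, r$dH == 0 & r$dN == 0)

  # unmatched residues are dropped with a warning
  expect_warning(csp(ref, p2), "only one table")
})

test_that("shifted-residue identification uses a strict threshold", {
  rec <- data.frame(resno = c(5, 9, 2), dH = 0, dN = 0,
                    combined = c(0.10, 0.25, 0.11))
  expect_identical(identifyShifted(rec, 0.1), c(2, 9))
  expect_identical(identifyShifted(data.frame(resno = 1, dH = 0, dN = 0,
                                              combined = 0), 0.1),
                   numeric(0))
})
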