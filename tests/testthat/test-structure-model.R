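test_that("mmCIF fixtures parse back with chains, frames and metadata", {
  dir <- withr::local_tempdir()
  fx <- makeScope(fixtureSpec(
    nNt = 11, nMembers = 1, rigidMotions = FALSE, protein = TRUE,
    modifiedResidues = data.frame(member = 1, position = 3,
                                  code = "PSU"),
    sequence = "GGUACGUAGCC", resolutions = 2.5,
    methods = "ELECTRON MICROSCOPY", seed = 11), dir)
  st <- parseStructure(fx$scope@members$path[1])

  # only the RNA chain becomes a ChainRecord; the peptide stays in the
  # atom inventory for neighbor detection
  expect_length(st@chains, 1L)
  expect_named(st@chains, "A")
  expect_true("P" %in% st@atomInventory$chain)
  expect_false(any(st@atomInventory$isNt[st@atomInventory$chain == "P"]))

  ch <- st@chains[["A"]]
  expect_equal(length(ch), 11L)
  expect_equal(nchar(ch@sequence), 11L)
  # pseudouridine maps to parent U in the sequence, keeps its component
  expect_equal(substr(ch@sequence, 3, 3), "U")
  expect_equal(parseUnitId(ch@unitIds[3])@component, "PSU")
  expect_equal(st@resolution, 2.5)
  expect_equal(st@method, "ELECTRON MICROSCOPY")

  # frame invariants on every parsed nucleotide
  for (R in ch@rotations) {
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
    expect_lt(abs(det(R) - 1), 1e-8)
  }
})

test_that("nucleotides without enough ring atoms are dropped with a warning", {
  dir <- withr::local_tempdir()
  fx <- makeScope(fixtureSpec(
    nNt = 11, nMembers = 1, rigidMotions = FALSE,
    missingAtoms = data.frame(member = 1, position = 6), seed = 12), dir)
  path <- fx$scope@members$path[1]

  # independent count from the file text: residues with >= 3 ring atoms
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  tok <- strsplit(lines, "[ \t]+")
  resno <- vapply(tok, `[[`, character(1), 16L)
  elety <- vapply(tok, `[[`, character(1), 4L)
  ringCount <- vapply(split(elety, resno), function(e)
    sum(e %in% c("N1","C2","N3","C4","C5","C6","N7","C8","N9")),
    integer(1))
  expect_equal(sum(ringCount >= 3), 10L)

  expect_warning(st <- parseStructure(path), "frame undefined")
  expect_equal(length(st@chains[["A"]]), 10L)
  # the defective residue's surviving atoms stay in the inventory
  inv <- st@atomInventory
  expect_true(any(inv$chain == "A" & !inv$isNt))
})

test_that("altloc resolution keeps the highest occupancy, ties by letter", {
  dir <- withr::local_tempdir()
  std <- standardBaseGeometry("G")
  base <- data.frame(model = 1L, chain = "A", entity = 1L, resid = "G",
                     resno = 1L, insert = NA_character_,
                     elety = rownames(std),
                     elesy = substr(rownames(std), 1, 1),
                     alt = NA_character_, occ = 1,
                     x = std[, 1], y = std[, 2], z = std[, 3])
  mkAlt <- function(occA, occB) {
    altB <- base[base$elety == "N9", ]
    altB$x <- altB$x + 5
    base$alt[base$elety == "N9"] <- "A"
    base$occ[base$elety == "N9"] <- occA
    altB$alt <- "B"; altB$occ <- occB
    rbind(base, altB)
  }
  p1 <- file.path(dir, "hi.cif")
  motifcorr:::.writeCif(p1, "ALT1", mkAlt(0.4, 0.6))
  n9 <- function(st) {
    a <- st@atomInventory
    unlist(a[a$elety == "N9", c("x", "y", "z")])
  }
  stdN9 <- std["N9", ]
  expect_equal(n9(parseStructure(p1)), stdN9 + c(5, 0, 0),
               ignore_attr = TRUE, tolerance = 1e-3)

  p2 <- file.path(dir, "tie.cif")
  motifcorr:::.writeCif(p2, "ALT2", mkAlt(0.5, 0.5))
  expect_equal(n9(parseStructure(p2)), stdN9, ignore_attr = TRUE,
               tolerance = 1e-3)
})

test_that("legacy PDB files parse with resolution and method", {
  dir <- withr::local_tempdir()
  std <- standardBaseGeometry("G")
  atomLines <- sprintf(
    "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(std)), rownames(std), "G", "B", 7,
    std[, 1], std[, 2], std[, 3], 1, 0,
    substr(rownames(std), 1, 1))
  path <- file.path(dir, "mini.pdb")
  writeLines(c(
    "HEADER    RIBONUCLEIC ACID                        01-JAN-20   9XYZ",
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.90 ANGSTROMS.",
    atomLines, "END"), path)
  st <- parseStructure(path)
  expect_equal(st@pdbId, "9XYZ")
  expect_equal(st@resolution, 1.9)
  expect_equal(st@method, "X-RAY DIFFRACTION")
  ch <- st@chains[["B"]]
  expect_equal(length(ch), 1L)
  expect_equal(ch@numbers, 7L)
  # coordinates carry 3 decimals in PDB format; the frame follows suit
  expect_lt(max(abs(ch@rotations[[1]] - diag(3))), 1e-3)
})

test_that("requesting an absent model lists the available ones", {
  dir <- withr::local_tempdir()
  fx <- makeScope(fixtureSpec(nNt = 5, nMembers = 1,
                              rigidMotions = FALSE, seed = 13), dir)
  expect_error(parseStructure(fx$scope@members$path[1], model = 2),
               "available models: 1")
  expect_error(parseStructure(file.path(dir, "nope.cif")), "no such file")
})

test_that("base frames are equivariant under rigid motions", {
  std <- standardBaseGeometry("C")
  atoms <- data.frame(elety = rownames(std), x = std[, 1], y = std[, 2],
                      z = std[, 3])
  f0 <- computeBaseFrame(atoms, "C")
  expect_equal(f0$center, colMeans(std[baseRingAtoms("C"), ]),
               ignore_attr = TRUE)
  expect_lt(max(abs(f0$rotation - diag(3))), 1e-8)

  set.seed(21)
  for (i in 1:20) {
    Q <- randomRotation(); t <- runif(3, -30, 30)
    moved <- applyRigidMotion(std, Q, t)
    f <- computeBaseFrame(data.frame(elety = rownames(std),
                                     x = moved[, 1], y = moved[, 2],
                                     z = moved[, 3]), "C")
    expect_lt(max(abs(f$rotation - Q %*% f0$rotation)), 1e-8)
    expect_lt(max(abs(f$center - (as.vector(Q %*% f0$center) + t))), 1e-8)
  }
})

test_that("frames stay accurate under coordinate noise and atom loss", {
  std <- standardBaseGeometry("A")
  ring <- baseRingAtoms("A")
  set.seed(31)
  Q <- randomRotation(); t <- runif(3, -10, 10)
  moved <- applyRigidMotion(std, Q, t)
  angles <- replicate(100, {
    noisy <- moved + matrix(rnorm(length(moved), sd = 0.05),
                            ncol = 3)
    f <- computeBaseFrame(data.frame(elety = rownames(std),
                                     x = noisy[, 1], y = noisy[, 2],
                                     z = noisy[, 3]), "A")
    rotationAngle(f$rotation, Q) * 180 / pi
  })
  expect_true(all(angles < 5))

  # a 3-ring-atom subset still defines a frame; fewer atoms do not
  sub <- data.frame(elety = ring[1:3],
                    x = std[ring[1:3], 1], y = std[ring[1:3], 2],
                    z = std[ring[1:3], 3])
  f <- computeBaseFrame(sub, "A")
  expect_lt(rotationAngle(f$rotation, diag(3)), 1e-6)
  expect_error(computeBaseFrame(sub[1:2, ], "A"), "frame undefined")
})
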