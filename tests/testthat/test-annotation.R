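test_that("ideal stacked steps annotate as stacks between neighbors only", {
  step <- atomsToInstance(generateIdealMotif(2))
  ann <- annotateInteractions(step)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$kind, "stack")
  # the criterion holds by direct geometry on the frames themselves
  d <- sqrt(sum((step@centers[1, ] - step@centers[2, ])^2))
  expect_lt(d, 5.5)
  expect_gte(ann$verticalOffset, 2.5)
  expect_lte(ann$verticalOffset, 5.5)
  expect_lt(ann$normalAngle, 30)

  helix <- atomsToInstance(generateIdealMotif(11))
  annH <- annotateInteractions(helix)
  expect_equal(nrow(annH), 10L)   # consecutive pairs, nothing else
  expect_true(all(annH$kind == "stack"))
  expect_equal(
    vapply(annH$unit2, function(u) parseUnitId(u)@number, integer(1)) -
      vapply(annH$unit1, function(u) parseUnitId(u)@number, integer(1)),
    rep(1L, 10L), ignore_attr = TRUE)
})

test_that("a canonical coplanar pair annotates as a pair", {
  inst <- atomsToInstance(wcPairAtoms())
  ann <- annotateInteractions(inst)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$kind, "pair")
  # direct geometry: three polar contacts in hydrogen-bond range
  atoms <- wcPairAtoms()
  g <- atoms[atoms$resno == 1 & grepl("^[NO]", atoms$elety), ]
  c_ <- atoms[atoms$resno == 2 & grepl("^[NO]", atoms$elety), ]
  dd <- as.matrix(dist(rbind(g[c("x", "y", "z")], c_[c("x", "y", "z")])))
  contacts <- dd[seq_len(nrow(g)), nrow(g) + seq_len(nrow(c_))]
  expect_gte(sum(contacts <= 3.4), 2)
  expect_true(ann$centerDist >= 4.5 && ann$centerDist <= 12)
})

test_that("distant bases yield no annotation", {
  atoms <- wcPairAtoms()
  atoms$x[atoms$resno == 2] <- atoms$x[atoms$resno == 2] + 30
  expect_equal(nrow(annotateInteractions(atomsToInstance(atoms))), 0L)
})

test_that("annotation is invariant under rigid motion and position order", {
  inst <- atomsToInstance(generateIdealMotif(5))
  ann0 <- annotateInteractions(inst)
  set.seed(71)
  for (i in 1:10) {
    moved <- rigidMoveInstance(inst, randomRotation(), runif(3, -30, 30))
    ann <- annotateInteractions(moved)
    expect_equal(ann$kind, ann0$kind)
    expect_equal(ann$centerDist, ann0$centerDist, tolerance = 1e-8)
    expect_equal(ann$normalAngle, ann0$normalAngle, tolerance = 1e-6)
    expect_equal(ann$verticalOffset, ann0$verticalOffset,
                 tolerance = 1e-8)
  }
  # reversing the nucleotide order gives the same unordered pair set
  atoms <- generateIdealMotif(5)
  rev_ <- atoms[order(-atoms$resno), ]
  annR <- annotateInteractions(atomsToInstance(rev_))
  key <- function(a) sort(paste(pmin(a$unit1, a$unit2),
                                pmax(a$unit1, a$unit2), a$kind))
  expect_equal(key(annR), key(ann0))
})

test_that("neighbor detection matches brute force at the cutoff", {
  dir <- withr::local_tempdir()
  fx <- makeScope(fixtureSpec(
    nNt = 6, nMembers = 1, rigidMotions = FALSE, protein = TRUE,
    neighbors = data.frame(member = c(1, 1), chain = c("X", "Z"),
                           distance = c(9.5, 11.0)),
    seed = 72), dir)
  st <- parseStructure(fx$scope@members$path[1])
  inst <- extractInstance(st, st@chains[["A"]]@unitIds)

  nb <- detectNeighborChains(inst, st, cutoff = 10)
  bf <- bruteForceNeighbors(inst, st, cutoff = 10)
  expect_setequal(nb$chain, bf$chain)
  expect_equal(nb$minDistance[order(nb$chain)],
               bf$minDistance[order(bf$chain)], tolerance = 1e-6)

  # the planted 9.5 A ion is a neighbor at its exact distance; the
  # 11 A one is not; distances carry the file's 3-decimal rounding
  expect_true("X" %in% nb$chain)
  expect_false("Z" %in% nb$chain)
  expect_equal(nb$minDistance[nb$chain == "X"], 9.5, tolerance = 1e-3)
  # entity descriptions name the neighbors
  expect_equal(nb$identity[nb$chain == "X"], "synthetic ion X")

  # with no other chains there are no neighbors: the whole chain is
  # the instance, so even the host chain has nothing left to offer
  fx2 <- makeScope(fixtureSpec(nNt = 6, nMembers = 1,
                               rigidMotions = FALSE, seed = 73), dir)
  st2 <- parseStructure(fx2$scope@members$path[1])
  inst2 <- extractInstance(st2, st2@chains[["A"]]@unitIds)
  expect_equal(nrow(detectNeighborChains(inst2, st2)), 0L)
})

test_that("the host chain can neighbor its own motif via flanking residues", {
  dir <- withr::local_tempdir()
  fx <- makeScope(fixtureSpec(nNt = 8, nMembers = 1,
                              rigidMotions = FALSE, seed = 74), dir)
  st <- parseStructure(fx$scope@members$path[1])
  ch <- st@chains[["A"]]
  inst <- extractInstance(st, parseRangeSelection("1:4", ch))
  nb <- detectNeighborChains(inst, st, cutoff = 10)
  expect_true("A" %in% nb$chain)
})

test_that("neighbor summaries count each instance once per identity", {
  r1 <- data.frame(chain = c("X", "Y"), identity = c("tRNA", "protein"),
                   minDistance = c(4, 6))
  r2 <- data.frame(chain = "X", identity = "tRNA", minDistance = 8)
  r3 <- data.frame(chain = character(), identity = character(),
                   minDistance = numeric())
  s <- summarizeNeighbors(list(a = r1, b = r2, c = r3))
  expect_equal(s$count[s$identity == "tRNA"], 2L)
  expect_equal(s$count[s$identity == "protein"], 1L)
  expect_equal(s$minDistance[s$identity == "tRNA"], 4)
  expect_equal(nrow(summarizeNeighbors(list(r3))), 0L)
  # duplicate identities within one instance still count once
  rDup <- data.frame(chain = c("X", "W"), identity = c("tRNA", "tRNA"),
                     minDistance = c(3, 5))
  s2 <- summarizeNeighbors(list(rDup))
  expect_equal(s2$count, 1L)
})
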