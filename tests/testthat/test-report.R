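# a small two-cluster scope used by the end-to-end report tests:
# members 4-6 share a conformational change (two bases rotated 0.9 rad)
clusterScope <- function(dir, nMembers = 6, seed = 91) {
  rot <- do.call(rbind, lapply(4:nMembers, function(m)
    data.frame(member = m, position = c(3, 7), angle = 0.9)))
  makeScope(fixtureSpec(
    nNt = 9, nMembers = nMembers, sequence = "GAUCGUACG",
    noiseSigma = 0.05, perBaseRotations = rot, protein = TRUE,
    seed = seed), dir)
}

test_that("superposition undoes rigid motions exactly", {
  inst <- idealInstance(7, id = "Q|1|A")
  set.seed(92)
  moved <- rigidMoveInstance(inst, randomRotation(), runif(3, -30, 30))
  moved@instanceId <- "M|1|A"
  insts <- list("Q|1|A" = inst, "M|1|A" = moved)

  # the reference itself is untouched
  sup <- superposeInstances(insts, reference = "Q|1|A",
                            selection = "Q|1|A")
  expect_equal(sup[["Q|1|A"]]$instance@atoms, inst@atoms)

  sup2 <- superposeInstances(insts, reference = "Q|1|A")
  a <- as.matrix(inst@atoms[c("x", "y", "z")])
  b <- as.matrix(sup2[["M|1|A"]]$instance@atoms[c("x", "y", "z")])
  expect_lt(sqrt(mean(rowSums((a - b)^2))), 1e-9)

  expect_error(superposeInstances(insts, reference = "nope"),
               "not in the selection")
})

test_that("noisy copies superpose to the oracle's residual", {
  set.seed(93)
  inst <- idealInstance(11, id = "Q|1|A")
  rmsds <- replicate(10, {
    noisy <- addNoiseInstance(inst, 0.3)
    noisy@instanceId <- "N|1|A"
    sup <- superposeInstances(list("Q|1|A" = inst, "N|1|A" = noisy),
                              reference = "Q|1|A")
    moved <- sup[["N|1|A"]]$instance
    resid <- sqrt(mean(rowSums((inst@centers - moved@centers)^2)))
    oracle <- hornSuperpose(inst@centers, noisy@centers)$rmsd
    expect_equal(resid, oracle, tolerance = 1e-9)
    resid
  })
  # base centers average ~8 ring atoms, so their noise is ~sigma/sqrt(8),
  # further shrunk by the 7 fitted dof; just pin the broad scale
  expect_gt(mean(rmsds), 0.02)
  expect_lt(mean(rmsds), 0.3)
})

test_that("the pipeline writes a consistent, re-parseable report", {
  dir <- withr::local_tempdir()
  fx <- clusterScope(file.path(dir, "scope"))
  out <- file.path(dir, "out")
  res <- runMotifCorrespondence(
    fx$scope@members$path[1], "A", selection = "1:9", scope = fx$scope,
    outDir = out, includeNeighborhood = TRUE)

  n <- length(motifInstances(res$correspondence))
  expect_equal(n, 6L)
  expect_equal(nrow(res$table), n)

  # table rows follow the seriation order
  ordIds <- instanceIds(res$discrepancy)[seriationOrder(res$seriation)]
  expect_equal(res$table$instance, ordIds, ignore_attr = TRUE)

  # instances.tsv re-parses and matches; the header carries the counts
  tsv <- read.table(file.path(out, "instances.tsv"), sep = "\t",
                    header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(tsv), n)
  hdr <- readLines(file.path(out, "instances.tsv"), n = 3)
  expect_match(hdr[2], "retained: 6")

  # ordered CSV re-parses to the reordered matrix
  csv <- read.csv(file.path(out, "discrepancy_ordered.csv"),
                  row.names = 1, check.names = FALSE)
  v <- discrepancyValues(res$discrepancy)
  ord <- seriationOrder(res$seriation)
  # CSV carries 6 decimals
  expect_lt(max(abs(as.matrix(csv) - v[ord, ord])), 1e-6)

  # JSON carries ids plus row-major values
  js <- jsonlite::read_json(file.path(out, "discrepancy.json"),
                            simplifyVector = TRUE)
  expect_equal(js$instance_ids, ordIds, ignore_attr = TRUE)
  expect_equal(matrix(js$values, n, n, byrow = TRUE), v[ord, ord],
               ignore_attr = TRUE)

  # superposition re-parses; one model per instance, unit ids preserved
  sup <- file.path(out, "superposition.cif")
  st1 <- parseStructure(sup, model = 1)
  expect_equal(length(st1@chains[["A"]]), 9L)
  stLast <- parseStructure(sup, model = n)
  expect_equal(stLast@chains[["A"]]@numbers, 1:9)
  # neighborhood residues ride along under their own chains
  expect_true(length(st1@chains) >= 1L)
  expect_true("P" %in% st1@atomInventory$chain)

  # neighbor summary re-parses
  nb <- read.table(file.path(out, "neighbors.tsv"), sep = "\t",
                   header = TRUE, stringsAsFactors = FALSE)
  expect_true("synthetic peptide" %in% nb$identity)
  expect_true(all(nb$count <= n))

  # query.json records enough to re-run
  q <- jsonlite::read_json(file.path(out, "query.json"),
                           simplifyVector = TRUE)
  expect_equal(q$selection, "1:9")
  expect_equal(q$scope$mode, "chain_set")
  expect_equal(nrow(q$scope$members), 6L)
})

test_that("planted clusters form contiguous dark blocks in the export", {
  dir <- withr::local_tempdir()
  fx <- clusterScope(file.path(dir, "scope"), seed = 94)
  res <- runMotifCorrespondence(
    fx$scope@members$path[1], "A", selection = "1:9", scope = fx$scope,
    outDir = file.path(dir, "out"), writePng = FALSE)
  ord <- seriationOrder(res$seriation)
  ids <- instanceIds(res$discrepancy)[ord]
  grp <- ifelse(ids %in% c("SY03|1|A", "SY04|1|A", "SY05|1|A"), 2L, 1L)
  expect_equal(sum(grp[-1] != grp[-length(grp)]), 1L)

  v <- discrepancyValues(res$discrepancy)
  within <- v[grp[match(instanceIds(res$discrepancy), ids)] == 1,
              grp[match(instanceIds(res$discrepancy), ids)] == 1]
  across <- v[grp[match(instanceIds(res$discrepancy), ids)] == 1,
              grp[match(instanceIds(res$discrepancy), ids)] == 2]
  expect_gt(mean(across) / mean(within[upper.tri(within)]), 5)
})

test_that("a reporting cutoff trims outputs but never the computation", {
  dir <- withr::local_tempdir()
  fx <- clusterScope(file.path(dir, "scope"), seed = 95)
  out <- file.path(dir, "out")
  res <- runMotifCorrespondence(
    fx$scope@members$path[1], "A", selection = "1:9", scope = fx$scope,
    maxDiscrepancy = 0.1, outDir = out, writePng = FALSE)
  # all six instances were computed and kept in the JSON
  expect_length(motifInstances(res$correspondence), 6L)
  js <- jsonlite::read_json(file.path(out, "discrepancy.json"),
                            simplifyVector = TRUE)
  expect_length(js$instance_ids, 6L)
  # but the far cluster is omitted from the table and ordered CSV
  expect_lt(nrow(res$table), 6L)
  csv <- read.csv(file.path(out, "discrepancy_ordered.csv"),
                  row.names = 1, check.names = FALSE)
  expect_equal(nrow(csv), nrow(res$table))
})

test_that("tiny and degenerate exports still round-trip", {
  dir <- withr::local_tempdir()
  dm <- new("DiscrepancyMatrix", instanceIds = c("a", "b"),
            values = matrix(0, 2, 2), nNt = 3L)
  exportHeatmap(dm, 1:2, file.path(dir, "m.csv"), file.path(dir, "m.json"))
  csv <- read.csv(file.path(dir, "m.csv"), row.names = 1)
  expect_true(all(csv == 0))
  js <- jsonlite::read_json(file.path(dir, "m.json"),
                            simplifyVector = TRUE)
  expect_equal(js$values, rep(0, 4))
})
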