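# a scope with distinct letters around every planted defect, so the
# ground-truth mapping is the unique alignment optimum
defectScope <- function(dir, seed = 61) {
  makeScope(fixtureSpec(
    nNt = 11, nMembers = 6, sequence = "GAUCGUACGCA",
    noiseSigma = 0.05,
    indels = data.frame(member = 5, position = 6),        # inside query
    missingAtoms = data.frame(member = 6, position = 4),  # inside query
    seed = seed), dir)
}

test_that("a single-member scope yields the identity self-correspondence", {
  dir <- withr::local_tempdir()
  fx <- makeScope(fixtureSpec(nNt = 7, nMembers = 1,
                              rigidMotions = FALSE, seed = 62), dir)
  ch <- parseStructure(fx$scope@members$path[1])@chains[["A"]]
  sel <- parseRangeSelection("2:6", ch)
  cs <- buildCorrespondence(sel, fx$scope)
  expect_length(motifInstances(cs), 1L)
  expect_equal(cs@query@unitIds, sel, ignore_attr = TRUE)
  log <- cs@mappingLog
  expect_true(all(log$status == "mapped"))
  expect_equal(log$targetUnit, log$queryUnit)
  expect_equal(nrow(droppedMembers(cs)), 0L)
})

test_that("an exact file copy yields a second instance at zero discrepancy", {
  dir <- withr::local_tempdir()
  fx <- makeScope(fixtureSpec(nNt = 7, nMembers = 1,
                              rigidMotions = FALSE, seed = 63), dir)
  orig <- fx$scope@members$path[1]
  copy <- file.path(dir, "copy.cif")
  file.copy(orig, copy)
  scope <- scopeChainSet(data.frame(path = c(orig, copy), chain = "A",
                                    model = 1L))
  ch <- parseStructure(orig)@chains[["A"]]
  cs <- buildCorrespondence(parseRangeSelection("1:7", ch), scope)
  expect_length(motifInstances(cs), 2L)
  insts <- motifInstances(cs)
  expect_lt(geometricDiscrepancy(insts[[1]], insts[[2]]), 1e-12)
  # same data block in both files: ids disambiguated deterministically
  expect_equal(sort(names(insts)), c("SY00|1|A", "SY00|1|A#2"))
})

test_that("incomplete members are dropped and bookkeeping balances", {
  dir <- withr::local_tempdir()
  fx <- defectScope(dir)
  ch <- parseStructure(fx$scope@members$path[1])@chains[["A"]]
  sel <- parseRangeSelection("3:9", ch)
  expect_warning(cs <- buildCorrespondence(sel, fx$scope),
                 "frame undefined")
  expect_length(motifInstances(cs), 4L)
  drops <- droppedMembers(cs)
  expect_equal(nrow(drops), 2L)
  expect_setequal(drops$member, c("SY04|1|A", "SY05|1|A"))
  # the log names the first failing query position
  expect_match(drops$reason[drops$member == "SY04|1|A"], "\\|6 is gap")
  expect_match(drops$reason[drops$member == "SY05|1|A"], "\\|4 is gap")
  # completeness bookkeeping: instances + drops == members after filter
  expect_equal(length(motifInstances(cs)) + nrow(drops),
               nrow(fx$scope@members))
})

test_that("indels outside the query shift mappings per the manifest", {
  dir <- withr::local_tempdir()
  fx <- makeScope(fixtureSpec(
    nNt = 11, nMembers = 3, sequence = "GAUCCGAUGCA",
    indels = data.frame(member = 3, position = 2), seed = 64), dir)
  ch <- parseStructure(fx$scope@members$path[1])@chains[["A"]]
  sel <- parseRangeSelection("5:9", ch)
  cs <- buildCorrespondence(sel, fx$scope)
  expect_length(motifInstances(cs), 3L)
  log <- cs@mappingLog
  shifted <- log[log$member == "SY02|1|A", ]
  expect_true(all(shifted$status == "mapped"))
  # author numbers in the indel member sit one below the query's
  expect_equal(
    vapply(shifted$targetUnit, function(u) parseUnitId(u)@number,
           integer(1)),
    vapply(shifted$queryUnit, function(u) parseUnitId(u)@number,
           integer(1)) - 1L,
    ignore_attr = TRUE)
})

test_that("stockholm scopes map through alignment columns", {
  dir <- withr::local_tempdir()
  fx <- makeScope(fixtureSpec(
    nNt = 11, nMembers = 4, sequence = "GAUCCGAUGCA",
    indels = data.frame(member = 3, position = 2), seed = 65), dir)
  scope <- scopeStockholm(fx$stockholm, fx$rowMap)
  ch <- parseStructure(fx$scope@members$path[1])@chains[["A"]]
  sel <- parseRangeSelection("5:9", ch)
  cs <- buildCorrespondence(sel, scope)
  expect_length(motifInstances(cs), 4L)
  shifted <- cs@mappingLog[cs@mappingLog$member == "SY02|1|A", ]
  expect_true(all(shifted$status == "mapped"))
  expect_equal(
    vapply(shifted$targetUnit, function(u) parseUnitId(u)@number,
           integer(1)),
    c(4L, 5L, 6L, 7L, 8L), ignore_attr = TRUE)

  # a query position sitting on the indel column is a gap for that
  # member, which is then dropped with that reason
  sel2 <- parseRangeSelection("1:4", ch)
  cs2 <- buildCorrespondence(sel2, scope)
  expect_length(motifInstances(cs2), 3L)
  expect_match(droppedMembers(cs2)$reason, "gap in target")
})

test_that("resolution and method filters are inclusive and logged", {
  dir <- withr::local_tempdir()
  fx <- makeScope(fixtureSpec(
    nNt = 5, nMembers = 4, resolutions = c(2.0, 3.0, 3.5, 2.5),
    methods = c("X-RAY DIFFRACTION", "X-RAY DIFFRACTION",
                "X-RAY DIFFRACTION", "ELECTRON MICROSCOPY"),
    seed = 66), dir)
  ch <- parseStructure(fx$scope@members$path[1])@chains[["A"]]
  sel <- parseRangeSelection("1:5", ch)

  scope <- scopeChainSet(fx$scope@members, resolutionMax = 3.0)
  cs <- buildCorrespondence(sel, scope)
  ids <- names(motifInstances(cs))
  expect_true("SY01|1|A" %in% ids)    # exactly at the ceiling: kept
  expect_false("SY02|1|A" %in% ids)
  expect_match(droppedMembers(cs)$reason[
    droppedMembers(cs)$member == "SY02|1|A"], "exceeds ceiling")

  scope2 <- scopeChainSet(fx$scope@members,
                          methodsAllowed = "X-RAY DIFFRACTION")
  cs2 <- buildCorrespondence(sel, scope2)
  expect_false("SY03|1|A" %in% names(motifInstances(cs2)))

  # sidecar metadata overrides the file header
  side <- data.frame(pdb_id = "SY00", resolution = 9.9,
                     method = NA_character_)
  scope3 <- scopeChainSet(fx$scope@members, resolutionMax = 3.0,
                          metadata = side)
  flt <- filterMembers(scope3)
  expect_true("SY00|1|A" %in% flt$dropped$member)

  # unknown resolution only matters when a ceiling is set
  sideNA <- data.frame(pdb_id = c("SY00", "SY01", "SY02", "SY03"),
                       resolution = NA_real_, method = NA_character_)
  # override only via sidecar rows that carry values; header wins here
  expect_equal(nrow(filterMembers(scopeChainSet(
    fx$scope@members, metadata = sideNA))$dropped), 0L)
})

test_that("identical inputs give byte-identical correspondence sets", {
  dir <- withr::local_tempdir()
  fx <- defectScope(dir, seed = 67)
  ch <- parseStructure(fx$scope@members$path[1])@chains[["A"]]
  sel <- parseRangeSelection("3:9", ch)
  cs1 <- suppressWarnings(buildCorrespondence(sel, fx$scope))
  cs2 <- suppressWarnings(buildCorrespondence(sel, fx$scope))
  expect_identical(serialize(cs1, NULL), serialize(cs2, NULL))
})

test_that("degenerate scopes fail with informative errors", {
  dir <- withr::local_tempdir()
  fx <- makeScope(fixtureSpec(nNt = 5, nMembers = 2, seed = 68), dir)
  ch <- parseStructure(fx$scope@members$path[1])@chains[["A"]]
  sel <- parseRangeSelection("1:5", ch)

  # duplicate members are rejected at scope construction
  expect_error(scopeChainSet(rbind(fx$scope@members,
                                   fx$scope@members[1, ])),
               "duplicate")
  # query chain must be in the scope
  other <- scopeChainSet(fx$scope@members[2, , drop = FALSE])
  expect_error(buildCorrespondence(sel, other), "not a member")
  # filtering the query away also surfaces as query-not-in-scope
  tight <- scopeChainSet(fx$scope@members, resolutionMax = 0.5)
  expect_error(buildCorrespondence(sel, tight), "not a member")
})
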