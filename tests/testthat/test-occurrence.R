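occFixture <- function() {
  g <- gridSpec(10, 20)
  mask <- makeRealmMaskForTest(g)
  list(grid = g, mask = mask)
}

# two vertical realm bands of 10 columns each
makeRealmMaskForTest <- function(g) {
  new("RealmMask",
      realm = as.integer(ifelse(cellCenters(g)$col <= 10, 1L, 2L)),
      levels = c("realm_1", "realm_2"), grid = g)
}

test_that("rasterization filters by range size, endemism and grid coverage", {
  f <- occFixture()
  r1cells <- realmCells(f$mask, "realm_1")
  ranges <- list(
    ok = r1cells[1:50],                    # exactly the minimum: included
    small = r1cells[1:49],                 # one short: excluded
    straddler = c(r1cells[1:30], realmCells(f$mask, "realm_2")[1:30]),
    lost = 100000L + 1:60)                 # entirely off-grid
  res <- rasterizeAndFilter(ranges, realmMask = f$mask)
  expect_length(res$records, 1)
  expect_equal(res$records[[1]]@speciesId, "ok")
  expect_equal(res$records[[1]]@realm, "realm_1")
  expect_equal(res$exclusions$reason[match(c("small", "straddler", "lost"),
                                           res$exclusions$species_id)],
               c("min_presence", "not_endemic", "outside_grid"))
  # included set and exclusion log partition the input
  expect_setequal(c(vapply(res$records, slot, "", "speciesId"),
                    res$exclusions$species_id), names(ranges))
})

test_that("pseudoabsences are 3x presences, realm-restricted, disjoint and seeded", {
  f <- occFixture()
  rec <- new("SpeciesRecord", speciesId = "s", family = "f", status = "LC",
             realm = "realm_1",
             presenceCells = realmCells(f$mask, "realm_1")[1:20])
  pa <- samplePseudoabsences(rec, f$mask, ratio = 3, seed = 4)
  expect_length(pa, 60)
  expect_length(intersect(pa, rec@presenceCells), 0)
  expect_true(all(realmOf(f$mask, pa) == "realm_1"))
  expect_identical(pa, samplePseudoabsences(rec, f$mask, ratio = 3, seed = 4))
  expect_false(identical(pa, samplePseudoabsences(rec, f$mask, ratio = 3,
                                                  seed = 5)))
  # pigeonhole: presence covering all but 10 realm cells cannot support 3:1
  big <- rec
  big@presenceCells <- realmCells(f$mask, "realm_1")[1:90]
  expect_error(samplePseudoabsences(big, f$mask, ratio = 3, seed = 1),
               "background")
})

test_that("70/30 runs use the floor rule and never leak labels", {
  pres <- 1:100
  pa <- 201:500
  des <- partitionRuns("s", pres, pa, seed = 9)
  expect_length(des@runs, 10)           # ten runs of random subsampling
  for (r in des@runs) {
    expect_length(r$trainPresence, 70)
    expect_length(r$testPresence, 30)
    expect_length(r$trainAbsence, 210)
    expect_length(r$testAbsence, 90)
  }
  expect_true(validObject(des))         # disjointness + partition invariants
  # runs differ from one another
  expect_gt(length(unique(lapply(des@runs, `[[`, "trainPresence"))), 1)
  # floor rule on a tiny set: 3 presences -> 2 train, 1 test
  tiny <- partitionRuns("s", 1:3, 11:14, nRuns = 2, seed = 1)
  expect_length(tiny@runs[[1]]$trainPresence, 2)
  expect_length(tiny@runs[[1]]$testPresence, 1)
  expect_error(partitionRuns("s", pres, pa, trainFrac = 1.2, seed = 1),
               "trainFrac")
  # stratification: presence:pseudoabsence stays 1:3 up to rounding
  r <- des@runs[[1]]
  expect_equal(length(r$trainAbsence) / length(r$trainPresence), 3)
  expect_equal(length(r$testAbsence) / length(r$testPresence), 3)
})
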