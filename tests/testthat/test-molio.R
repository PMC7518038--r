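# Molecular I/O and the packaged potency table.

test_that("PDB receptors round-trip and resolve altlocs by occupancy", {
  f <- writeToyPdb()
  rec <- readReceptor(f)
  expect_equal(nrow(residues(rec)), 2L)
  expect_equal(sort(unique(atoms(rec)$chain)), c("A", "B"))
  # round trip preserves coordinates to the format's 3 decimals
  f2 <- tempfile(fileext = ".pdb")
  writeReceptor(rec, f2)
  rec2 <- readReceptor(f2)
  expect_equal(coords(rec2), coords(rec), tolerance = 1e-9)

  # altloc fixture: 9 records collapse to 8 atoms, keeping the B conformer
  # of residue 1's N (the higher-occupancy one)
  reca <- readReceptor(writeAltlocPdb())
  expect_equal(nAtoms(reca), 8L)
  n1 <- atoms(reca)[atoms(reca)$elety == "N" & atoms(reca)$reskey == "1", ]
  expect_equal(n1$x, 11.204)

  # multi-model files are rejected with the model count
  fm <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", readLines(f), "ENDMDL",
               "MODEL     2", readLines(f), "ENDMDL"), fm)
  expect_error(readReceptor(fm), "2 models")
})

test_that("pose SDF I/O preserves geometry, order and ids", {
  toy <- getToy()
  poses <- c(list(toy$planted),
             makeDecoys(toy$planted, toy$receptor, 4L, seed = 5L))
  f <- tempfile(fileext = ".sdf")
  writePoses(poses, f)
  back <- readPoses(f, "sdf")
  expect_length(back, 5L)
  expect_equal(vapply(back, poseId, ""), vapply(poses, poseId, ""))
  for (k in seq_along(poses)) {
    h <- !atoms(poseMolecule(poses[[k]]))$is_hydrogen
    expect_lt(rmsdNoFit(coords(poses[[k]])[h, ], coords(back[[k]])[h, ]),
              1e-4)  # printed precision of the format
  }
  # duplicate ids are auto-suffixed, order preserved
  poses2 <- poses
  poses2[[2]]@poseId <- poses2[[1]]@poseId
  f2 <- tempfile(fileext = ".sdf")
  writePoses(poses2, f2)
  ids <- vapply(readPoses(f2, "sdf"), poseId, "")
  expect_false(anyDuplicated(ids) > 0)
})

test_that("2D records and empty files are rejected", {
  f <- tempfile(fileext = ".sdf")
  # record 1 is 3D, record 2 is flat (all z = 0)
  mk <- function(z) c("flat", "  t", "",
    " 2  1  0  0  0  0  0  0  0  0999 V2000",
    sprintf("%10.4f%10.4f%10.4f C   0  0  0  0  0  0  0  0  0  0  0  0", 0, 0, z),
    sprintf("%10.4f%10.4f%10.4f C   0  0  0  0  0  0  0  0  0  0  0  0", 1.5, 0, z),
    "  1  2  1  0  0  0  0", "M  END", "$$$$")
  writeLines(c(mk(0.5), mk(0)), f)
  expect_error(readPoses(f, "sdf"), "2")
  fe <- tempfile(fileext = ".sdf")
  writeLines(character(), fe)
  expect_error(readPoses(fe, "sdf"))
})

test_that("the packaged potency table loads with 19 curated compounds", {
  tab <- pqTable()
  expect_equal(nrow(tab), 19L)
  expect_equal(tab$name[tab$compound_id == 14], "PZ-II-028")
  expect_equal(tab$pEC50_a1b3[tab$compound_id == 14], 5.79)
  expect_equal(tab$compound_id[is.na(tab$pKi_a1g2)], c(15L, 17L, 19L))
  expect_true(all(tab$R3p == "H"))
  expect_true(all(tab$pEC50_a1b3 > 3 & tab$pEC50_a1b3 < 9))
})

test_that("compound-table validation catches malformed input", {
  tab <- pqTable()
  f <- tempfile(fileext = ".csv")
  bad <- tab; bad$compound_id[2] <- 1L
  write.csv(bad, f, row.names = FALSE)
  expect_error(loadCompoundTable(f), "duplicate")
  bad2 <- tab; bad2$pKi_a1g2 <- as.character(bad2$pKi_a1g2)
  bad2$pKi_a1g2[3] <- "high"
  write.csv(bad2, f, row.names = FALSE)
  expect_error(loadCompoundTable(f), "non-numeric")
  writeLines("compound_id,name,R6,R7,R8,R3p,R4p,pEC50_a1b3,pKi_a1g2", f)
  expect_error(loadCompoundTable(f), "empty")
  # label normalization
  expect_equal(normalizeLabel(c("Ome", "OME", "tbu", "h")),
               c("OMe", "OMe", "tBu", "H"))
})

test_that("relative potency reproduces the published delta columns", {
  tab <- pqTable()
  d3 <- relativePotency(tab, 1L, "pEC50_a1b3")
  expect_equal(unname(d3[["19"]]), 1.74, tolerance = 1e-9)
  expect_equal(unname(d3[["1"]]), 0)
  d2 <- relativePotency(tab, 1L, "pKi_a1g2")
  expect_equal(unname(d2[["7"]]), -2.30, tolerance = 1e-9)
  # recomputed deltas match the packaged (printed) columns to 0.01
  expect_true(all(abs(d3 - tab$delta_a1b3) <= 0.01 + 1e-12))
  ok <- !is.na(tab$delta_a1g2)
  expect_true(all(abs(d2[ok] - tab$delta_a1g2[ok]) <= 0.01 + 1e-12))
  expect_error(relativePotency(tab, 99L), "unknown reference")
})

test_that("the mean inter-site potency gap uses the dual-measured set", {
  tab <- pqTable()
  gap <- meanSiteDifference(tab)
  expect_equal(gap$n, 16L)
  expect_equal(round(gap$mean), 4)
  expect_equal(gap$mean, 4.079375, tolerance = 0.005)
  one <- tab[tab$compound_id == 1, ]
  expect_equal(meanSiteDifference(one)$mean, 9.77 - 4.66)
  none <- tab[tab$compound_id %in% c(15, 17, 19), ]
  expect_error(meanSiteDifference(none), "no compound")
})

test_that("scaffold maps survive the 0-based JSON interchange", {
  toy <- getToy()
  f <- tempfile(fileext = ".json")
  writeScaffoldMap(toy$scaffold, f)
  back <- readScaffoldMap(f)
  expect_equal(back@coreAtoms, toy$scaffold@coreAtoms)
  expect_equal(back@attachments$replaced_hydrogen,
               toy$scaffold@attachments$replaced_hydrogen)
  # the on-disk indices are 0-based
  js <- jsonlite::fromJSON(f)
  expect_equal(min(js$core_atoms), 0L)
})

test_that("external score import is strict about keys and blanks", {
  f <- tempfile(fileext = ".csv")
  tab <- data.frame(pose_id = c("p1", "p1", "p2"),
                    compound_id = c(1L, 2L, 1L),
                    dG_bind = c(-50.1, -47.3, -40.0))
  write.csv(tab, f, row.names = FALSE)
  got <- importScores(f)
  expect_equal(nrow(got), 3L)
  exportScores(got, f)
  expect_equal(importScores(f)$dG_bind, tab$dG_bind, tolerance = 1e-9)
  dup <- rbind(tab, tab[1, ])
  write.csv(dup, f, row.names = FALSE)
  expect_error(importScores(f), "duplicate")
  blank <- tab; blank$dG_bind[2] <- NA
  write.csv(blank, f, row.names = FALSE)
  expect_error(importScores(f), "row 2")
})
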