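# Post-docking derivatization: substituent placement geometry and pose
# expansion bookkeeping.

test_that("an H substituent on a bare position is the identity", {
  toy <- getToy()
  att <- toy$scaffold@attachments[3, ]  # R8, currently a hydrogen
  out <- placeSubstituent(toy$planted, att, toy$library[["H"]],
                          toy$receptor)
  expect_identical(atoms(out), atoms(poseMolecule(toy$planted)))
  expect_error(
    placeSubstituent(toy$planted, att,
                     methods::new("Substituent", label = "H",
                                  fragment = toy$library[["Cl"]]@fragment,
                                  linkAtom = 1L),
                     toy$receptor),
    "non-hydrogen")
})

test_that("halogen placement hits the tabulated bond length exactly", {
  toy <- getToy()
  att <- toy$scaffold@attachments[3, ]  # R8
  mol0 <- poseMolecule(toy$planted)
  out <- placeSubstituent(toy$planted, att, toy$library[["Cl"]],
                          toy$receptor)
  expect_equal(sum(!atoms(out)$is_hydrogen),
               sum(!atoms(mol0)$is_hydrogen) + 1L)
  im <- attr(out, "index_map")
  core <- im[toy$scaffold@coreAtoms]
  expect_equal(rmsdNoFit(coords(mol0)[toy$scaffold@coreAtoms, ],
                         coords(out)[core, ]), 0)
  cl <- which(atoms(out)$element == "Cl")
  d <- sqrt(sum((coords(out)[cl, ] - coords(out)[im[att$core_atom], ])^2))
  expect_equal(d, 1.73, tolerance = 1e-6)
})

test_that("the torsion scan tracks a 1-degree brute-force oracle", {
  toy <- getToy()
  att <- toy$scaffold@attachments[5, ]  # R4p
  sub <- toy$library[["OMe"]]
  out <- placeSubstituent(toy$planted, att, sub, toy$receptor,
                          torsionSteps = 12L)
  # recompute the chosen dihedral and compare against a 1-degree scan of the
  # same clash score, reimplemented here
  mol0 <- poseMolecule(toy$planted)
  core <- att$core_atom; repl <- att$replaced_hydrogen
  pc <- coords(mol0)[core, ]
  u <- (coords(mol0)[repl, ] - pc); u <- u / sqrt(sum(u^2))
  target <- pc + 1.36 * u
  im <- attr(out, "index_map")
  # fragment atoms are the appended block
  nKeep <- sum(!is.na(im))
  fidx <- (nKeep + 1L):nrow(atoms(out))
  link <- fidx[1L]
  env <- rbind(coords(toy$receptor),
               coords(out)[setdiff(seq_len(nKeep), im[core]), , drop = FALSE])
  envVdw <- c(atoms(toy$receptor)$vdw,
              atoms(out)$vdw[setdiff(seq_len(nKeep), im[core])])
  clash <- function(xyz, vdw) {
    s <- 0
    for (i in seq_len(nrow(xyz))) {
      r2 <- rowSums(sweep(env, 2L, xyz[i, ])^2)
      t <- pmin(((0.89 * (vdw[i] + envVdw))^2 / r2)^6, 1e4)
      s <- s + sum(t[t > 1e-6])
    }
    s
  }
  rotAbout <- function(xyz, theta) {
    R <- PoseSAR:::rotationMatrix(u, theta)
    sweep(sweep(xyz, 2L, target) %*% t(R), 2L, target, "+")
  }
  scanIdx <- setdiff(fidx, link)
  base <- coords(out)[scanIdx, , drop = FALSE]
  vdwF <- atoms(out)$vdw[scanIdx]
  s0 <- clash(base, vdwF)
  best <- Inf; bestTh <- 0
  for (th in (0:359) * pi / 180) {
    s <- clash(rotAbout(base, th), vdwF)
    if (s < best) { best <- s; bestTh <- th }
  }
  # chosen placement is within 30 degrees of the brute-force optimum
  delta <- min(bestTh, 2 * pi - bestTh) * 180 / pi
  expect_lt(delta, 30 + 1e-9)
})

test_that("pose expansion yields n_poses x n_compounds with invariant cores", {
  toy <- getToy()
  dec <- makeDecoys(toy$planted, toy$receptor, 1L, seed = 3L)
  poses <- c(list(toy$planted), dec)
  recs <- toy$records[1:4, ]  # reference + 3 analogs
  out <- list()
  for (p in poses) {
    out <- c(out, expandPose(p, toy$scaffold, recs, toy$library,
                             toy$receptor, referenceId = "1"))
  }
  expect_length(out, 2L * 4L)
  for (p in out) {
    base <- sub(":.*$", "", poseId(p))
    ref <- poses[[match(base, vapply(poses, poseId, ""))]]
    expect_equal(rmsdNoFit(coords(ref)[toy$scaffold@coreAtoms, ],
                           coords(p)[p@meta$core_atoms, ]), 0)
  }
  # derived pose ids carry the reference pose and compound
  expect_true(all(grepl(":", vapply(out[c(2:4, 6:8)], poseId, ""))))
  # single pose, reference-only table
  solo <- expandPose(toy$planted, toy$scaffold, toy$records[1, , drop = FALSE],
                     toy$library, toy$receptor, referenceId = "1")
  expect_length(solo, 1L)
})

test_that("derivatization is deterministic and rejects unknown labels", {
  toy <- getToy()
  recs <- toy$records[1:3, ]
  a <- expandPose(toy$planted, toy$scaffold, recs, toy$library, toy$receptor,
                  referenceId = "1")
  b <- expandPose(toy$planted, toy$scaffold, recs, toy$library, toy$receptor,
                  referenceId = "1")
  for (k in seq_along(a)) expect_identical(coords(a[[k]]), coords(b[[k]]))
  bad <- recs; bad$R8[2] <- "SF5"
  expect_error(expandPose(toy$planted, toy$scaffold, bad, toy$library,
                          toy$receptor, referenceId = "1"), "SF5")
})

test_that("every new attachment bond matches the lookup table", {
  toy <- getToy()
  tab <- attachmentBondLengths()
  for (lab in c("Cl", "Br", "F", "OMe", "Me", "CN", "NH2")) {
    att <- toy$scaffold@attachments[5, ]
    out <- placeSubstituent(toy$planted, att, toy$library[[lab]],
                            toy$receptor)
    im <- attr(out, "index_map")
    link <- sum(!is.na(im)) + 1L
    d <- sqrt(sum((coords(out)[link, ] - coords(out)[im[att$core_atom], ])^2))
    key <- switch(lab, OMe = "O", Me = "C.sp3", CN = "C.sp", NH2 = "N", lab)
    expect_equal(d, unname(tab[[key]]), tolerance = 1e-6)
  }
})
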