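# Structural interaction fingerprints: site enumeration, per-kind geometric
# criteria, and the pose-ensemble bit matrix.

# one-residue receptor helper: a bare carbon probe at a given distance
probeReceptor <- function(d, element = "C", resid = "UNK", charge = 0) {
  methods::new("Receptor", atoms = data.frame(
    chain = "A", resno = 1L, insert = "", reskey = "1", resid = resid,
    elety = paste0(element, "1"), element = element, x = d, y = 0, z = 0,
    occ = 1, charge = charge, vdw = PoseSAR:::elementProperty(element, "vdw"),
    is_hydrogen = FALSE, stringsAsFactors = FALSE))
}

probePose <- function() {
  mol <- newMolecule("probe", rbind(c(0, 0, 0)), "C",
                     data.frame(i = integer(), j = integer(),
                                order = integer()), charge = 0)
  newLigandPose("probe", mol)
}

test_that("the site cutoff is half-open at exactly 5 Angstrom", {
  p <- probePose()
  expect_equal(nrow(bindingSiteResidues(probeReceptor(4.9), p)), 1L)
  expect_equal(nrow(bindingSiteResidues(probeReceptor(5.1), p)), 0L)
  expect_equal(nrow(bindingSiteResidues(probeReceptor(100), p)), 0L)
})

test_that("site enumeration matches an all-pairs double loop", {
  toy <- getToy()
  site <- bindingSiteResidues(toy$receptor, toy$planted, 5.0)
  ra <- atoms(toy$receptor)
  lxyz <- coords(toy$planted)[!atoms(poseMolecule(toy$planted))$is_hydrogen, ]
  rxyz <- coords(toy$receptor)
  expectHit <- character()
  for (kk in unique(paste(ra$chain, ra$reskey))) {
    rows <- which(paste(ra$chain, ra$reskey) == kk & !ra$is_hydrogen)
    hit <- FALSE
    for (i in rows) for (j in seq_len(nrow(lxyz))) {
      if (sqrt(sum((rxyz[i, ] - lxyz[j, ])^2)) <= 5.0) hit <- TRUE
    }
    if (hit) expectHit <- c(expectHit, kk)
  }
  expect_setequal(paste(site$chain, site$reskey), expectHit)
  # shrinking the cutoff never adds residues
  for (cut in c(4.5, 4.0, 3.5)) {
    sub <- bindingSiteResidues(toy$receptor, toy$planted, cut)
    expect_true(all(paste(sub$chain, sub$reskey) %in%
                    paste(site$chain, site$reskey)))
  }
})

test_that("hydrogen-bond geometry gates on distance and angle", {
  # receptor: an O-H donor aimed at a ligand carbonyl-style O
  mkRec <- function(dOA) {
    methods::new("Receptor", atoms = data.frame(
      chain = "A", resno = 1L, insert = "", reskey = "1",
      resid = "UNK", elety = c("OG", "HG"), element = c("O", "H"),
      x = c(dOA, dOA - 0.96), y = c(0, 0.05), z = 0, occ = 1,
      charge = c(-0.6, 0.4), vdw = c(1.52, 1.2),
      is_hydrogen = c(FALSE, TRUE), stringsAsFactors = FALSE))
  }
  mol <- newMolecule("acc", rbind(c(0, 0, 0), c(-1.23, 0, 0)), c("O", "C"),
                     data.frame(i = 1L, j = 2L, order = 2L))
  pose <- newLigandPose("acc", mol)
  hit <- detectInteractions(mkRec(2.9), pose)
  hb <- hit[hit$kind == "hbond_donor_to_ligand", ]
  expect_true(hb$present)
  expect_equal(hb$distance, 2.9, tolerance = 0.01)
  expect_gt(hb$angle, 120)
  miss <- detectInteractions(mkRec(3.9), pose)
  expect_false(miss$present[miss$kind == "hbond_donor_to_ligand"])
})

test_that("pi-pi stacking requires distance and plane alignment", {
  hexbonds <- data.frame(i = 1:6, j = c(2:6, 1L), order = rep(c(2L, 1L), 3))
  th <- (0:5) * pi / 3
  lig <- cbind(1.4 * cos(th), 1.4 * sin(th), 0)
  mol <- newMolecule("benzene", lig, rep("C", 6), hexbonds)
  pose <- newLigandPose("bz", mol)
  ns <- asNamespace("PoseSAR")
  recRing <- function(z, normal) {
    res <- ns$buildResidue("PHE")
    res <- ns$placeResidue(res, "CZ", c(-1.39, 0, z), c(-1, 0, 0),
                           ringAtoms = c("CG", "CD1", "CD2", "CE1", "CE2",
                                         "CZ"),
                           ringNormal = normal)
    res$resname <- "PHE"
    ns$residuesToReceptor(list(res), "A")
  }
  par <- detectInteractions(recRing(3.8, c(0, 0, 1)), pose)
  expect_true(par$present[par$kind == "pi_pi"])
  far <- detectInteractions(recRing(7.0, c(1, 0, 0)), pose)
  # at 7 A the ring is outside the binding site entirely: no pi-pi bit
  expect_false(isTRUE(any(far$present[far$kind == "pi_pi"])))
})

test_that("the designed donor contacts near-native poses consistently", {
  toy <- getToy()
  # near-native ensemble: small seeded jitters of the planted pose
  poses <- lapply(1:6, function(k) {
    q <- toy$planted
    m <- poseMolecule(q)
    set.seed(60 + k)
    coords(m) <- coords(m) + matrix(rnorm(3 * nAtoms(m), sd = 0.1), ncol = 3L)
    q@molecule <- m
    q@poseId <- paste0("n", k)
    q
  })
  s <- siftMatrix(toy$receptor, poses)
  gln <- s$summary[s$summary$resid == "GLN" &
                   s$summary$kind == "hbond_donor_to_ligand", ]
  expect_gte(gln$frequency, 0.9)
  expect_true(all(s$summary$frequency >= 0 & s$summary$frequency <= 1))
  # a single pose reproduces detectInteractions
  s1 <- siftMatrix(toy$receptor, poses[1])
  d1 <- detectInteractions(toy$receptor, poses[[1]])
  expect_equal(nrow(s1$bits), nrow(d1))
  expect_equal(s1$bits$present, d1$present)
  # duplicated poses give identical rows
  s2 <- siftMatrix(toy$receptor, list(poses[[1]], poses[[1]]))
  half <- nrow(s2$bits) / 2
  expect_equal(s2$bits$present[seq_len(half)],
               s2$bits$present[half + seq_len(half)])
})

test_that("interaction bits are invariant under global rigid motion", {
  toy <- getToy()
  d0 <- detectInteractions(toy$receptor, toy$planted)
  R <- PoseSAR:::rotationMatrix(c(0.3, -1, 2), 1.9); t <- c(-7, 3, 11)
  rec2 <- toy$receptor
  coords(rec2) <- PoseSAR:::applyRigid(coords(toy$receptor), R, t)
  p2 <- toy$planted
  m2 <- poseMolecule(p2)
  coords(m2) <- PoseSAR:::applyRigid(coords(m2), R, t)
  p2@molecule <- m2
  d1 <- detectInteractions(rec2, p2)
  expect_equal(d1$present, d0$present)
  expect_equal(d1$distance, d0$distance, tolerance = 1e-9)
})
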