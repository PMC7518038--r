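# Pose-space analytics: RMSD matrices, classical MDS, binding modes and
# center-of-mass distances.

test_that("scaffold RMSD obeys closed forms and a brute-force oracle", {
  toy <- getToy()
  p <- toy$planted
  expect_equal(scaffoldRmsd(p, p), 0)
  shifted <- p
  m <- poseMolecule(p); coords(m) <- sweep(coords(m), 2L, c(3, 4, 0), "+")
  shifted@molecule <- m
  expect_equal(scaffoldRmsd(p, shifted), 5.0, tolerance = 1e-12)
  # random pair vs per-atom loop
  set.seed(21)
  q <- p
  mq <- poseMolecule(q)
  coords(mq) <- coords(mq) + matrix(rnorm(3 * nAtoms(mq)), ncol = 3L)
  q@molecule <- mq
  core <- toy$scaffold@coreAtoms
  acc <- 0
  for (i in core) acc <- acc + sum((coords(p)[i, ] - coords(q)[i, ])^2)
  expect_equal(scaffoldRmsd(p, q, core), sqrt(acc / length(core)),
               tolerance = 1e-12)
  expect_error(scaffoldRmsd(p, q, list(1:4, 1:5)), "differ")
})

test_that("the RMSD matrix is a metric on pose ensembles", {
  toy <- getToy()
  poses <- c(list(toy$planted),
             makeDecoys(toy$planted, toy$receptor, 7L, seed = 9L))
  m <- rmsdMatrix(poses, toy$scaffold@coreAtoms)
  expect_equal(diag(m), setNames(rep(0, 8L), rownames(m)))
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_true(all(m >= 0))
  # spot checks against the pairwise operation
  set.seed(2)
  for (k in 1:5) {
    ij <- sample(8L, 2L)
    expect_equal(m[ij[1], ij[2]],
                 scaffoldRmsd(poses[[ij[1]]], poses[[ij[2]]],
                              toy$scaffold@coreAtoms), tolerance = 1e-12)
  }
  # triangle inequality (no-superposition RMSD is a scaled Euclidean metric)
  for (a in 1:8) for (b in 1:8) for (cc in 1:8) {
    expect_lte(m[a, b], m[a, cc] + m[cc, b] + 1e-9)
  }
})

test_that("classical MDS reconstructs planar configurations exactly", {
  set.seed(31)
  pts <- cbind(rnorm(10, sd = 3), rnorm(10, sd = 1.5))
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("p", 1:10)
  emb <- classicalMds(d, dims = 2L)
  expect_equal(as.matrix(dist(emb$points)), d, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(colMeans(emb$points), c(0, 0), tolerance = 1e-9)
  expect_true(all(diff(emb$eig) <= 1e-9))
  # eigenvalues of an exactly Euclidean matrix are non-negative
  expect_gt(min(emb$eig), -1e-8 * max(emb$eig))
  # zero-distance matrix embeds everything at the origin
  z <- suppressWarnings(classicalMds(matrix(0, 4, 4,
                           dimnames = list(letters[1:4], letters[1:4]))))
  expect_equal(unname(z$points), matrix(0, 4, 2))
  # relabeling poses only rotates/reflects the embedding
  perm <- sample(10L)
  emb2 <- classicalMds(d[perm, perm], dims = 2L)
  expect_lt(procrustesResidual(emb$points[perm, ], emb2$points), 1e-8)
})

test_that("a 3D configuration triggers the truncation warning path", {
  set.seed(32)
  pts <- matrix(rnorm(18), ncol = 3L)
  d <- as.matrix(dist(pts))
  emb <- classicalMds(d, dims = 2L)
  expect_equal(dim(emb$points), c(6L, 2L))
  # a slightly perturbed (non-Euclidean) matrix warns about negative modes
  d2 <- d
  d2[1, 2] <- d2[2, 1] <- d2[1, 2] * 3
  expect_warning(classicalMds(d2, dims = 2L), "negative")
})

test_that("binding-mode labels flip with the scaffold orientation", {
  toy <- getToy()
  p <- toy$planted
  axis <- c(8L, 4L)  # ring nitrogen -> R8 carbon
  lxyz <- coords(p)
  normal <- PoseSAR:::planeNormal(lxyz[!atoms(poseMolecule(p))$is_hydrogen, ])
  flipped <- p
  mf <- poseMolecule(p)
  coords(mf) <- PoseSAR:::applyRigid(lxyz, PoseSAR:::rotationMatrix(normal, pi),
                                     center = colMeans(lxyz))
  flipped@molecule <- mf
  flipped@poseId <- "flipped"
  lab <- assignBindingModes(list(p, flipped), toy$receptor, axis,
                            coreAtoms = toy$scaffold@coreAtoms)
  expect_equal(sign(lab$orientation_score[1]), -sign(lab$orientation_score[2]))
  expect_true(lab$mode[1] != lab$mode[2])

  # jittered copies cluster together under one label
  jit <- lapply(1:5, function(k) {
    q <- p
    mq <- poseMolecule(q)
    set.seed(40 + k)
    coords(mq) <- coords(mq) + matrix(rnorm(3 * nAtoms(mq), sd = 0.15),
                                      ncol = 3L)
    q@molecule <- mq
    q@poseId <- paste0("j", k)
    q
  })
  labj <- assignBindingModes(jit, toy$receptor, axis,
                             coreAtoms = toy$scaffold@coreAtoms)
  expect_equal(length(unique(labj$cluster)), 1L)
  expect_equal(length(unique(labj$mode)), 1L)

  # labels are invariant under a global rigid motion of receptor + poses
  R <- PoseSAR:::rotationMatrix(c(1, 1, 0), 0.8); t <- c(4, -6, 2)
  rec2 <- toy$receptor
  coords(rec2) <- PoseSAR:::applyRigid(coords(toy$receptor), R, t)
  moved <- lapply(list(p, flipped), function(q) {
    mq <- poseMolecule(q)
    coords(mq) <- PoseSAR:::applyRigid(coords(mq), R, t)
    q@molecule <- mq
    q
  })
  lab2 <- assignBindingModes(moved, rec2, axis,
                             coreAtoms = toy$scaffold@coreAtoms)
  expect_equal(lab2$mode, lab$mode)
  expect_equal(lab2$orientation_score, lab$orientation_score,
               tolerance = 1e-9)
  # degenerate axis
  expect_error(assignBindingModes(list(p), toy$receptor, c(4L, 4L),
                                  coreAtoms = toy$scaffold@coreAtoms),
               "degenerate")
})

test_that("center-of-mass distances track translations and masses", {
  toy <- getToy()
  p <- toy$planted
  expect_equal(comDistance(p, p), 0)
  q <- p
  mq <- poseMolecule(q)
  coords(mq) <- sweep(coords(mq), 2L, c(1, 2, 2), "+")
  q@molecule <- mq
  expect_equal(comDistance(p, q), 3.0, tolerance = 1e-12)
  # mass-weighted variant against a hand-coded oracle
  set.seed(51)
  mq2 <- poseMolecule(p)
  coords(mq2) <- coords(mq2) + matrix(rnorm(3 * nAtoms(mq2)), ncol = 3L)
  q2 <- p; q2@molecule <- mq2
  comOracle <- function(pp) {
    at <- atoms(poseMolecule(pp))
    heavy <- !at$is_hydrogen
    w <- PoseSAR:::elementProperty(at$element[heavy], "mass")
    colSums(coords(pp)[heavy, ] * w) / sum(w)
  }
  expect_equal(comDistance(p, q2, massWeighted = TRUE),
               sqrt(sum((comOracle(p) - comOracle(q2))^2)), tolerance = 1e-12)
})
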