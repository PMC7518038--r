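# Surrogate scoring: energy terms against closed forms and brute-force
# oracles, binding-energy identities, minimization contract, mutation.

# Independent nonbonded oracle: plain double loop over atom pairs with the
# same functional form (LJ 12-6, screened Coulomb eps(r) = 4r, Gaussian
# desolvation, cubic switching between 10 and 12 A).
nonbondedOracle <- function(xyz, element, charge) {
  sig <- PoseSAR:::elementProperty(element, "sigma")
  eps <- PoseSAR:::elementProperty(element, "eps")
  ron <- 10; roff <- 12
  tot <- 0
  for (i in seq_len(nrow(xyz) - 1L)) for (j in (i + 1L):nrow(xyz)) {
    r2 <- sum((xyz[i, ] - xyz[j, ])^2)
    if (r2 >= roff^2) next
    s <- if (r2 <= ron^2) 1 else {
      (roff^2 - r2)^2 * (roff^2 + 2 * r2 - 3 * ron^2) / (roff^2 - ron^2)^3
    }
    sij <- sqrt(sig[i] * sig[j]); eij <- sqrt(eps[i] * eps[j])
    sr6 <- (sij^2 / r2)^3
    lj <- 4 * eij * (sr6^2 - sr6)
    coul <- 332.0636 * charge[i] * charge[j] / (4 * r2)
    solv <- 0.05 * (charge[i]^2 + charge[j]^2) * exp(-r2 / (2 * 3.5^2))
    tot <- tot + s * (lj + coul + solv)
  }
  tot
}

test_that("a neutral pair at the LJ minimum scores minus the well depth", {
  sigma <- PoseSAR:::elementProperty("C", "sigma")
  eps <- PoseSAR:::elementProperty("C", "eps")
  r <- 2^(1 / 6) * sigma
  mol <- newMolecule("pair", rbind(c(0, 0, 0), c(r, 0, 0)), c("C", "C"),
                     data.frame(i = integer(), j = integer(),
                                order = integer()), charge = c(0, 0))
  e <- systemEnergy(molecule = mol)
  expect_equal(as.numeric(e), -eps, tolerance = 1e-9)
})

test_that("pairwise sums match an independently coded double loop", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 5L + rep
    xyz <- matrix(rnorm(n * 3, sd = 4), ncol = 3L)
    el <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
    q <- runif(n, -0.5, 0.5)
    mol <- newMolecule("blob", xyz, el,
                       data.frame(i = integer(), j = integer(),
                                  order = integer()), charge = q)
    e <- systemEnergy(molecule = mol)
    expect_equal(as.numeric(e), nonbondedOracle(xyz, el, q), tolerance = 1e-9)
  }
})

test_that("a distant receptor leaves the molecule energy unchanged", {
  toy <- getToy()
  mol <- poseMolecule(toy$planted)
  eAlone <- as.numeric(systemEnergy(molecule = mol))
  far <- mol
  coords(far) <- sweep(coords(mol), 2L, c(100, 0, 0), "+")
  eFar <- as.numeric(systemEnergy(toy$receptor, far)) -
    as.numeric(systemEnergy(receptor = toy$receptor))
  expect_lt(abs(eFar - eAlone), 1e-3)
})

test_that("binding energy equals the three-call decomposition identically", {
  toy <- getToy()
  rep0 <- bindingEnergy(toy$receptor, toy$planted)
  gC <- as.numeric(systemEnergy(toy$receptor, toy$planted))
  gR <- as.numeric(systemEnergy(receptor = toy$receptor))
  gL <- as.numeric(systemEnergy(molecule = poseMolecule(toy$planted)))
  expect_identical(rep0@dGbind, gC - gR - gL)
  # the exported component breakdown sums to dG up to the bonded terms,
  # which cancel exactly between complex and parts
  expect_equal(sum(rep0@components), rep0@dGbind, tolerance = 1e-9)
  # far-away ligand binds with ~zero energy
  far <- toy$planted
  m <- poseMolecule(far); coords(m) <- sweep(coords(m), 2L, c(120, 0, 0), "+")
  far@molecule <- m
  expect_lt(abs(bindingEnergy(toy$receptor, far)@dGbind), 1e-3)
})

test_that("an attractive toy pair binds with negative energy", {
  rec <- methods::new("Receptor", atoms = data.frame(
    chain = "A", resno = 1L, insert = "", reskey = "1", resid = "UNK",
    elety = "O1", element = "O", x = 0, y = 0, z = 0, occ = 1,
    charge = -0.5, vdw = 1.52, is_hydrogen = FALSE,
    stringsAsFactors = FALSE))
  mol <- newMolecule("cat", rbind(c(3, 0, 0)), "N",
                     data.frame(i = integer(), j = integer(),
                                order = integer()), charge = 0.5)
  expect_lt(bindingEnergy(rec, newLigandPose("p", mol))@dGbind, 0)
})

test_that("binding energy is invariant under rigid motion of the complex", {
  toy <- getToy()
  e0 <- bindingEnergy(toy$receptor, toy$planted)@dGbind
  R <- PoseSAR:::rotationMatrix(c(2, -1, 0.5), 1.1)
  t <- c(5, -3, 8)
  rec2 <- toy$receptor
  coords(rec2) <- PoseSAR:::applyRigid(coords(toy$receptor), R, t)
  p2 <- toy$planted
  m2 <- poseMolecule(p2)
  coords(m2) <- PoseSAR:::applyRigid(coords(m2), R, t)
  p2@molecule <- m2
  expect_equal(bindingEnergy(rec2, p2)@dGbind, e0, tolerance = 1e-6)
})

test_that("overlapping atoms are reported as an error naming the pair", {
  mol <- newMolecule("clash", rbind(c(0, 0, 0), c(0.05, 0, 0)), c("C", "C"),
                     data.frame(i = integer(), j = integer(),
                                order = integer()), charge = c(0, 0))
  expect_error(systemEnergy(molecule = mol), "overlapping")
})

test_that("minimization decreases energy and satisfies its gradient target", {
  toy <- getToy()
  # seeded jitter on the ligand
  p <- toy$planted
  m <- poseMolecule(p)
  set.seed(11)
  coords(m) <- coords(m) + matrix(rnorm(3 * nAtoms(m), sd = 0.1), ncol = 3L)
  p@molecule <- m
  res <- minimizeComplex(toy$receptor, p,
                         minimizationParams(maxIterations = 2500))
  expect_true(all(diff(res$trace) <= 1e-9))
  expect_lte(utils::tail(res$trace, 1), res$trace[1])
  expect_lte(res$report@finalGradient, 0.05)
  expect_lte(res$report@iterations, 2500)
  expect_gte(res$scaffold_rmsd, 0)
  # restrained distal atoms (residues beyond the shell, k = 200) barely move
  ra <- atoms(toy$receptor)
  lxyz <- coords(toy$planted)[!atoms(poseMolecule(toy$planted))$is_hydrogen, ]
  mind <- apply(coords(toy$receptor), 1L, function(pp)
    sqrt(min(colSums((t(lxyz) - pp)^2))))
  rk <- PoseSAR:::mobileRestraints(toy$receptor, poseMolecule(toy$planted),
                                   5.0, 200)
  distal <- which(mind > 7.0 & rk[seq_len(nAtoms(toy$receptor))] > 0)
  expect_gt(length(distal), 0L)
  expect_true(all(rk[distal] == 200))
  disp <- sqrt(rowSums((coords(res$receptor)[distal, , drop = FALSE] -
                        coords(toy$receptor)[distal, , drop = FALSE])^2))
  expect_lt(max(disp), 0.05)
})

test_that("an already-converged system stops immediately", {
  toy <- getToy()
  res <- minimizeComplex(toy$receptor, toy$planted,
                         minimizationParams(maxIterations = 400))
  res2 <- minimizeComplex(res$receptor, res$pose,
                          minimizationParams(maxIterations = 400))
  drop1 <- res$trace[1] - utils::tail(res$trace, 1)
  drop2 <- res2$trace[1] - utils::tail(res2$trace, 1)
  expect_lt(drop2, 0.05 * drop1 + 1.0)
})

test_that("ligand strain behaves like a harmonic penalty and is non-negative", {
  toy <- getToy()
  mol <- poseMolecule(toy$planted)
  # free minimum first
  cs <- PoseSAR:::combineSystem(molecule = mol)
  sys <- PoseSAR:::assembleSystem(cs$xyz, cs$charge, cs$element, cs$top)
  fg <- function(x) {
    r <- PoseSAR:::ff_eval_cpp(x, sys, TRUE)
    list(total = r$total, grad = r$grad)
  }
  relaxed <- PoseSAR:::cgMinimize(cs$xyz, fg, 3000, 0.01)
  mmin <- mol; coords(mmin) <- relaxed$xyz
  expect_lt(abs(ligandStrain(mmin)), 0.05)
  # stretch one bond by +0.2 A from the relaxed geometry
  b <- bonds(mol)[1, ]
  xyz <- relaxed$xyz
  u <- xyz[b$j, ] - xyz[b$i, ]; u <- u / sqrt(sum(u^2))
  adj <- PoseSAR:::adjacencyList(bonds(mol), nAtoms(mol))
  branch <- PoseSAR:::branchAtoms(adj, b$j, blocked = b$i)
  xyz[branch, ] <- sweep(xyz[branch, , drop = FALSE], 2L, 0.2 * u, "+")
  mstr <- mol; coords(mstr) <- xyz
  s <- ligandStrain(mstr)
  expect_gt(s, -1e-6)
  expect_equal(s, 300 * 0.2^2, tolerance = 0.1 * 300 * 0.2^2 + 1)
})

test_that("side-chain truncation to alanine preserves the backbone", {
  toy <- getToy()
  gln <- residues(toy$receptor)
  row <- gln[gln$resid == "GLN", ][1, ]
  mut <- mutateResidue(toy$receptor, row$chain, row$reskey, "ALA")
  ra <- atoms(mut)
  sel <- ra$chain == row$chain & ra$reskey == row$reskey
  expect_equal(sum(sel & !ra$is_hydrogen), 5L)  # N, CA, C, O, CB
  expect_setequal(ra$elety[sel & !ra$is_hydrogen],
                  c("N", "CA", "C", "O", "CB"))
  # backbone coordinates unchanged
  a0 <- atoms(toy$receptor)
  for (nm in c("N", "CA", "C", "O")) {
    i0 <- which(a0$chain == row$chain & a0$reskey == row$reskey &
                a0$elety == nm)
    i1 <- which(sel & ra$elety == nm)
    expect_equal(unlist(ra[i1, c("x", "y", "z")]),
                 unlist(a0[i0, c("x", "y", "z")]), ignore_attr = TRUE)
  }
  expect_error(mutateResidue(toy$receptor, row$chain, row$reskey, "TRP"),
               "unsupported")
  expect_error(mutateResidue(toy$receptor, "Z", "99"), "not found")
})

test_that("glycine gains an ideally placed C-beta", {
  toy <- getToy()
  gly <- residues(toy$receptor)
  row <- gly[gly$resid == "GLY", ][1, ]
  mut <- mutateResidue(toy$receptor, row$chain, row$reskey, "ALA")
  ra <- atoms(mut)
  sel <- ra$chain == row$chain & ra$reskey == row$reskey
  get <- function(nm) unlist(ra[sel & ra$elety == nm, c("x", "y", "z")])
  ang <- PoseSAR:::bondAngle(get("N"), get("CA"), get("CB")) * 180 / pi
  expect_equal(ang, 110.5, tolerance = 1.0)
})

test_that("the planted pose outranks at least 95 percent of decoys", {
  toy <- getToy()
  dec <- makeDecoys(toy$planted, toy$receptor, 40L, spread = 2.0, seed = 17L)
  en <- scorePoses(toy$receptor, c(list(toy$planted), dec))
  frac <- mean(en$dG_bind[-1] > en$dG_bind[1])
  expect_gte(frac, 0.95)
})
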