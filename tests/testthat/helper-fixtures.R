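# Shared fixtures. The toy system is deterministic, so it is built once per
# test run and reused.

.fixture_env <- new.env(parent = emptyenv())

getToy <- function() {
  if (is.null(.fixture_env$toy)) {
    .fixture_env$toy <- makeToySystem(syntheticSpec(seed = 1L))
  }
  .fixture_env$toy
}

# Write a small two-residue PDB fixture and return its path.
writeToyPdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C",
    "ATOM      3  C   ALA A   1      12.800   7.020  -4.900  1.00 10.00           C",
    "ATOM      4  O   ALA A   1      13.000   8.000  -5.600  1.00 10.00           O",
    "ATOM      5  CB  ALA A   1      10.600   6.500  -4.100  1.00 10.00           C",
    "ATOM      6  N   GLY B   2      13.500   6.700  -3.800  1.00 10.00           N",
    "ATOM      7  CA  GLY B   2      14.700   7.500  -3.500  1.00 10.00           C",
    "ATOM      8  C   GLY B   2      15.900   6.600  -3.200  1.00 10.00           C",
    "ATOM      9  O   GLY B   2      16.000   5.500  -3.700  1.00 10.00           O",
    "END"), path)
  path
}

# PDB with altloc duplicates: residue 1 N has A (occ 0.4) and B (occ 0.6)
# conformers, so altloc resolution must keep B; 8 unique atoms in total.
writeAltlocPdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N  AALA A   1      11.104   6.134  -6.504  0.40 10.00           N",
    "ATOM      2  N  BALA A   1      11.204   6.234  -6.604  0.60 10.00           N",
    "ATOM      3  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C",
    "ATOM      4  C   ALA A   1      12.800   7.020  -4.900  1.00 10.00           C",
    "ATOM      5  O   ALA A   1      13.000   8.000  -5.600  1.00 10.00           O",
    "ATOM      6  N   GLY A   2      13.500   6.700  -3.800  1.00 10.00           N",
    "ATOM      7  CA  GLY A   2      14.700   7.500  -3.500  1.00 10.00           C",
    "ATOM      8  C   GLY A   2      15.900   6.600  -3.200  1.00 10.00           C",
    "ATOM      9  O   GLY A   2      16.000   5.500  -3.700  1.00 10.00           O",
    "END"), path)
  path
}

# A small rigid molecule for geometry tests (no receptor needed).
toyMolecule <- function() {
  xyz <- rbind(c(0, 0, 0), c(1.51, 0, 0), c(2.1, 1.3, 0.2), c(3.5, 1.4, 0.6),
               c(1.9, -1.2, -0.4))
  newMolecule("probe", xyz, c("C", "C", "O", "C", "N"),
              data.frame(i = c(1L, 2L, 3L, 2L), j = c(2L, 3L, 4L, 5L),
                         order = c(1L, 1L, 1L, 1L)))
}

# Orthogonal-Procrustes residual, reflections allowed (embeddings are
# defined only up to rotation/reflection).
procrustesResidual <- function(x, y) {
  xc <- sweep(x, 2L, colMeans(x)); yc <- sweep(y, 2L, colMeans(y))
  s <- svd(crossprod(yc, xc))
  R <- s$u %*% t(s$v)
  sqrt(mean(rowSums((xc - yc %*% R)^2)))
}
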