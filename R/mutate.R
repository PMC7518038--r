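# In-silico point mutation: side-chain truncation to alanine (or glycine),
# used to probe the effect of a pocket residue on a binding mode (e.g. a
# Gln -> Ala swap at the complementary face of the pocket).

#' Mutate a residue to alanine (or glycine)
#'
#' Truncates the side chain to C-beta: backbone atoms (and their hydrogens)
#' plus CB are retained, CB hydrogens are completed at ideal tetrahedral
#' geometry. For a glycine target with \code{to = "ALA"}, CB is built at the
#' ideal tetrahedral position on CA. Backbone coordinates are untouched.
#'
#' @param receptor a \linkS4class{Receptor}.
#' @param chain chain id; \code{resnum} residue number (reskey).
#' @param to "ALA" or "GLY".
#' @return the mutated \linkS4class{Receptor}.
#' @export
mutateResidue <- function(receptor, chain, resnum, to = "ALA") {
  to <- toupper(to)
  if (!(to %in% c("ALA", "GLY"))) {
    stop("unsupported target residue: ", to, " (only ALA and GLY)")
  }
  rows <- residueRows(receptor, chain, resnum)
  if (!length(rows)) {
    stop("residue ", chain, "/", resnum, " not found")
  }
  a <- receptor@atoms
  res <- a[rows, , drop = FALSE]
  if (!(res$resid[1L] %in% names(.residue_templates)) &&
      !(res$resid[1L] %in% c("ALA", "GLY"))) {
    stop("residue ", res$resid[1L], " is not a standard amino acid")
  }
  keepNames <- c("N", "CA", "C", "O", "OXT")
  keepH <- res$is_hydrogen & vapply(seq_len(nrow(res)), function(i) {
    # hydrogens bonded to backbone N or CA (by distance)
    p <- c(res$x[i], res$y[i], res$z[i])
    any(vapply(which(res$elety %in% c("N", "CA")), function(j) {
      sqrt(sum((p - c(res$x[j], res$y[j], res$z[j]))^2)) < 1.25
    }, TRUE))
  }, TRUE)
  keep <- res$elety %in% keepNames | keepH
  if (to == "ALA") keep <- keep | res$elety == "CB"
  newRes <- res[keep, , drop = FALSE]
  if (to == "ALA" && !("CB" %in% newRes$elety)) {
    # build CB from N, C, CA at ideal tetrahedral geometry (L-configuration)
    pN <- unlist(res[res$elety == "N", c("x", "y", "z")])
    pC <- unlist(res[res$elety == "C", c("x", "y", "z")])
    pCA <- unlist(res[res$elety == "CA", c("x", "y", "z")])
    uN <- unitVec(pN - pCA); uC <- unitVec(pC - pCA)
    dirs <- idealHDirections(list(uN, uC), "sp3", 2L)
    d <- dirs[[1L]]
    if (sum(crossProd(uN, uC) * d) < 0) d <- dirs[[2L]]
    pCB <- pCA + 1.53 * d
    # drop the CA hydrogen occupying the chosen C-beta position (glycine has
    # two of them; alanine keeps only the other one)
    hOnCA <- which(newRes$is_hydrogen & vapply(seq_len(nrow(newRes)),
      function(i) {
        p <- c(newRes$x[i], newRes$y[i], newRes$z[i])
        dd <- sqrt(sum((p - pCA)^2))
        dd > 1e-6 && dd < 1.25 && sum((p - pCA) / dd * d) > 0.7
      }, TRUE))
    if (length(hOnCA)) newRes <- newRes[-hOnCA[1L], , drop = FALSE]
    cb <- newRes[newRes$elety == "CA", , drop = FALSE][1L, ]
    cb$elety <- "CB"; cb$element <- "C"
    cb$x <- pCB[1L]; cb$y <- pCB[2L]; cb$z <- pCB[3L]
    cb$vdw <- elementProperty("C", "vdw"); cb$is_hydrogen <- FALSE
    newRes <- rbind(newRes, cb)
  }
  newRes$resid <- to
  # complete CB hydrogens (and any now-missing backbone valence H) locally
  xyz <- as.matrix(newRes[, c("x", "y", "z")])
  el <- newRes$element
  b <- inferBonds(xyz, el)
  comp <- completeHydrogens(xyz, el, b, only = which(newRes$elety == "CB"))
  nNew <- nrow(comp$xyz) - nrow(xyz)
  if (nNew > 0L) {
    hrows <- newRes[rep(1L, nNew), , drop = FALSE]
    hrows$elety <- paste0("HB", seq_len(nNew))
    hrows$element <- "H"
    hrows$x <- comp$xyz[nrow(xyz) + seq_len(nNew), 1L]
    hrows$y <- comp$xyz[nrow(xyz) + seq_len(nNew), 2L]
    hrows$z <- comp$xyz[nrow(xyz) + seq_len(nNew), 3L]
    hrows$vdw <- elementProperty("H", "vdw")
    hrows$is_hydrogen <- TRUE
    newRes <- rbind(newRes, hrows)
  }
  # reassign charges for the rebuilt residue
  xyz2 <- as.matrix(newRes[, c("x", "y", "z")])
  newRes$charge <- assignCharges(xyz2, newRes$element,
                                 inferBonds(xyz2, newRes$element))
  out <- rbind(
    if (min(rows) > 1L) a[seq_len(min(rows) - 1L), , drop = FALSE],
    newRes,
    if (max(rows) < nrow(a)) a[(max(rows) + 1L):nrow(a), , drop = FALSE]
  )
  rownames(out) <- NULL
  methods::new("Receptor", atoms = out, subunitLabels = receptor@subunitLabels)
}
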