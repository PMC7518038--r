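# Element tables and light-weight chemical perception: covalent/vdW radii,
# Lennard-Jones parameters, standard bond lengths, rule-based partial charges,
# bond inference from geometry, ring detection and hydrogen completion.
# The parameter tables below are the package's documented defaults; they are
# deliberately small (8 supported elements) and editable via options where
# the user-facing operations expose them.

SUPPORTED_ELEMENTS <- c("H", "C", "N", "O", "F", "S", "Cl", "Br")

.element_table <- data.frame(
  element = SUPPORTED_ELEMENTS,
  vdw     = c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.75, 1.85),  # Bondi radii
  covr    = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.05, 1.02, 1.20),
  mass    = c(1.008, 12.011, 14.007, 15.999, 18.998, 32.06, 35.45, 79.904),
  # Lennard-Jones (sigma Angstrom, epsilon kcal/mol), OPLS-like magnitudes
  sigma   = c(2.50, 3.55, 3.25, 2.96, 2.94, 3.55, 3.40, 3.47),
  eps     = c(0.030, 0.070, 0.170, 0.210, 0.060, 0.250, 0.300, 0.470),
  stringsAsFactors = FALSE
)
rownames(.element_table) <- SUPPORTED_ELEMENTS

elementProperty <- function(element, what) {
  bad <- !(element %in% SUPPORTED_ELEMENTS)
  if (any(bad)) {
    stop("unsupported element(s): ", paste(unique(element[bad]), collapse = ", "))
  }
  .element_table[element, what]
}

#' Standard bond lengths for substituent attachment
#'
#' Lookup of the bond length (Angstrom) used when a substituent link atom is
#' placed on an aromatic scaffold carbon. Keys are the link-atom element plus
#' a hybridization tag for carbon. The table can be overridden via
#' \code{options(PoseSAR.bond_lengths = ...)} with a named numeric vector.
#'
#' @return named numeric vector of bond lengths in Angstrom.
#' @export
attachmentBondLengths <- function() {
  defaults <- c(
    "Cl"    = 1.73,  # C(ar)-Cl
    "Br"    = 1.88,  # C(ar)-Br
    "F"     = 1.35,  # C(ar)-F
    "C.sp3" = 1.51,  # C(ar)-C(sp3)
    "O"     = 1.36,  # C(ar)-O
    "N"     = 1.40,  # C(ar)-N
    "C.sp"  = 1.43,  # C(ar)-C(sp)
    "H"     = 1.09   # C(ar)-H
  )
  user <- getOption("PoseSAR.bond_lengths", NULL)
  if (!is.null(user)) defaults[names(user)] <- user
  defaults
}

# Canonical bond lengths per element pair used to assign harmonic equilibrium
# values: the observed length is snapped to the nearest canonical entry so
# that single/aromatic/double flavors of a bond are distinguished without a
# full atom-typing engine.
.canonical_bonds <- list(
  "C-C"  = c(1.20, 1.33, 1.39, 1.51),
  "C-N"  = c(1.16, 1.33, 1.40, 1.47),
  "C-O"  = c(1.23, 1.36, 1.43),
  "C-S"  = c(1.81),
  "C-F"  = c(1.35),
  "C-Cl" = c(1.73),
  "C-Br" = c(1.88),
  "C-H"  = c(1.09),
  "N-H"  = c(1.01),
  "O-H"  = c(0.96),
  "S-H"  = c(1.34),
  "N-N"  = c(1.35),
  "N-O"  = c(1.25),
  "S-S"  = c(2.05),
  "O-O"  = c(1.45)
)

bondKey <- function(e1, e2) {
  paste(pmin(e1, e2), pmax(e1, e2), sep = "-")
}

# Equilibrium length for a bond: nearest canonical value for the element pair,
# falling back to the observed length when the pair is not tabulated.
equilibriumBondLength <- function(e1, e2, observed) {
  key <- bondKey(e1, e2)
  out <- observed
  for (k in unique(key)) {
    cand <- .canonical_bonds[[k]]
    idx <- key == k
    if (!is.null(cand)) {
      obs <- observed[idx]
      out[idx] <- vapply(obs, function(r) cand[which.min(abs(cand - r))], 0)
    }
  }
  out
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance lies between 0.4 Angstrom and the
#' sum of covalent radii plus 0.45 Angstrom. Used for receptor structures
#' (PDB files carry no bonds); ligand bonds always come from the input file.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param element character vector of element symbols.
#' @return data.frame with columns i, j, order (order is always 1).
#' @export
inferBonds <- function(xyz, element) {
  n <- nrow(xyz)
  if (n < 2L) return(data.frame(i = integer(), j = integer(), order = integer()))
  maxr <- elementProperty(element, "covr")
  res <- infer_bonds_cpp(xyz, maxr, 0.45)
  data.frame(i = res[, 1L], j = res[, 2L], order = 1L)
}

# Adjacency list (list of integer vectors) from a bond table.
adjacencyList <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer()
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Connected component containing `start`, never crossing `blocked`.
branchAtoms <- function(adj, start, blocked) {
  seen <- c(blocked, start)
  queue <- start
  out <- start
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    nb <- setdiff(adj[[cur]], seen)
    seen <- c(seen, nb)
    out <- c(out, nb)
    queue <- c(queue, nb)
  }
  sort(setdiff(out, blocked))
}

# All simple rings of size 5 or 6 in the bond graph (each ring reported once,
# as a sorted atom vector). Sizes involved here are tiny, so a bounded DFS is
# adequate.
findRings <- function(bonds, n, sizes = c(5L, 6L)) {
  adj <- adjacencyList(bonds, n)
  rings <- list()
  seen <- character()
  maxlen <- max(sizes)
  dfs <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == path[1L] && length(path) >= 3L && length(path) %in% sizes) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- sort(path)
        }
      } else if (!(nb %in% path) && length(path) < maxlen && nb > path[1L]) {
        dfs(c(path, nb))
      }
    }
  }
  for (s in seq_len(n)) dfs(s)
  unique(rings)
}

# Aromatic rings: 5/6-membered rings whose members are C/N with at most three
# heavy neighbors and whose atoms are coplanar within 0.25 Angstrom.
aromaticRings <- function(xyz, element, bonds) {
  n <- nrow(xyz)
  rings <- findRings(bonds, n)
  if (!length(rings)) return(list())
  adj <- adjacencyList(bonds, n)
  heavyDeg <- vapply(seq_len(n), function(i) {
    sum(element[adj[[i]]] != "H")
  }, 0L)
  keep <- vapply(rings, function(r) {
    if (!all(element[r] %in% c("C", "N"))) return(FALSE)
    if (any(heavyDeg[r] > 3L)) return(FALSE)
    cc <- sweep(xyz[r, , drop = FALSE], 2L, colMeans(xyz[r, , drop = FALSE]))
    nrm <- planeNormal(xyz[r, , drop = FALSE])
    max(abs(cc %*% nrm)) < 0.25
  }, TRUE)
  rings[keep]
}

# Hybridization tag used for angle equilibria and hydrogen completion:
# "sp" (linear), "sp2" (trigonal planar) or "sp3".
hybridization <- function(element, bonds, n) {
  ord <- rep(1L, nrow(bonds))
  if (nrow(bonds)) ord <- as.integer(bonds$order)
  maxOrder <- rep(1L, n)
  nDouble <- rep(0L, n)
  deg <- rep(0L, n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      maxOrder[i] <- max(maxOrder[i], ord[k])
      maxOrder[j] <- max(maxOrder[j], ord[k])
      if (ord[k] >= 2L) { nDouble[i] <- nDouble[i] + 1L; nDouble[j] <- nDouble[j] + 1L }
    }
  }
  out <- rep("sp3", n)
  out[maxOrder == 2L | (element == "N" & deg <= 3L & nDouble > 0L)] <- "sp2"
  # amide/aniline-type nitrogen: planar when conjugated to a carbonyl carbon
  if (nrow(bonds)) {
    adj <- adjacencyList(bonds, n)
    carbonylC <- which(element == "C" & vapply(seq_len(n), function(c) {
      any(vapply(adj[[c]], function(j)
        element[j] == "O" && any((bonds$i == c & bonds$j == j |
                                  bonds$j == c & bonds$i == j) &
                                 bonds$order >= 2L), TRUE))
    }, TRUE))
    amideN <- which(element == "N" & deg <= 3L &
                    vapply(seq_len(n), function(i)
                      any(adj[[i]] %in% carbonylC), TRUE))
    out[amideN] <- "sp2"
  }
  out[maxOrder >= 3L | nDouble >= 2L] <- "sp"
  out
}

# Standard valence per element (used to count implicit hydrogens).
.valence <- c(H = 1, C = 4, N = 3, O = 2, F = 1, S = 2, Cl = 1, Br = 1)

#' Complete missing hydrogens at idealized geometry
#'
#' Adds hydrogens to heavy atoms whose bond-order sum falls short of the
#' standard element valence. New hydrogens are placed at ideal tetrahedral,
#' trigonal or linear positions depending on the inferred hybridization of
#' the parent atom. The construction is deterministic.
#'
#' @param xyz n x 3 coordinates; \code{element} symbols; \code{bonds} table
#'   with i, j, order.
#' @param only index vector restricting which heavy atoms get completed
#'   (default: all).
#' @return list with \code{xyz}, \code{element}, \code{bonds}, and
#'   \code{parent} (index of the heavy atom each new H is attached to).
#' @keywords internal
completeHydrogens <- function(xyz, element, bonds, only = NULL) {
  n <- nrow(xyz)
  hyb <- hybridization(element, bonds, n)
  adj <- adjacencyList(bonds, n)
  bsum <- rep(0, n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      o <- as.numeric(bonds$order[k])
      bsum[bonds$i[k]] <- bsum[bonds$i[k]] + o
      bsum[bonds$j[k]] <- bsum[bonds$j[k]] + o
    }
  }
  targets <- seq_len(n)
  if (!is.null(only)) targets <- intersect(targets, only)
  newXyz <- NULL; newParent <- integer()
  for (i in targets) {
    if (element[i] == "H") next
    miss <- .valence[[element[i]]] - bsum[i]
    if (miss < 1) next
    miss <- as.integer(round(miss))
    blen <- equilibriumBondLength(element[i], "H", 1.0)
    nb <- adj[[i]]
    u <- lapply(nb, function(j) unitVec(xyz[j, ] - xyz[i, ]))
    dirs <- idealHDirections(u, hyb[i], miss)
    for (d in dirs) {
      newXyz <- rbind(newXyz, xyz[i, ] + blen * d)
      newParent <- c(newParent, i)
    }
  }
  if (is.null(newXyz)) {
    return(list(xyz = xyz, element = element, bonds = bonds, parent = integer()))
  }
  m <- nrow(newXyz)
  idx <- n + seq_len(m)
  list(
    xyz = rbind(xyz, newXyz),
    element = c(element, rep("H", m)),
    bonds = rbind(bonds, data.frame(i = newParent, j = idx, order = 1L)),
    parent = newParent
  )
}

# Ideal directions for `miss` new substituents on an atom with existing
# neighbor unit vectors `u` and the given hybridization.
idealHDirections <- function(u, hyb, miss) {
  k <- length(u)
  tet <- 109.47 * pi / 180
  if (k == 0L) {
    # isolated atom: deterministic tripod around +x
    base <- c(1, 0, 0)
    dirs <- list(base)
    if (miss > 1L) {
      perp <- pickPerpendicular(base)
      for (m in seq_len(miss - 1L)) {
        R <- rotationMatrix(base, 2 * pi * (m - 1) / max(1L, miss - 1L))
        dirs[[m + 1L]] <- as.numeric(R %*% (rotationMatrix(perp, tet) %*% base))
      }
    }
    return(dirs[seq_len(miss)])
  }
  if (k == 1L) {
    a <- u[[1L]]
    if (hyb == "sp" || miss == 1L && hyb == "spX") return(list(-a))
    ang <- if (hyb == "sp2") 120 * pi / 180 else tet
    perp <- pickPerpendicular(a)
    first <- as.numeric(rotationMatrix(perp, pi - ang) %*% (-a))
    dirs <- list(first)
    if (miss >= 2L) {
      step <- if (hyb == "sp2") pi else 2 * pi / 3
      for (m in seq_len(miss - 1L)) {
        dirs[[m + 1L]] <- as.numeric(rotationMatrix(a, m * step) %*% first)
      }
    }
    return(dirs[seq_len(miss)])
  }
  if (k == 2L) {
    bis <- -(u[[1L]] + u[[2L]])
    if (vecNorm(bis) < 1e-8) bis <- pickPerpendicular(u[[1L]])
    bis <- unitVec(bis)
    if (hyb == "sp2" || miss == 1L) {
      if (miss == 1L) return(list(bis))
    }
    cp <- crossProd(u[[1L]], u[[2L]])
    p <- if (vecNorm(cp) < 1e-8) pickPerpendicular(u[[1L]]) else unitVec(cp)
    half <- (tet / 2)
    d1 <- unitVec(cos(half) * bis + sin(half) * p)
    d2 <- unitVec(cos(half) * bis - sin(half) * p)
    return(list(d1, d2)[seq_len(miss)])
  }
  # k >= 3: single remaining position opposite the neighbor sum
  s <- -Reduce(`+`, u)
  if (vecNorm(s) < 1e-8) s <- pickPerpendicular(u[[1L]])
  list(unitVec(s))[seq_len(min(miss, 1L))]
}

#' Rule-based partial charges
#'
#' Assigns partial charges (elementary units) from the element and bonded
#' neighborhood of each atom. This is the package's documented fallback when
#' the input file carries no charges (SDF, PDB); MOL2 charges are used as-is
#' when present. The ruleset, in order of precedence:
#' \itemize{
#'   \item carboxylate (C bonded to two O, neither protonated): O -0.80, C +0.70
#'   \item carbonyl O (double bond to C): O -0.50, C +0.45
#'   \item hydroxyl O: O -0.60, its H +0.40; ether O: -0.40
#'   \item nitrile N: -0.45, its C +0.30
#'   \item quaternary/protonated N: N +0.30, each H +0.33
#'   \item amide/aromatic N: -0.50; amine N: -0.70; N-H hydrogens +0.35
#'   \item S: -0.25 (H on S +0.15); F -0.20, Cl -0.12, Br -0.10
#'   \item H on C: +0.06, compensated on the carbon (C stays near neutral)
#' }
#'
#' @param xyz coordinates (unused by the rules; kept for signature stability).
#' @param element element symbols; \code{bonds} bond table with order.
#' @return numeric vector of partial charges.
#' @export
assignCharges <- function(xyz, element, bonds) {
  n <- length(element)
  q <- rep(0, n)
  adj <- adjacencyList(bonds, n)
  ord <- function(i, j) {
    k <- which((bonds$i == i & bonds$j == j) | (bonds$i == j & bonds$j == i))
    if (length(k)) as.numeric(bonds$order[k[1L]]) else 0
  }
  deg <- vapply(adj, length, 0L)
  hasH <- vapply(seq_len(n), function(i) any(element[adj[[i]]] == "H"), TRUE)

  # carboxylate carbons
  for (i in which(element == "C")) {
    os <- adj[[i]][element[adj[[i]]] == "O"]
    if (length(os) == 2L && !any(hasH[os])) {
      q[i] <- 0.70; q[os] <- -0.80
    }
  }
  for (i in seq_len(n)) {
    if (q[i] != 0) next
    el <- element[i]
    if (el == "O") {
      dbl <- any(vapply(adj[[i]], function(j) ord(i, j) >= 2, TRUE))
      if (dbl) {
        q[i] <- -0.50
        cpart <- adj[[i]][element[adj[[i]]] == "C"]
        if (length(cpart) && q[cpart[1L]] == 0) q[cpart[1L]] <- 0.45
      } else if (hasH[i]) q[i] <- -0.60 else q[i] <- -0.40
    } else if (el == "N") {
      if (deg[i] >= 4L) {
        q[i] <- 0.30
      } else if (any(vapply(adj[[i]], function(j) ord(i, j) >= 3, TRUE))) {
        q[i] <- -0.45
        cpart <- adj[[i]][element[adj[[i]]] == "C"]
        if (length(cpart) && q[cpart[1L]] == 0) q[cpart[1L]] <- 0.30
      } else {
        nbC <- adj[[i]][element[adj[[i]]] == "C"]
        amide <- any(vapply(nbC, function(c) {
          any(vapply(adj[[c]], function(j) element[j] == "O" && ord(c, j) >= 2, TRUE))
        }, TRUE))
        sp2 <- any(vapply(adj[[i]], function(j) ord(i, j) >= 2, TRUE))
        q[i] <- if (amide || sp2) -0.50 else -0.70
      }
    } else if (el == "S") {
      q[i] <- -0.25
    } else if (el == "F") q[i] <- -0.20
    else if (el == "Cl") q[i] <- -0.12
    else if (el == "Br") q[i] <- -0.10
  }
  # hydrogens, then compensate carbons so CHn groups stay near neutral
  for (i in which(element == "H")) {
    p <- adj[[i]]
    if (!length(p)) next
    pel <- element[p[1L]]
    q[i] <- switch(pel,
      O = 0.40, S = 0.15,
      N = if (deg[p[1L]] >= 4L) 0.33 else 0.35,
      C = 0.06, 0.0)
  }
  for (i in which(element == "C")) {
    hs <- adj[[i]][element[adj[[i]]] == "H"]
    if (length(hs) && q[i] == 0) q[i] <- -0.06 * length(hs)
  }
  q
}
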