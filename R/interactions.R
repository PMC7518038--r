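# Structural interaction fingerprints (SIFt): binding-site residue
# enumeration at a heavy-atom cutoff and per-residue interaction bits
# (hydrogen bond, hydrophobic, pi-pi, salt bridge) for pose ensembles.
# Only the 5 A site cutoff is protocol-fixed; all other geometric
# thresholds are standard literature values exposed as arguments.

SIFT_DEFAULTS <- list(
  site_cutoff = 5.0,     # binding-site heavy-atom cutoff, A
  hbond_dist = 3.5,      # donor-acceptor heavy-atom distance, A
  hbond_angle = 120,     # minimum D-H...A angle, degrees
  hydrophobic_dist = 4.5,# apolar carbon pair distance, A
  pipi_dist = 5.5,       # ring centroid distance (parallel), A
  pipi_tshape_dist = 5.0,# ring centroid distance (T-shaped), A
  pipi_angle = 30,       # max interplanar angle for parallel stacking
  salt_dist = 4.0        # charged N/O pair distance, A
)

#' Binding-site residues around a pose
#'
#' Residues with at least one heavy atom within \code{cutoff} of at least
#' one ligand heavy atom, sorted by chain then residue number. The cutoff is
#' half-open: a distance strictly greater than \code{cutoff} excludes.
#'
#' @param receptor a \linkS4class{Receptor}.
#' @param pose a \linkS4class{LigandPose}.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5).
#' @return data.frame with chain, reskey, resid, min_distance.
#' @export
bindingSiteResidues <- function(receptor, pose, cutoff = SIFT_DEFAULTS$site_cutoff) {
  stopifnot(cutoff > 0)
  ra <- receptor@atoms
  rxyz <- coords(receptor)
  lxyz <- coords(pose)[!pose@molecule@atoms$is_hydrogen, , drop = FALSE]
  heavy <- !ra$is_hydrogen
  mind <- rep(Inf, nrow(ra))
  mind[heavy] <- apply(rxyz[heavy, , drop = FALSE], 1L, function(p) {
    sqrt(min(colSums((t(lxyz) - p)^2)))
  })
  key <- paste(ra$chain, ra$reskey, sep = "\r")
  resMin <- tapply(mind, key, min)
  hit <- names(resMin)[resMin <= cutoff]
  if (!length(hit)) {
    return(data.frame(chain = character(), reskey = character(),
                      resid = character(), min_distance = numeric()))
  }
  parts <- strsplit(hit, "\r", fixed = TRUE)
  out <- data.frame(
    chain = vapply(parts, `[`, "", 1L),
    reskey = vapply(parts, `[`, "", 2L),
    resid = ra$resid[match(hit, key)],
    min_distance = as.numeric(resMin[hit]),
    stringsAsFactors = FALSE
  )
  out[order(out$chain, suppressWarnings(as.numeric(out$reskey)), out$reskey), ,
      drop = FALSE]
}

# Polar hydrogens on demand: if a structure has no hydrogens on its N/O
# donors, build them at ideal geometry (flagged in the result).
.ensurePolarH <- function(xyz, element, bonds) {
  adj <- adjacencyList(bonds, length(element))
  donors <- which(element %in% c("N", "O"))
  needs <- donors[vapply(donors, function(i) {
    !any(element[adj[[i]]] == "H")
  }, TRUE)]
  # only add where valence is actually open
  comp <- completeHydrogens(xyz, element, bonds, only = needs)
  added <- length(comp$parent) > 0L
  list(xyz = comp$xyz, element = comp$element, bonds = comp$bonds,
       added = added)
}

# Aromatic ring atom indices for a receptor residue (template by name) or a
# molecule (perceived from the bond graph + planarity).
.receptorRings <- function(ra, rows) {
  resname <- ra$resid[rows[1L]]
  tpl <- .residue_rings[[resname]]
  if (is.null(tpl)) return(list())
  out <- list()
  for (ringNames in tpl) {
    idx <- rows[match(ringNames, ra$elety[rows])]
    if (!any(is.na(idx))) out[[length(out) + 1L]] <- idx
  }
  out
}

# Formal charge centers: receptor by residue template; ligand by perception
# (carboxylate O, quaternary N).
.chargedAtoms <- function(element, bonds, resid = NULL, elety = NULL) {
  n <- length(element)
  adj <- adjacencyList(bonds, n)
  sign <- rep(0, n)
  if (!is.null(resid)) {
    for (i in seq_len(n)) {
      info <- .residue_charged[[resid[i]]]
      if (!is.null(info) && elety[i] %in% info$atoms) sign[i] <- info$sign
    }
  } else {
    for (i in which(element == "O")) {
      cs <- adj[[i]][element[adj[[i]]] == "C"]
      for (cc in cs) {
        os <- adj[[cc]][element[adj[[cc]]] == "O"]
        if (length(os) == 2L &&
            !any(vapply(os, function(o) any(element[adj[[o]]] == "H"), TRUE))) {
          sign[os] <- -1
        }
      }
    }
    deg <- vapply(adj, length, 0L)
    sign[element == "N" & deg >= 4L] <- +1
  }
  sign
}

#' Detect ligand-residue interactions for one pose
#'
#' Geometric criteria (defaults in \code{SIFT_DEFAULTS}): hydrogen bond at
#' donor-acceptor distance <= 3.5 A and D-H...A angle >= 120 degrees;
#' hydrophobic contact between apolar carbons (not bonded to N/O/F) at
#' <= 4.5 A; pi-pi for ring centroids <= 5.5 A with interplanar angle
#' <= 30 degrees (parallel) or 60-120 degrees at <= 5.0 A (T-shaped); salt
#' bridge between formally charged N/O at <= 4.0 A. Polar hydrogens are
#' completed at ideal geometry when absent (flagged in the output attribute
#' \code{"hydrogens_added"}).
#'
#' @param receptor a \linkS4class{Receptor}.
#' @param pose a \linkS4class{LigandPose}.
#' @param cutoffs named list overriding \code{SIFT_DEFAULTS} entries.
#' @return data.frame: chain, reskey, resid, kind, present, distance, angle.
#' @export
detectInteractions <- function(receptor, pose, cutoffs = list()) {
  cf <- utils::modifyList(SIFT_DEFAULTS, cutoffs)
  ra <- receptor@atoms
  rxyz <- coords(receptor)
  rbonds <- inferBonds(rxyz, ra$element)
  rp <- .ensurePolarH(rxyz, ra$element, rbonds)
  hAdded <- rp$added
  # map completed arrays back: appended H atoms belong to parent residues
  nr0 <- nrow(rxyz)
  rxyz2 <- rp$xyz; rel2 <- rp$element; rbonds2 <- rp$bonds
  parent <- integer(0)
  if (nrow(rxyz2) > nr0) {
    padj <- adjacencyList(rbonds2, nrow(rxyz2))
    parent <- vapply((nr0 + 1L):nrow(rxyz2), function(i) padj[[i]][1L], 0L)
  }
  resKey <- c(paste(ra$chain, ra$reskey, sep = "\r"),
              paste(ra$chain, ra$reskey, sep = "\r")[parent])
  mol <- pose@molecule
  lxyz0 <- coords(mol)
  lp <- .ensurePolarH(lxyz0, mol@atoms$element, mol@bonds)
  hAdded <- hAdded || lp$added
  lxyz <- lp$xyz; lel <- lp$element; lbonds <- lp$bonds
  site <- bindingSiteResidues(receptor, pose, cf$site_cutoff)
  if (!nrow(site)) {
    out <- data.frame(chain = character(), reskey = character(),
                      resid = character(), kind = character(),
                      present = logical(), distance = numeric(),
                      angle = numeric())
    attr(out, "hydrogens_added") <- hAdded
    return(out)
  }
  ladj <- adjacencyList(lbonds, length(lel))
  lApolar <- which(lel == "C" & !vapply(seq_along(lel), function(i)
    any(lel[ladj[[i]]] %in% c("N", "O", "F")), TRUE))
  lDonH <- which(lel == "H" &
                 vapply(seq_along(lel), function(i)
                   length(ladj[[i]]) > 0L && lel[ladj[[i]][1L]] %in% c("N", "O"),
                   TRUE))
  lAcc <- which(lel %in% c("N", "O"))
  lRings <- aromaticRings(lxyz, lel, lbonds)
  lCharge <- .chargedAtoms(lel, lbonds)
  radj <- adjacencyList(rbonds2, length(rel2))
  rows <- list()
  for (s in seq_len(nrow(site))) {
    key <- paste(site$chain[s], site$reskey[s], sep = "\r")
    rIdx <- which(resKey == key)
    resname <- site$resid[s]
    geomNA <- data.frame(chain = site$chain[s], reskey = site$reskey[s],
                         resid = resname, kind = NA_character_,
                         present = FALSE, distance = NA_real_,
                         angle = NA_real_, stringsAsFactors = FALSE)
    # --- hydrogen bonds (both directions) ---
    best <- NULL
    rDonH <- rIdx[rel2[rIdx] == "H" &
                  vapply(rIdx, function(i) length(radj[[i]]) > 0L &&
                           rel2[radj[[i]][1L]] %in% c("N", "O"), TRUE)]
    rAcc <- rIdx[rel2[rIdx] %in% c("N", "O")]
    hbCase <- function(dIdx, hIdx, aXyz, dXyz, kind) {
      # hIdx rows pair with their parent donor
      res <- NULL
      for (h in hIdx) {
        d <- if (kind == "hbond_donor_to_ligand") radj[[h]][1L] else ladj[[h]][1L]
        dpos <- dXyz[d, ]; hpos <- if (kind == "hbond_donor_to_ligand")
          rxyz2[h, ] else lxyz[h, ]
        for (a in dIdx) {
          apos <- aXyz[a, ]
          dist <- vecNorm(dpos - apos)
          if (dist > cf$hbond_dist) next
          ang <- bondAngle(dpos, hpos, apos) * 180 / pi
          if (ang < cf$hbond_angle) next
          if (is.null(res) || dist < res$distance) {
            res <- list(distance = dist, angle = ang)
          }
        }
      }
      res
    }
    hb1 <- hbCase(lAcc, rDonH, lxyz, rxyz2, "hbond_donor_to_ligand")
    r1 <- geomNA; r1$kind <- "hbond_donor_to_ligand"
    if (!is.null(hb1)) { r1$present <- TRUE; r1$distance <- hb1$distance; r1$angle <- hb1$angle }
    hb2 <- hbCase(rAcc, lDonH, rxyz2, lxyz, "hbond_acceptor_from_ligand")
    r2 <- geomNA; r2$kind <- "hbond_acceptor_from_ligand"
    if (!is.null(hb2)) { r2$present <- TRUE; r2$distance <- hb2$distance; r2$angle <- hb2$angle }
    # --- hydrophobic ---
    rApolar <- rIdx[rel2[rIdx] == "C" & !vapply(rIdx, function(i)
      any(rel2[radj[[i]]] %in% c("N", "O", "F")), TRUE)]
    r3 <- geomNA; r3$kind <- "hydrophobic"
    if (length(rApolar) && length(lApolar)) {
      m1 <- rxyz2[rApolar, , drop = FALSE]
      m2 <- lxyz[lApolar, , drop = FALSE]
      d2 <- outer(rowSums(m1^2), rowSums(m2^2), "+") - 2 * m1 %*% t(m2)
      dmin <- sqrt(max(0, min(d2)))
      if (dmin <= cf$hydrophobic_dist) { r3$present <- TRUE; r3$distance <- dmin }
    }
    # --- pi-pi ---
    r4 <- geomNA; r4$kind <- "pi_pi"
    rRings <- .receptorRings(ra, rIdx[rIdx <= nr0])
    if (length(rRings) && length(lRings)) {
      for (rr in rRings) for (lr in lRings) {
        cR <- colMeans(rxyz2[rr, , drop = FALSE])
        cL <- colMeans(lxyz[lr, , drop = FALSE])
        dist <- vecNorm(cR - cL)
        nR <- planeNormal(rxyz2[rr, , drop = FALSE])
        nL <- planeNormal(lxyz[lr, , drop = FALSE])
        ang <- acos(min(1, abs(sum(nR * nL)))) * 180 / pi
        hit <- (dist <= cf$pipi_dist && ang <= cf$pipi_angle) ||
               (dist <= cf$pipi_tshape_dist && ang >= 60 && ang <= 120)
        if (hit && (!r4$present || dist < r4$distance)) {
          r4$present <- TRUE; r4$distance <- dist; r4$angle <- ang
        }
      }
    }
    # --- salt bridge ---
    r5 <- geomNA; r5$kind <- "salt_bridge"
    rH <- rIdx[rIdx <= nr0]
    rCh <- .chargedAtoms(rel2[rH],
                         data.frame(i = integer(), j = integer(),
                                    order = integer()),
                         resid = ra$resid[rH], elety = ra$elety[rH])
    rChargedIdx <- rH[rCh != 0]
    lChargedIdx <- which(lCharge != 0)
    if (length(rChargedIdx) && length(lChargedIdx)) {
      for (i in rChargedIdx) for (j in lChargedIdx) {
        si <- rCh[match(i, rH)]
        if (si * lCharge[j] >= 0) next  # opposite signs only
        dist <- vecNorm(rxyz2[i, ] - lxyz[j, ])
        if (dist <= cf$salt_dist && (!r5$present || dist < r5$distance)) {
          r5$present <- TRUE; r5$distance <- dist
        }
      }
    }
    rows[[length(rows) + 1L]] <- rbind(r1, r2, r3, r4, r5)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "hydrogens_added") <- hAdded
  out
}

#' SIFt matrix over a pose ensemble
#'
#' Interaction bits for every pose x site residue x kind, with a
#' per-(residue, kind) frequency summary identifying consensus contacts.
#'
#' @param receptor a \linkS4class{Receptor}.
#' @param poses list of \linkS4class{LigandPose} (at least 1).
#' @param cutoffs see \code{\link{detectInteractions}}.
#' @return list with \code{bits} (long data.frame with pose_id) and
#'   \code{summary} (residue, kind, frequency).
#' @export
siftMatrix <- function(receptor, poses, cutoffs = list()) {
  if (!length(poses)) stop("need at least one pose")
  rows <- lapply(poses, function(p) {
    d <- detectInteractions(receptor, p, cutoffs)
    if (nrow(d)) cbind(pose_id = poseId(p), d) else NULL
  })
  bits <- do.call(rbind, rows)
  if (is.null(bits)) {
    return(list(bits = data.frame(), summary = data.frame()))
  }
  key <- paste(bits$chain, bits$reskey, bits$resid, bits$kind, sep = "\r")
  freq <- tapply(bits$present, key, mean)
  parts <- strsplit(names(freq), "\r", fixed = TRUE)
  summary <- data.frame(
    chain = vapply(parts, `[`, "", 1L),
    reskey = vapply(parts, `[`, "", 2L),
    resid = vapply(parts, `[`, "", 3L),
    kind = vapply(parts, `[`, "", 4L),
    frequency = as.numeric(freq),
    stringsAsFactors = FALSE
  )
  summary <- summary[order(-summary$frequency), , drop = FALSE]
  rownames(summary) <- NULL
  stopifnot(all(summary$frequency >= 0 & summary$frequency <= 1))
  list(bits = bits, summary = summary)
}
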