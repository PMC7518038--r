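# Pose-space analytics: scaffold RMSD matrices (fixed correspondence, no
# superposition -- all poses share the receptor frame), classical
# multidimensional scaling of the pose space, binding-mode assignment by
# scaffold-axis orientation, and center-of-mass distances.

#' Scaffold RMSD between two poses
#'
#' sqrt(mean squared displacement) over the core atoms, with fixed atom
#' correspondence and no superposition.
#'
#' @param poseA,poseB \linkS4class{LigandPose} objects sharing atom order
#'   over the core.
#' @param coreAtoms core atom indices (per pose when a list of two vectors).
#' @return RMSD in Angstrom.
#' @export
scaffoldRmsd <- function(poseA, poseB, coreAtoms = NULL) {
  ca <- if (is.list(coreAtoms) && !is.null(coreAtoms)) coreAtoms[[1L]] else coreAtoms
  cb <- if (is.list(coreAtoms) && !is.null(coreAtoms)) coreAtoms[[2L]] else coreAtoms
  if (is.null(ca)) ca <- poseA@meta$core_atoms
  if (is.null(cb)) cb <- poseB@meta$core_atoms
  if (is.null(ca)) ca <- seq_len(nAtoms(poseA))
  if (is.null(cb)) cb <- seq_len(nAtoms(poseB))
  if (length(ca) != length(cb)) stop("core atom counts differ between poses")
  rmsdNoFit(coords(poseA)[ca, , drop = FALSE],
            coords(poseB)[cb, , drop = FALSE])
}

#' Pairwise scaffold RMSD matrix of a pose ensemble
#'
#' @param poses list of \linkS4class{LigandPose} (at least 2).
#' @param coreAtoms shared core indices (default: each pose's meta).
#' @return symmetric matrix with pose ids as dimnames; validated for zero
#'   diagonal, symmetry and non-negativity before return.
#' @export
rmsdMatrix <- function(poses, coreAtoms = NULL) {
  n <- length(poses)
  if (n < 2L) stop("need at least 2 poses")
  ids <- vapply(poses, poseId, "")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- scaffoldRmsd(poses[[i]], poses[[j]], coreAtoms)
    }
  }
  stopifnot(all(diag(m) == 0), all(m >= 0), isTRUE(all.equal(m, t(m))))
  m
}

#' Classical (Torgerson) multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances, eigendecomposes, and embeds into
#' \code{dims} dimensions scaled by sqrt(eigenvalue). Negative eigenvalues
#' are truncated at zero with a warning; if fewer positive eigenvalues than
#' \code{dims} exist, the remaining coordinates are zero-padded. The sign of
#' each axis is fixed by making its largest-magnitude coordinate positive.
#'
#' @param d symmetric distance matrix (e.g. from \code{\link{rmsdMatrix}}).
#' @param dims embedding dimensionality (default 2).
#' @return list with \code{points} (n x dims, centered), \code{eig}
#'   (descending eigenvalues) and \code{pose_ids}.
#' @export
classicalMds <- function(d, dims = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  mds <- stats::cmdscale(d, k = min(dims, n - 1L), eig = TRUE)
  eig <- mds$eig
  if (any(eig < -1e-8 * max(abs(eig)))) {
    warning("distance matrix is not exactly Euclidean: ",
            sum(eig < 0), " negative eigenvalue(s) truncated at zero")
  }
  npos <- sum(eig > 1e-12)
  pts <- matrix(0, n, dims)
  got <- min(dims, ncol(mds$points), npos)
  if (got < dims) {
    warning("only ", got, " positive dimension(s); zero-padding to ", dims)
  }
  if (got > 0L) pts[, seq_len(got)] <- mds$points[, seq_len(got), drop = FALSE]
  # deterministic sign convention per axis
  for (k in seq_len(dims)) {
    if (any(pts[, k] != 0)) {
      imax <- which.max(abs(pts[, k]))
      if (pts[imax, k] < 0) pts[, k] <- -pts[, k]
    }
  }
  pts <- sweep(pts, 2L, colMeans(pts))
  rownames(pts) <- rownames(d)
  list(points = pts, eig = sort(eig, decreasing = TRUE),
       pose_ids = rownames(d))
}

#' Assign binding-mode labels by scaffold orientation
#'
#' The orientation score of a pose is the signed projection of its scaffold
#' axis (vector between two designated core atoms, e.g. the ring nitrogen
#' and the R8 carbon) onto the receptor inter-subunit axis (unit vector from
#' the centroid of the first chain to the centroid of the second, through
#' \code{referencePoint}). Poses are first grouped by single-linkage
#' clustering on scaffold RMSD at \code{rmsdThreshold}; clusters take the
#' majority orientation sign (BM_I positive, BM_II negative, "other" for a
#' near-zero mean score).
#'
#' @param poses list of \linkS4class{LigandPose}.
#' @param receptor the \linkS4class{Receptor} (defines the subunit axis).
#' @param scaffoldAxis length-2 integer vector of core atom indices.
#' @param coreAtoms core indices for the RMSD clustering.
#' @param referencePoint 3-vector on the inter-subunit axis (default: pocket
#'   centroid between the chain centroids).
#' @param rmsdThreshold single-linkage cut height, Angstrom (default 2).
#' @return data.frame with pose_id, mode, orientation_score, cluster.
#' @export
assignBindingModes <- function(poses, receptor, scaffoldAxis,
                               coreAtoms = NULL, referencePoint = NULL,
                               rmsdThreshold = 2.0) {
  if (length(scaffoldAxis) != 2L) stop("scaffoldAxis must index two atoms")
  ch <- unique(receptor@atoms$chain)
  if (length(ch) < 2L) stop("receptor needs two chains for a subunit axis")
  c1 <- colMeans(coords(receptor)[receptor@atoms$chain == ch[1L], , drop = FALSE])
  c2 <- colMeans(coords(receptor)[receptor@atoms$chain == ch[2L], , drop = FALSE])
  axis <- unitVec(c2 - c1)
  scores <- vapply(poses, function(p) {
    xyz <- coords(p)
    v <- xyz[scaffoldAxis[2L], ] - xyz[scaffoldAxis[1L], ]
    if (vecNorm(v) < 1e-9) stop("degenerate scaffold axis (zero length)")
    sum(unitVec(v) * axis)
  }, 0)
  n <- length(poses)
  if (n > 1L) {
    m <- rmsdMatrix(poses, coreAtoms)
    hc <- stats::hclust(stats::as.dist(m), method = "single")
    cl <- stats::cutree(hc, h = rmsdThreshold)
  } else cl <- 1L
  mode <- character(n)
  for (g in unique(cl)) {
    sel <- cl == g
    ms <- mean(sign(scores[sel]))
    lab <- if (abs(mean(scores[sel])) < 1e-6) "other"
           else if (ms >= 0) "BM_I" else "BM_II"
    mode[sel] <- lab
  }
  data.frame(pose_id = vapply(poses, poseId, ""), mode = mode,
             orientation_score = scores, cluster = cl,
             stringsAsFactors = FALSE)
}

#' Center-of-mass distance between two ligand poses
#'
#' Euclidean distance between heavy-atom centers. Unit masses (geometric
#' centroid) by default; element masses with \code{massWeighted = TRUE}.
#'
#' @param poseA,poseB \linkS4class{LigandPose} objects.
#' @param massWeighted use atomic masses.
#' @return distance in Angstrom.
#' @export
comDistance <- function(poseA, poseB, massWeighted = FALSE) {
  com <- function(p) {
    at <- p@molecule@atoms
    heavy <- !at$is_hydrogen
    if (!any(heavy)) stop("empty molecule")
    xyz <- coords(p)[heavy, , drop = FALSE]
    w <- if (massWeighted) elementProperty(at$element[heavy], "mass") else
      rep(1, sum(heavy))
    colSums(xyz * w) / sum(w)
  }
  vecNorm(com(poseA) - com(poseB))
}
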