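# SAR congruency statistics: per-pose Pearson correlation between predicted
# binding energies and measured potencies (R_SAR), regression diagnostics,
# leave-one-out q2, Y-scrambling with an empirical (add-one) p-value, pose
# ranking with scree data, and outlier re-assessment.

# Drop pairs with missing values; error below the minimum usable size.
.pairedVectors <- function(energies, activities, minN = 3L) {
  ok <- is.finite(energies) & is.finite(activities)
  x <- energies[ok]; y <- activities[ok]
  if (length(x) < minN) {
    stop("fewer than ", minN, " complete (energy, activity) pairs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in ", if (stats::sd(x) == 0) "energies" else "activities")
  }
  list(x = x, y = y, n = length(x), dropped = sum(!ok))
}

#' SAR congruency coefficient (Pearson r)
#'
#' Pearson correlation between predicted binding energies and measured
#' potencies for one pose's analog series. Strongly negative values indicate
#' a SAR-consistent pose (lower energy tracking higher potency).
#'
#' @param energies per-compound binding energies, kcal/mol.
#' @param activities per-compound potencies, log units.
#' @return Pearson r, with attributes \code{n} (pairs used) and
#'   \code{dropped}.
#' @export
rSar <- function(energies, activities) {
  p <- .pairedVectors(energies, activities)
  r <- stats::cor(p$x, p$y)
  attr(r, "n") <- p$n
  attr(r, "dropped") <- p$dropped
  r
}

#' Regression diagnostics for one pose
#'
#' Ordinary least squares of activity on energy: slope, intercept, RMSE
#' (root mean squared residual) and r2.
#'
#' @inheritParams rSar
#' @return list(slope, intercept, RMSE, r2, n).
#' @export
regressionDiagnostics <- function(energies, activities) {
  p <- .pairedVectors(energies, activities)
  fit <- stats::lm(y ~ x, data = list(x = p$x, y = p$y))
  res <- stats::residuals(fit)
  sst <- sum((p$y - mean(p$y))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       RMSE = sqrt(mean(res^2)),
       r2 = 1 - sum(res^2) / sst,
       residuals = res,
       n = p$n)
}

#' Leave-one-out cross-validated q2
#'
#' q2 = 1 - PRESS/SS_tot, where PRESS accumulates the squared error of
#' predicting each left-out activity from the regression refitted on the
#' remaining points, and SS_tot uses the full-sample activity mean.
#'
#' @inheritParams rSar
#' @return q2 (dimensionless).
#' @export
looQ2 <- function(energies, activities) {
  p <- .pairedVectors(energies, activities, minN = 4L)
  x <- p$x; y <- p$y; n <- p$n
  # PRESS via the exact leverage identity for OLS: deleting point i and
  # predicting it equals res_i / (1 - h_i) on the full fit
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  b <- sum((x - xb) * (y - yb)) / sxx
  res <- y - (yb + b * (x - xb))
  h <- 1 / n + (x - xb)^2 / sxx
  1 - sum((res / (1 - h))^2) / sum((y - yb)^2)
}

#' Y-scrambling validation
#'
#' Permutes the activities \code{nIterations} times (uniformly, without
#' replacement), recomputing r2 and LOO q2 each time. The empirical p-value
#' uses the add-one rule, p = (1 + #\{scrambled r2 >= observed r2\}) /
#' (nIterations + 1), so it is never zero.
#'
#' @inheritParams rSar
#' @param nIterations number of permutations (default 1000).
#' @param seed mandatory RNG seed.
#' @return list with yscr_r2_mean/sd, yscr_q2_mean/sd (raw and clamped at
#'   zero), p_value, observed r2/q2, n, and rng metadata.
#' @export
yScramble <- function(energies, activities, nIterations = 1000L, seed) {
  if (missing(seed)) stop("a seed is required for reproducible scrambling")
  if (nIterations < 1L) stop("nIterations must be at least 1")
  if (nIterations < 100L) {
    message("yScramble: fewer than 100 iterations gives a coarse null")
  }
  p <- .pairedVectors(energies, activities, minN = 4L)
  obsR2 <- stats::cor(p$x, p$y)^2
  obsQ2 <- looQ2(p$x, p$y)
  r2s <- numeric(nIterations)
  q2s <- numeric(nIterations)
  withSeed(seed, {
    for (k in seq_len(nIterations)) {
      ys <- sample(p$y)
      r2s[k] <- stats::cor(p$x, ys)^2
      q2s[k] <- looQ2(p$x, ys)
    }
  })
  list(
    yscr_r2_mean = mean(r2s), yscr_r2_sd = stats::sd(r2s),
    yscr_q2_mean = mean(q2s), yscr_q2_sd = stats::sd(q2s),
    yscr_q2_mean_clamped = mean(pmax(q2s, 0)),
    p_value = (1 + sum(r2s >= obsR2)) / (nIterations + 1),
    observed_r2 = obsR2, observed_q2 = obsQ2,
    n = p$n, n_iterations = nIterations,
    rng = list(kind = "Mersenne-Twister", seed = seed)
  )
}

# Assemble one pose's assessment row.
.assessOne <- function(poseId, energies, activities, nIterations, seed,
                       yscramble = TRUE) {
  r <- rSar(energies, activities)
  diag <- regressionDiagnostics(energies, activities)
  q2 <- looQ2(energies, activities)
  row <- data.frame(
    pose_id = poseId, R_SAR = as.numeric(r), r2 = as.numeric(r)^2,
    RMSE = diag$RMSE, q2_loo = q2,
    yscr_r2_mean = NA_real_, yscr_r2_sd = NA_real_,
    yscr_q2_mean = NA_real_, yscr_q2_sd = NA_real_,
    p_value = NA_real_, n_compounds = attr(r, "n"),
    stringsAsFactors = FALSE
  )
  if (yscramble) {
    ys <- yScramble(energies, activities, nIterations, seed)
    row$yscr_r2_mean <- ys$yscr_r2_mean; row$yscr_r2_sd <- ys$yscr_r2_sd
    row$yscr_q2_mean <- ys$yscr_q2_mean; row$yscr_q2_sd <- ys$yscr_q2_sd
    row$p_value <- ys$p_value
  }
  row
}

#' Assess and rank a pose ensemble by SAR congruency
#'
#' Joins the per-pose, per-compound energy table with the activity table,
#' computes every pose's R_SAR, r2, RMSE, LOO q2 and (optionally)
#' Y-scrambling statistics, and ranks poses by most-negative R_SAR (ties by
#' lower RMSE, then pose id).
#'
#' @param energies data.frame with pose_id, compound_id and an energy column.
#' @param records activity table (see \code{\link{loadCompoundTable}}).
#' @param activityColumn "pEC50_a1b3" or "pKi_a1g2".
#' @param energyColumn which energy to correlate (default \code{dG_bind};
#'   use \code{dG_strain_corrected} for the strain-corrected variant).
#' @param includeReference include the reference compound itself in the
#'   correlation set (default TRUE, giving n = 19 for the packaged series).
#' @param referenceId reference compound id (only used when
#'   \code{includeReference = FALSE}).
#' @param yscramble run Y-scrambling per pose (default TRUE).
#' @param nIterations,seed Y-scrambling controls.
#' @return data.frame of pose assessments, ranked; attribute \code{"scree"}
#'   holds (rank, pose_id, R_SAR).
#' @export
assessPoses <- function(energies, records,
                        activityColumn = c("pEC50_a1b3", "pKi_a1g2"),
                        energyColumn = "dG_bind", includeReference = TRUE,
                        referenceId = NULL, yscramble = TRUE,
                        nIterations = 1000L, seed = 42L) {
  activityColumn <- match.arg(activityColumn)
  if (!all(c("pose_id", "compound_id", energyColumn) %in% names(energies))) {
    stop("energy table needs columns pose_id, compound_id, ", energyColumn)
  }
  tab <- records
  if (!includeReference) {
    if (is.null(referenceId)) stop("referenceId required when excluding it")
    tab <- tab[as.character(tab$compound_id) != as.character(referenceId), ,
               drop = FALSE]
  }
  act <- tab[[activityColumn]]
  names(act) <- as.character(tab$compound_id)
  # reference poses: pose_id up to the ":<compound>" suffix
  basePose <- sub(":[^:]*$", "", energies$pose_id)
  poseIds <- unique(basePose)
  cids <- as.character(tab$compound_id)
  # completeness check
  ragged <- character()
  perPose <- list()
  for (pid in poseIds) {
    sel <- basePose == pid
    e <- energies[[energyColumn]][sel]
    names(e) <- as.character(energies$compound_id[sel])
    if (!all(cids %in% names(e))) {
      ragged <- c(ragged, pid)
    }
    perPose[[pid]] <- e
  }
  if (length(ragged)) {
    stop("incomplete energy table for pose(s): ", paste(ragged, collapse = ", "))
  }
  rows <- lapply(poseIds, function(pid) {
    e <- perPose[[pid]][cids]
    .assessOne(pid, e, act, nIterations, seed, yscramble)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$R_SAR, out$RMSE, out$pose_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "scree") <- data.frame(rank = out$rank, pose_id = out$pose_id,
                                   R_SAR = out$R_SAR)
  out
}

#' Re-assess one pose after excluding compounds
#'
#' Identical computation on the reduced compound set (used for outlier
#' re-assessment of a candidate binding mode).
#'
#' @inheritParams rSar
#' @param exclude compound ids to drop; \code{energies}/\code{activities}
#'   must be named by compound id.
#' @param nIterations,seed,yscramble Y-scrambling controls.
#' @return one-row assessment data.frame with an \code{excluded} attribute.
#' @export
reassessWithout <- function(energies, activities, exclude = character(),
                            yscramble = FALSE, nIterations = 1000L,
                            seed = 42L) {
  keep <- setdiff(names(activities), as.character(exclude))
  if (length(keep) < 3L) stop("exclusion leaves fewer than 3 compounds")
  row <- .assessOne("reassessed", energies[keep], activities[keep],
                    nIterations, seed, yscramble)
  attr(row, "excluded") <- as.character(exclude)
  row
}
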