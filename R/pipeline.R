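# Orchestration: a one-shot report chaining derivatize -> score -> rank ->
# pose space -> SIFt, with per-stage seeds derived from one root seed.
# The thin command-line wrapper in inst/scripts/posesar drives these same
# functions.

# Stable per-stage substream seeds below 2^31.
stageSeed <- function(seed, stage) {
  offs <- c(derivatize = 101L, score = 211L, rank = 307L, posespace = 401L,
            sift = 503L, simulate = 601L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full SAR-congruency protocol and write a report directory
#'
#' Expands every reference pose into the analog series, scores all derived
#' complexes, ranks the reference poses by SAR congruency, embeds the pose
#' space by classical MDS, assigns binding modes and computes the SIFt
#' summary. Writes assessment.csv, scree.csv, energies.csv, mds.csv,
#' modes.csv, sift.csv and a markdown summary into \code{outDir}.
#'
#' @param receptor a \linkS4class{Receptor}.
#' @param poses list of reference \linkS4class{LigandPose} objects.
#' @param scaffold a \linkS4class{ScaffoldMap} on the reference molecule.
#' @param records compound/activity table.
#' @param library substituent library (default: the built-in one).
#' @param outDir output directory (created if absent).
#' @param activityColumn activity column for the congruency stage.
#' @param minimize run restrained minimization before scoring.
#' @param params a \linkS4class{MinimizationParams}.
#' @param torsionSteps dihedral grid for derivatization.
#' @param nIterations Y-scrambling iterations (default 1000).
#' @param seed root seed; every stochastic stage derives its own stream.
#' @param includeReference include the reference compound in correlations.
#' @param scaffoldAxis core atom pair for binding-mode orientation (default:
#'   first and last core atom).
#' @return the assessment data.frame (invisibly); files in \code{outDir}.
#' @export
runReport <- function(receptor, poses, scaffold, records,
                      library = substituentLibrary(), outDir,
                      activityColumn = "pEC50_a1b3", minimize = FALSE,
                      params = minimizationParams(), torsionSteps = 12L,
                      nIterations = 1000L, seed = 42L,
                      includeReference = TRUE, scaffoldAxis = NULL) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  stage <- "derivatize"
  result <- tryCatch({
    expanded <- list()
    for (p in poses) {
      expanded <- c(expanded, expandPose(p, scaffold, records, library,
                                         receptor, torsionSteps,
                                         referenceId = p@compoundId))
    }
    stage <- "score"
    energies <- scorePoses(receptor, expanded, minimize = minimize,
                           params = params)
    exportScores(energies, file.path(outDir, "energies.csv"))
    stage <- "rank"
    assessment <- assessPoses(energies, records,
                              activityColumn = activityColumn,
                              includeReference = includeReference,
                              referenceId = poses[[1L]]@compoundId,
                              nIterations = nIterations,
                              seed = stageSeed(seed, "rank"))
    utils::write.csv(assessment, file.path(outDir, "assessment.csv"),
                     row.names = FALSE)
    utils::write.csv(attr(assessment, "scree"), file.path(outDir, "scree.csv"),
                     row.names = FALSE)
    stage <- "posespace"
    refPoses <- expanded[vapply(expanded, function(p)
      !grepl(":", p@poseId, fixed = TRUE), TRUE)]
    m <- rmsdMatrix(refPoses, scaffold@coreAtoms)
    utils::write.csv(m, file.path(outDir, "rmsd_matrix.csv"))
    emb <- classicalMds(m, dims = 2L)
    utils::write.csv(data.frame(pose_id = emb$pose_ids,
                                dim1 = emb$points[, 1L],
                                dim2 = emb$points[, 2L]),
                     file.path(outDir, "mds.csv"), row.names = FALSE)
    if (is.null(scaffoldAxis)) {
      scaffoldAxis <- scaffold@coreAtoms[c(1L, length(scaffold@coreAtoms))]
    }
    modes <- assignBindingModes(refPoses, receptor, scaffoldAxis,
                                coreAtoms = scaffold@coreAtoms)
    utils::write.csv(modes, file.path(outDir, "modes.csv"), row.names = FALSE)
    stage <- "sift"
    sift <- siftMatrix(receptor, refPoses)
    utils::write.csv(sift$bits, file.path(outDir, "sift.csv"),
                     row.names = FALSE)
    utils::write.csv(sift$summary, file.path(outDir, "sift_summary.csv"),
                     row.names = FALSE)
    top <- assessment[1L, ]
    cfgHash <- sum(utf8ToInt(paste(activityColumn, minimize, torsionSteps,
                                   nIterations, includeReference,
                                   collapse = "|"))) + seed
    writeLines(c(
      "# SAR congruency report",
      "",
      sprintf("- poses assessed: %d", nrow(assessment)),
      sprintf("- top pose: %s (R_SAR = %.3f, r2 = %.3f, RMSE = %.3f, q2 = %.3f, p = %.4g)",
              top$pose_id, top$R_SAR, top$r2, top$RMSE, top$q2_loo, top$p_value),
      sprintf("- binding mode of top pose: %s",
              modes$mode[match(top$pose_id, modes$pose_id)]),
      sprintf("- config hash: %d, seed: %d", cfgHash, seed)
    ), file.path(outDir, "summary.md"))
    assessment
  }, error = function(e) {
    stop("report failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Simulate a toy study and write its inputs to disk
#'
#' Builds the synthetic system, generates decoys and activities from the
#' planted pose, and writes rec.pdb, poses.sdf, scaffold.json, table.csv and
#' truth.json into \code{outDir}.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param outDir output directory.
#' @return list with the in-memory objects (receptor, poses, scaffold,
#'   records, truth pose id), invisibly.
#' @export
simulateStudy <- function(spec = syntheticSpec(), outDir = NULL) {
  toy <- makeToySystem(spec)
  decoys <- makeDecoys(toy$planted, toy$receptor, spec$nPoses - 1L,
                       spread = spec$decoySpread,
                       seed = stageSeed(spec$seed, "simulate"))
  poses <- c(list(toy$planted), decoys)
  # true-pose energies over the analog series
  expanded <- expandPose(toy$planted, toy$scaffold, toy$records, toy$library,
                         toy$receptor, torsionSteps = 12L, referenceId = "1")
  en <- scorePoses(toy$receptor, expanded)
  ev <- en$dG_bind
  names(ev) <- en$compound_id
  records <- generateActivities(toy$records, ev, slope = spec$slope,
                                noiseSd = spec$noiseSd,
                                seed = stageSeed(spec$seed, "simulate") + 1L)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeReceptor(toy$receptor, file.path(outDir, "rec.pdb"))
    writePoses(poses, file.path(outDir, "poses.sdf"))
    writeScaffoldMap(toy$scaffold, file.path(outDir, "scaffold.json"))
    utils::write.csv(records, file.path(outDir, "table.csv"), row.names = FALSE)
    jsonlite::write_json(list(planted_pose = poseId(toy$planted)),
                         file.path(outDir, "truth.json"), auto_unbox = TRUE)
  }
  invisible(list(receptor = toy$receptor, poses = poses,
                 scaffold = toy$scaffold, library = toy$library,
                 records = records, truth = poseId(toy$planted)))
}
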