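## Factorial study driver: seven calibration-uncertainty scenarios by four
## calibration settings by N concatenations, with the secondary-calibration
## hand-off from subtree A to subtree B.

#' Calibration-uncertainty scenario codes
#'
#' Seven scenarios of uncertainty around the true time TT of a calibrated
#' node.  Balanced scenarios (0B, 10B, 20B) spread the error evenly; L
#' scenarios skew it toward younger times, H scenarios toward older times.
#' A rule of "1" means 1 my absolute; a percentage means that fraction of
#' TT.
#'
#' @return Character vector of the seven codes.
#' @export
scenarioCodes <- function()
  c("0B", "10B", "20B", "10L", "10H", "20L", "20H")

#' Turn a scenario code and a true age into a calibration constraint
#'
#' Rules per scenario (minimum, maximum around TT):
#' `0B`: -1 my, +1 my; `10B`: -5%, +5%; `20B`: -10%, +10%;
#' `10L`: -10%, +1 my; `10H`: -1 my, +10%; `20L`: -20%, +1 my;
#' `20H`: -1 my, +20%.
#'
#' @param code One of [scenarioCodes()].
#' @param TT True node age in my (> 1).
#' @param nodeId Node id the constraint applies to.
#' @return One-row constraint data.frame (see [calibrationConstraints()]).
#' @export
makeScenarioConstraint <- function(code, TT, nodeId) {
  stopifnot2(TT > 1, "TT must exceed 1 my")
  b <- switch(code,
    "0B"  = c(TT - 1,    TT + 1),
    "10B" = c(0.95 * TT, 1.05 * TT),
    "20B" = c(0.90 * TT, 1.10 * TT),
    "10L" = c(0.90 * TT, TT + 1),
    "10H" = c(TT - 1,    1.10 * TT),
    "20L" = c(0.80 * TT, TT + 1),
    "20H" = c(TT - 1,    1.20 * TT),
    stop("unknown scenario code: ", code, call. = FALSE))
  calibrationConstraints(nodeId, b[1L], b[2L])
}

#' Study configuration
#'
#' Bundles every tunable of the factorial experiment.  The defaults are
#' the package's desk-scale study: an 84-taxon master tree at a 220 my
#' root (subtree A about 60 and subtree B about 24 ingroup taxa), 100
#' genes, 10 concatenations of at least 5,000 sites and 200 CI resamples,
#' over all seven scenarios and all four calibration settings.
#'
#' @param nTaxa,rootAge,outgroupFrac Master-tree parameters
#'   (see [generateMasterTree()]).
#' @param overlapRelDepth,targetFracB Split parameters
#'   (see [splitNested()]).
#' @param shallowRelDepth,deepRelDepth Calibration-node placement
#'   (see [pickCalibrationNodes()]).
#' @param nGenes,lengthMean,lengthCV,gcRange,kappaRange,rateRange,meanRate
#'   Gene-profile parameters (see [sampleGeneProfiles()]).
#' @param nu,maxDev Rate-model parameters (see [rateModelParams()]).
#' @param nConcat,minLen Concatenation parameters
#'   (see [buildConcatenations()]).
#' @param B CI resamples per run.
#' @param scenarios,settings Factorial grid; settings are `A_primary`,
#'   `B_secondary`, `B_primary`, `B_distant_primary`.
#' @param seed Master seed; all per-step seeds derive from it.
#' @return list of class `StudyConfig`.
#' @export
studyConfig <- function(nTaxa = 84, rootAge = 220, outgroupFrac = 0.25,
                        overlapRelDepth = 0.76, targetFracB = 23 / 84,
                        shallowRelDepth = 0.29, deepRelDepth = 0.95,
                        nGenes = 100, lengthMean = 1354, lengthCV = 0.5,
                        gcRange = c(0.3, 0.7), kappaRange = c(2, 8),
                        rateRange = c(0.75, 1.25), meanRate = 0.002,
                        nu = 1, maxDev = 0.25,
                        nConcat = 10, minLen = 5000, B = 200,
                        scenarios = scenarioCodes(),
                        settings = c("A_primary", "B_secondary", "B_primary",
                                     "B_distant_primary"),
                        seed = 1L) {
  stopifnot2(all(scenarios %in% scenarioCodes()), "unknown scenario code")
  structure(as.list(environment()), class = "StudyConfig")
}

#' Generate the full data bundle for a study
#'
#' Master timetree, nested split, calibration nodes, gene profiles,
#' per-gene rated trees and alignments, and the concatenations.  Every
#' stochastic step draws its seed from the config's master seed.
#'
#' @param config A [studyConfig()].
#' @param verbose Print progress.
#' @return list with elements `split`, `calNodes`, `profiles`, `genes`
#'   (alignments), `concats`, `config`.
#' @export
buildStudyData <- function(config, verbose = FALSE) {
  cf <- config
  master <- generateMasterTree(cf$nTaxa, cf$rootAge, seed = cf$seed,
                               outgroupFrac = cf$outgroupFrac)
  split <- splitNested(master, overlapRelDepth = cf$overlapRelDepth,
                       targetFrac = cf$targetFracB, seed = cf$seed)
  calNodes <- pickCalibrationNodes(split, cf$shallowRelDepth, cf$deepRelDepth)
  profiles <- sampleGeneProfiles(cf$nGenes, lengthMean = cf$lengthMean,
                                 lengthCV = cf$lengthCV, gcRange = cf$gcRange,
                                 kappaRange = cf$kappaRange,
                                 rateRange = cf$rateRange,
                                 meanRate = cf$meanRate, seed = cf$seed)
  params <- rateModelParams(nu = cf$nu, maxDev = cf$maxDev)
  genes <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    pr <- profiles[i, ]
    rated <- evolveRates(master, pr, params)
    genes[[i]] <- simulateGeneAlignment(rated, pr)
    if (verbose && i %% 25 == 0) message("simulated ", i, " genes")
  }
  concats <- buildConcatenations(genes, nSets = cf$nConcat, minLen = cf$minLen,
                                 seed = cf$seed)
  list(split = split, calNodes = calNodes, profiles = profiles,
       genes = genes, concats = concats, config = cf)
}

## Constraints for the three A primaries under a scenario.
primaryConstraints <- function(split, calNodes, scenario) {
  tt <- split@treeA@ages
  do.call(rbind, lapply(unname(calNodes), function(n)
    makeScenarioConstraint(scenario, tt[[n]], n)))
}

## Fit one tree ("A", "B" or "AB") to one concatenation.
fitTree <- function(tree, concat, split) {
  tt <- switch(tree, A = split@treeA, B = split@treeB, AB = split@master,
               stop("unknown tree: ", tree, call. = FALSE))
  blt <- estimateBranchLengths(subsetAlignment(concat, tt@tree$tip.label), tt)
  list(timetree = tt, blt = blt, rt = relativeAges(blt))
}

#' Run one calibration setting for one scenario and concatenation
#'
#' * `A_primary`: date subtree A with the three scenario-transformed
#'   primary constraints.
#' * `B_secondary`: run `A_primary` first, then use the overlap node's CI
#'   verbatim as the single min/max constraint on the overlap node in
#'   subtree B.
#' * `B_primary`: date subtree B with one scenario-transformed constraint
#'   on the overlap node's true age.
#' * `B_distant_primary`: date the combined tree AB with the three A
#'   primaries and keep only subtree-B-side nodes.
#'
#' @param setting One of the four setting labels.
#' @param scenario One of [scenarioCodes()].
#' @param concat A concatenation [MultiGeneAlignment-class] covering the
#'   master taxa.
#' @param split A [NestedSplit].
#' @param calNodes Output of [pickCalibrationNodes()].
#' @param config A [studyConfig()] (supplies `B` and the master seed).
#' @param fits Optional cache of `fitTree()` results, keyed `A`, `B`,
#'   `AB`.
#' @param aResult Optional precomputed `A_primary` [DatingResult-class]
#'   for the secondary hand-off.
#' @param concatId Index of the concatenation (enters the per-run seed).
#' @return A [DatingResult-class].
#' @export
runSetting <- function(setting, scenario, concat, split, calNodes, config,
                       fits = NULL, aResult = NULL, concatId = 1L) {
  cf <- config
  need <- switch(setting, A_primary = "A", B_secondary = c("A", "B"),
                 B_primary = "B", B_distant_primary = "AB",
                 stop("unknown setting: ", setting, call. = FALSE))
  if (is.null(fits)) fits <- list()
  for (tr in need)
    if (is.null(fits[[tr]])) fits[[tr]] <- fitTree(tr, concat, split)
  ciSeed <- function(st) deriveSeed(cf$seed, "run", st, scenario, concatId)
  ov <- split@overlapNode
  if (setting == "A_primary") {
    cons <- primaryConstraints(split, calNodes, scenario)
    return(nodeCIs(fits$A$blt, cons, B = cf$B, seed = ciSeed(setting),
                   rt = fits$A$rt, timetree = split@treeA))
  }
  if (setting == "B_secondary") {
    if (is.null(aResult))
      aResult <- runSetting("A_primary", scenario, concat, split, calNodes,
                            cf, fits = fits, concatId = concatId)
    row <- aResult@nodes[aResult@nodes$node_id == ov, ]
    stopifnot2(nrow(row) == 1L && is.finite(row$ci_lo),
               paste("no overlap-node CI available from the A run for",
                     scenario))
    cons <- calibrationConstraints(ov, max(row$ci_lo, 1e-6), row$ci_hi)
    return(nodeCIs(fits$B$blt, cons, B = cf$B, seed = ciSeed(setting),
                   rt = fits$B$rt, timetree = split@treeB))
  }
  if (setting == "B_primary") {
    cons <- makeScenarioConstraint(scenario, split@treeB@ages[[ov]], ov)
    return(nodeCIs(fits$B$blt, cons, B = cf$B, seed = ciSeed(setting),
                   rt = fits$B$rt, timetree = split@treeB))
  }
  ## B_distant_primary
  cons <- primaryConstraints(split, calNodes, scenario)
  res <- nodeCIs(fits$AB$blt, cons, B = cf$B, seed = ciSeed(setting),
                 rt = fits$AB$rt, timetree = split@master)
  keep <- res@nodes$node_id %in% c(ingroupNodes(split@treeB),
                                   split@treeB@tree$tip.label)
  methods::new("DatingResult", nodes = res@nodes[keep, ], f = res@f,
               fInterval = res@fInterval, feasible = res@feasible,
               constraints = res@constraints)
}

#' Run the full factorial study
#'
#' Executes every (setting, scenario, concatenation) combination, caching
#' the per-(tree, concatenation) ML fits, and assembles the long node
#' comparison table used by the accuracy measures.  When `outDir` is
#' given, per-run CSVs are written incrementally and existing ones are
#' reused on a rerun, making an interrupted study resumable.
#'
#' @param config A [studyConfig()].
#' @param data Optional precomputed [buildStudyData()] bundle.
#' @param outDir Optional output directory for incremental results.
#' @param verbose Print progress.
#' @return list of class `StudyResults` with elements `comparisons` (one
#'   row per node per run, with columns setting, scenario, concat,
#'   node_id, TT, ET, ci_lo, ci_hi, relative_age, calibrated, overlap,
#'   in_metrics, feasible), `failures` (count of failed runs) and `meta`.
#' @export
runStudy <- function(config, data = NULL, outDir = NULL, verbose = FALSE) {
  cf <- config
  if (is.null(data)) data <- buildStudyData(cf, verbose = verbose)
  split <- data$split
  calNodes <- data$calNodes
  ov <- split@overlapNode
  needTrees <- unique(unlist(lapply(cf$settings, switch,
    A_primary = "A", B_secondary = c("A", "B"), B_primary = "B",
    B_distant_primary = "AB")))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  metricNodes <- list(
    A = setdiff(ingroupNodes(split@treeA), unname(calNodes)),
    B = setdiff(ingroupNodes(split@treeB), ov))
  rows <- list()
  failures <- 0L
  runFile <- function(setting, scenario, ci)
    if (is.null(outDir)) NULL else
      file.path(outDir, sprintf("run_%s_%s_c%02d.csv", setting, scenario, ci))
  for (ci in seq_along(data$concats)) {
    concat <- data$concats[[ci]]
    allDone <- !is.null(outDir) && all(vapply(cf$settings, function(st)
      all(file.exists(unlist(lapply(cf$scenarios, function(sc)
        runFile(st, sc, ci))))), logical(1L)))
    fits <- list()
    if (!allDone) {
      for (tr in needTrees) {
        fits[[tr]] <- fitTree(tr, concat, split)
        if (verbose) message("concat ", ci, ": fitted tree ", tr)
      }
    }
    for (scenario in cf$scenarios) {
      aRes <- NULL
      aFile <- runFile("A_primary", scenario, ci)
      if (any(c("A_primary", "B_secondary") %in% cf$settings)) {
        aRes <- if (!is.null(aFile) && file.exists(aFile) && allDone) {
          nd <- read.csv(aFile, stringsAsFactors = FALSE)
          methods::new("DatingResult", nodes = nd[, seq_len(7L)], f = 1,
                       fInterval = c(1, 1), feasible = all(nd$feasible),
                       constraints = data.frame())
        } else {
          tryCatch(
            runSetting("A_primary", scenario, concat, split, calNodes, cf,
                       fits = fits, concatId = ci),
            error = function(e) e)
        }
      }
      for (setting in cf$settings) {
        fn <- runFile(setting, scenario, ci)
        if (!is.null(fn) && file.exists(fn)) {
          rows[[length(rows) + 1L]] <- read.csv(fn, stringsAsFactors = FALSE)
          next
        }
        res <- tryCatch({
          if (setting == "A_primary") {
            if (inherits(aRes, "error")) stop(conditionMessage(aRes))
            aRes
          } else if (setting == "B_secondary") {
            if (inherits(aRes, "error"))
              stop("A_primary failed for ", scenario, " concat ", ci, ": ",
                   conditionMessage(aRes))
            runSetting(setting, scenario, concat, split, calNodes, cf,
                       fits = fits, aResult = aRes, concatId = ci)
          } else {
            runSetting(setting, scenario, concat, split, calNodes, cf,
                       fits = fits, concatId = ci)
          }
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures <- failures + 1L
          warning("run failed (", setting, ", ", scenario, ", concat ", ci,
                  "): ", conditionMessage(res), call. = FALSE)
          next
        }
        nd <- res@nodes
        nd <- nd[!nd$node_id %in% c(split@master@tree$tip.label), ]
        side <- if (setting == "A_primary") "A" else "B"
        nd$setting <- setting
        nd$scenario <- scenario
        nd$concat <- ci
        nd$overlap <- nd$node_id == ov
        nd$in_metrics <- nd$node_id %in% metricNodes[[side]]
        nd$feasible <- res@feasible
        rownames(nd) <- NULL
        rows[[length(rows) + 1L]] <- nd
        if (!is.null(fn)) write.csv(nd, fn, row.names = FALSE)
      }
    }
  }
  comparisons <- do.call(rbind, rows)
  rownames(comparisons) <- NULL
  out <- list(comparisons = comparisons, failures = failures,
              meta = list(config = cf, calNodes = calNodes,
                          overlapNode = ov,
                          sharedLineages = split@sharedLineages,
                          treeSizes = c(A = length(taxa(split@treeA)),
                                        B = length(taxa(split@treeB)),
                                        master = length(taxa(split@master)))))
  class(out) <- "StudyResults"
  if (!is.null(outDir)) {
    write.csv(comparisons, file.path(outDir, "comparisons.csv"),
              row.names = FALSE)
    writeManifest(cf[setdiff(names(cf), c("scenarios", "settings"))],
                  list.files(outDir, pattern = "\\.csv$"),
                  file.path(outDir, "manifest.json"))
  }
  out
}

#' @export
print.StudyResults <- function(x, ...) {
  cmp <- x$comparisons
  cat("StudyResults:", length(unique(cmp$setting)), "settings x",
      length(unique(cmp$scenario)), "scenarios x",
      length(unique(cmp$concat)), "concatenations;",
      nrow(cmp), "node comparisons;", x$failures, "failed runs\n")
  invisible(x)
}
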