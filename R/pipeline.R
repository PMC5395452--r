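#' Run the full plant-utilization analysis
#'
#' Orchestrates every stage on one dataset: read and reconcile the inputs,
#' compute cophenetic distances, utilizer ratios, mainland families and
#' PD_min; fit the binomial logit model, G test and derived quantities per
#' utilization group; estimate the Fritz-Purvis D per group; run the
#' family-level and cross-group regressions; and optionally the randomized
#' binomial baseline. Results are returned and, when `outDir` is given,
#' written as CSV tables plus a JSON run-metadata file. Identical inputs and
#' seed give byte-identical outputs. Any stage failure aborts with a
#' stage-tagged message.
#'
#' @param treePath,apparencyPath,matrixPath input file paths (Newick tree,
#'   apparency CSV, utilization CSV); alternatively pass `study`, the in-
#'   memory result of [simulateStudy()].
#' @param study optional simulated study used instead of file inputs.
#' @param outDir output directory; `NULL` suppresses file output.
#' @param measure apparency measure for the fits: `"species"`, `"genera"`
#'   or `"area"`.
#' @param mainlandFraction top fraction of families forming the mainland.
#' @param nPerm permutation count for [phyloD()].
#' @param baselineReps replicates per probability for
#'   [randomizedBaseline()]; 0 skips the baseline.
#' @param baselineProbs success probabilities for the baseline.
#' @param minHostFamilies host-breadth filter for groups.
#' @param seed integer master seed recorded in every output.
#' @return (invisibly when writing) a list with elements `families`,
#'   `groups`, `regressions`, `exclusions`, `baseline` (or NULL), and
#'   `metadata`.
#' @examples
#' study <- simulateStudy(nFamilies = 80, nGroups = 6, seed = 3)
#' res <- runPipeline(study = study, nPerm = 100, seed = 3)
#' res$regressions
#' @export
runPipeline <- function(treePath = NULL, apparencyPath = NULL,
                        matrixPath = NULL, study = NULL, outDir = NULL,
                        measure = c("species", "genera", "area"),
                        mainlandFraction = 0.10, nPerm = 1000L,
                        baselineReps = 0L,
                        baselineProbs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                        minHostFamilies = 10L, seed = 1L) {
  measure <- match.arg(measure)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  loadReport <- NULL
  droppedGroups <- character()
  if (!is.null(study)) {
    tree <- study$tree
    records <- study$apparency
    m <- study$utilization
  } else {
    tree <- stage("phylo", readNewickTree(treePath))
    records <- stage("tables", readFamilyTable(apparencyPath))
    loadReport <- attr(records, "loadReport")
    m <- stage("tables", readUtilizationMatrix(matrixPath, minHostFamilies))
    droppedGroups <- attr(m, "droppedGroups")
  }
  hie <- stage("tables", HostIslandExperiment(m, records, tree,
                                              minHostFamilies))
  tree <- hostTree(hie)
  m <- utilization(hie)
  records <- apparency(hie)
  pa <- records[[apparencyColumn(measure)]]
  names(pa) <- records$family

  dm <- stage("phylo", copheneticDistances(tree))
  mainland <- stage("tables", selectMainland(records, measure,
                                             mainlandFraction))
  pdm <- stage("tables", pdMin(dm, mainland))
  ur <- stage("tables", utilizerRatio(m))

  families <- data.frame(
    family = records$family,
    apparency = pa,
    UR = as.numeric(ur[records$family]),
    PD_min = as.numeric(pdm[records$family]),
    mainland = records$family %in% mainland,
    stringsAsFactors = FALSE, row.names = NULL)

  groupSeeds <- subSeeds(seed, ncol(m) + 1L)
  groups <- stage("glm/signal_d", {
    rows <- lapply(seq_len(ncol(m)), function(j) {
      g <- colnames(m)[j]
      y <- m[, j]
      fit <- tryCatch(fitBinomialLogit(pa[rownames(m)], y),
                      error = function(e) NULL)
      ok <- !is.null(fit) && fit@converged && !fit@separated
      gt <- if (ok && fit@varSlope > 0) gStatistic(fit) else
        list(G = NA_real_, p = NA_real_)
      dq <- if (ok && fit@slope != 0) derivedQuantities(fit) else
        list(PA_05 = NA_real_, PA_095 = NA_real_, UP_0 = NA_real_)
      dres <- tryCatch(
        phyloD(tree, setNames(as.integer(y), rownames(m)),
               nPerm = nPerm, seed = groupSeeds[j]),
        error = function(e) NULL)
      data.frame(
        group = g, measure = measure, HF = sum(y),
        n = if (is.null(fit)) NA_integer_ else fit@n,
        a = if (is.null(fit)) NA_real_ else fit@slope,
        var_a = if (is.null(fit)) NA_real_ else fit@varSlope,
        b = if (is.null(fit)) NA_real_ else fit@intercept,
        var_b = if (is.null(fit)) NA_real_ else fit@varIntercept,
        G = gt$G, p_G = gt$p,
        PA_05 = dq$PA_05, PA_095 = dq$PA_095, UP_0 = dq$UP_0,
        converged = !is.null(fit) && fit@converged,
        separated = !is.null(fit) && fit@separated,
        sum_d_obs = if (is.null(dres)) NA_real_ else dres@sumDObs,
        mean_random = if (is.null(dres)) NA_real_ else dres@meanRandom,
        mean_brownian = if (is.null(dres)) NA_real_ else dres@meanBrownian,
        D = if (is.null(dres)) NA_real_ else dres@D,
        p_random = if (is.null(dres)) NA_real_ else dres@pRandom,
        p_brownian = if (is.null(dres)) NA_real_ else dres@pBrownian,
        n_perm = as.integer(nPerm), seed = groupSeeds[j],
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  famFits <- stage("regressions", familyRelationships(families))
  grpRel <- stage("regressions", groupRelationships(groups))

  regRow <- function(name, f) {
    if (is.null(f)) {
      return(data.frame(regression = name, slope = NA_real_,
                        intercept = NA_real_, r2 = NA_real_, p = NA_real_,
                        n = NA_integer_, stringsAsFactors = FALSE))
    }
    data.frame(regression = name, slope = f@slope, intercept = f@intercept,
               r2 = f@r2, p = f@p, n = f@n, stringsAsFactors = FALSE)
  }
  allFits <- c(famFits, grpRel$fits)
  regressions <- do.call(rbind, Map(regRow, names(allFits), allFits))
  rownames(regressions) <- NULL

  baseline <- NULL
  if (baselineReps > 0L) {
    baseline <- stage("regressions",
      randomizedBaseline(pa, probs = baselineProbs, nReps = baselineReps,
                         seed = groupSeeds[ncol(m) + 1L]))
  }

  metadata <- list(
    seed = as.integer(seed), measure = measure,
    n_families = nrow(m), n_groups = ncol(m),
    mainland_fraction = mainlandFraction,
    n_mainland = length(mainland), n_perm = as.integer(nPerm),
    baseline_reps = as.integer(baselineReps),
    min_host_families = as.integer(minHostFamilies),
    dropped_groups = as.list(droppedGroups),
    load_report = loadReport,
    exclusions = grpRel$exclusions,
    package_version = as.character(utils::packageVersion("hostislands")))

  result <- list(families = families, groups = groups,
                 regressions = regressions,
                 exclusions = grpRel$exclusions,
                 baseline = baseline, metadata = metadata)

  if (!is.null(outDir)) {
    stage("output", {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      write.csv(families, file.path(outDir, "families.csv"),
                row.names = FALSE)
      write.csv(groups, file.path(outDir, "groups.csv"), row.names = FALSE)
      write.csv(regressions, file.path(outDir, "regressions.csv"),
                row.names = FALSE)
      write.csv(grpRel$exclusions, file.path(outDir, "exclusions.csv"),
                row.names = FALSE)
      if (!is.null(baseline)) {
        write.csv(baseline, file.path(outDir, "baseline.csv"),
                  row.names = FALSE)
      }
      jsonlite::write_json(metadata, file.path(outDir, "run_metadata.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
    })
    return(invisible(result))
  }
  result
}
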