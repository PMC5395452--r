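#' Container for a plant-utilization study
#'
#' `HostIslandExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] with plant families as rows
#' and utilization groups (consumer categories) as columns. The single assay,
#' `"presence"`, is the binary utilization matrix; family apparency (species
#' count, genus count, distribution area in km^2) lives in `rowData`; the
#' dated family-level phylogeny (an [ape::phylo] with branch lengths in Myr)
#' is stored in `metadata(x)$tree`.
#'
#' On construction the object is reconciled:
#' * families present in the utilization matrix but absent from the apparency
#'   table, or absent from the tree, are a hard error (a silent default would
#'   hide data mismatches);
#' * tree tips with no utilization data are pruned with a warning;
#' * groups utilizing fewer than `minHostFamilies` families are dropped with
#'   a warning (small host breadth destabilizes both the logit fit and the
#'   phylogenetic-signal estimate).
#'
#' @param utilization binary matrix, families x groups, with dimnames; or the
#'   value of [readUtilizationMatrix()].
#' @param apparency data.frame with columns `family`, `n_species`,
#'   `n_genera`, `area_km2`; typically from [readFamilyTable()].
#' @param tree rooted `phylo` with branch lengths (Myr); typically from
#'   [readNewickTree()].
#' @param minHostFamilies minimum host-family count for a group to be kept.
#' @return a `HostIslandExperiment`.
#' @examples
#' study <- simulateStudy(nFamilies = 40, nGroups = 5, seed = 1)
#' hie <- HostIslandExperiment(study$utilization, study$apparency, study$tree)
#' hie
#' hostBreadth(hie)
#' @aliases HostIslandExperiment-class
#' @export
HostIslandExperiment <- function(utilization, apparency, tree,
                                 minHostFamilies = 10L) {
  if (!is.matrix(utilization) || is.null(rownames(utilization)) ||
      is.null(colnames(utilization))) {
    stop("'utilization' must be a matrix with family rownames and group colnames")
  }
  checkBinaryMatrix(utilization)
  if (!is.data.frame(apparency)) stop("'apparency' must be a data.frame")
  need <- c("family", "n_species", "n_genera", "area_km2")
  miss <- setdiff(need, names(apparency))
  if (length(miss)) {
    stop("apparency table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo' object")

  fams <- rownames(utilization)
  noApp <- setdiff(fams, apparency$family)
  if (length(noApp)) {
    stop("families in the utilization matrix have no apparency record: ",
         paste(head(noApp, 5L), collapse = ", "),
         if (length(noApp) > 5L) ", ...")
  }
  noTip <- setdiff(fams, tree$tip.label)
  if (length(noTip)) {
    stop("families in the utilization matrix are not tips of the tree: ",
         paste(head(noTip, 5L), collapse = ", "),
         if (length(noTip) > 5L) ", ...")
  }
  extraTips <- setdiff(tree$tip.label, fams)
  if (length(extraTips)) {
    warning("pruning ", length(extraTips),
            " tree tip(s) with no utilization data")
    tree <- ape::drop.tip(tree, extraTips)
  }

  hf <- colSums(utilization)
  drop <- hf < minHostFamilies
  if (any(drop)) {
    warning("dropping ", sum(drop), " group(s) with fewer than ",
            minHostFamilies, " host families: ",
            paste(colnames(utilization)[drop], collapse = ", "))
    utilization <- utilization[, !drop, drop = FALSE]
  }
  if (ncol(utilization) == 0L) stop("no utilization group survives filtering")

  rd <- apparency[match(fams, apparency$family), , drop = FALSE]
  rownames(rd) <- fams
  se <- SummarizedExperiment(
    assays = list(presence = utilization),
    rowData = S4Vectors::DataFrame(rd[setdiff(need, "family")]),
    metadata = list(tree = tree, minHostFamilies = as.integer(minHostFamilies))
  )
  new("HostIslandExperiment", se)
}

#' @exportClass HostIslandExperiment
setClass("HostIslandExperiment", contains = "SummarizedExperiment")

setValidity("HostIslandExperiment", function(object) {
  msg <- character()
  if (!"presence" %in% assayNames(object)) {
    msg <- c(msg, "assay 'presence' is required")
  } else {
    m <- assay(object, "presence")
    if (!all(m %in% c(0, 1))) msg <- c(msg, "presence cells must be 0 or 1")
  }
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate family names")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate group names")
  rd <- rowData(object)
  if (!all(c("n_species", "n_genera", "area_km2") %in% colnames(rd))) {
    msg <- c(msg, "rowData must carry n_species, n_genera, area_km2")
  } else {
    if (any(rd$n_species < 0.5) || any(rd$n_genera < 0.5)) {
      msg <- c(msg, "species and genus counts must be >= 0.5")
    }
    if (any(rd$area_km2 < 1000)) {
      msg <- c(msg, "areas must be >= 1000 km^2 after default filling")
    }
  }
  tr <- S4Vectors::metadata(object)$tree
  if (is.null(tr) || !inherits(tr, "phylo")) {
    msg <- c(msg, "metadata(x)$tree must be a 'phylo'")
  } else if (!setequal(tr$tip.label, rownames(object))) {
    msg <- c(msg, "tree tips must match family names")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn HostIslandExperiment the family-level phylogeny (`phylo`).
#' @param x a `HostIslandExperiment`.
#' @export
hostTree <- function(x) S4Vectors::metadata(x)$tree

#' @describeIn HostIslandExperiment binary families x groups presence matrix.
#' @export
utilization <- function(x) assay(x, "presence")

#' @describeIn HostIslandExperiment apparency table as a base data.frame with
#'   a `family` column.
#' @export
apparency <- function(x) {
  rd <- as.data.frame(rowData(x))
  cbind(family = rownames(x), rd, row.names = NULL,
        stringsAsFactors = FALSE)
}

#' @describeIn HostIslandExperiment host breadth HF: the number of host
#'   families per utilization group (column sums of the presence matrix).
#' @export
hostBreadth <- function(x) colSums(assay(x, "presence"))

#' @export
setMethod("show", "HostIslandExperiment", function(object) {
  cat("HostIslandExperiment:", nrow(object), "plant families x",
      ncol(object), "utilization groups\n")
  hf <- hostBreadth(object)
  cat("  host breadth (HF): ", min(hf), "-", max(hf),
      " (median ", stats::median(hf), ")\n", sep = "")
  tr <- hostTree(object)
  cat("  tree: ", length(tr$tip.label), " tips, ",
      if (ape::is.binary(tr)) "binary" else "with polytomies",
      ", depth ", format(max(ape::node.depth.edgelength(tr)), digits = 4),
      " Myr\n", sep = "")
})

#' Binomial logit fit of utilization probability on apparency
#'
#' Result of [fitBinomialLogit()]: the maximum-likelihood slope and intercept
#' of `logit(UP) = a * PA + b`, their variances from the inverse observed
#' information, the residual deviance (-2 log-likelihood), and convergence /
#' separation diagnostics.
#'
#' @slot slope slope `a`, logit units per apparency unit.
#' @slot intercept intercept `b`, logit units.
#' @slot varSlope variance of the slope estimate.
#' @slot varIntercept variance of the intercept estimate.
#' @slot n number of observations.
#' @slot deviance -2 log-likelihood at the optimum.
#' @slot iterations IRLS iterations used.
#' @slot converged logical; deviance change fell below 1e-8.
#' @slot separated logical; quasi-complete separation detected (the MLE is
#'   effectively infinite and derived quantities refuse to compute).
#' @aliases ApparencyFit
#' @exportClass ApparencyFit
setClass("ApparencyFit",
  representation(slope = "numeric", intercept = "numeric",
                 varSlope = "numeric", varIntercept = "numeric",
                 n = "integer", deviance = "numeric", iterations = "integer",
                 converged = "logical", separated = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@varSlope < 0 || object@varIntercept < 0) {
      msg <- c(msg, "variances must be non-negative")
    }
    if (object@n < 2L) msg <- c(msg, "n must be >= 2")
    if (length(msg)) msg else TRUE
  })

#' @describeIn ApparencyFit named coefficients `(intercept, slope)`.
#' @param object an `ApparencyFit`.
#' @param ... ignored.
#' @export
setMethod("coef", "ApparencyFit", function(object, ...) {
  c(intercept = object@intercept, slope = object@slope)
})

#' @export
setMethod("show", "ApparencyFit", function(object) {
  cat("Binomial logit fit: logit(UP) = a * PA + b  (n = ", object@n, ")\n",
      sep = "")
  cat(sprintf("  a = %.6g (var %.3g)   b = %.6g (var %.3g)\n",
              object@slope, object@varSlope,
              object@intercept, object@varIntercept))
  cat(sprintf("  deviance = %.4f, %d IRLS iteration(s)%s%s\n",
              object@deviance, object@iterations,
              if (object@converged) "" else " [NOT CONVERGED]",
              if (object@separated) " [SEPARATED]" else ""))
})

#' Fritz-Purvis D result for one binary utilization trait
#'
#' Result of [phyloD()]: the observed sum of sister-clade differences, the
#' two null means, the standardized D statistic and its tail probabilities.
#'
#' @slot sumDObs observed sum of sister-clade differences.
#' @slot meanRandom mean of the sum under random shuffles of the trait.
#' @slot meanBrownian mean under Brownian-threshold traits at matched
#'   prevalence.
#' @slot D the standardized statistic: 1 is random, 0 is Brownian clumping.
#' @slot pRandom lower-tail probability against the permutation null.
#' @slot pBrownian upper-tail probability against the Brownian null.
#' @slot nPerm replicates per null.
#' @slot nTips tips used after pruning.
#' @slot prevalence proportion of tips scored 1.
#' @slot seed master seed used (recorded for reproducibility).
#' @aliases PhyloDResult
#' @exportClass PhyloDResult
setClass("PhyloDResult",
  representation(sumDObs = "numeric", meanRandom = "numeric",
                 meanBrownian = "numeric", D = "numeric",
                 pRandom = "numeric", pBrownian = "numeric",
                 nPerm = "integer", nTips = "integer",
                 prevalence = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@pRandom < 0 || object@pRandom > 1 ||
        object@pBrownian < 0 || object@pBrownian > 1) {
      msg <- c(msg, "p-values must lie in [0, 1]")
    }
    if (object@nPerm < 100L) msg <- c(msg, "nPerm must be >= 100")
    den <- object@meanRandom - object@meanBrownian
    if (abs(den) > 0 &&
        abs((object@sumDObs - object@meanBrownian) / den - object@D) > 1e-8) {
      msg <- c(msg, "D must satisfy the standardization identity")
    }
    if (length(msg)) msg else TRUE
  })

#' @export
setMethod("show", "PhyloDResult", function(object) {
  cat("Fritz-Purvis D for a binary trait on", object@nTips, "tips",
      sprintf("(prevalence %.3f)\n", object@prevalence))
  cat(sprintf("  sum(d) observed = %.4f; null means: random %.4f, Brownian %.4f\n",
              object@sumDObs, object@meanRandom, object@meanBrownian))
  cat(sprintf("  D = %.4f   p_random = %.4g   p_Brownian = %.4g   (%d permutations)\n",
              object@D, object@pRandom, object@pBrownian, object@nPerm))
})

#' Simple linear regression result
#'
#' Result of [olsFit()]: ordinary least squares slope and intercept, squared
#' Pearson correlation, and the two-sided t-test p-value on the slope
#' (df = n - 2). A response with zero variance is flagged `degenerate` and
#' returns slope 0, r2 0, p 1.
#'
#' @slot slope per x-unit.
#' @slot intercept y units.
#' @slot r2 coefficient of determination.
#' @slot p two-sided slope p-value.
#' @slot n number of points.
#' @slot degenerate logical; response had zero variance.
#' @aliases OLSFit
#' @exportClass OLSFit
setClass("OLSFit",
  representation(slope = "numeric", intercept = "numeric", r2 = "numeric",
                 p = "numeric", n = "integer", degenerate = "logical"),
  validity = function(object) {
    if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12) "r2 must lie in [0, 1]"
    else TRUE
  })

#' @export
setMethod("show", "OLSFit", function(object) {
  cat(sprintf("OLS: y = %.4g + %.4g x   (n = %d, r2 = %.3f, p = %.4g%s)\n",
              object@intercept, object@slope, object@n, object@r2, object@p,
              if (object@degenerate) ", degenerate" else ""))
})

# shared binary-matrix validation with coordinates in the message
checkBinaryMatrix <- function(m) {
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop(sprintf(
      "non-binary cell at row %d ('%s'), column %d ('%s'): %s",
      i, rownames(m)[i], j, colnames(m)[j], format(m[i, j])))
  }
  invisible(TRUE)
}
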