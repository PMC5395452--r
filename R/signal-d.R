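#' Sum of sister-clade differences for a binary trait
#'
#' The raw quantity the D statistic standardizes: ancestral values are
#' estimated with [estimateNodalValues()] and the absolute difference
#' between the two child values (tip values or nodal estimates) is summed
#' over all internal nodes. Phylogenetically clumped traits yield small
#' sums; overdispersed traits yield large ones.
#'
#' @param tree a binary `phylo` with branch lengths.
#' @param trait named 0/1 vector over the tips; must not be constant.
#' @return the scalar sum of sister differences.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' sumSisterDifferences(tr, c(A = 1, B = 1, C = 0, D = 0))  # clumped: 1
#' sumSisterDifferences(tr, c(A = 1, B = 0, C = 1, D = 0))  # dispersed: 2
#' @export
sumSisterDifferences <- function(tree, trait) {
  x <- alignTipValues(tree, trait)
  if (!all(x %in% c(0, 1))) stop("'trait' must be binary 0/1")
  if (length(unique(x)) < 2L) {
    stop("trait shows no variation; the sister-difference sum is trivially 0",
         call. = FALSE)
  }
  plan <- sisterPlan(tree)
  nodalPass(plan, matrix(x, ncol = 1L))$sumd
}

#' Binary trait from thresholded Brownian motion
#'
#' Simulates a Brownian trait on the tree (`sigma2 = 1`; the threshold rank
#' is scale-invariant so the rate is irrelevant) and scores the `k` tips
#' with the largest values as 1. This is the phylogenetically clumped null
#' used by [phyloD()], matched to an observed prevalence.
#'
#' @param tree a `phylo` with branch lengths.
#' @param k number of tips scored 1 (`1 <= k <= nTips - 1`).
#' @param seed integer seed.
#' @return named 0/1 vector with exactly `k` ones.
#' @examples
#' tr <- simulateTree(20, seed = 3)
#' sum(brownianThresholdTrait(tr, k = 5, seed = 1))
#' @export
brownianThresholdTrait <- function(tree, k, seed = 1L) {
  n <- length(tree$tip.label)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n - 1L) {
    stop("'k' must lie in [1, nTips - 1]")
  }
  x <- simulateBrownian(tree, sigma2 = 1, seed = seed)
  out <- as.integer(rank(-x, ties.method = "first") <= k)
  names(out) <- names(x)
  out
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Standardizes the observed sum of sister-clade differences between two
#' null expectations estimated by simulation on the same tree with the same
#' estimator:
#' `D = (sum_d_obs - mean_Brownian) / (mean_random - mean_Brownian)`,
#' where the random null shuffles the trait among tips and the Brownian
#' null thresholds simulated Brownian traits at the observed prevalence.
#' D near 1 means the trait is randomly arranged on the tree; D near 0
#' means clumping as strong as Brownian evolution produces; D > 1 is
#' overdispersion and D < 0 stronger-than-Brownian conservation.
#'
#' `p_random` is the lower tail of the permutation sums (clumping gives a
#' small sum) and `p_Brownian` the upper tail of the Brownian sums, both
#' with the `(count + 1) / (nPerm + 1)` small-sample correction. Tips absent
#' from the trait are pruned with a warning; polytomies are resolved by
#' seeded random pairing; shuffles, Brownian draws and the polytomy
#' resolution use independent sub-streams of `seed`.
#'
#' @param tree a rooted `phylo` with branch lengths; tips must cover the
#'   trait names.
#' @param trait named 0/1 vector; must not be constant.
#' @param nPerm replicates per null (>= 100).
#' @param seed integer master seed.
#' @return a [PhyloDResult].
#' @examples
#' tr <- simulateTree(60, seed = 2)
#' tipNames <- tr$tip.label
#' trait <- setNames(as.integer(seq_along(tipNames) %in% 1:15), tipNames)
#' phyloD(tr, trait, nPerm = 200, seed = 7)
#' @export
phyloD <- function(tree, trait, nPerm = 1000L, seed = 1L) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a 'phylo'")
  if (is.null(names(trait))) stop("'trait' must be named by tip label")
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) stop("'nPerm' must be >= 100")
  unknown <- setdiff(names(trait), tree$tip.label)
  if (length(unknown)) {
    stop("trait names absent from the tree: ",
         paste(head(unknown, 5L), collapse = ", "))
  }
  extra <- setdiff(tree$tip.label, names(trait))
  if (length(extra)) {
    warning("pruning ", length(extra), " tree tip(s) without trait data")
    tree <- ape::drop.tip(tree, extra)
  }
  x <- as.integer(trait[tree$tip.label])
  if (!all(x %in% c(0L, 1L))) stop("'trait' must be binary 0/1")
  k <- sum(x)
  n <- length(x)
  if (k == 0L || k == n) stop("trait shows no variation", call. = FALSE)

  seeds <- subSeeds(seed, 3L)
  tree <- resolvePolytomies(tree, seed = seeds[1L])
  plan <- sisterPlan(tree)

  obs <- nodalPass(plan, matrix(as.numeric(x), ncol = 1L))$sumd

  perm <- withSeed(seeds[2L], {
    vapply(seq_len(nPerm), function(i) sample(x), integer(n))
  })
  sumRandom <- nodalPass(plan, perm)$sumd

  bm <- simulateBrownianMatrix(tree, sigma2 = 1, seed = seeds[3L],
                               reps = nPerm)
  thr <- apply(bm, 2L, function(v) {
    as.numeric(rank(-v, ties.method = "first") <= k)
  })
  sumBrownian <- nodalPass(plan, thr)$sumd

  meanR <- mean(sumRandom)
  meanB <- mean(sumBrownian)
  if (abs(meanR - meanB) < 1e-12) {
    stop("degenerate standardization: random and Brownian null means ",
         "coincide (e.g., star tree)", call. = FALSE)
  }
  new("PhyloDResult",
      sumDObs = obs, meanRandom = meanR, meanBrownian = meanB,
      D = (obs - meanB) / (meanR - meanB),
      pRandom = (sum(sumRandom <= obs) + 1) / (nPerm + 1),
      pBrownian = (sum(sumBrownian >= obs) + 1) / (nPerm + 1),
      nPerm = nPerm, nTips = as.integer(n), prevalence = k / n,
      seed = as.integer(seed))
}
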