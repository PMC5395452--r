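#' Simulate an ultrametric family-level tree
#'
#' Pure-birth (Yule) tree with branch lengths in Myr and tips named
#' `F001, F002, ...`. The default birth rate of 0.05 per Myr gives a crown
#' depth near `ln(nTips)/0.05` Myr — roughly 120 Myr at 420 tips, the scale
#' of the angiosperm family radiation.
#'
#' @param nTips number of tips (>= 3).
#' @param seed integer seed.
#' @param birth speciation rate per Myr.
#' @return an ultrametric binary `phylo`.
#' @examples
#' tr <- simulateTree(12, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
simulateTree <- function(nTips, seed = 1L, birth = 0.05) {
  if (nTips < 3L) stop("'nTips' must be >= 3")
  if (birth <= 0) stop("'birth' must be positive")
  tr <- withSeed(seed, ape::rphylo(nTips, birth = birth, death = 0))
  tr$tip.label <- sprintf("F%03d", seq_len(nTips))
  tr
}

#' Simulate a heavy-tailed family apparency table
#'
#' Species counts per family are drawn from a rounded log-normal — the
#' empirical distribution of angiosperm family sizes is strongly
#' right-skewed, from monotypic families to tens of thousands of species —
#' floored at 0.5 like the real table's unresolved-family fill. Genus
#' counts are a tenth of the species count (floored at 0.5) and
#' distribution areas an independent log-normal in km^2 floored at the
#' 1,000 km^2 default.
#'
#' @param n number of families.
#' @param mu,sigma log-mean and log-sd of the species-count distribution
#'   (defaults: median 50 species, sd 1.8 on the log scale).
#' @param seed integer seed.
#' @param areaMu,areaSigma log-normal parameters of the area distribution.
#' @param familyNames optional family names (default `F001...`).
#' @return data.frame of family records (same shape as
#'   [readFamilyTable()]).
#' @examples
#' rec <- simulateApparency(100, seed = 1)
#' summary(rec$n_species)
#' @export
simulateApparency <- function(n, mu = log(50), sigma = 1.8, seed = 1L,
                              areaMu = log(1e7), areaSigma = 1.5,
                              familyNames = NULL) {
  if (sigma <= 0 || areaSigma <= 0) stop("'sigma' must be positive")
  if (is.null(familyNames)) familyNames <- sprintf("F%03d", seq_len(n))
  if (length(familyNames) != n) stop("'familyNames' must have length n")
  withSeed(seed, {
    sp <- pmax(0.5, round(rlnorm(n, mu, sigma)))
    data.frame(family = familyNames,
               n_species = sp,
               n_genera = pmax(0.5, round(sp / 10)),
               area_km2 = pmax(1000, rlnorm(n, areaMu, areaSigma)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate one utilization group's presence vector
#'
#' Three mechanisms mirror the structures the analysis is designed to
#' detect:
#' * `"logistic"` — presence is Bernoulli with
#'   `P(use) = logistic(a * PA + b)` (params `a`, `b`; PA is the species
#'   count), the data-generating model of the apparency fit;
#' * `"clumped"` — a Brownian trait is simulated on the tree and the top-k
#'   tips are used (param `k`), the phylogenetically conserved case;
#' * `"random"` — i.i.d. Bernoulli(`p`), no structure at all.
#'
#' @param records family table (provides PA and family names).
#' @param tree family tree (required by the clumped mechanism).
#' @param mechanism one of `"logistic"`, `"clumped"`, `"random"`.
#' @param params named list of mechanism parameters (see above).
#' @param seed integer seed.
#' @return named 0/1 vector over the families.
#' @examples
#' study <- simulateStudy(nFamilies = 50, nGroups = 2, seed = 1)
#' y <- simulateGroup(study$apparency, study$tree, "clumped",
#'                    list(k = 12), seed = 9)
#' sum(y)
#' @export
simulateGroup <- function(records, tree,
                          mechanism = c("logistic", "clumped", "random"),
                          params = list(), seed = 1L) {
  mechanism <- match.arg(mechanism)
  fams <- records$family
  n <- length(fams)
  y <- switch(mechanism,
    logistic = {
      if (is.null(params$a) || is.null(params$b)) {
        stop("logistic mechanism needs params a and b")
      }
      pr <- plogis(params$a * records$n_species + params$b)
      withSeed(seed, rbinom(n, 1L, pr))
    },
    clumped = {
      if (is.null(params$k)) stop("clumped mechanism needs param k")
      trait <- brownianThresholdTrait(tree, k = params$k, seed = seed)
      as.integer(trait[fams])
    },
    random = {
      if (is.null(params$p) || params$p <= 0 || params$p >= 1) {
        stop("random mechanism needs param p in (0, 1)")
      }
      withSeed(seed, rbinom(n, 1L, params$p))
    })
  names(y) <- fams
  y
}

#' Simulate a complete utilization study
#'
#' Generates a tree, an apparency table and a utilization matrix with the
#' statistical structure the pipeline assumes, so every stage can be
#' exercised without external data. Defaults describe the study scale the
#' analysis targets: 420 families, 44 groups, and an even split of group
#' mechanisms — logistic groups with `a = 0.0018`, `b = -2.15` (a typical
#' insect-herbivore fit), Brownian-clumped groups and unstructured random
#' groups, both at prevalence 0.13. Apparency and the tree are generated
#' independently: any apparency-phylogeny correlation in real data is an
#' empirical property, not an assumption, so the generator does not build
#' one in.
#'
#' @param nFamilies,nGroups dataset dimensions.
#' @param seed integer master seed; every component draws from an
#'   independent sub-stream.
#' @param groupModels optional data.frame with columns `group`,
#'   `mechanism` and parameter columns `a`, `b`, `k`, `p` (NA where
#'   unused); defaults to the even three-way split above.
#' @param mu,sigma species-count log-normal parameters.
#' @param birth tree birth rate per Myr.
#' @return list with `tree`, `apparency`, `utilization` (binary matrix),
#'   `groupModels`, and `seed`.
#' @examples
#' study <- simulateStudy(nFamilies = 60, nGroups = 6, seed = 11)
#' dim(study$utilization)
#' @export
simulateStudy <- function(nFamilies = 420L, nGroups = 44L, seed = 1L,
                          groupModels = NULL, mu = log(50), sigma = 1.8,
                          birth = 0.05) {
  if (nFamilies < 10L) stop("'nFamilies' must be >= 10")
  seeds <- subSeeds(seed, 3L + nGroups)
  tree <- simulateTree(nFamilies, seed = seeds[1L], birth = birth)
  records <- simulateApparency(nFamilies, mu = mu, sigma = sigma,
                               seed = seeds[2L],
                               familyNames = tree$tip.label)
  if (is.null(groupModels)) groupModels <- defaultGroupModels(nGroups, nFamilies)
  if (nrow(groupModels) != nGroups) {
    stop("'groupModels' must have one row per group")
  }
  m <- matrix(0L, nFamilies, nGroups,
              dimnames = list(records$family, groupModels$group))
  for (j in seq_len(nGroups)) {
    params <- as.list(groupModels[j, c("a", "b", "k", "p")])
    params <- params[!vapply(params, is.na, logical(1))]
    m[, j] <- simulateGroup(records, tree,
                            mechanism = groupModels$mechanism[j],
                            params = params, seed = seeds[3L + j])
  }
  list(tree = tree, apparency = records, utilization = m,
       groupModels = groupModels, seed = as.integer(seed))
}

defaultGroupModels <- function(nGroups, nFamilies) {
  mech <- rep(c("logistic", "clumped", "random"),
              c(ceiling(nGroups / 3),
                ceiling((nGroups - ceiling(nGroups / 3)) / 2),
                nGroups - ceiling(nGroups / 3) -
                  ceiling((nGroups - ceiling(nGroups / 3)) / 2)))
  data.frame(
    group = sprintf("%s_%02d", mech, seq_len(nGroups)),
    mechanism = mech,
    a = ifelse(mech == "logistic", 0.0018, NA_real_),
    b = ifelse(mech == "logistic", -2.15, NA_real_),
    k = ifelse(mech == "clumped", max(2L, round(0.13 * nFamilies)), NA_real_),
    p = ifelse(mech == "random", 0.13, NA_real_),
    stringsAsFactors = FALSE)
}

#' Write a simulated study to disk
#'
#' Writes the same formats the readers consume: a Newick tree, an apparency
#' CSV and a utilization CSV (family names in the first column), plus a
#' JSON metadata file recording the seed and group models.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return named list of file paths.
#' @examples
#' paths <- writeStudy(simulateStudy(30, 3, seed = 1), tempfile())
#' file.exists(paths$tree)
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(tree = file.path(dir, "tree.nwk"),
                apparency = file.path(dir, "apparency.csv"),
                utilization = file.path(dir, "utilization.csv"),
                metadata = file.path(dir, "simulation.json"))
  ape::write.tree(study$tree, file = paths$tree)
  write.csv(study$apparency, paths$apparency, row.names = FALSE)
  um <- data.frame(family = rownames(study$utilization),
                   study$utilization, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(um, paths$utilization, row.names = FALSE)
  jsonlite::write_json(
    list(seed = study$seed, n_families = nrow(study$utilization),
         n_groups = ncol(study$utilization),
         group_models = study$groupModels),
    paths$metadata, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths
}
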