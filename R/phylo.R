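#' Read and validate a dated family-level phylogeny
#'
#' Reads a rooted Newick tree whose tips are plant family names and whose
#' branch lengths are in Myr, and enforces the invariants the downstream
#' analyses rely on: unique non-empty tip labels, branch lengths present on
#' every edge, and no negative lengths. Internal labels are ignored.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- readNewickTree(tf)
#' length(tr$tip.label)
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  off <- newickScan(txt)
  if (!is.null(off)) {
    stop("malformed Newick in '", path, "': ", off$what,
         " at character offset ", off$offset, call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick in '", path, "': parser failed", call. = FALSE)
  }
  validateTree(tr)
  tr
}

# Cheap structural scan so parse failures can report a character offset.
newickScan <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(list(what = "unbalanced ')'", offset = i))
    }
  }
  if (depth != 0L) {
    return(list(what = sprintf("%d unclosed '('", depth),
                offset = length(chars)))
  }
  if (!any(chars == ";")) {
    return(list(what = "missing terminal ';'", offset = length(chars)))
  }
  NULL
}

validateTree <- function(tr) {
  tl <- tr$tip.label
  if (any(is.na(tl) | tl == "")) stop("empty tip label(s)", call. = FALSE)
  dup <- unique(tl[duplicated(tl)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge)) {
    stop("branch lengths missing on one or more edges", call. = FALSE)
  }
  if (anyNA(tr$edge.length)) {
    stop("branch lengths missing (NA) on one or more edges", call. = FALSE)
  }
  if (any(tr$edge.length < 0)) stop("negative branch length(s)", call. = FALSE)
  invisible(tr)
}

#' Resolve polytomies into a binary tree
#'
#' Multifurcations are resolved by seeded random pairing of child lineages
#' with inserted zero-length branches, so every internal node of the result
#' has exactly two children while all patristic (tip-to-tip) distances are
#' unchanged. A tree that is already binary is returned as-is.
#'
#' @param tree a rooted `phylo`.
#' @param seed integer seed controlling the random pairing.
#' @return a binary `phylo`.
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
#' btr <- resolvePolytomies(tr, seed = 1)
#' ape::is.binary(btr)
#' @export
resolvePolytomies <- function(tree, seed = 1L) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a 'phylo'")
  # the tree is treated as rooted as read; a multifurcating root is a
  # polytomy like any other
  if (ape::is.binary(tree)) return(tree)
  withSeed(seed, ape::multi2di(tree, random = TRUE))
}

#' Pairwise cophenetic (patristic) distances
#'
#' Sum of branch lengths along the tree path between every pair of tips,
#' in Myr. This is the PD matrix used for the minimum distance to mainland
#' families ([pdMin()]).
#'
#' @param tree a `phylo` with branch lengths.
#' @return symmetric numeric matrix with tip labels as dimnames.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' copheneticDistances(tr)
#' @export
copheneticDistances <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a 'phylo'")
  validateTree(tree)
  m <- stats::cophenetic(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Ancestral trait values by Felsenstein weighted averages
#'
#' Post-order weighted-average ancestral estimates on a binary tree: the
#' value at a node is the branch-length-weighted mean of its two (possibly
#' already-estimated) child values,
#' `(x_L/b_L' + x_R/b_R') / (1/b_L' + 1/b_R')`, where each child branch is
#' lengthened by the standard contrasts adjustment
#' `b' = b + b_L' b_R' / (b_L' + b_R')` as estimates propagate rootward.
#' Zero-length branches are replaced by 1e-9 Myr inside the weights only.
#' These nodal values are the ingredients of the sister-difference sum that
#' the D statistic standardizes.
#'
#' @param tree a binary `phylo` with branch lengths.
#' @param tipValues named numeric vector, one value per tip.
#' @return named numeric vector over all nodes: tips (by label) keep their
#'   own values, internal nodes are labeled `node<N>` in ape numbering.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' estimateNodalValues(tr, c(A = 1, B = 1, C = 0, D = 0))
#' @export
estimateNodalValues <- function(tree, tipValues) {
  plan <- sisterPlan(tree)
  x <- alignTipValues(tree, tipValues)
  res <- nodalPass(plan, matrix(x, ncol = 1L))
  v <- drop(res$values)
  names(v) <- c(tree$tip.label,
                paste0("node", seq.int(plan$nTip + 1L, plan$nTip + plan$nNode)))
  v
}

alignTipValues <- function(tree, tipValues) {
  if (is.null(names(tipValues))) stop("'tipValues' must be named by tip label")
  miss <- setdiff(tree$tip.label, names(tipValues))
  if (length(miss)) {
    stop("missing value for tip(s): ", paste(miss, collapse = ", "))
  }
  as.numeric(tipValues[tree$tip.label])
}

# Precomputed post-order traversal of a binary tree: for each internal node,
# its two children and their branch lengths, children-first order.
sisterPlan <- function(tree, eps = 1e-9) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a 'phylo'")
  if (!ape::is.binary(tree)) {
    stop("tree must be binary; use resolvePolytomies() first")
  }
  validateTree(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  e <- po$edge
  bl <- po$edge.length
  nodes <- unique(e[, 1L])                  # children-first
  kidRows <- split(seq_len(nrow(e)), e[, 1L])
  kidRows <- kidRows[as.character(nodes)]
  c1 <- vapply(kidRows, function(r) e[r[1L], 2L], integer(1))
  c2 <- vapply(kidRows, function(r) e[r[2L], 2L], integer(1))
  b1 <- vapply(kidRows, function(r) bl[r[1L]], numeric(1))
  b2 <- vapply(kidRows, function(r) bl[r[2L]], numeric(1))
  list(nTip = length(tree$tip.label), nNode = tree$Nnode,
       nodes = nodes, c1 = c1, c2 = c2, b1 = b1, b2 = b2, eps = eps)
}

# One post-order pass for a matrix of tip traits (tips x replicates).
# Returns all nodal values and, per replicate, the sum over internal nodes
# of |value(left child) - value(right child)|.
nodalPass <- function(plan, X) {
  nAll <- plan$nTip + plan$nNode
  reps <- ncol(X)
  V <- matrix(NA_real_, nAll, reps)
  V[seq_len(plan$nTip), ] <- X
  extra <- numeric(nAll)
  sumd <- numeric(reps)
  for (k in seq_along(plan$nodes)) {
    i1 <- plan$c1[k]; i2 <- plan$c2[k]
    b1 <- plan$b1[k] + extra[i1]
    b2 <- plan$b2[k] + extra[i2]
    if (b1 <= 0) b1 <- plan$eps
    if (b2 <= 0) b2 <- plan$eps
    v1 <- V[i1, ]; v2 <- V[i2, ]
    w1 <- 1 / b1; w2 <- 1 / b2
    V[plan$nodes[k], ] <- (v1 * w1 + v2 * w2) / (w1 + w2)
    extra[plan$nodes[k]] <- b1 * b2 / (b1 + b2)
    sumd <- sumd + abs(v1 - v2)
  }
  list(values = V, sumd = sumd)
}
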