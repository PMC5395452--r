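#' Simulate Brownian motion on a tree
#'
#' Simulates a continuous trait evolving by Brownian motion: the root value
#' is 0 and each node's value is its parent's value plus a
#' `Normal(0, sigma2 * branch length)` increment. Works on binary or
#' polytomous trees; deterministic given `seed`.
#'
#' @param tree a `phylo` with branch lengths (Myr).
#' @param sigma2 variance accrued per Myr of branch; must be >= 0.
#' @param seed integer seed.
#' @return named numeric vector of tip values.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):3,C:4);")
#' simulateBrownian(tr, sigma2 = 1, seed = 42)
#' @export
simulateBrownian <- function(tree, sigma2 = 1, seed = 1L) {
  drop(simulateBrownianMatrix(tree, sigma2, seed, reps = 1L))
}

# Vectorized form used by the Brownian null of the D statistic:
# simulates `reps` independent traits at once (tips x reps matrix).
simulateBrownianMatrix <- function(tree, sigma2, seed, reps) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a 'phylo'")
  validateTree(tree)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 < 0) {
    stop("'sigma2' must be a single non-negative number")
  }
  nTip <- length(tree$tip.label)
  nAll <- nTip + tree$Nnode
  cl <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  e <- cl$edge
  s <- sqrt(sigma2 * cl$edge.length)
  root <- nTip + 1L
  withSeed(seed, {
    V <- matrix(0, nAll, reps)
    for (i in seq_len(nrow(e))) {
      V[e[i, 2L], ] <- V[e[i, 1L], ] +
        if (s[i] > 0) rnorm(reps, 0, s[i]) else 0
    }
    tips <- V[seq_len(nTip), , drop = FALSE]
    rownames(tips) <- tree$tip.label
    tips
  })
}
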