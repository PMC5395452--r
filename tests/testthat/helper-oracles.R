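# Independent oracles, coded with different algorithms from the package
# internals so agreement is informative.

# Patristic distance by walking parent pointers: distance(i, j) is the sum
# of edge lengths on the two root paths minus twice the shared part.
oracleCophenetic <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  plen <- numeric(n + tree$Nnode)
  for (r in seq_len(nrow(tree$edge))) {
    parent[tree$edge[r, 2L]] <- tree$edge[r, 1L]
    plen[tree$edge[r, 2L]] <- tree$edge.length[r]
  }
  rootPath <- function(i) {
    nodes <- integer(0); lens <- numeric(0)
    while (parent[i] != 0L) {
      nodes <- c(nodes, i); lens <- c(lens, plen[i])
      i <- parent[i]
    }
    list(nodes = nodes, lens = lens)
  }
  paths <- lapply(seq_len(n), rootPath)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- intersect(paths[[i]]$nodes, paths[[j]]$nodes)
    keep_i <- !(paths[[i]]$nodes %in% shared)
    keep_j <- !(paths[[j]]$nodes %in% shared)
    d[i, j] <- sum(paths[[i]]$lens[keep_i]) + sum(paths[[j]]$lens[keep_j])
  }
  d
}

# Recursive (non-vectorized) Felsenstein nodal estimation and sister-
# difference sum, written over the tree's child list rather than a
# postorder plan.
oracleSumSisterDiff <- function(tree, trait) {
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  blen <- numeric(length(tree$tip.label) + tree$Nnode)
  blen[tree$edge[, 2L]] <- tree$edge.length
  nTip <- length(tree$tip.label)
  total <- 0
  rec <- function(node) {
    if (node <= nTip) {
      return(list(x = unname(trait[tree$tip.label[node]]),
                  b = max(blen[node], 1e-9)))
    }
    ch <- kids[[as.character(node)]]
    stopifnot(length(ch) == 2L)
    L <- rec(ch[1L]); R <- rec(ch[2L])
    total <<- total + abs(L$x - R$x)
    x <- (L$x / L$b + R$x / R$b) / (1 / L$b + 1 / R$b)
    list(x = x, b = max(blen[node], 1e-9) + L$b * R$b / (L$b + R$b))
  }
  rec(nTip + 1L)
  total
}

# Grid-search maximum-likelihood estimate of (intercept b, slope a) for the
# binomial logit model: three zoom stages over a coarse-to-fine grid.
oracleGridLogitMLE <- function(pa, y) {
  loglik <- function(b, a) {
    mu <- plogis(a * pa + b)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  bRange <- c(-10, 10)
  aRange <- c(-10, 10) / max(sd(pa), 1e-9)
  best <- c(0, 0)
  for (stage in 1:6) {
    bs <- seq(bRange[1L], bRange[2L], length.out = 61L)
    as <- seq(aRange[1L], aRange[2L], length.out = 61L)
    ll <- outer(bs, as, Vectorize(loglik))
    idx <- which(ll == max(ll), arr.ind = TRUE)[1L, ]
    best <- c(bs[idx[1L]], as[idx[2L]])
    bStep <- bs[2L] - bs[1L]; aStep <- as[2L] - as[1L]
    bRange <- best[1L] + c(-2, 2) * bStep
    aRange <- best[2L] + c(-2, 2) * aStep
  }
  c(intercept = best[1L], slope = best[2L])
}

# A small non-separated random logit dataset; regenerates deterministically
# until both classes are present and the fit is finite.
makeLogitDataset <- function(n, seed) {
  for (k in 0:50) {
    set.seed(seed * 1000L + k)
    pa <- runif(n, 0, 4)
    y <- rbinom(n, 1, plogis(0.8 * pa - 1.5))
    if (all(y == 0) || all(y == 1)) next
    fit <- tryCatch(suppressWarnings(fitBinomialLogit(pa, y)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit@converged && !fit@separated &&
        abs(fit@slope) < 8 && abs(fit@intercept) < 8) {
      return(list(pa = pa, y = y, fit = fit))
    }
  }
  stop("could not build a non-separated dataset")
}
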