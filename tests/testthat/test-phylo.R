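test_that("Newick reading validates structure and labels", {
  tf <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tf)
  tr <- readNewickTree(tf)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_length(tr$tip.label, 3L)

  writeLines("((A:1,A:1):1,C:2);", tf)
  expect_error(readNewickTree(tf), "duplicate tip labels: A")

  writeLines("((A:1,B:1:1,C:2);", tf)
  expect_error(readNewickTree(tf), "offset")

  writeLines("((A:1,B):1,C:2);", tf)
  expect_error(readNewickTree(tf), "branch lengths missing")

  expect_error(readNewickTree(file.path(tempdir(), "no-such.nwk")),
               "not found")
})

test_that("polytomy resolution is binary, seeded, and distance-preserving", {
  btr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_identical(resolvePolytomies(btr, seed = 1), btr)

  tr3 <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")
  res <- resolvePolytomies(tr3, seed = 5)
  expect_true(ape::is.binary(res))
  expect_equal(res$Nnode, tr3$Nnode + 1L)
  expect_equal(sort(res$edge.length), sort(c(tr3$edge.length, 0)))

  set.seed(99)
  poly <- ape::rtree(10)
  poly <- ape::di2multi(poly, tol = 0.3)   # force polytomies
  if (ape::is.binary(poly)) skip("no polytomy produced")
  before <- copheneticDistances(poly)
  after <- copheneticDistances(resolvePolytomies(poly, seed = 2))
  expect_equal(after[rownames(before), colnames(before)], before,
               tolerance = 1e-12)
})

test_that("cophenetic distances match hand values and a path-walk oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- copheneticDistances(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_true(all(diag(d) == 0))

  set.seed(11)
  big <- ape::rtree(50)
  d2 <- copheneticDistances(big)
  expect_equal(d2, oracleCophenetic(big)[rownames(d2), colnames(d2)],
               tolerance = 1e-10)
  expect_true(isSymmetric(d2))

  # triangle inequality on sampled triples
  set.seed(12)
  for (rep in 1:50) {
    ijk <- sample(50, 3)
    expect_lte(d2[ijk[1], ijk[2]],
               d2[ijk[1], ijk[3]] + d2[ijk[3], ijk[2]] + 1e-9)
  }

  # ultrametric tree: all tips equidistant from the root
  ultra <- simulateTree(30, seed = 4)
  depths <- ape::node.depth.edgelength(ultra)[1:30]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-8)
})

test_that("Brownian simulation is seeded and matches its covariance law", {
  tr <- ape::read.tree(text = "((A:1,B:1):3,C:4);")
  expect_identical(simulateBrownian(tr, 1, seed = 8),
                   simulateBrownian(tr, 1, seed = 8))
  expect_error(simulateBrownian(tr, -1, seed = 1), "non-negative")

  zero <- tr; zero$edge.length[] <- 0
  expect_equal(unname(simulateBrownian(zero, 1, seed = 3)), c(0, 0, 0))

  # covariance of sister tips across replicates ~= sigma2 * shared stem
  sigma2 <- 2.5
  reps <- 2000L
  X <- hostislands:::simulateBrownianMatrix(tr, sigma2, seed = 21,
                                            reps = reps)
  covAB <- cov(X["A", ], X["B", ])
  expected <- sigma2 * 3
  # var of a sample covariance of bivariate normals ~ (s11 s22 + s12^2)/n
  se <- sqrt((sigma2 * 4 * sigma2 * 4 + expected^2) / reps)
  expect_lt(abs(covAB - expected), 3 * se)
  varA <- var(X["A", ])
  seV <- sqrt(2 / (reps - 1)) * sigma2 * 4
  expect_lt(abs(varA - sigma2 * 4), 3 * seV)
})

test_that("nodal estimation: hand values, constants, linearity, zero branches", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  v <- estimateNodalValues(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(unname(v["node5"]), 0.5)   # root
  expect_equal(unname(v["node6"]), 1)     # AB ancestor
  expect_equal(unname(v["node7"]), 0)     # CD ancestor
  expect_equal(unname(v[c("A", "B", "C", "D")]), c(1, 1, 0, 0))

  const <- estimateNodalValues(tr, c(A = 3, B = 3, C = 3, D = 3))
  expect_true(all(const == 3))

  # linearity: estimates of a*x + b equal a*estimates + b
  set.seed(2)
  big <- resolvePolytomies(ape::rtree(20), seed = 1)
  x <- setNames(rnorm(20), big$tip.label)
  e1 <- estimateNodalValues(big, 2.5 * x + 1)
  e0 <- estimateNodalValues(big, x)
  expect_equal(e1, 2.5 * e0 + 1, tolerance = 1e-10)

  # zero-length cherry: epsilon guard gives the limit average at the cherry
  zc <- ape::read.tree(text = "((A:0,B:0):1,C:2);")
  vz <- estimateNodalValues(zc, c(A = 0, B = 1, C = 0))
  expect_equal(unname(vz["node5"]), 0.5, tolerance = 1e-6)   # AB ancestor
  expect_equal(unname(vz["node4"]), 1 / 3, tolerance = 1e-6) # root

  expect_error(estimateNodalValues(tr, c(A = 1, B = 1, C = 0)),
               "missing value for tip.*D")
})
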