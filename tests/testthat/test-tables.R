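writeCsv <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}

test_that("family table applies fill rules and rejects bad rows", {
  tf <- writeCsv(c("family,n_species,n_genera,area_km2",
                   "Asteraceae,25000,1600,1.2e8",
                   "Xfam,,,"))
  rec <- readFamilyTable(tf)
  expect_equal(rec$n_species, c(25000, 0.5))
  expect_equal(rec$n_genera, c(1600, 0.5))
  expect_equal(rec$area_km2, c(1.2e8, 1000))
  rep <- attr(rec, "loadReport")
  expect_equal(rep$species_filled, 1L)
  expect_equal(rep$area_defaulted, 1L)

  # zero counts are treated like missing; small areas floored
  tf2 <- writeCsv(c("family,n_species,n_genera,area_km2",
                    "Afam,0,0,500"))
  rec2 <- readFamilyTable(tf2)
  expect_equal(rec2$n_species, 0.5)
  expect_equal(rec2$area_km2, 1000)
  expect_equal(attr(rec2, "loadReport")$area_floored, 1L)

  dup <- writeCsv(c("family,n_species,n_genera,area_km2",
                    "Afam,1,1,2000", "Afam,2,2,3000"))
  expect_error(readFamilyTable(dup), "duplicate: Afam")

  neg <- writeCsv(c("family,n_species,n_genera,area_km2",
                    "Afam,-3,1,2000"))
  expect_error(readFamilyTable(neg), "negative")
})

test_that("utilization matrix filters narrow groups at the inclusive boundary", {
  fams <- sprintf("F%02d", 1:20)
  g9 <- as.integer(1:20 <= 9)
  g10 <- as.integer(1:20 <= 10)
  lines <- c(paste("family", "g9", "g10", sep = ","),
             paste(fams, g9, g10, sep = ","))
  tf <- writeCsv(lines)
  expect_warning(m <- readUtilizationMatrix(tf), "g9")
  expect_equal(colnames(m), "g10")
  expect_equal(attr(m, "droppedGroups"), "g9")
  expect_equal(unname(colSums(m)), 10)

  bad <- c(paste("family", "g1", sep = ","),
           paste(fams, ifelse(1:20 == 7, 2, 1), sep = ","))
  expect_error(readUtilizationMatrix(writeCsv(bad)),
               "row 7 \\('F07'\\), column 1 \\('g1'\\): 2")
})

test_that("utilizer ratio uses the matrix's own denominator", {
  m <- matrix(0L, 5, 44, dimnames = list(paste0("F", 1:5), paste0("g", 1:44)))
  m[1, 1:22] <- 1L
  m[2, 1:11] <- 1L
  ur <- utilizerRatio(m)
  expect_equal(unname(ur), c(0.5, 0.25, 0, 0, 0))

  # integer identity: sum(UR) * nGroups == total count of 1s
  set.seed(3)
  m2 <- matrix(rbinom(300, 1, 0.3), 20, 15,
               dimnames = list(paste0("F", 1:20), paste0("g", 1:15)))
  expect_equal(sum(utilizerRatio(m2)) * ncol(m2), sum(m2))
})

test_that("mainland selection takes the top decile and includes boundary ties", {
  rec <- data.frame(family = sprintf("F%03d", 1:420),
                    n_species = 421 - (1:420), n_genera = 1,
                    area_km2 = 1e6)
  ml <- selectMainland(rec, "species")
  expect_length(ml, 42L)           # ceil(0.1 * 420), all values distinct
  expect_setequal(ml, sprintf("F%03d", 1:42))

  # tie at the boundary pulls in the tied family -> 43
  rec$n_species[43] <- rec$n_species[42]
  expect_length(selectMainland(rec, "species"), 43L)

  rec10 <- data.frame(family = paste0("F", 1:10), n_species = 10:1,
                      n_genera = 1, area_km2 = 1e6)
  expect_equal(selectMainland(rec10, "species"), "F1")

  # excluded families are strictly smaller than the boundary value
  set.seed(5)
  recR <- data.frame(family = paste0("F", 1:57),
                     n_species = sample(1:30, 57, replace = TRUE),
                     n_genera = 1, area_km2 = 1e6)
  ml <- selectMainland(recR, "species")
  expect_gte(length(ml), ceiling(0.1 * 57))
  cutV <- min(recR$n_species[recR$family %in% ml])
  expect_true(all(recR$n_species[!recR$family %in% ml] < cutV))
})

test_that("PD_min is the minimum patristic distance to the mainland", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  dm <- copheneticDistances(tr)
  pm <- pdMin(dm, mainland = "C")
  expect_equal(unname(pm[c("A", "B", "C")]), c(4, 4, 0))
  expect_equal(unname(pdMin(dm, c("A", "C"))["B"]), 2)

  expect_error(pdMin(dm, character(0)), "empty")
  expect_error(pdMin(dm, "Z"), "absent")

  # bound: PD_min(f) <= d(f, m) for every mainland m
  set.seed(8)
  big <- ape::rtree(25)
  dmB <- copheneticDistances(big)
  ml <- sample(rownames(dmB), 5)
  pmB <- pdMin(dmB, ml)
  for (m in ml) expect_true(all(pmB <= dmB[, m] + 1e-12))

  # excludeSelf measures mainland members to the other mainland families
  pmX <- pdMin(dm, c("A", "C"), excludeSelf = TRUE)
  expect_equal(unname(pmX["A"]), 4)
})
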