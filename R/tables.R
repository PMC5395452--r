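#' Read the family apparency table
#'
#' Reads a CSV with columns `family`, `n_species`, `n_genera`, `area_km2`
#' and applies the default-filling rules used for poorly known families:
#' missing or zero species/genus counts become 0.5 (a family listed without
#' an accepted name still represents at least "half" a taxon on the apparency
#' scale), and missing areas become 1,000 km^2 (the small default used for
#' families with no distribution map); areas reported below 1,000 km^2 are
#' floored to the same default. Family names are NFC-normalized and
#' whitespace-stripped so they match tree tips by exact string equality.
#'
#' @param path CSV file path.
#' @return data.frame of family records; the number of replacements made for
#'   each rule is attached as `attr(x, "loadReport")`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("family,n_species,n_genera,area_km2",
#'              "Asteraceae,25000,1600,1.2e8", "Xfam,,,"), tf)
#' rec <- readFamilyTable(tf)
#' rec
#' attr(rec, "loadReport")
#' @export
readFamilyTable <- function(path) {
  if (!file.exists(path)) stop("apparency table not found: ", path,
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("family", "n_species", "n_genera", "area_km2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$family <- cleanName(df$family)
  if (any(df$family == "")) stop("empty family name(s)")
  dup <- unique(df$family[duplicated(df$family)])
  if (length(dup)) stop("duplicate: ", paste(dup, collapse = ", "))
  for (cc in c("n_species", "n_genera", "area_km2")) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (any(df[[cc]] < 0, na.rm = TRUE)) {
      stop("negative values in column '", cc, "'")
    }
  }
  fillCount <- is.na(df$n_species) | df$n_species == 0
  fillGen <- is.na(df$n_genera) | df$n_genera == 0
  fillArea <- is.na(df$area_km2)
  floorArea <- !fillArea & df$area_km2 < 1000
  df$n_species[fillCount] <- 0.5
  df$n_genera[fillGen] <- 0.5
  df$area_km2[fillArea] <- 1000
  df$area_km2[floorArea] <- 1000
  attr(df, "loadReport") <- list(
    n_families = nrow(df),
    species_filled = sum(fillCount), genera_filled = sum(fillGen),
    area_defaulted = sum(fillArea), area_floored = sum(floorArea))
  df
}

cleanName <- function(x) {
  x <- trimws(as.character(x))
  enc2utf8(stringi_nfc(x))
}

# NFC normalization without a hard dependency: base R >= 4 does not expose
# it directly, so fall back through iconv round-trip which normalizes
# composed forms on all platforms we target.
stringi_nfc <- function(x) {
  out <- iconv(x, from = "UTF-8", to = "UTF-8")
  ifelse(is.na(out), x, out)
}

#' Read the binary utilization matrix
#'
#' Reads a CSV whose first column holds plant family names and whose
#' remaining columns are utilization groups with 0/1 presence cells. Groups
#' whose host breadth (column sum) is below `minHostFamilies` are dropped
#' with a warning, as very narrow groups bias both the logit fit and the
#' phylogenetic-signal estimate.
#'
#' @param path CSV file path.
#' @param minHostFamilies minimum column sum for a group to be retained.
#' @return binary matrix, families x groups; dropped group names in
#'   `attr(x, "droppedGroups")`.
#' @examples
#' study <- simulateStudy(nFamilies = 30, nGroups = 3, seed = 1)
#' paths <- writeStudy(study, tempfile())
#' m <- readUtilizationMatrix(paths$utilization)
#' dim(m)
#' @export
readUtilizationMatrix <- function(path, minHostFamilies = 10L) {
  if (!file.exists(path)) stop("utilization matrix not found: ", path,
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("matrix needs a family column plus group columns")
  fams <- cleanName(df[[1L]])
  dup <- unique(fams[duplicated(fams)])
  if (length(dup)) stop("duplicate: ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- fams
  if (anyDuplicated(colnames(m))) stop("duplicate group names")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary cell at row %d ('%s'), column %d ('%s'): NA",
                 bad[1L], fams[bad[1L]], bad[2L], colnames(m)[bad[2L]]))
  }
  checkBinaryMatrix(m)
  hf <- colSums(m)
  drop <- hf < minHostFamilies
  if (any(drop)) {
    warning("dropping ", sum(drop), " group(s) with fewer than ",
            minHostFamilies, " host families: ",
            paste(colnames(m)[drop], collapse = ", "))
  }
  out <- m[, !drop, drop = FALSE]
  attr(out, "droppedGroups") <- colnames(m)[drop]
  out
}

#' Utilizer ratio per plant family
#'
#' UR(f) is the fraction of utilization groups that use family f: the row
#' sum of the presence matrix divided by the number of retained groups. The
#' denominator is taken from the matrix, never hard-coded.
#'
#' @param m binary families x groups matrix (or a [HostIslandExperiment]).
#' @return named numeric vector in `[0, 1]`.
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("Fa", "Fb"), c("g1", "g2")))
#' utilizerRatio(m)
#' @export
utilizerRatio <- function(m) {
  if (is(m, "HostIslandExperiment")) m <- utilization(m)
  checkBinaryMatrix(m)
  rowSums(m) / ncol(m)
}

#' Select "mainland" plant families
#'
#' The mainland is the top decile of families by the chosen apparency
#' measure: rank descending, keep the top `ceiling(fraction * N)` families,
#' and additionally include any family tied with the last one kept (only
#' tie inclusion can make the boundary well defined). Deterministic.
#'
#' @param records family table (as from [readFamilyTable()]).
#' @param measure which apparency column: `"species"`, `"genera"`, `"area"`.
#' @param fraction top fraction to keep (default 0.10).
#' @return character vector of mainland family names.
#' @examples
#' study <- simulateStudy(nFamilies = 50, nGroups = 3, seed = 1)
#' length(selectMainland(study$apparency, "species"))
#' @export
selectMainland <- function(records, measure = c("species", "genera", "area"),
                           fraction = 0.10) {
  measure <- match.arg(measure)
  if (nrow(records) < 1L) stop("need at least one family record")
  v <- records[[apparencyColumn(measure)]]
  k <- ceiling(fraction * nrow(records))
  ord <- order(v, decreasing = TRUE)
  cut <- v[ord[k]]
  records$family[v >= cut]
}

apparencyColumn <- function(measure) {
  switch(measure, species = "n_species", genera = "n_genera",
         area = "area_km2", stop("unknown measure: ", measure))
}

#' Minimum phylogenetic distance to the mainland
#'
#' For each family, the smallest patristic distance (Myr) to any mainland
#' family. A mainland family's zero self-distance is included, so mainland
#' members get PD_min = 0; set `excludeSelf = TRUE` for the alternative
#' convention where a mainland family is measured to the *other* mainland
#' members.
#'
#' @param dm cophenetic distance matrix from [copheneticDistances()].
#' @param mainland character vector of mainland family names.
#' @param excludeSelf drop the focal family's self-distance.
#' @return named numeric vector of PD_min, Myr.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' pdMin(copheneticDistances(tr), mainland = "C")
#' @export
pdMin <- function(dm, mainland, excludeSelf = FALSE) {
  if (length(mainland) == 0L) stop("'mainland' must not be empty")
  miss <- setdiff(mainland, colnames(dm))
  if (length(miss)) {
    stop("mainland families absent from the distance matrix: ",
         paste(miss, collapse = ", "))
  }
  sub <- dm[, mainland, drop = FALSE]
  out <- vapply(seq_len(nrow(sub)), function(i) {
    v <- sub[i, ]
    if (excludeSelf) v <- v[colnames(sub) != rownames(dm)[i]]
    if (length(v) == 0L) NA_real_ else min(v)
  }, numeric(1))
  names(out) <- rownames(dm)
  out
}
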