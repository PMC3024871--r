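# Text formats: PED-style genotypes, 3-column marker map, HLA TSV, YAML
# run configuration.
#
# The genotype file is a whitespace PED table: family, individual, father,
# mother, sex, then two allele columns per marker with alleles coded 1
# (reference) / 2 (alternate) and 0 for missing; '0' parent ids denote
# founders. Internally alleles are 0/1 and genotypes are minor-allele
# dosages. HLA allele names are stored as bare digit strings ("0201");
# a gene prefix and separators ("HLA-A*02:01") are stripped on input.

#' Truncate an HLA allele name to a digit resolution
#'
#' HLA allele names are hierarchical digit sets; the first two digits give
#' the allele group and the first four the protein subtype. Unknown
#' alleles stay unknown; names shorter than the requested resolution are
#' not resolvable at it and map to `NA`.
#'
#' @param name character vector of bare digit-string allele names
#'   (`NA` or `"-"` for unknown).
#' @param resolution 2 or 4 digits.
#' @return character vector of truncated names (vectorised).
#' @export
#' @examples
#' truncateAllele("0201", 2)  # "02"
#' truncateAllele("2401", 4)  # "2401"
truncateAllele <- function(name, resolution = 4L) {
  resolution <- as.integer(resolution)
  if (!resolution %in% c(2L, 4L)) stop("resolution must be 2 or 4")
  out <- as.character(name)
  unk <- is.na(out) | out == UNKNOWN_ALLELE
  short <- !unk & nchar(out) < resolution
  out[short] <- NA_character_  # not resolved at this level
  out[!unk & !short] <- substr(out[!unk & !short], 1L, resolution)
  out[is.na(name)] <- NA_character_
  out[!is.na(name) & name == UNKNOWN_ALLELE] <- UNKNOWN_ALLELE
  out
}

# Internal: normalise an allele name from disk: strip gene prefix and
# separators, keep the digits; "-" / "" -> NA.
.parseAllele <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c(UNKNOWN_ALLELE, "–", "", "NA")] <- NA_character_
  known <- !is.na(x)
  x[known] <- gsub("^[A-Za-z]+-?[A-Za-z0-9]*\\*", "", x[known])
  x[known] <- gsub("[^0-9]", "", x[known])
  bad <- known & x == ""
  if (any(bad)) stop("malformed HLA allele name")
  x
}

#' Read a pedigree population from PED-style text files
#'
#' @param pedFile whitespace PED genotype file (see the format note above).
#' @param mapFile 3-column whitespace file: marker id, chromosome,
#'   base-pair position.
#' @param hlaFile tab- or whitespace-separated table: individual id,
#'   allele 1, allele 2, with `-` for unknown. Optional.
#' @return An [HlaPopulation-class].
#' @export
#' @examples
#' d <- system.file("extdata", package = "pedhla")
#' pop <- readPopulation(file.path(d, "worked.ped"),
#'                       file.path(d, "worked.map"),
#'                       file.path(d, "worked.hla"))
#' pop
readPopulation <- function(pedFile, mapFile, hlaFile = NULL) {
  map <- utils::read.table(mapFile, header = FALSE,
                           col.names = c("marker", "chrom", "pos"),
                           stringsAsFactors = FALSE)
  m <- nrow(map)
  raw <- utils::read.table(pedFile, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) != 5L + 2L * m)
    stop(sprintf("PED file has %d columns; expected %d (5 + 2 x %d markers)",
                 ncol(raw), 5L + 2L * m, m))
  ped <- data.frame(family = raw[[1L]], id = raw[[2L]],
                    father = raw[[3L]], mother = raw[[4L]],
                    sex = suppressWarnings(as.integer(raw[[5L]])),
                    stringsAsFactors = FALSE)
  ped$father[ped$father == "0"] <- NA_character_
  ped$mother[ped$mother == "0"] <- NA_character_
  al <- as.matrix(raw[, -(1:5), drop = FALSE])
  suppressWarnings(storage.mode(al) <- "integer")
  if (anyNA(al) || !all(al %in% 0:2)) {
    bad <- which(apply(al, 1L, function(r) anyNA(r) || !all(r %in% 0:2)))[1L]
    stop(sprintf("malformed allele code in PED line %d (alleles must be 0, 1 or 2)",
                 bad))
  }
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  miss <- a1 == 0L | a2 == 0L
  g <- (a1 - 1L) + (a2 - 1L)
  g[miss] <- NA_integer_
  rownames(g) <- ped$id
  hla <- NULL
  if (!is.null(hlaFile)) {
    ht <- utils::read.table(hlaFile, header = FALSE,
                            col.names = c("id", "allele1", "allele2"),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    hla <- data.frame(id = ht$id,
                      allele1 = .parseAllele(ht$allele1),
                      allele2 = .parseAllele(ht$allele2),
                      stringsAsFactors = FALSE)
  }
  HlaPopulation(ped, g, map, hla)
}

#' Write a pedigree population to PED-style text files
#'
#' Inverse of [readPopulation]; a write-then-read round trip reproduces
#' the population exactly.
#'
#' @param pop an [HlaPopulation-class].
#' @param pedFile,mapFile,hlaFile output paths (`hlaFile` optional).
#' @return invisibly, the paths written.
#' @export
writePopulation <- function(pop, pedFile, mapFile, hlaFile = NULL) {
  map <- pop@map
  utils::write.table(map, mapFile, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  ped <- pop@pedigree
  g <- pop@genotypes
  m <- ncol(g)
  al <- matrix("0", nrow = nrow(g), ncol = 2L * m)
  for (l in seq_len(m)) {
    dos <- g[, l]
    a1 <- ifelse(is.na(dos), 0L, ifelse(dos >= 1L, 2L, 1L))
    a2 <- ifelse(is.na(dos), 0L, ifelse(dos == 2L, 2L, 1L))
    # het coded 1/2: put the alternate allele second
    a1[!is.na(dos) & dos == 1L] <- 1L
    a2[!is.na(dos) & dos == 1L] <- 2L
    al[, 2L * l - 1L] <- a1
    al[, 2L * l] <- a2
  }
  out <- cbind(ped$family, ped$id,
               ifelse(is.na(ped$father), "0", ped$father),
               ifelse(is.na(ped$mother), "0", ped$mother),
               ifelse(is.na(ped$sex), "0", as.character(ped$sex)), al)
  utils::write.table(out, pedFile, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  if (!is.null(hlaFile)) {
    h <- pop@hla
    hh <- data.frame(id = h$id,
                     allele1 = ifelse(is.na(h$allele1), UNKNOWN_ALLELE, h$allele1),
                     allele2 = ifelse(is.na(h$allele2), UNKNOWN_ALLELE, h$allele2))
    utils::write.table(hh, hlaFile, quote = FALSE, row.names = FALSE,
                       col.names = FALSE, sep = "\t")
  }
  invisible(c(pedFile, mapFile, hlaFile))
}

#' Select markers inside a window around a position
#'
#' All markers whose position lies in
#' `[center - window/2, center + window/2]`, inclusive at both ends, in
#' map order. A 200kb window spans 100kb upstream and downstream of the
#' gene center.
#'
#' @param map marker map (`marker`, `chrom`, `pos`).
#' @param centerBp window center in base pairs.
#' @param windowKb total window size in kilobases.
#' @return integer vector of marker indices (warns when empty).
#' @export
windowMarkers <- function(map, centerBp, windowKb) {
  stopifnot(windowKb > 0)
  half <- windowKb * 1000 / 2
  idx <- which(map$pos >= centerBp - half & map$pos <= centerBp + half)
  if (!length(idx)) warning("no markers fall inside the window")
  idx
}

#' Blank Mendelian-inconsistent markers per pedigree
#'
#' For every pedigree and marker, checks that each child's genotype is
#' composable from its parents' (dosage-level Mendelian consistency,
#' missing entries unconstrained). An inconsistent marker has that
#' pedigree's genotypes set to missing -- the least destructive repair,
#' applied before phasing.
#'
#' @param pop an [HlaPopulation-class].
#' @return list: `pop` (cleaned population) and `flagged` (data.frame
#'   `family`, `marker` of the blanked entries).
#' @export
cleanMendelianErrors <- function(pop) {
  ped <- pop@pedigree
  g <- pop@genotypes
  flagged <- data.frame(family = character(0), marker = character(0))
  alleleSet <- function(d) {
    if (is.na(d)) return(0:1)
    switch(as.character(d), "0" = 0L, "1" = 0:1, "2" = 1L)
  }
  for (fam in unique(ped$family)) {
    rows <- which(ped$family == fam)
    kids <- rows[!is.na(ped$father[rows])]
    if (!length(kids)) next
    for (l in seq_len(ncol(g))) {
      ok <- TRUE
      for (k in kids) {
        gc <- g[k, l]
        if (is.na(gc)) next
        fa <- match(ped$father[k], ped$id)
        mo <- match(ped$mother[k], ped$id)
        Af <- alleleSet(g[fa, l]); Am <- alleleSet(g[mo, l])
        if (!any(outer(Af, Am, "+") == gc)) { ok <- FALSE; break }
      }
      if (!ok) {
        g[rows, l] <- NA_integer_
        flagged <- rbind(flagged,
                         data.frame(family = fam,
                                    marker = colnames(g)[l] %||% as.character(l)))
      }
    }
  }
  pop@genotypes <- g
  list(pop = pop, flagged = flagged)
}

#' Read a run configuration from YAML
#'
#' Recognised keys: `gene`, `center_bp`, `window_kb`, `t_mis`, `t_s`,
#' `resolution`, and a `ga` block (`ps`, `gm`, `rc`, `rm`, `tc`, `seed`).
#' Missing keys take the package defaults.
#'
#' @param path YAML file path.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ga <- y$ga %||% list()
  RunConfig(gene = y$gene %||% "HLA",
            centerBp = y$center_bp %||% 31500000,
            windowKb = y$window_kb %||% 200,
            tMis = y$t_mis %||% 2L,
            tS = y$t_s %||% 0.65,
            resolution = y$resolution %||% 4L,
            ga = GAParams(ps = ga$ps %||% 400L, gm = ga$gm %||% 50L,
                          rc = ga$rc %||% 0.8, rm = ga$rm %||% 0.2,
                          tc = ga$tc %||% 10L, seed = ga$seed %||% 1L))
}
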