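## Readers and writers for the tabular interchange formats: genotype TSV /
## VCF, phenotype, landmark, climate and local-ancestry tables, kinship
## matrices, and ASCII OBJ/PLY meshes with JSON region masks.

stopMissingCols <- function(d, need, what) {
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop(what, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF: biallelic records only (multi-allelic records are skipped and
#' counted); the GT field is parsed to an alternate-allele dosage, missing
#' genotypes to NA. A population map (TSV with columns \code{id},
#' \code{population}) supplies the labels. TSV dialect: first column
#' \code{id}, second column \code{population}, remaining columns one SNP
#' each with entries 0/1/2/NA (the format written by [writeGenotypes()]).
#'
#' @param path input file
#' @param format \code{"auto"} (by extension), \code{"vcf"} or \code{"tsv"}
#' @param populationMap path to an id/population TSV, or a named character
#'   vector; required for VCF input
#' @return a \linkS4class{GenotypeMatrix}
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv"),
                          populationMap = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    bi <- vcfR::is.biallelic(v)
    nSkipped <- sum(!bi)
    if (nSkipped > 0) {
      message(nSkipped, " multi-allelic record(s) skipped")
      v <- v[bi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    countAlt <- function(g) {
      ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
             vapply(strsplit(g, "[/|]"), function(a)
               sum(a == "1"), numeric(1)))
    }
    dos <- apply(gt, 2, countAlt)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt))
    dimnames(dos) <- dimnames(gt)
    if (is.null(populationMap))
      stop("VCF input requires a population map")
    popMap <- if (is.character(populationMap) &&
                  length(populationMap) == 1 && file.exists(populationMap)) {
      pm <- read.delim(populationMap, stringsAsFactors = FALSE)
      stopMissingCols(pm, c("id", "population"), "population map")
      setNames(pm$population, pm$id)
    } else populationMap
    if (!all(colnames(dos) %in% names(popMap)))
      stop("population map misses individual(s): ",
           paste(head(setdiff(colnames(dos), names(popMap)), 5),
                 collapse = ", "))
    return(GenotypeMatrix(dos, population = popMap[colnames(dos)]))
  }
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
  stopMissingCols(d, c("id", "population"), "genotype TSV")
  snpCols <- setdiff(names(d), c("id", "population"))
  if (!length(snpCols)) stop("genotype TSV has no SNP columns")
  dos <- t(as.matrix(d[, snpCols, drop = FALSE]))
  colnames(dos) <- d$id
  GenotypeMatrix(dos, population = d$population)
}

#' Write genotypes as a dosage TSV
#'
#' One row per individual: \code{id}, \code{population}, then one 0/1/2/NA
#' column per SNP. Read back with [readGenotypes()] (round-trip identity).
#'
#' @param genos a \linkS4class{GenotypeMatrix}
#' @param path output file
#' @export
writeGenotypes <- function(genos, path) {
  stopifnot(is(genos, "GenotypeMatrix"))
  d <- dosage(genos)
  out <- data.frame(id = colnames(d), population = population(genos),
                    t(d), check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with mandatory \code{id} and \code{population} columns; remaining
#' columns are covariates and traits. Lines starting with \code{#} are
#' treated as unit/comment headers.
#'
#' @param path input TSV
#' @export
readPhenotypes <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopMissingCols(d, c("id", "population"), "phenotype table")
  d
}

#' Read a long-format landmark table
#'
#' Mandatory columns \code{id}, \code{landmark}, \code{x}, \code{y},
#' \code{z} (mm); \code{observer} and \code{replicate} default to a single
#' placement when absent. Placements missing any of the seven nose
#' landmarks are excluded with a message naming the count.
#'
#' @param path input TSV
#' @export
readLandmarks <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopMissingCols(d, c("id", "landmark", "x", "y", "z"), "landmark table")
  if (!"observer" %in% names(d)) d$observer <- "obs1"
  if (!"replicate" %in% names(d)) d$replicate <- 1L
  key <- interaction(d$id, d$observer, d$replicate, drop = TRUE)
  complete <- vapply(split(d$landmark, key), function(l)
    all(requiredLandmarks %in% l), logical(1))
  if (any(!complete)) {
    message(sum(!complete),
            " placement(s) excluded for missing landmarks")
    d <- d[complete[key], , drop = FALSE]
  }
  if (!nrow(d)) stop("no complete landmark placements")
  d
}

#' Read a per-individual climate table
#'
#' Mandatory \code{id} plus at least one climate column; relative and
#' absolute humidity are derived (via the Magnus and ideal-gas forms) when
#' temperature and vapor pressure are present but the humidity columns are
#' not.
#'
#' @param path input TSV
#' @export
readClimate <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopMissingCols(d, "id", "climate table")
  if (ncol(d) < 2) stop("climate table has no climate columns")
  if (all(c("temperature", "vapor_pressure") %in% names(d))) {
    if (!"relative_humidity" %in% names(d))
      d$relative_humidity <- relativeHumidity(d$vapor_pressure,
                                              d$temperature)
    if (!"absolute_humidity" %in% names(d))
      d$absolute_humidity <- absoluteHumidity(d$vapor_pressure,
                                              d$temperature)
  }
  d
}

#' Read a local-ancestry dosage TSV
#'
#' Same dialect as the genotype TSV minus the population column: first
#' column \code{id}, one 0/1/2 column per SNP.
#'
#' @param path input TSV
#' @export
readLocalAncestry <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
  stopMissingCols(d, "id", "local-ancestry table")
  snpCols <- setdiff(names(d), c("id", "population"))
  a <- t(as.matrix(d[, snpCols, drop = FALSE]))
  colnames(a) <- d$id
  LocalAncestryMatrix(a)
}

#' Write / read a kinship matrix TSV
#'
#' Square tab-separated matrix with individual ids as both header and first
#' column.
#'
#' @param K a \linkS4class{KinshipMatrix}
#' @param path file path
#' @export
writeKinship <- function(K, path) {
  stopifnot(is(K, "KinshipMatrix"))
  m <- kinship(K)
  out <- data.frame(id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKinship
#' @param source provenance tag recorded on the read matrix
#' @export
readKinship <- function(path, source = "external") {
  d <- read.delim(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  KinshipMatrix(m, source = source)
}

#' Report unmatched ids between two tables
#'
#' Inner-joins on \code{id} and warns, listing the ids present in one table
#' but not the other.
#'
#' @param x,y data.frames with an \code{id} column
#' @return merged data.frame
#' @export
joinById <- function(x, y) {
  un <- c(setdiff(x$id, y$id), setdiff(y$id, x$id))
  if (length(un))
    warning(length(un), " unmatched id(s): ",
            paste(head(un, 10), collapse = ", "),
            if (length(un) > 10) ", ..." else "")
  merge(x, y, by = "id", sort = FALSE)
}

## ---------------------------------------------------------------------------
## Meshes
## ---------------------------------------------------------------------------

#' Read a triangulated mesh from ASCII OBJ or PLY
#'
#' Minimal readers for the two interchange formats: OBJ \code{v}/\code{f}
#' records (polygon face indices may carry texture/normal slashes; faces
#' are 1-based) and ASCII PLY (vertex x/y/z properties and triangular
#' faces, 0-based).
#'
#' @param path mesh file ending in .obj or .ply
#' @return list with \code{vertices} (V x 3) and \code{faces}
#'   (F x 3, 1-based)
#' @export
readMesh <- function(path) {
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    vs <- lines[startsWith(lines, "v ")]
    fs <- lines[startsWith(lines, "f ")]
    vertices <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vs)),
                                               "\\s+"), function(t)
      as.numeric(t[1:3])))
    faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fs)),
                                            "\\s+"), function(t) {
      idx <- as.integer(vapply(strsplit(t, "/"), `[`, "", 1))
      if (length(idx) != 3) stop("non-triangular OBJ face")
      idx
    }))
  } else if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    if (!grepl("ascii", lines[2])) stop("only ASCII PLY is supported")
    nV <- as.integer(sub(".*vertex ", "",
                         grep("element vertex", lines, value = TRUE)[1]))
    nF <- as.integer(sub(".*face ", "",
                         grep("element face", lines, value = TRUE)[1]))
    body <- which(lines == "end_header") + 1L
    vertices <- do.call(rbind, lapply(
      strsplit(trimws(lines[body:(body + nV - 1)]), "\\s+"),
      function(t) as.numeric(t[1:3])))
    faces <- do.call(rbind, lapply(
      strsplit(trimws(lines[(body + nV):(body + nV + nF - 1)]), "\\s+"),
      function(t) {
        t <- as.integer(t)
        if (t[1] != 3) stop("non-triangular PLY face")
        t[2:4] + 1L
      }))
  } else stop("unsupported mesh format (need .obj or .ply)")
  if (max(faces) > nrow(vertices)) stop("face index out of range")
  list(vertices = vertices, faces = faces)
}

#' Read JSON region masks for a mesh
#'
#' JSON object mapping region names to arrays of 0-based vertex indices
#' (converted to 1-based on read).
#'
#' @param path JSON file
#' @export
readRegionMasks <- function(path) {
  masks <- jsonlite::fromJSON(path)
  lapply(masks, function(ix) as.integer(ix) + 1L)
}
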