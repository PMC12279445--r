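#' Write a GenotypeTable as VCF 4.2
#'
#' Emits every site of the table -- variant and invariant -- with per-genotype
#' `GT:DP:RQ` fields (`DP`/`RQ` are written as `.` when the table carries no
#' depth/quality annotations) and one `##contig` header line per contig.
#' Invariant sites are written with `ALT = .` and all-reference genotypes, as
#' produced by all-sites joint genotyping.
#'
#' @param gt A [GenotypeTable-class].
#' @param path Output file path (plain text; use a `.vcf` extension).
#' @return `path`, invisibly.
#' @seealso [readGenotypeVcf()] for the inverse operation.
#' @export
writeGenotypeVcf <- function(gt, path) {
  if (nSites(gt) == 0L) stop("refusing to write an empty genotype table")
  con <- file(path, open = "wt")
  on.exit(close(con))
  contigs <- unique(gt@chrom)
  lens <- vapply(split(gt@pos, gt@chrom)[contigs], max, integer(1))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=divscan",
    sprintf("##contig=<ID=%s,length=%d>", contigs, lens),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=RQ,Number=1,Type=Integer,Description=\"Phred-scaled genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt@samples), collapse = "\t")
  ), con)
  gtStr <- matrix("./.", nSites(gt), length(gt@samples))
  d <- gt@dosage
  gtStr[!is.na(d) & d == 0L] <- "0/0"
  gtStr[!is.na(d) & d == 1L] <- "0/1"
  gtStr[!is.na(d) & d == 2L] <- "1/1"
  dp <- if (is.null(gt@depth)) matrix(".", nrow(d), ncol(d)) else gt@depth
  rq <- if (is.null(gt@qual)) matrix(".", nrow(d), ncol(d)) else gt@qual
  cells <- matrix(paste(gtStr, dp, rq, sep = ":"), nrow(d), ncol(d))
  sampleField <- do.call(paste, c(split(cells, col(cells)), list(sep = "\t")))
  lines <- paste(gt@chrom, gt@pos, ".", gt@ref, gt@alt, ".", ".", ".",
                 "GT:DP:RQ", sampleField, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write / read a sample-to-population map
#'
#' Two-column tab-separated text: sample id, population label. No header.
#'
#' @param populations Named character vector (names = samples, values =
#'   population labels), e.g. from [populationOf()].
#' @param path File path.
#' @return `writePopmap` returns `path` invisibly; `readPopmap` returns a
#'   named character vector.
#' @export
writePopmap <- function(populations, path) {
  keep <- !is.na(populations)
  write.table(data.frame(names(populations)[keep], unname(populations)[keep]),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writePopmap
#' @export
readPopmap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("sample", "population"),
                   colClasses = "character")
  if (anyDuplicated(df$sample))
    stop("popmap lists samples more than once: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  stats::setNames(df$population, df$sample)
}

#' Write / read a target-region manifest
#'
#' BED-like tab-separated text with columns `region_id`, `chrom`, `start`,
#' `end` (0-based half-open), `genic` (0/1) and `frame` (0/1/2 or `.`).
#'
#' @param regions Region manifest data.frame.
#' @param path File path.
#' @return `writeRegions` returns `path` invisibly; `readRegions` a
#'   validated data.frame.
#' @export
writeRegions <- function(regions, path) {
  validateRegions(regions)
  write.table(regions[, c("region_id", "chrom", "start", "end", "genic", "frame")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeRegions
#' @export
readRegions <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("region_id", "chrom", "start", "end",
                                 "genic", "frame"),
                   colClasses = c("character", "character", "integer",
                                  "integer", "integer", "character"))
  validateRegions(df)
  df
}

#' Read an outgroup sample list
#'
#' One sample id per line; blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of sample ids.
#' @export
readOutgroupList <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' Read a VCF (with invariant sites) into a GenotypeTable
#'
#' Parses a VCF 4.x file (gzipped or plain) with `vcfR`, keeping invariant
#' records, and attaches population labels and the outgroup flag. Every
#' sample in the VCF must appear in the popmap or the outgroup list;
#' unknown samples are reported by name. Genotypes are reduced to ALT
#' dosages; half-called genotypes and genotypes involving a third allele are
#' set to missing (multi-allelic records keep `nAlleles > 2` and are removed
#' later by [filterSites()]). Per-genotype `DP` is read when present;
#' per-genotype quality is taken from the `RQ` format field, falling back to
#' `GQ`, falling back to the site `QUAL` column.
#'
#' @param path VCF file path.
#' @param popmap Named character vector (sample -> population), e.g. from
#'   [readPopmap()], or a path to a popmap file.
#' @param outgroup Character vector of outgroup sample ids, or a path to a
#'   one-per-line file. May be empty.
#' @return A [GenotypeTable-class].
#' @export
readGenotypeVcf <- function(path, popmap, outgroup = character()) {
  if (length(popmap) == 1L && is.character(popmap) && is.null(names(popmap)) &&
      file.exists(popmap))
    popmap <- readPopmap(popmap)
  if (length(outgroup) == 1L && file.exists(outgroup) &&
      !outgroup %in% names(popmap))
    outgroup <- readOutgroupList(outgroup)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  samples <- colnames(v@gt)[-1]
  unknown <- setdiff(samples, c(names(popmap), outgroup))
  if (length(unknown))
    stop("VCF samples missing from popmap/outgroup list: ",
         paste(unknown, collapse = ", "))
  gtRaw <- vcfR::extract.gt(v, element = "GT")
  gtRaw <- gsub("|", "/", gtRaw, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow(gtRaw), ncol(gtRaw))
  dosage[gtRaw %in% c("0/0", "0")] <- 0L
  dosage[gtRaw %in% c("0/1", "1/0")] <- 1L
  dosage[gtRaw %in% c("1/1", "1")] <- 2L
  depth <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
    error = function(e) NULL)
  qual <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "RQ", as.numeric = TRUE)),
    error = function(e) NULL)
  if (is.null(qual) || all(is.na(qual)))
    qual <- tryCatch(
      suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)),
      error = function(e) NULL)
  if (is.null(qual) || all(is.na(qual))) {
    siteQual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    if (!all(is.na(siteQual)))
      qual <- matrix(siteQual, nrow(dosage), ncol(dosage))
  }
  toIntMat <- function(m) {
    if (is.null(m)) return(NULL)
    m <- round(m)
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  }
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  ord <- order(match(fix[, "CHROM"], unique(fix[, "CHROM"])),
               as.integer(fix[, "POS"]))
  depth <- toIntMat(depth)
  qual <- toIntMat(qual)
  gt <- GenotypeTable(
    chrom = fix[ord, "CHROM"], pos = as.integer(fix[ord, "POS"]),
    ref = fix[ord, "REF"], alt = alt[ord],
    dosage = dosage[ord, , drop = FALSE],
    samples = samples,
    populations = popmap, outgroup = intersect(outgroup, samples),
    depth = if (is.null(depth)) NULL else depth[ord, , drop = FALSE],
    qual = if (is.null(qual)) NULL else qual[ord, , drop = FALSE])
  gt
}
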