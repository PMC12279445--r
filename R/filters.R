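#' Genotype- and site-level filter configuration
#'
#' Thresholds mirroring standard all-sites VCF filtering for population
#' genomic scans: per-genotype minimum quality 20 and depth within [15, 50]
#' (inclusive bounds, the conventional semantics of VCF filtering tools), a
#' maximum fraction of missing genotypes per site of 10%, and at most two
#' alleles per site.
#'
#' @param minQual Minimum per-genotype phred-scaled quality (inclusive).
#' @param minDepth,maxDepth Per-genotype depth bounds (inclusive).
#' @param maxMissing Maximum tolerated fraction of missing genotypes per
#'   site, in `[0, 1]`.
#' @param missingDenominator `"all"` counts missingness over every sample in
#'   the table (ingroup + outgroup, matching joint filtering of one combined
#'   VCF); `"ingroup"` restricts the denominator to ingroup samples.
#' @return A list of class `"divscanFilterConfig"`.
#' @export
filterConfig <- function(minQual = 20, minDepth = 15, maxDepth = 50,
                         maxMissing = 0.10,
                         missingDenominator = c("all", "ingroup")) {
  stopifnot(minDepth <= maxDepth, maxMissing >= 0, maxMissing <= 1)
  structure(list(minQual = minQual, minDepth = minDepth, maxDepth = maxDepth,
                 maxMissing = maxMissing,
                 missingDenominator = match.arg(missingDenominator)),
            class = "divscanFilterConfig")
}

#' Apply per-genotype depth and quality filters
#'
#' Sets to missing every genotype whose depth is below `minDepth`, above
#' `maxDepth`, or whose quality is below `minQual` (all bounds inclusive for
#' retention). Genotypes are never altered, only masked; tables without
#' depth/quality annotations pass through unchanged. The operation is
#' idempotent.
#'
#' @param gt A [GenotypeTable-class].
#' @param cfg A [filterConfig()] list.
#' @return The filtered [GenotypeTable-class].
#' @export
filterGenotypes <- function(gt, cfg = filterConfig()) {
  stopifnot(is(gt, "GenotypeTable"))
  d <- gt@dosage
  if (!is.null(gt@depth)) {
    bad <- !is.na(gt@depth) & (gt@depth < cfg$minDepth | gt@depth > cfg$maxDepth)
    d[bad] <- NA_integer_
  }
  if (!is.null(gt@qual)) {
    bad <- !is.na(gt@qual) & gt@qual < cfg$minQual
    d[bad] <- NA_integer_
  }
  initialize(gt, dosage = d)
}

#' Apply site-level missingness and biallelic filters
#'
#' Drops sites whose fraction of missing genotypes exceeds `maxMissing`
#' (strictly greater than; a site exactly at the threshold is retained) and
#' sites with more than two alleles. Invariant sites are never removed by
#' the biallelic rule. Apply [filterGenotypes()] first so that masked
#' genotypes count as missing.
#'
#' @param gt A [GenotypeTable-class].
#' @param cfg A [filterConfig()] list.
#' @return The filtered [GenotypeTable-class]; warns (not errors) if no
#'   site survives.
#' @export
filterSites <- function(gt, cfg = filterConfig()) {
  stopifnot(is(gt, "GenotypeTable"))
  cols <- if (cfg$missingDenominator == "ingroup")
    which(!gt@samples %in% gt@outgroup)
  else seq_along(gt@samples)
  missFrac <- rowMeans(is.na(gt@dosage[, cols, drop = FALSE]))
  keep <- missFrac <= cfg$maxMissing & gt@nAlleles <= 2L
  if (!any(keep)) warning("no sites survive the site-level filters")
  gt[keep]
}
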