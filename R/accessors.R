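#' @name GenotypeTable-accessors
#' @title Accessors for GenotypeTable objects
#'
#' @description Slot access for [GenotypeTable-class] objects. `nSites()` and
#' `sampleNames()` give the table dimensions; `dosage()` returns the ALT
#' dosage matrix; `populationOf()` the sample -> population mapping (`NA` for
#' outgroup samples); `populationNames()` the sorted unique ingroup labels;
#' `outgroupSamples()` the outgroup sample ids; `siteInfo()` a per-site
#' data.frame (chrom, pos, ref, alt, n_alleles).
#'
#' @param x A [GenotypeTable-class] object.
#' @return See description.
NULL

setGeneric("nSites", function(x) standardGeneric("nSites"))
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))
setGeneric("dosage", function(x) standardGeneric("dosage"))
setGeneric("populationOf", function(x) standardGeneric("populationOf"))
setGeneric("populationNames", function(x) standardGeneric("populationNames"))
setGeneric("outgroupSamples", function(x) standardGeneric("outgroupSamples"))
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname GenotypeTable-accessors
#' @export
setMethod("nSites", "GenotypeTable", function(x) length(x@pos))

#' @rdname GenotypeTable-accessors
#' @export
setMethod("sampleNames", "GenotypeTable", function(x) x@samples)

#' @rdname GenotypeTable-accessors
#' @export
setMethod("dosage", "GenotypeTable", function(x) {
  d <- x@dosage
  dimnames(d) <- list(NULL, x@samples)
  d
})

#' @rdname GenotypeTable-accessors
#' @export
setMethod("populationOf", "GenotypeTable", function(x) {
  p <- x@populations
  names(p) <- x@samples
  p
})

#' @rdname GenotypeTable-accessors
#' @export
setMethod("populationNames", "GenotypeTable", function(x)
  sort(unique(x@populations[!is.na(x@populations)])))

#' @rdname GenotypeTable-accessors
#' @export
setMethod("outgroupSamples", "GenotypeTable", function(x) x@outgroup)

#' @rdname GenotypeTable-accessors
#' @export
setMethod("siteInfo", "GenotypeTable", function(x)
  data.frame(chrom = x@chrom, pos = x@pos, ref = x@ref, alt = x@alt,
             n_alleles = x@nAlleles, stringsAsFactors = FALSE))

# internal: column indices of a population's samples (or of the outgroup)
.popCols <- function(gt, pop) {
  if (identical(pop, "outgroup")) which(gt@samples %in% gt@outgroup)
  else which(!is.na(gt@populations) & gt@populations == pop)
}

#' Subset a GenotypeTable by site index
#'
#' @param x A [GenotypeTable-class].
#' @param i Integer or logical site index.
#' @param j,...,drop Ignored (sample subsetting is not supported; use the
#'   population mapping instead).
#' @return A [GenotypeTable-class] restricted to the selected sites.
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
  initialize(x,
    chrom = x@chrom[i], pos = x@pos[i], ref = x@ref[i], alt = x@alt[i],
    nAlleles = x@nAlleles[i],
    dosage = x@dosage[i, , drop = FALSE],
    depth = if (is.null(x@depth)) NULL else x@depth[i, , drop = FALSE],
    qual = if (is.null(x@qual)) NULL else x@qual[i, , drop = FALSE])
})
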