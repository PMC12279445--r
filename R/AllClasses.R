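#' @import methods
#' @importFrom stats rbinom rbeta rgamma rnbinom runif sd lm coef cor complete.cases
#' @importFrom utils read.table write.table combn
NULL

setClassUnion("matrixOrNULL", members = c("matrix", "NULL"))

#' GenotypeTable: per-site diploid genotypes with depth/quality annotations
#'
#' The central data container of the package. It holds one row per genomic
#' site -- including invariant (monomorphic) sites, which are required for
#' unbiased per-site diversity denominators -- and one column per sample.
#' Genotypes are stored as ALT-allele dosages (0, 1, 2; `NA` = missing); a
#' half-called genotype is treated as fully missing. Per-genotype sequencing
#' depth and phred-scaled genotype quality matrices are optional and are only
#' consumed by [filterGenotypes()].
#'
#' @slot chrom character, contig of each site.
#' @slot pos integer, 1-based position of each site; strictly increasing
#'   within a contig.
#' @slot ref,alt character, reference and alternate allele per site. `alt`
#'   is `"."` for invariant sites. For multi-allelic records `alt` keeps the
#'   comma-separated allele list; such sites carry `nAlleles > 2` and are
#'   removed by [filterSites()].
#' @slot nAlleles integer, number of distinct alleles in the record.
#' @slot dosage integer matrix, sites x samples, ALT-allele dosage with `NA`
#'   for missing genotypes. For multi-allelic sites dosages are `NA`.
#' @slot depth,qual integer matrices (or `NULL`), per-genotype read depth and
#'   quality, same shape as `dosage`.
#' @slot samples character, sample identifiers (column order of `dosage`).
#' @slot populations named character, population label per sample;
#'   `NA` for outgroup samples.
#' @slot outgroup character, identifiers of the outgroup samples.
#'
#' @seealso [readGenotypeVcf()], [simulateGenotypes()], [filterGenotypes()],
#'   [computeWindowStats()]
#' @export
setClass("GenotypeTable",
  representation(
    chrom = "character",
    pos = "integer",
    ref = "character",
    alt = "character",
    nAlleles = "integer",
    dosage = "matrix",
    depth = "matrixOrNULL",
    qual = "matrixOrNULL",
    samples = "character",
    populations = "character",
    outgroup = "character"
  )
)

setValidity("GenotypeTable", function(object) {
  msg <- character()
  n <- length(object@pos)
  if (length(object@chrom) != n) msg <- c(msg, "chrom and pos lengths differ")
  if (length(object@ref) != n) msg <- c(msg, "ref and pos lengths differ")
  if (length(object@alt) != n) msg <- c(msg, "alt and pos lengths differ")
  if (length(object@nAlleles) != n) msg <- c(msg, "nAlleles and pos lengths differ")
  if (nrow(object@dosage) != n) msg <- c(msg, "dosage must have one row per site")
  if (ncol(object@dosage) != length(object@samples))
    msg <- c(msg, "dosage must have one column per sample")
  if (anyDuplicated(object@samples)) msg <- c(msg, "duplicated sample ids")
  for (sl in c("depth", "qual")) {
    m <- slot(object, sl)
    if (!is.null(m) && !identical(dim(m), dim(object@dosage)))
      msg <- c(msg, sprintf("%s matrix dimensions differ from dosage", sl))
  }
  if (length(object@populations) != length(object@samples))
    msg <- c(msg, "populations must have one entry per sample")
  if (!all(object@outgroup %in% object@samples))
    msg <- c(msg, "outgroup contains unknown sample ids")
  isOut <- object@samples %in% object@outgroup
  if (any(is.na(object@populations) & !isOut))
    msg <- c(msg, "non-outgroup samples must carry a population label")
  if (any(!is.na(object@populations) & isOut))
    msg <- c(msg, "outgroup samples must not carry a population label")
  bad <- object@dosage[!is.na(object@dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (n > 1) {
    o <- order(object@chrom)
    bychrom <- split(object@pos[o], object@chrom[o])
    if (any(vapply(bychrom, function(p) any(diff(p) <= 0), logical(1))))
      msg <- c(msg, "pos must be strictly increasing within each chrom")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeTable
#'
#' @param chrom,pos,ref,alt Per-site fields; see the class documentation.
#' @param dosage Integer matrix of ALT dosages, sites x samples.
#' @param samples Sample identifiers; defaults to `colnames(dosage)`.
#' @param populations Named character vector mapping sample -> population
#'   label. Samples absent from it must be listed in `outgroup`.
#' @param outgroup Character vector of outgroup sample ids (possibly empty).
#' @param depth,qual Optional per-genotype depth/quality matrices.
#' @param nAlleles Optional integer vector; derived from `alt` when missing.
#' @return A validated [GenotypeTable-class] object.
#' @export
GenotypeTable <- function(chrom, pos, ref, alt, dosage,
                          samples = colnames(dosage),
                          populations, outgroup = character(),
                          depth = NULL, qual = NULL, nAlleles = NULL) {
  if (is.null(samples)) stop("sample ids are required")
  if (is.null(nAlleles)) {
    nAlleles <- as.integer(ifelse(alt == "." | is.na(alt), 1L,
                                  vapply(strsplit(alt, ","), length, integer(1)) + 1L))
  }
  popOf <- rep(NA_character_, length(samples))
  names(popOf) <- samples
  known <- intersect(samples, names(populations))
  popOf[known] <- populations[known]
  storage.mode(dosage) <- "integer"
  new("GenotypeTable",
      chrom = as.character(chrom), pos = as.integer(pos),
      ref = as.character(ref), alt = as.character(alt),
      nAlleles = as.integer(nAlleles), dosage = dosage,
      depth = depth, qual = qual,
      samples = as.character(samples), populations = unname(popOf),
      outgroup = as.character(outgroup))
}

setMethod("show", "GenotypeTable", function(object) {
  pops <- table(object@populations[!is.na(object@populations)])
  cat("GenotypeTable with", length(object@pos), "sites x",
      length(object@samples), "samples\n")
  cat("  contigs:", length(unique(object@chrom)),
      " variant sites:", sum(object@nAlleles > 1L),
      " invariant sites:", sum(object@nAlleles == 1L), "\n")
  cat("  populations:",
      paste(sprintf("%s(%d)", names(pops), as.integer(pops)), collapse = " "),
      "\n")
  cat("  outgroup samples:", length(object@outgroup), "\n")
  cat("  depth/quality annotations:",
      if (is.null(object@depth)) "absent" else "present", "\n")
})

#' SimulationConfig: study design for the genotype simulator
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' study design the package targets: five diploid populations of unequal size
#' (156 ingroup samples) plus two outgroup samples, ancestral per-site
#' diversity theta = 0.003, per-population branch divergences yielding
#' pairwise D_XY around 0.0034-0.0041, 4,184 target regions (4,051 genic +
#' 133 non-genic) of ~600 usable bp each, and 10 kb windows. See
#' [simConfig()] for field semantics.
#'
#' @seealso [simConfig()], [simulateGenotypes()]
#' @export
setClass("SimulationConfig",
  representation(
    popNames = "character",
    samplesPerPop = "integer",
    nOutgroup = "integer",
    theta = "numeric",
    thetaShape = "numeric",
    branchDivergence = "numeric",
    outgroupDivergence = "numeric",
    driftF = "numeric",
    migration = "matrix",
    migrationShare = "numeric",
    expansionRate = "numeric",
    freqFloor = "numeric",
    nRegions = "integer",
    regionLengthBp = "integer",
    windowBp = "integer",
    genicFraction = "numeric",
    missingRate = "numeric",
    simulateDepth = "logical",
    depthMean = "numeric",
    depthSize = "numeric",
    lowQualRate = "numeric",
    qualHigh = "integer",
    qualLow = "integer",
    seed = "integer",
    scenarioInjections = "data.frame",
    codingInjections = "data.frame"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  k <- length(object@popNames)
  if (k < 1) msg <- c(msg, "at least one population required")
  if (length(object@samplesPerPop) != k)
    msg <- c(msg, "samplesPerPop must match popNames")
  if (any(object@samplesPerPop < 2L))
    msg <- c(msg, "each population needs at least 2 samples")
  if (object@nOutgroup < 0L) msg <- c(msg, "nOutgroup must be >= 0")
  for (f in c("theta", "outgroupDivergence", "missingRate", "lowQualRate",
              "migrationShare", "genicFraction", "freqFloor")) {
    v <- slot(object, f)
    if (length(v) != 1 || is.na(v) || v < 0)
      msg <- c(msg, sprintf("%s must be a single non-negative number", f))
  }
  for (f in c("missingRate", "lowQualRate", "migrationShare", "genicFraction")) {
    if (slot(object, f) > 1) msg <- c(msg, sprintf("%s must be in [0,1]", f))
  }
  if (object@freqFloor <= 0 || object@freqFloor >= 0.5)
    msg <- c(msg, "freqFloor must be in (0, 0.5)")
  if (length(object@branchDivergence) != k || any(object@branchDivergence < 0))
    msg <- c(msg, "branchDivergence must be non-negative, one per population")
  if (length(object@driftF) != k || any(object@driftF < 0 | object@driftF >= 1))
    msg <- c(msg, "driftF must be in [0,1), one per population")
  if (length(object@expansionRate) != k || any(object@expansionRate < 0))
    msg <- c(msg, "expansionRate must be non-negative, one per population")
  if (!identical(dim(object@migration), c(k, k)))
    msg <- c(msg, "migration must be a k x k logical matrix")
  if (object@nRegions < 1L || object@regionLengthBp < 1L || object@windowBp < 1L)
    msg <- c(msg, "nRegions, regionLengthBp and windowBp must be positive")
  si <- object@scenarioInjections
  if (nrow(si)) {
    need <- c("region", "label", "popA", "popB", "multiplier")
    if (!all(need %in% names(si)))
      msg <- c(msg, "scenarioInjections needs columns region, label, popA, popB, multiplier")
    else {
      if (!all(si$label %in% c("gene_flow", "allopatric", "recurrent", "balancing")))
        msg <- c(msg, "unknown scenario label in scenarioInjections")
      if (!all(si$region %in% seq_len(object@nRegions)))
        msg <- c(msg, "scenarioInjections region index out of range")
      if (!all(c(si$popA, si$popB) %in% object@popNames))
        msg <- c(msg, "scenarioInjections population not in popNames")
    }
  }
  ci <- object@codingInjections
  if (nrow(ci)) {
    need <- c("region", "population", "nFixedSyn", "nFixedNonsyn")
    if (!all(need %in% names(ci)))
      msg <- c(msg, "codingInjections needs columns region, population, nFixedSyn, nFixedNonsyn")
    else {
      if (!all(ci$region %in% seq_len(object@nRegions)))
        msg <- c(msg, "codingInjections region index out of range")
      if (!all(ci$population %in% object@popNames))
        msg <- c(msg, "codingInjections population not in popNames")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      length(object@popNames), "populations (",
      paste(object@samplesPerPop, collapse = "/"), "samples ) +",
      object@nOutgroup, "outgroup\n")
  cat("  theta =", object@theta,
      " branch divergence =", paste(signif(object@branchDivergence, 3), collapse = "/"),
      "\n")
  cat("  regions:", object@nRegions, "x", object@regionLengthBp,
      "bp; windows:", object@windowBp, "bp\n")
  cat("  missing rate:", object@missingRate,
      " depth model:", if (object@simulateDepth)
        sprintf("NB(mean %g, size %g)", object@depthMean, object@depthSize)
      else "disabled", "\n")
  cat("  injections:", nrow(object@scenarioInjections), "scenario,",
      nrow(object@codingInjections), "coding; seed:", object@seed, "\n")
})
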