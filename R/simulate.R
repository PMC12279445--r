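#' Build a simulation configuration
#'
#' Creates a validated [SimulationConfig-class]. The defaults emulate the
#' targeted-capture study design the package was built around: five diploid
#' populations of unequal size (156 ingroup samples total) plus two pooled
#' outgroup samples, ancestral per-site diversity `theta = 0.003`,
#' per-population branch divergences giving pairwise D_XY in the 0.0034-0.0041
#' range, 4,184 target regions (4,051 genic-coding + 133 non-genic) of ~600
#' usable bp each, and 10 kb analysis windows. Tests and examples pass smaller
#' explicit configurations.
#'
#' @details
#' The generative model is frequency-based and closed-form checkable:
#' * Each site is ancestrally polymorphic with probability
#'   `theta * log(1/freqFloor) / (1 - freqFloor)^2`; polymorphic frequencies
#'   are drawn with density proportional to `1/p` on `(freqFloor, 1)` -- the
#'   stationary neutral spectrum, so a binomial sample of haplotypes has the
#'   classical `E[xi_k] ~ 1/k` site-frequency spectrum and Tajima's D close
#'   to zero at equilibrium.
#' * Population `i` drifts by a Balding-Nichols Beta kernel with inbreeding
#'   parameter `driftF[i]` (within-population diversity shrinks by `1 - F`;
#'   expected cross-population divergence is unchanged).
#' * Population `i` additionally fixes new substitutions at `branchDivergence[i]`
#'   expected substitutions per site on its own branch, so a pair's expected
#'   window D_XY is `theta + branchDivergence[i] + branchDivergence[j]`.
#' * `migration[i, j] = TRUE` lets a substitution on either branch be shared
#'   with the partner population with probability `migrationShare`, deflating
#'   that pair's net divergence.
#' * `expansionRate[i] > 0` adds private singleton variants (one heterozygous
#'   carrier) at that per-site rate, producing the excess of rare alleles --
#'   and negative Tajima's D -- expected after a recent population expansion.
#'
#' @param popNames Population labels.
#' @param samplesPerPop Diploid sample count per population (each >= 2).
#' @param nOutgroup Number of pooled outgroup samples.
#' @param theta Expected ancestral per-site diversity (substitutions/site).
#' @param thetaShape Shape of the per-region Gamma(mean 1) diversity
#'   multiplier; regions genuinely differ in diversity under targeted capture.
#'   `0` disables heterogeneity.
#' @param branchDivergence Expected substitutions/site accumulated on each
#'   population's own branch (length matches `popNames`).
#' @param outgroupDivergence Expected substitutions/site on the outgroup
#'   branch (congeneric outgroup).
#' @param driftF Balding-Nichols inbreeding parameter per population.
#' @param migration Logical k x k matrix of pairwise migration flags.
#' @param migrationShare Probability a substitution is shared across a
#'   migrating pair.
#' @param expansionRate Per-site rate of extra private singletons per
#'   population (models post-bottleneck expansion; default 0 = equilibrium).
#' @param freqFloor Lower truncation of the ancestral frequency density.
#' @param nRegions,regionLengthBp Number of target regions and simulated bp
#'   per region (one contig per region).
#' @param windowBp Analysis window length in bp.
#' @param genicFraction Fraction of regions flagged genic (frame 0).
#' @param missingRate Per-genotype missingness probability.
#' @param simulateDepth Simulate per-genotype depth/quality annotations?
#' @param depthMean,depthSize Negative-binomial depth model (mean/size).
#' @param lowQualRate Probability a genotype gets `qualLow` instead of
#'   `qualHigh`.
#' @param qualHigh,qualLow Phred-scaled genotype qualities emitted.
#' @param seed Master seed; all randomness flows from it.
#' @param scenarioInjections data.frame(region, label, popA, popB, multiplier)
#'   of windows to push into a classifier scenario; see [injectScenario()].
#' @param codingInjections data.frame(region, population, nFixedSyn,
#'   nFixedNonsyn) of genes given fixed differences to the outgroup.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(popNames = c("A", "B"), samplesPerPop = c(6, 6),
#'                  nRegions = 10, regionLengthBp = 1000, windowBp = 1000,
#'                  seed = 42)
#' cfg
#' @export
simConfig <- function(popNames = c("EC", "CM", "WCC1", "WCC2", "WCC3"),
                      samplesPerPop = c(40, 36, 32, 28, 20),
                      nOutgroup = 2L,
                      theta = 0.003,
                      thetaShape = 4,
                      branchDivergence = c(4e-04, 6e-04, 2e-04, 2e-04, 3e-04),
                      outgroupDivergence = 0.02,
                      driftF = rep(0.02, length(popNames)),
                      migration = matrix(FALSE, length(popNames), length(popNames)),
                      migrationShare = 0.5,
                      expansionRate = rep(0, length(popNames)),
                      freqFloor = 0.005,
                      nRegions = 4184L,
                      regionLengthBp = 600L,
                      windowBp = 10000L,
                      genicFraction = 4051 / 4184,
                      missingRate = 0.03,
                      simulateDepth = TRUE,
                      depthMean = 30,
                      depthSize = 30,
                      lowQualRate = 0.01,
                      qualHigh = 99L,
                      qualLow = 10L,
                      seed = 1L,
                      scenarioInjections = NULL,
                      codingInjections = NULL) {
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
  }
  if (is.null(scenarioInjections))
    scenarioInjections <- data.frame(region = integer(0), label = character(0),
                                     popA = character(0), popB = character(0),
                                     multiplier = numeric(0))
  if (is.null(codingInjections))
    codingInjections <- data.frame(region = integer(0), population = character(0),
                                   nFixedSyn = integer(0), nFixedNonsyn = integer(0))
  new("SimulationConfig",
      popNames = as.character(popNames),
      samplesPerPop = as.integer(samplesPerPop),
      nOutgroup = as.integer(nOutgroup),
      theta = theta, thetaShape = thetaShape,
      branchDivergence = branchDivergence,
      outgroupDivergence = outgroupDivergence,
      driftF = driftF,
      migration = migration, migrationShare = migrationShare,
      expansionRate = expansionRate,
      freqFloor = freqFloor,
      nRegions = as.integer(nRegions),
      regionLengthBp = as.integer(regionLengthBp),
      windowBp = as.integer(windowBp),
      genicFraction = genicFraction,
      missingRate = missingRate,
      simulateDepth = simulateDepth,
      depthMean = depthMean, depthSize = depthSize,
      lowQualRate = lowQualRate,
      qualHigh = as.integer(qualHigh), qualLow = as.integer(qualLow),
      seed = as.integer(seed),
      scenarioInjections = scenarioInjections,
      codingInjections = codingInjections)
}

#' Push a window's allele frequencies into a classifier scenario
#'
#' Edits a sites x populations ALT-frequency matrix so that the expected
#' window statistics of the `popA`/`popB` pair land in the region of
#' (F_ST, D_XY, Pi) space corresponding to `label`:
#'
#' * `gene_flow`: within-pair polymorphism removed, fixed differences placed
#'   at roughly `mean D_XY + 5 SD` density (high F_ST, high D_XY, low Pi).
#' * `allopatric`: polymorphism removed, fixed differences at the neutral
#'   mean-D_XY density (high F_ST, moderate D_XY, low Pi).
#' * `recurrent`: polymorphism thinned to 25% and a small number of fixed
#'   differences added (slightly raised F_ST, lowered D_XY and Pi).
#' * `balancing`: `3 * theta * L` shared intermediate-frequency (p = 0.5)
#'   variants added to both populations (low F_ST, high D_XY and Pi).
#'
#' The per-window SDs entering those targets are the Poisson approximations
#' `sqrt(mean / L)`; `multiplier` scales the deviation from the neutral mean.
#'
#' @param freq Numeric matrix, sites x populations, of ALT frequencies for
#'   one window.
#' @param label One of `"gene_flow"`, `"allopatric"`, `"recurrent"`,
#'   `"balancing"`.
#' @param popA,popB Column indices (or names) of the targeted pair.
#' @param theta Neutral per-site diversity of the simulation.
#' @param dPair Expected neutral added divergence of the pair
#'   (`branchDivergence[popA] + branchDivergence[popB]`).
#' @param multiplier Effect-strength multiplier (>= 1 recommended).
#' @return The edited frequency matrix.
#' @seealso [simConfig()] `scenarioInjections` for use inside the simulator.
#' @export
injectScenario <- function(freq, label, popA = 1L, popB = 2L,
                           theta = 0.003, dPair = 0.001, multiplier = 1) {
  stopifnot(is.matrix(freq), multiplier > 0)
  L <- nrow(freq)
  if (is.character(popA)) popA <- match(popA, colnames(freq))
  if (is.character(popB)) popB <- match(popB, colnames(freq))
  meanDxy <- theta + dPair
  sdDxy <- sqrt(meanDxy / L)
  zeroPair <- function(f) {
    f[, c(popA, popB)] <- 0
    f
  }
  placeFixed <- function(f, nFix) {
    nFix <- max(1L, min(as.integer(nFix), L))
    at <- sample.int(L, nFix)
    half <- seq_len(ceiling(nFix / 2))
    f[at[half], popA] <- 1
    if (nFix > length(half)) f[at[-half], popB] <- 1
    f
  }
  switch(label,
    gene_flow = {
      f <- zeroPair(freq)
      placeFixed(f, round(L * (meanDxy + 5 * multiplier * sdDxy)))
    },
    allopatric = {
      f <- zeroPair(freq)
      placeFixed(f, round(L * meanDxy))
    },
    recurrent = {
      keep <- 0.25
      f <- freq
      poly <- which(f[, popA] > 0 | f[, popB] > 0)
      drop <- poly[runif(length(poly)) >= keep]
      f[drop, c(popA, popB)] <- 0
      placeFixed(f, ceiling(0.8 * multiplier * keep * theta * L))
    },
    balancing = {
      f <- freq
      nBal <- max(1L, min(round(3 * multiplier * theta * L), L))
      at <- sample.int(L, nBal)
      f[at, popA] <- 0.5
      f[at, popB] <- 0.5
      f
    },
    stop("unknown scenario label: ", label)
  )
}

# internal: diploid dosage sampling from per-site frequencies
.sampleDosage <- function(p, nInd) {
  out <- matrix(0L, length(p), max(nInd, 0L))
  if (nInd == 0L) return(out)
  idx <- which(p > 0)
  if (length(idx)) {
    draws <- rbinom(length(idx) * nInd, 2L, p[idx])
    out[idx, ] <- matrix(as.integer(draws), length(idx), nInd)
  }
  out
}

#' Simulate multi-population diploid genotypes with known truth
#'
#' Runs the generative model described in [simConfig()] and returns the
#' genotype table (including invariant sites and the outgroup samples), the
#' target-region manifest, and a ground-truth table recording what was
#' injected where. Identical config (including seed) gives identical output.
#'
#' @param config A [SimulationConfig-class].
#' @return A list with elements:
#'   \describe{
#'     \item{genotypes}{[GenotypeTable-class] over all regions.}
#'     \item{regions}{Region manifest data.frame (`region_id`, `chrom`,
#'       `start`, `end`, `genic`, `frame`; 0-based half-open).}
#'     \item{truth}{List of data.frames: `windows` (per-window injected
#'       scenario or `"neutral"`), `pairs` (true pair divergence and
#'       migration), `genes` (injected fixed syn/nonsyn counts and intended
#'       dN/dS).}
#'   }
#' @examples
#' cfg <- simConfig(popNames = c("A", "B"), samplesPerPop = c(5, 5),
#'                  nOutgroup = 0, nRegions = 5, regionLengthBp = 500,
#'                  windowBp = 500, simulateDepth = FALSE, seed = 7)
#' sim <- simulateGenotypes(cfg)
#' sim$genotypes
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  k <- length(config@popNames)
  R <- config@nRegions
  L <- config@regionLengthBp
  S <- R * L
  regionIds <- sprintf("region_%05d", seq_len(R))
  chrom <- rep(regionIds, each = L)
  pos <- rep.int(seq_len(L), R)

  # ancestral polymorphism with neutral 1/p frequency density
  eps <- config@freqFloor
  pPolyBase <- config@theta * log(1 / eps) / (1 - eps)^2
  thetaMult <- if (config@thetaShape > 0)
    rgamma(R, shape = config@thetaShape, rate = config@thetaShape)
  else rep(1, R)
  pPoly <- pmin(pPolyBase * rep(thetaMult, each = L), 0.5)
  p0 <- numeric(S)
  polyIdx <- which(runif(S) < pPoly)
  p0[polyIdx] <- eps^(1 - runif(length(polyIdx)))

  # per-population frequencies: Balding-Nichols drift then branch substitutions
  P <- matrix(rep(p0, k), ncol = k, dimnames = list(NULL, config@popNames))
  for (i in seq_len(k)) {
    Fst <- config@driftF[i]
    if (Fst > 0 && length(polyIdx)) {
      a <- 1 / Fst - 1
      P[polyIdx, i] <- rbeta(length(polyIdx), p0[polyIdx] * a,
                             (1 - p0[polyIdx]) * a)
    }
  }
  sub <- matrix(FALSE, S, k)
  for (i in seq_len(k)) sub[, i] <- runif(S) < config@branchDivergence[i]
  eff <- sub
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && isTRUE(config@migration[i, j])) {
      shared <- sub[, i] & runif(S) < config@migrationShare
      eff[, j] <- eff[, j] | shared
    }
  }
  for (i in seq_len(k)) P[eff[, i], i] <- 1 - P[eff[, i], i]
  pOut <- p0
  outSub <- runif(S) < config@outgroupDivergence
  pOut[outSub] <- 1 - pOut[outSub]

  # region manifest: one contig per region; leading regions are genic, frame 0
  nGenic <- round(config@genicFraction * R)
  regions <- data.frame(
    region_id = regionIds, chrom = regionIds,
    start = 0L, end = L,
    genic = as.integer(seq_len(R) <= nGenic),
    frame = ifelse(seq_len(R) <= nGenic, "0", "."),
    stringsAsFactors = FALSE)

  # scenario injections (window granularity = region)
  si <- config@scenarioInjections
  scenarioOfRegion <- rep("neutral", R)
  if (nrow(si)) {
    for (r in seq_len(nrow(si))) {
      reg <- si$region[r]
      rows <- ((reg - 1L) * L + 1L):(reg * L)
      ia <- match(si$popA[r], config@popNames)
      ib <- match(si$popB[r], config@popNames)
      dPair <- config@branchDivergence[ia] + config@branchDivergence[ib]
      P[rows, ] <- injectScenario(P[rows, , drop = FALSE], si$label[r],
                                  popA = ia, popB = ib,
                                  theta = config@theta, dPair = dPair,
                                  multiplier = si$multiplier[r])
      scenarioOfRegion[reg] <- si$label[r]
    }
  }

  # coding injections: exact fixed differences to the outgroup by codon class
  ci <- config@codingInjections
  genesTruth <- data.frame(region_id = character(0), population = character(0),
                           n_fixed_syn = integer(0), n_fixed_nonsyn = integer(0),
                           intended_dnds = numeric(0), stringsAsFactors = FALSE)
  if (nrow(ci)) {
    for (r in seq_len(nrow(ci))) {
      reg <- ci$region[r]
      if (regions$genic[reg] != 1L)
        stop("codingInjections region ", reg, " is not genic")
      ip <- match(ci$population[r], config@popNames)
      nCodon <- L %/% 3L
      offs <- (seq_len(3L * nCodon) - 1L) %% 3L
      nonsynPos <- which(offs < 2L)
      synPos <- which(offs == 2L)
      nN <- ci$nFixedNonsyn[r]
      nS <- ci$nFixedSyn[r]
      if (nN > length(nonsynPos) || nS > length(synPos))
        stop("codingInjections counts exceed site-class capacity in region ", reg)
      base <- (reg - 1L) * L
      pick <- c(sample(nonsynPos, nN), sample(synPos, nS))
      P[base + pick, ip] <- 1
      pOut[base + pick] <- 0
      genesTruth <- rbind(genesTruth, data.frame(
        region_id = regionIds[reg], population = ci$population[r],
        n_fixed_syn = nS, n_fixed_nonsyn = nN,
        intended_dnds = (nN / (2 * nCodon)) / max(nS / nCodon, 1e-12),
        stringsAsFactors = FALSE))
    }
  }

  # genotype sampling
  nIn <- sum(config@samplesPerPop)
  nAll <- nIn + config@nOutgroup
  G <- matrix(0L, S, nAll)
  colStart <- cumsum(c(0L, config@samplesPerPop))
  sampleIds <- character(nAll)
  for (i in seq_len(k)) {
    cols <- (colStart[i] + 1L):colStart[i + 1L]
    G[, cols] <- .sampleDosage(P[, i], config@samplesPerPop[i])
    sampleIds[cols] <- sprintf("%s_%02d", config@popNames[i],
                               seq_len(config@samplesPerPop[i]))
  }
  if (config@nOutgroup > 0L) {
    cols <- (nIn + 1L):nAll
    G[, cols] <- .sampleDosage(pOut, config@nOutgroup)
    sampleIds[cols] <- sprintf("OUT_%02d", seq_len(config@nOutgroup))
  }

  # expansion excess: private singletons (one heterozygous carrier)
  for (i in seq_len(k)) {
    rate <- config@expansionRate[i]
    if (rate > 0) {
      at <- which(runif(S) < rate)
      if (length(at)) {
        cols <- (colStart[i] + 1L):colStart[i + 1L]
        carrier <- sample(cols, length(at), replace = TRUE)
        G[cbind(at, carrier)] <- 1L
      }
    }
  }

  # depth / quality annotations
  depth <- qual <- NULL
  if (config@simulateDepth) {
    depth <- matrix(as.integer(rnbinom(S * nAll, size = config@depthSize,
                                       mu = config@depthMean)), S, nAll)
    qual <- matrix(ifelse(runif(S * nAll) < config@lowQualRate,
                          config@qualLow, config@qualHigh), S, nAll)
    storage.mode(qual) <- "integer"
  }

  # missingness
  if (config@missingRate > 0) {
    for (j in seq_len(nAll)) {
      G[runif(S) < config@missingRate, j] <- NA_integer_
    }
  }

  # allele letters; ALT assigned only where the alternate allele was observed
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, S, replace = TRUE)
  observedAlt <- rowSums(G > 0L, na.rm = TRUE) > 0L
  alt <- rep(".", S)
  vi <- which(observedAlt)
  if (length(vi)) {
    shift <- sample.int(3L, length(vi), replace = TRUE)
    alt[vi] <- bases[(match(ref[vi], bases) - 1L + shift) %% 4L + 1L]
  }

  populations <- rep(config@popNames, times = config@samplesPerPop)
  names(populations) <- sampleIds[seq_len(nIn)]
  outgroup <- if (config@nOutgroup > 0L) sampleIds[(nIn + 1L):nAll] else character()
  colnames(G) <- sampleIds
  gt <- GenotypeTable(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      dosage = G, samples = sampleIds,
                      populations = populations, outgroup = outgroup,
                      depth = depth, qual = qual)

  windows <- tileWindows(regions, windowBp = config@windowBp)
  windows$scenario <- scenarioOfRegion[match(windows$chrom, regionIds)]
  if (k >= 2) {
    pairs <- pairwisePlan(config@popNames)
    pairs$true_divergence <-
      config@branchDivergence[match(pairs$popA, config@popNames)] +
      config@branchDivergence[match(pairs$popB, config@popNames)]
    pairs$migration <- mapply(function(a, b) {
      ia <- match(a, config@popNames); ib <- match(b, config@popNames)
      isTRUE(config@migration[ia, ib]) || isTRUE(config@migration[ib, ia])
    }, pairs$popA, pairs$popB)
  } else {
    pairs <- data.frame(popA = character(0), popB = character(0),
                        pair = character(0), true_divergence = numeric(0),
                        migration = logical(0))
  }

  list(genotypes = gt, regions = regions,
       truth = list(windows = windows, pairs = pairs, genes = genesTruth))
}

#' Simulate one coding gene with exact fixed differences to an outgroup
#'
#' Builds a minimal single-population [GenotypeTable-class] (plus outgroup)
#' for one genic region of `geneLenCodons` codons in frame 0. Exactly
#' `nFixedNonsyn` population-vs-outgroup fixed differences are placed at
#' codon positions 1-2 and `nFixedSyn` at codon position 3; every other site
#' is identical between population and outgroup. Alternatively,
#' `nFixedTotal` places that many fixed differences uniformly at random over
#' all coding positions (the neutral expectation for downstream dN/dS is 1).
#'
#' @param geneLenCodons Gene length in codons (>= 1).
#' @param nFixedSyn,nFixedNonsyn Exact fixed-difference counts by class.
#' @param nFixedTotal If non-`NULL`, overrides the per-class counts with
#'   uniform placement across all positions.
#' @param missingRate Per-genotype missingness probability.
#' @param nSamples Diploid samples in the focal population.
#' @param nOutgroup Outgroup samples.
#' @param population Population label.
#' @param seed Seed (`NULL` leaves the RNG state alone, for use inside loops).
#' @return A list with `genotypes` ([GenotypeTable-class]) and `regions`
#'   (one-row manifest, genic, frame 0).
#' @examples
#' g <- simulateCodingGene(30, nFixedSyn = 2, nFixedNonsyn = 3, seed = 1)
#' geneDnDs(g$genotypes, g$regions)
#' @export
simulateCodingGene <- function(geneLenCodons, nFixedSyn = 0L, nFixedNonsyn = 0L,
                               nFixedTotal = NULL, missingRate = 0,
                               nSamples = 10L, nOutgroup = 2L,
                               population = "pop1", seed = NULL) {
  stopifnot(geneLenCodons >= 1, nSamples >= 2, nOutgroup >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- 3L * as.integer(geneLenCodons)
  offs <- (seq_len(L) - 1L) %% 3L
  nonsynPos <- which(offs < 2L)
  synPos <- which(offs == 2L)
  if (is.null(nFixedTotal)) {
    if (nFixedNonsyn > length(nonsynPos))
      stop("nFixedNonsyn exceeds the ", length(nonsynPos), " non-synonymous sites")
    if (nFixedSyn > length(synPos))
      stop("nFixedSyn exceeds the ", length(synPos), " synonymous sites")
    pick <- c(if (nFixedNonsyn > 0) sample(nonsynPos, nFixedNonsyn),
              if (nFixedSyn > 0) sample(synPos, nFixedSyn))
  } else {
    if (nFixedTotal > L) stop("nFixedTotal exceeds gene length")
    pick <- sample.int(L, nFixedTotal)
  }
  nAll <- nSamples + nOutgroup
  G <- matrix(0L, L, nAll)
  G[pick, seq_len(nSamples)] <- 2L
  if (missingRate > 0) G[runif(L * nAll) < missingRate] <- NA_integer_
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- rep(".", L)
  if (length(pick)) {
    shift <- sample.int(3L, length(pick), replace = TRUE)
    alt[pick] <- bases[(match(ref[pick], bases) - 1L + shift) %% 4L + 1L]
  }
  ids <- c(sprintf("%s_%02d", population, seq_len(nSamples)),
           sprintf("OUT_%02d", seq_len(nOutgroup)))
  colnames(G) <- ids
  populations <- rep(population, nSamples)
  names(populations) <- ids[seq_len(nSamples)]
  gt <- GenotypeTable(chrom = rep("gene_1", L), pos = seq_len(L),
                      ref = ref, alt = alt, dosage = G, samples = ids,
                      populations = populations,
                      outgroup = ids[(nSamples + 1L):nAll])
  regions <- data.frame(region_id = "gene_1", chrom = "gene_1",
                        start = 0L, end = L, genic = 1L, frame = "0",
                        stringsAsFactors = FALSE)
  list(genotypes = gt, regions = regions)
}
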