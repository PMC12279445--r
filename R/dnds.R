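#' Label codon positions of a genic region
#'
#' Applies the 4-fold-degeneracy approximation literally: within each codon,
#' positions 1 and 2 are non-synonymous and position 3 is synonymous,
#' regardless of the actual genetic code. Codons are counted from the
#' region start plus the reading-frame offset; a trailing partial codon is
#' dropped.
#'
#' @param start,end 0-based half-open region interval.
#' @param frame Reading-frame offset (0, 1 or 2; `"."`/`NA` means unknown).
#' @return data.frame with `pos` (1-based genomic position) and `class`
#'   (`"nonsyn"` or `"syn"`); zero rows when the frame is unknown or no
#'   complete codon fits.
#' @export
codonSiteClasses <- function(start, end, frame = 0) {
  if (is.na(frame) || frame == ".")
    return(data.frame(pos = integer(0), class = character(0)))
  frame <- as.integer(frame)
  stopifnot(frame %in% 0:2, end > start)
  nCodon <- (end - start - frame) %/% 3L
  if (nCodon < 1L)
    return(data.frame(pos = integer(0), class = character(0)))
  pos0 <- start + frame + seq_len(3L * nCodon) - 1L
  offs <- (pos0 - start - frame) %% 3L
  data.frame(pos = pos0 + 1L,
             class = ifelse(offs == 2L, "syn", "nonsyn"),
             stringsAsFactors = FALSE)
}

#' Is a site a fixed difference between a population and the outgroup?
#'
#' The default rule declares a fixed difference when the set of alleles
#' observed in the population shares no allele with the set observed in the
#' outgroup (`rule = "disjoint"`; robust to residual low-frequency
#' polymorphism on either side is NOT granted -- any shared allele cancels
#' the call). `rule = "strict"` additionally requires both sides to be
#' monomorphic.
#'
#' @param popC0,popC1 REF/ALT allele counts in the population (vectorised).
#' @param outC0,outC1 REF/ALT allele counts in the outgroup.
#' @param rule `"disjoint"` (default) or `"strict"`.
#' @return Logical vector; `FALSE` wherever either side has no observed
#'   allele.
#' @export
isFixedDifference <- function(popC0, popC1, outC0, outC1,
                              rule = c("disjoint", "strict")) {
  rule <- match.arg(rule)
  popHas0 <- popC0 > 0; popHas1 <- popC1 > 0
  outHas0 <- outC0 > 0; outHas1 <- outC1 > 0
  nonempty <- (popHas0 | popHas1) & (outHas0 | outHas1)
  disjoint <- nonempty & !(popHas0 & outHas0) & !(popHas1 & outHas1)
  if (rule == "disjoint") return(disjoint)
  disjoint & !(popHas0 & popHas1) & !(outHas0 & outHas1)
}

#' Degenerate-site dN/dS per gene and population against the outgroup
#'
#' For every genic region with a known reading frame and every population,
#' counts covered and fixed synonymous/non-synonymous sites against the
#' pooled outgroup and forms `dN = fixed_nonsyn / covered_nonsyn`,
#' `dS = fixed_syn / covered_syn`, `ratio = dN / dS`.
#'
#' A site enters the covered counts for a gene x population only if it
#' survived upstream filtering (is present in the table), at most
#' `maxMissing` of that population's genotypes are missing (inclusive
#' bound), and at least one outgroup allele was observed. Genes are gated:
#' the ratio is reported only when at least one synonymous AND one
#' non-synonymous fixed difference exist; otherwise the row carries an
#' `excluded` reason and an `NA` ratio.
#'
#' @param gt A filtered [GenotypeTable-class] with outgroup samples.
#' @param regions Region manifest data.frame; only genic rows with a frame
#'   are analysed.
#' @param populations Population labels; defaults to all ingroup
#'   populations.
#' @param maxMissing Maximum tolerated fraction of missing genotypes in the
#'   focal population per site (inclusive; default 0.5).
#' @param rule Fixed-difference rule, see [isFixedDifference()].
#' @return data.frame with one row per gene x population: `gene`,
#'   `population`, `covered_nonsyn`, `covered_syn`, `fixed_nonsyn`,
#'   `fixed_syn`, `dN`, `dS`, `ratio`, `excluded` (`NA` when the gene
#'   qualifies, otherwise a reason code).
#' @export
geneDnDs <- function(gt, regions, populations = NULL, maxMissing = 0.5,
                     rule = c("disjoint", "strict")) {
  rule <- match.arg(rule)
  stopifnot(is(gt, "GenotypeTable"))
  if (length(gt@outgroup) == 0L)
    stop("geneDnDs requires outgroup samples in the genotype table")
  if (is.null(populations)) populations <- populationNames(gt)
  genic <- regions[regions$genic == 1L, , drop = FALSE]
  outCols <- which(gt@samples %in% gt@outgroup)
  outCt <- .alleleCounts(gt, outCols)
  siteKey <- paste(gt@chrom, gt@pos)
  popData <- lapply(populations, function(p) {
    cols <- .popCols(gt, p)
    list(ct = .alleleCounts(gt, cols),
         missFrac = rowMeans(is.na(gt@dosage[, cols, drop = FALSE])))
  })
  names(popData) <- populations

  rows <- vector("list", nrow(genic) * length(populations))
  ri <- 0L
  for (g in seq_len(nrow(genic))) {
    cls <- codonSiteClasses(genic$start[g], genic$end[g], genic$frame[g])
    if (nrow(cls) == 0L) {
      warning("gene ", genic$region_id[g],
              " skipped: unknown frame or no complete codon")
      next
    }
    idx <- match(paste(genic$chrom[g], cls$pos), siteKey)
    present <- !is.na(idx)
    for (p in populations) {
      pd <- popData[[p]]
      sIdx <- idx[present]
      covered <- pd$missFrac[sIdx] <= maxMissing &
        outCt$n[sIdx] >= 1 & pd$ct$n[sIdx] >= 1
      klass <- cls$class[present]
      covN <- sum(covered & klass == "nonsyn")
      covS <- sum(covered & klass == "syn")
      fx <- isFixedDifference(pd$ct$c0[sIdx], pd$ct$c1[sIdx],
                              outCt$c0[sIdx], outCt$c1[sIdx], rule)
      fixN <- sum(covered & fx & klass == "nonsyn")
      fixS <- sum(covered & fx & klass == "syn")
      excluded <- NA_character_
      if (covN == 0L || covS == 0L) excluded <- "no_covered_sites"
      else if (fixN < 1L || fixS < 1L) excluded <- "fixed_site_gate"
      ratio <- dN <- dS <- NA_real_
      if (is.na(excluded)) {
        dN <- fixN / covN
        dS <- fixS / covS
        ratio <- dN / dS
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        gene = genic$region_id[g], population = p,
        covered_nonsyn = covN, covered_syn = covS,
        fixed_nonsyn = fixN, fixed_syn = fixS,
        dN = dN, dS = dS, ratio = ratio, excluded = excluded,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  if (is.null(out))
    out <- data.frame(gene = character(0), population = character(0),
                      covered_nonsyn = integer(0), covered_syn = integer(0),
                      fixed_nonsyn = integer(0), fixed_syn = integer(0),
                      dN = numeric(0), dS = numeric(0), ratio = numeric(0),
                      excluded = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Outlier dN/dS genes per population
#'
#' Flags, within each population, genes whose dN/dS ratio strictly exceeds
#' the population mean plus 3 population-SD of the defined ratios, and
#' summarises how outlier genes are shared across populations.
#'
#' @param dnds Output of [geneDnDs()].
#' @param threshold Outlier threshold in SD units (strict `>`; default 3).
#' @param sdType `"population"` (divide by N, default) or `"sample"`.
#' @return list with `perPopulation` (named list of outlier gene vectors),
#'   `thresholds` (per-population mean/sd/cutoff/n data.frame; populations
#'   with zero sd are flagged `degenerate` and yield no outliers),
#'   `membership` (table: outlier gene x number of populations it is
#'   an outlier in) and `union` (all outlier genes).
#' @export
dndsOutliers <- function(dnds, threshold = 3,
                         sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  pops <- unique(dnds$population)
  perPop <- list()
  thr <- list()
  for (p in pops) {
    d <- dnds[dnds$population == p & !is.na(dnds$ratio), , drop = FALSE]
    if (nrow(d) < 2) {
      thr[[p]] <- data.frame(population = p, mean = NA_real_, sd = NA_real_,
                             cutoff = NA_real_, n = nrow(d), degenerate = TRUE)
      perPop[[p]] <- character(0)
      next
    }
    m <- mean(d$ratio)
    s <- if (sdType == "population") sqrt(mean((d$ratio - m)^2)) else sd(d$ratio)
    degenerate <- !is.finite(s) || s == 0
    cut <- m + threshold * s
    perPop[[p]] <- if (degenerate) character(0) else d$gene[d$ratio > cut]
    thr[[p]] <- data.frame(population = p, mean = m, sd = s, cutoff = cut,
                           n = nrow(d), degenerate = degenerate)
  }
  allOut <- unlist(perPop, use.names = FALSE)
  list(perPopulation = perPop,
       thresholds = do.call(rbind, thr),
       membership = if (length(allOut)) table(allOut) else table(character(0)),
       union = sort(unique(allOut)))
}

#' Genes under divergent selection: F_ST x dN/dS outlier concordance
#'
#' Intersects the union (over pairwise comparisons) of genes hit by
#' outlier-F_ST windows with the union (over populations) of outlier-dN/dS
#' genes.
#'
#' @param fstOutlierGenes Character vector (or list of vectors, one per
#'   pair) of genes overlapped by outlier-F_ST windows.
#' @param dndsOutlierGenes Character vector (or list of vectors, one per
#'   population) of outlier-dN/dS genes, e.g. `dndsOutliers(...)$union`.
#' @return Sorted character vector of concordant genes.
#' @export
divergentSelectionGenes <- function(fstOutlierGenes, dndsOutlierGenes) {
  f <- unique(unlist(fstOutlierGenes, use.names = FALSE))
  d <- unique(unlist(dndsOutlierGenes, use.names = FALSE))
  sort(intersect(f, d))
}
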