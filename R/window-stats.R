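#' Per-site building blocks of the windowed estimators
#'
#' Count-based per-site quantities that are summed within windows
#' (ratio-of-sums aggregation, which stays unbiased under per-genotype
#' missingness). All functions are vectorised over sites.
#'
#' `sitePi()` gives within-population pairwise differences: with `c0`/`c1`
#' copies of each allele among `n = c0 + c1` genotyped haplotypes, the number
#' of differing haplotype pairs is `c0 * c1` out of `n * (n - 1) / 2`; sites
#' with `n < 2` contribute nothing.
#'
#' `siteDxy()` gives between-population differences: `cA0 * cB1 + cA1 * cB0`
#' differing pairs out of `nA * nB` cross-population pairs; either side
#' ungenotyped contributes nothing.
#'
#' `hudsonFstSite()` gives Hudson's estimator with the Bhatia sample-size
#' correction: numerator `(p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) -
#' p2 (1 - p2) / (n2 - 1)`, denominator `p1 (1 - p2) + p2 (1 - p1)`, with
#' `n1`, `n2` the genotyped haplotype counts; sites with fewer than two
#' haplotypes on either side contribute nothing. Set `correction = FALSE`
#' for the uncorrected numerator `(p1 - p2)^2`.
#'
#' @param c0,c1 Allele counts in the focal population.
#' @param cA0,cA1,cB0,cB1 Allele counts in populations A and B.
#' @param p1,p2 ALT frequencies in the two populations.
#' @param n1,n2 Genotyped haplotype counts in the two populations.
#' @param correction Apply the sample-size correction to the numerator?
#' @return A list with per-site `diffs`/`comparisons` (or
#'   `numerator`/`denominator` for F_ST); unusable sites carry zeros so that
#'   window sums can ignore them.
#' @name site-estimators
NULL

#' @rdname site-estimators
#' @export
sitePi <- function(c0, c1) {
  n <- c0 + c1
  ok <- n >= 2
  list(diffs = ifelse(ok, c0 * c1, 0),
       comparisons = ifelse(ok, n * (n - 1) / 2, 0))
}

#' @rdname site-estimators
#' @export
siteDxy <- function(cA0, cA1, cB0, cB1) {
  nA <- cA0 + cA1
  nB <- cB0 + cB1
  ok <- nA >= 1 & nB >= 1
  list(diffs = ifelse(ok, cA0 * cB1 + cA1 * cB0, 0),
       comparisons = ifelse(ok, nA * nB, 0))
}

#' @rdname site-estimators
#' @export
hudsonFstSite <- function(p1, n1, p2, n2, correction = TRUE) {
  ok <- n1 >= 2 & n2 >= 2 & !is.na(p1) & !is.na(p2)
  num <- (p1 - p2)^2
  if (correction)
    num <- num - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(numerator = ifelse(ok, num, 0), denominator = ifelse(ok, den, 0))
}

# internal: per-site allele counts for a set of sample columns.
# Sites with more than two alleles are unusable and get n = 0.
.alleleCounts <- function(gt, cols) {
  D <- gt@dosage[, cols, drop = FALSE]
  n <- 2L * rowSums(!is.na(D))
  c1 <- rowSums(D, na.rm = TRUE)
  bad <- gt@nAlleles > 2L
  n[bad] <- 0L
  c1[bad] <- 0
  list(n = as.numeric(n), c1 = as.numeric(c1), c0 = as.numeric(n) - c1)
}

# internal: sum per-site vectors into windows via an assignWindows() map
.windowSum <- function(x, map, nWindows) {
  out <- numeric(nWindows)
  if (nrow(map)) {
    s <- rowsum(x[map$site], map$window)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Tajima's D from window summaries
#'
#' Evaluates Tajima's standardized difference between the pairwise-diversity
#' and Watterson estimators for a window with `S` segregating sites,
#' summed pairwise-difference proportion `thetaPi`, and `n` sampled
#' haplotypes, using Tajima's constants
#' (`a1 = sum 1/i`, `a2 = sum 1/i^2` for `i < n`,
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`):
#' `D = (thetaPi - S/a1) / sqrt(e1 S + e2 S (S-1))`.
#'
#' @param n Number of haplotypes (>= 4 for a defined variance).
#' @param S Number of segregating sites (vectorised).
#' @param thetaPi Summed per-site pairwise-difference proportions over the
#'   segregating sites (vectorised).
#' @return Tajima's D; `NA` where `S = 0`.
#' @export
tajimaDFromSummary <- function(n, S, thetaPi) {
  stopifnot(length(n) == 1, n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  ifelse(S > 0 & v > 0, (thetaPi - S / a1) / sqrt(v), NA_real_)
}

#' Windowed diversity, divergence and Tajima's D
#'
#' Computes, for every window, within-population nucleotide diversity (Pi),
#' between-population absolute divergence (D_XY), Hudson's F_ST
#' (ratio-of-averages over variant sites; negative values retained), and
#' Tajima's D. Pi and D_XY are ratios of summed per-site differences over
#' summed per-site comparisons across all usable sites -- variant plus
#' invariant -- never means of per-site ratios, so per-genotype missingness
#' does not bias them. A statistic whose denominator is zero in a window is
#' undefined (`NA`), not zero.
#'
#' Tajima's D uses complete-case windows: sites with any missing genotype in
#' the focal population are excluded and `n` is the population's full
#' haplotype count (the fixed-`n` convention of the classical formula).
#'
#' @param gt A filtered [GenotypeTable-class].
#' @param win Result of [assignWindows()] (list with `windows` and `map`).
#' @param populations Population labels to analyse; defaults to all.
#' @param pairs Two-column data.frame (`popA`, `popB`) of pairs; defaults to
#'   [pairwisePlan()] over `populations`.
#' @param minSites Minimum usable sites for a window statistic to be
#'   reported (default 1).
#' @param fstCorrection Use the Bhatia sample-size-corrected Hudson
#'   numerator (default) or the plain `(p1 - p2)^2` form.
#' @return A long-format data.frame with columns `window_id`, `chrom`,
#'   `window_start`, `window_end`, `group` (population or `"A|B"` pair),
#'   `stat` (`"pi"`, `"dxy"`, `"fst"`, `"tajima_d"`), `value`, `n_sites`,
#'   `n_variant_sites`.
#' @seealso [classifyWindows()], [writeWindowStats()]
#' @export
computeWindowStats <- function(gt, win, populations = NULL, pairs = NULL,
                               minSites = 1L, fstCorrection = TRUE) {
  stopifnot(is(gt, "GenotypeTable"))
  if (is.null(populations)) populations <- populationNames(gt)
  if (is.null(pairs) && length(populations) >= 2)
    pairs <- pairwisePlan(populations)
  windows <- win$windows
  map <- win$map
  nW <- nrow(windows)
  counts <- lapply(populations, function(p) .alleleCounts(gt, .popCols(gt, p)))
  names(counts) <- populations

  base <- windows[, c("window_id", "chrom", "start", "end")]
  names(base) <- c("window_id", "chrom", "window_start", "window_end")
  rows <- list()
  emit <- function(group, stat, value, nSites, nVar) {
    value[nSites < minSites] <- NA_real_
    rows[[length(rows) + 1L]] <<- cbind(
      base, data.frame(group = group, stat = stat, value = value,
                       n_sites = as.integer(nSites),
                       n_variant_sites = as.integer(nVar)))
  }

  for (p in populations) {
    ct <- counts[[p]]
    sp <- sitePi(ct$c0, ct$c1)
    diffs <- .windowSum(sp$diffs, map, nW)
    comps <- .windowSum(sp$comparisons, map, nW)
    used <- .windowSum(as.numeric(sp$comparisons > 0), map, nW)
    nvar <- .windowSum(as.numeric(ct$c0 > 0 & ct$c1 > 0), map, nW)
    emit(p, "pi", ifelse(comps > 0, diffs / comps, NA_real_), used, nvar)

    # Tajima's D: complete-case sites, fixed full-sample n
    cols <- .popCols(gt, p)
    nHap <- 2L * length(cols)
    complete <- rowSums(is.na(gt@dosage[, cols, drop = FALSE])) == 0L &
      gt@nAlleles <= 2L
    seg <- complete & ct$c1 > 0 & ct$c1 < nHap
    piProp <- ifelse(seg, (ct$c0 * ct$c1) / (nHap * (nHap - 1) / 2), 0)
    S <- .windowSum(as.numeric(seg), map, nW)
    thetaPi <- .windowSum(piProp, map, nW)
    usedT <- .windowSum(as.numeric(complete), map, nW)
    emit(p, "tajima_d", tajimaDFromSummary(nHap, S, thetaPi), usedT, S)
  }

  if (!is.null(pairs) && nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$popA[r]; b <- pairs$popB[r]
      ca <- counts[[a]]; cb <- counts[[b]]
      pairId <- paste(a, b, sep = "|")

      sd <- siteDxy(ca$c0, ca$c1, cb$c0, cb$c1)
      diffs <- .windowSum(sd$diffs, map, nW)
      comps <- .windowSum(sd$comparisons, map, nW)
      used <- .windowSum(as.numeric(sd$comparisons > 0), map, nW)
      both <- sd$comparisons > 0
      anyVar <- both & (ca$c1 + cb$c1 > 0) & (ca$c0 + cb$c0 > 0)
      nvar <- .windowSum(as.numeric(anyVar), map, nW)
      emit(pairId, "dxy", ifelse(comps > 0, diffs / comps, NA_real_),
           used, nvar)

      p1 <- ifelse(ca$n > 0, ca$c1 / ca$n, NA_real_)
      p2 <- ifelse(cb$n > 0, cb$c1 / cb$n, NA_real_)
      hf <- hudsonFstSite(p1, ca$n, p2, cb$n, correction = fstCorrection)
      num <- .windowSum(hf$numerator, map, nW)
      den <- .windowSum(hf$denominator, map, nW)
      usable <- hf$denominator > 0
      usedF <- .windowSum(as.numeric(usable), map, nW)
      emit(pairId, "fst", ifelse(den > 0, num / den, NA_real_),
           usedF, usedF)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write window statistics as TSV
#'
#' One row per window x statistic, mirroring the long layout of windowed
#' popgen tools: `chrom`, `window_start`, `window_end`, `group`, `stat`,
#' `value`, `n_sites`, `n_variant_sites`. Lines starting with `#` carry
#' provenance metadata.
#'
#' @param stats Output of [computeWindowStats()].
#' @param path Output path.
#' @param meta Optional named character vector echoed into `#` header lines.
#' @return `path`, invisibly.
#' @export
writeWindowStats <- function(stats, path, meta = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  writeLines(paste(c("chrom", "window_start", "window_end", "group", "stat",
                     "value", "n_sites", "n_variant_sites"), collapse = "\t"),
             con)
  df <- stats[, c("chrom", "window_start", "window_end", "group", "stat",
                  "value", "n_sites", "n_variant_sites")]
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = "NA")
  invisible(path)
}
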