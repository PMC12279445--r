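# Builders and independent oracles used across the suite.

# A small GenotypeTable from a dosage matrix (sites x samples).
# populations: character vector per sample (NA = outgroup member).
makeGT <- function(dos, populations, outgroup = character(),
                   chrom = "chr1", pos = seq_len(nrow(dos)),
                   ref = NULL, alt = NULL, depth = NULL, qual = NULL,
                   nAlleles = NULL) {
  dos <- as.matrix(dos)
  storage.mode(dos) <- "integer"
  ns <- ncol(dos)
  ids <- colnames(dos)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(ns))
  colnames(dos) <- ids
  if (is.null(ref)) ref <- rep("A", nrow(dos))
  if (is.null(alt)) {
    variant <- rowSums(dos > 0, na.rm = TRUE) > 0
    alt <- ifelse(variant, "T", ".")
  }
  pops <- populations
  names(pops) <- ids
  pops <- pops[!is.na(pops)]
  GenotypeTable(chrom = rep(chrom, length.out = nrow(dos)), pos = pos,
                ref = ref, alt = alt, dosage = dos, samples = ids,
                populations = pops, outgroup = ids[is.na(populations)],
                depth = depth, qual = qual, nAlleles = nAlleles)
}

# Expand a dosage vector into haplotype alleles (NA genotype -> dropped).
.haplotypes <- function(dosVec) {
  h <- c()
  for (d in dosVec[!is.na(dosVec)]) {
    h <- c(h, switch(as.character(d), "0" = c(0, 0), "1" = c(0, 1),
                     "2" = c(1, 1)))
  }
  h
}

# Exhaustive pairwise-enumeration window Pi for one population.
oraclePi <- function(dos) {
  diffs <- comps <- 0
  for (s in seq_len(nrow(dos))) {
    h <- .haplotypes(dos[s, ])
    n <- length(h)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      comps <- comps + 1
      if (h[i] != h[j]) diffs <- diffs + 1
    }
  }
  if (comps == 0) NA_real_ else diffs / comps
}

# Exhaustive cross-population enumeration window D_XY.
oracleDxy <- function(dosA, dosB) {
  diffs <- comps <- 0
  for (s in seq_len(nrow(dosA))) {
    ha <- .haplotypes(dosA[s, ])
    hb <- .haplotypes(dosB[s, ])
    if (!length(ha) || !length(hb)) next
    for (x in ha) for (y in hb) {
      comps <- comps + 1
      if (x != y) diffs <- diffs + 1
    }
  }
  if (comps == 0) NA_real_ else diffs / comps
}

# Independent Hudson F_ST (Bhatia sample-size-corrected ratio of sums),
# written directly from haplotype enumeration per site.
oracleFst <- function(dosA, dosB) {
  num <- den <- 0
  for (s in seq_len(nrow(dosA))) {
    ha <- .haplotypes(dosA[s, ])
    hb <- .haplotypes(dosB[s, ])
    n1 <- length(ha); n2 <- length(hb)
    if (n1 < 2 || n2 < 2) next
    p1 <- mean(ha); p2 <- mean(hb)
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  if (den == 0) NA_real_ else num / den
}

# Independent Tajima's D for a complete-case window: n haplotypes,
# per-site derived-allele counts over segregating sites.
oracleTajimaD <- function(n, derivedCounts) {
  seg <- derivedCounts[derivedCounts > 0 & derivedCounts < n]
  S <- length(seg)
  if (S == 0) return(NA_real_)
  thetaPi <- sum(seg * (n - seg)) / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (thetaPi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Random small fixture: two populations of diploid genotypes with missing
# entries, plus invariant sites.
randomFixture <- function(nA = 4, nB = 5, nSitesV = 20, nSitesI = 10,
                          missRate = 0.15) {
  nS <- nSitesV + nSitesI
  dos <- matrix(0L, nS, nA + nB)
  for (s in seq_len(nSitesV)) {
    p <- runif(1, 0.05, 0.95)
    dos[s, ] <- rbinom(nA + nB, 2, p)
  }
  dos[runif(length(dos)) < missRate] <- NA_integer_
  dos <- dos[sample(nS), , drop = FALSE]
  makeGT(dos, c(rep("A", nA), rep("B", nB)))
}

# One-region manifest covering a whole contig (0-based half-open).
oneRegion <- function(len, chrom = "chr1", genic = 0L, frame = ".",
                      id = "r1") {
  data.frame(region_id = id, chrom = chrom, start = 0L, end = as.integer(len),
             genic = as.integer(genic), frame = as.character(frame),
             stringsAsFactors = FALSE)
}

# Long stats row shortcut used by classifier tests.
statRows <- function(windowIds, group, stat, values) {
  data.frame(window_id = windowIds, chrom = "chr1",
             window_start = seq_along(windowIds), window_end = seq_along(windowIds),
             group = group, stat = stat, value = values,
             n_sites = 1L, n_variant_sites = 1L, stringsAsFactors = FALSE)
}
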