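.SCENARIOS <- c("divergence_with_gene_flow", "allopatric_selection",
                "recurrent_selection", "balancing_selection")
.SCENARIO_SHORT <- c(divergence_with_gene_flow = "gene_flow",
                     allopatric_selection = "allopatric",
                     recurrent_selection = "recurrent",
                     balancing_selection = "balancing")

#' Z-standardize window values for one pairwise comparison
#'
#' `z = (x - mean) / sd` with mean and sd taken over all windows of the
#' comparison with a defined value. The population (divide-by-N) standard
#' deviation is the default. A constant vector has `sd = 0`: every z is
#' undefined and the comparison is flagged via the `"degenerate"` attribute.
#'
#' @param x Numeric window values (`NA` = undefined window).
#' @param sdType `"population"` (divide by N) or `"sample"` (divide by N-1).
#' @return Numeric vector of z-scores (`NA` where `x` is `NA` or the sd is
#'   zero), with attribute `degenerate = TRUE` when sd was zero.
#' @export
standardizeValues <- function(x, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  ok <- !is.na(x)
  if (sum(ok) < 2) {
    z <- rep(NA_real_, length(x))
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  m <- mean(x[ok])
  s <- if (sdType == "population") sqrt(mean((x[ok] - m)^2)) else sd(x[ok])
  if (!is.finite(s) || s == 0) {
    z <- rep(NA_real_, length(x))
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  z <- (x - m) / s
  attr(z, "degenerate") <- FALSE
  z
}

#' Assign an evolutionary scenario from z-scored window statistics
#'
#' Applies the four SD-threshold rules in fixed order (first match wins, so
#' the categories are mutually exclusive):
#'
#' 1. `divergence_with_gene_flow`: F_ST > 2 SD, D_XY > 3 SD, Pi < 3 SD
#' 2. `allopatric_selection`: F_ST > 2 SD, D_XY < 3 SD, Pi < 1 SD
#' 3. `recurrent_selection`: F_ST > 1 SD, D_XY < 1 SD, Pi < 1 SD
#' 4. `balancing_selection`: F_ST < 3 SD, D_XY > 3 SD, Pi > 3 SD
#'
#' "< k SD" is ambiguous between an upper and a lower boundary. The default
#' `semantics = "two-sided"` reads the D_XY/Pi thresholds against explicit
#' upper (+3 SD) and lower (-1 SD) boundaries: "< 3 SD" means `z < +3`
#' (below the upper boundary) and "< 1 SD" means `z < -1` (below the lower
#' boundary), while "> k SD" always means `z > +k`. `semantics = "upper"`
#' instead reads every threshold above the mean (`"< k SD"` means `z < +k`).
#'
#' @param zFst,zDxy,zPi Z-scores (vectorised; any `NA` gives `"none"`).
#' @param semantics Threshold reading, `"two-sided"` (default) or `"upper"`.
#' @return Character vector: a scenario name or `"none"`.
#' @export
classifyScenario <- function(zFst, zDxy, zPi,
                             semantics = c("two-sided", "upper")) {
  semantics <- match.arg(semantics)
  lo <- if (semantics == "two-sided") -1 else 1
  piHi <- 3
  out <- rep("none", length(zFst))
  ok <- !is.na(zFst) & !is.na(zDxy) & !is.na(zPi)
  gf <- ok & zFst > 2 & zDxy > 3 & zPi < piHi
  al <- ok & !gf & zFst > 2 & zDxy < 3 & zPi < lo
  re <- ok & !gf & !al & zFst > 1 & zDxy < lo & zPi < lo
  ba <- ok & !gf & !al & !re & zFst < 3 & zDxy > 3 & zPi > 3
  out[gf] <- "divergence_with_gene_flow"
  out[al] <- "allopatric_selection"
  out[re] <- "recurrent_selection"
  out[ba] <- "balancing_selection"
  out
}

# internal: wide per-window view of one pair's fst, dxy and averaged pi
.pairWide <- function(stats, popA, popB) {
  pairId <- paste(popA, popB, sep = "|")
  pairIdRev <- paste(popB, popA, sep = "|")
  pick <- function(stat, group) {
    s <- stats[stats$stat == stat & stats$group %in% group, ]
    s[!duplicated(s$window_id), c("window_id", "chrom", "window_start",
                                  "window_end", "value")]
  }
  fst <- pick("fst", c(pairId, pairIdRev))
  dxy <- pick("dxy", c(pairId, pairIdRev))
  piA <- pick("pi", popA)
  piB <- pick("pi", popB)
  w <- fst[, c("window_id", "chrom", "window_start", "window_end")]
  w$fst <- fst$value
  w$dxy <- dxy$value[match(w$window_id, dxy$window_id)]
  pa <- piA$value[match(w$window_id, piA$window_id)]
  pb <- piB$value[match(w$window_id, piB$window_id)]
  w$pi <- (pa + pb) / 2
  w
}

#' Classify every window of a pairwise comparison
#'
#' Builds the per-window (F_ST, D_XY, averaged Pi) triples for one
#' population pair from long-format window statistics, z-standardizes each
#' statistic over the comparison's windows (Pi first averaged between the
#' two populations), and applies [classifyScenario()]. Windows with any
#' undefined statistic are excluded from the mean/sd computation and are
#' never classified.
#'
#' @param stats Long-format output of [computeWindowStats()].
#' @param popA,popB The two population labels of the comparison.
#' @param semantics,sdType Passed to [classifyScenario()] /
#'   [standardizeValues()].
#' @return data.frame with `window_id`, `chrom`, `window_start`,
#'   `window_end`, `pair`, raw `fst`/`dxy`/`pi`, `z_fst`/`z_dxy`/`z_pi` and
#'   `scenario`. Attribute `degenerate` is `TRUE` when any statistic had
#'   zero spread (then nothing is classified).
#' @export
classifyWindows <- function(stats, popA, popB,
                            semantics = c("two-sided", "upper"),
                            sdType = c("population", "sample")) {
  semantics <- match.arg(semantics)
  sdType <- match.arg(sdType)
  w <- .pairWide(stats, popA, popB)
  w$pair <- paste(popA, popB, sep = "|")
  zf <- standardizeValues(w$fst, sdType)
  zd <- standardizeValues(w$dxy, sdType)
  zp <- standardizeValues(w$pi, sdType)
  w$z_fst <- as.numeric(zf)
  w$z_dxy <- as.numeric(zd)
  w$z_pi <- as.numeric(zp)
  w$scenario <- classifyScenario(w$z_fst, w$z_dxy, w$z_pi, semantics)
  w <- w[, c("window_id", "chrom", "window_start", "window_end", "pair",
             "fst", "dxy", "pi", "z_fst", "z_dxy", "z_pi", "scenario")]
  attr(w, "degenerate") <- isTRUE(attr(zf, "degenerate")) ||
    isTRUE(attr(zd, "degenerate")) || isTRUE(attr(zp, "degenerate"))
  w
}

#' Per-pair scenario counts
#'
#' Tabulates one comparison's scenario calls into the standard summary
#' shape: one row per pair with columns `pair`, `gene_flow`, `allopatric`,
#' `recurrent`, `balancing` and `total_windows` (windows with all three
#' statistics defined).
#'
#' @param calls Output of [classifyWindows()] (one pair).
#' @return One-row data.frame.
#' @seealso [aggregateScenarios()]
#' @export
scenarioSummary <- function(calls) {
  defined <- !is.na(calls$z_fst) & !is.na(calls$z_dxy) & !is.na(calls$z_pi)
  counts <- vapply(.SCENARIOS, function(s) sum(calls$scenario == s),
                   integer(1))
  out <- data.frame(pair = calls$pair[1], t(counts), sum(defined),
                    stringsAsFactors = FALSE)
  names(out) <- c("pair", unname(.SCENARIO_SHORT[.SCENARIOS]), "total_windows")
  out
}

#' Linear and rank association between D_XY and averaged Pi
#'
#' Ordinary-least-squares slope of window D_XY on the pair-averaged window
#' Pi, plus the Spearman rank correlation, over windows where both are
#' defined.
#'
#' @param dxy,pi Numeric window vectors (or pass a [classifyWindows()]
#'   data.frame as `dxy` and leave `pi` missing).
#' @return list with `slope`, `rho` and `n` (windows used); `slope`/`rho`
#'   are `NA` with fewer than 3 complete windows or degenerate variance.
#' @export
dxyPiRelationship <- function(dxy, pi) {
  if (is.data.frame(dxy) && missing(pi)) {
    pi <- dxy$pi
    dxy <- dxy$dxy
  }
  ok <- !is.na(dxy) & !is.na(pi)
  n <- sum(ok)
  if (n < 3 || stats::var(pi[ok]) == 0 || stats::var(dxy[ok]) == 0)
    return(list(slope = NA_real_, rho = NA_real_, n = n))
  fit <- lm(dxy[ok] ~ pi[ok])
  rho <- suppressWarnings(cor(dxy[ok], pi[ok], method = "spearman"))
  list(slope = unname(coef(fit)[2]), rho = rho, n = n)
}

#' Outlier-F_ST windows and their genic regions
#'
#' Returns the windows whose z-standardized F_ST strictly exceeds +3 SD and
#' maps each to the genic regions it overlaps in the target-region manifest
#' (any interval overlap assigns the gene; a window overlapping no genic
#' region is reported with an empty gene list).
#'
#' @param calls Output of [classifyWindows()] (provides `z_fst` and window
#'   coordinates), or any data.frame with `window_id`, `chrom`,
#'   `window_start`, `window_end`, `z_fst`.
#' @param regions Region manifest data.frame; genic rows (`genic == 1`)
#'   provide the gene intervals. `NULL` skips the mapping.
#' @param threshold Outlier threshold in SD units (strict `>`; default 3).
#' @return data.frame of outlier windows with a `genes` column
#'   (comma-separated region ids, `""` when none).
#' @export
fstOutlierWindows <- function(calls, regions = NULL, threshold = 3) {
  out <- calls[!is.na(calls$z_fst) & calls$z_fst > threshold, , drop = FALSE]
  out$genes <- character(nrow(out))
  if (!is.null(regions) && nrow(out)) {
    gen <- regions[regions$genic == 1L, , drop = FALSE]
    if (nrow(gen)) {
      winGr <- GenomicRanges::GRanges(out$chrom,
        IRanges::IRanges(out$window_start, out$window_end))
      genGr <- GenomicRanges::GRanges(gen$chrom,
        IRanges::IRanges(gen$start + 1L, gen$end))
      hits <- GenomicRanges::findOverlaps(winGr, genGr)
      gl <- split(gen$region_id[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
      out$genes[as.integer(names(gl))] <-
        vapply(gl, function(g) paste(unique(g), collapse = ","), character(1))
    }
  }
  rownames(out) <- NULL
  out
}
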