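#' Enumerate pairwise population comparisons
#'
#' All unordered pairs of the unique population labels, in deterministic
#' lexicographic order (so five populations give ten comparisons).
#'
#' @param populations Character vector of population labels (duplicates
#'   collapse to one population; no self-pairs).
#' @return data.frame with columns `popA`, `popB` and `pair`
#'   (`"popA|popB"`).
#' @export
pairwisePlan <- function(populations) {
  labs <- sort(unique(as.character(populations)))
  if (length(labs) < 2)
    stop("need at least two distinct population labels, got ", length(labs))
  cmb <- combn(labs, 2)
  data.frame(popA = cmb[1, ], popB = cmb[2, ],
             pair = paste(cmb[1, ], cmb[2, ], sep = "|"),
             stringsAsFactors = FALSE)
}

#' Aggregate scenario counts across pairwise comparisons
#'
#' Column-sums a per-comparison scenario count table (one row per pair,
#' columns `gene_flow`, `allopatric`, `recurrent`, `balancing`,
#' `total_windows`) into per-scenario totals plus the grand total of windows
#' analysed. Row order never matters.
#'
#' @param summaryTable data.frame as produced by [scenarioSummary()]
#'   (rbind-ed over comparisons).
#' @return Named numeric vector with `gene_flow`, `allopatric`, `recurrent`,
#'   `balancing` and `total_windows` totals.
#' @export
aggregateScenarios <- function(summaryTable) {
  need <- c("gene_flow", "allopatric", "recurrent", "balancing",
            "total_windows")
  missingCols <- setdiff(need, names(summaryTable))
  if (length(missingCols))
    stop("scenario summary table lacks columns: ",
         paste(missingCols, collapse = ", "))
  vapply(need, function(cn) sum(as.numeric(summaryTable[[cn]])), numeric(1))
}

#' Validate a target-region manifest
#'
#' Checks schema and coordinate sanity (0-based half-open, `start < end`),
#' that `genic` is 0/1 and `frame` is 0/1/2 or `.`, and that the genic +
#' non-genic split adds up to the manifest total (optionally against
#' expected counts, e.g. a capture kit's published composition).
#'
#' @param regions Region manifest data.frame.
#' @param expectTotal,expectGenic,expectNongenic Optional expected counts;
#'   a mismatch is an error.
#' @return list with `n`, `genic`, `nongenic`, invisibly on success.
#' @export
validateRegions <- function(regions, expectTotal = NULL, expectGenic = NULL,
                            expectNongenic = NULL) {
  need <- c("region_id", "chrom", "start", "end", "genic", "frame")
  missingCols <- setdiff(need, names(regions))
  if (length(missingCols))
    stop("region manifest lacks columns: ", paste(missingCols, collapse = ", "))
  if (anyDuplicated(regions$region_id))
    stop("duplicated region ids in manifest")
  if (any(regions$start < 0L) || any(regions$end <= regions$start))
    stop("regions must satisfy 0 <= start < end (0-based half-open)")
  if (!all(regions$genic %in% c(0L, 1L)))
    stop("genic flag must be 0 or 1")
  if (!all(regions$frame %in% c("0", "1", "2", ".")))
    stop("frame must be 0, 1, 2 or '.'")
  nGenic <- sum(regions$genic == 1L)
  nNon <- sum(regions$genic == 0L)
  if (nGenic + nNon != nrow(regions))
    stop("genic + nongenic does not equal the manifest total")
  chk <- function(got, want, what) {
    if (!is.null(want) && got != want)
      stop(sprintf("manifest has %d %s regions, expected %d", got, what, want))
  }
  chk(nrow(regions), expectTotal, "total")
  chk(nGenic, expectGenic, "genic")
  chk(nNon, expectNongenic, "non-genic")
  invisible(list(n = nrow(regions), genic = nGenic, nongenic = nNon))
}

#' Run the full genome-scan pipeline
#'
#' Orchestrates ingest (or takes an in-memory [GenotypeTable-class]),
#' genotype- and site-level filtering, window assignment, window statistics,
#' per-pair scenario classification, F_ST outlier detection, per-gene dN/dS
#' with outlier detection, and the divergent-selection concordance set.
#' All tables are written as TSV under `outDir` together with an
#' `output_manifest.tsv` of MD5 checksums, so reruns on identical inputs are
#' byte-identical.
#'
#' @param vcf Path to an all-sites VCF, or a [GenotypeTable-class] (then
#'   `popmap`/`outgroup` are ignored).
#' @param popmap Popmap path or named vector (see [readGenotypeVcf()]).
#' @param regions Region manifest path or data.frame.
#' @param outgroup Outgroup list path or character vector.
#' @param outDir Output directory (created if needed). `NULL` skips writing.
#' @param filter A [filterConfig()].
#' @param windowBp,step Window tiling, see [assignWindows()].
#' @param pairs Optional two-column data.frame restricting the pairwise
#'   comparisons (default: all pairs).
#' @param semantics,sdType Classifier conventions, see [classifyWindows()].
#' @param fstCorrection,minSites See [computeWindowStats()].
#' @param dndsMaxMissing,fixedRule See [geneDnDs()].
#' @return (invisibly) list with `genotypes`, `stats`, `calls` (per pair),
#'   `summary`, `totals`, `fstOutliers`, `dnds`, `dndsOutliers`,
#'   `divergentSelection`, `relationships`, and `files` (paths written).
#' @export
runPipeline <- function(vcf, popmap = NULL, regions, outgroup = character(),
                        outDir = NULL,
                        filter = filterConfig(),
                        windowBp = 10000L, step = windowBp,
                        pairs = NULL,
                        semantics = c("two-sided", "upper"),
                        sdType = c("population", "sample"),
                        fstCorrection = TRUE, minSites = 1L,
                        dndsMaxMissing = 0.5,
                        fixedRule = c("disjoint", "strict")) {
  semantics <- match.arg(semantics)
  sdType <- match.arg(sdType)
  fixedRule <- match.arg(fixedRule)
  if (is.character(regions)) regions <- readRegions(regions)
  validateRegions(regions)
  gt <- if (is(vcf, "GenotypeTable")) vcf
        else readGenotypeVcf(vcf, popmap, outgroup)

  gt <- filterSites(filterGenotypes(gt, filter), filter)
  win <- assignWindows(gt, regions, windowBp = windowBp, step = step)
  if (is.null(pairs)) pairs <- pairwisePlan(populationNames(gt))
  stats <- computeWindowStats(gt, win, pairs = pairs, minSites = minSites,
                              fstCorrection = fstCorrection)

  calls <- list()
  summaries <- list()
  rel <- list()
  fstGenes <- list()
  outlierRows <- list()
  for (r in seq_len(nrow(pairs))) {
    cl <- classifyWindows(stats, pairs$popA[r], pairs$popB[r],
                          semantics = semantics, sdType = sdType)
    pid <- pairs$pair[r]
    calls[[pid]] <- cl
    summaries[[pid]] <- scenarioSummary(cl)
    rr <- dxyPiRelationship(cl)
    rel[[pid]] <- data.frame(pair = pid, slope = rr$slope, rho = rr$rho,
                             n = rr$n)
    fo <- fstOutlierWindows(cl, regions)
    fstGenes[[pid]] <- setdiff(unique(unlist(strsplit(fo$genes, ","))), "")
    if (nrow(fo)) outlierRows[[pid]] <- fo
  }
  summaryTab <- do.call(rbind, summaries)
  rownames(summaryTab) <- NULL
  totals <- aggregateScenarios(summaryTab)

  dnds <- if (length(gt@outgroup))
    geneDnDs(gt, regions, maxMissing = dndsMaxMissing, rule = fixedRule)
  else NULL
  dOut <- if (!is.null(dnds) && nrow(dnds)) dndsOutliers(dnds) else NULL
  divergent <- if (!is.null(dOut))
    divergentSelectionGenes(fstGenes, dOut$union) else character(0)

  files <- character(0)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name) {
      p <- file.path(outDir, name)
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                  na = "NA")
      files[[length(files) + 1L]] <<- p
      p
    }
    writeWindowStats(stats, file.path(outDir, "window_stats.tsv"),
                     meta = c(windows_bp = windowBp))
    files[[length(files) + 1L]] <- file.path(outDir, "window_stats.tsv")
    wt(do.call(rbind, c(calls, list(make.row.names = FALSE))),
       "scenario_calls.tsv")
    wt(summaryTab, "scenario_summary.tsv")
    wt(data.frame(scenario = names(totals), windows = as.numeric(totals)),
       "scenario_totals.tsv")
    wt(do.call(rbind, c(rel, list(make.row.names = FALSE))),
       "dxy_pi_relationship.tsv")
    if (length(outlierRows))
      wt(do.call(rbind, c(outlierRows, list(make.row.names = FALSE))),
         "fst_outlier_windows.tsv")
    if (!is.null(dnds)) wt(dnds, "gene_dnds.tsv")
    if (!is.null(dOut)) {
      wt(dOut$thresholds, "dnds_outlier_thresholds.tsv")
      wt(data.frame(gene = dOut$union), "dnds_outlier_genes.tsv")
    }
    wt(data.frame(gene = divergent), "divergent_selection_genes.tsv")
    manifest <- data.frame(file = basename(unlist(files)),
                           md5 = unname(tools::md5sum(unlist(files))))
    write.table(manifest, file.path(outDir, "output_manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  invisible(list(genotypes = gt, stats = stats, calls = calls,
                 summary = summaryTab, totals = totals,
                 fstOutliers = outlierRows, fstOutlierGenes = fstGenes,
                 dnds = dnds, dndsOutliers = dOut,
                 divergentSelection = divergent,
                 relationships = do.call(rbind, rel),
                 files = unlist(files)))
}
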