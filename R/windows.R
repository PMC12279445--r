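#' Tile target regions into analysis windows
#'
#' Cuts each region of the manifest into consecutive `windowBp` tiles
#' starting at the region start (the last tile may be short). Windows are
#' reported in VCF-style 1-based inclusive coordinates: window `w` of a
#' region starting at 0-based `s` covers positions `s + (w-1)*windowBp + 1`
#' to `s + w*windowBp`. With `step < windowBp` the tiling becomes a sliding
#' window and tiles overlap.
#'
#' @param regions Region manifest data.frame (see [readRegions()]).
#' @param windowBp Window length in bp.
#' @param step Step between window starts; defaults to `windowBp`
#'   (non-overlapping tiles).
#' @return data.frame with `window_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), `region_id`.
#' @export
tileWindows <- function(regions, windowBp = 10000L, step = windowBp) {
  stopifnot(windowBp >= 1L, step >= 1L)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$start[i]
    e <- regions$end[i]
    starts <- seq.int(s, max(s, e - 1L), by = step)
    data.frame(chrom = regions$chrom[i],
               start = starts + 1L,
               end = pmin(starts + windowBp, e),
               region_id = regions$region_id[i],
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, out)
  w <- w[w$end >= w$start, , drop = FALSE]
  w$window_id <- sprintf("%s:%d-%d", w$chrom, w$start, w$end)
  rownames(w) <- NULL
  w[, c("window_id", "chrom", "start", "end", "region_id")]
}

#' Assign each site of a GenotypeTable to analysis windows
#'
#' Maps sites to the windows produced by [tileWindows()]. Sites on a contig
#' not covered by any region are assigned to an ad-hoc chromosome-level
#' tiling (anchored at position 1) and flagged with `in_region = FALSE`.
#' With the default non-overlapping tiling each site maps to exactly one
#' window; with a sliding `step` a site may map to several.
#'
#' @param gt A [GenotypeTable-class].
#' @param regions Region manifest data.frame.
#' @param windowBp Window length in bp.
#' @param step Step between window starts (see [tileWindows()]).
#' @return A list with `windows` (the window table, including windows that
#'   contain no genotyped site) and `map`, a data.frame with `site` (row
#'   index into `gt`), `window` (row index into `windows`) and `in_region`.
#' @export
assignWindows <- function(gt, regions, windowBp = 10000L, step = windowBp) {
  windows <- tileWindows(regions, windowBp, step)
  windows$in_region <- TRUE
  siteGr <- GenomicRanges::GRanges(gt@chrom,
                                   IRanges::IRanges(gt@pos, gt@pos))
  regGr <- GenomicRanges::GRanges(regions$chrom,
                                  IRanges::IRanges(regions$start + 1L,
                                                   regions$end))
  orphan <- !IRanges::overlapsAny(siteGr, regGr)
  if (any(orphan)) {
    oc <- unique(gt@chrom[orphan])
    lens <- vapply(split(gt@pos[orphan], gt@chrom[orphan])[oc], max, integer(1))
    extra <- tileWindows(data.frame(region_id = paste0(oc, "_unassigned"),
                                    chrom = oc, start = 0L, end = lens,
                                    genic = 0L, frame = ".",
                                    stringsAsFactors = FALSE),
                         windowBp, step)
    extra$in_region <- FALSE
    # keep only off-region tiles that actually host an orphan site
    windows <- rbind(windows, extra)
  }
  winGr <- GenomicRanges::GRanges(windows$chrom,
                                  IRanges::IRanges(windows$start, windows$end))
  hits <- GenomicRanges::findOverlaps(siteGr, winGr)
  map <- data.frame(site = S4Vectors::queryHits(hits),
                    window = S4Vectors::subjectHits(hits))
  map$in_region <- windows$in_region[map$window]
  # a site inside a region must not also feed that chromosome's ad-hoc tiling
  drop <- !orphan[map$site] & !map$in_region
  map <- map[!drop, , drop = FALSE]
  rownames(map) <- NULL
  list(windows = windows, map = map)
}
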