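#' Tile scaffolds into non-overlapping genomic windows
#'
#' Produces the 50-kb tiling used by all windowed statistics.  Windows are
#' half-open `[k*w, (k+1)*w)` internally (returned as 1-based inclusive
#' GRanges, the reporting convention); terminal partial windows are
#' retained and flagged in the `partial` metadata column.
#'
#' @param scaffoldLengths named numeric vector of scaffold lengths in bp,
#'   or a [HaplotypeMatrix-class].
#' @param windowSize window width in bp (default 50,000).
#' @return a [GenomicRanges::GRanges] tiling with a `partial` mcol.
#' @examples
#' length(makeWindows(c(chr = 25e6)))      # 500
#' makeWindows(c(s = 125000), 50000)       # 2 full + 1 partial
#' @export
makeWindows <- function(scaffoldLengths, windowSize = 50000) {
  if (is(scaffoldLengths, "HaplotypeMatrix")) {
    sl <- stats::setNames(scaffoldLength(scaffoldLengths),
                          scaffoldName(scaffoldLengths))
  } else sl <- scaffoldLengths
  stopifnot(all(sl >= 1), !is.null(names(sl)))
  sl <- floor(sl)
  parts <- lapply(names(sl), function(sc) {
    starts <- seq(1, sl[[sc]], by = windowSize)
    GenomicRanges::GRanges(
      sc, IRanges::IRanges(starts, pmin(starts + windowSize - 1, sl[[sc]])),
      seqinfo = GenomeInfoDb::Seqinfo(names(sl), unname(sl)))
  })
  gr <- do.call(c, parts)
  S4Vectors::mcols(gr)$partial <- GenomicRanges::width(gr) < windowSize
  gr
}

# map window GRanges on one scaffold to site-index ranges in `hap`;
# returns list(from, to, width) with from > to for windows without sites
.windowSiteIndex <- function(hap, windows) {
  keep <- as.character(GenomeInfoDb::seqnames(windows)) == scaffoldName(hap)
  if (!all(keep)) windows <- windows[keep]
  pos <- sitePositions(hap)
  from <- findInterval(GenomicRanges::start(windows) - 1L, pos) + 1L
  to <- findInterval(GenomicRanges::end(windows), pos)
  list(windows = windows, from = from, to = to,
       width = GenomicRanges::width(windows))
}

# aggregate per-site values over windows: sums of `x` and of `callable`
.windowAggregate <- function(positions, x, callable, starts, ends) {
  x[!callable] <- 0
  csx <- cumsum(x)
  csn <- cumsum(as.numeric(callable))
  i0 <- findInterval(starts - 1L, positions)
  i1 <- findInterval(ends, positions)
  at <- function(cs, i) ifelse(i >= 1, cs[pmax(i, 1L)], 0)
  list(sum = at(csx, i1) - at(csx, i0), n = at(csn, i1) - at(csn, i0))
}

.windowRecord <- function(windows, statistic, value, nUsed, nPossible,
                          minCallableFrac, extra = list()) {
  value[!(nUsed > minCallableFrac * nPossible)] <- NA_real_
  mc <- S4Vectors::DataFrame(statistic = statistic, value = value,
                             nSitesUsed = as.integer(nUsed),
                             nSitesPossible = as.integer(nPossible))
  for (nm in names(extra)) mc[[nm]] <- extra[[nm]]
  out <- windows
  S4Vectors::mcols(out) <- mc
  out
}

#' Export window records as a BED-compatible data.frame
#'
#' Converts a window-statistic GRanges (1-based inclusive) to 0-based
#' half-open BED coordinates.
#'
#' @param records a GRanges as returned by the window statistics.
#' @return data.frame with `chrom`, `chromStart`, `chromEnd` and the
#'   metadata columns.
#' @export
windowsToBed <- function(records) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(records)),
             chromStart = GenomicRanges::start(records) - 1L,
             chromEnd = GenomicRanges::end(records),
             as.data.frame(S4Vectors::mcols(records)),
             stringsAsFactors = FALSE)
}
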