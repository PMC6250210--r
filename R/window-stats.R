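# Per-site allele counts for one population: nsites x 5 integer matrix with
# counts of A, C, G, T alleles and of heterozygous (IUPAC two-base) calls.
.popCounts <- function(hap, popmap, population) {
  idx <- .popSamples(popmap, population, hap)
  .site_counts_cpp(callMatrix(hap), as.integer(idx), ploidy(hap))
}

.resolveWindows <- function(hap, windows, windowSize = 50000) {
  if (is.null(windows)) makeWindows(hap, windowSize) else windows
}

#' Windowed nucleotide diversity (pi)
#'
#' Nei's mean intrapopulation nucleotide diversity.  Per site with allele
#' counts `c_i` of `n` called alleles (`n >= 2`), the unbiased per-site
#' heterozygosity is `(n(n-1) - sum c_i (c_i - 1)) / (n(n-1))`
#' (equivalently `2c(n-c)/(n(n-1))` at a biallelic site); the window value
#' is the mean over callable sites, monomorphic sites contributing 0.
#' Windows whose callable-site count does not exceed
#' `minCallableFrac * width` are reported NA.
#'
#' @param hap a [HaplotypeMatrix-class].
#' @param popmap a [populationMap()] data.frame.
#' @param population population (or role) label.
#' @param windows GRanges of windows; default: non-overlapping 50-kb tiling.
#' @param minCallableFrac minimum callable fraction of the window (default
#'   0.2, i.e. >20% of sites genotyped).
#' @return GRanges with mcols `statistic`, `value`, `nSitesUsed`,
#'   `nSitesPossible`, `population`.
#' @export
piWindows <- function(hap, popmap, population, windows = NULL,
                      minCallableFrac = 0.2) {
  windows <- .resolveWindows(hap, windows)
  cnt <- .popCounts(hap, popmap, population)
  n <- rowSums(cnt[, 1:4, drop = FALSE])
  callable <- n >= 2
  nn1 <- n * (n - 1)
  het <- cnt[, 1:4, drop = FALSE]
  piSite <- (nn1 - rowSums(het * (het - 1))) / ifelse(nn1 > 0, nn1, 1)
  piSite[!callable] <- 0
  ag <- .windowAggregate(sitePositions(hap), piSite, callable,
                         GenomicRanges::start(windows),
                         GenomicRanges::end(windows))
  value <- ifelse(ag$n > 0, ag$sum / ag$n, NA_real_)
  .windowRecord(windows, "pi", value, ag$n, GenomicRanges::width(windows),
                minCallableFrac, list(population = population))
}

# per-site dxy and joint callability between two populations
.dxySites <- function(cntA, cntB) {
  nA <- rowSums(cntA[, 1:4, drop = FALSE])
  nB <- rowSums(cntB[, 1:4, drop = FALSE])
  callable <- nA >= 1 & nB >= 1
  fA <- cntA[, 1:4, drop = FALSE] / ifelse(nA > 0, nA, 1)
  fB <- cntB[, 1:4, drop = FALSE] / ifelse(nB > 0, nB, 1)
  d <- 1 - rowSums(fA * fB)
  d[!callable] <- 0
  list(d = d, callable = callable)
}

#' Windowed absolute divergence (dXY)
#'
#' Nei's absolute divergence: the mean per-site probability that two
#' alleles, one drawn from each population, differ.  Per site
#' `d = 1 - sum_b pA_b * pB_b` over the four bases (equal to
#' `pA(1-pB) + pB(1-pA)` at a biallelic site); the window value is the mean
#' over sites callable in both populations.
#'
#' @inheritParams piWindows
#' @param popA,popB the two population (or role) labels.
#' @return GRanges with mcols `statistic`, `value`, `nSitesUsed`,
#'   `nSitesPossible`, `popA`, `popB`.
#' @export
dxyWindows <- function(hap, popmap, popA, popB, windows = NULL,
                       minCallableFrac = 0.2) {
  windows <- .resolveWindows(hap, windows)
  s <- .dxySites(.popCounts(hap, popmap, popA), .popCounts(hap, popmap, popB))
  ag <- .windowAggregate(sitePositions(hap), s$d, s$callable,
                         GenomicRanges::start(windows),
                         GenomicRanges::end(windows))
  value <- ifelse(ag$n > 0, ag$sum / ag$n, NA_real_)
  .windowRecord(windows, "dxy", value, ag$n, GenomicRanges::width(windows),
                minCallableFrac, list(popA = popA, popB = popB))
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# Inputs are the 5-column count matrices; ploidy 1 treats every haploid
# allele as an individual with zero heterozygosity.
.wcSiteComponents <- function(cntA, cntB, ploidyVal) {
  aA <- cntA[, 1:4, drop = FALSE]
  aB <- cntB[, 1:4, drop = FALSE]
  nA <- rowSums(aA)
  nB <- rowSums(aB)
  u <- aA + aB
  present <- u > 0
  nAlleles <- rowSums(present)
  biallelic <- nAlleles == 2
  b1 <- max.col(present, ties.method = "first")
  i <- seq_len(nrow(aA))
  pA <- aA[cbind(i, b1)] / ifelse(nA > 0, nA, 1)
  pB <- aB[cbind(i, b1)] / ifelse(nB > 0, nB, 1)
  n1 <- nA / ploidyVal
  n2 <- nB / ploidyVal
  h1 <- if (ploidyVal == 2) cntA[, 5] / ifelse(n1 > 0, n1, 1) else 0
  h2 <- if (ploidyVal == 2) cntB[, 5] / ifelse(n2 > 0, n2, 1) else 0
  r <- 2
  nbar <- (n1 + n2) / r
  ok <- biallelic & n1 >= 1 & n2 >= 1 & (n1 + n2) > 2 & nA >= 2 & nB >= 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * pA + n2 * pB) / (r * nbar)
  s2 <- (n1 * (pA - pbar)^2 + n2 * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) * hbar / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- 0; b[!ok] <- 0; cc[!ok] <- 0
  list(a = a, abc = a + b + cc, ok = ok,
       callable = nA >= 2 & nB >= 2,
       polymorphic = ok & pbar > 0 & pbar < 1)
}

#' Windowed Weir-Cockerham FST
#'
#' The weighted windowed estimator `sum(a) / sum(a + b + c)` of Weir &
#' Cockerham's (1984) variance components over the biallelic polymorphic
#' sites of each window (the estimator VCFtools reports for windowed FST).
#' Sites with more than two alleles are excluded.  The NA gate uses the
#' count of callable sites (>= 2 called alleles in each population), not
#' only polymorphic ones.
#'
#' @inheritParams dxyWindows
#' @return GRanges with mcols `statistic`, `value`, `nSitesUsed`,
#'   `nSitesPossible`, `nPolymorphic`, `popA`, `popB`.
#' @export
fstWindows <- function(hap, popmap, popA, popB, windows = NULL,
                       minCallableFrac = 0.2) {
  windows <- .resolveWindows(hap, windows)
  w <- .wcSiteComponents(.popCounts(hap, popmap, popA),
                         .popCounts(hap, popmap, popB), ploidy(hap))
  pos <- sitePositions(hap)
  st <- GenomicRanges::start(windows); en <- GenomicRanges::end(windows)
  agA <- .windowAggregate(pos, w$a, w$polymorphic, st, en)
  agD <- .windowAggregate(pos, w$abc, w$polymorphic, st, en)
  agC <- .windowAggregate(pos, rep(0, length(w$a)), w$callable, st, en)
  value <- ifelse(agA$n > 0 & agD$sum != 0, agA$sum / agD$sum, NA_real_)
  .windowRecord(windows, "fst", value, agC$n, GenomicRanges::width(windows),
                minCallableFrac,
                list(nPolymorphic = as.integer(agA$n),
                     popA = popA, popB = popB))
}

# Tajima (1989) constants for sample size n
.tajimaConstants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, e1 = e1, e2 = e2)
}

#' Windowed Tajima's D
#'
#' The standard Tajima (1989) statistic
#' `D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S - 1))`, with `pi_sum` the sum
#' of per-site unbiased pairwise-difference fractions and `S` the number of
#' segregating (biallelic) sites.  With ragged missingness the constants
#' are computed from the window's modal number of called alleles, an
#' approximation documented in the methods vignette.  Windows with `S = 0`
#' or fewer than 3 modal sequences are NA.
#'
#' @inheritParams piWindows
#' @return GRanges with mcols `statistic`, `value`, `nSitesUsed`,
#'   `nSitesPossible`, `nSegregating`, `population`.
#' @export
tajimaDWindows <- function(hap, popmap, population, windows = NULL,
                           minCallableFrac = 0.2) {
  windows <- .resolveWindows(hap, windows)
  cnt <- .popCounts(hap, popmap, population)
  ac <- cnt[, 1:4, drop = FALSE]
  n <- rowSums(ac)
  nAlleles <- rowSums(ac > 0)
  callable <- n >= 2 & nAlleles <= 2
  seg <- callable & nAlleles == 2
  nn1 <- n * (n - 1)
  piSite <- (nn1 - rowSums(ac * (ac - 1))) / ifelse(nn1 > 0, nn1, 1)
  piSite[!callable] <- 0
  wi <- .windowSiteIndex(hap, windows)
  k <- length(wi$from)
  value <- rep(NA_real_, k)
  nUsed <- integer(k)
  nSeg <- integer(k)
  for (w in seq_len(k)) {
    if (wi$to[w] < wi$from[w]) next
    idx <- wi$from[w]:wi$to[w]
    use <- idx[callable[idx]]
    nUsed[w] <- length(use)
    if (!length(use)) next
    nStar <- as.integer(names(which.max(table(n[use]))))
    S <- sum(seg[use])
    nSeg[w] <- S
    if (S == 0 || nStar < 3) next
    cst <- .tajimaConstants(nStar)
    piSum <- sum(piSite[use])
    value[w] <- (piSum - S / cst$a1) /
      sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  }
  .windowRecord(wi$windows, "tajima_d", value, nUsed,
                GenomicRanges::width(wi$windows), minCallableFrac,
                list(nSegregating = nSeg, population = population))
}

#' Sliding-window absolute divergence
#'
#' dXY over overlapping windows `[k*step, k*step + windowSize)` clipped to
#' the scaffold end, used to inspect candidate introgressed scaffolds at
#' finer resolution (default 10-kb windows sliding by 2 kb).
#'
#' @inheritParams dxyWindows
#' @param windowSize window width in bp.
#' @param step slide in bp (`windowSize >= step >= 1`).
#' @return GRanges of overlapping windows scored like [dxyWindows()].
#' @export
slidingDxy <- function(hap, popmap, popA, popB, windowSize = 10000,
                       step = 2000, minCallableFrac = 0.2) {
  stopifnot(windowSize >= step, step >= 1)
  L <- scaffoldLength(hap)
  if (L < windowSize) {
    starts <- 0
  } else {
    starts <- seq(0, floor((L - windowSize) / step) * step, by = step)
  }
  ends <- pmin(starts + windowSize, L)
  gr <- GenomicRanges::GRanges(scaffoldName(hap),
                               IRanges::IRanges(starts + 1, ends))
  dxyWindows(hap, popmap, popA, popB, windows = gr,
             minCallableFrac = minCallableFrac)
}

#' Histogram rescaled to unit maximum
#'
#' Bins values at a fixed width and divides the counts by the maximum bin
#' count, so the distribution's maximum is exactly 1 -- the normalisation
#' used for all genome-wide dXY and proportion summaries.
#'
#' @param values numeric vector (NA/Inf dropped).
#' @param binWidth bin width (default 0.05).
#' @return data.frame with `binStart`, `binEnd`, `mid`, `count`, `height`.
#' @export
rescaleDensity <- function(values, binWidth = 0.05) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to bin")
  lo <- floor(min(values) / binWidth) * binWidth
  hi <- ceiling(max(values) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  data.frame(binStart = utils::head(breaks, -1), binEnd = breaks[-1],
             mid = h$mids, count = h$counts,
             height = h$counts / max(h$counts))
}
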