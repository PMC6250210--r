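#' Per-site f3 values
#'
#' The Patterson-style unbiased three-population statistic at one site:
#' with sample allele frequencies `a`, `b`, `c` of the two sources and the
#' target, returns `(c - a)(c - b) - h_C / n_C` where
#' `h_C = c (1 - c) n_C / (n_C - 1)` corrects for sampling error in the
#' target frequency.  Vectorised over sites; sites with `n_C < 2` are NA
#' (the correction is undefined).
#'
#' @param freqA,freqB source-population allele frequencies.
#' @param freqC target-population allele frequency.
#' @param nC number of called target alleles.
#' @return numeric vector of per-site f3 values.
#' @examples
#' f3Site(0, 1, 0.5, nC = 2)  # -0.5
#' @export
f3Site <- function(freqA, freqB, freqC, nC) {
  val <- (freqC - freqA) * (freqC - freqB) -
    freqC * (1 - freqC) / (nC - 1)
  val[nC < 2] <- NA_real_
  val
}

# site ascertainment and per-site f3 values for three count matrices
.f3SiteValues <- function(cntA, cntB, cntC) {
  aA <- cntA[, 1:4, drop = FALSE]
  aB <- cntB[, 1:4, drop = FALSE]
  aC <- cntC[, 1:4, drop = FALSE]
  nA <- rowSums(aA); nB <- rowSums(aB); nC <- rowSums(aC)
  u <- aA + aB + aC
  present <- u > 0
  nAlleles <- rowSums(present)
  use <- nAlleles == 2 & nC >= 2 & nA >= 1 & nB >= 1
  b1 <- max.col(present, ties.method = "first")
  i <- seq_len(nrow(aA))
  fA <- aA[cbind(i, b1)] / ifelse(nA > 0, nA, 1)
  fB <- aB[cbind(i, b1)] / ifelse(nB > 0, nB, 1)
  fC <- aC[cbind(i, b1)] / ifelse(nC > 0, nC, 1)
  val <- f3Site(fA, fB, fC, nC)
  list(value = val, use = use)
}

# weighted delete-one-block jackknife (Busing et al. 1999) for a mean
.blockJackknife <- function(values, blockId) {
  tot <- sum(values)
  N <- length(values)
  bs <- tapply(values, blockId, sum)
  bn <- tapply(values, blockId, length)
  G <- length(bs)
  est <- tot / N
  loo <- (tot - bs) / (N - bn)
  h <- N / bn
  tau <- h * est - (h - 1) * loo
  thetaJ <- G * est - sum((1 - bn / N) * loo)
  v <- sum((tau - thetaJ)^2 / (h - 1)) / G
  list(estimate = est, se = sqrt(v), nBlocks = as.integer(G),
       loo = as.numeric(loo))
}

#' Genome-wide f3 with block-jackknife standard error
#'
#' Computes the f3 point estimate over all biallelic sites polymorphic in
#' the union of the three populations (target callable with at least two
#' alleles, each source with at least one), and a standard error from a
#' delete-one-block jackknife over contiguous genomic blocks weighted by
#' per-block site counts.  A negative Z indicates the target carries
#' ancestry from populations related to both sources, i.e. admixture.
#'
#' @param hap a [HaplotypeMatrix-class].
#' @param popmap a [populationMap()] data.frame.
#' @param target target (C) population or role label.
#' @param sourceA,sourceB source (A, B) population or role labels.
#' @param blockSize jackknife block length in bp (default 500 kb).
#' @return an [F3Result-class].
#' @export
f3Genome <- function(hap, popmap, target, sourceA, sourceB,
                     blockSize = 5e5) {
  sv <- .f3SiteValues(.popCounts(hap, popmap, sourceA),
                      .popCounts(hap, popmap, sourceB),
                      .popCounts(hap, popmap, target))
  keep <- sv$use & !is.na(sv$value)
  if (!any(keep))
    stop("no usable sites: no biallelic site polymorphic across ",
         sourceA, ", ", sourceB, ", ", target)
  vals <- sv$value[keep]
  blockId <- (sitePositions(hap)[keep] - 1L) %/% as.integer(blockSize)
  if (length(unique(blockId)) < 2)
    stop("fewer than 2 jackknife blocks contain data; reduce blockSize")
  jk <- .blockJackknife(vals, blockId)
  z <- if (jk$se > 0) jk$estimate / jk$se else NA_real_
  if (jk$se == 0 && jk$estimate != 0)
    warning("zero jackknife SE with nonzero estimate; z unreliable")
  new("F3Result", target = target, sources = c(sourceA, sourceB),
      estimate = jk$estimate, se = jk$se, z = z,
      nBlocks = jk$nBlocks, nSites = as.integer(length(vals)),
      blockEstimates = jk$loo)
}

#' f3 for all three tip orderings
#'
#' Applies [f3Genome()] with each population in turn as the target:
#' `f3(I1, I2; O)`, `f3(I1, O; I2)` and `f3(I2, O; I1)` (sources listed
#' first, target after the semicolon).  Without introgression all three
#' are expected positive; a negative `f3(I1, O; I2)` indicates I2 is
#' admixed between relatives of I1 and O.
#'
#' @inheritParams f3Genome
#' @param popI1,popI2,popO population (or role) labels.
#' @return named list of three [F3Result-class] objects.
#' @export
f3AllOrderings <- function(hap, popmap, popI1 = "I1", popI2 = "I2",
                           popO = "O", blockSize = 5e5) {
  list(
    "f3(I1,I2;O)" = f3Genome(hap, popmap, popO, popI1, popI2, blockSize),
    "f3(I1,O;I2)" = f3Genome(hap, popmap, popI2, popI1, popO, blockSize),
    "f3(I2,O;I1)" = f3Genome(hap, popmap, popI1, popI2, popO, blockSize)
  )
}

setMethod("show", "F3Result", function(object) {
  cat(sprintf("f3(%s, %s; %s) = %.6g  (SE %.3g, Z %.3g; %d sites, %d blocks)\n",
              object@sources[1], object@sources[2], object@target,
              object@estimate, object@se, object@z,
              object@nSites, object@nBlocks))
})

#' @name F3Result-accessors
#' @title Accessors for F3Result
#' @param x an [F3Result-class].
#' @return `f3Estimate` the point estimate; `f3Z` the Z-score.
NULL

#' @rdname F3Result-accessors
#' @export
f3Estimate <- function(x) x@estimate

#' @rdname F3Result-accessors
#' @export
f3Z <- function(x) x@z
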