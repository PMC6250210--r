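.jcDistance <- function(p, maxDistance = 5) {
  d <- ifelse(p >= 0.75, maxDistance, -0.75 * log(pmax(1 - 4 * p / 3, 1e-300)))
  pmin(d, maxDistance)
}

#' Jukes-Cantor-corrected pairwise distance between two samples
#'
#' Mismatch fraction over the jointly callable sites of a window, with
#' IUPAC ambiguity codes contributing the mean mismatch over compatible
#' base resolutions (a heterozygote versus a matching homozygote counts
#' 0.5), corrected as `-(3/4) log(1 - (4/3) p)`.  Saturated comparisons
#' (`p >= 0.75`) are capped at `maxDistance` rather than erroring.
#'
#' @param hap a [HaplotypeMatrix-class].
#' @param sample1,sample2 sample names or column indices.
#' @param window a single GRanges window (default: the whole scaffold).
#' @param maxDistance saturation cap (default 5).
#' @return list with `distance`, `p` (mismatch fraction) and `nSites`
#'   (jointly callable sites); `distance` is NA when no site is callable.
#' @export
pairwiseDistance <- function(hap, sample1, sample2, window = NULL,
                             maxDistance = 5) {
  if (is.character(sample1)) sample1 <- match(sample1, sampleNames(hap))
  if (is.character(sample2)) sample2 <- match(sample2, sampleNames(hap))
  stopifnot(!is.na(sample1), !is.na(sample2))
  if (is.null(window)) {
    from <- 1L; to <- nSites(hap)
  } else {
    wi <- .windowSiteIndex(hap, window)
    from <- wi$from[1]; to <- wi$to[1]
  }
  if (to < from) return(list(distance = NA_real_, p = NA_real_, nSites = 0L))
  mm <- .pair_mismatch_cpp(callMatrix(hap), sample1, sample2,
                           as.integer(from), as.integer(to))
  n <- mm[1, 2]
  if (n == 0) return(list(distance = NA_real_, p = NA_real_, nSites = 0L))
  p <- mm[1, 1] / n
  list(distance = .jcDistance(p, maxDistance), p = p, nSites = as.integer(n))
}

#' Four-taxon distance tree
#'
#' Builds the unrooted quartet tree from a 4x4 distance matrix: the
#' topology is the pairing minimising the four-point-condition residual
#' (the smallest of the three pair sums), branch lengths are the
#' least-squares estimates, and negative branch lengths are clamped to 0.
#' For four taxa this is exactly neighbor-joining's choice.
#'
#' @param d symmetric 4x4 numeric distance matrix with dimnames.
#' @return list with `patristic` (4x4 tip-to-tip distances on the fitted
#'   tree), `branches` (four external lengths plus `internal`), `cherries`
#'   (the paired taxa), `residual` (four-point residual) and `tree`
#'   (an [ape::phylo]).
#' @export
quartetTree <- function(d) {
  stopifnot(is.matrix(d), all(dim(d) == 4))
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:4)
  labs <- rownames(d)
  pairsums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  topo <- which.min(pairsums)
  ord <- switch(topo, c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  A <- ord[1]; B <- ord[2]; C <- ord[3]; D <- ord[4]
  resid <- abs(diff(sort(pairsums)[2:3]))
  a <- (d[A, B] + (d[A, C] + d[A, D] - d[B, C] - d[B, D]) / 2) / 2
  b <- (d[A, B] + (d[B, C] + d[B, D] - d[A, C] - d[A, D]) / 2) / 2
  cc <- (d[C, D] + (d[A, C] + d[B, C] - d[A, D] - d[B, D]) / 2) / 2
  dd <- (d[C, D] + (d[A, D] + d[B, D] - d[A, C] - d[B, C]) / 2) / 2
  m <- (d[A, C] + d[A, D] + d[B, C] + d[B, D]) / 4 - (d[A, B] + d[C, D]) / 2
  br <- pmax(c(a, b, cc, dd, m), 0)
  pat <- matrix(0, 4, 4, dimnames = list(labs, labs))
  pat[A, B] <- pat[B, A] <- br[1] + br[2]
  pat[C, D] <- pat[D, C] <- br[3] + br[4]
  pat[A, C] <- pat[C, A] <- br[1] + br[5] + br[3]
  pat[A, D] <- pat[D, A] <- br[1] + br[5] + br[4]
  pat[B, C] <- pat[C, B] <- br[2] + br[5] + br[3]
  pat[B, D] <- pat[D, B] <- br[2] + br[5] + br[4]
  tree <- list(edge = rbind(c(5L, A), c(5L, B), c(5L, 6L),
                            c(6L, C), c(6L, D)),
               edge.length = br[c(1, 2, 5, 3, 4)],
               tip.label = labs, Nnode = 2L)
  class(tree) <- "phylo"
  list(patristic = pat,
       branches = stats::setNames(br, c(labs[c(A, B, C, D)], "internal")),
       cherries = list(labs[c(A, B)], labs[c(C, D)]),
       residual = resid, tree = tree)
}

#' Tree-tip distance proportion for a role-labelled quartet
#'
#' `Proportion_ab = d_a / (d_a + d_b)` where `d_a` is the patristic
#' distance between the sympatric ingroup tip (role `I2`) and the outgroup
#' tip (role `O`), and `d_b` is the mean patristic distance of the two
#' allopatric ingroup tips (role `I1`) to the outgroup.  Values near 0.5
#' are concordant with the species tree; values well below 0.5 mark
#' candidate admixed windows where the outgroup is closer to the sympatric
#' ingroup.
#'
#' @param patristic 4x4 patristic distance matrix (as from [quartetTree()]).
#' @param roles named character: role (`"I1"`, `"I2"`, `"O"`) per tip label.
#' @return one-row data.frame with `dA`, `dB`, `proportion` (NA when
#'   `dA + dB` is 0).
#' @export
proportionAB <- function(patristic, roles) {
  roles <- roles[rownames(patristic)]
  i2 <- names(roles)[roles == "I2"]
  o <- names(roles)[roles == "O"]
  i1 <- names(roles)[roles == "I1"]
  if (length(i2) != 1 || length(o) != 1 || length(i1) != 2)
    stop("quartet roles must be exactly {I2, O, I1, I1}")
  dA <- patristic[i2, o]
  dB <- mean(c(patristic[i1[1], o], patristic[i1[2], o]))
  prop <- if (dA + dB > 0) dA / (dA + dB) else NA_real_
  data.frame(dA = dA, dB = dB, proportion = prop)
}

#' Enumerate quartet sample combinations
#'
#' `"simulated"` mode crosses every ingroup-2 sample with every outgroup
#' sample, the allopatric pair being the two fixed `I1` samples (8 x 8
#' populations give 64 combinations).  `"empirical"` mode pairs the two
#' species within each sympatric population (all I2-role x O-role sample
#' pairs per population), again with the fixed `I1` pair.
#'
#' @param popmap a [populationMap()] data.frame with exactly two
#'   `fixedI1` samples.
#' @param mode `"simulated"` or `"empirical"`.
#' @return data.frame with `comboId`, `i2`, `o`, `i1a`, `i1b`, `population`.
#' @export
enumerateQuartets <- function(popmap, mode = c("simulated", "empirical")) {
  mode <- match.arg(mode)
  fixed <- popmap$sample[popmap$fixedI1 & popmap$role == "I1"]
  if (length(fixed) != 2)
    stop("exactly 2 fixed I1 samples required (found ", length(fixed), ")")
  i2 <- popmap[popmap$role == "I2", , drop = FALSE]
  o <- popmap[popmap$role == "O", , drop = FALSE]
  if (!nrow(i2) || !nrow(o)) stop("missing role: need I2 and O samples")
  if (mode == "simulated") {
    cmb <- expand.grid(i2 = i2$sample, o = o$sample,
                       stringsAsFactors = FALSE)
    cmb$population <- "simulated"
  } else {
    pops <- intersect(unique(i2$population), unique(o$population))
    if (!length(pops)) stop("no population contains both I2 and O samples")
    cmb <- do.call(rbind, lapply(pops, function(p) {
      g <- expand.grid(i2 = i2$sample[i2$population == p],
                       o = o$sample[o$population == p],
                       stringsAsFactors = FALSE)
      g$population <- p
      g
    }))
  }
  data.frame(comboId = paste(cmb$i2, cmb$o, sep = "."),
             i2 = cmb$i2, o = cmb$o, i1a = fixed[1], i1b = fixed[2],
             population = cmb$population, stringsAsFactors = FALSE)
}

#' Per-window quartet proportion scan
#'
#' For every window x combination whose four tips each have more than
#' `minCallableFrac` of the window's sites genotyped, builds the quartet
#' distance tree ([pairwiseDistance()] + [quartetTree()]) and computes the
#' tree-tip distance proportion.  Windows/combinations failing the
#' callable rule or with an uncomputable pairwise distance are skipped and
#' counted in the `skipped` attribute.
#'
#' @param hap a [HaplotypeMatrix-class].
#' @param popmap a [populationMap()] data.frame.
#' @param windows GRanges (default: non-overlapping 50-kb tiling).
#' @param combinations data.frame from [enumerateQuartets()]; by default
#'   enumerated in `mode`.
#' @param mode passed to [enumerateQuartets()] when `combinations` is NULL.
#' @param minCallableFrac per-tip callable-fraction threshold (default 0.2,
#'   i.e. only windows with >20% of sites genotyped are analysed).
#' @param maxDistance saturation cap for [pairwiseDistance()].
#' @return data.frame with one row per analysed window x combination:
#'   `scaffold`, `start`, `end` (1-based inclusive), `comboId`, `i2`, `o`,
#'   `dA`, `dB`, `proportion`, `nSitesUsed`; attribute `skipped` holds the
#'   number of skipped window x combination pairs.
#' @export
windowProportionScan <- function(hap, popmap, windows = NULL,
                                 combinations = NULL,
                                 mode = c("simulated", "empirical"),
                                 minCallableFrac = 0.2, maxDistance = 5) {
  mode <- match.arg(mode)
  windows <- .resolveWindows(hap, windows)
  if (is.null(combinations)) combinations <- enumerateQuartets(popmap, mode)
  wi <- .windowSiteIndex(hap, windows)
  k <- length(wi$from)
  empty <- wi$to < wi$from
  from <- pmax(wi$from, 1L); to <- pmax(wi$to, 1L)

  tips <- unique(c(combinations$i2, combinations$o,
                   combinations$i1a, combinations$i1b))
  tipIdx <- match(tips, sampleNames(hap))
  if (anyNA(tipIdx))
    stop("combination samples missing from haplotype matrix: ",
         paste(tips[is.na(tipIdx)], collapse = ", "))
  names(tipIdx) <- tips

  callable <- .callable_counts_cpp(callMatrix(hap), as.integer(tipIdx),
                                   as.integer(from), as.integer(to))
  colnames(callable) <- tips
  callable[empty, ] <- 0L

  # unique unordered pairs needed across all combinations
  pairKey <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  combPairs <- cbind(pairKey(combinations$i2, combinations$o),
                     pairKey(combinations$i1a, combinations$o),
                     pairKey(combinations$i1b, combinations$o),
                     pairKey(combinations$i1a, combinations$i2),
                     pairKey(combinations$i1b, combinations$i2),
                     pairKey(combinations$i1a, combinations$i1b))
  pairs <- unique(as.vector(combPairs))
  pd <- vector("list", length(pairs))
  names(pd) <- pairs
  for (pk in pairs) {
    ab <- strsplit(pk, "\r", fixed = TRUE)[[1]]
    mm <- .pair_mismatch_cpp(callMatrix(hap), tipIdx[ab[1]], tipIdx[ab[2]],
                             as.integer(from), as.integer(to))
    p <- ifelse(mm[, 2] > 0, mm[, 1] / mm[, 2], NA_real_)
    pd[[pk]] <- list(dist = ifelse(is.na(p), NA_real_,
                                   .jcDistance(p, maxDistance)),
                     n = mm[, 2])
  }

  width <- GenomicRanges::width(wi$windows)
  res <- vector("list", k * nrow(combinations))
  skipped <- 0L
  ri <- 0L
  starts <- GenomicRanges::start(wi$windows)
  ends <- GenomicRanges::end(wi$windows)
  scf <- as.character(GenomeInfoDb::seqnames(wi$windows))
  for (w in seq_len(k)) {
    for (ci in seq_len(nrow(combinations))) {
      cmb <- combinations[ci, ]
      four <- c(cmb$i1a, cmb$i1b, cmb$i2, cmb$o)
      if (empty[w] ||
          any(callable[w, four] <= minCallableFrac * width[w])) {
        skipped <- skipped + 1L
        next
      }
      dv <- vapply(combPairs[ci, ], function(pk) pd[[pk]]$dist[w], 0)
      nv <- vapply(combPairs[ci, ], function(pk) pd[[pk]]$n[w], 0)
      if (anyNA(dv)) { skipped <- skipped + 1L; next }
      dm <- matrix(0, 4, 4, dimnames = list(four, four))
      dm[cmb$i2, cmb$o] <- dm[cmb$o, cmb$i2] <- dv[1]
      dm[cmb$i1a, cmb$o] <- dm[cmb$o, cmb$i1a] <- dv[2]
      dm[cmb$i1b, cmb$o] <- dm[cmb$o, cmb$i1b] <- dv[3]
      dm[cmb$i1a, cmb$i2] <- dm[cmb$i2, cmb$i1a] <- dv[4]
      dm[cmb$i1b, cmb$i2] <- dm[cmb$i2, cmb$i1b] <- dv[5]
      dm[cmb$i1a, cmb$i1b] <- dm[cmb$i1b, cmb$i1a] <- dv[6]
      qt <- quartetTree(dm)
      roles <- stats::setNames(c("I1", "I1", "I2", "O"), four)
      pr <- proportionAB(qt$patristic, roles)
      ri <- ri + 1L
      res[[ri]] <- data.frame(scaffold = scf[w], start = starts[w],
                              end = ends[w], comboId = cmb$comboId,
                              i2 = cmb$i2, o = cmb$o,
                              dA = pr$dA, dB = pr$dB,
                              proportion = pr$proportion,
                              nSitesUsed = as.integer(min(nv)),
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (ri) do.call(rbind, res[seq_len(ri)]) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               comboId = character(), i2 = character(), o = character(),
               dA = numeric(), dB = numeric(), proportion = numeric(),
               nSitesUsed = integer(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Tail symmetry analysis of proportion distributions
#'
#' For each sample combination: the mean proportion, the counts of windows
#' above and below the mean at the given offsets, and the windows flagged
#' below `mean - flagOffset` (candidate introgressed regions), aggregated
#' across combinations by scaffold.  Under no admixture the tails are
#' expected to be symmetric; widespread introgression from the outgroup
#' into the sympatric ingroup makes the lower tail heavier.
#'
#' @param results data.frame from [windowProportionScan()].
#' @param offsets offsets from the mean (default `c(0.05, 0.10, 0.15)`).
#' @param flagOffset flagging offset (default 0.15).
#' @param minResults minimum non-NA results required per combination.
#' @return a [TailReport-class].
#' @export
tailAnalysis <- function(results, offsets = c(0.05, 0.10, 0.15),
                         flagOffset = 0.15, minResults = 30) {
  ok <- !is.na(results$proportion)
  nPer <- table(results$comboId[ok])
  if (!length(nPer) || any(nPer < minResults))
    stop("fewer than ", minResults,
         " non-NA proportions for some combination")
  res <- results[ok, , drop = FALSE]
  combos <- unique(res$comboId)
  srows <- lapply(combos, function(cid) {
    p <- res$proportion[res$comboId == cid]
    m <- mean(p)
    row <- data.frame(comboId = cid, n = length(p), mean = m,
                      stringsAsFactors = FALSE)
    for (off in offsets) {
      row[[sprintf("nAbove_%.2f", off)]] <- sum(p > m + off)
      row[[sprintf("nBelow_%.2f", off)]] <- sum(p < m - off)
    }
    row
  })
  summary <- do.call(rbind, srows)
  means <- stats::setNames(summary$mean, summary$comboId)
  flagged <- res[res$proportion < means[res$comboId] - flagOffset,
                 c("comboId", "scaffold", "start", "end", "proportion"),
                 drop = FALSE]
  rownames(flagged) <- NULL
  if (nrow(flagged)) {
    hits <- stats::aggregate(comboId ~ scaffold, data = flagged,
                             FUN = function(x) length(unique(x)))
    names(hits)[2] <- "nCombinations"
    hits <- hits[order(-hits$nCombinations), , drop = FALSE]
    rownames(hits) <- NULL
  } else {
    hits <- data.frame(scaffold = character(), nCombinations = integer(),
                       stringsAsFactors = FALSE)
  }
  new("TailReport", offsets = offsets, summary = summary,
      flagged = flagged, scaffoldHits = hits, flagOffset = flagOffset)
}

setMethod("show", "TailReport", function(object) {
  cat(sprintf("TailReport: %d combination(s), offsets %s\n",
              nrow(object@summary),
              paste(object@offsets, collapse = ", ")))
  cat(sprintf("  mean proportion range: %.4f - %.4f\n",
              min(object@summary$mean), max(object@summary$mean)))
  cat(sprintf("  %d window(s) flagged below mean - %.2f on %d scaffold(s)\n",
              nrow(object@flagged), object@flagOffset,
              nrow(object@scaffoldHits)))
})
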