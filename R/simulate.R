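.roleCode <- c(I1 = 0L, I2 = 1L, O = 2L)

.tipLabels <- function(n) {
  paste0(rep(c("I1", "I2", "O"), each = n), "_", rep(seq_len(n), 3))
}

#' Sample marginal genealogies under the structured coalescent
#'
#' Simulates the sequence of local trees along the chromosome for the three
#' populations of `model`, backwards in time: within-population pairs
#' coalesce at rate 2 (time in 4N-generation units), admixture pulses
#' relabel recipient lineages to the donor population with their pulse
#' fraction, the ingroups merge at `splitTimeIngroups` and the outgroup at
#' `splitTimeRoot`.  Recombination follows the model's
#' `recombinationModel`: `"smc"` detaches a uniformly chosen branch point
#' at each breakpoint and re-coalesces it under the same structured process
#' (Markovian approximation); `"blocks"` draws an independent tree per
#' block.
#'
#' @param model a [DemographicModel-class].
#' @return a [LocalGenealogies-class] whose intervals tile
#'   `[0, chromosomeLength)`.
#' @examples
#' gen <- sampleGenealogies(DemographicModel(chromosomeLength = 1e5, seed = 7))
#' length(gen)
#' @export
sampleGenealogies <- function(model) {
  validObject(model)
  p <- model@pulses
  res <- .sim_genealogies_cpp(
    model@samplesPerPopulation,
    model@splitTimeIngroups, model@splitTimeRoot,
    as.numeric(p$time),
    .roleCode[as.character(p$source)],
    .roleCode[as.character(p$dest)],
    as.numeric(p$fraction),
    model@recombinationRate, model@chromosomeLength,
    as.double(model@seed), model@recombinationModel, model@blockSize)
  new("LocalGenealogies",
      breaks = res$breaks, parent = res$parent, nodeTime = res$time,
      tipLabels = .tipLabels(model@samplesPerPopulation))
}

#' Evolve sequences along genealogies under HKY
#'
#' Per-site simulation down each marginal tree: the root state is drawn
#' from the model's base frequencies and every branch applies the HKY
#' transition-probability matrix for `branchLength * branchScale` expected
#' substitutions (the rate matrix is normalised to unit mean rate).
#' Deterministic given the model seed.
#'
#' @param genealogies a [LocalGenealogies-class] tiling the chromosome.
#' @param model the generating [DemographicModel-class].
#' @return a [SimulatedHaplotypes-class] with complete (no missing) calls.
#' @export
evolveSequences <- function(genealogies, model) {
  if (!length(genealogies@breaks)) stop("empty genealogy list")
  L <- as.integer(model@chromosomeLength)
  calls <- .evolve_seq_cpp(genealogies@breaks, genealogies@parent,
                           genealogies@nodeTime, L,
                           as.numeric(model@baseFrequencies),
                           model@hkyKappa, model@branchScale,
                           as.double(model@seed))
  colnames(calls) <- genealogies@tipLabels
  new("SimulatedHaplotypes",
      scaffold = "sim_1", scaffoldLength = as.numeric(L),
      positions = seq_len(L), calls = calls, ploidy = 1L,
      provenance = "simulated", model = model, genealogies = genealogies)
}

#' Simulate haplotypes in one step
#'
#' Convenience wrapper: [sampleGenealogies()] then [evolveSequences()].
#'
#' @param model a [DemographicModel-class].
#' @return a [SimulatedHaplotypes-class].
#' @examples
#' hap <- simulateHaplotypes(DemographicModel(chromosomeLength = 5e4))
#' hap
#' @export
simulateHaplotypes <- function(model) {
  evolveSequences(sampleGenealogies(model), model)
}

#' Extract one marginal tree as an ape phylo object
#'
#' @param genealogies a [LocalGenealogies-class].
#' @param i tree index (1-based).
#' @return an [ape::phylo] rooted tree with branch lengths in 4N units.
#' @export
localTree <- function(genealogies, i = 1L) {
  stopifnot(i >= 1, i <= length(genealogies@breaks))
  par <- genealogies@parent[, i]
  tim <- genealogies@nodeTime[, i]
  ntips <- length(genealogies@tipLabels)
  nn <- length(par)
  root <- which(par == 0L)
  # ape numbering: tips 1..ntips keep ids; internal nodes renumbered so the
  # root is ntips + 1
  internal <- setdiff(seq_len(nn), seq_len(ntips))
  internal <- c(root, setdiff(internal, root))
  newId <- integer(nn)
  newId[seq_len(ntips)] <- seq_len(ntips)
  newId[internal] <- ntips + seq_along(internal)
  child <- setdiff(seq_len(nn), root)
  edge <- cbind(newId[par[child]], newId[child])
  len <- tim[par[child]] - tim[child]
  tr <- list(edge = edge, edge.length = len,
             tip.label = genealogies@tipLabels, Nnode = nn - ntips)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Pairwise time to most recent common ancestor
#'
#' TMRCA of two tips in one (or every) marginal tree, in 4N units.
#'
#' @param genealogies a [LocalGenealogies-class].
#' @param tipA,tipB tip labels or indices.
#' @param trees tree indices (default: all trees).
#' @return numeric vector of TMRCAs, one per requested tree.
#' @export
pairTMRCA <- function(genealogies, tipA, tipB, trees = NULL) {
  if (is.character(tipA)) tipA <- match(tipA, genealogies@tipLabels)
  if (is.character(tipB)) tipB <- match(tipB, genealogies@tipLabels)
  stopifnot(!is.na(tipA), !is.na(tipB))
  if (is.null(trees)) trees <- seq_along(genealogies@breaks)
  vapply(trees, function(i) {
    par <- genealogies@parent[, i]
    tim <- genealogies@nodeTime[, i]
    anc <- integer(0)
    v <- tipA
    while (v != 0L) { anc <- c(anc, v); v <- par[v] }
    v <- tipB
    while (v != 0L) {
      if (v %in% anc) return(tim[v])
      v <- par[v]
    }
    NA_real_
  }, numeric(1))
}

#' Interval bounds of the marginal genealogies
#'
#' @param genealogies a [LocalGenealogies-class].
#' @return data.frame with half-open `[start, end)` bp coordinates per tree.
#' @export
intervalBounds <- function(genealogies) {
  b <- genealogies@breaks
  data.frame(start = c(0, b[-length(b)]), end = b)
}

#' Write genealogies as Newick with a tab-separated interval sidecar
#'
#' Writes the selected marginal trees in Newick format (one per line) and a
#' sidecar `<file>.intervals.tsv` with columns `tree`, `start`, `end`
#' (half-open bp coordinates).
#'
#' @param genealogies a [LocalGenealogies-class].
#' @param file output Newick path.
#' @param which tree indices to write (default: all).
#' @return invisibly, the sidecar path.
#' @export
writeGenealogies <- function(genealogies, file, which = NULL) {
  if (is.null(which)) which <- seq_along(genealogies@breaks)
  trees <- lapply(which, function(i) localTree(genealogies, i))
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = file)
  iv <- intervalBounds(genealogies)[which, , drop = FALSE]
  side <- paste0(file, ".intervals.tsv")
  utils::write.table(cbind(tree = which, iv), side, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(side)
}

setMethod("show", "LocalGenealogies", function(object) {
  cat(sprintf("LocalGenealogies: %d marginal tree(s), %d tips, chromosome %.4g bp\n",
              length(object@breaks), length(object@tipLabels),
              max(object@breaks)))
})

#' @describeIn LocalGenealogies-class number of marginal trees.
#' @param x a `LocalGenealogies` object.
#' @export
setMethod("length", "LocalGenealogies", function(x) length(x@breaks))
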