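#' @import methods
NULL

#' Demographic model for a three-population admixture simulation
#'
#' An S4 container holding the full demographic and mutational specification
#' of the structured-coalescent simulator: three populations with roles
#' ingroup 1 (`I1`), ingroup 2 (`I2`) and outgroup (`O`), joined by the
#' species topology `((I1, I2), O)`, plus an arbitrary schedule of
#' directional admixture pulses.  Times are in units of 4N generations
#' (a pair of lineages within a population coalesces at rate 2).
#'
#' @slot populationLabels named character of length 3 with names
#'   `I1`, `I2`, `O`.
#' @slot samplesPerPopulation number of haploid samples drawn per population.
#' @slot splitTimeIngroups time of the I1/I2 split (4N units).
#' @slot splitTimeRoot time of the root split (4N units).
#' @slot pulses data.frame with columns `time`, `source`, `dest`, `fraction`:
#'   backwards in time, each lineage in `dest` relabels to `source` with
#'   probability `fraction` at `time`.
#' @slot recombinationRate population-scaled recombination rate 4Nr per bp.
#' @slot chromosomeLength chromosome length in base pairs.
#' @slot branchScale expected substitutions per site per 4N-generation unit.
#' @slot hkyKappa HKY transition/transversion rate ratio.
#' @slot baseFrequencies named numeric of length 4 (A, C, G, T) summing to 1.
#' @slot recombinationModel `"smc"` (sequentially Markovian tree updating,
#'   the default) or `"blocks"` (independent genealogy per block).
#' @slot blockSize block length in bp for the `"blocks"` model.
#' @slot seed integer master seed; genealogy and mutation sampling use
#'   independent streams derived from it.
#'
#' @seealso [DemographicModel()], [pulseSchedule()], [simulateHaplotypes()]
#' @exportClass DemographicModel
setClass("DemographicModel",
  representation(
    populationLabels = "character",
    samplesPerPopulation = "integer",
    splitTimeIngroups = "numeric",
    splitTimeRoot = "numeric",
    pulses = "data.frame",
    recombinationRate = "numeric",
    chromosomeLength = "numeric",
    branchScale = "numeric",
    hkyKappa = "numeric",
    baseFrequencies = "numeric",
    recombinationModel = "character",
    blockSize = "numeric",
    seed = "integer"
  )
)

setValidity("DemographicModel", function(object) {
  msg <- character()
  if (length(object@populationLabels) != 3 ||
      !identical(sort(names(object@populationLabels)), c("I1", "I2", "O")))
    msg <- c(msg, "populationLabels must be named I1, I2, O")
  if (object@samplesPerPopulation < 1)
    msg <- c(msg, "samplesPerPopulation must be >= 1")
  if (!(object@splitTimeIngroups > 0 &&
        object@splitTimeIngroups < object@splitTimeRoot))
    msg <- c(msg, "need 0 < splitTimeIngroups < splitTimeRoot")
  p <- object@pulses
  if (nrow(p)) {
    if (!all(c("time", "source", "dest", "fraction") %in% names(p)))
      msg <- c(msg, "pulses needs columns time, source, dest, fraction")
    else {
      if (any(p$time <= 0)) msg <- c(msg, "pulse times must be > 0")
      if (any(p$time >= object@splitTimeIngroups))
        msg <- c(msg, paste0("pulse at time >= splitTimeIngroups (",
                             object@splitTimeIngroups,
                             "): population no longer exists"))
      if (any(p$fraction < 0 | p$fraction > 1))
        msg <- c(msg, "pulse fractions must be in [0, 1]")
      if (any(p$source == p$dest))
        msg <- c(msg, "pulse source and dest must differ")
      if (!all(c(p$source, p$dest) %in% c("I1", "I2", "O")))
        msg <- c(msg, "pulse populations must be roles I1, I2 or O")
    }
  }
  if (object@recombinationRate < 0)
    msg <- c(msg, "recombinationRate must be >= 0")
  if (object@chromosomeLength < 1)
    msg <- c(msg, "chromosomeLength must be >= 1")
  if (length(object@baseFrequencies) != 4 ||
      abs(sum(object@baseFrequencies) - 1) > 1e-12 ||
      any(object@baseFrequencies < 0))
    msg <- c(msg, "baseFrequencies must be 4 non-negative values summing to 1")
  if (!object@recombinationModel %in% c("smc", "blocks"))
    msg <- c(msg, "recombinationModel must be 'smc' or 'blocks'")
  if (length(msg)) msg else TRUE
})

#' Marginal genealogies tiling a simulated chromosome
#'
#' Compact storage of the sequence of local trees produced by the
#' structured-coalescent simulator.  Every tree has exactly `2 * nTips - 1`
#' nodes; trees are stored column-wise as parent pointers and node times,
#' with half-open intervals `[breakStart, breakEnd)` tiling
#' `[0, chromosomeLength)`.
#'
#' @slot breaks numeric vector of interval end coordinates (bp); the last
#'   equals the chromosome length.
#' @slot parent integer matrix, nodes x trees; 1-based parent ids, 0 = root.
#' @slot nodeTime numeric matrix, nodes x trees; node times in 4N units.
#' @slot tipLabels character tip names (`"I1_1"`, ..., `"O_8"`).
#'
#' @seealso [sampleGenealogies()], [localTree()], [pairTMRCA()]
#' @exportClass LocalGenealogies
setClass("LocalGenealogies",
  representation(
    breaks = "numeric",
    parent = "matrix",
    nodeTime = "matrix",
    tipLabels = "character"
  )
)

setValidity("LocalGenealogies", function(object) {
  msg <- character()
  nt <- length(object@tipLabels)
  if (nrow(object@parent) != 2 * nt - 1)
    msg <- c(msg, "parent must have 2 * nTips - 1 rows")
  if (!identical(dim(object@parent), dim(object@nodeTime)))
    msg <- c(msg, "parent and nodeTime dimensions differ")
  if (ncol(object@parent) != length(object@breaks))
    msg <- c(msg, "one interval per tree required")
  if (length(object@breaks) && any(diff(object@breaks) <= 0))
    msg <- c(msg, "interval breaks must be strictly increasing")
  if (any(object@nodeTime < 0)) msg <- c(msg, "node times must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Haplotype matrix: samples x sites nucleotide calls on one scaffold
#'
#' The shared currency of all statistics in the package.  Calls are stored
#' as raw ASCII bytes (`A`, `C`, `G`, `T`, IUPAC ambiguity codes for diploid
#' heterozygotes, `N` for missing), one column per sample, one row per site.
#'
#' @slot scaffold scaffold/chromosome identifier.
#' @slot scaffoldLength scaffold length in bp (>= max position).
#' @slot positions strictly increasing 1-based site coordinates.
#' @slot calls raw matrix, sites x samples, with sample names as colnames.
#' @slot ploidy 1 (haploid sequences) or 2 (diploid, heterozygotes as IUPAC).
#' @slot provenance `"simulated"` or `"vcf"`.
#'
#' @seealso [simulateHaplotypes()], [readVcfHaplotypes()], [dxyWindows()]
#' @exportClass HaplotypeMatrix
setClass("HaplotypeMatrix",
  representation(
    scaffold = "character",
    scaffoldLength = "numeric",
    positions = "integer",
    calls = "matrix",
    ploidy = "integer",
    provenance = "character"
  )
)

setValidity("HaplotypeMatrix", function(object) {
  msg <- character()
  if (!is.raw(object@calls)) msg <- c(msg, "calls must be a raw matrix")
  if (nrow(object@calls) != length(object@positions))
    msg <- c(msg, "one row of calls per position required")
  if (is.null(colnames(object@calls)))
    msg <- c(msg, "calls must carry sample names as colnames")
  if (length(object@positions) > 1 && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be unique and sorted")
  if (length(object@positions) &&
      object@scaffoldLength < max(object@positions))
    msg <- c(msg, "scaffoldLength smaller than the largest position")
  if (!object@ploidy %in% c(1L, 2L)) msg <- c(msg, "ploidy must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Simulated haplotypes with their generating model and true genealogies
#'
#' A [HaplotypeMatrix] extended with the [DemographicModel] that produced it
#' and the list of true marginal genealogies, kept as ground truth for
#' calibration and testing.
#'
#' @slot model the generating [DemographicModel].
#' @slot genealogies the [LocalGenealogies] the sequences evolved along.
#' @seealso [simulateHaplotypes()]
#' @exportClass SimulatedHaplotypes
setClass("SimulatedHaplotypes",
  contains = "HaplotypeMatrix",
  representation(
    model = "DemographicModel",
    genealogies = "LocalGenealogies"
  )
)

#' Three-population f3 test result
#'
#' Point estimate, weighted block-jackknife standard error and Z-score of
#' the f3 statistic for one tip ordering `f3(target; sourceA, sourceB)`.
#' Significantly negative values indicate the target population is admixed
#' between populations related to the two sources.
#'
#' @slot target target (C) population label.
#' @slot sources the two source (A, B) population labels.
#' @slot estimate f3 point estimate (mean of per-site values).
#' @slot se delete-one-block weighted jackknife standard error.
#' @slot z Z-score `estimate / se` (NA if `se` is 0).
#' @slot nBlocks number of non-empty jackknife blocks.
#' @slot nSites number of sites used.
#' @slot blockEstimates per-block leave-one-out estimates (diagnostics).
#' @seealso [f3Genome()], [f3AllOrderings()]
#' @exportClass F3Result
setClass("F3Result",
  representation(
    target = "character",
    sources = "character",
    estimate = "numeric",
    se = "numeric",
    z = "numeric",
    nBlocks = "integer",
    nSites = "integer",
    blockEstimates = "numeric"
  )
)

setValidity("F3Result", function(object) {
  msg <- character()
  if (length(object@sources) != 2) msg <- c(msg, "exactly two sources required")
  if (object@nBlocks < 2) msg <- c(msg, "at least 2 jackknife blocks required")
  if (is.finite(object@se) && object@se > 0 && is.finite(object@z) &&
      abs(object@z - object@estimate / object@se) > 1e-8)
    msg <- c(msg, "z must equal estimate / se")
  if (length(msg)) msg else TRUE
})

#' Tail-symmetry report for tree-tip distance proportions
#'
#' Per sample-combination summary of the genome-wide distribution of the
#' tree-tip distance proportion: mean, counts of windows above and below the
#' mean at fixed offsets, and the windows flagged below `mean - 0.15`
#' (candidate introgressed regions), aggregated by scaffold.
#'
#' @slot offsets the offsets from the mean at which tails are counted.
#' @slot summary data.frame, one row per combination: `comboId`, `n`, `mean`,
#'   and `nAbove`/`nBelow` columns per offset.
#' @slot flagged data.frame of windows below `mean - flagOffset`.
#' @slot scaffoldHits data.frame of flagged scaffolds with the number of
#'   combinations in which each was flagged.
#' @slot flagOffset the offset used for flagging.
#' @seealso [tailAnalysis()]
#' @exportClass TailReport
setClass("TailReport",
  representation(
    offsets = "numeric",
    summary = "data.frame",
    flagged = "data.frame",
    scaffoldHits = "data.frame",
    flagOffset = "numeric"
  )
)

#' Divergence scan result: top-1% windows by dXY and FST
#'
#' Ranks a common set of genomic windows under absolute divergence and
#' Weir-Cockerham FST, extracts the most divergent 1% under each statistic,
#' and reports their intersection together with each top window's percentile
#' under the other statistic.
#'
#' @slot ranked data.frame of analyzed windows with values, ranks and
#'   percentiles for both statistics.
#' @slot topDxy,topFst data.frames of the top-1% windows per statistic.
#' @slot intersection data.frame of windows in both top sets.
#' @slot topFraction the tail fraction used (default 0.01).
#' @seealso [divergenceScan()]
#' @exportClass DivergenceScanResult
setClass("DivergenceScanResult",
  representation(
    ranked = "data.frame",
    topDxy = "data.frame",
    topFst = "data.frame",
    intersection = "data.frame",
    topFraction = "numeric"
  )
)
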