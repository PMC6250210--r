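#' Construct a demographic model
#'
#' Builds the three-population model used throughout the package.  The
#' defaults are the simulation study's conditions: 8 haploid samples per
#' population, ingroup split at 0.4 and root at 1.5 (units of 4N
#' generations), population-scaled recombination rate 4Nr = 0.001 per bp,
#' a 25 Mb chromosome, and HKY sequence evolution with branch scaling 0.01
#' expected substitutions per site per 4N-generation unit.
#'
#' @param samplesPerPopulation haploid samples per population (default 8,
#'   i.e. 24 tips in total).
#' @param splitTimeIngroups,splitTimeRoot split times in 4N units.
#' @param pulses admixture pulse schedule as returned by [pulseSchedule()]
#'   or [admixturePulse()]; empty for no gene flow.
#' @param recombinationRate 4Nr per base pair.
#' @param chromosomeLength chromosome length in bp.
#' @param branchScale expected substitutions per site per 4N unit.
#' @param hkyKappa HKY transition/transversion rate ratio.
#' @param baseFrequencies equilibrium base frequencies (A, C, G, T).
#' @param recombinationModel `"smc"` for sequentially Markovian tree
#'   updating or `"blocks"` for an independent genealogy per block.
#' @param blockSize block length in bp for `recombinationModel = "blocks"`.
#' @param seed integer master seed.
#' @return a validated [DemographicModel-class] object.
#' @examples
#' mod <- DemographicModel(chromosomeLength = 1e5,
#'                         pulses = pulseSchedule(0.2, "single"))
#' mod
#' @export
DemographicModel <- function(samplesPerPopulation = 8,
                             splitTimeIngroups = 0.4,
                             splitTimeRoot = 1.5,
                             pulses = emptyPulses(),
                             recombinationRate = 0.001,
                             chromosomeLength = 25e6,
                             branchScale = 0.01,
                             hkyKappa = 2,
                             baseFrequencies = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                             recombinationModel = c("smc", "blocks"),
                             blockSize = 1000,
                             seed = 1L) {
  recombinationModel <- match.arg(recombinationModel)
  if (is.null(names(baseFrequencies)))
    names(baseFrequencies) <- c("A", "C", "G", "T")
  new("DemographicModel",
      populationLabels = c(I1 = "I1", I2 = "I2", O = "O"),
      samplesPerPopulation = as.integer(samplesPerPopulation),
      splitTimeIngroups = splitTimeIngroups,
      splitTimeRoot = splitTimeRoot,
      pulses = pulses,
      recombinationRate = recombinationRate,
      chromosomeLength = chromosomeLength,
      branchScale = branchScale,
      hkyKappa = hkyKappa,
      baseFrequencies = baseFrequencies,
      recombinationModel = recombinationModel,
      blockSize = blockSize,
      seed = as.integer(seed))
}

#' @rdname pulseSchedule
#' @export
emptyPulses <- function() {
  data.frame(time = numeric(), source = character(), dest = character(),
             fraction = numeric(), stringsAsFactors = FALSE)
}

#' A single admixture pulse
#'
#' Backwards in time, each lineage currently in `dest` relabels to `source`
#' with probability `fraction` at `time`: forwards in time this is an
#' instantaneous replacement of a fraction of the recipient (`dest`)
#' population by migrants from the donor (`source`).
#'
#' @param time pulse time in 4N units (must predate the ingroup split).
#' @param source donor population role (`"I1"`, `"I2"` or `"O"`).
#' @param dest recipient population role.
#' @param fraction admixture fraction in `[0, 1]`.
#' @return a one-row pulse data.frame.
#' @examples
#' admixturePulse(0.01, source = "O", dest = "I2", fraction = 0.2)
#' @export
admixturePulse <- function(time, source, dest, fraction) {
  stopifnot(time > 0, fraction >= 0, fraction <= 1, source != dest)
  data.frame(time = time, source = source, dest = dest, fraction = fraction,
             stringsAsFactors = FALSE)
}

#' Build a pulse schedule for a total admixture fraction
#'
#' `"single"` places one *en masse* pulse at 0.01 x 4N generations with the
#' full fraction.  `"five_event"` spreads the same total over five
#' breakdowns in assortative mating at 0.01, 0.008, 0.006, 0.004 and
#' 0.002 x 4N generations; by default each pulse carries
#' `q = 1 - (1 - totalFraction)^(1/5)` so that the cumulative admixed
#' ancestry equals `totalFraction` (an `"equal"` split of
#' `totalFraction / 5` per pulse is available).
#'
#' @param totalFraction total admixed ancestry, in `[0, 1)`.
#' @param mode `"single"` or `"five_event"`.
#' @param source,dest donor and recipient population roles.
#' @param times pulse times; defaults depend on `mode`.
#' @param split for `"five_event"`: `"compound"` (default) or `"equal"`.
#' @return a pulse data.frame suitable for [DemographicModel()].
#' @examples
#' pulseSchedule(0.3, "single")
#' pulseSchedule(0.2, "five_event")
#' @export
pulseSchedule <- function(totalFraction, mode = c("single", "five_event"),
                          source = "O", dest = "I2", times = NULL,
                          split = c("compound", "equal")) {
  mode <- match.arg(mode)
  split <- match.arg(split)
  if (totalFraction < 0 || totalFraction >= 1)
    stop("totalFraction must lie in [0, 1)")
  if (mode == "single") {
    if (is.null(times)) times <- 0.01
    data.frame(time = times, source = source, dest = dest,
               fraction = totalFraction, stringsAsFactors = FALSE)
  } else {
    if (is.null(times)) times <- c(0.01, 0.008, 0.006, 0.004, 0.002)
    q <- if (split == "compound") 1 - (1 - totalFraction)^(1 / length(times))
         else totalFraction / length(times)
    data.frame(time = times, source = source, dest = dest, fraction = q,
               stringsAsFactors = FALSE)
  }
}

#' Read a demographic model from a key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment.  Keys mirror the
#' arguments of [DemographicModel()] (snake_case or camelCase accepted);
#' the convenience keys `admixture_fraction`, `admixture_mode`,
#' `admixture_source` and `admixture_dest` build the pulse schedule via
#' [pulseSchedule()].
#'
#' @param path path to the configuration file.
#' @return a [DemographicModel-class].
#' @export
readModelConfig <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", ln[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  names(vals) <- gsub("_(.)", "\\U\\1", tolower(keys), perl = TRUE)
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  chr <- function(k, d) if (k %in% names(vals)) vals[[k]] else d
  pulses <- emptyPulses()
  if ("admixtureFraction" %in% names(vals) && as.numeric(vals[["admixtureFraction"]]) > 0)
    pulses <- pulseSchedule(as.numeric(vals[["admixtureFraction"]]),
                            mode = chr("admixtureMode", "single"),
                            source = chr("admixtureSource", "O"),
                            dest = chr("admixtureDest", "I2"))
  DemographicModel(
    samplesPerPopulation = num("samplesPerPopulation", 8),
    splitTimeIngroups = num("splitTimeIngroups", 0.4),
    splitTimeRoot = num("splitTimeRoot", 1.5),
    pulses = pulses,
    recombinationRate = num("recombinationRate", 0.001),
    chromosomeLength = num("chromosomeLength", 25e6),
    branchScale = num("branchScale", 0.01),
    hkyKappa = num("hkyKappa", 2),
    recombinationModel = chr("recombinationModel", "smc"),
    blockSize = num("blockSize", 1000),
    seed = num("seed", 1))
}

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel: ((I1, I2), O)\n")
  cat(sprintf("  %d haploid samples/population (%d tips)\n",
              object@samplesPerPopulation, 3 * object@samplesPerPopulation))
  cat(sprintf("  splits: ingroups %.3g, root %.3g (4N units)\n",
              object@splitTimeIngroups, object@splitTimeRoot))
  if (nrow(object@pulses)) {
    cat(sprintf("  %d admixture pulse(s): %s -> %s, fractions %s at times %s\n",
                nrow(object@pulses), object@pulses$source[1],
                object@pulses$dest[1],
                paste(signif(object@pulses$fraction, 3), collapse = ","),
                paste(object@pulses$time, collapse = ",")))
  } else cat("  no admixture pulses\n")
  cat(sprintf("  chromosome %.4g bp, 4Nr = %g/bp (%s), HKY kappa %.3g, branch scale %g\n",
              object@chromosomeLength, object@recombinationRate,
              object@recombinationModel, object@hkyKappa, object@branchScale))
  cat(sprintf("  seed %d\n", object@seed))
})
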