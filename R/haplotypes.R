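#' @name HaplotypeMatrix-accessors
#' @title Accessors for HaplotypeMatrix objects
#' @param x a [HaplotypeMatrix-class].
#' @return `callMatrix` the raw calls matrix; `sitePositions` the 1-based
#'   site coordinates; `sampleNames` the sample identifiers; `scaffoldName`
#'   and `scaffoldLength` the scaffold id and length; `ploidy` 1 or 2;
#'   `nSites`/`nSamples` the matrix dimensions.
NULL

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("callMatrix", function(x) standardGeneric("callMatrix"))
#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("callMatrix", "HaplotypeMatrix", function(x) x@calls)

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))
#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("sitePositions", "HaplotypeMatrix", function(x) x@positions)

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))
#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("sampleNames", "HaplotypeMatrix", function(x) colnames(x@calls))

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("scaffoldName", function(x) standardGeneric("scaffoldName"))
#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("scaffoldName", "HaplotypeMatrix", function(x) x@scaffold)

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("scaffoldLength", function(x) standardGeneric("scaffoldLength"))
#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("scaffoldLength", "HaplotypeMatrix", function(x) x@scaffoldLength)

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))
#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("ploidy", "HaplotypeMatrix", function(x) x@ploidy)

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("nSites", "HaplotypeMatrix", function(x) length(x@positions))

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("nSamples", "HaplotypeMatrix", function(x) ncol(x@calls))

setMethod("show", "HaplotypeMatrix", function(object) {
  cat(sprintf("%s: %d samples x %d sites on %s (%.4g bp), ploidy %d, %s\n",
              class(object), ncol(object@calls), length(object@positions),
              object@scaffold, object@scaffoldLength, object@ploidy,
              object@provenance))
})

#' Construct a HaplotypeMatrix from character sequences
#'
#' Mostly a convenience for tests and small examples; large data come from
#' [simulateHaplotypes()] or [readVcfHaplotypes()].
#'
#' @param sequences named character vector (one string per sample, equal
#'   lengths) or a sites x samples character matrix of single bases.
#' @param scaffold scaffold identifier.
#' @param positions 1-based site coordinates (default: consecutive).
#' @param scaffoldLength scaffold length (default: max position).
#' @param ploidy 1 or 2.
#' @param provenance provenance tag.
#' @return a [HaplotypeMatrix-class].
#' @examples
#' HaplotypeMatrix(c(s1 = "ACGT", s2 = "ACGA"))
#' @export
HaplotypeMatrix <- function(sequences, scaffold = "scaffold_1",
                            positions = NULL, scaffoldLength = NULL,
                            ploidy = 1L, provenance = "simulated") {
  if (is.matrix(sequences)) {
    m <- matrix(charToRaw(paste(sequences, collapse = "")),
                nrow = nrow(sequences))
    dim(m) <- dim(sequences)
    colnames(m) <- colnames(sequences)
  } else {
    stopifnot(!is.null(names(sequences)),
              length(unique(nchar(sequences))) == 1)
    m <- vapply(sequences, charToRaw, raw(nchar(sequences[1])))
  }
  if (is.null(positions)) positions <- seq_len(nrow(m))
  if (is.null(scaffoldLength)) scaffoldLength <- max(positions)
  new("HaplotypeMatrix", scaffold = scaffold,
      scaffoldLength = as.numeric(scaffoldLength),
      positions = as.integer(positions), calls = m,
      ploidy = as.integer(ploidy), provenance = provenance)
}

#' Population map for samples
#'
#' Assigns each sample a population label, a species label, one of the
#' roles `I1` (allopatric ingroup), `I2` (sympatric ingroup) or `O`
#' (outgroup), and optionally marks the two fixed `I1` individuals used by
#' the tree-tip distance quartets.
#'
#' @param sample sample identifiers.
#' @param population population labels (e.g. collection site/year).
#' @param role one of `"I1"`, `"I2"`, `"O"` per sample.
#' @param species species labels (defaults to the role).
#' @param fixedI1 logical, marks the two fixed `I1` quartet tips.
#' @return a validated data.frame with those columns.
#' @export
populationMap <- function(sample, population, role, species = role,
                          fixedI1 = FALSE) {
  pm <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   role = as.character(role),
                   species = as.character(species),
                   fixedI1 = rep_len(fixedI1, length(sample)),
                   stringsAsFactors = FALSE)
  if (!all(pm$role %in% c("I1", "I2", "O")))
    stop("roles must be I1, I2 or O")
  if (anyDuplicated(pm$sample)) stop("duplicated sample identifiers")
  pm
}

#' Default population map for simulated haplotypes
#'
#' @param x a [SimulatedHaplotypes-class], [LocalGenealogies-class] or the
#'   number of samples per population.
#' @return a [populationMap()] data.frame; the first two `I1` samples are
#'   the fixed quartet tips.
#' @export
simPopulationMap <- function(x) {
  n <- if (is(x, "SimulatedHaplotypes")) x@model@samplesPerPopulation
       else if (is(x, "LocalGenealogies")) length(x@tipLabels) / 3
       else x
  lab <- .tipLabels(n)
  role <- rep(c("I1", "I2", "O"), each = n)
  populationMap(lab, population = role, role = role,
                fixedI1 = lab %in% c("I1_1", "I1_2"))
}

.popSamples <- function(popmap, population, hap = NULL) {
  s <- popmap$sample[popmap$population == population |
                     popmap$role == population]
  if (!length(s)) stop("no samples mapped to population '", population, "'")
  if (!is.null(hap)) {
    idx <- match(s, sampleNames(hap))
    if (anyNA(idx))
      stop("samples missing from haplotype matrix: ",
           paste(s[is.na(idx)], collapse = ", "))
    idx
  } else s
}
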