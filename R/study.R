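#' Run the full simulation calibration study
#'
#' Simulates the grid of admixture direction x total fraction x pulse mode,
#' and for every cell computes the three f3 orderings, windowed dXY means
#' for the three population pairs, and the quartet proportion distribution.
#' Each cell draws its own seed derived from `seed`, so a fixed seed gives
#' byte-identical reports across reruns.  Any cell failure aborts with the
#' cell identified.
#'
#' @param baseModel template [DemographicModel-class]; its pulse schedule
#'   is replaced per cell.
#' @param directions subset of `c("OtoI2", "I2toO")`.
#' @param fractions total admixture fractions (default the study grid
#'   `c(0, 0.05, 0.1, 0.2, 0.3)`).
#' @param modes subset of `c("single", "five_event")`.
#' @param replicates independent replicates per cell.
#' @param windowSize window width in bp for dXY and proportions.
#' @param blockSize f3 jackknife block size in bp.
#' @param maxCombinations cap on quartet combinations per cell (default
#'   all, 64 at the default sample sizes); set 0 to skip proportions.
#' @param seed integer; per-cell seeds are derived from it.
#' @return an object of class `admixStudy`: list with `summary` (one row
#'   per cell x replicate), `details` (per-cell results) and `config`.
#' @export
runSimulationStudy <- function(baseModel = DemographicModel(),
                               directions = c("OtoI2", "I2toO"),
                               fractions = c(0, 0.05, 0.1, 0.2, 0.3),
                               modes = "single",
                               replicates = 1,
                               windowSize = 50000,
                               blockSize = 5e5,
                               maxCombinations = NULL,
                               seed = baseModel@seed) {
  directions <- match.arg(directions, c("OtoI2", "I2toO"),
                          several.ok = TRUE)
  modes <- match.arg(modes, c("single", "five_event"), several.ok = TRUE)
  grid <- expand.grid(replicate = seq_len(replicates),
                      fraction = fractions, mode = modes,
                      direction = directions, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  details <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cellId <- sprintf("direction=%s f=%g mode=%s rep=%d", g$direction,
                      g$fraction, g$mode, g$replicate)
    cellSeed <- (seed + 7919L * (i - 1L)) %% .Machine$integer.max
    res <- tryCatch(
      .runStudyCell(baseModel, g, cellSeed, windowSize, blockSize,
                    maxCombinations),
      error = function(e) stop("simulation study cell [", cellId,
                               "] failed: ", conditionMessage(e),
                               call. = FALSE))
    rows[[i]] <- res$row
    details[[i]] <- res$detail
    names(details)[i] <- cellId
  }
  out <- list(summary = do.call(rbind, rows), details = details,
              config = list(directions = directions, fractions = fractions,
                            modes = modes, replicates = replicates,
                            windowSize = windowSize, blockSize = blockSize,
                            seed = seed,
                            chromosomeLength = baseModel@chromosomeLength))
  class(out) <- "admixStudy"
  out
}

.runStudyCell <- function(baseModel, g, cellSeed, windowSize, blockSize,
                          maxCombinations) {
  src <- if (g$direction == "OtoI2") "O" else "I2"
  dst <- if (g$direction == "OtoI2") "I2" else "O"
  pulses <- if (g$fraction > 0)
    pulseSchedule(g$fraction, g$mode, source = src, dest = dst)
  else emptyPulses()
  model <- baseModel
  model@pulses <- pulses
  model@seed <- as.integer(cellSeed)
  validObject(model)
  hap <- simulateHaplotypes(model)
  popmap <- simPopulationMap(hap)
  windows <- makeWindows(hap, windowSize)
  f3 <- f3AllOrderings(hap, popmap, blockSize = blockSize)
  dxy <- list(
    I1I2 = dxyWindows(hap, popmap, "I1", "I2", windows),
    I1O = dxyWindows(hap, popmap, "I1", "O", windows),
    I2O = dxyWindows(hap, popmap, "I2", "O", windows))
  meanDxy <- vapply(dxy, function(x)
    mean(S4Vectors::mcols(x)$value, na.rm = TRUE), 0)
  props <- NULL
  meanProp <- NA_real_
  nProp <- 0L
  if (is.null(maxCombinations) || maxCombinations > 0) {
    combos <- enumerateQuartets(popmap, "simulated")
    if (!is.null(maxCombinations) && nrow(combos) > maxCombinations)
      combos <- combos[seq_len(maxCombinations), , drop = FALSE]
    props <- windowProportionScan(hap, popmap, windows, combos)
    meanProp <- mean(props$proportion, na.rm = TRUE)
    nProp <- sum(!is.na(props$proportion))
  }
  row <- data.frame(
    direction = g$direction, mode = g$mode, fraction = g$fraction,
    replicate = g$replicate, seed = cellSeed,
    f3_I1I2_O = f3Estimate(f3[["f3(I1,I2;O)"]]),
    f3_I1O_I2 = f3Estimate(f3[["f3(I1,O;I2)"]]),
    f3_I2O_I1 = f3Estimate(f3[["f3(I2,O;I1)"]]),
    z_I1O_I2 = f3Z(f3[["f3(I1,O;I2)"]]),
    meanDxy_I1I2 = meanDxy[["I1I2"]],
    meanDxy_I1O = meanDxy[["I1O"]],
    meanDxy_I2O = meanDxy[["I2O"]],
    meanProportion = meanProp,
    nWindows = length(windows), nProportions = nProp,
    stringsAsFactors = FALSE)
  list(row = row, detail = list(f3 = f3, dxy = dxy, proportions = props,
                                seed = cellSeed))
}

#' @export
print.admixStudy <- function(x, ...) {
  cat(sprintf("admixStudy: %d cell(s), chromosome %.4g bp, seed %d\n",
              nrow(x$summary), x$config$chromosomeLength, x$config$seed))
  print(x$summary[, c("direction", "mode", "fraction", "replicate",
                      "f3_I1O_I2", "meanDxy_I2O", "meanProportion")])
  invisible(x)
}

#' Rank windows and extract the most divergent 1%
#'
#' Ranks a common window set under dXY and FST (each excluding its own NA
#' windows), extracts the top `topFraction` (default 1%, set size
#' `ceiling(topFraction * analyzed)`) under each statistic, and reports
#' the intersection together with each window's percentile under the
#' other statistic.
#'
#' @param dxy,fst GRanges from [dxyWindows()] and [fstWindows()] over the
#'   same windows.
#' @param topFraction tail fraction (default 0.01).
#' @return a [DivergenceScanResult-class].
#' @export
divergenceScan <- function(dxy, fst, topFraction = 0.01) {
  if (length(dxy) != length(fst) ||
      any(GenomicRanges::start(dxy) != GenomicRanges::start(fst)) ||
      any(as.character(GenomeInfoDb::seqnames(dxy)) !=
          as.character(GenomeInfoDb::seqnames(fst))))
    stop("dxy and fst must be computed over the same window set")
  df <- data.frame(
    scaffold = as.character(GenomeInfoDb::seqnames(dxy)),
    start = GenomicRanges::start(dxy), end = GenomicRanges::end(dxy),
    dxy = S4Vectors::mcols(dxy)$value, fst = S4Vectors::mcols(fst)$value,
    stringsAsFactors = FALSE)
  okD <- !is.na(df$dxy); okF <- !is.na(df$fst)
  if (sum(okD) < 100 || sum(okF) < 100)
    warning("fewer than 100 analyzed windows; top 1% is a single window")
  df$dxyRank <- NA_integer_; df$fstRank <- NA_integer_
  df$dxyRank[okD] <- rank(-df$dxy[okD], ties.method = "first")
  df$fstRank[okF] <- rank(-df$fst[okF], ties.method = "first")
  df$dxyPercentile <- NA_real_; df$fstPercentile <- NA_real_
  df$dxyPercentile[okD] <- 100 * (1 - (df$dxyRank[okD] - 1) / sum(okD))
  df$fstPercentile[okF] <- 100 * (1 - (df$fstRank[okF] - 1) / sum(okF))
  kD <- ceiling(topFraction * sum(okD))
  kF <- ceiling(topFraction * sum(okF))
  topD <- df[okD & df$dxyRank <= kD, , drop = FALSE]
  topF <- df[okF & df$fstRank <= kF, , drop = FALSE]
  key <- function(d) paste(d$scaffold, d$start, d$end)
  inter <- topD[key(topD) %in% key(topF), , drop = FALSE]
  rownames(topD) <- rownames(topF) <- rownames(inter) <- NULL
  new("DivergenceScanResult", ranked = df, topDxy = topD, topFst = topF,
      intersection = inter, topFraction = topFraction)
}

setMethod("show", "DivergenceScanResult", function(object) {
  cat(sprintf("DivergenceScanResult: %d windows; top %.3g%%: %d by dXY, %d by FST, %d shared\n",
              nrow(object@ranked), 100 * object@topFraction,
              nrow(object@topDxy), nrow(object@topFst),
              nrow(object@intersection)))
})

#' Write a simulation-study report to disk
#'
#' Emits `summary.tsv` (one row per cell x replicate), an `f3.tsv` table,
#' per-cell proportion tables, and a plain-text run manifest recording the
#' configuration and per-cell seeds.  Sections whose stage was not run are
#' marked "not run" in the manifest.  With a fixed study seed the output
#' is byte-identical across reruns.
#'
#' @param study an `admixStudy` from [runSimulationStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeStudyReport <- function(study, dir) {
  stopifnot(inherits(study, "admixStudy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(study$summary, "summary.tsv")
  f3rows <- do.call(rbind, lapply(names(study$details), function(nm) {
    f3 <- study$details[[nm]]$f3
    do.call(rbind, lapply(names(f3), function(ord) {
      r <- f3[[ord]]
      data.frame(cell = nm, ordering = ord, estimate = r@estimate,
                 se = r@se, z = r@z, nSites = r@nSites,
                 nBlocks = r@nBlocks, stringsAsFactors = FALSE)
    }))
  }))
  tsv(f3rows, "f3.tsv")
  propRun <- FALSE
  for (nm in names(study$details)) {
    pr <- study$details[[nm]]$proportions
    if (!is.null(pr) && nrow(pr)) {
      propRun <- TRUE
      tsv(pr, paste0("proportions_", gsub("[^A-Za-z0-9.]+", "_", nm),
                     ".tsv"))
    }
  }
  cfg <- study$config
  manifest <- c("admixscan simulation study manifest",
                paste0("package_version=",
                       as.character(utils::packageVersion("admixscan"))),
                vapply(names(cfg), function(k)
                  paste0(k, "=", paste(cfg[[k]], collapse = ",")), ""),
                paste0("cells=", length(study$details)),
                paste0("cell_seeds=",
                       paste(vapply(study$details, function(d)
                         d$seed, 0), collapse = ",")),
                paste0("proportions=",
                       if (propRun) "written" else "not run"))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
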