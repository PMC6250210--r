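library(GenomicRanges)

oneWindow <- function(scaffold, start, end)
  GRanges(scaffold, IRanges::IRanges(start, end))

test_that("pi matches single-site arithmetic and the pair-enumeration oracle", {
  # one site with 2 of 4 ref alleles among 10 callable sites:
  # pi = (2*2*2 / (4*3)) / 10
  seqs <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA",
            c = "AAAAACAAAA", d = "AAAAACAAAA")
  toy <- toyHaplotypes(seqs, roles = rep("I1", 4))
  pr <- piWindows(toy$hap, toy$popmap, "I1",
                  windows = oneWindow("scaffold_1", 1, 10),
                  minCallableFrac = 0)
  expect_equal(mcols(pr)$value, (2 * 2 * 2 / (4 * 3)) / 10)
  expect_equal(mcols(pr)$nSitesUsed, 10L)

  # all monomorphic -> exactly 0
  mono <- toyHaplotypes(c(a = "ACGT", b = "ACGT", c = "ACGT"),
                        roles = rep("I1", 3))
  pm <- piWindows(mono$hap, mono$popmap, "I1",
                  windows = oneWindow("scaffold_1", 1, 4),
                  minCallableFrac = 0)
  expect_equal(mcols(pm)$value, 0)

  # simulated data: window pi equals the all-pairs mismatch average exactly
  hap <- simulateHaplotypes(tinyModel(L = 2e4, seed = 21))
  popmap <- simPopulationMap(hap)
  pw <- piWindows(hap, popmap, "O", windows = oneWindow("sim_1", 1, 2e4))
  oracle <- allPairsPi(hap, paste0("O_", 1:8))
  expect_equal(mcols(pw)$value, oracle, tolerance = 1e-12)
})

test_that("dxy handles fixed differences, shared polymorphism and the exact identity", {
  # fixed difference at every site -> dxy = 1
  fx <- toyHaplotypes(c(a = "AAAA", b = "AAAA", c = "GGGG", d = "GGGG"),
                      roles = c("I1", "I1", "I2", "I2"))
  d <- dxyWindows(fx$hap, fx$popmap, "I1", "I2",
                  windows = oneWindow("scaffold_1", 1, 4),
                  minCallableFrac = 0)
  expect_equal(mcols(d)$value, 1)

  # both populations at p = 0.5 -> 2p(1-p) = 0.5
  eq <- toyHaplotypes(c(a = "AAAA", b = "GGGG", c = "AAAA", d = "GGGG"),
                      roles = c("I1", "I1", "I2", "I2"))
  d2 <- dxyWindows(eq$hap, eq$popmap, "I1", "I2",
                   windows = oneWindow("scaffold_1", 1, 4),
                   minCallableFrac = 0)
  expect_equal(mcols(d2)$value, 0.5)

  # on complete data dxy equals all-pairs mismatch averaging exactly, and
  # is symmetric in its population arguments
  hap <- simulateHaplotypes(tinyModel(L = 2e4, seed = 22))
  popmap <- simPopulationMap(hap)
  win <- oneWindow("sim_1", 1, 2e4)
  dAB <- dxyWindows(hap, popmap, "I1", "I2", win)
  dBA <- dxyWindows(hap, popmap, "I2", "I1", win)
  expect_identical(mcols(dAB)$value, mcols(dBA)$value)
  oracle <- allPairsMismatch(hap, paste0("I1_", 1:8), paste0("I2_", 1:8))
  expect_equal(mcols(dAB)$value, oracle, tolerance = 1e-12)

  # species-tree expectation: ingroup-ingroup divergence below
  # ingroup-outgroup divergence
  dIO <- dxyWindows(hap, popmap, "I2", "O", win)
  expect_lt(mcols(dAB)$value, mcols(dIO)$value)
})

test_that("Weir-Cockerham FST matches limits and the single-site oracle", {
  # two samples of n = 8 haploids from identical allele frequencies -> ~0
  set.seed(230)
  S <- 2000
  p <- stats::runif(S, 0.1, 0.9)
  draw <- function(prefix) {
    m <- matrix("A", S, 8)
    for (s in seq_len(S)) m[s, ] <- ifelse(stats::runif(8) < p[s], "G", "A")
    colnames(m) <- paste0(prefix, 1:8)
    m
  }
  m <- cbind(draw("x"), draw("y"))
  hap0 <- HaplotypeMatrix(m)
  pm0 <- populationMap(colnames(m), population = rep(c("X", "Y"), each = 8),
                       role = rep(c("I1", "I2"), each = 8))
  f0 <- fstWindows(hap0, pm0, "X", "Y",
                   windows = oneWindow("scaffold_1", 1, S),
                   minCallableFrac = 0)
  expect_lt(abs(mcols(f0)$value), 0.05)

  # fixed difference -> 1 within 2/n
  fx <- toyHaplotypes(
    stats::setNames(c(rep("AAAA", 8), rep("GGGG", 8)), paste0("s", 1:16)),
    roles = rep(c("I1", "I2"), each = 8))
  f1 <- fstWindows(fx$hap, fx$popmap, "I1", "I2",
                   windows = oneWindow("scaffold_1", 1, 4),
                   minCallableFrac = 0)
  expect_gt(mcols(f1)$value, 1 - 2 / 8)
  expect_lte(mcols(f1)$value, 1)

  # 5+5 diploids at 3 sites against the hand-computed W&C components
  gt <- list(
    list(p = c(0.2, 0.5), h = c(0.4, 0.2)),
    list(p = c(0.1, 0.9), h = c(0.2, 0.2)),
    list(p = c(0.6, 0.4), h = c(0.4, 0.4)))
  # build diploid IUPAC sequences realising those counts: allele A vs G,
  # het coded R; 5 individuals per population
  mk <- function(p, h, n = 5) {
    nHet <- round(h * n)
    nAA <- round((p * 2 * n - nHet) / 2)
    c(rep("A", nAA), rep("R", nHet), rep("G", n - nAA - nHet))
  }
  seqA <- do.call(rbind, lapply(gt, function(s) mk(s$p[1], s$h[1])))
  seqB <- do.call(rbind, lapply(gt, function(s) mk(s$p[2], s$h[2])))
  m <- cbind(seqA, seqB)
  colnames(m) <- paste0("d", 1:10)
  toy <- list(hap = HaplotypeMatrix(m, ploidy = 2),
              popmap = populationMap(paste0("d", 1:10),
                                     population = rep(c("P1", "P2"), each = 5),
                                     role = rep(c("I1", "I2"), each = 5)))
  fw <- fstWindows(toy$hap, toy$popmap, "P1", "P2",
                   windows = oneWindow("scaffold_1", 1, 3),
                   minCallableFrac = 0)
  comp <- sapply(gt, function(s)
    wcSiteOracle(c(5, 5), s$p, s$h))
  expect_equal(mcols(fw)$value,
               sum(comp["a", ]) / sum(colSums(comp)), tolerance = 1e-12)
})

test_that("Tajima's D matches the textbook constants and neutral expectation", {
  # all sequences identical -> S = 0 -> NA
  mono <- toyHaplotypes(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"),
                        roles = rep("I1", 4))
  td <- tajimaDWindows(mono$hap, mono$popmap, "I1",
                       windows = oneWindow("scaffold_1", 1, 4),
                       minCallableFrac = 0)
  expect_true(is.na(mcols(td)$value))

  # n = 4 sequences, 3 segregating sites with derived counts {1, 1, 2}
  seqs <- c(a = "CACAAA", b = "ACCAAA", c = "AAAAAA", d = "AAAAAA")
  toy <- toyHaplotypes(seqs, roles = rep("I1", 4))
  td2 <- tajimaDWindows(toy$hap, toy$popmap, "I1",
                        windows = oneWindow("scaffold_1", 1, 6),
                        minCallableFrac = 0)
  piSum <- sum(2 * c(1, 1, 2) * (4 - c(1, 1, 2)) / (4 * 3))
  expect_equal(mcols(td2)$value, tajimaOracle(4, 3, piSum),
               tolerance = 1e-12)
  expect_equal(mcols(td2)$nSegregating, 3L)

  # neutral equilibrium: mean D over many windows near 0
  hap <- simulateHaplotypes(tinyModel(L = 1e6, seed = 24))
  popmap <- simPopulationMap(hap)
  td3 <- tajimaDWindows(hap, popmap, "I1",
                        windows = makeWindows(c(sim_1 = 1e6), 5000))
  expect_lt(abs(mean(mcols(td3)$value, na.rm = TRUE)), 0.3)
})

test_that("sliding windows follow the tiling arithmetic", {
  hap <- simulateHaplotypes(tinyModel(L = 5e4, seed = 25))
  popmap <- simPopulationMap(hap)
  sl <- slidingDxy(hap, popmap, "I1", "I2", windowSize = 1e4, step = 2e3)
  expect_equal(length(sl), floor((5e4 - 1e4) / 2e3) + 1)
  # step == windowSize reduces to the non-overlapping tiling
  sl2 <- slidingDxy(hap, popmap, "I1", "I2", windowSize = 1e4, step = 1e4)
  tiled <- dxyWindows(hap, popmap, "I1", "I2",
                      windows = makeWindows(c(sim_1 = 5e4), 1e4))
  expect_equal(mcols(sl2)$value, mcols(tiled)$value)
  # scaffold shorter than the window: one clipped window
  sh <- simulateHaplotypes(tinyModel(L = 5e3, seed = 26))
  sl3 <- slidingDxy(sh, simPopulationMap(sh), "I1", "I2",
                    windowSize = 1e4, step = 2e3)
  expect_equal(length(sl3), 1L)
  expect_equal(GenomicRanges::width(sl3), 5e3)
})

test_that("an implanted low-divergence tract depresses sliding dxy", {
  hap <- simulateHaplotypes(tinyModel(L = 1e5, seed = 27))
  popmap <- simPopulationMap(hap)
  calls <- callMatrix(hap)
  # copy the I1_1 haplotype into every I2 sample across 30-60 kb
  tract <- 30001:60000
  for (s in paste0("I2_", 1:8)) calls[tract, s] <- calls[tract, "I1_1"]
  hap2 <- HaplotypeMatrix(
    structure(sapply(colnames(calls), function(j)
      rawToChar(calls[, j])), names = colnames(calls)),
    scaffold = "sim_1")
  sl <- slidingDxy(hap2, popmap, "I1", "I2", windowSize = 1e4, step = 2e3)
  v <- mcols(sl)$value
  inside <- GenomicRanges::start(sl) >= 30001 & GenomicRanges::end(sl) <= 60000
  # a contiguous run of depressed windows covers the tract
  expect_true(all(v[inside] < stats::median(v[!inside])))
  expect_true(inside[which.min(v)])
  expect_lt(mean(v[inside]), mean(v[!inside]))
})

test_that("density rescaling pins the modal bin at one", {
  h <- rescaleDensity(c(rep(0.5, 10), 0.61, 0.74), binWidth = 0.05)
  expect_equal(max(h$height), 1)
  expect_equal(h$height[h$binStart == 0.5], 1)
  single <- rescaleDensity(rep(0.2, 5))
  expect_equal(sum(single$count > 0), 1L)
  expect_equal(max(single$height), 1)
  expect_error(rescaleDensity(c(NA, Inf)), "finite")
})

test_that("windows failing the minimum-callable rule propagate NA", {
  # 10 sites of data inside a 100-bp window: 10% callable < 20% threshold
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAA",
            c = "ACGTACGTAC", d = "ACGTACGTAA")
  toy <- toyHaplotypes(seqs, roles = c("I1", "I1", "I2", "I2"))
  hap <- HaplotypeMatrix(seqs, positions = 1:10, scaffoldLength = 100)
  d <- dxyWindows(hap, toy$popmap, "I1", "I2",
                  windows = oneWindow("scaffold_1", 1, 100))
  expect_true(is.na(mcols(d)$value))
  expect_equal(mcols(d)$nSitesUsed, 10L)
  expect_equal(mcols(d)$nSitesPossible, 100L)
})
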