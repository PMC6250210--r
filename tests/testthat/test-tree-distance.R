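test_that("pairwise distances invert the Jukes-Cantor map and saturate", {
  toy <- toyHaplotypes(c(a = "ACGTACGTAC", b = "ACGTACGTAC"),
                       roles = c("I1", "I1"))
  expect_equal(pairwiseDistance(toy$hap, "a", "b")$distance, 0)

  # mismatch fraction p = 0.75 (1 - exp(-4t/3)) recovers exactly t
  t <- 0.3
  p <- 0.75 * (1 - exp(-4 * t / 3))
  n <- 10000
  k <- round(p * n)
  s1 <- paste(rep("A", n), collapse = "")
  s2 <- paste(c(rep("C", k), rep("A", n - k)), collapse = "")
  hap <- HaplotypeMatrix(c(a = s1, b = s2))
  expect_equal(pairwiseDistance(hap, "a", "b")$distance,
               -0.75 * log(1 - 4 * (k / n) / 3), tolerance = 1e-12)

  # saturated pairs cap at maxDistance instead of erroring
  sat <- HaplotypeMatrix(c(a = paste(rep("A", 100), collapse = ""),
                           b = paste(rep("C", 100), collapse = "")))
  expect_equal(pairwiseDistance(sat, "a", "b", maxDistance = 5)$distance, 5)

  # no jointly callable sites -> NA
  nn <- HaplotypeMatrix(c(a = "ANN", b = "NAN"))
  expect_true(is.na(pairwiseDistance(nn, "a", "b")$distance))

  # heterozygote against matching homozygote counts half a mismatch
  het <- HaplotypeMatrix(c(a = paste(rep("R", 1000), collapse = ""),
                           b = paste(rep("A", 1000), collapse = "")),
                         ploidy = 2)
  expect_equal(pairwiseDistance(het, "a", "b")$p, 0.5)
})

test_that("quartet trees reproduce additive matrices and match neighbor joining", {
  set.seed(77)
  for (i in 1:25) {
    d <- randomAdditiveMatrix()
    qt <- quartetTree(d)
    expect_lt(max(abs(qt$patristic - d)), 1e-9)
    nj <- ape::nj(d)
    cm <- ape::cophenetic.phylo(nj)[rownames(d), colnames(d)]
    expect_lt(max(abs(qt$patristic - cm)), 1e-9)
  }
})

test_that("degenerate distance matrices are handled gracefully", {
  labs <- paste0("t", 1:4)
  # star-like: all pairwise distances equal
  d <- matrix(0.4, 4, 4, dimnames = list(labs, labs))
  diag(d) <- 0
  qt <- quartetTree(d)
  expect_equal(unname(qt$patristic[upper.tri(qt$patristic)]),
               rep(0.4, 6), tolerance = 1e-12)
  # all-zero: zero branch lengths, downstream proportion NA
  z <- matrix(0, 4, 4, dimnames = list(labs, labs))
  qz <- quartetTree(z)
  expect_true(all(qz$patristic == 0))
  roles <- stats::setNames(c("I1", "I1", "I2", "O"), labs)
  expect_true(is.na(proportionAB(qz$patristic, roles)$proportion))
})

test_that("the proportion statistic follows its defining arithmetic", {
  labs <- c("h1", "h2", "aus", "out")
  roles <- stats::setNames(c("I1", "I1", "I2", "O"), labs)
  pat <- matrix(0, 4, 4, dimnames = list(labs, labs))
  fill <- function(a, b, v) pat[a, b] <<- pat[b, a] <<- v
  fill("aus", "out", 0.03); fill("h1", "out", 0.01); fill("h2", "out", 0.01)
  pr <- proportionAB(pat, roles)
  expect_equal(pr$proportion, 0.75)
  # equal distances -> 0.5 (species-tree concordance)
  fill("aus", "out", 0.01)
  expect_equal(proportionAB(pat, roles)$proportion, 0.5)
  # zero ingroup-outgroup distance -> 0 (maximal introgression signature)
  fill("aus", "out", 0)
  expect_equal(proportionAB(pat, roles)$proportion, 0)
  # swapping the two I1 tips leaves the proportion unchanged
  perm <- c("h2", "h1", "aus", "out")
  expect_equal(proportionAB(pat[perm, perm], roles)$proportion, 0)
})

test_that("quartet enumeration yields 64 simulated and Table-1-style 32 empirical combinations", {
  pm <- simPopulationMap(8)
  cmb <- enumerateQuartets(pm, "simulated")
  expect_equal(nrow(cmb), 64L)
  expect_equal(length(unique(cmb$comboId)), 64L)
  expect_true(all(cmb$i1a == "I1_1" & cmb$i1b == "I1_2"))

  one <- populationMap(c("h1", "h2", "x", "o"),
                       population = c("H", "H", "S", "S"),
                       role = c("I1", "I1", "I2", "O"),
                       fixedI1 = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(enumerateQuartets(one, "empirical")), 1L)

  # sympatric population sizes 2+4, 2+4 and 4+4 give 8 + 8 + 16 = 32
  emp <- populationMap(
    sample = c(paste0("hw", 1:8),
               paste0("xA14_", 1:2), paste0("aA14_", 1:4),
               paste0("xA15_", 1:2), paste0("aA15_", 1:4),
               paste0("xS14_", 1:4), paste0("aS14_", 1:4)),
    population = c(rep("Hawaii", 8), rep("ACT2014", 6), rep("ACT2015", 6),
                   rep("SA2014", 8)),
    role = c(rep("I1", 8), rep(c("I2", "O"), times = c(2, 4)),
             rep(c("I2", "O"), times = c(2, 4)),
             rep(c("I2", "O"), times = c(4, 4))),
    fixedI1 = c(TRUE, TRUE, rep(FALSE, 26)))
  cmb32 <- enumerateQuartets(emp, "empirical")
  expect_equal(nrow(cmb32), 32L)
  expect_equal(as.vector(table(cmb32$population)[c("ACT2014", "ACT2015",
                                                   "SA2014")]),
               c(8L, 8L, 16L))

  expect_error(enumerateQuartets(populationMap("a", "A", "I2"),
                                 "simulated"), "fixed I1")
})

test_that("the proportion scan skips windows under the 20% genotyped rule", {
  hap <- simulateHaplotypes(tinyModel(L = 4e4, seed = 41))
  popmap <- simPopulationMap(hap)
  windows <- makeWindows(c(sim_1 = 4e4), 2e4)
  calls <- callMatrix(hap)
  # mask 90% of the outgroup tip O_1 in the first window
  chr <- sapply(colnames(calls), function(j) rawToChar(calls[, j]))
  msk <- chr
  sub <- strsplit(msk[["O_1"]], "")[[1]]
  sub[1:18000] <- "N"
  msk[["O_1"]] <- paste(sub, collapse = "")
  hap2 <- HaplotypeMatrix(msk, scaffold = "sim_1")
  res <- windowProportionScan(hap2, popmap, windows)
  touched <- res$start == 1 & res$o == "O_1"
  expect_false(any(touched))
  expect_gt(attr(res, "skipped"), 0)
  # untouched combinations still analysed in both windows
  expect_true(any(res$start == 1))
  expect_true(all(res$proportion >= 0 & res$proportion <= 1, na.rm = TRUE))
})

test_that("tail analysis counts symmetric and constant distributions correctly", {
  mk <- function(p) data.frame(scaffold = "s", start = seq_along(p),
                               end = seq_along(p), comboId = "c1",
                               i2 = "x", o = "o", dA = 1, dB = 1,
                               proportion = p, nSitesUsed = 100L)
  # exactly symmetric about its mean: equal counts at every offset
  p <- 0.5 + c(-0.2, -0.12, -0.07, -0.02, rep(0, 42), 0.02, 0.07, 0.12, 0.2)
  tr <- tailAnalysis(mk(p))
  for (off in c("0.05", "0.10", "0.15"))
    expect_equal(tr@summary[[paste0("nAbove_", off)]],
                 tr@summary[[paste0("nBelow_", off)]])
  expect_equal(nrow(tr@flagged), 1L)
  expect_equal(tr@scaffoldHits$nCombinations, 1L)

  # constant proportions: zero counts everywhere
  tc <- tailAnalysis(mk(rep(0.5, 40)))
  expect_true(all(tc@summary$nAbove_0.05 == 0 & tc@summary$nBelow_0.15 == 0))
  expect_equal(nrow(tc@flagged), 0L)

  expect_error(tailAnalysis(mk(rep(0.5, 10))), "fewer than")
})

test_that("five-pulse admixture still shifts the proportion distribution left", {
  base <- simulateHaplotypes(tinyModel(L = 1e6, seed = 42))
  pm <- simPopulationMap(base)
  cmb <- enumerateQuartets(pm, "simulated")[1:8, ]
  p0 <- windowProportionScan(base, pm, combinations = cmb)
  five <- simulateHaplotypes(
    tinyModel(L = 1e6, seed = 42,
              pulses = pulseSchedule(0.3, "five_event", source = "O",
                                     dest = "I2")))
  p5 <- windowProportionScan(five, pm, combinations = cmb)
  expect_lt(mean(p5$proportion, na.rm = TRUE),
            mean(p0$proportion, na.rm = TRUE))
})
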