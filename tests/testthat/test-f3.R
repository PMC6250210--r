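test_that("per-site f3 follows the Patterson algebra", {
  # large target: correction vanishes
  expect_equal(f3Site(0, 1, 0.5, nC = 1e9), -0.25, tolerance = 1e-6)
  expect_equal(f3Site(0.3, 0.3, 0.3, nC = 1e9), 0, tolerance = 1e-6)
  # x_C = 1 of n_C = 2, a = 0, b = 1:
  # (0.5)(-0.5) - 0.5*0.5*2/(2-1)/2 = -0.5
  expect_equal(f3Site(0, 1, 0.5, nC = 2), -0.5)
  # correction undefined below two target alleles
  expect_true(is.na(f3Site(0, 1, 1, nC = 1)))
})

test_that("genome-wide f3 equals a naive site loop and is source-symmetric", {
  hap <- simulateHaplotypes(tinyModel(L = 1e4, seed = 31))
  popmap <- simPopulationMap(hap)
  r1 <- f3Genome(hap, popmap, "I2", "I1", "O", blockSize = 1000)
  r2 <- f3Genome(hap, popmap, "I2", "O", "I1", blockSize = 1000)
  expect_identical(f3Estimate(r1), f3Estimate(r2))
  expect_identical(r1@se, r2@se)
  oracle <- naiveF3(hap, popmap, "I2", "I1", "O")
  expect_equal(f3Estimate(r1), oracle, tolerance = 1e-12)
  expect_gte(r1@nBlocks, 2L)
  expect_equal(r1@z, f3Estimate(r1) / r1@se)
})

test_that("an admixture-intermediate target drives f3 negative", {
  # build C site-wise as a 50/50 mix of two fixed sources with drift noise
  set.seed(404)
  S <- 4000
  n <- 20
  fa <- rep(0, S); fb <- rep(1, S)
  fc <- 0.5 + stats::rnorm(S, 0, 0.02)
  mkpop <- function(f, prefix) {
    m <- matrix("A", S, n)
    for (s in seq_len(S)) m[s, ] <- sample(c("G", "A"), n, replace = TRUE,
                                           prob = c(f[s], 1 - f[s]))
    colnames(m) <- paste0(prefix, seq_len(n))
    m
  }
  m <- cbind(mkpop(fa, "a"), mkpop(fb, "b"), mkpop(fc, "c"))
  hap <- HaplotypeMatrix(m)
  pm <- populationMap(colnames(m),
                      population = rep(c("A", "B", "C"), each = n),
                      role = rep(c("I1", "O", "I2"), each = n))
  r <- f3Genome(hap, pm, "C", "A", "B", blockSize = 500)
  expect_lt(f3Estimate(r), 0)
  expect_lt(f3Z(r), -3)
})

test_that("jackknife SE scales roughly as one over the square root of blocks", {
  # fixed 50-kb blocks over growing amounts of homogeneous data
  lengths <- c(1e5, 2e5, 4e5, 8e5)
  ses <- vapply(seq_along(lengths), function(i) {
    hap <- simulateHaplotypes(tinyModel(L = lengths[i], seed = 320 + i))
    f3Genome(hap, simPopulationMap(hap), "I2", "I1", "O",
             blockSize = 5e4)@se
  }, 0)
  blocks <- lengths / 5e4
  slope <- stats::coef(stats::lm(log(ses) ~ log(blocks)))[2]
  expect_gt(slope, -0.7)
  expect_lt(slope, -0.3)
})

test_that("degenerate inputs are rejected with informative errors", {
  mono <- toyHaplotypes(
    stats::setNames(rep("AAAA", 6), paste0("s", 1:6)),
    roles = rep(c("I1", "I2", "O"), each = 2))
  expect_error(f3Genome(mono$hap, mono$popmap, "I2", "I1", "O"),
               "no usable sites")
  hap <- simulateHaplotypes(tinyModel(L = 1e3, seed = 33))
  expect_error(f3Genome(hap, simPopulationMap(hap), "I2", "I1", "O",
                        blockSize = 1e6), "blocks")
})

test_that("all three orderings are positive without admixture", {
  hap <- simulateHaplotypes(tinyModel(L = 3e5, seed = 34))
  popmap <- simPopulationMap(hap)
  f3 <- f3AllOrderings(hap, popmap, blockSize = 3e4)
  expect_named(f3, c("f3(I1,I2;O)", "f3(I1,O;I2)", "f3(I2,O;I1)"))
  for (r in f3) expect_gt(f3Estimate(r), 0)
  # exchangeable ingroups: the two ingroup-target orderings agree within
  # a few joint standard errors
  d <- abs(f3Estimate(f3[[2]]) - f3Estimate(f3[[3]]))
  expect_lt(d, 4 * sqrt(f3[[2]]@se^2 + f3[[3]]@se^2))
})

test_that("spreading admixture over five pulses does not ease f3 detection", {
  # at 2 Mb and f in {0.1, 0.3}: the smallest fraction giving a negative
  # majority under five pulses is never smaller than under a single pulse
  thresh <- function(mode) {
    for (f in c(0.1, 0.3)) {
      est <- vapply(1:3, function(r) {
        mod <- tinyModel(L = 2e6, seed = 5200 + 10 * r + round(100 * f),
                         pulses = pulseSchedule(f, mode, source = "O",
                                                dest = "I2"))
        hap <- simulateHaplotypes(mod)
        f3Estimate(f3Genome(hap, simPopulationMap(hap), "I2", "I1", "O"))
      }, 0)
      if (sum(est < 0) >= 2) return(f)
    }
    Inf
  }
  expect_gte(thresh("five_event"), thresh("single"))
})
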