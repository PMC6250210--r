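test_that("simulated haplotypes round-trip exactly through VCF", {
  hap <- simulateHaplotypes(tinyModel(L = 3e3, seed = 51))
  vcf <- tempfile(fileext = ".vcf")
  writeVcfHaplotypes(hap, vcf)
  back <- readVcfHaplotypes(vcf)
  expect_length(back, 1L)
  rt <- back[["sim_1"]]
  expect_equal(sampleNames(rt), sampleNames(hap))
  expect_equal(sitePositions(rt), sitePositions(hap))
  expect_equal(scaffoldLength(rt), scaffoldLength(hap))
  expect_equal(ploidy(rt), 1L)
  expect_identical(callMatrix(rt), callMatrix(hap))
})

test_that("window statistics agree between the VCF path and in-memory data", {
  hap <- simulateHaplotypes(tinyModel(L = 2e4, seed = 52))
  popmap <- simPopulationMap(hap)
  vcf <- tempfile(fileext = ".vcf")
  writeVcfHaplotypes(hap, vcf)
  rt <- readVcfHaplotypes(vcf)[["sim_1"]]
  win <- makeWindows(c(sim_1 = 2e4), 5e3)
  for (fn in list(dxyWindows, fstWindows)) {
    a <- fn(hap, popmap, "I1", "I2", win)
    b <- fn(rt, popmap, "I1", "I2", win)
    expect_identical(S4Vectors::mcols(a)$value, S4Vectors::mcols(b)$value)
  }
})

test_that("depth masking and the 40% missingness rule drop the right sites", {
  samples <- paste0("s", 1:5)
  gt <- function(...) paste(..., sep = "\t")
  rows <- c(
    # site 1: clean, kept
    gt("scaf_1", 1, ".", "A", "C", ".", ".", ".", "GT:DP",
       "0:9", "0:9", "1:9", "1:9", "0:9"),
    # site 2: two genotypes below depth 5 -> 40% missing, still kept
    gt("scaf_1", 5, ".", "G", "T", ".", ".", ".", "GT:DP",
       "0:4", "0:3", "1:9", "1:9", "0:9"),
    # site 3: three genotypes below depth -> 60% missing, dropped
    gt("scaf_1", 9, ".", "A", "G", ".", ".", ".", "GT:DP",
       "0:4", "0:4", "1:2", "1:9", "0:9"),
    # site 4: invariant site, kept
    gt("scaf_1", 12, ".", "T", ".", ".", ".", ".", "GT:DP",
       "0:9", "0:9", "0:9", "0:9", "0:9"),
    # sites 5-7: explicit missing genotypes beyond the threshold, dropped
    gt("scaf_1", 15, ".", "A", "C", ".", ".", ".", "GT:DP",
       ".:0", ".:0", ".:0", "1:9", "0:9"),
    gt("scaf_1", 20, ".", "A", "C", ".", ".", ".", "GT:DP",
       ".:0", ".:0", "0:4", "1:9", "0:9"),
    # site 7: indel allele treated as missing for carriers, dropped (3/5)
    gt("scaf_1", 25, ".", "A", "ATT", ".", ".", ".", "GT:DP",
       "1:9", "1:9", "1:9", "0:9", "0:9"),
    # sites 8-10: clean, kept
    gt("scaf_1", 30, ".", "C", "G", ".", ".", ".", "GT:DP",
       "0:9", "0:9", "0:9", "1:9", "1:9"),
    gt("scaf_1", 35, ".", "C", "T", ".", ".", ".", "GT:DP",
       "0:9", "1:5", "0:9", "1:9", "1:9"),
    gt("scaf_1", 40, ".", "G", "C", ".", ".", ".", "GT:DP",
       "0:9", "0:9", "0:9", "0:9", "1:9"))
  path <- writeToyVcf(tempfile(fileext = ".vcf"), samples, rows)
  hap <- readVcfHaplotypes(path)[["scaf_1"]]
  # 10 sites in, 4 dropped by the filters -> 6 retained
  expect_equal(sitePositions(hap), c(1L, 5L, 12L, 30L, 35L, 40L))
  expect_equal(scaffoldLength(hap), 1000)
  # site 2 keeps its two sub-threshold genotypes as missing
  chr <- rawToChar(callMatrix(hap)[2, ])
  expect_equal(chr, "NNTTG")
})

test_that("diploid genotypes become IUPAC-coded single sequences", {
  rows <- c(paste("scaf_1", 1, ".", "A", "G", ".", ".", ".", "GT:DP",
                  "0/0:9", "0/1:9", "1/1:9", sep = "\t"),
            paste("scaf_1", 2, ".", "C", "T", ".", ".", ".", "GT:DP",
                  "0/1:9", "./.:9", "0/0:9", sep = "\t"))
  path <- writeToyVcf(tempfile(fileext = ".vcf"), paste0("d", 1:3), rows)
  hap <- readVcfHaplotypes(path)[["scaf_1"]]
  expect_equal(ploidy(hap), 2L)
  expect_equal(rawToChar(callMatrix(hap)[1, ]), "ARG")
  expect_equal(rawToChar(callMatrix(hap)[2, ]), "YNC")
  # and they round-trip back out
  out <- tempfile(fileext = ".vcf")
  writeVcfHaplotypes(hap, out)
  rt <- readVcfHaplotypes(out)[["scaf_1"]]
  expect_identical(callMatrix(rt), callMatrix(hap))
})

test_that("a VCF without per-genotype depth is rejected by name", {
  rows <- paste("scaf_1", 1, ".", "A", "G", ".", ".", ".", "GT",
                "0", "1", sep = "\t")
  path <- writeToyVcf(tempfile(fileext = ".vcf"), c("a", "b"), rows)
  expect_error(readVcfHaplotypes(path), "DP")
})

test_that("an unsorted VCF is rejected", {
  rows <- c(paste("scaf_1", 10, ".", "A", "G", ".", ".", ".", "GT:DP",
                  "0:9", "1:9", sep = "\t"),
            paste("scaf_1", 5, ".", "C", "T", ".", ".", ".", "GT:DP",
                  "0:9", "1:9", sep = "\t"))
  path <- writeToyVcf(tempfile(fileext = ".vcf"), c("a", "b"), rows)
  expect_error(readVcfHaplotypes(path), "sorted")
})

test_that("window FASTA export round-trips alignments", {
  hap <- simulateHaplotypes(tinyModel(L = 2e3, seed = 53))
  dir <- tempfile()
  paths <- writeWindowFasta(hap, dir, makeWindows(c(sim_1 = 2e3), 1e3))
  expect_length(paths, 2L)
  back <- readFastaHaplotypes(paths[2], scaffold = "sim_1",
                              startPosition = 1001L)
  expect_equal(sitePositions(back), 1001:2000)
  expect_identical(callMatrix(back),
                   callMatrix(hap)[1001:2000, , drop = FALSE])
})
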