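# Shared fixtures and independent oracle implementations.  The oracles are
# deliberately written as direct transcriptions of the textbook formulas,
# independent of the package's vectorised code paths.

tinyModel <- function(L = 5e4, seed = 1, pulses = emptyPulses(), ...) {
  DemographicModel(chromosomeLength = L, pulses = pulses, seed = seed, ...)
}

# haplotype matrix from explicit per-sample sequences with a role popmap
toyHaplotypes <- function(seqs, roles, ploidy = 1L, ...) {
  hap <- HaplotypeMatrix(seqs, ploidy = ploidy, ...)
  pm <- populationMap(names(seqs), population = roles, role = roles,
                      fixedI1 = seq_along(seqs) %in% which(roles == "I1")[1:2])
  list(hap = hap, popmap = pm)
}

# random sequences with fixed per-population site frequencies is overkill;
# most toys are written explicitly in the tests.

# --- oracle: mean pairwise mismatch fraction between two sample sets -------
allPairsMismatch <- function(hap, samplesA, samplesB, start = 1,
                             end = scaffoldLength(hap)) {
  calls <- callMatrix(hap)
  pos <- sitePositions(hap)
  rows <- which(pos >= start & pos <= end)
  chr <- apply(calls[rows, , drop = FALSE], 2, function(x)
    strsplit(rawToChar(x), "")[[1]])
  vals <- c()
  for (a in samplesA) for (b in samplesB) {
    sa <- chr[, a]; sb <- chr[, b]
    ok <- sa %in% c("A", "C", "G", "T") & sb %in% c("A", "C", "G", "T")
    vals <- c(vals, mean(sa[ok] != sb[ok]))
  }
  mean(vals)
}

# --- oracle: within-population pi by pair enumeration ----------------------
allPairsPi <- function(hap, samples, start = 1, end = scaffoldLength(hap)) {
  # mean over sites of the unbiased pairwise-difference probability equals
  # the mean over all unordered sample pairs of their mismatch fraction
  prs <- utils::combn(samples, 2)
  vals <- vapply(seq_len(ncol(prs)), function(i)
    allPairsMismatch(hap, prs[1, i], prs[2, i], start, end), 0)
  mean(vals)
}

# --- oracle: naive per-site f3 loop ----------------------------------------
naiveF3 <- function(hap, popmap, target, sourceA, sourceB) {
  calls <- callMatrix(hap)
  chr <- apply(calls, 2, function(x) strsplit(rawToChar(x), "")[[1]])
  if (is.null(dim(chr))) chr <- matrix(chr, nrow = nrow(calls))
  colnames(chr) <- colnames(calls)
  grab <- function(p) chr[, popmap$sample[popmap$role == p |
                                          popmap$population == p],
                          drop = FALSE]
  A <- grab(sourceA); B <- grab(sourceB); C <- grab(target)
  vals <- c()
  for (s in seq_len(nrow(chr))) {
    al <- function(m) m[s, m[s, ] %in% c("A", "C", "G", "T")]
    a <- al(A); b <- al(B); cc <- al(C)
    alleles <- sort(unique(c(a, b, cc)))
    if (length(alleles) != 2 || length(cc) < 2 ||
        length(a) < 1 || length(b) < 1) next
    ref <- alleles[1]
    fa <- mean(a == ref); fb <- mean(b == ref); fc <- mean(cc == ref)
    nC <- length(cc)
    vals <- c(vals, (fc - fa) * (fc - fb) - fc * (1 - fc) / (nC - 1))
  }
  mean(vals)
}

# --- oracle: single-site Weir & Cockerham (1984) ---------------------------
# direct transcription for r populations given individual counts n_i,
# allele frequencies p_i and observed heterozygote frequencies h_i
wcSiteOracle <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) * s2 / r -
                                (2 * nbar - 1) * hbar / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# --- oracle: Tajima's D from first principles ------------------------------
tajimaOracle <- function(n, S, piSum) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piSum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# write a small VCF text fixture; `rows` are complete body lines
writeToyVcf <- function(path, samples, rows, contig = "scaf_1",
                        contigLength = 1000) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", contig, contigLength),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

randomAdditiveMatrix <- function() {
  # random quartet tree -> additive distances
  br <- stats::runif(5, 0.01, 1)
  labs <- paste0("t", 1:4)
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d[1, 2] <- d[2, 1] <- br[1] + br[2]
  d[3, 4] <- d[4, 3] <- br[3] + br[4]
  d[1, 3] <- d[3, 1] <- br[1] + br[5] + br[3]
  d[1, 4] <- d[4, 1] <- br[1] + br[5] + br[4]
  d[2, 3] <- d[3, 2] <- br[2] + br[5] + br[3]
  d[2, 4] <- d[4, 2] <- br[2] + br[5] + br[4]
  d
}

# hand-built two-tip genealogy: a single tree with tip-to-tip path length t
twoTipGenealogy <- function(t, L) {
  new("LocalGenealogies", breaks = as.numeric(L),
      parent = matrix(c(3L, 3L, 0L), ncol = 1),
      nodeTime = matrix(c(0, 0, t / 2), ncol = 1),
      tipLabels = c("a", "b"))
}
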