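.IUPAC_PAIR <- c(AA = "A", CC = "C", GG = "G", TT = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
.BASES <- c("A", "C", "G", "T")
# mask -> index of lowest / highest set bit (A=1, C=2, G=4, T=8)
.MASK_LOW <- c(1L, 2L, 1L, 3L, 1L, 2L, 1L, 4L, 1L, 2L, 1L, 3L, 1L, 2L, 1L)
.MASK_HIGH <- c(1L, 2L, 2L, 3L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 4L, 4L, 4L, 4L)
.CHAR_MASK <- stats::setNames(
  c(1L, 2L, 4L, 8L, 5L, 10L, 6L, 9L, 12L, 3L),
  c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M"))

#' Read a multi-sample VCF into filtered haplotype matrices
#'
#' Applies the study's genotype filters while importing: genotypes with
#' per-sample depth below `minDepth` are set missing, and sites where more
#' than `maxMissing` of the samples are missing afterwards are dropped
#' entirely.  Diploid genotypes become single IUPAC-coded calls
#' (heterozygotes as ambiguity codes); invariant sites are retained.
#' Indel alleles are treated as missing.
#'
#' @param path path to a VCF (plain or bgzipped) with a per-genotype `DP`
#'   field; its absence is an error naming the field.
#' @param minDepth minimum per-genotype depth (default 5; genotypes with
#'   `DP < minDepth` are masked).
#' @param maxMissing maximum tolerated fraction of missing samples per
#'   site (default 0.40).
#' @return named list of [HaplotypeMatrix-class], one per scaffold.
#' @export
readVcfHaplotypes <- function(path, minDepth = 5, maxMissing = 0.40) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)
  if (!nrow(fix)) stop("VCF contains no sites")
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)DP(:|$)", fmt)))
    stop("per-genotype depth field 'DP' missing from FORMAT")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                          as.numeric = TRUE))
  gt[is.na(dp) | dp < minDepth] <- NA

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  for (sc in unique(chrom)) {
    p <- pos[chrom == sc]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("VCF not sorted within scaffold ", sc)
  }

  ploidyVal <- if (any(grepl("[/|]", gt[!is.na(gt)]))) 2L else 1L
  a1c <- sub("[/|].*$", "", gt)
  a2c <- ifelse(grepl("[/|]", gt), sub("^.*[/|]", "", gt), a1c)
  a1 <- suppressWarnings(as.integer(a1c))
  a2 <- suppressWarnings(as.integer(a2c))

  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  alleles <- strsplit(ifelse(alt == ".", fix[, "REF"],
                             paste(fix[, "REF"], alt, sep = ",")),
                      ",", fixed = TRUE)
  nal <- lengths(alleles)
  offs <- c(0L, cumsum(nal))[seq_along(nal)]
  flat <- unlist(alleles, use.names = FALSE)
  flat[!flat %in% .BASES] <- NA   # indels / symbolic alleles -> missing

  S <- nrow(gt)
  base1 <- matrix(flat[offs + a1 + 1L], nrow = S)
  base2 <- matrix(flat[offs + a2 + 1L], nrow = S)
  call <- ifelse(is.na(base1) | is.na(base2), "N",
                 .IUPAC_PAIR[paste0(pmin(base1, base2),
                                    pmax(base1, base2))])
  call[is.na(call)] <- "N"
  dim(call) <- dim(gt)

  keep <- rowMeans(call == "N") <= maxMissing
  # filter accounting per scaffold: sites kept + dropped = sites read
  for (sc in unique(chrom)) {
    i <- chrom == sc
    message(sprintf("%s: %d sites read, %d kept, %d dropped (>%d%% missing after depth<%g masking)",
                    sc, sum(i), sum(keep[i]), sum(i) - sum(keep[i]),
                    round(100 * maxMissing), minDepth))
  }
  call <- call[keep, , drop = FALSE]
  chrom <- chrom[keep]
  pos <- pos[keep]

  contigLen <- .contigLengths(vcf@meta)
  out <- lapply(unique(chrom), function(sc) {
    i <- chrom == sc
    m <- matrix(charToRaw(paste(t(call[i, , drop = FALSE]), collapse = "")),
                nrow = ncol(call))
    m <- t(m)
    colnames(m) <- colnames(gt)
    len <- if (sc %in% names(contigLen)) contigLen[[sc]] else max(pos[i])
    new("HaplotypeMatrix", scaffold = sc, scaffoldLength = as.numeric(len),
        positions = pos[i], calls = m, ploidy = ploidyVal,
        provenance = "vcf")
  })
  names(out) <- unique(chrom)
  out
}

.contigLengths <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  id <- sub('.*ID=([^,>"]+).*', "\\1", ln)
  len <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ln)))
  stats::setNames(len, id)[!is.na(len)]
}

#' Write a HaplotypeMatrix as a minimal multi-sample VCF
#'
#' Emits a plain-text VCF 4.2 with a contig header line, 1-based
#' positions, `GT:DP` genotypes (haploid `0`/`1`, diploid `0/1` with
#' IUPAC heterozygotes expanded), all sites including invariant ones.
#' The per-genotype depth written is constant (`depth`) so that the file
#' round-trips through [readVcfHaplotypes()] at the default filters;
#' missing calls get depth 0.  REF is the alphabetically first allele
#' observed at the site.
#'
#' @param hap a [HaplotypeMatrix-class].
#' @param path output path.
#' @param depth constant per-genotype depth to write (default 99).
#' @return invisibly, `path`.
#' @export
writeVcfHaplotypes <- function(hap, path, depth = 99L) {
  calls <- callMatrix(hap)
  S <- nrow(calls); N <- ncol(calls)
  ch <- matrix(strsplit(rawToChar(as.vector(calls)), "")[[1]], nrow = S)
  mask <- matrix(0L, S, N)
  known <- ch %in% names(.CHAR_MASK)
  mask[known] <- .CHAR_MASK[ch[known]]
  if (ploidy(hap) == 1L) mask[matrix(!mask %in% c(1L, 2L, 4L, 8L),
                                     S, N)] <- 0L

  cnt <- .site_counts_cpp(calls, seq_len(N), ploidy(hap))
  pres <- cnt[, 1:4, drop = FALSE] > 0
  noAllele <- rowSums(pres) == 0
  pres[noAllele, 1] <- TRUE  # all-missing sites: REF placeholder "A"
  aidx <- t(apply(pres, 1, cumsum)) - 1L  # base -> 0-based allele index
  ref <- .BASES[max.col(pres, ties.method = "first")]
  altStr <- vapply(seq_len(S), function(s) {
    a <- .BASES[pres[s, ]][-1]
    if (length(a)) paste(a, collapse = ",") else "."
  }, "")

  lowI <- matrix(.MASK_LOW[pmax(mask, 1L)], S, N)
  highI <- matrix(.MASK_HIGH[pmax(mask, 1L)], S, N)
  row <- matrix(seq_len(S), S, N)
  g1 <- matrix(aidx[cbind(as.vector(row), as.vector(lowI))], S, N)
  g2 <- matrix(aidx[cbind(as.vector(row), as.vector(highI))], S, N)
  gtStr <- if (ploidy(hap) == 1L) {
    ifelse(mask == 0L, ".", as.character(g1))
  } else {
    ifelse(mask == 0L, "./.", paste0(g1, "/", g2))
  }
  dim(gtStr) <- c(S, N)
  field <- ifelse(mask == 0L, paste0(gtStr, ":0"),
                  paste0(gtStr, ":", depth))
  dim(field) <- c(S, N)

  body <- paste(hap@scaffold, sitePositions(hap), ".", ref, altStr, ".",
                ".", ".", "GT:DP",
                do.call(paste, c(split(field, col(field)), sep = "\t")),
                sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=admixscan",
              sprintf("##contig=<ID=%s,length=%d>", hap@scaffold,
                      as.integer(scaffoldLength(hap))),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(calls)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write per-window FASTA alignments
#'
#' One FASTA file per window (`<prefix>_<scaffold>_<start>_<end>.fa`),
#' sequences named by sample.
#'
#' @param hap a [HaplotypeMatrix-class].
#' @param dir output directory (created if needed).
#' @param windows GRanges (default: 50-kb tiling).
#' @param prefix file-name prefix.
#' @return invisibly, the vector of file paths.
#' @export
writeWindowFasta <- function(hap, dir, windows = NULL, prefix = "window") {
  windows <- .resolveWindows(hap, windows)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wi <- .windowSiteIndex(hap, windows)
  calls <- callMatrix(hap)
  paths <- character(length(wi$from))
  for (w in seq_along(wi$from)) {
    if (wi$to[w] < wi$from[w]) next
    block <- calls[wi$from[w]:wi$to[w], , drop = FALSE]
    seqs <- apply(block, 2, rawToChar)
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- colnames(calls)
    paths[w] <- file.path(dir, sprintf("%s_%s_%d_%d.fa", prefix,
                                       scaffoldName(hap),
                                       GenomicRanges::start(wi$windows)[w],
                                       GenomicRanges::end(wi$windows)[w]))
    Biostrings::writeXStringSet(ss, paths[w])
  }
  invisible(paths[nzchar(paths)])
}

#' Read an alignment FASTA as a HaplotypeMatrix
#'
#' Reads an aligned FASTA (equal-length sequences, e.g. one written by
#' [writeWindowFasta()]) into a [HaplotypeMatrix-class] with consecutive
#' positions starting at `startPosition`.
#'
#' @param path FASTA path.
#' @param scaffold scaffold identifier for the result.
#' @param startPosition 1-based coordinate of the first column.
#' @param ploidy 1 or 2.
#' @return a [HaplotypeMatrix-class].
#' @export
readFastaHaplotypes <- function(path, scaffold = "scaffold_1",
                                startPosition = 1L, ploidy = 1L) {
  ss <- Biostrings::readDNAStringSet(path)
  wid <- unique(Biostrings::width(ss))
  if (length(wid) != 1) stop("sequences are not aligned (unequal lengths)")
  seqs <- stats::setNames(as.character(ss), names(ss))
  HaplotypeMatrix(seqs, scaffold = scaffold,
                  positions = seq.int(startPosition,
                                      length.out = wid),
                  scaffoldLength = startPosition + wid - 1,
                  ploidy = ploidy, provenance = "vcf")
}
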