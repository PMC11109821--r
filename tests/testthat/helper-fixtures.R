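suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# small GenoMatrix with passing INFO annotations at every site
mkGeno <- function(dosages, chrom = NULL, pos = NULL, ref = "A", alt = "C",
                   qual = 50, qd = 20, sor = 1, fs = 10, mq = 60,
                   mqrs = 0, rprs = 0, dp = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(dp)) dp <- 10 * ncol(dosages)
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(gr)$ref <- ref
  mcols(gr)$alt <- alt
  mcols(gr)$nAlt <- 1L
  mcols(gr)$QUAL <- qual
  mcols(gr)$QD <- qd
  mcols(gr)$SOR <- sor
  mcols(gr)$FS <- fs
  mcols(gr)$MQ <- mq
  mcols(gr)$MQRankSum <- mqrs
  mcols(gr)$ReadPosRankSum <- rprs
  mcols(gr)$DP <- dp
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("s", seq_len(ncol(dosages)))
  GenoMatrix(gr, dosages)
}

# random diploid population sample at given allele frequencies
mkPopGeno <- function(nSites, nSamples, seed = 1, chroms = 3,
                      chromLen = 10e6) {
  set.seed(seed)
  p <- runif(nSites, 0.05, 0.95)
  d <- matrix(rbinom(nSites * nSamples, 2, p), nSites, nSamples)
  chrom <- sort(rep_len(paste0("chr", seq_len(chroms)), nSites))
  pos <- integer(nSites)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos[sel] <- sort(sample.int(chromLen, sum(sel)))
  }
  mkGeno(d, chrom = chrom, pos = pos)
}
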