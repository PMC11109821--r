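#' Sliding-window ROH calling parameters
#'
#' Defaults reproduce the common whole-genome calling setup for runs of
#' homozygosity > 500 kb: 50-SNP scanning windows tolerating at most one
#' heterozygote and five missing calls each, a 5% window-hit threshold for a
#' SNP to be ROH-eligible, segments of at least 30 SNPs and 500 kb at a
#' density of at most 30 kb per SNP, split at gaps over 1000 kb.
#'
#' @param windowSnp scanning window size in SNPs.
#' @param windowHet maximum heterozygous calls tolerated per window.
#' @param windowMissing maximum missing calls tolerated per window.
#' @param windowHitThreshold minimum fraction of passing windows covering a
#'   SNP for it to be ROH-eligible.
#' @param minSnp minimum SNPs per reported segment.
#' @param minKb minimum segment length (kb).
#' @param densityKbPerSnp maximum average spacing (kb per SNP) in a segment.
#' @param maxGapKb split a candidate run at inter-SNP gaps larger than this.
#' @return list of class \code{ROHParams}.
#' @export
rohParams <- function(windowSnp = 50L, windowHet = 1L, windowMissing = 5L,
                      windowHitThreshold = 0.05, minSnp = 30L, minKb = 500,
                      densityKbPerSnp = 30, maxGapKb = 1000) {
  stopifnot(windowSnp > 0, windowHet >= 0, windowMissing >= 0,
            windowHitThreshold > 0, minSnp > 0, minKb > 0,
            densityKbPerSnp > 0, maxGapKb > 0)
  structure(list(windowSnp = as.integer(windowSnp),
                 windowHet = as.integer(windowHet),
                 windowMissing = as.integer(windowMissing),
                 windowHitThreshold = windowHitThreshold,
                 minSnp = as.integer(minSnp), minKb = minKb,
                 densityKbPerSnp = densityKbPerSnp, maxGapKb = maxGapKb),
            class = "ROHParams")
}

# windowed sum of a 0/1 vector: out[w] = sum(x[w..(w+k-1)])
.winSum <- function(x, k) {
  cs <- cumsum(x)
  cs[k:length(x)] - c(0, cs[seq_len(length(x) - k)])
}

.callRohChrom <- function(pos, geno, params) {
  n <- length(pos)
  k <- params$windowSnp
  if (n < k) {
    warning(sprintf("chromosome with %d < %d SNPs: no calls", n, k))
    return(NULL)
  }
  het <- as.numeric(!is.na(geno) & geno == 1L)
  miss <- as.numeric(is.na(geno))
  passes <- .winSum(het, k) <= params$windowHet &
    .winSum(miss, k) <= params$windowMissing
  nW <- length(passes)
  # windows covering SNP i are w in [max(1, i-k+1), min(nW, i)]
  csPass <- c(0, cumsum(passes))
  lo <- pmax(1L, seq_len(n) - k + 1L)
  hi <- pmin(nW, seq_len(n))
  cover <- hi - lo + 1L
  passing <- csPass[hi + 1L] - csPass[lo]
  eligible <- passing / cover >= params$windowHitThreshold
  segs <- NULL
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (runIdx in which(r$values)) {
    idx <- starts[runIdx]:ends[runIdx]
    # split at large physical gaps between consecutive run SNPs
    gaps <- diff(pos[idx])
    brk <- which(gaps > params$maxGapKb * 1000)
    pieceStart <- c(1L, brk + 1L)
    pieceEnd <- c(brk, length(idx))
    for (pc in seq_along(pieceStart)) {
      sub <- idx[pieceStart[pc]:pieceEnd[pc]]
      # trim to outermost homozygous (non-missing, non-het) SNPs
      hom <- which(!is.na(geno[sub]) & geno[sub] != 1L)
      if (!length(hom)) next
      sub <- sub[hom[1]:hom[length(hom)]]
      nSnp <- length(sub)
      len <- pos[sub[nSnp]] - pos[sub[1]] + 1L
      if (nSnp < params$minSnp) next
      if (len < params$minKb * 1000) next
      if (len / nSnp > params$densityKbPerSnp * 1000) next
      segs <- rbind(segs, c(pos[sub[1]], pos[sub[nSnp]], nSnp))
    }
  }
  segs
}

#' Call runs of homozygosity for one sample
#'
#' Slides a window of \code{windowSnp} SNPs along each chromosome; a window
#' passes when it contains at most \code{windowHet} heterozygous and
#' \code{windowMissing} missing calls. Each SNP's hit rate is the fraction of
#' windows covering it that pass; SNPs at or above
#' \code{windowHitThreshold} are ROH-eligible. Maximal eligible runs are
#' split at gaps over \code{maxGapKb}, trimmed to their outermost homozygous
#' SNPs and filtered by \code{minSnp}, \code{minKb} and the density bound.
#'
#' @param gm a diploid \code{GenoMatrix} with sorted sites.
#' @param sample sample id.
#' @param params a \code{\link{rohParams}} list.
#' @return \code{GRanges} of segments (1-based inclusive) with metadata
#'   \code{sample} and \code{nSnps}; empty when nothing is called.
#'   Chromosomes with fewer SNPs than one window yield no calls (warning).
#' @export
callRoh <- function(gm, sample, params = rohParams()) {
  if (ploidy(gm) != "diploid") stop("ROH calling needs diploid genotypes")
  if (!sample %in% sampleIds(gm)) stop("unknown sample: ", sample)
  stopifnot(inherits(params, "ROHParams"))
  gr <- sites(gm)
  geno <- dosages(gm)[, sample]
  out <- GRanges()
  for (chr in unique(as.character(seqnames(gr)))) {
    sel <- as.character(seqnames(gr)) == chr
    segs <- .callRohChrom(start(gr)[sel], geno[sel], params)
    if (!is.null(segs)) {
      g <- GRanges(chr, IRanges(segs[, 1], segs[, 2]))
      mcols(g)$nSnps <- as.integer(segs[, 3])
      out <- c(out, g)
    }
  }
  if (length(out)) mcols(out)$sample <- sample
  out
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Sum of ROH segment lengths divided by the (autosomal) genome size.
#'
#' @param segments \code{GRanges} of one sample's ROH segments (must be
#'   disjoint).
#' @param autosomalGenomeBp denominator, e.g. the summed autosome lengths of
#'   the reference assembly.
#' @return numeric F_ROH in [0, 1].
#' @export
fRoh <- function(segments, autosomalGenomeBp) {
  if (autosomalGenomeBp <= 0) stop("autosomalGenomeBp must be positive")
  if (length(segments) > 1 &&
      sum(width(reduce(segments))) != sum(width(segments)))
    stop("overlapping ROH segments; the caller must produce disjoint runs")
  sum(as.numeric(width(segments))) / autosomalGenomeBp
}

#' Date the inbreeding event behind an ROH length class
#'
#' An ROH of length L Mb coalesces on average g = 100 / (2 r L) generations
#' ago, with r the recombination rate in cM/Mb. Years are obtained with the
#' generation interval.
#'
#' @param lengthMb ROH length (or class midpoint / mean) in Mb.
#' @param rCmPerMb recombination rate, default 1.5 cM/Mb.
#' @param genYears generation time in years, default 3.
#' @return list with \code{generations} (unrounded), \code{generationsInt}
#'   (nearest integer) and \code{years} (unrounded, g x genYears).
#' @export
inbreedingTime <- function(lengthMb, rCmPerMb = 1.5, genYears = 3) {
  if (any(lengthMb <= 0) || rCmPerMb <= 0 || genYears <= 0)
    stop("lengthMb, rCmPerMb and genYears must be positive")
  g <- 100 / (2 * rCmPerMb * lengthMb)
  list(generations = g, generationsInt = round(g), years = g * genYears)
}

#' Summarize ROH segments into size classes
#'
#' Counts per half-open length class [0.5, 1), [1, 2), [2, 3), [3, 5) Mb
#' plus an overflow class >= 5 Mb, with total length, F_ROH left to the
#' caller, and mean segment length.
#'
#' @param segments \code{GRanges} of one sample's (disjoint) ROH segments.
#' @return list with \code{nSegments}, \code{totalLength}, \code{meanLength}
#'   and \code{classCounts} (named integer vector).
#' @export
classifySizes <- function(segments) {
  lens <- as.numeric(width(segments)) / 1e6
  breaks <- c(0.5, 1, 2, 3, 5, Inf)
  labels <- c("0.5-1Mb", "1-2Mb", "2-3Mb", "3-5Mb", ">=5Mb")
  counts <- integer(length(labels))
  names(counts) <- labels
  if (length(lens)) {
    cls <- cut(lens, breaks = breaks, right = FALSE, labels = labels)
    tab <- table(cls)
    counts[names(tab)] <- as.integer(tab)
  }
  list(nSegments = length(lens),
       totalLength = sum(as.numeric(width(segments))),
       meanLength = if (length(lens)) mean(lens) * 1e6 else 0,
       classCounts = counts)
}
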