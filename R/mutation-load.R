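#' Conserved regions from a per-base conservation track
#'
#' Maximal runs of consecutive positions (increments of exactly 1) whose
#' score is strictly greater than the threshold. The per-region score g_i is
#' the mean per-base score of the run.
#'
#' @param track data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{score}, or a width-1 \code{GRanges} with a \code{score} column.
#'   Positions must be unique per chromosome; the track is sorted
#'   internally.
#' @param threshold conservation cutoff (default 4, strict inequality).
#' @return \code{GRanges} of regions with metadata \code{g} (mean score) and
#'   \code{nBases}; empty for an empty track.
#' @export
conservedRegions <- function(track, threshold = 4.0) {
  if (is(track, "GRanges")) {
    track <- data.frame(chrom = as.character(seqnames(track)),
                        pos = start(track), score = mcols(track)$score)
  }
  stopifnot(all(c("chrom", "pos", "score") %in% names(track)))
  if (nrow(track) == 0) return(GRanges())
  track <- track[order(track$chrom, track$pos), , drop = FALSE]
  if (anyDuplicated(paste(track$chrom, track$pos)))
    stop("duplicated positions in conservation track")
  out <- GRanges()
  for (chr in unique(track$chrom)) {
    sub <- track[track$chrom == chr, , drop = FALSE]
    above <- sub$score > threshold
    # break runs at score drops and at physical discontinuities
    newRun <- c(TRUE, diff(sub$pos) != 1L | diff(above) != 0L)
    runId <- cumsum(newRun)
    keep <- which(above)
    if (!length(keep)) next
    for (id in unique(runId[keep])) {
      sel <- which(runId == id)
      g <- GRanges(chr, IRanges(sub$pos[sel[1]], sub$pos[sel[length(sel)]]))
      mcols(g)$g <- mean(sub$score[sel])
      mcols(g)$nBases <- length(sel)
      out <- suppressWarnings(c(out, g))
    }
  }
  out
}

#' Polarize genotypes into derived-allele counts
#'
#' The ancestral allele at each site is the allele carried homozygously by
#' the outgroup genome; sites at which the outgroup is heterozygous or
#' missing are dropped (their count is reported). The derived dosage of a
#' sample is its count of non-ancestral alleles: 0, 1 (heterozygous) or 2
#' (homozygous derived).
#'
#' @param gm a diploid \code{GenoMatrix} containing the outgroup.
#' @param outgroupSample outgroup sample id.
#' @return list with \code{derived} (integer matrix, sites x non-outgroup
#'   samples), \code{sites} (the retained \code{GRanges}) and
#'   \code{nDropped}.
#' @export
polarizeDerived <- function(gm, outgroupSample) {
  if (!outgroupSample %in% sampleIds(gm))
    stop("outgroup sample not present: ", outgroupSample)
  og <- dosages(gm)[, outgroupSample]
  keep <- !is.na(og) & og != 1L
  nDropped <- sum(!keep)
  d <- dosages(gm)[keep, setdiff(sampleIds(gm), outgroupSample),
                   drop = FALSE]
  ancAlt <- og[keep] == 2L          # outgroup homozygous for the alt allele
  derived <- d
  derived[ancAlt, ] <- 2L - d[ancAlt, , drop = FALSE]
  list(derived = derived, sites = sites(gm)[keep], nDropped = nDropped)
}

#' Relative mutation load (RML)
#'
#' RML_x = sum_i n_i g_i / N, a derived-allele-count-weighted mean of the
#' conserved-region scores: n_i is sample x's derived-allele count inside
#' conserved region i (1 per heterozygous, 2 per homozygous-derived site)
#' and N is the total derived-allele count. By default N counts derived
#' alleles inside conserved regions only, which makes RML a weighted mean of
#' the g_i and hence bounded by their range; \code{genomeWideN = TRUE}
#' divides instead by the sample's total derived-allele count everywhere.
#'
#' @param polarized result of \code{\link{polarizeDerived}}.
#' @param regions \code{GRanges} from \code{\link{conservedRegions}}.
#' @param sample sample id (a column of \code{polarized$derived}).
#' @param genomeWideN use all derived alleles as the denominator.
#' @return list with \code{sample}, \code{rml}, \code{N} (denominator) and
#'   \code{kUsed} (regions holding at least one derived allele).
#' @export
rml <- function(polarized, regions, sample, genomeWideN = FALSE) {
  if (!sample %in% colnames(polarized$derived))
    stop("unknown sample: ", sample)
  der <- polarized$derived[, sample]
  der[is.na(der)] <- 0L
  hits <- findOverlaps(polarized$sites, regions)
  nPerRegion <- rep(0, length(regions))
  agg <- rowsum(der[queryHits(hits)], subjectHits(hits))
  nPerRegion[as.integer(rownames(agg))] <- agg[, 1]
  nConserved <- sum(nPerRegion)
  N <- if (genomeWideN) sum(der) else nConserved
  if (N == 0) stop("no derived alleles ",
                   if (genomeWideN) "in the genome" else
                     "inside conserved regions",
                   " for sample ", sample)
  list(sample = sample,
       rml = sum(nPerRegion * mcols(regions)$g) / N,
       N = N, kUsed = sum(nPerRegion > 0))
}

#' Write conserved regions as BED
#'
#' BED interchange is 0-based half-open; internal coordinates are 1-based
#' inclusive, so starts are shifted by one.
#'
#' @param regions \code{GRanges} with a \code{g} column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions),
                   score = mcols(regions)$g)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
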