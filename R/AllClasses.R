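#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width findOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

#' Genotype matrix with site coordinates
#'
#' The central container of the package: a sites-by-samples matrix of
#' alternate-allele dosages (0, 1, 2 or \code{NA} for missing) together with
#' the site coordinates and alleles as a \code{GRanges}. After
#' pseudo-haploidization the dosages take values in \{0, 2, NA\} and the
#' \code{ploidy} slot records the change.
#'
#' Site metadata columns (\code{mcols}) carry the alleles (\code{ref},
#' \code{alt}), the number of ALT alleles in the source record (\code{nAlt};
#' > 1 flags a multiallelic record awaiting removal by
#' \code{\link{applySiteFilters}}) and any INFO annotations
#' (\code{QUAL}, \code{QD}, \code{SOR}, \code{FS}, \code{MQ},
#' \code{MQRankSum}, \code{ReadPosRankSum}, \code{DP}).
#'
#' @slot sites \code{GRanges}, one range of width 1 per site, sorted by
#'   (chromosome, position) with no duplicated positions.
#' @slot dosages integer matrix, \code{length(sites)} rows, one column per
#'   sample (column names are the sample ids).
#' @slot ploidy \code{"diploid"} or \code{"pseudohaploid"}.
#'
#' @seealso \code{\link{readGenoVcf}}, \code{\link{applySiteFilters}},
#'   \code{\link{pseudoHaploidize}}
#' @export
setClass("GenoMatrix",
  representation(sites = "GRanges", dosages = "matrix", ploidy = "character"))

setValidity("GenoMatrix", function(object) {
  msg <- character()
  if (nrow(object@dosages) != length(object@sites))
    msg <- c(msg, "nrow(dosages) must equal length(sites)")
  if (is.null(colnames(object@dosages)))
    msg <- c(msg, "dosages must have sample ids as column names")
  if (anyDuplicated(colnames(object@dosages)))
    msg <- c(msg, "duplicated sample ids")
  if (!object@ploidy %in% c("diploid", "pseudohaploid"))
    msg <- c(msg, "ploidy must be 'diploid' or 'pseudohaploid'")
  v <- object@dosages[!is.na(object@dosages)]
  allowed <- if (identical(object@ploidy, "pseudohaploid")) c(0, 2) else 0:2
  if (length(v) && !all(v %in% allowed))
    msg <- c(msg, sprintf("dosages must be in {%s} or NA",
                          paste(allowed, collapse = ",")))
  if (length(object@sites) > 1) {
    key <- paste(as.character(seqnames(object@sites)), start(object@sites))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (chrom, pos) among sites")
    o <- order(as.integer(seqnames(object@sites)), start(object@sites))
    if (!identical(o, seq_along(object@sites)))
      msg <- c(msg, "sites must be sorted by (chrom, pos)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenoMatrix
#'
#' Sites are sorted by (chromosome, position); the dosage matrix rows are
#' reordered accordingly.
#'
#' @param sites \code{GRanges} of width-1 site positions with at least
#'   \code{ref} and \code{alt} metadata columns.
#' @param dosages numeric/integer matrix of alt-allele dosages
#'   (sites x samples), \code{NA} for missing calls; column names are sample
#'   ids.
#' @param ploidy \code{"diploid"} (default) or \code{"pseudohaploid"}.
#' @return A \code{\linkS4class{GenoMatrix}}.
#' @export
GenoMatrix <- function(sites, dosages, ploidy = "diploid") {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  o <- order(as.integer(seqnames(sites)), start(sites))
  new("GenoMatrix", sites = sites[o],
      dosages = dosages[o, , drop = FALSE], ploidy = ploidy)
}

#' Result of an f3 or f4 statistic
#'
#' Holds the point estimate, its weighted block-jackknife standard error and
#' the derived Z score, together with the block and site counts that entered
#' the computation.
#'
#' @slot kind \code{"f3"} or \code{"f4"}.
#' @slot pops population arguments in order (target first for f3).
#' @slot estimate,se,z numeric scalars; \code{se}/\code{z} are \code{NA} when
#'   fewer than two blocks were available.
#' @slot nBlocks,nSites integer counts of jackknife blocks and used sites.
#' @export
setClass("FStatResult",
  representation(kind = "character", pops = "character", estimate = "numeric",
                 se = "numeric", z = "numeric", nBlocks = "integer",
                 nSites = "integer"))

setValidity("FStatResult", function(object) {
  msg <- character()
  if (!object@kind %in% c("f3", "f4")) msg <- c(msg, "kind must be f3 or f4")
  if (object@kind == "f3" && length(object@pops) != 3L)
    msg <- c(msg, "f3 takes 3 populations")
  if (object@kind == "f4" && length(object@pops) != 4L)
    msg <- c(msg, "f4 takes 4 populations")
  if (!is.na(object@se) && object@se < 0) msg <- c(msg, "se must be >= 0")
  if (object@nSites <= 0L) msg <- c(msg, "nSites must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-population allele frequency table
#'
#' Alternate-allele frequencies and observed allele counts per population and
#' site. Frequencies are \code{NA} where a population has allele count zero;
#' downstream statistics use complete cases over their own arguments.
#'
#' @slot freq,count numeric matrices (sites x populations); \code{count} is
#'   the number of observed alleles (2 per non-missing diploid genotype, 1 per
#'   pseudo-haploid call).
#' @slot sites the site \code{GRanges} carried over from the genotype matrix.
#' @export
setClass("AlleleFreqTable",
  representation(freq = "matrix", count = "matrix", sites = "GRanges"))

setValidity("AlleleFreqTable", function(object) {
  msg <- character()
  if (!identical(dim(object@freq), dim(object@count)))
    msg <- c(msg, "freq and count must have identical dimensions")
  if (nrow(object@freq) != length(object@sites))
    msg <- c(msg, "row count must match number of sites")
  if (is.null(colnames(object@freq)))
    msg <- c(msg, "populations must be named in column names")
  f <- object@freq[!is.na(object@freq)]
  if (length(f) && (min(f) < 0 || max(f) > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
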