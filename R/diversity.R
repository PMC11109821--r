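#' Per-individual heterozygosity
#'
#' Fraction of callable sites at which the individual's called genotype is
#' heterozygous: count(dosage == 1) / callableSites. With accurate genotype
#' calls this estimates per-site heterozygosity (pi) directly.
#'
#' @param gm a diploid \code{GenoMatrix}.
#' @param sample sample id.
#' @param callableSites denominator: the number of sites at which a genotype
#'   call was possible for this sample (not just the segregating sites held
#'   in \code{gm}).
#' @return list with \code{scope}, \code{sample}, \code{value} and
#'   \code{nSites}.
#' @export
individualHeterozygosity <- function(gm, sample, callableSites) {
  if (callableSites <= 0) stop("callableSites must be positive")
  if (!sample %in% sampleIds(gm)) stop("unknown sample: ", sample)
  d <- dosages(gm)[, sample]
  nHet <- sum(!is.na(d) & d == 1L)
  list(scope = "sample", sample = sample, value = nHet / callableSites,
       nSites = callableSites)
}

#' Within-population diversity from pairwise 1 - outgroup-f3
#'
#' Mean over unordered member pairs of 1 - f3(outgroup; ind_i, ind_j), each
#' individual treated as its own population. Larger values indicate more
#' interindividual differentiation, i.e. higher within-population diversity.
#'
#' @param af an \code{AlleleFreqTable} in which every member individual is a
#'   population of its own.
#' @param members character vector of >= 2 member labels.
#' @param outgroup outgroup population label.
#' @param blocks block ids from \code{\link{makeBlocks}}.
#' @return list with \code{value} (mean pairwise 1 - f3), \code{nPairs} and
#'   the per-pair values. Undefined pairs are skipped with a warning; all
#'   pairs undefined is an error.
#' @export
pairwiseF3Diversity <- function(af, members, outgroup, blocks) {
  if (length(members) < 2) stop("need at least 2 members")
  pairs <- utils::combn(members, 2)
  vals <- numeric(0)
  nms <- character(0)
  for (k in seq_len(ncol(pairs))) {
    v <- tryCatch(
      1 - f3stat(af, outgroup, pairs[1, k], pairs[2, k], blocks)@estimate,
      error = function(e) {
        warning("skipping undefined pair (", pairs[1, k], ", ", pairs[2, k],
                "): ", conditionMessage(e))
        NA_real_
      })
    if (!is.na(v)) {
      vals <- c(vals, v)
      nms <- c(nms, paste(pairs[, k], collapse = ":"))
    }
  }
  if (!length(vals)) stop("no defined pairs")
  names(vals) <- nms
  list(scope = "population", value = mean(vals), nPairs = length(vals),
       pairs = vals)
}

#' Mitochondrial nucleotide diversity (pi)
#'
#' pi = [ sum_{i<j} pi_ij / (n(n-1)/2) ] / L, where pi_ij is the number of
#' nucleotide differences between sequences i and j at the included sites
#' and L is the number of included sites. A site is included iff it is
#' non-missing (not N or gap) in at least two individuals and carries at
#' most two distinct bases among the non-missing calls; inclusion is decided
#' once across the whole alignment. Sites at which either member of a pair
#' is missing contribute 0 to that pair's pi_ij under the default single-L
#' normalization.
#'
#' @param aln a \code{Biostrings::DNAStringSet} (or plain character vector)
#'   of equal-length aligned sequences over A/C/G/T/N/-.
#' @param perPairL alternative normalization: divide each pi_ij by that
#'   pair's own count of jointly non-missing included sites, then average.
#' @return list with \code{value} (pi), \code{nSites} (L) and \code{nPairs}.
#' @export
mtdnaPi <- function(aln, perPairL = FALSE) {
  if (is(aln, "DNAStringSet")) {
    mat <- as.matrix(aln)
  } else {
    seqs <- toupper(as.character(aln))
    if (length(unique(nchar(seqs))) != 1)
      stop("sequences must have equal length")
    mat <- do.call(rbind, strsplit(seqs, ""))
  }
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 sequences")
  ok <- mat %in% c("A", "C", "G", "T")
  dim(ok) <- dim(mat)
  nNonMissing <- colSums(ok)
  nAlleles <- apply(mat, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")]))
  })
  included <- nNonMissing >= 2 & nAlleles <= 2 & nAlleles >= 1
  L <- sum(included)
  if (L == 0) stop("no included sites")
  sub <- mat[, included, drop = FALSE]
  subOk <- ok[, included, drop = FALSE]
  total <- 0
  nPairs <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- subOk[i, ] & subOk[j, ]
    diffs <- sum(both & sub[i, ] != sub[j, ])
    total <- total + if (perPairL) {
      if (sum(both) > 0) diffs / sum(both) else 0
    } else diffs
    nPairs <- nPairs + 1L
  }
  val <- if (perPairL) total / nPairs else (total / nPairs) / L
  list(scope = "population", compartment = "mtDNA", value = val,
       nSites = L, nPairs = nPairs)
}

#' Autosome / chrX diversity ratio and its neutral expectation
#'
#' There are three X chromosomes for every four autosomes in a population
#' with equal numbers of breeding males and females, so under equal
#' sex-specific effective sizes the autosomal/chrX diversity ratio is
#' expected to be 4/3 (printed as 1.33). Smaller observed ratios indicate a
#' relatively reduced male effective size.
#'
#' @param divAut,divX autosomal and chrX diversity values (same estimator).
#' @return list with \code{ratio}, \code{expectation} (4/3) and
#'   \code{expectationPrinted} (1.33).
#' @export
autosomeXRatio <- function(divAut, divX) {
  if (divX <= 0) stop("divX must be > 0")
  list(ratio = divAut / divX, expectation = 4 / 3,
       expectationPrinted = round(4 / 3, 2))
}
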