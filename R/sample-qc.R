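#' X/autosome coverage ratio (Rx)
#'
#' For each autosome i, r_i = depth(chrX) / depth(autosome i), with depth =
#' aligned bases / chromosome length. Rx is the mean of the r_i and its
#' standard error is sd(r_i)/sqrt(n autosomes), so the uncertainty reflects
#' variance among autosomes. Rx is expected near 1 for XX and near 0.5 for
#' XY individuals.
#'
#' @param profile data.frame with columns \code{chrom}, \code{length},
#'   \code{alignedBases} for one sample (>= 2 autosomes plus the X).
#' @param chrX chromosome id of the X (default \code{"chrX"}).
#' @param sample optional sample id carried through to the result.
#' @return list with \code{sample}, \code{rx}, \code{se},
#'   \code{nAutosomes} and \code{assignment = "unassigned"} (see
#'   \code{\link{assignSex}}). Zero-depth autosomes are dropped with a
#'   warning; all dropped is an error.
#' @export
computeRx <- function(profile, chrX = "chrX", sample = NA_character_) {
  stopifnot(all(c("chrom", "length", "alignedBases") %in% names(profile)))
  if (!chrX %in% profile$chrom) stop("chrX chromosome absent: ", chrX)
  if (any(profile$length <= 0)) stop("chromosome lengths must be positive")
  depth <- profile$alignedBases / profile$length
  names(depth) <- profile$chrom
  dx <- depth[chrX]
  dAuto <- depth[setdiff(profile$chrom, chrX)]
  if (length(dAuto) < 2) stop("need at least 2 autosomes")
  zero <- dAuto == 0
  if (any(zero)) {
    warning("dropping zero-depth autosome(s): ",
            paste(names(dAuto)[zero], collapse = ", "))
    dAuto <- dAuto[!zero]
  }
  if (!length(dAuto)) stop("all autosomes have zero depth")
  r <- dx / dAuto
  list(sample = sample, rx = mean(r),
       se = stats::sd(r) / sqrt(length(r)),
       nAutosomes = length(r), assignment = "unassigned")
}

#' Assign genetic sex from Rx
#'
#' XX when rx - 1.96 se > xxThreshold; XY when rx + 1.96 se < xyThreshold;
#' otherwise unassigned. The default thresholds 0.65 and 0.5 suit
#' assemblies in which X-homologous sequence inflates apparent chrX coverage
#' so that the XX/XY cluster means sit near 0.74 and 0.42 rather than the
#' idealized 1 and 0.5.
#'
#' @param rxResult result of \code{\link{computeRx}}.
#' @param xxThreshold,xyThreshold assignment thresholds.
#' @return \code{rxResult} with \code{assignment} set to \code{"XX"},
#'   \code{"XY"} or \code{"unassigned"}.
#' @export
assignSex <- function(rxResult, xxThreshold = 0.65, xyThreshold = 0.5) {
  rx <- rxResult$rx
  se <- rxResult$se
  rxResult$assignment <-
    if (rx - 1.96 * se > xxThreshold) "XX"
    else if (rx + 1.96 * se < xyThreshold) "XY"
    else "unassigned"
  rxResult
}

#' Advisory k-means clustering of Rx values
#'
#' Lloyd's algorithm seeded by deterministic farthest-point initialization
#' (first center drawn under the seed, each further center the value most
#' distant from the chosen ones). Cluster means are reported sorted, with
#' suggested cutoffs at the midpoints between adjacent means, for operator
#' review: sex assignment itself always uses the configured thresholds of
#' \code{\link{assignSex}}.
#'
#' @param rxValues numeric vector (>= 2k values).
#' @param k number of clusters (default 2).
#' @param seed integer seed.
#' @return list with sorted \code{means}, \code{suggestedCutoffs} and
#'   cluster \code{sizes}.
#' @export
kmeansThresholds <- function(rxValues, k = 2, seed = 1L) {
  if (length(rxValues) < 2 * k) stop("need at least 2k values")
  if (length(unique(rxValues)) < k)
    stop("degenerate input: fewer than k distinct values")
  set.seed(seed)
  centers <- rxValues[sample.int(length(rxValues), 1)]
  while (length(centers) < k) {
    dmin <- vapply(rxValues, function(v) min(abs(v - centers)), numeric(1))
    centers <- c(centers, rxValues[which.max(dmin)])
  }
  km <- stats::kmeans(rxValues, centers = matrix(centers, ncol = 1),
                      algorithm = "Lloyd", iter.max = 100)
  o <- order(km$centers)
  means <- as.numeric(km$centers)[o]
  list(means = means,
       suggestedCutoffs = (means[-1] + means[-length(means)]) / 2,
       sizes = km$size[o])
}

#' Pairwise pseudo-haploid mismatch rate (P0)
#'
#' P0 in a window is the fraction of jointly non-missing sites at which the
#' two pseudo-haploid genotypes disagree; the genome-wide P0 is the
#' unweighted mean over windows containing at least one usable site.
#'
#' @param phGm a pseudo-haploid \code{GenoMatrix}
#'   (\code{\link{pseudoHaploidize}}).
#' @param pair character vector of two sample ids.
#' @param windowBp window size in bp (default 1 Mb).
#' @return list with \code{pair}, \code{p0} (genome-wide), \code{perWindow}
#'   (data.frame chrom/window/p0/nSites) and \code{nWindows}.
#' @export
pairwiseMismatch <- function(phGm, pair, windowBp = 1e6) {
  if (ploidy(phGm) != "pseudohaploid")
    stop("input must be pseudo-haploid")
  stopifnot(length(pair) == 2)
  d <- dosages(phGm)[, pair, drop = FALSE]
  both <- !is.na(d[, 1]) & !is.na(d[, 2])
  gr <- sites(phGm)
  winNo <- floor((start(gr) - 1) / windowBp)
  win <- (as.integer(seqnames(gr)) - 1) * (max(winNo) + 1) + winNo
  mm <- as.numeric(both & d[, 1] != d[, 2])
  nUse <- rowsum(as.numeric(both), win, reorder = FALSE)[, 1]
  nMm <- rowsum(mm, win, reorder = FALSE)[, 1]
  usable <- nUse > 0
  if (!any(usable)) stop("zero usable windows for pair ",
                         paste(pair, collapse = ", "))
  p0w <- nMm[usable] / nUse[usable]
  lvl <- levels(seqnames(gr))
  ids <- as.numeric(names(nUse)[usable])
  lab <- paste(lvl[ids %/% (max(winNo) + 1) + 1],
               ids %% (max(winNo) + 1), sep = ":")
  list(pair = pair, p0 = mean(p0w),
       perWindow = data.frame(window = lab, p0 = p0w,
                              nSites = nUse[usable], row.names = NULL),
       nWindows = sum(usable))
}

#' Kinship classification configuration
#'
#' The expected kinship coefficient (theta) ladder for identical, first-,
#' second- and third-degree relatives and unrelated pairs; classification
#' thresholds are the midpoints (theta1 + theta2)/2 of adjacent rungs.
#'
#' @param windowBp P0 window size (default 1 Mb).
#' @param expectedTheta named, strictly decreasing ladder.
#' @return list of class \code{KinshipConfig} with derived \code{thresholds}.
#' @export
kinshipConfig <- function(windowBp = 1e6,
                          expectedTheta = c(identical = 0.5, `1st` = 0.25,
                                            `2nd` = 0.125, `3rd` = 0.0625,
                                            unrelated = 0)) {
  stopifnot(all(diff(expectedTheta) < 0))
  thr <- (expectedTheta[-length(expectedTheta)] + expectedTheta[-1]) / 2
  names(thr) <- names(expectedTheta)[-length(expectedTheta)]
  structure(list(windowBp = windowBp, expectedTheta = expectedTheta,
                 thresholds = thr),
            class = "KinshipConfig")
}

#' Classify pairwise kinship from P0 within a population
#'
#' P0 values are normalized by the population median (so an average
#' unrelated pair sits at normalized P0 = 1), theta = 1 - normalized P0, and
#' each pair is assigned the closest degree class by comparing theta to the
#' midpoint thresholds of \code{\link{kinshipConfig}}.
#'
#' @param p0Results list of \code{\link{pairwiseMismatch}} results for all
#'   pairs of one population (>= 3 pairs recommended for a meaningful
#'   median).
#' @param cfg a \code{\link{kinshipConfig}}.
#' @return data.frame with sample1, sample2, p0, normalizedP0, theta,
#'   degree (factor identical/1st/2nd/3rd/unrelated) and nWindows.
#' @export
classifyKinship <- function(p0Results, cfg = kinshipConfig()) {
  stopifnot(inherits(cfg, "KinshipConfig"))
  p0 <- vapply(p0Results, function(r) r$p0, numeric(1))
  med <- stats::median(p0)
  if (med == 0) stop("population median P0 is zero (population of clones?)")
  norm <- p0 / med
  theta <- 1 - norm
  thr <- cfg$thresholds
  lvls <- names(cfg$expectedTheta)
  degree <- vapply(theta, function(t) {
    i <- which(t >= thr)
    if (length(i)) lvls[min(i)] else lvls[length(lvls)]
  }, character(1))
  data.frame(
    sample1 = vapply(p0Results, function(r) r$pair[1], character(1)),
    sample2 = vapply(p0Results, function(r) r$pair[2], character(1)),
    p0 = p0, normalizedP0 = norm, theta = theta,
    degree = factor(degree, levels = lvls),
    nWindows = vapply(p0Results, function(r) r$nWindows, numeric(1)),
    row.names = NULL)
}

#' Greedy pruning of related samples
#'
#' Repeatedly removes the sample participating in the most relationships at
#' or closer than \code{maxDegree}, until no such relationship remains. Ties
#' are broken by lower nominal coverage first, then lexicographically by id.
#'
#' @param kinship data.frame from \code{\link{classifyKinship}}.
#' @param maxDegree most distant degree still treated as "related" for
#'   pruning (default \code{"2nd"}: identical, 1st and 2nd degree pairs are
#'   broken up).
#' @param coverage optional named numeric vector of per-sample coverages
#'   used for tie-breaking.
#' @return character vector of sample ids to exclude (possibly empty).
#' @export
pruneRelatives <- function(kinship, maxDegree = "2nd", coverage = NULL) {
  lvls <- levels(kinship$degree)
  related <- kinship[as.integer(kinship$degree) <=
                       match(maxDegree, lvls), , drop = FALSE]
  excluded <- character(0)
  while (nrow(related) > 0) {
    ids <- c(related$sample1, related$sample2)
    cnt <- table(ids)
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) > 1 && !is.null(coverage)) {
      cv <- coverage[top]
      cv[is.na(cv)] <- Inf
      top <- top[cv == min(cv)]
    }
    drop <- sort(top)[1]
    excluded <- c(excluded, drop)
    related <- related[related$sample1 != drop & related$sample2 != drop, ,
                       drop = FALSE]
  }
  excluded
}
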