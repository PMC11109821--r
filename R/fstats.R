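#' Per-population allele frequencies
#'
#' @param gm a \code{GenoMatrix} (diploid or pseudo-haploid).
#' @param grouping named character vector mapping sample id to population
#'   label; a single individual may form its own population. Samples absent
#'   from \code{grouping} are ignored.
#' @return An \code{\linkS4class{AlleleFreqTable}}. Allele counts are 2 per
#'   non-missing diploid genotype and 1 per pseudo-haploid call; frequencies
#'   are \code{NA} where the count is zero.
#' @export
alleleFrequencies <- function(gm, grouping) {
  stopifnot(!is.null(names(grouping)))
  bad <- setdiff(names(grouping), sampleIds(gm))
  if (length(bad)) stop("grouping names not in matrix: ",
                        paste(bad, collapse = ", "))
  pops <- unique(unname(grouping))
  d <- dosages(gm)
  perCall <- if (ploidy(gm) == "pseudohaploid") 1L else 2L
  freq <- count <- matrix(NA_real_, nSites(gm), length(pops),
                          dimnames = list(NULL, pops))
  for (p in pops) {
    cols <- names(grouping)[grouping == p]
    if (!length(cols)) stop("empty population: ", p)
    dp <- d[, cols, drop = FALSE]
    nm <- rowSums(!is.na(dp))
    cnt <- perCall * nm
    alt <- rowSums(dp, na.rm = TRUE) * (perCall / 2)
    count[, p] <- cnt
    freq[, p] <- ifelse(cnt > 0, alt / cnt, NA_real_)
  }
  new("AlleleFreqTable", freq = freq, count = count, sites = sites(gm))
}

#' Assign sites to jackknife blocks
#'
#' @param sites site \code{GRanges} (or an \code{AlleleFreqTable}).
#' @param mode \code{"span"}: blocks of fixed physical span per chromosome
#'   (default 5 Mb, the usual linkage-robust choice); \code{"count"}: blocks
#'   of a fixed number of consecutive SNPs, the final partial block kept.
#' @param size span in bp (mode "span") or SNPs per block (mode "count").
#' @return integer vector of block ids (1..nBlocks), one per site; empty
#'   blocks do not occur.
#' @export
makeBlocks <- function(sites, mode = c("span", "count"), size = 5e6) {
  if (is(sites, "AlleleFreqTable")) sites <- sites@sites
  mode <- match.arg(mode)
  if (mode == "count") {
    if (size > length(sites)) stop("block size exceeds number of sites")
    raw <- ceiling(seq_along(sites) / size)
  } else {
    key <- paste(as.character(seqnames(sites)),
                 floor((start(sites) - 1) / size))
    raw <- match(key, unique(key))
  }
  as.integer(raw)
}

# Weighted delete-one-block jackknife (Busing et al. 1999) on per-site terms.
# Returns the plain mean estimate and the jackknife SE; blocks are weighted
# by their site counts (the final chunk may be smaller).
.blockJackknife <- function(terms, blocks) {
  n <- length(terms)
  est <- mean(terms)
  tab <- rowsum(cbind(terms, 1), blocks)
  S <- sum(terms)
  m <- tab[, 2]
  G <- nrow(tab)
  if (G < 2) return(list(estimate = est, se = NA_real_, nBlocks = G))
  thetaMinus <- (S - tab[, 1]) / (n - m)
  h <- n / m
  thetaDot <- G * est - sum((1 - m / n) * thetaMinus)
  tau <- h * est - (h - 1) * thetaMinus
  var <- sum((tau - thetaDot)^2 / (h - 1)) / G
  list(estimate = est, se = sqrt(var), nBlocks = G)
}

.fstatFromTerms <- function(kind, pops, terms, blocks, used) {
  t <- terms[used]
  if (!length(t)) stop("zero usable sites for ",
                       kind, "(", paste(pops, collapse = ", "), ")")
  jk <- .blockJackknife(t, blocks[used])
  z <- if (!is.na(jk$se) && jk$se > 0) jk$estimate / jk$se else NA_real_
  new("FStatResult", kind = kind, pops = pops, estimate = jk$estimate,
      se = jk$se, z = z, nBlocks = as.integer(jk$nBlocks),
      nSites = length(t))
}

#' Outgroup-f3 statistic
#'
#' f3(O; A, B) = mean over usable sites of (o - a)(o - b), where o, a, b are
#' the alt-allele frequencies of the target (outgroup) and the two test
#' populations. Large values indicate much shared drift of A and B relative
#' to O. A site is usable iff all three populations have allele count > 0.
#' The standard error comes from a weighted delete-one-block jackknife.
#'
#' @param af an \code{AlleleFreqTable}.
#' @param target,a,b population labels (target is the outgroup for
#'   outgroup-f3).
#' @param blocks integer block ids from \code{\link{makeBlocks}}.
#' @param corrected subtract the target's per-site sampling-noise term
#'   h_O/n_O (unbiased target heterozygosity over target allele count).
#'   Requires target allele count >= 2 at every used site.
#' @return An \code{\linkS4class{FStatResult}}; \code{se} is \code{NA} with
#'   fewer than two blocks.
#' @export
f3stat <- function(af, target, a, b, blocks, corrected = FALSE) {
  p <- af@freq
  cnt <- af@count
  for (x in c(target, a, b)) if (!x %in% colnames(p))
    stop("unknown population: ", x)
  used <- cnt[, target] > 0 & cnt[, a] > 0 & cnt[, b] > 0
  terms <- (p[, target] - p[, a]) * (p[, target] - p[, b])
  if (corrected) {
    nO <- cnt[, target]
    if (any(used & nO < 2))
      stop("corrected f3 requires target allele count >= 2 at every used ",
           "site (pseudo-haploid target not allowed)")
    hO <- 2 * p[, target] * (1 - p[, target]) * nO / (nO - 1)
    terms <- terms - hO / nO
  }
  .fstatFromTerms("f3", c(target, a, b), terms, blocks, used)
}

#' f4 statistic
#'
#' f4(A, B; C, D) = mean over usable sites of (a - b)(c - d); zero in
#' expectation when (A, B) and (C, D) lie on opposite sides of a tree edge
#' with no gene flow across it. SE and Z as in \code{\link{f3stat}}.
#'
#' @inheritParams f3stat
#' @param a,b,c,d population labels.
#' @return An \code{\linkS4class{FStatResult}}.
#' @export
f4stat <- function(af, a, b, c, d, blocks) {
  p <- af@freq
  cnt <- af@count
  for (x in c(a, b, c, d)) if (!x %in% colnames(p))
    stop("unknown population: ", x)
  used <- cnt[, a] > 0 & cnt[, b] > 0 & cnt[, c] > 0 & cnt[, d] > 0
  terms <- (p[, a] - p[, b]) * (p[, c] - p[, d])
  .fstatFromTerms("f4", c(a, b, c, d), terms, blocks, used)
}

#' 1 - outgroup-f3 distance matrix
#'
#' D[p, q] = 1 - f3(outgroup; p, q) for p != q, zero diagonal; symmetric by
#' construction (f3 is symmetric in its last two arguments).
#'
#' @param af an \code{AlleleFreqTable}.
#' @param populationsUsed labels to include (default: all populations except
#'   the outgroup).
#' @param outgroup outgroup population label (the f3 target).
#' @param blocks block ids from \code{\link{makeBlocks}}.
#' @param corrected passed to \code{\link{f3stat}} (default off: the
#'   distances are used comparatively).
#' @return square numeric matrix with dimnames.
#' @export
distanceMatrix <- function(af, populationsUsed = NULL, outgroup, blocks,
                           corrected = FALSE) {
  pops <- populationsUsed
  if (is.null(pops)) pops <- setdiff(populations(af), outgroup)
  if (length(pops) < 3) stop("need at least 3 populations")
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    f <- tryCatch(
      f3stat(af, outgroup, pops[i], pops[j], blocks, corrected = corrected),
      error = function(e) stop("f3 undefined for pair (", pops[i], ", ",
                               pops[j], "): ", conditionMessage(e)))
    D[i, j] <- D[j, i] <- 1 - f@estimate
  }
  D
}

#' Chunked-bootstrap replicates of the 1 - outgroup-f3 distance matrix
#'
#' Divides the retained sites into consecutive chunks of \code{chunkSize}
#' SNPs (the final partial chunk kept as its own chunk), resamples chunks
#' with replacement and recomputes every pairwise 1 - f3 on the resampled
#' concatenation. Deterministic under a fixed seed.
#'
#' @param gm a \code{GenoMatrix}.
#' @param grouping named sample-to-population map (see
#'   \code{\link{alleleFrequencies}}).
#' @param outgroup outgroup population label.
#' @param chunkSize SNPs per chunk (default 30000).
#' @param reps number of replicates (default 500).
#' @param seed integer seed.
#' @param resample set \code{FALSE} to take every chunk exactly once in
#'   order (identity draw; then \code{reps} copies of the point-estimate
#'   matrix are returned).
#' @return list of \code{reps} distance matrices.
#' @export
bootstrapDistanceMatrices <- function(gm, grouping, outgroup,
                                      chunkSize = 30000L, reps = 500L,
                                      seed = 1L, resample = TRUE) {
  if (chunkSize > nSites(gm)) stop("chunkSize exceeds total sites")
  af <- alleleFrequencies(gm, grouping)
  pops <- setdiff(populations(af), outgroup)
  chunk <- as.integer(ceiling(seq_len(nSites(gm)) / chunkSize))
  nChunk <- max(chunk)
  if (nChunk < 2) stop("need at least 2 chunks")
  p <- af@freq
  cnt <- af@count
  pairs <- utils::combn(pops, 2)
  # per-chunk sums of f3 terms and usable-site counts, per pair
  sumT <- cntT <- matrix(0, nChunk, ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    used <- cnt[, outgroup] > 0 & cnt[, a] > 0 & cnt[, b] > 0
    terms <- (p[, outgroup] - p[, a]) * (p[, outgroup] - p[, b])
    terms[!used] <- 0
    sumT[, k] <- rowsum(terms, chunk)
    cntT[, k] <- rowsum(as.numeric(used), chunk)
  }
  set.seed(seed)
  lapply(seq_len(reps), function(r) {
    idx <- if (resample) sample.int(nChunk, nChunk, replace = TRUE)
           else seq_len(nChunk)
    est <- colSums(sumT[idx, , drop = FALSE]) /
      colSums(cntT[idx, , drop = FALSE])
    D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (k in seq_len(ncol(pairs)))
      D[pairs[1, k], pairs[2, k]] <- D[pairs[2, k], pairs[1, k]] <-
        1 - est[k]
    D
  })
}

#' Write f-statistic results as TSV
#'
#' @param results list of \code{FStatResult} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFStatTsv <- function(results, path) {
  rows <- lapply(results, function(r) {
    data.frame(kind = r@kind, pops = paste(r@pops, collapse = ","),
               estimate = r@estimate, se = r@se, z = r@z,
               n_blocks = r@nBlocks, n_sites = r@nSites)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
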