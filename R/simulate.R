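#' Default drift tree for the synthetic generator
#'
#' Ten ingroup populations plus one distant outgroup on a fixed topology
#' echoing the wild/domestic sheep clades: a North-American/Siberian clade
#' (BGH, (THN, SNW)), an ARG branch, and a nested mouflon/domestic series
#' (URI, (ASM, (ANM, (CYM, (EUM, DOM))))). Edge lengths are Balding-Nichols
#' drift parameters F in [0, 1); the outgroup branch carries heavy drift
#' (F = 0.5) so that it is strongly diverged from every ingroup population.
#'
#' @return data.frame with columns \code{node}, \code{parent}, \code{F}
#'   (NA for the root).
#' @export
defaultSimTree <- function() {
  data.frame(
    node   = c("ROOT", "OUT", "N1", "N2", "BGH", "N3", "THN", "SNW",
               "N4", "ARG", "N5", "URI", "N6", "ASM", "N7", "ANM",
               "N8", "CYM", "N9", "EUM", "DOM"),
    parent = c(NA, "ROOT", "ROOT", "N1", "N2", "N2", "N3", "N3",
               "N1", "N4", "N4", "N5", "N5", "N6", "N6", "N7",
               "N7", "N8", "N8", "N9", "N9"),
    F      = c(NA, 0.5, 0.02, 0.08, 0.12, 0.04, 0.10, 0.10,
               0.02, 0.15, 0.02, 0.08, 0.02, 0.06, 0.02, 0.06,
               0.015, 0.08, 0.015, 0.05, 0.03),
    stringsAsFactors = FALSE)
}

#' Synthetic-data configuration
#'
#' The default configuration is the package's reference study design: ten
#' ingroup populations plus one outgroup on \code{\link{defaultSimTree}},
#' three diploid samples per ingroup population, 50,000 SNP sites spread
#' over five 30-Mb autosomes, ancestral allele frequencies uniform on
#' (0.05, 0.95), and alternating XX/XY sexes.
#'
#' @param tree drift tree (see \code{\link{defaultSimTree}}).
#' @param samplesPerPop diploid samples per ingroup population.
#' @param nSites number of SNP sites.
#' @param freqLaw ancestral-frequency law: \code{"uniform"} on
#'   (\code{freqMin}, \code{freqMax}) or \code{"beta"} with shape
#'   parameters \code{betaShape}.
#' @param freqMin,freqMax support of the uniform law.
#' @param betaShape length-2 shape parameters for the beta law.
#' @param chromLengths named autosome lengths in bp.
#' @param chrXLength chrX length in bp (coverage simulation only).
#' @param outgroupPop label of the outgroup leaf in \code{tree}.
#' @param relatives optional data.frame(population, degree) of planted
#'   relative pairs, degree 0 (identical) to 3.
#' @param rohSpec optional data.frame(sample, chrom, start, length) of
#'   homozygous tracts to plant.
#' @param seed root seed; every generator derives its randomness from it.
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(tree = defaultSimTree(), samplesPerPop = 3L,
                      nSites = 50000L, freqLaw = c("uniform", "beta"),
                      freqMin = 0.05, freqMax = 0.95,
                      betaShape = c(0.8, 0.8),
                      chromLengths = stats::setNames(rep(30e6, 5),
                                                     paste0("chr", 1:5)),
                      chrXLength = 25e6, outgroupPop = "OUT",
                      relatives = NULL, rohSpec = NULL, seed = 1L) {
  freqLaw <- match.arg(freqLaw)
  Fv <- tree$F[!is.na(tree$F)]
  stopifnot(all(Fv >= 0), all(Fv < 1))
  if (!is.null(relatives)) stopifnot(all(relatives$degree %in% 0:3))
  structure(list(tree = tree, samplesPerPop = as.integer(samplesPerPop),
                 nSites = as.integer(nSites), freqLaw = freqLaw,
                 freqMin = freqMin, freqMax = freqMax,
                 betaShape = betaShape, chromLengths = chromLengths,
                 chrXLength = chrXLength, outgroupPop = outgroupPop,
                 relatives = relatives, rohSpec = rohSpec,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

.treeLeaves <- function(tree) setdiff(tree$node, tree$parent)

# one Balding-Nichols step: child frequency given parent p and drift F
.bnStep <- function(p, F) {
  if (F == 0) return(p)
  out <- p
  idx <- which(p > 0 & p < 1)
  if (length(idx))
    out[idx] <- stats::rbeta(length(idx), p[idx] * (1 - F) / F,
                             (1 - p[idx]) * (1 - F) / F)
  out
}

#' Simulate per-population allele frequencies on the drift tree
#'
#' Ancestral frequencies are drawn from the configured law; each branch
#' applies one Balding-Nichols step, Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#' parent frequency p (F = 0 copies exactly; fixed frequencies 0/1 stay
#' fixed). Deterministic under the configuration seed.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param seed override seed (default \code{cfg$seed}).
#' @return matrix (nSites x leaves) of alt-allele frequencies.
#' @export
simulateFrequencies <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(seed)
  tree <- cfg$tree
  root <- tree$node[is.na(tree$parent)]
  anc <- switch(cfg$freqLaw,
    uniform = stats::runif(cfg$nSites, cfg$freqMin, cfg$freqMax),
    beta = stats::rbeta(cfg$nSites, cfg$betaShape[1], cfg$betaShape[2]))
  freqs <- list()
  freqs[[root]] <- anc
  pending <- tree[!is.na(tree$parent), , drop = FALSE]
  while (nrow(pending)) {
    ready <- pending$parent %in% names(freqs)
    if (!any(ready)) stop("tree is not connected")
    for (i in which(ready))
      freqs[[pending$node[i]]] <- .bnStep(freqs[[pending$parent[i]]],
                                          pending$F[i])
    pending <- pending[!ready, , drop = FALSE]
  }
  leaves <- .treeLeaves(tree)
  do.call(cbind, stats::setNames(freqs[leaves], leaves))
}

# one gamete per site from a diploid dosage vector (no linkage: per-site
# independent transmission)
.gamete <- function(g) {
  al <- g / 2
  het <- which(!is.na(g) & g == 1L)
  al[het] <- stats::rbinom(length(het), 1L, 0.5)
  al
}

.freshDiploid <- function(p) stats::rbinom(length(p), 2L, p)

#' Simulate genotypes (with planted relatives) from population frequencies
#'
#' Unrelated individuals are binomial(2, p) draws per site. Planted relative
#' pairs are built by explicit gamete transmission: degree 0 duplicates a
#' genome, degree 1 is parent/offspring, degrees 2 and 3 chain one and two
#' further meioses (grandparent/grandchild, great-grandparent), each
#' transmission per-site independent so the expected kinship ladder is
#' exact. One diploid outgroup sample \code{<outgroupPop>_1} is always
#' generated. SNP positions are drawn uniformly over the configured
#' autosomes.
#'
#' @param freqs matrix from \code{\link{simulateFrequencies}}.
#' @param cfg a \code{\link{simConfig}}.
#' @param seed override seed (default \code{cfg$seed + 1}).
#' @return list with \code{gm} (diploid \code{GenoMatrix}) and \code{truth}
#'   (sample table with population and planted relationships, tree, seed).
#' @export
simulateGenotypes <- function(freqs, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(seed)
  nS <- cfg$nSites
  stopifnot(nrow(freqs) == nS)
  chrom <- sample(rep(names(cfg$chromLengths),
                      length.out = nS))  # balanced assignment, random order
  chrom <- sort(chrom)
  pos <- integer(nS)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos[sel] <- sort(sample.int(cfg$chromLengths[[ch]], sum(sel)))
  }
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(gr)$ref <- "A"
  mcols(gr)$alt <- "C"
  mcols(gr)$nAlt <- 1L

  ingroups <- setdiff(colnames(freqs), cfg$outgroupPop)
  cols <- list()
  truthSamples <- NULL
  addSample <- function(id, pop, relation = "unrelated", pairId = NA) {
    truthSamples <<- rbind(truthSamples,
      data.frame(sample = id, population = pop, relation = relation,
                 pairId = pairId, stringsAsFactors = FALSE))
  }
  for (p in ingroups) {
    for (s in seq_len(cfg$samplesPerPop)) {
      id <- sprintf("%s_%d", p, s)
      cols[[id]] <- .freshDiploid(freqs[, p])
      addSample(id, p)
    }
  }
  ogId <- paste0(cfg$outgroupPop, "_1")
  cols[[ogId]] <- .freshDiploid(freqs[, cfg$outgroupPop])
  addSample(ogId, cfg$outgroupPop, "outgroup")

  relTruth <- NULL
  if (!is.null(cfg$relatives)) {
    for (k in seq_len(nrow(cfg$relatives))) {
      pop <- cfg$relatives$population[k]
      deg <- cfg$relatives$degree[k]
      if (!pop %in% ingroups) stop("relative spec references absent ",
                                   "population: ", pop)
      p <- freqs[, pop]
      a <- .freshDiploid(p)
      if (deg == 0) {
        b <- a
      } else {
        b <- a
        for (g in seq_len(deg))    # chain meioses: deg 1 = offspring, ...
          b <- .gamete(b) + .gamete(.freshDiploid(p))
      }
      idA <- sprintf("%s_rel%dA_%d", pop, deg, k)
      idB <- sprintf("%s_rel%dB_%d", pop, deg, k)
      cols[[idA]] <- a
      cols[[idB]] <- b
      addSample(idA, pop, sprintf("degree%d", deg), k)
      addSample(idB, pop, sprintf("degree%d", deg), k)
      relTruth <- rbind(relTruth,
        data.frame(sample1 = idA, sample2 = idB, degree = deg, pairId = k))
    }
  }
  dos <- do.call(cbind, cols)
  gm <- GenoMatrix(gr, dos)
  list(gm = gm,
       truth = list(samples = truthSamples, relatives = relTruth,
                    tree = cfg$tree, outgroup = ogId, seed = seed))
}

#' Plant homozygous tracts into a genotype matrix
#'
#' Inside each target interval the sample's genotype is made homozygous by
#' duplicating one uniformly sampled allele of the carried genotype
#' (heterozygotes collapse to 0 or 2 with equal probability; homozygotes
#' are unchanged). Outside the intervals the matrix is untouched.
#'
#' @param gm a diploid \code{GenoMatrix}.
#' @param spec data.frame(sample, chrom, start, length) of tracts; intervals
#'   of one sample must not overlap.
#' @param seed integer seed.
#' @return list with \code{gm} (modified) and \code{truth} (a \code{GRanges}
#'   of the planted intervals with a \code{sample} column).
#' @export
plantRoh <- function(gm, spec, seed = 1L) {
  if (is.null(spec) || nrow(spec) == 0)
    return(list(gm = gm, truth = GRanges()))
  set.seed(seed)
  stopifnot(all(c("sample", "chrom", "start", "length") %in% names(spec)))
  truth <- GRanges(spec$chrom,
                   IRanges(spec$start, spec$start + spec$length - 1L))
  mcols(truth)$sample <- spec$sample
  for (s in unique(spec$sample)) {
    tr <- truth[mcols(truth)$sample == s]
    if (sum(width(reduce(tr))) != sum(width(tr)))
      stop("overlapping planted intervals for sample ", s)
  }
  d <- dosages(gm)
  gr <- sites(gm)
  for (k in seq_len(nrow(spec))) {
    sel <- as.character(seqnames(gr)) == spec$chrom[k] &
      start(gr) >= spec$start[k] &
      start(gr) <= spec$start[k] + spec$length[k] - 1L
    g <- d[sel, spec$sample[k]]
    het <- which(!is.na(g) & g == 1L)
    g[het] <- 2L * stats::rbinom(length(het), 1L, 0.5)
    d[sel, spec$sample[k]] <- g
  }
  list(gm = new("GenoMatrix", sites = gr, dosages = d, ploidy = "diploid"),
       truth = truth)
}

#' Simulate per-chromosome coverage profiles
#'
#' Aligned bases per chromosome are Poisson(depth x length). The expected
#' chrX depth is \code{depth x xxRx} for XX samples and \code{depth x xyRx}
#' for XY samples: in an ideal assembly these factors would be 1 and 0.5,
#' but incomplete X assemblies and X-homologous autosomal sequence attenuate
#' the apparent chrX coverage, so the defaults emulate the empirically
#' observed XX/XY Rx cluster means of 0.74 and 0.42 that the 0.65/0.5
#' assignment thresholds are designed for. Feeds \code{\link{computeRx}} /
#' \code{\link{assignSex}}.
#'
#' @param sexes named character vector (sample -> "XX"/"XY").
#' @param chromLengths named autosome lengths (bp).
#' @param chrXLength chrX length (bp).
#' @param depth expected autosomal depth.
#' @param xxRx,xyRx expected Rx of XX and XY samples.
#' @param seed integer seed.
#' @return data.frame(sample, chrom, length, alignedBases); chrX rows carry
#'   chromosome id \code{"chrX"}.
#' @export
simulateCoverage <- function(sexes, chromLengths, chrXLength = 25e6,
                             depth = 2, xxRx = 0.74, xyRx = 0.42,
                             seed = 1L) {
  set.seed(seed)
  out <- NULL
  for (s in names(sexes)) {
    lens <- c(chromLengths, chrX = chrXLength)
    mult <- c(rep(1, length(chromLengths)),
              if (sexes[[s]] == "XY") xyRx else xxRx)
    ab <- stats::rpois(length(lens), depth * mult * lens)
    out <- rbind(out, data.frame(sample = s, chrom = names(lens),
                                 length = unname(lens),
                                 alignedBases = ab, row.names = NULL))
  }
  out
}

#' Simulate a conservation track with population-weighted derived alleles
#'
#' Builds a per-base score track on one synthetic chromosome: conserved
#' blocks with scores above the threshold separated by low-scoring gaps.
#' Each sample then receives derived alleles placed into conserved regions
#' with probability proportional to (population weight x region score), so a
#' population with weight proportional to the score accumulates its derived
#' alleles preferentially in strongly conserved regions and acquires a
#' higher relative mutation load.
#'
#' @param populations named list: population -> character vector of sample
#'   ids.
#' @param weights named numeric vector per population: exponent on the
#'   region score in the placement probability (0 = uniform over regions,
#'   1 = proportional to score).
#' @param nRegions number of conserved regions.
#' @param regionLen region length in bases.
#' @param gapLen gap length between regions.
#' @param scoreRange range of conserved-region score levels (> threshold):
#'   each region draws one level from this range and its per-base scores
#'   vary only slightly around it, so regions differ cleanly in their mean
#'   score g_i.
#' @param derivedPerSample derived alleles placed per sample.
#' @param chrom chromosome id of the track.
#' @param seed integer seed.
#' @return list with \code{track} (data.frame chrom/pos/score),
#'   \code{regions} (truth \code{GRanges} with mean score \code{g}),
#'   \code{polarized} (a \code{\link{polarizeDerived}}-shaped list ready for
#'   \code{\link{rml}}) and \code{weights}.
#' @export
simulateLoad <- function(populations, weights, nRegions = 60,
                         regionLen = 40L, gapLen = 20L,
                         scoreRange = c(4.5, 9), derivedPerSample = 200L,
                         chrom = "chrL", seed = 1L) {
  set.seed(seed)
  pos <- integer(0)
  score <- numeric(0)
  regStart <- integer(nRegions)
  regG <- numeric(nRegions)
  cur <- 1L
  for (i in seq_len(nRegions)) {
    level <- stats::runif(1, scoreRange[1], scoreRange[2])
    sc <- pmax(scoreRange[1],
               level + stats::runif(regionLen, -0.2, 0.2))
    pos <- c(pos, cur:(cur + regionLen - 1L),
             (cur + regionLen):(cur + regionLen + gapLen - 1L))
    score <- c(score, sc, stats::runif(gapLen, 0, 3))
    regStart[i] <- cur
    regG[i] <- mean(sc)
    cur <- cur + regionLen + gapLen
  }
  track <- data.frame(chrom = chrom, pos = pos, score = score)
  regions <- GRanges(chrom, IRanges(regStart, width = regionLen))
  mcols(regions)$g <- regG
  mcols(regions)$nBases <- regionLen

  samples <- unlist(populations, use.names = FALSE)
  placements <- list()
  for (p in names(populations)) {
    w <- regG^weights[[p]]
    for (s in populations[[p]]) {
      if (derivedPerSample == 0) { placements[[s]] <- integer(0); next }
      reg <- sample.int(nRegions, derivedPerSample, replace = TRUE,
                        prob = w / sum(w))
      placements[[s]] <- regStart[reg] +
        sample.int(regionLen, derivedPerSample, replace = TRUE) - 1L
    }
  }
  allPos <- sort(unique(unlist(placements)))
  derived <- matrix(0L, length(allPos), length(samples),
                    dimnames = list(NULL, samples))
  for (s in samples) {
    tab <- table(placements[[s]])
    idx <- match(as.integer(names(tab)), allPos)
    derived[idx, s] <- pmin(2L, as.integer(tab))
  }
  sitesGr <- GRanges(rep(chrom, length(allPos)),
                     IRanges(allPos, width = 1L))
  list(track = track, regions = regions,
       polarized = list(derived = derived, sites = sitesGr, nDropped = 0L),
       weights = weights)
}

#' Simulate an mtDNA haplotype alignment on a mutation tree
#'
#' Sequences evolve along a tree under the infinite-sites assumption within
#' a fixed length L: each branch mutates Poisson(m) previously unmutated
#' positions to a different base. The default tree is a star over
#' \code{nTips} tips with equal expected mutation count per branch, for
#' which the expected pairwise diversity is E[pi] = 2m/L.
#'
#' @param nTips number of tips of the default star tree.
#' @param length alignment length L.
#' @param mPerBranch expected mutations per branch.
#' @param tree optional data.frame(node, parent, m) for a general topology
#'   (m = expected mutations on the edge above \code{node}).
#' @param seed integer seed.
#' @return list with \code{aln} (\code{DNAStringSet} of tip sequences) and
#'   \code{truth} (realized per-branch mutation counts).
#' @export
simulateMtdna <- function(nTips = 5L, length = 10000L, mPerBranch = 10,
                          tree = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(tree))
    tree <- data.frame(node = c("ROOT", paste0("tip", seq_len(nTips))),
                       parent = c(NA, rep("ROOT", nTips)),
                       m = c(NA, rep(mPerBranch, nTips)))
  bases <- c("A", "C", "G", "T")
  root <- tree$node[is.na(tree$parent)]
  seqs <- list()
  seqs[[root]] <- sample(bases, length, replace = TRUE)
  unmutated <- seq_len(length)
  counts <- stats::setNames(numeric(0), character(0))
  pending <- tree[!is.na(tree$parent), , drop = FALSE]
  while (nrow(pending)) {
    ready <- which(pending$parent %in% names(seqs))
    if (!length(ready)) stop("tree is not connected")
    for (i in ready) {
      k <- stats::rpois(1, pending$m[i])
      if (k > length(unmutated))
        stop("requested mutations exceed remaining sequence length")
      sq <- seqs[[pending$parent[i]]]
      if (k > 0) {
        at <- sample(unmutated, k)
        unmutated <- setdiff(unmutated, at)
        for (j in at) sq[j] <- sample(setdiff(bases, sq[j]), 1)
      }
      seqs[[pending$node[i]]] <- sq
      counts[pending$node[i]] <- k
    }
    pending <- pending[-ready, , drop = FALSE]
  }
  tips <- .treeLeaves(tree)
  aln <- Biostrings::DNAStringSet(
    vapply(tips, function(t) paste(seqs[[t]], collapse = ""), character(1)))
  names(aln) <- tips
  list(aln = aln, truth = list(mutations = counts, tree = tree))
}
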