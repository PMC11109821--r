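#' @importFrom vcfR read.vcfR extract.gt getFIX
NULL

.INFO_FIELDS <- c("QD", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "DP")

#' Read a VCF into a GenoMatrix
#'
#' Parses GT fields into alt-allele dosages. Multiallelic records are
#' retained with \code{nAlt > 1} in the site metadata and are removed later by
#' \code{\link{applySiteFilters}}. Records are re-sorted by (chromosome,
#' position) if needed (deterministically), with a message.
#'
#' @param path path to a VCF (v4.x) file, plain or gzipped.
#' @param sampleSubset optional character vector of sample ids to keep;
#'   requesting an absent sample is an error listing the available ids.
#' @return A diploid \code{\linkS4class{GenoMatrix}} whose site metadata
#'   carries \code{ref}, \code{alt}, \code{nAlt}, \code{QUAL} and the INFO
#'   annotations QD, SOR, FS, MQ, MQRankSum, ReadPosRankSum, DP (NA where
#'   absent).
#' @export
readGenoVcf <- function(path, sampleSubset = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) stop("VCF contains no records: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n,
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  avail <- colnames(gt)
  if (!is.null(sampleSubset)) {
    bad <- setdiff(sampleSubset, avail)
    if (length(bad))
      stop("sample(s) not in VCF: ", paste(bad, collapse = ", "),
           "; available: ", paste(avail, collapse = ", "))
    gt <- gt[, sampleSubset, drop = FALSE]
  }
  dos <- .gtToDosage(gt)
  rownames(dos) <- NULL
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) stop("malformed POS at VCF record line(s): ",
                       paste(which(is.na(pos)), collapse = ", "))
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  nAlt <- lengths(strsplit(alt, ",", fixed = TRUE))
  info <- .parseInfo(fix[, "INFO"])
  gr <- GRanges(fix[, "CHROM"], IRanges(pos, width = 1L))
  mcols(gr)$ref <- fix[, "REF"]
  mcols(gr)$alt <- alt
  mcols(gr)$nAlt <- as.integer(nAlt)
  mcols(gr)$QUAL <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  for (f in .INFO_FIELDS) mcols(gr)[[f]] <- info[[f]]
  o <- order(as.integer(seqnames(gr)), start(gr))
  if (!identical(o, seq_len(n)))
    message("VCF records out of order; re-sorting by (chrom, pos)")
  GenoMatrix(gr, dos)
}

.gtToDosage <- function(gt) {
  # alt-allele count from a GT string; any '.' allele -> missing
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  g <- gsub("|", "/", gt, fixed = TRUE)
  dos[g %in% c("0/0", "0")] <- 0L
  dos[g %in% c("0/1", "1/0")] <- 1L
  dos[g %in% c("1/1", "1")] <- 2L
  # other allele numbers (multiallelic GTs): count non-ref alleles
  unresolved <- which(!is.na(g) & is.na(dos) & !grepl(".", g, fixed = TRUE))
  for (i in unresolved) {
    al <- strsplit(g[i], "/", fixed = TRUE)[[1]]
    dos[i] <- sum(al != "0")
  }
  dos
}

.parseInfo <- function(info) {
  out <- lapply(.INFO_FIELDS, function(f) {
    m <- regmatches(info, regexpr(paste0("(^|;)", f, "=[^;]*"), info))
    val <- rep(NA_real_, length(info))
    hit <- grepl(paste0("(^|;)", f, "="), info)
    val[hit] <- suppressWarnings(as.numeric(sub(paste0(".*", f, "="), "",
      regmatches(info, regexpr(paste0("(^|;)", f, "=[^;]*"), info)))))
    val
  })
  names(out) <- .INFO_FIELDS
  out
}

#' Write a GenoMatrix as a plain-text VCF
#'
#' Emits a minimal VCF v4.2 with the site QUAL/INFO annotations and GT
#' genotypes, suitable for round-tripping through \code{\link{readGenoVcf}}.
#'
#' @param gm a diploid \code{GenoMatrix}.
#' @param path output file path (uncompressed text).
#' @return \code{path}, invisibly.
#' @export
writeGenoVcf <- function(gm, path) {
  if (ploidy(gm) != "diploid")
    stop("only diploid matrices are written as VCF")
  gr <- sites(gm)
  m <- mcols(gr)
  hdr <- c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(as.character(seqnames(gr)))),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            .INFO_FIELDS, .INFO_FIELDS),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(gm)), collapse = "\t"))
  info <- vapply(seq_along(gr), function(i) {
    vals <- vapply(.INFO_FIELDS, function(f) {
      x <- m[[f]][i]
      if (is.null(x) || is.na(x)) NA_character_
      else paste0(f, "=", format(x, trim = TRUE, scientific = FALSE))
    }, character(1))
    vals <- vals[!is.na(vals)]
    if (length(vals)) paste(vals, collapse = ";") else "."
  }, character(1))
  gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- dosages(gm)
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtcode[as.character(d[ok])]
  qual <- if (!is.null(m$QUAL)) ifelse(is.na(m$QUAL), ".",
                                       format(m$QUAL, trim = TRUE)) else "."
  body <- paste(as.character(seqnames(gr)), start(gr), ".",
                m$ref, m$alt, qual, "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Site filter configuration
#'
#' Default thresholds follow standard short-read hard-filtering practice:
#' QUAL >= 20, QD >= 2, SOR <= 3, FS <= 60, MQ >= 40, MQRankSum > -12.5,
#' ReadPosRankSum > -8, per-site mean depth in [4, 16] inclusive,
#' MAF >= 0.05 and Hardy-Weinberg exact-test p >= 0.001.
#'
#' @param minQual,minQd,maxSor,maxFs,minMq,minMqRankSum,minReadPosRankSum
#'   INFO-annotation thresholds.
#' @param minDepth,maxDepth inclusive bounds on per-site mean depth
#'   (INFO/DP divided by the sample count).
#' @param minMaf minor-allele-frequency floor, computed across the
#'   non-missing genotypes of all samples.
#' @param minHweP floor on the two-sided Hardy-Weinberg exact-test p-value
#'   (no mid-p), computed on genotype counts pooled across non-outgroup
#'   samples.
#' @param required character vector of annotation names that must be present;
#'   a site missing a required annotation fails that test, while missing
#'   non-required annotations are not evaluated.
#' @return A \code{list} of class \code{FilterConfig}.
#' @export
filterConfig <- function(minQual = 20, minQd = 2, maxSor = 3, maxFs = 60,
                         minMq = 40, minMqRankSum = -12.5,
                         minReadPosRankSum = -8, minDepth = 4, maxDepth = 16,
                         minMaf = 0.05, minHweP = 0.001,
                         required = character()) {
  stopifnot(minDepth < maxDepth, minMaf >= 0, minMaf <= 0.5)
  structure(list(minQual = minQual, minQd = minQd, maxSor = maxSor,
                 maxFs = maxFs, minMq = minMq, minMqRankSum = minMqRankSum,
                 minReadPosRankSum = minReadPosRankSum, minDepth = minDepth,
                 maxDepth = maxDepth, minMaf = minMaf, minHweP = minHweP,
                 required = required),
            class = "FilterConfig")
}

# two-sided exact Hardy-Weinberg test on genotype counts (Wigginton-style,
# plain exact test without mid-p): p = sum of probabilities of heterozygote
# counts no more likely than the observed one, conditional on allele counts.
.hweExactP <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (n == 0L) return(NA_real_)
  nA <- 2L * nAA + nAB
  nB <- 2L * nBB + nAB
  rare <- min(nA, nB)
  hets <- seq(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    homRare <- (rare - h) %/% 2L
    homCom <- (n - h - homRare)
    lfactorial(n) - lfactorial(h) - lfactorial(homRare) -
      lfactorial(homCom) + h * log(2) +
      lfactorial(nA) + lfactorial(nB) - lfactorial(2L * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(nAB, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Apply site-level hard filters
#'
#' Retains biallelic SNPs passing all annotation thresholds, the
#' minor-allele-frequency floor and the Hardy-Weinberg exact test (pooled
#' genotype counts across non-outgroup samples). Multiallelic records and
#' non-SNP alleles are dropped. Filtering is idempotent.
#'
#' @param gm a diploid \code{GenoMatrix}.
#' @param cfg a \code{\link{filterConfig}}.
#' @param outgroup optional sample id excluded from the HWE genotype counts
#'   (MAF still uses all samples).
#' @return The filtered \code{GenoMatrix}; empty (with a warning) when no
#'   site survives.
#' @export
applySiteFilters <- function(gm, cfg = filterConfig(), outgroup = NULL) {
  stopifnot(inherits(cfg, "FilterConfig"))
  gr <- sites(gm)
  m <- mcols(gr)
  d <- dosages(gm)
  n <- nSites(gm)

  test <- function(field, fn) {
    x <- m[[field]]
    if (is.null(x)) x <- rep(NA_real_, n)
    ok <- fn(x)
    ok[is.na(x)] <- !(field %in% cfg$required)
    ok
  }
  keep <- m$nAlt == 1L & nchar(m$ref) == 1L & nchar(m$alt) == 1L &
    m$ref != m$alt & m$alt %in% c("A", "C", "G", "T")
  keep <- keep & test("QUAL", function(x) x >= cfg$minQual)
  keep <- keep & test("QD", function(x) x >= cfg$minQd)
  keep <- keep & test("SOR", function(x) x <= cfg$maxSor)
  keep <- keep & test("FS", function(x) x <= cfg$maxFs)
  keep <- keep & test("MQ", function(x) x >= cfg$minMq)
  keep <- keep & test("MQRankSum", function(x) x > cfg$minMqRankSum)
  keep <- keep & test("ReadPosRankSum", function(x) x > cfg$minReadPosRankSum)
  keep <- keep & test("DP", function(x) {
    md <- x / nSamples(gm)
    md >= cfg$minDepth & md <= cfg$maxDepth
  })

  nm <- rowSums(!is.na(d))
  altc <- rowSums(d, na.rm = TRUE)
  af <- ifelse(nm > 0, altc / (2 * nm), NA_real_)
  maf <- pmin(af, 1 - af)
  keep <- keep & !is.na(maf) & maf >= cfg$minMaf

  hweCols <- setdiff(sampleIds(gm), outgroup)
  dh <- d[, hweCols, drop = FALSE]
  nAA <- rowSums(dh == 0L, na.rm = TRUE)
  nAB <- rowSums(dh == 1L, na.rm = TRUE)
  nBB <- rowSums(dh == 2L, na.rm = TRUE)
  hwe <- vapply(seq_len(n), function(i) .hweExactP(nAA[i], nAB[i], nBB[i]),
                numeric(1))
  keep <- keep & (is.na(hwe) | hwe >= cfg$minHweP)

  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("all sites removed by filters")
  gm[keep, ]
}

#' Restrict to sites heterozygous in the outgroup
#'
#' Ascertainment used to control reference/discovery bias: only sites at
#' which the (diploid) outgroup genome is heterozygous are retained, so the
#' site discovery is independent of the ingroup lineages.
#'
#' @param gm a \code{GenoMatrix} containing the outgroup sample.
#' @param outgroupSample outgroup sample id.
#' @return The ascertained \code{GenoMatrix}; empty with a warning when the
#'   outgroup carries no heterozygous site.
#' @export
ascertainOutgroupHet <- function(gm, outgroupSample) {
  if (!outgroupSample %in% sampleIds(gm))
    stop("outgroup sample not present: ", outgroupSample)
  og <- dosages(gm)[, outgroupSample]
  if (all(is.na(og))) stop("outgroup sample is entirely missing")
  keep <- !is.na(og) & og == 1L
  if (!any(keep)) warning("no heterozygous outgroup sites")
  gm[keep, ]
}

#' Pseudo-haploidize a diploid genotype matrix
#'
#' Replaces each non-missing genotype by a single allele drawn uniformly from
#' the two carried alleles, coded as dosage 0 or 2. Homozygotes are invariant;
#' heterozygotes map to 0 or 2 with probability 1/2 each. Deterministic under
#' a fixed seed.
#'
#' @param gm a diploid \code{GenoMatrix}.
#' @param seed integer seed.
#' @return A \code{GenoMatrix} with \code{ploidy == "pseudohaploid"}.
#' @export
pseudoHaploidize <- function(gm, seed = 1L) {
  if (ploidy(gm) != "diploid") stop("input must be diploid")
  set.seed(seed)
  d <- dosages(gm)
  het <- which(!is.na(d) & d == 1L)
  d[het] <- 2L * stats::rbinom(length(het), 1L, 0.5)
  new("GenoMatrix", sites = sites(gm), dosages = d, ploidy = "pseudohaploid")
}

#' Export genotypes as a TSV table
#'
#' One row per site (chrom, pos, ref, alt) followed by one dosage column per
#' sample; missing as NA.
#'
#' @param gm a \code{GenoMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenoTsv <- function(gm, path) {
  gr <- sites(gm)
  df <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                   ref = mcols(gr)$ref, alt = mcols(gr)$alt,
                   dosages(gm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
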