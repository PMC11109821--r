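#' @importFrom jsonlite write_json read_json toJSON
NULL

# small polynomial rolling hash over the canonical JSON form of the config,
# for output provenance lines
.configHash <- function(cfg) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.writeStageTsv <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash=%s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Default pipeline run configuration
#'
#' Points every stage at the files written by \code{\link{makeFixture}} and
#' fills in the standard parameters (filters, 1-Mb kinship windows, 0.65/0.5
#' Rx thresholds, 5-Mb jackknife blocks, bootstrap chunk/rep counts).
#'
#' @param fixtureDir directory holding the fixture files.
#' @param outdir output directory for the run.
#' @param seed root seed for all stochastic stages.
#' @param bootstrapReps,bootstrapChunk NJ bootstrap settings.
#' @return config list consumable by \code{\link{runPipeline}}.
#' @export
defaultRunConfig <- function(fixtureDir, outdir, seed = 1L,
                             bootstrapReps = 50L, bootstrapChunk = 5000L) {
  list(
    inputs = list(
      vcf = file.path(fixtureDir, "genotypes.vcf"),
      coverage = file.path(fixtureDir, "coverage.tsv"),
      gerpTrack = file.path(fixtureDir, "gerp_track.tsv"),
      mtdnaFasta = file.path(fixtureDir, "mtdna.fasta"),
      metadata = file.path(fixtureDir, "metadata.tsv")),
    stages = c("filter", "sexdet", "kinship", "fstats", "tree",
               "diversity", "roh", "load"),
    seed = as.integer(seed),
    filter = list(minMaf = 0.05, minHweP = 0.001),
    kinship = list(windowBp = 1e6, pruneMaxDegree = "2nd"),
    sexdet = list(xxThreshold = 0.65, xyThreshold = 0.5),
    fstats = list(blockSpanBp = 5e6, bootstrapReps = bootstrapReps,
                  bootstrapChunk = bootstrapChunk),
    roh = list(),
    outdir = outdir)
}

#' Run the full viability pipeline
#'
#' Executes filter, sex determination, kinship (with pruning), f-statistics
#' and distances, MDS/NJ with bootstrap support, diversity, ROH and mutation
#' load on the configured inputs, writing per-stage TSVs (each carrying the
#' config hash), a Newick tree and a JSON run manifest. Re-running with an
#' identical config reproduces every output byte-for-byte; a stage failure
#' halts the run with the failing stage named and a FAILED marker file.
#'
#' @param config config list (see \code{\link{defaultRunConfig}}) or path to
#'   a JSON file holding one.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(config)
  seed <- as.integer(config$seed)
  manifest <- list(configHash = hash, seed = seed, stages = list(),
                   counts = list())
  done <- function(stage, ...) {
    manifest$stages[[stage]] <<- "complete"
    extra <- list(...)
    for (n in names(extra)) manifest$counts[[n]] <<- extra[[n]]
  }
  runStage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop("pipeline halted at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  stages <- config$stages

  meta <- utils::read.table(config$inputs$metadata, header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  gm <- readGenoVcf(config$inputs$vcf)
  outgroupSample <- meta$sample[meta$outgroup][1]
  manifest$counts$input_sites <- nSites(gm)
  manifest$counts$input_samples <- nSamples(gm)

  if ("filter" %in% stages) runStage("filter", function() {
    cfgF <- do.call(filterConfig, as.list(config$filter))
    gm <<- applySiteFilters(gm, cfgF, outgroup = outgroupSample)
    gr <- sites(gm)
    .writeStageTsv(data.frame(chrom = as.character(seqnames(gr)),
                              pos = start(gr)),
                   file.path(outdir, "filtered_sites.tsv"), hash)
    done("filter", filtered_sites = nSites(gm))
  })

  if ("sexdet" %in% stages) runStage("sexdet", function() {
    cov <- utils::read.table(config$inputs$coverage, header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    rows <- lapply(unique(cov$sample), function(s) {
      rx <- assignSex(computeRx(cov[cov$sample == s, ], sample = s),
                      config$sexdet$xxThreshold, config$sexdet$xyThreshold)
      data.frame(sample = s, rx = rx$rx, se = rx$se,
                 assignment = rx$assignment)
    })
    .writeStageTsv(do.call(rbind, rows),
                   file.path(outdir, "sex_assignments.tsv"), hash)
    done("sexdet", sexed_samples = length(rows))
  })

  excluded <- character(0)
  if ("kinship" %in% stages) runStage("kinship", function() {
    ph <- pseudoHaploidize(gm, seed = seed)
    kcfg <- kinshipConfig(windowBp = config$kinship$windowBp)
    rows <- NULL
    for (popn in unique(meta$lineage[!meta$outgroup])) {
      ids <- intersect(meta$sample[meta$lineage == popn], sampleIds(gm))
      if (length(ids) < 2) next
      pairs <- utils::combn(ids, 2)
      p0s <- lapply(seq_len(ncol(pairs)), function(k)
        pairwiseMismatch(ph, pairs[, k], windowBp = kcfg$windowBp))
      kin <- classifyKinship(p0s, kcfg)
      kin$population <- popn
      excluded <<- c(excluded,
                     pruneRelatives(kin, config$kinship$pruneMaxDegree))
      rows <- rbind(rows, kin)
    }
    .writeStageTsv(rows, file.path(outdir, "kinship.tsv"), hash)
    writeLines(sort(excluded), file.path(outdir, "excluded_samples.txt"))
    done("kinship", kinship_pairs = if (is.null(rows)) 0L else nrow(rows),
         excluded_samples = length(excluded))
  })
  keepSamples <- setdiff(sampleIds(gm), excluded)
  gm <- gm[, keepSamples]
  meta <- meta[meta$sample %in% keepSamples, , drop = FALSE]

  grouping <- stats::setNames(meta$lineage, meta$sample)
  outgroupPop <- meta$lineage[meta$outgroup][1]
  af <- NULL; blocks <- NULL; D <- NULL; boots <- NULL
  if ("fstats" %in% stages) runStage("fstats", function() {
    af <<- alleleFrequencies(gm, grouping)
    blocks <<- makeBlocks(af, "span", config$fstats$blockSpanBp)
    D <<- distanceMatrix(af, outgroup = outgroupPop, blocks = blocks)
    dfD <- data.frame(population = rownames(D), D, check.names = FALSE)
    .writeStageTsv(dfD, file.path(outdir, "f3_distances.tsv"), hash)
    pops <- setdiff(unique(grouping), outgroupPop)
    res <- list()
    for (i in seq_along(pops)) for (j in seq_len(i - 1L))
      res[[length(res) + 1L]] <-
        f3stat(af, outgroupPop, pops[i], pops[j], blocks)
    .writeStageTsv(do.call(rbind, lapply(res, as.data.frame.FStatResult)),
                   file.path(outdir, "f3_stats.tsv"), hash)
    boots <<- bootstrapDistanceMatrices(gm, grouping, outgroupPop,
                                        chunkSize = config$fstats$bootstrapChunk,
                                        reps = config$fstats$bootstrapReps,
                                        seed = seed)
    done("fstats", f3_pairs = length(res))
  })

  if ("tree" %in% stages) runStage("tree", function() {
    if (is.null(D)) stop("tree stage requires fstats stage")
    mds <- classicalMds(D, k = 2)
    .writeStageTsv(data.frame(population = rownames(mds$points),
                              mds$points, check.names = FALSE),
                   file.path(outdir, "mds_coordinates.tsv"), hash)
    main <- njTree(D)
    reps <- lapply(boots, njTree)
    supported <- bootstrapSupport(main, reps)
    writeNewick(supported, file.path(outdir, "nj_tree.nwk"))
    rooted <- rootWithOutgroup(D, outgroupPop, distance = 1.0)
    writeNewick(rooted, file.path(outdir, "nj_tree_rooted.nwk"))
    done("tree", bootstrap_replicates = length(reps))
  })

  if ("diversity" %in% stages) runStage("diversity", function() {
    het <- do.call(rbind, lapply(setdiff(sampleIds(gm), outgroupSample),
      function(s) {
        h <- individualHeterozygosity(gm, s, callableSites = nSites(gm))
        data.frame(sample = s, heterozygosity = h$value,
                   n_sites = h$nSites)
      }))
    .writeStageTsv(het, file.path(outdir, "heterozygosity.tsv"), hash)
    indGrouping <- stats::setNames(meta$sample, meta$sample)
    indGrouping[meta$sample[meta$outgroup]] <- outgroupPop
    afInd <- alleleFrequencies(gm, indGrouping)
    blk <- makeBlocks(afInd, "span", config$fstats$blockSpanBp)
    rows <- NULL
    for (popn in setdiff(unique(meta$lineage), outgroupPop)) {
      ids <- meta$sample[meta$lineage == popn]
      if (length(ids) < 2) next
      pd <- pairwiseF3Diversity(afInd, ids, outgroupPop, blk)
      rows <- rbind(rows, data.frame(population = popn, diversity = pd$value,
                                     n_pairs = pd$nPairs))
    }
    if (!is.null(rows))
      .writeStageTsv(rows, file.path(outdir, "pairwise_f3_diversity.tsv"),
                     hash)
    if (!is.null(config$inputs$mtdnaFasta) &&
        file.exists(config$inputs$mtdnaFasta)) {
      aln <- Biostrings::readDNAStringSet(config$inputs$mtdnaFasta)
      pi <- mtdnaPi(aln)
      .writeStageTsv(data.frame(compartment = "mtDNA", pi = pi$value,
                                n_sites = pi$nSites),
                     file.path(outdir, "mtdna_pi.tsv"), hash)
    }
    done("diversity", diversity_populations =
           if (is.null(rows)) 0L else nrow(rows))
  })

  if ("roh" %in% stages) runStage("roh", function() {
    params <- do.call(rohParams, as.list(config$roh))
    genomeBp <- sum(vapply(
      split(end(sites(gm)), as.character(seqnames(sites(gm)))), max,
      numeric(1)))
    segRows <- NULL; sumRows <- NULL
    for (s in setdiff(sampleIds(gm), outgroupSample)) {
      segs <- suppressWarnings(callRoh(gm, s, params))
      if (length(segs))
        segRows <- rbind(segRows, data.frame(
          sample = s, chrom = as.character(seqnames(segs)),
          start = start(segs), end = end(segs),
          n_snps = mcols(segs)$nSnps, kb = width(segs) / 1000))
      cls <- classifySizes(segs)
      sumRows <- rbind(sumRows, data.frame(
        sample = s, n_segments = cls$nSegments,
        total_bp = cls$totalLength, f_roh = fRoh(segs, genomeBp),
        t(cls$classCounts), check.names = FALSE))
    }
    if (is.null(segRows))
      segRows <- data.frame(sample = character(), chrom = character(),
                            start = integer(), end = integer(),
                            n_snps = integer(), kb = numeric())
    .writeStageTsv(segRows, file.path(outdir, "roh_segments.tsv"), hash)
    .writeStageTsv(sumRows, file.path(outdir, "roh_summary.tsv"), hash)
    done("roh", roh_segments = nrow(segRows))
  })

  if ("load" %in% stages) runStage("load", function() {
    track <- utils::read.table(config$inputs$gerpTrack, header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
    regions <- conservedRegions(track, threshold = 4.0)
    pol <- polarizeDerived(gm, outgroupSample)
    rows <- do.call(rbind, lapply(colnames(pol$derived), function(s) {
      r <- tryCatch(rml(pol, regions, s), error = function(e) NULL)
      if (is.null(r)) data.frame(sample = s, rml = NA_real_, N = 0L,
                                 k_used = 0L)
      else data.frame(sample = s, rml = r$rml, N = r$N, k_used = r$kUsed)
    }))
    .writeStageTsv(rows, file.path(outdir, "mutation_load.tsv"), hash)
    done("load", conserved_regions = length(regions),
         polarized_sites_dropped = pol$nDropped)
  })

  manifest$counts$final_sites <- nSites(gm)
  manifest$counts$final_samples <- nSamples(gm)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write a complete synthetic fixture directory
#'
#' Generates the genotype VCF (with passing INFO annotations), coverage TSV,
#' GERP-style per-base score track over a subset of chr1 SNP neighborhoods,
#' mtDNA FASTA, sample metadata TSV and a truth JSON, all deterministically
#' from the configuration seed.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return invisibly, the truth list.
#' @export
makeFixture <- function(cfg, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE): ",
         dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  freqs <- simulateFrequencies(cfg)
  sim <- simulateGenotypes(freqs, cfg)
  gm <- sim$gm
  truth <- sim$truth
  if (!is.null(cfg$rohSpec)) {
    pr <- plantRoh(gm, cfg$rohSpec, seed = cfg$seed + 2L)
    gm <- pr$gm
    truth$plantedRoh <- as.data.frame(pr$truth)
  }
  ns <- nSamples(gm)
  gr <- sites(gm)
  mcols(gr)$QUAL <- 50
  mcols(gr)$QD <- 20
  mcols(gr)$SOR <- 1
  mcols(gr)$FS <- 10
  mcols(gr)$MQ <- 60
  mcols(gr)$MQRankSum <- 0
  mcols(gr)$ReadPosRankSum <- 0
  mcols(gr)$DP <- round(7.5 * ns)
  gm <- new("GenoMatrix", sites = gr, dosages = dosages(gm),
            ploidy = "diploid")
  writeGenoVcf(gm, file.path(dir, "genotypes.vcf"))

  ids <- sampleIds(gm)
  sexes <- stats::setNames(rep(c("XX", "XY"), length.out = length(ids)), ids)
  truth$sexes <- as.list(sexes)
  cov <- simulateCoverage(sexes, cfg$chromLengths, cfg$chrXLength,
                          depth = 2, seed = cfg$seed + 3L)
  utils::write.table(cov, file.path(dir, "coverage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # conserved blocks centered on a sample of chr1 SNPs so that polarized
  # derived alleles fall inside scored regions
  set.seed(cfg$seed + 4L)
  chr1 <- names(cfg$chromLengths)[1]
  snp1 <- start(gr)[as.character(seqnames(gr)) == chr1]
  centers <- sort(sample(snp1, min(200L, length(snp1))))
  rows <- lapply(centers, function(p) {
    pos <- (p - 20L):(p + 20L)
    data.frame(chrom = chr1, pos = pos,
               score = stats::runif(length(pos), 4.5, 9))
  })
  track <- do.call(rbind, rows)
  track <- track[!duplicated(paste(track$chrom, track$pos)), ]
  utils::write.table(track, file.path(dir, "gerp_track.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  mt <- simulateMtdna(nTips = length(unique(truth$samples$population)),
                      length = 8000L, mPerBranch = 15,
                      seed = cfg$seed + 5L)
  Biostrings::writeXStringSet(mt$aln, file.path(dir, "mtdna.fasta"))

  meta <- data.frame(sample = truth$samples$sample,
                     lineage = truth$samples$population,
                     outgroup = truth$samples$relation == "outgroup",
                     sex = unname(sexes[truth$samples$sample]))
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth$nSites <- nSites(gm)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       dataframe = "rows")
  invisible(truth)
}
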