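#' @rdname GenoMatrix-class
#' @param x,object a \code{GenoMatrix}
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname GenoMatrix-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenoMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenoMatrix-class
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))

#' @rdname GenoMatrix-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname GenoMatrix-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname AlleleFreqTable-class
#' @param x an \code{AlleleFreqTable}
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @export
setMethod("sites", "GenoMatrix", function(x) x@sites)

#' @export
setMethod("dosages", "GenoMatrix", function(x) x@dosages)

#' @export
setMethod("sampleIds", "GenoMatrix", function(x) colnames(x@dosages))

#' @export
setMethod("ploidy", "GenoMatrix", function(x) x@ploidy)

#' @export
setMethod("nSites", "GenoMatrix", function(x) length(x@sites))

#' @export
setMethod("nSamples", "GenoMatrix", function(x) ncol(x@dosages))

#' Subset a GenoMatrix by sites and/or samples
#'
#' @param x a \code{GenoMatrix}
#' @param i site index (logical or integer)
#' @param j sample index (logical, integer or sample ids)
#' @param ... ignored
#' @param drop ignored (always \code{FALSE})
#' @export
setMethod("[", "GenoMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSites(x))
  if (missing(j)) j <- seq_len(nSamples(x))
  if (is.character(j)) {
    bad <- setdiff(j, sampleIds(x))
    if (length(bad))
      stop("unknown sample id(s): ", paste(bad, collapse = ", "),
           "; available: ", paste(sampleIds(x), collapse = ", "))
    j <- match(j, sampleIds(x))
  }
  new("GenoMatrix", sites = x@sites[i],
      dosages = x@dosages[i, j, drop = FALSE], ploidy = x@ploidy)
})

setMethod("show", "GenoMatrix", function(object) {
  miss <- mean(is.na(object@dosages))
  cat(sprintf("GenoMatrix: %d sites x %d samples (%s), %.1f%% missing\n",
              nSites(object), nSamples(object), object@ploidy, 100 * miss))
  chroms <- unique(as.character(seqnames(object@sites)))
  cat("  chromosomes:", paste(utils::head(chroms, 8), collapse = ", "),
      if (length(chroms) > 8) "..." else "", "\n")
  cat("  samples:", paste(utils::head(sampleIds(object), 8), collapse = ", "),
      if (nSamples(object) > 8) "..." else "", "\n")
})

setMethod("show", "FStatResult", function(object) {
  cat(sprintf("%s(%s) = %.6g  SE = %.3g  Z = %.2f  [%d blocks, %d sites]\n",
              object@kind, paste(object@pops, collapse = ", "),
              object@estimate, object@se, object@z,
              object@nBlocks, object@nSites))
})

#' @export
setMethod("populations", "AlleleFreqTable", function(x) colnames(x@freq))

setMethod("show", "AlleleFreqTable", function(object) {
  cat(sprintf("AlleleFreqTable: %d sites x %d populations\n",
              nrow(object@freq), ncol(object@freq)))
  cat("  populations:", paste(colnames(object@freq), collapse = ", "), "\n")
})

#' Turn an FStatResult into a one-row data.frame
#'
#' @param x an \code{FStatResult}
#' @param row.names,optional,... passed through for generic consistency
#' @return one-row \code{data.frame} with kind, populations, estimate, SE, Z
#'   and counts.
#' @exportS3Method base::as.data.frame
#' @export
as.data.frame.FStatResult <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  pops <- x@pops
  names(pops) <- paste0("pop", seq_along(pops))
  data.frame(kind = x@kind, as.list(pops), estimate = x@estimate, se = x@se,
             z = x@z, n_blocks = x@nBlocks, n_sites = x@nSites,
             stringsAsFactors = FALSE)
}
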