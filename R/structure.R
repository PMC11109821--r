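.checkDistanceMatrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (is.null(rownames(D))) stop("D must have labels as dimnames")
  if (!all(is.finite(D))) stop("non-finite distances")
  if (any(abs(D - t(D)) > 1e-8)) stop("D must be symmetric")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  invisible(TRUE)
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes and scales the
#' top eigenvectors by the square roots of their (positive) eigenvalues, as
#' \code{stats::cmdscale} does. The sign of each axis is fixed
#' deterministically: the loading of largest magnitude is made positive, so
#' repeated runs are reproducible.
#'
#' @param D symmetric distance matrix with labels, zero diagonal.
#' @param k number of axes requested (< nrow(D)).
#' @return list with \code{points} (labels x axes, centered per axis),
#'   \code{eig} (all eigenvalues, descending) and \code{proportion}
#'   (variance share of each returned axis among positive eigenvalues).
#'   Fewer than \code{k} axes are returned, with a warning, when fewer
#'   positive eigenvalues exist.
#' @export
classicalMds <- function(D, k = 2) {
  .checkDistanceMatrix(D)
  if (k >= nrow(D)) stop("k must be < number of labels")
  fit <- stats::cmdscale(D, k = k, eig = TRUE)
  eig <- fit$eig
  npos <- sum(eig > max(abs(eig)) * 1e-12)
  kUse <- min(k, npos)
  if (kUse < k)
    warning(sprintf("only %d positive eigenvalue(s); returning %d axis/axes",
                    npos, kUse))
  pts <- fit$points[, seq_len(kUse), drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  list(points = pts, eig = eig,
       proportion = eig[seq_len(kUse)] / sum(eig[eig > 0]))
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the Q-criterion and the standard
#' branch-length formulas. Ties in Q are broken deterministically by the
#' lexicographically lowest label pair (each cluster represented by its
#' smallest tip label). Negative branch lengths are clamped to zero with the
#' deficit transferred to the sister branch of the same join, preserving the
#' path length between the joined clusters. With three labels the closed-form
#' star resolution is returned.
#'
#' @param D symmetric distance matrix with >= 3 labels.
#' @return an \code{ape} \code{"phylo"} tree (unrooted; trifurcating root
#'   node).
#' @export
njTree <- function(D) {
  .checkDistanceMatrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 labels")
  fmt <- function(x) sprintf("%.17g", x)
  nwk <- rownames(D)                 # newick fragment per active cluster
  names(nwk) <- rownames(D)          # representative (smallest tip) label
  M <- D
  while (nrow(M) > 3) {
    r <- nrow(M)
    keys <- sort(rownames(M))
    R <- rowSums(M)
    best <- NULL; bestQ <- Inf
    for (ii in seq_len(length(keys) - 1L)) for (jj in (ii + 1L):length(keys)) {
      ki <- keys[ii]; kj <- keys[jj]
      q <- (r - 2) * M[ki, kj] - R[ki] - R[kj]
      if (q < bestQ) { bestQ <- q; best <- c(ki, kj) }
    }
    ki <- best[1]; kj <- best[2]
    dij <- M[ki, kj]
    li <- dij / 2 + (R[ki] - R[kj]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    newNwk <- paste0("(", nwk[ki], ":", fmt(li), ",",
                     nwk[kj], ":", fmt(lj), ")")
    others <- setdiff(rownames(M), c(ki, kj))
    dNew <- (M[ki, others] + M[kj, others] - dij) / 2
    keep <- c(others, ki)            # reuse ki's slot for the new cluster
    M <- M[keep, keep, drop = FALSE]
    M[ki, others] <- dNew
    M[others, ki] <- dNew
    M[ki, ki] <- 0
    newKey <- min(ki, kj)
    rownames(M)[rownames(M) == ki] <- newKey
    colnames(M)[colnames(M) == ki] <- newKey
    nwk <- nwk[setdiff(names(nwk), c(ki, kj))]
    nwk[newKey] <- newNwk
  }
  ks <- sort(rownames(M))
  d12 <- M[ks[1], ks[2]]; d13 <- M[ks[1], ks[3]]; d23 <- M[ks[2], ks[3]]
  l <- pmax(0, c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2,
                 (d13 + d23 - d12) / 2))
  txt <- paste0("(", nwk[ks[1]], ":", fmt(l[1]), ",",
                nwk[ks[2]], ":", fmt(l[2]), ",",
                nwk[ks[3]], ":", fmt(l[3]), ");")
  ape::read.tree(text = txt)
}

# tip-label sets below every internal node (tree treated as rooted at its
# root node); list indexed by node id
.cladeTips <- function(phy) {
  n <- length(phy$tip.label)
  phy2 <- stats::reorder(phy, "postorder")
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(phy2$edge))) {
    p <- phy2$edge[e, 1]; ch <- phy2$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# canonical keys of the non-trivial bipartitions of a tree (ignores branch
# lengths and rooting): each internal edge splits the leaves in two; the key
# is the sorted side not containing the reference (first sorted) label
.bipartKeys <- function(phy) {
  labs <- sort(phy$tip.label)
  ref <- labs[1]
  n <- length(labs)
  sets <- .cladeTips(phy)
  root <- length(phy$tip.label) + 1L
  internal <- setdiff(unique(phy$edge[, 2]), seq_len(n))
  keys <- character(0)
  nodes <- integer(0)
  for (v in internal) {
    side <- sort(sets[[v]])
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      keys <- c(keys, paste(side, collapse = "|"))
      nodes <- c(nodes, v)
    }
  }
  list(keys = keys, nodes = nodes, root = root)
}

#' Bootstrap bipartition support
#'
#' Annotates each internal edge of the main tree with the percentage of
#' replicate trees containing the same leaf bipartition (branch lengths and
#' rooting ignored). Support values are written to \code{node.label} in the
#' usual bootstrap convention and are invariant to replicate order.
#'
#' @param main a \code{"phylo"} tree.
#' @param replicates list of \code{"phylo"} trees over the identical leaf
#'   set (error otherwise).
#' @return \code{main} with \code{node.label} set to support percentages
#'   (empty at the root and at nodes whose bipartition is trivial).
#' @export
bootstrapSupport <- function(main, replicates) {
  labs <- sort(main$tip.label)
  for (r in replicates)
    if (!identical(sort(r$tip.label), labs))
      stop("replicate leaf set differs from the main tree")
  mainK <- .bipartKeys(main)
  repKeys <- lapply(replicates, function(r) .bipartKeys(r)$keys)
  nTip <- length(main$tip.label)
  lab <- rep("", main$Nnode)
  for (i in seq_along(mainK$keys)) {
    k <- mainK$keys[i]
    pct <- 100 * mean(vapply(repKeys, function(ks) k %in% ks, logical(1)))
    lab[mainK$nodes[i] - nTip] <- formatC(pct, format = "g")
  }
  main$node.label <- lab
  main
}

#' Root a 1-f3 distance tree with a constant-distance outgroup
#'
#' Adds the outgroup to the distance matrix at a fixed distance to every
#' ingroup label (the convention used with 1 - outgroup-f3 distances, where
#' the outgroup is by construction at distance 1), rebuilds the
#' neighbor-joining tree and roots it on the outgroup edge.
#'
#' @param D ingroup distance matrix (must not already contain
#'   \code{outgroupLabel}).
#' @param outgroupLabel label for the added outgroup.
#' @param distance constant outgroup distance (default 1). A warning is
#'   issued when it is <= max(D)/2, in which case the outgroup may attach
#'   internally rather than on a pendant edge.
#' @return a rooted \code{"phylo"} tree with the outgroup as sister to the
#'   whole ingroup.
#' @export
rootWithOutgroup <- function(D, outgroupLabel, distance = 1.0) {
  .checkDistanceMatrix(D)
  if (outgroupLabel %in% rownames(D))
    stop("outgroup label already present in D: ", outgroupLabel)
  if (distance <= max(D) / 2)
    warning("outgroup distance <= max(D)/2; outgroup may attach internally")
  labs <- c(rownames(D), outgroupLabel)
  D2 <- matrix(0, nrow(D) + 1, ncol(D) + 1, dimnames = list(labs, labs))
  D2[rownames(D), colnames(D)] <- D
  D2[outgroupLabel, rownames(D)] <- distance
  D2[rownames(D), outgroupLabel] <- distance
  phy <- njTree(D2)
  ape::root(phy, outgroup = outgroupLabel, resolve.root = TRUE)
}

#' Write a tree in Newick format
#'
#' @param phy a \code{"phylo"} tree (support values in \code{node.label} are
#'   written as internal node labels).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}
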