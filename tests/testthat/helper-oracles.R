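# Independent oracles used to freeze expected values. These deliberately use
# brute-force enumeration or direct formula evaluation, not the package's own
# code paths.

# exact two-sided HWE p-value by direct rational enumeration of every
# heterozygote count compatible with the allele counts
oracleHweP <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  rare <- min(nA, 2 * n - nA)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- sapply(hets, function(h) {
    homR <- (rare - h) / 2
    homC <- n - h - homR
    # multinomial genotype configurations x 2^het over allele arrangements
    exp(lgamma(n + 1) - lgamma(h + 1) - lgamma(homR + 1) - lgamma(homC + 1) +
          h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) -
          lgamma(2 * n + 1))
  })
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[match(nAB, hets)] + 1e-12])
}

# brute-force weighted delete-one-block jackknife: recompute every
# leave-one-block-out mean from scratch
oracleJackknife <- function(terms, blocks) {
  est <- mean(terms)
  ub <- sort(unique(blocks))
  G <- length(ub)
  n <- length(terms)
  thm <- sapply(ub, function(g) mean(terms[blocks != g]))
  m <- sapply(ub, function(g) sum(blocks == g))
  h <- n / m
  thetaDot <- G * est - sum((1 - m / n) * thm)
  tau <- h * est - (h - 1) * thm
  list(estimate = est,
       se = sqrt(sum((tau - thetaDot)^2 / (h - 1)) / G))
}

# --- exhaustive neighbor-joining oracle: enumerate every unrooted binary
# topology on n <= 6 tips, least-squares-fit branch lengths and pick the
# minimum-RSS tree ------------------------------------------------------------

# all unrooted binary topologies by recursive edge insertion; a tree is an
# edge matrix over tips 1..n and internal nodes n+1, n+2, ...
.allTopologies <- function(n) {
  stopifnot(n >= 3, n <= 6)
  base <- list(list(edge = rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3)),
                    nextNode = n + 2))
  trees <- base
  for (tip in seq(4, length.out = max(0, n - 3))) {
    out <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
        m <- tr$nextNode
        edge <- rbind(tr$edge[-e, , drop = FALSE],
                      c(u, m), c(m, v), c(m, tip))
        out[[length(out) + 1]] <- list(edge = edge, nextNode = m + 1)
      }
    }
    trees <- out
  }
  trees
}

# tips on one side of each edge (BFS without crossing the edge)
.edgeSplits <- function(edge, n) {
  adj <- list()
  addAdj <- function(a, b) {
    adj[[as.character(a)]] <<- c(adj[[as.character(a)]], b)
  }
  for (e in seq_len(nrow(edge))) {
    addAdj(edge[e, 1], edge[e, 2]); addAdj(edge[e, 2], edge[e, 1])
  }
  lapply(seq_len(nrow(edge)), function(e) {
    u <- edge[e, 1]; v <- edge[e, 2]
    seen <- v; queue <- v
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      for (y in adj[[as.character(x)]]) {
        if (y == u && x == v) next
        if (!y %in% seen) { seen <- c(seen, y); queue <- c(queue, y) }
      }
    }
    sort(seen[seen <= n])
  })
}

# least-squares branch lengths for a fixed topology; returns RSS and the
# fitted tip-to-tip distance matrix
.lsFit <- function(edge, n, D) {
  splits <- .edgeSplits(edge, n)
  pairs <- t(combn(n, 2))
  A <- sapply(splits, function(s) {
    (pairs[, 1] %in% s) != (pairs[, 2] %in% s)
  }) * 1
  y <- D[pairs]
  fit <- lm.fit(A, y)
  fitted <- A %*% fit$coefficients
  Dfit <- matrix(0, n, n)
  Dfit[pairs] <- fitted
  Dfit <- Dfit + t(Dfit)
  list(rss = sum((y - fitted)^2), D = Dfit,
       splits = splits, lengths = fit$coefficients)
}

# best-fitting topology over the full enumeration; returns canonical
# bipartition keys (non-trivial splits as sorted label strings)
oracleBestTopology <- function(D) {
  n <- nrow(D)
  labs <- rownames(D)
  best <- NULL
  for (tr in .allTopologies(n)) {
    f <- .lsFit(tr$edge, n, D)
    if (is.null(best) || f$rss < best$rss - 1e-12) best <- f
  }
  keys <- sapply(best$splits, function(s) {
    side <- sort(labs[s])
    if (sort(labs)[1] %in% side) side <- sort(setdiff(labs, side))
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(side, collapse = "|")
  })
  list(keys = sort(keys[!is.na(keys)]), rss = best$rss,
       D = {
         dimnames(best$D) <- dimnames(D)
         best$D
       })
}

# canonical bipartition keys of an ape tree, independent of ovipop internals
treeBipartitions <- function(phy) {
  phy <- ape::unroot(phy)
  labs <- sort(phy$tip.label)
  pp <- ape::prop.part(phy)
  n <- length(labs)
  keys <- sapply(pp, function(idx) {
    side <- sort(attr(pp, "labels")[idx])
    if (labs[1] %in% side) side <- sort(setdiff(labs, side))
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(side, collapse = "|")
  })
  sort(keys[!is.na(keys)])
}
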