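#' Tanimoto similarity between two maps
#'
#' Generalized Jaccard index for nonnegative vectors,
#' T = (a.b) / (||a||^2 + ||b||^2 - a.b), computed on rectified values
#' (negative values clipped to 0, preserving the gradation of positive
#' z-values). T(a, a) = 1 for nonzero a; disjoint supports give 0. If both
#' maps are identically zero after rectification the similarity is defined
#' as 0 with a warning.
#'
#' @param a,b numeric vectors on a common mask.
#' @return similarity in [0, 1].
#' @export
tanimotoSimilarity <- function(a, b) {
  a <- pmax(as.numeric(a), 0)
  b <- pmax(as.numeric(b), 0)
  stopIfNot(length(a) == length(b), "maps must share a mask")
  ab <- sum(a * b)
  den <- sum(a^2) + sum(b^2) - ab
  if (den == 0) {
    warning("both maps identically zero after rectification; similarity 0")
    return(0)
  }
  ab / den
}

# Full Tanimoto Gram matrix of the columns of V (rectified internally).
tanimotoGram <- function(v) {
  r <- pmax(v, 0)
  cp <- crossprod(r)
  n2 <- diag(cp)
  den <- outer(n2, n2, `+`) - cp
  g <- cp / den
  g[den == 0] <- 0
  g
}

# Cross Tanimoto matrix between columns of a and columns of b.
tanimotoCross <- function(a, b) {
  ra <- pmax(a, 0)
  rb <- pmax(b, 0)
  cp <- crossprod(ra, rb)
  den <- outer(colSums(ra^2), colSums(rb^2), `+`) - cp
  g <- cp / den
  g[den == 0] <- 0
  g
}

#' Bidirectional (mutual argmax) partner matching of two collections
#'
#' Pair (i, j) is returned iff map j is the most similar map in collection
#' 2 to map i AND map i is the most similar map in collection 1 to map j,
#' under Tanimoto similarity on rectified values. Every map appears in at
#' most one pair; argmax ties break toward the lowest index.
#'
#' @param collection1,collection2 \linkS4class{SpatialMapSet}s or voxels x
#'   maps matrices on a common mask.
#' @return data.frame with columns \code{i}, \code{j}, \code{similarity}
#'   (possibly zero rows).
#' @export
bidirectionalMatch <- function(collection1, collection2) {
  a <- if (methods::is(collection1, "SpatialMapSet")) {
    mapValues(collection1)
  } else as.matrix(collection1)
  b <- if (methods::is(collection2, "SpatialMapSet")) {
    mapValues(collection2)
  } else as.matrix(collection2)
  stopIfNot(ncol(a) >= 1 && ncol(b) >= 1, "both collections must be nonempty")
  s <- tanimotoCross(a, b)
  fwd <- apply(s, 1, which.max)        # ties -> lowest index
  bwd <- apply(s, 2, which.max)
  i <- which(bwd[fwd] == seq_len(ncol(a)))
  data.frame(i = i, j = fwd[i],
    similarity = s[cbind(i, fwd[i])])
}

#' Match maps across many owners into clusters
#'
#' Builds a graph with one node per map and an edge for every bidirectional
#' match over all owner pairs; clusters are the connected components. If a
#' component holds more than one map from a single owner, the map with the
#' highest mean similarity to the rest of the component is kept and the
#' others are detached. Clusters with fewer than 2 members, or spanning
#' fewer than \code{minOwnerFraction} of the owners, are dropped.
#'
#' @param collections named list; each element is a
#'   \linkS4class{SpatialMapSet} or voxels x maps matrix belonging to one
#'   owner (a subject at level 2, a component-number setting at level 3).
#' @param minOwnerFraction minimum fraction of owners a cluster must span
#'   (default 0.75).
#' @return list of clusters; each has \code{members} (data.frame
#'   \code{owner}, \code{ownerIndex}, \code{mapIndex}) and
#'   \code{meanSimilarity}.
#' @export
matchAcrossOwners <- function(collections, minOwnerFraction = 0.75) {
  stopIfNot(length(collections) >= 2, "need at least 2 collections")
  owners <- names(collections)
  if (is.null(owners)) owners <- as.character(seq_along(collections))
  mats <- lapply(collections, function(cc) {
    if (methods::is(cc, "SpatialMapSet")) mapValues(cc) else as.matrix(cc)
  })
  counts <- vapply(mats, ncol, integer(1))
  offset <- c(0L, cumsum(counts))[seq_along(mats)]
  all <- do.call(cbind, mats)
  if (is.null(all) || ncol(all) == 0) return(list())
  nodeOwner <- rep(seq_along(mats), counts)
  nodeMapIdx <- unlist(lapply(counts, seq_len), use.names = FALSE)
  gram <- tanimotoGram(all)
  edges <- integer(0)
  for (p in seq_len(length(mats) - 1)) {
    for (q in (p + 1):length(mats)) {
      if (counts[p] == 0 || counts[q] == 0) next
      s <- gram[offset[p] + seq_len(counts[p]),
        offset[q] + seq_len(counts[q]), drop = FALSE]
      fwd <- apply(s, 1, which.max)
      bwd <- apply(s, 2, which.max)
      i <- which(bwd[fwd] == seq_len(counts[p]))
      if (length(i)) {
        edges <- c(edges, rbind(offset[p] + i, offset[q] + fwd[i]))
      }
    }
  }
  g <- igraph::make_empty_graph(n = ncol(all), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  clusters <- list()
  for (cid in seq_len(max(comp))) {
    nodes <- which(comp == cid)
    if (length(nodes) < 2) next
    # owner-conflict pruning: keep the member closest (in mean Tanimoto) to
    # the rest of the component
    keep <- nodes
    for (ow in unique(nodeOwner[nodes])) {
      cand <- nodes[nodeOwner[nodes] == ow]
      if (length(cand) > 1) {
        score <- vapply(cand, function(nd) {
          mean(gram[nd, setdiff(nodes, nd)])
        }, numeric(1))
        best <- cand[order(-score, cand)[1]]
        keep <- setdiff(keep, setdiff(cand, best))
      }
    }
    keep <- sort(keep)
    if (length(keep) < 2) next
    span <- length(unique(nodeOwner[keep])) / length(collections)
    if (span < minOwnerFraction) next
    sub <- gram[keep, keep, drop = FALSE]
    clusters[[length(clusters) + 1]] <- list(
      members = data.frame(
        owner = owners[nodeOwner[keep]],
        ownerIndex = nodeOwner[keep],
        mapIndex = nodeMapIdx[keep]),
      meanSimilarity = mean(sub[upper.tri(sub)]))
  }
  clusters
}

#' Cluster map: one-sample t-map over a match cluster's members
#'
#' Shares the t-map kernel with \code{\link{groupMap}}.
#'
#' @param members a \linkS4class{SpatialMapSet} or voxels x members matrix
#'   of the cluster's maps (>= 2).
#' @param mask logical 3-D mask when \code{members} is a matrix.
#' @return a one-map \linkS4class{SpatialMapSet} (see
#'   \code{\link{groupMap}}).
#' @export
clusterMap <- function(members, mask = NULL) {
  out <- groupMap(members, mask)
  out@info$kind <- "cluster_map"
  out
}

#' Cronbach's alpha reliability of a set of maps
#'
#' Maps are the items, voxels the observations:
#' alpha = (k/(k-1)) (1 - sum_i var_i / var_total) with var_total the
#' voxelwise variance of the sum map. alpha <= 1 always; alpha = 1 iff the
#' members are affinely identical over voxels.
#'
#' @param members a \linkS4class{SpatialMapSet} or voxels x k matrix,
#'   k >= 2, on a common mask.
#' @return list with \code{alpha} (NA when the total variance is 0, in
#'   which case \code{flagged} is TRUE and the score ranks last) and
#'   \code{k}.
#' @export
cronbachAlpha <- function(members) {
  v <- if (methods::is(members, "SpatialMapSet")) mapValues(members) else {
    as.matrix(members)
  }
  k <- ncol(v)
  stopIfNot(k >= 2, "Cronbach's alpha needs at least 2 maps")
  varTotal <- stats::var(rowSums(v))
  if (varTotal == 0) {
    return(list(alpha = NA_real_, k = k, flagged = TRUE))
  }
  alpha <- (k / (k - 1)) * (1 - sum(colSds(v)^2) / varTotal)
  list(alpha = alpha, k = k, flagged = FALSE)
}
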