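#' Correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation of the two
#' samples' taxon abundance vectors; range [0, 2]. This is the sample
#' distance used for community dendrograms of relative-abundance profiles.
#' A sample whose taxon vector has zero variance has no defined correlation
#' and is reported as an error by name.
#'
#' @param profile an `abundance_profile` (or any numeric matrix with taxa as
#'   rows and samples as columns).
#' @return a symmetric `corr_dist` matrix with zero diagonal.
#' @export
correlation_distance <- function(profile) {
  m <- unclass(profile)
  if (!is.matrix(m) || !is.numeric(m)) sip_stop("profile must be a numeric matrix")
  if (ncol(m) < 2L) sip_stop("need at least 2 samples")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    sip_stop(sprintf("sample '%s' has zero variance across taxa; correlation undefined",
                     colnames(m)[sds == 0][1L]))
  }
  d <- 1 - stats::cor(m)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(d, class = c("corr_dist", "matrix", "array"))
}

#' Ward minimum-variance hierarchical clustering
#'
#' Agglomerative clustering by Lance–Williams updates on *squared*
#' distances (the "ward.D2" semantics: input distances are squared
#' internally and merge heights are reported on the original distance
#' scale). At each step the pair of clusters whose merge least increases
#' the within-cluster sum of squares is joined; ties are broken by the
#' lowest-index pair, where clusters are ordered by creation (input samples
#' first, merged clusters appended), which makes the tree deterministic.
#'
#' @param d a symmetric distance matrix (e.g. from
#'   [correlation_distance()]) with sample ids as dimnames.
#' @return a `sip_dendrogram`: list with hclust-style `merge` (n-1 x 2,
#'   negative entries are leaves, positive entries earlier merges),
#'   `height` (non-decreasing), `labels`, and `bp` (bootstrap percentages,
#'   `NULL` until [bootstrap_support()] fills them).
#' @export
ward_linkage <- function(d) {
  D <- unclass(d)
  if (!is.matrix(D) || nrow(D) != ncol(D)) sip_stop("d must be a square matrix")
  n <- nrow(D)
  if (n < 2L) sip_stop("need at least 2 samples to cluster")
  if (max(abs(D - t(D))) > 1e-12) sip_stop("distance matrix not symmetric")
  labels <- colnames(D)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))

  D2 <- D^2
  size <- rep(1L, n)
  code <- -seq_len(n)             # hclust codes for current clusters
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    m <- nrow(D2)
    W <- D2
    W[lower.tri(W, diag = TRUE)] <- Inf
    best <- min(W)
    cand <- which(W == best, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    height[k] <- sqrt(max(best, 0))
    merge[k, ] <- sort(c(code[i], code[j]))
    others <- setdiff(seq_len(m), c(i, j))
    si <- size[i]; sj <- size[j]; sk <- size[others]
    newrow <- ((si + sk) * D2[i, others] + (sj + sk) * D2[j, others] -
                 sk * D2[i, j]) / (si + sj + sk)
    D2 <- rbind(cbind(D2[others, others, drop = FALSE], newrow),
                c(newrow, 0))
    size <- c(size[others], si + sj)
    code <- c(code[others], k)
  }
  structure(list(merge = merge, height = height, labels = labels, bp = NULL),
            class = "sip_dendrogram")
}

#' @export
print.sip_dendrogram <- function(x, ...) {
  cat(sprintf("sip_dendrogram: %d leaves, root height %.4g%s\n",
              length(x$labels), max(x$height),
              if (is.null(x$bp)) "" else ", with bootstrap support"))
  invisible(x)
}

#' Convert to a base-R hclust object (for plotting)
#'
#' @param x a `sip_dendrogram`.
#' @param ... unused.
#' @importFrom stats as.hclust
#' @export
as.hclust.sip_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = leaf_order(x$merge), labels = x$labels,
                 method = "ward.D2", dist.method = "correlation"),
            class = "hclust")
}

leaf_order <- function(merge) {
  rec <- function(code) {
    if (code < 0) -code else c(rec(merge[code, 1L]), rec(merge[code, 2L]))
  }
  rec(nrow(merge))
}

#' Leaf bipartitions of a dendrogram
#'
#' Returns, for each internal node, the set of leaf labels under it. Two
#' trees "share a node" when one contains the other's leaf set as a
#' cluster; this is the matching used for bootstrap probabilities.
#'
#' @param tree a `sip_dendrogram`.
#' @return list of character vectors (sorted leaf labels), one per merge.
#' @export
cluster_splits <- function(tree) {
  merge <- tree$merge
  labels <- tree$labels
  sets <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    get <- function(code) if (code < 0) labels[-code] else sets[[code]]
    sets[[k]] <- sort(c(get(merge[k, 1L]), get(merge[k, 2L])))
  }
  sets
}

#' Bootstrap probabilities for dendrogram nodes
#'
#' Resamples taxa (rows) with replacement `n_boot` times, rebuilds the
#' correlation-distance Ward dendrogram on each resample, and scores each
#' node of the observed tree by the percentage of bootstrap trees that
#' contain the same leaf set as a cluster (the plain bootstrap probability
#' shown in green at dendrogram nodes; no multiscale extrapolation is
#' applied). Reproducible: the RNG stream is private to this call and
#' derived from `seed`.
#'
#' A bootstrap resample that leaves some sample with zero variance has no
#' defined tree and counts as containing no nodes (this is rare for
#' realistic profiles and conservative for the support values).
#'
#' @param profile an `abundance_profile` (taxa x samples).
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed RNG seed.
#' @return a `sip_dendrogram` of the observed profile whose `bp` field
#'   holds one support percentage in [0, 100] per internal node.
#' @export
bootstrap_support <- function(profile, n_boot = 1000L, seed = 1L) {
  m <- unclass(profile)
  if (nrow(m) < 2L) sip_stop("bootstrap needs at least 2 taxa to resample")
  if (n_boot < 1L) sip_stop("n_boot must be >= 1")
  base_tree <- ward_linkage(correlation_distance(m))
  splits <- cluster_splits(base_tree)
  keys <- vapply(splits, paste, "", collapse = "\r")
  hits <- numeric(length(keys))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
      mb <- m[idx, , drop = FALSE]
      if (any(apply(mb, 2L, stats::sd) == 0)) next
      tb <- ward_linkage(correlation_distance(mb))
      kb <- vapply(cluster_splits(tb), paste, "", collapse = "\r")
      hits <- hits + (keys %in% kb)
    }
  })
  base_tree$bp <- 100 * hits / n_boot
  base_tree
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths are differences of merge heights (leaves sit at height
#' 0), and bootstrap percentages, when present, become internal node
#' labels, so the tree can be read by any standard phylogenetics tool.
#'
#' @param tree a `sip_dendrogram`.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string, terminated by `;`.
#' @export
to_newick <- function(tree, digits = 10) {
  labels <- tree$labels
  bad <- grepl("[](),:;'\"[ ]", labels)
  if (any(bad)) {
    sip_stop(sprintf("label '%s' contains characters not allowed in Newick",
                     labels[bad][1L]))
  }
  merge <- tree$merge
  height <- tree$height
  fmt <- function(x) sprintf("%.*g", digits, x)
  sub <- function(code, parent_h) {
    if (code < 0) {
      sprintf("%s:%s", labels[-code], fmt(parent_h))
    } else {
      h <- height[code]
      lab <- if (!is.null(tree$bp)) fmt(tree$bp[code]) else ""
      sprintf("(%s,%s)%s:%s", sub(merge[code, 1L], h), sub(merge[code, 2L], h),
              lab, fmt(parent_h - h))
    }
  }
  root <- nrow(merge)
  h <- height[root]
  lab <- if (!is.null(tree$bp)) fmt(tree$bp[root]) else ""
  sprintf("(%s,%s)%s;", sub(merge[root, 1L], h), sub(merge[root, 2L], h), lab)
}
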