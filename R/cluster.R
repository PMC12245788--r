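#' All-against-all fingerprint RMSD matrix
#'
#' Distance between two ligands' inverse docking fingerprints: the
#' root-mean-square deviation of their Z-scores over all N_t common
#' targets,
#' \deqn{R_{l,k} = \sqrt{\frac{1}{N_t}\sum_{i=1}^{N_t}(Z_l(i)-Z_k(i))^2}.}
#' This is the Euclidean distance between fingerprint vectors scaled by
#' 1/sqrt(N_t), hence a proper metric. It is computed over the full common
#' target set, not a curated top subset, for statistical robustness.
#'
#' @param fps A `dock_fingerprints` object with at least 2 ligands.
#' @return An object of class `fingerprint_dist`: list with `R` (symmetric
#'   numeric matrix, zero diagonal, ligand ids as dimnames) and
#'   `n_targets`.
#' @export
fingerprint_rmsd <- function(fps) {
  Z <- fps$Z
  if (nrow(Z) < 2L) stop("need at least 2 ligands", call. = FALSE)
  R <- as.matrix(stats::dist(Z, method = "euclidean")) / sqrt(ncol(Z))
  diag(R) <- 0
  structure(list(R = R, n_targets = ncol(Z)), class = "fingerprint_dist")
}

#' @export
print.fingerprint_dist <- function(x, ...) {
  cat(sprintf("Fingerprint RMSD matrix: %d ligands over %d targets\n",
              nrow(x$R), x$n_targets))
  cat(sprintf("  range %.3f - %.3f (off-diagonal)\n",
              min(x$R[upper.tri(x$R)]), max(x$R[upper.tri(x$R)])))
  invisible(x)
}

#' @export
as.matrix.fingerprint_dist <- function(x, ...) x$R

#' Ward agglomerative clustering of a fingerprint distance matrix
#'
#' Agglomerative hierarchical clustering with the Ward minimum-variance
#' criterion, run directly on a precomputed distance matrix via the
#' Lance-Williams recurrence on squared distances:
#' \deqn{d^2(k, i \cup j) = \frac{(n_i+n_k)d^2_{ki} + (n_j+n_k)d^2_{kj}
#'   - n_k d^2_{ij}}{n_i+n_j+n_k}.}
#' Entries are treated as Euclidean distances (the fingerprint RMSD is one,
#' up to the 1/sqrt(N_t) scale) and merge heights are reported on the
#' distance scale, so a dendrogram height reads directly as a fingerprint
#' RMSD. Two singletons therefore merge exactly at their distance.
#'
#' Ties between equal-distance merge candidates are broken by the
#' lexicographically smallest pair of cluster indices (leaves 1..n in input
#' order, then merge creation order), making the tree deterministic across
#' platforms. The returned object is `hclust`-compatible, so
#' [stats::cutree()], [stats::cophenetic()] and `plot()` all apply.
#'
#' @param R A `fingerprint_dist`, `dist`, or symmetric numeric matrix with
#'   dimnames.
#' @return An object of classes `dock_hclust` and `hclust` with the usual
#'   `merge`, `height`, `order`, `labels` components. Leaf display order
#'   puts the smaller subtree first, ties by alphabetically first leaf.
#' @export
ward_linkage <- function(R) {
  if (inherits(R, "fingerprint_dist")) R <- R$R
  if (inherits(R, "dist")) R <- as.matrix(R)
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  n <- nrow(R)
  if (n < 2L) stop("need at least 2 ligands to cluster", call. = FALSE)
  labels <- rownames(R)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (max(abs(R - t(R))) > 1e-12 || any(diag(R) != 0))
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)

  D2 <- R^2
  diag(D2) <- Inf
  active <- rep(TRUE, n + n - 1L)
  active[(n + 1L):(2L * n - 1L)] <- FALSE
  size <- c(rep(1L, n), integer(n - 1L))
  # slot i holds cluster with creation index i; D2 grows to cover new slots
  D2 <- rbind(cbind(D2, matrix(Inf, n, n - 1L)),
              matrix(Inf, n - 1L, 2L * n - 1L))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  # hclust merge codes: negative = leaf, positive = earlier merge row
  code <- c(-seq_len(n), seq_len(n - 1L))

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D2[act, act, drop = FALSE]
    best <- min(sub)
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    # deterministic tie-break: smallest (i, j) creation-index pair
    pick <- hit[order(act[hit[, 1]], act[hit[, 2]])[1L], ]
    i <- act[pick[1L]]
    j <- act[pick[2L]]

    new <- n + step
    ni <- size[i]; nj <- size[j]
    height[step] <- sqrt(best)
    a <- code[i]; b <- code[j]
    merge[step, ] <- c(min(a, b), max(a, b))  # leaves (negative) first
    others <- act[act != i & act != j]
    if (length(others) > 0L) {
      nk <- size[others]
      d2new <- ((nk + ni) * D2[i, others] + (nk + nj) * D2[j, others] -
                  nk * best) / (nk + ni + nj)
      D2[new, others] <- d2new
      D2[others, new] <- d2new
    }
    active[c(i, j)] <- FALSE
    active[new] <- TRUE
    size[new] <- ni + nj
  }

  tree <- structure(list(merge = merge, height = height,
                         order = integer(n), labels = labels,
                         method = "ward", dist.method = "fingerprint RMSD",
                         call = match.call()),
                    class = c("dock_hclust", "hclust"))
  tree$order <- .leaf_order(tree)
  tree
}

# display order: smaller subtree first, ties by alphabetically first leaf
.leaf_order <- function(tree) {
  n <- nrow(tree$merge) + 1L
  rec <- function(node) {
    if (node < 0L) {
      leaves <- -node
      first <- tree$labels[-node]
    } else {
      a <- rec(tree$merge[node, 1L])
      b <- rec(tree$merge[node, 2L])
      swap <- length(b$leaves) < length(a$leaves) ||
        (length(b$leaves) == length(a$leaves) && b$first < a$first)
      if (swap) { tmp <- a; a <- b; b <- tmp }
      leaves <- c(a$leaves, b$leaves)
      first <- a$first
    }
    list(leaves = leaves, first = first)
  }
  rec(n - 1L)$leaves
}

#' Cut a dendrogram into flat clusters
#'
#' Cuts the Ward tree either at a height (keeping together every pair
#' merged strictly below it) or into exactly `k` clusters. Exactly one of
#' `height` and `k` must be given.
#'
#' @param tree A `dock_hclust`/`hclust` object.
#' @param height Cut height on the distance (RMSD) scale.
#' @param k Desired number of clusters, between 1 and the number of leaves.
#' @return Integer vector of cluster labels, contiguous from 0, named by
#'   leaf label; label 0 is the cluster of the first leaf in label order,
#'   then by first appearance.
#' @export
cut_tree <- function(tree, height = NULL, k = NULL) {
  if (is.null(height) == is.null(k))
    stop("give exactly one of height or k", call. = FALSE)
  n <- length(tree$labels)
  if (!is.null(height)) k <- n - sum(tree$height < height)
  if (k < 1L || k > n) stop(sprintf("invalid k = %d", k), call. = FALSE)
  raw <- stats::cutree(tree, k = k)
  relabel <- match(raw, unique(raw)) - 1L
  names(relabel) <- tree$labels
  relabel
}

#' Export a dendrogram as a Newick tree
#'
#' Writes the merge tree as a rooted Newick string with branch lengths
#' derived from merge heights: each child branch spans (parent height -
#' child height), leaves sitting at height 0, so the tree is ultrametric
#' with root-to-leaf depth equal to the final merge height and the height
#' of the most recent common ancestor of two leaves equal to their
#' cophenetic distance.
#'
#' @param tree A `dock_hclust`/`hclust` object.
#' @param path Output file path, or `NULL` to only return the string.
#' @return The Newick string, invisibly when `path` is given.
#' @export
newick_export <- function(tree, path = NULL) {
  # child branch length = this node's height minus the child's own height
  rec <- function(node) {
    if (node < 0L) return(list(str = tree$labels[-node], h = 0))
    kids <- .order_children(tree, node)
    h <- tree$height[node]
    a <- rec(kids[1L]); b <- rec(kids[2L])
    list(str = sprintf("(%s:%.10g,%s:%.10g)", a$str, h - a$h, b$str, h - b$h),
         h = h)
  }
  root <- rec(nrow(tree$merge))
  out <- paste0(root$str, ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# children of an internal node in display order (same rule as .leaf_order)
.order_children <- function(tree, node) {
  kids <- tree$merge[node, ]
  info <- lapply(kids, function(kid) {
    if (kid < 0L) list(n = 1L, first = tree$labels[-kid])
    else {
      ord <- .subtree_leaves(tree, kid)
      list(n = length(ord), first = min(tree$labels[ord]))
    }
  })
  swap <- info[[2L]]$n < info[[1L]]$n ||
    (info[[2L]]$n == info[[1L]]$n && info[[2L]]$first < info[[1L]]$first)
  if (swap) rev(kids) else kids
}

.subtree_leaves <- function(tree, node) {
  if (node < 0L) return(-node)
  c(.subtree_leaves(tree, tree$merge[node, 1L]),
    .subtree_leaves(tree, tree$merge[node, 2L]))
}

#' Write distance and linkage tables as CSV
#'
#' @param x A `fingerprint_dist` (for `write_distance_csv`) or
#'   `dock_hclust` (for `write_linkage_csv`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(x, path) {
  R <- if (inherits(x, "fingerprint_dist")) x$R else as.matrix(x)
  df <- data.frame(ligand_id = rownames(R), R, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
write_linkage_csv <- function(x, path) {
  n <- nrow(x$merge) + 1L
  size <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- x$merge[i, ]
    size[i] <- sum(ifelse(kids < 0L, 1L, size[pmax(kids, 1L)]))
  }
  df <- data.frame(merge_a = x$merge[, 1L], merge_b = x$merge[, 2L],
                   height = x$height, size = size)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
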