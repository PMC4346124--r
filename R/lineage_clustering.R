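# Unsupervised hierarchical clustering of copy-number profiles:
# uncentred correlation distance + complete linkage, k-cuts, sibling
# queries, the gene-size model-selection sweep, and
# stable/intermediate/unstable lineage labelling.

#' Uncentred correlation distance between two vectors
#'
#' `d = 1 - sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))` — Pearson's
#' formula without mean-centring (the cosine of the raw vectors), range
#' [0, 2].  Positions where either vector is missing are dropped
#' (pairwise-complete); at least 2 complete pairs are required.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return Distance in [0, 2].
#' @export
uncentred_correlation_distance <- function(x, y) {
  abort_if(length(x) != length(y), "vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  abort_if(sum(ok) < 2, "fewer than 2 complete pairs")
  x <- x[ok]; y <- y[ok]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  abort_if(nx == 0 || ny == 0, "undefined distance: all-zero vector")
  1 - sum(x * y) / (nx * ny)
}

# Full pairwise uncentred-correlation distance matrix over the rows of `m`.
# Fast path (crossprod) when there are no missing values; pairwise-complete
# loop otherwise.  Errors name the offending item (pair).
uncentred_distance_matrix <- function(m) {
  n <- nrow(m)
  abort_if(n < 2, "need at least 2 items")
  labs <- rownames(m) %||% as.character(seq_len(n))
  if (!anyNA(m)) {
    norms <- sqrt(rowSums(m^2))
    zero <- which(norms == 0)
    abort_if(length(zero) > 0, "undefined distance: all-zero item ", labs[zero[1]])
    d <- 1 - (m %*% t(m)) / outer(norms, norms)
    diag(d) <- 0
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- tryCatch(
          uncentred_correlation_distance(m[i, ], m[j, ]),
          error = function(e) stop("distance undefined for items ", labs[i],
                                   " / ", labs[j], ": ", conditionMessage(e),
                                   call. = FALSE))
      }
    }
  }
  dimnames(d) <- list(labs, labs)
  d
}

#' Agglomerative complete-linkage clustering
#'
#' Builds the dendrogram by repeatedly merging the two clusters with the
#' smallest inter-cluster distance, where the inter-cluster distance is the
#' maximum pairwise item distance.  Ties are broken by the lexicographically
#' smallest pair of cluster representatives (a cluster is represented by the
#' smallest original item index it contains), making results order-stable.
#'
#' @param x a `gene_matrix` (clustered along `axis`), a symmetric distance
#'   matrix with dimnames, or a `dist` object.
#' @param axis when `x` is a `gene_matrix`: cluster "samples" (rows) or
#'   "genes" (columns).
#' @return An `hclust`-compatible object (classes `gc_hclust`, `hclust`)
#'   with `merge`, `height`, `order`, `labels`; usable with
#'   [stats::cutree()] and plotting.
#' @export
complete_linkage <- function(x, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  if (inherits(x, "gene_matrix")) {
    m <- if (axis == "samples") x$values else t(x$values)
    rownames(m) <- if (axis == "samples") x$samples else x$genes$gene_id
    d <- uncentred_distance_matrix(m)
  } else if (inherits(x, "dist")) {
    d <- as.matrix(x)
    if (is.null(rownames(d))) {
      dimnames(d) <- list(as.character(seq_len(nrow(d))),
                          as.character(seq_len(nrow(d))))
    }
  } else if (is.matrix(x)) {
    abort_if(nrow(x) != ncol(x) || any(abs(x - t(x)) > 1e-12),
             "distance matrix must be symmetric")
    d <- x
    if (is.null(rownames(d))) {
      dimnames(d) <- list(as.character(seq_len(nrow(d))),
                          as.character(seq_len(nrow(d))))
    }
  } else {
    stop("x must be a gene_matrix, matrix or dist", call. = FALSE)
  }
  abort_if(anyNA(d), "undefined pairwise distance for items ",
           paste(rownames(d)[which(is.na(d), arr.ind = TRUE)[1, ]],
                 collapse = " / "))
  n <- nrow(d)
  abort_if(n < 2, "need at least 2 items")
  labels <- rownames(d)

  # active cluster bookkeeping: node id (<0 leaf, >0 internal merge index),
  # representative = smallest original member index
  active <- seq_len(n)
  node_id <- -seq_len(n)
  rep_idx <- seq_len(n)
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best_i <- best_j <- 0L
    best_d <- Inf
    for (ii in seq_len(k - 1L)) {
      for (jj in seq(ii + 1L, k)) {
        dij <- D[ii, jj]
        if (dij < best_d) {
          best_d <- dij; best_i <- ii; best_j <- jj
        } else if (dij == best_d) {
          # tie-break: smallest (min rep, max rep) pair
          cur <- sort(c(rep_idx[best_i], rep_idx[best_j]))
          cand <- sort(c(rep_idx[ii], rep_idx[jj]))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best_i <- ii; best_j <- jj
          }
        }
      }
    }
    # record merge; put the cluster with the smaller representative first
    a <- best_i; b <- best_j
    if (rep_idx[b] < rep_idx[a]) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(node_id[a], node_id[b])
    height[step] <- best_d

    # complete linkage (Lance-Williams): new distance = max of the two
    new_members <- c(members[[a]], members[[b]])
    keep <- setdiff(seq_len(k), c(a, b))
    new_D <- matrix(0, length(keep) + 1L, length(keep) + 1L)
    if (length(keep) > 0) {
      new_D[seq_along(keep), seq_along(keep)] <- D[keep, keep, drop = FALSE]
      new_D[length(keep) + 1L, seq_along(keep)] <-
        pmax(D[a, keep], D[b, keep])
      new_D[seq_along(keep), length(keep) + 1L] <-
        new_D[length(keep) + 1L, seq_along(keep)]
    }
    D <- new_D
    node_id <- c(node_id[keep], step)
    rep_idx <- c(rep_idx[keep], min(rep_idx[a], rep_idx[b]))
    members <- c(members[keep], list(new_members))
    active <- seq_along(node_id)
  }

  # leaf order by in-order traversal of the merge tree
  leaf_order <- function(node) {
    if (node < 0) return(-node)
    c(leaf_order(merge[node, 1]), leaf_order(merge[node, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = leaf_order(n - 1L), labels = labels,
                 method = "complete",
                 dist.method = "uncentred_correlation",
                 call = match.call()),
            class = c("gc_hclust", "hclust"))
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges (complete-linkage heights are monotone,
#' so this equals [stats::cutree()] at k groups).
#'
#' @param tree an `hclust`-compatible dendrogram.
#' @param k number of clusters, `1 <= k <= n`.
#' @return Named integer vector mapping each leaf label to a cluster id.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  abort_if(!is.numeric(k) || length(k) != 1 || k < 1 || k > n,
           "k out of range [1, ", n, "]")
  stats::cutree(tree, k = as.integer(k))
}

# canonical form of a partition for set-equality comparison
partition_sets <- function(part) {
  s <- split(names(part), part)
  s <- lapply(s, sort)
  unname(s[order(vapply(s, `[`, "", 1))])
}

#' Are two leaves siblings in a dendrogram?
#'
#' TRUE iff `a` and `b` merge with each other before either merges with any
#' other item, i.e. some merge joins exactly the two singletons.  Invariant
#' under any left/right flip of the drawn dendrogram.
#'
#' @param tree an `hclust`-compatible dendrogram.
#' @param a,b leaf labels.
#' @return Logical.
#' @export
are_siblings <- function(tree, a, b) {
  ia <- match(a, tree$labels)
  ib <- match(b, tree$labels)
  abort_if(is.na(ia), "unknown leaf: ", a)
  abort_if(is.na(ib), "unknown leaf: ", b)
  if (ia == ib) return(FALSE)
  any((tree$merge[, 1] == -ia & tree$merge[, 2] == -ib) |
        (tree$merge[, 1] == -ib & tree$merge[, 2] == -ia))
}

#' Sample pairs from cohort metadata
#'
#' Same-tumour pairs are the two parts (mucosal + deep) of one lesion;
#' concurrent pairs are the mucosal samples of two different lesions of one
#' patient.
#'
#' @param metadata cohort metadata (sample_id, patient_id, lesion_id,
#'   part).
#' @return List with `same_tumour` and `concurrent`, each a list of
#'   2-element sample-id vectors.
#' @export
sample_pairs_from_metadata <- function(metadata) {
  same <- list()
  for (les in unique(metadata$lesion_id)) {
    ids <- metadata$sample_id[metadata$lesion_id == les]
    if (length(ids) == 2) same[[length(same) + 1L]] <- sort(ids)
  }
  conc <- list()
  muc <- metadata[metadata$part == "mucosal", , drop = FALSE]
  for (pat in unique(muc$patient_id)) {
    ids <- muc$sample_id[muc$patient_id == pat]
    if (length(ids) == 2) conc[[length(conc) + 1L]] <- sort(ids)
  }
  list(same_tumour = same, concurrent = conc)
}

#' Are two leaves adjacent in the drawn leaf order?
#'
#' The looser neighbouring criterion: TRUE iff `a` and `b` occupy
#' consecutive positions in the dendrogram's leaf ordering.  Unlike
#' [are_siblings()], this depends on the drawn left/right orientation of
#' the merges (the package's in-order traversal).
#'
#' @param tree an `hclust`-compatible dendrogram.
#' @param a,b leaf labels.
#' @return Logical.
#' @export
adjacent_in_leaf_order <- function(tree, a, b) {
  pos <- match(c(a, b), tree$labels[tree$order])
  abort_if(anyNA(pos), "unknown leaf: ", c(a, b)[is.na(pos)][1])
  abs(pos[1] - pos[2]) == 1
}

count_adjacent <- function(tree, pairs, adjacency = "sibling") {
  if (length(pairs) == 0) return(c(adjacent = 0L, total = 0L))
  test <- if (adjacency == "sibling") are_siblings else adjacent_in_leaf_order
  present <- vapply(pairs, function(p) all(p %in% tree$labels), TRUE)
  adj <- vapply(pairs[present], function(p) test(tree, p[1], p[2]), TRUE)
  c(adjacent = sum(adj), total = sum(present))
}

#' Gene-size model-selection sweep
#'
#' Re-clusters the cohort at decreasing minimum-probe-count thresholds
#' (larger genes first) and evaluates, at each threshold, (1) how many
#' same-tumour and concurrent pairs sit at neighbouring (sibling) positions
#' in the dendrogram and (2) the k-cluster partition.  The selected
#' threshold is the largest one whose partition is identical (as a set
#' partition) to the next smaller threshold's partition and whose
#' same-tumour-pair adjacency is maximal across thresholds — larger genes
#' average more probes and cancel more noise, so the largest threshold that
#' still reproduces both standards is preferred.
#'
#' @param matrix a `gene_matrix` (with per-gene probe counts).
#' @param pairs pair list as from [sample_pairs_from_metadata()].
#' @param thresholds minimum probe counts, sorted descending (default
#'   `c(10, 6, 4, 3, 2)`).
#' @param k number of clusters for the partition standard (default 3).
#' @param adjacency "sibling" (default; flip-invariant) or "leaf_order"
#'   (consecutive positions in the drawn leaf ordering, the looser
#'   criterion).
#' @return A `sweep_result`: list with `table` (threshold, n_genes,
#'   adjacency counts, partition_equal_next), `partitions`, `trees` and
#'   `selected` (the winning threshold, or `NA` if no threshold meets both
#'   standards).
#' @export
sweep_gene_size <- function(matrix, pairs, thresholds = c(10, 6, 4, 3, 2), k = 3,
                            adjacency = c("sibling", "leaf_order")) {
  stopifnot(inherits(matrix, "gene_matrix"))
  adjacency <- match.arg(adjacency)
  thresholds <- sort(unique(as.integer(thresholds)), decreasing = TRUE)
  rows <- list(); partitions <- list(); trees <- list()
  for (t in thresholds) {
    keep <- matrix$genes$gene_id[matrix$genes$probe_count >= t]
    if (length(keep) < 2) {
      warning("threshold >=", t, " leaves <2 genes; skipped", call. = FALSE)
      next
    }
    gm <- subset_genes(matrix, keep)
    tree <- complete_linkage(gm, axis = "samples")
    part <- cut_tree(tree, k)
    st <- count_adjacent(tree, pairs$same_tumour, adjacency)
    co <- count_adjacent(tree, pairs$concurrent, adjacency)
    key <- as.character(t)
    partitions[[key]] <- part
    trees[[key]] <- tree
    rows[[key]] <- data.frame(
      min_probes = t, n_genes = length(keep),
      same_tumour_adjacent = st["adjacent"], same_tumour_total = st["total"],
      concurrent_adjacent = co["adjacent"], concurrent_total = co["total"],
      stringsAsFactors = FALSE)
  }
  abort_if(length(rows) == 0, "no threshold leaves >=2 genes")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  used <- tab$min_probes
  eq_next <- rep(NA, nrow(tab))
  for (i in seq_len(nrow(tab) - 1)) {
    eq_next[i] <- identical(partition_sets(partitions[[as.character(used[i])]]),
                            partition_sets(partitions[[as.character(used[i + 1])]]))
  }
  tab$partition_equal_next <- eq_next
  max_adj <- max(tab$same_tumour_adjacent)
  ok <- !is.na(eq_next) & eq_next & tab$same_tumour_adjacent == max_adj
  selected <- if (any(ok)) used[which(ok)[1]] else NA_integer_
  structure(list(table = tab, partitions = partitions, trees = trees,
                 selected = selected, k = k),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  print(x$table)
  cat("selected min_probes threshold:", x$selected, "\n")
  invisible(x)
}

#' Label k=3 clusters as stable / intermediate / unstable
#'
#' In `auto` mode the cluster with the lowest mean CNA burden is labelled
#' stable; of the remaining two, the larger is unstable (the unstable
#' lineage dominates invasive disease) and the other intermediate.  Exact
#' ties abort with a request for manual mode.  In `manual` mode a complete
#' cluster -> label mapping must be supplied.
#'
#' @param partition named cluster vector from [cut_tree()] at k = 3.
#' @param burdens output of [cna_burden()] covering all partition samples.
#' @param mode "auto" or "manual".
#' @param manual_map named vector mapping each cluster id (as character) to
#'   a label, required in manual mode.
#' @return A `lineage_assignment`: list with `assignments` (sample_id,
#'   cluster, lineage), `clusters` (per-cluster n, mean burden count and
#'   fraction, label) and `mode`.
#' @export
label_lineages <- function(partition, burdens, mode = c("auto", "manual"),
                           manual_map = NULL) {
  mode <- match.arg(mode)
  cl_ids <- sort(unique(partition))
  abort_if(length(cl_ids) != 3, "need a k=3 partition with 3 non-empty clusters")
  m <- match(names(partition), burdens$sample_id)
  abort_if(any(is.na(m)), "burden missing for sample(s): ",
           paste(utils::head(names(partition)[is.na(m)], 5), collapse = ", "))
  mean_count <- vapply(cl_ids, function(cl)
    mean(burdens$count[m][partition == cl]), 0)
  mean_frac <- vapply(cl_ids, function(cl)
    mean(burdens$fraction[m][partition == cl], na.rm = TRUE), 0)
  sizes <- vapply(cl_ids, function(cl) sum(partition == cl), 0L)

  if (mode == "auto") {
    min_b <- min(mean_count)
    abort_if(sum(mean_count == min_b) > 1,
             "tie in lowest mean CNA burden; use manual mode")
    labels <- rep(NA_character_, 3)
    stable_i <- which.min(mean_count)
    labels[stable_i] <- "stable"
    rest <- setdiff(seq_len(3), stable_i)
    abort_if(sizes[rest[1]] == sizes[rest[2]],
             "tie in size of the remaining clusters; use manual mode")
    unstable_i <- rest[which.max(sizes[rest])]
    labels[unstable_i] <- "unstable"
    labels[setdiff(rest, unstable_i)] <- "intermediate"
  } else {
    abort_if(is.null(manual_map), "manual mode requires manual_map")
    mm <- manual_map[as.character(cl_ids)]
    abort_if(any(is.na(mm)), "manual_map must cover every cluster")
    abort_if(!setequal(mm, c("stable", "intermediate", "unstable")),
             "manual_map must use each of stable/intermediate/unstable once")
    labels <- unname(mm)
  }
  assignments <- data.frame(
    sample_id = names(partition),
    cluster = unname(partition),
    lineage = labels[match(partition, cl_ids)],
    row.names = NULL, stringsAsFactors = FALSE)
  clusters <- data.frame(cluster = cl_ids, n = sizes,
                         mean_count = mean_count, mean_fraction = mean_frac,
                         label = labels, row.names = NULL,
                         stringsAsFactors = FALSE)
  structure(list(assignments = assignments, clusters = clusters, mode = mode),
            class = "lineage_assignment")
}

#' @export
print.lineage_assignment <- function(x, ...) {
  print(x$clusters)
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper over [mclust::adjustedRandIndex()] keeping the package's
#' cluster-recovery checks in one place.
#'
#' @param a,b two labelings of the same samples (named vectors are matched
#'   by name when both are named).
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    abort_if(!setequal(names(a), names(b)), "labelings cover different samples")
    b <- b[names(a)]
  }
  abort_if(length(a) != length(b), "labelings differ in length")
  mclust::adjustedRandIndex(a, b)
}
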