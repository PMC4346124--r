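# Independent oracles used by the tests.  These deliberately share no code
# with the package: the agglomeration oracle re-derives every inter-cluster
# distance from the original matrix at each step (O(n^3)), and the Fisher
# oracle enumerates the hypergeometric support directly.

# Naive complete-linkage re-agglomeration: returns the cophenetic matrix,
# the list of sibling pairs (merges of two singletons, by item index) and
# the membership vector at every cluster count k.
naive_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), function(i) i)
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  sibs <- list()
  partitions <- vector("list", n)
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1) {
    k <- length(clusters)
    bi <- bj <- NA
    bd <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        dm <- max(d[clusters[[i]], clusters[[j]]])
        if (dm < bd) {
          bd <- dm; bi <- i; bj <- j
        }
      }
    }
    if (length(clusters[[bi]]) == 1 && length(clusters[[bj]]) == 1) {
      sibs[[length(sibs) + 1]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    }
    coph[clusters[[bi]], clusters[[bj]]] <- bd
    coph[clusters[[bj]], clusters[[bi]]] <- bd
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    memb <- integer(n)
    for (ci in seq_along(clusters)) memb[clusters[[ci]]] <- ci
    partitions[[k - 1]] <- memb
  }
  list(coph = coph, siblings = sibs, partitions = partitions)
}

# canonical set-partition form of a membership vector over labelled items
as_set_partition <- function(memb, labels) {
  s <- split(labels, memb)
  s <- lapply(s, sort)
  unname(s[order(vapply(s, `[`, "", 1))])
}

random_distance_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[lower.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  d
}

# Two-sided Fisher by exhaustive hypergeometric enumeration (probability
# ordering, with the customary 1e-7 relative tie tolerance).
fisher_enumeration <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  k <- max(0, n1 - m2):min(n1, m1)
  pk <- dhyper(k, m1, m2, n1)
  sum(pk[pk <= dhyper(a, m1, m2, n1) * (1 + 1e-7)])
}

# Engineered gene matrix for the gene-size sweep: the 2 largest genes
# (>= 6 probes) carry a misleading signal, the mid-size (4-5 probes) and
# small (3 probes) genes agree on the true 3-pair structure, so the
# partition changes between thresholds 6 and 4 but not between 4 and 3.
sweep_fixture_matrix <- function() {
  samples <- paste0("s", 1:6)
  sig <- function(hot, n_genes, hi = 1, lo = 0.05) {
    v <- matrix(lo, 6, n_genes)
    v[hot, ] <- hi
    v
  }
  # misleading big genes: pair s2 with s3 and isolate s1
  big <- cbind(c(1, 0.1, 0.1, 0.5, 0.5, 0.5), c(0.1, 1, 1, 0.5, 0.5, 0.5))
  mid <- cbind(sig(1:2, 3), sig(3:4, 3), sig(5:6, 2))
  small <- cbind(sig(1:2, 2), sig(3:4, 2), sig(5:6, 1))
  vals <- cbind(big, mid, small)
  # deterministic jitter to break exact ties
  vals <- vals + matrix(seq_len(length(vals)) %% 7, nrow = 6) * 1e-4
  colnames(vals) <- sprintf("g%02d", seq_len(ncol(vals)))
  rownames(vals) <- samples
  genes <- data.frame(gene_id = colnames(vals), chrom = "chr1",
                      start = (seq_len(ncol(vals)) - 1L) * 1000L,
                      end = (seq_len(ncol(vals)) - 1L) * 1000L + 500L,
                      probe_count = c(7L, 6L, rep(5L, 4), rep(4L, 4), rep(3L, 5)),
                      stringsAsFactors = FALSE)
  gene_matrix(vals, genes)
}

with_seed_shuffle <- function(df) {
  set.seed(123)
  df[sample(nrow(df)), , drop = FALSE]
}

# small default-noise cohort used by several tests
small_cohort <- function(seed, n = c(stable = 5, intermediate = 5, unstable = 5),
                         probe_sd = 0.3, same_tumour_pairs = 2,
                         concurrent_pairs = 1,
                         genes_per_chromosome = 40) {
  cc <- cohort_config(
    lineages = n, same_tumour_pairs = same_tumour_pairs,
    concurrent_pairs = concurrent_pairs,
    noise = noise_model(probe_sd = probe_sd),
    genome = build_genome(genes_per_chromosome = genes_per_chromosome,
                          seed = seed + 1000L),
    seed = seed)
  simulate_cohort(cc)
}
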