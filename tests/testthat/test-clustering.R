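# Uncentred correlation distance, complete-linkage agglomeration, cuts,
# sibling queries, the gene-size sweep and lineage labelling.

test_that("uncentred correlation distance follows the closed form", {
  expect_equal(uncentred_correlation_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(uncentred_correlation_distance(c(1, -1), c(-1, 1)), 2)
  expect_equal(uncentred_correlation_distance(c(1, 2), c(2, 1)), 0.2)
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(10); y <- rnorm(10); a <- runif(1, 0.1, 10)
    d <- uncentred_correlation_distance(x, y)
    expect_equal(d, 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2)))
    expect_equal(uncentred_correlation_distance(y, x), d)       # symmetry
    expect_equal(uncentred_correlation_distance(a * x, y), d)   # scale invariance
    expect_equal(uncentred_correlation_distance(x, x), 0)
    expect_gte(d, 0); expect_lte(d, 2)
  }
  expect_error(uncentred_correlation_distance(c(0, 0), c(1, 2)), "all-zero")
  expect_error(uncentred_correlation_distance(c(1, NA, NA), c(NA, 1, 2)),
               "fewer than 2 complete pairs")
})

test_that("pairwise-complete handling inside the distance matches manual removal", {
  x <- c(1, 2, NA, 4, 5)
  y <- c(2, NA, 3, 8, 10)
  ok <- !is.na(x) & !is.na(y)
  expect_equal(uncentred_correlation_distance(x, y),
               uncentred_correlation_distance(x[ok], y[ok]))
})

test_that("the worked 4-item example agglomerates as derived by hand", {
  d <- matrix(c(0, .1, .5, .9,
                .1, 0, .6, .8,
                .5, .6, 0, .2,
                .9, .8, .2, 0), 4, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  tree <- complete_linkage(d)
  expect_equal(tree$height, c(0.1, 0.2, 0.9))
  expect_identical(tree$merge[1, ], c(-1L, -2L))
  expect_identical(tree$merge[2, ], c(-3L, -4L))
  expect_identical(tree$merge[3, ], c(1L, 2L))
  p2 <- cut_tree(tree, 2)
  expect_identical(as_set_partition(p2, names(p2)),
                   list(c("s1", "s2"), c("s3", "s4")))
  expect_true(are_siblings(tree, "s1", "s2"))
  expect_false(are_siblings(tree, "s2", "s3"))
  expect_error(are_siblings(tree, "s1", "zz"), "unknown leaf")
  # 2-leaf tree: the pair are siblings, merged at their distance
  t2 <- complete_linkage(d[1:2, 1:2])
  expect_equal(t2$height, 0.1)
  expect_true(are_siblings(t2, "s1", "s2"))
})

test_that("trees match the naive re-agglomeration oracle on random instances", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    d <- random_distance_matrix(n)
    tree <- complete_linkage(d)
    oracle <- naive_complete_linkage(d)
    expect_equal(as.matrix(stats::cophenetic(tree))[rownames(d), colnames(d)],
                 oracle$coph, tolerance = 1e-12)
    for (k in seq_len(n)) {
      expect_identical(as_set_partition(cut_tree(tree, k), tree$labels),
                       as_set_partition(oracle$partitions[[k]], rownames(d)))
    }
    sib_oracle <- oracle$siblings
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        in_oracle <- any(vapply(sib_oracle, function(p) identical(p, c(i, j)), TRUE))
        expect_identical(are_siblings(tree, rownames(d)[i], rownames(d)[j]),
                         in_oracle)
      }
    }
  }
})

test_that("agglomeration also agrees with stats::hclust", {
  set.seed(13)
  for (rep in 1:20) {
    d <- random_distance_matrix(sample(4:10, 1))
    mine <- complete_linkage(d)
    ref <- stats::hclust(as.dist(d), method = "complete")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-12)
    expect_equal(as.matrix(stats::cophenetic(mine))[rownames(d), colnames(d)],
                 as.matrix(stats::cophenetic(ref))[rownames(d), colnames(d)],
                 tolerance = 1e-12)
  }
})

test_that("tree heights are monotone and cuts respect bounds", {
  set.seed(3)
  d <- random_distance_matrix(8)
  tree <- complete_linkage(d)
  expect_true(all(diff(tree$height) >= 0))
  expect_equal(unname(cut_tree(tree, 1)), rep(1L, 8))
  expect_equal(sort(unname(cut_tree(tree, 8))), 1:8)
  expect_error(cut_tree(tree, 0), "out of range")
  expect_error(cut_tree(tree, 9), "out of range")
})

test_that("partitions are invariant to sample order", {
  coh <- small_cohort(seed = 31, n = c(stable = 4, intermediate = 4, unstable = 4),
                      same_tumour_pairs = 0, concurrent_pairs = 0)
  gm <- suppressMessages(average_probes_to_genes(coh$probes, coh$genome$genes))
  tree1 <- complete_linkage(gm, "samples")
  set.seed(9)
  perm <- sample(length(gm$samples))
  gm_perm <- gene_matrix(gm$values[perm, , drop = FALSE], gm$genes)
  tree2 <- complete_linkage(gm_perm, "samples")
  p1 <- cut_tree(tree1, 3); p2 <- cut_tree(tree2, 3)
  expect_identical(as_set_partition(p1, names(p1)), as_set_partition(p2, names(p2)))
})

test_that("sibling relation is invariant under left/right flips", {
  set.seed(21)
  d <- random_distance_matrix(6)
  tree <- complete_linkage(d)
  flipped <- tree
  flipped$merge <- tree$merge[, 2:1]
  for (i in 1:5) {
    for (j in seq(i + 1, 6)) {
      expect_identical(are_siblings(tree, paste0("s", i), paste0("s", j)),
                       are_siblings(flipped, paste0("s", i), paste0("s", j)))
    }
  }
})

test_that("leaf-order adjacency is implied by siblinghood but looser", {
  d <- matrix(c(0, .1, .5, .9,
                .1, 0, .6, .8,
                .5, .6, 0, .2,
                .9, .8, .2, 0), 4, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  tree <- complete_linkage(d)
  # siblings are always leaf-order adjacent
  expect_true(adjacent_in_leaf_order(tree, "s1", "s2"))
  expect_true(adjacent_in_leaf_order(tree, "s3", "s4"))
  # s2 and s3 are not siblings, yet sit next to each other in the drawing
  expect_false(are_siblings(tree, "s2", "s3"))
  expect_true(adjacent_in_leaf_order(tree, "s2", "s3"))
  expect_false(adjacent_in_leaf_order(tree, "s1", "s4"))
  expect_error(adjacent_in_leaf_order(tree, "s1", "zz"), "unknown leaf")
  # the sweep's leaf-order mode counts at least as many adjacent pairs
  gm <- sweep_fixture_matrix()
  pairs <- list(same_tumour = list(c("s1", "s2"), c("s2", "s3")), concurrent = list())
  sw_sib <- sweep_gene_size(gm, pairs, thresholds = c(4, 3), k = 3)
  sw_leaf <- sweep_gene_size(gm, pairs, thresholds = c(4, 3), k = 3,
                             adjacency = "leaf_order")
  expect_true(all(sw_leaf$table$same_tumour_adjacent >=
                    sw_sib$table$same_tumour_adjacent))
})

test_that("gene-size sweep selects the largest threshold meeting both standards", {
  gm <- sweep_fixture_matrix()
  pairs <- list(same_tumour = list(c("s1", "s2")), concurrent = list())
  sw <- sweep_gene_size(gm, pairs, thresholds = c(6, 4, 3), k = 3)
  expect_equal(sw$selected, 4)
  expect_false(sw$table$partition_equal_next[1])
  expect_true(sw$table$partition_equal_next[2])
  expect_equal(sw$table$same_tumour_adjacent, c(0, 1, 1))
  # gene counts non-increasing in the threshold
  expect_true(all(diff(sw$table$n_genes) >= 0))
  # a threshold that strips all genes is skipped with a warning
  expect_warning(sweep_gene_size(gm, pairs, thresholds = c(20, 4, 3), k = 3),
                 "skipped")
})

test_that("same-tumour pairs with identical profiles are siblings at every threshold", {
  cc <- cohort_config(lineages = c(stable = 3, intermediate = 3, unstable = 3),
                      same_tumour_pairs = 2, concurrent_pairs = 0,
                      noise = noise_model(probe_sd = 0, part_divergence = 0,
                                          concurrent_divergence = 0.05),
                      genome = build_genome(genes_per_chromosome = 30, seed = 41),
                      seed = 5)
  coh <- simulate_cohort(cc)
  gm <- suppressMessages(average_probes_to_genes(coh$probes, coh$genome$genes))
  pairs <- sample_pairs_from_metadata(coh$metadata)
  sw <- sweep_gene_size(gm, pairs, thresholds = c(10, 6, 4, 3, 2), k = 3)
  expect_true(all(sw$table$same_tumour_adjacent == sw$table$same_tumour_total))
})

test_that("lineage labelling follows the burden/size rule", {
  part <- setNames(rep(1:3, c(11, 28, 4)), sprintf("t%02d", 1:43))
  burden <- data.frame(sample_id = names(part),
                       count = rep(c(9370, 15262, 15727), c(11, 28, 4)),
                       fraction = rep(c(9370, 15262, 15727), c(11, 28, 4)) / 30098)
  la <- label_lineages(part, burden)
  lab <- setNames(la$clusters$label, la$clusters$cluster)
  expect_equal(unname(lab[c("1", "2", "3")]),
               c("stable", "unstable", "intermediate"))
  expect_equal(la$clusters$n[la$clusters$label == "unstable"], 28)

  # plain rule application: lowest burden stable, larger of the rest unstable
  part2 <- setNames(rep(1:3, c(5, 4, 3)), letters[1:12])
  burden2 <- data.frame(sample_id = names(part2),
                        count = rep(c(0, 100, 200), c(5, 4, 3)),
                        fraction = rep(c(0, .1, .2), c(5, 4, 3)))
  la2 <- label_lineages(part2, burden2)
  lab2 <- setNames(la2$clusters$label, la2$clusters$cluster)
  expect_equal(unname(lab2[c("1", "2", "3")]),
               c("stable", "unstable", "intermediate"))

  # equal burdens: auto mode refuses
  burden3 <- burden2; burden3$count <- 7
  expect_error(label_lineages(part2, burden3), "manual")

  # manual mode must cover all clusters with the three labels
  mm <- c("1" = "unstable", "2" = "stable", "3" = "intermediate")
  la3 <- label_lineages(part2, burden2, mode = "manual", manual_map = mm)
  expect_equal(la3$assignments$lineage[1], "unstable")
  expect_error(label_lineages(part2, burden2, mode = "manual",
                              manual_map = mm[1:2]), "cover")
})

test_that("noisy default cohorts recover the true lineages", {
  coh <- small_cohort(seed = 55, n = c(stable = 7, intermediate = 4, unstable = 9),
                      same_tumour_pairs = 0, concurrent_pairs = 0,
                      genes_per_chromosome = 60)
  gm <- suppressMessages(average_probes_to_genes(coh$probes, coh$genome$genes))
  gmf <- subset_genes(gm, gm$genes$gene_id[gm$genes$probe_count >= 4])
  part <- cut_tree(complete_linkage(gmf, "samples"), 3)
  truth <- setNames(coh$metadata$truth_lineage, coh$metadata$sample_id)
  expect_gte(adjusted_rand_index(part, truth[names(part)]), 0.9)
  # labels follow burden ordering
  la <- label_lineages(part, cna_burden(call_cna(gm)))
  cl <- la$clusters
  expect_lt(cl$mean_count[cl$label == "stable"],
            min(cl$mean_count[cl$label != "stable"]))
})
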