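# Probe-to-gene averaging, CNA calling, burden, group frequencies and arm
# penetrance.

make_probe_row <- function(sample, probe, chrom, start, lr) {
  data.frame(sample_id = sample, probe_id = probe, chrom = chrom,
             start = start, end = start + 60L, log2_ratio = lr,
             stringsAsFactors = FALSE)
}

test_that("probe averaging uses midpoint containment and arithmetic means", {
  ann <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                    start = c(0L, 1000L), end = c(500L, 1500L),
                    stringsAsFactors = FALSE)
  probes <- rbind(
    make_probe_row("S1", "P1", "chr1", 100L, 0.2),
    make_probe_row("S1", "P2", "chr1", 300L, 0.4),
    make_probe_row("S1", "P3", "chr1", 700L, 9.9),   # midpoint in no gene
    make_probe_row("S1", "P4", "chr1", 1100L, -1.0))
  expect_message(gm <- average_probes_to_genes(probes, ann), "1 probe")
  expect_equal(unname(gm$values["S1", c("G1", "G2")]), c(0.3, -1.0))
  expect_equal(gm$genes$probe_count, c(2L, 1L))

  # a probe straddling the gene edge counts iff its midpoint is inside:
  # start 480 -> midpoint 510, outside [0,500)
  straddle <- rbind(probes, make_probe_row("S1", "P5", "chr1", 480L, 5))
  gm2 <- suppressMessages(average_probes_to_genes(straddle, ann))
  expect_equal(unname(gm2$values["S1", "G1"]), 0.3)
  # start 440 -> midpoint 470, inside
  inside <- rbind(probes, make_probe_row("S1", "P6", "chr1", 440L, 0.6))
  gm3 <- suppressMessages(average_probes_to_genes(inside, ann))
  expect_equal(unname(gm3$values["S1", "G1"]), mean(c(0.2, 0.4, 0.6)))

  expect_error(average_probes_to_genes(make_probe_row("S1", "P1", "chr9", 5L, 1), ann),
               "no probe overlaps any gene")
})

test_that("averaging equals a brute-force per-gene mean and ignores row order", {
  coh <- small_cohort(seed = 21, n = c(stable = 3, unstable = 3),
                      same_tumour_pairs = 0, concurrent_pairs = 0)
  gm <- suppressMessages(average_probes_to_genes(coh$probes, coh$genome$genes))
  # brute force: loop over genes and samples
  ann <- coh$genome$genes
  for (gid in sample(ann$gene_id, 50)) {
    row <- ann[ann$gene_id == gid, ]
    for (sid in gm$samples) {
      sub <- coh$probes[coh$probes$sample_id == sid, ]
      mid <- (sub$start + sub$end) %/% 2
      inside <- sub$chrom == row$chrom & mid >= row$start & mid < row$end
      expect_equal(unname(gm$values[sid, gid]),
                   mean(sub$log2_ratio[inside], na.rm = TRUE),
                   info = paste(gid, sid))
    }
  }
  # permutation invariance in probe row order
  perm <- with_seed_shuffle(coh$probes)
  gm2 <- suppressMessages(average_probes_to_genes(perm, coh$genome$genes))
  expect_equal(gm2$values[gm$samples, gm$genes$gene_id], gm$values)
})

test_that("full-overlap assignment is stricter than midpoint assignment", {
  ann <- data.frame(gene_id = "G1", chrom = "chr1", start = 0L, end = 500L,
                    stringsAsFactors = FALSE)
  probes <- rbind(
    make_probe_row("S1", "P1", "chr1", 100L, 0.2),   # fully inside
    make_probe_row("S1", "P2", "chr1", 460L, 0.8))   # midpoint 490 in, end 520 out
  gm_mid <- average_probes_to_genes(probes, ann)
  expect_equal(unname(gm_mid$values["S1", "G1"]), 0.5)
  gm_full <- suppressMessages(average_probes_to_genes(probes, ann,
                                                      assignment = "full_overlap"))
  expect_equal(unname(gm_full$values["S1", "G1"]), 0.2)
  expect_equal(gm_full$genes$probe_count, 1L)
})

test_that("missing probes are excluded from gene means, not imputed", {
  ann <- data.frame(gene_id = "G1", chrom = "chr1", start = 0L, end = 1000L,
                    stringsAsFactors = FALSE)
  probes <- rbind(make_probe_row("S1", "P1", "chr1", 100L, 0.4),
                  make_probe_row("S1", "P2", "chr1", 200L, NA_real_),
                  make_probe_row("S2", "P1", "chr1", 100L, NA_real_),
                  make_probe_row("S2", "P2", "chr1", 200L, NA_real_))
  gm <- average_probes_to_genes(probes, ann)
  expect_equal(unname(gm$values["S1", "G1"]), 0.4)
  expect_true(is.na(gm$values["S2", "G1"]))  # all probes missing -> missing
})

test_that("CNA calls honour the +/-0.3219 thresholds with strict comparison", {
  vals <- matrix(c(0.40, 0.3219, 0.0, -1.0, -0.3219, 0.322),
                 nrow = 1, dimnames = list("S1", paste0("g", 1:6)))
  calls <- call_cna(gene_matrix(vals))
  expect_equal(unname(calls$state["S1", ]), c(1L, 0L, 0L, -1L, 0L, 1L))
  # inclusive mode calls the boundary values
  calls_inc <- call_cna(gene_matrix(vals), cna_call_params(strict = FALSE))
  expect_equal(unname(calls_inc$state["S1", c("g2", "g5")]), c(1L, -1L))
  # monotone: raising a value never moves gain->neutral or neutral->loss
  v2 <- vals + 0.1
  calls2 <- call_cna(gene_matrix(v2, gene_matrix(vals)$genes))
  expect_true(all(calls2$state >= calls$state))
  # missing stays missing
  vals[1, 1] <- NA
  expect_true(is.na(call_cna(gene_matrix(vals))$state[1, 1]))
  expect_error(cna_call_params(gain_threshold = -1), "loss_threshold < 0 < gain")
})

test_that("burden counts and fractions match a brute-force recount", {
  coh <- small_cohort(seed = 22, n = c(stable = 3, unstable = 3),
                      same_tumour_pairs = 0, concurrent_pairs = 0)
  gm <- suppressMessages(average_probes_to_genes(coh$probes, coh$genome$genes))
  calls <- call_cna(gm)
  b <- cna_burden(calls)
  for (i in seq_len(nrow(b))) {
    st <- calls$state[b$sample_id[i], ]
    expect_equal(b$count[i], sum(st == 1L, na.rm = TRUE) + sum(st == -1L, na.rm = TRUE))
    expect_equal(b$fraction[i], b$count[i] / sum(!is.na(st)))
  }
  # partition identity: gains + losses + neutrals + missing = genes
  expect_true(all(rowSums(calls$state == 1L, na.rm = TRUE) +
                    rowSums(calls$state == -1L, na.rm = TRUE) +
                    rowSums(calls$state == 0L, na.rm = TRUE) +
                    rowSums(is.na(calls$state)) == nrow(calls$genes)))
  # trivial: 3 of 10 genes altered -> 0.30
  vals <- matrix(c(1, -1, 1, rep(0, 7)), nrow = 1,
                 dimnames = list("S1", paste0("g", 1:10)))
  expect_equal(cna_burden(call_cna(gene_matrix(vals)))$fraction, 0.3)
  # all neutral -> 0
  vals0 <- matrix(0, 1, 4, dimnames = list("S1", paste0("g", 1:4)))
  expect_equal(cna_burden(call_cna(gene_matrix(vals0)))$count, 0)
})

test_that("group CNA frequencies separate lineages and handle small groups", {
  coh <- small_cohort(seed = 23, n = c(stable = 6, unstable = 6),
                      same_tumour_pairs = 0, concurrent_pairs = 0)
  gm <- suppressMessages(average_probes_to_genes(coh$probes, coh$genome$genes))
  b <- cna_burden(call_cna(gm))
  gf <- group_cna_frequency(b, coh$metadata, group_col = "truth_lineage")
  m <- setNames(gf$means$mean_fraction, gf$means$group)
  expect_gt(m["unstable"], m["stable"])
  expect_equal(nrow(gf$tests), 1)
  expect_lt(gf$tests$p, 0.05)

  # single-sample group: warning, no test
  md <- coh$metadata
  md$grp <- c("solo", rep("rest", nrow(md) - 1))
  expect_warning(gf2 <- group_cna_frequency(b, md, group_col = "grp"), "<2 samples")
  expect_equal(nrow(gf2$tests), 0)
})

test_that("arm penetrance reflects forced arm events and empty calls", {
  g <- build_genome(n_chromosomes = 2, genes_per_chromosome = 20, seed = 3)
  arms <- data.frame(chrom = g$chromosomes$name,
                     centromere = g$chromosomes$centromere,
                     stringsAsFactors = FALSE)
  spec <- lineage_spec("unstable", focal_cna_rate = 0,
                       arm_events = data.frame(arm = "chr3q", type = "gain", prob = 1))
  probe_tabs <- lapply(1:3, function(i) {
    p <- simulate_profile(g, spec, seed = i)
    simulate_sample(p, g, noise_model(probe_sd = 0), seed = i, sprintf("S%d", i))
  })
  gm <- suppressMessages(average_probes_to_genes(do.call(rbind, probe_tabs), g$genes))
  pen <- arm_penetrance(call_cna(gm), arms, metadata = NULL)
  expect_equal(pen$pct_gain[pen$arm == "chr3q"], 100)
  expect_true(all(pen$pct_gain[pen$arm != "chr3q"] == 0))
  expect_true(all(pen$pct_loss == 0))

  # no calls anywhere -> all penetrance 0
  vals <- matrix(0, 2, nrow(g$genes),
                 dimnames = list(c("A", "B"), g$genes$gene_id))
  gm0 <- gene_matrix(vals, g$genes)
  pen0 <- arm_penetrance(call_cna(gm0), arms, metadata = NULL)
  expect_true(all(pen0$pct_gain == 0) && all(pen0$pct_loss == 0))
})

test_that("penetrance of a probabilistic arm event sits in its binomial interval", {
  g <- build_genome(n_chromosomes = 2, genes_per_chromosome = 20, seed = 3)
  arms <- data.frame(chrom = g$chromosomes$name,
                     centromere = g$chromosomes$centromere,
                     stringsAsFactors = FALSE)
  prob <- 0.4
  n <- 60
  spec <- lineage_spec("unstable", focal_cna_rate = 0,
                       arm_events = data.frame(arm = "chr1q", type = "gain", prob = prob))
  probe_tabs <- lapply(seq_len(n), function(i) {
    p <- simulate_profile(g, spec, seed = 100 + i)
    simulate_sample(p, g, noise_model(probe_sd = 0), seed = i, sprintf("S%02d", i))
  })
  gm <- suppressMessages(average_probes_to_genes(do.call(rbind, probe_tabs), g$genes))
  pen <- arm_penetrance(call_cna(gm), arms, metadata = NULL)
  observed <- pen$pct_gain[pen$arm == "chr1q"] / 100
  half_width <- qnorm(0.995) * sqrt(prob * (1 - prob) / n)
  expect_gt(observed, prob - half_width)
  expect_lt(observed, prob + half_width)
})

test_that("zero-noise calls reproduce the true gain/loss pattern exactly", {
  coh <- small_cohort(seed = 24, n = c(stable = 2, intermediate = 2, unstable = 2),
                      probe_sd = 0, same_tumour_pairs = 0, concurrent_pairs = 0)
  gm <- suppressMessages(average_probes_to_genes(coh$probes, coh$genome$genes))
  calls <- call_cna(gm)
  md <- coh$metadata
  for (i in seq_len(nrow(md))) {
    truth <- coh$truth[[md$lesion_id[i]]]$copy
    expected <- ifelse(truth == 3L, 1L, ifelse(truth == 1L, -1L, 0L))
    got <- calls$state[md$sample_id[i], names(truth)]
    expect_identical(unname(got), unname(expected), info = md$sample_id[i])
  }
})
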