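# Genome-wide Welch t screen for genes whose averaged log2 copy-number
# ratios differ between lineage clusters, with Bonferroni correction per
# contrast, and the 2-D supervised clustering on the selected genes.

#' Welch's unequal-variance two-sample t-test
#'
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with sample variances
#' and Welch-Satterthwaite degrees of freedom; two-sided p.  Semantics
#' match [stats::t.test()] with `var.equal = FALSE`, plus explicit errors
#' on degenerate input (either group < 2 values, or both variances zero).
#'
#' @param x,y numeric vectors (each n >= 2 after NA removal).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  abort_if(length(x) < 2 || length(y) < 2, "each group needs n >= 2")
  vx <- var(x); vy <- var(y)
  abort_if(vx == 0 && vy == 0, "degenerate test: both variances zero")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# Row-wise Welch t over two column subsets of a genes-in-rows matrix.
# Plain arithmetic (cross-checked against stats::t.test in the tests) so a
# genome-wide screen is a handful of vectorised operations.
welch_t_rows <- function(mx, my) {
  nx <- rowSums(!is.na(mx)); ny <- rowSums(!is.na(my))
  meanx <- rowMeans(mx, na.rm = TRUE); meany <- rowMeans(my, na.rm = TRUE)
  vx <- rowSums((mx - meanx)^2, na.rm = TRUE) / pmax(nx - 1, 1)
  vy <- rowSums((my - meany)^2, na.rm = TRUE) / pmax(ny - 1, 1)
  se2 <- vx / nx + vy / ny
  t <- (meanx - meany) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  p <- 2 * pt(-abs(t), df)
  testable <- nx >= 2 & ny >= 2 & (vx > 0 | vy > 0)
  t[!testable] <- NA_real_; df[!testable] <- NA_real_; p[!testable] <- NA_real_
  data.frame(t = t, df = df, p = p, testable = testable,
             n1 = nx, n2 = ny, row.names = NULL)
}

#' Bonferroni adjustment with explicit family size
#'
#' @param p raw p-value(s) in [0, 1].
#' @param m family size (>= 1).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni <- function(p, m) {
  abort_if(any(p < 0 | p > 1, na.rm = TRUE), "p must be in [0,1]")
  abort_if(m < 1, "m must be >= 1")
  pmin(1, p * m)
}

#' The five lineage contrasts of the differential screen
#'
#' stable vs intermediate, stable vs unstable, intermediate vs unstable,
#' stable+intermediate vs unstable, and stable vs unstable+intermediate.
#'
#' @return Named list of contrasts, each with `group1` and `group2` label
#'   sets.
#' @export
default_contrasts <- function() {
  list(
    stable_vs_intermediate = list(group1 = "stable", group2 = "intermediate"),
    stable_vs_unstable = list(group1 = "stable", group2 = "unstable"),
    intermediate_vs_unstable = list(group1 = "intermediate", group2 = "unstable"),
    stable_intermediate_vs_unstable = list(group1 = c("stable", "intermediate"),
                                           group2 = "unstable"),
    stable_vs_unstable_intermediate = list(group1 = "stable",
                                           group2 = c("unstable", "intermediate"))
  )
}

#' Find genes with lineage-differential copy number
#'
#' Per contrast, a Welch t-test per gene on the averaged log2 T/R values,
#' Bonferroni-adjusted with m = the number of genes tested in that
#' contrast.  A gene enters the selected set if significant (adjusted
#' p <= alpha) in at least one contrast (union rule); the per-contrast sets
#' and their intersection are also returned.  Genes failing test
#' preconditions in a contrast are recorded as untestable there, never
#' silently dropped.
#'
#' @param matrix a `gene_matrix`.
#' @param lineages a `lineage_assignment` (or data frame with sample_id and
#'   lineage).
#' @param contrasts contrast list, default [default_contrasts()].
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return List with `table` (gene_id, contrast, t, df, p, p_adj,
#'   significant, testable), `selected` (union), `per_contrast` (named list
#'   of selected sets), `intersection`, `alpha`.
#' @export
find_differential_genes <- function(matrix, lineages,
                                    contrasts = default_contrasts(),
                                    alpha = 0.05) {
  stopifnot(inherits(matrix, "gene_matrix"))
  abort_if(alpha <= 0 || alpha > 1, "alpha must be in (0,1]")
  assign_df <- if (inherits(lineages, "lineage_assignment")) {
    lineages$assignments
  } else {
    lineages
  }
  abort_if(!all(c("sample_id", "lineage") %in% names(assign_df)),
           "lineages needs sample_id and lineage")
  lab <- setNames(assign_df$lineage, assign_df$sample_id)
  vals <- t(matrix$values)   # genes x samples
  gene_ids <- matrix$genes$gene_id

  tabs <- list(); per_contrast <- list()
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    s1 <- matrix$samples[lab[matrix$samples] %in% ct$group1]
    s2 <- matrix$samples[lab[matrix$samples] %in% ct$group2]
    abort_if(length(s1) == 0 || length(s2) == 0,
             "empty contrast group in ", cn)
    abort_if(length(s1) < 2 || length(s2) < 2,
             "contrast group with <2 samples in ", cn)
    res <- welch_t_rows(vals[, s1, drop = FALSE], vals[, s2, drop = FALSE])
    m_tested <- sum(res$testable)
    p_adj <- rep(NA_real_, nrow(res))
    if (m_tested > 0) {
      p_adj[res$testable] <- bonferroni(res$p[res$testable], m_tested)
    }
    sig <- !is.na(p_adj) & p_adj <= alpha
    tabs[[cn]] <- data.frame(
      gene_id = gene_ids, contrast = cn,
      t = res$t, df = res$df, p = res$p, p_adj = p_adj,
      m_tested = m_tested, testable = res$testable, significant = sig,
      stringsAsFactors = FALSE)
    per_contrast[[cn]] <- gene_ids[sig]
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  selected <- sort(unique(unlist(per_contrast)))
  intersection <- sort(Reduce(intersect, per_contrast))
  list(table = table, selected = selected, per_contrast = per_contrast,
       intersection = intersection, alpha = alpha)
}

#' Two-dimensional supervised clustering on the selected genes
#'
#' Clusters both samples and genes of the restricted matrix with the same
#' uncentred-correlation / complete-linkage procedure as the unsupervised
#' analysis, and optionally writes a Cluster 3.0 CDT/GTR/ATR bundle.
#'
#' @param matrix a `gene_matrix`.
#' @param gene_ids selected genes (>= 2).
#' @param out_prefix optional path prefix for [write_cdt_gtr()].
#' @return List with `sample_tree`, `gene_tree`, `matrix` (the restricted
#'   `gene_matrix`) and `files` (written paths, if any).
#' @export
supervised_2d_cluster <- function(matrix, gene_ids, out_prefix = NULL) {
  stopifnot(inherits(matrix, "gene_matrix"))
  gene_ids <- intersect(matrix$genes$gene_id, gene_ids)
  abort_if(length(gene_ids) < 2,
           "fewer than 2 selected genes; consider relaxing alpha")
  gm <- subset_genes(matrix, gene_ids)
  sample_tree <- complete_linkage(gm, axis = "samples")
  gene_tree <- complete_linkage(gm, axis = "genes")
  files <- NULL
  if (!is.null(out_prefix)) {
    files <- write_cdt_gtr(gm, sample_tree, gene_tree, out_prefix)
  }
  list(sample_tree = sample_tree, gene_tree = gene_tree, matrix = gm,
       files = files)
}
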