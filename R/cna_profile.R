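# Probe-to-gene averaging, CNA calling, per-sample burden, group
# frequencies and chromosome-arm penetrance.

#' Average probe log2 ratios within genes
#'
#' A probe is assigned to a gene iff the probe's midpoint lies within the
#' gene interval (0-based, half-open); a gene's value for a sample is the
#' arithmetic mean of its non-missing probe log2 ratios.  Averaging within
#' genes raises the signal-to-noise ratio of noisy FFPE/WGA measurements,
#' which is why downstream clustering restricts to genes with many probes.
#' Probes falling in no gene are dropped (a count is reported); genes that
#' acquire zero probes are dropped from the matrix.  The result is
#' invariant to probe input order.
#'
#' @param probes long probe table (sample_id, probe_id, chrom, start, end,
#'   log2_ratio).
#' @param annotation gene annotation (gene_id, chrom, start, end).
#' @param assignment "midpoint" (default; probe midpoint inside the gene) or
#'   "full_overlap" (the whole probe interval inside the gene).
#' @return A `gene_matrix`: list with `values` (samples x genes matrix of
#'   mean log2 ratios; `NA` only where all of a gene's probes were missing
#'   for that sample), `genes` (retained annotation rows plus
#'   `probe_count`), `samples`.
#' @export
average_probes_to_genes <- function(probes, annotation,
                                    assignment = c("midpoint", "full_overlap")) {
  assignment <- match.arg(assignment)
  abort_if(nrow(probes) == 0, "empty probe table")
  abort_if(!all(c("gene_id", "chrom", "start", "end") %in% names(annotation)),
           "annotation needs gene_id, chrom, start, end")

  # unique physical probes
  probe_key <- paste(probes$chrom, probes$start, probes$end, sep = ":")
  up <- !duplicated(probe_key)
  u_key <- probe_key[up]
  u_chrom <- probes$chrom[up]
  u_mid <- (probes$start[up] + probes$end[up]) %/% 2L
  u_start <- probes$start[up]
  u_end <- probes$end[up]

  # probe-to-gene assignment, per chromosome, via IRanges overlap
  hit_probe <- integer(0)
  hit_gene <- integer(0)
  for (ch in unique(u_chrom)) {
    pi <- which(u_chrom == ch)
    gi <- which(annotation$chrom == ch)
    if (length(gi) == 0) next
    q <- if (assignment == "midpoint") {
      IRanges::IRanges(start = u_mid[pi] + 1L, width = 1L)
    } else {
      IRanges::IRanges(start = u_start[pi] + 1L, end = u_end[pi])
    }
    s <- IRanges::IRanges(start = annotation$start[gi] + 1L,
                          end = annotation$end[gi])
    ov <- IRanges::findOverlaps(q, s,
                                type = if (assignment == "midpoint") "any" else "within")
    hit_probe <- c(hit_probe, pi[S4Vectors::queryHits(ov)])
    hit_gene <- c(hit_gene, gi[S4Vectors::subjectHits(ov)])
  }
  abort_if(length(hit_probe) == 0, "no probe overlaps any gene")
  n_dropped <- length(u_key) - length(unique(hit_probe))
  if (n_dropped > 0) {
    message(n_dropped, " probe(s) in no gene dropped")
  }

  samples <- unique(probes$sample_id)
  vals <- matrix(NA_real_, nrow = length(u_key), ncol = length(samples),
                 dimnames = list(u_key, samples))
  vals[cbind(match(probe_key, u_key), match(probes$sample_id, samples))] <-
    probes$log2_ratio

  # expand assigned probes (a probe overlapping two genes contributes to
  # both) and average per gene with per-sample missing handling
  v <- vals[hit_probe, , drop = FALSE]
  grp <- annotation$gene_id[hit_gene]
  vz <- v; vz[is.na(vz)] <- 0
  sums <- rowsum(vz, grp)
  cnt <- rowsum((!is.na(v)) * 1L, grp)
  means <- sums / cnt
  means[cnt == 0] <- NA_real_

  probe_count <- table(grp)[rownames(means)]
  keep_genes <- annotation$gene_id[annotation$gene_id %in% rownames(means)]
  means <- means[keep_genes, , drop = FALSE]
  genes <- annotation[match(keep_genes, annotation$gene_id), , drop = FALSE]
  genes$probe_count <- as.integer(probe_count[keep_genes])
  rownames(genes) <- NULL

  structure(list(values = t(means), genes = genes, samples = samples),
            class = "gene_matrix")
}

#' Construct a gene matrix from a values matrix
#'
#' Programmatic constructor for simulations and tests that bypass probe
#' averaging.
#'
#' @param values samples x genes numeric matrix with dimnames.
#' @param genes optional annotation data frame (gene_id, chrom, start, end,
#'   probe_count); a minimal one is synthesised from the column names when
#'   absent.
#' @return A `gene_matrix`.
#' @export
gene_matrix <- function(values, genes = NULL) {
  abort_if(!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)),
           "values must be a matrix with sample row names and gene column names")
  if (is.null(genes)) {
    genes <- data.frame(gene_id = colnames(values), chrom = "chr1",
                        start = (seq_len(ncol(values)) - 1L) * 1000L,
                        end = (seq_len(ncol(values)) - 1L) * 1000L + 500L,
                        probe_count = 1L, stringsAsFactors = FALSE)
  }
  abort_if(!identical(genes$gene_id, colnames(values)),
           "genes$gene_id must match the value columns")
  structure(list(values = values, genes = genes, samples = rownames(values)),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("gene_matrix: %d samples x %d genes (probe counts %d-%d)\n",
              length(x$samples), nrow(x$genes),
              min(x$genes$probe_count), max(x$genes$probe_count)))
  invisible(x)
}

#' Restrict a gene matrix to a gene subset
#' @param matrix a `gene_matrix`.
#' @param gene_ids genes to keep (order preserved from the matrix).
#' @return A `gene_matrix`.
#' @export
subset_genes <- function(matrix, gene_ids) {
  stopifnot(inherits(matrix, "gene_matrix"))
  keep <- matrix$genes$gene_id %in% gene_ids
  abort_if(!any(keep), "no matching genes")
  structure(list(values = matrix$values[, keep, drop = FALSE],
                 genes = matrix$genes[keep, , drop = FALSE],
                 samples = matrix$samples),
            class = "gene_matrix")
}

#' Restrict a gene matrix to a sample subset
#' @param matrix a `gene_matrix`.
#' @param sample_ids samples to keep.
#' @return A `gene_matrix`.
#' @export
subset_samples <- function(matrix, sample_ids) {
  stopifnot(inherits(matrix, "gene_matrix"))
  keep <- matrix$samples %in% sample_ids
  abort_if(!any(keep), "no matching samples")
  structure(list(values = matrix$values[keep, , drop = FALSE],
                 genes = matrix$genes,
                 samples = matrix$samples[keep]),
            class = "gene_matrix")
}

#' CNA calling parameters
#'
#' Gains and losses are called when the gene-level log2 T/R ratio exceeds
#' `gain_threshold` or falls below `loss_threshold`.  The defaults
#' +/-0.3219 correspond to a 1.25-fold copy-number change
#' (log2(2.5/2) = 0.3219); comparisons are strict (exclusive) by default.
#'
#' @param gain_threshold log2 threshold for a gain (> 0).
#' @param loss_threshold log2 threshold for a loss (< 0).
#' @param strict use exclusive comparison (default TRUE).
#' @return A `cna_call_params` list.
#' @export
cna_call_params <- function(gain_threshold = 0.3219,
                            loss_threshold = -0.3219,
                            strict = TRUE) {
  abort_if(!(loss_threshold < 0 && 0 < gain_threshold),
           "need loss_threshold < 0 < gain_threshold")
  structure(list(gain_threshold = gain_threshold,
                 loss_threshold = loss_threshold, strict = isTRUE(strict)),
            class = "cna_call_params")
}

#' Call copy-number alterations from a gene matrix
#'
#' @param matrix a `gene_matrix`.
#' @param params a `cna_call_params`.
#' @return A `cna_calls` object: list with `state` (samples x genes integer
#'   matrix: +1 gain, -1 loss, 0 neutral, `NA` missing), `params`, `genes`,
#'   `samples`.
#' @export
call_cna <- function(matrix, params = cna_call_params()) {
  stopifnot(inherits(matrix, "gene_matrix"), inherits(params, "cna_call_params"))
  v <- matrix$values
  state <- matrix(0L, nrow = nrow(v), ncol = ncol(v), dimnames = dimnames(v))
  if (params$strict) {
    state[v > params$gain_threshold] <- 1L
    state[v < params$loss_threshold] <- -1L
  } else {
    state[v >= params$gain_threshold] <- 1L
    state[v <= params$loss_threshold] <- -1L
  }
  state[is.na(v)] <- NA_integer_
  structure(list(state = state, params = params, genes = matrix$genes,
                 samples = matrix$samples),
            class = "cna_calls")
}

#' Per-sample CNA burden
#'
#' @param calls a `cna_calls` object.
#' @return Data frame with sample_id, n_gain, n_loss, n_called (non-missing
#'   genes), count (gains + losses) and fraction (count / n_called;
#'   `NA` for a sample whose genes are all missing, which is flagged with a
#'   warning).
#' @export
cna_burden <- function(calls) {
  stopifnot(inherits(calls, "cna_calls"))
  abort_if(length(calls$samples) == 0 || ncol(calls$state) == 0, "empty call matrix")
  st <- calls$state
  n_gain <- rowSums(st == 1L, na.rm = TRUE)
  n_loss <- rowSums(st == -1L, na.rm = TRUE)
  n_called <- rowSums(!is.na(st))
  count <- n_gain + n_loss
  fraction <- ifelse(n_called > 0, count / n_called, NA_real_)
  if (any(n_called == 0)) {
    warning("sample(s) with all genes missing: ",
            paste(calls$samples[n_called == 0], collapse = ", "), call. = FALSE)
  }
  data.frame(sample_id = calls$samples, n_gain = n_gain, n_loss = n_loss,
             n_called = n_called, count = count, fraction = fraction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-group mean CNA frequency with pairwise Welch tests
#'
#' @param burdens output of [cna_burden()].
#' @param metadata sample metadata with `sample_id` and the grouping
#'   column.
#' @param group_col metadata column defining groups (default
#'   "vienna_group").
#' @return List with `means` (group, n, mean_fraction, mean_count) and
#'   `tests` (pairwise Welch t on the per-sample fractions; groups with
#'   fewer than 2 samples are skipped with a warning).
#' @export
group_cna_frequency <- function(burdens, metadata, group_col = "vienna_group") {
  abort_if(!group_col %in% names(metadata), "missing column: ", group_col)
  m <- match(burdens$sample_id, metadata$sample_id)
  abort_if(any(is.na(m)), "sample(s) missing from metadata: ",
           paste(utils::head(burdens$sample_id[is.na(m)], 5), collapse = ", "))
  grp <- metadata[[group_col]][m]
  groups <- unique(grp)
  means <- data.frame(
    group = groups,
    n = as.integer(table(grp)[groups]),
    mean_fraction = vapply(groups, function(g)
      mean(burdens$fraction[grp == g], na.rm = TRUE), 0),
    mean_count = vapply(groups, function(g)
      mean(burdens$count[grp == g], na.rm = TRUE), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  tests <- list()
  if (length(groups) >= 2) {
    for (i in seq_len(length(groups) - 1)) {
      for (j in seq(i + 1, length(groups))) {
        x <- burdens$fraction[grp == groups[i] & !is.na(burdens$fraction)]
        y <- burdens$fraction[grp == groups[j] & !is.na(burdens$fraction)]
        if (length(x) < 2 || length(y) < 2) {
          warning("group with <2 samples; test ", groups[i], " vs ",
                  groups[j], " skipped", call. = FALSE)
          next
        }
        wt <- tryCatch(welch_t(x, y), error = function(e) NULL)
        if (is.null(wt)) next
        tests[[length(tests) + 1L]] <- data.frame(
          group1 = groups[i], group2 = groups[j],
          t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(group1 = character(), group2 = character(),
               t = numeric(), df = numeric(), p = numeric())
  list(means = means, tests = tests)
}

# gene -> arm mapping by gene midpoint vs centromere
gene_arms <- function(annotation, arms) {
  m <- match(annotation$chrom, arms$chrom)
  abort_if(any(is.na(m)), "arm table does not cover chromosome(s): ",
           paste(unique(annotation$chrom[is.na(m)]), collapse = ", "))
  mid <- (annotation$start + annotation$end) / 2
  paste0(annotation$chrom, ifelse(mid < arms$centromere[m], "p", "q"))
}

#' Chromosome-arm penetrance per group
#'
#' A sample carries an arm-level gain (loss) iff at least
#' `arm_fraction_threshold` of that arm's called (non-missing) genes are in
#' the gain (loss) state.  Penetrance is the percentage of a group's
#' samples carrying the arm event.
#'
#' @param calls a `cna_calls` object.
#' @param arms arm table (chrom, centromere).
#' @param metadata sample metadata with `sample_id` and the grouping
#'   column; pass NULL to treat the cohort as one group "all".
#' @param group_col grouping column (default "vienna_group").
#' @param arm_fraction_threshold fraction of arm genes that must be altered
#'   (default 0.5).
#' @return Data frame (group, arm, n_samples, pct_gain, pct_loss).
#' @export
arm_penetrance <- function(calls, arms, metadata = NULL,
                           group_col = "vienna_group",
                           arm_fraction_threshold = 0.5) {
  stopifnot(inherits(calls, "cna_calls"))
  arm_of <- gene_arms(calls$genes, arms)
  all_arms <- unique(arm_of)
  st <- calls$state
  # per sample x arm: fraction of called genes gained / lost
  arm_gain <- matrix(FALSE, nrow = nrow(st), ncol = length(all_arms),
                     dimnames = list(calls$samples, all_arms))
  arm_loss <- arm_gain
  for (a in all_arms) {
    idx <- which(arm_of == a)
    if (length(idx) == 0) {
      warning("arm with zero genes excluded: ", a, call. = FALSE)
      next
    }
    sub <- st[, idx, drop = FALSE]
    n_called <- rowSums(!is.na(sub))
    fg <- ifelse(n_called > 0, rowSums(sub == 1L, na.rm = TRUE) / n_called, 0)
    fl <- ifelse(n_called > 0, rowSums(sub == -1L, na.rm = TRUE) / n_called, 0)
    arm_gain[, a] <- fg >= arm_fraction_threshold
    arm_loss[, a] <- fl >= arm_fraction_threshold
  }
  if (is.null(metadata)) {
    grp <- rep("all", length(calls$samples))
  } else {
    m <- match(calls$samples, metadata$sample_id)
    abort_if(any(is.na(m)), "sample(s) missing from metadata")
    grp <- metadata[[group_col]][m]
  }
  out <- list()
  for (g in unique(grp)) {
    rows <- grp == g
    out[[g]] <- data.frame(
      group = g, arm = all_arms, n_samples = sum(rows),
      pct_gain = 100 * colMeans(arm_gain[rows, , drop = FALSE]),
      pct_loss = 100 * colMeans(arm_loss[rows, , drop = FALSE]),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
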