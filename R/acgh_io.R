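# Readers and writers for every external format the pipeline touches.
# All genomic intervals are 0-based, half-open (BED convention).
# Floating point is written with 10 significant digits, so write -> read
# round-trips are identity at that precision.

REQUIRED_PROBE_COLS <- c("sample_id", "probe_id", "chrom", "start", "end", "log2_ratio")

# Reject silently truncated files: every data line must have as many fields
# as the header.
check_field_counts <- function(path, sep = "\t") {
  n <- utils::count.fields(path, sep = sep, quote = "", comment.char = "#")
  if (length(n) > 1 && any(n[-1] != n[1])) {
    bad <- which(n[-1] != n[1]) + 1L
    stop("malformed/truncated rows (wrong field count) at line(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a probe-level log2 ratio table
#'
#' Tab-delimited with header columns sample_id, probe_id, chrom, start, end,
#' log2_ratio.  Non-numeric ratios (e.g. "NA") are flagged missing with a
#' warning, never silently dropped; rows with the wrong field count abort
#' with their line numbers.
#'
#' @param path file path.
#' @return Data frame of probe measurements; missing ratios are `NA`.
#' @export
read_probe_table <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  check_field_counts(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  missing_cols <- setdiff(REQUIRED_PROBE_COLS, names(df))
  abort_if(length(missing_cols) > 0,
           "missing column: ", paste(missing_cols, collapse = ", "))
  df <- df[REQUIRED_PROBE_COLS]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  abort_if(any(is.na(df$start)) || any(is.na(df$end)),
           "non-numeric start/end coordinates")
  abort_if(any(df$start >= df$end), "start >= end at line(s): ",
           paste(utils::head(which(df$start >= df$end) + 1L, 10), collapse = ", "))
  raw <- df$log2_ratio
  val <- suppressWarnings(as.numeric(raw))
  newly_na <- is.na(val) & !is.na(raw) & !(trimws(raw) %in% c("", "NA", "na", "NaN"))
  if (any(newly_na)) {
    warning(sum(newly_na), " non-numeric log2_ratio value(s) flagged missing ",
            "(line(s) ", paste(utils::head(which(newly_na) + 1L, 10), collapse = ", "), ")",
            call. = FALSE)
  }
  df$log2_ratio <- val
  df
}

#' Write a probe table
#' @param probes probe measurement data frame.
#' @param path output path.
#' @export
write_probe_table <- function(probes, path) {
  out <- probes[REQUIRED_PROBE_COLS]
  out$log2_ratio <- signif(out$log2_ratio, 10)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from a BED file
#'
#' Accepts BED4 or BED6 (an optional 7th column carries a probe count).
#' Intervals are kept 0-based, half-open verbatim.
#'
#' @param path BED file path.
#' @return Data frame gene_id, chrom, start, end, strand (and probe_count
#'   when a 7th column is present).
#' @export
read_gene_bed <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t|[ ]+")
  nf <- lengths(fields)
  abort_if(any(nf < 4), "BED line with fewer than 4 fields at line ",
           which(nf < 4)[1])
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  name <- vapply(fields, `[`, "", 4)
  abort_if(any(is.na(start)) || any(is.na(end)),
           "non-numeric BED coordinates at line ",
           which(is.na(start) | is.na(end))[1])
  bad <- which(start >= end)
  abort_if(length(bad) > 0, "start >= end at line ", bad[1])
  strand <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 6 && fields[[i]][6] %in% c("+", "-")) fields[[i]][6] else "unknown"
  }, "")
  out <- data.frame(gene_id = name, chrom = chrom, start = start, end = end,
                    strand = strand, stringsAsFactors = FALSE)
  pc <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 7) suppressWarnings(as.integer(fields[[i]][7])) else NA_integer_
  }, 1L)
  if (!all(is.na(pc))) out$probe_count <- pc
  abort_if(anyDuplicated(out$gene_id) > 0, "duplicate gene_id in BED: ",
           out$gene_id[anyDuplicated(out$gene_id)])
  out
}

#' Read a chromosome-arm table (chrom, centromere TSV)
#' @param path TSV path with header columns chrom, centromere.
#' @return Data frame chrom, centromere.
#' @export
read_arm_table <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  check_field_counts(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(c("chrom", "centromere"), names(df))
  abort_if(length(missing_cols) > 0,
           "missing column: ", paste(missing_cols, collapse = ", "))
  df$centromere <- as.integer(df$centromere)
  df
}

#' Read a sample metadata table
#' @param path TSV path; must contain a sample_id column.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  check_field_counts(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  abort_if(!"sample_id" %in% names(df), "missing column: sample_id")
  df
}

#' Write the synthetic genome as BED/TSV files
#'
#' Genes go to `<prefix>_genes.bed` (BED6 plus a probe-count column),
#' probes to `<prefix>_probes.bed` (BED4) and arms to `<prefix>_arms.tsv`
#' (chrom, centromere).
#'
#' @param genome a `genome_model`.
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_genome_files <- function(genome, prefix) {
  g <- genome$genes
  gene_path <- paste0(prefix, "_genes.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+\t%d",
                     g$chrom, g$start, g$end, g$gene_id, g$probe_count),
             gene_path)
  p <- genome$probes
  probe_path <- paste0(prefix, "_probes.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", p$chrom, p$start, p$end, p$probe_id),
             probe_path)
  arm_path <- paste0(prefix, "_arms.tsv")
  utils::write.table(genome$chromosomes[c("name", "centromere")],
                     arm_path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("chrom", "centromere"))
  invisible(c(genes = gene_path, probes = probe_path, arms = arm_path))
}

fmt10 <- function(x) formatC(x, digits = 10, format = "g")

# One Cluster-3.0 tree file (.gtr or .atr): node per line,
# "NODE<k>X  <left>  <right>  <similarity>", similarity = 1 - merge height.
write_tree_file <- function(tree, path, leaf_prefix) {
  n <- length(tree$labels)
  id_of <- function(x) {
    ifelse(x < 0, sprintf("%s%dX", leaf_prefix, -x - 1L), sprintf("NODE%dX", x))
  }
  lines <- sprintf("NODE%dX\t%s\t%s\t%s",
                   seq_len(n - 1L),
                   id_of(tree$merge[, 1]), id_of(tree$merge[, 2]),
                   fmt10(1 - tree$height))
  writeLines(lines, path)
  invisible(path)
}

#' Write a Cluster 3.0-compatible CDT/GTR/ATR bundle
#'
#' Rows of the `.cdt` are genes in gene-tree leaf order (or matrix order
#' when `gene_tree` is NULL); columns are samples in sample-tree leaf
#' order.  Node ids follow the Cluster 3.0 dialect (`NODE<k>X`,
#' `GENE<k>X`, `ARRY<k>X`, 0-based leaf numbering in input order) and merge
#' scores are written as similarity `1 - distance`.
#'
#' @param matrix a `gene_matrix` restricted to the clustered items.
#' @param sample_tree dendrogram (`hclust`-compatible) over the matrix's
#'   samples.
#' @param gene_tree optional dendrogram over the matrix's genes.
#' @param out_prefix path prefix; writes `<prefix>.cdt`, `<prefix>.atr` and
#'   (if `gene_tree` is given) `<prefix>.gtr`.
#' @return Invisibly, the written paths.
#' @export
write_cdt_gtr <- function(matrix, sample_tree, gene_tree = NULL, out_prefix) {
  stopifnot(inherits(matrix, "gene_matrix"))
  samples <- matrix$samples
  genes <- matrix$genes$gene_id
  abort_if(!identical(sort(sample_tree$labels), sort(samples)),
           "sample tree leaves do not match matrix samples")
  if (!is.null(gene_tree)) {
    abort_if(!identical(sort(gene_tree$labels), sort(genes)),
             "gene tree leaves do not match matrix genes")
  }
  paths <- character()

  atr_path <- paste0(out_prefix, ".atr")
  write_tree_file(sample_tree, atr_path, "ARRY")
  paths <- c(paths, atr = atr_path)
  if (!is.null(gene_tree)) {
    gtr_path <- paste0(out_prefix, ".gtr")
    write_tree_file(gene_tree, gtr_path, "GENE")
    paths <- c(paths, gtr = gtr_path)
  }

  sample_order <- sample_tree$order               # leaf order, indexes labels
  sample_ids_ordered <- sample_tree$labels[sample_order]
  col_idx <- match(sample_ids_ordered, samples)
  if (!is.null(gene_tree)) {
    gene_order <- gene_tree$order
    gene_ids_ordered <- gene_tree$labels[gene_order]
  } else {
    gene_ids_ordered <- genes
  }
  row_idx <- match(gene_ids_ordered, genes)

  vals <- t(matrix$values)[row_idx, col_idx, drop = FALSE]  # genes x samples
  con <- file(paste0(out_prefix, ".cdt"), "w")
  on.exit(close(con))
  header <- c(if (!is.null(gene_tree)) "GID", "UNIQID", "NAME", "GWEIGHT",
              sample_ids_ordered)
  writeLines(paste(header, collapse = "\t"), con)
  aid <- c(if (!is.null(gene_tree)) "AID", "", "", "",
           sprintf("ARRY%dX", match(sample_ids_ordered, sample_tree$labels) - 1L))
  writeLines(paste(aid, collapse = "\t"), con)
  # EWEIGHT row: label, blanks for the remaining annotation columns, then 1
  # per array
  eweight <- c(if (!is.null(gene_tree)) c("EWEIGHT", "", "", "") else c("EWEIGHT", "", ""),
               rep("1", length(sample_ids_ordered)))
  writeLines(paste(eweight, collapse = "\t"), con)
  for (r in seq_along(gene_ids_ordered)) {
    gid <- if (!is.null(gene_tree)) {
      sprintf("GENE%dX", match(gene_ids_ordered[r], gene_tree$labels) - 1L)
    } else {
      NULL
    }
    row <- c(gid, gene_ids_ordered[r], gene_ids_ordered[r], "1",
             fmt10(vals[r, ]))
    writeLines(paste(row, collapse = "\t"), con)
  }
  paths <- c(paths, cdt = paste0(out_prefix, ".cdt"))
  invisible(paths)
}

#' Parse a Cluster 3.0 .gtr/.atr tree file
#'
#' Inverse of the tree part of [write_cdt_gtr()]: reconstructs the merge
#' table and merge heights (`height = 1 - similarity`).
#'
#' @param path tree file path.
#' @param leaf_prefix "GENE" or "ARRY".
#' @return List with `merge` (hclust convention) and `height`.
#' @export
read_tree_file <- function(path, leaf_prefix = c("ARRY", "GENE")) {
  leaf_prefix <- match.arg(leaf_prefix)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  abort_if(any(lengths(parts) < 4), "malformed tree line")
  parse_id <- function(s) {
    out <- integer(length(s))
    node <- startsWith(s, "NODE")
    out[node] <- as.integer(sub("^NODE(\\d+)X$", "\\1", s[node]))
    out[!node] <- -(as.integer(sub(paste0("^", leaf_prefix, "(\\d+)X$"), "\\1",
                                   s[!node])) + 1L)
    abort_if(anyNA(out), "unparseable node/leaf id in tree file")
    out
  }
  merge <- cbind(parse_id(vapply(parts, `[`, "", 2)),
                 parse_id(vapply(parts, `[`, "", 3)))
  height <- 1 - as.numeric(vapply(parts, `[`, "", 4))
  list(merge = merge, height = height)
}

#' Import a GEO-style series matrix into the probe-table format
#'
#' Offline import recipe for two-colour aCGH series: a series-matrix file
#' whose data block has probe IDs in column `ID_REF` and one log2 T/R
#' column per sample, plus a platform probe-position table (TSV with
#' columns probe_id, chrom, start, end; 0-based half-open).  Probes missing
#' from the position table are dropped with a message.  If the series
#' supplementary files provide only raw two-channel intensities instead of
#' log ratios, they must first be reduced to log2 T/R per probe; this
#' importer takes the ratio representation.
#'
#' @param series_path series-matrix file (the block between
#'   `!series_matrix_table_begin` and `!series_matrix_table_end`, with or
#'   without the surrounding `!` metadata lines).
#' @param positions_path probe-position TSV.
#' @return Probe measurement data frame (long format).
#' @export
import_geo_series <- function(series_path, positions_path) {
  abort_if(!file.exists(series_path), "file not found: ", series_path)
  lines <- readLines(series_path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) == 1 && length(end) == 1) {
    lines <- lines[(beg + 1L):(end - 1L)]
  } else {
    lines <- lines[!startsWith(lines, "!")]
  }
  lines <- lines[nzchar(lines)]
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  abort_if(!"ID_REF" %in% names(tab), "missing column: ID_REF")
  pos <- utils::read.delim(positions_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("probe_id", "chrom", "start", "end"), names(pos))
  abort_if(length(missing_cols) > 0,
           "missing column: ", paste(missing_cols, collapse = ", "))
  keep <- tab$ID_REF %in% pos$probe_id
  if (any(!keep)) {
    message(sum(!keep), " probe(s) without a position record dropped")
  }
  tab <- tab[keep, , drop = FALSE]
  abort_if(nrow(tab) == 0, "no probes with positions")
  m <- match(tab$ID_REF, pos$probe_id)
  samples <- setdiff(names(tab), "ID_REF")
  out <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s, probe_id = tab$ID_REF,
               chrom = pos$chrom[m], start = pos$start[m], end = pos$end[m],
               log2_ratio = suppressWarnings(as.numeric(tab[[s]])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

provenance_header <- function(config_hash, seed) {
  sprintf("# gclineage %s; config_hash=%s; seed=%s",
          as.character(utils::packageVersion("gclineage")), config_hash, seed)
}

write_tsv_with_provenance <- function(df, path, config_hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config_hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the pipeline result bundle
#'
#' Emits lineage assignments, per-sample CNA burden, penetrance tables, the
#' differential gene table and (when present) the phenotype table, each as
#' TSV with a provenance comment, plus a JSON manifest.  Output is
#' deterministic: rerunning the same bundle writes byte-identical files.
#'
#' @param results result bundle from [run_pipeline()] (or a compatible
#'   list).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  abort_if(!ok || file.access(out_dir, 2) != 0, "cannot write to directory: ", out_dir)
  h <- results$config_hash %||% "unknown"
  s <- results$seed %||% "NA"
  paths <- character()
  emit <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(out_dir, name)
    write_tsv_with_provenance(df, p, h, s)
    paths[[name]] <<- p
  }
  emit(results$lineages, "lineage_assignments.tsv")
  emit(results$burden, "cna_burden.tsv")
  emit(results$penetrance, "arm_penetrance.tsv")
  emit(results$differential, "differential_genes.tsv")
  emit(results$phenotypes, "phenotypes.tsv")
  emit(results$sweep, "gene_size_sweep.tsv")
  manifest <- list(
    package = "gclineage",
    version = as.character(utils::packageVersion("gclineage")),
    config_hash = h,
    seed = s,
    files = as.list(sort(names(paths)))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  paths[["manifest.json"]] <- mp
  invisible(unlist(paths))
}
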