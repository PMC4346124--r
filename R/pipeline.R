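# End-to-end orchestration: simulate/load -> average -> call -> burden ->
# penetrance -> gene-size sweep -> lineage labels -> differential screen ->
# phenotype -> report, from one validated config, with provenance stamping.

PIPELINE_DEFAULTS <- list(
  gain_threshold = 0.3219,
  loss_threshold = -0.3219,
  strict = TRUE,
  sweep_thresholds = c(10, 6, 4, 3, 2),
  k = 3,
  alpha = 0.05,
  arm_fraction_threshold = 0.5,
  labelling = "auto",
  seed = 1
)

KNOWN_CONFIG_KEYS <- c(names(PIPELINE_DEFAULTS),
                       "simulate", "inputs", "manual_map", "out_dir")

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML file path or a list.  Fills defaults (CNA thresholds
#' +/-0.3219, sweep thresholds 10/6/4/3/2, k = 3, alpha = 0.05), rejects
#' unknown keys, and reports every error at once rather than stopping at
#' the first.
#'
#' @param config YAML file path or list.  Must contain either a `simulate`
#'   block (lineages, same_tumour_pairs, concurrent_pairs, noise fields) or
#'   an `inputs` block (paths: probes, genes, arms, metadata, optional
#'   ihc).
#' @return A normalised `run_config` list, or an error listing every
#'   problem.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    abort_if(!file.exists(config), "config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  abort_if(!is.list(config), "config must be a list or YAML file")
  errors <- character()
  unknown <- setdiff(names(config), KNOWN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  for (k in names(PIPELINE_DEFAULTS)) {
    config[[k]] <- config[[k]] %||% PIPELINE_DEFAULTS[[k]]
  }
  if (!is.numeric(config$alpha) || length(config$alpha) != 1 ||
      config$alpha <= 0 || config$alpha > 1) {
    errors <- c(errors, "alpha must be in (0,1]")
  }
  if (!is.numeric(config$gain_threshold) || config$gain_threshold <= 0) {
    errors <- c(errors, "gain_threshold must be > 0")
  }
  if (!is.numeric(config$loss_threshold) || config$loss_threshold >= 0) {
    errors <- c(errors, "loss_threshold must be < 0")
  }
  if (!is.numeric(config$k) || config$k < 1) {
    errors <- c(errors, "k must be a positive integer")
  }
  if (!is.numeric(config$sweep_thresholds) || any(config$sweep_thresholds < 1)) {
    errors <- c(errors, "sweep_thresholds must be positive integers")
  }
  if (!config$labelling %in% c("auto", "manual")) {
    errors <- c(errors, "labelling must be auto or manual")
  }
  if (identical(config$labelling, "manual") && is.null(config$manual_map)) {
    errors <- c(errors, "manual labelling requires manual_map")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    errors <- c(errors, "seed must be a single integer")
  }
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs) {
    errors <- c(errors, "config needs a simulate or inputs block")
  }
  if (has_sim && has_inputs) {
    errors <- c(errors, "config cannot have both simulate and inputs")
  }
  if (has_inputs) {
    for (key in c("probes", "genes", "arms", "metadata")) {
      p <- config$inputs[[key]]
      if (is.null(p)) {
        errors <- c(errors, paste0("inputs$", key, " is required"))
      } else if (!file.exists(p)) {
        errors <- c(errors, paste0("inputs$", key, ": file not found: ", p))
      }
    }
  }
  abort_if(length(errors) > 0,
           "invalid config:\n  - ", paste(errors, collapse = "\n  - "))
  structure(config, class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  # drop the output directory from the hash: it does not affect results
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tf)
  unname(tools::md5sum(tf))
}

run_stage <- function(name, quiet, code) {
  if (!quiet) message("[", name, "] ...")
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(code), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (!quiet) {
    message(sprintf("[%s] done (%.1fs)", name, proc.time()[["elapsed"]] - t0))
  }
  res
}

#' Run the full analysis pipeline
#'
#' Stages run in order (simulate/load, average, call, burden, group
#' frequencies, penetrance, gene-size sweep, lineage labelling,
#' differential screen, phenotype); intermediate artifacts are kept in the
#' returned bundle, a failed stage aborts with the stage name, and the
#' report carries a manifest with version, config hash and seed.
#'
#' The gene-size sweep (pair-adjacency
#' standard) runs on the combined mucosal + deep sample set, while the
#' final k-cluster lineage call is made on the mucosal samples only.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @param out_dir optional output directory for [write_report()] and the
#'   CDT/GTR/ATR bundles.
#' @param quiet suppress stage messages (default TRUE).
#' @return The result bundle (invisibly when writing a report): a list with
#'   the gene matrix, calls, burden, penetrance, sweep, lineages,
#'   differential results, phenotypes, config hash and seed.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  h <- config_hash(config)
  seed <- as.integer(config$seed)

  data <- run_stage("load", quiet, {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      cc <- cohort_config(
        lineages = unlist(sim$lineages %||% c(stable = 11, intermediate = 4, unstable = 28)),
        same_tumour_pairs = sim$same_tumour_pairs %||% 16,
        concurrent_pairs = sim$concurrent_pairs %||% 5,
        noise = noise_model(
          probe_sd = sim$probe_sd %||% 0.3,
          gene_bias_sd = sim$gene_bias_sd %||% 0.5,
          part_divergence = sim$part_divergence %||% 0.005,
          concurrent_divergence = sim$concurrent_divergence %||% 0.05,
          purity = sim$purity %||% 1.0),
        genome = if (!is.null(sim$n_chromosomes) || !is.null(sim$genes_per_chromosome)) {
          build_genome(n_chromosomes = sim$n_chromosomes %||% 8,
                       genes_per_chromosome = sim$genes_per_chromosome %||% 100,
                       seed = derive_seed(seed, "genome"))
        } else {
          NULL
        },
        seed = seed)
      cohort <- simulate_cohort(cc)
      annotation <- cohort$genome$genes
      arms <- data.frame(chrom = cohort$genome$chromosomes$name,
                         centromere = cohort$genome$chromosomes$centromere,
                         stringsAsFactors = FALSE)
      ihc <- simulate_ihc(cohort$metadata, seed = derive_seed(seed, "ihc"))
      list(probes = cohort$probes, metadata = cohort$metadata,
           annotation = annotation, arms = arms, ihc = ihc,
           truth = cohort$truth)
    } else {
      probes <- read_probe_table(config$inputs$probes)
      annotation <- read_gene_bed(config$inputs$genes)
      arms <- read_arm_table(config$inputs$arms)
      metadata <- read_metadata(config$inputs$metadata)
      ihc <- if (!is.null(config$inputs$ihc)) {
        utils::read.delim(config$inputs$ihc, stringsAsFactors = FALSE)
      } else {
        NULL
      }
      list(probes = probes, metadata = metadata, annotation = annotation,
           arms = arms, ihc = ihc, truth = NULL)
    }
  })

  gm <- run_stage("average", quiet,
                  average_probes_to_genes(data$probes, data$annotation))
  params <- cna_call_params(config$gain_threshold, config$loss_threshold,
                            config$strict)
  calls <- run_stage("call", quiet, call_cna(gm, params))
  burden <- run_stage("burden", quiet, cna_burden(calls))
  group_freq <- run_stage("group_frequency", quiet,
                          group_cna_frequency(burden, data$metadata))
  penetrance <- run_stage("penetrance", quiet,
                          arm_penetrance(calls, data$arms, data$metadata,
                                         arm_fraction_threshold = config$arm_fraction_threshold))

  pairs <- sample_pairs_from_metadata(data$metadata)
  sweep <- run_stage("sweep", quiet,
                     sweep_gene_size(gm, pairs,
                                     thresholds = config$sweep_thresholds,
                                     k = config$k))
  sel <- sweep$selected
  if (is.na(sel)) sel <- utils::tail(sweep$table$min_probes, 1)

  lineages <- run_stage("label", quiet, {
    # final lineage call on the mucosal set at the selected gene size
    muc_ids <- data$metadata$sample_id[data$metadata$part == "mucosal"]
    gm_sel <- subset_genes(gm, gm$genes$gene_id[gm$genes$probe_count >= sel])
    gm_muc <- subset_samples(gm_sel, muc_ids)
    tree <- complete_linkage(gm_muc, axis = "samples")
    part <- cut_tree(tree, config$k)
    la <- label_lineages(part, burden,
                         mode = config$labelling,
                         manual_map = unlist(config$manual_map))
    la$tree <- tree
    la$selected_min_probes <- sel
    la
  })

  differential <- run_stage("differential", quiet,
                            find_differential_genes(
                              subset_samples(gm, lineages$assignments$sample_id),
                              lineages, alpha = config$alpha))

  twod <- NULL
  if (length(differential$selected) >= 2) {
    twod <- run_stage("supervised_2d", quiet,
                      supervised_2d_cluster(
                        subset_samples(gm, lineages$assignments$sample_id),
                        differential$selected,
                        out_prefix = if (!is.null(out_dir)) {
                          dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
                          file.path(out_dir, "supervised_2d")
                        } else {
                          NULL
                        }))
  }

  phenotypes <- NULL
  phenotype_report <- NULL
  if (!is.null(data$ihc)) {
    phenotypes <- run_stage("phenotype", quiet, classify_phenotypes(data$ihc))
    phenotype_report <- run_stage("phenotype_report", quiet,
                                  phenotype_by_group_report(phenotypes, data$metadata))
  }

  diff_table <- differential$table
  results <- list(
    gene_matrix = gm,
    calls = calls,
    burden = burden,
    group_frequency = group_freq,
    penetrance = penetrance,
    sweep = sweep$table,
    sweep_full = sweep,
    lineages = lineages$assignments,
    lineage_assignment = lineages,
    differential = diff_table[diff_table$significant |
                                !diff_table$testable, , drop = FALSE],
    differential_full = differential,
    supervised_2d = twod,
    phenotypes = phenotypes,
    phenotype_report = phenotype_report,
    metadata = data$metadata,
    truth = data$truth,
    config_hash = h,
    seed = seed
  )
  if (!is.null(out_dir)) {
    run_stage("report", quiet, write_report(results, out_dir))
    return(invisible(results))
  }
  results
}
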