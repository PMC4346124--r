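# Synthetic aCGH cohort generator.
#
# Emulates the data structure of an FFPE/WGA array-CGH study of gastric
# intramucosal neoplasms: a miniature genome of genes carrying 2-12 probes
# each, three lineage archetypes of increasing CNA burden with recurrent
# chromosome-arm events (8q/20q gains, 5q/21q losses), paired samples from
# two parts of one tumour, concurrent separate lesions in one patient, probe
# noise, and a gene-specific amplification bias that enters both channels
# and cancels exactly in the emitted tumour/reference ratio.
#
# Coordinates are 0-based, half-open throughout (BED convention).

#' Build a miniature genome model
#'
#' Lays out `n_chromosomes` chromosomes of equal gene capacity, with a
#' centromere at 40% of each chromosome's length.  Each gene occupies a slot
#' of 10 kb and carries a number of probes drawn from
#' `probe_count_distribution`; a few intergenic probes per chromosome fall
#' outside every gene (they are dropped during gene averaging).
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param genes_per_chromosome number of genes per chromosome (>= 1).
#' @param probe_count_distribution function of one argument `n` returning
#'   `n` integer probe counts >= 1.  The default draws uniformly from 2-12
#'   so the >=2 ... >=10 gene-size sweep is exercisable.
#' @param intergenic_probes_per_chromosome probes per chromosome assigned to
#'   no gene (default 5).
#' @param chromosome_names names for the chromosomes; the default names the
#'   8 miniature chromosomes after human chromosomes relevant to gastric
#'   cancer copy-number biology (including 5, 8, 20 and 21, whose arms carry
#'   the recurrent events of the lineage archetypes).
#' @param seed integer seed; the genome is deterministic given it.
#' @return An object of class `genome_model`: a list with data frames
#'   `chromosomes` (name, length, centromere), `genes` (gene_id, chrom,
#'   start, end, probe_count, arm) and `probes` (probe_id, chrom, start,
#'   end, gene_id; `gene_id` is `NA` for intergenic probes).
#' @export
build_genome <- function(n_chromosomes = 8,
                         genes_per_chromosome = 100,
                         probe_count_distribution = function(n) sample(2:12, n, replace = TRUE),
                         intergenic_probes_per_chromosome = 5,
                         chromosome_names = NULL,
                         seed = 1) {
  abort_if(!is.numeric(n_chromosomes) || n_chromosomes < 1,
           "n_chromosomes must be a positive integer")
  abort_if(!is.numeric(genes_per_chromosome) || genes_per_chromosome < 1,
           "genes_per_chromosome must be a positive integer")
  n_chromosomes <- as.integer(n_chromosomes)
  genes_per_chromosome <- as.integer(genes_per_chromosome)

  slot_bp <- 10000L          # one gene slot
  gene_start_off <- 2000L    # gene occupies [slot+2000, slot+8000)
  gene_end_off <- 8000L

  if (is.null(chromosome_names)) {
    default8 <- c("chr1", "chr3", "chr5", "chr8", "chr17", "chr18", "chr20", "chr21")
    chromosome_names <- if (n_chromosomes <= length(default8)) {
      default8[seq_len(n_chromosomes)]
    } else {
      paste0("chr", seq_len(n_chromosomes))
    }
  }
  abort_if(length(chromosome_names) != n_chromosomes ||
             anyDuplicated(chromosome_names) > 0,
           "chromosome_names must be ", n_chromosomes, " unique names")

  with_seed(seed, {
    chrom_len <- genes_per_chromosome * slot_bp
    chroms <- data.frame(
      name = chromosome_names,
      length = chrom_len,
      centromere = as.integer(round(0.4 * chrom_len)),
      stringsAsFactors = FALSE
    )

    gene_list <- vector("list", n_chromosomes)
    probe_list <- vector("list", n_chromosomes)
    for (ci in seq_len(n_chromosomes)) {
      chrom <- chroms$name[ci]
      slot0 <- (seq_len(genes_per_chromosome) - 1L) * slot_bp
      gstart <- slot0 + gene_start_off
      gend <- slot0 + gene_end_off
      counts <- as.integer(probe_count_distribution(genes_per_chromosome))
      abort_if(any(!is.finite(counts)) || any(counts < 1L),
               "probe_count_distribution must yield integers >= 1")
      mid <- (gstart + gend) / 2
      arm <- ifelse(mid < chroms$centromere[ci], "p", "q")
      genes <- data.frame(
        gene_id = sprintf("G%s_%03d", sub("^chr", "", chrom), seq_len(genes_per_chromosome)),
        chrom = chrom,
        start = gstart,
        end = gend,
        probe_count = counts,
        arm = paste0(chrom, arm),
        stringsAsFactors = FALSE
      )
      # probes at distinct positions inside the gene interval
      ppos <- unlist(lapply(seq_len(genes_per_chromosome), function(gi) {
        span <- gend[gi] - gstart[gi] - 60L
        gstart[gi] + sort(sample.int(span, counts[gi]))
      }), use.names = FALSE)
      pg <- rep(genes$gene_id, counts)
      if (intergenic_probes_per_chromosome > 0) {
        # intergenic probes live in the [slot, slot+2000) gaps
        gap_slots <- sample.int(genes_per_chromosome, intergenic_probes_per_chromosome,
                                replace = TRUE)
        ipos <- (gap_slots - 1L) * slot_bp + sample.int(gene_start_off - 60L,
                                                        intergenic_probes_per_chromosome)
        ppos <- c(ppos, ipos)
        pg <- c(pg, rep(NA_character_, intergenic_probes_per_chromosome))
      }
      o <- order(ppos)
      ppos <- ppos[o]; pg <- pg[o]
      dup <- duplicated(ppos)
      ppos <- ppos[!dup]; pg <- pg[!dup]
      probe_list[[ci]] <- data.frame(
        probe_id = sprintf("P%s_%05d", sub("^chr", "", chrom), seq_along(ppos)),
        chrom = chrom,
        start = as.integer(ppos),
        end = as.integer(ppos) + 60L,
        gene_id = pg,
        stringsAsFactors = FALSE
      )
      gene_list[[ci]] <- genes
    }
    genes <- do.call(rbind, gene_list)
    probes <- do.call(rbind, probe_list)
    rownames(genes) <- rownames(probes) <- NULL
    # true probe count after de-duplication
    tab <- table(probes$gene_id[!is.na(probes$gene_id)])
    genes$probe_count <- as.integer(tab[genes$gene_id])
    structure(
      list(chromosomes = chroms, genes = genes, probes = probes, seed = as.integer(seed)),
      class = "genome_model"
    )
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %d genes, %d probes (%d intergenic)\n",
              nrow(x$chromosomes), nrow(x$genes), nrow(x$probes),
              sum(is.na(x$probes$gene_id))))
  invisible(x)
}

#' Lineage archetype specification
#'
#' @param label one of "stable", "intermediate", "unstable".
#' @param focal_cna_rate per-gene probability of a private focal gain/loss.
#' @param arm_events data frame with columns `arm`, `type` ("gain"/"loss"),
#'   `prob`; may be empty.
#' @param copy_gain integer copy number of a gain (default 3).
#' @param copy_loss integer copy number of a loss (default 1).
#' @return A `lineage_spec` list.
#' @export
lineage_spec <- function(label, focal_cna_rate, arm_events = NULL,
                         copy_gain = 3L, copy_loss = 1L) {
  abort_if(!label %in% c("stable", "intermediate", "unstable"),
           "label must be one of stable/intermediate/unstable")
  abort_if(focal_cna_rate < 0 || focal_cna_rate > 1,
           "focal_cna_rate must be in [0,1]")
  if (is.null(arm_events)) {
    arm_events <- data.frame(arm = character(), type = character(),
                             prob = numeric(), stringsAsFactors = FALSE)
  }
  abort_if(!all(c("arm", "type", "prob") %in% names(arm_events)),
           "arm_events needs columns arm, type, prob")
  abort_if(any(arm_events$prob < 0 | arm_events$prob > 1),
           "arm event probabilities must be in [0,1]")
  abort_if(!all(arm_events$type %in% c("gain", "loss")),
           "arm event type must be gain or loss")
  structure(list(label = label, focal_cna_rate = focal_cna_rate,
                 arm_events = arm_events,
                 copy_gain = as.integer(copy_gain),
                 copy_loss = as.integer(copy_loss)),
            class = "lineage_spec")
}

#' Default lineage archetypes
#'
#' Each lineage is an independent genetic lineage with its own recurrent
#' copy-number signature — clustering groups samples by shared alteration
#' patterns (the uncentred correlation is scale-invariant), so what makes a
#' lineage a cluster is recurrence, not burden alone.  Core signature
#' events carry probability 1 (the defining lesions of the lineage);
#' secondary events are sub-clonal.  Stable tumours carry a recurrent 5q
#' loss and little else (5q losses concentrate in non-invasive tumours);
#' intermediate tumours an 8q gain with 17p/18q losses; unstable tumours
#' the 8q and 20q gains and 21q losses recurrent in invasive gastric
#' cancer, plus the highest private focal rate.  Focal rates are ordered
#' stable < intermediate <= unstable.
#'
#' @return Named list of three `lineage_spec` objects.
#' @export
default_lineage_specs <- function() {
  list(
    stable = lineage_spec("stable", focal_cna_rate = 0.02,
      arm_events = data.frame(arm = "chr5q", type = "loss", prob = 1.0,
                              stringsAsFactors = FALSE)),
    intermediate = lineage_spec("intermediate", focal_cna_rate = 0.08,
      arm_events = data.frame(arm = c("chr8q", "chr17p", "chr18q"),
                              type = c("gain", "loss", "loss"),
                              prob = c(1.0, 0.6, 0.5), stringsAsFactors = FALSE)),
    unstable = lineage_spec("unstable", focal_cna_rate = 0.15,
      arm_events = data.frame(arm = c("chr8q", "chr20q", "chr21q", "chr1q", "chr3p"),
                              type = c("gain", "gain", "loss", "gain", "loss"),
                              prob = c(1.0, 1.0, 0.7, 0.5, 0.5),
                              stringsAsFactors = FALSE))
  )
}

#' Noise model for simulated probe measurements
#'
#' @param probe_sd SD of additive probe-level noise on the log2 scale.
#' @param gene_bias_sd SD of a per-gene offset applied identically to the
#'   tumour and reference channels, emulating reproducible whole-genome
#'   amplification bias; it cancels exactly in the emitted log2 T/R ratio.
#' @param part_divergence per-gene probability of an extra private event in
#'   a second sample of the same tumour.
#' @param concurrent_divergence same, for a separate concurrent lesion of
#'   the same patient; must exceed `part_divergence`.
#' @param purity neoplastic cell fraction of the tumour sample (default 1).
#' @return A `noise_model` list.
#' @export
noise_model <- function(probe_sd = 0.3, gene_bias_sd = 0.5,
                        part_divergence = 0.005, concurrent_divergence = 0.05,
                        purity = 1.0) {
  abort_if(probe_sd < 0, "probe_sd must be >= 0")
  abort_if(gene_bias_sd < 0, "gene_bias_sd must be >= 0")
  abort_if(part_divergence < 0 || concurrent_divergence > 1 ||
             part_divergence >= concurrent_divergence,
           "need 0 <= part_divergence < concurrent_divergence <= 1")
  abort_if(purity <= 0 || purity > 1, "purity must be in (0,1]")
  structure(list(probe_sd = probe_sd, gene_bias_sd = gene_bias_sd,
                 part_divergence = part_divergence,
                 concurrent_divergence = concurrent_divergence,
                 purity = purity),
            class = "noise_model")
}

#' Simulate a true copy-number profile for one lesion
#'
#' Arm events are applied first (setting every gene on the arm to the event
#' copy number); focal events then override individual genes.  Genes hit by
#' no event stay diploid (copy 2).
#'
#' @param genome a `genome_model`.
#' @param spec a `lineage_spec`.
#' @param seed integer seed.
#' @return A `true_profile`: list with integer vector `copy` (named by
#'   gene_id) and the lineage `label`.
#' @export
simulate_profile <- function(genome, spec, seed) {
  stopifnot(inherits(genome, "genome_model"), inherits(spec, "lineage_spec"))
  known_arms <- unique(genome$genes$arm)
  bad <- setdiff(spec$arm_events$arm, known_arms)
  abort_if(length(bad) > 0,
           "unknown arm(s) in lineage spec: ", paste(bad, collapse = ", "))
  with_seed(seed, {
    copy <- setNames(rep(2L, nrow(genome$genes)), genome$genes$gene_id)
    if (nrow(spec$arm_events) > 0) {
      for (i in seq_len(nrow(spec$arm_events))) {
        ev <- spec$arm_events[i, ]
        if (runif(1) < ev$prob) {
          hit <- genome$genes$arm == ev$arm
          copy[hit] <- if (ev$type == "gain") spec$copy_gain else spec$copy_loss
        }
      }
    }
    if (spec$focal_cna_rate > 0) {
      focal <- runif(length(copy)) < spec$focal_cna_rate
      dir_gain <- runif(length(copy)) < 0.5
      copy[focal & dir_gain] <- spec$copy_gain
      copy[focal & !dir_gain] <- spec$copy_loss
    }
    structure(list(copy = copy, label = spec$label), class = "true_profile")
  })
}

# Divergence step shared by same-tumour parts and concurrent lesions: with
# probability `rate` per gene, a diploid gene acquires a random private
# gain/loss and an altered gene reverts to diploid.
diverge_profile <- function(profile, rate, copy_gain, copy_loss, seed) {
  if (rate <= 0) return(profile)
  with_seed(seed, {
    copy <- profile$copy
    hit <- runif(length(copy)) < rate
    was_diploid <- copy == 2L
    gain <- runif(length(copy)) < 0.5
    copy[hit & was_diploid & gain] <- copy_gain
    copy[hit & was_diploid & !gain] <- copy_loss
    copy[hit & !was_diploid] <- 2L
    profile$copy <- copy
    profile
  })
}

# Reproducible per-gene WGA bias: a function of the genome only, so the
# same gene receives the same bias in every sample and in both channels.
gene_bias_vector <- function(genome, gene_bias_sd) {
  with_seed(derive_seed(genome$seed, "gene_bias"),
            setNames(rnorm(nrow(genome$genes), 0, gene_bias_sd),
                     genome$genes$gene_id))
}

#' Simulate probe-level measurements for one sample
#'
#' Each probe's emitted value is the difference of log2 tumour and reference
#' channel intensities.  The per-gene amplification bias enters both
#' channels and therefore cancels exactly; with `probe_sd = 0` the emitted
#' log2 ratio equals `log2(copy/2)` (with a purity adjustment when
#' `purity < 1`).  Intergenic probes behave as diploid.
#'
#' @param profile a `true_profile`.
#' @param genome the `genome_model` the profile was simulated on.
#' @param noise a `noise_model`.
#' @param seed integer seed.
#' @param sample_id sample identifier for the output table.
#' @return Data frame with columns sample_id, probe_id, chrom, start, end,
#'   log2_ratio (one row per genome probe).
#' @export
simulate_sample <- function(profile, genome, noise, seed, sample_id = "S1") {
  stopifnot(inherits(profile, "true_profile"), inherits(genome, "genome_model"),
            inherits(noise, "noise_model"))
  abort_if(!identical(names(profile$copy), genome$genes$gene_id),
           "profile and genome gene sets do not match")
  probes <- genome$probes
  copy <- rep(2, nrow(probes))
  has_gene <- !is.na(probes$gene_id)
  copy[has_gene] <- profile$copy[probes$gene_id[has_gene]]
  # purity: observed tumour copy is a mixture of tumour and diploid stroma
  eff_copy <- noise$purity * copy + (1 - noise$purity) * 2
  bias <- rep(0, nrow(probes))
  if (noise$gene_bias_sd > 0) {
    gb <- gene_bias_vector(genome, noise$gene_bias_sd)
    bias[has_gene] <- gb[probes$gene_id[has_gene]]
  }
  # both channels carry the same per-gene bias; it cancels by construction
  channel_t <- log2(eff_copy) + bias
  channel_r <- log2(2) + bias
  lr <- channel_t - channel_r
  with_seed(seed, {
    if (noise$probe_sd > 0) lr <- lr + rnorm(length(lr), 0, noise$probe_sd)
    data.frame(sample_id = sample_id, probe_id = probes$probe_id,
               chrom = probes$chrom, start = probes$start, end = probes$end,
               log2_ratio = lr, stringsAsFactors = FALSE)
  })
}

#' Cohort configuration
#'
#' Defaults give a study-shaped cohort: 11 stable, 4
#' intermediate and 28 unstable mucosal lesions; 16 of the unstable lesions
#' contribute a second, deeply invasive part; 5 patients carry a concurrent
#' second lesion.
#'
#' @param lineages named list/vector of lesion counts per lineage.
#' @param same_tumour_pairs number of lesions sampled in two parts
#'   (mucosal + deep); allocated to unstable lesions first.
#' @param concurrent_pairs number of patients with two concurrent separate
#'   lesions; allocated within stable, then intermediate, then unstable.
#' @param noise a `noise_model`.
#' @param specs named list of `lineage_spec` objects.
#' @param genome a `genome_model`, or NULL to build the default one.
#' @param seed integer seed for the whole cohort.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(lineages = c(stable = 11, intermediate = 4, unstable = 28),
                          same_tumour_pairs = 16,
                          concurrent_pairs = 5,
                          noise = noise_model(),
                          specs = default_lineage_specs(),
                          genome = NULL,
                          seed = 1) {
  lineages <- unlist(lineages)
  abort_if(is.null(names(lineages)) ||
             !all(names(lineages) %in% c("stable", "intermediate", "unstable")),
           "lineages must be named with stable/intermediate/unstable")
  abort_if(any(lineages < 0) || sum(lineages) < 1, "need at least one lesion")
  abort_if(!all(names(lineages) %in% names(specs)),
           "every lineage needs a spec")
  n_lesions <- sum(lineages)
  abort_if(same_tumour_pairs > n_lesions,
           "same_tumour_pairs (", same_tumour_pairs,
           ") exceeds the number of lesions (", n_lesions, ")")
  abort_if(2 * concurrent_pairs > n_lesions,
           "concurrent_pairs (", concurrent_pairs,
           ") exceeds available lesions")
  structure(list(lineages = lineages,
                 same_tumour_pairs = as.integer(same_tumour_pairs),
                 concurrent_pairs = as.integer(concurrent_pairs),
                 noise = noise, specs = specs, genome = genome,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Vienna-group and size assignment used for synthetic metadata.  Stable and
# intermediate lesions are non-invasive (A/B); unstable lesions span B, Cm
# and Cd, matching the observation that only the unstable cluster contains
# invasive carcinomas.  Sizes are drawn from lognormals roughly matching the
# reported per-group means (5.7 / 9.4 / 27.1 / 51.1 mm).
assign_vienna_group <- function(lineage, idx_in_lineage) {
  if (lineage == "stable") {
    if (idx_in_lineage %% 2 == 1) "A" else "B"
  } else if (lineage == "intermediate") {
    if (idx_in_lineage %% 2 == 1) "B" else "A"
  } else {
    c("B", "Cm", "Cd")[1 + (idx_in_lineage %% 3)]
  }
}

group_size_mm <- function(group) {
  mu <- c(A = 5.7, B = 9.4, Cm = 27.1, Cd = 51.1)[group]
  round(rlnorm(1, meanlog = log(mu), sdlog = 0.4), 1)
}

#' Simulate a full cohort
#'
#' Generates true profiles per lesion, probe-level measurements per sample,
#' and sample metadata with ground-truth lineage labels.  Same-tumour pairs
#' share one profile modified at rate `part_divergence`; concurrent lesions
#' of one patient derive from a shared patient-level base profile with
#' per-lesion divergence at rate `concurrent_divergence`.  Random streams
#' are split per lesion/sample, so enlarging the cohort never perturbs
#' earlier samples.
#'
#' @param config a `cohort_config`.
#' @return List with `probes` (long probe table), `metadata` (one row per
#'   sample: sample_id, patient_id, lesion_id, part, vienna_group, size_mm,
#'   truth_lineage), `truth` (list of per-lesion `true_profile`s) and
#'   `genome`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  genome <- config$genome %||% build_genome(seed = derive_seed(config$seed, "genome"))
  noise <- config$noise
  specs <- config$specs
  seed <- config$seed

  lineage_of <- rep(names(config$lineages), config$lineages)
  n_lesions <- length(lineage_of)
  lesion_ids <- sprintf("L%02d", seq_len(n_lesions))

  # concurrent pairs: walk lineages in order stable, intermediate, unstable
  # and join consecutive unpaired lesions of one lineage into one patient
  conc_partner <- rep(NA_integer_, n_lesions)
  remaining <- config$concurrent_pairs
  for (lin in c("stable", "intermediate", "unstable")) {
    idx <- which(lineage_of == lin & is.na(conc_partner))
    while (remaining > 0 && length(idx) >= 2) {
      conc_partner[idx[1]] <- idx[2]
      conc_partner[idx[2]] <- idx[1]
      idx <- idx[-(1:2)]
      remaining <- remaining - 1
    }
  }
  abort_if(remaining > 0, "not enough same-lineage lesions for concurrent_pairs")

  # patient assignment: one patient per lesion except concurrent pairs
  patient_of <- integer(n_lesions)
  pid <- 0L
  for (i in seq_len(n_lesions)) {
    if (patient_of[i] == 0L) {
      pid <- pid + 1L
      patient_of[i] <- pid
      if (!is.na(conc_partner[i])) patient_of[conc_partner[i]] <- pid
    }
  }

  # same-tumour (two-part) lesions: unstable first, then intermediate, stable
  two_part <- rep(FALSE, n_lesions)
  want <- config$same_tumour_pairs
  for (lin in c("unstable", "intermediate", "stable")) {
    idx <- which(lineage_of == lin & !two_part)
    take <- min(want, length(idx))
    if (take > 0) two_part[idx[seq_len(take)]] <- TRUE
    want <- want - take
  }

  # lesion profiles; concurrent pairs share a patient-level base profile
  profiles <- vector("list", n_lesions)
  for (i in seq_len(n_lesions)) {
    if (!is.na(conc_partner[i]) && conc_partner[i] < i) {
      base <- attr(profiles[[conc_partner[i]]], "base")
      profiles[[i]] <- diverge_profile(base, noise$concurrent_divergence,
                                       specs[[lineage_of[i]]]$copy_gain,
                                       specs[[lineage_of[i]]]$copy_loss,
                                       derive_seed(seed, "conc", i))
    } else {
      base <- simulate_profile(genome, specs[[lineage_of[i]]],
                               derive_seed(seed, "lesion", i))
      prof <- base
      if (!is.na(conc_partner[i])) {
        prof <- diverge_profile(base, noise$concurrent_divergence,
                                specs[[lineage_of[i]]]$copy_gain,
                                specs[[lineage_of[i]]]$copy_loss,
                                derive_seed(seed, "conc", i))
        attr(prof, "base") <- base
      }
      profiles[[i]] <- prof
    }
  }

  meta_rows <- list()
  probe_tabs <- list()
  lineage_counter <- setNames(integer(length(config$lineages)), names(config$lineages))
  for (i in seq_len(n_lesions)) {
    lin <- lineage_of[i]
    lineage_counter[lin] <- lineage_counter[lin] + 1L
    group <- assign_vienna_group(lin, lineage_counter[lin])
    size_mm <- with_seed(derive_seed(seed, "size", i), group_size_mm(group))
    prof <- profiles[[i]]
    attr(prof, "base") <- NULL

    sid_m <- sprintf("%s_m", lesion_ids[i])
    probe_tabs[[sid_m]] <- simulate_sample(prof, genome, noise,
                                           derive_seed(seed, "sample", i, 1), sid_m)
    meta_rows[[sid_m]] <- data.frame(
      sample_id = sid_m, patient_id = sprintf("P%02d", patient_of[i]),
      lesion_id = lesion_ids[i], part = "mucosal", vienna_group = group,
      size_mm = size_mm, truth_lineage = lin, stringsAsFactors = FALSE)

    if (two_part[i]) {
      deep_prof <- diverge_profile(prof, noise$part_divergence,
                                   specs[[lin]]$copy_gain, specs[[lin]]$copy_loss,
                                   derive_seed(seed, "part", i))
      sid_d <- sprintf("%s_d", lesion_ids[i])
      probe_tabs[[sid_d]] <- simulate_sample(deep_prof, genome, noise,
                                             derive_seed(seed, "sample", i, 2), sid_d)
      meta_rows[[sid_d]] <- data.frame(
        sample_id = sid_d, patient_id = sprintf("P%02d", patient_of[i]),
        lesion_id = lesion_ids[i], part = "deep", vienna_group = group,
        size_mm = size_mm, truth_lineage = lin, stringsAsFactors = FALSE)
    }
  }

  probes <- do.call(rbind, probe_tabs)
  metadata <- do.call(rbind, meta_rows)
  rownames(probes) <- rownames(metadata) <- NULL
  names(profiles) <- lesion_ids
  profiles <- lapply(profiles, function(p) { attr(p, "base") <- NULL; p })
  list(probes = probes, metadata = metadata, truth = profiles, genome = genome)
}

#' Simulate immunohistochemistry positivity percentages
#'
#' Draws per-marker percent-positive values whose implied mucin phenotypes
#' follow the qualitative pattern typical of the Vienna groups: low-grade (A) lesions
#' are intestinal, high-grade (B) lesions mostly gastric/mixed, invasive
#' (Cm/Cd) lesions a mixture of gastric, intestinal and null phenotypes.
#'
#' @param metadata cohort metadata (one row per sample); only mucosal
#'   samples receive IHC rows.
#' @param seed integer seed.
#' @return Data frame with sample_id and percent-positive columns MUC2,
#'   MUC5AC, MUC6, CD10.
#' @export
simulate_ihc <- function(metadata, seed = 1) {
  m <- metadata[metadata$part == "mucosal", , drop = FALSE]
  draw_pct <- function(positive) {
    # positive markers land in [10, 95], negative in [0, 4]
    if (positive) runif(1, 10, 95) else runif(1, 0, 4)
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(m)), function(i) {
      g <- m$vienna_group[i]
      pheno <- if (g == "A") {
        "I"
      } else if (g == "B") {
        sample(c("G", "GI", "I"), 1, prob = c(0.4, 0.3, 0.3))
      } else {
        sample(c("G", "GI", "I", "N"), 1, prob = c(0.3, 0.28, 0.33, 0.09))
      }
      gastric <- pheno %in% c("G", "GI")
      intestinal <- pheno %in% c("I", "GI")
      data.frame(
        sample_id = m$sample_id[i],
        MUC2 = round(draw_pct(intestinal), 1),
        MUC5AC = round(draw_pct(gastric), 1),
        MUC6 = round(draw_pct(gastric && runif(1) < 0.7), 1),
        CD10 = round(draw_pct(intestinal && runif(1) < 0.6), 1),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
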