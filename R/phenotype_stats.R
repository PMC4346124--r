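# Mucin marker scoring, G/GI/I/N phenotype classification, and the
# categorical statistics used alongside (Cochran-Armitage trend, Fisher
# exact).

MARKERS <- c("MUC2", "MUC5AC", "MUC6", "CD10")
SCORE_LEVELS <- c("-", "+", "++", "+++")

#' Ordinal score from a percent-positive value
#'
#' Bands: "-" for [0, 5), "+" for [5, 30), "++" for [30, 60), "+++" for
#' [60, 100].  Vectorised; monotone in the percentage.
#'
#' @param percent_positive percentage(s) in [0, 100].
#' @return Ordered factor with levels `-`, `+`, `++`, `+++`.
#' @export
score_marker <- function(percent_positive) {
  abort_if(any(is.na(percent_positive)), "missing percent value")
  abort_if(any(percent_positive < 0 | percent_positive > 100),
           "percent must be in [0,100]")
  idx <- findInterval(percent_positive, c(0, 5, 30, 60))
  factor(SCORE_LEVELS[idx], levels = SCORE_LEVELS, ordered = TRUE)
}

score_is_positive <- function(score) {
  as.integer(factor(as.character(score), levels = SCORE_LEVELS)) >= 2L
}

#' Classify the mucin phenotype from the four marker scores
#'
#' Gastric positivity = MUC5AC and/or MUC6 scored at least "+"; intestinal
#' positivity = MUC2 and/or CD10 scored at least "+".  G = gastric only,
#' I = intestinal only, GI = both, N = neither.  Total and deterministic
#' over all score combinations.
#'
#' @param scores named vector/list with entries MUC2, MUC5AC, MUC6, CD10
#'   (characters among `-`, `+`, `++`, `+++`, or factors from
#'   [score_marker()]).
#' @return A `mucin_phenotype` list: `label` in G/GI/I/N,
#'   `gastric_positive`, `intestinal_positive`.
#' @export
classify_phenotype <- function(scores) {
  scores <- lapply(scores, as.character)
  missing <- setdiff(MARKERS, names(scores))
  abort_if(length(missing) > 0,
           "missing marker score(s): ", paste(missing, collapse = ", "))
  bad <- !unlist(scores[MARKERS]) %in% SCORE_LEVELS
  abort_if(any(bad), "invalid score value for ",
           paste(MARKERS[bad], collapse = ", "))
  gastric <- score_is_positive(scores$MUC5AC) || score_is_positive(scores$MUC6)
  intestinal <- score_is_positive(scores$MUC2) || score_is_positive(scores$CD10)
  label <- if (gastric && intestinal) "GI"
  else if (gastric) "G"
  else if (intestinal) "I"
  else "N"
  structure(list(label = label, gastric_positive = gastric,
                 intestinal_positive = intestinal),
            class = "mucin_phenotype")
}

#' Score and classify a table of IHC percent positivity
#'
#' @param ihc data frame with sample_id and percent-positive columns MUC2,
#'   MUC5AC, MUC6, CD10.
#' @return Data frame with sample_id, the four ordinal scores, phenotype
#'   (G/GI/I/N) and gastric/intestinal positivity flags.
#' @export
classify_phenotypes <- function(ihc) {
  missing <- setdiff(c("sample_id", MARKERS), names(ihc))
  abort_if(length(missing) > 0,
           "missing column: ", paste(missing, collapse = ", "))
  out <- data.frame(sample_id = ihc$sample_id, stringsAsFactors = FALSE)
  for (mk in MARKERS) out[[paste0(mk, "_score")]] <- as.character(score_marker(ihc[[mk]]))
  cls <- lapply(seq_len(nrow(ihc)), function(i) {
    classify_phenotype(setNames(as.list(out[i, paste0(MARKERS, "_score")]), MARKERS))
  })
  out$phenotype <- vapply(cls, `[[`, "", "label")
  out$gastric_positive <- vapply(cls, `[[`, TRUE, "gastric_positive")
  out$intestinal_positive <- vapply(cls, `[[`, TRUE, "intestinal_positive")
  out
}

#' Cochran-Armitage trend test for a 2 x k table
#'
#' Tests for a linear trend in a binary outcome across k ordered groups.
#' `Z = sum(s_i (x_i - n_i pbar)) / sqrt(pbar (1-pbar) (sum n_i s_i^2 -
#' (sum n_i s_i)^2 / N))` with default scores 1..k; two-sided asymptotic
#' normal p.  Z is 0 when the outcome proportion is identical across
#' groups and is negated when the group order is reversed.
#'
#' @param x successes per group (length k >= 2), or a 2 x k matrix whose
#'   first row holds successes and second row failures.
#' @param n group totals (ignored when `x` is a matrix).
#' @param scores group scores (default `1:k`).
#' @return List with `z` and two-sided `p`.
#' @export
cochran_armitage <- function(x, n = NULL, scores = NULL) {
  if (is.matrix(x)) {
    abort_if(nrow(x) != 2, "matrix input must be 2 x k")
    n <- colSums(x)
    x <- x[1, ]
  }
  k <- length(x)
  abort_if(k < 2, "need k >= 2 groups")
  abort_if(length(n) != k, "x and n differ in length")
  abort_if(any(n <= 0), "zero-margin table: every group total must be > 0")
  abort_if(any(x < 0 | x > n), "successes must lie in [0, n]")
  if (is.null(scores)) scores <- seq_len(k)
  N <- sum(n)
  pbar <- sum(x) / N
  abort_if(pbar == 0 || pbar == 1,
           "zero-margin table: outcome is constant")
  num <- sum(scores * (x - n * pbar))
  den <- pbar * (1 - pbar) * (sum(n * scores^2) - sum(n * scores)^2 / N)
  z <- num / sqrt(den)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Two-sided Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p by summing hypergeometric probabilities of all tables (with
#' the observed margins) at most as probable as the observed one, the
#' probability-ordering convention of [stats::fisher.test()], which this
#' wraps.
#'
#' @param table 2 x 2 matrix of non-negative integer counts with positive
#'   margins.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  abort_if(!is.matrix(table) || !all(dim(table) == c(2, 2)),
           "need a 2 x 2 table")
  abort_if(any(table < 0), "negative cell count")
  abort_if(any(table != round(table)), "cell counts must be integers")
  abort_if(any(rowSums(table) == 0) || any(colSums(table) == 0),
           "zero-margin table")
  stats::fisher.test(table)$p.value
}

#' Phenotype-by-group contingency report with trend and exact tests
#'
#' Builds the groups x (G/GI/I/N) contingency table and, for each
#' configured ordering of groups, a Cochran-Armitage trend test on the
#' binary outcome "expresses gastric markers (G or GI) vs not"; 2-group
#' orderings additionally get a Fisher exact test.
#'
#' @param phenotypes data frame with sample_id and phenotype (e.g. from
#'   [classify_phenotypes()]).
#' @param metadata sample metadata with sample_id and the grouping column.
#' @param group_col grouping column (default "vienna_group").
#' @param orderings list of ordered group vectors to test (default: all
#'   groups in their sorted order, if >= 2 groups).
#' @param outcome "gastric_positive" (default: the binary outcome
#'   "expresses gastric markers, G or GI") or "phenotype_ordinal", an
#'   interpretive variant that scores phenotypes on the gastric-intestinal
#'   axis G < GI < I (N excluded) and tests linear-by-linear association
#'   with the group ordering.
#' @return List with `table` (contingency counts), `tests` (data frame of
#'   trend/exact results).
#' @export
phenotype_by_group_report <- function(phenotypes, metadata,
                                      group_col = "vienna_group",
                                      orderings = NULL,
                                      outcome = c("gastric_positive",
                                                  "phenotype_ordinal")) {
  outcome <- match.arg(outcome)
  abort_if(!group_col %in% names(metadata), "missing column: ", group_col)
  if (nrow(phenotypes) == 0) {
    return(list(table = table(character(), factor(character(), levels = c("G", "GI", "I", "N"))),
                tests = data.frame()))
  }
  m <- match(phenotypes$sample_id, metadata$sample_id)
  abort_if(any(is.na(m)), "unknown sample(s): ",
           paste(utils::head(phenotypes$sample_id[is.na(m)], 5), collapse = ", "))
  grp <- metadata[[group_col]][m]
  tab <- table(group = grp,
               phenotype = factor(phenotypes$phenotype, levels = c("G", "GI", "I", "N")))
  gastric_pos <- phenotypes$phenotype %in% c("G", "GI")
  if (is.null(orderings)) {
    gl <- sort(unique(grp))
    orderings <- if (length(gl) >= 2) list(gl) else list()
  }
  tests <- list()
  for (ord in orderings) {
    bad <- setdiff(ord, grp)
    abort_if(length(bad) > 0, "unknown group(s): ", paste(bad, collapse = ", "))
    if (outcome == "gastric_positive") {
      x <- vapply(ord, function(g) sum(gastric_pos & grp == g), 0L)
      n <- vapply(ord, function(g) sum(grp == g), 0L)
      ca <- tryCatch(cochran_armitage(x, n), error = function(e) NULL)
      fp <- if (length(ord) == 2) {
        tb <- rbind(x, n - x)
        tryCatch(fisher_exact_2x2(tb), error = function(e) NA_real_)
      } else {
        NA_real_
      }
      z <- if (is.null(ca)) NA_real_ else ca$z
      p <- if (is.null(ca)) NA_real_ else ca$p
    } else {
      # linear-by-linear association of group order with the G<GI<I axis;
      # Z = r * sqrt(N - 1), two-sided normal p
      pheno_score <- c(G = 1, GI = 2, I = 3)[phenotypes$phenotype]
      keep <- !is.na(pheno_score) & grp %in% ord
      gs <- match(grp[keep], ord)
      ps <- pheno_score[keep]
      if (sum(keep) >= 3 && stats::sd(gs) > 0 && stats::sd(ps) > 0) {
        r <- stats::cor(gs, ps)
        z <- r * sqrt(sum(keep) - 1)
        p <- 2 * pnorm(-abs(z))
      } else {
        z <- NA_real_; p <- NA_real_
      }
      fp <- NA_real_
    }
    tests[[length(tests) + 1L]] <- data.frame(
      ordering = paste(ord, collapse = "<"),
      outcome = outcome, trend_z = z, trend_p = p,
      fisher_p = fp, stringsAsFactors = FALSE)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else data.frame()
  list(table = tab, tests = tests)
}
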