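#' Configure the gene-combination survival scan
#'
#' Thresholds and knobs for [combo_scan()] and its building blocks. The
#' defaults encode the analysis conventions the scan was designed around:
#' gene subsets of size 2 and 3 drawn from family genes with mean expression
#' strictly above 200 (RSEM scale), retained when mutated in at least 5% of
#' the cohort, and scored against a bootstrap background of random gene sets
#' whose accumulated mutation count lies within +/- 5 of the target.
#'
#' @param subset_sizes Subset sizes to enumerate; subset of `c(2, 3)`.
#' @param expression_threshold Mean-expression gate (strict `>`).
#' @param prevalence_threshold Minimum fraction of samples mutated in the
#'   subset (`>=`).
#' @param mutation_count_tolerance Half-width of the background matching
#'   window on total mutation count.
#' @param n_background Background draws per subset-size stratum (>= 100).
#' @param q_threshold Significance level on the empirical q-value, used by
#'   the size-3 exclusion rule and [inclusion_frequencies()].
#' @param exclude_significant_subsets Drop any size-3 subset that contains a
#'   size-2 subset already significant at `q_threshold` (default `TRUE`).
#' @param classes Mutation classes defining the per-sample indicator.
#' @param match Background matching target: `"candidate"` (default) draws
#'   each background set to match the total mutation count of a candidate
#'   of the same size; `"family_total"` matches the family-wide total.
#' @param exclude_family_background Exclude family genes from the background
#'   pool (default `TRUE`).
#' @param max_retries Redraw budget per background draw.
#' @param seed Integer seed governing all scan randomness.
#' @return Object of class `combo_config`.
#' @export
combo_config <- function(subset_sizes = c(2L, 3L),
                         expression_threshold = 200,
                         prevalence_threshold = 0.05,
                         mutation_count_tolerance = 5L,
                         n_background = 1000L,
                         q_threshold = 0.05,
                         exclude_significant_subsets = TRUE,
                         classes = c("missense", "truncation"),
                         match = c("candidate", "family_total"),
                         exclude_family_background = TRUE,
                         max_retries = 1000L,
                         seed = 1L) {
  cfg <- list(subset_sizes = sort(unique(as.integer(subset_sizes))),
              expression_threshold = expression_threshold,
              prevalence_threshold = prevalence_threshold,
              mutation_count_tolerance = as.integer(mutation_count_tolerance),
              n_background = as.integer(n_background),
              q_threshold = q_threshold,
              exclude_significant_subsets = exclude_significant_subsets,
              classes = classes,
              match = match.arg(match),
              exclude_family_background = exclude_family_background,
              max_retries = as.integer(max_retries),
              seed = seed)
  if (length(cfg$subset_sizes) == 0L ||
      !all(cfg$subset_sizes %in% c(2L, 3L))) {
    stopf("subset_sizes must be a non-empty subset of {2, 3}")
  }
  if (!is_positive_scalar(cfg$expression_threshold) &&
      cfg$expression_threshold != 0) {
    stopf("expression_threshold must be nonnegative")
  }
  if (!is_proportion(cfg$prevalence_threshold) ||
      cfg$prevalence_threshold <= 0) {
    stopf("prevalence_threshold must lie in (0, 1]")
  }
  if (cfg$mutation_count_tolerance < 0L) {
    stopf("mutation_count_tolerance must be nonnegative")
  }
  if (cfg$n_background < 100L) stopf("n_background must be >= 100")
  if (!is_proportion(cfg$q_threshold)) stopf("q_threshold must lie in [0, 1]")
  if (!all(cfg$classes %in% c("missense", "truncation", "other"))) {
    stopf("classes must be a subset of missense/truncation/other")
  }
  class(cfg) <- "combo_config"
  cfg
}

#' Expressed family genes eligible for the combination scan
#'
#' Family genes whose mean expression strictly exceeds the threshold
#' (a gene at exactly the threshold is excluded). Family genes absent from
#' the expression table are excluded with a warning.
#'
#' @param expression Data frame with columns `gene`, `mean_rsem`.
#' @param family Character vector of family gene symbols.
#' @param config A [combo_config()].
#' @return Sorted character vector of eligible gene symbols.
#' @export
eligible_genes <- function(expression, family, config = combo_config()) {
  missing <- setdiff(family, expression$gene)
  if (length(missing) > 0L) {
    warnf("eligible_genes: %d family gene(s) missing from the expression table excluded",
          length(missing))
    family <- setdiff(family, missing)
  }
  expr <- expression$mean_rsem[match(family, expression$gene)]
  eligible <- sort(family[expr > config$expression_threshold])
  if (length(eligible) == 0L) {
    stopf("no family gene passes the expression threshold (%g); review the threshold",
          config$expression_threshold)
  }
  eligible
}

#' Enumerate candidate gene subsets with mutated-sample indicators
#'
#' For every subset of each requested size over the eligible genes, the
#' per-sample indicator is 1 iff the sample has at least one qualifying
#' mutation in any subset gene. Subsets mutated in fewer than
#' `prevalence_threshold` of samples are dropped. Subsets containing any
#' gene set listed in `exclude_supersets_of` (the already-significant
#' smaller combinations) are dropped as well.
#'
#' @param eligible Character vector of eligible genes (subset of the matrix
#'   genes).
#' @param matrix A [build_mutation_matrix()] result whose `classes` define
#'   the qualifying mutations.
#' @param config A [combo_config()].
#' @param sizes Subset sizes to enumerate (default: `config$subset_sizes`).
#' @param exclude_supersets_of Optional list of character vectors; subsets
#'   containing any of them entirely are skipped.
#' @return Object of class `combo_candidates`: list with `sets` (list of
#'   gene vectors), `size`, `n_mutated`, `prevalence`, `indicator`
#'   (samples x candidates logical matrix) and `samples`.
#' @export
enumerate_candidates <- function(eligible, matrix, config = combo_config(),
                                 sizes = config$subset_sizes,
                                 exclude_supersets_of = NULL) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  if (!all(eligible %in% matrix$genes)) {
    stopf("eligible genes missing from the mutation matrix: %s",
          paste(setdiff(eligible, matrix$genes), collapse = ", "))
  }
  M <- matrix$indicator[, eligible, drop = FALSE] > 0L
  n <- nrow(M)
  min_count <- ceiling(config$prevalence_threshold * n)
  sets <- list()
  inds <- list()
  for (k in sizes) {
    if (length(eligible) < k) next
    combos <- utils::combn(length(eligible), k)
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j]
      genes <- eligible[idx]
      if (!is.null(exclude_supersets_of) &&
          any(vapply(exclude_supersets_of,
                     function(s) all(s %in% genes), logical(1)))) {
        next
      }
      ind <- rowSums(M[, idx, drop = FALSE]) > 0L
      cnt <- sum(ind)
      if (cnt < min_count) next
      sets[[length(sets) + 1L]] <- genes
      inds[[length(inds) + 1L]] <- ind
    }
  }
  m <- length(sets)
  indicator <- if (m > 0L) {
    matrix(unlist(inds), nrow = n, ncol = m,
           dimnames = list(matrix$samples, NULL))
  } else {
    matrix(logical(0), nrow = n, ncol = 0L,
           dimnames = list(matrix$samples, NULL))
  }
  n_mutated <- if (m > 0L) colSums(indicator) else integer(0)
  structure(list(sets = sets,
                 size = vapply(sets, length, integer(1)),
                 n_mutated = as.integer(n_mutated),
                 prevalence = as.numeric(n_mutated) / n,
                 indicator = indicator,
                 samples = matrix$samples),
            class = "combo_candidates")
}

#' Draw one background gene set matched on total mutation count
#'
#' Genes are drawn uniformly without replacement from the background pool,
#' accumulating their observed mutation counts, until the running total
#' enters `[target - tolerance, target + tolerance]`. A draw that overshoots
#' the window is discarded and redrawn, up to `max_retries` attempts.
#'
#' @param profiles [gene_profiles()] data frame for the background pool
#'   (already excluding genes that must not be drawn).
#' @param target_mutations Target total mutation count (> 0).
#' @param tolerance Window half-width (nonnegative integer).
#' @param max_retries Redraw budget.
#' @return List with `genes` (character vector) and `total_mutations`.
#' @export
sample_background <- function(profiles, target_mutations, tolerance = 5L,
                              max_retries = 1000L) {
  if (!is_count(target_mutations) || target_mutations <= 0) {
    stopf("target_mutations must be a positive integer")
  }
  counts <- profiles$n_mutations
  genes <- profiles$gene
  lo <- target_mutations - tolerance
  hi <- target_mutations + tolerance
  for (try in seq_len(max_retries)) {
    perm <- sample.int(length(genes))
    cs <- cumsum(counts[perm])
    i <- which(cs >= lo)[1]
    if (!is.na(i) && cs[i] <= hi) {
      return(list(genes = genes[perm[seq_len(i)]],
                  total_mutations = as.integer(cs[i])))
    }
  }
  stopf("sample_background: no gene set reached the window [%d, %d] in %d attempts",
        lo, hi, max_retries)
}

# KM median survival for a subgroup; NA when the curve never reaches 0.5.
km_median_of <- function(time, event) {
  if (sum(event) == 0L) return(NA_real_)
  km_median(km_estimate(data.frame(time = time, event = event)))
}

#' Score candidate combinations against a bootstrap background null
#'
#' Each candidate's mutated-vs-wildtype survival separation is tested with
#' the log-rank statistic; its direction is the sign of the Kaplan-Meier
#' median-survival difference (falling back to observed-vs-expected events
#' when a median is undefined). Per subset-size stratum, `n_background`
#' random gene sets are drawn from the background pool, each matched on
#' total mutation count (to a randomly chosen candidate of that stratum
#' under `match = "candidate"`, or to the family total under
#' `"family_total"`), pushed through the identical indicator / prevalence /
#' log-rank procedure; draws failing the prevalence rule are excluded from
#' the null. The empirical q-value of candidate *i* is
#' `F0(p_i) * m / rank(p_i)` with
#' `F0(p) = (1 + #background p <= p) / (n_valid + 1)`, monotonized by the
#' step-up sweep and capped at 1.
#'
#' @param candidates An [enumerate_candidates()] result.
#' @param clinical Data frame covering all matrix samples, with `sample`,
#'   `os_months`, `os_event`.
#' @param profiles [gene_profiles()] data frame over all profiled genes
#'   (counts restricted to the scan's mutation classes).
#' @param config A [combo_config()].
#' @param background_matrix [build_mutation_matrix()] result over all
#'   profiled genes, used to build background indicators.
#' @param seed Seed for the background stream (default `config$seed`).
#' @return Data frame of class `combo_results`: `genes` (comma-joined),
#'   `size`, `n_mutated`, `prevalence`, `total_mutations`, `logrank_p`,
#'   `direction` (`longer_OS` / `shorter_OS`), `q_value`. Attributes
#'   `background` (per-stratum draw diagnostics) and `sets` (the gene
#'   vectors).
#' @export
score_combinations <- function(candidates, clinical, profiles,
                               config = combo_config(),
                               background_matrix, seed = config$seed) {
  stopifnot(inherits(candidates, "combo_candidates"))
  stopifnot(inherits(background_matrix, "mutation_matrix"))
  if (!all(candidates$samples %in% clinical$sample)) {
    stopf("clinical table does not cover all matrix samples")
  }
  m <- length(candidates$sets)
  cl <- clinical[match(candidates$samples, clinical$sample), , drop = FALSE]
  time <- cl$os_months
  event <- cl$os_event
  prep <- logrank_prep(time, event)
  n <- length(time)
  min_count <- ceiling(config$prevalence_threshold * n)

  empty <- data.frame(genes = character(0), size = integer(0),
                      n_mutated = integer(0), prevalence = numeric(0),
                      total_mutations = integer(0), logrank_p = numeric(0),
                      direction = character(0), q_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (m == 0L) {
    attr(empty, "sets") <- list()
    attr(empty, "background") <- list()
    class(empty) <- c("combo_results", "data.frame")
    return(empty)
  }

  counts_by_gene <- stats::setNames(profiles$n_mutations, profiles$gene)
  totals <- vapply(candidates$sets,
                   function(g) sum(counts_by_gene[g]), numeric(1))
  p_obs <- numeric(m)
  direction <- character(m)
  for (i in seq_len(m)) {
    x <- candidates$indicator[, i]
    res <- logrank_engine(prep, x)
    p_obs[i] <- res$p_value
    med_mut <- km_median_of(time[x], event[x])
    med_wt <- km_median_of(time[!x], event[!x])
    direction[i] <- if (!is.na(med_mut) && !is.na(med_wt) &&
                        med_mut != med_wt) {
      if (med_mut > med_wt) "longer_OS" else "shorter_OS"
    } else {
      if (res$o1 < res$e1) "longer_OS" else "shorter_OS"
    }
  }

  # background pool: all profiled genes, optionally minus the family
  pool <- profiles
  if (config$exclude_family_background && "in_family" %in% names(pool)) {
    pool <- pool[!pool$in_family, , drop = FALSE]
  }
  family_total <- if ("in_family" %in% names(profiles)) {
    sum(profiles$n_mutations[profiles$in_family])
  } else {
    sum(totals)
  }
  M_bg <- background_matrix$indicator
  if (!identical(rownames(M_bg), candidates$samples)) {
    M_bg <- M_bg[match(candidates$samples, background_matrix$samples), ,
                 drop = FALSE]
  }

  bg_info <- list()
  Fq <- numeric(m)
  local_seed(seed, {
    for (k in unique(candidates$size)) {
      in_k <- which(candidates$size == k)
      bg_p <- numeric(0)
      n_invalid <- 0L
      for (b in seq_len(config$n_background)) {
        target <- if (config$match == "candidate") {
          totals[in_k[sample.int(length(in_k), 1L)]]
        } else {
          family_total
        }
        draw <- sample_background(pool, max(1, round(target)),
                                  config$mutation_count_tolerance,
                                  config$max_retries)
        x <- rowSums(M_bg[, draw$genes, drop = FALSE]) > 0L
        if (sum(x) < min_count) {
          n_invalid <- n_invalid + 1L
          next
        }
        bg_p <- c(bg_p, logrank_engine(prep, x)$p_value)
      }
      if (length(bg_p) < 10L) {
        stopf("fewer than 10 valid background draws in the size-%d stratum; null is insufficient", k)
      }
      bg_sorted <- sort(bg_p)
      nv <- length(bg_sorted)
      Fq[in_k] <- (1 + findInterval(p_obs[in_k], bg_sorted)) / (nv + 1)
      bg_info[[as.character(k)]] <- list(size = k, n_valid = nv,
                                         n_invalid = n_invalid)
    }
  })

  rk <- rank(p_obs, ties.method = "max")
  raw_q <- pmin(1, Fq * m / rk)
  ord <- order(p_obs)
  q_sorted <- raw_q[ord]
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted

  out <- data.frame(
    genes = vapply(candidates$sets, paste, character(1), collapse = ","),
    size = candidates$size,
    n_mutated = candidates$n_mutated,
    prevalence = candidates$prevalence,
    total_mutations = as.integer(totals),
    logrank_p = p_obs,
    direction = direction,
    q_value = q,
    stringsAsFactors = FALSE
  )
  attr(out, "sets") <- candidates$sets
  attr(out, "background") <- bg_info
  class(out) <- c("combo_results", "data.frame")
  out
}

#' Per-gene inclusion frequencies among significant combinations
#'
#' Counts, separately by survival direction, how often each gene appears in
#' combinations significant at the q-value threshold — the summary used to
#' rank which family genes drive the survival association.
#'
#' @param results A [score_combinations()] result (or a row-bound set of
#'   them retaining the `sets` attribute).
#' @param q_threshold Significance cutoff on `q_value`.
#' @return Data frame `gene`, `direction`, `n_combinations`, sorted by
#'   decreasing count.
#' @export
inclusion_frequencies <- function(results, q_threshold = 0.05) {
  sets <- attr(results, "sets")
  if (is.null(sets)) sets <- strsplit(results$genes, ",", fixed = TRUE)
  sig <- which(results$q_value <= q_threshold)
  if (length(sig) == 0L) {
    return(data.frame(gene = character(0), direction = character(0),
                      n_combinations = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(sig, function(i) {
    data.frame(gene = sets[[i]], direction = results$direction[i],
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(list(n_combinations = rep(1L, nrow(df))),
                          by = df[, c("gene", "direction")], FUN = sum)
  agg[order(-agg$n_combinations, agg$gene), , drop = FALSE]
}

#' Full combination-survival scan
#'
#' Orchestrates the scan: gate family genes on expression, enumerate and
#' score size-2 subsets, apply the exclusion rule (size-3 subsets containing
#' an already-significant pair are not considered), then enumerate and score
#' size-3 subsets, and summarize per-gene inclusion frequencies. Each size
#' stratum is scored against its own background null; q-values are computed
#' within stratum. Fully deterministic given `config$seed`.
#'
#' @param records Mutation records ([read_maf()] output or the `maf` table
#'   of a simulated cohort — column names are mapped automatically).
#' @param clinical Clinical table (`sample`, `os_months`, `os_event`, ...).
#' @param expression Expression table (`gene`, `mean_rsem`).
#' @param gene_table Gene annotation table (`gene`, `coding_length`,
#'   `in_family`).
#' @param family Family gene symbols; defaults to `gene_table$gene` flagged
#'   `in_family`.
#' @param config A [combo_config()].
#' @param msi_status Optional: restrict the cohort to samples with this
#'   `msi_status` value in the clinical table.
#' @return List of class `combo_scan`: `results` (all scored candidates),
#'   `inclusion` (inclusion frequencies at `config$q_threshold`),
#'   `eligible`, `n_samples`, `config`.
#' @export
combo_scan <- function(records, clinical, expression, gene_table,
                       family = NULL, config = combo_config(),
                       msi_status = NULL) {
  records <- normalize_records(records)
  if (is.null(family)) {
    if (!"in_family" %in% names(gene_table)) {
      stopf("family not given and gene_table has no in_family column")
    }
    family <- gene_table$gene[as.logical(gene_table$in_family)]
  }
  if (!is.null(msi_status)) {
    clinical <- clinical[clinical$msi_status %in% msi_status, , drop = FALSE]
    if (nrow(clinical) == 0L) stopf("no samples with msi_status %s",
                                    paste(msi_status, collapse = "/"))
  }
  samples <- clinical$sample
  records <- records[records$sample %in% samples, , drop = FALSE]

  eligible <- eligible_genes(expression, family, config)
  all_genes <- gene_table$gene
  matrix_all <- build_mutation_matrix(records, samples, all_genes,
                                      classes = config$classes)
  profiles <- gene_profiles(records, gene_table, family_genes = family,
                            classes = config$classes)

  cand2 <- NULL
  res2 <- NULL
  sig_pairs <- list()
  if (2L %in% config$subset_sizes) {
    cand2 <- enumerate_candidates(eligible, matrix_all, config, sizes = 2L)
    res2 <- score_combinations(cand2, clinical, profiles, config, matrix_all,
                               seed = config$seed)
    if (config$exclude_significant_subsets) {
      sig_pairs <- attr(res2, "sets")[res2$q_value <= config$q_threshold]
    }
  }
  res3 <- NULL
  if (3L %in% config$subset_sizes) {
    cand3 <- enumerate_candidates(eligible, matrix_all, config, sizes = 3L,
                                  exclude_supersets_of = sig_pairs)
    res3 <- score_combinations(cand3, clinical, profiles, config, matrix_all,
                               seed = config$seed + 1L)
  }
  results <- rbind_combo_results(res2, res3)
  structure(list(results = results,
                 inclusion = inclusion_frequencies(results,
                                                   config$q_threshold),
                 eligible = eligible,
                 n_samples = length(samples),
                 config = config),
            class = "combo_scan")
}

# Accept either reader-style records (gene/sample/...) or raw MAF-dialect
# column names from the generator's table.
normalize_records <- function(records) {
  records <- as.data.frame(records)
  if (all(c("gene", "sample") %in% names(records))) return(records)
  if (all(c("Hugo_Symbol", "Tumor_Sample_Barcode",
            "Variant_Classification") %in% names(records))) {
    out <- data.frame(gene = records$Hugo_Symbol,
                      sample = records$Tumor_Sample_Barcode,
                      variant_class = records$Variant_Classification,
                      stringsAsFactors = FALSE)
    if ("Protein_position" %in% names(records)) {
      out$protein_position <- parse_protein_position(records$Protein_position)
    }
    out$mutation_class <- classify_mutation(out$variant_class)
    return(out)
  }
  stopf("records must have gene/sample columns or MAF-dialect columns")
}

rbind_combo_results <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  sets <- c(attr(a, "sets"), attr(b, "sets"))
  bg <- c(attr(a, "background"), attr(b, "background"))
  out <- rbind(as.data.frame(a), as.data.frame(b))
  rownames(out) <- NULL
  attr(out, "sets") <- sets
  attr(out, "background") <- bg
  class(out) <- c("combo_results", "data.frame")
  out
}

#' @export
print.combo_scan <- function(x, ...) {
  cat(sprintf("Combination scan: %d candidates over %d eligible genes, %d samples\n",
              nrow(x$results), length(x$eligible), x$n_samples))
  nsig <- sum(x$results$q_value <= x$config$q_threshold)
  cat(sprintf("  %d combination(s) significant at q <= %g\n",
              nsig, x$config$q_threshold))
  if (nsig > 0) {
    top <- x$results[order(x$results$q_value), ][seq_len(min(5, nsig)), ]
    print(top[, c("genes", "n_mutated", "prevalence", "logrank_p",
                  "direction", "q_value")], row.names = FALSE)
  }
  invisible(x)
}
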